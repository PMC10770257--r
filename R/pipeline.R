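#' Build a pipeline configuration
#'
#' Assembles and defaults the single structured configuration driving
#' [run_full()]. Every headline threshold of the analysis (alpha 0.05,
#' 10% positive-expression ratio, correlation threshold 0.2) is a named
#' field defaulting to its canonical value.
#'
#' @param bulk_counts,bulk_samples paths to the bulk counts TSV
#'   (genes x samples) and sample metadata TSV (sample_id, meta_status,
#'   bom_status).
#' @param sc_counts path to single-cell counts (MTX triplet directory or
#'   TSV) and `sc_format` one of `"mtx_triplet"`/`"tsv"`.
#' @param sc_cells path to the cell metadata TSV (cell_id, sample_id,
#'   sample_type, condition, subgroup).
#' @param lr_db optional ligand-receptor CSV.
#' @param gmt optional GMT gene-set file.
#' @param screen list of screen thresholds (`alpha`, `min_ratio`,
#'   `adjustment`, `high_corr_threshold`), see [screen_config()].
#' @param screen_subgroups subgroup labels for the condition screen
#'   (default: all subgroups in the cell table).
#' @param lr_pairs list of `list(from = ..., to = ...)` subgroup
#'   directions for the L-R screen.
#' @param correlations list of `list(subgroup = , anchors = , targets = )`.
#' @param out_dir output directory.
#' @param seed integer recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters when the config points at
#'   simulation outputs).
#' @param sc_format single-cell counts format.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(bulk_counts = NULL, bulk_samples = NULL,
                            sc_counts = NULL, sc_cells = NULL,
                            sc_format = c("mtx_triplet", "tsv"),
                            lr_db = NULL, gmt = NULL,
                            screen = list(), screen_subgroups = NULL,
                            lr_pairs = list(), correlations = list(),
                            out_dir = "bomscope_out", seed = 42L) {
  sc_format <- match.arg(sc_format)
  sc_defaults <- list(alpha = 0.05, min_ratio = 0.10, adjustment = "none",
                      high_corr_threshold = 0.2)
  screen <- utils::modifyList(sc_defaults, screen)
  structure(list(
    bulk_counts = bulk_counts, bulk_samples = bulk_samples,
    sc_counts = sc_counts, sc_cells = sc_cells, sc_format = sc_format,
    lr_db = lr_db, gmt = gmt, screen = screen,
    screen_subgroups = screen_subgroups, lr_pairs = lr_pairs,
    correlations = correlations, out_dir = out_dir, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' JSON is the native format; `.yml`/`.yaml` files are parsed with the
#' yaml package when installed.
#'
#' @param path config file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) .stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      .stopf("YAML configs need the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  raw$screen <- as.list(raw$screen %||% list())
  norm_pairs <- function(x) {
    if (is.null(x)) return(list())
    if (is.data.frame(x)) x <- split(x, seq_len(nrow(x)))
    lapply(x, as.list)
  }
  raw$lr_pairs <- norm_pairs(raw$lr_pairs)
  raw$correlations <- norm_pairs(raw$correlations)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) .warnf("ignoring unknown config field(s): %s",
                              paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw[intersect(names(raw), known)])
}

#' Validate a pipeline configuration
#'
#' Checks paths, threshold ranges, and label references (subgroups named
#' in L-R directions, screens and correlations against the cell table)
#' without running any stage. Errors block [run_full()]; warnings do
#' not.
#'
#' @param config a [pipeline_config()].
#' @return list with character vectors `errors` and `warnings` and
#'   logical `ok`.
#' @export
validate_config <- function(config) {
  errors <- character(0); warnings <- character(0)
  err <- function(fmt, ...) errors <<- c(errors, sprintf(fmt, ...))
  wrn <- function(fmt, ...) warnings <<- c(warnings, sprintf(fmt, ...))
  chk_path <- function(p, what, required = FALSE) {
    if (is.null(p)) { if (required) err("%s is required but not set", what) }
    else if (!file.exists(p)) err("%s does not exist: %s", what, p)
  }
  chk_path(config$bulk_counts, "bulk_counts")
  chk_path(config$bulk_samples, "bulk_samples")
  chk_path(config$sc_counts, "sc_counts")
  chk_path(config$sc_cells, "sc_cells")
  chk_path(config$gmt, "gmt")
  if (length(config$lr_pairs) && is.null(config$lr_db))
    err("L-R screen directions given but lr_db is not set")
  chk_path(config$lr_db, "lr_db")
  s <- config$screen
  if (!is.numeric(s$alpha) || s$alpha <= 0 || s$alpha >= 1)
    err("alpha out of range (0, 1): %s", format(s$alpha))
  if (!is.numeric(s$min_ratio) || s$min_ratio < 0 || s$min_ratio >= 1)
    err("min_ratio out of range [0, 1): %s", format(s$min_ratio))
  if (!s$adjustment %in% c("none", "BH", "bonferroni"))
    err("unknown adjustment: %s", s$adjustment)
  if (!is.null(config$sc_cells) && file.exists(config$sc_cells)) {
    cells <- data.table::fread(config$sc_cells, data.table = FALSE)
    labels <- unique(cells$subgroup)
    refs <- c(unlist(lapply(config$lr_pairs, function(p) c(p$from, p$to))),
              unlist(lapply(config$correlations, `[[`, "subgroup")),
              config$screen_subgroups)
    bad <- setdiff(refs, labels)
    if (length(bad)) err("unknown subgroup label(s): %s", paste(bad, collapse = ", "))
    if (!"condition" %in% names(cells)) err("cell table lacks a condition column")
  }
  if (is.null(config$bulk_counts) && is.null(config$sc_counts))
    wrn("config drives neither a bulk nor a single-cell stage")
  list(errors = errors, warnings = warnings, ok = length(errors) == 0L)
}

# Canonical md5 of a config's analysis-relevant fields (the output
# location does not change the analysis identity).
.config_hash <- function(config) {
  x <- unclass(config)
  x$out_dir <- NULL
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

.write_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  nrow(df)
}

# Upper-case gene symbols; disambiguate collisions introduced by the
# case folding.
.harmonize_genes <- function(m) {
  up <- toupper(rownames(m))
  if (anyDuplicated(up)) {
    .warnf("gene symbol collisions after upper-casing; suffixing duplicates")
    up <- make.unique(up)
  }
  rownames(m) <- up
  m
}

#' Run the full discovery pipeline
#'
#' Executes the study flow from a single config: bulk differential
#' expression and overlap panel; single-cell log-normalization,
#' dot-profiles of the panel, marker detection and panel-marker overlap;
#' per-subgroup BoM-vs-Other condition screens; the five-step
#' ligand-receptor screen per configured direction; anchor-target
#' correlations; and gene-set over-representation of the panel. Each
#' stage consumes only raw inputs and earlier stages, all tables are
#' written to `out_dir` as TSV/JSON, and a run manifest records row
#' counts, thresholds, the config hash and package version. Reruns on
#' identical inputs are byte-identical.
#'
#' @param config a [pipeline_config()] (or path to one).
#' @param stages subset of
#'   `c("bulk", "panel", "profile", "markers", "screen", "lr",
#'   "correlate", "enrich")`; defaults to every stage whose inputs are
#'   configured.
#' @return (invisibly) list of in-memory results (`report bundle`):
#'   panel, de tables, profiles, markers, overlaps, screens, lr
#'   candidates and summaries, correlations, enrichment, manifest.
#' @export
run_full <- function(config, stages = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  v <- validate_config(config)
  for (w in v$warnings) .warnf("%s", w)
  if (!v$ok)
    .stopf("configuration invalid:\n- %s", paste(v$errors, collapse = "\n- "))

  all_stages <- c("bulk", "panel", "profile", "markers", "screen", "lr",
                  "correlate", "enrich")
  if (is.null(stages)) {
    stages <- character(0)
    if (!is.null(config$bulk_counts)) stages <- c(stages, "bulk", "panel")
    if (!is.null(config$sc_counts)) stages <- c(stages, "profile", "markers", "screen")
    if (!is.null(config$lr_db) && length(config$lr_pairs)) stages <- c(stages, "lr")
    if (length(config$correlations)) stages <- c(stages, "correlate")
    if (!is.null(config$gmt)) stages <- c(stages, "enrich")
  }
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need_bulk <- any(c("bulk", "panel", "enrich") %in% stages)
  need_sc <- any(c("profile", "markers", "screen", "lr", "correlate") %in% stages)
  if (need_bulk && is.null(config$bulk_counts))
    .stopf("requested stage needs bulk inputs, but bulk_counts is not set")
  if (need_sc && is.null(config$sc_counts))
    .stopf("requested stage needs single-cell inputs, but sc_counts is not set")
  if ("lr" %in% stages && (is.null(config$lr_db) || !length(config$lr_pairs)))
    .stopf("lr stage requested without lr_db and lr_pairs")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list(); counts_log <- list()
  cfg_screen <- screen_config(alpha = config$screen$alpha,
                              min_ratio = config$screen$min_ratio,
                              adjustment = config$screen$adjustment,
                              high_corr_threshold = config$screen$high_corr_threshold)
  stage <- "load"
  done <- character(0)
  tryCatch({
    if (need_bulk) {
      bulk <- .harmonize_genes(read_counts(config$bulk_counts, "tsv"))
      smp <- data.table::fread(config$bulk_samples, data.table = FALSE)
      bulk <- bulk[, smp$sample_id, drop = FALSE]
    }
    if (need_sc) {
      scm <- .harmonize_genes(read_counts(config$sc_counts, config$sc_format))
      cells <- data.table::fread(config$sc_cells, data.table = FALSE)
      scm <- scm[, cells$cell_id, drop = FALSE]
      expr <- lognormalize(scm)
    }

    if ("bulk" %in% stages) {
      stage <- "bulk"
      meta_f <- factor(smp$meta_status, levels = c("nonMeta", "Meta"))
      out$de_meta <- nb_wald_de(bulk, meta_f, alpha = cfg_screen$alpha)
      in_meta <- which(smp$meta_status == "Meta")
      bom_f <- factor(smp$bom_status[in_meta], levels = c("nonBoM", "BoM"))
      out$de_bom <- nb_wald_de(bulk[, in_meta, drop = FALSE], bom_f,
                               alpha = cfg_screen$alpha)
      counts_log$de_meta <- .write_table(out$de_meta,
                                         file.path(config$out_dir, "de_meta.tsv"))
      counts_log$de_bom <- .write_table(out$de_bom,
                                        file.path(config$out_dir, "de_bom.tsv"))
      done <- c(done, stage)
    }
    if ("panel" %in% stages) {
      stage <- "panel"
      out$panel <- derive_panel(out$de_meta, out$de_bom, alpha = cfg_screen$alpha)
      counts_log$panel <- .write_table(
        data.frame(gene = out$panel$genes),
        file.path(config$out_dir, "panel.tsv"))
      writeLines(jsonlite::toJSON(out$panel[c("genes", "provenance")],
                                  auto_unbox = TRUE, pretty = TRUE, digits = NA),
                 file.path(config$out_dir, "panel.json"))
      done <- c(done, stage)
    }
    if ("profile" %in% stages) {
      stage <- "profile"
      genes <- if (!is.null(out$panel)) out$panel$genes else rownames(scm)
      out$profile <- dot_profile(expr, scm, cells, genes)
      counts_log$profile <- .write_table(out$profile,
                                         file.path(config$out_dir, "dot_profile.tsv"))
      done <- c(done, stage)
    }
    if ("markers" %in% stages) {
      stage <- "markers"
      out$markers <- find_markers(expr, scm, cells, alpha = cfg_screen$alpha,
                                  min_ratio = cfg_screen$min_ratio)
      counts_log$markers <- .write_table(out$markers,
                                         file.path(config$out_dir, "markers.tsv"))
      if (!is.null(out$panel)) {
        out$marker_overlap <- panel_marker_overlap(out$panel, out$markers)
        writeLines(jsonlite::toJSON(out$marker_overlap, pretty = TRUE, digits = NA),
                   file.path(config$out_dir, "marker_overlap.json"))
      }
      done <- c(done, stage)
    }
    if ("screen" %in% stages) {
      stage <- "screen"
      sgs <- config$screen_subgroups %||% sort(unique(cells$subgroup))
      out$screens <- lapply(sgs, function(sg)
        screen_condition_genes(expr, scm, cells, sg, cfg_screen))
      names(out$screens) <- sgs
      for (sg in sgs)
        counts_log[[paste0("screen_", sg)]] <- .write_table(
          out$screens[[sg]], file.path(config$out_dir,
                                       sprintf("screen_%s.tsv", sg)))
      done <- c(done, stage)
    }
    if ("lr" %in% stages) {
      stage <- "lr"
      db <- read_lr_db(config$lr_db)
      out$lr <- list(); out$lr_summaries <- list()
      for (pr in config$lr_pairs) {
        key <- sprintf("%s_to_%s", pr$from, pr$to)
        cand <- screen_lr(expr, scm, cells, pr$from, pr$to, db, cfg_screen)
        out$lr[[key]] <- cand
        out$lr_summaries[[key]] <- lr_summary(cand, expr, scm, cells)
        counts_log[[paste0("lr_", key)]] <- .write_table(
          cand, file.path(config$out_dir, sprintf("lr_%s.tsv", key)))
        .write_table(out$lr_summaries[[key]],
                     file.path(config$out_dir, sprintf("lr_summary_%s.tsv", key)))
      }
      done <- c(done, stage)
    }
    if ("correlate" %in% stages) {
      stage <- "correlate"
      out$correlations <- lapply(config$correlations, function(cc)
        subgroup_gene_correlations(expr, cells, cc$subgroup,
                                   unlist(cc$anchors), unlist(cc$targets),
                                   cfg_screen))
      corr_all <- do.call(rbind, out$correlations)
      counts_log$correlations <- .write_table(
        corr_all %||% data.frame(),
        file.path(config$out_dir, "correlations.tsv"))
      done <- c(done, stage)
    }
    if ("enrich" %in% stages) {
      stage <- "enrich"
      sets <- read_gmt(config$gmt)
      universe <- rownames(bulk)
      query <- out$panel$genes
      out$enrichment <- if (length(query))
        ora_hypergeometric(query, sets, universe)
      else data.frame()
      counts_log$enrichment <- .write_table(
        out$enrichment, file.path(config$out_dir, "enrichment.tsv"))
      done <- c(done, stage)
    }
  }, error = function(e) {
    partial <- list(failed_stage = stage, completed_stages = done,
                    error = conditionMessage(e))
    writeLines(jsonlite::toJSON(partial, auto_unbox = TRUE, pretty = TRUE),
               file.path(config$out_dir, "manifest.json"))
    .stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })

  manifest <- list(
    package = "bomscope",
    version = as.character(utils::packageVersion("bomscope")),
    seed = config$seed,
    config_hash = .config_hash(config),
    thresholds = config$screen,
    stages = done,
    table_rows = counts_log
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(config$out_dir, "manifest.json"))
  out$manifest <- manifest
  invisible(out)
}
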