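#' Read a ligand-receptor pair database
#'
#' Reads a CSV export with `ligand` and `receptor` columns (a
#' pre-expanded simple-pair database; multi-subunit complex rows must be
#' expanded to gene-gene pairs upstream). Gene symbols are upper-cased,
#' duplicate rows dropped with a warning, and self-pairs flagged.
#'
#' @param path CSV file.
#' @return data.frame (`ligand`, `receptor`, `self_pair`) of class
#'   `lr_database`.
#' @export
read_lr_db <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  db <- data.table::fread(path, data.table = FALSE)
  if (!all(c("ligand", "receptor") %in% names(db)))
    .stopf("ligand-receptor database needs 'ligand' and 'receptor' columns")
  if (nrow(db) == 0L) .stopf("ligand-receptor database is empty")
  db$ligand <- toupper(trimws(as.character(db$ligand)))
  db$receptor <- toupper(trimws(as.character(db$receptor)))
  if (any(!nzchar(db$ligand)) || any(!nzchar(db$receptor)))
    .stopf("empty gene ids in the ligand-receptor database")
  dup <- duplicated(paste(db$ligand, db$receptor, sep = "\r"))
  if (any(dup)) {
    .warnf("dropping %d duplicate ligand-receptor row(s)", sum(dup))
    db <- db[!dup, , drop = FALSE]
  }
  db$self_pair <- db$ligand == db$receptor
  rownames(db) <- NULL
  class(db) <- c("lr_database", "data.frame")
  db
}

#' Write a ligand-receptor database to CSV
#' @param db data.frame with `ligand` and `receptor` columns.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_lr_db <- function(db, path) {
  data.table::fwrite(db[, intersect(c("ligand", "receptor", "true_pair"),
                                    names(db)), drop = FALSE], path)
  invisible(path)
}

# Per-gene BoM-vs-Other statistics within one subgroup, for the L-R
# screen: p from a two-sided rank-sum on log-normalized values, mean
# difference, and the positive ratio among *BoM* cells only (the screen's
# denominator is the BoM arm, unlike the condition screen).
.lr_gene_stats <- function(expr, counts, cell_table, subgroup, genes, cfg) {
  ann <- cell_table[match(colnames(expr), cell_table$cell_id), ]
  in_sg <- which(ann$subgroup == subgroup)
  if (!length(in_sg)) .stopf("subgroup not found: %s", subgroup)
  bom <- in_sg[ann$condition[in_sg] == "BoM"]
  oth <- in_sg[ann$condition[in_sg] != "BoM"]
  if (!length(bom) || !length(oth))
    .stopf("subgroup %s lacks BoM or Other cells", subgroup)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes))
    return(data.frame(gene = character(0), p_raw = numeric(0),
                      p_adj = numeric(0), delta_mean = numeric(0),
                      pos_ratio_bom = numeric(0), qualifies = logical(0)))
  dense <- .as_dense(expr[genes, , drop = FALSE])
  p <- .ranksum_rows(dense, bom, oth)
  p_adj <- .adjust_p(p, cfg$adjustment)
  delta <- rowMeans(dense[, bom, drop = FALSE]) - rowMeans(dense[, oth, drop = FALSE])
  rb <- .row_pos_ratio(counts[genes, , drop = FALSE], bom)
  data.frame(
    gene = genes, p_raw = p, p_adj = p_adj, delta_mean = delta,
    pos_ratio_bom = rb,
    qualifies = p_adj < cfg$alpha & delta > 0 & rb > cfg$min_ratio,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Five-step ligand-receptor candidate screen
#'
#' Screens database pairs between a ligand-side subgroup A and a
#' receptor-side subgroup B under the BoM-vs-Other contrast:
#' (1) take the pair database; (2) within subgroup A, test each database
#' ligand's log-normalized expression in BoM-derived vs other cells
#' (two-sided Wilcoxon rank-sum) and keep significantly upregulated
#' ligands (default raw p < alpha with positive mean difference);
#' (3) keep ligands whose positive-expression ratio among subgroup A's
#' BoM cells (cells with raw count > 0 over all BoM cells) exceeds
#' `min_ratio`; (4) screen receptor candidates in subgroup B the same
#' way; (5) database pairs whose ligand and receptor both qualify are
#' the candidate interactions.
#'
#' @param expr log-normalized matrix.
#' @param counts matching raw count matrix.
#' @param cell_table per-cell annotations (condition column with `"BoM"`
#'   marking the metastatic arm).
#' @param subgroup_a ligand-side subgroup label.
#' @param subgroup_b receptor-side subgroup label.
#' @param db ligand-receptor database ([read_lr_db()] /
#'   [simulate_lr_db()] or any data.frame with ligand/receptor columns).
#' @param cfg a [screen_config()]; the default performs no multiplicity
#'   adjustment inside the screen.
#' @return data.frame of class `lr_candidates`: one row per evaluated
#'   database pair (both genes present in the matrix) with ligand and
#'   receptor statistics (`*_p_raw`, `*_delta_mean`, `*_pos_ratio_bom`,
#'   `*_qualifies`) and a `passed` flag; ordered lexicographically by
#'   (ligand, receptor). Pairs whose genes are absent are dropped.
#' @export
screen_lr <- function(expr, counts, cell_table, subgroup_a, subgroup_b,
                      db, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  empty <- data.frame(
    ligand = character(0), receptor = character(0),
    subgroup_a = character(0), subgroup_b = character(0),
    ligand_p_raw = numeric(0), ligand_delta_mean = numeric(0),
    ligand_pos_ratio_bom = numeric(0), ligand_qualifies = logical(0),
    receptor_p_raw = numeric(0), receptor_delta_mean = numeric(0),
    receptor_pos_ratio_bom = numeric(0), receptor_qualifies = logical(0),
    passed = logical(0), stringsAsFactors = FALSE
  )
  class(empty) <- c("lr_candidates", "data.frame")
  if (is.null(db) || nrow(db) == 0L) {
    .warnf("empty ligand-receptor database; no candidates")
    return(empty)
  }
  keep <- db$ligand %in% rownames(expr) & db$receptor %in% rownames(expr)
  db <- db[keep, , drop = FALSE]
  if (nrow(db) == 0L) {
    .warnf("no database pair has both genes in the matrix")
    return(empty)
  }
  lstats <- .lr_gene_stats(expr, counts, cell_table, subgroup_a,
                           unique(db$ligand), cfg)
  rstats <- .lr_gene_stats(expr, counts, cell_table, subgroup_b,
                           unique(db$receptor), cfg)
  li <- match(db$ligand, lstats$gene)
  ri <- match(db$receptor, rstats$gene)
  out <- data.frame(
    ligand = db$ligand, receptor = db$receptor,
    subgroup_a = subgroup_a, subgroup_b = subgroup_b,
    ligand_p_raw = lstats$p_raw[li],
    ligand_delta_mean = lstats$delta_mean[li],
    ligand_pos_ratio_bom = lstats$pos_ratio_bom[li],
    ligand_qualifies = lstats$qualifies[li],
    receptor_p_raw = rstats$p_raw[ri],
    receptor_delta_mean = rstats$delta_mean[ri],
    receptor_pos_ratio_bom = rstats$pos_ratio_bom[ri],
    receptor_qualifies = rstats$qualifies[ri],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$passed <- out$ligand_qualifies & out$receptor_qualifies
  out <- out[.lex_order(out$ligand, out$receptor), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("lr_candidates", "data.frame")
  out
}

#' Dot-plot summary statistics for candidate interactions
#'
#' For each passed candidate, computes per (gene, condition) the mean
#' log-normalized expression in the relevant subgroup's cells of that
#' condition, its z-score across conditions (same semantics as
#' [dot_profile()], grouping by condition within the subgroup), and the
#' positive-expression ratio.
#'
#' @param candidates a [screen_lr()] result (only rows with
#'   `passed = TRUE` are summarized).
#' @param expr log-normalized matrix.
#' @param counts matching raw count matrix.
#' @param cell_table per-cell annotations.
#' @return data.frame (ligand, receptor, role, gene, subgroup,
#'   condition, mean_expr, z_expr, pos_ratio): 4 rows per candidate for
#'   a two-condition design (2 genes x conditions).
#' @export
lr_summary <- function(candidates, expr, counts, cell_table) {
  hdr <- data.frame(ligand = character(0), receptor = character(0),
                    role = character(0), gene = character(0),
                    subgroup = character(0), condition = character(0),
                    mean_expr = numeric(0), z_expr = numeric(0),
                    pos_ratio = numeric(0), stringsAsFactors = FALSE)
  cand <- candidates[candidates$passed, , drop = FALSE]
  if (nrow(cand) == 0L) return(hdr)
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    for (role in c("ligand", "receptor")) {
      gene <- cand[[role]][i]
      sg <- if (role == "ligand") cand$subgroup_a[i] else cand$subgroup_b[i]
      sub_cells <- cell_table$cell_id[cell_table$subgroup == sg]
      sub <- cell_table[cell_table$cell_id %in% sub_cells, ]
      # condition plays the grouping role that subgroup plays in dot_profile
      fake <- data.frame(cell_id = sub$cell_id, subgroup = sub$condition,
                         stringsAsFactors = FALSE)
      dp <- dot_profile(expr[, sub$cell_id, drop = FALSE],
                        counts[, sub$cell_id, drop = FALSE], fake, gene)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = cand$ligand[i], receptor = cand$receptor[i], role = role,
        gene = gene, subgroup = sg, condition = dp$subgroup,
        mean_expr = dp$mean_expr, z_expr = dp$z_expr,
        pos_ratio = dp$pos_ratio, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
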