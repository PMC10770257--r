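#' Anchor-target Pearson correlations within a subgroup
#'
#' For every (anchor, target) gene pair, computes the Pearson
#' correlation of log-normalized expression across the subgroup's cells
#' with a two-sided t-based p-value, and flags high correlations
#' (r above the threshold, default 0.2, with p below alpha). Pairs with
#' anchor = target are skipped. Cells with zero expression are retained
#' unless `expressing_only = TRUE`, in which case only cells expressing
#' both genes (raw count > 0) enter the correlation.
#'
#' @param expr log-normalized matrix.
#' @param cell_table per-cell annotations.
#' @param subgroup subgroup label (must have >= 3 cells).
#' @param anchor_genes,target_genes character vectors; missing genes are
#'   reported and skipped.
#' @param cfg a [screen_config()] supplying `alpha` and
#'   `high_corr_threshold`.
#' @param counts raw counts, required when `expressing_only = TRUE`.
#' @param expressing_only restrict to cells expressing both genes.
#' @return data.frame (context, gene_a, gene_b, n, r, p, status,
#'   high_corr).
#' @export
subgroup_gene_correlations <- function(expr, cell_table, subgroup,
                                       anchor_genes, target_genes,
                                       cfg = screen_config(),
                                       counts = NULL, expressing_only = FALSE) {
  stopifnot(inherits(cfg, "screen_config"))
  if (expressing_only && is.null(counts))
    .stopf("expressing_only requires the raw count matrix")
  ann <- cell_table[match(colnames(expr), cell_table$cell_id), ]
  cells <- which(ann$subgroup == subgroup)
  if (length(cells) < 3L) .stopf("subgroup %s has fewer than 3 cells", subgroup)
  all_genes <- unique(c(anchor_genes, target_genes))
  missing_genes <- setdiff(all_genes, rownames(expr))
  if (length(missing_genes))
    .warnf("skipping %d missing gene(s): %s", length(missing_genes),
           paste(utils::head(missing_genes, 5), collapse = ", "))
  anchor_genes <- setdiff(anchor_genes, missing_genes)
  target_genes <- setdiff(target_genes, missing_genes)
  rows <- list()
  for (a in anchor_genes) {
    xa <- as.numeric(expr[a, cells])
    for (b in target_genes) {
      if (a == b) next
      xb <- as.numeric(expr[b, cells])
      if (expressing_only) {
        keep <- as.numeric(counts[a, cells]) > 0 & as.numeric(counts[b, cells]) > 0
        if (sum(keep) < 3L) {
          rows[[length(rows) + 1L]] <- data.frame(
            context = subgroup, gene_a = a, gene_b = b, n = sum(keep),
            r = NA_real_, p = NA_real_, status = "too_few_cells",
            high_corr = FALSE, stringsAsFactors = FALSE)
          next
        }
        pc <- pearson_cor(xa[keep], xb[keep])
      } else {
        pc <- pearson_cor(xa, xb)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        context = subgroup, gene_a = a, gene_b = b, n = pc$n,
        r = pc$r, p = pc$p, status = pc$status,
        high_corr = !is.na(pc$r) && !is.na(pc$p) &&
          pc$r > cfg$high_corr_threshold && pc$p < cfg$alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(context = character(0), gene_a = character(0),
               gene_b = character(0), n = integer(0), r = numeric(0),
               p = numeric(0), status = character(0), high_corr = logical(0))
  rownames(out) <- NULL
  out
}

#' Fixed epithelial-mesenchymal transition gene panel
#'
#' The classic EMT readout genes used for correlation validation:
#' E-cadherin (CDH1), N-cadherin (CDH2), vimentin (VIM), Slug (SNAI2),
#' Twist (TWIST1) and beta-catenin (CTNNB1).
#' @return character vector of gene symbols.
#' @export
emt_panel <- function() c("CDH1", "CDH2", "VIM", "SNAI2", "TWIST1", "CTNNB1")

#' Pan-cancer bulk anchor-target correlations
#'
#' For each cancer-type table (genes x samples of log-scale or
#' normalized expression), genes are z-scored across samples and Pearson
#' correlations computed per (anchor, target) pair. The z-scoring leaves
#' r unchanged (Pearson is affine-invariant) and is retained only so
#' emitted per-group values are on a comparable scale. Groups with fewer
#' than 3 samples are skipped with a reason.
#'
#' @param bulk_expr_by_group named list of gene x sample matrices.
#' @param anchors,targets character gene vectors.
#' @param cfg a [screen_config()].
#' @return data.frame (context, gene_a, gene_b, n, r, p, status,
#'   high_corr) over all retained groups; skipped groups are recorded in
#'   the `skipped` attribute.
#' @export
bulk_panel_correlations <- function(bulk_expr_by_group, anchors, targets,
                                    cfg = screen_config()) {
  stopifnot(is.list(bulk_expr_by_group), length(names(bulk_expr_by_group)) ==
              length(bulk_expr_by_group))
  rows <- list(); skipped <- character(0)
  for (grp in names(bulk_expr_by_group)) {
    m <- bulk_expr_by_group[[grp]]
    if (ncol(m) < 3L) {
      skipped <- c(skipped, sprintf("%s: only %d samples", grp, ncol(m)))
      next
    }
    z <- t(scale(t(.as_dense(m))))      # per-gene z-score across samples
    for (a in intersect(anchors, rownames(m))) {
      for (b in intersect(targets, rownames(m))) {
        if (a == b) next
        za <- z[a, ]; zb <- z[b, ]
        if (anyNA(za) || anyNA(zb)) {   # zero-variance gene in this group
          pc <- list(r = NA_real_, p = NA_real_, n = ncol(m),
                     status = "zero_variance")
        } else {
          pc <- pearson_cor(za, zb)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          context = grp, gene_a = a, gene_b = b, n = pc$n, r = pc$r,
          p = pc$p, status = pc$status,
          high_corr = !is.na(pc$r) && !is.na(pc$p) &&
            pc$r > cfg$high_corr_threshold && pc$p < cfg$alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(context = character(0), gene_a = character(0),
               gene_b = character(0), n = integer(0), r = numeric(0),
               p = numeric(0), status = character(0), high_corr = logical(0))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
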