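#' Screen configuration shared by the condition and L-R screens
#'
#' Bundles the thresholds used throughout the condition-stratified
#' screens: the significance cutoff, the minimum positive-expression
#' ratio ("more than 10% of the cells"), the per-screen multiple-testing
#' adjustment, and the high-correlation threshold shared with the
#' correlation module.
#'
#' @param alpha significance cutoff (default 0.05).
#' @param min_ratio minimum positive-expression ratio (default 0.10;
#'   comparisons are strict: ratio must exceed it).
#' @param adjustment `"none"` (default, raw p < alpha), `"BH"` or
#'   `"bonferroni"`.
#' @param high_corr_threshold correlation threshold for the
#'   high-correlation flag (default 0.2).
#' @return object of class `screen_config`.
#' @export
screen_config <- function(alpha = 0.05, min_ratio = 0.10,
                          adjustment = c("none", "BH", "bonferroni"),
                          high_corr_threshold = 0.2) {
  .check_alpha(alpha)
  if (min_ratio < 0 || min_ratio >= 1) .stopf("min_ratio out of range [0, 1)")
  adjustment <- match.arg(adjustment)
  structure(list(alpha = alpha, min_ratio = min_ratio,
                 adjustment = adjustment,
                 high_corr_threshold = high_corr_threshold),
            class = "screen_config")
}

.adjust_p <- function(p, adjustment) {
  switch(adjustment,
         none = p,
         BH = bh_adjust(p),
         bonferroni = pmin(1, p * length(p)),
         .stopf("unknown adjustment: %s", adjustment))
}

#' Condition-stratified upregulation screen within a subgroup
#'
#' Splits the subgroup's cells into those derived from BoM samples
#' (condition `"BoM"`) and all others, pre-filters genes to those
#' detected (raw count > 0) in more than `min_ratio` of the subgroup's
#' cells, and tests each remaining gene with a two-sided Wilcoxon
#' rank-sum test on log-normalized values. A gene is flagged `up_in_bom`
#' when its (optionally adjusted) p-value is below `alpha`, its mean
#' log-normalized expression is higher in BoM cells, and its
#' positive-expression ratio among BoM cells exceeds `min_ratio`.
#'
#' @param expr log-normalized matrix.
#' @param counts matching raw count matrix.
#' @param cell_table per-cell annotations with `condition` column.
#' @param subgroup subgroup label to screen.
#' @param cfg a [screen_config()].
#' @return data.frame (subgroup, gene, n_bom, n_other, pos_ratio_bom,
#'   pos_ratio_other, delta_mean, p_raw, p_adj, up_in_bom), ordered by p
#'   then gene id. If a condition is absent, an empty table with a
#'   `reason` attribute is returned.
#' @export
screen_condition_genes <- function(expr, counts, cell_table, subgroup,
                                   cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  if (!all(c("cell_id", "subgroup", "condition") %in% names(cell_table)))
    .stopf("cell table needs cell_id, subgroup and condition columns")
  ann <- cell_table[match(colnames(expr), cell_table$cell_id), ]
  in_sg <- which(ann$subgroup == subgroup)
  if (!length(in_sg)) .stopf("subgroup not found: %s", subgroup)
  bom <- in_sg[ann$condition[in_sg] == "BoM"]
  oth <- in_sg[ann$condition[in_sg] != "BoM"]
  empty <- data.frame(subgroup = character(0), gene = character(0),
                      n_bom = integer(0), n_other = integer(0),
                      pos_ratio_bom = numeric(0), pos_ratio_other = numeric(0),
                      delta_mean = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), up_in_bom = logical(0))
  if (length(bom) < 3L || length(oth) < 3L) {
    attr(empty, "reason") <- sprintf(
      "subgroup %s has %d BoM and %d Other cells; need >= 3 in each",
      subgroup, length(bom), length(oth))
    return(empty)
  }
  ratio_all <- .row_pos_ratio(counts, in_sg)
  keep <- which(ratio_all > cfg$min_ratio)
  if (!length(keep)) {
    attr(empty, "reason") <- "no gene passes the expression-ratio filter"
    return(empty)
  }
  dense <- .as_dense(expr[keep, , drop = FALSE])
  p <- .ranksum_rows(dense, bom, oth)
  p_adj <- .adjust_p(p, cfg$adjustment)
  delta <- rowMeans(dense[, bom, drop = FALSE]) - rowMeans(dense[, oth, drop = FALSE])
  rb <- .row_pos_ratio(counts[keep, , drop = FALSE], bom)
  ro <- .row_pos_ratio(counts[keep, , drop = FALSE], oth)
  out <- data.frame(
    subgroup = subgroup, gene = rownames(counts)[keep],
    n_bom = length(bom), n_other = length(oth),
    pos_ratio_bom = rb, pos_ratio_other = ro, delta_mean = delta,
    p_raw = p, p_adj = p_adj,
    up_in_bom = p_adj < cfg$alpha & delta > 0 & rb > cfg$min_ratio,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(out$p_adj, out$gene, method = "radix"), , drop = FALSE]
}

#' Pairwise sample-type comparisons of one gene within a subgroup
#'
#' Compares the log-normalized expression of a single gene between every
#' unordered pair of sample-type levels present in the subgroup, using
#' two-sided Wilcoxon rank-sum tests with Bonferroni correction over the
#' number of tested pairs, and maps adjusted p-values to significance
#' stars (`***` < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise).
#'
#' @param expr log-normalized matrix.
#' @param cell_table per-cell annotations with `sample_type` column.
#' @param subgroup subgroup label.
#' @param gene gene id.
#' @param levels optional subset/order of sample-type levels (default:
#'   all levels present in the subgroup, sorted).
#' @return data.frame (level_a, level_b, n_a, n_b, p_raw, p_adj, stars);
#'   pairs with a level below 2 cells are reported with `NA` p-values.
#' @export
pairwise_condition_test <- function(expr, cell_table, subgroup, gene,
                                    levels = NULL) {
  if (!all(c("cell_id", "subgroup", "sample_type") %in% names(cell_table)))
    .stopf("cell table needs cell_id, subgroup and sample_type columns")
  if (!gene %in% rownames(expr)) .stopf("gene not found: %s", gene)
  ann <- cell_table[match(colnames(expr), cell_table$cell_id), ]
  in_sg <- which(ann$subgroup == subgroup)
  if (!length(in_sg)) .stopf("subgroup not found: %s", subgroup)
  lv <- levels %||% sort(unique(ann$sample_type[in_sg]))
  lv <- lv[lv %in% ann$sample_type[in_sg]]
  if (length(lv) < 2L) .stopf("need at least 2 sample-type levels in %s", subgroup)
  vals <- as.numeric(expr[gene, in_sg])
  types <- ann$sample_type[in_sg]
  pairs <- utils::combn(lv, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    xa <- vals[types == a]; xb <- vals[types == b]
    p <- if (length(xa) < 2L || length(xb) < 2L) NA_real_ else
      wilcoxon_rank_sum(xa, xb, exact = FALSE)$p
    data.frame(level_a = a, level_b = b, n_a = length(xa), n_b = length(xb),
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  k <- sum(!is.na(out$p_raw))
  out$p_adj <- pmin(1, out$p_raw * k)
  out$stars <- as.character(.star_code(out$p_adj))
  out$stars[is.na(out$p_adj)] <- NA_character_
  rownames(out) <- NULL
  attr(out, "skipped") <- out[is.na(out$p_raw), c("level_a", "level_b")]
  out
}
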