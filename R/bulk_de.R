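#' Median-of-ratios size factors
#'
#' Per-sample normalization factors in the DESeq tradition: for each
#' sample, the median over eligible genes of the ratio of that sample's
#' count to the gene's geometric mean across samples. Eligible genes are
#' those with a positive geometric mean (i.e. positive counts in every
#' sample).
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @return named numeric vector of positive factors, one per sample.
#' @examples
#' m <- cbind(A = c(2, 4, 8), B = c(1, 2, 4))
#' rownames(m) <- paste0("g", 1:3)
#' size_factors(m)  # sqrt(2), 1/sqrt(2)
#' @export
size_factors <- function(counts) {
  .assert_count_matrix(counts)
  counts <- .as_dense(counts)
  logg <- rowMeans(log(counts))           # -Inf for any zero count
  eligible <- is.finite(logg)
  if (!any(eligible))
    .stopf("no gene has positive counts in every sample; size factors undefined")
  lr <- log(counts[eligible, , drop = FALSE]) - logg[eligible]
  sf <- exp(apply(lr, 2L, stats::median))
  setNames(sf, colnames(counts))
}

#' Negative-binomial Wald differential expression
#'
#' Two-group differential expression on raw bulk counts: samples are
#' normalized by median-of-ratios [size_factors()], a gene-level NB
#' dispersion is estimated by the method of moments from pooled
#' within-group variances (floored at 1e-8), and a Wald z statistic is
#' formed for the log2 fold change (group 2 over group 1, pseudo-count
#' 0.5) with a delta-method standard error. Two-sided p-values come from
#' the standard normal and are BH-adjusted across genes.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups two-level factor/character vector along columns; the
#'   first level (factor order, or lexicographic for characters) is the
#'   reference (group 1).
#' @param alpha significance cutoff on the adjusted p-value used for the
#'   `direction` call (default 0.05).
#' @return data.frame of class `de_result` with columns gene, log2fc,
#'   p_raw, p_adj, mean_norm_g1, mean_norm_g2, direction (`up`/`down`/
#'   `ns`). Genes with zero counts everywhere are `ns` with p = 1.
#' @export
nb_wald_de <- function(counts, groups, alpha = 0.05) {
  .assert_count_matrix(counts)
  .check_alpha(alpha)
  counts <- .as_dense(counts)
  if (length(groups) != ncol(counts))
    .stopf("groups must have one label per sample column")
  f <- if (is.factor(groups)) droplevels(groups) else factor(groups)
  if (nlevels(f) != 2L) .stopf("exactly two group levels required")
  n1 <- sum(f == levels(f)[1L]); n2 <- sum(f == levels(f)[2L])
  if (min(n1, n2) < 2L) .stopf("each group needs at least 2 samples")

  sf <- size_factors(counts)
  # geometric-mean-1 rescaling makes the normalized matrix (hence z)
  # exactly invariant to scaling any single sample's column
  sf <- sf / exp(mean(log(sf)))
  y <- sweep(counts, 2L, sf, "/")
  i1 <- which(f == levels(f)[1L]); i2 <- which(f == levels(f)[2L])
  m1 <- rowMeans(y[, i1, drop = FALSE]); m2 <- rowMeans(y[, i2, drop = FALSE])
  v1 <- apply(y[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(y[, i2, drop = FALSE], 1L, stats::var)

  # method-of-moments dispersion: var = mu + disp * mu^2, pooled over groups
  num <- (n1 - 1) * (v1 - m1) + (n2 - 1) * (v2 - m2)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  disp <- ifelse(den > 0, pmax(num / den, 1e-8), 1e-8)

  cpc <- 0.5
  log2fc <- log2((m2 + cpc) / (m1 + cpc))
  var_m1 <- (m1 + disp * m1^2) / n1
  var_m2 <- (m2 + disp * m2^2) / n2
  se <- sqrt(var_m1 / (m1 + cpc)^2 + var_m2 / (m2 + cpc)^2) / log(2)
  z <- ifelse(se > 0, log2fc / se, ifelse(log2fc == 0, 0, Inf * sign(log2fc)))
  p_raw <- pmin(1, 2 * stats::pnorm(-abs(z)))
  allzero <- m1 == 0 & m2 == 0
  p_raw[allzero] <- 1
  log2fc[allzero] <- 0
  p_adj <- bh_adjust(p_raw)
  direction <- rep("ns", nrow(counts))
  direction[p_adj < alpha & log2fc > 0] <- "up"
  direction[p_adj < alpha & log2fc < 0] <- "down"
  direction[allzero] <- "ns"
  res <- data.frame(
    gene = rownames(counts), log2fc = log2fc, p_raw = p_raw, p_adj = p_adj,
    mean_norm_g1 = m1, mean_norm_g2 = m2, direction = direction,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "groups") <- levels(f)
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Derive the overlap gene panel from two DE comparisons
#'
#' Intersects the upregulated gene sets of two differential-expression
#' tables (e.g. Meta vs nonMeta and BoM vs nonBoM): the panel contains
#' genes called `up` at the given adjusted-p cutoff in both tables, in
#' deterministic lexicographic order.
#'
#' @param de_meta,de_bom `de_result` tables sharing a gene namespace.
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return object of class `gene_panel`: list with `genes` (sorted
#'   character vector) and `provenance` (comparison labels and alpha).
#' @export
derive_panel <- function(de_meta, de_bom, alpha = 0.05) {
  .check_alpha(alpha)
  up <- function(de) de$gene[de$p_adj < alpha & de$log2fc > 0]
  if (!length(intersect(de_meta$gene, de_bom$gene)))
    .warnf("the two DE tables share no genes; panel is empty")
  genes <- .lex_sort(intersect(up(de_meta), up(de_bom)))
  structure(list(
    genes = genes,
    provenance = list(
      comparison_meta = attr(de_meta, "groups") %||% c(NA, NA),
      comparison_bom = attr(de_bom, "groups") %||% c(NA, NA),
      alpha = alpha
    )
  ), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("Gene panel: %d genes (alpha = %g)\n",
              length(x$genes), x$provenance$alpha))
  if (length(x$genes))
    cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
        if (length(x$genes) > 10) "...\n" else "\n")
  invisible(x)
}

#' Classify samples by a bone-site phenotype string
#'
#' Thin helper for phenotype tables whose metastatic-site annotation is
#' free text: flags samples whose annotation contains a target substring
#' (default `"bone"`), case-insensitively.
#'
#' @param site_text character vector of free-text site annotations.
#' @param pattern substring to search for (fixed, not regex).
#' @return logical vector (`NA` in, `NA` out).
#' @export
classify_bone_site <- function(site_text, pattern = "bone") {
  out <- grepl(tolower(pattern), tolower(site_text), fixed = TRUE)
  out[is.na(site_text)] <- NA
  out
}
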