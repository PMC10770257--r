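#' Read a single-cell or bulk count matrix
#'
#' Reads either a Matrix Market triplet directory (`matrix.mtx` +
#' `genes.tsv` + `barcodes.tsv`, genes in rows) or a plain TSV with gene
#' ids in the first column and observation ids in the header. Duplicate
#' gene symbols are disambiguated by suffixing (`make.unique`).
#'
#' @param path directory (mtx_triplet) or file (tsv).
#' @param format `"mtx_triplet"` or `"tsv"`.
#' @return genes x observations count matrix (sparse `dgCMatrix` for
#'   mtx_triplet, dense for tsv).
#' @export
read_counts <- function(path, format = c("mtx_triplet", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (fp in c(mtx, gf, bf)) if (!file.exists(fp)) .stopf("missing file: %s", fp)
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (length(genes) != nrow(m))
      .stopf("gene file has %d entries but matrix has %d rows",
             length(genes), nrow(m))
    if (length(cells) != ncol(m))
      .stopf("barcode file has %d entries but matrix has %d columns",
             length(cells), ncol(m))
    genes <- vapply(strsplit(genes, "\t", fixed = TRUE), `[[`, character(1), 1L)
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    genes <- as.character(dt[[1L]])
    m <- as.matrix(dt[, -1L, drop = FALSE])
    cells <- colnames(m)
  }
  if (ncol(m) == 0L) .stopf("count matrix has zero observations (no cells/samples)")
  if (nrow(m) == 0L) .stopf("count matrix has zero genes")
  if (anyDuplicated(genes)) {
    .warnf("duplicate gene ids disambiguated by suffixing")
    genes <- make.unique(genes)
  }
  if (anyDuplicated(cells)) .stopf("duplicate observation ids")
  dimnames(m) <- list(genes, cells)
  .assert_count_matrix(m)
  m
}

#' Write a count matrix as an MTX triplet directory
#'
#' @param counts genes x cells count matrix.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  .assert_count_matrix(counts)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a count matrix as TSV (gene column first)
#' @param counts genes x observations count matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  .assert_count_matrix(counts)
  dt <- data.table::data.table(gene = rownames(counts))
  dt <- cbind(dt, data.table::as.data.table(.as_dense(counts)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by log transform:
#' `value = ln(1 + scale * count / total)` where `total` is the cell's
#' summed counts. Cells with zero total counts are dropped with a
#' message.
#'
#' @param counts genes x cells count matrix (dense or sparse).
#' @param scale scale constant (default 1e4).
#' @return matrix of the same class with attribute
#'   `normalization = "lognorm"`; axes match the retained cells.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  .assert_count_matrix(counts)
  totals <- if (methods::is(counts, "Matrix")) Matrix::colSums(counts) else colSums(counts)
  drop <- totals == 0
  if (any(drop)) {
    message(sprintf("dropping %d cell(s) with zero total counts", sum(drop)))
    counts <- counts[, !drop, drop = FALSE]
    totals <- totals[!drop]
  }
  if (methods::is(counts, "sparseMatrix")) {
    m <- methods::as(counts, "CsparseMatrix")
    percell <- rep.int(seq_len(ncol(m)), diff(m@p))
    m@x <- log1p(scale * m@x / totals[percell])
    out <- m
  } else {
    out <- log1p(sweep(.as_dense(counts) * scale, 2L, totals, "/"))
    dimnames(out) <- dimnames(counts)
  }
  attr(out, "normalization") <- "lognorm"
  attr(out, "scale_constant") <- scale
  out
}

# Resolve the cell columns of each subgroup; validates alignment of the
# annotation table with the matrix columns.
.subgroup_index <- function(mat, cell_table) {
  if (!all(c("cell_id", "subgroup") %in% names(cell_table)))
    .stopf("cell table needs cell_id and subgroup columns")
  idx <- match(colnames(mat), cell_table$cell_id)
  if (anyNA(idx)) .stopf("%d matrix columns missing from the cell table",
                         sum(is.na(idx)))
  split(seq_len(ncol(mat)), cell_table$subgroup[idx])
}

#' Dot-profile statistics per (subgroup, gene)
#'
#' The statistics behind cluster dot plots: per subgroup and gene, the
#' mean log-normalized expression, its z-score across subgroups (per
#' gene, sample SD; genes with zero variance across subgroups get z = 0),
#' and the positive-expression ratio (fraction of the subgroup's cells
#' with raw count > 0).
#'
#' @param expr log-normalized matrix from [lognormalize()].
#' @param counts matching raw count matrix.
#' @param cell_table per-cell annotations (cell_id, subgroup, ...).
#' @param genes genes to profile; unknown genes are reported and skipped.
#' @return data.frame (subgroup, gene, mean_expr, z_expr, pos_ratio).
#' @export
dot_profile <- function(expr, counts, cell_table, genes) {
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes)) {
    .warnf("skipping %d gene(s) absent from the matrix: %s",
           length(missing_genes),
           paste(utils::head(missing_genes, 5), collapse = ", "))
    genes <- setdiff(genes, missing_genes)
  }
  if (!length(genes)) return(data.frame(subgroup = character(0),
                                        gene = character(0), mean_expr = numeric(0),
                                        z_expr = numeric(0), pos_ratio = numeric(0)))
  idx <- .subgroup_index(expr, cell_table)
  sgs <- names(idx)
  means <- sapply(idx, function(i) .row_means(expr[genes, , drop = FALSE], i))
  ratios <- sapply(idx, function(i) .row_pos_ratio(counts[genes, , drop = FALSE], i))
  means <- matrix(means, nrow = length(genes), dimnames = list(genes, sgs))
  ratios <- matrix(ratios, nrow = length(genes), dimnames = list(genes, sgs))
  z <- means
  if (length(sgs) >= 2L) {
    mu <- rowMeans(means)
    sdv <- apply(means, 1L, stats::sd)
    z <- (means - mu) / ifelse(sdv > 0, sdv, Inf)   # zero variance -> z = 0
  } else {
    z[] <- 0
  }
  out <- data.frame(
    subgroup = rep(sgs, each = length(genes)),
    gene = rep(genes, times = length(sgs)),
    mean_expr = as.vector(means), z_expr = as.vector(z),
    pos_ratio = as.vector(ratios), stringsAsFactors = FALSE
  )
  out[order(out$subgroup, out$gene, method = "radix"), , drop = FALSE]
}

#' One-vs-rest Wilcoxon marker detection
#'
#' For each subgroup, tests each gene's log-normalized expression in the
#' subgroup's cells against all remaining cells with a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie and continuity
#' corrections). Only positive candidate markers are tested: genes must
#' be detected (raw count > 0) in at least `min_ratio` of the subgroup's
#' cells and have ln fold change (natural log of mean ratio,
#' pseudo-count 1e-9) of at least `min_lnfc`. P-values are BH-adjusted
#' within each subgroup across its tested genes.
#'
#' @param expr log-normalized matrix.
#' @param counts matching raw count matrix.
#' @param cell_table per-cell annotations.
#' @param alpha adjusted-p cutoff for the marker call (default 0.05).
#' @param min_lnfc minimum ln fold change (default 0.25).
#' @param min_ratio minimum in-subgroup positive-expression ratio
#'   (default 0.10).
#' @param min_cells subgroups below this size are excluded with a
#'   warning (default 3).
#' @return data.frame (subgroup, gene, lnfc, p_raw, p_adj, pos_ratio_in,
#'   pos_ratio_rest, is_marker) covering the tested genes only.
#' @export
find_markers <- function(expr, counts, cell_table, alpha = 0.05,
                         min_lnfc = 0.25, min_ratio = 0.10, min_cells = 3L) {
  .check_alpha(alpha)
  idx <- .subgroup_index(expr, cell_table)
  small <- names(idx)[vapply(idx, length, 1L) < min_cells]
  if (length(small)) {
    .warnf("excluding subgroup(s) below %d cells: %s", min_cells,
           paste(small, collapse = ", "))
    idx <- idx[setdiff(names(idx), small)]
  }
  if (length(idx) < 2L) .stopf("need at least 2 subgroups for marker detection")
  dense <- .as_dense(expr)
  res <- list()
  for (sg in names(idx)) {
    cells_in <- idx[[sg]]
    cells_out <- setdiff(unlist(idx, use.names = FALSE), cells_in)
    ratio_in <- .row_pos_ratio(counts, cells_in)
    ratio_out <- .row_pos_ratio(counts, cells_out)
    mean_in <- rowMeans(dense[, cells_in, drop = FALSE])
    mean_out <- rowMeans(dense[, cells_out, drop = FALSE])
    lnfc <- log((mean_in + 1e-9) / (mean_out + 1e-9))
    keep <- which(ratio_in >= min_ratio & lnfc >= min_lnfc)
    if (!length(keep)) next
    p <- .ranksum_rows(dense[keep, , drop = FALSE], cells_in, cells_out)
    padj <- bh_adjust(p)
    res[[sg]] <- data.frame(
      subgroup = sg, gene = rownames(dense)[keep], lnfc = lnfc[keep],
      p_raw = p, p_adj = padj,
      pos_ratio_in = ratio_in[keep], pos_ratio_rest = ratio_out[keep],
      is_marker = padj < alpha, stringsAsFactors = FALSE, row.names = NULL
    )
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(subgroup = character(0), gene = character(0), lnfc = numeric(0),
               p_raw = numeric(0), p_adj = numeric(0), pos_ratio_in = numeric(0),
               pos_ratio_rest = numeric(0), is_marker = logical(0))
  rownames(out) <- NULL
  out[order(out$subgroup, out$p_adj, out$gene, method = "radix"), , drop = FALSE]
}

#' Overlap a gene panel with per-subgroup markers
#'
#' For each subgroup, intersects the panel genes with the subgroup's
#' marker genes (rows of the marker table with `is_marker = TRUE`).
#'
#' @param panel a [derive_panel()] `gene_panel` (or character vector).
#' @param markers a [find_markers()] result.
#' @return named list, subgroup -> sorted character vector of panel
#'   genes that are markers of that subgroup (empty sets included).
#' @export
panel_marker_overlap <- function(panel, markers) {
  genes <- if (inherits(panel, "gene_panel")) panel$genes else as.character(panel)
  sgs <- sort(unique(markers$subgroup))
  out <- lapply(sgs, function(sg) {
    mk <- markers$gene[markers$subgroup == sg & markers$is_marker]
    .lex_sort(intersect(genes, mk))
  })
  names(out) <- sgs
  out
}
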