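#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT format (set name, description, then
#' member genes). Duplicate members within a set are stored once.
#'
#' @param path GMT file.
#' @return named list of character vectors of class
#'   `gene_set_collection`, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) .stopf("GMT line %d has fewer than 3 fields", bad[1L])
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) .stopf("duplicate set names in GMT")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[[`, character(1), 2L), nm)
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of character vectors (descriptions taken from
#'   the `descriptions` attribute, or `"na"`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions") %||% setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]] %||% "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list against each gene set: with a universe of N
#' genes of which K belong to the set, and a query of n genes of which k
#' overlap the set, the enrichment p-value is the upper hypergeometric
#' tail P(X >= k). Query genes outside the universe are dropped with a
#' warning; sets are intersected with the universe, and sets with no
#' universe member are skipped. P-values are BH-adjusted across the
#' tested sets.
#'
#' @param query character vector of genes.
#' @param sets a [read_gmt()] collection (or named list).
#' @param universe character vector of background genes.
#' @return data.frame (set, k, K, n, N, p_raw, p_adj, genes) sorted by
#'   p_adj then set name; `genes` is a comma-joined overlap list.
#' @export
ora_hypergeometric <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) .stopf("empty universe")
  query <- unique(as.character(query))
  if (!length(query)) .stopf("empty query")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    .warnf("dropping %d query gene(s) outside the universe", length(outside))
    query <- setdiff(query, outside)
    if (!length(query)) .stopf("no query gene lies in the universe")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    ov <- intersect(query, members)
    k <- length(ov)
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p_raw = .hyper_tail(k, N, K, n),
               genes = paste(.lex_sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), genes = character(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[, c("set", "k", "K", "n", "N", "p_raw", "p_adj", "genes")]
  out <- out[order(out$p_adj, out$set, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top significantly enriched terms
#'
#' First `k` rows of a sorted enrichment table with adjusted p below
#' `alpha` (fewer if not enough pass). Ties in p_adj are already broken
#' by set name in [ora_hypergeometric()].
#'
#' @param results an [ora_hypergeometric()] table.
#' @param k maximum number of terms (> 0).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return head of the passing rows.
#' @export
top_terms <- function(results, k, alpha = 0.05) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    .stopf("k must be a positive integer")
  pass <- results[results$p_adj < alpha, , drop = FALSE]
  utils::head(pass, as.integer(k))
}
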