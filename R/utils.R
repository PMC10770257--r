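# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_count_matrix <- function(counts, what = "counts") {
  if (!(is.matrix(counts) || methods::is(counts, "Matrix")))
    .stopf("%s must be a matrix (genes x observations)", what)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    .stopf("%s must carry gene rownames and observation colnames", what)
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.vector(counts)
  if (length(vals) && (any(vals < 0) || any(vals != floor(vals))))
    .stopf("%s must contain nonnegative integer counts", what)
  invisible(counts)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards so generators do not perturb sessions.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    .stopf("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(expr)
}

# Row means / positive-fractions restricted to a column subset, tolerating
# both dense and dgCMatrix inputs without densifying the full matrix.
.row_means <- function(m, cols) {
  sub <- m[, cols, drop = FALSE]
  if (methods::is(sub, "Matrix")) Matrix::rowMeans(sub) else rowMeans(sub)
}

.row_pos_ratio <- function(counts, cols) {
  sub <- counts[, cols, drop = FALSE]
  if (ncol(sub) == 0L) return(setNames(rep(NA_real_, nrow(sub)), rownames(sub)))
  if (methods::is(sub, "Matrix")) Matrix::rowMeans(sub > 0) else rowMeans(sub > 0)
}

.as_dense <- function(m) {
  if (methods::is(m, "Matrix")) as.matrix(m) else m
}

# Stable lexicographic ordering independent of the session locale.
.lex_order <- function(...) {
  args <- lapply(list(...), as.character)
  do.call(order, c(args, list(method = "radix")))
}

.lex_sort <- function(x) x[.lex_order(x)]

.check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    .stopf("alpha out of range (0, 1): %s", format(alpha))
  alpha
}

.star_code <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "ns"), right = FALSE)
}
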