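#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of p-values for multiple testing by controlling the
#' false discovery rate: p-values are sorted ascending, scaled by m/i,
#' made monotone non-decreasing from the largest rank downwards, capped
#' at 1, and returned in the original order.
#'
#' @param p numeric vector of p-values, all finite and in \[0, 1\].
#' @return numeric vector of adjusted p-values, same length and order;
#'   always elementwise \eqn{\ge} the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .stopf("p-values must be finite and within [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)          # largest first
  ro <- order(o)
  q <- pmin(1, cummin(p[o] * m / (m:1)))    # running minimum enforces monotonicity
  q[ro]
}

# Exact null distribution of the rank-sum of a sample of size m drawn
# without replacement from ranks 1..N: counts[s + 1] = number of subsets
# of size m with rank sum s (s = 0 .. N(N+1)/2). Dynamic programming over
# ranks; feasible for the small-N exact path (N <= 16).
.ranksum_counts <- function(m, N) {
  smax <- N * (N + 1) / 2
  f <- matrix(0, nrow = m + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (v in seq_len(N)) {
    kmax <- min(m, v)
    for (k in kmax:1) {
      f[k + 1L, (v + 1L):(smax + 1L)] <-
        f[k + 1L, (v + 1L):(smax + 1L)] + f[k, 1L:(smax + 1L - v)]
    }
  }
  f[m + 1L, ]
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Two-sample Wilcoxon (Mann-Whitney) rank-sum test. For small samples
#' (total n \eqn{\le} 16) without ties the exact permutation distribution
#' of the rank sum is used (two-sided p = twice the smaller tail, capped
#' at 1); otherwise a normal approximation with tie correction and
#' continuity correction is applied.
#'
#' @param x,y numeric vectors (each non-empty).
#' @param exact force (`TRUE`)/suppress (`FALSE`) the exact path;
#'   `NULL` (default) selects it automatically.
#' @param correct apply the continuity correction on the normal path.
#' @return list with `statistic` (Mann-Whitney U of `x`), `rank_sum`
#'   (rank sum of `x`), and two-sided `p`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # exact, 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL, correct = TRUE) {
  if (length(x) < 1L || length(y) < 1L) .stopf("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("inputs must be finite")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)])
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (N <= 16L) && !ties
  if (exact && ties) .stopf("exact p-value undefined in the presence of ties")
  if (exact) {
    cnt <- .ranksum_counts(m, N)
    tot <- sum(cnt)
    s <- seq_along(cnt) - 1L
    p_le <- sum(cnt[s <= W]) / tot
    p_ge <- sum(cnt[s >= W]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- m * (N + 1) / 2
    tie_tab <- tabulate(match(r, unique(r)))
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    d <- W - mu
    if (correct) d <- sign(d) * max(0, abs(d) - 0.5)
    z <- if (sigma2 <= 0) 0 else d / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W - m * (m + 1) / 2, rank_sum = W, p = p)
}

# Vectorised normal-approximation rank-sum over the rows of a dense
# matrix: group 1 = columns idx1, group 2 = idx2. Returns two-sided p per
# row with tie and continuity corrections (the workhorse behind the
# per-gene screens, where cell numbers rule out the exact path anyway).
.ranksum_rows <- function(mat, idx1, idx2) {
  m <- length(idx1); n <- length(idx2); N <- m + n
  sub <- mat[, c(idx1, idx2), drop = FALSE]
  mu <- m * (N + 1) / 2
  base_var <- m * n / 12
  apply(sub, 1L, function(v) {
    r <- rank(v)
    W <- sum(r[seq_len(m)])
    tie_tab <- tabulate(match(r, unique(r)))
    sigma2 <- base_var * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    d <- W - mu
    d <- sign(d) * max(0, abs(d) - 0.5)
    min(1, 2 * stats::pnorm(-abs(d) / sqrt(sigma2)))
  })
}

#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation between two vectors, with the usual
#' two-sided p-value from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n-2
#' degrees of freedom. r is clamped to \[-1, 1\] against floating-point
#' rounding. Zero variance in either input yields a degenerate result
#' (`status = "zero_variance"`, `r` and `p` set to `NA`) rather than NaN
#' propagation.
#'
#' @param x,y numeric vectors of equal length \eqn{\ge} 3.
#' @return list with `r`, `p`, `n`, `status` (`"ok"` or `"zero_variance"`).
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) .stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("inputs must be finite")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, status = "zero_variance"))
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n, status = "ok")
}

# Upper hypergeometric tail P(X >= k) for X ~ Hypergeometric(N, K, n):
# k successes drawn among n from a universe of N containing K successes.
.hyper_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}
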