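# Small statistical utilities shared across analyses.

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1); a thin wrapper over
#' [stats::p.adjust()] kept as the single FDR entry point so every table in
#' the pipeline corrects the same way (within each analysis table / epoch
#' duration).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values (empty input gives empty output).
#' @examples
#' fdr_adjust(c(0.005, 0.05))  # 0.01 0.05
#' @export
fdr_adjust <- function(p, method = "BH") {
  if (!length(p)) return(numeric())
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop_gp("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = method)
}

#' Two-sample pooled-variance t-test
#'
#' Two-tailed, unpaired, assuming equal variance; df = n_a + n_b - 2.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return A list with `t`, `df`, `p`.
#' @examples
#' two_sample_t(c(1, 2, 3), c(3, 4, 5))  # t = -2.449, df = 4
#' @export
two_sample_t <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_gp("two_sample_t needs >= 2 values per group")
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stop_gp("pooled variance is zero; t undefined")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Yates-corrected chi-square test of independence for a 2x2 table
#'
#' @param counts A 2x2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts with all margins > 0.
#' @return A list with `statistic`, `df`, `p`.
#' @examples
#' chi_square_independence(matrix(c(74, 38, 31, 10), 2))
#' @export
chi_square_independence <- function(counts) {
  m <- matrix(as.numeric(counts), nrow = 2)
  if (any(m < 0) || any(abs(m - round(m)) > 1e-9))
    stop_gp("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop_gp("all table margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Partial rank correlation via rank-residual regression
#'
#' The rank-based partial correlation of `x` and `y` controlling `z` (from
#' `x`) and `w` (from `y`): all four variables are transformed to rank
#' scores, `rank(x)` is regressed on `rank(z)` and `rank(y)` on `rank(w)`
#' by simple linear regression, and the Pearson correlation between the two
#' residual vectors is returned (Pearson, because the data are already
#' rank-transformed). With constant covariates this reduces to the plain
#' Spearman correlation of `x` and `y`.
#'
#' @param x,y Variables to correlate.
#' @param z,w Covariates partialled out of `x` and `y` respectively.
#' @return A single correlation.
#' @export
partial_rank_correlation <- function(x, y, z, w) {
  n <- length(x)
  if (length(y) != n || length(z) != n || length(w) != n)
    stop_gp("x, y, z, w must have equal length")
  if (n < 3) stop_gp("need >= 3 observations")
  resid_on <- function(v, cv) {
    rv <- rank(v); rc <- rank(cv)
    vc <- stats::var(rc)
    beta <- if (vc > 0) stats::cov(rv, rc) / vc else 0
    rv - mean(rv) - beta * (rc - mean(rc))
  }
  r1 <- resid_on(x, z); r2 <- resid_on(y, w)
  if (stats::sd(r1) == 0 || stats::sd(r2) == 0)
    stop_gp("zero-variance residuals; partial correlation undefined")
  stats::cor(r1, r2)
}
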