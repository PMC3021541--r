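#' Pearson correlation with significance
#'
#' Computes the product-moment correlation between two vectors together
#' with its Fisher z transform and a two-tailed significance test. The
#' default test is the exact-under-normality t test,
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} with \eqn{n-2} degrees of freedom;
#' the variance-stabilized normal test on \eqn{z\sqrt{n-3}} is available
#' via `method = "fisher"`.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @param method Significance route: `"t"` (default) or `"fisher"`.
#' @return A `correlation_result`: list with elements `r`, `n`,
#'   `z_fisher`, `stat`, `df` (`NA` for the Fisher route), `p`, `method`.
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 1, 3))
#' @export
pearson_r <- function(x, y, method = c("t", "fisher")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    stop("non-finite values in correlation input")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: input has zero variance")
  }
  r <- stats::cor(x, y)
  # guard against rounding pushing |r| infinitesimally above 1
  r <- max(-1, min(1, r))
  zf <- if (abs(r) < 1) fisher_z(r) else sign(r) * Inf
  if (method == "t") {
    df <- n - 2L
    stat <- if (abs(r) < 1) r * sqrt(df) / sqrt(1 - r^2) else sign(r) * Inf
    p <- 2 * stats::pt(-abs(stat), df = df)
  } else {
    df <- NA_integer_
    stat <- zf * sqrt(n - 3)
    p <- 2 * stats::pnorm(-abs(stat))
  }
  structure(
    list(r = r, n = n, z_fisher = zf, stat = stat, df = df, p = p,
         method = method),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (n = %d)\n", x$r, x$n))
  cat(sprintf("  Fisher z = %.4f; %s = %.4f%s; two-tailed p = %.3g\n",
              x$z_fisher,
              if (identical(x$method, "t")) "t" else "Z",
              x$stat,
              if (is.na(x$df)) "" else sprintf(" (df = %d)", x$df),
              x$p))
  invisible(x)
}

#' Fisher z transform of a correlation coefficient
#'
#' \eqn{z = \tfrac{1}{2}\,\ln\bigl((1+r)/(1-r)\bigr)}, the
#' variance-stabilizing map that makes correlation coefficients
#' approximately normal; strictly increasing and odd on (-1, 1).
#'
#' @param r Correlation coefficient(s) with |r| < 1.
#' @return Transformed z score(s).
#' @seealso [fisher_z_inv()]
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1")
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Inverse Fisher z transform
#'
#' @param z Fisher z score(s).
#' @return Correlation coefficient(s) in (-1, 1).
#' @export
fisher_z_inv <- function(z) {
  tanh(z)
}

#' Compare two correlation coefficients
#'
#' Tests equality of two correlations from (assumed) independent samples:
#' \eqn{Z = (z_1 - z_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}} on the
#' Fisher-transformed values, with a two-tailed normal p value. When the
#' two correlations share subjects (as ROI-to-ROI comparisons within one
#' cohort do) the independence assumption is an approximation; the result
#' carries `assumption = "independent samples"` to make that explicit.
#'
#' @param r1,r2 The two correlation coefficients (|r| < 1).
#' @param n1,n2 Their sample sizes (>= 4).
#' @return List with `z1`, `z2`, `stat` (the Z statistic), `p`, and
#'   `assumption`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z1 <- fisher_z(r1)
  z2 <- fisher_z(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  stat <- (z1 - z2) / se
  list(z1 = z1, z2 = z2, stat = stat,
       p = 2 * stats::pnorm(-abs(stat)),
       assumption = "independent samples")
}

#' Partial correlation after removing up to two covariates
#'
#' Residualizes `y` and `x` on the covariates by least squares (with
#' intercept) and Pearson-correlates the residuals. Significance uses
#' \eqn{t = r_p\sqrt{df}/\sqrt{1-r_p^2}} with \eqn{df = n - 2 - k} where
#' k is the number of covariates removed ("second order" when k = 2).
#'
#' @param y,x Numeric vectors of equal length.
#' @param covariates Optional numeric vector, matrix, or data frame with
#'   at most two columns and the same number of rows.
#' @return List with `r_partial`, `order` (k), `n`, `stat`, `df`, `p`.
#' @export
partial_correlation <- function(y, x, covariates = NULL) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  n <- length(y)
  if (length(x) != n) stop("y and x must have equal length")
  if (is.null(covariates)) {
    cov_mat <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    cov_mat <- as.matrix(as.data.frame(covariates))
    storage.mode(cov_mat) <- "double"
  }
  k <- ncol(cov_mat)
  if (k > 2L) stop("at most two covariates are supported (second order)")
  if (nrow(cov_mat) != n) stop("covariates must have one row per observation")
  if (n < k + 3L) stop("too few observations for the requested order")
  if (k > 0L) {
    design <- cbind(1, cov_mat)
    if (qr(design)$rank < ncol(design)) {
      stop("degenerate design: covariates are collinear (with the intercept)")
    }
    res_y <- stats::lm.fit(design, y)$residuals
    res_x <- stats::lm.fit(design, x)$residuals
    if (stats::sd(res_x) < sqrt(.Machine$double.eps) * stats::sd(x)) {
      stop("degenerate design: x is explained exactly by the covariates")
    }
  } else {
    res_y <- y - mean(y)
    res_x <- x - mean(x)
  }
  if (stats::sd(res_x) == 0 || stats::sd(res_y) == 0) {
    stop("partial correlation undefined: residuals have zero variance")
  }
  r <- max(-1, min(1, stats::cor(res_x, res_y)))
  df <- n - 2L - k
  stat <- if (abs(r) < 1) r * sqrt(df) / sqrt(1 - r^2) else sign(r) * Inf
  list(r_partial = r, order = k, n = n, stat = stat, df = df,
       p = 2 * stats::pt(-abs(stat), df = df))
}

#' Variance explained by a correlation
#'
#' @param r Correlation coefficient(s) with |r| <= 1.
#' @return `r^2`, the fraction of variance accounted for.
#' @export
r_squared <- function(r) {
  if (any(abs(r) > 1)) stop("|r| must not exceed 1")
  r^2
}

#' Relative score improvement via percentile ranks
#'
#' Raw game scores can be negative, so a plain percent change is
#' ill-defined. Instead each subject's session-1 score is converted to an
#' empirical percentile rank R(t1) within the session-1 sample (average
#' ranks for ties, Hazen scaling `100 * (rank - 0.5) / n`), and the
#' session-2 score to R(t2) = 100 * Phi((s2 - mean(s1)) / sd(s1)), i.e.
#' a percentile against the session-1 mean and variance. The relative
#' improvement is `(R(t2) - R(t1)) / R(t1)`. Note the percentile map is
#' non-linear, so this measure is not an affine function of the absolute
#' improvement s2 - s1.
#'
#' @param scores_s1,scores_s2 Per-subject total scores in sessions 1 and 2.
#' @return Data frame with `rank_s1`, `rank_s2`, `relative_improvement`.
#' @export
relative_improvement <- function(scores_s1, scores_s2) {
  s1 <- as.numeric(scores_s1)
  s2 <- as.numeric(scores_s2)
  n <- length(s1)
  if (length(s2) != n) stop("session score vectors must have equal length")
  if (n < 3L) stop("need at least 3 subjects")
  sd1 <- stats::sd(s1)
  if (sd1 == 0) stop("session-1 scores have zero variance")
  r1 <- 100 * (rank(s1, ties.method = "average") - 0.5) / n
  r2 <- 100 * stats::pnorm((s2 - mean(s1)) / sd1)
  data.frame(rank_s1 = r1, rank_s2 = r2,
             relative_improvement = (r2 - r1) / r1)
}
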