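#' Configuration for the linear epsilon-SVR solver
#'
#' @param C Positive trade-off constant between flatness of the weight
#'   vector and tolerance for residuals beyond epsilon. Note that C is
#'   scale-dependent: targets spanning hundreds of units need a
#'   correspondingly larger C than unit-scale targets.
#' @param epsilon Half-width of the insensitivity tube, in target units.
#'   `NULL` (default) means scale-aware: 0.1 * SD of the training-fold
#'   targets, resolved at fit time.
#' @param kkt_tol Convergence tolerance on the maximal KKT violation (in
#'   target units).
#' @param max_iter Cap on pairwise dual-ascent updates.
#' @param standardize If `TRUE`, features are standardized inside the
#'   training fold (mean 0, SD 1) and new data transformed accordingly.
#'   Off by default: the intended inputs are already globally
#'   intensity-normalized volumes.
#' @return An `svr_config` list.
#' @export
svr_config <- function(C = 1.0, epsilon = NULL, kkt_tol = 1e-6,
                       max_iter = 1e5, standardize = FALSE) {
  stopifnot(is.numeric(C), length(C) == 1L, C > 0)
  if (!is.null(epsilon)) {
    stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0)
  }
  stopifnot(kkt_tol > 0, max_iter >= 1)
  structure(list(C = C, epsilon = epsilon, kkt_tol = kkt_tol,
                 max_iter = as.integer(max_iter),
                 standardize = isTRUE(standardize)),
            class = "svr_config")
}

#' Fit a linear epsilon-insensitive support vector regression
#'
#' Solves the SVR dual (box constraints \eqn{0 \le \alpha_i,
#' \alpha_i^* \le C}, equality \eqn{\sum_i (\alpha_i - \alpha_i^*) = 0})
#' by pairwise working-set ascent on the maximal-KKT-violating pair,
#' carried out in the \eqn{\beta_i = \alpha_i - \alpha_i^*}
#' parametrization so that \eqn{\alpha_i \alpha_i^* = 0} holds exactly.
#' The weight vector is \eqn{w = \sum_i \beta_i x_i}; the bias b is
#' recovered from the KKT conditions: averaged over free support vectors
#' (\eqn{0 < \alpha_i < C \Rightarrow b = y_i - w \cdot x_i - \epsilon};
#' \eqn{0 < \alpha_i^* < C \Rightarrow b = y_i - w \cdot x_i +
#' \epsilon}), or, when no free support vector exists, the midpoint of
#' the KKT-feasible interval.
#'
#' @param X Numeric feature matrix, one row per sample.
#' @param y Numeric target vector, one value per row of X.
#' @param config An [svr_config()].
#' @return An `svr_model` with elements `w`, `b`, `alpha`, `alpha_star`,
#'   `C`, `epsilon`, `support_idx`, `slack`, `slack_star`,
#'   `dual_objective`, `iterations`, `kkt_violation`.
#' @examples
#' X <- cbind(x = c(0, 1, 2, 3))
#' fit <- fit_svr(X, c(0, 2, 4, 6), svr_config(C = 100, epsilon = 0.01))
#' round(c(fit$w, fit$b), 3)
#' @export
fit_svr <- function(X, y, config = svr_config()) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training samples")
  if (ncol(X) < 1L) stop("need at least 1 feature")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in SVR training input")
  }
  if (!inherits(config, "svr_config")) stop("config must be an svr_config")

  centers <- NULL
  scales <- NULL
  if (config$standardize) {
    centers <- colMeans(X)
    scales <- apply(X, 2, stats::sd)
    scales[scales == 0] <- 1
    X <- sweep(sweep(X, 2, centers), 2, scales, "/")
  }

  eps <- if (is.null(config$epsilon)) 0.1 * stats::sd(y) else config$epsilon
  if (!is.finite(eps)) eps <- 0

  K <- tcrossprod(X)
  sol <- svr_smo_cpp(K, y, config$C, eps, config$kkt_tol, config$max_iter)
  if (sol$violation > config$kkt_tol) {
    stop(sprintf(
      "SVR solver did not reach kkt_tol = %g within %d iterations (achieved violation %g)%s",
      config$kkt_tol, config$max_iter, sol$violation,
      if (isTRUE(sol$stalled)) "; update stalled" else ""))
  }

  beta <- sol$beta
  f <- drop(K %*% beta)
  r <- y - f
  C <- config$C
  tol_b <- 1e-7 * C

  free_pos <- beta > tol_b & beta < C - tol_b
  free_neg <- beta < -tol_b & beta > -C + tol_b
  if (any(free_pos) || any(free_neg)) {
    b <- mean(c(r[free_pos] - eps, r[free_neg] + eps))
  } else {
    # midpoint of the interval of bias values compatible with the KKT system
    lower <- ifelse(beta < C, ifelse(beta < 0, r + eps, r - eps), -Inf)
    upper <- ifelse(beta > -C, ifelse(beta > 0, r - eps, r + eps), Inf)
    b <- (max(lower) + min(upper)) / 2
  }

  resid <- y - f - b
  model <- structure(list(
    w = drop(crossprod(X, beta)),
    b = b,
    alpha = pmax(beta, 0),
    alpha_star = pmax(-beta, 0),
    C = C,
    epsilon = eps,
    support_idx = which(abs(beta) > tol_b),
    slack = pmax(0, resid - eps),
    slack_star = pmax(0, -resid - eps),
    dual_objective = svr_dual_objective(beta, K, y, eps),
    iterations = sol$iterations,
    kkt_violation = sol$violation,
    standardize = config$standardize,
    feature_center = centers,
    feature_scale = scales,
    n_features = ncol(X)
  ), class = "svr_model")
  model
}

#' Dual objective of the epsilon-SVR at a given solution
#'
#' Evaluates \eqn{-\tfrac12 \beta^\top K \beta - \epsilon \sum_i |\beta_i|
#' + \sum_i y_i \beta_i} for \eqn{\beta = \alpha - \alpha^*}; useful for
#' comparing solvers.
#'
#' @param beta Dual coefficient vector (alpha - alpha_star).
#' @param K Gram matrix of the training samples.
#' @param y Training targets.
#' @param epsilon Insensitivity half-width used in the fit.
#' @return The (maximized) dual objective value.
#' @export
svr_dual_objective <- function(beta, K, y, epsilon) {
  beta <- as.numeric(beta)
  -0.5 * drop(crossprod(beta, K %*% beta)) -
    epsilon * sum(abs(beta)) + sum(y * beta)
}

#' Predict from a fitted SVR model
#'
#' @param object An `svr_model`.
#' @param newdata Numeric matrix (or vector for a single sample) with the
#'   model's feature count.
#' @param ... Unused.
#' @return Numeric vector of predictions \eqn{f(x) = w \cdot x + b}.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != object$n_features) {
    stop(sprintf("model expects %d features, got %d",
                 object$n_features, ncol(X)))
  }
  if (isTRUE(object$standardize)) {
    X <- sweep(sweep(X, 2, object$feature_center), 2, object$feature_scale, "/")
  }
  drop(X %*% object$w + object$b)
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf(
    "Linear eps-SVR: %d features, %d support vectors (C = %g, epsilon = %g)\n",
    x$n_features, length(x$support_idx), x$C, x$epsilon))
  cat(sprintf("  bias %.4g; dual objective %.6g; %d iterations (KKT violation %.2g)\n",
              x$b, x$dual_objective, x$iterations, x$kkt_violation))
  invisible(x)
}

#' Serialize a fitted SVR model to JSON
#'
#' Writes a documented JSON layout with fields `w`, `b`, `C`, `epsilon`,
#' `support_idx`, `alpha`, `alpha_star` (1-based indices).
#'
#' @param model An `svr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_svr_model <- function(model, path) {
  stopifnot(inherits(model, "svr_model"))
  payload <- list(
    format = "mvpasvr-svr-model",
    version = 1L,
    w = unname(model$w), b = model$b, C = model$C, epsilon = model$epsilon,
    support_idx = model$support_idx,
    alpha = model$alpha, alpha_star = model$alpha_star
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized SVR model
#'
#' @param path JSON file written by [write_svr_model()].
#' @return An `svr_model` usable with [predict.svr_model()].
#' @export
read_svr_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mvpasvr-svr-model")) {
    stop("not an mvpasvr SVR model file: ", path)
  }
  structure(list(
    w = as.numeric(payload$w), b = payload$b,
    alpha = as.numeric(payload$alpha),
    alpha_star = as.numeric(payload$alpha_star),
    C = payload$C, epsilon = payload$epsilon,
    support_idx = as.integer(payload$support_idx),
    standardize = FALSE,
    n_features = length(payload$w)
  ), class = "svr_model")
}
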