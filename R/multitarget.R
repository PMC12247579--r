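#' Fit one set of shrinkage hyperparameters across many targets
#'
#' Variant for regression problems with many outcome variables sharing one
#' design matrix (for example, thousands of voxels in an encoding analysis):
#' a single set of group scales lambda_j and one residual variance nu are
#' estimated jointly across all T target columns. Because X, lambda and nu
#' are shared, the weight-posterior covariance is identical for every target,
#' so each EM iteration needs exactly one matrix factorization regardless of
#' T — only the posterior means (one column per target) scale with T.
#'
#' The M-step maximizes the expected complete-data objective summed over
#' targets, giving
#' \code{lambda_j = (sum_t mu_jt' Oinv mu_jt + T Tr(Oinv Sigma_j) + 2 tau) /
#' (T D_j + 2 eta + 2)} and the analogous pooled update for nu with
#' denominator \code{T M + 2 + 2 phi}. With T = 1 the fit reduces exactly to
#' \code{\link{fit_em}}.
#'
#' @inheritParams fit_em
#' @param Y Numeric matrix of targets, M rows x T columns (each column is
#'   centered independently when \code{center = TRUE}).
#' @return An object of class \code{em_banded_multi}: like an
#'   \code{em_banded} fit but with \code{weights} a D x T matrix and a single
#'   shared \code{Sigma}. Element \code{n_factorizations} records the number
#'   of posterior factorizations performed.
#' @export
fit_em_shared <- function(design, Y, hyper = hyperpriors(gamma = 1e-4),
                          h = NULL, max_iter = 200L, tol = 1e-8, center = TRUE,
                          init_lambda = 1, init_nu = 1, route = "auto",
                          verbose = FALSE) {
  if (!inherits(design, "grouped_design"))
    design <- make_grouped_design(list(F1 = as.matrix(design)))
  stopifnot(inherits(hyper, "hyperpriors"))
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  if (nrow(Y) != design$M)
    stop(sprintf("Y has %d rows; design has %d observations", nrow(Y),
                 design$M), call. = FALSE)
  if (!all(is.finite(Y))) stop("Y contains non-finite entries", call. = FALSE)
  max_iter <- as.integer(max_iter)
  stopifnot(max_iter >= 1L, tol > 0)

  x_means <- rep(0, design$D)
  y_means <- rep(0, ncol(Y))
  if (center) {
    cc <- center_columns(design$X, Y)
    design$X <- cc$X
    Y <- as.matrix(cc$y)
    x_means <- cc$x_means
    y_means <- cc$y_means
  }

  res <- em_engine(design, Y, hyper = hyper, h = h, max_iter = max_iter,
                   tol = tol, init_lambda = init_lambda, init_nu = init_nu,
                   route = route, verbose = verbose)
  structure(list(
    lambdas = res$prior$lambdas, nu = res$nu,
    weights = res$mu, Sigma = res$Sigma,
    objective_trace = res$objective_trace,
    lambda_trace = res$lambda_trace, nu_trace = res$nu_trace,
    n_iter = res$n_iter, converged = res$converged,
    n_factorizations = res$n_factorizations,
    x_means = x_means, y_means = y_means,
    groups = design$groups,
    settings = list(hyper = hyper, h = h, max_iter = max_iter, tol = tol,
                    center = center, init_lambda = init_lambda,
                    init_nu = init_nu, route = route)),
    class = c("em_banded_multi", "em_banded_fit"))
}
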