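#' Sweep the hyperprior scalar gamma and score held-out predictions
#'
#' Fits one EM-banded model per gamma value on a training split and scores
#' point predictions on the held-out remainder. Small gamma means broad
#' hyperpriors (aggressive shrinkage allowed); the sweep makes the trade-off
#' visible and supports choosing gamma by held-out accuracy when desired.
#' The split is contiguous (last fraction held out), respecting serial
#' dependence in time-series designs.
#'
#' @param design A \code{grouped_design}.
#' @param y Numeric target vector.
#' @param gammas Positive gamma values to evaluate.
#' @param holdout_fraction Fraction of rows (from the end) held out.
#' @param metric \code{"pearson"} or \code{"mse"}.
#' @param h,max_iter,tol Passed to \code{\link{fit_em}}.
#' @return List with \code{table} (data frame: gamma, score, nu, n_iter,
#'   converged) and \code{fits} (one \code{em_banded} per gamma).
#' @export
sweep_gamma <- function(design, y, gammas = 10^(-6:-1),
                        holdout_fraction = 0.25, metric = c("pearson", "mse"),
                        h = NULL, max_iter = 200L, tol = 1e-8) {
  metric <- match.arg(metric)
  stopifnot(inherits(design, "grouped_design"),
            holdout_fraction > 0, holdout_fraction < 1,
            all(gammas > 0))
  M <- design$M
  n_test <- max(1L, floor(M * holdout_fraction))
  test <- seq.int(M - n_test + 1L, M)
  train <- seq_len(M - n_test)
  gd_train <- design
  gd_train$X <- design$X[train, , drop = FALSE]
  gd_train$M <- length(train)
  X_test <- design$X[test, , drop = FALSE]
  fits <- vector("list", length(gammas))
  tab <- data.frame(gamma = as.numeric(gammas), score = NA_real_,
                    nu = NA_real_, n_iter = NA_integer_, converged = NA)
  for (i in seq_along(gammas)) {
    fit <- fit_em(gd_train, y[train], hyper = hyperpriors(gamma = gammas[i]),
                  h = h, max_iter = max_iter, tol = tol)
    pred <- predict(fit, X_test)
    tab$score[i] <- if (metric == "pearson") stats::cor(y[test], pred)
                    else mean((y[test] - pred)^2)
    tab$nu[i] <- fit$nu
    tab$n_iter[i] <- fit$n_iter
    tab$converged[i] <- fit$converged
    fits[[i]] <- fit
  }
  list(table = tab, fits = fits, metric = metric)
}
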