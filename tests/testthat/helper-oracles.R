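# Independent oracles used across tests. These re-derive quantities from the
# model definition directly (dense matrices, textbook formulas, 1-D numerical
# optimization) and never call the package's solver internals.

# Expected complete-data objective: the function whose coordinate-wise
# maximizers the closed-form hyperparameter updates must reproduce. Written
# from the model's joint log-density with the weight posterior moments held
# fixed; supports multi-target Y (summed over columns, one set of priors).
ecd_objective <- function(lambdas, nu, X, Y, mu, Sigma, groups, omegas_inv,
                          hyper) {
  Y <- as.matrix(Y); mu <- as.matrix(mu)
  M <- nrow(X); Tt <- ncol(Y)
  XtX <- crossprod(X)
  rss <- sum((Y - X %*% mu)^2)
  val <- -(rss + Tt * sum(XtX * Sigma)) / (2 * nu) - Tt * M / 2 * log(nu)
  for (j in seq_len(nrow(groups))) {
    idx <- seq.int(groups$start[j], groups$end[j])
    Oinv <- omegas_inv[[j]]
    mu_j <- mu[idx, , drop = FALSE]
    quad <- sum(mu_j * (Oinv %*% mu_j)) + Tt * sum(Oinv * Sigma[idx, idx])
    val <- val - quad / (2 * lambdas[j]) -
      (Tt * length(idx) / 2 + 1 + hyper$eta) * log(lambdas[j]) -
      hyper$tau / lambdas[j]
  }
  val - (1 + hyper$phi) * log(nu) - hyper$kappa / nu
}

# 1-D numerical maximizer of the expected complete-data objective in one
# lambda_j (or in nu), everything else fixed.
numeric_mstep_lambda <- function(j, lambdas, nu, X, Y, mu, Sigma, groups,
                                 omegas_inv, hyper, guess) {
  f <- function(l) {
    ll <- lambdas; ll[j] <- l
    ecd_objective(ll, nu, X, Y, mu, Sigma, groups, omegas_inv, hyper)
  }
  stats::optimize(f, interval = c(guess * 1e-3, guess * 1e3), maximum = TRUE,
                  tol = guess * 1e-9)$maximum
}

numeric_mstep_nu <- function(lambdas, nu_guess, X, Y, mu, Sigma, groups,
                             omegas_inv, hyper) {
  f <- function(v) ecd_objective(lambdas, v, X, Y, mu, Sigma, groups,
                                 omegas_inv, hyper)
  stats::optimize(f, interval = c(nu_guess * 1e-3, nu_guess * 1e3),
                  maximum = TRUE, tol = nu_guess * 1e-9)$maximum
}

# Random small grouped-regression instance (centered), with the posterior at
# given hyperparameters computed by dense textbook linear algebra.
random_instance <- function(seed, M = NULL, J = NULL, n_targets = 1L) {
  set.seed(seed)
  if (is.null(M)) M <- sample(8:64, 1)
  if (is.null(J)) J <- sample(1:4, 1)
  sizes <- sample(1:4, J, replace = TRUE)
  blocks <- lapply(sizes, function(d) matrix(rnorm(M * d), M, d))
  names(blocks) <- paste0("g", seq_len(J))
  gd <- make_grouped_design(blocks)
  w <- rnorm(gd$D)
  Y <- gd$X %*% w %*% t(rep(1, n_targets)) +
    matrix(rnorm(M * n_targets), M, n_targets)
  Y <- scale(Y, scale = FALSE)
  gd$X <- scale(gd$X, scale = FALSE)
  attr(gd$X, "scaled:center") <- NULL
  attr(Y, "scaled:center") <- NULL
  list(design = gd, Y = Y, y = drop(Y[, 1]))
}

# Dense-textbook posterior at fixed (lambda, nu): explicit inverses.
dense_posterior <- function(design, Y, lambdas, nu, omegas = NULL) {
  D <- design$D
  Lam <- matrix(0, D, D)
  for (j in seq_len(nrow(design$groups))) {
    idx <- group_columns(design, j)
    Om <- if (is.null(omegas)) diag(1, length(idx)) else omegas[[j]]
    Lam[idx, idx] <- lambdas[j] * Om
  }
  Sigma <- solve(solve(Lam) + crossprod(design$X) / nu)
  mu <- Sigma %*% crossprod(design$X, as.matrix(Y)) / nu
  list(mu = mu, Sigma = Sigma, Lambda = Lam)
}
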