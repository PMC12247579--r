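test_that("closed-form M-step matches numerical maximization of the bound", {
  hp <- hyperpriors(gamma = 1e-3)
  for (seed in 1:8) {
    inst <- random_instance(seed)
    gd <- inst$design
    J <- nrow(gd$groups)
    lam <- runif(J, 0.2, 3)
    nu <- runif(1, 0.5, 2)
    pr <- prior_state(gd, lam)
    post <- posterior_update(gd, inst$y, pr, nu)
    Oinv <- pr$omega_inv
    for (j in seq_len(J)) {
      closed <- update_lambda(post, pr, hp, j)
      numeric <- numeric_mstep_lambda(j, lam, nu, gd$X, inst$y, post$mu,
                                      post$Sigma, gd$groups, Oinv, hp,
                                      guess = closed)
      expect_equal(closed, numeric, tolerance = 1e-5)
    }
    closed_nu <- update_nu(gd, inst$y, post, hp)
    numeric_nu <- numeric_mstep_nu(lam, closed_nu, gd$X, inst$y, post$mu,
                                   post$Sigma, gd$groups, Oinv, hp)
    expect_equal(closed_nu, numeric_nu, tolerance = 1e-5)
  }
})

test_that("the EM objective never decreases across iterations", {
  for (seed in 1:20) {
    inst <- random_instance(seed)
    fit <- fit_em(inst$design, inst$y, hyperpriors(gamma = 10^runif(1, -4, -1)),
                  max_iter = 60, center = FALSE)
    tr <- fit$objective_trace
    expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-1]))),
                label = sprintf("monotone trace (seed %d)", seed))
    expect_true(all(fit$lambda_trace > 0))
    expect_true(all(fit$nu_trace > 0))
    expect_lte(fit$n_iter, 60)
  }
})

test_that("recorded objective equals an independent evaluation at the iterates", {
  inst <- random_instance(3)
  hp <- hyperpriors(gamma = 1e-2)
  fit <- fit_em(inst$design, inst$y, hp, max_iter = 5, tol = 1e-14,
                center = FALSE)
  for (k in seq_along(fit$objective_trace)) {
    pr <- prior_state(inst$design, fit$lambda_trace[k, ])
    expect_equal(fit$objective_trace[k],
                 log_marginal_objective(inst$design, inst$y, pr,
                                        fit$nu_trace[k], hp, route = "direct"),
                 tolerance = 1e-8)
  }
})

test_that("hyperparameters respect their Inverse-Gamma lower bounds", {
  hp <- hyperpriors(eta = 0.5, tau = 0.3, phi = 0.2, kappa = 0.4)
  for (seed in c(2, 9)) {
    inst <- random_instance(seed)
    fit <- fit_em(inst$design, inst$y, hp, max_iter = 40)
    sizes <- inst$design$groups$size
    expect_true(all(fit$lambdas >= 2 * hp$tau / (sizes + 2 * hp$eta + 2) - 1e-12))
    expect_gte(fit$nu, 2 * hp$kappa / (inst$design$M + 2 + 2 * hp$phi) - 1e-12)
  }
  # zero target: weights vanish and the scales settle just above their
  # prior-driven floors (the posterior-trace term keeps them slightly off)
  gd <- make_grouped_design(list(a = matrix(rnorm(30), 10, 3)))
  fit0 <- fit_em(gd, rep(0, 10), hp, max_iter = 300)
  floor_lam <- 2 * hp$tau / (3 + 2 * hp$eta + 2)
  expect_lt(max(abs(fit0$weights)), 1e-6)
  expect_true(fit0$converged)
  expect_gte(unname(fit0$lambdas), floor_lam)
  expect_lt(unname(fit0$lambdas), 2 * floor_lam)
  expect_gte(fit0$nu, 2 * hp$kappa / (10 + 2 + 2 * hp$phi))
})

test_that("permuting group order permutes estimates without changing values", {
  set.seed(21)
  A <- matrix(rnorm(40 * 3), 40, 3)
  B <- matrix(rnorm(40 * 5), 40, 5)
  w <- c(rnorm(3), rep(0, 5))
  y <- cbind(A, B) %*% w + rnorm(40)
  f1 <- fit_em(make_grouped_design(list(A = A, B = B)), y, max_iter = 50)
  f2 <- fit_em(make_grouped_design(list(B = B, A = A)), y, max_iter = 50)
  expect_equal(f1$lambdas[c("A", "B")], f2$lambdas[c("A", "B")],
               tolerance = 1e-10)
  expect_equal(f1$nu, f2$nu, tolerance = 1e-10)
  expect_equal(f1$weights[1:3], f2$weights[6:8], tolerance = 1e-10)
  expect_equal(f1$weights[4:8], f2$weights[1:5], tolerance = 1e-10)
})

test_that("pinned hyperparameters reproduce the Ridge solution", {
  set.seed(5)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- X %*% rnorm(6) + rnorm(30)
  lam <- 0.5; nu <- 2         # alpha = nu / lambda = 4
  # pin via concentrated Inverse-Gamma hyperpriors (mode at the target value)
  K <- 1e12
  hp <- hyperpriors(eta = K, tau = lam * K, phi = K, kappa = nu * K)
  fit <- fit_em(X, y, hp, max_iter = 50)
  rr <- ridge_fit(X, y, alpha = nu / lam)
  expect_equal(fit$weights, rr$weights, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("predictions follow the fitted posterior and carry sane variances", {
  set.seed(8)
  gd <- make_grouped_design(list(g = matrix(rnorm(60), 20, 3)))
  y <- gd$X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.3)
  fit <- fit_em(gd, y)
  # training-row point prediction is X mu (plus centering offsets)
  Xc <- sweep(gd$X, 2, fit$x_means)
  expect_equal(predict(fit, gd$X), drop(Xc %*% fit$weights) + fit$y_means,
               tolerance = 1e-12)
  dist <- predict(fit, gd$X[1:4, ], type = "distribution")
  expect_equal(dist$cov, t(dist$cov), tolerance = 1e-10)
  expect_true(all(diag(dist$cov) >= fit$nu - 1e-10))
  # a row at the training mean predicts the target mean, variance nu + x S x'
  x0 <- matrix(fit$x_means, 1)
  d0 <- predict(fit, x0, type = "distribution")
  expect_equal(drop(d0$mean), unname(fit$y_means))
  expect_equal(drop(d0$cov), fit$nu, tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 2, 5)), "expects")
})

test_that("a mid-fit numerical failure names the offending quantity", {
  gd <- make_grouped_design(list(g = matrix(c(1, 0, 0, 1), 2, 2)))
  expect_error(fit_em(gd, c(1e200, -1e200), center = FALSE, max_iter = 5),
               "iteration|finite")
})
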