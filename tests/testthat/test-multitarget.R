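test_that("a single-column multi-target fit reproduces the single-target fit", {
  inst <- random_instance(13)
  f1 <- fit_em(inst$design, inst$y, hyperpriors(gamma = 1e-3), max_iter = 40)
  fm <- fit_em_shared(inst$design, matrix(inst$y, ncol = 1),
                      hyperpriors(gamma = 1e-3), max_iter = 40)
  expect_identical(unname(f1$lambdas), unname(fm$lambdas))
  expect_identical(f1$nu, fm$nu)
  expect_identical(f1$weights, drop(fm$weights))
  expect_identical(f1$objective_trace, fm$objective_trace)
})

test_that("duplicating the target column leaves shared scales almost unchanged", {
  # the duplicated-target fit matches the single-target fit up to the
  # prior-normalization term in the update denominators (T D_j + 2 eta + 2
  # versus D_j + 2 eta + 2), an O(1/D_j) effect — so compare at sizeable D_j
  set.seed(17)
  M <- 200
  gd <- make_grouped_design(list(a = matrix(rnorm(M * 32), M, 32),
                                 b = matrix(rnorm(M * 32), M, 32)))
  w <- c(rnorm(32), rnorm(32, sd = 0.2))
  y <- drop(gd$X %*% w + rnorm(M))
  hp <- hyperpriors(gamma = 1e-10)
  f1 <- fit_em_shared(gd, matrix(y, ncol = 1), hp, max_iter = 80)
  f2 <- fit_em_shared(gd, cbind(y, y), hp, max_iter = 80)
  expect_equal(unname(f2$lambdas), unname(f1$lambdas), tolerance = 0.05)
  expect_equal(f2$nu, f1$nu, tolerance = 0.05)
  expect_equal(f2$weights[, 1], f2$weights[, 2])
})

test_that("shared M-step matches numerical maximization of the summed bound", {
  hp <- hyperpriors(gamma = 1e-2)
  for (seed in c(4, 11, 23)) {
    inst <- random_instance(seed, n_targets = 3)
    gd <- inst$design
    J <- nrow(gd$groups)
    set.seed(seed + 100)
    lam <- runif(J, 0.2, 3); nu <- runif(1, 0.5, 2)
    pr <- prior_state(gd, lam)
    st <- bandedem:::engine_estep(gd$X, inst$Y, gd$groups, pr, nu, "direct",
                                  crossprod(gd$X), crossprod(gd$X, inst$Y))
    Tt <- ncol(inst$Y)
    for (j in seq_len(J)) {
      idx <- group_columns(gd, j)
      Oinv <- pr$omega_inv[[j]]
      mu_j <- st$mu[idx, , drop = FALSE]
      closed <- (sum(mu_j * (Oinv %*% mu_j)) +
                   Tt * sum(Oinv * st$Sigma[idx, idx]) + 2 * hp$tau) /
        (Tt * length(idx) + 2 * hp$eta + 2)
      numeric <- numeric_mstep_lambda(j, lam, nu, gd$X, inst$Y, st$mu,
                                      st$Sigma, gd$groups, pr$omega_inv, hp,
                                      guess = closed)
      expect_equal(closed, numeric, tolerance = 1e-5)
    }
    closed_nu <- (sum((inst$Y - gd$X %*% st$mu)^2) +
                    Tt * sum(crossprod(gd$X) * st$Sigma) + 2 * hp$kappa) /
      (Tt * gd$M + 2 + 2 * hp$phi)
    numeric_nu <- numeric_mstep_nu(lam, closed_nu, gd$X, inst$Y, st$mu,
                                   st$Sigma, gd$groups, pr$omega_inv, hp)
    expect_equal(closed_nu, numeric_nu, tolerance = 1e-5)
  }
})

test_that("one covariance factorization per iteration regardless of T", {
  inst <- random_instance(31, n_targets = 6)
  fA <- fit_em_shared(inst$design, inst$Y[, 1, drop = FALSE],
                      max_iter = 12, tol = 1e-16)
  fB <- fit_em_shared(inst$design, inst$Y, max_iter = 12, tol = 1e-16)
  expect_identical(fA$n_factorizations, fB$n_factorizations)
  expect_identical(fB$n_factorizations, fB$n_iter + 1L)
  # shared objective is monotone too
  tr <- fB$objective_trace
  expect_true(all(diff(tr) >= -1e-8 * (1 + abs(tr[-1]))))
})

test_that("pooling independent targets sharpens the shared scale estimates", {
  # targets drawn from one weight prior: the pooled fit should recover the
  # group scales with smaller squared log-error than single-target fits
  set.seed(55)
  M <- 200; sizes <- c(6, 6); true_lam <- c(4, 0.05); true_nu <- 1; Tt <- 8
  blocks <- lapply(sizes, function(d) matrix(rnorm(M * d), M, d))
  names(blocks) <- c("big", "small")
  gd <- make_grouped_design(blocks)
  W <- rbind(matrix(rnorm(sizes[1] * Tt, sd = sqrt(true_lam[1])), sizes[1]),
             matrix(rnorm(sizes[2] * Tt, sd = sqrt(true_lam[2])), sizes[2]))
  Y <- gd$X %*% W + matrix(rnorm(M * Tt, sd = sqrt(true_nu)), M)
  hp <- hyperpriors(gamma = 1e-6)
  shared <- fit_em_shared(gd, Y, hp, max_iter = 100)
  err_shared <- sum((log(shared$lambdas) - log(true_lam))^2)
  err_single <- sapply(seq_len(Tt), function(t)
    sum((log(fit_em(gd, Y[, t], hp, max_iter = 100)$lambdas) -
           log(true_lam))^2))
  # pooling T targets must beat the typical single-target fit decisively
  # (individual single fits can occasionally get lucky on one draw)
  expect_lt(err_shared, median(err_single))
  expect_lt(err_shared, mean(err_single))
})
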