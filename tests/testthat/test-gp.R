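test_that("a noise-free GP interpolates its training data", {
  X <- matrix(seq(0, 1, length.out = 8))
  y <- sin(2 * pi * X[, 1]) + 0.3 * X[, 1]
  fit <- gp_fit(X, y, noise_floor = 1e-8, seed = 1)
  p <- predict(fit, X, native = TRUE)
  expect_lt(max(abs(p$mean - y)), 1e-6 * diff(range(y)))
  expect_lt(max(p$sd), 1e-3)
})

test_that("posterior matches an independent dense-solve oracle at fixed hyperparameters", {
  set.seed(3)
  X <- matrix(runif(12), ncol = 2)
  y <- X[, 1]^2 - X[, 2]
  fit <- gp_fit(X, y, bounds = rbind(c(0, 0), c(1, 1)), transform = "none",
                noise_floor = 1e-6, optimize_noise = FALSE, seed = 1)
  Xnew <- matrix(runif(10), ncol = 2)
  p <- predict(fit, Xnew)
  # oracle conditions on the centred response with the fitted hyperparameters
  orc <- gp_posterior_oracle(X, y - fit$mean_t, Xnew,
                             ell = fit$lengthscales,
                             s2 = fit$signal_variance,
                             noise = fit$noise_variance + 1e-12 * fit$signal_variance)
  expect_equal(p$mean, orc$mean + fit$mean_t, tolerance = 1e-8)
  expect_equal(p$sd, orc$sd, tolerance = 1e-6)
})

test_that("constant responses give a constant mean and near-zero sd at data", {
  X <- matrix(seq(0, 1, length.out = 5))
  fit <- gp_fit(X, rep(4.2, 5), seed = 1)
  p <- predict(fit, matrix(c(0.1, 0.55, 0.99)), native = TRUE)
  expect_equal(p$mean, rep(4.2, 3), tolerance = 1e-6)
  ptr <- predict(fit, X, native = TRUE)
  expect_lt(max(ptr$sd), 1e-2)
})

test_that("far from all data the posterior reverts to the prior", {
  X <- matrix(seq(0, 0.05, length.out = 5))
  y <- c(1, 2, 1.5, 1.2, 1.8)
  fit <- gp_fit(X, y, bounds = rbind(0, 1), transform = "none", seed = 1)
  p <- predict(fit, matrix(1e3))
  expect_equal(p$mean, fit$mean_t, tolerance = 1e-6)
  expect_equal(p$sd, sqrt(fit$signal_variance), tolerance = 1e-6)
})

test_that("GP recovers a known lengthscale within a factor of two (median of 20 sims)", {
  ell_true <- 0.3
  n <- 40
  X <- matrix(seq(0, 1, length.out = n))
  r <- as.matrix(dist(X / ell_true))
  K <- (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r) + diag(1e-8, n)
  L <- chol(K)
  rec <- vapply(1:20, function(i) {
    set.seed(1000 + i)
    y <- drop(t(L) %*% rnorm(n))
    gp_fit(X, y, bounds = rbind(0, 1), seed = i)$lengthscales[1]
  }, 0)
  expect_gt(median(rec), ell_true / 2)
  expect_lt(median(rec), ell_true * 2)
})

test_that("GP beats the constant-mean baseline on a held-out sine grid", {
  set.seed(11)
  Xtr <- matrix(runif(15))
  ytr <- sin(2 * pi * Xtr[, 1])
  fit <- gp_fit(Xtr, ytr, bounds = rbind(0, 1), seed = 2)
  Xte <- matrix(seq(0.01, 0.99, length.out = 50))
  yte <- sin(2 * pi * Xte[, 1])
  p <- predict(fit, Xte, native = TRUE)
  mse_gp <- mean((p$mean - yte)^2)
  mse_const <- mean((mean(ytr) - yte)^2)
  expect_lt(mse_gp, mse_const)
})

test_that("adding an observation at a point never increases sigma there", {
  set.seed(5)
  X <- matrix(runif(10))
  y <- cos(3 * X[, 1])
  xstar <- 0.42
  fit1 <- gp_fit(X, y, bounds = rbind(0, 1), transform = "none",
                 optimize_noise = FALSE, seed = 3)
  s1 <- predict(fit1, matrix(xstar))$sd
  # condition on the extended set at the same hyperparameters
  fit2 <- gp_update(fit1, rbind(X, xstar), c(y, cos(3 * xstar)))
  s2 <- predict(fit2, matrix(xstar))$sd
  expect_lte(s2, s1 + 1e-12)
  expect_lt(s2, 1e-2)
})

test_that("output transforms round-trip and max10 scales measured values to 10", {
  y <- c(1573, 3289, 812)
  for (type in c("zscore", "max10", "none")) {
    tr <- reactbo:::make_transform(type, y)
    expect_equal(reactbo:::untransform_y(tr, reactbo:::transform_y(tr, y)), y,
                 tolerance = 1e-10)
  }
  tr <- reactbo:::make_transform("max10", y)
  expect_equal(max(reactbo:::transform_y(tr, y)), 10)
})

test_that("fits are deterministic for a fixed seed and differ only via data", {
  set.seed(8)
  X <- matrix(runif(14), ncol = 2)
  y <- X[, 1] - X[, 2]^2
  f1 <- gp_fit(X, y, seed = 9)
  f2 <- gp_fit(X, y, seed = 9)
  expect_identical(coef(f1), coef(f2))
})

test_that("degenerate inputs are rejected with instructive errors", {
  X <- matrix(c(0, 0, 1), ncol = 1)
  expect_error(gp_fit(X, c(1, 2, 3), noise_floor = 0),
               class = "reactbo_conflicting_duplicates")
  expect_silent(gp_fit(X, c(1, 2, 3), noise_floor = 1e-4, seed = 1))
  expect_error(gp_fit(matrix(1), 1), class = "reactbo_bad_fit")
  expect_error(gp_fit(matrix(c(0, 1)), c(1, NA)), class = "reactbo_nonfinite")
})

test_that("believer records carry the exact predictive mean and shrink sigma on refit", {
  sp <- space_2d(gp = 4L)
  g <- build_grid(sp)
  set.seed(2)
  idx <- sample(nrow(g$points), 6)
  led <- measured_ledger(sp, g$points[idx, ], rowSums(g$points[idx, ]))
  fit <- fit_fom_gp(led, sp, seed = 4)
  xstar <- g$points[1, ]
  bel <- apply_believer(fit, xstar)
  expect_equal(bel$fom, predict(fit, matrix(xstar, nrow = 1), native = TRUE)$mean[1],
               tolerance = 1e-12)
  expect_identical(bel$source, "believer")
  led2 <- ledger_append(led, matrix(xstar, nrow = 1),
                        stats::setNames(list(bel$fom), "TON"),
                        iteration = 0L, source = "believer")
  fit2 <- fit_fom_gp(led2, sp, seed = 4)
  expect_lt(predict(fit2, matrix(xstar, nrow = 1))$sd, 1e-2)
})

test_that("believer rows never shift the max10 transform", {
  sp <- space_2d(gp = 4L)
  g <- build_grid(sp)
  led <- measured_ledger(sp, g$points[c(1, 6, 11), ], c(100, 400, 250))
  led <- ledger_append(led, g$points[16, , drop = FALSE],
                       list(TON = 900),  # believer above the measured max
                       iteration = 0L, source = "believer")
  fit <- fit_fom_gp(led, sp, transform = "max10", seed = 1)
  expect_equal(fit$transform$scale, 400 / 10)
})
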