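test_that("expected improvement handles the degenerate and tail regimes exactly", {
  # no uncertainty, no improvement
  expect_equal(expected_improvement(1, 0, 1, xi = 0.01), 0)
  # sigma = 0 branch is the closed-form limit
  expect_equal(expected_improvement(2, 0, 1, xi = 0.01), 0.99)
  # limit agreement as sigma -> 0+
  expect_equal(expected_improvement(2, 1e-12, 1, xi = 0.01), 0.99, tolerance = 1e-9)
  expect_equal(expected_improvement(0.5, 1e-12, 1, xi = 0.01), 0)
  # deep-tail value stays positive and matches the high-precision evaluation
  v <- expected_improvement(0, 1, 10, xi = 0)
  expect_gt(v, 0)
  expect_lt(v, 1e-20)
  expect_equal(v, stats::dnorm(10) - 10 * stats::pnorm(-10), tolerance = 1e-6)
})

test_that("expected improvement agrees with a Monte-Carlo estimate", {
  set.seed(101)
  draws <- rnorm(1e5)
  for (mu in c(-1, 0, 1)) for (sig in c(0.3, 1, 2)) {
    y <- pmax(mu + sig * draws - 0 - 0.01, 0)
    mc <- mean(y)
    se <- sd(y) / sqrt(length(y))
    expect_lt(abs(expected_improvement(mu, sig, 0, 0.01) - mc), 3 * se + 1e-12)
  }
})

test_that("EI is monotone in mu and, below the incumbent, in sigma", {
  mus <- seq(-3, 3, length.out = 25)
  expect_true(all(diff(expected_improvement(mus, 1, 0, 0.01)) >= 0))
  sigmas <- seq(0, 3, length.out = 25)
  v <- expected_improvement(-0.5, sigmas, 0, 0.01)  # mu <= f_best + xi
  expect_true(all(diff(v) >= 0))
  expect_true(all(expected_improvement(rnorm(50), abs(rnorm(50)), 0) >= 0))
})

test_that("the variance-squared acquisition is EI evaluated at sigma squared", {
  set.seed(7)
  for (i in 1:200) {
    mu <- rnorm(1, 5, 3); sig <- runif(1, 0, 4); fb <- rnorm(1, 5, 3)
    expect_equal(boa2_acquisition(mu, sig, fb, 0.01),
                 expected_improvement(mu, sig^2, fb, 0.01), tolerance = 1e-12)
  }
  # sigma = 1 is the fixed point; sigma = 2 at the incumbent doubles the density term
  expect_equal(boa2_acquisition(3, 1, 0), expected_improvement(3, 1, 0))
  expect_equal(boa2_acquisition(0, 2, 0, xi = 0),
               expected_improvement(0, 4, 0, xi = 0))
  expect_equal(expected_improvement(0, 4, 0, xi = 0), 4 * dnorm(0))
  # below unit sigma the variant is more exploitative than plain EI
  expect_lt(boa2_acquisition(-1, 0.5, 0, 0.01),
            expected_improvement(-1, 0.5, 0, 0.01))
})

test_that("the constrained factor is a probability: 0.5 at threshold, bounded by EI", {
  expect_equal(constrained_acquisition(2, mu2 = 70, sigma2 = 5, threshold = 70), 1)
  expect_equal(constrained_acquisition(2, mu2 = 75, sigma2 = 5, threshold = 70),
               2 * pnorm(1), tolerance = 1e-12)
  expect_equal(constrained_acquisition(1, mu2 = 120, sigma2 = 5, threshold = 70), 1,
               tolerance = 1e-9)
  set.seed(21)
  for (i in 1:200) {
    ei <- runif(1, 0, 5); mu2 <- rnorm(1, 70, 20); s2 <- runif(1, 0.1, 10)
    v <- constrained_acquisition(ei, mu2, s2, 70)
    expect_gte(v, 0); expect_lte(v, ei)
  }
  # sigma2 = 0 limit: step with 0.5 at equality
  expect_equal(constrained_acquisition(3, 80, 0, 70), 3)
  expect_equal(constrained_acquisition(3, 60, 0, 70), 0)
  expect_equal(constrained_acquisition(3, 70, 0, 70), 1.5)
})

test_that("constrained factor matches a Monte-Carlo feasibility probability", {
  set.seed(31)
  y <- rnorm(1e5, 75, 5)
  mc <- 2 * mean(y > 70)
  se <- 2 * sd(y > 70) / sqrt(length(y))
  expect_lt(abs(constrained_acquisition(2, 75, 5, 70) - mc), 3 * se)
})

test_that("max-10 scaling fixes the maximum at 10 and round-trips", {
  s <- scale_fom_max10(c(1573, 3289))
  expect_equal(max(s$scaled), 10)
  expect_equal(s$scaled[2], 10)
  expect_equal(s$scaled * s$factor, c(1573, 3289), tolerance = 1e-12)
  expect_equal(scale_fom_max10(10)$scaled, 10)
  expect_error(scale_fom_max10(c(-5, 0)), class = "reactbo_bad_input")
})

test_that("candidate scoring matches a brute-force per-point scorer", {
  sp <- space_2d(gp = 6L)
  g <- build_grid(sp)
  set.seed(12)
  idx <- sample(nrow(g$points), 8)
  led <- measured_ledger(sp, g$points[idx, ],
                         rowSums(g$points[idx, ]) + rnorm(8, 0, 0.1))
  for (strat in c("conventional", "boa2")) {
    cfg <- acquisition_config(strat, batch_size = 1L)
    fit <- fit_fom_gp(led, sp, transform = reactbo:::strategy_transform(strat),
                      seed = 5)
    fb <- max(reactbo:::transform_y(fit$transform, led$TON))
    sc <- score_candidates(fit, g, cfg, fb)
    pr <- predict(fit, g$points)
    brute <- vapply(seq_len(nrow(g$points)), function(i) {
      if (strat == "boa2") boa2_acquisition(pr$mean[i], pr$sd[i], fb, cfg$xi)
      else expected_improvement(pr$mean[i], pr$sd[i], fb, cfg$xi)
    }, 0)
    expect_equal(sc$scores, brute, tolerance = 1e-12)
    expect_equal(sc$argmax, which.max(brute))
  }
})

test_that("identical candidates tie and an infeasible second FoM zeroes all scores", {
  sp <- space_2d(gp = 4L)
  g <- build_grid(sp)
  set.seed(14)
  idx <- sample(nrow(g$points), 6)
  led <- measured_ledger(sp, g$points[idx, ], runif(6))
  fit <- fit_fom_gp(led, sp, seed = 2)
  fb <- max(reactbo:::transform_y(fit$transform, led$TON))
  same <- g
  same$points <- g$points[rep(1, 5), , drop = FALSE]
  sc <- score_candidates(fit, same, acquisition_config("conventional"), fb)
  expect_true(sc$tie)
  expect_equal(sc$argmax, 1L)
  expect_equal(length(unique(sc$scores)), 1L)
  # second FoM predicted far below threshold everywhere -> scores ~ 0
  led2 <- measured_ledger(sp, g$points[idx, ], runif(6), fom = "sel")
  fit2 <- fit_fom_gp(led2, sp, fom = "sel", transform = "zscore", seed = 2)
  cfg <- acquisition_config("conventional", fom2_threshold = 1e4)
  sc2 <- score_candidates(fit, g, cfg, fb, fit2 = fit2)
  expect_true(all(sc2$scores < 1e-8))
})
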