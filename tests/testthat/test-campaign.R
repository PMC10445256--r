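quad_oracle <- function(point) {
  # smooth deterministic single-peak surface over space_2d coordinates
  list(TON = 100 * exp(-((point[["a"]] - 0.6)^2 / 0.1 +
                           (point[["b"]] - 7)^2 / 8)))
}

test_that("initial designs are reproducible, feasible and correctly tagged", {
  sp <- space_constrained()
  cfg <- campaign_config(n_initial = 5L, seed = 3L)
  led1 <- init_campaign(sp, cfg)
  led2 <- init_campaign(sp, cfg)
  expect_identical(led1, led2)
  expect_equal(nrow(led1), 5L)
  expect_true(all(led1$source == "proposed"))
  expect_true(all(is.na(led1$TON)))
  expect_true(all(is_feasible(as.matrix(led1[, 1:3]), sp)))
})

test_that("ledger files refuse silent overwrites and round-trip through CSV", {
  sp <- space_2d()
  cfg <- campaign_config(seed = 5L)
  path <- tempfile(fileext = ".csv")
  led <- init_campaign(sp, cfg, path = path)
  expect_error(init_campaign(sp, cfg, path = path), class = "reactbo_ledger_exists")
  led <- record_measurements(led, list(TON = c(5, 9, 2, 7, 4)))
  write_ledger(led, path, force = TRUE)
  back <- read_ledger(path)
  expect_equal(back$TON, led$TON)
  expect_equal(back$source, led$source)
  expect_equal(back[, 1:2], led[, 1:2], ignore_attr = TRUE)
})

test_that("a zero-iteration campaign contains only the initial design", {
  sp <- space_2d()
  cfg <- campaign_config(n_iterations = 0L, seed = 2L)
  camp <- run_closed_loop(sp, quad_oracle, cfg)
  expect_equal(length(camp$iterations), 0L)
  expect_equal(nrow(camp$ledger), cfg$n_initial)
  expect_equal(length(camp$best_so_far), 1L)
})

test_that("budget accounting and monotone best-so-far hold on a noise-free oracle", {
  sp <- space_2d(gp = 7L)
  cfg <- campaign_config(n_initial = 4L, batch_size = 3L, n_iterations = 2L,
                         strategy = "conventional", seed = 7L)
  camp <- run_closed_loop(sp, quad_oracle, cfg)
  expect_equal(sum(camp$ledger$source == "measured"), 4L + 2L * 3L)
  expect_true(all(diff(camp$best_so_far) >= 0))
  expect_gte(max(camp$best_so_far), camp$best_so_far[1])
  s <- summary(camp)
  expect_equal(nrow(s$trajectory), 3L)
  expect_equal(s$trajectory$best_so_far, camp$best_so_far)
})

test_that("replay with an identical config reproduces the history exactly", {
  sp <- space_2d(gp = 6L)
  noisy_oracle <- function(point)
    list(TON = quad_oracle(point)$TON * stats::rlnorm(1, 0, 0.05))
  cfg <- campaign_config(n_initial = 4L, batch_size = 2L, n_iterations = 2L,
                         strategy = "boa1", seed = 11L)
  c1 <- run_closed_loop(sp, noisy_oracle, cfg)
  c2 <- run_closed_loop(sp, noisy_oracle, cfg)
  expect_identical(c1$ledger, c2$ledger)
  expect_identical(c1$best_so_far, c2$best_so_far)
})

test_that("the stop target halts the loop before the full budget", {
  sp <- space_2d(gp = 7L)
  cfg <- campaign_config(n_initial = 4L, batch_size = 3L, n_iterations = 5L,
                         seed = 13L, stop_target = 50)
  camp <- run_closed_loop(sp, quad_oracle, cfg)
  expect_lt(length(camp$iterations), 5L)
  best <- max(camp$ledger$TON[camp$ledger$source == "measured"])
  expect_gte(best, 50)
  # no proposals exist after the stopping iteration
  expect_equal(max(camp$ledger$iteration), length(camp$iterations))
})

test_that("a non-finite oracle value names the offending condition", {
  sp <- space_2d()
  bad <- function(point) list(TON = NaN)
  cfg <- campaign_config(n_iterations = 0L, seed = 1L)
  expect_error(run_closed_loop(sp, bad, cfg), class = "reactbo_bad_oracle")
})

test_that("best_observed filters on the second FoM and breaks ties early", {
  sp <- space_2d()
  led <- new_ledger(sp, fom = "TON", fom2 = "sel")
  led <- ledger_append(led, matrix(c(0.1, 1, 0.2, 2), 2, byrow = TRUE),
                       list(TON = c(1426, 5441), sel = c(94, 90.5)),
                       iteration = 0L, source = "measured")
  expect_equal(best_observed(led)$TON, 5441)
  expect_equal(best_observed(led, fom2_threshold = 70)$TON, 5441)
  expect_equal(best_observed(led, fom2_threshold = 92)$TON, 1426)
  expect_equal(nrow(best_observed(led, fom2_threshold = 95)), 0L)
  # tie on TON: earliest row wins
  led2 <- ledger_append(led, matrix(c(0.3, 3), 1), list(TON = 5441, sel = 80),
                        iteration = 1L, source = "measured")
  expect_equal(rownames(best_observed(led2)), "2")
  # single measured row is returned as-is
  led3 <- ledger_append(new_ledger(sp), matrix(c(0.5, 5), 1), list(TON = 10),
                        iteration = 0L, source = "measured")
  expect_equal(best_observed(led3)$TON, 10)
})

test_that("the strategy benchmark returns equal-budget trajectories", {
  sp <- space_2d(gp = 6L)
  cfg <- campaign_config(n_initial = 3L, batch_size = 2L, n_iterations = 1L)
  bench <- benchmark_strategies(sp, quad_oracle,
                                strategies = c("conventional", "random", "rsm"),
                                n_seeds = 2L, config = cfg, seed0 = 100L)
  expect_setequal(unique(bench$strategy), c("conventional", "random", "rsm"))
  bo <- bench[bench$strategy == "conventional" & bench$seed == 101, ]
  expect_equal(bo$n_measured, c(3L, 5L))
  rnd <- bench[bench$strategy == "random" & bench$seed == 101, ]
  expect_equal(rnd$n_measured, c(3L, 5L))
  expect_true(all(diff(bo$best_so_far) >= 0))
  # rsm: one-shot design plus a single confirmation run
  rsm <- bench[bench$strategy == "rsm" & bench$seed == 101, ]
  expect_equal(nrow(rsm), 2L)
  expect_equal(diff(rsm$n_measured), 1L)
})
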