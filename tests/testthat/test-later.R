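test_that("race_cdf is a valid CDF matching the sampler", {
  # symmetry at the main mean when truncation mass is negligible
  expect_equal(race_cdf(6.04, 6.04, 1.38, 0), 0.5, tolerance = 1e-6)

  # nondecreasing over a grid for random admissible parameters
  set.seed(51)
  for (k in 1:20) {
    mu <- runif(1, 1, 15); sg <- runif(1, 0.2, 5); se <- runif(1, 0, 10)
    p <- seq(1e-3, 30, length.out = 1000)
    expect_true(all(diff(race_cdf(p, mu, sg, se)) >= -1e-12))
  }

  # Monte-Carlo oracle: model CDF vs empirical CDF of the sampler
  for (pars in list(c(6.04, 1.38, 0), c(6.04, 1.38, 4.9))) {
    n <- 1e5
    p <- sample_promptness(pars[1], pars[2], pars[3], n, seed = 52)
    d <- ks_statistic(p, function(q) race_cdf(q, pars[1], pars[2], pars[3]))
    expect_lt(d, 3 / sqrt(n))
  }
  expect_error(race_cdf(5, 6, -1), "sigma")
})

test_that("ks_statistic is exact and agrees with an independent oracle", {
  # quantile-spaced sample fits its own law nearly perfectly
  n <- 500
  cdf <- function(q) race_cdf(q, 6, 1.4, 0)
  grid <- seq(0.01, 20, by = 0.001)
  qs <- approx(cdf(grid), grid, xout = (1:n) / (n + 1), ties = "ordered")$y
  expect_lte(ks_statistic(qs, cdf), 1 / (n + 1) + 1e-3)

  # single point with F = 0.5
  one <- approx(cdf(grid), grid, xout = 0.5, ties = "ordered")$y
  expect_equal(ks_statistic(one, cdf), 0.5, tolerance = 1e-6)

  # oracle equivalence: stats::ks.test computes the same sup-distance
  set.seed(53)
  for (k in 1:20) {
    x <- sample_promptness(runif(1, 3, 9), runif(1, 0.5, 3), 0,
                           sample(20:200, 1))
    f <- function(q) race_cdf(q, 5.5, 1.2, 0)
    expect_equal(ks_statistic(x, f),
                 unname(suppressWarnings(ks.test(x, f))$statistic),
                 tolerance = 1e-10)
  }
})

test_that("fit_later recovers generating parameters", {
  p <- sample_promptness(6.04, 1.38, 0, 5000, seed = 54)
  f <- fit_later(p)
  expect_true(f$converged)
  expect_equal(f$mu, 6.04, tolerance = 0.03)
  expect_equal(f$sigma, 1.38, tolerance = 0.05)
  # optimality sanity: the truth never beats the fit by more than it should
  ks_true <- ks_statistic(p, function(q) race_cdf(q, 6.04, 1.38, 0))
  expect_lte(f$ks, ks_true)
  expect_lte(ks_true - f$ks, 0.01)

  # self-consistency: a quantile sample of the fitted law refits to ks ~ 0
  grid <- seq(0.01, 20, by = 0.001)
  Fg <- race_cdf(grid, f$mu, f$sigma, 0)
  qs <- approx(Fg, grid, xout = ((1:400) - 0.5) / 400, ties = "ordered")$y
  f2 <- fit_later(qs)
  expect_lt(f2$ks, 0.01)

  expect_error(fit_later(p[1:5]), "at least 10")
  expect_error(fit_later(rep(5, 50)), "degenerate")
  expect_error(fit_later(p[1:15], with_early = TRUE), "at least 20")
})

test_that("3-parameter recovery holds across seeds (scaled-down suite)", {
  rel_err <- function(est, truth) abs(est - truth) / truth
  errs <- sapply(1:5, function(s) {
    p <- sample_promptness(6.04, 1.38, 4.9, 4000, seed = 540 + s)
    f <- fit_later(p, with_early = TRUE)
    c(mu = rel_err(f$mu, 6.04), sigma = rel_err(f$sigma, 1.38),
      sigma_e = rel_err(f$sigma_e, 4.9))
  })
  med <- apply(errs, 1, median)
  expect_lt(med[["mu"]], 0.02)
  expect_lt(med[["sigma"]], 0.05)
  expect_lt(med[["sigma_e"]], 0.15)
})

test_that("reciprobit coordinates are linear for a recinormal sample", {
  grid <- seq(0.01, 20, by = 0.001)
  Fg <- race_cdf(grid, 6.04, 1.38, 0)
  qs <- approx(Fg, grid, xout = ((1:500) - 0.5) / 500, ties = "ordered")$y
  rc <- reciprobit_coords(qs)
  expect_equal(nrow(rc), 500)
  expect_gt(summary(lm(y ~ x, rc))$r.squared, 0.999)

  expect_equal(nrow(reciprobit_coords(c(5, 6))), 2L)
  expect_error(reciprobit_coords(5), "at least 2")

  # early-unit mixture: the short-latency tail deviates from the main line
  p <- sample_promptness(6.04, 1.38, 4.9, 1e4, seed = 55)
  rc2 <- reciprobit_coords(p)
  bulk <- rc2[rc2$latency_ms > quantile(rc2$latency_ms, 0.3) &
                rc2$latency_ms < quantile(rc2$latency_ms, 0.9), ]
  line <- lm(y ~ x, bulk)
  shortest <- rc2[rc2$latency_ms <= quantile(rc2$latency_ms, 0.02), ]
  res <- shortest$y - predict(line, shortest)
  # extra express mass lifts the early limb above the main line
  expect_gt(mean(res), 0.5)
})

test_that("express-window mass rises with sigma_e and calibrates", {
  mass <- vapply(seq(0, 8, by = 1),
                 function(se) express_mass(6.04, 1.38, se), numeric(1))
  expect_true(all(diff(mass) > 0))

  se <- calibrate_sigma_e(6.04, 1.38, target = 0.14)
  m <- express_mass(6.04, 1.38, se) /
    express_mass(6.04, 1.38, se, window = c(80, 1000))
  expect_equal(m, 0.14, tolerance = 1e-4)

  # unattainable unconditional target falls back to the maximiser
  expect_warning(
    se_max <- calibrate_sigma_e(6.04, 1.38, target = 0.2,
                                condition_window = NULL),
    "attainable")
  expect_gt(se_max, 5)
})
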