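# direct child-level table builder: fast oracle input for the GLM stage
child_table <- function(n, group, rate, trials = 13, seed = 1) {
  set.seed(seed)
  data.frame(child_id = sprintf("%s%03d", group, seq_len(n)),
             group = group,
             corrected_rate = rbinom(n, trials, rate) / trials)
}

test_that("mixed_model recovers an injected group offset", {
  cfg <- sim_config(n_per_group = c(HC = 40, chronic = 30, controlled = 30),
                    covariate_effects = list(group_mu_offset_chronic = 1),
                    seed = 61)
  sim <- simulate_cohort(cfg)
  lab <- classify_trials(sim$trials, sim$events)
  tt <- trial_table(lab, sim$children)
  eff <- mixed_model(tt, "recip_srt")
  expect_false(attr(eff, "fallback"))
  expect_lt(eff$p[eff$term == "group"], 0.05)
  ctr <- attr(eff, "contrasts")
  ps <- ctr[ctr$family == "recip_srt:PS" &
              ctr$contrast == "HC - chronic", ]
  # +1 Hz chronic offset: HC - chronic estimate ~ -1, inside its 95% CI
  expect_lt(abs(ps$estimate - (-1)), 1.96 * ps$se)
  expect_true(all(ctr$p_adj >= ctr$p_raw))
  expect_true(all(ctr$p_adj <= pmin(1, 3 * ctr$p_raw) + 1e-12))

  expect_error(mixed_model(transform(tt, recip_srt = 1), "recip_srt"),
               "constant")
})

test_that("proportion_glm detects the corrected-rate group difference", {
  hits <- 0L
  for (s in 1:10) {
    tab <- rbind(child_table(48, "HC", 0.90, seed = 70 + s),
                 child_table(11, "controlled", 0.65, seed = 170 + s))
    tab$group <- factor(tab$group, levels = c("HC", "chronic", "controlled"))
    eff <- proportion_glm(tab, "corrected_rate")
    if (eff$p[eff$term == "group"] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)

  # identical groups: effect size stays near zero
  etas <- sapply(1:15, function(s) {
    tab <- rbind(child_table(48, "HC", 0.9, seed = 200 + s),
                 child_table(20, "controlled", 0.9, seed = 300 + s))
    tab$group <- factor(tab$group, levels = c("HC", "chronic", "controlled"))
    eff <- proportion_glm(tab, "corrected_rate")
    eff$eta_sq[eff$term == "group"]
  })
  expect_lt(median(etas), 0.02)
})

test_that("proportion_glm guards degenerate inputs", {
  tab <- rbind(child_table(10, "HC", 0.9), child_table(10, "chronic", 0.8))
  tab$group <- factor(tab$group, levels = c("HC", "chronic", "controlled"))
  tab$iq <- 100
  expect_error(proportion_glm(tab, "corrected_rate",
                              predictors = c("group", "iq")),
               "`iq`.*constant|constant.*iq")
  tab$corrected_rate <- NA_real_
  expect_message(res <- proportion_glm(tab, "corrected_rate"), "skipped")
  expect_null(res)
  expect_error(proportion_glm(tab, "nope"), "unknown outcome")
})

test_that("age_and_epilepsy_models: quadratic vertex and stepwise entry", {
  set.seed(81)
  n <- 80
  age <- runif(n, 8, 18)
  d <- data.frame(group = factor("HC", c("HC", "chronic", "controlled")),
                  age = age,
                  vel = 340 - 1.8 * (age - 13)^2 + rnorm(n, 0, 12))
  tab <- age_and_epilepsy_models(d, "vel", form = "quadratic")
  expect_true(attr(tab, "vertex_age") > 12 && attr(tab, "vertex_age") < 14)
  expect_lt(tab$p[tab$term == "I(age^2)"], 0.01)

  # stepwise: a strong onset effect is entered with the right sign
  set.seed(82)
  np <- 26
  pat <- data.frame(
    group = factor(rep(c("chronic", "controlled"), length.out = np),
                   c("HC", "chronic", "controlled")),
    iq = rnorm(np, 90, 15), onset = runif(np, 1, 12),
    duration = runif(np, 1, 8), last_seizure = runif(np, 0, 5))
  pat$y <- 300 + 8 * pat$onset + rnorm(np, 0, 10)
  st <- age_and_epilepsy_models(pat, "y", stepwise = TRUE)
  expect_true("onset" %in% attr(st, "retained"))
  expect_gt(attr(st, "coefficients")[["onset"]], 0)

  # null effects: forward entry retains factors only rarely, and any
  # factor that does enter carried an entry p-value below the threshold
  # (one retention per ~7 null runs is the procedure's own false-entry
  # rate for 3 candidate factors at alpha = 0.05)
  retained_n <- sapply(1:10, function(s) {
    set.seed(800 + s)
    pat$y0 <- rnorm(np, 300, 10)
    length(attr(age_and_epilepsy_models(pat, "y0", stepwise = TRUE),
                "retained"))
  })
  expect_lte(sum(retained_n > 0), 3L)
  # entry threshold is honoured: with alpha_enter = 0 nothing ever enters
  pat$y0 <- rnorm(np, 300, 10)
  st_strict <- age_and_epilepsy_models(pat, "y0", stepwise = TRUE,
                                       alpha_enter = 0)
  expect_length(attr(st_strict, "retained"), 0L)

  hc_only <- d
  expect_error(age_and_epilepsy_models(hc_only, "vel", stepwise = TRUE),
               "patient")
})

test_that("assoc_stats: Spearman and R-squared change", {
  x <- 1:20
  expect_equal(assoc_stats(x, x^3, "spearman")$statistic, 1)
  expect_equal(assoc_stats(x, rev(x), "spearman")$statistic, -1)
  expect_error(assoc_stats(rep(1, 10), 1:10, "spearman"), "constant")
  expect_error(assoc_stats(1:3, 1:3, "spearman"), "at least 4")

  # pure-noise term: non-negative, typically tiny, R-squared change
  set.seed(91)
  r2c <- replicate(50, {
    n <- 30
    base <- data.frame(age = rnorm(n))
    y <- 2 * base$age + rnorm(n)
    assoc_stats(rnorm(n), y, "ols_r2_change", base = base)$statistic
  })
  expect_true(all(r2c >= -1e-12))
  expect_lt(median(r2c), 0.02)
})
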