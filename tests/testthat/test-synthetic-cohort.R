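test_that("make_cohort respects group counts, invariants and determinism", {
  cfg <- sim_config(seed = 7)
  prof <- make_cohort(cfg)
  expect_equal(as.vector(table(prof$group)[c("HC", "chronic", "controlled")]),
               c(48, 15, 11))
  hc <- prof[prof$group == "HC", ]
  expect_true(all(is.na(hc$onset)) && all(is.na(hc$duration)))
  pat <- prof[prof$group != "HC", ]
  expect_true(all(pat$onset + pat$duration <= pat$age + 1e-9))
  expect_true(all(prof$age >= 8 & prof$age <= 18))

  expect_identical(make_cohort(cfg), prof)
  expect_error(sim_config(n_per_group = c(HC = 0, chronic = 0,
                                          controlled = 0)),
               "non-empty")
  expect_error(sim_config(trials_per_task = 0), "positive")
  expect_error(sim_config(blink_rate = 1.2), "probabilities")
})

test_that("sample_promptness follows the race promptness law", {
  p <- sample_promptness(6.04, 1.38, 0, 1e5, seed = 11)
  expect_true(all(p > 0))
  expect_equal(mean(p), 6.04, tolerance = 0.005)
  expect_equal(sd(p), 1.38, tolerance = 0.01)

  # with the early unit off, the law is the truncated main Gaussian
  p0 <- sample_promptness(6.04, 1.38, 0, 1e4, seed = 12)
  trunc_cdf <- function(q) {
    lo <- pnorm(0, 6.04, 1.38)
    (pnorm(q, 6.04, 1.38) - lo) / (1 - lo)
  }
  expect_gt(suppressWarnings(ks.test(p0, trunc_cdf))$p.value, 0.01)

  # raising sigma_e raises the express-window (80-120 ms) fraction
  frac_express <- function(se) {
    p <- sample_promptness(6.04, 1.38, se, 1e5, seed = 13)
    lat <- 1000 / p
    mean(lat >= 80 & lat <= 120)
  }
  f <- vapply(c(0, 2.5, 5), frac_express, numeric(1))
  expect_true(all(diff(f) > 0))

  expect_error(sample_promptness(-10, 1, 0, 10), "acceptance")
  expect_error(sample_promptness(5, -1, 0, 10))
})

test_that("simulate_trials realises error, correction and fault config", {
  # no errors configured: every AS trial planned correct
  cfg0 <- tiny_config(as_error = list(slope = 0.5,
                                      target_rate = c(HC = 0, chronic = 0,
                                                      controlled = 0)))
  ch <- make_cohort(cfg0)
  sim <- simulate_trials(ch[1, ], cfg0, seed = 3)
  as_tr <- sim$trials[sim$trials$task == "AS", ]
  expect_true(all(as_tr$planned_class == "AS_correct"))

  # all-blink config: every trial excluded downstream
  cfgb <- tiny_config(blink_rate = 1, fixbreak_rate = 0)
  simb <- simulate_cohort(cfgb)
  labb <- classify_trials(simb$trials, simb$events)
  expect_true(all(labb$status == "excluded"))
  expect_true(all(labb$reason == "blink"))

  # corrections: fixed 150 ms delay, prob 0.9 -> ~90% detected corrected
  cfgc <- sim_config(n_per_group = c(HC = 15, chronic = 0, controlled = 0),
                     trials_per_task = 20,
                     as_error = list(slope = 0.5,
                                     target_rate = c(HC = 0.6, chronic = 0.6,
                                                     controlled = 0.6)),
                     correction_prob = c(HC = 0.9, chronic = 0.9,
                                         controlled = 0.9),
                     correction_delay = c(150, 150),
                     blink_rate = 0, fixbreak_rate = 0, seed = 21)
  simc <- simulate_cohort(cfgc)
  labc <- classify_trials(simc$trials, simc$events)
  pe <- labc[labc$class == "PE", ]
  expect_gt(nrow(pe), 100)
  expect_equal(mean(pe$corrected), 0.9, tolerance = 0.08)
})

test_that("synth_gaze_trace round-trips planned saccades through detection", {
  tr <- make_trial_row()
  ev <- make_event(onset = 400, amp = 8, pv = 340)
  set.seed(41)
  g <- synth_gaze_trace(tr, ev)
  det <- detect_saccades(g)
  det <- det[abs(det$amp_deg) >= 1, ]
  expect_equal(nrow(det), 1L)
  expect_equal(det$amp_deg, 8, tolerance = 0.25 / 8)
  expect_equal(det$peak_vel_dps, 340, tolerance = 0.05)

  # zero planned saccade: nothing above threshold
  set.seed(42)
  g0 <- synth_gaze_trace(tr, no_events())
  expect_equal(nrow(detect_saccades(g0)), 0L)

  # two saccades 200 ms apart: two ordered events
  ev2 <- rbind(make_event(400, 6, 320),
               make_event(600, -6, 320, x_start = 6))
  set.seed(43)
  g2 <- synth_gaze_trace(tr, ev2)
  det2 <- detect_saccades(g2)
  det2 <- det2[abs(det2$amp_deg) >= 1, ]
  expect_equal(nrow(det2), 2L)
  expect_true(det2$onset_ms[1] < det2$onset_ms[2])
  expect_equal(det2$amp_deg, c(6, -6), tolerance = 0.05)

  expect_error(synth_gaze_trace(tr, make_event(400, 0)), "amplitude")
})

test_that("planned trials survive the full trace round trip (property)", {
  # planned valid saccades are recovered as the planned class
  mismatch <- 0L; total <- 0L
  for (s in 1:12) {
    cfg <- sim_config(n_per_group = c(HC = 1, chronic = 0, controlled = 0),
                      trials_per_task = 10, blink_rate = 0,
                      fixbreak_rate = 0, seed = 100 + s)
    sim <- simulate_cohort(cfg)
    set.seed(200 + s)
    for (i in seq_len(nrow(sim$trials))) {
      tr <- sim$trials[i, ]
      # skip trials whose planned SRT sits within detector jitter of a
      # validity/express boundary
      if (tr$planned_srt_ms < 90 || tr$planned_srt_ms > 990) next
      ev <- sim$events[sim$events$trial_id == tr$trial_id, ]
      g <- synth_gaze_trace(tr, ev)
      det <- detect_saccades(g)
      evd <- if (nrow(det)) cbind(child_id = tr$child_id,
                                  trial_id = tr$trial_id, det)
             else ev[0, ]
      lab <- classify_trials(tr, evd)
      total <- total + 1L
      if (!identical(lab$class, tr$planned_class)) mismatch <- mismatch + 1L
    }
  }
  expect_gt(total, 150)
  expect_lt(mismatch / total, 0.01)
})

test_that("cohort generation is deterministic end-to-end", {
  cfg <- tiny_config(seed = 77)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(tiny_config(seed = 78))
  expect_false(identical(s1$trials, s3$trials))
})
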