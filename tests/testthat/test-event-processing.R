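make_samples <- function(n = 400, amp = 8, onset = 150, pv = 340,
                         seed = 1) {
  set.seed(seed)
  tr <- make_trial_row(blink = c(NA, NA), fix_x = 0)
  ev <- make_event(onset, amp, pv)
  synth_gaze_trace(tr, ev, duration_ms = n)
}

test_that("read_gaze parses CSV and ASC dialects equivalently", {
  s1 <- data.frame(t_ms = 0:99, x_deg = round(sin(0:99 / 20), 4),
                   y_deg = 0, valid_flag = 1)
  s2 <- data.frame(t_ms = 0:49, x_deg = round(cos(0:49 / 10), 4),
                   y_deg = 0, valid_flag = 1)
  csv <- file.path(tempdir(), "gaze.csv")
  write.csv(rbind(cbind(trial_id = 1, s1), cbind(trial_id = 2, s2)),
            csv, row.names = FALSE)
  tr <- read_gaze(csv, "csv")
  expect_length(tr, 2L)
  expect_equal(nrow(tr[[1]]$samples), 100L)
  expect_equal(nrow(tr[[2]]$samples), 50L)
  expect_equal(tr[[1]]$samples$x_deg, s1$x_deg)

  # same data in the ASC-like dialect
  asc <- file.path(tempdir(), "gaze.asc")
  lines <- c("MSG 0 TRIALID 1", "MSG 150 TARGET_ON R",
             sprintf("%d %s 0", s1$t_ms, format(s1$x_deg)),
             "MSG 100 TRIALID 2",
             sprintf("%d %s 0", s2$t_ms, format(s2$x_deg)))
  writeLines(lines, asc)
  ta <- read_gaze(asc, "asc")
  expect_length(ta, 2L)
  expect_equal(ta[["1"]]$samples$x_deg, tr[[1]]$samples$x_deg)
  expect_equal(ta[["1"]]$target_side, "R")
  expect_equal(ta[["1"]]$target_onset_ms, 150)

  # duplicated timestamp is a parse error naming the trial
  bad <- rbind(cbind(trial_id = 1, s1[c(1, 1, 2:10), ]))
  badf <- file.path(tempdir(), "bad.csv")
  write.csv(bad, badf, row.names = FALSE)
  expect_error(read_gaze(badf, "csv"), "non-monotone.*trial 1")
  expect_error(read_gaze(csv, "tsv"))
})

test_that("detect_saccades finds events and handles blinks", {
  g <- make_samples(seed = 2)
  det <- detect_saccades(g)
  expect_equal(nrow(det), 1L)
  expect_true(det$offset_ms > det$onset_ms)
  expect_equal(det$amp_deg, det$x_end - det$x_start)

  # constant-position trace: no events
  flat <- data.frame(t_ms = 0:199, x_deg = 1.5, y_deg = 0, valid = TRUE)
  expect_equal(nrow(detect_saccades(flat)), 0L)

  # a 40 ms gap mid-trial is recorded as a blink and splits detection
  g2 <- make_samples(seed = 3)
  g2$valid[251:290] <- FALSE
  g2$x_deg[251:290] <- NA
  det2 <- detect_saccades(g2)
  blinks <- attr(det2, "blinks")
  expect_equal(nrow(blinks), 1L)
  expect_equal(blinks$start_ms, 250)
  expect_false(any(det2$onset_ms <= 290 & det2$offset_ms >= 250))

  # all samples invalid: empty result flagged unusable
  g3 <- make_samples(seed = 4)
  g3$valid[] <- FALSE
  det3 <- detect_saccades(g3)
  expect_equal(nrow(det3), 0L)
  expect_true(attr(det3, "no_usable"))
  expect_error(detect_saccades(g3[1:5, ]), "10 samples")
})

test_that("detection is translation-invariant and mirror-symmetric", {
  g <- make_samples(seed = 5)
  det <- detect_saccades(g)
  g_shift <- g; g_shift$x_deg <- g_shift$x_deg + 2
  det_s <- detect_saccades(g_shift)
  expect_equal(det_s$onset_ms, det$onset_ms)
  expect_equal(det_s$offset_ms, det$offset_ms)
  expect_equal(det_s$amp_deg, det$amp_deg, tolerance = 1e-12)

  g_neg <- g; g_neg$x_deg <- -g_neg$x_deg
  det_n <- detect_saccades(g_neg)
  expect_equal(det_n$amp_deg, -det$amp_deg, tolerance = 1e-12)
  expect_equal(det_n$peak_vel_dps, det$peak_vel_dps, tolerance = 1e-12)
})

test_that("sg_velocity matches the analytic derivative of a smooth signal", {
  t <- 0:200
  x <- 5 * sin(t / 30)
  v_true <- 5 / 30 * cos(t / 30) * 1000   # deg/s
  v <- sg_velocity(x, dt_ms = 1, window = 5)
  i <- 10:190
  expect_equal(v[i], v_true[i], tolerance = 5e-3)
  expect_error(sg_velocity(x, window = 4), "odd")
})

test_that("gate_trial applies fixation, blink and head-movement rules", {
  ok <- make_trial_row(fix_x = 0.2)
  expect_true(gate_trial(ok)$pass)

  far <- make_trial_row(fix_x = 3)
  g <- gate_trial(far, fixation_radius = 1.5)
  expect_false(g$pass); expect_equal(g$reason, "fixation_break")

  bl <- make_trial_row(blink = c(180, 260))   # spans target onset at 200
  g2 <- gate_trial(bl)
  expect_false(g2$pass); expect_equal(g2$reason, "blink")

  hm <- make_trial_row(head = TRUE)
  expect_equal(gate_trial(hm)$reason, "head_movement")

  # sample-mode: pre-target mean and in-window invalid samples
  tr <- make_trial_row()
  set.seed(6)
  smp <- synth_gaze_trace(tr, make_event(450, 8, 340))
  expect_true(gate_trial(tr, samples = smp)$pass)
  smp_off <- smp; smp_off$x_deg <- smp_off$x_deg + 3
  expect_equal(gate_trial(tr, samples = smp_off)$reason, "fixation_break")
  smp_bl <- smp; smp_bl$valid[400:440] <- FALSE
  expect_equal(gate_trial(tr, samples = smp_bl)$reason, "blink")
})
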