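## minimum-jerk displacement profile; peak velocity = 1.875 * A / D
minjerk <- function(tau) tau^3 * (10 - 15 * tau + 6 * tau^2)

#' Simulate the trials of one child
#'
#' Produces the event-level truth for `trials_per_task` prosaccade and
#' antisaccade trials: target sides in random order, saccadic reaction times
#' drawn from the child's LATER race units, endpoint amplitudes from the
#' task gain law, peak velocities from the linear main sequence, antisaccade
#' direction errors with a latency-dependent (logistic-in-promptness)
#' probability followed by corrective saccades with the configured
#' probability and delay, and per-trial blink / broken-fixation faults.
#'
#' @param child one row of [make_cohort()] output.
#' @param config the [sim_config()] used to build the cohort.
#' @param seed optional seed (NULL uses the current RNG stream).
#' @return list with `trials` (one row per trial: identity, task, side,
#'   target onset, fixation position, blink interval, plus `planned_*`
#'   truth columns) and `events` (one row per saccade event).
#' @export
simulate_trials <- function(child, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_local_seed(seed, {
    ecc <- config$target_eccentricity_deg
    t_on <- config$target_onset_ms
    ntr <- config$trials_per_task
    ms_noise <- config$mainseq[["noise_sd"]]

    trial <- list(); event <- list()
    tid <- 0L
    for (task in c("PS", "AS")) {
      sides <- sample(rep(c("L", "R"), length.out = ntr))
      for (k in seq_len(ntr)) {
        tid <- tid + 1L
        side_sign <- if (sides[k] == "R") 1 else -1
        blink <- stats::runif(1) < config$blink_rate
        fixbreak <- stats::runif(1) < config$fixbreak_rate
        b_start <- b_end <- NA_real_
        if (blink) {
          b_start <- stats::runif(1, t_on - 50, t_on + 800)
          b_end <- b_start + stats::runif(1, 50, 150)
        }
        fix_x <- if (fixbreak) 3 * sample(c(-1, 1), 1) else
          stats::rnorm(1, 0, 0.15)

        ## response plan
        if (task == "PS") {
          p <- sample_promptness(child$mu_PS, child$sigma_PS, child$sige_PS, 1)
          cls <- "PS_correct"; dir_sign <- side_sign
          gain_mean <- child$gain_PS; vint <- child$vel_int_PS
        } else {
          p_pe <- sample_promptness(child$mu_PE, child$sigma_PE,
                                    child$sige_PE, 1)
          err <- stats::runif(1) <
            stats::plogis(child$err_logit + config$as_error$slope * p_pe)
          if (err) {
            p <- p_pe; cls <- "PE"; dir_sign <- side_sign
            gain_mean <- child$gain_PE; vint <- child$vel_int_PE
          } else {
            p <- sample_promptness(child$mu_AS, child$sigma_AS,
                                   child$sige_AS, 1)
            cls <- "AS_correct"; dir_sign <- -side_sign
            gain_mean <- child$gain_AS; vint <- child$vel_int_AS
          }
        }
        srt <- 1000 / p
        amp_mag <- max(abs(stats::rnorm(1, gain_mean, config$gain_noise_sd)) *
                         ecc, 0.1)
        pv <- max(child$vel_slope * amp_mag + vint +
                    stats::rnorm(1, 0, ms_noise), 25)
        dur <- 1875 * amp_mag / pv            # ms; minimum-jerk duration
        onset <- t_on + srt
        ev <- data.frame(child_id = child$child_id, trial_id = tid,
                         onset_ms = onset, offset_ms = onset + dur,
                         amp_deg = dir_sign * amp_mag, peak_vel_dps = pv,
                         x_start = 0, x_end = dir_sign * amp_mag)
        corrected <- NA
        corr_delay <- NA_real_
        if (cls == "PE") {
          corrected <- stats::runif(1) < child$corr_prob
          if (corrected) {
            corr_delay <- stats::runif(1, config$correction_delay[1],
                                       config$correction_delay[2])
            c_on <- ev$offset_ms + corr_delay
            c_amp <- max(abs(stats::rnorm(1, child$gain_AS,
                                          config$gain_noise_sd)) * ecc, 1.1)
            c_pv <- max(child$vel_slope * c_amp + child$vel_int_AS +
                          stats::rnorm(1, 0, ms_noise), 25)
            ev <- rbind(ev, data.frame(
              child_id = child$child_id, trial_id = tid, onset_ms = c_on,
              offset_ms = c_on + 1875 * c_amp / c_pv,
              amp_deg = -side_sign * (amp_mag + c_amp), peak_vel_dps = c_pv,
              x_start = dir_sign * amp_mag, x_end = -side_sign * c_amp))
          }
        }
        trial[[tid]] <- data.frame(
          child_id = child$child_id, trial_id = tid, task = task,
          target_side = sides[k], target_ecc = ecc, target_onset_ms = t_on,
          fix_x_deg = fix_x, fix_y_deg = 0,
          blink_start_ms = b_start, blink_end_ms = b_end,
          head_movement = FALSE,
          planned_class = cls, planned_srt_ms = srt,
          planned_amp_deg = dir_sign * amp_mag, planned_peak_vel = pv,
          planned_corrected = corrected, planned_corr_delay_ms = corr_delay)
        event[[tid]] <- ev
      }
    }
    list(trials = do.call(rbind, trial), events = do.call(rbind, event))
  })
}

#' Simulate a full cohort: profiles plus trial/event tables
#'
#' Convenience wrapper: [make_cohort()] then [simulate_trials()] for every
#' child, all under the configuration seed, so a fixed seed reproduces the
#' three tables exactly.
#'
#' @param config a [sim_config()].
#' @return list with `children`, `trials`, `events` data.frames.
#' @export
simulate_cohort <- function(config) {
  children <- make_cohort(config)
  with_local_seed(config$seed + 1L, {
    sims <- lapply(seq_len(nrow(children)), function(i)
      simulate_trials(children[i, ], config))
    list(children = children,
         trials = do.call(rbind, lapply(sims, `[[`, "trials")),
         events = do.call(rbind, lapply(sims, `[[`, "events")))
  })
}

#' Synthesize a 1000-Hz gaze trace for one planned trial
#'
#' Renders planned saccade events as a raw gaze sample series: position
#' follows a minimum-jerk sigmoidal displacement whose peak instantaneous
#' velocity equals the planned value, fixation epochs carry smooth
#' autocorrelated jitter (AR(1), stationary SD `jitter_sd`), and blink
#' intervals become missing samples. The trace is the raw-input counterpart
#' of the event table and feeds [detect_saccades()] round-trip checks.
#'
#' @param trial one row of the `trials` table from [simulate_trials()].
#' @param events the event rows for that trial (may be empty).
#' @param sampling_hz sampling rate, default 1000.
#' @param duration_ms trace length from trial start.
#' @param jitter_sd stationary SD (deg) of fixation jitter.
#' @return data.frame of `gaze_samples`: `t_ms`, `x_deg`, `y_deg`, `valid`.
#' @export
synth_gaze_trace <- function(trial, events, sampling_hz = 1000,
                             duration_ms = 1500, jitter_sd = 0.05) {
  dt <- 1000 / sampling_hz
  t <- seq(0, duration_ms, by = dt)
  n <- length(t)
  x <- numeric(n)
  if (nrow(events)) {
    events <- events[order(events$onset_ms), , drop = FALSE]
    if (any(events$amp_deg == 0)) stop("planned amplitude must be non-zero",
                                       call. = FALSE)
    for (j in seq_len(nrow(events))) {
      ev <- events[j, ]
      dur <- ev$offset_ms - ev$onset_ms
      if (dur <= 0) stop("planned event has non-positive duration",
                         call. = FALSE)
      tau <- pmin(pmax((t - ev$onset_ms) / dur, 0), 1)
      x <- x + (ev$x_end - ev$x_start) * minjerk(tau)
    }
  }
  # smooth fixation jitter: AR(1), phi chosen so velocity noise stays small
  phi <- 0.97
  innov_sd <- jitter_sd * sqrt(1 - phi^2)
  e <- stats::rnorm(n, 0, innov_sd)
  jit <- as.numeric(stats::filter(e, phi, method = "recursive"))
  x <- x + jit
  y <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                method = "recursive"))
  valid <- rep(TRUE, n)
  if (!is.na(trial$blink_start_ms))
    valid[t >= trial$blink_start_ms & t <= trial$blink_end_ms] <- FALSE
  out <- data.frame(t_ms = t, x_deg = x + trial$fix_x_deg, y_deg = y,
                    valid = valid)
  out$x_deg[!valid] <- NA_real_
  out$y_deg[!valid] <- NA_real_
  out
}
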