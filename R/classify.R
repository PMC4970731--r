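#' First valid saccade of a gated trial
#'
#' Scans the trial's events in onset order for the first horizontal
#' movement with |amplitude| >= `min_amp` starting at or after target
#' onset. A qualifying movement with SRT below the lower latency bound is
#' an anticipation and invalidates the whole trial; sub-amplitude
#' (vertical-dominant or drift) events are skipped. A qualifying event must
#' have SRT inside `srt_range` (default 80--1000 ms).
#'
#' @param trial one trial-table row (needs `target_onset_ms`).
#' @param events events of that trial.
#' @param min_amp deg, default 1.
#' @param srt_range valid SRT window in ms.
#' @return list with `status` in `c("valid", "anticipation", "none")` and,
#'   when valid, `event` (one-row data.frame) and `srt_ms`.
#' @export
first_valid_saccade <- function(trial, events, min_amp = 1,
                                srt_range = c(80, 1000)) {
  ev <- events[events$onset_ms >= trial$target_onset_ms &
                 abs(events$amp_deg) >= min_amp, , drop = FALSE]
  if (!nrow(ev)) return(list(status = "none"))
  ev <- ev[order(ev$onset_ms), , drop = FALSE]
  srt <- ev$onset_ms[1] - trial$target_onset_ms
  if (srt < srt_range[1]) return(list(status = "anticipation"))
  if (srt > srt_range[2]) return(list(status = "none"))
  list(status = "valid", event = ev[1, , drop = FALSE], srt_ms = srt)
}

#' Classify a trial's first valid saccade
#'
#' Applies the task's operational definitions: on prosaccade (PS) trials a
#' movement toward the target is correct (`PS_correct`) and an away
#' movement is excluded as a PS-task direction error (too rare to
#' analyse); on antisaccade (AS) trials an away movement is `AS_correct`
#' and a movement toward the target is a prosaccade error (`PE`,
#' inhibitory failure). Correct prosaccades with SRT inside
#' `express_window` (inclusive bounds) are flagged express. A horizontal
#' amplitude below 0.1 deg is a direction tie and excludes the trial.
#'
#' @param trial one trial-table row (`task`, `target_side`).
#' @param first result of [first_valid_saccade()] with status `"valid"`.
#' @param express_window ms, default `c(80, 120)`.
#' @return list: `status` (`"valid"` or `"excluded"`), `reason`, `class`
#'   in `c("PS_correct", "AS_correct", "PE", "none")`, `srt_ms`, `express`.
#' @export
classify_saccade <- function(trial, first, express_window = c(80, 120)) {
  amp <- first$event$amp_deg
  if (abs(amp) < 0.1)
    return(list(status = "excluded", reason = "ambiguous direction",
                class = "none", srt_ms = NA_real_, express = FALSE))
  toward <- sign(amp) == (if (trial$target_side == "R") 1 else -1)
  if (trial$task == "PS") {
    if (!toward)
      return(list(status = "excluded", reason = "ps_direction_error",
                  class = "none", srt_ms = NA_real_, express = FALSE))
    cls <- "PS_correct"
  } else {
    cls <- if (toward) "PE" else "AS_correct"
  }
  list(status = "valid", reason = "none", class = cls, srt_ms = first$srt_ms,
       express = cls == "PS_correct" &&
         first$srt_ms >= express_window[1] & first$srt_ms <= express_window[2])
}

#' Detect correction of a prosaccade error
#'
#' An antisaccade-task error counts as corrected when a secondary saccade
#' with |amplitude| >= `min_amp` starts within `window_ms` after the error
#' offset and moves opposite to the target.
#'
#' @param trial trial-table row.
#' @param events the trial's events.
#' @param first_event the erroneous first saccade (one-row data.frame).
#' @param window_ms correction window after error offset, default 300.
#' @param min_amp deg, default 1.
#' @return logical flag.
#' @export
detect_correction <- function(trial, events, first_event, window_ms = 300,
                              min_amp = 1) {
  away_sign <- if (trial$target_side == "R") -1 else 1
  off <- first_event$offset_ms
  cand <- events[events$onset_ms > off &
                   events$onset_ms < off + window_ms &
                   abs(events$amp_deg) >= min_amp &
                   sign(events$amp_deg) == away_sign, , drop = FALSE]
  nrow(cand) > 0
}

#' Gate and classify every trial of a cohort
#'
#' Runs [gate_trial()], [first_valid_saccade()], [classify_saccade()] and
#' [detect_correction()] over cohort trial/event tables, producing one
#' label row per trial with the first-saccade kinematics attached.
#'
#' @param trials cohort trial table (as from [simulate_cohort()]).
#' @param events cohort event table.
#' @param params list of classification parameters: `fixation_radius`,
#'   `min_amp`, `srt_range`, `express_window`, `correction_window_ms`,
#'   `response_window_ms`.
#' @return data.frame (`trial_labels`): `child_id`, `trial_id`, `task`,
#'   `target_side`, `status`, `reason`, `class`, `srt_ms`, `express`,
#'   `corrected`, `amp_deg`, `peak_vel_dps`, `gain`.
#' @export
classify_trials <- function(trials, events, params = list()) {
  p <- utils::modifyList(list(fixation_radius = 1.5, min_amp = 1,
                              srt_range = c(80, 1000),
                              express_window = c(80, 120),
                              correction_window_ms = 300,
                              response_window_ms = 1000), params)
  ev_split <- split(events, interaction(events$child_id, events$trial_id,
                                        drop = TRUE))
  key <- function(cid, tid) paste(cid, tid, sep = ".")
  out <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    ev <- ev_split[[key(tr$child_id, tr$trial_id)]]
    if (is.null(ev)) ev <- events[0, ]
    base <- data.frame(child_id = tr$child_id, trial_id = tr$trial_id,
                       task = tr$task, target_side = tr$target_side,
                       status = "excluded", reason = "none",
                       class = "none", srt_ms = NA_real_, express = FALSE,
                       corrected = NA, amp_deg = NA_real_,
                       peak_vel_dps = NA_real_, gain = NA_real_)
    g <- gate_trial(tr, fixation_radius = p$fixation_radius,
                    response_window_ms = p$response_window_ms)
    if (!g$pass) {
      base$reason <- g$reason
    } else {
      fv <- first_valid_saccade(tr, ev, min_amp = p$min_amp,
                                srt_range = p$srt_range)
      if (fv$status == "anticipation") {
        base$reason <- "anticipation"
      } else if (fv$status == "none") {
        base$reason <- "no_valid_saccade"
      } else {
        cl <- classify_saccade(tr, fv, express_window = p$express_window)
        base$status <- cl$status; base$reason <- cl$reason
        base$class <- cl$class; base$srt_ms <- cl$srt_ms
        base$express <- cl$express
        if (cl$status == "valid") {
          base$amp_deg <- fv$event$amp_deg
          base$peak_vel_dps <- fv$event$peak_vel_dps
          base$gain <- abs(fv$event$amp_deg) / tr$target_ecc
          if (cl$class == "PE")
            base$corrected <- detect_correction(
              tr, ev, fv$event, window_ms = p$correction_window_ms,
              min_amp = p$min_amp)
        }
      }
    }
    out[[i]] <- base
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
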