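# Shared fixture builders: trials and events constructed in code.

tiny_config <- function(...) {
  defaults <- list(n_per_group = c(HC = 3, chronic = 2, controlled = 2),
                   trials_per_task = 10, seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

make_trial_row <- function(task = "PS", side = "R", t_on = 200,
                           fix_x = 0, fix_y = 0, blink = c(NA, NA),
                           head = FALSE, child_id = "T1", trial_id = 1L,
                           ecc = 8) {
  data.frame(child_id = child_id, trial_id = trial_id, task = task,
             target_side = side, target_ecc = ecc, target_onset_ms = t_on,
             fix_x_deg = fix_x, fix_y_deg = fix_y,
             blink_start_ms = blink[1], blink_end_ms = blink[2],
             head_movement = head)
}

make_event <- function(onset, amp, pv = 300, x_start = 0,
                       child_id = "T1", trial_id = 1L) {
  dur <- 1875 * abs(amp) / pv
  data.frame(child_id = child_id, trial_id = trial_id, onset_ms = onset,
             offset_ms = onset + dur, amp_deg = amp, peak_vel_dps = pv,
             x_start = x_start, x_end = x_start + amp)
}

no_events <- function() make_event(0, 1)[0, ]

# mirror a cohort left/right: flip sides, negate horizontal positions
mirror_cohort <- function(trials, events) {
  trials$target_side <- ifelse(trials$target_side == "R", "L", "R")
  trials$fix_x_deg <- -trials$fix_x_deg
  events$amp_deg <- -events$amp_deg
  events$x_start <- -events$x_start
  events$x_end <- -events$x_end
  list(trials = trials, events = events)
}
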