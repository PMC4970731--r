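#' Read gaze samples from CSV or an ASC-like event/sample text dialect
#'
#' The CSV dialect is the one written by the cohort generator: columns
#' `trial_id`, `t_ms`, `x_deg`, `y_deg`, `valid_flag` (0 during blinks).
#' The ASC-like dialect mirrors an eye-tracker transcript: `MSG <t> TRIALID
#' <n>` opens a trial, `MSG <t> TARGET_ON <L|R>` marks target onset,
#' `SBLINK <t>` / `EBLINK <t>` bracket blinks, and bare `<t> <x> <y>` lines
#' are samples. Timestamps must be strictly increasing within a trial.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"asc"`.
#' @return named list of trials; each element is a list with `samples`
#'   (data.frame `t_ms`, `x_deg`, `y_deg`, `valid`), and for the ASC
#'   dialect also `target_onset_ms` and `target_side` when present.
#' @export
read_gaze <- function(path, dialect = c("csv", "asc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "csv") read_gaze_csv(path) else read_gaze_asc(path)
}

read_gaze_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("trial_id", "t_ms", "x_deg", "y_deg")
  if (!all(need %in% names(d)))
    stop("gaze CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(d$valid_flag)) d$valid_flag <- 1L
  out <- lapply(split(seq_len(nrow(d)), d$trial_id), function(idx) {
    s <- d[idx, ]
    dup <- which(diff(s$t_ms) <= 0)
    if (length(dup))
      stop(sprintf(
        "non-monotone timestamps in trial %s (file row %d)",
        s$trial_id[1], idx[dup[1] + 1] + 1L), call. = FALSE)
    list(samples = data.frame(t_ms = s$t_ms, x_deg = s$x_deg,
                              y_deg = s$y_deg,
                              valid = s$valid_flag != 0))
  })
  out[order(as.numeric(names(out)))]
}

read_gaze_asc <- function(path) {
  lines <- readLines(path)
  trials <- list(); cur <- NULL; cur_id <- NULL
  blink_open <- NA_real_
  flush <- function() {
    if (is.null(cur_id)) return(invisible())
    s <- do.call(rbind, cur$samples)
    if (!is.null(s) && any(diff(s$t_ms) <= 0)) {
      bad <- which(diff(s$t_ms) <= 0)[1] + 1L
      stop(sprintf("non-monotone timestamps in trial %s (sample %d)",
                   cur_id, bad), call. = FALSE)
    }
    trials[[cur_id]] <<- list(samples = s,
                              target_onset_ms = cur$target_on,
                              target_side = cur$side)
  }
  for (ln in seq_along(lines)) {
    f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (!length(f) || f[1] == "") next
    if (f[1] == "MSG") {
      if (length(f) >= 4 && f[3] == "TRIALID") {
        flush()
        cur_id <- f[4]
        cur <- list(samples = list(), target_on = NA_real_,
                    side = NA_character_)
        blink_open <- NA_real_
      } else if (length(f) >= 4 && f[3] == "TARGET_ON") {
        cur$target_on <- as.numeric(f[2]); cur$side <- f[4]
      }
    } else if (f[1] == "SBLINK") {
      blink_open <- as.numeric(f[2])
    } else if (f[1] == "EBLINK") {
      blink_open <- NA_real_
    } else if (grepl("^[-0-9.]", f[1])) {
      if (is.null(cur_id))
        stop(sprintf("sample before any TRIALID at line %d", ln),
             call. = FALSE)
      if (length(f) < 3)
        stop(sprintf("malformed sample at line %d", ln), call. = FALSE)
      tt <- as.numeric(f[1])
      miss <- !is.na(blink_open) || f[2] %in% c(".", "NA")
      cur$samples[[length(cur$samples) + 1L]] <-
        data.frame(t_ms = tt,
                   x_deg = if (miss) NA_real_ else as.numeric(f[2]),
                   y_deg = if (miss) NA_real_ else as.numeric(f[3]),
                   valid = !miss)
    }
  }
  flush()
  trials
}

#' Write a cohort's gaze, event and covariate CSV files
#'
#' Emits the generator's external interface: one gaze CSV per child
#' (optional), one event CSV per child, a cohort covariate CSV, and a JSON
#' manifest recording files, seed and a config digest.
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created).
#' @param config the generating [sim_config()].
#' @param gaze write raw gaze traces as well (slow for large cohorts)?
#' @return the manifest, invisibly.
#' @export
write_cohort <- function(sim, dir, config, gaze = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cov_cols <- c("child_id", "group", "age", "iq", "cbcl_attention", "onset",
                "duration", "last_seizure", "on_medication")
  utils::write.csv(sim$children[cov_cols],
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(sim$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$events, file.path(dir, "events.csv"),
                   row.names = FALSE)
  files <- c("covariates.csv", "trials.csv", "events.csv")
  if (gaze) {
    for (id in unique(sim$trials$child_id)) {
      tr <- sim$trials[sim$trials$child_id == id, ]
      gz <- do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
        ev <- sim$events[sim$events$child_id == id &
                           sim$events$trial_id == tr$trial_id[i], ]
        g <- synth_gaze_trace(tr[i, ], ev)
        cbind(trial_id = tr$trial_id[i], g)
      }))
      names(gz)[names(gz) == "valid"] <- "valid_flag"
      fn <- sprintf("gaze_%s.csv", id)
      utils::write.csv(gz, file.path(dir, fn), row.names = FALSE)
      files <- c(files, fn)
    }
  }
  manifest <- list(files = files, seed = config$seed,
                   config_digest = config_digest(config),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

config_digest <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 1e9
}

#' Savitzky-Golay-style velocity from position samples
#'
#' Instantaneous velocity as the slope of a local linear least-squares fit
#' over an odd window of samples: for window half-width m the estimate at i
#' is `sum(k * x[i+k]) / (sum(k^2) * dt)`. Raw central differencing at
#' 1000 Hz amplifies jitter; the windowed slope is the standard remedy.
#'
#' @param x position (deg), may contain `NA`.
#' @param dt_ms sample interval (ms).
#' @param window odd window length (samples), >= 3.
#' @return velocity (deg/s), `NA` at edges and around missing samples.
#' @export
sg_velocity <- function(x, dt_ms = 1, window = 5L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  m <- window %/% 2L
  k <- seq(-m, m)
  denom <- sum(k^2) * dt_ms / 1000          # deg per (deg/s)
  n <- length(x)
  v <- rep(NA_real_, n)
  if (n < window) return(v)
  acc <- numeric(n - 2L * m)
  for (j in seq_along(k)) acc <- acc + k[j] * x[(1L + j - 1L):(n - window + j)]
  v[(m + 1L):(n - m)] <- acc / denom
  v
}

#' Detect saccades in a gaze sample series
#'
#' Velocity-threshold detector over smoothed instantaneous velocity
#' ([sg_velocity()]): maximal runs with |velocity| >= `vel_thresh` lasting
#' at least `min_dur_ms` and containing peak absolute acceleration >=
#' `accel_thresh` become events. Samples invalid during blinks split the
#' trace; events never span a gap and the gaps are returned as blink
#' intervals.
#'
#' @param samples data.frame with `t_ms`, `x_deg`, and optionally `valid`.
#' @param params list: `vel_thresh` (deg/s, default 30), `accel_thresh`
#'   (deg/s^2, default 8000), `min_dur_ms` (default 4), `smooth_window`
#'   (odd samples, default 5).
#' @return data.frame of events (`onset_ms`, `offset_ms`, `amp_deg`,
#'   `peak_vel_dps`, `x_start`, `x_end`) with attributes `blinks`
#'   (data.frame of gap intervals) and `no_usable` (flag).
#' @export
detect_saccades <- function(samples, params = list()) {
  p <- utils::modifyList(list(vel_thresh = 30, accel_thresh = 8000,
                              min_dur_ms = 4, smooth_window = 5L), params)
  if (nrow(samples) < 10L) stop("need at least 10 samples", call. = FALSE)
  valid <- if (is.null(samples$valid)) !is.na(samples$x_deg)
           else samples$valid & !is.na(samples$x_deg)
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amp_deg = numeric(0), peak_vel_dps = numeric(0),
                      x_start = numeric(0), x_end = numeric(0))
  r <- rle(valid)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  blinks <- data.frame(
    start_ms = samples$t_ms[starts[!r$values]],
    end_ms = samples$t_ms[ends[!r$values]])
  if (!any(valid)) {
    attr(empty, "blinks") <- blinks; attr(empty, "no_usable") <- TRUE
    return(empty)
  }
  dt <- stats::median(diff(samples$t_ms))
  events <- list()
  for (seg in which(r$values)) {
    i0 <- starts[seg]; i1 <- ends[seg]
    if (i1 - i0 + 1L < p$smooth_window + 2L) next
    tt <- samples$t_ms[i0:i1]; xx <- samples$x_deg[i0:i1]
    v <- sg_velocity(xx, dt_ms = dt, window = p$smooth_window)
    a <- c(NA, diff(v)) / (dt / 1000)
    fast <- !is.na(v) & abs(v) >= p$vel_thresh
    rr <- rle(fast)
    re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
    lo <- max(p$vel_thresh / 3, 10)       # offset criterion for boundaries
    prev_end <- 0L
    for (run in which(rr$values)) {
      j0 <- rs[run]; j1 <- re[run]
      if (tt[j1] - tt[j0] < p$min_dur_ms) next
      aa <- a[j0:j1]
      if (all(is.na(aa)) || max(abs(aa), na.rm = TRUE) < p$accel_thresh) next
      while (j0 > prev_end + 1L && !is.na(v[j0 - 1L]) &&
             abs(v[j0 - 1L]) > lo) j0 <- j0 - 1L
      while (j1 < length(v) && !is.na(v[j1 + 1L]) &&
             abs(v[j1 + 1L]) > lo) j1 <- j1 + 1L
      prev_end <- j1
      events[[length(events) + 1L]] <- data.frame(
        onset_ms = tt[j0], offset_ms = tt[j1],
        amp_deg = xx[j1] - xx[j0],
        peak_vel_dps = max(abs(v[j0:j1])),
        x_start = xx[j0], x_end = xx[j1])
    }
  }
  out <- if (length(events)) do.call(rbind, events) else empty
  out <- out[order(out$onset_ms), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "blinks") <- blinks
  attr(out, "no_usable") <- FALSE
  out
}

#' Trial validity gate: central fixation and blink-free response window
#'
#' A trial is excluded when mean gaze over the `fix_window_ms` before
#' target onset lies outside `fixation_radius` of the display centre
#' (fixation break), when a blink overlaps the response window (target
#' onset to +`response_window_ms`), or when an external head-movement flag
#' is set. Works from a trial-table row carrying `fix_x_deg`/`fix_y_deg`
#' and blink columns, or from raw samples when supplied.
#'
#' @param trial one row of a trial table.
#' @param samples optional gaze samples for the trial.
#' @param fixation_radius deg, default 1.5.
#' @param fix_window_ms pre-target averaging window, default 50.
#' @param response_window_ms default 1000.
#' @return list with `pass` (flag) and `reason` in
#'   `c("none", "fixation_break", "blink", "head_movement")`.
#' @export
gate_trial <- function(trial, samples = NULL, fixation_radius = 1.5,
                       fix_window_ms = 50, response_window_ms = 1000) {
  t_on <- trial$target_onset_ms
  if (isTRUE(trial$head_movement))
    return(list(pass = FALSE, reason = "head_movement"))
  if (!is.null(samples)) {
    pre <- samples[samples$t_ms >= t_on - fix_window_ms &
                     samples$t_ms < t_on, ]
    ok_pre <- pre[!is.na(pre$x_deg), ]
    fx <- mean(ok_pre$x_deg); fy <- mean(ok_pre$y_deg)
    valid <- if (is.null(samples$valid)) !is.na(samples$x_deg)
             else samples$valid
    resp <- samples$t_ms >= t_on & samples$t_ms <= t_on + response_window_ms
    blink_hit <- any(!valid[resp])
  } else {
    fx <- trial$fix_x_deg; fy <- trial$fix_y_deg
    blink_hit <- !is.na(trial$blink_start_ms) &&
      trial$blink_start_ms <= t_on + response_window_ms &&
      trial$blink_end_ms >= t_on
  }
  if (is.na(fx) || sqrt(fx^2 + fy^2) > fixation_radius)
    return(list(pass = FALSE, reason = "fixation_break"))
  if (blink_hit) return(list(pass = FALSE, reason = "blink"))
  list(pass = TRUE, reason = "none")
}
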