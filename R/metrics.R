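#' Trial-level measures: reciprocal SRT, gain, peak velocity
#'
#' Promptness is 1000 / SRT(ms) in Hz; gain is |amplitude| divided by
#' target eccentricity; peak velocity passes through from the detector.
#'
#' @param srt_ms saccadic reaction time (ms), >= 80 by the validity gate.
#' @param amp_deg signed horizontal amplitude (deg).
#' @param peak_vel_dps peak velocity (deg/s).
#' @param target_ecc target eccentricity (deg).
#' @return data.frame with `recip_srt_hz`, `gain`, `peak_vel_dps`.
#' @export
trial_measures <- function(srt_ms, amp_deg, peak_vel_dps, target_ecc) {
  stopifnot(target_ecc > 0)
  data.frame(recip_srt_hz = 1000 / srt_ms,
             gain = abs(amp_deg) / target_ecc,
             peak_vel_dps = peak_vel_dps)
}

#' Per-child main-sequence fit and velocity at 8 degrees
#'
#' Peak velocity grows with amplitude (the saccadic main sequence), so raw
#' velocities are not comparable across children with different endpoint
#' scatter. An ordinary least-squares regression of peak velocity on
#' unsigned amplitude is fitted per child and saccade type, and evaluated
#' at the reference amplitude (8 deg) to give an amplitude-normalised
#' velocity. The estimate is missing when fewer than `min_trials` events
#' are available, or when the amplitudes are degenerate.
#'
#' @param amp_deg signed amplitudes of one child's saccades of one type.
#' @param peak_vel_dps corresponding peak velocities.
#' @param min_trials minimum events for a fit, default 5.
#' @param at_deg evaluation amplitude, default 8.
#' @return list with `slope`, `intercept`, `v8`, `n`, `r2`; or an empty
#'   list with attribute `reason` when no fit is possible (test with
#'   `length(fit) == 0`).
#' @export
fit_main_sequence <- function(amp_deg, peak_vel_dps, min_trials = 5,
                              at_deg = 8) {
  ok <- !is.na(amp_deg) & !is.na(peak_vel_dps)
  a <- abs(amp_deg[ok]); v <- peak_vel_dps[ok]
  if (length(a) < min_trials)
    return(structure(list(), reason = "too_few_trials"))
  if (stats::sd(a) < 1e-9)
    return(structure(list(), reason = "degenerate amplitudes"))
  fit <- stats::lm(v ~ a)
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       v8 = unname(co[1] + co[2] * at_deg), n = length(a),
       r2 = summary(fit)$r.squared)
}

#' Per-child aggregates of all saccade measures
#'
#' Collapses one child's trial labels into the study's child-level
#' measures: per saccade type (PS_correct, AS_correct, PE) the trial
#' count, mean promptness, mean gain, mean peak velocity and the
#' main-sequence velocity at 8 deg; plus the proportion measures -- error
#' rate (PE / valid AS trials), corrected rate (corrected PE / PE) and
#' express rate (express PS_correct / PS_correct). Fields with no eligible
#' trials are `NA`, never zero.
#'
#' @param labels trial-label rows of one child ([classify_trials()]).
#' @param target_ecc target eccentricity (deg), default 8.
#' @param min_trials minimum events for the main-sequence fit.
#' @return one-row data.frame of child measures.
#' @export
summarise_child <- function(labels, target_ecc = 8, min_trials = 5) {
  stopifnot(length(unique(labels$child_id)) == 1L)
  val <- labels[labels$status == "valid", ]
  out <- data.frame(child_id = labels$child_id[1])
  for (cls in c("PS_correct", "AS_correct", "PE")) {
    sub <- val[val$class == cls, ]
    tag <- sub("_correct", "", cls)
    n <- nrow(sub)
    out[[paste0("n_", tag)]] <- n
    out[[paste0("recip_srt_", tag)]] <- if (n) mean(1000 / sub$srt_ms) else NA
    out[[paste0("gain_", tag)]] <- if (n) mean(sub$gain) else NA
    out[[paste0("vel_", tag)]] <- if (n) mean(sub$peak_vel_dps) else NA
    ms <- fit_main_sequence(sub$amp_deg, sub$peak_vel_dps,
                            min_trials = min_trials)
    out[[paste0("v8_", tag)]] <- if (length(ms)) ms$v8 else NA_real_
  }
  as_val <- val[val$task == "AS", ]
  n_as <- nrow(as_val)
  n_pe <- sum(as_val$class == "PE")
  out$error_rate <- if (n_as) n_pe / n_as else NA_real_
  out$corrected_rate <- if (n_pe) sum(as_val$corrected[as_val$class == "PE"],
                                      na.rm = TRUE) / n_pe else NA_real_
  n_ps <- sum(val$class == "PS_correct")
  out$es_rate <- if (n_ps) sum(val$express[val$class == "PS_correct"]) / n_ps
                 else NA_real_
  out
}

#' Child-level measures table for a whole cohort
#'
#' [summarise_child()] per child, optionally adding per-child LATER fits of
#' the prosaccade promptness distribution (2-parameter; the early unit is
#' fitted only when `fit_early = TRUE` and the child has enough trials).
#'
#' @param labels cohort trial-label table.
#' @param target_ecc deg.
#' @param min_trials main-sequence minimum.
#' @param later fit per-child prosaccade LATER parameters?
#' @param fit_early include the early unit (needs >= 20 PS trials)?
#' @param grid_density grid stage density for [fit_later()].
#' @return data.frame keyed by `child_id`.
#' @export
cohort_measures <- function(labels, target_ecc = 8, min_trials = 5,
                            later = FALSE, fit_early = FALSE,
                            grid_density = 25L) {
  rows <- lapply(split(labels, labels$child_id), function(lb) {
    m <- summarise_child(lb, target_ecc = target_ecc,
                         min_trials = min_trials)
    if (later) {
      ps <- lb[lb$status == "valid" & lb$class == "PS_correct", ]
      p <- 1000 / ps$srt_ms
      m$later_mu <- m$later_sigma <- m$later_sigma_e <- m$later_ks <- NA_real_
      if (length(p) >= 10) {
        f <- fit_later(p, with_early = FALSE, grid_density = grid_density)
        m$later_mu <- f$mu; m$later_sigma <- f$sigma; m$later_ks <- f$ks
        if (fit_early && length(p) >= 20) {
          f3 <- fit_later(p, with_early = TRUE, grid_density = grid_density)
          m$later_sigma_e <- f3$sigma_e
        }
      }
    }
    m
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Join child measures to covariates: the cohort analysis table
#'
#' @param measures output of [cohort_measures()].
#' @param children child profile/covariate table.
#' @return merged data.frame, one row per child, `group` as a factor with
#'   levels HC, chronic, controlled.
#' @export
build_cohort_table <- function(measures, children) {
  cov_cols <- intersect(c("child_id", "group", "age", "iq", "cbcl_attention",
                          "onset", "duration", "last_seizure",
                          "on_medication"), names(children))
  out <- merge(children[cov_cols], measures, by = "child_id")
  out$group <- factor(out$group, levels = c("HC", "chronic", "controlled"))
  out
}
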