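#' Simulation configuration for a synthetic pro/antisaccade cohort
#'
#' Builds the stated world the generator emulates: three groups of children
#' (healthy controls `HC`, medicated chronic epilepsy `chronic`, unmedicated
#' controlled epilepsy `controlled`), each performing 30 prosaccade (PS) and
#' 30 antisaccade (AS) trials in an overlap paradigm at +-8 deg target
#' eccentricity, sampled at 1000 Hz. Defaults describe one fixed reference
#' cohort: group sizes 48/15/11, per-group LATER
#' promptness parameters, main-sequence kinematics whose expected peak
#' velocity at 8 deg equals the control value 334.6 deg/s, per-task gain
#' means, error rates 0.36/0.65/0.48 and correction probabilities
#' 0.90/0.79/0.65.
#'
#' @param n_per_group integer vector of 3 counts, named `HC`, `chronic`,
#'   `controlled`.
#' @param trials_per_task trials per task per child.
#' @param target_eccentricity_deg horizontal target eccentricity (deg).
#' @param sampling_hz gaze sampling rate (Hz).
#' @param later_params nested list `group -> task -> c(mu, sigma, sigma_e)`
#'   in Hz; tasks `PS` (correct prosaccades), `AS` (correct antisaccades),
#'   `PE` (prosaccade errors in the AS task).
#' @param mainseq main-sequence kinematics `c(slope, intercept, noise_sd)`:
#'   peak velocity = slope * amplitude + intercept + N(0, noise_sd^2), in
#'   deg/s (slope per deg).
#' @param gain_means per-task mean gain (amplitude / eccentricity).
#' @param gain_noise_sd SD of the gain ratio around its task mean.
#' @param as_error list: `slope` of the logistic linking the reflexive
#'   unit's promptness (Hz) to the error probability, and per-group
#'   `target_rate` used to calibrate the intercept at config time. Set
#'   `target_rate` to 0 to disable errors.
#' @param correction_prob per-group probability that an error is followed by
#'   a corrective saccade.
#' @param correction_delay `c(min, max)` ms, uniform delay between error
#'   offset and correction onset.
#' @param blink_rate per-trial probability of a blink overlapping the
#'   response window.
#' @param fixbreak_rate per-trial probability of broken fixation at target
#'   onset.
#' @param covariate_effects named numeric coefficients injecting covariate
#'   effects into generator parameters (all default 0): `age_on_mu` (Hz per
#'   year, all tasks, age centred at 13), `age_on_vel` (deg/s per year on
#'   the velocity intercept), `age_quad_on_vel` (deg/s per squared year;
#'   negative gives an inverted-U peaking at `age_vel_peak`), `age_vel_peak`
#'   (years, default 13), `onset_on_as_vel` (deg/s per year of onset age on
#'   AS velocity intercept, patients), `onset_on_ps_mu` (Hz per year of
#'   onset on PS mu, patients), `duration_on_mu` (Hz per year of duration),
#'   `age_on_error` / `iq_on_error` / `cbcl_on_error` (logit units per unit
#'   covariate on the AS error intercept), `group_mu_offset_chronic` /
#'   `group_mu_offset_controlled` (Hz added to all task mu for that group).
#' @param child_mu_sd between-child SD (Hz) of the realised task `mu`
#'   around its group value; gives the random intercept its variance.
#' @param child_vel_sd between-child SD (deg/s) of the velocity intercept.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return an object of class `sim_config` (validated list).
#' @export
sim_config <- function(n_per_group = c(HC = 48, chronic = 15, controlled = 11),
                       trials_per_task = 30,
                       target_eccentricity_deg = 8,
                       sampling_hz = 1000,
                       later_params = default_later_params(),
                       mainseq = c(slope = 30, intercept = 94.6, noise_sd = 30),
                       gain_means = c(PS = 1.00, AS = 1.21, PE = 0.82),
                       gain_noise_sd = 0.2,
                       as_error = list(slope = 0.5,
                                       target_rate = c(HC = 0.36,
                                                       chronic = 0.65,
                                                       controlled = 0.48)),
                       correction_prob = c(HC = 0.90, chronic = 0.79,
                                           controlled = 0.65),
                       correction_delay = c(100, 250),
                       blink_rate = 0.04,
                       fixbreak_rate = 0.02,
                       covariate_effects = list(),
                       child_mu_sd = 0.5,
                       child_vel_sd = 20,
                       seed = 1L) {
  groups <- c("HC", "chronic", "controlled")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!all(groups %in% names(n_per_group)))
    stop("`n_per_group` must name HC, chronic and controlled", call. = FALSE)
  n_per_group <- n_per_group[groups]
  if (any(n_per_group < 0) || sum(n_per_group) == 0 ||
      any(n_per_group != round(n_per_group)))
    stop("group counts must be non-negative integers with a non-empty cohort",
         call. = FALSE)
  if (trials_per_task <= 0)
    stop("`trials_per_task` must be positive", call. = FALSE)
  stopifnot(target_eccentricity_deg > 0, sampling_hz > 0)
  for (g in groups) for (tk in c("PS", "AS", "PE")) {
    lp <- later_params[[g]][[tk]]
    if (length(lp) != 3 || lp[2] <= 0 || lp[3] < 0)
      stop(sprintf("later_params$%s$%s must be c(mu, sigma>0, sigma_e>=0)",
                   g, tk), call. = FALSE)
  }
  probs <- c(correction_prob, blink_rate, fixbreak_rate,
             as_error$target_rate)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (gain_noise_sd < 0 || mainseq[["noise_sd"]] < 0)
    stop("noise SDs must be >= 0", call. = FALSE)

  ce_default <- list(age_on_mu = 0, age_on_vel = 0, age_quad_on_vel = 0,
                     age_vel_peak = 13, onset_on_as_vel = 0,
                     onset_on_ps_mu = 0, duration_on_mu = 0,
                     age_on_error = 0, iq_on_error = 0, cbcl_on_error = 0,
                     group_mu_offset_chronic = 0,
                     group_mu_offset_controlled = 0)
  unknown <- setdiff(names(covariate_effects), names(ce_default))
  if (length(unknown))
    stop("unknown covariate effect(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ce_default[names(covariate_effects)] <- covariate_effects

  # calibrate the AS-error logistic intercept per group: expected error
  # probability under the group's PE promptness law equals the target rate
  icept <- vapply(groups, function(g) {
    tr <- as_error$target_rate[[g]]
    if (tr <= 0) return(-Inf)
    if (tr >= 1) return(Inf)
    lp <- later_params[[g]][["PE"]]
    calibrate_error_intercept(as_error$slope, tr, lp[1], lp[2], lp[3])
  }, numeric(1))

  structure(list(
    n_per_group = n_per_group, trials_per_task = as.integer(trials_per_task),
    target_eccentricity_deg = target_eccentricity_deg,
    sampling_hz = sampling_hz, later_params = later_params,
    mainseq = mainseq, gain_means = gain_means,
    gain_noise_sd = gain_noise_sd,
    as_error = list(slope = as_error$slope,
                    target_rate = as_error$target_rate, intercept = icept),
    correction_prob = correction_prob, correction_delay = correction_delay,
    blink_rate = blink_rate, fixbreak_rate = fixbreak_rate,
    covariate_effects = ce_default,
    child_mu_sd = child_mu_sd, child_vel_sd = child_vel_sd,
    seed = as.integer(seed),
    target_onset_ms = 200, response_window_ms = 1000
  ), class = "sim_config")
}

#' Default per-group LATER parameters
#'
#' Promptness (1/SRT, Hz) parameters `c(mu, sigma, sigma_e)` per group and
#' saccade type, for the default control/patient reference cohort.
#' `sigma_e` applies to the prosaccade distribution only.
#' @return nested list `group -> task -> numeric(3)`.
#' @export
default_later_params <- function() {
  list(
    HC = list(PS = c(6.04, 1.38, 4.9), AS = c(3.56, 1.07, 0),
              PE = c(7.54, 1.78, 0)),
    chronic = list(PS = c(6.03, 1.96, 4.9), AS = c(3.43, 1.26, 0),
                   PE = c(7.73, 1.66, 0)),
    controlled = list(PS = c(5.50, 1.78, 4.8), AS = c(3.49, 0.67, 0),
                      PE = c(7.01, 2.04, 0))
  )
}

## expected error rate E[plogis(a + b p)] under the race law, by quadrature
calibrate_error_intercept <- function(slope, target, mu, sigma, sigma_e) {
  grid <- seq(1e-4, 0.9999, length.out = 2001)
  # promptness quantiles via inverse CDF (numeric inversion on a fine grid)
  pg <- seq(1e-3, mu + 6 * sigma + 6 * sigma_e + 5, length.out = 4000)
  Fg <- race_cdf(pg, mu, sigma, sigma_e)
  q <- stats::approx(Fg, pg, xout = grid, ties = "ordered", rule = 2)$y
  f <- function(a) mean(stats::plogis(a + slope * q)) - target
  stats::uniroot(f, c(-50, 50), tol = 1e-9)$root
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d HC + %d chronic + %d controlled children\n",
              x$n_per_group[["HC"]], x$n_per_group[["chronic"]],
              x$n_per_group[["controlled"]]))
  cat(sprintf("  %d PS + %d AS trials/child, +-%g deg targets, %g Hz, seed %d\n",
              x$trials_per_task, x$trials_per_task,
              x$target_eccentricity_deg, x$sampling_hz, x$seed))
  invisible(x)
}
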