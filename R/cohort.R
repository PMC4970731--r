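## seed hygiene: run `code` under `seed` without disturbing the caller's RNG
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

rnorm_clamp <- function(n, mean, sd, lo = -Inf, hi = Inf)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Sample promptness values from the LATER race
#'
#' Draws promptness (1/SRT, Hz) as the maximum of a main rate
#' `N(mu, sigma^2)` and an early rate `N(0, sigma_e^2)`; draws where both
#' rates are non-positive are rejected and redrawn, so every value is
#' positive. With `sigma_e = 0` the early unit is disabled and the law is
#' the main Gaussian truncated at zero.
#'
#' @inheritParams race_cdf
#' @param n number of draws.
#' @param seed optional seed (caller's RNG state is preserved).
#' @return numeric vector of `n` positive promptness values (Hz).
#' @export
sample_promptness <- function(mu, sigma, sigma_e = 0, n, seed = NULL) {
  stopifnot(sigma > 0, sigma_e >= 0, n > 0)
  acc <- 1 - stats::pnorm(-mu / sigma) * (if (sigma_e > 0) 0.5 else 1)
  if (acc < 1e-8)
    stop("vanishing acceptance probability: mu too far below 0", call. = FALSE)
  with_local_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      m <- ceiling((n - length(out)) / acc * 1.1) + 16L
      r_main <- stats::rnorm(m, mu, sigma)
      r <- if (sigma_e > 0) pmax(r_main, stats::rnorm(m, 0, sigma_e)) else r_main
      out <- c(out, r[r > 0])
    }
    out[seq_len(n)]
  })
}

#' Generate child profiles for a synthetic cohort
#'
#' Draws one row per child: group membership, demographic and clinical
#' covariates (age, IQ, CBCL attention T-score; age at epilepsy onset,
#' duration and last-seizure recency for patients), and the child-level
#' realisation of every generator parameter (per-task LATER promptness
#' parameters, main-sequence velocity intercepts, error-logit intercept,
#' correction probability) after applying the configured covariate effects.
#' Healthy controls carry `NA` in the epilepsy fields, and onset + duration
#' never exceeds age.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `child_profiles`, one row per child.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  npg <- config$n_per_group
  if (sum(npg) <= 0) stop("empty cohort", call. = FALSE)
  with_local_seed(config$seed, {
    rows <- lapply(c("HC", "chronic", "controlled"), function(g) {
      n <- npg[[g]]
      if (n == 0) return(NULL)
      age <- rnorm_clamp(n, switch(g, HC = 13.1, chronic = 13.1,
                                   controlled = 12.5),
                         switch(g, HC = 2.6, chronic = 2.4, controlled = 2.8),
                         8, 18)
      cbcl <- rnorm_clamp(n, switch(g, HC = 53.9, chronic = 63.1,
                                    controlled = 54.9),
                          switch(g, HC = 5.3, chronic = 12.4,
                                 controlled = 6.2), 30, 100)
      if (g == "HC") {
        iq <- rep(NA_real_, n); onset <- rep(NA_real_, n)
        duration <- rep(NA_real_, n); last_seiz <- rep(NA_real_, n)
        med <- rep(FALSE, n)
      } else {
        iq <- rnorm_clamp(n, if (g == "chronic") 86.7 else 93.8,
                          if (g == "chronic") 15.9 else 16.4, 50, 140)
        onset <- rnorm_clamp(n, if (g == "chronic") 6.5 else 7.9,
                             if (g == "chronic") 2.0 else 2.6, 0.5, age - 0.5)
        duration <- pmin(rnorm_clamp(n, if (g == "chronic") 5.5 else 2.0,
                                     if (g == "chronic") 2.8 else 1.6,
                                     0.1, Inf), age - onset)
        last_seiz <- rnorm_clamp(n, if (g == "chronic") 0.5 else 3.2,
                                 if (g == "chronic") 2.5 else 1.9, 0, age)
        med <- rep(g == "chronic", n)
      }
      data.frame(group = g, age = age, iq = iq, cbcl_attention = cbcl,
                 onset = onset, duration = duration, last_seizure = last_seiz,
                 on_medication = med)
    })
    prof <- do.call(rbind, rows)
    prof$child_id <- sprintf("C%03d", seq_len(nrow(prof)))
    prof <- prof[c("child_id", setdiff(names(prof), "child_id"))]
    prof$group <- factor(prof$group, levels = c("HC", "chronic", "controlled"))

    ce <- config$covariate_effects
    ms <- config$mainseq
    age_c <- prof$age - 13
    grp_off <- ifelse(prof$group == "chronic", ce$group_mu_offset_chronic,
                      ifelse(prof$group == "controlled",
                             ce$group_mu_offset_controlled, 0))
    onset0 <- ifelse(is.na(prof$onset), 0, prof$onset)
    dur0 <- ifelse(is.na(prof$duration), 0, prof$duration)
    # one promptness trait per child, shared across tasks: children with a
    # faster reflexive rise show both more express saccades and more
    # antisaccade errors, reproducing the express/error coupling
    mu_trait <- stats::rnorm(nrow(prof), 0, config$child_mu_sd)
    for (tk in c("PS", "AS", "PE")) {
      lp <- t(vapply(as.character(prof$group),
                     function(g) config$later_params[[g]][[tk]], numeric(3)))
      mu <- lp[, 1] + ce$age_on_mu * age_c + ce$duration_on_mu * dur0 +
        grp_off + mu_trait
      if (tk == "PS") mu <- mu + ce$onset_on_ps_mu * onset0
      prof[[paste0("mu_", tk)]] <- pmax(mu, 0.3)
      prof[[paste0("sigma_", tk)]] <- lp[, 2]
      prof[[paste0("sige_", tk)]] <- lp[, 3]
      vint <- ms[["intercept"]] + ce$age_on_vel * age_c +
        ce$age_quad_on_vel * (prof$age - ce$age_vel_peak)^2 +
        stats::rnorm(nrow(prof), 0, config$child_vel_sd)
      if (tk == "AS") vint <- vint + ce$onset_on_as_vel * onset0
      prof[[paste0("vel_int_", tk)]] <- vint
      prof[[paste0("gain_", tk)]] <- config$gain_means[[tk]]
    }
    prof$vel_slope <- ms[["slope"]]
    icept <- config$as_error$intercept[as.character(prof$group)]
    prof$err_logit <- icept + ce$age_on_error * age_c +
      ce$iq_on_error * (ifelse(is.na(prof$iq), 90, prof$iq) - 90) +
      ce$cbcl_on_error * (prof$cbcl_attention - 50)
    prof$corr_prob <- config$correction_prob[as.character(prof$group)]
    rownames(prof) <- NULL
    class(prof) <- c("child_profiles", "data.frame")
    prof
  })
}
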