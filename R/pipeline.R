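#' Run the full analysis pipeline
#'
#' Orchestrates the stages simulate -> classify -> metrics -> later ->
#' stats -> report with file-based handoff in `out_dir`: each stage reads
#' its upstream CSVs, writes its own, and appends to a JSON run manifest
#' recording config digest and seed. Requesting a stage whose inputs are
#' missing raises an error naming the stage to run first. With
#' `stages = "all"` everything runs in dependency order.
#'
#' @param config list (`run_config`): `out_dir`; `stages` (character subset
#'   of simulate, classify, metrics, later, stats, report, or "all");
#'   `sim` a [sim_config()] (for the simulate stage); `class_params` passed
#'   to [classify_trials()]; `min_trials`; `later_grid` grid density for
#'   group LATER fits; `seed` overriding the sim seed.
#' @return the manifest (list), invisibly.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% "all"
  all_stages <- c("simulate", "classify", "metrics", "later", "stats",
                  "report")
  if (identical(stages, "all")) stages <- all_stages
  stages <- all_stages[all_stages %in% stages]
  if (!length(stages)) stop("no known stage requested", call. = FALSE)

  pth <- function(f) file.path(out_dir, f)
  need <- function(f, stage) {
    if (!file.exists(pth(f)))
      stop(sprintf("missing %s: run the `%s` stage first", f, stage),
           call. = FALSE)
    utils::read.csv(pth(f))
  }
  manifest_file <- pth("manifest.json")
  manifest <- if (file.exists(manifest_file))
    jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  else list(outputs = character(0))
  log_out <- function(stage, files) {
    manifest$outputs <<- union(manifest$outputs, files)
    manifest$stages[[stage]] <<- list(
      files = files, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  }

  sim_cfg <- config$sim %||% sim_config(seed = config$seed %||% 1L)
  if (!is.null(config$seed)) sim_cfg$seed <- as.integer(config$seed)
  manifest$seed <- sim_cfg$seed
  manifest$config_digest <- config_digest(sim_cfg)

  for (st in stages) {
    if (st == "simulate") {
      sim <- simulate_cohort(sim_cfg)
      write_cohort(sim, out_dir, sim_cfg, gaze = isTRUE(config$write_gaze))
      log_out(st, c("covariates.csv", "trials.csv", "events.csv"))
    } else if (st == "classify") {
      trials <- need("trials.csv", "simulate")
      events <- need("events.csv", "simulate")
      labels <- classify_trials(trials, events,
                                params = config$class_params %||% list())
      utils::write.csv(labels, pth("labels.csv"), row.names = FALSE)
      log_out(st, "labels.csv")
    } else if (st == "metrics") {
      labels <- need("labels.csv", "classify")
      children <- need("covariates.csv", "simulate")
      meas <- cohort_measures(labels,
                              target_ecc = sim_cfg$target_eccentricity_deg,
                              min_trials = config$min_trials %||% 5)
      utils::write.csv(meas, pth("measures.csv"), row.names = FALSE)
      cohort <- build_cohort_table(meas, children)
      utils::write.csv(cohort, pth("cohort.csv"), row.names = FALSE)
      log_out(st, c("measures.csv", "cohort.csv"))
    } else if (st == "later") {
      labels <- need("labels.csv", "classify")
      fits <- later_stage(labels, grid_density = config$later_grid %||% 25L)
      utils::write.csv(fits$child, pth("later_child.csv"), row.names = FALSE)
      utils::write.csv(fits$group, pth("later_group.csv"), row.names = FALSE)
      utils::write.csv(fits$reciprobit, pth("reciprobit.csv"),
                       row.names = FALSE)
      log_out(st, c("later_child.csv", "later_group.csv", "reciprobit.csv"))
    } else if (st == "stats") {
      labels <- need("labels.csv", "classify")
      children <- need("covariates.csv", "simulate")
      cohort <- need("cohort.csv", "metrics")
      cohort$group <- factor(cohort$group,
                             levels = c("HC", "chronic", "controlled"))
      tt <- trial_table(labels, children)
      eff <- list()
      for (oc in c("recip_srt", "peak_vel", "gain")) {
        tab <- mixed_model(tt, oc)
        tab$outcome <- oc; tab$analysis <- "mixed_model"
        eff[[oc]] <- tab
      }
      for (oc in c("error_rate", "corrected_rate", "es_rate")) {
        tab <- proportion_glm(cohort, oc)
        if (!is.null(tab)) {
          tab$outcome <- oc; tab$analysis <- "proportion_glm"
          eff[[oc]] <- tab
        }
      }
      effects <- do.call(rbind, eff)
      utils::write.csv(effects, pth("effects.csv"), row.names = FALSE)
      log_out(st, "effects.csv")
    } else if (st == "report") {
      cohort <- need("cohort.csv", "metrics")
      cohort$group <- factor(cohort$group,
                             levels = c("HC", "chronic", "controlled"))
      rep <- make_report(cohort)
      utils::write.csv(rep$summary, pth("summary.csv"), row.names = FALSE)
      utils::write.csv(rep$scatter, pth("scatter_es_error.csv"),
                       row.names = FALSE)
      log_out(st, c("summary.csv", "scatter_es_error.csv"))
    }
  }
  jsonlite::write_json(manifest, manifest_file, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' LATER fits for a labelled cohort
#'
#' Per-child 2-parameter fits of the prosaccade promptness distribution,
#' per-child early-sigma (3-parameter) fits when enough trials exist, and
#' pooled-by-group fits for the AS and PE distributions (following the
#' convention that AS/PE parameters come from grouped data), plus
#' reciprobit coordinates per group and task.
#'
#' @param labels trial-label table joined or joinable to groups via a
#'   `group` column; if absent, grouping is skipped.
#' @param grid_density grid stage density.
#' @param fit_early fit per-child early sigma (needs >= 20 PS trials)?
#' @return list of data.frames `child`, `group`, `reciprobit`.
#' @export
later_stage <- function(labels, grid_density = 25L, fit_early = FALSE) {
  val <- labels[labels$status == "valid", ]
  child_rows <- lapply(split(val, val$child_id), function(d) {
    ps <- d[d$class == "PS_correct", ]
    row <- data.frame(child_id = d$child_id[1], task = "PS",
                      mu = NA_real_, sigma = NA_real_, sigma_e = NA_real_,
                      ks = NA_real_, n = nrow(ps), converged = NA)
    if (nrow(ps) >= 10) {
      f <- fit_later(1000 / ps$srt_ms, grid_density = grid_density)
      row[c("mu", "sigma", "ks", "converged")] <-
        list(f$mu, f$sigma, f$ks, f$converged)
      if (fit_early && nrow(ps) >= 20)
        row$sigma_e <- fit_later(1000 / ps$srt_ms, with_early = TRUE,
                                 grid_density = grid_density)$sigma_e
    }
    row
  })
  grp_col <- if ("group" %in% names(labels)) labels$group else
    rep("all", nrow(labels))
  valg <- cbind(val, grp = grp_col[labels$status == "valid"])
  group_rows <- list(); recip <- list()
  for (g in unique(valg$grp)) for (tk in c("AS_correct", "PE")) {
    d <- valg[valg$grp == g & valg$class == tk, ]
    if (nrow(d) < 10) next
    p <- 1000 / d$srt_ms
    f <- fit_later(p, grid_density = grid_density)
    group_rows[[paste(g, tk)]] <- data.frame(
      group = g, task = sub("_correct", "", tk), mu = f$mu, sigma = f$sigma,
      sigma_e = 0, ks = f$ks, n = f$n, converged = f$converged)
    rc <- reciprobit_coords(p)
    recip[[paste(g, tk)]] <- cbind(group = g,
                                   task = sub("_correct", "", tk), rc)
  }
  for (g in unique(valg$grp)) {
    d <- valg[valg$grp == g & valg$class == "PS_correct", ]
    if (nrow(d) >= 2)
      recip[[paste(g, "PS")]] <- cbind(group = g, task = "PS",
                                       reciprobit_coords(1000 / d$srt_ms))
  }
  list(child = do.call(rbind, c(child_rows,
                                list(make.row.names = FALSE))),
       group = if (length(group_rows)) do.call(rbind, group_rows)
               else data.frame(),
       reciprobit = if (length(recip)) do.call(rbind, recip)
                    else data.frame())
}

#' Summary tables and plot data for a cohort
#'
#' Produces the study-style summary: group means (SD) of every saccade
#' measure, and the per-child express-rate vs error-rate scatter with a
#' per-group regression slope (the express/inhibition coupling figure).
#'
#' @param cohort child-level table ([build_cohort_table()]).
#' @return list with `summary` (measure x group long table: `measure`,
#'   `group`, `n`, `mean`, `sd`) and `scatter` (per child `es_rate`,
#'   `error_rate`, `group`) carrying attribute `slopes` (per-group OLS
#'   slope of error rate on express rate).
#' @export
make_report <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  measures <- intersect(
    c("recip_srt_PS", "recip_srt_AS", "recip_srt_PE",
      "vel_PS", "vel_AS", "vel_PE", "gain_PS", "gain_AS", "gain_PE",
      "v8_PS", "v8_AS", "v8_PE", "error_rate", "corrected_rate", "es_rate"),
    names(cohort))
  rows <- list()
  for (m in measures) for (g in levels(cohort$group)) {
    v <- cohort[[m]][cohort$group == g]
    v <- v[!is.na(v)]
    rows[[paste(m, g)]] <- data.frame(
      measure = m, group = g, n = length(v),
      mean = if (length(v)) mean(v) else NA_real_,
      sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  summary <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  scatter <- cohort[!is.na(cohort$es_rate) & !is.na(cohort$error_rate),
                    c("child_id", "group", "es_rate", "error_rate")]
  slopes <- vapply(levels(cohort$group), function(g) {
    d <- scatter[scatter$group == g, ]
    if (nrow(d) < 3 || stats::sd(d$es_rate) == 0) return(NA_real_)
    unname(stats::coef(stats::lm(error_rate ~ es_rate, data = d))[2])
  }, numeric(1))
  attr(scatter, "slopes") <- slopes
  list(summary = summary, scatter = scatter)
}
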