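#' Bonferroni adjustment for a family of pairwise contrasts
#'
#' @param p raw p-values.
#' @param m family size; 3 for the three pairwise group contrasts.
#' @return adjusted p-values `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = 3) pmin(1, m * p)

#' Trial-level analysis table
#'
#' Valid trials only, with saccade type recoded PS / AS / PE, the
#' trial-level outcomes (reciprocal SRT in Hz, gain, peak velocity) and the
#' child covariates joined in.
#'
#' @param labels trial-label table ([classify_trials()]).
#' @param children child covariate table.
#' @return data.frame, one row per valid trial.
#' @export
trial_table <- function(labels, children) {
  d <- labels[labels$status == "valid" & labels$class != "none", ]
  d$type <- factor(sub("_correct", "", d$class), levels = c("PS", "AS", "PE"))
  d$recip_srt <- 1000 / d$srt_ms
  d$peak_vel <- d$peak_vel_dps
  cov_cols <- intersect(c("child_id", "group", "age", "iq", "cbcl_attention",
                          "onset", "duration", "last_seizure"),
                        names(children))
  out <- merge(d, children[cov_cols], by = "child_id")
  out$group <- factor(out$group, levels = c("HC", "chronic", "controlled"))
  out$child_id <- factor(out$child_id)
  out
}

effects_table <- function(term, F, df_num, df_den, p) {
  data.frame(term = term, F = F, df_num = df_num, df_den = df_den, p = p,
             eta_sq = F * df_num / (F * df_num + df_den))
}

## pairwise group contrasts from a fitted model's coefficients
group_contrasts <- function(beta, V, df, X_cells, groups, label) {
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    L <- X_cells[pr[1], ] - X_cells[pr[2], ]
    est <- sum(L * beta)
    se <- sqrt(drop(t(L) %*% V %*% L))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df)
    data.frame(family = label, contrast = paste(pr[1], "-", pr[2]),
               estimate = est, se = se, t = tval, df = df, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni_adjust(out$p_raw, m = nrow(out))
  out
}

#' Random-intercept mixed model on trial-level outcomes
#'
#' Two-level model of a trial outcome (reciprocal SRT, peak velocity or
#' gain): fixed full-factorial effects of saccade type (PS, AS, PE) and
#' group (HC, chronic, controlled) plus their interaction, and a random
#' intercept per child; fitted by REML ([nlme::lme()]) with marginal
#' (type-III-style) F tests. Pairwise group contrasts are computed within
#' each saccade type from the fixed-effect covariance, with Bonferroni
#' adjustment over the 3 contrasts of a family. On a singular or
#' non-converging fit the analysis falls back to an ordinary linear model
#' on child-type means, with a warning.
#'
#' @param data trial-level table from [trial_table()].
#' @param outcome one of `"recip_srt"`, `"peak_vel"`, `"gain"`.
#' @param extra_fixed optional character vector of additional fixed-effect
#'   column names (e.g. `"age"`).
#' @return an `effects_table` data.frame (`term`, `F`, `df_num`, `df_den`,
#'   `p`, `eta_sq`) with attributes `contrasts` (pairwise table) and
#'   `fallback` (flag).
#' @export
mixed_model <- function(data, outcome = c("recip_srt", "peak_vel", "gain"),
                        extra_fixed = NULL) {
  outcome <- match.arg(outcome)
  d <- data[!is.na(data[[outcome]]), ]
  d$.y <- d[[outcome]]
  if (stats::sd(d$.y) < 1e-12)
    stop("degenerate fit: outcome is constant", call. = FALSE)
  d <- droplevels(d)
  rhs <- paste(c("type * group", extra_fixed), collapse = " + ")
  form <- stats::as.formula(paste(".y ~", rhs))
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | child_id, data = d, method = "REML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, returnObject = TRUE)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("mixed model failed (", conditionMessage(fit),
            "); falling back to child-mean linear model", call. = FALSE)
    agg <- stats::aggregate(.y ~ child_id + type + group, data = d, FUN = mean)
    lmfit <- stats::lm(stats::as.formula(paste(".y ~",
                                               paste(c("type * group"),
                                                     collapse = " + "))),
                       data = agg)
    dr <- stats::drop1(stats::lm(.y ~ type + group, data = agg), test = "F")
    tab <- effects_table(rownames(dr)[-1], dr$`F value`[-1], dr$Df[-1],
                         lmfit$df.residual, dr$`Pr(>F)`[-1])
    attr(tab, "fallback") <- TRUE
    return(tab)
  }
  an <- stats::anova(fit, type = "marginal")
  keep <- rownames(an) != "(Intercept)"
  tab <- effects_table(rownames(an)[keep], an$`F-value`[keep],
                       an$numDF[keep], an$denDF[keep], an$`p-value`[keep])
  beta <- nlme::fixef(fit)
  V <- fit$varFix
  df_grp <- an["group", "denDF"]
  contrasts <- list()
  groups <- levels(d$group)
  if (length(groups) > 1) {
    for (tp in levels(d$type)) {
      nd <- expand.grid(type = factor(tp, levels(d$type)),
                        group = factor(groups, levels(d$group)))
      if (!is.null(extra_fixed))
        for (cf in extra_fixed) nd[[cf]] <- mean(d[[cf]], na.rm = TRUE)
      X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), nd)
      rownames(X) <- groups
      contrasts[[tp]] <- group_contrasts(beta, V, df_grp, X, groups,
                                         label = paste0(outcome, ":", tp))
    }
  }
  attr(tab, "contrasts") <- do.call(rbind, contrasts)
  attr(tab, "fallback") <- FALSE
  tab
}

#' Linear model on child-level proportions and parameters
#'
#' The study's GLM stage: child-level outcomes (error rate, corrected
#' rate, express rate, LATER sigma / early sigma, velocity at 8 deg) are
#' analysed untransformed with group and optional covariate terms;
#' marginal F tests per term, partial eta squared, and Bonferroni-adjusted
#' pairwise group contrasts.
#'
#' @param cohort child-level table ([build_cohort_table()]).
#' @param outcome outcome column name.
#' @param predictors character vector of predictor columns (default
#'   `"group"`).
#' @return `effects_table` with attribute `contrasts`, or `NULL`
#'   (invisibly, with a message) when the outcome is entirely missing.
#' @export
proportion_glm <- function(cohort, outcome, predictors = "group") {
  y <- cohort[[outcome]]
  if (is.null(y)) stop("unknown outcome column: ", outcome, call. = FALSE)
  d <- cohort[!is.na(y), , drop = FALSE]
  if (!nrow(d)) {
    message("outcome ", outcome, " entirely missing; analysis skipped")
    return(invisible(NULL))
  }
  d <- droplevels(d)
  for (pr in predictors) {
    v <- d[[pr]]
    if (length(unique(v[!is.na(v)])) < 2)
      stop("predictor column `", pr, "` is constant (rank deficient)",
           call. = FALSE)
  }
  d$.y <- d[[outcome]]
  form <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- stats::lm(form, data = d)
  dr <- stats::drop1(fit, test = "F")
  keep <- !is.na(dr$Df)
  tab <- effects_table(rownames(dr)[keep], dr$`F value`[keep], dr$Df[keep],
                       fit$df.residual, dr$`Pr(>F)`[keep])
  if ("group" %in% predictors && nlevels(d$group) > 1) {
    nd <- data.frame(group = factor(levels(d$group), levels(d$group)))
    for (pr in setdiff(predictors, "group"))
      nd[[pr]] <- mean(d[[pr]], na.rm = TRUE)
    X <- stats::model.matrix(form[-2], nd)
    rownames(X) <- levels(d$group)
    attr(tab, "contrasts") <- group_contrasts(
      stats::coef(fit), stats::vcov(fit), fit$df.residual, X,
      levels(d$group), label = outcome)
  }
  tab
}

#' Age-curve and stepwise epilepsy-factor models
#'
#' Two analyses behind one interface. With `form = "quadratic"` the
#' outcome is regressed on age and age squared (curve estimation); the
#' vertex age `-b1 / (2 b2)` is reported, locating developmental peaks.
#' With `stepwise = TRUE` the epilepsy factors (age at onset, duration,
#' last-seizure recency) are entered forward, on patient rows only, on top
#' of a base model with patient group and IQ; a factor enters when its
#' F-test improvement has p below `alpha_enter`.
#'
#' @param cohort child-level table.
#' @param outcome outcome column.
#' @param predictors epilepsy-factor columns to consider in stepwise mode.
#' @param form `"linear"` or `"quadratic"` age trend.
#' @param stepwise run forward entry of epilepsy factors?
#' @param alpha_enter entry threshold, default 0.05.
#' @return `effects_table`; for quadratic form the attribute `vertex_age`
#'   holds the fitted peak; for stepwise the attribute `retained` lists the
#'   entered factors.
#' @export
age_and_epilepsy_models <- function(cohort, outcome,
                                    predictors = c("onset", "duration",
                                                   "last_seizure"),
                                    form = c("linear", "quadratic"),
                                    stepwise = FALSE, alpha_enter = 0.05) {
  form <- match.arg(form)
  d <- cohort[!is.na(cohort[[outcome]]), , drop = FALSE]
  d$.y <- d[[outcome]]
  if (stepwise) {
    pat <- droplevels(d[d$group %in% c("chronic", "controlled"), ])
    if (!nrow(pat))
      stop("epilepsy-factor models need patient rows; none present",
           call. = FALSE)
    if (any(!predictors %in% names(pat)) ||
        any(vapply(predictors, function(p) all(is.na(pat[[p]])), logical(1))))
      stop("patients-only predictors requested on rows without them",
           call. = FALSE)
    base_terms <- c(if (nlevels(pat$group) > 1) "group",
                    if (!all(is.na(pat$iq))) "iq")
    if (is.null(base_terms)) base_terms <- "1"
    fit <- stats::lm(stats::as.formula(
      paste(".y ~", paste(base_terms, collapse = " + "))), data = pat)
    remaining <- predictors
    retained <- character(0)
    repeat {
      if (!length(remaining)) break
      adds <- stats::add1(fit, scope = stats::as.formula(
        paste("~ . +", paste(remaining, collapse = " + "))), test = "F")
      cand <- rownames(adds)[-1]
      pv <- adds$`Pr(>F)`[-1]
      j <- which.min(pv)
      if (!length(j) || is.na(pv[j]) || pv[j] > alpha_enter) break
      retained <- c(retained, cand[j])
      remaining <- setdiff(remaining, cand[j])
      fit <- stats::update(fit, stats::as.formula(paste(". ~ . +", cand[j])))
    }
    dr <- stats::drop1(fit, test = "F")
    keep <- !is.na(dr$Df)
    tab <- effects_table(rownames(dr)[keep], dr$`F value`[keep],
                         dr$Df[keep], fit$df.residual, dr$`Pr(>F)`[keep])
    attr(tab, "retained") <- retained
    attr(tab, "coefficients") <- stats::coef(fit)
    return(tab)
  }
  fit <- if (form == "quadratic")
    stats::lm(.y ~ age + I(age^2), data = d)
  else stats::lm(.y ~ age, data = d)
  dr <- stats::drop1(fit, test = "F")
  keep <- !is.na(dr$Df)
  tab <- effects_table(rownames(dr)[keep], dr$`F value`[keep], dr$Df[keep],
                       fit$df.residual, dr$`Pr(>F)`[keep])
  if (form == "quadratic") {
    co <- stats::coef(fit)
    attr(tab, "vertex_age") <- unname(-co["age"] / (2 * co["I(age^2)"]))
  }
  tab
}

#' Bivariate association statistics
#'
#' `"spearman"`: rank correlation with average-rank tie handling and the
#' usual t approximation for the p-value. `"ols_r2_change"`: the increase
#' in R squared when `x` is added to a base linear model of `y` (supply
#' the base predictors via `base`), with the partial-F p-value.
#'
#' @param x,y paired numeric vectors (pairs with missing values dropped).
#' @param method `"spearman"` or `"ols_r2_change"`.
#' @param base optional data.frame of base-model predictors for the
#'   R-squared-change method.
#' @return list with `statistic` (`rho` or `r2_change`) and `p`.
#' @export
assoc_stats <- function(x, y, method = c("spearman", "ols_r2_change"),
                        base = NULL) {
  method <- match.arg(method)
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(base)) ok <- ok & stats::complete.cases(base)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input", call. = FALSE)
  if (method == "spearman") {
    rho <- stats::cor(rank(x), rank(y))
    n <- length(x)
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
    p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tval), n - 2)
    return(list(statistic = rho, p = p))
  }
  bd <- if (is.null(base)) data.frame(row.names = seq_along(y))
        else as.data.frame(base)[ok, , drop = FALSE]
  d0 <- cbind(.y = y, bd)
  f0 <- stats::lm(.y ~ ., data = d0)
  d1 <- cbind(d0, .x = x)
  f1 <- stats::lm(.y ~ ., data = d1)
  r2c <- summary(f1)$r.squared - summary(f0)$r.squared
  an <- stats::anova(f0, f1)
  list(statistic = r2c, p = an$`Pr(>F)`[2])
}
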