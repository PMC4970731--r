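#' LATER latency-distribution model with an early-saccade race unit
#'
#' Under the LATER (Linear Approach to Threshold with Ergodic Rate) model a
#' decision signal rises to threshold at a normally distributed rate, so
#' promptness -- the reciprocal of saccadic reaction time, in Hz -- is
#' Gaussian: the "recinormal" latency law. Very short-latency (express)
#' saccades are carried by a second, low-mean high-variance unit racing the
#' main unit. `oculokit` uses the conventional construction: the early unit
#' has mean 0 and standard deviation `sigma_e`, the observed promptness is
#' the maximum of the two rates, and draws where both rates are non-positive
#' are rejected, so all promptness values are positive.
#'
#' `race_cdf()` evaluates the cumulative distribution of this race,
#' \deqn{F(p) = \frac{\Phi\!\left(\frac{p-\mu}{\sigma}\right)
#'   \Phi\!\left(\frac{p}{\sigma_E}\right) - G(0)}{1 - G(0)},}
#' where \eqn{G(p)} is the unconditioned product and the renormalisation
#' conditions on promptness > 0. With `sigma_e = 0` the early unit is
#' disabled and `F` reduces to the main unit's Gaussian truncated at 0.
#'
#' @param p numeric vector of promptness values (Hz), > 0.
#' @param mu,sigma mean and SD of the main unit (Hz); `sigma > 0`.
#' @param sigma_e SD of the early unit (Hz); `0` disables the unit.
#' @return `race_cdf`: vector of probabilities, same length as `p`.
#' @seealso [fit_later()], [reciprobit_coords()], [sample_promptness()]
#' @export
race_cdf <- function(p, mu, sigma, sigma_e = 0) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (sigma_e < 0) stop("`sigma_e` must be >= 0", call. = FALSE)
  G <- if (sigma_e > 0) {
    function(q) stats::pnorm((q - mu) / sigma) * stats::pnorm(q / sigma_e)
  } else {
    function(q) stats::pnorm((q - mu) / sigma) * as.numeric(q >= 0)
  }
  g0 <- if (sigma_e > 0) stats::pnorm(-mu / sigma) * 0.5 else 0
  out <- (G(p) - g0) / (1 - g0)
  out[p <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' One-sample Kolmogorov-Smirnov statistic
#'
#' Exact sup-distance between the empirical CDF of a sample and a model CDF,
#' evaluated at the sorted sample points:
#' \eqn{\max_i \max(|F(p_{(i)}) - i/n|, |F(p_{(i)}) - (i-1)/n|)}.
#'
#' @param x numeric sample (any order).
#' @param cdf vectorised CDF function.
#' @return the KS sup-distance in `[0, 1]`.
#' @export
ks_statistic <- function(x, cdf) {
  n <- length(x)
  if (n < 1L) stop("need at least one observation", call. = FALSE)
  Fp <- cdf(sort(x))
  i <- seq_len(n)
  max(abs(Fp - i / n), abs(Fp - (i - 1) / n))
}

## KS sup restricted to pre-sorted values with their original ecdf ranks.
## Used by the grid stage on a stratified subsample: a lower bound on the
## full-sample statistic that preserves the location of the minimum well.
ks_at <- function(sorted_sub, lo_rank, hi_rank, n, mu, sigma, sigma_e) {
  Fp <- race_cdf(sorted_sub, mu, sigma, sigma_e)
  max(abs(Fp - hi_rank / n), abs(Fp - lo_rank / n))
}

#' Fit LATER parameters by Kolmogorov-Smirnov minimisation
#'
#' Estimates the main-unit mean `mu` and SD `sigma` (and, when
#' `with_early = TRUE`, the early-unit SD `sigma_e`) of the promptness
#' distribution by minimising the one-sample KS statistic against
#' [race_cdf()] -- the procedure the SPIC program applies to latency data.
#' A deterministic coarse grid search over `bounds` seeds a Nelder-Mead
#' refinement (tolerance 1e-4 in KS); there are no random restarts.
#'
#' @param p promptness sample (Hz), all > 0; `n >= 10` for the 2-parameter
#'   fit, `n >= 20` with the early unit.
#' @param with_early fit the early-unit SD as a third parameter?
#' @param bounds named list with elements `mu`, `sigma`, `sigma_e`, each a
#'   length-2 numeric range (Hz).
#' @param grid_density grid points per parameter for the coarse stage.
#' @return an object of class `later_fit`: list with `mu`, `sigma`,
#'   `sigma_e`, `ks`, `n`, `converged`.
#' @examples
#' set.seed(1)
#' p <- sample_promptness(6.04, 1.38, 0, 500)
#' fit_later(p)
#' @export
fit_later <- function(p, with_early = FALSE,
                      bounds = list(mu = c(1e-3, 20), sigma = c(1e-3, 10),
                                    sigma_e = c(0, 20)),
                      grid_density = 25L) {
  n <- length(p)
  n_min <- if (with_early) 20L else 10L
  if (n < n_min)
    stop(sprintf("need at least %d observations for this fit", n_min),
         call. = FALSE)
  if (stats::sd(p) == 0) stop("degenerate sample: all values equal",
                              call. = FALSE)
  sp <- sort(p)
  i <- seq_len(n)
  # stratified subsample for the grid stage only (exact ranks retained)
  if (n > 2000L) {
    keep <- unique(round(seq(1L, n, length.out = 2000L)))
  } else keep <- i
  sub <- sp[keep]

  mus <- seq(bounds$mu[1], bounds$mu[2], length.out = grid_density)
  sgs <- seq(bounds$sigma[1], bounds$sigma[2], length.out = grid_density)
  ses <- if (with_early)
    seq(bounds$sigma_e[1], bounds$sigma_e[2], length.out = grid_density)
  else 0

  best <- c(ks = Inf, mu = NA, sigma = NA, sigma_e = 0)
  for (se in ses) {
    Fe <- if (se > 0) stats::pnorm(sub / se) else rep(1, length(sub))
    pe0 <- if (se > 0) 0.5 else 0
    for (sg in sgs) {
      z <- outer(sub, mus, function(q, m) stats::pnorm((q - m) / sg))
      g0 <- if (se > 0) stats::pnorm(-mus / sg) * pe0 else 0
      Fm <- sweep(sweep(z * Fe, 2, g0, "-"), 2, 1 - g0, "/")
      d <- pmax(abs(Fm - keep[row(Fm)] / n), abs(Fm - (keep[row(Fm)] - 1) / n))
      ks_col <- apply(d, 2, max)
      j <- which.min(ks_col)
      if (ks_col[j] < best["ks"])
        best <- c(ks = ks_col[j], mu = mus[j], sigma = sg, sigma_e = se)
    }
  }

  obj <- function(th) {
    mu <- th[1]; sg <- th[2]
    se <- if (with_early) th[3] else 0
    if (mu < bounds$mu[1] || mu > bounds$mu[2] ||
        sg < bounds$sigma[1] || sg > bounds$sigma[2] ||
        (with_early && (se < bounds$sigma_e[1] || se > bounds$sigma_e[2])))
      return(1)
    Fp <- race_cdf(sp, mu, sg, se)
    max(abs(Fp - i / n), abs(Fp - (i - 1) / n))
  }
  start <- if (with_early) unname(best[c("mu", "sigma", "sigma_e")])
           else unname(best[c("mu", "sigma")])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-6, abstol = 1e-6,
                                     maxit = 2000L))
  grid_ks <- obj(start)
  use_opt <- opt$value <= grid_ks
  th <- if (use_opt) opt$par else start
  ks <- if (use_opt) opt$value else grid_ks
  at_bound <- th[1] <= bounds$mu[1] + 1e-8 || th[1] >= bounds$mu[2] - 1e-8 ||
    th[2] <= bounds$sigma[1] + 1e-8 || th[2] >= bounds$sigma[2] - 1e-8 ||
    (with_early && th[3] >= bounds$sigma_e[2] - 1e-8)
  structure(list(mu = th[1], sigma = th[2],
                 sigma_e = if (with_early) max(th[3], 0) else 0,
                 ks = ks, n = n, converged = use_opt && !at_bound),
            class = "later_fit")
}

#' @export
print.later_fit <- function(x, ...) {
  cat(sprintf(
    "LATER fit (KS minimisation): mu = %.3f Hz, sigma = %.3f Hz, sigma_e = %.3f Hz\n",
    x$mu, x$sigma, x$sigma_e))
  cat(sprintf("  KS = %.4f on n = %d%s\n", x$ks, x$n,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' Reciprobit coordinates of a latency sample
#'
#' A recinormal latency population plots as a straight line when the
#' cumulative probability (probit axis) is drawn against minus the
#' reciprocal of latency. Returns, for each observation sorted by latency,
#' `x = -1/latency` (1/s) and `y = qnorm((i - 0.5)/n)`.
#'
#' @param p promptness sample (Hz), `n >= 2`.
#' @return data.frame with `latency_ms`, `x`, `y`.
#' @export
reciprobit_coords <- function(p) {
  n <- length(p)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  lat_s <- sort(1 / p)           # latency in s, ascending
  i <- seq_len(n)
  data.frame(latency_ms = lat_s * 1000,
             x = -1 / lat_s,
             y = stats::qnorm((i - 0.5) / n))
}

#' Express-window probability mass of the race model
#'
#' Probability that a latency drawn from the promptness race falls inside a
#' latency window (default the 80--120 ms express range).
#'
#' @inheritParams race_cdf
#' @param window latency window in ms, length 2.
#' @return scalar probability.
#' @export
express_mass <- function(mu, sigma, sigma_e = 0, window = c(80, 120)) {
  lo_p <- 1000 / window[2]  # latency upper bound -> promptness lower bound
  hi_p <- 1000 / window[1]
  race_cdf(hi_p, mu, sigma, sigma_e) - race_cdf(lo_p, mu, sigma, sigma_e)
}

#' Calibrate the early-unit SD to a target express proportion
#'
#' Finds `sigma_e` such that the race model's mass in the express latency
#' window equals `target` at fixed `(mu, sigma)`. When `condition_window`
#' is given (default the 80--1000 ms validity window) the target is the
#' conditional mass given a valid latency -- the scale on which the
#' express proportion is reported, since its denominator contains valid
#' trials only. The window mass is increasing in `sigma_e` only up to an
#' interior maximum; if `target` exceeds the attainable supremum the
#' maximiser is returned with a warning, since no parameter reaches the
#' target exactly.
#'
#' @inheritParams race_cdf
#' @param target desired express-window probability.
#' @param upper search upper bound for `sigma_e` (Hz).
#' @param window latency window in ms.
#' @param condition_window latency validity window in ms, or `NULL` for
#'   the unconditional mass.
#' @return calibrated `sigma_e` (Hz).
#' @export
calibrate_sigma_e <- function(mu, sigma, target, upper = 20,
                              window = c(80, 120),
                              condition_window = c(80, 1000)) {
  stopifnot(target > 0, target < 1)
  f <- function(se) {
    m <- express_mass(mu, sigma, se, window)
    if (is.null(condition_window)) m
    else m / express_mass(mu, sigma, se, condition_window)
  }
  opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = 1e-6)
  if (opt$objective < target) {
    warning(sprintf(
      "target mass %.3f exceeds attainable maximum %.4f; returning maximiser",
      target, opt$objective), call. = FALSE)
    return(opt$maximum)
  }
  # mass is monotone increasing on [0, maximiser]; root-find there
  stats::uniroot(function(se) f(se) - target, c(0, opt$maximum),
                 tol = 1e-8)$root
}
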