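#' Pyrene assembly curve
#'
#' Raw fluorescence versus time from a pyrene-actin polymerization assay,
#' plus the assay composition needed to convert signal to polymer
#' concentration (the canonical condition is 4 uM monomeric actin
#' containing 5% pyrene-labelled actin, sampled at 1 s intervals).
#'
#' @param times time points (s), strictly increasing.
#' @param signal fluorescence (arbitrary units).
#' @param total_actin total monomeric actin (uM).
#' @param pyrene_fraction fraction of labelled actin.
#' @return object of class `assembly_curve`.
#' @export
assembly_curve <- function(times, signal, total_actin = 4, pyrene_fraction = 0.05) {
  if (length(times) != length(signal))
    abort("arpdyn_shape_error", "times and signal lengths differ")
  if (length(times) > 1L && any(diff(times) <= 0))
    abort("arpdyn_parse_error", "curve times must be strictly increasing")
  if (total_actin <= 0) abort("arpdyn_spec_error", "total_actin must be positive")
  structure(list(times = as.numeric(times), signal = as.numeric(signal),
                 total_actin = total_actin, pyrene_fraction = pyrene_fraction),
            class = "assembly_curve")
}

#' Fluorescence calibration for an assembly curve
#'
#' @param f_baseline fluorescence at 0% polymer (AU).
#' @param f_plateau fluorescence when all polymerizable actin is filament
#'   (AU).
#' @param critical_conc critical concentration left monomeric at steady
#'   state (uM); 0.1 uM is a standard barbed-end value, 0 idealises it away.
#' @return object of class `curve_calibration`.
#' @export
curve_calibration <- function(f_baseline, f_plateau, critical_conc = 0.1) {
  if (f_plateau <= f_baseline)
    abort("arpdyn_calibration_error",
          "f_plateau (%g) must exceed f_baseline (%g)", f_plateau, f_baseline)
  if (critical_conc < 0)
    abort("arpdyn_calibration_error", "critical_conc must be >= 0")
  structure(list(f_baseline = f_baseline, f_plateau = f_plateau,
                 critical_conc = critical_conc),
            class = "curve_calibration")
}

#' Kinetics configuration
#'
#' @param k_plus barbed-end association rate constant (uM^-1 s^-1);
#'   default 10.
#' @param rate_fraction polymerized fraction at which the assembly rate is
#'   read out; default 0.8 (i.e. "at 80% of polymerization").
#' @param slope_window fraction of curve points in the local least-squares
#'   slope window (minimum 7 points); default 0.05.
#' @return object of class `kinetics_config`.
#' @export
kinetics_config <- function(k_plus = 10, rate_fraction = 0.8, slope_window = 0.05) {
  if (k_plus <= 0) abort("arpdyn_spec_error", "k_plus must be positive")
  if (rate_fraction <= 0 || rate_fraction >= 1)
    abort("arpdyn_spec_error", "rate_fraction must lie in (0, 1)")
  structure(list(k_plus = k_plus, rate_fraction = rate_fraction,
                 slope_window = slope_window),
            class = "kinetics_config")
}

#' Convert a fluorescence curve to polymer concentration
#'
#' Linear map between calibration anchors:
#' `polymer(t) = (signal - f_baseline) / (f_plateau - f_baseline) *
#' (total_actin - critical_conc)`, clipped to the physical range.
#'
#' @param curve an [assembly_curve()].
#' @param cal a [curve_calibration()].
#' @return object of class `polymer_series`: data.frame with `time_s`,
#'   `polymer_uM`, plus attributes `capacity_uM` (polymerizable pool),
#'   `total_actin`, `critical_conc`.
#' @export
normalize_curve <- function(curve, cal) {
  capacity <- curve$total_actin - cal$critical_conc
  if (capacity <= 0)
    abort("arpdyn_calibration_error",
          "critical concentration (%g uM) >= total actin (%g uM)",
          cal$critical_conc, curve$total_actin)
  p <- (curve$signal - cal$f_baseline) / (cal$f_plateau - cal$f_baseline) * capacity
  p <- pmin(pmax(p, 0), capacity)
  out <- data.frame(time_s = curve$times, polymer_uM = p)
  attr(out, "capacity_uM") <- capacity
  attr(out, "total_actin") <- curve$total_actin
  attr(out, "critical_conc") <- cal$critical_conc
  class(out) <- c("polymer_series", "data.frame")
  out
}

## Crossing detection on noisy curves: the first raw sample above a target
## is biased early (any upward noise excursion triggers it), so targets are
## located on a centred running mean; interpolation and slope fits still use
## the raw samples. The window (0.5% of points) trades noise rejection
## against the curvature bias of the mean (~ k*w^2/24 on an exponential
## approach), which stays below 0.3% of the half-time at this width.
smooth_series <- function(p, window = max(5L, ceiling(0.005 * length(p)))) {
  if (length(p) < window || window < 3L) return(p)
  if (window %% 2L == 0L) window <- window + 1L
  sm <- stats::filter(p, rep(1 / window, window), sides = 2L)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- p[is.na(sm)]
  sm
}

first_crossing <- function(times, p, target) {
  sm <- smooth_series(p)
  i <- which(sm >= target)[1L]
  if (is.na(i)) return(list(index = NA_integer_, time = NA_real_))
  t_cross <- if (i == 1L) times[1L] else {
    t0 <- times[i - 1L]; t1 <- times[i]
    p0 <- sm[i - 1L]; p1 <- sm[i]
    if (p1 == p0) t1 else t0 + (target - p0) / (p1 - p0) * (t1 - t0)
  }
  list(index = i, time = t_cross)
}

## Plateau estimate and censoring rule shared by half_time/rate_at_fraction:
## plateau = mean of the final 5% of samples; the curve counts as plateaued
## only if the average slope over its final 10% is < 5% of the peak slope
## (a still-rising truncated curve fails this and is flagged censored).
curve_plateau <- function(times, polymer) {
  n <- length(times)
  tail_n <- max(3L, ceiling(0.05 * n))
  plateau <- mean(polymer[(n - tail_n + 1L):n])
  slopes <- diff(polymer) / diff(times)
  win <- max(2L, ceiling(0.10 * (n - 1L)))
  tail_slope <- mean(slopes[(n - win):(n - 1L)])
  peak_slope <- max(abs(slopes))
  censored <- n < 4L || (peak_slope > 0 && tail_slope > 0.05 * peak_slope)
  list(plateau = plateau, censored = censored)
}

#' Assembly half-time
#'
#' First crossing time of 50% of the curve's plateau, linearly interpolated
#' between samples. A curve that has not flattened (truncated before its
#' plateau) is flagged censored and no number is reported.
#'
#' @param polymer_series a [normalize_curve()] result, or a data.frame with
#'   `time_s` and `polymer_uM`.
#' @return list with `t_half` (s, `NA` when censored), `censored` (logical),
#'   `plateau` (uM).
#' @export
half_time <- function(polymer_series) {
  times <- polymer_series$time_s; p <- polymer_series$polymer_uM
  if (!length(times)) abort("arpdyn_empty_input_error", "empty polymer series")
  cp <- curve_plateau(times, p)
  if (cp$censored || max(p) < 0.5 * cp$plateau)
    return(list(t_half = NA_real_, censored = TRUE, plateau = cp$plateau))
  cross <- first_crossing(times, p, 0.5 * cp$plateau)
  if (is.na(cross$index))
    return(list(t_half = NA_real_, censored = TRUE, plateau = cp$plateau))
  list(t_half = cross$time, censored = FALSE, plateau = cp$plateau)
}

#' Assembly rate at a stated polymerization fraction
#'
#' Slope of a local least-squares line fitted on a symmetric window of
#' `slope_window` of the points (at least 7), centred on the first crossing
#' of `rate_fraction` of the plateau. Reported in nM/s.
#'
#' @param polymer_series a [normalize_curve()] result.
#' @param cfg a [kinetics_config()].
#' @return list with `rate_nM_s` (`NA` when censored), `censored`,
#'   `fraction`, `plateau`.
#' @export
rate_at_fraction <- function(polymer_series, cfg = kinetics_config()) {
  times <- polymer_series$time_s; p <- polymer_series$polymer_uM
  n <- length(times)
  if (!n) abort("arpdyn_empty_input_error", "empty polymer series")
  cp <- curve_plateau(times, p)
  ## "fraction of polymerization" is a fraction of the polymerizable pool;
  ## the calibrated capacity is used when known, else the plateau estimate.
  capacity <- attr(polymer_series, "capacity_uM")
  target <- cfg$rate_fraction * (if (is.null(capacity)) cp$plateau else capacity)
  cross <- first_crossing(times, p, target)
  i <- cross$index
  if (is.na(i) || max(p) < target)
    return(list(rate_nM_s = NA_real_, censored = TRUE,
                fraction = cfg$rate_fraction, plateau = cp$plateau))
  half_w <- max(3L, ceiling(cfg$slope_window * n / 2))
  lo <- max(1L, i - half_w); hi <- min(n, i + half_w)
  fit <- stats::lm(y ~ x, data = data.frame(x = times[lo:hi], y = p[lo:hi]))
  list(rate_nM_s = unname(stats::coef(fit)[2L]) * 1000,
       censored = FALSE, fraction = cfg$rate_fraction, plateau = cp$plateau)
}

## canonicalize a concentration to uM
to_uM <- function(value, units) {
  switch(match.arg(units, c("uM", "nM", "M")),
         uM = value, nM = value / 1000, M = value * 1e6)
}

#' Filament-end concentration from the elongation relationship R = k+[A][E]
#'
#' Inverts the elongation rate law: `[E] = R / (k+ [A])`, where the free
#' monomer at the readout point is
#' `[A] = (1 - fraction) * (total_actin - critical_conc) + critical_conc`.
#' With R in nM/s, k+ in uM^-1 s^-1 and [A] in uM, [E] comes out in nM.
#' Inputs in other concentration units are canonicalized internally.
#'
#' @param rate assembly rate at the readout fraction.
#' @param cfg a [kinetics_config()] (supplies `k_plus` and the default
#'   fraction).
#' @param total_actin total actin concentration.
#' @param fraction polymerized fraction at the readout (default from `cfg`).
#' @param critical_conc critical concentration.
#' @param rate_units units of `rate` per second (`"nM"` default).
#' @param actin_units units of `total_actin` and `critical_conc` (`"uM"`
#'   default).
#' @return filament-end concentration in nM.
#' @export
filament_ends <- function(rate, cfg = kinetics_config(), total_actin = 4,
                          fraction = cfg$rate_fraction, critical_conc = 0,
                          rate_units = "nM", actin_units = "uM") {
  if (is.na(rate)) return(NA_real_)
  if (rate < 0) abort("arpdyn_domain_error", "rate must be >= 0")
  rate_nM <- to_uM(rate, rate_units) * 1000
  a_tot <- to_uM(total_actin, actin_units)
  cc <- to_uM(critical_conc, actin_units)
  a_free <- (1 - fraction) * (a_tot - cc) + cc
  if (a_free <= 0)
    abort("arpdyn_domain_error", "free monomer concentration is non-positive")
  rate_nM / (cfg$k_plus * a_free)
}

#' Analyse one assembly curve end to end
#'
#' Normalizes, extracts the half-time and the rate at the configured
#' fraction, and inverts to a filament-end concentration.
#'
#' @param curve an [assembly_curve()].
#' @param cal a [curve_calibration()].
#' @param cfg a [kinetics_config()].
#' @param arp_conc Arp2/3 complex concentration for bookkeeping (nM).
#' @return object of class `nucleation_result`: list with `t_half`,
#'   `rate_nM_s`, `filament_ends_nM`, `arp_conc_nM`, `censored`.
#' @export
analyze_assembly_curve <- function(curve, cal, cfg = kinetics_config(),
                                   arp_conc = NA_real_) {
  ps <- normalize_curve(curve, cal)
  ht <- half_time(ps)
  rt <- rate_at_fraction(ps, cfg)
  ends <- filament_ends(rt$rate_nM_s, cfg, total_actin = curve$total_actin,
                        critical_conc = cal$critical_conc)
  structure(list(t_half = ht$t_half, rate_nM_s = rt$rate_nM_s,
                 filament_ends_nM = ends, arp_conc_nM = arp_conc,
                 censored = ht$censored || rt$censored),
            class = "nucleation_result")
}

#' Filament ends as a function of nucleator concentration
#'
#' @param results list of `nucleation_result` objects.
#' @return data.frame with `arp_conc_nM`, `filament_ends_nM`, `fold_change`
#'   (vs the lowest concentration), `censored`. Duplicate concentrations are
#'   merged by mean with a warning.
#' @export
ends_vs_concentration <- function(results) {
  if (!length(results)) abort("arpdyn_empty_input_error", "no results supplied")
  df <- do.call(rbind, lapply(results, function(r)
    data.frame(arp_conc_nM = r$arp_conc_nM, filament_ends_nM = r$filament_ends_nM,
               censored = r$censored)))
  if (anyDuplicated(df$arp_conc_nM)) {
    warn("arpdyn_duplicate_warning",
         "duplicate Arp2/3 concentrations merged by mean")
    df <- do.call(rbind, lapply(split(df, df$arp_conc_nM), function(g)
      data.frame(arp_conc_nM = g$arp_conc_nM[1],
                 filament_ends_nM = mean(g$filament_ends_nM),
                 censored = any(g$censored))))
  }
  df <- df[order(df$arp_conc_nM), , drop = FALSE]
  rownames(df) <- NULL
  base <- df$filament_ends_nM[1L]
  df$fold_change <- if (!is.na(base) && base > 0) df$filament_ends_nM / base else NA_real_
  df[, c("arp_conc_nM", "filament_ends_nM", "fold_change", "censored")]
}

#' Pointed-end binding isotherm fit
#'
#' Fits `rate(c) = rate_free - (rate_free - rate_bound) * c / (Kd + c)` to
#' pointed-end elongation rates measured across capper concentrations, by
#' Levenberg-Marquardt least squares. Reports the dissociation constant and
#' asymptotic standard errors. A titration with no curvature (elongation
#' unchanged across concentrations) is flagged non-identifiable instead of
#' returning a spurious Kd.
#'
#' @param conc nucleator concentrations (nM), >= 4 points spanning the
#'   expected Kd.
#' @param rate elongation rates (same length as `conc`).
#' @return object of class `binding_fit`: list with `kd`, `rate_free`,
#'   `rate_bound`, `se` (named vector), `identifiable`, `diagnostics`.
#' @export
fit_pointed_end_kd <- function(conc, rate) {
  if (length(conc) != length(rate))
    abort("arpdyn_shape_error", "conc and rate lengths differ")
  if (length(conc) < 4L)
    abort("arpdyn_insufficient_data_error",
          "need >= 4 titration points, got %d", length(conc))
  span <- diff(range(rate))
  if (span <= 1e-12 * max(abs(rate), 1)) {
    return(structure(list(kd = NA_real_, rate_free = mean(rate),
                          rate_bound = mean(rate), se = NULL,
                          identifiable = FALSE,
                          diagnostics = "no curvature: rates identical across concentrations"),
                     class = "binding_fit"))
  }
  ord <- order(conc)
  start <- list(rate_free = rate[ord][1L],
                rate_bound = rate[ord][length(rate)],
                kd = max(stats::median(conc), 1e-6))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      rate ~ rate_free - (rate_free - rate_bound) * conc / (kd + conc),
      data = data.frame(conc = conc, rate = rate),
      start = start, lower = c(-Inf, -Inf, 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(kd = NA_real_, rate_free = NA_real_,
                          rate_bound = NA_real_, se = NULL,
                          identifiable = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "binding_fit"))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  resid_sd <- stats::sd(stats::resid(fit))
  identifiable <- is.finite(est[["kd"]]) &&
    abs(est[["rate_free"]] - est[["rate_bound"]]) > 2 * resid_sd
  structure(list(kd = est[["kd"]], rate_free = est[["rate_free"]],
                 rate_bound = est[["rate_bound"]], se = se,
                 identifiable = identifiable,
                 diagnostics = sprintf("residual sd %.4g", resid_sd)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  if (!x$identifiable) cat("binding_fit: non-identifiable (", x$diagnostics, ")\n")
  else cat(sprintf("binding_fit: Kd = %.4g, rate_free = %.4g, rate_bound = %.4g\n",
                   x$kd, x$rate_free, x$rate_bound))
  invisible(x)
}
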