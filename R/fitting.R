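#' Endpoint gradient-plate data
#'
#' A long-format container for endpoint dose-response plate data: one row
#' per well, with the perchlorate concentration, replicate id, and raw
#' response (growth or sulfide signal). A valid plate contains a 0 mM
#' control series; nonzero concentrations are expected to form a
#' descending two-fold dilution series (other grids are accepted with a
#' warning).
#'
#' @param concentration_mM well concentrations, mM (must include 0).
#' @param response raw endpoint measurements.
#' @param replicate replicate identifier per well (default all 1).
#' @return Data frame of class \code{gradient_plate}.
#' @export
gradient_plate <- function(concentration_mM, response,
                           replicate = rep(1L, length(response))) {
  stopifnot(length(concentration_mM) == length(response),
            length(replicate) == length(response))
  if (any(concentration_mM < 0)) stop("concentrations must be non-negative")
  if (!any(concentration_mM == 0))
    stop("plate must contain a 0 mM control series")
  conc <- sort(unique(concentration_mM[concentration_mM > 0]),
               decreasing = TRUE)
  if (length(conc) >= 2) {
    ratios <- conc[-length(conc)] / conc[-1]
    if (any(abs(ratios - 2) > 0.05 * 2))
      warning("nonzero concentrations are not a two-fold dilution series")
  }
  structure(
    data.frame(concentration_mM = concentration_mM,
               replicate = replicate, response = response),
    class = c("gradient_plate", "data.frame")
  )
}

#' Normalize plate responses to the 0 mM control
#'
#' Divides every response by the mean response of the 0 mM control wells,
#' so the control maps to 1 on average and fully inhibited wells approach
#' 0.
#'
#' @param plate a [gradient_plate()].
#' @return The plate with an added \code{response_norm} column.
#' @export
normalize_to_control <- function(plate) {
  stopifnot(inherits(plate, "gradient_plate"))
  ctrl <- mean(plate$response[plate$concentration_mM == 0])
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control mean response must be positive")
  plate$response_norm <- plate$response / ctrl
  plate
}

new_dose_response_fit <- function(log_ic50, hill_slope, log_ic50_ci,
                                  residual_sse, n_points, source) {
  structure(
    list(log_ic50 = log_ic50, hill_slope = hill_slope,
         log_ic50_ci = log_ic50_ci, residual_sse = residual_sse,
         n_points = n_points, source = source),
    class = "dose_response_fit"
  )
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("<dose_response_fit> (%s, %d concentrations)\n",
              x$source, x$n_points))
  cat(sprintf("  log_ic50:   %.4f  [95%% CI %.4f, %.4f]  (IC50 = %.3g mM)\n",
              x$log_ic50, x$log_ic50_ci[1], x$log_ic50_ci[2],
              1000 * 10^x$log_ic50))
  cat(sprintf("  hill_slope: %.4f\n", x$hill_slope))
  cat(sprintf("  SSE: %.3g\n", x$residual_sse))
  invisible(x)
}

# normalized variable-slope inhibition model on log10-molar concentration
dr_model <- function(log_conc_M, log_ic50, hill_slope) {
  1 / (1 + 10^((log_ic50 - log_conc_M) * hill_slope))
}

#' Fit the normalized variable-slope dose-response model
#'
#' Nonlinear least squares of the two-parameter inhibition curve
#' \code{y = 1 / (1 + 10^((logIC50 - log10 c) * h))} with top fixed at 1
#' and bottom at 0, on log10-molar concentration. Responses must already
#' be normalized to the control ([normalize_to_control()]); 0 mM points
#' are excluded from the fit (their log concentration is undefined — they
#' enter only through the normalization). The 95\% CI on logIC50 comes
#' from the asymptotic parameter covariance; \code{ci = "bootstrap"}
#' resamples residuals instead.
#'
#' Initialization takes logIC50 at the log concentration whose response is
#' nearest 0.5 and a Hill slope of -1; if the optimizer fails to converge
#' a coarse grid search over logIC50 in [-4, 0] and slope in [-5, -0.1]
#' supplies a fresh start before erroring out.
#'
#' @param concentrations_mM concentrations, mM.
#' @param responses normalized responses (control about 1); values must
#'   lie within [-0.1, 1.2].
#' @param source label recorded in the fit: "endpoint" or "growth_rate".
#' @param ci confidence-interval method.
#' @param n_boot bootstrap replicates when \code{ci = "bootstrap"}.
#' @return A \code{dose_response_fit} object.
#' @export
fit_dose_response <- function(concentrations_mM, responses,
                              source = c("endpoint", "growth_rate"),
                              ci = c("asymptotic", "bootstrap"),
                              n_boot = 500) {
  source <- match.arg(source)
  ci <- match.arg(ci)
  stopifnot(length(concentrations_mM) == length(responses))
  keep <- concentrations_mM > 0
  conc <- concentrations_mM[keep]
  resp <- responses[keep]
  if (length(unique(conc)) < 4)
    stop("need at least 4 distinct nonzero concentrations for a 2-parameter fit")
  if (any(resp < -0.1) || any(resp > 1.2))
    stop("normalized responses must lie within [-0.1, 1.2]")
  lc <- log10(conc / 1000)
  start <- list(log_ic50 = lc[which.min(abs(resp - 0.5))], hill_slope = -1)
  dat <- data.frame(lc = lc, resp = resp)
  do_fit <- function(st) {
    minpack.lm::nlsLM(
      resp ~ dr_model(lc, log_ic50, hill_slope),
      data = dat, start = st,
      lower = c(log_ic50 = -8, hill_slope = -10),
      upper = c(log_ic50 = 2, hill_slope = -1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
  }
  fit <- tryCatch(do_fit(start), error = function(e) NULL)
  if (is.null(fit)) {
    grid <- expand.grid(log_ic50 = seq(-4, 0, by = 0.25),
                        hill_slope = seq(-5, -0.1, by = 0.35))
    sse <- apply(grid, 1, function(g)
      sum((resp - dr_model(lc, g[1], g[2]))^2))
    best <- grid[which.min(sse), ]
    fit <- tryCatch(do_fit(as.list(best)), error = function(e)
      stop("dose-response fit failed to converge; best grid start was ",
           sprintf("logIC50=%.2f hill=%.2f (SSE %.3g)",
                   best$log_ic50, best$hill_slope, min(sse))))
  }
  est <- stats::coef(fit)
  res_sse <- sum(stats::residuals(fit)^2)
  df <- length(resp) - 2
  ci_bounds <- if (ci == "asymptotic") {
    se <- sqrt(diag(stats::vcov(fit)))[["log_ic50"]]
    est[["log_ic50"]] + c(-1, 1) * stats::qt(0.975, df) * se
  } else {
    fitted_v <- stats::fitted(fit)
    res <- stats::residuals(fit)
    boots <- replicate(n_boot, {
      dat_b <- data.frame(lc = lc,
                          resp = fitted_v + sample(res, replace = TRUE))
      b <- tryCatch(minpack.lm::nlsLM(
        resp ~ dr_model(lc, log_ic50, hill_slope), data = dat_b,
        start = as.list(est),
        lower = c(-8, -10), upper = c(2, -1e-3)), error = function(e) NULL)
      if (is.null(b)) NA_real_ else stats::coef(b)[["log_ic50"]]
    })
    stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  new_dose_response_fit(
    log_ic50 = est[["log_ic50"]], hill_slope = est[["hill_slope"]],
    log_ic50_ci = ci_bounds, residual_sse = res_sse,
    n_points = length(unique(conc)), source = source
  )
}

#' Batch growth-curve data across perchlorate levels
#'
#' Long-format container for replicated batch growth curves: one row per
#' observation with time (h), the perchlorate level of the tube (mM), a
#' replicate id, and the measurement (OD600 or sulfide, mM). Each curve
#' needs at least 4 time points.
#'
#' @param time_h observation times, h.
#' @param perchlorate_mM tube concentration, mM.
#' @param measurement OD or sulfide value.
#' @param replicate replicate id (default 1).
#' @return Data frame of class \code{growth_curve_set}.
#' @export
growth_curve_set <- function(time_h, perchlorate_mM, measurement,
                             replicate = rep(1L, length(time_h))) {
  stopifnot(length(time_h) == length(perchlorate_mM),
            length(time_h) == length(measurement),
            length(time_h) == length(replicate))
  d <- data.frame(time_h = time_h, perchlorate_mM = perchlorate_mM,
                  replicate = replicate, measurement = measurement)
  for (key in split(d, interaction(d$perchlorate_mM, d$replicate, drop = TRUE))) {
    if (nrow(key) < 4)
      stop("each curve needs at least 4 time points")
    if (any(diff(order(key$time_h)) <= 0) || any(duplicated(key$time_h)))
      stop("times within a curve must be strictly increasing")
  }
  structure(d, class = c("growth_curve_set", "data.frame"))
}

# best exponential window of one curve: sliding window (>= 4 points)
# maximizing R^2 of log(measurement) ~ time; longest window wins ties
fit_exp_window <- function(time_h, measurement, min_points = 4) {
  ok <- measurement > 0
  time_h <- time_h[ok]; y <- log(measurement[ok])
  n <- length(y)
  if (n < min_points)
    return(list(rate = NA_real_, r_squared = NA_real_, window = c(NA, NA)))
  best <- list(r2 = -Inf, len = 0)
  for (w in min_points:n) {
    for (i in 1:(n - w + 1)) {
      idx <- i:(i + w - 1)
      f <- stats::lm(y[idx] ~ time_h[idx])
      sst <- sum((y[idx] - mean(y[idx]))^2)
      r2 <- if (sst > 0) 1 - sum(stats::residuals(f)^2) / sst else 0
      if (is.nan(r2)) r2 <- 0   # flat segment: zero variance explained
      if (r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 && w > best$len)) {
        best <- list(r2 = r2, len = w,
                     rate = unname(stats::coef(f)[2]),
                     window = range(time_h[idx]))
      }
    }
  }
  list(rate = best$rate, r_squared = best$r2, window = best$window)
}

#' Estimate exponential growth rates from batch curves
#'
#' For every (perchlorate level, replicate) curve, finds the sliding
#' time window (minimum 4 points) over which a linear regression of
#' log(measurement) on time has maximal R-squared, and takes its slope as
#' the specific growth rate. Rates are then averaged across replicates per
#' level. Curves whose best window has R-squared below 0.9 are flagged
#' with a warning (the estimate is still returned).
#'
#' @param curves a [growth_curve_set()].
#' @param min_points minimum window width.
#' @return Data frame with one row per perchlorate level: rate_per_h
#'   (replicate mean), mean window R-squared, and a \code{flagged} column.
#'   The per-curve detail is attached as attribute \code{"per_curve"}.
#' @export
estimate_growth_rate <- function(curves, min_points = 4) {
  stopifnot(inherits(curves, "growth_curve_set"))
  groups <- split(curves,
                  interaction(curves$perchlorate_mM, curves$replicate,
                              drop = TRUE))
  per_curve <- do.call(rbind, lapply(groups, function(g) {
    g <- g[order(g$time_h), ]
    w <- fit_exp_window(g$time_h, g$measurement, min_points)
    data.frame(perchlorate_mM = g$perchlorate_mM[1],
               replicate = g$replicate[1],
               rate_per_h = w$rate, r_squared = w$r_squared,
               window_start_h = w$window[1], window_end_h = w$window[2])
  }))
  rownames(per_curve) <- NULL
  per_curve$flagged <- !is.finite(per_curve$r_squared) |
    per_curve$r_squared < 0.9
  if (any(per_curve$flagged))
    warning(sum(per_curve$flagged),
            " curve(s) lack a clean exponential window (R^2 < 0.9); ",
            "their rate estimates are unreliable")
  agg <- stats::aggregate(
    cbind(rate_per_h, r_squared) ~ perchlorate_mM, data = per_curve,
    FUN = mean)
  agg$flagged <- stats::aggregate(flagged ~ perchlorate_mM,
                                  data = per_curve, FUN = any)$flagged
  agg <- agg[order(agg$perchlorate_mM), ]
  rownames(agg) <- NULL
  attr(agg, "per_curve") <- per_curve
  agg
}

#' Dose-response curve from growth rates
#'
#' Normalizes per-level growth rates to the 0 mM control rate (the mean,
#' if several control entries exist) and fits the variable-slope model —
#' the growth-rate-based route to the strain's inhibition constants.
#'
#' @param rates data frame with columns \code{perchlorate_mM} and
#'   \code{rate_per_h}, e.g. from [estimate_growth_rate()].
#' @param ... passed to [fit_dose_response()].
#' @return A \code{dose_response_fit} with source "growth_rate".
#' @export
dose_response_from_growth_rates <- function(rates, ...) {
  stopifnot(all(c("perchlorate_mM", "rate_per_h") %in% names(rates)))
  ctrl <- rates$rate_per_h[rates$perchlorate_mM == 0]
  if (length(ctrl) == 0) stop("a 0 mM control rate is required")
  ctrl <- mean(ctrl)
  if (!is.finite(ctrl) || ctrl <= 0)
    stop("control growth rate must be positive")
  fit_dose_response(rates$perchlorate_mM, rates$rate_per_h / ctrl,
                    source = "growth_rate", ...)
}

#' Fit the SRM-to-sulfide calibration regression
#'
#' Ordinary least squares of log10(sulfide) on log10(%SRM) across paired
#' observations; the slope/intercept define the power-law conversion used
#' by [sulfide_from_srm()], and R-squared is computed in log-log space.
#' Fitting can use all replicate points or per-group means; the choice is
#' recorded on the result.
#'
#' @param srm_pct SRM community percentages; positive.
#' @param sulfide_mM paired sulfide concentrations, mM; positive.
#' @param data_used "points" (all pairs, the default) or "means"
#'   (pairs are first averaged over duplicated srm values).
#' @return A [sulfide_calibration()] with attributes \code{data_used} and
#'   \code{n}.
#' @export
fit_sulfide_calibration <- function(srm_pct, sulfide_mM,
                                    data_used = c("points", "means")) {
  data_used <- match.arg(data_used)
  stopifnot(length(srm_pct) == length(sulfide_mM))
  if (any(srm_pct <= 0) || any(sulfide_mM <= 0))
    stop("calibration requires positive %SRM and sulfide values")
  if (data_used == "means") {
    agg <- stats::aggregate(sulfide_mM ~ srm_pct,
                            data = data.frame(srm_pct, sulfide_mM),
                            FUN = mean)
    srm_pct <- agg$srm_pct; sulfide_mM <- agg$sulfide_mM
  }
  if (length(srm_pct) < 3)
    stop("need at least 3 positive pairs to fit the calibration")
  f <- stats::lm(log10(sulfide_mM) ~ log10(srm_pct))
  ly <- log10(sulfide_mM)
  r2 <- 1 - sum(stats::residuals(f)^2) / sum((ly - mean(ly))^2)
  cal <- sulfide_calibration(slope = unname(stats::coef(f)[2]),
                             intercept = unname(stats::coef(f)[1]),
                             r_squared = r2)
  attr(cal, "data_used") <- data_used
  attr(cal, "n") <- length(srm_pct)
  cal
}

#' IC50 fold change between two dose-response fits
#'
#' \code{10^(logIC50_treated - logIC50_control)}: the multiplicative shift
#' in half-inhibitory concentration, used to quantify adaptation of
#' treated cultures relative to controls.
#'
#' @param fit_treated,fit_control \code{dose_response_fit} objects.
#' @return Dimensionless fold change.
#' @export
ic50_fold_change <- function(fit_treated, fit_control) {
  stopifnot(inherits(fit_treated, "dose_response_fit"),
            inherits(fit_control, "dose_response_fit"))
  10^(fit_treated$log_ic50 - fit_control$log_ic50)
}
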