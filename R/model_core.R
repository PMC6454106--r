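#' Strain (or community) growth and inhibition parameters
#'
#' Bundles the three constants that characterize how a sulfate-reducing
#' strain or community grows and how perchlorate inhibits it: the maximal
#' specific growth rate \code{mu_max} (per hour), and the two constants of
#' the variable-slope dose-response curve, \code{log_ic50} (log10 of the
#' half-inhibitory perchlorate concentration in mol/L) and \code{hill_slope}
#' (dimensionless, negative for inhibitors).
#'
#' Note the unit convention: perchlorate concentrations are carried in mM
#' throughout the package API, but the dose-response curve operates on
#' log10 molar concentration, so \code{log_ic50 = -1.914} corresponds to an
#' IC50 of \code{1000 * 10^-1.914} = 12.2 mM.
#'
#' @param name text label for the strain or community.
#' @param mu_max maximal specific growth rate, per hour; must be positive.
#' @param log_ic50 log10 of the half-inhibitory concentration in mol/L.
#' @param hill_slope slope of the inhibition curve; must be negative.
#' @return An object of class \code{strain_params}.
#' @seealso [strain_preset()] for the packaged parameter sets.
#' @examples
#' sp <- strain_params("community", mu_max = 0.13,
#'                     log_ic50 = -1.914, hill_slope = -1.813)
#' inhibition_fraction(50, sp)
#' @export
strain_params <- function(name, mu_max, log_ic50, hill_slope) {
  stopifnot(is.character(name), length(name) == 1)
  mu_max <- as.numeric(mu_max)
  log_ic50 <- as.numeric(log_ic50)
  hill_slope <- as.numeric(hill_slope)
  if (!is.finite(mu_max) || mu_max <= 0)
    stop("mu_max must be a finite positive rate (per hour)")
  if (!is.finite(hill_slope) || hill_slope >= 0)
    stop("hill_slope must be negative (inhibition orientation)")
  if (!is.finite(log_ic50) || !is.finite(10^log_ic50) || 10^log_ic50 <= 0)
    stop("10^log_ic50 must be a finite positive concentration")
  structure(
    list(name = name, mu_max = mu_max,
         log_ic50 = log_ic50, hill_slope = hill_slope),
    class = "strain_params"
  )
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf("<strain_params> %s\n", x$name))
  cat(sprintf("  mu_max:     %.4g /h\n", x$mu_max))
  cat(sprintf("  log_ic50:   %.4g (IC50 = %.3g mM)\n",
              x$log_ic50, ic50_mM(x)))
  cat(sprintf("  hill_slope: %.4g\n", x$hill_slope))
  invisible(x)
}

#' Packaged strain parameter presets
#'
#' The two empirically determined parameter sets shipped with the package:
#' \code{"community"}, a mixed marine sulfidogenic enrichment community
#' (mu_max 0.13/h, logIC50 -1.914, Hill slope -1.813), and \code{"bmsr"},
#' the pure-culture isolate Desulfovibrio sp. BMSR dominating that
#' community (mu_max 0.2/h, logIC50 -2.099, Hill slope -1.108). Presets are
#' read from the YAML parameter file under \code{inst/extdata}.
#'
#' @param name preset name, one of \code{"community"} or \code{"bmsr"}.
#' @return A [strain_params()] object.
#' @export
strain_preset <- function(name = c("community", "bmsr")) {
  name <- match.arg(name)
  path <- system.file("extdata", "strain_presets.yaml", package = "percsim")
  presets <- yaml::read_yaml(path)
  p <- presets[[name]]
  strain_params(p$name, p$mu_max_per_h, p$log_ic50_log10M, p$hill_slope)
}

# IC50 in the package's mM API units
ic50_mM <- function(strain) 1000 * 10^strain$log_ic50

#' Fractional growth activity under perchlorate (dose-response curve)
#'
#' Evaluates the variable-slope inhibition curve
#' \deqn{y = \frac{1}{1 + 10^{(\log IC50 - \log_{10} P) \cdot h}}}
#' where P is the perchlorate concentration converted to mol/L and h is the
#' (negative) Hill slope. y is the fraction of the uninhibited growth rate
#' retained at concentration p: y(0) = 1 (continuous limit), y(IC50) = 0.5,
#' and y is monotone non-increasing in p for negative slopes.
#'
#' @param p perchlorate concentration in mM; vectorized, must be >= 0.
#' @param strain a [strain_params()] object.
#' @return Numeric vector of fractions in (0, 1].
#' @export
inhibition_fraction <- function(p, strain) {
  stopifnot(inherits(strain, "strain_params"))
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0))
    stop("perchlorate concentration must be finite and non-negative (mM)")
  y <- numeric(length(p))
  pos <- p > 0
  y[!pos] <- 1
  if (any(pos)) {
    expo <- (strain$log_ic50 - log10(p[pos] / 1000)) * strain$hill_slope
    y[pos] <- 1 / (1 + 10^expo)
  }
  y
}

#' Effective specific growth rate under perchlorate
#'
#' The model assumes perchlorate acts solely by scaling the maximal growth
#' rate: mu(p) = mu_max * y(p), with y from [inhibition_fraction()].
#'
#' @inheritParams inhibition_fraction
#' @return Growth rate(s), per hour.
#' @export
effective_growth_rate <- function(p, strain) {
  strain$mu_max * inhibition_fraction(p, strain)
}

#' Sulfide calibration constants (log-log regression)
#'
#' Holds the constants of the power-law mapping from total SRM community
#' fraction (percent) to dissolved sulfide (mM):
#' \code{[sulfide] = 10^(slope * log10(Nt) + intercept)}, together with the
#' R-squared of the underlying log-log regression. The packaged empirical
#' calibration is slope 0.6786, intercept -0.7375, R-squared 0.79.
#'
#' @param slope coefficient on log10(Nt).
#' @param intercept offset in log10(mM) space.
#' @param r_squared coefficient of determination of the fit, in [0, 1].
#' @return An object of class \code{sulfide_calibration}.
#' @export
sulfide_calibration <- function(slope = 0.6786, intercept = -0.7375,
                                r_squared = 0.79) {
  slope <- as.numeric(slope); intercept <- as.numeric(intercept)
  r_squared <- as.numeric(r_squared)
  stopifnot(is.finite(slope), is.finite(intercept))
  if (!is.finite(r_squared) || r_squared < 0 || r_squared > 1)
    stop("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared),
            class = "sulfide_calibration")
}

#' @export
print.sulfide_calibration <- function(x, ...) {
  cat(sprintf(
    "<sulfide_calibration> [sulfide] = 10^(%.4g*log10(Nt) %+.4g), R^2 = %.3g\n",
    x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert total SRM percent to sulfide concentration
#'
#' @param n_t total SRM abundance, percent of community (0-100 scale);
#'   must be positive (callers integrate with a floor, see
#'   [chemostat_config()]).
#' @param calib a [sulfide_calibration()] object.
#' @return Sulfide concentration(s), mM.
#' @export
sulfide_from_srm <- function(n_t, calib = sulfide_calibration()) {
  stopifnot(inherits(calib, "sulfide_calibration"))
  n_t <- as.numeric(n_t)
  if (any(!is.finite(n_t)) || any(n_t <= 0))
    stop("n_t must be positive (percent of community); log10 is undefined at 0")
  10^(calib$slope * log10(n_t) + calib$intercept)
}

#' Invert the sulfide calibration: sulfide concentration to SRM percent
#'
#' Exact algebraic inverse of [sulfide_from_srm()]; used by the synthetic
#' data generators to manufacture community tables consistent with a
#' sulfide trajectory.
#'
#' @param s sulfide concentration(s), mM; must be positive.
#' @inheritParams sulfide_from_srm
#' @return Total SRM percent.
#' @export
srm_from_sulfide <- function(s, calib = sulfide_calibration()) {
  stopifnot(inherits(calib, "sulfide_calibration"))
  if (calib$slope == 0) stop("calibration slope must be nonzero to invert")
  s <- as.numeric(s)
  if (any(!is.finite(s)) || any(s <= 0))
    stop("sulfide concentration must be positive (mM)")
  10^((log10(s) - calib$intercept) / calib$slope)
}

#' Carrying capacities of the two SRM compartments
#'
#' The model splits the SRM population into a planktonic compartment with
#' carrying capacity \code{k_p} (subject to washout) and a surface-attached
#' compartment with capacity \code{k_a} (not diluted). Both are on the 0-100
#' percent-of-community scale; \code{k_a = 0} models a purely planktonic
#' system.
#'
#' @param k_p planktonic carrying capacity, percent; must be positive.
#' @param k_a surface-attached carrying capacity, percent; non-negative.
#' @return An object of class \code{compartment_params}.
#' @export
compartment_params <- function(k_p = 40, k_a = 0.5) {
  k_p <- as.numeric(k_p); k_a <- as.numeric(k_a)
  if (!is.finite(k_p) || k_p <= 0) stop("k_p must be positive (percent)")
  if (!is.finite(k_a) || k_a < 0) stop("k_a must be non-negative (percent)")
  structure(list(k_p = k_p, k_a = k_a), class = "compartment_params")
}

#' @export
print.compartment_params <- function(x, ...) {
  cat(sprintf("<compartment_params> K_p = %.4g%%, K_a = %.4g%%\n",
              x$k_p, x$k_a))
  invisible(x)
}
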