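# shared fixtures: printed parameter presets and closed-form oracles

comm <- strain_preset("community")
bmsr <- strain_preset("bmsr")
ref_calib <- sulfide_calibration()   # slope 0.6786, intercept -0.7375
D_ref <- 2.6 / 125                   # dilution rate, per h

# analytic logistic-with-dilution solution for constant perchlorate:
# dn/dt = r n - (mu/Kp) n^2 with r = mu - D, valid for either sign of r
logistic_dilution_sol <- function(t, n0, mu, D, k_p) {
  r <- mu - D
  a <- mu / k_p
  if (abs(r) < 1e-14) return(n0 / (1 + a * n0 * t))
  C <- r / n0 - a
  r / (a + C * exp(-r * t))
}

# closed-form critical perchlorate: invert the Hill curve at y = D/mu_max
critical_p_closed_form <- function(strain, D) {
  ystar <- D / strain$mu_max
  x <- log10(1 / ystar - 1)
  1000 * 10^(strain$log_ic50 - x / strain$hill_slope)
}

# random strain generator for property tests
random_strain <- function() {
  strain_params("rand",
                mu_max = stats::runif(1, 0.05, 0.5),
                log_ic50 = log10(stats::runif(1, 1, 200) / 1000),
                hill_slope = -stats::runif(1, 0.5, 4))
}

fit_plate <- function(strain, ...) {
  pl <- normalize_to_control(gen_plate_gradient(strain, ...))
  fit_dose_response(pl$concentration_mM, pl$response_norm)
}
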