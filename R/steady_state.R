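#' Planktonic steady state of the logistic-with-dilution model
#'
#' Setting \code{dNp/dt = mu Np (1 - Np/Kp) - D Np} to zero gives the
#' nontrivial fixed point \code{Kp (1 - D/mu(p))} whenever the effective
#' growth rate exceeds the dilution rate, and washout (0) otherwise. The
#' boundary case \code{mu(p) = D} is assigned to washout.
#'
#' @param strain a [strain_params()] object.
#' @param k_p planktonic carrying capacity, percent.
#' @param dilution dilution rate D = F/V, per hour.
#' @param p perchlorate concentration(s), mM.
#' @return Steady-state planktonic SRM percent (vectorized over p).
#' @export
planktonic_steady_state <- function(strain, k_p, dilution, p = 0) {
  if (!is.finite(dilution) || dilution < 0)
    stop("dilution rate must be non-negative")
  mu <- effective_growth_rate(p, strain)
  ifelse(mu > dilution, k_p * (1 - dilution / mu), 0)
}

#' Does the planktonic population wash out at this perchlorate level?
#'
#' TRUE when the inhibited growth rate falls below the dilution rate, so
#' the planktonic compartment cannot sustain itself against outflow.
#'
#' @inheritParams planktonic_steady_state
#' @return Logical (vectorized over p).
#' @export
washout_condition <- function(strain, dilution, p) {
  effective_growth_rate(p, strain) < dilution
}

#' Critical perchlorate concentration for planktonic washout
#'
#' The concentration at which the inhibited growth rate equals the dilution
#' rate: below it the planktonic population persists, above it it washes
#' out. Found by bisection on the monotone inhibition curve to
#' \code{|mu(p) - D| < 1e-10}.
#'
#' @inheritParams planktonic_steady_state
#' @param p_max upper bracket for the search, mM.
#' @return Concentration in mM.
#' @export
critical_perchlorate <- function(strain, dilution, p_max = 1e6) {
  if (strain$mu_max <= dilution)
    stop("population washes out even untreated (mu_max <= D)")
  f <- function(p) effective_growth_rate(p, strain) - dilution
  lo <- 0; hi <- p_max
  if (f(hi) > 0) stop("no washout below p_max = ", p_max, " mM")
  while (abs(f((lo + hi) / 2)) >= 1e-10 && (hi - lo) > 1e-13 * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Sulfide floor sustained by the surface-attached compartment
#'
#' Under full planktonic washout the attached compartment remains at its
#' carrying capacity (it is not diluted), so sulfide asymptotes to the
#' calibration evaluated at \code{k_a} rather than to zero. With
#' \code{k_a = 0} there is no floor and sulfide decays toward 0.
#'
#' @param k_a attached carrying capacity, percent.
#' @param calib a [sulfide_calibration()].
#' @return Sulfide concentration, mM.
#' @export
inhibited_sulfide_floor <- function(k_a, calib = sulfide_calibration()) {
  if (!is.finite(k_a) || k_a < 0) stop("k_a must be non-negative")
  if (k_a == 0) return(0)
  sulfide_from_srm(k_a, calib)
}

#' Time for sulfide to rebound after treatment cessation
#'
#' Scans a simulated trajectory for the first time after the final
#' treatment-cessation breakpoint (a schedule segment returning the inflow
#' to 0 mM) at which sulfide reaches \code{(1 - tolerance)} of the
#' pre-treatment level. Time is reported relative to cessation.
#'
#' @param sim a \code{sim_result} from [simulate_chemostat()].
#' @param pre_treatment_level reference sulfide level, mM.
#' @param tolerance fractional shortfall allowed (default 0.1: rebound
#'   means reaching 90\% of the reference).
#' @return Hours since cessation (0 if already at level), or \code{NA}
#'   with class note "no rebound" if the level is never reached within the
#'   simulated horizon.
#' @export
rebound_time <- function(sim, pre_treatment_level, tolerance = 0.1) {
  stopifnot(inherits(sim, "sim_result"))
  config <- attr(sim, "config")
  sched <- config$schedule
  off <- which(sched$inflow_perchlorate_mM == 0 & seq_len(nrow(sched)) > 1)
  treated <- which(sched$inflow_perchlorate_mM > 0)
  if (length(treated) == 0 || length(off) == 0 ||
      max(off) < max(treated))
    stop("schedule contains no treatment-cessation breakpoint")
  t_off <- sched$t_start_h[max(off[off > max(treated)])]
  target <- (1 - tolerance) * pre_treatment_level
  after <- sim[sim$time_h >= t_off, ]
  hit <- which(after$sulfide_mM >= target)
  if (length(hit) == 0) {
    res <- NA_real_
    attr(res, "status") <- "no rebound"
    return(res)
  }
  res <- after$time_h[hit[1]] - t_off
  attr(res, "status") <- "rebound"
  res
}

#' Steady-state summary across a perchlorate gradient
#'
#' Convenience table of the closed-form analytics across user-supplied
#' concentrations: effective growth rate, washout flag, planktonic steady
#' state, total steady SRM, and the converted steady sulfide.
#'
#' @param strain a [strain_params()].
#' @param compartments a [compartment_params()].
#' @param dilution dilution rate, per hour.
#' @param p_grid perchlorate concentrations, mM.
#' @param calib a [sulfide_calibration()].
#' @return Data frame with one row per concentration.
#' @export
steady_state_table <- function(strain, compartments, dilution, p_grid,
                               calib = sulfide_calibration()) {
  mu <- effective_growth_rate(p_grid, strain)
  np <- planktonic_steady_state(strain, compartments$k_p, dilution, p_grid)
  nt <- np + compartments$k_a
  data.frame(
    perchlorate_mM = p_grid,
    mu_per_h = mu,
    washout = washout_condition(strain, dilution, p_grid),
    n_p_pct = np,
    n_t_pct = nt,
    sulfide_mM = ifelse(nt > 0, sulfide_from_srm(pmax(nt, 1e-6), calib), 0)
  )
}
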