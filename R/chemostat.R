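#' Chemostat run configuration
#'
#' Collects everything needed to simulate a continuous-culture run: vessel
#' geometry (volume, flow), the two-compartment carrying capacities, the
#' strain's growth/inhibition parameters, the sulfide calibration, a
#' piecewise-constant inflow-perchlorate schedule, and the initial state.
#'
#' The schedule is a data frame with columns \code{t_start_h} (strictly
#' increasing, first row at 0) and \code{inflow_perchlorate_mM}; each row
#' sets the reservoir perchlorate concentration from its start time until
#' the next row (or \code{t_end}). The default initial state is the
#' pre-treatment steady state: planktonic at its logistic-with-dilution
#' fixed point \code{k_p * (1 - D/mu_max)}, attached at \code{k_a}, no
#' perchlorate in the vessel — matching the experimental protocol of
#' treating only once sulfide production is stable.
#'
#' @param volume culture volume, mL (default 125).
#' @param flow flow rate, mL/h (default 2.6; residence time V/F = 48 h).
#' @param compartments a [compartment_params()] object.
#' @param strain a [strain_params()] object.
#' @param calib a [sulfide_calibration()] object.
#' @param schedule data frame of \code{t_start_h},
#'   \code{inflow_perchlorate_mM} segments.
#' @param t_end simulation horizon, h.
#' @param initial_state optional named numeric vector
#'   \code{c(n_p=, n_a=, p=)} (percent, percent, mM); defaults to the
#'   untreated steady state.
#' @param floor_np numerical floor (percent) applied to the planktonic
#'   state during integration so that rebound after deep washout remains
#'   possible; rebound timing is sensitive to this value (see the package
#'   vignette).
#' @param floor_nt floor applied to total SRM before the log-log sulfide
#'   conversion, which is undefined at 0.
#' @return An object of class \code{chemostat_config}.
#' @export
chemostat_config <- function(volume = 125, flow = 2.6,
                             compartments = compartment_params(),
                             strain = strain_preset("community"),
                             calib = sulfide_calibration(),
                             schedule = data.frame(t_start_h = 0,
                                                   inflow_perchlorate_mM = 0),
                             t_end = 500,
                             initial_state = NULL,
                             floor_np = 1e-9,
                             floor_nt = 1e-6) {
  stopifnot(inherits(compartments, "compartment_params"),
            inherits(strain, "strain_params"),
            inherits(calib, "sulfide_calibration"))
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive (mL)")
  if (!is.finite(flow) || flow < 0) stop("flow must be non-negative (mL/h)")
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive (h)")
  schedule <- as.data.frame(schedule)
  req <- c("t_start_h", "inflow_perchlorate_mM")
  if (!all(req %in% names(schedule)))
    stop("schedule needs columns t_start_h and inflow_perchlorate_mM")
  if (nrow(schedule) == 0 || schedule$t_start_h[1] != 0)
    stop("schedule must start with a segment at t = 0")
  if (any(diff(schedule$t_start_h) <= 0))
    stop("schedule start times must be strictly increasing")
  if (any(schedule$inflow_perchlorate_mM < 0))
    stop("inflow perchlorate must be non-negative (mM)")
  D <- flow / volume
  if (is.null(initial_state)) {
    np0 <- max(compartments$k_p * (1 - D / strain$mu_max), floor_np)
    initial_state <- c(n_p = np0, n_a = compartments$k_a, p = 0)
  } else {
    initial_state <- initial_state[c("n_p", "n_a", "p")]
    if (any(is.na(initial_state)) || any(initial_state < 0))
      stop("initial_state needs non-negative n_p, n_a, p")
  }
  structure(
    list(volume = volume, flow = flow, dilution = D,
         compartments = compartments, strain = strain, calib = calib,
         schedule = schedule, t_end = t_end,
         initial_state = initial_state,
         floor_np = floor_np, floor_nt = floor_nt),
    class = "chemostat_config"
  )
}

#' @export
print.chemostat_config <- function(x, ...) {
  cat("<chemostat_config>\n")
  cat(sprintf("  V = %g mL, F = %g mL/h  (D = %.4g /h, residence %.3g h)\n",
              x$volume, x$flow, x$dilution, x$volume / x$flow))
  cat(sprintf("  strain: %s (mu_max %.3g /h), K_p %.3g%%, K_a %.3g%%\n",
              x$strain$name, x$strain$mu_max,
              x$compartments$k_p, x$compartments$k_a))
  cat(sprintf("  schedule: %d segment(s), horizon %g h\n",
              nrow(x$schedule), x$t_end))
  invisible(x)
}

# inflow concentration at time t (right-continuous piecewise constant)
inflow_at <- function(config, t) {
  idx <- findInterval(t, config$schedule$t_start_h)
  config$schedule$inflow_perchlorate_mM[pmax(idx, 1)]
}

#' Closed-form perchlorate concentration in the vessel
#'
#' The perchlorate mass balance \code{dP/dt = D * (P_in(t) - P)} is linear,
#' so within each schedule segment with inflow \code{P_in} the solution is
#' the exponential relaxation
#' \code{P(t) = P_in + (P_seg_start - P_in) * exp(-D * dt)}. This function
#' evaluates that piecewise closed form; the ODE integrator is checked
#' against it in the test suite.
#'
#' @param config a [chemostat_config()].
#' @param t time point(s) in hours, within \code{[0, t_end]}.
#' @return Perchlorate concentration(s), mM.
#' @export
perchlorate_trajectory <- function(config, t) {
  stopifnot(inherits(config, "chemostat_config"))
  t <- as.numeric(t)
  if (any(t < 0) || any(t > config$t_end))
    stop("t must lie within [0, t_end]")
  D <- config$dilution
  starts <- config$schedule$t_start_h
  pin <- config$schedule$inflow_perchlorate_mM
  # concentration at each segment start, propagated forward
  p_seg <- numeric(length(starts))
  p_seg[1] <- unname(config$initial_state["p"])
  if (length(starts) > 1) {
    for (i in seq_len(length(starts) - 1)) {
      dt <- starts[i + 1] - starts[i]
      p_seg[i + 1] <- pin[i] + (p_seg[i] - pin[i]) * exp(-D * dt)
    }
  }
  idx <- pmax(findInterval(t, starts), 1)
  pin[idx] + (p_seg[idx] - pin[idx]) * exp(-D * (t - starts[idx]))
}

#' Simulate the two-compartment chemostat model
#'
#' Integrates the coupled system
#' \deqn{dN_p/dt = \mu N_p (1 - N_p/K_p) - N_p F/V}
#' \deqn{dN_a/dt = \mu N_a (1 - N_a/K_a)}
#' \deqn{dP/dt = D (P_{in}(t) - P)}
#' with \code{mu = mu_max * y(P)} from the strain's inhibition curve.
#' Integration uses a stiff-capable adaptive solver (lsoda, rtol 1e-8,
#' atol 1e-10) and restarts at every schedule breakpoint, where the inflow
#' is discontinuous. The planktonic state is floored at
#' \code{config$floor_np} at every output step so that regrowth after deep
#' washout is representable. Total SRM is converted to sulfide through the
#' calibration, flooring \code{n_t} at \code{config$floor_nt}.
#'
#' @param config a [chemostat_config()].
#' @param dt output grid spacing, hours (default 1).
#' @return An object of class \code{sim_result}: a data frame with columns
#'   \code{time_h}, \code{n_p_pct}, \code{n_a_pct}, \code{n_t_pct},
#'   \code{perchlorate_mM}, \code{sulfide_mM}, carrying the config as an
#'   attribute.
#' @export
simulate_chemostat <- function(config, dt = 1) {
  stopifnot(inherits(config, "chemostat_config"))
  D <- config$dilution
  strain <- config$strain
  kp <- config$compartments$k_p
  ka <- config$compartments$k_a
  floor_np <- config$floor_np

  deriv <- function(t, y, parms) {
    mu <- effective_growth_rate(max(y[3], 0), strain)
    dnp <- mu * y[1] * (1 - y[1] / kp) - y[1] * D
    dna <- if (ka > 0) mu * y[2] * (1 - y[2] / ka) else 0
    dp <- D * (parms$pin - y[3])
    list(c(dnp, dna, dp))
  }
  floor_event <- function(t, y, parms) {
    y[1] <- max(y[1], floor_np)
    y
  }

  breaks <- config$schedule$t_start_h
  seg_bounds <- unique(c(breaks, config$t_end))
  seg_bounds <- seg_bounds[seg_bounds <= config$t_end]
  if (seg_bounds[length(seg_bounds)] < config$t_end)
    seg_bounds <- c(seg_bounds, config$t_end)

  state <- c(config$initial_state["n_p"], config$initial_state["n_a"],
             config$initial_state["p"])
  names(state) <- c("n_p", "n_a", "p")
  state["n_p"] <- max(state["n_p"], floor_np)
  out_rows <- list()
  for (i in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[i]; t1 <- seg_bounds[i + 1]
    times <- unique(c(seq(t0, t1, by = dt), t1))
    pin <- inflow_at(config, t0)
    sol <- deSolve::ode(
      y = state, times = times, func = deriv, parms = list(pin = pin),
      method = "lsoda", rtol = 1e-8, atol = 1e-10,
      events = list(func = floor_event, time = times[-1])
    )
    if (attr(sol, "istate")[1] < 0)
      stop("ODE solver failed to converge on segment [", t0, ", ", t1,
           "] (istate ", attr(sol, "istate")[1], ")")
    sol <- as.data.frame(sol)
    if (any(sol$n_p < -1e-8) || any(sol$n_a < -1e-8) || any(sol$p < -1e-8))
      stop("negative state encountered; solver tolerances misconfigured")
    # drop the duplicated segment-start row after the first segment
    out_rows[[i]] <- if (i == 1) sol else sol[-1, ]
    last <- sol[nrow(sol), ]
    state <- c(n_p = max(last$n_p, floor_np), n_a = last$n_a,
               p = max(last$p, 0))
  }
  traj <- do.call(rbind, out_rows)
  n_t <- traj$n_p + traj$n_a
  res <- data.frame(
    time_h = traj$time,
    n_p_pct = pmax(traj$n_p, 0),
    n_a_pct = pmax(traj$n_a, 0),
    n_t_pct = pmax(n_t, 0),
    perchlorate_mM = pmax(traj$p, 0),
    sulfide_mM = sulfide_from_srm(pmax(n_t, config$floor_nt), config$calib)
  )
  rownames(res) <- NULL
  structure(res, class = c("sim_result", "data.frame"), config = config)
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<sim_result> %d time points over %g h\n",
              nrow(x), max(x$time_h)))
  last <- x[nrow(x), ]
  cat(sprintf("  final: n_t = %.3g%%, perchlorate = %.3g mM, sulfide = %.3g mM\n",
              last$n_t_pct, last$perchlorate_mM, last$sulfide_mM))
  invisible(x)
}

#' Batch co-culture growth of competing strains
#'
#' Simulates batch (no dilution) growth of one or more strains sharing a
#' single logistic niche: each strain grows at its own
#' perchlorate-modulated rate \code{mu_i(p)} while all strains compete for
#' the same ceiling,
#' \code{dX_i/dt = mu_i X_i (1 - sum(X)/ceiling)}. Perchlorate is held
#' constant (no flow, no consumption). This reproduces the co-culture
#' plate assay in which the mixture's apparent dose-response is set by the
#' most resistant strain.
#'
#' @param strains list of [strain_params()] objects.
#' @param initial_percents starting abundance of each strain, percent.
#' @param p perchlorate concentration, mM (constant over the run).
#' @param duration incubation time, h.
#' @param ceiling shared logistic ceiling, percent (default 100).
#' @param dt output grid spacing, h.
#' @return List with \code{final} (named vector of per-strain endpoints and
#'   \code{total}) and \code{trajectory} (data frame, one column per
#'   strain).
#' @export
simulate_batch_mixture <- function(strains, initial_percents, p, duration,
                                   ceiling = 100, dt = 1) {
  if (length(strains) == 0) stop("need at least one strain")
  if (length(strains) != length(initial_percents))
    stop("strains and initial_percents must have the same length")
  if (!is.finite(duration) || duration <= 0) stop("duration must be positive")
  mus <- vapply(strains, function(s) effective_growth_rate(p, s), numeric(1))
  nm <- vapply(strains, function(s) s$name, character(1))
  nm <- make.unique(nm)
  deriv <- function(t, y, parms) {
    crowd <- 1 - sum(y) / ceiling
    list(mus * y * crowd)
  }
  times <- unique(c(seq(0, duration, by = dt), duration))
  y0 <- as.numeric(initial_percents); names(y0) <- nm
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  sol <- as.data.frame(sol)
  final <- as.numeric(sol[nrow(sol), -1])
  names(final) <- nm
  list(final = c(final, total = sum(final)), trajectory = sol)
}

#' Endpoint dose-response of a strain mixture across a gradient
#'
#' Runs [simulate_batch_mixture()] at every concentration of a gradient
#' (which must include a 0 mM control) and returns total endpoint biomass
#' normalized to the control well — the in-silico analogue of an endpoint
#' gradient-plate assay.
#'
#' @inheritParams simulate_batch_mixture
#' @param gradient perchlorate concentrations, mM; must contain 0.
#' @return Data frame with columns \code{concentration_mM} and
#'   \code{response} (normalized to the 0 mM control).
#' @export
effective_mixture_dose_response <- function(strains, initial_percents,
                                            gradient, duration,
                                            ceiling = 100) {
  gradient <- as.numeric(gradient)
  if (!any(gradient == 0))
    stop("gradient must include a 0 mM control well")
  totals <- vapply(gradient, function(p) {
    simulate_batch_mixture(strains, initial_percents, p, duration,
                           ceiling = ceiling)$final[["total"]]
  }, numeric(1))
  control <- mean(totals[gradient == 0])
  data.frame(concentration_mM = gradient, response = totals / control)
}
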