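#' Measurement noise model
#'
#' Describes how observation noise is applied to synthetic measurements.
#' The default, multiplicative lognormal noise, reflects that replicate
#' scatter in sulfide measurements scales roughly with the mean (large SD
#' at high sulfide, small SD at inhibited levels), which additive noise
#' cannot mimic. \code{sd} is the log-space standard deviation for the
#' lognormal kind, or the absolute SD (mM) for additive Gaussian noise.
#' Generators seeded with the same \code{seed} are bit-reproducible.
#'
#' @param kind noise family.
#' @param sd noise scale; non-negative.
#' @param seed integer random seed.
#' @return An object of class \code{noise_model}.
#' @export
noise_model <- function(kind = c("multiplicative-lognormal",
                                 "additive-gaussian"),
                        sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  sd <- as.numeric(sd)
  if (!is.finite(sd) || sd < 0) stop("noise sd must be non-negative")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  structure(list(kind = kind, sd = sd, seed = seed), class = "noise_model")
}

apply_noise <- function(x, noise) {
  if (noise$sd == 0) return(x)
  if (noise$kind == "multiplicative-lognormal") {
    x * exp(stats::rnorm(length(x), 0, noise$sd))
  } else {
    x + stats::rnorm(length(x), 0, noise$sd)
  }
}

#' Generate replicated noisy chemostat time series
#'
#' Simulates one ground-truth trajectory from the config, samples it at a
#' fixed interval (default 12 h, mimicking at-most-daily manual sampling),
#' and draws per-replicate noisy sulfide (and %SRM) observations. The
#' noiseless truth is returned alongside so recovery can be scored.
#'
#' @param config a [chemostat_config()].
#' @param noise a [noise_model()].
#' @param replicates number of replicate observation series.
#' @param sampling_interval observation spacing, h.
#' @param observe_srm also emit noisy total-SRM percent observations.
#' @return List with \code{truth} (the full \code{sim_result}) and
#'   \code{observations} (long data frame: replicate, time_h, sulfide_mM
#'   and optionally n_t_pct).
#' @export
gen_chemostat_timeseries <- function(config, noise = noise_model(),
                                     replicates = 3,
                                     sampling_interval = 12,
                                     observe_srm = TRUE) {
  stopifnot(inherits(config, "chemostat_config"),
            inherits(noise, "noise_model"), replicates >= 1)
  truth <- simulate_chemostat(config)
  keep <- truth$time_h %in% seq(0, config$t_end, by = sampling_interval)
  sampled <- truth[keep, ]
  set.seed(noise$seed)
  obs <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    d <- data.frame(replicate = r, time_h = sampled$time_h,
                    sulfide_mM = apply_noise(sampled$sulfide_mM, noise))
    if (observe_srm) d$n_t_pct <- apply_noise(sampled$n_t_pct, noise)
    d
  }))
  rownames(obs) <- NULL
  list(truth = truth, observations = obs)
}

#' Generate a two-fold serial-dilution gradient plate
#'
#' Builds the concentration series \{top, top/2, ..., 0\} and sets the
#' noise-free response at each well to
#' \code{control_signal * inhibition_fraction(p, strain)} — the endpoint
#' signal of a culture whose growth is scaled by the inhibition curve.
#' Noise is then applied per well.
#'
#' @param strain a [strain_params()].
#' @param top_mM highest concentration, mM (default 500).
#' @param n_dilutions number of nonzero wells in the two-fold series.
#' @param noise a [noise_model()].
#' @param replicates replicate series.
#' @param control_signal raw signal of the uninhibited control well.
#' @return A [gradient_plate()].
#' @export
gen_plate_gradient <- function(strain, top_mM = 500, n_dilutions = 9,
                               noise = noise_model(), replicates = 1,
                               control_signal = 1) {
  stopifnot(inherits(strain, "strain_params"))
  if (n_dilutions < 4) stop("need at least 4 dilutions for a usable plate")
  conc <- c(top_mM / 2^(0:(n_dilutions - 1)), 0)
  set.seed(noise$seed)
  rows <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    signal <- control_signal * inhibition_fraction(conc, strain)
    data.frame(concentration_mM = conc, replicate = r,
               response = apply_noise(signal, noise))
  }))
  gradient_plate(rows$concentration_mM, rows$response, rows$replicate)
}

#' Generate logistic batch growth curves under perchlorate
#'
#' Emits closed-form logistic curves
#' \code{N(t) = K / (1 + ((K - N0)/N0) exp(-mu (t - lag)))} with the
#' intrinsic rate set to the strain's perchlorate-modulated growth rate at
#' each level, so the early-phase log slope recovers
#' \code{effective_growth_rate(p, strain)}.
#'
#' @param strain a [strain_params()].
#' @param perchlorate_levels tube concentrations, mM (should include 0).
#' @param duration incubation, h; should cover a few doublings at mu_max.
#' @param noise a [noise_model()].
#' @param replicates replicate tubes per level.
#' @param sampling_interval measurement spacing, h.
#' @param n0 inoculum signal (same units as the ceiling).
#' @param capacity logistic ceiling of the measurement.
#' @param lag lag time before growth starts, h.
#' @return A [growth_curve_set()].
#' @export
gen_growth_curves <- function(strain, perchlorate_levels, duration = 72,
                              noise = noise_model(), replicates = 1,
                              sampling_interval = 2, n0 = 0.02,
                              capacity = 1, lag = 0) {
  stopifnot(inherits(strain, "strain_params"))
  if (duration * strain$mu_max < 3 * log(2))
    stop("duration must cover at least 3 doublings at mu_max")
  times <- seq(0, duration, by = sampling_interval)
  set.seed(noise$seed)
  rows <- do.call(rbind, lapply(perchlorate_levels, function(p) {
    mu <- effective_growth_rate(p, strain)
    tt <- pmax(times - lag, 0)
    truth <- capacity / (1 + ((capacity - n0) / n0) * exp(-mu * tt))
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      data.frame(time_h = times, perchlorate_mM = p, replicate = r,
                 measurement = apply_noise(truth, noise))
    }))
  }))
  growth_curve_set(rows$time_h, rows$perchlorate_mM, rows$measurement,
                   rows$replicate)
}

srm_genera <- c("Desulfovibrio", "Desulforhopalus",
                "Desulfocurvus", "Desulfomicrobium")
# fixed within-SRM split, Desulfovibrio-dominant
srm_split <- c(0.75, 0.10, 0.10, 0.05)

#' Generate a toy relative-abundance community table
#'
#' Distributes each sample's total SRM percent across the four SRM genera
#' observed in the community (fixed Desulfovibrio-dominant proportions)
#' and splits the remaining mass across exchangeable filler taxa by a
#' symmetric Dirichlet draw. Rows sum to 100.
#'
#' @param n_t total SRM percent per sample; each in (0, 100).
#' @param filler_taxa number of non-SRM taxa (>= 1).
#' @param concentration_param symmetric Dirichlet concentration of the
#'   filler split.
#' @param seed integer seed.
#' @return Data frame, one row per sample, columns the four SRM genera
#'   then \code{filler_1 ... filler_k}.
#' @export
gen_community_table <- function(n_t, filler_taxa = 10,
                                concentration_param = 1, seed = 1L) {
  n_t <- as.numeric(n_t)
  if (any(n_t <= 0) || any(n_t >= 100))
    stop("n_t values must lie strictly between 0 and 100 percent")
  if (filler_taxa < 1) stop("at least one filler taxon is required")
  set.seed(as.integer(seed))
  tab <- t(vapply(n_t, function(nt) {
    srm <- nt * srm_split
    g <- stats::rgamma(filler_taxa, shape = concentration_param)
    filler <- (100 - nt) * g / sum(g)
    c(srm, filler)
  }, numeric(4 + filler_taxa)))
  colnames(tab) <- c(srm_genera, paste0("filler_", seq_len(filler_taxa)))
  as.data.frame(tab)
}

#' Total SRM percent from a relative-abundance table
#'
#' Row-wise sum of the listed SRM genera's relative abundances — the
#' community-level quantity the chemostat model tracks.
#'
#' @param table data frame of relative abundances (percent), taxa in
#'   columns.
#' @param srm_genus_list genus column names to sum; unknown names warn and
#'   contribute 0.
#' @return Numeric vector, percent per sample (row).
#' @export
srm_fraction_from_table <- function(table, srm_genus_list = srm_genera) {
  if (length(srm_genus_list) == 0) stop("genus list must be non-empty")
  known <- intersect(srm_genus_list, colnames(table))
  missing <- setdiff(srm_genus_list, colnames(table))
  if (length(missing) > 0)
    warning("genera not in table (treated as 0): ",
            paste(missing, collapse = ", "))
  if (length(known) == 0) return(rep(0, nrow(table)))
  rowSums(table[, known, drop = FALSE])
}
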