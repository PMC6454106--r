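---
title: "Modeling perchlorate inhibition of sulfate reducers in continuous culture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling perchlorate inhibition of sulfate reducers in continuous culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percsim)
```

## The model and its assumptions

`percsim` models a sulfidogenic chemostat community under perchlorate
stress with three coupled states: planktonic SRM $N_p$, surface-attached
SRM $N_A$ (both on a 0–100 percent-of-community scale), and dissolved
perchlorate $P$ (mM). With dilution rate $D = F/V$:

$$\frac{dN_p}{dt} = \mu N_p\Big(1 - \frac{N_p}{K_p}\Big) - D\,N_p,
\qquad
\frac{dN_A}{dt} = \mu N_A\Big(1 - \frac{N_A}{K_A}\Big),
\qquad
\frac{dP}{dt} = D\,(P_{in}(t) - P).$$

The perchlorate balance is written as a concentration balance — inflow
concentration times dilution minus washout — which is the dimensionally
consistent form of a well-mixed vessel's mass balance and yields the
standard exponential wash-in/wash-out
$P(t) = P_{in} + (P_0 - P_{in})e^{-Dt}$ within each constant-inflow
segment.

The central mechanistic assumption is that perchlorate is *not*
biocidal: it only scales the specific growth rate, through a
variable-slope (Hill) inhibition curve on log$_{10}$-molar
concentration,

$$\mu = \mu_{max}\, y(P), \qquad
y(P) = \frac{1}{1 + 10^{(\log IC_{50} - \log_{10} P)\,h}}, \quad h < 0,$$

with $y(0) = 1$ taken as the continuous limit and $y(IC_{50}) = 1/2$ by
construction. Everything interesting in the system follows from the
competition between $\mu(P)$ and $D$: when the inhibited growth rate
falls below the dilution rate the planktonic compartment washes out;
the attached compartment sees no dilution term and persists at its
capacity, sustaining a small residual sulfide signal.

The two compartments do not exchange biomass. In a real vessel attached
and planktonic cells certainly interconvert, but the available
observations constrain only the two capacities, not attachment or
detachment rates, so the model keeps the compartments independent and
absorbs surface effects entirely into $K_A$.

Model output $N_t = N_p + N_A$ is converted to sulfide through a
power-law calibration fitted in log-log space,
$[\mathrm{sulfide}] = 10^{\,a \log_{10} N_t + b}$, packaged with
$a = 0.6786$, $b = -0.7375$ ($R^2 = 0.79$). The calibration is
monotone, so it maps the washout dichotomy directly onto sulfide levels.

## Parameters, units, and defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `volume` | vessel volume | 125 | mL |
| `flow` | feed rate | 2.6 | mL/h |
| `mu_max` | maximal growth rate | 0.13 (community), 0.2 (BMSR) | /h |
| `log_ic50` | half-inhibitory concentration | −1.914 (community), −2.099 (BMSR) | log10 mol/L |
| `hill_slope` | dose-response steepness | −1.813 (community), −1.108 (BMSR) | — |
| `k_p` | planktonic carrying capacity | 40 | % of community |
| `k_a` | attached carrying capacity | 0.5 | % of community |

The defaults give $D = 0.0208$/h (residence time $V/F \approx 48$ h) and
an untreated steady state of $K_p(1 - D/\mu_{max}) = 33.6\%$ planktonic
SRM, 34.1% total, converting to 2.0 mM sulfide.

**Unit convention.** The API carries perchlorate in mM everywhere, but
the Hill curve's log argument is molar, so `log_ic50 = -1.914` means
$IC_{50} = 12.2$ mM. This is the only reading under which 20 mM is
marginally inhibitory while 50 mM suppresses the community —
$\mu(20) = 0.038 > D$ but $\mu(50) = 0.0093 < D$ — so the package
adopts it and converts explicitly at the API boundary. Feeding molar
concentrations to the fitting routines simply shifts the fitted
$\log IC_{50}$ by $\log_{10} 1000$; a test asserts exactly that.

**Hill slopes are stored signed** (negative for inhibitors), matching
how such constants are reported, rather than as a magnitude plus an
orientation flag.

## Numerical choices

*Integration.* `simulate_chemostat()` uses `deSolve::ode` with `lsoda`
(stiff-capable, adaptive) at `rtol = 1e-8`, `atol = 1e-10`. Treatment
schedules are piecewise constant and their breakpoints are known a
priori, so the integrator is restarted at every schedule segment
boundary instead of relying on event detection; the inflow is
discontinuous exactly there. The integrator is verified in the test
suite against closed forms: the piecewise-exponential perchlorate
trajectory, pure planktonic washout $n_p(0)e^{-Dt}$, and the exact
finite-time logistic-with-dilution solution
$n_p(t) = r/(a + C e^{-rt})$ with $r = \mu - D$, $a = \mu/K_p$, which
is valid on both sides of the washout boundary and avoids the
arbitrarily slow convergence near $\mu(P) = D$ that makes asymptotic
comparisons there ill-posed.

*Planktonic floor.* $N_p$ is floored at $10^{-9}$% at every output step.
Without a floor, deep washout drives $N_p$ to values from which numerical
rebound is effectively impossible; with it, regrowth after cessation is
representable. The floor is a configurable knob
(`chemostat_config(floor_np = ...)`), and rebound *timing* after long,
deep suppression depends on it — a genuine indeterminacy of this model
class, since nothing in the data pins the depth of the surviving
planktonic inoculum. The packaged rebound analyses therefore assert that
rebound occurs (and its order of magnitude), not an exact rebound hour.

*Sulfide conversion floor.* The log-log calibration is undefined at
$N_t = 0$, so conversion evaluates at $\max(N_t, 10^{-6})$.

*Ties.* The measure-zero boundary case $\mu(P) = D$ is assigned to
washout (steady state 0).

*Critical concentration.* `critical_perchlorate()` bisects the monotone
curve $\mu(P) - D$ to $|\mu - D| < 10^{-10}$; for the community preset
at $D = 2.6/125$ this gives 30.4 mM — between the marginally inhibitory
20 mM and the suppressive 50 mM — and 55.6 mM for the faster-growing
BMSR isolate, consistent with 50 mM sitting right at that strain's
washout edge and producing replicate-to-replicate inconsistency.

## Fitting

*Dose-response.* `fit_dose_response()` fits the two-parameter normalized
variable-slope model with top fixed at 1 and bottom at 0 — the
normalized-response variant appropriate after dividing by the 0 mM
control. Four-parameter fitting (floating top/bottom) is out of scope;
partially inhibiting plateaus would require it. 0 mM wells enter only
through normalization (their log concentration is undefined).
Initialization takes $\log IC_{50}$ at the concentration whose response
is nearest 0.5 and slope $-1$; on failure a coarse grid over
$\log IC_{50} \in [-4, 0]$, $h \in [-5, -0.1]$ supplies a restart. The
95% CI is asymptotic (linearized covariance), matching common
curve-fitting software; a residual-bootstrap CI is available via
`ci = "bootstrap"`. Replicate wells are fitted as individual points with
equal weight, not averaged first.

*Growth rates.* How a single rate is extracted from a batch curve is
genuinely open; `estimate_growth_rate()` uses a sliding window (minimum
4 points) over $\log$(measurement) versus time and takes the slope of
the window maximizing $R^2$, preferring longer windows at ties. Windows
with best $R^2 < 0.9$ are flagged with a warning rather than dropped.
Note the estimator carries a small negative bias on logistic curves
(crowding already reduces the realized slope at the inoculum density,
about 3% at an inoculum of 2% of capacity); the bias largely cancels in
the growth-rate dose-response because rates are normalized to the
control before fitting. Whether curves are measured as OD or sulfide is
irrelevant to the estimator and both are accepted.

*Calibration.* `fit_sulfide_calibration()` is OLS in log-log space, with
$R^2$ computed there. Whether to fit on all replicate points or on
replicate means is left to the caller (`data_used`), and the choice is
recorded on the returned object.

## What the synthetic data emulate — and what they do not

The generators exist so every pipeline stage is testable with known
ground truth, emulating the study designs the model was built for:

- `gen_chemostat_timeseries()`: replicated sulfide/%SRM series from one
  simulated trajectory, sampled every 12 h by default, with
  multiplicative lognormal noise. Lognormal is the default because
  replicate scatter in such data scales with the mean (more than half a
  mM at a 2 mM steady state, under a tenth of a mM at inhibited
  levels); additive noise cannot reproduce that.
- `gen_plate_gradient()`: two-fold serial dilutions from 500 mM down,
  plus a 0 mM control; noise-free responses are exactly
  `control_signal * y(P)`.
- `gen_growth_curves()`: closed-form logistic curves whose intrinsic
  rate is $\mu(P)$, with optional lag.
- `gen_community_table()`: the SRM mass split across the four SRM genera
  in fixed, Desulfovibrio-dominant proportions, filler taxa drawn from a
  symmetric Dirichlet.

All generators are seed-deterministic (identical seed, identical bytes).

What passing tests on these data do **not** show about real systems: the
generators contain no adaptation (real treated cultures shift their IC50
over weeks), no donor dependence of sensitivity, no perchlorate-reducing
populations consuming the inhibitor or oxidizing sulfide, no real
community structure beyond the SRM fraction, and noise that is exactly
lognormal and independent across time points. Recovery envelopes
measured here are therefore best-case floors, not field performance.

*Batch co-cultures.* `simulate_batch_mixture()` gives every strain its
own $\mu_i(P)$ but a *shared* logistic ceiling, because co-cultured SRM
compete for one electron donor in one niche. This reproduces the
observed property that a mixture's endpoint dose-response overlays that
of its most resistant member: at inhibitory concentrations the resistant
strain simply fills the niche. Endpoint assay duration matters — too
short and nothing has grown, too long and even strongly inhibited
strains saturate; the packaged tests use 72 h, within the incubation
range such assays use.

## Problem sizes

The shipped test-and-verification runs use: untreated and 50 mM
simulations of 600–2000 h at 1 h output resolution; steady-state grids
of 12 (unit tests) and 50 (acceptance properties) perchlorate levels
with constant-inflow runs up to $2\times10^4$ h; and Monte-Carlo
recovery envelopes of 100 seeds at plate noise sd 0.05 (median
$|\Delta \log IC_{50}| < 0.05$) and calibration noise sized so typical
$R^2 \approx 0.79$ (median slope error $< 0.1$). These sizes were chosen
to resolve the dynamics they probe; the full suite runs in well under a
minute.

## Known limitations

- No biomass exchange between compartments, no biofilm spatial
  structure; $K_A$ is a lumped, empirical stand-in for all surface
  effects.
- The inhibition curve is phenomenological; there is no mechanistic
  model of sulfate-pathway de-repression or perchlorate transport.
- No perchlorate consumption: the inhibitor is conservative, so
  bio-competitive (perchlorate-reducing) suppression of sulfide is
  outside the model.
- Rebound timing after deep washout is floor-dependent (above); treat
  reported rebound times as order-of-magnitude.
- The calibration maps community fraction to sulfide with $R^2 = 0.79$;
  absolute sulfide predictions inherit that scatter.
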