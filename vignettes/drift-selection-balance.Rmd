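---
title: "Quantifying the balance between drift and selection in simulated biofilms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the balance between drift and selection in simulated biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftbalance)
library(dplyr)
```

## The question

When a young biofilm assembles from a handful of founder cells, two forces
decide which lineages prosper. *Selection* favours cells with better Monod
kinetics — a higher maximum specific growth rate $\mu_{max}$ or a lower
half-saturation constant $K_s$ in

$$\mu = \mu_{max}\,\frac{[S]}{K_s + [S]},$$

where $[S]$ is the local substrate concentration. *Ecological drift* is pure
luck: the random direction a cell divides in, and the random 40–60% biomass
split between daughters, compound over generations into large differences in
lineage success even among perfectly identical cells.

`driftbalance` quantifies the exchange rate between the two. Because every
run's randomness flows from a single Park–Miller stream, a run can be
replayed with *identical luck* but altered kinetics. The protocol is:

1. Simulate identical founders competing on an even grid until biomass fills
   a set fraction of the domain; lineages whose final share $X_i$ of the
   total falls below $0.3\,X_E$ (where $X_E = X_t/N$ is the neutral
   expectation) are *languishing*, those above $0.9\,X_E$ *thriving*, the
   rest *barely surviving*.
2. Identify the *biggest loser* — the lineage with the lowest final share.
3. Re-run with the same seed, giving only the loser a percent change in
   $\mu_{max}$ and/or $K_s$.
4. Across many seeds, record $p_{thrive}$: the probability that the loser's
   alteration rescued it to thriving.
5. Along each line of constant $K_s$ change, fit the logistic threshold
   $$p_{thrive} = \frac{1}{1 + e^{-k\,(\mu_{50} - \mu)}},$$
   where $\mu$ is the percent change in $\mu_{max}$. $\mu_{50}$ is the
   growth-rate advantage giving 50–50 odds against drift; the width of the
   band where $p_{thrive}$ is strictly between its extremes
   ($spread_{95}$: 2.5–97.5%, $spread_{68}$: 16–84%) measures where *both*
   forces matter. As printed, the curve rises with $\mu$ when $k < 0$;
   spreads use $|k|$: $spread_{95} = 2\ln(39)/|k|$,
   $spread_{68} = 2\ln(5.25)/|k|$.
6. Describe the whole $p_{thrive}$ surface with a linear model on guarded
   log-odds and with a generalized additive model (GAM) fitted directly to
   the probabilities, comparing their fidelity by probability-scale RMSE.

## The simulator

The agent-based core simulates spherical cells on a cuboid with periodic
X/Y walls, a substratum floor, and a fixed bulk substrate concentration at
the top. Each step:

* the substrate field is solved to diffusion–reaction steady state on a
  voxel grid (`solve_substrate()`), with each cell's Monod uptake
  $\mu m / Y$ apportioned to its voxel;
* every cell's mass is multiplied by $e^{\mu\,\Delta t}$ at its local
  concentration, and its diameter follows the constant-density sphere
  convention $m = \rho \pi d^3/6$;
* cells whose diameter exceeds the 1.36 µm threshold divide: the first
  daughter takes $f \sim U(0.4, 0.6)$ of the biomass, daughters sit tangent
  along a direction drawn uniformly on the sphere, centred on the parent;
* overlaps are relieved by iterative pairwise "shoving" along centre lines.

The run stops when total cell volume reaches the stop fraction (default
20%) of the full cuboid. Defaults mirror the study conditions: founder
diameter 1 µm, $\mu_{max} = 1\,\mathrm{h^{-1}}$,
$K_s = 3.5\times10^{-5}\,\mathrm{kg\,m^{-3}}$, yield 0.61, bulk substrate
$10^{-4}\,\mathrm{kg\,m^{-3}}$, domain height $2\times10^{-4}$ m, founder
populations of 4/9/16 spaced 2.5/5/10 diameters apart.

### Where drift comes from

Drift is not injected as noise on growth; it emerges. Under low-nutrient
conditions the film is diffusion-limited, so cells shaded inside or below
the advancing front starve while surface cells grow. Early random division
choices decide who ends up buried, and the disadvantage compounds. Without
meaningful substrate gradients the same simulator shows almost no drift —
all lineages track the neutral expectation — which is why the resolution
choices below preserve the supply/demand regime rather than just shrinking
the box.

### Design choices the underlying model description leaves open

* **Transport.** Advection and explicit fluid coupling are omitted — the
  scenario has no imposed flow — and the substrate is solved quasi-statically
  each growth step, since diffusion relaxes in seconds at these scales while
  growth acts over hours. The solver is a semi-implicit Gauss–Seidel sweep
  with the Monod sink linearised about the current iterate, which keeps
  every update within $[0, S_{bulk}]$ (a discrete maximum principle).
* **Biomass density.** $\rho = 150\,\mathrm{kg\,m^{-3}}$ by convention. The
  density is not free in isolation — uptake scales with $\rho$ — but the pair
  $(\rho, D)$ only enters through their ratio, which the test suite verifies
  by halving both and obtaining byte-identical lineage fractions.
* **Diffusivity.** $D = 2.3\times10^{-9}\,\mathrm{m^2\,s^{-1}}$, a typical
  small organic solute in water.
* **Integration.** Per-cell exponential update with an adaptive step
  capped so the fastest-growing cell gains at most ~10% mass per step
  (`dt_max` bounds the step when the whole film is starved).
* **Relaxation.** Damped pairwise overlap projection, tolerance $10^{-3}$
  of the pair's summed radii. Inside the run loop each step spends a bounded
  sweep budget (default 20); residual overlaps carry into the next step,
  which behaves like damped contact dynamics rather than full static
  re-equilibration and leaves the drift statistics unchanged (verified
  against fully relaxed runs).
* **RNG.** The Park–Miller minimal standard ($a = 16807$,
  $m = 2^{31}-1$), one stream per run. Divisions consume three draws in a
  fixed order — biomass fraction, direction $z$, azimuth — so seeds are
  portable across implementations.
* **Ties.** The biggest loser takes the lowest lineage id on ties.
* **Voxels.** Default edge 5 µm, rounded to tile the domain.

## Desk-scale conditions

The full-scale campaign behind the protocol is enormous (two full factorial
sweeps of 1089 kinetic/crowding combinations × 120 seeds, each run hours of
CPU). This package reproduces the *statistical machinery* and runs the
simulator at desk scale:

* `sim_config_desk()` lowers the domain height to $10^{-5}$ m and scales
  the diffusivity by the square of the height ratio, preserving the
  dimensionless supply/demand group ($\propto H^2/D$) that controls
  diffusion limitation — and with it the drift-generating mechanism. The
  voxel edge is refined to 2 µm so within-film gradients stay resolved.
* Campaigns default to reduced seed counts (`campaign_config(n_seeds = 5)`).
* The test suite exercises: drift fairness at 60 seeds of the 4-founder,
  5-diameter condition; a selection sweep at 9 founders, 10 diameters,
  $\Delta K_s = 0$, 20 seeds, 7 $\Delta\mu_{max}$ levels. These sizes keep
  the whole suite in the tens of minutes on one CPU while leaving the
  qualitative findings intact: losers languish far below $X_E$, no founder
  site is privileged, and a positive $\mu_{50}$ emerges on the baseline
  $K_s$ line.

What desk scale does *not* reproduce: the printed full-scale values
($\mu_{50}$ maps, regression slopes, model RMSEs) depend on the full domain
height, 120 seeds and the complete factor grid. Statements the package can
check are properties (fairness, monotone selection response, positive
$\mu_{50}$, model-family ordering), not those exact numbers.

## What the fixture generator emulates

`generate_fixture_pmap()` synthesises $p_{thrive}$ surfaces with known
logistic structure: per crowding condition a true steepness $k$ and a
linearly shifting cliff $\mu_{50}(\Delta K_s)$, observed through binomial
sampling with `n_seeds` trials per grid point. It reproduces the surface
*geometry* the simulator produces (saturating plateaus, moving cliff,
crowding-dependent steepness) and is the ground truth for testing the
fitting stages without simulation. It does not emulate seed-to-seed
correlation (each grid point samples independently, whereas paired-seed
re-runs share their luck across kinetic levels) or any asymmetry of real
profiles around the cliff.

## Fitting choices

* `fit_logistic()` minimises squared error on the probability scale with
  Levenberg–Marquardt and an analytic Jacobian (start values from a
  clamped-logit regression). A binomial GLM route (`method = "glm"`) is
  available for likelihood-based uncertainty. Profiles whose observed
  probability range is below 0.1 are declared degenerate and flagged
  non-converged rather than erroring; $\mu_{50}$ outside the swept range is
  flagged extrapolated.
* `bootstrap_logistic_ci()` uses a parametric bootstrap with a Student-t
  quantile on $n_{points}-2$ degrees of freedom; with 11-point profiles the
  plain percentile interval noticeably undercovers.
* Spreads are read from the *fitted* curve (closed forms above), not the
  raw points.
* `fit_mlr()` models the $\varepsilon$-guarded log-odds
  $\log(p/(1-p+\varepsilon)+\varepsilon)$, $\varepsilon = 10^{-6}$, and
  back-transforms predictions (clipped to $[0,1]$) before computing RMSE, so
  linear and additive models are compared on the same scale.
* `fit_gam()` (via `mgcv`) fits the probabilities directly with a Gaussian
  response, univariate smooths plus tensor-product interaction smooths and a
  by-factor smooth of population within spacing; smoothing parameters by
  GCV; basis dimension 5 per continuous marginal (the 3-level design factors
  cap theirs at 3). Predictions are deliberately unclipped — exceeding
  $[0,1]$ is reported with a flag.
* `backward_select()` removes, one at a time, the least significant term
  among the highest-order terms above $p = 0.05$, never removing a term
  nested inside a retained one — so main effects survive while any of their
  interactions remain.

## A small worked pipeline

```{r pipeline, eval = FALSE}
cfg <- campaign_config(populations = 4, spacings = 5,
                       dKs_levels = 0, dmu_levels = seq(-20, 60, 20),
                       n_seeds = 10)
res <- run_campaign(cfg, out_dir = "campaign-artifacts")
res$pmap
fit <- fit_logistic(res$pmap)
glance(fit)
```

Campaign artifacts are plain CSV with headers (JSON for model reports) and
are byte-identical across repeated invocations of the same configuration.

## Numerical edge cases

* Substrate solves error on non-convergence (cap 20,000 sweeps); runs error
  if the stop fraction is unreachable within `max_steps`.
* Coincident cell centres (never produced by division, possible in
  hand-built configurations) separate along a fixed deterministic axis so
  relaxation stays seed-free.
* Exact equality at the classification boundaries is *barely surviving*
  (the closed interval $[0.3\,X_E,\, 0.9\,X_E]$).
* Probability maps refuse to renormalise over missing seeds: gaps in the
  paired design are hard errors.
* Mass at division is conserved to machine precision (the split is
  $m_1, m - m_1$).

## Known limitations

* Identical, synchronised, grid-placed founders are the point of the design
  but not a natural situation; quantitative thresholds here do not transfer
  to real communities.
* Mechanical contact is overlap projection, not calibrated spring–dashpot
  physics; EPS, detachment, multispecies interactions and oxygen dynamics
  are out of scope.
* Desk-scale sweeps use tens of seeds; binomial noise on $p_{thrive}$ is
  correspondingly larger than in a 120-seed campaign.
* The GAM term p-values are approximate Wald tests for penalized smooths;
  selection decisions near $p = 0.05$ should not be over-read.
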