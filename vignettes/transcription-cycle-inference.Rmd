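---
title: "Inferring the transcription cycle from dual-color nascent RNA traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the transcription cycle from dual-color nascent RNA traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcycle)
library(dplyr)
```

## The measurement and the model

A reporter gene carries MS2 stem loops near its 5' end and PP7 stem loops
near its 3' end.  As each RNA polymerase (RNAP) transcribes through a
cassette, fluorescently tagged coat proteins bind the nascent loops, so the
fluorescence of a transcription spot in each channel is proportional to the
number of polymerases that have elongated past that cassette.  The two
channels therefore read out different stages of the same transcription
cycle: the MS2 (mCherry) signal responds almost immediately after
initiation, while the PP7 (eGFP) signal lags by the transit time to the 3'
cassette.

`txcycle` models one cell's pair of traces with a deterministic forward
model.  Polymerases load at rate $R(t) = \langle R\rangle + \delta R(t)$
from the onset time $t_{on}$, move at a single uniform elongation rate
$v_{elon}$ (kb/min), and, on reaching the gene end $L$, wait a deterministic
cleavage time $\tau_{cleave}$ after which the transcript — and its signal in
both channels — disappears instantly.  The predicted fluorescence is the
loading-history convolution

$$F_{PP7}(t) = PP7_{basal} + \int_{t_{on}}^{t} R(t')\,
  s_{PP7}(t - t')\, dt', \qquad
  F_{MS2}(t) = MS2_{basal} + \alpha \int_{t_{on}}^{t} R(t')\,
  s_{MS2}(t - t')\, dt',$$

where $s_c(a)$ is the fraction of cassette $c$ transcribed by a polymerase
of age $a$ (a linear ramp across the cassette, assuming evenly spaced
loops), and $\alpha$ is the mCherry/eGFP calibration factor — the
fluorescence of a full MS2 cassette in units of a full PP7 cassette.  One
fully transcribed PP7 cassette defines 1 AU, and rates are in AU/min.

For a constant-rate pulse this produces the familiar trapezoid shape: the
MS2 signal rises first, PP7 follows after $d/v_{elon}$ (with $d$ the
distance to the PP7 cassette), both plateau once the oldest transcripts
begin to cleave at $t_{on} + L/v_{elon} + \tau_{cleave}$, and after
shut-off the 5' signal decays before the 3' one.
`trapezoid_closed_form()` evaluates this case exactly (piecewise quadratic
in time) and serves as the oracle for the numeric model.

```{r trapezoid, fig.width = 6, fig.height = 3.2}
geom <- reporter_geometry()
p <- transcription_params(r_mean = 15, v_elon = 1.7, tau_cleave = 2,
                          t_on = 1.5, alpha = 0.145,
                          ms2_basal = 1, pp7_basal = 2)
plot_trace(generate_trace(p, geom, seed = 1))
```

### Numerical evaluation

`predict_traces()` discretizes the loading integral on a grid 4x finer than
the observation grid (15-s frames by default).  Within each fine interval
the live loading window is clipped exactly against the two step
discontinuities — the onset $t_{on}$ and the cleavage cutoff $t - (L/v +
\tau)$ — and the cassette ramp is integrated in closed form.  The only
remaining discretization error is treating $R(t')$ as constant across a
fine interval, which is exact for constant $R$ and $O(\Delta t^2)$ for the
slowly varying $\delta R(t)$ basis.  The forward-model test suite verifies
agreement with the closed form at machine precision for constant rates.

$\delta R(t)$ is parameterized as values at 5 evenly spaced knots across
the fit window, linearly interpolated and zero outside; the knot count is a
configuration option.  A zero-mean Gaussian prior (sd 1 AU/min by default)
keeps these fluctuations small relative to $\langle R\rangle$, as intended
by the mean-field decomposition: the knots absorb slow drifts of the
initiation rate, not bursts.

## Per-cell Bayesian inference

`run_mcmc()` samples the full parameter vector — $\langle R\rangle$, the
$\delta R$ knots, $v_{elon}$, $\tau_{cleave}$, $t_{on}$, $\alpha$, and both
basal levels — for each cell independently, under a Gaussian observation
model with per-channel noise sds.  Priors are uniform boxes chosen to
bracket all plausible values for this system ($v_{elon} \in (0.1, 10)$
kb/min, $\tau_{cleave} \in (0, 15)$ min, $\alpha \in (0.01, 1)$, rates and
basal levels non-negative), plus the Gaussian penalty on the $\delta R$
knots; $t_{on}$ and the basal levels are fitted jointly with everything
else.

By default the two noise sds are *sampled* as additional parameters rather
than fixed.  A robust point estimate (the median absolute deviation of the
double-differenced trace divided by $\sqrt 6$, which ignores the smooth
trace shape) only initializes them.  We chose sampling over fixing because
synthetic-data calibration experiments showed that fixing an estimated
noise scale makes the 90% credible intervals overconfident — fluorescence
near the detection floor is clipped at zero, so no single pre-computed
scale is exactly right — while sampling the sds restores close-to-nominal
interval coverage.  Supplying `noise_sd` in `tc_inference_config()` fixes
them instead.

The sampler is an adaptive random-walk Metropolis in the spirit of the
Haario algorithm: the proposal covariance is the scaled
($2.38^2/d$) running covariance of the chain, regularized, with a global
scale factor tuned by a Robbins-Monro recursion to a 23% acceptance rate.
Two refinements matter in practice:

* **Laplace warm start.** Before sampling, a box-constrained quasi-Newton
  optimization from the data-driven starting point (and two jittered
  restarts) finds the posterior mode, and the inverse Hessian there seeds
  the proposal covariance.  Without this, chains of a few thousand steps
  are dominated by the adaptation transient.
* **Occasional wide proposals.** 5% of proposals use a 5x wider kernel.
  Cells whose MS2 amplitude is small (low $\alpha$ draws) have genuinely
  multimodal posteriors — a fast-elongation mode can fit almost as well as
  the true one — and the wide component lets the chain hop between modes so
  the posterior mean averages over them.

Chains are reproducible bit-for-bit under a fixed seed.  Convergence is
assessed per cell with trace plots (`autoplot()` on a chain) and the chain
autocorrelation function (`chain_autocorrelation()`); the package default
is 30,000 steps with a 25% burn-in, while the bundled tests use shorter
chains (4,000–15,000 steps) that the warm start makes adequate for
synthetic traces.

The posterior mean of each parameter's chain is the per-cell point estimate
retained downstream, with central credible intervals from the post-burn-in
quantiles (`summarize_chain()`).

## Curation

`fit_quality()` scores each fit by a coefficient of determination pooled
over both channels after rescaling MS2 by $1/\alpha$; `curate()` accepts
cells above a threshold (default 0.8) that are not flagged as bursting, and
reports an acceptance-bias check (accepted-vs-all parameter means in units
of the standard error) rather than enforcing one.

The bursting flag targets telegraph-like ON/OFF initiation, which violates
the constant-mean-rate model.  A cell is flagged when its basal-subtracted
signal drops below 30% of its running maximum in *both* channels for at
least 1 min, ignoring the rise phase.  These defaults interact with the
reporter's relaxation time: after initiation shuts off, the signal decays
over $L/v_{elon} + \tau_{cleave} \approx 5$ min, so an OFF period must last
roughly $0.7 \times 5 + 0.5 \approx 4$ min before the trough becomes
detectable at all.  The synthetic telegraph mode therefore uses ON dwells
of 2–4 min and OFF dwells of 4–6 min: shorter OFF periods produce traces
that are operationally indistinguishable from a slightly noisy constant
rate, and no threshold choice could (or should) flag them.

## Synthetic data

Two generators are first-class parts of the package.

**Trace-level** (`generate_population()`): per-cell parameters are drawn
independently from truncated normal distributions, traces are simulated
through the forward model at 15-s sampling over an 18-min window, and
independent Gaussian noise is added per channel and clipped at zero.
Defaults describe the system under study: $v_{elon}$ centered at 1.72
kb/min, $\tau_{cleave}$ at 2.25 min (the middle of the reported 1.5–3 min
range), $\alpha$ at 0.145, onset around 2 min.  The initiation-rate center
(15 AU/min) and the generative sds (e.g. 30% CV for $\langle R\rangle$,
0.35 kb/min for $v_{elon}$) are this package's choices of realistic
single-embryo variability: wide enough that cell-to-cell differences
dominate inferential noise, narrow enough that every draw stays physical.
Noise sds default to roughly 5% of a typical plateau per channel.  An
optional step profile divides $\langle R\rangle$ by a configurable fold
change (default 26) posterior of 45% embryo length, emulating the
anterior-posterior expression step; an optional telegraph mode replaces a
fraction of cells with ON/OFF initiation for curation testing.

What the generator does *not* emulate: intensity-dependent measurement
noise, photobleaching, segmentation artifacts, correlated noise between
channels, non-processive polymerases, and true transcriptional bursting
dynamics beyond the two-state telegraph.  Passing recovery tests on these
synthetic populations therefore demonstrates the estimator's correctness
and calibration under the model's own assumptions, not robustness to every
feature of real imaging data.

**Molecule-level** (`simulate_single_molecule()`): an exact Gillespie
simulation of RNAPs stepping base-by-base along the gene with hard-core
exclusion over a 40-base footprint.  Loading attempts succeed when the
first footprint is clear; each molecule carries its own stepping rate,
drawn from a Gamma distribution (positive support; the family is
configurable) with a chosen mean and CV.  Blocked steps are rejected
without state change, which is an exact thinning of the exponential clocks.
Fluorescence is computed from molecule positions through the same cassette
ramps and $\alpha$; after a molecule steps off the gene end its finished
transcript keeps its full two-channel signal for the deterministic cleavage
wait (default 2 min) and then vanishes instantly, mirroring the forward
model.  This 3' pool dominates the PP7 plateau, exactly as in the
deterministic model — omitting it leaves a PP7 signal so small and so
demographically noisy that per-cell inference on the simulated traces
becomes ill-conditioned.  The minimum inter-molecule gap ever observed is
returned and asserted to be at least the footprint.

`elongation_distribution_experiment()` chains the two levels: simulated
fluorescence from the stepping model is pushed through the full MCMC so the
cross-cell distribution of inferred elongation rates includes inferential
noise.  Comparing per-molecule rate CV 0 (stochastic stepping and traffic
jams only) against CV 0.5 shows that identical molecules cannot produce a
wide cross-cell spread of inferred rates, while molecule-to-molecule
variability can — the qualitative ordering this package's acceptance
checks assert.

## Downstream statistics

* `fit_alpha_through_origin()` estimates $\alpha$ from interlaced-reporter
  data (both cassettes report the same signal) as the least-squares slope
  through the origin, $\sum m p / \sum p^2$, plus the per-point ratio
  histogram.
* `decompose_cv2()` splits the squared CV of paired two-color measurements
  into uncorrelated (channel-difference) and correlated (covariance)
  components; the additivity of the two parts is an algebraic identity,
  exact on every input.  MS2 values are rescaled by $1/\alpha$ beforehand;
  by default the global mean $\alpha$ is used rather than per-cell values,
  which keeps the rescaling independent of single-cell inference noise.
* `bootstrap_cv()` attaches a standard error to CV or CV² from 100
  with-replacement resamples.
* `spearman()` wraps the rank correlation with an exact permutation null
  for $n \le 9$ (no ties) and the t-approximation otherwise — the choice of
  approximation is this package's, made for determinism and speed.
* `transcript_density()` is $\langle R\rangle / v_{elon}$ (AU/kb), and
  `occupancy_fraction()` converts a molecule density to the fraction of the
  gene covered by 40-base footprints, capped at 1.
* `bin_by_position()` aggregates per-cell results in AP-position bins
  (default width 2.5% embryo length — fine enough to resolve the expression
  step, coarse enough to keep several cells per bin).
* `posterior_correlation_mc()` propagates full posteriors into cross-cell
  correlations by repeatedly drawing one posterior sample per cell.

## Numerical choices and limitations

* Loading-grid refinement 4x, with exact boundary clipping (above);
  refinement is configurable and the oracle test pins the accuracy.
* Initialization heuristics (onset from the first sustained rise, basal
  levels from the pre-onset floor, amplitude-based rate and $\alpha$
  guesses) only set the optimizer's starting point; results are insensitive
  to them once the warm start converges.
* Ties between $t_{on}$ and the basal levels are resolved by fitting both
  jointly; for cells that never clearly rise, the posterior for $t_{on}$ is
  wide, and fit-quality curation is the intended guard.
* The model deliberately excludes sequence-dependent pausing, polymerase
  loss, and bursting; bursting-like cells are flagged, not modeled.
* Problem sizes in the bundled tests and the acceptance script (30–100
  synthetic cells, chains of 4,000–15,000 steps, 6 stepping simulations per
  condition) were chosen as the smallest sizes at which the statistical
  checks are stable; the package defaults are larger.
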