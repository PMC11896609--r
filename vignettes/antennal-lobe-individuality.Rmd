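---
title: "Modeling antennal-lobe individuality: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling antennal-lobe individuality: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flyAL)
```

This vignette documents the models implemented in `flyAL`, the choices
behind their defaults, what the synthetic-data generators do and do not
emulate, and the numerical decisions a user may want to revisit.

## The circuit model

The antennal lobe (AL) is represented as a roster of neurons — olfactory
receptor neurons (ORNs), uniglomerular and multiglomerular projection
neurons (uPNs, mPNs), and local neurons (LNs) — plus a pre-by-post matrix
of synapse counts. ORNs and uPNs carry a glomerulus label; neurons of
seven non-olfactory (hygro-/thermosensory) glomeruli (VP1d, VP1l, VP1m,
VP2–VP5) are removed at load time, which on a full hemibrain-style export
leaves 51 olfactory glomeruli.

Polarities: ORNs are excitatory. PNs with a neurotransmitter annotation
use it; unannotated mPNs (resp. uPNs) are drawn excitatory with
probability equal to the cholinergic fraction among annotated mPNs (resp.
uPNs). This draw is made once per roster under a caller-supplied seed and
is meant to be serialized with the roster — reloading never re-randomizes.
A fixed fraction of LNs is excitatory: `round(n_LN / (1 + 5.4))` under the
1:5.4 eLN:iLN ratio (197 LNs give 31 eLNs). Because excitatory LNs
innervate the AL broadly, eLNs are drawn uniformly from the top half of
LNs ranked by innervated-glomerulus count. Two conventions the source
material leaves open are fixed here: rank ties break by neuron id, and an
odd pool keeps `ceiling(n/2)` candidates. An LN "innervates" a glomerulus
if it has at least one synapse, in either direction, with any
glomerulus-labeled neuron of that glomerulus — the threshold and
directionality are package conventions.

The effective weight from j to i is
`polarity(j) * count(j, i) * a_class(i)`, with the postsynaptic
class-specific sensitivities `a = (0.1, 0.04, 0.02, 0.4)` for ORN, eLN,
iLN and PN columns. These four numbers are the model's only free
parameters, and the defaults are the tuned configuration. No edges are
filtered beyond the glomerulus exclusion: whatever class pairs appear in
the edge list are simulated.

## Odor drive

ORN firing during an odor follows
`FR = FR_max * D * (f_a + (1 - f_a) * exp(-t / t_a))` with
`FR_max = 400` Hz, `f_a = 0.75` and `t_a = 110` ms, where `D` in [0, 1]
is the odorant-response value for that glomerulus-odor pair. The adapted
ceiling is therefore 300 Hz; off-odor ORNs fire at 10 Hz. Spike times are
drawn by per-time-step Bernoulli thinning of the inhomogeneous Poisson
process (the discretization must satisfy `max(rate) * dt < 0.1`
spikes/step; at dt = 0.1 ms the 400 Hz ceiling gives 0.04).

Two points the drive description leaves open are resolved as follows.
During an odor, the evoked process *replaces* the spontaneous one for
glomeruli with `D > 0`, while `D = 0` glomeruli continue at 10 Hz —
summing both would double-count drive. Adaptation resets at each odor
onset; with 300 ms odor-free gaps between 400 ms presentations this is
the simplest defensible convention.

Missing odorant-response values (about 40% of a DoOR-style matrix) are
imputed by alternating-least-squares matrix completion, repeated from
random starts (1000 by default) and averaged, then clamped to [0, 1].
The completion rank — not stated anywhere authoritative — is the smallest
number of components explaining 75% of the variance of the mean-infilled
matrix; convergence is declared at a relative change of 1e-6, capped at
200 iterations per repeat.

## The LIF engine

Each neuron obeys
`C dV/dt = (V_0 - V)/R + I_odor + sum_j a_i W_ji I_j(t)` below threshold,
integrated by forward Euler at dt = 0.1 ms (units mV/ms/pA/pF/GOhm, under
which no conversion constants appear). Membrane parameters per class
(ORN/LN/PN): rest −70/−50/−55 mV, threshold −50/−40/−40 mV, spike minimum
−70/−60/−55 mV, spike peak 0/0/−30 mV, spike duration 2/4/2 ms,
capacitance 73/64/73 pF, resistance 1.8/1/0.3 GOhm.

On threshold crossing, a templated action potential is written into the
voltage trace — piecewise-linear rise to the spike peak over the first
half of the spike duration, fall to the spike minimum over the second
half — during which integration is suspended, so the template acts as an
absolute refractory period. The template shape beyond its endpoint
voltages and duration is a package choice. Each spike also launches a
unit-amplitude single-exponential postsynaptic current, delivered to
downstream neurons scaled by the signed effective weight, beginning the
time step after the spike. Scheduled ORN spikes are forced by injecting
1e6 pA for exactly one time step.

The PSC decay timescale `tau_syn` is not a measured quantity; it trades
off against the sensitivity multipliers (both scale total synaptic
charge). With the multipliers pinned at their tuned values, `tau_syn` is
the remaining gain knob, and the package default of 4 ms is the value
under which the shipped synthetic fixture reproduces the canonical AL
computations (below). It is exposed as an argument everywhere.

Glomerular responses are mean firing rates over each 400 ms odor window
(half-open `[start, end)` spike counting), averaged over the glomerulus's
uPNs (or ORNs). Baseline subtraction is off by default — the response
vectors are raw rates — with a flag for delta-f/f-style comparisons.

## Tuning and validation

Four canonical computations define a "working" AL: (1) literature-range
firing rates (defaults: mean ORN baseline 5–20 Hz, mean odor-evoked PN
rate 10–200 Hz — configuration values, since the electrophysiology table
gives membrane constants, not target rates), (2) PN odor-evoked rates
distributed more uniformly than ORN rates, (3) PN odor representations
more separated than ORN representations, and (4) a sublinear ORN-to-PN
transfer. The comparative criteria need concrete statistics, which are
fixed here for reproducibility: uniformity is the Gini coefficient of
per-neuron mean evoked rates; separation is the mean pairwise Euclidean
distance between unit-normalized per-odor population vectors; the
transfer exponent is the log-log slope of `log(PN + 1)` on `log(ORN + 1)`
over glomerulus-odor pairs. Any monotone statistic would serve; these are
the package's choices.

Sensitivity is quantified by re-simulating the panel with each multiplier
scaled up to 4x or 1/4x (and with joint log-Normal manipulations,
`sd_log = log 2`, so one SD is a 2x or 0.5x scaling) and reporting
Cohen's d of PN glomerulus-odor responses against baseline, with the same
input-spike seed throughout.

## Idiosyncrasy generators

Simulated individuals differ from the reference circuit through:

- **Cell-type bootstrapping.** ORNs (and uPNs) are resampled with
  replacement within each glomerulus pool, preserving pool sizes; all LNs
  form a single pool. A resampled neuron keeps its original rows and
  columns of the count matrix, so no synapse ever appears between pairs
  unconnected in the source. mPNs, which lack a unique glomerulus, stay
  fixed under PN bootstrapping.
- **Synapse-density resampling.** Per glomerulus, a target total PN input
  synapse count is drawn from `log S = log(a V^d) + eps` and all synapses
  onto that glomerulus's PNs are multiplied by one scalar. Weights become
  real-valued; nothing is re-rounded. "PN input synapses" means every
  edge onto a uPN of the glomerulus, regardless of presynaptic class.
- **Poisson-only** (`"poisson"` mode): no circuit change; individuals
  differ only in input spike timing. This is the negative control.

Combined modes apply bootstrap first, then density rescaling. The
power-law fit itself is ordinary least squares of `log S` on `log V` with
the maximum-likelihood (divisor n) residual SD — exactly the MLE under
the log-normal model.

## Latent-correlation inference

An observed calcium-behavior model R² understates the latent correlation
because both measurements are noisy. The correction simulates, for each
`r_latent` on a 0–0.01–1 grid, latent states `X_c` and
`X_b = r_latent X_c + sqrt(1 - r_latent^2) Z` for N individuals, then
noisy readouts mixed at `r_c = (R2_cc)^{1/4}` and `r_b = (R2_bb)^{1/4}`
(so that two readouts of the same state correlate at the measured
repeatability), and records `corr(X_c', X_b')^2`. Repeatability
uncertainty enters by cycling bootstrap samples of `R2_cc` and `R2_bb`
through simulation iterations (index cycling; the coupling is a package
convention). Each bootstrap draw of the observed R² contributes the
marginal distribution of `r_latent` consistent with it — a window of
half-width 0.02 around the observed value, with equal prior weight per
grid point — and the summed posterior is transformed to `R²_latent` by
quantile matching (`P(r_latent <= q) = P(R2_latent <= q^2)`, i.e. the
posterior pushforward through squaring). The median and 5th–95th
quantiles are reported. Defaults are 10,000 simulations per grid point;
tests run reduced sizes (300–1000) chosen so Monte-Carlo error stays well
under the tolerances asserted.

Calcium repeatability `R2_cc` is estimated by comparing PCA eigenvalues
of the trial-level response matrix to rank-matched eigenvalues of shuffled
data, where shuffling permutes the feature values of each individual
(jointly across that individual's trials, preserving every individual's
multiset of values). The leading components whose eigenvalues exceed the
rank-matched 95th percentile of the shuffled eigenvalues (Horn's parallel
analysis; the percentile rather than the mean keeps the estimate at zero
for structureless data) are read as signal; `R2_cc` is their cumulative
variance fraction. Uncertainty comes from bootstrapping individuals, with
duplicated individuals shuffled independently.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage of the pipeline is exercised
without downloads. `generate_connectome()` builds a glomerularly
organized AL at reduced scale; its defaults were chosen once, by matching
class-wise synaptic-input compositions to hemibrain-scale statistics at
about 1/20 the cell count, and then selecting the shipped configuration
by grid exploration until the canonical-computation battery held — the
same manual-tuning procedure used for the original full-scale model.
Concretely:

- 8 glomeruli, 12 ORNs and 1–3 uPNs per glomerulus, 6 mPNs, 16 LNs
  (~134 neurons). Volumes are log-uniform on [2e3, 4e4] um^3 and each
  glomerulus's total PN input synapse count follows the printed
  volume-synapse law, so refitting the law on generated circuits recovers
  its parameters.
- uPN number grows sublinearly (square-root) with glomerular synapse
  mass, as in the connectome where large glomeruli harbor more PNs; ORNs
  contribute 85% of PN input mass, innervating LNs the rest.
- Sister ORNs are heterogeneous: each ORN's output weight carries
  log-normal variation (`sd_log = 0.7`). This is what gives ORN
  bootstrapping its glomerulus-level variance, as in the real circuit
  where sister-ORN synapse counts differ severalfold.
- LNs innervate 5–8 of the 8 glomeruli (broad, as the eLN-biased top
  half requires) and connect reciprocally with ORNs, uPNs and each other
  within innervated glomeruli, with per-edge Poisson counts whose means
  (125/40/40/20 for ORN->LN, LN->ORN, PN->LN, LN->LN) preserve per-LN
  input totals at the reduced ORN count.
- `generate_door_matrix()` emulates the odorant-response database's
  breadth-magnitude structure: broadly tuned glomeruli respond strongly
  to most odors, narrow ones weakly and odor-specifically, many pairs not
  at all, with odor-specific low-rank structure in the responsive cells
  and missingness applied uniformly at random (40% by default).

`canonical_fixture()` freezes the tuned realization (circuit seed 17,
response-matrix seed 7) used by the package's validation tests. Passing
the battery on this fixture shows the dynamics, tuning logic and analysis
pipeline are coherent at desk scale; it does *not* show that an arbitrary
random 8-glomerulus circuit behaves like a real AL — at this size,
realization noise in the battery's comparative statistics is substantial
— nor does it reproduce hemibrain mesoscale features beyond glomerular
block structure and the volume-synapse law.

`generate_paired_dataset()` mirrors the statistical assumptions of the
latent-correlation analysis exactly (the same mixing construction), adds
a feature-space embedding along a loading vector, and calibrates
isotropic trial noise against the analytic variance-share approximation
(optionally by bisection against the repeatability estimator itself).
Real calcium data differ in ways the generator ignores: trial-order
effects, hemispheric asymmetries, non-isotropic noise, and more than one
behavior-linked direction.

## Numerical choices and problem sizes

- Forward Euler at dt = 0.1 ms; the subthreshold trajectory matches the
  analytic exponential to O(dt), and halving dt changes panel-mean PN
  rates by under 5% on the fixture.
- Scheduled spikes landing inside an ongoing action-potential template
  are absorbed by it (the neuron is refractory); at 10 Hz spontaneous
  rates this censors about 2% of scheduled spikes, visible in the
  measured spontaneous rate (~9.8 Hz against the 10 Hz schedule).
- Population experiments in the tests use 100 simulated individuals per
  variation source on the 8-glomerulus fixture with a 12-odor panel
  (about one second of simulated biological time per individual); the
  latent-recovery experiment uses 20 replicate datasets at N = 69 with
  1000 simulations per grid point. These sizes put Monte-Carlo error
  comfortably below the asserted margins while keeping a full test run
  in the tens of minutes.
- Ties in PCA sign conventions are resolved by making each component's
  largest-magnitude loading positive, so loadings, scores and downstream
  regression signs are reproducible across platforms.
- Degenerate inputs error early and specifically: all-zero rate vectors
  (no Gini), fully missing rows/columns (no imputation anchor), single
  classes (no decoding), zero pooled SD (no effect size).

## Known limitations

- The AP/PSC template shapes are stylized; only their endpoints,
  durations and integral scale are constrained.
- No synaptic conductances, plasticity or neuromodulation; PN input sums
  linearly, so very strong convergent input is bounded only by the
  refractory ceiling.
- The latent-correlation posterior treats the grid inversion with a flat
  prior over `r_latent`; a different prior would shift small-N inferences.
- The shipped fixture is one tuned realization. Conclusions about
  variation sources (e.g. GOI orderings) replicate across fixture seeds,
  but the four-computation battery as a strict conjunction does not —
  tuning at this scale is per-realization, as it was for the original
  full-scale circuit.
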