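---
title: "Global signal correction and voxel-level connectivity networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global signal correction and voxel-level connectivity networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(gsrnet)
```

## The problem

Voxel-level resting-state functional connectivity networks are built by
correlating every pair of voxel time courses, thresholding the correlation
matrix into a binary graph, and analysing that graph. A contested
preprocessing choice sits upstream of everything: whether to regress the
*global signal* — the mean time course over the whole brain — out of every
voxel before correlating. `gsrnet` implements the full comparison pipeline
for four standard correction schemes:

* **NoCorr** — six motion regressors only;
* **NoWB** — motion plus deep-white-matter and ventricle mean series;
* **WBonly** — motion plus the whole-brain mean;
* **Full** — motion, white matter, ventricle, and whole-brain means.

All regressions are per-node ordinary least squares with an intercept, on
de-meaned regressors; near-collinear regressor sets (condition number
greater than 1e8 after unit-scaling) raise an error rather than being
silently dropped.

## Why an uncorrected global signal biases correlations

If two voxel series share an additive signal, `W1 = Y1 + G` and
`W2 = Y2 + G` with `G` uncorrelated with the intrinsic parts, then

$$\mathrm{Corr}(W_1, W_2) \;=\;
  \frac{\mathrm{Var}(G)}
       {\sqrt{(\mathrm{Var}(Y_1) + \mathrm{Var}(G))
              (\mathrm{Var}(Y_2) + \mathrm{Var}(G))}} \;>\; 0 ,$$

strictly positive whenever `Var(G) > 0` (`expected_shared_correlation()`).
Equal intrinsic and shared variances give correlation 0.5. The whole
distribution of sample correlations shifts: with `t` time points and
population correlation zero the sample correlation has density

$$f(r) = \frac{\Gamma((t-1)/2)}{\sqrt{\pi}\,\Gamma((t-2)/2)}
         (1-r^2)^{(t-4)/2},$$

symmetric about zero (`central_corr_density()`; at `t = 4` it is uniform).
With population correlation $\rho \neq 0$ the density takes the classical
series form implemented in `noncentral_corr_density()`:

$$f(r) = \frac{(1-\rho^2)^{(t-1)/2} (1-r^2)^{(t-4)/2}}
              {\sqrt{\pi}\,\Gamma((t-1)/2)\,\Gamma((t-2)/2)}
         \sum_{j=0}^{\infty}
         \frac{\Gamma^2\!\big((t-1+j)/2\big)}{j!} (2\rho r)^j .$$

A variant of this formula circulates with $(1-\rho)$ in place of
$(1-\rho^2)$ in the prefactor base. Only the $(1-\rho^2)$ base integrates
to one — the $(1-\rho)$ variant integrates to $(1+\rho)^{-(t-1)/2}$ — and
only the $(1-\rho^2)$ base matches Monte-Carlo histograms of sample
correlations, so that is the default; the other form is kept behind
`base = "printed"` purely for comparison. Normalization is decisive and
testable, which is why the package settles the discrepancy this way. Series
terms are evaluated in log-gamma space and summed by log-sum-exp (terms peak
near $j \approx \rho r t$, far beyond overflow range for naive evaluation),
truncated at relative size 1e-12 with a hard cap of 500 terms.

## The phantom

No public voxel-level resting-state dataset accompanies this package;
instead `generate_phantom()` + `signal_model()` + `simulate_timeseries()`
synthesize datasets with the statistical structure the analysis assumes,
with known ground truth. Every latent signal is band-limited Gaussian noise
(FFT mask to the passband, rescaled to exact unit sample variance), so the
variance bookkeeping above holds in-sample, not just in expectation.

A node's series is assembled from:

* its **module signal** (contiguous spatial blocks from recursive
  bisection of the lattice; variance `var_module`);
* **graded mixed membership**: a node at Manhattan distance $d$ from the
  nearest foreign module mixes that module's signal in with amplitude
  fraction $\eta(d) = \eta_0 e^{-(d-1)/\lambda}$ (defaults
  $\eta_0 = 0.7, \lambda = 2$), with the primary amplitude reduced so the
  module-part variance is unchanged;
* the **global signal** `G`, with a loading profile that peaks at the
  first-axis midplane (peak multiplier 2.5, decay length 1.5 voxels) —
  the interhemispheric-fissure analogue;
* the **ventricle signal**, carried by all gray nodes at amplitude 1.2 —
  broadly shared physiological noise;
* for white-matter-adjacent nodes (8% of nodes, drawn from module
  boundaries): extra shared white-matter-signal variance
  `var_wm * wm_adjacent_loading` (default 8) and module amplitude
  attenuated by 0.8;
* independent band-limited node noise (`var_noise`).

Auxiliary voxels outside the network lattice carry the white-matter and
ventricle signals plus noise and provide the nuisance masks; the
whole-brain (parenchyma) mean is taken over the network nodes plus the
white-matter sphere, excluding the ventricle mask — the package's reading
of a parenchyma mask "including gray and white matter". Six smooth motion
regressors are always generated (NoCorr still regresses them) and by
default do not leak into the data.

### Why these ingredients, and not fewer

Each component exists because a documented phenomenon requires it:

* *Ventricle signal on all gray nodes.* Removing white-matter and
  ventricle means (NoWB) must reduce the positive bias relative to NoCorr.
  That is only possible if those signals are broadly shared across gray
  matter; confining them to their masks makes NoWB indistinguishable from
  NoCorr on the mean (or worse, inverted by the wm-adjacent dilution
  effect).
* *Midline loading gradient.* Hub concentration along the
  interhemispheric fissure under uncorrected data requires nodes whose
  global-signal loading is elevated; a smoothly decaying profile produces
  graded edge reallocation and partial fragmentation, where a binary
  high/low slab produces an all-or-nothing clique that either starves the
  whole network or does nothing.
* *Graded mixed membership.* After full regression the giant component
  must span modules (in the reference regime about 93-94% of nodes
  connect). Discrete "bridge" nodes carrying two module signals at full
  strength fail instructively: their loading on the whole-brain mean is
  doubled, so whole-brain regression subtracts twice as much from them and
  leaves them *anti*-correlated with other modules — the well-known
  GSR-induced anticorrelation, turned against the network's connectedness.
  A spatial gradient of membership mixing survives regression because
  facing boundary nodes correlate through module-specific (not global)
  signal.
* *White-matter-adjacent loading and attenuation.* Junk-module
  concentration near white matter under NoCorr needs boundary nodes whose
  variance is dominated by a shared non-neuronal signal that the NoWB/Full
  regressors can remove; attenuation of their module signal makes them the
  first nodes to disconnect when the threshold rises.

Defaults were fixed by analysing the population correlation matrix implied
by each candidate mechanism and checking which regimes reproduce the
documented contrasts (bias ordering, fragmentation, junk concentration,
hub placement) robustly across seeds at the package's default problem
size; they are study conditions, not tuning knobs, and the full set is
recorded in `signal_model()`'s defaults.

### What the phantom does not model

Exchangeable nodes within a module (no empirical spatial autocorrelation
beyond the optional smooth local field, which defaults off), no scanner
physics, no slice-timing or motion-as-image-transformation, no
physiological waveform structure (cardiac/respiratory phases), and no
anatomical atlas. Passing tests demonstrate that the *pipeline* behaves
correctly under the assumed generative structure — not that real fMRI data
follow that structure.

## Pipeline order and filtering

Filtering precedes nuisance regression (`run_study()` enforces this
order). The band-pass filter is a zero-phase forward-backward 4th-order
Butterworth (0.009-0.08 Hz defaults), with an ideal FFT brick-wall filter
as an alternative. Regressing after filtering has been criticized because
unfiltered regressors can reintroduce out-of-band variance; the
`bandpass_regressors = TRUE` option addresses that critique, while the
default keeps the conventional order. Note the simulated signals are
already band-limited, so filtering is nearly a no-op on phantom data; the
stage exists (and is tested on sinusoids) because the pipeline's contract
is defined on arbitrary input series.

## Network construction

`threshold_for_S()` picks a positive correlation threshold so that
$S = \log N / \log K$ (N all mask nodes, K mean degree) is as close as
possible to the target (default 3.0; the conventional range is 2.5-3.5).
`N` counts every mask node, connected or not: thresholding happens first
and disconnection is a *result*. Edges require `r > threshold` strictly;
the achievable edge sets are exactly the strict upper sets of the distinct
observed positive values, so the search scans all of them (via cumulative
counts of the sorted distinct values) and is exact, with ties in
$|S - S_\mathrm{target}|$ broken toward the sparser network. A binary
search plus local scan gives the same optimum; the exhaustive vectorized
scan was chosen because at this package's scale (up to a few thousand
nodes) it is instantaneous and leaves no edge cases.

Graph metrics follow the standard definitions: Watts-Strogatz local
clustering averaged over nodes (by default over nodes of degree >= 2 — C
is then comparable across networks with very different disconnected-node
counts; `denominator = "all"` zero-counts them instead), and path length
as the reciprocal of global efficiency over all ordered pairs of the full
node set, so disconnected pairs (efficiency 0) lengthen L rather than
vanishing from it. Hubs are the top 20% of nodes by degree, ties broken by
node index for determinism.

## Parcellation

`qcut_partition()` first separates everything outside the giant component
into a distinguished junk module (id 0), then parcellates the giant
component by recursive spectral bipartition on the leading eigenvector of
the generalized modularity matrix, with Kernighan-Lin single-node
refinement after each split and a final greedy pairwise merge pass;
splitting and merging stop when no move improves Q by more than 1e-10.
Giant components of at most 10 nodes are solved exactly by enumerating all
set partitions. The eigen-decomposition is deterministic, so the procedure
is reproducible; the `seed` argument only breaks exact ties. This is a
behavior-level reimplementation of iterative modularity-cut parcellation,
not a line-by-line port of any published code.

`n_modules` excludes the junk module by default: junk is a bookkeeping
container for disconnected material, not a community the algorithm found.
The module count of a near-optimal modularity partition is intrinsically
ambiguous by roughly +-2 at a few hundred nodes — partitions differing by
that many modules can carry practically identical Q — which is worth
remembering when comparing counts across conditions at small problem
sizes (see the limitations section).

## The study runner

`run_study()` executes, for each replicate subject (same phantom geometry,
fresh signal seed) and each correction method: simulate, filter, extract
nuisance means, regress, correlate, summarize the correlation
distribution, threshold at the target S, compute components, C, L, degree
metrics, parcellate, count white-matter-adjacent junk nodes, and rebuild
the network without wm-adjacent nodes for the paired path-length check.
Method pairs are compared by paired two-sample t tests per metric and by a
variance-ratio F test on the maximum degree. P values are raw — no
multiple-testing correction, matching the convention of the comparison
this package implements — with an opt-in Benjamini-Hochberg column.
Stage failures are caught per (subject, method) cell and recorded, so one
degenerate network does not abort a study.

Problem sizes: the default study is a 600-node lattice (10 x 10 x 6), 6
modules, t = 120 samples at TR 2.5 s, 10 subjects, 4 methods. A full
default study takes on the order of a minute and a half on one core;
module counts and giant-component sizes at this scale are about 1/27 of
the voxel-count regime the thresholding rule S = 3 was designed around,
which matters only for statistics that count discrete communities.

## Numerical choices

* Band-limited synthesis rescales each series to *exact* zero mean and
  unit variance, so closed-form correlation targets hold without
  asymptotics.
* The correlation-density series uses log-gamma + log-sum-exp; the CDF
  integrates the density on an 8001-point grid with the trapezoid rule.
* Regressor matrices are de-meaned, checked for exact rank deficiency via
  QR, and for near-collinearity via the exact condition number of the
  unit-scaled matrix.
* The threshold search and hub selection are fully deterministic; every
  stochastic step flows from a single integer seed per subject, and RNG
  state is restored after each simulation call.
* Zero-variance node series abort correlation by default
  (`drop_zero_variance = TRUE` drops them with a warning).

## Known limitations

* The phantom's within-module exchangeability understates the spatial
  autocorrelation of real voxel data; an optional smoothed local field
  exists (`var_local`) but defaults off.
* WBonly does not remove the white-matter-adjacent nodes' tract signal
  (only the whole-brain projection of it), so WBonly networks fragment
  more in the phantom than in the reference regime — the direction of the
  effect is right but its size is exaggerated.
* Community *counts* at a few hundred nodes are noisy in the +-2 range for
  both corrected and uncorrected networks, so per-replicate strict
  orderings of module counts are unstable even when the mean-level
  ordering is clear; the package reports both.
* The paired t and F tests inherit their usual normality assumptions; at
  10 subjects they are the convention of the design being replicated, not
  a recommendation.
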