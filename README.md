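# gsrnet

Global signal correction and its consequences for voxel-level resting-state
functional connectivity networks.

Whether to regress the *global signal* — the mean BOLD time course over the
whole brain — out of every voxel before computing functional connectivity is
a long-standing controversy in resting-state fMRI. `gsrnet` implements a
complete, reproducible comparison pipeline for the four standard correction
schemes, exercised end to end on a synthetic resting-state phantom with
known ground truth, for researchers who want to study (or teach) how this
preprocessing choice reshapes graph-theoretic analyses:

* **NoCorr** — six motion regressors only;
* **NoWB** — motion + deep-white-matter + ventricle mean series;
* **WBonly** — motion + whole-brain mean;
* **Full** — motion + white matter + ventricle + whole-brain mean.

## The statistics at the core

If two voxel series share an additive signal, `W₁ = Y₁ + G`, `W₂ = Y₂ + G`
with `Cov(Yᵢ, G) = 0`, their correlation

```
Corr(W₁, W₂) = Var(G) / √((Var(Y₁)+Var(G)) (Var(Y₂)+Var(G)))  > 0
```

is positive whenever `Var(G) > 0` — an uncorrected shared signal biases the
entire correlation matrix upward. The package provides the exact sampling
densities of the Pearson correlation for `t` time points: the central form

```
f(r) = Γ((t−1)/2) / (√π Γ((t−2)/2)) · (1−r²)^((t−4)/2)
```

and the non-central series (population correlation ρ)

```
f(r) = (1−ρ²)^((t−1)/2) (1−r²)^((t−4)/2) / (√π Γ((t−1)/2) Γ((t−2)/2))
       · Σⱼ Γ²((t−1+j)/2) (2ρr)ʲ / j!
```

evaluated stably via log-gamma and log-sum-exp. Networks are built by
thresholding the correlation matrix so that `S = log N / log K` hits a
target (3.0 by default, after the voxel-network convention); metrics include
Watts–Strogatz clustering, efficiency-based (harmonic-mean) path length in
which disconnected pairs lengthen paths, giant-component size, hub-overlap
maps, and a modularity-maximizing spectral parcellation with
Kernighan–Lin refinement, a merge pass, and a distinguished "junk" module
for everything outside the giant component.

A full simulated study — phantom subjects × four methods, paired t tests
per metric and a variance F test on the maximum degree — runs through one
call, `run_study()`, and returns tidy tibbles with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(gsrnet)

ph <- generate_phantom(c(10, 10, 6), n_modules = 6, seed = 1)
ph
#> <phantom> 10 x 10 x 6 lattice, 600 gray nodes, 6 modules
#>   wm-adjacent: 48; midline: 60; bridge: 0
#>   aux voxels: wm sphere 33, ventricle 27

ts <- simulate_timeseries(ph, signal_model(seed = 101)) |>
  bandpass(0.009, 0.08)
full <- apply_correction(ts, "Full")
summarize_distribution(correlation_matrix(full))
#> <corr_summary> n = 600 (unordered pairs: 179,700 pairs)
#>   mean -0.00160  sd 0.2578  skewness 0.251

net <- threshold_for_S(correlation_matrix(full), S_target = 3)
net
#> <binary_network> n = 600, edges = 2530, K = 8.433, threshold = 0.5481 (rule >), S = 3.000
qcut_partition(net)
#> <partition> 8 modules (+ junk of 39 nodes), giant 561, Q = 0.7026
```

After full correction the correlation distribution is centred at zero
(mean −0.0016), the thresholded graph keeps 94% of nodes in the giant
component, and the parcellation recovers the planted community structure
(6 modules, plus boundary-zone splits) at Q = 0.70.

The four-method comparison:

```r
st <- run_study(study_config(seed = 1, n_subjects = 4))
st
#> <gsr_study> 4 subjects x 4 methods; 600 nodes, S_target = 3
#>   method mean_corr     C     L    Nc connected_fraction     Q n_modules
#> 1 Full    -0.00153 0.300  4.91  554.              0.928 0.697      6.75
#> 2 NoCorr   0.680   0.393  7.52  422.              0.797 0.676      9
#> 3 NoWB     0.569   0.399  6.11  434.              0.744 0.583      8.25
#> 4 WBonly   0.0106  0.359  7.93  470.              0.885 0.738      9.75
```

Without whole-brain correction (NoCorr, NoWB) the correlation mean is
biased far above zero, path length grows, the giant component shrinks, and
white-matter-adjacent nodes drop into the junk module; whole-brain
regression (Full, WBonly) recentres the distribution at zero. Formal
contrasts live in `tidy(st)` (paired t per metric and method pair, plus
the max-degree variance F tests), and `autoplot(st)` draws the per-method
metric boxplots.

See the methods vignette (`vignettes/global-signal-networks.Rmd`) for the
signal model behind the phantom, the design decisions, and known
limitations.

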