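---
title: "Temporal stability and community motifs of functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal stability and community motifs of functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfctools)
```

## Overview

`dfctools` characterizes a resting-state functional connectome along two
complementary axes:

1. **Temporal**: how stable the pattern of region-to-region coupling is
   over the course of a scan. Time-resolved connectivity is estimated by
   instantaneous phase coherence, each timepoint's pattern is reduced to
   its dominant subspace, and the principal angles between subspaces at
   all timepoint pairs form a time-by-time *temporal landscape*, which is
   summarized by histogram entropy and by the mean angle between
   successive timepoints (the *global temporal distance*).
2. **Spatial**: how the regions organize into mesoscale communities. A
   weighted stochastic block model (WSBM) is fitted to the Fisher-z
   static connectivity matrix by variational Bayes, and the interactions
   between the recovered communities are classified into assortative,
   core–periphery, and disassortative motifs, with per-community
   diversity indices, per-region assortativity scores, and morphospace
   coordinates.

Both branches accept any parcellated region-by-time signal matrix; the
package also ships generators for synthetic cohorts with controllable
temporal stability and planted community structure, and a
normality-gated group-comparison protocol with covariate
residualization.

## The temporal branch

### Phase-coherence dynamic connectivity

Each region's signal is mean-centered (the phase of a signal with a
nonzero mean is ill-defined) and converted to an analytic signal with
the Hilbert transform; the instantaneous phase $\theta(n,t)$ is the
argument of the analytic signal, stored in $(-\pi, \pi]$. The
time-resolved coupling between regions $n$ and $p$ is

$$\mathrm{dFC}(n,p,t) = \cos\!\big(\theta(n,t) - \theta(p,t)\big),$$

so each time slice is symmetric with unit diagonal and — because
$\cos(a-b) = \cos a\cos b + \sin a \sin b$ — has exact rank at most 2.
This rank bound is the branch's strongest structural property and is
asserted throughout the test suite (third eigenvalue below $10^{-8}$ of
the leading one).

No band-pass filter is applied before the transform by default: the
estimation procedure itself does not require one, and silently adding a
preprocessing step would change the measure. Because the phase-coherence
literature commonly band-passes BOLD signals into the slow band, a
zero-phase Butterworth filter (suggested band 0.01–0.1 Hz, order 2) is
available behind the `bandpass` argument.

### Dominant subspaces and principal angles

The dominant pattern at time $t$ is the span of the eigenvectors of the
slice belonging to its $k$ largest eigenvalues. The default is $k = 2$:
a phase-coherence slice has exactly two nonzero eigenvalues, so two
components capture it losslessly, and the subspace is simply
$\mathrm{span}\{\cos\theta(\cdot,t), \sin\theta(\cdot,t)\}$. $k = 1$
(leading eigenvector only, in the style of leading-eigenvector dynamics
analyses) is available as a flag. Requesting more components than the
slice's numerical rank is an error rather than a silent padding.
Eigenvalue ties are broken deterministically (descending eigenvalue;
each eigenvector's first component of magnitude above $10^{-12}$ made
positive).

The discrepancy between two subspaces with orthonormal bases $B_1, B_2$
is measured by principal angles: $\arccos$ of the singular values of
$B_1^\top B_2$, each in $[0, \pi/2]$. For $k > 1$ a convention is needed
for which angle represents the pair; the default is the **largest**
principal angle — the most conservative choice, which preserves the full
$[0, \pi/2]$ range (two subspaces score $0$ only when they coincide).
`"smallest"` and `"mean"` are selectable. Entries of the resulting
$T \times T$ stability matrix $\phi(t_x, t_y)$ are computed by a closed
form for the $2\times 2$ cross-Gram singular values, vectorized over all
timepoint pairs; $k > 2$ falls back to per-pair SVD.

### Summaries of the landscape

* **Entropy** (order/disorder of the whole landscape): entries are
  mapped linearly from $[0, \pi/2]$ to $[0,1]$ and binned into a uniform
  256-bin histogram — mirroring an 8-bit image-histogram computation —
  including all $T^2$ entries, diagonal included; the entropy of the
  normalized counts is reported in bits, and overall temporal stability
  is its inverse. The bin count and diagonal inclusion are arguments, so
  sensitivity can be checked. The fixed $[0,\pi/2]$ normalization (not
  each matrix's own min–max) keeps values comparable across subjects.
* **Global temporal distance**: the mean of $\phi(t_i, t_{i+1})$ over
  successive timepoints, i.e. the superdiagonal mean; global temporal
  stability is its inverse. An `all_offdiagonal` flag averages every
  off-diagonal entry instead, for comparison. When a summary's
  denominator is exactly zero (degenerate inputs such as a constant
  landscape), the inverse is reported as an `Inf` sentinel and
  serialized in JSON as `"inf"` rather than raising an error, because
  degenerate synthetic inputs legitimately produce it.

Per-network summaries restrict the dFC tensor to one network's member
regions and rerun the whole pipeline on the restriction, so each
network's summary depends only on its own regions' signals.

## The spatial branch

### Static connectivity and the block model

Static connectivity is the Pearson correlation of each region pair over
the whole scan, r-to-z transformed with correlations clipped to
$[-1 + 10^{-12},\, 1 - 10^{-12}]$ so that duplicated signals give a
large finite weight instead of an infinity; the diagonal is fixed at 0
and self-connections are excluded everywhere downstream.

The WSBM treats this signed, dense adjacency as a complete weighted
graph: each node $i$ carries a latent community label $z_i$, and each
pair's weight is drawn from
$\mathcal{N}(\mu_{z_i z_j}, \sigma^2_{z_i z_j})$. Only the weight
component of the general WSBM is modeled — with a dense signed
connectivity matrix, an edge-presence component carries no information.
The normal family matches Fisher-z weights (real line, signed).
Conjugate priors are weakly informative and configurable: symmetric
Dirichlet(1) over community proportions and Normal–Gamma
($\mu_0 = 0$, pseudo-count 1, shape 1, rate 1) on each block's mean and
precision. The mean-field posterior is optimized by coordinate ascent:
closed-form conjugate updates for the block and proportion factors, then
one sequential sweep of label updates per iteration. Each substep is an
exact coordinate maximization, so the evidence lower bound is
non-decreasing within a restart — an invariant asserted on every fitted
model in the test suite. Iteration stops when the relative ELBO change
falls below `tol` ($10^{-6}$ by default; not prescribed by the
estimation problem itself) or at `max_iter`.

**Initialization.** Each restart initializes labels by k-means on the
rows of the adjacency matrix with random centers (the restart index
seeds the RNG). This choice is deliberate: initializations that are
random in *label space* — uniform responsibilities or uniform random
hard labels — give every block the same weight distribution, which is a
symmetric fixed point of the mean-field updates; coordinate ascent
started there collapses all nodes into one community. Since stochastic
equivalence is similarity of connection profiles, clustering the rows
breaks the symmetry in exactly the space the model cares about. The
best of `restarts` runs by final ELBO is returned (default 30, the
standard multi-restart protocol for this model; planted-structure tests
use 5–10, which recover the truth exactly at desk scale).

Communities left empty by the fit are tracked, not renumbered, and
singleton communities are excluded from all motif statistics below.

### Motif taxonomy

Community interactions are characterized by densities

$$\omega_{rr} = \frac{1}{N_r N_r}\sum_{i \in r, j \in r} A_{ij}, \qquad
\omega_{rs} = \frac{1}{N_r N_s}\sum_{i \in s, j \in r} A_{ij}.$$

The $N_r^2$ denominator counts diagonal positions; since $A_{ii} = 0$
they contribute nothing, and the definition is kept literally as stated
(an `offdiag_denominator` flag switches to $N_r(N_r-1)$ for sensitivity
checks — with zero diagonals this only rescales within-densities
uniformly). A pair $\{r,s\}$ is **assortative** if
$\min(\omega_{rr}, \omega_{ss}) > \omega_{rs}$, **core–periphery** if
$\omega_{rs}$ lies strictly between the two within-densities (the denser
community is the core), and **disassortative** if
$\omega_{rs} > \max(\omega_{rr}, \omega_{ss})$. Equalities are
measure-zero for real-valued connectivity but must still be
deterministic: they fall through the rules in that order and, when no
strict rule applies, the pair is labelled *degenerate* and excluded from
profiles.

For each community, the frequencies $P_a, P_c, P_p, P_d$ of its
interaction classes (a core–periphery pair contributes *core* to its
denser side and *periphery* to the other) give the diversity index

$$H_r = -\left[P_a \log P_a + P_c \log P_c + P_p \log P_p\right]$$

with natural logarithms and zero-frequency terms dropped: $0$ when the
community participates in a single class, $\log 3$ at equal
participation in all three. The disassortative frequency is tallied and
reported but not part of $H_r$ by default (an
`include_disassortative` flag adds it). Subject-level assortativity,
coreness and peripheryness are the means of $P_a, P_c, P_p$ across
retained communities. Regional scores use
$a_{ir} = \frac{1}{n_r}\sum_{j \in r} A_{ij}$ and
$\mathrm{Assr}_{reg} = a_{i z_i} - \max_{r \neq z_i} a_{ir}$, with the
maximum over retained communities. The morphospace table places one
point per retained pair at $(\omega_{rr}, \omega_{rs}, \omega_{ss})$,
ordered so the first within-density is the larger, with the motif class
attached.

All density and score computations are verified against independent
brute-force double-loop oracles at $10^{-12}$ in the test suite.

## Synthetic data

The generators produce inputs with exactly the statistical structure the
two branches assume, so the pipeline can be exercised end to end without
clinical data.

* `gen_weighted_sbm()` draws each edge weight independently from the
  normal law of its planted block — the generative inverse of the fitted
  model. Zero block standard deviations are allowed and give
  deterministic weights (the separable limit used in recovery tests).
* `gen_oscillator_timeseries()` produces region signals
  $\cos(2\pi f t \cdot TR + \theta_c(t) + \varepsilon_i(t))$ plus
  measurement noise: a shared carrier (default 0.05 Hz at TR = 2 s, the
  slow resting-state band), a community-shared random phase offset
  $\theta_c$, and per-region phase jitter $\varepsilon_i(t)$ whose
  marginal standard deviation $(1-\text{coupling})\,\pi$ interpolates
  linearly between identical phases (coupling 1) and near-uniform phases
  (coupling 0). The jitter evolves as a stationary AR(1) process with
  lag-1 correlation 0.9 rather than as white noise: resting-state signals
  are band-limited and their phase noise is slow, and white jitter would
  make the instantaneous phase estimate jump from sample to sample,
  masking genuine coupling reconfiguration. With `switch_period` set,
  the community offsets are re-drawn every that many samples — abrupt
  large-scale reconfiguration of the coupling structure — which raises
  the global temporal distance; without it the dominant subspace is
  essentially constant in time. Defaults (30 regions in 3 equal
  communities, T = 150, coupling 0.8, noise sd 0.1) are a desk-scale
  stand-in for a 400-region parcellation at the same scan length.
* `gen_cohort()` assembles two groups with per-subject seeds derived
  deterministically from a master seed (an integer mix of master seed
  and subject index), so cohorts are pure functions of their
  specification, with uniform ages and random sexes recorded alongside.

**What the generators do not emulate:** hemodynamic response
convolution, physiological and motion noise, spatial autocorrelation of
a real parcellation, and scanner drift. Passing tests therefore
demonstrate the estimators' correctness and discriminative behavior
under controlled conditions — not performance on clinical fMRI.

## Group comparison protocol

Two-group comparisons follow a normality-gated protocol: both samples
must pass both the Jarque–Bera and the D'Agostino–Pearson omnibus test
(at $\alpha = 0.05$) for the parametric path — a two-sided,
pooled-variance, unpaired t-test; otherwise the Wilcoxon rank-sum test
with normal approximation and tie correction is used. Requiring both
tests on both samples is the conservative combination rule; an
`"either"` rule is available. Samples below 8 observations cannot be gated (the kurtosis
normalization is undefined) and fall back to the nonparametric path with
a warning. Both normality statistics are implemented from their
published closed forms and verified against independently computed
reference values in the test suite; the gate-plus-test pipeline's type-I
error at $n = 30$ per group is confirmed to sit near the nominal 5%
level over 2000 null simulations.

Confound control regresses age and sex out of the pooled measure by
ordinary least squares before testing; constant or collinear columns are
dropped with a warning. Region-wise maps apply the same residualize-
then-t-test per region and append Benjamini–Hochberg q-values across
regions, so both the raw and the FDR-adjusted readings are available.

## Numerical choices and degenerate inputs

* Fisher-z clipping at $1 - 10^{-12}$; $\mathrm{atanh}$ then yields
  weights around 14, keeping the adjacency finite for the block model.
* Dominant-subspace rank tolerance: $10^{-8}$ relative to the leading
  eigenvalue; the same threshold accepts a basis as orthonormal.
* Singular values are clipped to $[0,1]$ before $\arccos$; angles near 0
  are consequently resolved only to about $\sqrt{\varepsilon}$ (~$10^{-8}$),
  which is far below any bin width used by the entropy summary.
* Histogram bin assignment is left-closed with the last bin closed at 1,
  so an all-zero landscape occupies exactly one bin (entropy 0, inverse
  reported as the `Inf` sentinel).
* The WSBM guards block-update denominators so empty blocks fall back to
  their prior; its ELBO monotonicity is asserted to $10^{-9}$ slack.
* TSV matrices are written with 17 significant digits (round-trips to at
  least 12 significant digits); JSON summaries use 10 significant
  digits, with positive and negative infinities encoded as `"inf"` /
  `"-inf"`.

## Worked example

```{r example}
# a subject whose coupling structure switches every 20 samples
ts_switch <- gen_oscillator_timeseries(
  oscillator_spec(switch_period = 20, seed = 1), subject_id = "switching")
ts_static <- gen_oscillator_timeseries(
  oscillator_spec(seed = 1), subject_id = "static")

s1 <- subject_stability(ts_switch)$summary
s2 <- subject_stability(ts_static)$summary
c(switching = s1$global_temporal_distance,
  static = s2$global_temporal_distance)
```

The switching subject's global temporal distance exceeds the static
subject's: more frequent reconfiguration, lower temporal stability.

```{r example-wsbm}
g <- gen_weighted_sbm(block_graph_spec(
  c(20, 20, 20), diag(3), matrix(0.3, 3, 3), seed = 7))
model <- fit_wsbm(g$adjacency, K = 3, restarts = 10, seed = 5)
partition <- map_partition(model)
table(partition$labels, g$truth$labels)
subject_motif_summary(g$adjacency, partition)
```

A strongly assortative planted graph is recovered exactly and every
community-pair interaction classifies assortative (subject-level
assortativity 1, diversity 0).

## Problem sizes and limitations

Tests and examples run at desk scale — tens of regions, 150 timepoints,
cohorts of up to 20 per group, 2000-replicate calibration loops — sizes
at which every computation completes in seconds while still exercising
the same code paths as a 400-region scan. Known limitations: the number
of communities $K$ must be chosen by the user (no model-evidence
selection); cross-subject community labels are not aligned (all motif
measures are label-invariant, so none is needed); sliding-window
correlation dFC and state-clustering approaches are out of scope; and
conclusions about clinical data require real cohorts, which the
synthetic generators deliberately do not imitate beyond their
statistical skeleton.
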