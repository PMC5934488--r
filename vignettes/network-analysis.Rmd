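---
title: "Weighted small-world and spanning-tree analysis of lagged-coherence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted small-world and spanning-tree analysis of lagged-coherence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coherenet)
```

## The analysis

`coherenet` implements a resting-state functional-network analysis for
source-space EEG. The unit of analysis is a subject's 84×84 weighted
adjacency matrix per frequency band: nodes are the Brodmann areas that
standard source-localisation software resolves (BA 1–47 without 12, 14,
15, 16, 26, in both hemispheres), and edge weights are band-averaged
lagged coherences in [0, 1]. Four bands are analysed: theta [4, 8),
alpha [8, 12), beta1 [12, 20) and beta2 [20, 30) Hz, half-open so the
shared edges are counted once.

The pipeline has four stages:

1. **Connectivity.** Cross-spectra are estimated by the mean Hann-tapered
   periodogram over artifact-free epochs (defaults: 25 epochs, 1024
   samples at 250 Hz, so the bin spacing is 250/1024 ≈ 0.244 Hz). Per
   frequency bin and channel pair the *lagged coherence* is
   Im(S_xy)² / (S_xx S_yy − Re(S_xy)²), clamped to [0, 1] and averaged
   over the band's bins. Because a static (zero-lag) mixture of sources —
   the volume-conduction artifact of EEG — contributes only to the real
   part of the cross-spectrum, it inflates ordinary coherence but not the
   lagged measure; the test suite verifies this suppression on simulated
   mixtures.
2. **Weighted graph.** Each matrix is characterised by the Onnela
   weighted clustering coefficient C (weights normalised by the matrix
   maximum, triangle intensities as geometric means), the characteristic
   path length L over inverse-weight distances d = 1/w, and the
   Small-World Propensity
   φ = 1 − sqrt((Δ_C² + Δ_L²)/2), with
   Δ_C = (C_latt − C)/(C_latt − C_rand) and
   Δ_L = (L − L_rand)/(L_latt − L_rand), each clamped to [0, 1]. Both
   null models preserve the weight multiset exactly: the lattice null
   places the sorted weights band-by-band along the diagonal (largest
   nearest), the random null permutes them uniformly over node pairs;
   the random reference is the mean of 50 permutations. φ > 0.6 is the
   conventional small-world classification bound.
3. **Minimum spanning tree.** The MST of d = 1/w (equivalently the
   maximum spanning tree of the coherences) is extracted by Kruskal's
   algorithm with lexicographic tie-breaking, and summarised by maximum
   betweenness centrality, leaf fraction (#degree-1 nodes / (N−1)),
   diameter and average eccentricity (both in edges), plus the per-node
   BC and eccentricity vectors. BC uses the *ordered-pair, unnormalised*
   convention — a leaf scores 0, the centre of an 84-node star scores
   83 × 82 = 6806 — because reported maxima on 84-node trees in this
   literature (≈4700–5000) exceed the unordered-pair ceiling of 3403.
4. **Group statistics.** Each of the 7 indices (φ, L, C, max BC, leaf
   fraction, diameter, average eccentricity) is compared between groups
   in each band by a label-shuffling permutation test (Welch t statistic,
   5000 shuffles by default, two-sided add-one p-values), giving 28
   tests; Benjamini–Hochberg FDR is applied jointly across all 28 and
   significance read at q < 0.05. When max BC or average eccentricity is
   significant in a band, a gated nodal follow-up compares that metric
   for each of the 84 ROIs, with FDR across the 84 ROIs within each
   metric/band family.

## Design choices

Several conventions are under-determined by the verbal definitions this
analysis follows; the package fixes them as follows.

* **Lagged-coherence formula.** The standard imaginary-part form above is
  the one implemented by the source-localisation software this style of
  analysis uses. Degenerate bins (denominator ≤ 0) contribute 0 and are
  counted in a message. Band values average the per-bin coherences; an
  alternative (coherence of band-integrated spectra) would weight bins by
  power, and is deliberately not used so that all bins in the band count
  equally.
* **Welch t.** The group sizes this design targets are unbalanced (19
  vs 52), so the unequal-variance statistic is the safe choice. The
  permutation p-value does not rely on its null distribution, only on its
  ordering of shuffles.
* **FDR families.** All 28 global tests form one family; each nodal
  metric/band forms its own 84-ROI family. Both choices are exposed
  through the result tables (p and q are always reported together).
* **Lattice null ordering.** Weights are sorted onto positions ordered by
  |i − j| (diagonal banding). A ring-distance ordering (wrapping around
  the node sequence) was evaluated and rejected: on dense
  uniform-weight graphs it fails to out-cluster the random null (≈15/100
  seeds), whereas diagonal banding succeeds (≈99/100), matching the
  construction of the toolbox that introduced the propensity measure.
* **Distance transform.** d = 1/w for both L and the MST. Any strictly
  monotone transform yields the same tree (tested); 1/w keeps L
  commensurate with the near-1 values dense coherence matrices produce.
* **Tie-breaking.** MST edges are considered in order (d, i, j), so equal
  coherences resolve deterministically; the generator's continuous
  truncated-normal weights make exact ties a measure-zero event anyway.
* **Determinism.** Every stochastic step (null ensembles, permutation
  shuffles, generators) takes a seed, evaluated in a local RNG scope
  that does not disturb the caller's stream. The pipeline fans a master
  seed out to fixed per-stage substreams, so stages can be re-run in
  isolation and whole reports are bit-reproducible.

## The synthetic cohort generator

No public EEG recordings accompany this design, so the package ships a
generator that emulates the statistical structure the analysis assumes,
making every stage testable end-to-end.

A subject's matrix is built from a coherence *profile* that decays with
node distance: strong coherence (truncated normal, mean 0.85, sd 0.04)
within a lattice neighbourhood of the k = 6 nearest nodes in atlas order,
then an exponential decay (e-folding 4 spans) down to a weak noise floor
(mean 0.05, sd 0.015) for distant pairs. A fraction `p_rewire` (default
0.1) of all weights is then relocated by a random permutation, creating
long-range shortcuts. This mirrors two robust features of real coherence
matrices — coupling falls off with cortical distance, and a minority of
strong long-range links exists — and produces graphs whose clustering
sits near their lattice null while their path length sits near their
random null, i.e. genuinely small-world weighted networks (φ ≈ 0.65–0.7
at the defaults, against φ ≈ 0.3 for the same weights uniformly
permuted). Two points of the construction deserve emphasis:

* A spatially *uniform* background was evaluated and rejected: with the
  same weights scattered without a distance profile, the Onnela
  coefficient becomes almost insensitive to weight placement (the
  lattice–random clustering gap shrinks to numerical noise) and no
  parameter setting classifies as small-world. The decaying profile is
  therefore not cosmetic; it is what gives the clustering deviation Δ_C
  a well-defined scale.
* `p_rewire = 1` is exactly a uniform permutation of the whole weight
  multiset — the random null itself — so the generator spans the full
  lattice-to-random continuum with one parameter.

Cohorts default to 19 cases and 52 controls with four bands per subject.
Between-subject variability enters through jitter (sd 0.03) of the
strong-weight mean and rewiring fraction. Group effects perturb the case
generator per band:

| target | mechanism | rationale |
|---|---|---|
| `clustering` | scales the profile's distance decay | uniform scaling of strong weights cancels in the max-normalised Onnela coefficient; narrowing the clustered neighbourhood moves C by many within-group SDs |
| `path` | scales all weights by 1/(1+δ) | scales every 1/w distance, hence L, while leaving normalised clustering untouched |
| `diameter` | scales the rewiring fraction | fewer shortcuts stretch the spanning tree |
| `hub_bc` / `nodal_bc:<ROI>` | scales one ROI's row/column | pulls tree paths through that node, raising its BC |

What the generator does **not** emulate: genuine spectral structure per
band (matrices are drawn independently across bands rather than from one
broadband process), spatial correlation induced by anatomy, inter-metric
correlations of real cohorts, or volume-conduction residue. Passing the
calibration and recovery tests therefore demonstrates that the
*machinery* is correct and well-calibrated under its assumed data model,
not that real EEG effects of these magnitudes exist. For end-to-end
exercise of the spectral stage, `generate_coupled_timeseries()` produces
band-limited stochastic oscillations shared between channel pairs at a
controlled sample lag, with an optional zero-lag common source to
emulate volume conduction.

## Numerical and degenerate cases

* Coherence matrices are validated on input: symmetry to 1e−8,
  entries in [0, 1], zero diagonal; violations name the file and cause.
* Disconnected graphs are rejected with the smallest component named;
  an all-zero graph has clustering 0 (with a warning).
* If a random weight permutation happens to disconnect a sparse graph,
  the null is resampled (up to 20 attempts) before path lengths are
  taken.
* Degenerate nulls (C_latt = C_rand or L_latt = L_rand, e.g. all-equal
  weights) set the corresponding Δ to 0 with a warning, keeping
  φ ∈ [0, 1].
* Zero pooled variance in a permutation test yields p = 1 with a
  warning; p-values can never be 0 by the add-one convention, and never
  fall below 1/(n_perm + 1).
* Epochs of 1000–1250 samples are zero-padded to the next power of two
  before the FFT; a band containing no frequency bins is a configuration
  error.

## Problem sizes in the test suite

The shipped tests keep simulation sizes modest by choice: oracle
equivalence runs on 100 random graphs/trees with n ≤ 8 against exhaustive
enumeration; small-world classification uses 10 generator seeds with the
full 50-null ensemble; permutation calibration uses 1000 replicates of
500 shuffles at the 19/52 design; cohort-level calibration and effect
recovery use 12 null cohorts and 10 effect cohorts with reduced null
ensembles (3 per propensity evaluation) and 300–500 shuffles. The
`scripts/acceptance.R` entry point recomputes the star-tree leaf
fraction and the two small-world classification medians (10 seeds ×
50 nulls) from scratch at any seed.

## Limitations

* The analysis begins at ROI time series or adjacency matrices; scalp
  preprocessing, artifact rejection and the source-localisation inverse
  problem are out of scope.
* Graphs are analysed as weighted and undirected only; binary-threshold
  variants are deliberately not provided.
* The lattice null is a weight-sorting construction; it preserves the
  weight multiset and (on dense matrices) the degree distribution, but
  it is not a degree-sequence-constrained rewiring for sparse graphs.
* Tree metrics beyond the five reported (e.g. hierarchy measures) are
  not implemented.
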