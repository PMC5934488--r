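# coherenet

Weighted small-world and minimum-spanning-tree analysis of band-limited
lagged-coherence brain networks, with permutation-based two-group
inference.

## What it is for

Resting-state EEG studies of clinical populations often summarise each
subject's functional connectome — an 84×84 matrix of lagged coherences
between Brodmann-area sources, per frequency band — and ask whether its
graph topology differs between a patient group and controls. `coherenet`
implements that analysis as a tested R pipeline for researchers working
with source-space EEG connectivity:

* **Connectivity**: band-averaged lagged coherence
  Im(S_xy)²/(S_xx·S_yy − Re(S_xy)²) from epoched ROI time series
  (mean Hann-tapered periodogram; theta/alpha/beta1/beta2 bands), a
  measure that suppresses spurious zero-lag coupling from volume
  conduction;
* **Weighted graph topology**: Onnela clustering coefficient C,
  characteristic path length L (distances d = 1/w), and the Small-World
  Propensity φ = 1 − √((Δ_C² + Δ_L²)/2) against weight-preserving lattice
  and random null graphs (φ > 0.6 ⇒ small-world);
* **Minimum spanning tree**: the loop-free backbone of strongest
  coherences and its integration metrics — maximum betweenness centrality
  (ordered-pair counts), leaf fraction, diameter, eccentricity;
* **Group statistics**: label-shuffling permutation tests (Welch t, 5000
  shuffles, add-one two-sided p) over 7 indices × 4 bands with joint
  Benjamini–Hochberg FDR, plus a gated per-ROI follow-up for betweenness
  and eccentricity;
* **Synthetic cohorts**: a seeded generator of small-world coherence
  matrices (19 cases vs 52 controls by default) with controllable group
  effects on clustering, path length, diameter and hub betweenness, so
  the whole pipeline can be exercised and calibrated without recordings.

## Worked example

```r
library(coherenet)

# one synthetic subject: 84-ROI small-world coherence matrix
W <- generate_sw_matrix(seed = 42)
small_world_propensity(W, n_null = 50, seed = 1)
#> <swp_result> phi = 0.662 (delta_C = 0.469, delta_L = 0.092)
#>   C: given 0.1161, lattice 0.1177, random 0.1143
#>   L: given 3.4554, lattice 10.5706, random 2.7355

tree_metrics(minimum_spanning_tree(W))
#> <tree_metrics> max BC 4068, leaf fraction 0.398, diameter 29, avg ecc 21.95
```

φ = 0.662 > 0.6 classifies the graph as small-world: its clustering is
much nearer the lattice null's than the random null's (Δ_C well below 1)
while its path length is nearly as short as the random null's
(Δ_L ≈ 0.09). The spanning tree's maximum betweenness of 4068 means the
busiest hub lies on 4068 of the 83×82 = 6806 possible ordered source →
target paths.

A full two-group analysis on a synthetic cohort with an injected theta
clustering deficit in the cases:

```r
cfg <- pipeline_config(
  mode = "synthetic",
  effects = list(effect_spec("theta", "clustering", 0.15, -1)),
  n_null = 5, n_perm = 1000, seed = 7)
rep <- run_pipeline(cfg)
rep
#> <pipeline_report> 71 subjects, 28 global tests (1 significant)

subset(rep$global, significant,
       select = c(index, band, t, p, q, mean_case, mean_control))
#>   index  band     t        p     q mean_case mean_control
#> 3     C theta -11.8 0.000999 0.028     0.108        0.116
```

Exactly the injected effect — and nothing else — survives FDR across the
28 index × band cells: theta-band clustering is lower in cases
(t = −11.8, permutation p = 1/1001, q = 0.028).

A thin command-line wrapper with verbs `simulate`, `connect`, `metrics`,
`compare` and `run-all` is installed at `inst/cli/coherenet.R`:

```sh
Rscript inst/cli/coherenet.R simulate --out cohort --seed 3
Rscript inst/cli/coherenet.R metrics  --manifest cohort/manifest.csv --out mt
Rscript inst/cli/coherenet.R compare  --metrics mt/metrics.csv --out results
```

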