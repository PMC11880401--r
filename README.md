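# crtclust

Movement-pattern analysis of the **five times chair rise test (5CRT)** from
force-plate recordings.

The 5CRT — rise from a chair and sit back down five times, as fast as
possible — is a standard assessment of lower-extremity function in older
adults, usually reduced to a single stopwatch time and an SPPB score of 0-4
points. A force plate under the feet records far more: each rise shows a
seat-unloading dip, a seat-off peak above body weight, a stabilization dip
while balance is recovered, a standing plateau, and a sit-down landing
transient. `crtclust` is for researchers in biomechanics and geriatric
functional assessment who want to mine that structure: it segments
continuous vertical ground-reaction-force (Fz) recordings into the five
chair-rise cycles, quantifies the per-phase normalized forces, and clusters
first-rise waveforms into movement patterns with **k-means under the
dynamic time warping (DTW) metric** using **DBA (DTW Barycenter Averaging)**
centroids.

## Core method

For series `x` (length *M*) and `y` (length *N*), DTW finds the monotone
warp path `π = [(i,j), …]` from (1,1) to (*M*,*N*) minimizing the
accumulated cost, with

&nbsp;&nbsp;&nbsp;&nbsp;`DTW(x, y) = sqrt( min_π Σ_{(i,j)∈π} (x_i − y_j)² )`

computed by exact dynamic programming (C++ kernel, path recovered by
backtracking with fixed tie order). A cluster barycenter `μ` minimizes
`Σ_{x∈D} DTW(μ, x)²` and is refined by the DBA update (align every series
to `μ`, average the values mapped onto each coordinate — monotone
non-increasing in that objective). K-means alternates DTW assignment and
DBA updates, restarts `n_init = 10` times, keeps the lowest-inertia fit,
and canonicalizes labels so **cluster 1 is always the fast,
low-stabilization-force pattern**. Cluster counts are validated by a
silhouette sweep over k = 2..10 plus the Davies-Bouldin index; group
contrasts use two-sided Mann-Whitney tests at α = 0.01; stopwatch and
force-plate test durations are related by OLS. Soft-DTW barycenters
(soft-min with parameter γ, analytic gradients) are available for smooth
cluster visualization.

Because public 5CRT force-plate data are not available, the package also
ships a calibrated synthetic cohort generator (`synth_cohort()`) with a
full ground-truth channel — two movement-pattern archetypes whose phase
forces, stopwatch durations, cohort sizes (72 + 100) and
stopwatch-to-GRF duration relation (`t_GRF = 0.89·t_stopwatch + 2.86`)
match the published cluster statistics — used by the test suite for
parameter-recovery checks. See the vignette
(`vignettes/crt-movement-patterns.Rmd`) for the model, the generator's
assumptions, and what recovery on synthetic data does and does not show.

## Worked example

```r
library(crtclust)

cohort <- synth_cohort(cohort_config(n_per_archetype = c(8, 12), seed = 1))
result <- run_crt_pipeline(cohort, k = 2, n_init = 5, seed = 2)
print(result)
```

```
5CRT pipeline: 20 participants analysed, 0 excluded
5CRT cohort summary
cluster sizes: 1: 9, 2: 11
 cluster  n stopwatch_mean stopwatch_sd t_grf_mean t_grf_sd
       1  9       9.384563     2.156482   11.08444 2.071229
       2 11      13.441400     2.521811   14.80136 2.401808
phase-force comparison:
 variable mean_1   sd_1 mean_2   sd_2  p_value significant
   unload  0.459 0.1576  0.487 0.1942 7.66e-01       FALSE
  seatoff  1.245 0.1152  1.155 0.0961 1.31e-01       FALSE
     stab  0.348 0.1126  0.677 0.1420 4.76e-05        TRUE
    stand  1.056 0.0654  1.011 0.0878 1.75e-01       FALSE
t_GRF = 0.936 * t_stopwatch + 2.256  (n = 20, SE 0.015 / 0.176)
```

Reading this: all 20 recordings segmented into five cycles; the two
recovered movement patterns differ sharply in stabilization-phase force
(0.35 vs 0.68 body weights, Mann-Whitney p ≈ 5·10⁻⁵) but not in
seat-unloading, seat-off or standing forces — the signature that separates
the patterns is how hard the participant loads the plate while regaining
balance, not how strongly they push off. Cluster 1 is also faster (9.4 s vs
13.4 s stopwatch). The force-plate-labeled duration runs ~2 s longer than
the stopwatch with a near-unit slope, the expected systematic offset
between the two timing conventions.

```r
result$consistency          # how often rises 2-5 share the first rise's cluster
guralnik_score(c(10.8, 12.0, 14.1, 17.0, 61))
#> [1] 4 3 2 1 0              # SPPB chair-rise points by duration band
```

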