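# hexsource

EEG source localization of epileptic spikes with hexahedral-FEM head
models, sLORETA and multiple sparse priors.

## What this is for

In pre-surgical epilepsy evaluation, averaged interictal spikes recorded
with dense-array EEG are localized to the cortex and compared against
the surgically resected region. `hexsource` implements that whole chain
for researchers working on electrical source imaging:

* **Forward problem**: a volume-conductor model built directly from a
  labelled voxel segmentation — one trilinear hexahedral finite element
  per voxel with literature tissue conductivities — and the **lead
  field** matrix `L` (scalp volts per unit dipole moment) computed by
  the **reciprocity principle**: one current-injection solve per
  electrode instead of one solve per dipole.
* **Inverse problem**, two solvers:
  * **sLORETA**: for each dipole `r`,
    `s(r) = l(r)' C^{-1} y / sqrt(l(r)' C^{-1} l(r))`, `C = L L' + αI`,
    swept over the nine-decade grid `α = 1e-4 … 1e4`;
  * **MSP (multiple sparse priors)**: sensor covariance modelled as
    `Σ = exp(λ0) I + Σ_i exp(λ_i) L Q_i L'` with rank-one patch priors
    `Q_i = g_i g_i'` taken from the graph smoothing matrix
    `G = Σ_{k≤8} σ^k/k! A^k` (σ = 0.6) over the cortical patch
    adjacency `A`; the weights `λ` are optimized by Fisher-scoring
    restricted maximum likelihood on the free energy, and the sources
    are the MAP estimate `E = Σ_src L' Σ^{-1} U' Y`.
* **Candidate selection**: per source map, three polarity candidates
  ("max" = two most positive dipoles, "min" = two most negative,
  "both" = one of each); each candidate's simulated scalp field is
  scored against the measured snapshot with the normalized relative
  difference measure (NRDM ∈ [0, 2]) and the minimizer wins — no ground
  truth needed.
* **Evaluation against a VOI** (e.g. the resection mask): localization
  error `LE` (distance from the intensity-weighted center of mass to
  the closest VOI voxel), spatial dispersion
  `SD = Σ min_j D_ij² s_i² / Σ s_i²` (mm²), focality
  `Foc = Σ_{VOI+5mm} s_i² / Σ s_i²`, and a ±15% scalp/skull
  conductivity-robustness grid (3×3 LE matrix).
* **Sphere phantoms**: multilayer-sphere segmentations, quasi-uniform
  montages and source shells, spike-like simulated EEG with controlled
  SNR, and spherical VOIs — plus an analytic multilayer-sphere series
  oracle — so the entire stack is testable without clinical data.

## Worked example

Localize a simulated focal spike on a three-layer sphere phantom
(4-mm voxels, 64 electrodes, 500 cortical patches):

```r
library(hexsource)

seg  <- make_sphere_segmentation(c(80, 85, 92), voxel_mm = 4)
src  <- make_sphere_source_space(radius_mm = 72, n_dipoles = 500, seed = 7)
mont <- make_sphere_montage(64, radius_mm = 92)
lf   <- compute_leadfield_reciprocity(seg, conductivity_table(), mont,
                                      src$source_space)
#> lead_field: 64 channels x 500 dipoles (average-referenced)

rec  <- simulate_spike(lf, patches = 137, moments_nAm = 20, snr_db = 10,
                       seed = 1)
y    <- snapshot_at(rec, time_ms = -12)      # rising slope before the peak
best <- select_best(y, sloreta_sweep(y, lf), lf)
#> candidate [sloreta a=10000, max]: dipoles 137,103,
#>   intensities 0.00561,0.00558, NRDM 0.3963

voi  <- make_voi(src$source_space, seg, center_patch = 137, radius_mm = 10)
winner_map <- Filter(function(m) identical(m$alpha, best$alpha),
                     sloreta_sweep(y, lf))[[1]]
metrics_report(best, winner_map, voi, src$source_space)
#> CoM (-44.0, -13.6, 55.0) mm | LE 1.85 mm [hit] | SD 4430.6 mm^2 | Foc 0.234
```

Reading the output: the selection chose the "max" polarity pair whose
strongest dipole is the true generator (#137); its center of mass lands
1.85 mm from the 10-mm VOI around the truth — a hit (LE < 5 mm). The
large SD and modest Foc are the expected signature of an unthresholded
sLORETA map, whose energy is spread far beyond the focus; the MSP
solver (`msp_invert()` + `msp_snapshot()`) produces much more compact
maps. `run_pipeline()` wraps these stages into one call with caching,
and `inst/cli/run_pipeline.R` exposes it to the shell.

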