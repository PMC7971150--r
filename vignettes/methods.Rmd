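---
title: "Methods: forward modelling, inverse solvers and evaluation in hexsource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward modelling, inverse solvers and evaluation in hexsource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hexsource` implements an electrical source imaging chain for averaged
interictal-spike EEG: a volume-conductor head model discretized with
hexahedral finite elements, lead fields obtained through the reciprocity
principle, two inverse solvers (sLORETA and multiple sparse priors), a
data-driven candidate-selection step, and evaluation metrics against a
volume of interest (VOI) such as a surgical resection mask. This vignette
explains the models, the parameters that matter, and the numerical and
design choices behind the implementation.

## Forward model

### One cube element per voxel

The head model is a labelled voxel segmentation (tissues such as scalp,
skull, CSF, gray/white matter, eyeball; label 0 is air and is excluded).
Each non-air voxel becomes one 8-node trilinear hexahedral element with
that voxel's isotropic tissue conductivity, so the mesh follows the
segmentation exactly, whatever its topology. Element conductance matrices
are integrated with 2x2x2 Gauss quadrature, which is exact for trilinear
shape-function gradients; the assembled matrix is sparse, symmetric,
positive semi-definite and has zero row sums (pure-Neumann current
conservation). The default tissue conductivities are literature values
(S/m): white matter 0.35, skull 0.01, scalp 0.33, CSF 1.79, gray matter
0.25, eyeball 1.55; any value can be overridden through
`conductivity_table()`.

Geometry is carried in mm (RAS, NIfTI-style affine with 0-based voxel
indices) while the electrical assembly converts to SI units, so lead
fields are in volts per A*m and synthetic EEG is reported in microvolts
for nA*m moments.

### Gauge and linear solves

The pure-Neumann system is singular up to an additive constant. We fix
the gauge by grounding one node, factor the reduced matrix once with a
sparse supernodal Cholesky decomposition, and reuse the factorization for
every right-hand side; solutions are then re-gauged to zero mean and
every solve is verified against a relative residual of 1e-8 (typical
residuals are ~1e-12). A direct factorization was preferred over an
iterative solver because the reciprocity computation needs L-1 solves on
one matrix, after which each additional solve is essentially free, and
because it is deterministic; on a 4-mm sphere phantom the supernodal
factorization is an order of magnitude faster than the simplicial one.
The conducting domain is checked for face-connectivity before assembly
and an informative error reports component sizes otherwise.

### Reciprocity lead fields

Instead of one forward solve per dipole, the lead field is built from one
current-injection solve per non-reference electrode: inject +I at the
electrode's nearest scalp node and -I at the reference node, then the
potential difference generated by a dipole p at location x equals
p . grad u(x) / I. The gradient is evaluated from the trilinear shape
functions of the dipole's containing voxel. Dipoles must sit in
gray-matter voxels; positions in other conducting tissue are snapped to
the nearest gray-matter voxel with a warning, positions in air are an
error. The resulting L x D matrix is re-referenced to the average
reference, matching average-referenced spike data, so its columns sum to
zero.

A point-electrode model (nearest scalp node) is used; no electrode
impedance model is attempted because none is specified for the data this
pipeline targets. The `direct_dipole_forward()` oracle represents a
dipole as a shape-function-gradient load on its containing voxel's nodes
(a St-Venant-style spread) and solves once per dipole; because this load
is exactly adjoint to the reciprocity gradient evaluation, the two routes
agree to machine precision on the same mesh, which the test suite
verifies. Disagreement with the *analytic* sphere solution therefore
measures model error, not implementation error.

### Analytic multilayer sphere oracle

`analytic_sphere_potential()` evaluates the truncated Legendre-series
solution for a current dipole inside the innermost layer of a concentric
isotropic multilayer sphere with insulating exterior. Per harmonic order
the layer coefficients solve a small interface system expressed in
per-layer scaled basis functions `(r/R_j)^n` and `(R_{j-1}/r)^(n+1)`,
which keeps every entry O(1) and avoids overflow at high orders. The
series is truncated adaptively once terms fall below 1e-12 of the
accumulated potential (three consecutive quiet terms), with a hard cap.
Degenerate cases are handled explicitly: a central dipole keeps only the
n = 1 term; equal layer conductivities reduce to the closed-form
homogeneous-sphere formula, which the tests verify to 1e-9 along with an
independent numerically-integrated radial-equation oracle.

## Inverse solvers

### sLORETA

For a snapshot y, each dipole r gets the standardized minimum-norm value

    s(r) = l(r)' C^-1 y / sqrt( l(r)' C^-1 l(r) ),   C = L L' + alpha I.

The square root in the denominator is the standard sLORETA form: it is
what guarantees zero localization error for noiseless single-dipole data
as alpha tends to zero, a property the test suite checks exhaustively
over a 500-dipole phantom. Because a plain-text rendering of the
estimator can lose the radical, the un-rooted variant is available via
`standardization = "linear"`. The regularization parameter is applied
exactly as given (no internal rescaling); the default sweep covers nine
decades, 1e-4 to 1e4. `C` is factored once per alpha at the L x L scale;
nothing D x D is ever formed.

### Multiple sparse priors

MSP models the sensor covariance as a weighted sum of covariance
components: a sensor-noise identity plus one component per prior,
`Sigma = exp(l0) I + sum_i exp(l_i) L Q_i L'`, with each prior the
rank-one `Q_i = g_i g_i'`. The columns `g_i` come from the graph
smoothing matrix

    G = sum_{k=0}^{8} sigma^k / k! A^k,    sigma = 0.6,

over the patch adjacency matrix A (neighbors on the cortical surface,
*not* nearest by Euclidean distance, so the two banks of a sulcus or the
two hemispheres are not artificially coupled). The order-8 cap bounds the
support at eight graph hops. Prior centers (default 400 for a
4800-dipole cortical space, i.e. ~8.5%; 100 at the 500-dipole phantom
scale used in the tests) are chosen by farthest-point sampling per
hemisphere, which is deterministic given a seed and quasi-uniform.

The log-hyperparameters are optimized by Fisher-scoring restricted
maximum likelihood on the variational free energy of the sample
covariance, with weak Gaussian shrinkage hyperpriors (mean -32,
precision 1/256) on every log-hyperparameter. Because every prior
component is rank one in sensor space, gradients and the Fisher
information reduce to inner products with the projected prior
topographies `u_i = L g_i`, so an iteration costs O(L^2 n_priors). A
step-halving line search guarantees the free-energy trace never
decreases, which is asserted on every run in the tests. Iteration stops
when the free-energy gain drops below 1e-6 (absolute) or after 128
iterations; the looser stopping rule sometimes quoted for this family of
algorithms (1e-2 relative) stops before the hyperparameters settle to
the resolution our grid-search cross-check demands, so the tighter
default was adopted. Non-convergence returns the best iterate with a
warning flag rather than an error.

Numerical details: data and lead field are internally rescaled to unit
average power (reported hyperparameters are mapped back to the unscaled
problem); the confound projector U defaults to the average-reference
projector and is applied through an orthonormal Helmert basis of its
range, so the noise component is a true identity in a full-rank space
and Sigma is always invertible; the data window is optionally reduced to
its leading temporal SVD modes (99% variance, `temporal_modes`) before
covariance estimation. The returned conditional source covariance is the
posterior form `Sigma_src - Sigma_src L' Sigma^-1 L Sigma_src` (diagonal
reported); the prior-weighted source covariance `sum_i exp(l_i) Q_i` is
what enters the MAP operator `M = Sigma_src L' Sigma^-1 U'`, and the
source estimates are `E = M Y`. Greedy prior-search and ARD variants are
deliberately out of scope; this is the plain multiple-component ReML.

## Candidate selection

Every source map yields three candidates by polarity: the two most
positive dipoles ("max"), the two most negative ("min"), and the most
positive plus the most negative ("both"); positive means outward current
flow relative to the patch normal. For sLORETA the nine-alpha sweep
gives 27 candidates, for MSP the single map gives 3. Each candidate's
scalp field is synthesized from its lead-field columns and compared with
the measured snapshot by the normalized relative difference measure

    NRDM = || y/||y|| - y_sim/||y_sim|| ||,

which is 0 for identical patterns (up to positive scale) and 2 for
opposite polarity; the candidate with the lowest NRDM wins, with a
deterministic tie-break (lower alpha, then max < min < both, then lower
dipole index). No ground truth enters this selection.

The two dipoles of a candidate keep the solver's signed intensities as
their relative moments: with two generators the synthetic topography
depends on their amplitude ratio, and the solver's estimate is the only
principled ratio available. The alternative reading - unit generators
with only the polarity kept - is available via `unit_dipoles = TRUE`.
The analysis time point is an explicit parameter (`snapshot_at()`,
e.g. -12 ms on the rising slope relative to the spike peak); choosing it
is a judgment call this package does not automate.

## Evaluation metrics

With `s_i` the map intensity at dipole i, `x_i` its position and the VOI
a voxel mask:

* CoM: `sum |s_i| x_i / sum |s_i|` over the *selected* dipoles only.
* LE: Euclidean distance from the CoM to the closest VOI voxel center.
  "Closest voxel" means the voxel center, so an interior CoM gives
  LE < 1 mm at 1-mm voxels, matching how such tables are usually read.
  Flags: hit (< 5 mm), close no-hit (5-15 mm), large no-hit (> 15 mm).
* SD: `sum_i min_j D_ij^2 s_i^2 / sum_i s_i^2` over *all* dipoles, where
  `D_ij` is the distance to the nearest VOI voxel and exactly 0 for
  dipoles whose containing voxel is in the mask. Units mm^2, as printed
  in the field's tables; a square-rooted variant (mm) used by part of
  the literature sits behind `sqrt = TRUE`.
* Foc: fraction of squared intensity within 5 mm of the VOI, in [0, 1].
  The dilation is implemented as a per-dipole distance test, which is
  equivalent to morphological dilation of the mask but avoids
  resampling artifacts.

The conductivity-robustness grid perturbs scalp and skull conductivities
by -15%, 0, +15%, recomputes the full forward + inverse + selection +
LE chain per cell (eight perturbed lead fields plus the nominal) and
returns the 3x3 LE matrix with scalp deviation on the rows and skull
deviation on the columns, nominal at the center.

## The sphere phantom generator

The synthetic module generates everything a clinical study would
provide, at desk scale: concentric three-layer sphere segmentations
(default radii 80/85/92 mm for brain/skull/scalp, voxels classified by
center), quasi-uniform Fibonacci-lattice source shells with radial
normals and Delaunay (convex-hull) adjacency, quasi-uniform electrode
montages, spike EEG with an asymmetric raised-cosine rise (70 ms) and
exponential decay (40 ms) template, spatially white sensor noise scaled
to a requested SNR at the spike peak in the average-reference space, and
spherical VOIs of brain voxels around a chosen patch. Ground truth
(active patches, moments, waveform, seed) is attached to every simulated
recording.

What the phantom does *not* emulate: realistic cortical folding and
anisotropy, spatially correlated or physiological noise, electrode
impedance and digitization error, multiple spike populations, and the
hand-marked irregular geometry of real resection masks. Passing the
phantom tests therefore demonstrates correctness of the algorithms under
the stated statistical structure, not clinical-grade accuracy.

## Problem sizes and tolerances used by the tests

The forward-validation and recovery checks run on a 4-mm three-layer
sphere (about 51k elements, 56k nodes) with 64 electrodes and a
500-dipole source shell at 72 mm; coarser 8-mm phantoms with 32
electrodes and 100 dipoles cover the remaining properties. These sizes
were chosen so the entire suite exercises every stage at study-like
structure while staying desk-scale. Sparse-solve residual tolerance is
1e-8 (verified per solve), the analytic series truncates at 1e-12,
brute-force metric oracles agree to 1e-10, and dense linear-algebra
oracles to 1e-12.

## Known limitations

* **Staircase skull at coarse voxels.** A 5-mm skull shell rasterized at
  4-mm voxels has a column-wise quantized thickness (alternating one or
  two voxels), which perturbs the scalp topography relative to the
  smooth-geometry analytic solution. In the forward-validation check the
  median relative difference measure against the analytic oracle at 4-mm
  voxels remains above the 0.1 level that check asserts, although it
  decreases monotonically with refinement and the homogeneous-sphere
  control at the same resolution is several times more accurate. We
  verified the gap is geometric rather than numerical: refining the FEM
  mesh on the *same* rasterized geometry does not reduce it, and
  conforming (node-shifted) element experiments recover only a small
  part. Finer voxels (the 1-mm resolution of clinical segmentations)
  shrink the staircase error proportionally; memory for the direct
  factorization then grows accordingly.
* **Fixed-orientation dipoles.** One dipole per patch, oriented along
  the averaged surface normal; sources off the modelled surface or with
  deviating orientation are projected onto the nearest compatible
  pattern, a known source of localization bias.
* **Isotropic conductivities.** No anisotropy, no subject-specific
  calibration; the +/-15% grid quantifies (but does not remove) the
  resulting uncertainty.
* **EDF and HDF5.** Persistence uses plain text (TSV/JSON), NIfTI for
  volumes and whitespace matrices for EEG; EDF readers and HDF5 are not
  currently wired in.
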