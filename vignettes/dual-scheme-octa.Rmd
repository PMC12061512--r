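---
title: "Dual acquisition scheme OCT angiography: methods and design notes"
author: "dualocta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual acquisition scheme OCT angiography: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

OCT angiography (OCTA) maps vasculature by the temporal fluctuation of the
complex OCT field: moving red blood cells decorrelate the backscattered
field, static tissue does not. Two practical acquisition schemes probe that
fluctuation at very different time scales, and each fails in its own way:

* **Repeated B-scans** (a few frames, ~10 ms apart) give slow-flowing
  capillaries ample time to decorrelate, so capillary sensitivity is
  excellent — but multiply scattered photons from large pial vessels carry
  dynamic signal to *apparent* depths below the vessel, painting bright
  **projection ("tail") artifacts** that bury the real vasculature
  underneath.
* **Repeated A-scans** (M-mode: many samples, ~0.013 ms apart, total span
  well under a millisecond) resolve the field autocorrelation g1 finely
  enough to *recognize* tail voxels by their phase statistics and suppress
  them — but over so short a window capillary flow barely decorrelates, so
  capillary contrast is weak.

`dualocta` implements the combination: compute both contrasts over the same
volume, build an en-face mask of large vessels (where tails originate),
take the artifact-suppressing M-mode contrast *inside* the axially extruded
mask columns and the capillary-sensitive B-scan contrast *outside*, match
brightness, and finally enhance the capillary compartment with a multiscale
Hessian-eigenvalue (optimally-oriented-flux, OOF) filter.

## The two contrast engines

**OMAG (repeated B-scans).** After per-A-line bulk-motion phase
compensation, the dynamic index is the mean magnitude of consecutive
complex differences over the N repeated frames:

    Id = (1/(N-1)) * sum_{t=1}^{N-1} |R(t+1) - R(t)|

The phase correction estimates one global phase per A-line and frame pair
(the argument of the depth-summed cross product) and rotates the later
frame; a per-voxel correction would erase the flow signal itself, so only
the line-global component is removed.

**Ag1 (repeated A-scans).** Per voxel, the normalized field autocorrelation

    g1(tau) = <R*(t) R(t+tau)>_t / <|R(t)|^2>_t

is computed for lags up to `max_lag` (49 for the 50-repeat protocol), each
lag averaging over its available pairs. The dynamic index takes the
maximum decorrelation reached within a per-voxel horizon n_tau:

    Id = |g1(1)| - min_{1<=tau<=n_tau} |g1(tau)|

Tail voxels decorrelate as fast as the large-vessel lumen above them, so
|g1| decay alone cannot separate the two. What does separate them is the
*phase* of g1: flowing blood shows a smooth Doppler-like phase ramp across
lags, while the multiply-scattered tail signal has chaotic phase. The
horizon is therefore chosen adaptively: voxels whose g1 phase is unstable
get `n_tau = 1`, which makes Id exactly zero (the minimum then ranges over
the single lag that is also the reference), while stable voxels get the
full horizon and hence maximal contrast.

**The phase-chaos statistic.** We quantify phase instability as the sample
variance (rad^2) of the lag-to-lag phase increments
`dphi(tau) = Arg g1(tau+1) - Arg g1(tau)`, wrapped to (-pi, pi], over
`probe_lags = 8` increments. Several "circular variance" conventions exist;
we chose the wrapped variance because (a) its natural range [0, pi^2)
matches the configured threshold domain, (b) a constant drift of any slope
scores exactly zero, so fast laminar flow is never mistaken for chaos, and
(c) under an iid-uniform-phase null essentially every draw exceeds the 0.4
threshold, giving the sharpest separation of the three conventions we
evaluated. The threshold (0.4 rad^2), probe depth (8), and the two horizons
(1 and 49) are all exposed in `pipeline_config()`.

## Mask, fusion, enhancement

The large-vessel mask derives from the OMAG volume: axial maximum-intensity
projection over the full depth (a slab range is configurable), Otsu
binarization (with a guard that re-thresholds at the median if the
foreground would exceed half the image, so the kept class is always the
brighter minority), then a diameter filter: local diameter is twice the
Euclidean distance transform sampled on the skeleton (Zhang–Suen thinning),
skeleton points at or above the 20 um threshold seed a geodesic
reconstruction restricted to the original foreground, and one pixel of
dilation covers the projection halo at vessel edges. The 2-D mask extruded
along z forms the projection-column mask.

Fusion is a hard voxelwise switch — scaled Ag1 inside the columns, OMAG
outside — after matching the two sub-volumes at their in-mask 99th
percentile (robust against the mostly-background voxel population; the
Ag1 volume is rescaled toward OMAG because OMAG populates most of the
output). The merge is deliberately not feathered by default so that every
output voxel is bit-traceable to one source; a linear feather is available
for rendering.

The OOF stage computes, at each scale r, the Gaussian-derivative Hessian
(sigma = 0.5 r), its eigenvalues, and the response
`P = max(0, max_r(-lambda1 / r^2))` with lambda1 the most negative
eigenvalue — strongly negative across the axis of a bright tube of radius
near r. We take lambda1 as the *minimum* eigenvalue: that is the sign the
clamped response formula requires for bright tubes, even though one could
also describe the principal direction via the largest eigenvalue. Because
the 1/r^2 normalization makes the response to wide vessels fade at large
scales, the filter is applied only to the capillary compartment (outside
the mask columns), rescaled there to the fused volume's out-of-mask p99;
a config switch enables whole-volume application instead.

## The phantom: what it emulates, what it does not

The simulator provides ground truth where no public acquisition exists.
Per voxel the field is `R(t) = S + A D(t) + n(t)`:

* **static tissue** — a fixed circular complex Gaussian speckle draw `S`
  (r.m.s. amplitude 1), no dynamics;
* **lumen voxels** — a unit-variance complex AR(1) process with lag-1
  coefficient `exp(-dt/tau_c)`; the discrete Ornstein–Uhlenbeck form is the
  minimal process with exactly exponential field autocorrelation, so every
  test has the closed form `E g1(tau) = exp(-tau/tau_c)` as an oracle.
  Correlation times: 0.05 ms for large vessels, 5 ms for capillaries —
  fast flow decorrelates three orders of magnitude faster than capillary
  flow, spanning the two protocols' windows. Lumens also carry a small
  deterministic Doppler phase drift (0.2 rad per M-mode step) so "smooth
  phase" is a measurable property, not an absence;
* **tail voxels** — the large-vessel temporal model at 60% amplitude plus
  an independent random-walk phase with 2 rad per-step increments: fully
  decorrelating, chaotic-phase, magnitude-indistinguishable from lumen
  decay. Tails occupy the en-face columns beneath each large-vessel lumen
  down to 120 um;
* **additive noise** — iid circular complex Gaussian, std 5% of the static
  amplitude.

The default study conditions are a 64 x 128 x 128 voxel grid at 3 um
isotropic pitch (near the instrument-class axial/lateral resolution of
~3.5-3.7 um) holding one 30 um-diameter pial vessel and four 8 um
capillaries, one of them directly beneath the large vessel — the voxel
population whose recovery is the entire point of the method. Protocols:
50 repeats at 1/76 ms (M-mode) and 5 frames at 10 ms (repeated B).

Not emulated: the scanning-beam point-spread function and transverse RBC
translation (decorrelation is purely temporal, as the per-voxel contrast
formulas assume), wavelength-dependent attenuation, multiple-scattering
photon transport beyond the scalar tail attenuation, and bulk motion beyond
a global per-frame phase. Passing tests therefore demonstrate the
*algorithmic* claims — artifact suppression, capillary preservation,
provenance exactness — under controlled signal physics, not instrument
performance on tissue.

## Numerical choices

* **Axis order** is `(z, x, y[, t])`, depth-major, so en-face slicing and
  axial extrusion are contiguous; 1-based inclusive ranges in R.
* **Gaussian-derivative kernels** are sampled at integer offsets with
  radius `max(3, ceil(4 sigma))` and calibrated so polynomial inputs give
  exact derivatives (`sum g0 = 1`, `sum g1 k = 1`, `sum g2 k^2 = 2`, both
  derivative kernels zero-sum). Derivative convolutions subtract the
  window's central sample before weighting, so constant volumes yield an
  *exactly* zero Hessian and hence an exactly zero OOF response. Boundary
  handling is reflect (edge value repeated). Anisotropic grids express
  sigma per axis in voxels; scales with sigma under half a voxel on any
  axis are rejected as under-resolved.
* **Symmetric 3x3 eigenvalues** use the closed-form trigonometric solution
  (with the acos argument clamped to [-1, 1] and an isotropic-matrix guard);
  eigenvectors come from cross products of rows of `H - lambda I`, picking
  the largest-norm product, with a dense `eigen()` fallback for degenerate
  voxels. Accuracy against a dense solver is ~1e-13 on O(1) matrices.
* **g1 estimation** normalizes by the full lag-0 power (no noise-floor
  correction, which is out of scope) and averages each lag over all its
  pairs — lower variance at the cost of a small-sample correlation between
  adjacent-lag estimates. Zero-power voxels are flagged and given
  `g1 = 1, 0, 0, ...`, which the horizon logic then treats as maximally
  stable (their index is 0 regardless).
* **Ties and guards**: the stitcher breaks similarity ties toward the
  smallest offset and scores zero-norm overlaps 0; brightness matching
  returns scale 1 with a warning on an empty mask or zero percentile;
  constant en-face images binarize to an empty mask with a warning.
* **Storage**: the field container is HDF5 with an h5py-compatible
  compound complex64 dataset plus protocol attributes; angiogram stacks are
  32-bit multi-page TIFF scaled to [0, 1] with the physical scale in a JSON
  sidecar (restoring values to better than float32 precision). Config files
  are YAML mirroring `pipeline_config()` plus an optional `phantom:`
  section.

## Problem sizes and runtime

All phantom-driven tests run the full 64 x 128 x 128 default conditions
(one shared seeded run, ~1.5 min including both simulations); closed-form
g1 checks use ensembles of >= 1000 voxels per flow class; the eigenvalue
oracle uses 10^4 random matrices; stitching robustness uses 20 seeded
trials at 10% noise with a 60-slice overlap. These sizes were chosen so the
whole suite completes on a laptop-class single core in a couple of minutes
while keeping every Monte-Carlo margin comfortably wider than its
tolerance.

## Known limitations

* The diameter filter's geodesic reconstruction keeps any thin vessel that
  is 8-connected to a large one in the en-face projection; on dense real
  vasculature this inflates the mask (and is inherent to
  reconstruction-style filtering). Slab-wise masking would reduce the
  effect and the MIP range is already configurable.
* Ag1 contrast for capillaries is intrinsically small over the short
  M-mode span — inside the mask columns, capillary sensitivity is whatever
  Ag1 provides; the method preserves OMAG sensitivity only outside.
* The phase-chaos classifier assigns the short horizon to ~10% of true
  large-vessel lumen voxels at defaults (their g1 phase becomes
  noise-dominated once |g1| has decayed); this slightly dims large-vessel
  interiors in the fused volume but leaves detection intact.
* Stitching searches integer axial offsets only; lateral registration and
  sub-slice interpolation are assumed handled by the scanner geometry.
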