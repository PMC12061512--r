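# dualocta

3-D optical coherence tomography angiography (OCTA) reconstruction from a
**dual acquisition scheme**, for researchers imaging microvasculature (e.g.
cortical vessels through a cranial window) who need capillary-level detail
*beneath* large pial vessels — exactly where conventional OCTA is blinded by
projection ("tail") artifacts.

## The method

Two complex-field acquisitions of the same volume feed two contrast engines:

* **OMAG** (5 repeated B-scans, ~10 ms apart), after per-A-line bulk-phase
  compensation:

  `Id = (1/(N-1)) Σ_t |R(t+1) − R(t)|`

  Long inter-frame time ⇒ high capillary sensitivity, but strong tail
  artifacts beneath large vessels.

* **Ag1** (M-mode, 50 repeated A-scans at 76 kHz): per voxel the field
  autocorrelation `g1(τ) = ⟨R*(t)R(t+τ)⟩ / ⟨|R|²⟩` and the adaptive index

  `Id = |g1(1)| − min_{1≤τ≤nτ} |g1(τ)|`

  where the horizon `nτ` is 1 (forcing `Id = 0`) for voxels whose g1 phase
  is chaotic — the signature of multiply-scattered tail signal — and the
  full 49 lags for genuine flow with its smooth Doppler phase ramp.

A large-vessel mask (Otsu + skeleton/distance-transform diameter filter at
20 µm on the en-face OMAG MIP, extruded axially) decides which engine owns
each voxel: Ag1 inside the projection columns (tails suppressed, vessels
beneath pial trunks recovered), OMAG outside (capillaries preserved
bit-for-bit), with p99 brightness matching. Finally an optimally-oriented-
flux filter `P = max(0, max_r(−λ₁/r²))` (λ₁ = most negative Hessian
eigenvalue at scale r) enhances capillary continuity outside the mask.

A speckle-field **phantom simulator** with per-voxel ground truth (static /
capillary / large-vessel / tail classes; AR(1) field dynamics with exact
exponential g1) makes the whole pipeline testable without hardware, and an
axial **stitcher** (cosine similarity) merges multi-focal-depth volumes.

## Worked example

```r
library(dualocta)
cfg <- pipeline_config(seed = 1L)                    # all knobs, defaulted
res <- run_pipeline(cfg, phantom = phantom_spec(seed = 1L), verbose = FALSE)
print(res$report)
```

```
<octa_report>
  tail_suppression_ratio     0.02606
  capillary_dice             0.1682
  large_vessel_dice          0.8687
  capillary_dice_omag        0.05564
  capillary_dice_ag1         0.01476
  large_vessel_dice_omag     0.334
  large_vessel_dice_ag1      0.682
  mask_column_recall         1
  mask_column_precision      0.8333
  capillary_only_column_cover 0
  brightness_scale           2.248
  ...
```

Reading it: the fused volume retains only ~2.6% of OMAG's spurious signal in
true tail voxels (`tail_suppression_ratio`), detects capillaries an order of
magnitude better than M-mode contrast alone (`capillary_dice` 0.168 vs
0.015), and more than doubles large-vessel Dice over raw OMAG (0.87 vs 0.33)
because the tail false positives are gone. The mask caught every en-face
column containing a large vessel (`mask_column_recall = 1`) and no
capillary-only column. Volumes (`res$omag`, `res$ag1`, `res$fused`,
`res$oof`) are `(z, x, y)` angiogram arrays; pass `outdir=` to write TIFF
stacks and a JSON report.

A command-line interface wraps the same functions:

```sh
exec/dualocta phantom --outdir out            # write HDF5 field series + truth
exec/dualocta run --config cfg.yaml --outdir out
exec/dualocta help                            # all subcommands
```

## Package layout

| Area | Files |
| --- | --- |
| Containers, protocols, I/O (HDF5/TIFF/YAML) | `R/protocol.R`, `R/containers.R`, `R/io.R`, `src/h5io.c` |
| Phantom simulator + ground truth | `R/phantom.R` |
| Contrast engines | `R/omag.R`, `R/ag1.R`, `src/g1.c` |
| Mask, fusion, OOF, stitching | `R/vessel_mask.R`, `R/fuse.R`, `R/oof.R`, `R/stitch.R` |
| Orchestration, evaluation, CLI | `R/pipeline.R`, `R/cli.R`, `exec/dualocta` |

The methods vignette (`vignettes/dual-scheme-octa.Rmd`) documents the model,
parameter choices, numerical decisions and limitations.
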