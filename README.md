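# miregsa

Rigid registration of 3D multimodal image volumes by mutual-information
maximization, driven by a hybrid genetic-algorithm / simulated-annealing
optimizer — plus the small clinical statistics pipeline (rates, group
comparisons, logistic regression with Hosmer–Lemeshow calibration and
ROC/AUC) that typically accompanies the imaging study.

## Who this is for

Researchers aligning multimodal volume pairs (CT–MR and the like) who want
a self-contained, reproducible implementation of:

* **Mutual information** `I(A,B) = H(A) + H(B) − H(A,B)` estimated from a
  **partial-volume (PV) interpolated joint histogram**: each sampled
  reference voxel deposits the trilinear weights of its mapped location
  into the histogram as fractional counts, so the objective varies smoothly
  with the 6 rigid parameters.
* A **6-parameter rigid transform** `p → Rx(φx)Ry(φy)Rz(φz) p + t`
  operating in centre-of-gravity-centred world frames (millimetres,
  degrees, anisotropic voxels handled throughout).
* A **GA–SA hybrid optimizer**: 57-bit binary chromosomes
  (9 bits per translation over ±15 mm, 10 bits per rotation over ±10°,
  ≈ 0.06 mm and ≈ 0.02° per bit), roulette selection, single-point
  crossover (p = 0.6), per-bit mutation (p = 0.02), Metropolis acceptance
  of children against their parents, and geometric cooling from a starting
  temperature calibrated to an initial acceptance rate χ₀.
* An **8-vertex registration-error metric** (mean corner distance Δ and
  per-axis Δx, Δy, Δz against a gold-standard transform) with the
  **sub-voxel criterion** Δ < `sqrt(sx² + sy² + sz²)`.
* A **synthetic multimodal phantom generator** (nested ellipsoids rendered
  with non-monotonically related contrast maps + noise) with known
  ground-truth transforms, so everything is testable without external data.

File formats: NIfTI-1, Analyze 7.5 and raw-array-with-sidecar volumes;
plain-text transform files; CSV cohort tables.

## Worked example

```r
library(miregsa)

# a 64^3 multimodal phantom pair and a known displacement
pair    <- make_phantom_pair(phantom_spec(dims = c(64, 64, 64), seed = 11))
tf_true <- rigid_transform(t = c(6, -4, 8), phi = c(5, -6, 3))
flt     <- displace(pair$flt, tf_true)

# register: maximize PV-histogram MI with the hybrid optimizer, sampling
# the bright region of the reference at a stride of 2
fit <- run_hybrid(pair$ref, flt, hybrid_config(seed = 2), bins = 64,
                  mask = foreground_mask(pair$ref, 0.5),
                  stride = c(2, 2, 2))
fit
#> <registration_result> best MI = 0.95449 nats after 200 generations (seed 2)
#> <rigid_transform> t = (2.2603, -1.6732, 3.3170) mm, phi = (4.9169, -6.2072, 2.9814) deg

# evaluate against the effective gold transform (the truth expressed in
# the centre-of-gravity frames registration actually works in)
gold <- gold_transform(pair$ref, flt, tf_true, template = pair$flt)
err  <- vertex_error(fit$best_transform, gold, volume_vertices(flt))
subpixel_check(err, flt$voxel_size)$row
#>   delta_x delta_y delta_z delta threshold subpixel
#> 1   0.113   0.047   0.135 0.198     1.732     TRUE
```

The recovered rotation agrees with the truth to about a tenth of a degree;
the translation differs from `tf_true` by design, because
centre-of-gravity framing absorbs part of the shift (that is the coarse
pre-alignment), and `gold_transform()` accounts for it. The mean corner
error of 0.198 mm is far below the 1.732 mm voxel diagonal: sub-voxel.

The statistics side in two lines:

```r
cohort <- simulate_cohort(seed = 78)     # 157 lesion vs 33 control subjects
rm <- risk_model(cohort)                 # univariate screen -> IRLS -> HL + ROC
rm$roc
#> <roc_result> AUC = 0.996; Youden cutoff 0.8849: sensitivity 96.82%, specificity 96.97%
```

A command-line front end over the same functions lives in
`inst/scripts/miregsa-cli.R` (subcommands `phantom`, `register`,
`evaluate`, `simulate`, `epi`).

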