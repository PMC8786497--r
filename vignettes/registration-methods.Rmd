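---
title: "Mutual-information rigid registration with a genetic-annealing hybrid"
author: "miregsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutual-information rigid registration with a genetic-annealing hybrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miregsa)
```

## The problem

Multimodal medical images of the same anatomy — a CT and an MR volume of
one patient, say — carry complementary information but live on different
grids in different poses. Rigid registration finds the 6-parameter motion
(three translations in mm, three rotations in degrees) that brings the
*floating* image into the frame of the *reference* image. Because CT and MR
intensities are not related by any simple functional mapping, similarity is
measured by **mutual information**

$$ I(A, B) = H(A) + H(B) - H(A, B), $$

the reduction in joint entropy achieved by correct alignment. MI requires no
segmentation or feature extraction and is maximal (for rigid motion, under
mild assumptions) at the true pose.

`miregsa` implements this registration pipeline end to end: volume handling
with anisotropic voxels, the MI metric on a partial-volume joint histogram,
a hybrid genetic-algorithm/simulated-annealing optimizer over a binary
parameter encoding, an 8-vertex registration-error metric against gold
standards, a synthetic multimodal phantom generator, and a small clinical
statistics toolkit (rates, group comparisons, logistic regression with
Hosmer–Lemeshow calibration and ROC/AUC) of the kind used in the vascular
screening study the registration supports.

## Coordinate conventions

A `volume` is a 3D intensity array with per-axis voxel sizes in mm. Voxel
indices are 0-based; world coordinates are
`(index − centre_of_gravity) × voxel_size`, so each volume's world frame is
centred on its intensity-weighted **centre of gravity**. Registering in
CoG-centred frames coarsely pre-aligns the two volumes before the search
starts, which is why the optimizer can afford a translation range of only
±15 mm. An all-zero volume falls back to the geometric centre, and
intensities are shifted non-negative at load (CT Hounsfield offsets) because
histogram binning assumes a non-negative range.

The rigid map is `p → R p + t` with `R = Rx(φx) Ry(φy) Rz(φz)` applied to
column points; angles are degrees at every interface. Any consistent
composition order would do — the vertex-error metric is order-agnostic — but
this one is fixed so transform files are unambiguous.

## The MI estimator

`joint_histogram_pv()` accumulates a `bins × bins` joint histogram by
**partial-volume interpolation**: every sampled reference voxel is mapped
through the inverse transform into the floating grid, and the eight
surrounding floating voxels receive their trilinear weights as *fractional
counts* in the row of the reference voxel's intensity bin. No intensity is
ever interpolated, so no spurious intensity values enter the histogram and
the MI changes smoothly with the transform — the property the optimizer
relies on. Samples falling outside the floating grid are excluded entirely
(not clamped), avoiding artificial border correlations; the weights of every
counted sample sum to exactly one.

Numerical choices, all configurable:

* **64 bins** per image by default, edges spanning `[min, max]` of each
  untransformed volume. Entropies are in nats (the argmax does not depend on
  the logarithm base).
* Sampling visits **every reference voxel** (optionally restricted by a
  mask and/or an integer stride); nothing is drawn at random, so the
  objective is deterministic and test-friendly. `foreground_mask()`
  reproduces the common practice of restricting sampling to the bright
  region around the image's centre of gravity; the stride mirrors the usual
  subsampling speed-up while keeping geometry at full resolution.
* An empty-overlap transform evaluates to MI = 0 rather than erroring, so
  the optimizer can traverse degenerate poses.

A caveat worth knowing when reading test output: the plug-in histogram MI
is biased upward by roughly `(B − 1)² / 2N` nats for `B` bins and `N`
samples, so two *independent* 16³ noise volumes still show ≈ 0.1 nats at 32
bins. Tests of the independence limit therefore use few bins, where the
bias bound is far below the asserted ceiling.

## The hybrid optimizer

The searcher is a genetic algorithm with a Metropolis acceptance rule — an
annealing schedule embedded in the replacement step, which counters the
premature convergence GAs are prone to while keeping their population-level
exploration.

**Encoding.** Each transform is a 57-bit chromosome: 9 bits per translation
over ±15 mm and 10 bits per rotation over ±10°, concatenated as
(tx, ty, tz, φx, φy, φz) in plain big-endian binary. The quantization steps
are 30/511 ≈ 0.059 mm/bit and 20/1023 ≈ 0.0196°/bit (both endpoints
reachable, denominator `2^b − 1`).

**Per generation** (population 50 by default): MI is evaluated for all
individuals; fitness is MI shifted by the generation minimum; 25 parent
pairs are drawn by roulette (fitness-proportionate, uniform when all
fitnesses tie at zero); single-point crossover fires with probability 0.6
and each bit mutates with probability 0.02; each child then competes
against its own parent — accepted outright if no worse, otherwise with
probability `exp(−Δf/T)` on the raw MI scale (the per-generation fitness
shift would distort Δf). Replacement is **in place**: the population
persists between generations and an individual changes only when it is
selected as a parent and its child passes the Metropolis test. This
matters — a variant that rebuilds each generation solely from the selected
pairs silently discards unselected individuals, including the best one,
and in our convergence experiments that drift cost several millimetres of
final accuracy. The best-ever individual is additionally archived for
reporting, and the temperature cools geometrically, `T ← αT`.

**Starting temperature.** `T0 = mean positive MI increment between random
transform pairs / ln(1/χ0)`, so a typical worsening move is initially
accepted with probability about `χ0`. The textbook prescription χ0 ≈ 1 is
singular in this formula; the default is χ0 = 0.9, hot enough that the
first generations explore almost freely.

**Cooling and stopping.** The defaults are α = 0.95, at most 200
generations, stop on 60 generations of best-MI stagnation or when T falls
below `1e-5 × T0`. The budget and the patience are deliberately generous,
for a reason convergence experiments on 64³ phantom pairs made plain:
during the hot phase the best-ever MI improves only sporadically, so a
short stagnation rule (say 15 generations) routinely fires around
generation 30 — while the temperature is still high — and aborts the run
with an essentially random answer several millimetres off. Given the full
schedule, the same runs converge to a fraction of a voxel. Slow cooling
at α = 0.95 with ~200 generations consistently beat faster schedules cut
to 100 generations; the stagnation rule exists only to cut off runs that
have genuinely frozen early.

A single RNG stream seeded from the config drives every stochastic draw in
a documented order (temperature probe, population init, then per generation
selection → crossover/mutation → Metropolis), so runs are bit-reproducible.

## Registration error and the sub-voxel criterion

Accuracy against a gold-standard transform is summarized on the 8 corners
of the floating volume's grid: `Δ` is the mean Euclidean distance between
gold-mapped and estimate-mapped corners, and `Δx, Δy, Δz` are per-axis mean
absolute differences. Corner errors bound the error anywhere inside the
volume for a rigid discrepancy. A result is **sub-voxel accurate** when
`Δ` is strictly below the voxel diagonal `sqrt(sx² + sy² + sz²)` — 4.373 mm
for a typical 1.25 × 1.25 × 4 mm MR grid.

## The synthetic phantom pair

Real multimodal pairs with published gold standards cannot be
redistributed, so every registration test runs on `make_phantom_pair()`:
a field of nested ellipsoids rendered twice with different per-structure
contrast maps plus independent Gaussian noise (sd 2 by default, a few
percent of the structure contrast). The default maps are deliberately
non-monotone between renderings (background 10 vs 120; structures 80, 150,
220 vs 220, 30, 125), so the pair correlates weakly (|r| ≈ 0.3) while
sharing every region boundary — exactly the regime where correlation-based
similarity fails and MI does not. The ellipsoids have unequal semi-axes and
the innermost is slightly off-centre, making all three rotations
identifiable within the ±10° search range. Defaults: 64³ voxels of
1 × 1 × 1 mm (near-isotropic MR-like), three structures.

`displace(template, tf_true)` resamples the aligned floating rendering
trilinearly so that registering the pair should recover `tf_true`.
Trilinear interpolation here is an *image resampler*, distinct from the PV
rule of the metric, which interpolates histogram weights. One subtlety is
handled explicitly: registration works in CoG-centred frames of the volumes
*as they are*, and displacement moves the floating volume's centre of
gravity with its content (less a little border loss), so the transform that
exactly aligns the pair in working frames differs from `tf_true` by the CoG
offsets. `gold_transform()` computes this effective gold standard; vertex
errors are evaluated against it, which is the registration error actually
incurred.

What the phantom does **not** emulate: real anatomy, bias fields, modality
physics, partial-volume tissue mixtures, or resolution mismatch between the
two images. Passing recovery tests therefore demonstrates the correctness
and convergence of the machinery under controlled multimodal contrast, not
clinical-grade robustness on patient data.

## The clinical statistics module

The statistics pipeline mirrors a vascular-screening analysis: detection
and lesion-rate tables (`rate()`, `lesion_table()`), two-group baseline
comparison from summary statistics (`two_sample_t()`, pooled or Welch;
`chi_square_2x2()`; `rank_sum()` with midranks and tie-corrected normal
approximation), and a risk model: logistic regression fitted by IRLS
(`fit_logistic()`), Hosmer–Lemeshow calibration over near-equal-count risk
deciles with ties kept in the lower group and degenerate groups merged
(`hosmer_lemeshow()`), and an empirical ROC whose trapezoid AUC equals the
tie-corrected Mann–Whitney probability, reporting the Youden-optimal
operating point (`roc()`).

The IRLS fitter is implemented in the package rather than delegated so the
score equations (`Σ(yᵢ − p̂ᵢ)xᵢⱼ = 0`) and a brute-force likelihood-grid
oracle are meaningful tests; `glm()` serves as an independent cross-check
in the suite, never as the implementation. Complete separation is detected
and flagged rather than silently returning divergent coefficients.
Two-sided p-values are used throughout with 0.05/0.01 annotation levels.

`simulate_cohort()` generates a structure-preserving synthetic cohort of
157 lesion and 33 control subjects: age, disease duration, systolic blood
pressure, LDL-C, triglycerides and total cholesterol differ between groups,
while BMI, DBP, fasting glucose, HbA1c and HDL-C share a precision-weighted
common distribution — reproducing the significance pattern of the
corresponding baseline table. Covariates are drawn independently normal per
group; real cohorts have correlated covariates and non-normal tails, so the
synthetic AUC (≈ 0.99, the groups being separated on six covariates at
their reported effect sizes under independence) is far higher than any
patient-level value, and no patient-level quantity should be read off it.

A note on the baseline table it emulates: the printed t-statistics of that
table (e.g. 7.791 for age) are not reproducible from its own printed
means, SDs and group sizes by either the pooled or the Welch formula
(which give 11.73 for age); the package reports its own correctly derived
statistics.

## Problem sizes and runtime

The test suite and the acceptance script use 64³ phantoms with stride-2
histogram sampling restricted to the reference's bright region (the
foreground mask, emulating the practice of sampling only around the
object's centre of gravity — background voxels dilute the MI signal and
measurably blunt the optimum) for end-to-end recovery, and 16³–32³
volumes for unit-level checks; a full 100-generation registration of a
64³ pair takes well under a minute on one core with the compiled PV
loop. One caution learned the hard way: the ±15 mm search range assumes
an object substantially larger than the displacement, as CoG pre-alignment
implies; on a 16 mm toy volume most of the search space has no overlap at
all and recovery is unreliable, which is a property of the problem
geometry, not of the optimizer. Calibration checks (Metropolis rate, roulette
frequencies, Hosmer–Lemeshow type-I error) use 10⁴–10⁵ draws.

## Known limitations

* Rigid motion only; no affine or deformable component, no
  direction-cosine/orientation handling (axis-aligned volumes), no DICOM.
* The plug-in MI estimator is biased at high bin counts on small sample
  sets; no Parzen/B-spline smoothing is provided.
* The optimizer is stochastic: on hard displacements a run can settle in a
  wrong-rotation basin; the recovery guarantee asserted by the tests is
  "most seeded runs sub-voxel", not "every run".
* The synthetic cohort draws covariates independently; it preserves
  group-wise margins, not the joint dependence structure of real patients.
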