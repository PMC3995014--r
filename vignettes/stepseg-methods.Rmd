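---
title: "Multi-atlas hippocampal segmentation by locally ranked label fusion: models and design"
author: "stepseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas hippocampal segmentation by locally ranked label fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Hippocampal volumetry underpins the diagnosis of hippocampal sclerosis in
refractory temporal lobe epilepsy: atrophy lateralizes the seizure focus and
informs surgical planning. Manual delineation is the gold standard but slow
and rater dependent, and single-atlas automated methods fail exactly where
they are needed most — sclerotic hippocampi are small, have altered signal,
and are often atypically shaped, so one template cannot represent them.

`stepseg` implements a multi-atlas pipeline for this setting: a large
labelled template database is registered to the target scan, the most
similar templates are chosen, and their labels are fused with a
similarity-aware variant of STAPLE in which only the locally best-matching
templates vote at each voxel. Everything downstream of image acquisition is
covered: contour-to-voxel conversion of manual outlines, groupwise template
construction, registration, ranked selection, local fusion with a Markov
random field, intracranial-volume (ICV) correction, normative reference
ranges, and agreement statistics.

## The pipeline

1. **Groupwise template** (`build_group_template`). Iteration 1 registers
   every database scan affinely to an arbitrary reference (the first entry
   by sorted id, for reproducibility) and averages; later iterations
   register everyone nonrigidly to the evolving average. Each round applies
   a first-order *mean-displacement debiasing*: the average forward
   displacement is subtracted so the template geometry tracks the group
   mean rather than the reference. Without this step the average inherits
   the reference's pose, and the template built from two translated twins
   would sit on one of them instead of halfway between. Convergence is
   declared when the mean absolute intensity change between successive
   averages falls below 1% of the brain-mask mean (at most 5 iterations;
   the criterion and cap are package choices — only "until convergence" is
   inherited from the method).

2. **Localization** (`propagate_prior`, `extract_roi`). The template mean
   is registered to the subject and the averaged left/right label maps are
   carried along, giving a per-side spatial prior. The region of interest
   is the bounding box of the prior's 0.5-level set plus a margin (default
   2 voxels). The margin was tuned on phantoms and is deliberately tight:
   the ROI is also the support of every similarity metric downstream, and
   a generous margin admits distractor anatomy (ventricle, brain edge)
   whose strong contrast dominates the NCC and visibly degrades the
   registration of a small, low-contrast hippocampus. With the tight
   margin the atrophic-subject experiments improve dramatically at the
   cost of occasionally clipping a few boundary voxels of an unusually
   large hippocampus. The prior is an *approximate localization* device
   only: with
   a mixed-atrophy database its 0.5-level is close to the median template
   shape, so it overlaps an atrophic hippocampus much better than a normal
   one — the box, not the level set, is what the pipeline consumes.

3. **Ranked selection** (`select_templates`, `refine_templates`). Each
   template, cropped around its own hippocampus label, is affinely
   registered to the ROI (initialized by aligning its label centroid with
   the prior centroid) and scored by global normalized cross-correlation
   (NCC) over the ROI brain mask; the best `k_coarse = 75` continue to
   nonrigid refinement, and their labels are propagated as continuous
   probability maps (binarizing before fusion would discard propagation
   uncertainty). NCC over the brain mask rather than the full box avoids
   the score being dominated by background agreement.

4. **Locally ranked fusion** (`lncc`, `local_rank_select`, `staple_em`,
   `fuse`). The local similarity of each warped template to the subject is
   the locally normalized cross-correlation under a Gaussian window of SD
   2 voxels. At each voxel the `k_local = 15` most similar templates are
   selected (ties broken by template index) and fused by STAPLE-style EM:
   the E-step forms the consensus probability from the selected templates'
   labels and their current sensitivity/specificity `(p_j, q_j)`; the
   M-step re-estimates `(p_j, q_j)` over the voxels where template `j` is
   selected. Performance parameters are global per template; locality
   enters through selection only. A mean-field Markov random field
   (6-connectivity, `beta = 0.5`) is interleaved between EM iterations.
   The consensus is binarized at 0.5 (ties to foreground) and the largest
   6-connected component is kept.

5. **Volumetry and reporting** (`mask_volume`, `estimate_icv`,
   `fit_normative`, `correct_volume`, `classify_volumes`). Volumes are
   slice area times thickness, doubled when only alternate slices were
   outlined. ICV comes from running the identical selection-and-fusion
   machinery with a whole-brain label database. The normative model
   regresses control hippocampal volume on ICV; corrected volumes are
   `raw − Grad × (ICV − mean ICV)`, which makes corrected control volumes
   exactly ICV-orthogonal (the one testable consequence of the published
   correction), and the reference range is the corrected mean ± 1.96 SD.
   Sides falling below the lower limit are flagged atrophic; this
   volumetric surrogate stands in for a radiological reading.

## Numerical design of the fusion

Three decisions here departed from the most literal reading of the
published description, each forced by a failure mode that phantom
experiments exposed:

* **Prevalence prior instead of a flat 0.5 blend.** Blending the
  propagated prior 50/50 with a flat 0.5 field floors the background prior
  at 0.25 while the true foreground fraction of an ROI is 2–15%. Under the
  STAPLE likelihood this inflates the posterior decision region and the
  consensus systematically over-segments; with the tiny foregrounds of
  sparse structures the flat prior can even drive EM to a degenerate
  cluster split. The default prior is therefore the *prevalence* of the
  propagated labels (a scalar), with `prior_weight` in `fusion_config`
  available to mix the spatial prior back in. The spatial prior still does
  its real job — defining the ROI.

* **MRF as external field.** The pairwise mean-field update
  `pi = sigmoid(beta (S1 − S0))` alone *replaces* the prior: at a
  foreground/background interface it resets the prior odds to even,
  re-creating the over-segmentation the prevalence prior fixes. The
  update is therefore combined with the static prior in log-odds — the
  prior acts as the external field of the MRF. With `beta = 0` the prior
  field is untouched and the classic EM monotonicity guarantee holds
  (asserted per iteration in the tests).

* **Consensus-voxel exclusion.** Estimated specificities saturate at
  their clamp (0.999) because the large, error-free background dominates
  the M-step; a clamped `q` makes a single foreground vote override many
  background votes (`p/(1−q)` is enormous) so the effective decision
  threshold collapses to a handful of votes. Performance parameters are
  therefore estimated only over voxels where the selected templates
  disagree; unanimous voxels keep their unanimous label. This is the
  standard remedy in the STAPLE literature for prevalence-imbalanced
  regions and is what lets the fused consensus beat both the best single
  template and majority voting in the dominance experiment. Set
  `consensus_exclude = FALSE` in `staple_em` for the textbook estimator —
  the rater-simulation recovery experiment uses that form, since there the
  generative model matches the estimator exactly.

`(p_j, q_j)` are clamped to [0.05, 0.999]; EM stops when the mean absolute
consensus change falls below 1e-4 (at most 50 iterations).

## The registration engine

Registration is deliberately self-contained (no external engine):

* **Affine**: 9 dof (translation, rotation, log-scale) about the
  centre-of-mass pair, Nelder–Mead on NCC over a two-level pyramid with
  deterministic stride subsampling of the metric (at most 40,000 voxels).
  Convergence is declared when short restarts stop improving the
  similarity. NCC is used throughout the pipeline — the selection metric
  and the registration metric agree by construction.
* **Nonrigid**: cubic-B-spline free-form deformation, steepest ascent on
  NCC with a bending-energy penalty (weight 0.02 per control point),
  backtracking line search with the step reset each iteration (monotone in
  the penalized objective), over a coarse-to-fine schedule. The `"coarse"`
  preset runs one half-resolution level at 8-voxel control spacing; the
  `"fine"` preset continues at full resolution with 4- then 2-voxel
  spacing. Images are lightly smoothed per level (0.5–1 voxel) so the
  trilinear interpolation landscape is differentiable in practice. A
  Jacobian-determinant check flags folding when more than 1% of voxels
  invert. All schedules were tuned on phantoms; they are package choices,
  not claims about any external implementation.

Transforms map fixed-grid world coordinates to moving-image world
coordinates (the resampling convention); nonrigid transforms store a dense
mm displacement field with the initial affine folded in.

## What the phantoms emulate — and what they do not

`make_phantom` builds a head ellipsoid (the ICV proxy), two ventricle-like
CSF bodies, and two curved hippocampi, each the union of three overlapping
ellipsoids along an arc — a curved shape stresses nonrigid registration
harder than a single ellipsoid. Atrophy scales the radii isotropically and
moves the intensity partway toward CSF (sclerosis combines volume loss
with signal change; the default moves 50% of the gap per unit of volume
loss). A smooth linear multiplicative bias (±10%) and additive Gaussian
noise (SD 4 against a brain level of 100 and hippocampus level of 135)
complete the image. One global seed fans out to fixed-offset child seeds;
geometry jitter and noise are seeded separately so noise can be varied
with the anatomy held fixed.

Default study scale is a 64 × 64 × 48 grid at 2 mm spacing: one
hippocampus is then 130–400 voxels, which keeps the full pipeline
(20-template database, 10 subjects) inside desk-scale compute while
leaving the structures just a few voxels in radius — boundary errors of
half a voxel already cost several Dice points, which is the regime where
local ranking has to earn its keep. The phantoms do **not** emulate
cortical folding, the amygdala boundary, Rician noise, partial-volume
tissue mixtures, or scanner-specific contrast; passing the phantom
experiments therefore demonstrates the machinery (registration recovers
known deformations, fusion dominates its baselines, volumetry is exact)
— it does not certify clinical accuracy on real scans.

The normative/ICV layer runs at phantom scale too (head volumes around
330 cm^3 rather than ~1,400 cm^3); the correction formula is
scale-free, so its orthogonality property is unaffected.

## Experiment sizes

The packaged experiments (tests and `scripts/acceptance.R`) use: a
20-template mixed-atrophy database (¼ each left / right / bilateral /
normal; affected sides scaled by 0.55–0.8); 10 generator-drawn subjects
for the fusion-dominance comparison; atrophy robustness compared at
factors 1.0 vs 0.6 on the same database; 5 simulated-rater seeds for
parameter recovery on a 48³ phantom with enlarged hippocampi (~2,000
foreground voxels, so the ±0.03 recovery band sits several binomial
standard errors above the noise floor of the realized rates); and a
left-side-only pipeline where a single side suffices to test the
machinery. The single-template baseline in the dominance experiment is
the template the pipeline itself ranks most similar after fine
registration — i.e. the single-atlas segmentation a practitioner would
get without fusion.

## Known limitations

* The registration engine favours robustness at desk scale; it has no
  diffeomorphic guarantee (only the Jacobian guard) and the full-volume
  `"fine"` preset is slow — the pipeline only ever runs it on ROIs.
* Sensitivity/specificity are global per template; the consensus-exclusion
  band makes them boundary-informative but they remain non-spatial.
* The per-voxel template ranking is computed once from the LNCC maps, not
  recomputed inside EM.
* Left and right hippocampi are processed independently; nothing couples
  the sides.
* The atrophy classifier is a volumetric threshold (lower reference
  limit), a surrogate for — not a reimplementation of — expert visual
  classification.
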