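# stepseg

Multi-atlas hippocampal segmentation and volumetry with locally ranked
STAPLE label fusion, in pure R (plus a few Rcpp kernels).

## What problem this solves

Hippocampal sclerosis — the common pathology of refractory temporal lobe
epilepsy — presents as hippocampal atrophy with signal change on
T1-weighted MRI. Volumetry of the hippocampus lateralizes the seizure
focus and informs surgical planning, but manual delineation takes an
expert around 15 minutes per side and varies between raters, while
single-template automated tools fail on exactly the small, atypically
shaped hippocampi that matter clinically.

`stepseg` implements the multi-atlas answer for users who want a fully
inspectable, self-contained R implementation: many labelled template
scans are registered to the target, the most similar templates are
selected by normalized cross-correlation (NCC), and their propagated
labels are fused with a similarity-ranked STAPLE variant. Because the
package ships a seeded 3D phantom generator, the entire pipeline is
testable end-to-end without any clinical data.

## The method in brief

* **Groupwise template.** Iterative register-and-average over the
  template database (affine to an arbitrary reference, then nonrigid to
  the evolving mean, with mean-displacement debiasing), producing an
  average anatomy and left/right label priors.
* **Localization.** The priors are propagated to the subject; the
  region of interest is the 0.5-level set's bounding box plus a margin.
* **Ranked selection.** Every template is coarsely registered to the ROI
  and scored by global NCC; the best `k_coarse = 75` are refined with
  cubic-B-spline free-form deformation and their labels propagated as
  continuous probability maps.
* **Locally ranked fusion (the STEPS idea).** At each voxel the
  `k_local = 15` templates with the highest locally normalized
  cross-correlation (Gaussian window, SD 2 voxels) vote. STAPLE-style EM
  alternates the consensus probability
  `W_i = a_i / (a_i + b_i)`, with
  `a_i = pi_i * prod_j p_j^d_ij (1 - p_j)^(1 - d_ij)` and
  `b_i = (1 - pi_i) * prod_j (1 - q_j)^d_ij q_j^(1 - d_ij)`,
  against per-template sensitivity/specificity `(p_j, q_j)`, under a
  mean-field Markov random field prior (`beta = 0.5`, 6-connectivity).
  The consensus is thresholded at 0.5 and the largest connected
  component kept.
* **Volumetry.** Manual-style contours are voxelized by the at-least-half
  coverage rule; volumes are slice area x thickness (doubled for
  alternate-slice protocols); intracranial volume (ICV) comes from the
  same fusion machinery with whole-brain labels; volumes are corrected as
  `corrected = raw - Grad * (ICV - mean ICV)` against a control
  regression, with the reference range `mean +/- 1.96 SD` and a
  sum/difference atrophy classification.
* **Evaluation.** Dice overlap, Pearson correlation, Bland-Altman bias
  and limits, and inter-/intrarater reliability tables.

See `vignettes/stepseg-methods.Rmd` for the full model description,
parameter table and design rationale.

## Worked example

```r
library(stepseg)

## a synthetic template database of 8 mixed-atrophy brains + group template
db <- make_template_database(8, seed = 2)
gt <- build_group_template(db, list(max_iter = 3))

## a new "patient" with left hippocampal atrophy (70% linear scale)
sub <- make_phantom(phantom_spec(seed = 999, atrophy = c(left = 0.7, right = 1)))

cfg <- pipeline_config(n_templates = 8, k_coarse = 8, k_local = 5, sides = "left")
seg <- segment_subject(sub$image, db, gt, cfg)
seg
#> <segmentation>
#>   left: 0.888 cm^3, 12 EM iterations

## accuracy against the phantom's ground truth
dice(seg$sides$left$mask, side_mask(sub$label, "left"))
#> Dice 0.8880 (|A|=111, |B|=139, |A&B|=111)

summary(seg$sides$left$state)[1:3, ]
#>   template sensitivity specificity
#> 1        1   0.9027606   0.8327227
#> 2        2   0.9053248   0.8142240
#> 3        3   0.8864590   0.8194824
```

The fused left hippocampus of this atrophic subject (true volume
1.11 cm^3) is recovered at 0.888 cm^3 with Dice 0.89 against the ground
truth; the sensitivity/specificity table shows how much each template was
trusted over the voxels where it was locally selected. A command-line
wrapper (`exec/stepseg`) exposes `build-db`, `segment`, `report` and
`simulate` subcommands over the same functions.

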