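# gazepheno

Quantifying individual gaze phenotypes from eye tracking of naturalistic
video.

When people watch rich video stimuli (sitcom episodes, movies), where they
look is a stable, individually distinctive behavioural signature. In autism
research this matters for a specific question: are the well-documented group
differences in gaze (less looking at faces and eyes) driven by *noisier*
gaze in autistic viewers, or by *reliable but heterogeneous* individual
patterns? The two explanations make opposite predictions for reliability,
fingerprinting and diagnostic classification, and distinguishing them
requires a pipeline that measures all three from the same data.

`gazepheno` implements that pipeline for screen-based eye tracking of
annotated video, plus a synthetic cohort generator so every stage can be
exercised and calibrated without raw participant data:

- **AOI construction** — per-frame areas of interest from detector outputs:
  body parts merged to head/hands/other-body, eyes and mouth boxes built
  from the five facial keypoints (smallest keypoint box → medium box with
  corners at midpoints toward the face box → split at the nose line), the
  remainder of the screen coded as non-social content.
- **Gaze coding** — raw gaze (120/300 Hz) averaged per video frame
  (24 fps), each frame's gaze point represented as a disk of 1° visual
  angle and assigned to the AOI with maximum rasterized overlap
  (hierarchically: coarse level, then eyes/mouth within faces). Features
  are percentages of on-screen frames; participants missing more than half
  of either session are excluded.
- **Gaze heatmaps** — per 1-s bin, a sum of isotropic Gaussians
  (σ = 0.5°, 41 px/°) over the bin's gaze points; leave-one-out group
  reference heatmaps; per-bin Pearson correlation of the flattened grids;
  4-SD outlier exclusion on the participant means.
- **Effect sizes** — Cohen's *d* (pooled SD) with participant bootstrap
  (percentile CI, sign-crossing p) and the epoch-sampling variant: a random
  contiguous epoch plus bootstrap resampling per iteration, FDR across
  features.
- **Reliability** — Spearman correlation of each feature across two
  non-overlapping random epochs, per group; partial rank correlation
  (rank-transform, residualize on a covariate, Pearson on residuals) to
  control for on-screen time; familiarity-split t-tests and severity
  correlations.
- **Fingerprinting** — nearest-neighbour (minimum L2) identification of
  individuals across epochs from the standardized 8-feature gaze vector,
  with a label-shuffling permutation null (chance ≈ the fixed-point law of
  a random permutation: 95th percentile 3/n).
- **Subgrouping** — Gaussian naive Bayes diagnostic classification with
  epoch-sampled cross-validation and a label-permutation empirical chance
  level; variational Bayesian Gaussian-mixture clustering over moving
  windows with small-cluster reassignment and cross-window identity
  matching.

## Worked example

Simulate a small cohort (two 2-minute episodes, 10 autistic / 14 control
participants with the default calibrated traits), run the coding pipeline,
and estimate group effects and fingerprinting:

```r
library(gazepheno)
cfg  <- pipeline_config(heatmap_downsample = 4)
spec <- cohort_spec(n_asd = 10, n_td = 14, seed = 7)
co   <- simulate_cohort(spec, cfg)
tl   <- build_timeline(co$recordings, co$scenes, co$meta, co$config)
tl
#> <cohort_timeline> 24 participants (10 ASD / 14 TD), 5760 frames (4.0 min)
#>   over episodes A+B, 240 bins, ref TD

ft <- feature_table(tl)
aggregate(cbind(pct_face, pct_eyes) ~ group + episode_id, ft,
          function(v) round(mean(v), 1))
#>   group episode_id pct_face pct_eyes
#> 1   ASD          A     81.0     54.5
#> 2    TD          A     83.3     57.8
#> 3   ASD          B     68.7     50.3
#> 4    TD          B     70.1     49.3

epoch_sampled_effect(tl, duration_s = 120, n_iter = 500, seed = 1)
#>             feature      d ci_low ci_high     p epoch_minutes n_iter p_adj
#> 1      pct_onscreen 0.3260 -0.638   1.408 0.519             2    500 0.937
#> 2          pct_face 0.4208 -0.543   1.349 0.395             2    500 0.937
#> 3          pct_eyes 0.1775 -0.944   1.151 0.703             2    500 0.937
#> 4 mean_heatmap_corr 0.0368 -0.919   0.965 1.000             2    500 1.000

sampled_fingerprint(tl, duration_s = 60, n_iter = 200, group = "TD",
                    seed = 2)
#> <sampled_fingerprint> TD (eight features, 1 min): accuracy 37.4%,
#>   p = 0.05473, null 95% = 36.1%
```

Reading the output: group means reproduce the calibrated structure (more
face gaze in controls, less face gaze for everyone in the second episode);
at this small demo size the face effect points the right way (d ≈ 0.42)
but its bootstrap CI covers zero, and within-group identification (37%)
sits at the edge of the permutation chance band — both effects sharpen
with more participants and longer epochs, which is exactly the sweep the
epoch-sampling analyses are for. `heterogeneous_cohort_spec()` builds the
scenario where the autistic group is a mixture of typical-like and shifted
gaze traits; see the methods vignette (`vignettes/gaze-phenotyping.Rmd`).

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/gazepheno.R simulate --n-asd 20 --n-td 20 --seed 1 --data cohort
Rscript inst/cli/gazepheno.R features --data cohort --out results
Rscript inst/cli/gazepheno.R fingerprint --data cohort --duration 2 --iters 500 --out results
```

Every command writes its results as JSON/CSV plus a manifest (config
snapshot, seed, input digests) that makes the run reproducible.

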