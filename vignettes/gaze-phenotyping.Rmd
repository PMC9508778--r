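---
title: "Gaze phenotyping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze phenotyping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`gazepheno`: the coding model, the resampling statistics, the synthetic
generative model used to exercise them, and the places where a design
decision was genuinely open.

## The coding model

Gaze is analysed on the video's frame grid. Raw tracker samples (120 or
300 Hz) are reduced to one mean gaze point per frame (24 fps); the frame
spans the half-open interval `[f/fps, (f+1)/fps)` and a sample exactly on
the boundary belongs to the later frame. Because the reduction depends
only on which samples fall into each span, tracker rate differences are
compensated by construction.

Screen coordinates are pixels with the origin at the top-left and y
increasing downward; boxes and the screen are half-open
(`[x0, x1) × [y0, y1)`). All areas are rasterized at 1-pixel resolution
with the pixel-centre rule (a pixel belongs to a region iff its centre
does), so box-set and mask inputs behave identically and overlap areas are
integers.

Areas of interest have two levels. Coarse: face (head), hands, other body,
and non-social content (the complement of every detected person region);
where coarse regions overlap, face takes precedence over hands and hands
over other body — the socially informative, typically smaller region wins.
Detectors are not part of the package: it consumes face boxes, five facial
keypoints, and body-part boxes (either already grouped, or in the 24-part
dense-pose taxonomy via a fixed lookup: head parts 23–24, hand parts 3–4,
everything else other-body).

Within each face, eyes and mouth boxes are built in three steps: the
smallest box enclosing the five keypoints; a medium box whose corners are
midpoints between the corresponding corners of that small box and of the
detector's face box (with axis-aligned boxes the only consistent reading
of "corners at midpoints"); and a horizontal split through the nose
keypoint — upper part eyes, lower part mouth, the split row itself
belonging to the mouth so the two are tie-free and disjoint. If the nose
falls on or outside the medium box the face is coded with empty eye/mouth
regions and a warning.

A frame's gaze point is a disk of 1° visual angle diameter (radius
20.5 px at the default 41 px/°; a pixel belongs to the disk iff its centre
is within the radius). The frame's label is the AOI with the maximum
rasterized disk overlap. Because eyes ⊂ face, a flat argmax over all AOIs
would be ill-posed (the face overlap can never be smaller than the eyes
overlap), so assignment is hierarchical: coarse label first, then, within
face frames, the maximum-overlap facial sub-region. Each of the eyes and
mouth percentages is therefore a sub-share of the face percentage, which
matches the relative magnitudes these quantities take in real cohorts
(eyes well below faces). Ties are broken in the fixed order
face > hands > other body > non-social and eyes > mouth > other face.

On-screen percentage divides by all frames; every AOI percentage divides
by on-screen frames, which controls AOI fractions for individual
differences in looking at the screen at all. A participant is excluded
when more than half (strictly) of either session's frames lack on-screen
gaze, or when a session is missing.

## Heatmaps

A heatmap for a 1-s bin places an isotropic Gaussian (σ = 0.5° = 20.5 px)
at each of the bin's frame-level gaze points. The kernel is truncated at
4σ — omitting under 3×10⁻⁴ of its mass — which makes the cost linear in
points; it is also separable, so each point costs two 1-D evaluations and
an outer product. Reference heatmaps pool a group's points per bin and are
always leave-one-out when the compared participant belongs to the group.
Heatmaps are compared by Pearson correlation of the flattened grids; bins
where a participant has no on-screen gaze, or where a grid is constant,
are skipped rather than zero-filled, and the participant's feature is the
mean over defined bins. Participants whose mean correlation deviates from
the mean of all others by more than 4 SD of the others are excluded; the
flagging is leave-one-out per participant so an extreme value cannot mask
itself by inflating the pooled SD.

Two open readings are worth recording. First, "pixels per degree" is
interpreted as 41 *linear* pixels per degree (a 23-inch 1920×1080 screen
at ~65 cm gives ≈ 42 px/°, consistent with that reading); the conversion
is a config field so the other reading is reproducible. Second, heatmaps
are built from the frame-rate gaze points (the same stream the coding
uses) rather than raw-rate samples; since the per-frame mean is an
unbiased summary of the frame's samples and bins aggregate 24 frames, the
correlation structure is essentially unchanged, and the choice keeps the
two analyses consistent. The grid may be downsampled by an integer factor
(`heatmap_downsample`); correlations are stable under modest factors, and
the test suite uses 4 for speed while 1 is the faithful default.

## Resampling statistics

*Effect sizes.* Cohen's *d* is the pooled-SD standardized mean difference,
oriented TD − ASD (positive = controls higher). The bootstrap resamples
each group with replacement (10,000 iterations at study scale), reports
the mean bootstrap *d* and the 2.5/97.5 percentile interval, and a
two-sided sign-crossing p with add-one smoothing,
`p = min(1, 2(1 + #{d* on the other side of 0})/(n_iter + 1))` — the
specific construction is our choice, as only "bootstrap test" is standard
terminology. The epoch-sampling variant additionally draws one random
contiguous epoch per iteration from the concatenated two-episode timeline
before resampling participants; epoch starts are uniform on whole-second
boundaries (so 1-s heatmap bins align), and for epoch pairs the first
start is drawn from the starts that leave room for a disjoint second one,
then the second uniformly from its feasible set.

*Reliability.* Spearman correlation across a group's participants between
a feature computed in two non-overlapping random epochs, averaged over
iterations. The group comparison uses a second stream in which each
group's participants are bootstrap-resampled before correlating, so the
difference distribution reflects participant sampling uncertainty, not
only epoch variability; the epoch-only distribution is kept for the
reliability point estimates themselves.

*Partial rank correlation* rank-transforms all four variables, residualizes
`rank(x)` on `rank(z)` and `rank(y)` on `rank(w)` by simple regression, and
Pearson-correlates the residuals (Pearson because the data are already
ranks). With constant covariates it reduces to the plain Spearman
correlation.

*FDR* is Benjamini–Hochberg, applied within each analysis table (one epoch
duration at a time). BH is not idempotent in general; the invariants the
package asserts are monotonicity in the sorted-p order, the cap at 1, and
the fixed point at all-equal p-values.

*Fingerprinting* runs within a group: features are standardized to zero
mean and unit population variance across the group's participants within
each epoch, and each epoch-1 vector is identified as the owner of the
nearest epoch-2 vector (self included). The permutation null shuffles the
epoch-2 identities; with fixed nearest neighbours the null match count is
the number of fixed points hit through a uniform permutation, i.e. the
rencontres law (≈ Poisson(1)), whose 95th percentile is 3 — hence the
chance levels 3/48 ≈ 6.2% and 3/105 ≈ 2.9% at the study's group sizes.
When bootstrap resampling duplicates participants, an identification
counts as success if the nearest neighbour is any copy of the same
original participant, which keeps chance at ~1/n distinct participants.
Identification is directional (epoch 1 → epoch 2) and only the epoch-2
labels are shuffled; the chance behaviour is identical under the
symmetric variants.

*Classification* is Gaussian naive Bayes on the four headline features
(on-screen, face, eyes percentages, mean reference-heatmap correlation):
per-class per-feature Gaussians with a small variance floor, priors from
training frequencies, posterior ties to the majority class. Each CV
iteration samples an epoch, holds out one third of each group, and scores
the held-out participants; each participant's correct-classification
frequency uses as denominator the iterations in which they were held out.
The empirical chance level is the 95th percentile of the same CV procedure
run with diagnosis labels permuted once per iteration — a standard
construction that preserves class imbalance and the CV structure (the
original construction is unspecified in the literature this mirrors).

*Clustering* fits a variational Bayesian Gaussian mixture (full
covariance, Dirichlet weight prior with concentration 1/K, data-scaled
Wishart prior, k-means initialization) per moving window; the sparse
weight prior lets superfluous components empty, so the number of clusters
is learned. No installed R package provides the variational formulation
(EM/BIC mixtures are a different model-selection mechanism), so it is
implemented here and cross-checked against planted-structure recovery.
Features are z-scored across participants within each window before
fitting so percentage-scale and correlation-scale features are
commensurate. Clusters smaller than 4 members (generalizing the observed
1–3-member strays) are dissolved into the nearest large-cluster mean
(means computed before reassignment). Cluster identity is matched across
windows by greedy nearest-mean matching in raw feature space, with
unmatched window clusters opening new entries; final clusters are
numbered by decreasing size in the first window. With a 43-min timeline,
10-min window and 1-min step the window count is ⌊(43−10)/1⌋+1 = 34; a
33-window convention is reproduced by any timeline a minute shorter, and
nothing downstream depends on the count.

## The synthetic cohort generator

The analyses assume a specific statistical structure; the generator
produces data with exactly that structure so each stage can be calibrated
against known ground truth.

*Scenes* are shot-structured: lognormal shot durations (median ≈ 4 s),
0–3 persons per shot, at least one person in 96% of shots by default
(matching the fraction of frames depicting a person in sitcom-like
material). Each person carries a face box (11–24% of screen height), five
keypoints placed deterministically inside it (eyes at 40% of box height,
nose at 55%, mouth corners at 72%), a body box and up to two hand boxes.

*Traits* are logit-normal: each participant draws latent logits for
on-screen probability, face preference, eyes-within-face and
mouth-within-non-eyes-face share, from group distributions; each episode's
effective traits add an episode offset (the second episode has a
−0.39-logit face offset, reproducing the episode-level drop in face gaze)
and independent session jitter (default SD 0.15). Logit-normal rather
than Beta so that the group shift and the heterogeneity are independent
knobs. Group means are calibrated so realized cohort fractions land near
the magnitudes reported for adults watching sitcom material (faces
~77–81%, eyes ~52–60% of on-screen time in a first episode, less face
gaze in a second); between-participant SDs similarly follow the reported
group SDs. The mouth share is parameterized as a fraction of the
non-eyes remainder so `p_eyes + p_mouth ≤ 1` holds by construction.

*Gaze* follows a dwell process: a target AOI drawn from the trait-weighted
categorical over the AOIs present in the shot (the face mass is
redistributed to the present non-face AOIs, in fixed proportions
0.55/0.30/0.15 non-social/body/hands, when no face is on screen); an
anchor at the target centroid — for "other face", the forehead strip
between the face-box top and the eyes region, since the face-box centre
lies inside the eyes box — blended slightly toward screen centre
(weight 0.02) with Gaussian scatter (0.25°); raw samples at the tracker
rate with 2 px per-sample noise; with probability 1 − p_onscreen the
dwell is off-screen and its samples invalid. Dwell lengths are
exponential (mean 0.5 s), rounded to whole frames and capped at shot
boundaries, so no frame mixes two targets and realized AOI fractions
converge to the trait probabilities — the "generator honesty" property the
tests assert (±2% at 10 simulated minutes). The scatter and centre-bias
defaults were set by pilot calibration so that realized face/eyes
fractions, after disk coding, match the trait calibration targets; larger
values displace anchors off the (small) eye regions and depress the
realized fractions below any real cohort's values.

What the generator does *not* emulate: semantic content and saliency
dynamics (anchors are box centroids, not salient features), smooth
pursuit and saccade kinematics (gaze is piecewise-constant within
dwells), blink structure, calibration drift, or correlations between
traits and demographics. Passing tests therefore show that the
*statistics* behave correctly on data with the assumed structure — not
that real gaze has that structure.

*The heterogeneous scenario* (`heterogeneous_cohort_spec()`) builds the
cohort used for the subgroup analyses: half of the autistic group and a
quarter of the control group share a shifted trait mode (−1.2 logits
face, −1.0 eyes, −0.5 on-screen), the rest are typical-like, and the
autistic group carries a small global shift (−0.08 logits). The shifted
minority of controls mirrors the observed structure in which the
data-driven second cluster contains more controls than autistic members;
the alignment of the on-screen shift with the mode reflects that atypical
viewers are atypical on several axes at once (and, practically, a
structure axis orthogonal to the planted split would itself be resolved
by the mixture model as a third cluster — a behaviour shared by other
variational mixture implementations, not an artefact of this one).
Within-mode trait spread is tight (0.15 logits on the shifted axes) and
truncated at 2 SD so planted subgroup membership is unambiguous — the
construct under test is recovery of a real split, not boundary behaviour.
With this design a single cohort simultaneously shows a significant group
effect, high within-group reliability, near-chance diagnostic
classification with a bimodal per-participant profile, and clean planted
recovery by the clustering — the signature that distinguishes "reliable
but heterogeneous" from both "noisy" and "homogeneous" accounts.

## Numerical choices and problem sizes

- Disk and AOI areas are integer pixel counts; the disk-assignment fast
  path (a per-shot label raster indexed by disk pixels) is tested for
  exact equality against brute-force pixel enumeration.
- Heatmap kernels truncate at 4σ; grids downsample by an integer factor.
- The variational mixture iterates to a mean absolute responsibility
  change below 10⁻⁶ (≤ 500 iterations), with up to 3 re-initializations;
  covariances carry a 10⁻⁶ ridge.
- Degenerate cases are contracts, not crashes: empty bins are flagged and
  skipped, zero on-screen epochs yield missing feature vectors that
  propagate to exclusion, constant features abort standardization with
  the feature named.
- Test and acceptance runs use desk-scale sizes chosen to keep the full
  suite in a few minutes while leaving the statistics well-identified:
  2–2.5-minute episodes, cohorts of 14–66 participants, 150–500
  resampling iterations, heatmap downsampling 4. Study scale (48 + 105
  participants, ~43 minutes, 10,000 iterations, full-resolution heatmaps)
  is reached purely through arguments.

## Limitations

Eyes/mouth fractions depend on the hierarchical-assignment reading; an
alternative (excluding eye/mouth pixels from "face") would change the
nested percentages, and both are consistent with published magnitudes.
The bootstrap p construction and the classification null are explicit
choices where the mirrored analyses leave the construction unstated. The
generator's dwell process is the minimum structure that makes the
downstream statistics identifiable; conclusions about real cohorts
require real data through the same interfaces (`read_gaze_table()`,
`read_annotations()`, `participant_meta()`).
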