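---
title: "From keypoint tracks to behavioral ethograms: methods and design"
author: "PoseEthogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From keypoint tracks to behavioral ethograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PoseEthogram)
```

## The problem

Drug-induced motor stereotypy in rodents — here, rhythmic head weaving —
has historically been scored by hand from video, which is slow and
observer-dependent. Markerless pose estimation (DeepLabCut and similar
tools) replaces the video with per-frame keypoint coordinates plus a
tracking-confidence ("likelihood") value per keypoint. PoseEthogram turns
such keypoint tables from a bottom-view open-field recording into a
frame-by-frame ethogram over five mutually exclusive behavioral states —
head-weaving stereotypy, quiet-awake, locomotion, grooming and rearing —
and derives the downstream summaries a pharmacology study needs:
state occupancies, stereotypy onset latency, run-level Markov transition
networks, and clustered per-animal motor profiles.

The input convention is seven keypoints (nose, both forepaws, both hind
paws, the column point midway between the hind paws and the tail base,
and the tail base) recorded at 60 frames per second in 720 x 480 px
image coordinates. A 39 cm arena spanning roughly 500 px gives the
default scale of 0.078 cm/px.

## The classification rules

Every rule operates on kinematics or likelihood only; there is no learned
classifier downstream of the pose network.

**Locomotion vs quiet-awake.** The four paw keypoints are cleaned (points
with likelihood below 0.95 are replaced by linear interpolation between
the nearest confident frames) and averaged into a body centroid. The
per-frame Euclidean displacement of this centroid is segmented into
600-frame (10 s) snippets; a snippet's speed is its mean per-step
displacement converted to cm/s. The decision threshold is not fixed: it
is calibrated per session as the maximum snippet speed inside a known
quiet interval — by default the 15-minute pre-injection baseline of a
habituated animal. Snippets at or below the threshold are quiet-awake,
above it locomotion. Because the threshold is a maximum over a finite
quiet sample, its stability grows with the calibration segment; a 15-min
baseline provides 90 snippets, which in our synthetic experiments is
enough to make spurious locomotion labels rare.

**Head weaving.** A pelvic centroid is computed from the two hind paws
and the tail base; the body axis runs from this centroid to the column
point, and the head angle is the signed angle between the body axis and
the centroid-to-nose vector. Weaving appears as a smooth lateral
oscillation of this angle while the body stays put. Detection proceeds
in five steps:

1. the angle series is low-passed with a 0.25 s moving average. Keypoint
   jitter is white at the frame rate while weaving is a smooth
   oscillation far below Nyquist, so this suppresses noise-driven
   band crossings at a small cost in signal amplitude;
2. the series is centred by a 10 s rolling mean, making the detector
   robust to slow postural drift;
3. a tolerance band of plus/minus `band_k` (default 2) reference
   standard deviations is placed about the centre. The reference SD is
   measured on the quiet calibration segment of the same session and
   floored at `sd_floor_deg` (default 2.5 deg, i.e. a minimum half-width
   of 5 deg). Using the signal's own rolling SD here would be
   self-defeating — a sustained oscillation of amplitude A has SD about
   A/sqrt(2), so a 2-SD band would always contain it — hence the quiet
   reference, mirroring the speed-threshold calibration. The floor keeps
   angular keypoint noise (typically under 1 deg after smoothing, but
   dependent on body geometry) from defining a band so narrow that noise
   alone crosses it;
4. excursions beyond the band are chained when successive excursions
   alternate in sign with gaps of at most `cycle_max_gap_s` (default
   2 s); a chain with at least `min_cycles` (default 2) alternations is
   a weaving candidate. This operationalizes "rhythmic fluctuation"
   while excluding single head turns, and localizes episode boundaries
   to the first and last crossing;
5. candidates are reconciled with the motion labels: a locomotor run
   spending more than 10 s inside a candidate disqualifies it (weaving
   is defined in opposition to locomotion; interruptions up to one
   snippet are treated as minor), and candidate episodes separated by
   less than 10 s are merged into one continuous episode spanning the
   gap regardless of what happens in between.

**Rearing.** From a bottom-up camera a rearing animal lifts nose and
forepaws out of view while the hind paws stay planted. A frame is
rearing when the nose and at least one forepaw drop below likelihood
0.80 while both hind paws exceed 0.90. Crucially these detectors read
*raw* likelihoods — occlusion is the signal — so likelihood cleaning is
deliberately per-analysis, not global.

**Grooming.** One or both forepaws oscillate rapidly against the face or
body, dropping below likelihood 0.79, while every other keypoint stays
above 0.90 and the body stationary. Candidate runs must last at least
100 consecutive frames (about 1.67 s) and show a forepaw
direction-reversal rate of at least `grooming_min_hz` (default 2 Hz,
measured over the run); the rate gate separates scratching from a paw
that is merely occluded. Evaluating the oscillation over the whole run,
rather than a rolling window, keeps the 100-frame rule exact at run
boundaries.

**Assembly.** Per-frame labels are combined with the precedence
stereotypy > grooming > rearing > locomotion > quiet-awake. Stereotypy
outranks everything because it is the scientific target and is defined
in opposition to locomotion; the occlusion-based states outrank the
motion labels because occlusion corrupts the paw centroid. Runs shorter
than `min_duration_frames` (default 10 frames) are absorbed into the
longer flanking run (ties go to the preceding run), so only sustained
behaviors register. Episodes are re-derived from the final labels,
which makes labels and episodes consistent by construction. The
10-frame minimum is adopted as the frame-denominated rule even though
10 frames at 60 fps is 167 ms, not 330 ms — every other rule in the
pipeline is frame-denominated, and the knob is configurable.

## Downstream summaries

**Occupancy and onset.** Occupancy is the fraction of post-injection
frames per state (it always sums to 1). Onset is the time from injection
to the first post-injection stereotypy episode, in minutes; sessions
without stereotypy are *censored* (reported `NA`), never coded as the
session length — except inside the clustering feature matrix, where a
censored onset becomes a 240-min sentinel plus an indicator column so
that non-stereotypic animals are retained rather than dropped.

**Transitions.** The post-injection label array is run-length encoded;
transitions are counted between the end state of one run and the start
state of the next, so the 5 x 5 count matrix has a structurally zero
diagonal. Counts from all sessions are summed first and the accumulated
matrix is then row-normalized (not averaged per session); rows with no
outgoing transitions remain zero and are flagged. The exported network
is a directed weighted graph (GraphML plus TSV edge list) with node size
equal to occupancy and edge weight equal to transition probability;
edges under `network_display_threshold` (default 0.01) are omitted from
the files but retained in the matrix. A frame-level kernel is
deliberately not offered: with a 10-frame minimum episode the dwell
times are far from geometric, and the run-level chain is the object of
interest.

**Motor profiles.** Each rat-session contributes a feature vector: five
occupancies, onset (with censoring sentinel and indicator), day, and
one-hot treatment group and sex. Including group and day follows the
original feature set even though it partially circularizes
"treatment separates clusters"; `includeMetadata = FALSE` gives an
occupancy-only map. Columns are z-scored (constant columns are zeroed
and recorded in the schema). PCA retains the fewest components
explaining 90% of variance (capped at `nPcs`), and the scores are
embedded in 2-D by exact t-SNE with a fixed seed — the pipeline is a
pure function of (matrix, seed). Default perplexity is 15, suited to
cohorts of roughly 40-100 rows; it is shrunk automatically (and
reported) when the row count is below 3 x perplexity + 1. The embedding
is clustered by Ward-linkage hierarchical clustering, and the cluster
count is chosen by the elbow of the within-cluster sum-of-squares curve,
computed as the maximum second difference over k (ties to the smaller
k). The winning second difference normalized by the total sum of squares
is reported as an *elbow strength*; when it falls below 0.4 the curve
has no dominant elbow and one cluster is reported. The 0.4 floor sits
between the strength a featureless 2-D Gaussian produces (about 0.1-0.35,
since its WSS curve decays smoothly) and the near-1 strength of genuinely
separated groups. Ward linkage, Euclidean distance and the
second-difference elbow are this package's choices; alternatives were
not specified upstream.

**Closed-form summaries.** The coefficient of variation is
SD/|mean| x 100; the absolute mean keeps the CV positive for groups
with negative mean weight change, and raw-value CVs use the sample SD.
When a CV is recomputed from a *printed* two-decimal mean and SD, the
check uses the interval those roundings imply
(`cvRoundingBounds`) — for small means the print rounding alone moves
the CV by more than a tenth of a point. The high-fat-diet preference
index is hfd/(hfd+chow), scale-invariant, 0.5 at indifference, undefined
(NA) at zero total intake. In the bundled intake table the aggregate
formula reproduces the published female indices within 0.015 but not six
of the male cells (most likely computed per day and then averaged from
per-day intakes that are not published); those cells are flagged in the
fixture, not fitted. The stereotypy-locomotion relation across treatment
days is an ordinary Pearson correlation of the paired daily means,
undefined when either series is constant.

## The synthetic generator

The study's raw videos are not redistributable, so validation rests on a
generator that renders ground-truth-labelled keypoint sessions. A
`SyntheticScript` fixes a seed, a quiet pre-injection baseline (default
900 s, matching the 15-minute baseline of the study design), a
post-injection state sequence and kinematic parameters. Rendering places
a rigid 7-point body at a position/heading that is stationary with
Gaussian jitter (default sigma 1 px) in all states except locomotion,
where it performs a heading-persistent walk at the scripted speed
(default 8 cm/s) reflecting off the arena walls. Head weaving swings the
nose about the body axis as A sin(2 pi f t) (defaults 25 deg, 1.5 Hz —
plausible values for rhythmic head weaving, not measurements). Rearing
and grooming are rendered through their likelihood signatures: a visible
keypoint draws likelihood around 0.975 (SD 0.008), an occluded one
around 0.40 (SD 0.08); grooming additionally oscillates the forepaws at
6 Hz. Likelihoods are clamped to [0, 1].

State sequences for cohort work are built by exact time allocation:
each state receives exactly its target fraction of the session, split
into randomly sized bouts (minimum 2 s) and shuffled, so ground-truth
occupancies hit their targets by construction. The bundled two-archetype
cohort contrasts a stereotypy-dominant profile (60% weaving, short
onset) with a quiet-dominant profile (65% quiet, no weaving, censored
onset), 20 sessions each with multiplicative occupancy jitter.

What the generator does *not* emulate: body flexion (the rigid skeleton
cannot rear geometrically, so rearing exists only in the likelihood
channel), posture-dependent keypoint noise, pose-estimation identity
swaps, gradual drug onset/offset dynamics (onset is scripted, not
pharmacokinetic), and orolingual or gait stereotypies. Recovery results
on synthetic data therefore demonstrate that the implementation applies
its stated rules correctly and that the rules are mutually consistent —
not that the rules themselves capture real rat behavior.

## Numerical choices and degenerate inputs

* Frame indexing is 0-based with half-open [start, end) intervals
  throughout; a 4-h session at 60 fps is exactly 864,000 frames.
* Interpolation during cleaning is linear in x and y independently;
  gaps longer than `max_gap_frames` (default 60) are filled but flagged
  in the session metadata. A part with no confident frame at all raises
  an error rather than inventing a trajectory.
* Degenerate head-angle frames (nose or column coincident with the
  pelvic centroid) carry the previous frame's angle and are flagged.
* A zero-variance angle series cannot produce weaving: with no band
  crossings there are no candidate chains, independent of the SD floor.
* Occupancy vectors sum to 1 within 1e-9; probability rows of supported
  states likewise.
* Trailing partial snippets are classified by the same speed rule as
  full snippets and flagged.
* All stochastic steps (generator, t-SNE) consume explicit integer
  seeds; rendering restores the caller's RNG state.

## Validation problem sizes

The bundled validation suite runs scripted 5-minute sessions (plus the
15-min calibration baseline) for frame-level recovery over five seeds, a
40-session cohort for cluster-count selection over five embedding seeds,
and 20 simulated sessions of 500 runs each for transition-kernel
recovery; these sizes keep the whole suite in the tens of seconds on one
CPU while leaving the statistical headroom the checks need. A
"full-scale" 4-h session (864,000 frames) exercises only bookkeeping,
not detection quality, and is therefore not part of the default suite.

## Known limitations

* Quiet-awake conflates immobility and sleep by design; telling them
  apart needs signals this pipeline does not see.
* The weaving detector presumes a usable quiet reference segment in the
  same session; a session that begins mid-stereotypy needs an explicit
  reference interval.
* The speed threshold, being a maximum over the calibration segment, is
  sensitive to contamination of that segment by actual movement.
* Occupancy features feed the clustering together with group/day
  metadata by default, which favours reproducing treatment structure;
  use the occupancy-only flag for an unbiased map.
* Minute behaviors (under 10 frames) are absorbed by design and can
  never appear in the ethogram.
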