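---
title: "Models and methods behind trackmorph"
author: "trackmorph maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trackmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trackmorph` extracts abundance, morphology and movement behaviour for
every moving individual in a grayscale microscopy video. This vignette
explains the models behind each stage, the parameters that matter, the
numerical conventions that make results reproducible bit-for-bit, and what
the synthetic-video tests do and do not establish about real data.

## Segmentation: the dynamic difference image

Organisms filmed under dark-field illumination appear bright on a dark but
*heterogeneous* background (uneven lighting, debris, chamber walls), which
defeats plain intensity thresholding. Instead, each analyzed frame
$I_t$ is subtracted from a reference frame a constant offset later,
$I_{t+\Delta}$, and the result is thresholded: pixels that did not change
cancel, so the stationary background — and, importantly, immobile
individuals and debris — never enter the foreground.

Two conventions are offered:

* `method = "subtract"` (default): $D_t = \max(I_t - I_{t+\Delta},\, 0)$.
  For bright-on-dark video this keeps each mover at its position in frame
  $t$ only.
* `method = "abs"`: $D_t = |I_t - I_{t+\Delta}|$, which additionally images
  the position the organism occupies in the *reference* frame ("ghost
  blob").

The signed default is a deliberate design choice. A ghost is not noise: as
$t$ advances, ghosts trace a coherent, time-shifted copy of the real
trajectory that passes every downstream quality filter, so under `"abs"`
every mover is eventually counted twice and by-frame abundances double.
The unsigned mode is retained for diagnostics (e.g. visualising where an
organism came from) and its invariances are tested, but the counting path
uses the clamped difference.

Parameters, with units and defaults:

* `offset` (frames, default 25 = 1 s at 25 fps). Must be large enough that
  an individual moves at least its own body length between the two frames,
  otherwise the difference truncates its shape ("partial overlap"). The
  per-trajectory averaging of morphology later mitigates residual
  truncation.
* `threshold` (gray value, default 40). System-specific; there is no
  automatic selection because the correct value depends on illumination,
  optics and organism brightness. `check_threshold_values()` writes
  raw/difference/mask montages so the user can validate it by eye.
* `min_area`, `max_area` (px², defaults 5 / 1e5): particle-size gate of the
  component analysis.
* `blur_sigma` (px, default 0 = off): optional Gaussian pre-blur for noisy
  recordings; off by default to keep the reference behaviour minimal.

Thresholding is inclusive (difference ≥ threshold is foreground), fixed so
that results are bit-exact reproducible; raising the threshold can only
remove foreground (a tested invariant).

## Morphometry: the ImageJ-style descriptor set

Connected components are labelled under 8-connectivity; components touching
the border are kept because the viewing field is open (truncating them
would bias counts). Per component, on the difference frame by default
(`grey_source = "raw"` switches to the original frame):

* area $A = n_{px}\cdot\text{scale}^2$ (µm²); centroid in px (x = column,
  y = row, origin at the top-left pixel centre, 0-based).
* fitted ellipse from second-order central moments (with the 1/12
  pixel-extent term), rescaled so that $\pi\,\frac{major}{2}\frac{minor}{2} = A$;
  the angle is reported in degrees $[0,180)$, counterclockwise from the
  x-axis with y up. With the moment matching, roundness
  $= 4A/(\pi\,major^2)$ reduces to minor/major, so roundness × aspect ratio
  ≈ 1 is a tested internal-consistency invariant.
* perimeter from Moore boundary tracing of the component, diagonal steps
  weighted $\sqrt 2$. On a digital disk this overestimates the true
  circumference by ~5 %, so measured circularities $4\pi A/P^2$ of circles
  land near 0.9; circularity is clamped at 1.
* solidity as a ratio of *pixel counts*: component pixels over pixel
  centres inside the component's convex hull. Using the same
  discretisation in numerator and denominator makes convex shapes score
  ≈ 1 regardless of stair-step rasterization (a polygon-area version
  systematically read ~0.97 for disks).
* single-pixel components stay finite because of the 1/12 moment term
  (their area-matched disc has diameter $2/\sqrt\pi$ px); a half-pixel
  semi-minor floor guards pathological thin components, and such rows are
  flagged.

Scale equivariance (area ×4, lengths ×2, shape descriptors unchanged when
µm/px doubles) and rotation robustness (reported angle tracks a rotated
ellipse within 3°) are tested properties.

## Linking: staged cost-minimizing assignment with gap closing

Linking uses positions only. Frames are processed in order; at frame $t$,
trajectories whose last detection lies $g$ frames back ($g = 1,\dots,L$)
compete in turn for the still-unmatched detections. Each stage is solved
exactly as a linear assignment problem (an $O(n^3)$ Hungarian/
shortest-augmenting-path solver written for this package, since no LSAP
solver is available in the dependency set) with squared-displacement costs,
a null option priced at $\text{max\_disp}^2$, and links beyond the gap
allowance excluded. The gap allowance is $g \cdot \text{max\_disp}$ by
default (`gap_mode = "linear"`); a constant allowance is available. Stage
optimality is verified against exhaustive enumeration on small instances in
the test suite.

Conventions fixed for determinism: detections are ordered by (frame, x, y)
before linking, trajectory ids are assigned in birth order (frame, then x,
then y), and assignment ties resolve toward the lower trajectory id. The
output partition is invariant to permutations of the input rows (tested).

Occlusions are handled conservatively: when two trajectories converge on
one detection the cheaper predecessor continues, the loser goes unmatched
and ends once it stays unmatched for more than $L$ frames; fragments are
never recombined, because recombination would require assumptions about
movement that bias the movement statistics themselves. A consequence worth
stating plainly: when two organisms actually touch and merge into one blob,
no position-based linker can guarantee identity through the encounter — at
separation the crossed pairing is often the cost-optimal one. Identity
recovery metrics are therefore meaningful only in dilute, well-separated
scenarios (see the generator below).

Per consecutive detection pair the package computes step length (µm),
absolute angle (radians, y-up, in $(-\pi,\pi]$), turning angle (wrapped
difference of consecutive absolute angles, defined from the second step),
net squared displacement from the trajectory start, and gross (cumulative)
displacement. Zero-length steps have undefined angles (NA), which
propagates to any turning angle involving them. For ballistic motion
nsd = gross² exactly; for unbiased walks the mean turning angle is 0 —
both are tested closed forms.

## Summaries and quality filters

Each trajectory becomes one row: detection counts and temporal coverage,
displacement and step statistics, and mean/median/SD of every morphology
descriptor ("variability" is taken as the sample SD; the IQR of step
length is emitted alongside). Definitions with fixed boundary semantics:

* duration = (last − first frame)/fps — gaps count as elapsed time;
* detection rate = detections / frames spanned, inclusive span
  (last − first + 1): a 10-frame span needs 8 detections for 80 %;
* filters (defaults 50 µm, 0.2 s, 0.8, 2 µm): net displacement, duration
  and detection rate are inclusive minima ("at least"), while the median
  step must *strictly* exceed its threshold (">2 µm"). Filtering is
  monotone in every threshold, and the all-zero filter (with
  min_median_step = −1) is the identity; both are tested.

Abundance is counted **by frame** over the frames for which a difference
image exists ($T - \Delta$ frames) and then averaged. This is robust to
occlusion splits: an individual recorded as three fragments still
contributes exactly one count per frame it was detected in.

## The synthetic-video generator

`simulate_video()` emulates the features of dark-field recordings that the
pipeline must cope with: bright ellipsoidal bodies over a static
low-frequency background gradient plus per-frame Gaussian pixel noise;
immobile debris (rendered identically every frame, so it must cancel);
correlated-random-walk motion (per-frame truncated-normal step from the
species' speed distribution, wrapped-normal turning); an open field with
exits and optional Poisson entries; and per-frame detection dropout.
Bodies are rendered as filled ellipses oriented along the heading; one RNG
stream makes every output bit-reproducible from the seed.

`min_separation` produces a *well-separated* (dilute) sample: paths are
simulated first and any path that ever approaches another within the given
distance is redrawn until the configuration is conflict-free. The
separation is thus verifiable in the ground truth, and — because close
encounters are what destroy linker identities — this is the regime in which
trajectory-identity recovery can honestly be required to be near-perfect.
Rejection converges only for dilute scenarios (roughly up to ~15
individuals on a 512×512 field over a few hundred frames); denser requests
error out rather than silently violating the guarantee.

What the generator does **not** emulate: optics (point-spread function,
depth of field, halo), 3-D motion and out-of-focus excursions, organisms
that deform while swimming, colonies/clusters, and background drift over
time. Passing the synthetic tests therefore demonstrates the correctness
of the algorithms under their stated assumptions, not performance on any
particular real system — segmentation threshold and offset still need
per-system validation by overlay inspection, exactly as the work flow
prescribes for real videos.

Validation scenarios used by the acceptance script (chosen once, as
realistic for ciliate-scale organisms at stereomicroscope calibration):

* *Recovery*: 3 species × 4 individuals, 200 frames at 25 fps, 512×512 px
  at 4 µm/px, bodies 40/50/60 µm, speeds 150/200/250 µm/s (per-frame steps
  1.5–2.5 px, well under half the 20 px linking allowance), turning SD
  0.20/0.17/0.14 rad, no dropout, `min_separation = 30` px. The dilute
  density reflects how counting methods are validated in practice (samples
  diluted into a counting chamber) and is the separated regime discussed
  above; the measured quantities are mean-abundance error vs truth,
  pairwise trajectory-identity F1, and median major-axis recovery.
* *Classification direction*: two species identical in morphology
  (major 18 µm, aspect 1.6) differing only in movement (80 vs 170 µm/s,
  turning SD 0.5 vs 0.15), 6 individuals each, 60 frames, 160×160 px,
  ten seeds; out-of-bag success of morphology-only vs morphology+movement
  random forests. The morphology-only model should hover near chance and
  adding movement features should win in (at least) 9 of 10 seeds.

Problem sizes were set so the whole validation suite completes in a few
minutes on a single CPU while leaving each measured effect far from its
acceptance boundary.

## Species identification demo

Classification is deliberately a demo module, not core functionality: the
pipeline's product is a classifier-agnostic trait table. The demo trains a
random forest (`randomForest`, 500 trees by default) on labelled
monoculture summaries and predicts mixed-culture trajectories, reporting
out-of-bag success (1 − OOB error, %) and the row-normalized confusion
matrix. The morphology feature set comprises the mean/median/SD summary
columns of the eleven shape/gray descriptors; the movement set adds step,
speed, turning and displacement summaries (detection rate and counts are
quality metrics, not behaviour, and are excluded). Class imbalance is
surfaced via per-class support but not corrected — minority classes can be
absorbed into similar majority classes, which is a known failure mode users
should watch for; swapping in imbalance-aware classifiers is left to the
user on the exported trait tables.

## Numerical and interface conventions

* Frames are 0-based everywhere in tables (`frame_1` provided alongside in
  the trajectory CSV); pixel coordinates have x = column, y = row, origin
  at the top-left pixel centre.
* Angles are radians internally; the trajectory CSV adds degree columns.
  Movement angles use the mathematical y-up convention, matching the
  ellipse angle.
* fps and µm/px are always supplied by the user (container metadata is
  unreliable); they default to 25 fps and 1 µm/px in the config.
* The config file is YAML with one section per stage
  (`video`, `segmentation`, `linking`, `filtering`, `io`); every value is
  range-checked before a run, and the manifest written next to the outputs
  records the full configuration and package version.
* `run_pipeline()` is deterministic: identical inputs and config produce
  byte-identical CSVs (tested). Only the synthetic generator and the random
  forest consume randomness, both behind explicit seeds.
* AVI decoding/encoding is unavailable (no decoder backend in the
  dependency set): videos enter as numbered PNG/TIFF sequences and
  overlays leave as PNG sequences. `.cxd` (a proprietary camera format) is
  recognized by the file-name check but cannot be read.

## Known limitations

* Two-dimensional tracking only; vertical excursions appear as
  disappearances.
* No watershed splitting of touching individuals: a cluster is one
  particle. The by-frame counting convention limits, but does not remove,
  the resulting undercount in dense samples.
* Identity is not maintained through real occlusions (no appearance
  fingerprinting); trajectory-level behaviour statistics are unbiased but
  individual-level longitudinal analyses should use dilute preparations.
* The ghost-blob geometry of difference imaging biases shapes whenever an
  individual moves less than a body length per offset; choose the offset
  accordingly and rely on trajectory-level averaging.
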