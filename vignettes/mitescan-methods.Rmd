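---
title: "Quantifying spider-mite symptoms from two-sided leaf scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spider-mite symptoms from two-sided leaf scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay

The two-spotted spider mite (*Tetranychus urticae*, TSSM) is a
piercing-sucking herbivore whose activity on a host leaf leaves three
measurable traces: eggs (translucent to orange ellipsoids, roughly
100–150 µm across, laid mostly on the lower leaf surface), black fecal
pellets derived from digestive cells (tens to a few hundred µm), and
chlorotic feeding damage — yellowed patches where mesophyll cells were
destroyed. Susceptibility assays detach all rosette leaves of an
infested plant (commonly *Arabidopsis thaliana*, three weeks old,
infested with 10 adult females for 72 h), tape them to a plate youngest
first — upper row left to right, then lower row — and scan the plate
once per side at high resolution (8500 dpi ≈ 3 µm/px; `mitescan` works
at any stated scale). Turning the plate over mirrors the image, and the
adaxial scan passes through the plate and adhesive tape, so it is
blurrier, noisier, and carries confounders: air bubbles in the tape
glue that resemble eggs, and white guanine excretions that are not
quantified.

`mitescan` implements the full analysis chain: decoding the filename
convention, segmenting and numbering leaves, pairing the two views of
each leaf, detecting eggs and black feces as discrete objects with
confidence scores, segmenting damage per pixel, merging damage across
sides without double counting, and aggregating per-leaf, per-side and
per-plant results in mm². A statistics layer computes
reference-normalised relative values, one-way ANOVA with Tukey HSD and
compact letter displays (CLD), dynamic ranges, and symptom
distributions over consecutive leaves and leaf sides.

## The synthetic scan generator

No microscope data ships with the package; every stage is exercised
against a seeded generator (`plant_spec()`, `generate_plant()`,
`generate_experiment()`) that renders paired plate scans with exact
ground truth. Generation happens in two stages: a *layout* stage draws
every random quantity in physical units (leaf positions and shapes,
object positions, diameters, tints, damage blob geometry), and a
deterministic *rasterisation* stage renders that layout at a chosen
dpi. Physical ground truth is therefore independent of resolution up
to rasterisation error, and the same spec plus seed is bit-reproducible.

What the generator emulates, and the defaults it uses:

* **Leaves.** Elliptical blades with petioles, youngest (≥ 4 mm, since
  smaller leaves are not mounted; the default youngest leaf is 4.5 mm
  so the 4 mm detection gate is never tested against rasterisation
  noise) to oldest, mounted in two rows with 2 mm clear spacing, with
  small random jitter and rotation. The blade spans ~70 % of the
  stated leaf length.
* **Eggs.** Ellipsoids with equivalent diameter drawn uniformly from
  100–150 µm, in three tints mimicking 0–3-day egg age (translucent,
  straw-yellow, orange) with a glossy specular highlight. The adaxial
  side receives each egg with probability `p_adaxial_egg` (default
  1/6, the ~1:5 adaxial:abaxial preference typical of TSSM;
  configurable per ecotype to emulate adaxial-preferring accessions).
* **Black feces.** Near-black irregular blobs, equivalent diameter
  80–250 µm, with no strong side preference (default 0.5).
* **Damage.** Irregular chlorotic blobs whose per-leaf area is a
  specified fraction of the blade. Each blob is visible on both sides
  with probability `damage_side_overlap` (default 0.6 — damage largely,
  but only partially, shows through the blade), otherwise on one side
  only; the merged truth is the union.
* **Within-plant distribution.** Defaults put no eggs, feces or damage
  on the two youngest leaves, whose dense trichome coating deters
  mites; experiment-level draws weight symptom load towards older
  leaves.
* **Adaxial degradation and confounders.** The adaxial rendering is the
  horizontal mirror of the plate, Gaussian-blurred (σ = 0.7 px at the
  default 1200 dpi), with extra noise, air bubbles (bright rim, dark
  core; default 2 cm⁻²) anywhere on the plate, and white guanine
  streaks (elongated, achromatic) on the leaves.
* **Trichomes.** Bright glints whose density falls from youngest to
  oldest leaf (`trichome_density_gradient`, default 3×). Real trichome
  appearance is only qualitatively known; this is a stylised stand-in.

The default rendering scale is 1200 dpi (≈ 21 µm/px): desk-scale work
and the test suite stay tractable while eggs (5–7 px) and pellets
(4–12 px) remain just-resolvable, which is the regime that actually
stresses the detectors. 8500 dpi rendering of small plates is supported
but slow.

What the generator does *not* model: real optics (vignetting, chromatic
aberration, stitching seams between camera tiles), leaf venation and
curvature-induced defocus, condensation under the tape, mites
themselves, or egg-age colour continua. Passing tests therefore show
that the pipeline's logic and geometry are correct under controlled
appearance, not that the classical detectors would transfer to real
microscope scans unchanged — on real data the detector parameters (or
the trainable backend) would be re-calibrated on annotated examples.

## Leaf identification

Leaf/background separation uses the excess-green index (2G − R − B)
with an Otsu threshold, followed by morphological closing (disc,
150 µm) and hole filling so damage, eggs and pellets stay inside the
leaf mask. An absolute excess-green floor (0.2) prevents Otsu from
hallucinating foreground on an empty plate. Components shorter than
4 mm along their principal axis are discarded (debris; the protocol
mounts only ≥ 4 mm leaves). Leaf numbering splits rows by 1-D 2-means
on centroid row (collapsing to one row when the between-row gap is
smaller than a mean leaf height) and orders the upper row first, left
to right — the mounting convention, so index 0 is the youngest leaf.
Abaxial/adaxial views are paired by mirroring the adaxial masks about
the vertical plate axis (the axis is configurable for rigs that flip
the other way) and greedy one-to-one matching by mask IOU with a 0.5
threshold, the conventional detection-matching cutoff; pairs below it
are flagged rather than forced. A mismatch between the leaf count
declared in the filename and the count found is a warning, not an
error — the declared count is treated as a hint.

## Detectors

The package's reference backend is classical and fully deterministic;
its parameters were calibrated once on the generator's default
appearance (the same role annotated training data plays for a learned
model) and live in `ms_config()`.

**Eggs** are found in a brightness-plus-redness channel (luma +
0.5 max(R−G, 0)), computed with the outside of the leaf filled with
the leaf median so the leaf boundary produces no response. The channel
is band-pass filtered by a difference of Gaussians at the egg radius
(σ₁ = r/√2, σ₂ = 1.6 σ₁), augmented with the smoothed positive part of
a trichome-scale band-pass — on chlorotic tissue the glossy highlight
is the egg's surviving signal. Candidate support comes from a
hysteresis threshold split by a watershed on the response (tolerance
half the floor contrast), so adjacent eggs are not merged. A candidate
becomes a detection if its half-peak support has an equivalent
diameter in the 70–200 µm size gate and circularity 4πA/P² ≥ 0.6, its
peak is chromatic (max(R,G) − B ≥ 0.1; guanine streaks, glints and
bubbles are achromatic), its fine-scale energy does not dominate
(trichome-glint veto), its gradient field is not strongly oriented
(streak veto), its neighbourhood matches a Gaussian disc template
(NCC ≥ 0.55), and the band-pass response is isolated on a surrounding
ring (boundary-arc veto). On the adaxial side a polarity check (core
vs annulus) removes air bubbles, whose core is dark. Confidence maps
the peak response linearly from a floor contrast (0.02) to a reference
contrast (0.033) and is clipped to [0, 1]; the user-facing
significance level for eggs is restricted to [0.8, 0.95]
(default 0.90).

**Black feces** are dark blobs in a darkness map: local background
luminance (heavy masked blur, 600 µm) minus pixel luminance,
thresholded at an absolute contrast (0.1). Because that low threshold
also catches the blur halo, each component is refined to its half-peak
support, which carries the physical area; the support must fall in the
40–250 µm equivalent-diameter gate. Confidence is the mean core
contrast normalised by a reference (0.38); the significance level
spans [0.5, 0.95] (default 0.75, the mid-range).

**Damage** is segmented per pixel — chlorosis score = (yellowness −
leaf median yellowness) + 0.5 (luma − leaf median luma) — at a fixed
threshold (0.11; damage has no user-adjustable level), followed by a
morphological opening at the 100 µm scale, which removes egg- and
pellet-sized false positives, and clipping to the leaf mask.

The significance-level defaults (eggs 0.90, feces 0.75) sit at the
midpoints of their legal ranges. Detection counts are non-increasing
in the level by construction, for both classical and trained backends.

**Trainable backend.** `train_patch_model()` fits a deliberately small
pixel classifier — logistic regression on per-pixel colour, colour
range and local spot contrast — on patches from `make_patches()`
(non-overlapping 128 px tiles by default, reflection-padded,
optionally standardised per channel, with annotation masks expanded by
iterated 3×3 dilation; "five-fold dilation" is read as five iterations
of the unit element, not 5× area scaling). The returned model
satisfies the same call contract as the classical backend: its
probability maps pass through the identical component labelling, size
gates, significance levels and mask clipping. The reference model is
trained on *unstandardised, undilated* masks: dilation is a recall
device for training detectors on sparse annotations, and inflating the
target masks of a pixel classifier would bias its areas. 80-10-10
train/validation/test splitting uses floor sizes with the remainder
assigned train-first.

## Quantification

Areas use pixel area (µm/px ÷ 1000)². Damage on the two sides of a
leaf partly describes the same lesions, so the merged damage area is
the area of the union after registering the adaxial mask into the
abaxial frame: mirror about the plate axis, translate leaf centroids
onto each other, and rotate to align leaf principal axes — a rigid
registration; taped-down leaves do not deform enough to justify
warping. Unpaired leaves fall back to their single side and are
flagged. The oviposition rate is eggs per female over the whole
infestation window (default 10 females, 72 h; a per-day variant is
deliberately not the default since the assay reports the 72-h total).
Off-leaf eggs (`additional_eggs`) attach to the plant, not to any
leaf or side. Manual corrections (add by box, remove by id) are
applied in order, recompute all counts from the detection table, and
append to an audit log; corrections apply to countable objects only —
damage masks are not hand-edited in this workflow.

## Validation

`pixel_iou()` is the Jaccard index, with the empty/empty case defined
as 1 (perfect agreement on absence); `pixel_accuracy()` is also
reported because published pixel-agreement percentages do not always
distinguish the two. `object_efficiency()` reports per-item program ÷
reference × 100, the mean and range, and a paired two-sided t-test —
chosen as the standard paired comparison where the original analysis
reports only a significance conclusion. Items with a zero reference
are excluded with a warning (the ratio is undefined); a single
surviving pair yields no p-value rather than a fabricated one.

## Statistics

Relative values divide each plant's trait by the mean of the reference
ecotype's plants in the same repetition batch (default Col-0, 6 plants
per batch), so reference plants average to 1 per batch by
construction. `anova_cld()` runs one-way ANOVA and, when the F-test is
significant at α (default 0.05), all pairwise Tukey HSD comparisons —
Tukey is the standard post-hoc family controlling family-wise error
where only "ANOVA + letters" is specified. Letters come from the
insert-and-absorb algorithm: start with one column holding all groups;
for each significant pair, split every column containing both; absorb
columns contained in others. The resulting minimal cover shares a
letter between two groups exactly when they are not significantly
different — the test suite checks this equivalence on every run and
cross-checks the structure against `multcomp::cld()`. Because Tukey
comparisons are gated on the ANOVA F-test, the empirical family-level
type-I error sits slightly below the nominal α (measured ≈ 0.048 at
α = 0.05 over 1000 null simulations of 3 groups × 5 plants — the
reduced scale keeps the simulation inside a test-suite run).

Consecutive-leaf distributions re-index per-leaf vectors from the
oldest leaf (leaves are mounted youngest-first but inspected
oldest-first); plants with fewer leaves contribute nothing at the
positions they lack, and single-plant positions are flagged rather
than given a fabricated SE. Side distributions use the per-plant
adaxial fraction, excluding zero-total plants with a warning. Both
absolute and relative value sets can be analysed; the package keeps
them separate rather than committing to one.

## Numerical choices and problem sizes

Raster convention: 0-based (row, col), origin top-left, half-open
boxes, stated once and used in every exported value. Scale precedence
when reading a scan: explicit argument > TIFF resolution tag > JSON
sidecar > configured default — reproducibility over guessing; the
sidecar exists because the available TIFF writer emits no resolution
tags, while the reader honours them. Scans are quantised to exact
8-bit levels so write/read round trips are bit-exact. The detection
benchmark used by the tests and the acceptance script runs 13 plants ×
8 leaves (≥ 100 leaves) at 1200 dpi; the CLD null study uses 1000
simulations of 3 groups × 5; parameter-recovery experiments use 6
plants per ecotype, matching the assay's replication.

## Known limitations

The classical detectors are calibrated to the generator's appearance
model; real scans need re-calibration or the trainable backend with
annotated patches. Registration is rigid and integer-shifted, adequate
for flat taped leaves but not for folded ones. Touching or overlapping
leaves are out of scope (the mounting protocol forbids them), as are
white guanine feces (rendered as confounders, never quantified),
egg-age classification, mite counting, and batch-effect modelling
beyond per-batch reference normalisation.
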