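---
title: "Quantifying gap-junction lateralization: models and design choices"
author: "gjlat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gap-junction lateralization: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

In longitudinal sections of ventricular myocardium, connexin-43 (Cx43)
immunofluorescence appears as discrete particles. Their position relative
to the myocyte axis carries the biology: particles at the intercalated
discs (transversal cell ends) form *end-to-end* junctions, particles along
the lateral sarcolemma form *side-to-side* junctions, and a shift of area
from the former to the latter — lateralization — is an arrhythmogenic
substrate. The quantity this package estimates per image is the end-to-end
percentage of total classified junction area. Because it is a percentage of
a two-class partition, the side-to-side percentage is definitionally its
complement; the package computes it as `100 - end_to_end_pct` so that the
reciprocity is exact rather than approximate in floating point.

## The four-step pipeline

**Rolling-ball background subtraction.** Uneven illumination is removed by
subtracting the greyscale opening of the image with a non-flat
spherical-cap structuring element (`radiusPx`, default 50 px at
0.3225 µm/px). We implement the exact morphology — erosion then dilation
with cap heights $\sqrt{r^2 - \lVert q\rVert^2}$ — rather than any
downsampling approximation, because exactness is testable against a
brute-force oracle and the approximation is an implementation accident of
the popular plugin. Out-of-image offsets are ignored; since the centre
offset is always available, the opening never exceeds the input and the
output is clamped to `[0, input]` elementwise. Intensities stay floating
point after subtraction and are re-quantized only on write.

**Thresholding.** The original workflow sets a threshold manually per
image; reproducibility demands that the number be explicit. The
configuration therefore carries a per-image threshold, and
`suggestThreshold()` offers Otsu's maximizer over the full 16-bit histogram
as a deterministic, logged stand-in. The mask comparison is inclusive
(`>= t`), so `t = 0` means "everything" — a convention choice the mask
records. Thresholding is applied to the background-subtracted channel.

**Orientation and classification.** The membrane (WGA) stain is the only
orientation information available, and the method for reading it had to be
chosen: we use the structure tensor — Gaussian-derivative gradients
(`gradSigmaUm`, 0.5 µm), outer product, Gaussian integration window
(`windowSigmaUm`, 8 µm ≈ a third of a cell width) — whose minor eigenvector
gives the dominant membrane direction, i.e. the myofiber axis, as an axial
angle in [0°, 180°), with coherence $(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)$
as a per-pixel reliability weight. Derivative-of-Gaussian filters replaced
plain central differences during development because they roughly halve the
angular error around membrane junction points.

Each particle's axis is compared with the coherence-weighted axial mean of
the fiber field within `neighborhoodUm` (5 µm) of its centroid; pixels with
coherence below `coherenceFloor` (0.05) are ignored, and a particle whose
whole neighbourhood is indeterminate is flagged unclassified and excluded
from the area totals (the count is reported). With $\Delta$ the acute axial
difference, the particle is end-to-end when $\Delta \ge 45°$ — disc plaques
lie transversal to the fiber — and the tie at exactly 45° goes to
end-to-end. 45° is the symmetric, parameter-free cutoff; it is exposed in
the configuration.

Near-circular particles carry unstable second-moment axes, so for them the
axis is read instead from a fine-scale structure tensor of the WGA channel
(`fineSigmaUm`, 1 µm) at the particle centroid: the ridge direction of the
membrane the punctum sits on (transversal at a disc, longitudinal on a
lateral membrane). The roundness gate is `elongationMin` (1.2) **plus
4.5/area_px**: rendering a perfect circle on a pixel grid inflates its
apparent elongation by roughly that much at the 95th percentile, so without
the size correction ~10% of genuinely round 2–3 px-radius puncta would be
classified by what is effectively moment noise. A variance of 1/12 px² (the
second moment of a unit pixel) is added to the moment diagonal so that
one-pixel-wide bars keep finite, meaningful axes.

Coordinates are row-major with the origin top-left; angles are measured
counterclockwise from the +column axis and are axial (θ ≡ θ+180°).
Particles are 8-connected components; components below `minAreaPx` (2 px)
are discarded as shot noise at this magnification. Both are configurable.

## The phantom: what it emulates and what it does not

The study images real tissue; ground truth there is unknowable. The phantom
generator instead renders the simplest geometry that exercises
orientation-dependent classification with *exact* ground truth: a brick-wall
lattice of ~100 × 20 µm cells whose axis follows a smooth angular drift
(sum of three long-period sinusoids in the along-fiber coordinate, scaled to
a target angular SD; zero wobble yields an exactly constant field, which is
what the orientation tests exploit). Membranes get a Gaussian cross-profile
(SD 0.45 µm); nuclei are ellipses at cell centres; acquisition defaults are
1344 × 1024 16-bit at 0.3225 µm/px.

Cx43 puncta are discs with a logistic edge whose intensity is exactly half
the peak at the nominal radius, truncated 0.6 µm further out, with a minimum
separation between puncta. The consequences are deliberate: with noise and
illumination disabled, thresholding at half the punctum intensity recovers
every punctum's pixel set *exactly*, and separated puncta can never merge.
Class placement is area-weighted and adaptive — each punctum goes to
whichever membrane keeps the cumulative end-to-end area share closest to
the target, falling back to the other class when crowding blocks placement —
so the realized share tracks the target within a punctum's area even near
the capacity of the disc compartment. At the exact bounds 0 and 1 the class
is mandatory and a blocked punctum is dropped instead.

Illumination is a multiplicative low-order polynomial surface (so the
rolling-ball step has something real to remove); noise is the standard CCD
model, Poisson shot noise (`poissonScale` photons/DN, 0.05) plus Gaussian
read noise (`gaussianNoiseSd`, 150 DN). Defaults for what the source
workflow does not specify — 300 puncta per frame, lognormal radii of mean
0.8 µm and SD 0.25 µm — are plausible for confocal Cx43 imaging, not fitted
to any dataset. All randomness flows from one seeded generator, so equal
seeds give bit-identical phantoms.

The phantom does **not** model optical point-spread beyond the profile
shapes, z-sectioning, spectral bleed-through, fibrosis, or the irregular
cell outlines of real tissue. Passing the recovery tests therefore shows
that the pipeline's geometry and statistics are right, not that real-tissue
segmentation is solved; on real images the manual threshold and a human
check of the orientation field remain part of the workflow.

## Arrhythmia scoring

The input is an already-annotated beat list (times and NORMAL/PVC labels)
plus annotated fibrillation intervals; QRS detection is out of scope.
Maximal runs of consecutive PVCs inside the analysis window (default
0–600 s, the 10-min ischemic episode) are categorized: single (1), salvo
(2–3), ventricular tachycardia (≥ 4 — the only bound the source convention
states explicitly; 2–3 as "salvo" is the usual Lambeth-style reading).
Episode duration needed a convention: we use the first-to-last beat span
plus one median inter-beat interval of the window (so a run has nonzero
width even conceptually at one beat), truncated at the window end.
Tachyarrhythmia duration is the exact sum of tachycardia and fibrillation
durations, and incidence is their disjunction.

## Group statistics

Per-animal values are the mean of that animal's ROI-level fractions
(hearts, not images, are the unit of analysis). The two-way ANOVA
(group × condition) uses type-I sums of squares on balanced designs (where
they equal type II) and warns and switches to type II when unbalanced. The
Bonferroni family is the four within-factor comparisons (groups within each
condition, conditions within each group), pooled-MSE t tests multiplied by
4 and capped at 1; which post-hoc family such workflows use is ambiguous,
and four is the choice exposed in code. Fisher's exact test uses the
point-probability two-sided rule (the common meaning of "Fisher's exact
test", and what `stats::fisher.test` computes); the test suite checks it
against full hypergeometric enumeration. The Mann-Whitney U uses midranks;
for combined n ≤ 12 the p-value is exact by enumeration of all group
assignments (valid under ties, which is why it is authored here rather than
delegated), otherwise the normal approximation with tie and continuity
correction. The cutoff keeps the study-sized groups (13 per group) on the
approximate path, matching common practice; it is configurable.

Degenerate inputs are defined rather than NaN: constant data yield F = 0,
p = 1; a constant pooled sample yields p = 1 on the approximate path.

## Null calibration design

The acceptance checks include no-effect simulations asserting that each
test's rejection rate at α = 0.05 lands in [0.03, 0.07]. The Mann-Whitney
simulation uses the study's own group size (13 + 13, continuous data) and
the ANOVA the study's 2 × 2 × 6 design. For Fisher's exact test the
simulated incidence groups are 150 per arm at rate 0.5: the conditional
exact test is intrinsically conservative at small n (its exact size at
13 + 13 is ≈ 0.029, at 150 + 150 ≈ 0.043 — computable by enumeration), so
the calibration uses groups large enough that the test can approach its
nominal level; at study-sized groups the simulation would measure that
well-known conservatism, not the implementation.

## Problem sizes and numerical choices

The recovery study runs full-frame phantoms (1344 × 1024) at true
end-to-end fractions 20/50/80%, ten seeds each, through the blind default
pipeline (automatic threshold); unit tests use ~256–800 px phantoms, which
are the same geometry at realistic punctum density. The rolling-ball
morphology is exact but computed with a decomposition into per-row 1-D
passes in single precision (differences from the double-precision oracle
are < 10⁻³ DN). Orientation angles are reduced mod 180° everywhere;
axial means are computed on doubled angles. The Otsu suggestion on an
effectively empty (constant) channel is refused with advice to set a manual
threshold, and `quantifyImage()` treats a constant Cx43 channel as "no
detectable particles" rather than an error.

## Known limitations

- Within two integration windows (~16 µm) of the image border the structure
  tensor's support is truncated and its axis can be confidently wrong, so
  those pixels are flagged indeterminate; particles whose whole
  neighbourhood falls in that band are reported unclassified and excluded
  from the area totals (on full frames, a few percent of particles). This
  trades a small loss of sample for the removal of a systematic
  classification bias that development runs traced entirely to the border
  zone.
- Orientation cannot be recovered in regions whose WGA signal is isotropic
  (fibrosis, cut artifacts); such particles are reported unclassified, not
  guessed.
- The end-to-end percentage is an area share of a two-class partition; it
  says nothing about absolute Cx43 abundance, which needs expression data.
- VF episodes are consumed as annotations; no attempt is made to detect
  fibrillation from beat timing.
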