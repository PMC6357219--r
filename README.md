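# gjlat — gap-junction lateralization quantification and arrhythmia scoring

Connexin-43 (Cx43) is the principal ventricular gap-junction protein. In
healthy working myocardium its channel plaques sit almost entirely at the
intercalated discs — the transversal ends of the rod-shaped cardiomyocytes —
where they carry *end-to-end* conduction. Under many pathological and
adaptive conditions part of the Cx43 pool relocates to the lateral
sarcolemma (*side-to-side* junctions), a remodeling called lateralization
that is an established arrhythmogenic substrate. `gjlat` quantifies this
distribution from multi-channel immunofluorescence micrographs and scores
the ischemic ventricular arrhythmias such studies pair it with. It is aimed
at cardiac physiology groups doing quantitative immunofluorescence on
longitudinal sections.

## What it computes

**Junction census.** For a calibrated three-channel image (Cx43 particles,
WGA membrane stain, DAPI nuclei) the pipeline runs four steps:

1. *Background subtraction* — exact greyscale rolling-ball opening
   (spherical-cap structuring element, default radius 50 px) removes uneven
   illumination.
2. *Thresholding* — an explicit per-image threshold (or a logged Otsu
   suggestion) selects Cx43 particles; the mask comparison is inclusive.
3. *Particle classification* — particles are 8-connected components. The
   local myofiber axis θ_f is estimated from the WGA channel with the
   structure tensor J = G_σ ∗ (∇I ∇Iᵀ) (the fiber axis is the minor
   eigenvector of J; coherence (λ₁−λ₂)/(λ₁+λ₂) gates unreliable pixels).
   Each particle is compared to the coherence-weighted local fiber axis:
   with Δ the acute axial angle between particle axis and fiber axis, the
   particle is **end-to-end** when Δ ≥ 45° (disc plaques lie transversal to
   the fiber) and **side-to-side** otherwise.
4. *End-to-end fraction* — the statistic of interest,

   `end_to_end_pct = 100 × Σ area(end-to-end) / Σ area(all classified)`,

   with the side-to-side percentage its exact complement.

**Synthetic phantom.** `generateTissuePhantom()` renders longitudinal
cardiac tissue with exact ground truth: a brick-wall lattice of ~100 × 20 µm
cells following a smooth fiber field, WGA-bright membranes, Cx43 puncta
placed at discs or lateral membranes with a controllable end-to-end area
fraction, polynomial illumination gradient, and Poisson + Gaussian camera
noise. Same seed, same bits.

**Arrhythmia scoring.** `summarizeBeats()` classifies annotated beat series
over the 10-min ischemic window: maximal runs of premature ventricular
complexes become singles (1), salvos (2–3) or ventricular tachycardia (a run
of ≥ 4 consecutive PVCs); tachyarrhythmia incidence and total duration
combine tachycardia runs with annotated fibrillation intervals.

**Group statistics.** Mean ± SEM tables, two-way ANOVA (group × condition)
with four Bonferroni post-tests, Fisher's exact test for incidence, and a
Mann-Whitney U test (exact with ties for combined n ≤ 12) for durations and
PVC counts.

## Worked example

```r
library(gjlat)

ph <- generateTissuePhantom(phantomParams(trueEndToEndFraction = 0.8, seed = 3))
ph$truth
#> PhantomTruth: 300 puncta, end-to-end area 80.3%

qr <- quantifyImage(ph$image)
#> quantifyImage: using Otsu threshold suggestion 11607.8 DN
qr
#> QuantResult 'phantom_seed3': 300 particles (19 unclassified)
#>   total junction area 736.99 um^2, end-to-end 79.3%
```

The phantom placed 300 puncta so that 80.3% of their area lies at
intercalated discs; the blind pipeline (automatic threshold, default
settings) recovers 79.3%. The 19 unclassified particles sit where the
orientation field is indeterminate (image border band) and are excluded
from the area totals. `particleTable(qr)` holds the per-particle table
(area, axis, local fiber angle, Δ, class) and `qr@provenance` the threshold,
radius and settings used.

For shell use, `inst/cli/gjlat.R` exposes `generate`, `preprocess`,
`quantify`, `ecg` and `report` subcommands; outputs are byte-identical when
re-run with the same config and seed.

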