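---
title: "Quantifying glial synapse engulfment: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying glial synapse engulfment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

After a stroke, reactive microglia/macrophages and astrocytes proliferate
around the lesion and can engulf synapses in the gliosis region. gliaquant
implements the quantification machinery such studies rely on: 3D
reporter-based engulfment scoring from confocal stacks, dendritic-spine
morphometry, serial-section volumetry, behavioral indices, and the
single-cell QC / differential-expression / enrichment filters applied to
the accompanying transcriptomics. Every stage can be exercised on synthetic
data with known ground truth, so the pipeline's accuracy is measurable
rather than assumed.

## The engulfment reporter model

The imaging readout rests on a pH-sensitive dual fluorophore fused to a
synaptic protein. eGFP (pKa 6.0) is quenched and degraded in the acidic
lysosome, while mCherry (pKa 4.5) persists. A punctum that is mCherry+GFP
double positive is intact; a punctum that is mCherry-alone has been
internalised and delivered to a lysosome. The scored quantities are:

* **mCherry-alone volume** in a compartment: total mCherry-positive punctum
  volume minus total GFP-positive punctum volume there, floored at 0
  (`mcherry_alone_volume()`). The subtraction is read with "reporter
  puncta" meaning *all* mCherry-positive puncta; the strictly
  double-positive reading is available via `reading = "double_positive"`,
  but only the default reading makes the difference equal the quenched
  volume.
* **In-unit-glia score (AU)**: engulfed punctum volume divided by total
  phagocytic glial volume (`score_in_unit_glia()`), a dimensionless
  normalisation that removes field-to-field variation in glial content.
  "Phagocytic glia" is not defined operationally in the imaging literature
  we follow; the package defines it as glial labels containing at least one
  inside punctum, with `which = "all"` as the alternative.
* **Inside/outside percentages** and the **lysosomal fraction** of inside
  puncta, volume-weighted by default (the readout quantifies punctum
  *size*; count weighting is available).
* **Double-positive cell fractions** (e.g. Iba-1+/Mac-2+), as the share of
  marker-A labels overlapping marker-B foreground above a configurable
  overlap fraction (default 0.1 of the cell's voxels).

Per-animal values average the per-field reports with an unweighted mean
(`aggregate_fields()`), mirroring the practice of imaging several
perifocal fields per section.

## Segmentation choices and their rationale

Stacks are `(channel, z, y, x)` arrays with anisotropic voxel sizes carried
in micrometres; all volumes are voxel counts times physical voxel volume,
and all distances are computed in physical units. Voxel `i` (1-based) is
centred at `(i - 0.5) * voxel_size`. Connectivity is the full 26-voxel 3D
neighbourhood, the common choice for confocal blob analysis; labeling is
done in compiled code.

Three thresholding rules are provided:

* `"otsu"` — a single global histogram split maximising between-class
  variance. It is parameter free and works well when foreground occupies a
  sizeable voxel fraction (glial somata). It **fails structurally** on
  punctum channels: with foreground well under 1% of voxels, the
  between-class criterion is maximised by bisecting the noise mode, and the
  "segmentation" is noise. This failure is easy to reproduce with the
  synthetic generator.
* `"robust"` — background median + 4 MAD. The background statistics are
  insensitive to a small foreground, so the rule behaves identically on
  dense and sparse channels, and reduces to "strictly above background" on
  noise-free images. The multiplier 4 was chosen so that the detected
  volume of a PSF-blurred punctum is an unbiased estimate of its geometric
  volume: on synthetic fields the volume bias is about +1% at 4 MAD,
  against −6% at 5 MAD and +37% at 3 MAD, because the cut slides along the
  blurred intensity shoulder of the punctum. This is the default for
  punctum detection and for the end-to-end pipeline.
* `"fixed"` — an explicit value, used by tests and for reproducing external
  settings.

`detect_puncta()` applies a volume band-pass after labeling. The default
floor of 0.5 µm³ (two voxels at the default sampling) exists because
additive noise occasionally pushes isolated voxels above any threshold;
such single-voxel specks are far below any real synaptic punctum
(≈ 2 µm³ at 0.8 µm radius) but, if kept, can merge into true puncta during
channel matching and silently flip a quenched punctum to double-positive.

Cross-channel identity is established by greedy nearest-centroid matching
within a radius (default 1 µm, the punctum scale): the closest unmatched
pair merges first. Merged puncta take the union of voxels, so a
double-positive punctum contributes identical volume to both channel
totals and cancels exactly in the mCherry-alone subtraction.

Compartment assignment uses the centroid rule by default (a punctum is
where its centroid voxel is); a majority-voxel rule is available. The
partial-overlap behaviour of boundary puncta is genuinely underdetermined
in the source methodology, so both rules are exposed and the invariant
*in lysosome ⇒ inside glia* is enforced either way.

## The synthetic engulfment field

`generate_engulfment_stack()` emulates the statistical structure the
analysis assumes, not the optics of a microscope. Glial cells are spheres
(default 4 cells of radius 7 µm in a 24 × 48 × 48 µm field at
1 × 0.5 × 0.5 µm voxels) each containing one spherical lysosome blob at
0.55 of the cell radius; synaptic puncta are 0.8 µm spheres. A planted
fraction of puncta (default 0.3) lies strictly inside glia, and a planted
fraction of those (default 0.6) inside the lysosome, where the quenching
rule sets GFP emission to exactly zero before noise. Engulfed and
lysosomal counts are deterministic round-offs, so small fixtures have
exact planted counts. Channels are blurred with an isotropic Gaussian PSF
surrogate (σ = 0.3 µm) and corrupted with additive Gaussian noise at
σ = peak/SNR (default SNR 10). Puncta are kept ≥ 2(r + σ_psf) + 1 voxel
apart (a relaxed hard-core spacing inside the lysosome), so noiseless,
blur-free fields are exactly countable. The placement sampler retries a
bounded number of times and raises an explicit placement error for
infeasible geometry.

What the generator deliberately does **not** model: diffraction-realistic
PSFs, Poisson/EMCCD noise, autofluorescence, irregular cell morphology,
and partial engulfment. Passing the recovery tests therefore demonstrates
that the scoring machinery is correct and unbiased under the stated
geometry and noise model — not that any specific biological imaging
dataset would be recovered at the same accuracy.

The ground truth records the planted masks and per-punctum flags, and
`planted_scores()` recomputes all planted quantities by brute force from
the emitted voxel masks, which the tests compare against independent
recomputation.

## Spine morphometry

Spines are classified from `(length, width, heads)` by six rules —
filopodia: length > 2 µm; long-thin: length < 2 µm; thin: length < 1 µm;
stubby: length/width < 1; mushroom: width > 0.6 µm; branched: ≥ 2 heads —
which overlap as stated (a 0.5 × 0.7 µm spine satisfies thin, stubby and
mushroom). The package fixes the precedence *branched → filopodia →
mushroom → stubby → thin → long-thin*, follows the strict inequalities
exactly as printed, and sends the only unreachable boundary case (single
head, length exactly 2 µm, no other rule firing) to long-thin. Any other
precedence can be supplied, making the map total and deterministic by
construction. Mature spines are stubby + mushroom + branched; densities
are reported per 10 µm of dendrite. The spine generator samples geometry
strictly inside each class's decision cell, so classification round-trips
planted classes exactly — that is a property of the generator/classifier
pair, by design.

## Serial-section volumetry and behavior

Brain atrophy, infarct and ventricular volumes use the conic frustum
formula over adjacent serial sections, V = Σ h/3 (S_n + √(S_n·S_{n+1}) +
S_{n+1}), with h the centre-to-centre section interval (for 30 µm sections
every 300 µm, h = 0.3 mm — the interval, not the thickness). The formula
is exact for piecewise-conic profiles (cylinders, cones) and converges
quadratically for smooth solids; `generate_section_series()` provides
cylinder, cone and ellipsoid fixtures with closed-form volumes. For
atrophy/infarct the input is the contralateral-minus-ipsilateral area
difference; negative differences are floored at zero with a warning by
default (atrophy cannot be negative) or rejected in strict mode. No
extrapolation beyond the terminal sections is performed. The grid-walking
foot-fault index is the signed percentage
(contra − ipsi)/total steps × 100, preserved with its sign.

## Single-cell filters

`qc_filter_cells()` discards cells whose UMI or detected-gene count falls
outside mean ± 2 SD (each metric's own statistics over the input table —
the per-table reading; a pooled band across samples would be an
alternative), then cells with ≥ 30% mitochondrial counts
(threshold-inclusive). Reasons partition the discarded set, and the band is
computed on raw counts by default with a log-scale option. Under Gaussian
counts the expected retention is P(|Z| < 2) ≈ 95.45%; the synthetic counts
generator makes gene counts an affine, tightly correlated function of UMI
(as both track library size in droplet data), so the two bands largely
coincide rather than multiplying their losses.

`deg_filter()` applies p < 0.05 and |log2FC| > 0.58 (≈ 1.5-fold), strict
as printed, idempotent and order-preserving, on raw p-values by default
(BH adjustment behind a flag). `hypergeom_enrich()` computes the
upper-tail P(X ≥ k) for X ~ Hypergeometric(N, K, n) per term via R's
`phyper`; the tests validate it against exhaustive enumeration (both a
closed-form sum over outcomes for every N ≤ 20 configuration and literal
`combn` enumeration of all draws at small N) to 1e−12. Clustering,
normalisation, batch correction and cell-type annotation are out of scope:
only the filters and the enrichment test defined in prose are implemented.

## Numerical and testing choices

Determinism: every generator routes its randomness through a private RNG
stream seeded from its `seed` parameter, so identical parameters give
bit-identical outputs and generator calls do not perturb the session RNG.

Problem sizes: the validation suite and the acceptance script use 24 × 96
× 96 voxel fields with 120 puncta (nine fields across three planted
fractions and three seeds), 600 spines, 10,000-cell QC tables and
10,000-gene differential tables — sizes at which every planted quantity is
statistically identifiable while a full run completes in seconds on one
core.

Known limitations: punctum volumes are voxel counts, so sub-voxel
precision is not claimed (tolerances in the tests are one voxel shell per
object); densely packed quenched puncta may merge into one detection,
which conserves volume-based scores but can undercount puncta; Otsu
thresholding should not be used on sparse channels (see above); and the
synthetic generator's idealised geometry means real-data performance
depends on segmentation quality in ways these tests do not measure.
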