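---
title: "Quantifying striosome–matrix compartments: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying striosome–matrix compartments: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(striocompart)
```

## The problem

The rodent caudoputamen is organized into two neurochemical compartments:
patchy, labyrinthine **striosomes** embedded in the much larger **matrix**.
In the Q175 knock-in (Q175KI) mouse model of Huntington's disease, the
expression of several cAMP-pathway molecules (PDE10A, Gα~olf~, Drd1, Drd2,
A2A) declines preferentially in striosomes, while the striosome marker
MOR1 (mu-opioid receptor 1) is upregulated. Quantifying this requires
three steps this package implements as a reusable pipeline:

1. **Segmentation** — find striosome borders on the MOR1 reference channel
   with a residual U-Net, trained on tiles of annotated sections;
2. **Densitometry** — measure background-referenced mean gray levels of a
   target molecule per compartment within caudoputamen segments
   (dorsomedial DM, dorsolateral DL, ventromedial VM, ventrolateral VL,
   and their union WH), excluding fiber bundles and vessels;
3. **Statistics** — compare genotypes with Kruskal–Wallis and pairwise
   Mann–Whitney U tests under Bonferroni correction, reporting Cohen's r.

Two unitless indices summarize the biology: **RI** (relative intensity),
the ratio of Q175KI to wildtype group-mean intensity per molecule,
segment, age and compartment; and **ISMP** (index of striosome-to-matrix
predominance), the within-sample ratio of striosomal to matrix intensity.

Because the raw whole-slide images are not shipped with the package, a
first-class synthetic-section generator stands in for the tissue: it
produces two-channel sections with known per-pixel ground truth, so every
downstream quantity has a configured true value against which the
pipeline is validated.

## The synthetic-section generator

`generate_striosome_mask()` builds the geometry: a convex-ish striatal
territory (an ellipse with low-frequency radial perturbation), striosomes
carved by thresholding difference-of-Gaussians band-pass-filtered white
noise at the quantile matching the configured area fraction, plus
elliptical fiber bundles and thin vessel tubes carved out of the matrix.
Band-pass thresholding is the simplest generator we know of that yields
connected, elongated, labyrinthine minority-compartment shapes with an
exactly controllable area fraction; real striosome morphology is only
qualitatively characterized, so any generator here is a modeling choice.

`render_section()` assigns each pixel the mean gray level of its
(segment, compartment) cell from an *effect table*, adds independent
Gaussian noise, and clips to the bit-depth range. The reference channel
is always rendered from the MOR1 rows, because MOR1 defines the
compartments in the double-staining design; the target channel uses the
molecule under study. The noise stream is seeded separately from the
geometry stream so that noise is independent of striosome placement.

Key defaults, with reasons:

* `striosome_area_fraction = 0.10` — striosomes are a minority
  compartment, typically 5–15% of striatal area; 0.10 is the midpoint.
* `noise_sd = 15` gray levels (8-bit) — calibrated so that plain Otsu
  thresholding of the reference channel is a poor segmenter (held-out
  Dice ≈ 0.55 on the benchmark cohort), making the learned segmenter's
  contribution visible. Means and noise are jointly chosen so that
  ≥ 3σ intensity excursions stay inside the 8-bit range (no clipping
  bias on compartment means).
* `background_level = 10` — slide glass outside the tissue; densitometry
  subtracts the mean over this region, chosen (over merely recording it)
  because it makes all records invariant to a global intensity shift.
* `animal_cv = 0.06` — between-animal multiplicative intensity offset
  (log-normal, mean 1), shared by both hemispheres of an animal. This is
  what makes group comparisons statistically nontrivial. The magnitude is
  a design choice: small enough that the configured effect directions are
  identifiable at the study size (n = 8 mice per group), large enough
  that per-sample variation dominates pixel noise, as it does in tissue.
* Default effect table — wildtype means give every molecule a
  striosome/matrix contrast (MOR1 strongly striosome-enriched; PDE10A
  mildly so, matching its slight striosomal predominance in naïve
  animals). Q175KI ratios move MOR1 up in striosomes and every other
  molecule down, with magnitudes growing with age. Only the *directions*
  are constrained by the biology; the magnitudes are configuration, and
  `expected_indices()` converts the table into the background-referenced
  RI/ISMP values the pipeline must recover.

What the generator deliberately does **not** emulate: DAB chromogenic
optics (higher gray = stronger signal, fluorescence convention; an
optical-density inversion would be a preprocessing step), anatomical
atlas geometry, section-to-section registration, staining gradients
within a section, and spatially correlated noise. Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline arithmetic
and learning protocol* are correct, not that the segmenter transfers to
real tissue — for that, the training stage accepts real sections and
manual label maps in the same formats.

## Segmentation protocol

The segmenter is a fully convolutional residual U-Net
(`unet_spec()`): per resolution level one two-convolution residual block
(identity skip, or 1×1 projection where channel counts change), 2×2 max
pooling on the way down, nearest-neighbour upsampling, 1×1 projection and
skip concatenation on the way up, and a 1×1 two-class head. Depth 4 with
16 base channels is the default — the smallest configuration that
exercises the full multi-resolution protocol at desk scale. The network
and its training loop are implemented in C++ on BLAS matrix products
(im2col convolutions), single precision, fully seeded.

Training (`train_striosome_unet()`) follows the tiled protocol:

* sections are split 85/15 into train and held-out sets *by section*
  ("training rate 0.85" is read as the split fraction: 0.85 is
  implausible as a learning rate for cross-entropy U-Net training, and a
  held-out fraction is required by the reported test metrics; the Adam
  learning rate is a separate parameter, default `1e-3`);
* sections are cut into `tile_size` tiles; tiles without striatal tissue
  may be dropped from the training set, never from inference;
* two augmentation arms: `vflip_only` (vertical flip with probability
  1/2, applied identically to image and labels) or
  `vflip_plus_photometric`, which additionally jitters brightness (±20%)
  — and hue (±0.05 cycles) and saturation (±20%) for RGB tiles — on the
  image only. On single-channel sections hue and saturation are identity
  operations, so brightness is the active photometric component;
* optimization is Adam on unweighted pixel-wise two-class cross-entropy,
  batch 32; per epoch the curve records train loss, held-out loss and
  held-out pixel accuracy;
* the returned model is the checkpoint from the epoch with **minimum
  held-out cross-entropy** (`select_checkpoint()` = argmin, first epoch
  on ties), never the final epoch.

Inference (`predict_striosomes()`) tiles the reference channel, stitches
the probability map (edge tiles are anchored to overlap their
predecessor, so stitching is exact), and binarizes at 0.5 with ties
assigned to striosome. No morphological post-processing is applied.
Because convolutional context differs near tile seams, probabilities may
differ slightly there between tilings; for a converged model the binary
masks agree to Dice ≳ 0.97 across tile sizes.

`otsu_preannotate()` provides the Otsu-assisted draft used for manual
annotation: an exhaustive between-class-variance-maximizing threshold
(exact over ≤ 256 distinct values, histogram-binned above) applied within
the tissue region. It doubles as the baseline segmenter in the benchmark.

Evaluation metrics (IoU, Dice, precision, recall, accuracy) are computed
**macro** (per image, then averaged) by default, with pooled variants
also available: the pooled identities Dice = 2·IoU/(1+IoU) and
Dice = harmonic mean(precision, recall) hold exactly and serve as
self-checks, while macro averages are what the per-image reporting
convention implies. Overlap metrics are evaluated over the striatal
region by default; pixel accuracy is whole-tile (background included).

## Desk-scale problem sizes

The package validates the protocol at sizes a workstation handles in
minutes, chosen once and fixed:

* benchmark cohort (`segmentation_benchmark()`): 48 sections of
  512 × 512 px (8 mice-equivalents × 2 hemispheres × 3 ages, MOR1), 85/15
  split → 40 training and 8 held-out sections; depth-4/base-16 U-Net,
  128-px training tiles, batch 32, 14 epochs sampling 192 tiles per
  epoch; the per-epoch test curve uses a fixed random subset of 24
  held-out tiles, and final metrics use every pixel of all 8 held-out
  sections at the selected checkpoint;
* parameter-recovery cohorts: 128 × 128 px sections, all six molecules,
  n = 1 (noiseless, exact recovery) and n = 8 (noisy, recovery within
  three standard errors);
* training for real 12,000 × 9,000 px sections uses the same code path —
  only the tile grid grows.

## Statistics layer

`mann_whitney_pairwise()` computes two-sided Mann–Whitney U tests: exact
p-values (via the null distribution of U) for combined n ≤ 20 without
ties, otherwise a tie- and continuity-corrected normal approximation.
Cohen's r = |Z|/√N uses the tie-corrected Z *without* continuity
correction, so r = 0 exactly when U sits at its null mean; bins at
0.1/0.3/0.5 give the negligible/small/medium/large labels. The Bonferroni
family size is an explicit parameter because the printed thresholds imply
two conventions: family 10 → α = 0.005 (genotype comparisons across the
heatmap panels) and family 3 → α ≈ 0.0167 (three-age comparisons).
Two-sided tests are assumed throughout.

RI is computed as a **ratio of group means** (the index is defined on
group mean intensities), with qc-excluded records dropped; ISMP is
computed **per sample** and then summarized as mean ± SEM, because its
figure convention shows group distributions. This asymmetry is
deliberate and documented here.

`heatmap_tables()` assembles the molecule × (segment × age) RI matrix
with significance markers, the matching Cohen's-r matrix, and per-
molecule ISMP summaries; missing cells are explicit `NA`, never silently
dropped.

## Numerical and degenerate-input choices

* Otsu on a constant image errors (no threshold exists); ties in the
  between-class variance resolve to the first maximum.
* Overlap ratios with zero denominators are 1 when both masks are empty,
  else 0.
* Empty compartment-within-segment densitometry records are flagged
  `qc_excluded` with `NA` intensity rather than dropped, mirroring the
  visual-QC exclusion of poorly stained segments.
* A non-positive matrix mean drops the ISMP record with a warning; a
  non-positive wildtype group mean makes RI error.
* One-vs-one Mann–Whitney comparisons get p = 1 and a `degenerate` flag.
* Per-section seeds derive from the global seed through a counter that
  encodes the condition coordinates, so enlarging a cohort (more mice or
  molecules) never reshuffles existing sections.
* Training aborts with a diagnostic if the loss becomes non-finite.

## Known limitations

* **Hemisphere clustering.** Following the study design, the sampling
  unit is the caudoputamen (animal × hemisphere), 16 samples per group of
  8 mice. Both hemispheres share the animal's intensity offset, so the 16
  samples are not independent and rank tests on them are
  anti-conservative; no mixed-effects correction is applied because the
  reference protocol applies none. The type-I-error validation therefore
  draws exchangeable samples; inference on strongly clustered cohorts
  should be interpreted accordingly (or run on per-animal means).
* **Segment boundaries.** DM/DL/VM/VL are manual outlines in tissue
  work; `partition_segments()` substitutes a deterministic
  centroid-quadrant rule (dorsal = top of image, medial side set by the
  hemisphere flag). Real-mode runs can supply their own segment masks.
* **Synthetic-to-real gap.** See the generator section: results on
  synthetic cohorts validate the machinery, not tissue performance.
* **Bit depth.** Synthetic defaults are 8-bit and uncalibrated; the
  acquisition calibration of real scans is out of scope. 16-bit TIFF
  output is supported.
* **Serialization quantization.** The disk pipeline stores sections as
  8-bit PNG; exactness statements (noiseless recovery) refer to the
  in-memory chain. Disk round trips agree to half a gray level.
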