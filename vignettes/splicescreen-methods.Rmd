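---
title: "Methods: quantifying two-colour splicing reporters from high-content images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying two-colour splicing reporters from high-content images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay and its readout

splicescreen analyses high-content screening (HCS) plates of cells carrying a
two-colour fluorescent alternative-splicing reporter. The reporter minigene
produces, from one pre-mRNA, either an exon-included transcript translated
into RFP or an exon-skipped transcript translated into GFP, in a mutually
exclusive way. The per-cell ratio of background-corrected mean GFP to mean
RFP intensity (the G/R ratio) is therefore an optical readout of that cell's
exon-inclusion balance: predominantly red cells include the exon (E10+ in
the MAPT exon 10 system this package was developed around), predominantly
green cells skip it, and intermediate cells express both isoforms.

The pipeline runs in five stages, each an exported function so any stage can
be used, inspected, or replaced on its own:

1. **Segmentation** (`find_nuclei`): nuclei from the Hoechst channel via
   Gaussian smoothing, a global Otsu threshold, hole filling, a
   distance-transform watershed for touching nuclei, and an area filter.
2. **Regions of interest** (`expand_rois`): each nucleus dilated by a fixed
   radius; contested pixels go to the nearest nucleus (seeded Voronoi
   propagation), so ROIs are disjoint and cover the union of the dilations.
   The ROI includes the nucleus because the reporter signal is assumed
   homogeneously distributed over the cell; an annulus variant can be
   obtained by differencing masks but is deliberately not the default.
3. **Intensity** (`background_level`, `measure_cells`): per field and per
   channel, the background is the median intensity of the cell-free area
   (the complement of all ROIs dilated by a safety margin); per-cell
   corrected means are `max(raw - background, 0)`.
4. **Gating and classification** (`derive_gates`, `classify_cells`,
   `summarize_wells`): a cell is transfected when either corrected reporter
   channel reaches its gate, `mean + 3 sd` of the corrected intensities of
   cells in untransfected control wells. Each cell's regularised ratio
   `(G + eps)/(R + eps)` is classified against the lower threshold K = 2 and
   the upper threshold J = 5: below K, RFP/exon-included; above J,
   GFP/exon-skipped; between them (boundaries included), dual.
5. **Plate statistics** (`zprime`, `welch_t`, `bonferroni`,
   `dose_response`): assay quality via the Z' factor
   `Z' = 1 - 3 (sigma_neg + sigma_pos) / |mu_neg - mu_pos|`
   (1.0 is the noise-free maximum; >= 0.4 is usable, >= 0.6 robust), Welch
   t-tests with Bonferroni correction on replicate well summaries, and
   dose-response deltas of the three class percentages against
   scramble-control wells matched by dose.

A companion densitometry module reproduces the semiquantitative RT-PCR
arithmetic used to validate such assays: ladder calibration
(position ~ log10 bp), band detection and integration on 1-D lane profiles,
assignment to the expected amplicons (reporter set 300/207 bp, endogenous
set 368/275 bp, Beta-Actin 650 bp), actin normalisation, the within-lane
percent inclusion `E10+ / (E10+ + E10-) * 100`, and cross-lane fold-changes
of actin-normalised E10+ levels.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `smoothing_sigma` | 1.5 | px | suppresses detector noise before thresholding without merging 4-7 px nuclei |
| `min/max_nucleus_area` | 20 / 500 | px^2 | rejects speckles and clumps at the ~5.5 px nucleus radius of the default geometry |
| `watershed_tolerance` | 1 | distance-map units | splits touching nuclei whose distance peaks differ by > 1 px |
| `roi_expansion_radius` | 4 | px | perinuclear ROI reaching into the cytoplasm while staying inside most cells |
| `bg_margin` | 5 | px | keeps dim cell fringes out of the cell-free background area |
| `k_sigma` | 3 | sd | gate = upper envelope of control autofluorescence; ~0.1% false-positive rate if control intensities were Gaussian |
| `K`, `J` | 2, 5 | ratio | the class thresholds of the assay; boundaries fall in the dual class |
| `epsilon` | 1 | counts | keeps the ratio finite when corrected RFP is 0; negligible against reporter signals of hundreds of counts |
| `baseline_window` | 51 | samples | gel baseline opening window; must exceed the widest band footprint (~6 band sigmas) |
| `tolerance` (band assignment) | 0.10 | relative | generous against ladder-fit error while keeping 207/275/300/368 bp separable |

Thresholds K and J, the 12-fields-per-well minimum, the amplicon sizes, and
the Z' bands are assay constants; the segmentation geometry parameters have
no universal values and must be adapted to magnification and cell type. The
nucleus-area bounds and ROI radius used here are declared defaults for the
synthetic geometry, not values inherited from any instrument protocol.

## What the synthetic generator emulates — and what it does not

`generate_plate()` renders each well's fields from an explicit image
formation model: cells are concentric discs (nucleus inside cytoplasm)
placed by rejection sampling so that nuclei never overlap; each cell carries
a Bernoulli transfection flag, a log-normal expression level (log-mean
`log(350)` counts, log-sd 0.5), and an exon-inclusion fraction psi drawn
from a Beta distribution (or mixture) with the condition's mean and
concentration. A transfected cell adds homogeneous reporter intensity
`expression * (1 - psi)` to GFP and `expression * psi` to RFP over its
cytoplasm disc, so the summed reporter amplitude equals its expression
regardless of psi. Channels share a constant background plus a smooth
low-order polynomial illumination gradient; every cell adds a small
autofluorescence offset in all channels; Gaussian detector noise is added
and the image is quantised to 16 bits. All stochastic steps are driven by a
single seed through deterministic per-well/per-field child seeds, so
identical inputs give byte-identical plates.

Because cytoplasm discs may touch and overlap (only nuclei are kept apart),
dense fields show reporter cross-talk between neighbouring cells — a real
feature of adherent monolayers that measurably inflates the dual class at
~100 cells per 256x256 px field. The per-cell psi distribution is a modelling
choice: the real assay only reports population-level isoform percentages, and
the Beta family is the minimal bounded distribution with controllable mean
and spread.

The generator deliberately omits: point-spread-function optics, spectral
bleed-through between filter sets, photobleaching, uneven cell morphology,
nuclear/cytoplasmic partitioning of the reporter proteins, focus drift, and
debris. Passing the package's tests therefore shows that the *analysis
arithmetic* is correct under a controlled image model; it does not certify
performance on real microscope images, where segmentation quality and
background structure are far harsher. The headline biological percentages of
a live-cell experiment are likewise not reproduced numerically anywhere —
the validation suite checks directions and parameter recovery, not biology.

Default generator conditions mirror the reference biology: a wild-type-like
reporter condition uses mean inclusion 0.35 and a mutant-like condition 0.85
(matching the ~35% vs ~85% E10+ transcript levels the imaging assay was
validated against), with 70% transfection efficiency. Cell density per field
is not reported for the real assay; the default of 90 cells per 256x256
field (~1400 cells/mm^2 at 20x-like sampling) was chosen once as a realistic
adherent-culture density and is documented here rather than inferred.

## Numerical choices

* **Otsu on the observed range.** The global threshold is computed on the
  min-max-normalised smoothed image, making segmentation exactly invariant
  to additive intensity offsets.
* **Voronoi ROI partition.** Contested dilation pixels are assigned by
  seeded propagation with a purely geometric metric, giving a deterministic,
  orientation-independent partition that preserves label identities.
* **Median background.** The cell-free background estimator is the median,
  robust to hot pixels and stray debris; it is estimated per field and per
  channel so slow illumination drift across a well does not bias corrections.
  (Whether the original instrument pipeline estimated background per field
  or per well is unknown; per field is the safer choice and is documented
  as such.)
* **Flooring corrected intensities at 0.** Intensities are physical counts
  and the ratio stage requires non-negative inputs; cells dimmer than the
  background estimate read as 0, which the gate then excludes.
* **Ratio regulariser.** `(G + 1)/(R + 1)` in counts: finite for R = 0,
  and a 1-count shift is negligible against gated cells' signals.
* **Boundary rule.** Ratios exactly equal to K or J go to the dual class:
  the threshold definitions use strict inequalities on both sides, which
  leaves the boundaries unassigned; dual is the conservative bucket.
* **Gel baseline.** Morphological opening (moving minimum then moving
  maximum) with a 5-sample median prefilter: the prefilter stops the moving
  minimum from tracking downward noise excursions, which would bias the
  baseline low and inflate every integrated area. Band supports run between
  flanking minima but are truncated where the median-smoothed signal
  returns to the baseline, so band-free stretches contribute no accumulated
  noise. On a noise-free Gaussian band the integral is exact to rounding.
* **Degenerate inputs.** Blank images give zero labels; uniformly saturated
  images, empty background masks, near-confluent fields (< 1% cell-free),
  fewer than 50 gating-control cells, equal control means in Z', missing
  actin bands and non-monotone ladders are all explicit errors, not silent
  results.

## Design choices that were genuinely open

* **Gate formula.** The reference protocol states only that an intensity
  threshold was derived from control wells. `mean + 3 sd` of untransfected
  cells' corrected intensities is the conventional upper-envelope gate and
  is exposed via `k_sigma`.
* **Median G/R denominator.** The protocol text says the median over all
  cells, but an all-cells median is dominated by untransfected
  autofluorescence at realistic transfection rates; the default is the
  median over transfected cells, with `median_over = "all"` available.
* **Class percentage denominator.** The three class percentages are
  reported over transfected cells (they then partition to 100%); published
  figures in this assay family are ambiguous between total and transfected
  denominators, and the transfected denominator is self-consistent.
* **Z' readout.** The per-well mean corrected RFP intensity is the default
  readout, with control arms selectable by role or condition, because the
  assay literature does not fix the channel; per-well summaries (not
  per-cell values) are the replicates entering the control statistics.
* **Welch over pooled-variance t.** Control and treated wells have no
  reason to share variances; the Welch form is the robust default.

## Validation problem sizes

The test suite validates each stage against generator ground truth at desk
scale: segmentation recovery on ten 256x256 fields of ~100 cells at default
noise (centroid-matched F1 >= 0.95); classification parameter recovery on a
bimodal well of >= 2000 transfected cells plated at 55 cells/field over 44
fields, with mixture components at mean psi 0.04 and 0.75 (concentration
60) — chosen so both populations sit cleanly past the K/J-equivalent psi
thresholds *after* accounting for the ~0.02 shift that unsubtracted
cellular autofluorescence imposes on measured ratios, and plated sparsely
to limit neighbour cross-talk; recovered class percentages agree with
truth-derived percentages within 3 points. Directional checks compare
wild-type-like and mutant-like wells over three seeds, and a four-dose
titration (10/25/50/100 nM with generator inclusion knocked down to
0.75/0.60/0.45/0.25, concentration 6) reproduces the expected monotone
red-population decrease against dose-matched scramble controls. Gel
round-trips use lanes with actin 4000 counts-px and isoform bands summing
to 4000 at 85/15 and 35/65 splits; areas recover within 5% and inclusion
percentages within 2 points at the default noise.

## Known limitations

* Scalar per-field background only: no flat-field or illumination-profile
  correction, no spectral unmixing. Strong vignetting would bias corrected
  intensities near field corners.
* The watershed split assumes roughly convex nuclei; elongated or budding
  nuclei may over-split.
* Transfection gating assumes negative-control wells share the sample
  wells' autofluorescence distribution; a plate-position effect on
  autofluorescence would shift gates.
* Densitometry operates on 1-D lane profiles; extracting profiles from 2-D
  gel images (lane finding, tilt correction) is out of scope.
* Dose-response pairing requires a scramble control at every dose; there is
  no interpolation across doses.
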