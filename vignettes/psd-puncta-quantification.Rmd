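---
title: "Counting synaptic puncta and quantifying longitudinal synapse loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting synaptic puncta and quantifying longitudinal synapse loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdscreen)
```

## The assay

`psdscreen` implements the image-analysis core of a longitudinal high-content
synapse assay. Cultured neurons express PSD95-eGFP, which concentrates at the
postsynaptic density of excitatory synapses and appears as bright puncta, and
mCherry, which fills the cell and outlines somata and neurites. Each region of
interest (ROI) is imaged as two 10-plane z-stacks (1 µm steps, 0.15 µm/px)
before treatment (t = 0) and again at 24/48/72 h. The readout per ROI is the
percent change in the number of accepted puncta relative to its own baseline:

$$\%\Delta \mathrm{PSDs} = 100 \cdot \frac{N_t - N_{t_0}}{N_{t_0}}.$$

Each ROI is one statistical sample; the package's outputs are tables ready for
any downstream test battery.

## Image processing model

All 2-D analysis runs on the maximum-intensity projection of each channel.
The projection is the representation in which puncta counts are defined here;
per-slice analysis with 3-D merging is a different estimator and is
deliberately out of scope.

**Masking (structural channel).** Two binary masks are built by automatic
triangle thresholding of filtered images:

* a *soma mask* from a wide difference-of-Gaussians band (σ = 1 and 30 px) —
  a loose threshold that captures every bright core;
* a *process mask* from a narrow DoG band (σ = 8 and 9 px) followed by a
  negated 4-neighbour Laplacian, which responds to neurite-scale ridges and
  rejects flat bright interiors.

The final mask is `process AND NOT soma`, so somatic territory is excluded
from analysis by construction. A practical note on the mechanics: with a
background-dominated histogram the triangle threshold of the soma band lands
just above background, so thin neurite centre-lines also enter the loose soma
mask. Analysis on neurites survives because the process band extends several
pixels beyond the centre-line, while the soma is removed wholesale — the
behaviour that matters (puncta countable on neurites, never on somata) is
what the tests assert.

**Punctum enhancement (puncta channel).** A Gaussian blur (σ = 5 px)
suppresses noise, a grayscale white top-hat with a 5-px-radius square
structuring element removes background structures larger than the element,
and squaring accentuates high-intensity regions. The enhanced image is
triangle-thresholded and 8-connected components become punctum candidates.

**Object filters.** Candidates pass four criteria in fixed order, each
rejected object recording the first criterion it failed:

1. *elongation*: maximum distance of any member pixel to the object centroid
   must not exceed 10 px (exactly 10 is retained) — removes mask fragments;
2. *mask*: at least one pixel must lie in the final neurite mask;
3. *size*: 6–200 px, both bounds inclusive;
4. *local SNR*: mean object intensity over mean local background intensity,
   both measured on the **original, unprocessed** puncta projection, must be
   at least 1.2. The local background is the annulus between 1-px and 5-px
   dilations of the object, excluding pixels of any candidate; an empty
   annulus widens in 2-px steps to 11 px and then falls back to the median of
   the non-candidate masked region. SNR is computed only for survivors of the
   first three filters. A zero background yields an infinite SNR and the
   candidate is retained by this criterion.

All thresholds are configuration data (`default_config()`), not code.

## Longitudinal quantification and QC

* **ROI gate**: ROIs with fewer than 50 baseline puncta are excluded (a
  sparse denominator makes `%ΔPSDs` unstable); exactly 50 is included.
* **Plate gates** at 24 h: a plate fails if more than 50% of its ROIs had
  fewer than 50 baseline puncta; if untreated wells lost more than 10%
  (compromised culture); if the diffuse-label control (2-BP, which prevents
  PSD95 palmitoylation so labelling is diffuse) failed to lose at least 10%
  (instrument/analysis/expression failure); or if the network-activity
  control (picrotoxin + 4-AP, which drives downscaling) failed to lose at
  least 10% (no functional network). Boundaries follow the rule wording:
  mean changes of exactly −10% pass every gate. Control means are taken over
  gate-passing ROIs; vehicle wells never gate a plate.
* **Outlier removal**: within each experiment group (one treatment on one
  plate at one timepoint, configurable) the percent changes are screened by
  a robust FDR outlier test (below). Flagged ROIs are excluded at that
  timepoint and at all later ones; earlier timepoints are untouched.
* **SSMD** `(μ₁−μ₂)/√(σ₁²+σ₂²)` quantifies assay quality between groups.
* `log10(x + 101)` maps the `%Δ` domain `[−100, ∞)` to `[0, ∞)` for
  downstream tests that need variance stabilisation.

## The outlier test

The data per group are one-dimensional, so the robust-regression-and-
outlier-removal procedure specialises to a constant model: the robust fit is
the sample median. The residual scale (RSDR) is the 68.27th percentile of the
absolute residuals — the robust analogue of one standard deviation — with a
small-sample correction `sqrt(n/(n−1))` for the one fitted parameter. Each
point gets a two-tailed t tail probability on `residual/RSDR` with `n−1`
degrees of freedom, and detection steps inward from the most extreme point:
the i-th most extreme point is an outlier if its p-value is below `Q·i/n`,
stopping at the first non-significant point. Samples of fewer than 3 values
are never flagged; a zero RSDR with all values equal flags nothing, while a
zero RSDR with off-median points treats those as infinitely extreme. The
default `Q` is 10%.

## The synthetic generator

`make_scene()` renders what the filters sense, not cell biology: somata as
bright disks, neurites as jittered random-walk branches (width 3 px),
puncta as 2-D Gaussian spots (σ = 1.8 px) placed on the skeleton away from
somata, plus diffuse neurite bleed-through in the puncta channel. Intensities
are Poisson shot noise on expected photon counts plus Gaussian read noise
(σ = 3). Signal is split over three adjacent z-planes (weights 0.5/1/0.5 of
the design) so the maximum projection recovers the 2-D pattern.

Two generator choices are forced by the fixed enhancement chain and are worth
recording. First, the triangle threshold of the enhanced (squared) image
lands at roughly 1–2% of the histogram maximum, which gives enhanced blobs a
support radius of ~8.5 px; puncta closer than ~18 px (2.7 µm at this pixel
size — ordinary synapse spacing) merge and are then removed by the elongation
or size filter. The default minimum punctum separation is therefore 18 px.
Second, punctum amplitudes are lognormal (`sdlog = 0.35` around 800 photons):
a realistic brightness spread that also keeps segmented areas inside the
6–200 px window, because the scene-wide threshold scales with the brightest
punctum. Default render settings give accepted-punctum local SNRs of about
2–4, spanning the 1.2 cutoff when amplitudes are lowered.

Longitudinal behaviour is emulated by `advance_timepoint()` (Bernoulli
punctum loss, optional new puncta for synaptogenesis drift, bleaching,
fresh noise on preserved geometry) and `make_diffuse_control()`
(redistributes every punctum's integrated intensity uniformly along the
neurite, conserving total expected intensity — the diffuse-label control
phenotype). `make_plate_fixture()` writes whole plates to disk in the layout
the reader expects, with untreated wells drifting up ~5%/day and the
activity control losing ~17%, mirroring the assay's control regimes.

What passing tests on these scenes do **not** show: robustness to optical
PSF structure, focus drift, uneven illumination, autofluorescent debris, or
densely overlapping puncta — real-data failure modes the generator does not
model (debris-like outliers are exercised separately through the outlier
test's fixtures).

## Numerical choices

* Gaussian kernels truncated at 4σ and normalised; all convolutions use
  edge-replicate borders (FFT on the padded image; kernels may exceed the
  image size).
* The Laplacian is the 3×3 4-neighbour stencil, negated so bright ridges are
  positive; the positive band is thresholded (an `"absolute"` switch exists).
* Triangle thresholds use 256-bin histograms of the min–max-scaled image;
  the tail side is the longer tail from the peak (ties to the upper side);
  single-valued images return that value, i.e. an empty binary.
* Labeling is 8-connected; objects touching the border are kept.
* Problem sizes in the tests are chosen to exercise the pipeline at scale
  while staying desk-runnable: 384-px scenes with ~70 puncta for
  longitudinal runs, 768-px four-soma scenes with 200 puncta for detection
  scoring, 25–50 ROIs per designed loss fraction.

## Known limitations

* Per-ROI identity across timepoints assumes perfectly registered re-imaging;
  alignment drift appears only through the outlier test, as in the assay.
* The soma/process masks inherit the triangle threshold's sensitivity to
  histogram shape; pathological fields (e.g. a saturated full-frame soma)
  should be caught by the plate gates, not the masks.
* The outlier procedure follows the published algorithm; it is not a
  numerical clone of any proprietary implementation.
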