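---
title: "Grading lumbar disc herniation from sagittal T2 images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading lumbar disc herniation from sagittal T2 images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldhgrade)
```

## The problem and the approach

On a mid-sagittal T2-weighted image the healthy lumbar spine shows a column
of moderately bright vertebral bodies separated by bright, fluid-rich
intervertebral discs, with the bright spinal-canal band running behind them
(posterior, drawn to the image right here). A herniated disc pushes material
past the posterior margin of the vertebral column; a degenerating disc loses
water and darkens. `ldhgrade` turns those two observations into a fully
deterministic, rule-based grading pipeline:

1. **Preprocess** the image (grayscale opening, gamma brightening, fuzzy
   contrast intensification, histogram equalization) so that fixed gray
   thresholds become usable across scans.
2. **Segment vertebrae** with a band-pass threshold: vertebral bone occupies
   the mid-gray band between the two troughs of the image histogram
   (defaults 105 and 205). Morphological opening separates touching
   vertebrae; contours are screened by area (3000--6000 px), bounding-box
   aspect ratio (0.6--1.4) and perimeter (< 400 px).
3. **Localize** each vertebra: a total-least-squares line through the
   contour gives its tilt; a tilt magnitude in [0.1, 1] marks the caudal
   (sacral-side) vertebra, whose corners are taken from the contour poles
   rather than the bounding box. The **demarcation line** of each disc joins
   the posterior-inferior corner of the upper vertebra to the
   posterior-superior corner of the lower one; disc tissue posterior to this
   line is herniated material.
4. **Segment discs** with a global threshold at gray 50 plus a small
   opening, screened by area (100--2000 px) and an anti-spinous rule
   (tall, thin, posterior contours are removed).
5. **Measure five indicators** per disc: protrusion distance (maximum
   perpendicular distance of posterior disc pixels to the demarcation line),
   protrusion area, the ratio of distance to the disc's x-extent, the ratio
   of protrusion to whole-disc area, and the mean gray level.
6. **Grade** each disc by the interval table:

   | grade | distance (mm) | area (mm²) | length ratio | area ratio | mean gray |
   |---|---|---|---|---|---|
   | bulge | 1–5 | 10–100 | 0.01–0.1 | 0.01–0.1 | > 35 |
   | protrusion | 5–10 | 100–200 | 0.1–0.2 | 0.1–0.2 | 15–35 |
   | extrusion | > 10 | > 200 | > 0.2 | > 0.2 | < 15 |

   Each indicator votes for at most one grade; a grade with at least three
   of the five votes wins. Without a majority the indicators are walked in
   the fixed priority order (distance, area, length ratio, area ratio, mean
   gray) and the first one that votes decides. A disc whose protrusion part
   is absent or tiny (area < 10 mm² and distance < 1 mm) is normal.
7. **Spinal-canal continuity**: contours of the disc-stage mask whose left
   edge falls in a window 2--40 px posterior of the mean posterior vertebral
   edge are canal candidates; the canal is continuous when their union
   covers at least 80% of the column's vertical extent in one unbroken run.
   Extruded material interrupts the band. A degeneration flag (mean gray
   strictly below 20) is reported alongside the grade.

## Numerical conventions

* Images are 8-bit; every preprocessing step rounds half-to-even back to
  the integer grid and clips to [0, 255].
* Touching interval endpoints in the grade table are made disjoint with the
  half-open convention `[low, high)` for the four increasing indicators, so
  5 mm votes protrusion and 10 mm votes extrusion. Mean gray decreases with
  severity; both of its boundaries (15 and 35) are assigned to the middle
  grade, so every boundary value votes for exactly one grade.
* Pixels exactly on the demarcation line count as normal tissue (protrusion
  requires strictly positive signed distance); the degeneration comparison
  is strict (a mean gray of exactly 20 is not flagged).
* Contour features come from 8-connected components: area is the shoelace
  area of the traced outer boundary, the perimeter is its chain length, and
  the aspect ratio uses the axis-aligned bounding box (the tilted caudal
  vertebra is handled separately, so a rotated box is unnecessary).
* Corner ties are broken by first occurrence in contour order. When the
  caudal pole labelling degenerates (poles exactly on the centroid axes),
  labels fall back to the tilt sign.
* The automatic upper threshold takes the second trough of the
  Gaussian-smoothed histogram (sigma 2 bins), with a 2%-of-maximum
  prominence filter so counting ripple does not create spurious troughs;
  with fewer than two troughs the configured defaults stand.
* Structuring elements are flat "ellipses" in the usual raster sense: the
  3x3 element is the 4-connected cross, the 2x2 element a filled box
  (zero-padded internally to an odd grid so that opening is position-exact).

## Design choices where the method left room

* **Fuzzy step.** The contrast intensification is the classical fuzzy
  intensification operator with linear membership `mu = r/255`:
  `mu' = 2 mu^2` below mid-gray, `1 - 2 (1 - mu)^2` above. It widens
  mid-gray separation, which is the stated purpose; note it *contracts*
  differences near the ends of the range (saturation), so "contrast never
  decreases" holds only for mid-range populations.
* **Gamma constant.** The power law is computed on intensities normalized
  to [0, 1] with a multiplicative constant `c` (default 1); `c = 0` would
  null the image, so it is not a valid offset.
* **Corner rule.** Upright vertebra corners are the contour points nearest
  each bounding-box corner. The alternative reading — the contour point
  farthest from each corner of the picture, which selects the diagonally
  opposite vertebra corner — is available as `corner_mode = "farthest"`.
* **Tie-break order and weights.** A per-indicator weight of 0.25 cannot
  distribute over five indicators; the implemented decision procedure is
  the operational one: majority of at least three votes, then the printed
  priority order. The priority tie-break makes the classifier *not*
  monotone in severity: `(0.9, 150, 0.15, 0.15, 40)` grades protrusion by
  majority, while the strictly more severe `(1.0, 210, 0.21, 0.16, 40)`
  splits the votes 2/2/1 and the distance vote (bulge) decides. This is a
  property of the rule set itself and is pinned by a regression test.
* **Disc polarity.** "Pixels above gray 50 become black" is read as the
  background (below 50) going black — the only reading under which bright
  T2 discs separate from the background.
* **Caudal discs.** The disc adjacent to the caudal vertebra is detected
  and reported but labelled `ungraded`: tail discs are excluded from
  grading and from recognition counts.

## The phantom: what it emulates and what it does not

`generate_phantom()` renders a 448 x 700 px, 0.5 mm/px mid-sagittal scene:
five upright vertebral bodies (70 x 55 px) plus a tilted caudal one, bright
lens-shaped discs in the gaps, a posterior canal band (optionally
interrupted by a 20% gap), smooth background texture, and optional additive
Gaussian noise, clipped to [0, 255]. Ground truth is exact: per-structure
masks, the true demarcation lines, and per-disc indicator vectors computed
on the noiseless render (so a disc's true mean gray equals its spec
intensity exactly). The true grade of a disc is *defined* as the
classifier's output on its true indicator vector.

Herniations are half-elliptical bumps attached to the disc's posterior edge
at the demarcation line. Distance and area are independently controllable:
the bump's x-extent sets the distance (quantized to the pixel grid, so the
rendered apex lands exactly at the requested distance), and its height is
solved numerically so the rasterized pixel count matches the requested area
(typically within 1–2%). The bump keeps a 2-px minimum thickness so its
apex survives small openings, and must fit strictly inside the
inter-vertebral gap — at the disc threshold everything bright is foreground,
and a bump touching a vertebra would merge with it. `generate_phantom()`
rejects specs whose shapes would overlap, touch across a gap, or leave the
canvas.

The geometry is sized so every rendered structure falls inside the default
screening ranges at 0.5 mm/px, which fixes two tensions in the published
thresholds themselves: disc areas above 500 mm² cannot pass a 2000 px area
ceiling at this resolution, so the phantom's disc bodies are ~210 mm² and
grade-scale bump areas ride on top; and a disc darker than gray 50 — the
extrusion row of the grade table wants mean gray < 15 — is invisible to the
disc threshold, so the recovery batches render extrusion discs at gray
62–80 ("degenerating" but detectable) and let the four geometric indicators
carry the extrusion majority. Deep degeneration (< 20) and the gray-vote
pathway are exercised by classifier tests and by explicit dark-disc
phantoms whose ground truth is read from masks rather than detection.

Default study conditions (`random_phantom_spec()`): six vertebrae; the four
graded discs drawn uniformly from the four grades; bulge bumps 2–4.5 mm and
20–60 mm², protrusion 5.5–9 mm and 110–190 mm², extrusion 10.5–13.5 mm and
210–240 mm² (areas additionally capped by the bump capacity of the gap);
caudal tilt 12–22 degrees; vertebra gray 140–160; bright discs 208–223.
The phantom emulates geometry and contrast, not MRI physics: no bias
fields, no Rician noise floor, no partial-volume fading, no anatomical
shape variation, no neighbouring soft-tissue structures that mimic discs.
Passing its recovery tests shows the chain of rules measures what it
defines, under the stated conditions — not that the thresholds transfer to
clinical scans.

### The phantom evaluation protocol

`phantom_pipeline_config()` grades phantoms with the enhancement chain
(gamma, fuzzy, equalization), the grayscale opening, the vertebra-stage
adhesion breaking and the disc-stage opening switched off. The phantom's
intensities are calibrated and its Gaussian noise leaves every threshold at
least two standard deviations from the nearest tissue mean, so these
cleanup steps have nothing to clean; what they would do is bias the
pixel-exact landmarks the recovery experiments measure — grayscale opening
clips the one-pixel bump apex, corner erosion shifts the demarcation line,
and the 2x2 opening shaves single-pixel steps off the bump silhouette
(up to ~5% of a small bulge's area). Each disabled step has its own unit
tests on fixtures built to need it: salt noise for the opening, adhered
squares for the erosion stage, compressed ramps for the equalization.
Sharp vertebra corners (corner radius 0) are the default for the same
reason: corner landmarks define the demarcation line, and rounding them
biases every distance measurement by the rounding radius; rounded
vertebrae remain available through `corner_radius_px`.

## Problem sizes used by the test-suite and the acceptance script

The recovery experiments run 50 noiseless and 50 noisy (sigma 10) phantoms
in the test-suite and 30 + 30 in the acceptance script; classifier-oracle
agreement uses 10,000 random indicator vectors with boundary values mixed
in; mask-invariant checks render 100 random specs. At 448 x 700 px a full
pipeline run takes well under a second, so the whole suite completes in a
few minutes on one CPU.

## Known limitations

* The pipeline is resolution-bound: every pixel-denominated screening
  threshold assumes ~0.5 mm/px sagittal images; other resolutions require
  rescaling the config, not just the pixel spacing.
* The classifier is not monotone in severity (see above) — an inherent
  property of the priority tie-break.
* Degeneration below the disc-segmentation threshold is a blind spot of
  the thresholding design: a disc dark enough to satisfy the extrusion
  gray range (< 15) cannot be found by a 50-gray global threshold.
* Single mid-sagittal slices only; no multi-slice/3-D reasoning, no
  anatomical level naming (L1..S1), and no DICOM input — readers accept
  8-bit grayscale PNG (spacing from the fixture manifest or config).
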