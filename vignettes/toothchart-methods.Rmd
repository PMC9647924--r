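---
title: "Methods: tooth numbering, FMS layout and bone-loss staging in toothchart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tooth numbering, FMS layout and bone-loss staging in toothchart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothchart)
```

`toothchart` charts dental radiographs that come with segmentation masks:
it extracts individual teeth, assigns FDI numbers by template matching,
arranges intraoral radiographs into the full-mouth-series (FMS) template,
and stages radiographic bone loss (RBL). This vignette explains the
procedures, their assumptions, the parameters that matter, and the design
choices that were genuinely open.

## Coordinates and containers

Everything uses one convention: origin at the top-left pixel, x right,
y down, 0-based, boxes half-open `[x0, x1) × [y0, y1)`. Images and masks
are plain R matrices `m[row, col]` with intensities in `[0, 1]`; masks are
strictly 0/1 after cleaning.

## Mask postprocessing

Segmentation models emit soft, speckled masks. `clean_mask()` smooths a
soft raster with a Gaussian (`sigma`, default 1 px at the 512 × 512 working
resolution), binarizes at `threshold` (default 0.5) and drops 8-connected
components below `min_area` (default 50 px — small enough to keep thin
roots, large enough to kill speckle; scale it with image area at other
resolutions). A strictly binary input skips the blur: blurring a decision
raster would only erode curved boundaries by ~1 px per application, and
skipping it makes the operator exactly idempotent — a property the test
suite checks, and one that matters when cleaned masks are re-fed through
the pipeline.

The CEJ (cementoenamel junction) is predicted as disconnected fragments,
one per tooth. `connect_cej()` slides a window (default 8 columns) across
the image, takes the pixel centroid per window as a knot, linearly bridges
empty stretches up to `gap_factor` (default 3) windows wide, and
interpolates one point per column. Longer gaps split the line; the longest
segment is kept with a warning. The CEJ is assumed near-horizontal
(|slope| ≤ 1), which is what keeps consecutive polyline points 8-connected;
steeply rotated radiographs violate the assumption and are out of scope.
Bitewings have two CEJ branches; `connect_cej_pair()` splits the mask at
the widest row gap and connects each half.

Contours are traced with Moore-neighbour border following on 8-connected
components (compiled code; EBImage's labeling is 4-connected, which merges
fewer diagonal touches than border-following conventions expect, so the
package carries its own labeling).

## Tooth extraction

On panoramics a tooth box is simply its component's contour extent. On
intraoral images the box follows a four-point rule: the mesial and distal
crossings of the tooth outline with the CEJ polyline (the extreme-x contour
points within `tol` = 3 rows of the polyline — the tolerance absorbs raster
quantization) plus the root apex, the rootward extreme of the component
(minimum y for maxillae, maximum for mandibles, both per half for
bitewings, which are split at the midline between the two CEJ branches).
The box is padded by `pad` = 2 px. Components that never cross the CEJ are
skipped with a warning and count as missed detections. Two teeth merged
into one mask component produce one box: components are never split, a
documented limitation.

## FDI numbering by multi-scale matching

Each extracted crop is compared with every entry of a reference set:

* **repository mode** — a persistent, FDI-labeled collection of tooth
  crops built from annotated panoramics (`build_repository()`); several
  exemplars per FDI number are allowed and useful;
* **panoramic-view mode** — when the patient's own panoramic is available,
  its extracted teeth form a transient repository labeled purely by arch
  order: rows are separated at the largest vertical gap between box
  centers, each row is walked left to right along the FDI sequence
  (18…11, 21…28 above; 48…41, 31…38 below), and an inter-box gap wider
  than 1.5 × the median gap advances the slot counter by the estimated
  number of missing teeth. Leading/trailing missing teeth (e.g. an absent
  third molar at the arch end) cannot be detected this way — a known
  limitation of arch-order labeling.

The similarity is the maximum **zero-normalized cross-correlation** of the
crop slid over the entry, after both patches are histogram-equalized
(rank-based; intraoral and panoramic exposures differ, and equalization
makes the score invariant to any monotone intensity change, not just
affine). The crop is resized over a scale grid and the best score over the
grid is kept per entry. Entries are ranked and the top `k` = 10 vote with
their labels; ties are broken by the larger mean score among tied labels,
then the single best score, then the smaller FDI number, making the
assignment deterministic and invariant to repository order.

The scale grid defaults to 0.5–1.5 in steps of 0.05. A coarser 0.1 step
was considered and rejected: its worst-case scale quantization of 5 %
drifts a textured root by several pixels across its length, which
decorrelates high-frequency patterns and measurably costs accuracy when
only one exemplar per tooth exists (panoramic-view mode). Both grid and
`k` are exposed in the configuration.

Degenerate (constant) patches have no defined correlation; their score is
0 with a warning rather than an error, so one blank crop cannot abort a
batch.

## Radiograph position and FMS arrangement

`detect_position()` applies the rules in order: (a) two bone-area
components (≥ `min_area`, default 200 px) whose centroid rows differ by at
least 20 % of image height → bitewing — the separation requirement stops a
horizontally split bone band from masquerading as two arches; otherwise
(b) bone centroid above the CEJ mean row → maxilla, (c) below → mandible.

`arrange_fms()` routes radiographs by position into the top (maxillary),
middle (bitewing) and bottom (mandibular) rows. Within a row, slots are
ordered patient-right → patient-left. The ordering key is the mean of an
arch coordinate derived from universal numbers: universal 1–16 already
runs patient-right to left along the maxilla, but the sequence snakes back
along the mandible (17 starts lower-left), so mandibular numbers are
reflected (`49 − u`). The mean (rather than, say, the minimum) keeps a
partially mis-numbered radiograph near its true slot. Radiographs with no
assignments land in an explicit `unplaced` list; overlapping tooth
coverage within a row is kept and flagged, never silently dropped.

## Radiographic bone loss and staging

Per tooth side, three landmarks are read off the masks: the CEJ point (the
polyline at the mesial/distal box edge), the root apex (the rootward
contour extreme), and the alveolar crest — the first bone-mask pixel met
when walking the CEJ→apex segment in quarter-pixel steps (the step bounds
the localization error at a fraction of a pixel; with roots ~50–75 px long
that is well under one RBL percentage point). Then

RBL = 100 × (CEJ→crest distance projected on the CEJ→apex axis) / (CEJ→apex distance),

clipped to [0, 100]. Stages follow the 2018 periodontitis classification:
Stage 1 below 15 %, Stage 2 from 15 to 33 inclusive, Stage 3 above 33.
The three intervals partition [0, 100] exactly; the boundaries are tested
at machine-epsilon offsets. Records are emitted per side (mesial/distal);
landmark provenance is checked against the assignment's crop so records
cannot silently mix teeth.

## Evaluation metrics

Dice and Jaccard are defined 1.0 for two empty masks (agreement about
absence). Box IoU is closed-form and equals the rasterized Jaccard — a
property the tests verify on random boxes. Detection evaluation pairs
predicted and gold boxes greedily by descending IoU, one-to-one; a pair is
a successful match only if its IoU strictly exceeds 0.7. Ratios with zero
denominators are reported as `NA`, deliberately distinct from 0: zero
predictions have recall 0 but *undefined* precision. Sensitivity is
TP/(TP+FN) and specificity TN/(TN+FP) in one-vs-rest reduction.

## The phantom generator

The generator renders radiograph-like cases so that every stage has a
seeded, annotated test bed. Each tooth position in the arch (1–8) has its
own glyph drawn from four shape families — incisor, canine, premolar,
molar — parameterized by crown width and height, root length, a lateral
apex drift, root count (two roots for molars and, narrower and more
apical, for first premolars), crown notching, and a two-frequency cosine
intensity texture. All parameters vary with the position index so that
every position is discriminable under the matching score, not just the
family; a seed drives mild (±3 %) within-class variation. Left-quadrant
glyphs are exact horizontal mirrors of right-quadrant ones; maxillary
glyphs are vertical flips of mandibular ones (roots point away from the
occlusal plane).

A case comprises one panoramic (teeth at 0.75 × the intraoral scale, two
arches), 14 periapicals (seven per arch, the standard molar / premolar /
canine / incisor blocks) and 4 bitewings, at 512 × 512. Maxillary
periapicals place the bone band above the CEJ, mandibular below, bitewings
two bands flanking a double CEJ. Background is 0, bone mid-gray (0.4),
teeth bright (≥ 0.55); the CEJ exists only in its gold mask, mirroring
that it is an annotation, not a visible edge. The bone crest sits at
`bone_level_fraction` × root length from the CEJ (default 0.10 — below the
Stage-1 threshold, so default phantoms are healthy). Configurable missing
teeth leave their gap in the arch; `scale_jitter` and `position_jitter`
perturb individual teeth; images are quantized to 8 bits at generation so
PNG round trips are lossless, and generation is bit-identical under a
fixed seed.

What the phantom does **not** emulate: photorealistic anatomy and texture,
overlapping/crowded teeth, restorations and implants, caries, rotation or
projection distortion, and soft (probabilistic) segmentation errors — its
gold masks are clean. Passing phantom tests therefore demonstrates the
correctness of the geometry, matching, layout and measurement machinery
under controlled variation, not clinical performance on real radiographs.

## Problem sizes in the test suite

The suite exercises: metric oracles on 200 random instances each;
numbering on four seeded cases (128 periapical teeth) against a repository
from three phantom panoramics (96 entries), without jitter and at 10 %
scale jitter; RBL recovery on two cases with per-tooth fractions drawn in
[0.05, 0.6] (> 50 tooth sides); position detection on 100 intraoral
images across six cases; and two full pipeline reruns compared byte for
byte. These sizes keep the default run in the low minutes on one CPU while
covering every FDI position in every condition.

## Known limitations

* Merged mask components are not split; crowded dentition loses teeth.
* Arch-order labeling cannot see missing teeth at the arch ends.
* Upside-down or mirrored radiographs are not recognized.
* The CEJ reconstruction assumes a near-horizontal line per arch.
* Staging uses the RBL rule only; no learned classifier is involved.
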