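# toothchart

Automated dental charting from segmentation masks of panoramic, periapical
and bitewing radiographs.

Clinicians chart which tooth is which (tooth *numbering*), where each
intraoral radiograph belongs in a full-mouth series (FMS), and how much
alveolar bone each tooth has lost. `toothchart` automates this chain for
radiographs that already have tooth / bone-area / cementoenamel-junction
(CEJ) segmentation masks — whether those come from a trained segmentation
network (plugged in through the pipeline's segmentation hook) or from the
package's built-in phantom generator, which renders radiograph-like images
with gold-standard annotations so the whole pipeline can be exercised and
scored without clinical data.

## What it does

1. **Mask postprocessing** — Gaussian denoising of soft masks, binarization,
   small-component removal (`clean_mask()`); border-following contour
   extraction (`extract_contours()`); sliding-window reconnection of the
   fragmented CEJ line into a single polyline (`connect_cej()`).
2. **Tooth extraction** — per-tooth bounding boxes: contour extents on
   panoramics (`boxes_from_panoramic()`); on intraoral images the four-point
   rule — mesial and distal tooth–CEJ intersection points plus the root
   apex/apexes (`boxes_from_intraoral()`), then pixel-exact crops
   (`crop_teeth()`).
3. **FDI numbering** — multi-scale template matching: each crop is
   histogram-equalized, resized over a scale grid (default 0.5–1.5, step
   0.05) and slid over every reference crop; the similarity is the maximum
   zero-normalized cross-correlation

   `ZNCC(t, w) = Σ (t − t̄)(w − w̄) / √(Σ(t − t̄)² · Σ(w − w̄)²) ∈ [−1, 1]`,

   and the **top-10 scores vote** on the FDI number (`assign_number()`).
   The reference is either a persistent FDI-labeled tooth repository
   (`build_repository()`), or the patient's own panoramic, whose extracted
   teeth are labeled transiently by arch order with missing-tooth gap
   detection (`assign_numbers_via_panoramic()`).
4. **FMS layout** — radiograph position from bone/CEJ geometry (two bone
   bands → bitewing; bone above the CEJ → maxilla; below → mandible;
   `detect_position()`), then arrangement into the 3-row FMS template, rows
   ordered patient-right → patient-left (`arrange_fms()`).
5. **Periodontal staging** — radiographic bone loss
   `RBL = 100 × d(CEJ, crest) / d(CEJ, apex)` per tooth side
   (`compute_rbl()`), staged by the 2018 classification: Stage 1 < 15 %,
   Stage 2 15–33 %, Stage 3 > 33 % (`assign_stage()`).
6. **Evaluation** — Dice and Jaccard for masks, closed-form box IoU, the
   JI > 0.7 successful-match rule with detection/numbering precision and
   recall, numbering and position accuracy, one-vs-rest
   sensitivity/specificity (`evaluate_detection()` and friends).

## Worked example

```r
library(toothchart)

# A synthetic patient with moderate bone loss everywhere
case <- generate_phantom_case(phantom_config(seed = 42, bone_level_fraction = 0.25))
#> phantom_case: 14 periapicals, 4 bitewings, 32/32 teeth present (seed 42)

# Extract the upper-right molar block periapical
pa   <- case$periapicals[[1]]
cej  <- connect_cej(pa$cej_mask)
boxes <- boxes_from_intraoral(pa$tooth_mask, cej, position = "maxilla")
boxes
#>    x0  y0  x1  y1 component    arch apex_x apex_y source_kind
#> 1 181 207 220 259         1 maxilla    198    209  periapical
#> 2 229 203 274 259         2 maxilla    231    205  periapical
#> 3 284 199 331 259         3 maxilla    304    201  periapical

# Number the first tooth against a repository built from a labeled panoramic
crops <- crop_teeth(pa$image, boxes, provenance = pa$id)
repo  <- build_repository(list(list(image = case$panoramic$image,
                                    annotations = case$panoramic$teeth,
                                    source_id = "pan42")))
a <- assign_number(crops[[1]], repo)
a
#> fdi_assignment: 18 (repository mode, 1/10 votes, best score 0.574)

# Bone-loss record for that tooth
bone <- clean_mask(pa$bone_mask)
lm   <- landmarks_from_masks(boxes[1, ], cej, bone, provenance = pa$id)
tooth_report(a, lm)
#>   fdi   side rbl_percent stage
#> 1  18 mesial    24.50981     2
```

The tooth is identified as FDI 18 (upper-right third molar, universal
number 1); its measured bone loss of 24.5 % recovers the generated 25 %
fraction and lands in Stage 2 (15 % ≤ RBL ≤ 33 %).

`run_pipeline()` runs the same chain over a whole case directory and writes
`assignments.json`, `fms_template.json` (+ a montage PNG), `rbl_report.csv`
and `evaluation.json`. A command-line wrapper lives in
`inst/cli/toothchart.R`:

```sh
Rscript inst/cli/toothchart.R simulate --seed 3 --out case3 --missing 36
Rscript inst/cli/toothchart.R chart --in case3 --out run3 --mode panoramic_view
```

## Scope

The package implements the charting framework around segmentation, not the
segmentation networks themselves: tooth/bone/CEJ masks are inputs (the
phantom's gold masks stand in during testing). Caries detection is likewise
out of scope, though the report schema reserves a slot for an external
detector. Incorrectly oriented (upside-down or mirrored) radiographs are
not handled.
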