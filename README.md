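# podrot

Machine-vision severity grading of peanut pod rot from RGB images.

Pod rot is a soil-borne fungal disease complex that rots peanut pods in the
ground; resistance breeding needs per-plant severity grades, which are
conventionally assigned by hand-counting rotten pods. `podrot` implements a
complete detect-and-grade pipeline for this task in R:

* a compact **YOLOv5s-style one-stage detector** for two pod classes —
  `G` (non-rotted) and `R` (rotten) — with **Shuffle Attention (SA)** blocks
  inserted after every backbone C3 stage and **EIoU** bounding-box
  regression replacing CIoU, trained and run entirely on CPU at reduced
  scale;
* a **grade-classification module** that turns per-image counts into the
  rotten pod rate and a five-level ordinal grade;
* detection **evaluation statistics** (precision, recall, AP / mAP@0.5,
  image-level comparison precision, k-fold splits);
* Pascal VOC XML / YOLO txt **annotation I/O** with the seven standard
  augmentation primitives; and
* a **synthetic scene generator** that draws pod clusters under three
  adhesion (overlap) conditions with exact ground truth, so the whole
  pipeline is testable end to end on one CPU.

## The statistics at the core

For a predicted box $b$ and ground-truth box $b^{gt}$ with widths/heights
$w, h, w^{gt}, h^{gt}$, minimum enclosing box of width $c_w$, height $c_h$
and diagonal $c$:

$$\mathrm{CIoU} = 1 - \mathrm{IoU} + \frac{\rho^2(b, b^{gt})}{c^2} + \alpha v,
\qquad v = \frac{4}{\pi^2}\Big(\arctan\frac{w^{gt}}{h^{gt}} - \arctan\frac{w}{h}\Big)^2$$

with $\alpha = 0$ when $\mathrm{IoU} < 0.5$ and $\alpha = v/(1-\mathrm{IoU}+v)$
otherwise. EIoU replaces the aspect-ratio surrogate with the true size
differences:

$$\mathrm{EIoU} = 1 - \mathrm{IoU} + \frac{\rho^2(b, b^{gt})}{c^2}
 + \frac{(w - w^{gt})^2}{c_w^2} + \frac{(h - h^{gt})^2}{c_h^2}.$$

The total training loss is the plain sum
$L = L_{cla} + L_{loc} + L_{conf}$.

Grading uses the rotten pod rate
$r = N_R / (N_G + N_R)$ mapped to levels
$1$ ($r = 0$), $3$ ($0 < r \le 0.10$), $5$ ($0.10 < r \le 0.25$),
$7$ ($0.25 < r \le 0.50$), $9$ ($r > 0.50$).

Image-level accuracy is the comparison precision
$\mathrm{CP} = 100 \cdot AS/RS$, where $AS$ counts images on which every pod
of both classes is detected exactly once and $RS$ the images evaluated.

## Worked example

```r
library(podrot)

# a synthetic plant image: 12 pods, 25% rotten, slight adhesion
scene <- generateScene(sceneSpec(nPods = 12, rottenFraction = 0.25,
                                 adhesion = "slight", seed = 5))
scene
#> AnnotatedImage 'scene_slight_seed5': 320 x 320 px, 12 boxes (G: 9, R: 3)

# grade it from its ground-truth boxes (perfect-detector oracle)
groundTruthGrading(list(scene))[, c("n_nonrotted", "n_rotten", "rate", "grade")]
#>   n_nonrotted n_rotten rate grade
#> 1           9        3 0.25     5

# rate 0.25 sits on the right-closed knot of the (0.10, 0.25] interval,
# hence Level 5 of the {1,3,5,7,9} scale.

# image-level comparison precision from tallies of fully-correct images
comparisonPrecision(142, 150)
#> [1] 94.67

# build the attention-augmented detector and train at smoke scale
scenes <- lapply(1:80, function(i) generateScene(
  sceneSpec(nPods = 8, rottenFraction = 0.3,
            adhesion = c("none", "slight", "severe")[(i %% 3) + 1],
            seed = 1000 + i)))
spec <- insertSAAfterC3(yoloArchSpec("tiny"), groups = 4)
det  <- buildDetector(spec, seed = 1)
det
#> podrot detector ('tiny-ES'): 80 nodes, 423983 parameters, input 320
fit  <- fitDetector(det, scenes, epochs = 12, batchSize = 4, lr = 0.003)
dets <- predictDetections(fit$detector, scene, confThresh = 0.25)
recordFromDetections(sourceId(scene), dets)
```

On 80 such scenes (72 train / 8 held out) the tiny ES variant reaches a
held-out mAP@0.5 in the 60–90% range after 12 epochs (~4 min on one CPU
core; 92.4% at seed 1, 63.5% at seed 42), against 0% for the untrained
network; the full-scale
configuration (`defaultRunConfig()`: 640 px, 200 epochs, batch 32,
lr 0.01) is provided but is not a desk-scale computation.

Command-style wrappers (`cmdGenerate`, `cmdTrain`, `cmdDetectAndGrade`,
`cmdEval`, `cmdAblate`) wire the modules into the
generate → train → detect → grade → eval → ablate workflow; a thin shell
entry point lives at `inst/scripts/podrot.R`. `cmdDetectAndGrade` writes
per-image count files plus the aggregate grading table as CSV and XLSX
(columns: image id, non-rotted count, rotten count, total, rate, grade).

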