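# gocao

Registration of visible / thermal-infrared image pairs of animal bodies
taken by co-mounted camera units (FLIR C2 class: 640 x 480 visible next to
80 x 60 infrared). The two channels differ by an 8x resolution ratio,
reversed contrast, heavy thermal blur, and whatever the barn lighting does
to the visible frame — so the package registers them through the one thing
they share, the geometry of body contours. It is written for people
building multi-modal livestock-monitoring pipelines (image fusion,
shape/temperature feature extraction) who need the visible and infrared
frames in one coordinate system, with metrics and synthetic ground truth to
prove it.

## Method

Contour feature maps are built with an even-symmetric Gabor bank,

```
G(x,y) = γ/(2πσ²) · exp(−(x_θ² + γ²y_θ²)/(2σ²)) · cos(2πf·x_θ),
F = I ⊗ G  (signed max over 8 orientations × 3 scales),
S = F ⊗ Ordinal   (zero-sum centre–surround filter)
```

Contour chains are extracted from `|S|`, corner keypoints are detected by
curvature-scale-space analysis, and each keypoint's **main orientation** is
the angular bisector of its two contour arms,

```
v = min(‖L‖,‖R‖) · (L/‖L‖ + R/‖R‖),    O = atan2-style angle of v in [0, 2π)
```

Modified-SIFT descriptors (gradient orientations folded mod π — invariant
to the visible/infrared contrast reversal) are matched bilaterally (mutual
nearest neighbours under a rig-prior search radius), a similarity transform
is estimated by RANSAC, and the registration is refined to sub-pixel
accuracy by normal-constrained |ZNCC| correlation on the intensity images
(rough-to-fine). Evaluation implements the standard suite: RMSE between
registered and reference points, precision/recall under the 5-px
correct-match rule, confusion-matrix accuracy, and the 5-degree
orientation-agreement count.

## Worked example

```r
library(gocao)

spec <- scene_pair_spec(seed = 1, illumination_level = 2)  # dim lighting
pair <- generate_pair(spec)           # 640x480 visible, 80x60 infrared
res  <- register_pair(pair$visible, pair$ir, truth = pair$truth)
print(res)
```

```
<registration_result>
<similarity: s = 8.39894, phi = 0.0499 rad (2.86 deg), t = (9.853, 0.356)>
  resolution ratio: 8.000
  corners 9/12, dense 290/307, bilateral 14, rough 7, fine 290
  refinement: 4.836 -> 1.196 px
<metrics: RMSE 0.559 px | precision 1.000 | recall 0.024 | 290 matches>
```

The generator planted `s = 8.4, phi = 0.05 rad` (an 8x resolution ratio
times a 1.05 scale): the recovered transform matches it to 0.01% in scale
and 0.006 degrees in rotation. The line of counts tells the pipeline's
story: 9 and 12 CSS corners plus ~300 dense contour keypoints per image, 14
bilateral descriptor matches of which RANSAC keeps 7, and 290 fine
correspondences after the normal-constrained refinement, which here pulled
the mean normal residual from 4.8 px down to 1.2 px. The final metrics line
reads: 0.56 px root-mean-square error on the ground-truth control points,
every fine correspondence within the 5-px correct-match radius (precision
1.0), and a recall of 0.024 — the bilateral stage is deliberately
conservative, keeping only 7 of ~200 possible keypoint correspondences,
because the fine stage rebuilds density afterwards.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/gocao.R", package = "gocao"))')
Rscript $CLI synth --seed 5 --level 2 --out pairdir
Rscript $CLI register pairdir/vis.png pairdir/ir.png \
        --out outdir --truth pairdir/truth.tsv --save-overlay
Rscript $CLI eval --matches outdir/matches.tsv --truth pairdir/truth.tsv \
        --out report.json
Rscript $CLI orient-compare --seed 4 --level 1
```

`register` writes `transform.json`, `matches.tsv` and an overlay PNG (green
inlier lines, purple rejects); `orient-compare` contrasts keypoint counts
and orientation agreement between the Gabor-ordinal maps and raw images.

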