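---
title: "Contour-based registration of visible and infrared animal-body images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contour-based registration of visible and infrared animal-body images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gocao)
```

## The problem

Co-mounted visible/thermal camera units (FLIR C2 class) deliver a 640 x 480
visible frame and an 80 x 60 infrared frame of the same scene. For livestock
monitoring the two must be fused, so they must first be registered — but the
two modalities differ in resolution by a factor of eight, in spectral
response (thermal contrast is typically *reversed* relative to visible
contrast), in sharpness (the thermal channel is strongly diffused), and the
visible channel additionally varies with barn illumination. Intensity-based
registration fails across such a gap; what the two modalities do share is
the *geometry of body contours*. This package registers the pair through
that shared geometry and provides ground-truthed synthetic pairs and the
standard metrics so that the whole pipeline is testable end to end.

## The pipeline

`register_pair()` runs seven stages. Throughout, images are matrices with
0-based pixel coordinates (x = column, y = row, origin top-left) and angles
are measured counter-clockwise from +x with +y pointing down.

**1. Resolution equalization.** The IR frame is bilinearly upsampled to the
visible grid. With ratio $k$ and pixel centres at integers, upsampled pixel
$p$ corresponds to native IR coordinate $(p - c)/k$, $c = (k-1)/2$; the
reported transform maps native IR coordinates to visible coordinates with
this factored in. The half-pixel rim outside the source grid replicates the
edge, because a constant fill would paint a spurious frame contour.

**2. Contour feature maps.** An even-symmetric Gabor bank
$$G(x,y) = \frac{\gamma}{2\pi\sigma^2}
  \exp\!\Big(-\frac{x_\theta^2 + \gamma^2 y_\theta^2}{2\sigma^2}\Big)
  \cos(2\pi f x_\theta), \qquad
  x_\theta = x\cos\theta + y\sin\theta,\;
  y_\theta = -x\sin\theta + y\cos\theta$$
is applied at 8 orientations and 3 scales ($\sigma \in \{2, 4, 8\}$ px,
$f = 0.75/\sigma$, $\gamma = 0.5$), and the bank is reduced by signed
maximum magnitude into one map $F$. The frequency–scale product
$f\sigma = 0.75$ keeps the filter's DC gain negligible (about $10^{-5}$
after discretization with the support covering $3\sigma/\gamma$), so an
illumination offset produces no response; at the more common
$f = 1/(2\sigma)$ the DC gain is $\exp(-\pi^2/2) \approx 7\times10^{-3}$
and flat regions leak through. $F$ is then convolved with a zero-sum
ordinal (centre–surround) filter — a unit-mass positive centre Gaussian
minus a balanced negative surround realized as four Gaussians at offset
$\omega = 2$ px — producing $S$. Each lobe is normalized to unit *discrete*
mass so the balance is exact rather than accurate only to the truncated
Gaussian tails. Feature maps are normalized by their maximum absolute value
(not min–max): a min–max rescale would shift the zero level of the
band-pass response and flat background would acquire spurious magnitude.

**3. Contour extraction.** An even band-pass filter answers a step edge
with an antisymmetric $\pm$ double ridge whose zero crossing sits on the
edge; $|S|$ is therefore smoothed with a small Gaussian (1.5 px) to merge
the two humps into a single band centred on the contour before
thresholding. The binarization threshold is the 90th percentile of the
smoothed $|S|$, floored at 0.2 of its maximum — a pure percentile keeps a
fixed 10% of pixels regardless of how sparse the true contours are and
floods large frames with texture. The band is morphologically closed (3 px)
to bridge the response dips at sharp corners, thinned to a one-pixel
skeleton (Zhang–Suen), spur-pruned, and traced into ordered 8-connected
chains. Chains whose mean response falls below 0.35 of the strongest
chain's are dropped: the filter flanks every true ridge with side lobes at
roughly 0.4 of its amplitude, and this relative cut removes their skeletons
while keeping genuinely weaker object contours.

**4. Keypoints and main orientations.** Corner keypoints are curvature
maxima of the Gaussian-smoothed chains (scales 3, 6, 9 steps; the finest
scale stays above the raster-aliasing ripple of diagonal edges), detected
at the coarsest scale, required to persist at the finer ones, localized to
sub-step precision by parabolic interpolation, and thinned by non-maximum
suppression. Each corner's main orientation is the angular bisector of its
two contour arms,
$$v = \min(\lVert L\rVert, \lVert R\rVert)
      \left(\frac{L}{\lVert L\rVert} + \frac{R}{\lVert R\rVert}\right),$$
mapped to $[0, 2\pi)$ by the quadrant-resolved arctangent. The arms are
estimated as *standoff chords*: the chord from 8 to 24 chain steps away on
each side of the vertex. Skipping the first 8 steps keeps the rasterized
corner apex — whose staircase shape depends on the corner's angle to the
pixel grid — out of the direction estimate; with plain vertex-anchored arms
the orientations wobbled by up to 15 degrees under a 30-degree scene
rotation, with standoff chords they reproduce to better than 3 degrees.
Anti-parallel-arm (straight-line) candidates are degenerate and dropped.
In addition to corners, every 4th chain point becomes a *dense* keypoint
whose bisector is the local contour normal; these carry the correspondence
load for matching, because corner detections do not repeat reliably across
an eight-fold blur gap while the chains themselves coincide to a pixel
or two.

**5. Descriptors and bilateral matching.** Descriptors are 4 x 4 x 8
gradient-orientation histograms with angles folded modulo $\pi$ — the
16-to-8-bin reduction that makes a descriptor blind to the contrast
reversal between spectra — magnitude-normalized, trilinearly interpolated,
clamped at 0.2 and renormalized to unit length. They are computed not on
$S$ itself but on the smoothed contour-energy map
$\mathrm{gblur}(\lvert S\rvert, 5)$: at true correspondences the *signed*
maps of the two modalities are essentially uncorrelated (which kernel of
the bank wins, and with what sign, is spectrum-specific), while the
smoothed energy correlates strongly. Patches are matched *upright* by
default (`descriptors$align = FALSE`): a fixed rig leaves only a few
degrees of true rotation between the frames, far less than the noise of
per-point normal estimates, and rotating each patch into its noisy frame
decorrelated otherwise-matching descriptors. Set `align = TRUE` when the
rotation between inputs is genuinely unknown. Matching keeps mutual
nearest neighbours whose nearest/second-nearest ratio passes 0.95, with
candidates restricted to a 100 px spatial neighbourhood (guided matching —
again the rig prior). Multi-scale descriptors (radii 16, 24, 32 px) are
computed on the visible side, one radius (24 px) on the blurred IR side.

**6. Rough transform.** RANSAC over two-match samples fits the closed-form
similarity, counts inliers at 4 px, and refits by least squares on the best
consensus. Hypotheses violating the rig prior (scale outside
$[1/1.3, 1.3]$ in the equalized frame, rotation above 0.26 rad, translation
above 150 px, sample separation below 20 px) are discarded before voting so
that small spurious consensus sets cannot out-vote the true one. The
`ransac_similarity()` function itself defaults to *no* gating — the prior
enters only through the pipeline configuration — and is deterministic given
its seed.

**7. Fine refinement.** For every dense IR keypoint the IR intensity patch
around its projected location is compared by absolute zero-normalized
cross-correlation against visible patches shifted *along the keypoint's
contour normal*; the location is renewed to the (sub-pixel, parabolic)
correlation peak when $|\mathrm{ZNCC}| \ge 0.6$, and the transform is refit
from the resulting point-to-normal-line constraints with residual trimming,
iterating with a shrinking search window (10, 6, 4, 3 px). Three choices
matter here, each forced by measurement on synthetic pairs. First, the
correlation runs on the *intensity* images, not the feature maps: feature
maps carry the Gabor side-lobe pattern, which makes the correlation surface
multi-modal across the contour (renewals scattered by $\pm 5$ px even when
started at the true transform), while intensity patches — with the absolute
value absorbing the contrast reversal — localize 60% of renewals within
1 px. Second, the search is one-dimensional along the normal: sliding along
a smooth contour is unobservable (the aperture problem), and a 2-D argmax
turns that blindness into noise; the point-to-line least squares uses
exactly the observable component. Third, refinement falls back to the
rough transform whenever the mean normal residual would increase, so the
fine stage can never degrade a registration — the monotonicity the tests
assert.

## The synthetic generator

`generate_pair()` renders what the evaluation protocol needs but no public
dataset provides: pairs with exact ground truth. A scene of smooth closed
body-like shapes (star-shaped Fourier-perturbed ellipses) on a weakly
textured background is rendered at 640 x 480; the infrared channel is the
same scene seen through the planted similarity (default $s = 1.05$,
$\varphi = 0.05$ rad, $t = (6, -4)$ px beyond the 8x resolution ratio —
plausible mechanical misalignment of a co-mounted unit), blurred with
$\sigma = 3.5$ px, sampled onto the 80 x 60 grid, contrast-reversed through
the monotone map $1 - v^{0.9}$, and given its own noise. The shapes carry a
strong 4th harmonic and a small 7th so each has at least four pronounced
curvature maxima — animal silhouettes have limb- and ear-like protrusions,
and a bare ellipse (whose curvature never rises above ~0.04/px at these
sizes) would present the corner detector with nothing to detect. Four
illumination groups apply gain/offset/gamma to the visible channel only:
level 1 dark ($0.45 \cdot v^{1.5}$), level 2 dim, level 3 neutral
(identity), level 4 over-bright ($1.4 \cdot v^{0.7} + 0.08$, clipped), the
last chosen to saturate highlights and compress contrast without erasing
it. All randomness flows from the single spec seed, and regeneration is
byte-identical.

What passing tests on these pairs do show: the pipeline bridges an 8x
resolution gap, full contrast reversal, heavy blur and a 3x illumination
range, recovering planted transforms to sub-pixel control-point RMSE. What
they do not show: robustness to occlusion, specularities, non-rigid body
deformation between exposures, structured background clutter (pen bars,
bedding), or thermal textures absent from the visible channel — real
barn imagery has all of these, and the deformation in particular is outside
the similarity model entirely.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `gabor$sigmas` | 2, 4, 8 | px | envelope scales spanning fine edge detail to blurred-IR contour width |
| `contours$threshold` | 0.90 | quantile | band selection on smoothed energy; floored by `min_response` = 0.2 of max |
| `contours$curvature_threshold` | 0.05 | 1/px | corners sharper than a ~20 px radius arc |
| `contours$arm_gap`, `arm_span` | 8, 16 | steps | standoff chords for corner orientation |
| `contours$dense_step` | 4 | px | contour sampling density for matching |
| `descriptors$smooth` | 5 | px | energy-map blur bridging the modality sharpness gap |
| `descriptors$ratio` | 0.95 | — | permissive: RANSAC, not the ratio test, removes the bad matches |
| `descriptors$search_radius` | 100 | px | rig prior: how far a correspondence can move |
| `ransac$inlier_tol` | 4 | px | matches sit on chains sampled every 4 px |
| `refine$min_cc` | 0.6 | — | minimum \|ZNCC\| for a renewal to constrain the fit |
| `metrics$radius` | 5 | px | the correct-match rule (boundary counts as correct) |

Every default is config-exposed (`default_config()`, YAML-overridable via
`load_config()`); the evaluation thresholds follow the conventions of the
field: a match is correct when within 5 px of its reference (inclusive),
orientations agree when their circular difference is strictly below 5
degrees.

## Numerical choices and degenerate inputs

Convolution is true convolution (kernel flipped), verified by impulse
response, with symmetric reflected borders. Maps whose maximum response
falls below $10^{-4}$ are treated as empty rather than having numerical
residue amplified to full scale by normalization — a structureless pair
fails with a staged `gocao_registration_failure` error instead of
registering noise. Equal-distance nearest neighbours break towards the
lower index; RANSAC ties break towards the smaller total inlier error; all
sampling is seeded and restores the caller's RNG state. Orientation
boundary cases ($x = 0$) map by continuity to $\pi/2$ and $3\pi/2$.
Open-chain corners closer than two coarse smoothing lengths to an endpoint
are discarded (reflection-padding artifacts), as are corners whose arms
cannot be formed.

## Problem sizes used by the test suite

The packaged tests exercise unit fixtures at 96–320 px, the brute-force
convolution oracle at 16 x 16, and four full-size (640 x 480 / 80 x 60)
end-to-end registrations — one per illumination level — which dominate the
suite's run time at roughly 15 s each. The acceptance script repeats the
four end-to-end runs plus the RANSAC, equivariance and
orientation-comparison measurements from scratch at the seed given on its
command line.

## Known limitations

The transform family is a similarity (an affine or projective model would
need a different minimal sample and gating); scenes whose contours are
dominated by straight lines leave the normal-constrained refinement
ill-posed in the tangent directions (the point-to-line system needs normals
spanning both axes); corner detection assumes contours at least ~50 chain
steps long, so very small or heavily fragmented structures contribute no
keypoints; and the upright-descriptor default trades full rotation
invariance for cross-modal stability — appropriate for a fixed rig, wrong
for arbitrarily rotated inputs (use `descriptors$align = TRUE` there, at a
cost in matching density).
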