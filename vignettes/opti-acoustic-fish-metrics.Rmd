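---
title: "Opti-acoustic fish metrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opti-acoustic fish metrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishsonar)
```

`fishsonar` estimates fish length/weight distributions and cage quantities
from imaging-sonar video, with a stereo camera supplying 3D calibration and
species information. This vignette explains the models behind each pipeline,
the parameters that matter, what the synthetic generators do and do not
emulate, and the numerical choices made where the design was genuinely open.

## 1. Geometry and calibration

### Stereo side

A rectified pair with focal length $f$ (px), principal point $(c_x, c_y)$
and baseline $b$ (cm) triangulates a pixel $(u, v)$ with disparity $d$ to

$$z = \frac{f\,b}{d}, \qquad x = \frac{(u - c_x)\,z}{f}, \qquad
  y = \frac{(v - c_y)\,z}{f}.$$

Correspondences are found by block matching: sum of absolute differences
over an odd square window (default 11 px) along the same row, disparities
quantised to integer pixels, ties broken toward the smallest disparity so
textureless patches degrade predictably to $d = 0$. Sub-pixel refinement and
dense disparity maps are out of scope; the toolkit assumes rectified input.
Pixels are 0-based $(u, v) = (\text{column}, \text{row})$ with origin
top-left throughout; the epipolar tolerance defaults to 0 rows (perfect
rectification) and is configurable for noisy fixtures.

### Sonar side

A 2D imaging sonar discards elevation: a return at range $r$, azimuth
$\theta$, elevation $\phi$ lands at plane position $(r\cos\theta,
r\sin\theta)$ whatever its $\phi$. The package therefore treats the sonar
frame as a vertical fan slice: pixel $(u,v)$ maps to world position
$(x_S - u\,w,\; y_S,\; v\,h)$, all pixels sharing the device's
$y$-coordinate. The elevation ambiguity is accepted, not modelled. Pixel
footprints come from the imaged extent over the frame shape; a 630 cm pond
over 1080 columns gives $w = 0.583$ cm. (For the matching 600 cm over 1092
rows the same division gives $h = 0.549$ cm; reference material for this
rig quotes 0.3125 cm, which is inconsistent with its own extents, so the
package always computes sizes from config.) Critical points — the
shortest-range beam reflections — use the transducer tilt $t$ and spreading
angle $s$ through $\sin((t+s)/2)$; Euler rotations are fixed to
$R_z R_y R_x$ order with no alternative conventions.

### Rigid registration

With marker pixels lifted to 3D on both sides, the sonar→optical transform
minimises the pooled mean squared residual over all calibration frames.
This is the orthogonal Procrustes problem, solved exactly by centroid
subtraction and SVD of the cross-covariance with reflection correction. A
rigid solver is the deliberate default even though generic affine solvers
exist for this task: both point sets are metric reconstructions in
centimetres, so the physical relation between the devices is a rotation
plus translation, and extra degrees of freedom would only absorb noise. An
optional similarity mode estimates one isotropic scale for rigs with
uncertain scale calibration; full 12-dof affine is out of scope. Collinear
markers leave the rotation unidentifiable and raise a rank-deficiency
error; at least 3 non-collinear points are required (4 markers per frame
recommended).

Overlap detection interprets "common area" as field-of-view membership: a
sonar point overlaps if its transformed image has positive depth and
projects inside the optical frame. Kept points are mapped back to sonar
pixels by inverting the pixel-to-world model, $u = (x_S - x)/w$, $v = z/h$
— the inversion is taken literally from the forward model so that the
round trip is exact — and the min/max corners of those pixels give the
cropping box.

## 2. Length and weight

An instance's standard length is the distance between the two farthest
pixels of its mask, with anisotropic pixel scaling applied per axis before
the distance. Internally the scaled pixels are reduced to their convex
hull first; the diameter of a finite set is attained at hull vertices, so
this is exact (verified against an all-pairs oracle in the tests) and keeps
large masks cheap.

Crowded schools contaminate the observed lengths: merged two-fish instances
land near twice the true length, truncated fragments well below it. The
observed lengths are modelled as a univariate Gaussian mixture fitted by EM
for $c = 1..5$; the order is selected by the non-Gaussianity score

$$\Phi(c) = \frac{1}{c}\sum_{i=1}^{c}
  \left( |\text{skew}_i| + |\text{kurt}_i - 3| \right),$$

where each component's skewness and kurtosis are computed over the samples
hard-assigned to it (largest posterior), standardised by the component's
fitted $\mu_i, \sigma_i$ rather than re-estimated moments — the score asks
"do the residuals of the fitted component look Gaussian", and reusing the
EM parameters keeps it a diagnostic of the fit, not of a refit. Hard
assignment is a design choice (soft weighting was the open alternative);
it matches the classification step that follows, where each instance is
attributed to exactly one component. Components with fewer than 4 assigned
samples cannot support third and fourth moments and disqualify the fit
($\Phi = \infty$). Ties in $\Phi$ break toward smaller $c$, and the
largest-weight component — ties toward the smaller mean — is taken as the
single-fish population, on the assumption that contaminants are the
minority.

Weight prediction is deliberately non-parametric: a 5-nearest-neighbour
mean against a manually measured length–weight table, which tracks any
monotone allometry without committing to a functional form. Fish thickness
is unobservable from a single sonar view, which caps achievable weight
accuracy; this is a reporting caveat, not something the package corrects.

EM numerics (all open choices, fixed once): k-means initialisation with 10
restarts keeping the best final log-likelihood; convergence when the
relative log-likelihood change drops below $10^{-8}$; at most 500
iterations; variance floor $10^{-6}$ cm² against component collapse;
responsibilities computed in log space. Components are reported sorted by
mean so results are deterministic up to the seed.

## 3. Cage quantity

During feeding the school converges near the surface. Only such gathering
frames are counted: the slant sonar beam (angle $\theta$ to the sea plane,
default 20°) cuts the school, the segmented region ℱ gives a packing
density $\delta$ (mean region pixel value over the region maximum), a
sea-plane area $A = |ℱ|\,\Delta x\,\Delta y\cos\theta$ and a school depth
$d = y_{\max}\Delta y\sin\theta$, and the count is
$n = A\,d\,\delta / V_\text{fish}$ with $V_\text{fish} = l^3/4$ the cuboid
volume of an average fish of length $l$ (measured beforehand; 20 cm
default). $y_{\max}$ counts rows from the top of the frame to the bottom
row of the region (0-based index + 1), a convention the package documents
because image-origin choices differ between tools. $g_{\max}$ is the
maximum value within the region of the current frame; normalising by the
dtype maximum instead is available behind a flag, which matters for
sequences where the school never saturates the receiver. Only the
non-rotating slant-beam geometry is implemented.

Per-frame estimates over the gathering frames aggregate into
mean ± $z$·sd intervals with $z = 1$ and $1.96$. This normal approximation
is the package's own convention: the per-frame counts are means of many
pixel contributions and empirically symmetric, and with dozens of frames
the normal quantiles are adequate; a bootstrap would add runtime without
changing the conclusion at these sample sizes.

The gathering classifier and region segmenter are pluggable contracts. The
production design puts small CNNs behind them (a 5-frame-stack classifier
and a U-Net-style segmenter); no trained weights exist to redistribute, and
training is not reproducible at a desk, so the package ships deterministic
classical fallbacks with the same signatures — bright-area fraction
thresholding for the classifier, threshold + minimum blob size +
3×3 morphological closing + largest 8-connected component for the
segmenter (EBImage supplies the morphology). Any callable can replace
them; frame stacks are 5 aligned frames (target ± 2), and how channels are
normalised before a learned model is the plugin author's concern.

Two-mode counting allocates the sonar total across species by the optical
detection ratio. Real-valued shares are exact; integer mode uses
largest-remainder rounding, the unique standard scheme that conserves the
total while keeping every share within one fish of its exact value.

## 4. What the generators emulate — and what they do not

All fixtures are generated, none stored. Each generator returns the ground
truth needed to score every downstream stage.

* **Calibration scenes**: random marker points mapped through a known
  transform with isotropic optical noise. Noiseless scenes are recoverable
  to machine precision; noisy scenes leave a residual RMS matching the
  injected $\sigma$.
* **Populations**: lengths $\mathcal{N}(21.98, 2^2)$ cm truncated at zero
  (the 21.98 cm / ~286 g default matches the tank regime the toolkit
  targets), weights $0.0269\,L^3$ g with 10% lognormal noise, a 200-row
  reference table from uncontaminated fish.
* **Instance masks**: fish are rasterised pixel segments whose
  farthest-point distance equals the drawn length to within one pixel;
  merged instances are two fish fused end to end (observed length = sum of
  the parents), partial instances retain 30–60% of the body (i.e. 40–70%
  truncated away — the fraction is stated as the part removed). Default
  contamination 20% merged / 10% partial: field data quantifies neither,
  and these values make mixture separation non-trivial but feasible, which
  is the regime worth testing.
* **Feeding sequences**: gathering frames carry one bright prism-projected
  region whose pixel count, bottom row and intensities are constructed so
  the density/area/depth chain returns that frame's stored count exactly
  (one saturated pixel pins $g_{\max}$; the rest sit at the level that
  makes the normalised mean equal $\delta_{\text{true}} = 0.6$).
  Frame-to-frame school variability is a 10% lognormal factor on the
  target volume; dispersing frames are sparse specks; optional linear
  range decay and Gaussian speckle degrade the frames (the exact-inversion
  guarantee holds only without them).

What passing tests on these fixtures show: the geometry, estimators and
selection criteria are implemented correctly, and the pipelines invert
their own generative assumptions. What they do not show: performance on
real sonar, where echoes are textured and blurred, instance segmentation
errs in ways richer than merge/truncate, schools are irregular, and the
density proxy $\delta$ only approximates true packing. The fallback
detectors are separability baselines, not substitutes for learned models
on field data.

## 5. Degenerate inputs and failure signals

Errors are classed conditions (`epipolar_violation`, `degenerate_depth`,
`rank_deficient`, `insufficient_data`, `empty_region`, ...). Two situations
are signals rather than errors: overlap detection with no overlapping
point returns an `overlap_result` with `n = 0`, and a quantity run with no
gathering frame returns a summary with `n_gathering = 0` — both are valid
outcomes of valid inputs. Negative disparities are returned by the
disparity stage (the flag that rectification or matching failed) but
rejected at triangulation.

## 6. Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in a few minutes while every statistical claim
still has headroom: 2000-instance populations for mixture selection,
calibration scenes of 4–24 markers, feeding sequences of 12–30 frames of
200×200 px. The estimators themselves are vectorised and run comfortably
at the native 1080×1092 sonar resolution.

## 7. Known limitations

* Lengths from a 2D sonar are projections; out-of-plane pitch shortens
  them. The mixture filter removes merge/truncate artefacts, not
  projection bias.
* Manual reference lengths measured as fork length bias comparisons
  against the (shorter) standard length the sonar sees; no correction is
  applied.
* The quantity model assumes the school fills a prism uniformly at density
  $\delta$; systematic packing gradients bias the count.
* Calibration assumes synchronised frames and undistorted, rectified
  optics; lens distortion and time offsets are out of scope.
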