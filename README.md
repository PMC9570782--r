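# fishsonar

Fish metrics for precision aquaculture from a two-mode underwater rig: an
imaging sonar (long range, works in turbid or dark water, but no colour and
no species cues) paired with a rectified stereo camera (short range, colour,
species cues). `fishsonar` is an offline, hardware-free toolkit: every
pipeline runs on image files, CSV tables and JSON configs, and a built-in
synthetic-data generator produces all required inputs with known ground
truth.

## What it computes

**Opti-acoustic calibration and overlap.** Marker pixels observed by both
sensors are lifted to 3D — sonar pixels through the fan-slice model
`X_S = (x_S − u·w, y_S, v·h)`, stereo pixels through disparity `d = x − x′`
and triangulation `z = f·b/d` — and the sonar→optical rigid transform
`(R, T)` minimising

```
L(R, T) = mean_i || X_O,i − (R X_S,i + T) ||²
```

is solved in closed form (centroid subtraction + SVD of the cross-covariance
with reflection correction). The calibrated transform then yields the
field-of-view overlap and the sonar-image bounding box that crops to the
jointly observed area.

**Length and weight distributions.** Each segmented fish instance's standard
length is the distance between its two farthest mask pixels. Because crowded
schools produce merged (two-fish) and truncated instances, the observed
lengths are modelled as a Gaussian mixture `p(x) = Σ w_i N(x; μ_i, σ_i²)`
fitted by EM for c = 1..5 components; the order is chosen by the
non-Gaussianity criterion

```
Φ(c) = (1/c) Σ_i ( |skew_i| + |kurt_i − 3| )
```

computed per component over its hard-assigned samples, and the
largest-weight component is taken as the single-fish population. Weights
follow by K-nearest-neighbour regression (K = 5) against a manually measured
length–weight table.

**Net-cage fish quantity.** During feeding the school gathers near the
surface; gathering frames are detected (pluggable classifier), the fish
region ℱ segmented (pluggable segmenter), and the count follows from the
prism-volume chain

```
δ = Σ g(x) / (g_max·|ℱ|)      A = |ℱ|·Δx·Δy·cos θ      d = y_max·Δy·sin θ
n_fish = A·d·δ / V_fish,      V_fish = l·(l/2)·(l/2)
```

with per-frame estimates aggregated into a mean and 68%/95% normal
confidence intervals.

**Two-mode counting.** The sonar total is split across species in proportion
to optical per-species detections: `C_i = C_sonar·c_i / c_total`, with
exact-conserving largest-remainder rounding in integer mode.

## Worked example

```r
library(fishsonar)

# a 2000-fish population (22 ± 2 cm), observed with 20% merged and 10%
# truncated instances, as crowded-school segmentation would produce
pop  <- gen_population(n = 2000, mean_length = 22, sd_length = 2, seed = 7)
cont <- contaminate_lengths(pop$lengths, frac_merged = 0.2, frac_partial = 0.1, seed = 8)
res  <- run_length_weight_pipeline(lengths = cont$observed, table = pop$table,
                                   manual_length = mean(pop$lengths),
                                   manual_weight = mean(pop$weights), seed = 9)
print(res)
#> length/weight summary: N = 2000, N_G = 1400, c = 3
#>   mean length: raw 25.23 cm, filtered 22.03 cm
#>   mean weight: raw 326.22 g, filtered 295.39 g
#>   rel. error length: raw 0.145, filtered 0.000
#>   rel. error weight: raw 0.103, filtered 0.002
```

The mixture finds three components — truncated fragments near 10 cm, singles
at 22.0 cm, merged pairs at 44.0 cm — and keeps the dominant (weight 0.70)
single-fish component: the raw 14.5% length error drops to 0.04%.

```r
fs <- gen_feeding_sequence(n_frames = 24, true_count = 2200, seed = 10)
qs <- run_quantity_pipeline(fs$frames, fs$l_fish, fs$theta, fs$dx, fs$dy)
print(qs)
#> quantity_summary over 16 gathering frame(s):
#>   mean 2252.97 fish, sd 286.25
#>   68% CI [1966.72, 2539.21], 95% CI [1691.93, 2814.01]

allocate_two_mode_counts(round(qs$mean), c(blochii = 55, other = 12), integer = TRUE)
#> count_allocation of sonar total 2253 across 2 species:
#> blochii   other
#>    1849     404
```

The cage's true count (2200) lies inside the 95% interval, and the sonar
total is allocated across species by the optical detection ratio 55:12.

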