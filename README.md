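# polypwatch

Time-lapse quantification and permutational statistics for the
polyp-expansion behaviour of passive suspension feeders (modelled on the
Mediterranean red coral *Corallium rubrum*).

Sessile suspension feeders feed by expanding their polyps into the ambient
flow, and the fraction of open polyps — from 0% (crowns retracted) to 100%
(fully open) — responds to current speed, temperature, and food cues. This
package provides the complete analysis chain needed to study that
behaviour from video and survey data, for behavioural ecologists working
with flume recordings or field monitoring of octocorals and similar taxa:

* **Synthetic data with ground truth** — a renderer that draws a colony
  (white polyps as discs on red branches over a dark background, 736 × 568
  px ≙ 104 mm, 140 µm px⁻¹, 3 frames/min) under a programmable aperture
  rhythm, plus generators for the field-survey (5 cycles × 4 times × 3
  replicates), temperature × current flume factorial (3 × 3, n = 12),
  nutritional-stimulus (4 levels, n = 8) and zooplankton count tables.
* **Imaging** — nearest-centroid colour segmentation into open polyp /
  coenenchyme / background, 8-connected region labelling with a minimum
  area filter, and overlap-based region tracking with gap tolerance.
* **Activity series** — per-frame open surface area, the frame-differencing
  activity index (pixels whose open-polyp membership changes between
  consecutive frames), maximum-normalised activity, percent expansion
  between calibration references, and the absolute derivative.
* **Rhythms** — the Lomb normalised periodogram

  P(ω) = (1/2σ²) { [Σ(x−x̄)cos ω(t−τ)]²/Σcos²ω(t−τ) +
                    [Σ(x−x̄)sin ω(t−τ)]²/Σsin²ω(t−τ) },

  valid for uneven sampling, with analytic peak significance
  p = 1 − (1 − e^(−z))^M and threshold lines at p = 0.1, 0.01, 0.001.
* **Permutational statistics** — Euclidean and fourth-root Bray–Curtis
  distance matrices; PERMANOVA for one-way, nested (upper-level F against
  the nested mean square, restricted permutation of whole cells) and
  two-way crossed designs (interaction tested by Freedman–Lane permutation
  of reduced-model residuals); pairwise tests with Monte-Carlo p-values;
  and SIMPER decomposition of between-group dissimilarity. On univariate
  Euclidean data every pseudo-F reduces exactly to the classical ANOVA F.

## Worked example

The `analysis/` directory holds the four-step workflow
(`01_simulate.R` … `04_stats.R`). In miniature:

```r
library(polypwatch)

# a colony with a programmed 12.4 h rhythm, recorded for 48 h
scene   <- scene_model(image_width_px = 184, image_height_px = 142,
                       n_polyps = 6, seed = 1)
program <- aperture_program(period_h = 12.4)
tl <- generate_time_lapse(scene, program, duration_h = 48,
                          frame_rate = 1/6, seed = 1)

masks <- lapply(tl$frames, function(f) segment_frame(f$image))
act   <- activity_table(masks, time_s = (seq_along(masks) - 1) * 360)
res   <- run_rhythms(act, alpha = 0.001)
print(res$periodogram)
```

```
<lomb_periodogram> 958 frequencies (0.005219-5 c/h), n = 480, M = 480
  top power 218.59 at period 12.8 h (p = 5.63e-93)
  thresholds: p=0.1 8.42 | p=0.01 10.77 | p=0.001 13.08
```

The dominant peak recovers the programmed 12.4 h rhythm within the
frequency-grid resolution (1/(4·span) ≈ 0.005 cycles/h), far above the
p = 0.001 significance line. On noise-free frames the segmented open-area
series equals the renderer's ground truth pixel-for-pixel.

The statistical stage, on a simulated temperature × current flume
experiment:

```r
fl <- generate_flume_experiment(seed = 20260923)
D  <- euclidean_matrix(matrix(fl$expansion_pct))
permanova_twoway(D, fl$temperature, fl$current, n_perm = 9999, seed = 1)
```

```
PERMANOVA (twoway design)
                      term  df         SS        MS  pseudo_F p_perm n_perm
            fl$temperature   2     3.5389    1.7695  0.010352 0.9881   9999
                fl$current   2  7152.7404 3576.3702 20.923047 0.0001   9999
 fl$temperature:fl$current   4  9166.9343 2291.7336 13.407462 0.0001   9999
                  residual  99 16922.0408  170.9297        NA     NA   9999
                     total 107 33245.2545        NA        NA     NA   9999
```

The simulated interaction (still-water expansion rising with temperature,
maximal expansion at low temperature + fast current) is detected at
p = 0.0001, the floor imposed by the (1 + count)/(1 + 9999) convention,
while the nearly balanced temperature marginal means leave no detectable
main effect — the behaviour is in the cross-term, as designed.

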