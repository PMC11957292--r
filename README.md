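# motrack

Label-free cell tracking and motility-based cell discrimination in R.

Adherent cells crawling on tissue-culture plastic can be phenotyped by *how*
they move, without fluorescent labels: phase-contrast time-lapse imaging at
one frame per minute resolves both cell-body displacement and the polarity
changes that accompany cell deformation. `motrack` implements the full
analysis chain for such recordings and is aimed at cell biologists who want
a scriptable, inspectable alternative to point-and-click trackers:

1. **Segmentation** — each frame is edge-filtered with the 3×3 Sobel
   operator, binarized at a per-setup threshold, smoothed morphologically
   (octagonal dilation of radius 3 px, hole filling, two erosions with a
   diamond of radius 5 px), and each connected component is replaced by its
   filled convex hull, from which centroid, area, and major axis are
   measured.
2. **Tracking** — every cell found in the first frame is followed through a
   moving square region of interest (side = 2 × major-axis length) centered
   on its previous centroid. Tracking stops automatically at cell division,
   cell–cell contact, or loss (two centroids or none inside the ROI; a
   sudden area jump flags a merge). Only data collected before the stop are
   used, and only tracks longer than 1 h are analyzed.
3. **Motility parameters** — ten per-cell trajectory parameters. With
   centroids $p_i$ at uniform interval $\Delta t$ and displacement vectors
   $r_i = p_i - p_{i-1}$, the turn angle at an interior point is
   $\theta_i = \angle(r_i, r_{i+1}) \in [0°, 180°]$, set to 0 whenever
   either displacement is the zero vector. The parameters are the mean
   migration speed, the frequency of turns below 90°/60°/30° (zero-speed
   instants excluded), the migration distance between turns below each
   threshold, the sum of turn angles, the quiescent time (speed strictly
   below the cell's own mean), and the total migration length.
   Duration-sensitive parameters are normalized to a 30-h window
   (hourly rate × 30).
4. **Discrimination** — per-group Pearson correlation matrices, Welch
   t-tests, and two-class linear/quadratic discriminant analysis: class
   covariances $S_1, S_2$ (pooled to
   $S = ((n_1{-}1)S_1 + (n_2{-}1)S_2)/(n_1{+}n_2{-}2)$ for LDA), squared
   Mahalanobis distances $d_i^2 = (x-\bar{x}_i)^\top S_i^{-1}(x-\bar{x}_i)$,
   nearest-class assignment, sensitivity/specificity/accuracy, stratified
   10-fold cross-validation, and an exhaustive ranking of all 45 parameter
   pairs.

A synthetic module generates ground-truthed persistent-random-walk
trajectories (wrapped-normal heading increments, one- or two-state speed
process) and renders them as phase-contrast-like stacks (elliptical body,
bright halo rim, faint protrusions, noise), so every stage is testable
without microscopy data.

## Worked example

Simulate two motility phenotypes — a directional two-speed-mode population
and a homogeneous slow one — profile them, and rank parameter pairs by
cross-validated discrimination accuracy:

```r
library(motrack)

spec_c <- preset_population_spec("cancerlike",     n_cells = 15, duration_min = 180)
spec_f <- preset_population_spec("fibroblastlike", n_cells = 15, duration_min = 180)
feats  <- simulate_population(spec_c, spec_f, "cancer", "fibro", seed = 42)

aggregate(cbind(mean_speed_um_s, freq_below_30, sum_turn_angles, total_length)
          ~ group, feats, function(x) round(mean(x), 4))
#>    group mean_speed_um_s freq_below_30 sum_turn_angles total_length
#> 1 cancer          0.0230     1531.3333        29458.21     2486.880
#> 2  fibro          0.0151      968.6667        57560.88     1629.636

rk <- pair_search(feats, kinds = c("lda", "qda"), positive = "cancer", seed = 0)
head(rk[, 1:6], 3)
#>   kind   parameter_1   parameter_2 sensitivity specificity accuracy
#> 1  lda freq_below_30 freq_below_60           1           1        1
#> 2  qda freq_below_30 freq_below_60           1           1        1
#> 3  lda freq_below_30 freq_below_90           1           1        1

welch_t_test(feats$mean_speed_um_s[feats$group == "cancer"],
             feats$mean_speed_um_s[feats$group == "fibro"])
#> t = 8.46, df = 14.1, p = 6.9e-07
```

The directional population moves ~1.5× faster, makes more shallow turns per
30 h, and accumulates less total turning; with this much separation every
speed/turn pair discriminates the groups perfectly under 10-fold
cross-validation.

Image stacks are processed the same way from R (`read_stack()`,
`track_all()`, `profile_tracks()`) or from the shell via the bundled CLI
(`system.file("cli", "motrack", package = "motrack")`) with subcommands
`simulate`, `track`, `motility`, `discriminate`, and `report`.

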