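# facenorm

Unsupervised severity scoring of localized facial anomalies — cleft lip is
the motivating case — by **generative face normalization**.  Instead of
comparing a face against a population norm, the pipeline compares it against
*its own* normalized counterpart: the closest face a generative model of
normal faces can synthesize.  Whatever the generator cannot reproduce is, by
construction, what is unusual about the face.

## Method

For a face image `x_org`:

1. **Canonicalize** — adjust the face/background ratio to 60/40 (mirroring
   and blurring added margin, or cropping excess background), rotate the
   eyes level, rescale to a 100 px inter-ocular distance, crop a
   1024 × 1024 window.
2. **Invert** — find the latent `w` and noise maps `n_i` minimizing

   `D_perc(x_org, G(w, n)) + α Σ_{i,j} L_{i,j}`,  α = 1e5,

   where `D_perc` is a layered perceptual distance (unit-normalized channel
   features, per-channel weights, squared differences averaged over
   positions, summed over layers) and `L_{i,j}` is the squared
   `r²`-normalized lag-1 autocorrelation of noise map `i` at pyramid level
   `j` — the regularizer that keeps noise maps random.
3. **Adapt** — freeze `w` and `n`, fine-tune a copy of the generator
   weights on `D_perc(x_org, x_norm) + D_L2(x_org, x_norm)` for a fixed
   small budget, yielding the normalized face `x_norm = G′(w, n)` with
   identity detail restored but the anomaly still suppressed.
4. **Compare** — transform both images to YCbCr
   (`Y′ = 16 + 65.481 R′ + 128.553 G′ + 24.966 B′`, …), optionally erode
   both with a 3 × 3 minimum filter, and form a difference heatmap:
   pixelwise squared error `PSE = (x_org − x_norm) ⊙ (x_org − x_norm)`
   (reference), SSIM, or a perceptual map.
5. **Score** — mask the heatmap to the oral/nasal region `M` (landmark
   convex hulls) and report

   `S = −log(‖M ⊙ D‖_F / N)`,

   `N` the mask pixel count.  Higher `S` means closer to normal, aligned
   with the human 1–7 rating scale; agreement with per-image mean human
   ratings (≥ 20 ratings each) is measured by Pearson correlation.

The generator behind steps 2–3 is a pluggable backend.  The package ships a
CPU-scale, fully differentiable `toy_generator()` (analytic gradients,
seeded weights, no downloads) so every stage runs and is tested on a laptop;
a pretrained style-based face generator wraps into the same contract for
production use.

## Worked example

```r
library(facenorm)

gen <- toy_generator(seed = 3)          # desk-scale generator backend
pb  <- randconv_backend()               # seeded perceptual backend

# ten faces, one base identity, planted anomaly amplitudes 0.1 .. 1.0
faces <- fixture_faces(seq(0.1, 1, by = 0.1), side = 64, seed = 5,
                       same_base = TRUE)
res <- run_pipeline(faces, gen, pb, toy_run_config(seed = 1))
res$scores[, c("image_id", "raw_energy", "score", "scaled_score")]
#>    image_id raw_energy  score scaled_score
#>  1   img001      141.5 -4.953        7.000
#>  2   img002      141.8 -4.954        6.975
#>  3   img003      145.5 -4.980        6.615
#>  4   img004      152.2 -5.025        5.983
#>  5   img005      163.9 -5.099        4.949
#>  6   img006      180.5 -5.196        3.600
#>  7   img007      192.3 -5.259        2.715
#>  8   img008      203.6 -5.316        1.915
#>  9   img009      210.8 -5.351        1.432
#> 10   img010      217.4 -5.382        1.000
```

The masked heatmap energy (`raw_energy`) grows with the planted amplitude,
so the severity score `S` falls strictly — the pipeline ranks the graded
anomalies exactly as planted (`scaled_score` is the same ranking mapped
affinely onto the 1–7 rating scale for visualization).  Against simulated
raters (25 per image, noisy saturating response) the same pipeline's scores
correlate with mean ratings at about `r = 0.90`.

Heatmaps and result objects plot directly:

```r
art <- run_pipeline(faces[10, ], gen, pb, toy_run_config(seed = 1),
                    keep_images = TRUE)$artifacts[[1]]
hm <- compute_heatmap(art$x_canon, art$x_norm, "pse",
                      ycbcr = TRUE, erosion = TRUE)
ggplot2::autoplot(hm)            # difference heatmap
tidy(art$latent)                 # inversion loss trace as a tibble
```

A thin command-line front end over the same functions lives at
`inst/cli/facenorm.R` (subcommands `preprocess`, `invert`, `adapt`,
`heatmap`, `score`, `evaluate`, `fixtures`, `run`, `ablation`).

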