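# shockfilter

Smoothed shock filtering for grayscale image enhancement and denoising,
with the classic filters it generalizes and a reproducible
(α, σ)-robustness evaluation harness.

## What it does

Shock filters sharpen images by a morphological switch on the sign of the
Laplacian: dilate where ΔI < 0, erode where ΔI > 0. Iterating creates
ruptures between local maxima and minima, but the hard min/max operators
are fragile under noise. The smoothed shock filter replaces them with
*smoothed rank-order operators* derived from smoothed local histograms:
each neighbor p′ of a pixel p contributes a Gaussian intensity bump,
weighted by spatial distance,

    f̂_p(s_k) = Σ_{p′∈V(p)} K(I(p′) − s_k) · W(‖p − p′‖),   1 ≤ k ≤ nb,

whose running integral over the bins,

    R_k(p) = 1 − (C(I(·) − s_k) * W)(p),       C = ∫K (an error function),

is a per-pixel smoothed CDF. Inverting R at a level t gives the smoothed
t-quantile of the neighborhood: t = 1/2 is a smoothed median, t < 1/2 a
smoothed erosion, t > 1/2 a smoothed dilation. One shock iteration applies
the rank filter at t(p) = 1/2 − ρ·sign(ΔI(p)), so ρ interpolates between a
pure smoothed median (ρ = 0) and classic shock filtering (ρ = 1/2 in the
degenerate-kernel limit). The package implements:

* the smoothed local histogram / CDF machinery with a direct-sum reference
  path (`smoothed_local_histogram()`, `smoothed_cdf_field()`,
  `quantile_lookup()`);
* smoothed rank filters and morphology (`smoothed_rank_filter()`,
  `smoothed_median()`, `smoothed_erode()`, `smoothed_dilate()`);
* the shock scheme and its scale space (`smoothed_shock_step()`,
  `smoothed_shock_filter()`, `normalized_laplacian()`,
  `shock_level_map()`);
* classic baselines reachable as limits (`classic_shock_filter()`,
  `median_filter()`);
* synthetic fixtures (`make_step()`, `make_disk()`, `make_texture()`,
  `fixture_set()`) so everything runs with no external data;
* the robustness harness: additive-Gaussian noise ladders, SSIM, quality
  curves and the (α, σ) summary (`add_gaussian_noise()`, `ssim()`,
  `quality_curve()`, `alpha_sigma()`, `run_robustness_experiment()`);
* PNG/TIFF/PGM I/O with channel selection (`load_image()`,
  `save_image()`), broom-style `tidy()`/`glance()` methods, ggplot2
  `autoplot()` methods, and a CLI (`inst/cli/shockfilter.R`) with
  `filter` and `robustness` subcommands.

It is intended for researchers in biological and medical image analysis
who want a transparent, dependency-light enhancement step (contour
enhancement before segmentation or texture description) and a
reproducible way to compare denoisers' robustness.

## Worked example

```r
library(shockfilter)

# a blurred step edge, corrupted by sigma = 15 Gaussian noise (0-255 scale)
clean <- make_step(64, 64, 32, low = 0.1, high = 0.9, blur_sigma = 2)
noisy <- add_gaussian_noise(clean, 15, seed = 42)

params <- shock_params(rho = 0.1, nit = 3, spec = histogram_spec(sigma_w = 3))
ss <- smoothed_shock_filter(noisy, params)

round(ssim(clean, noisy), 3)
#> [1] 0.355
round(ssim(clean, ss$iterates[[4]]), 3)
#> [1] 0.816
print(tidy(ss), digits = 3)
#> # A tibble: 4 × 7
#>   iteration    min   max  mean total_variation rms_residual n_intermediate
#>       <int>  <dbl> <dbl> <dbl>           <dbl>        <dbl>          <int>
#> 1         0 0      1     0.499            543.       0                 260
#> 2         1 0.0685 0.931 0.499            284.       0.0469            234
#> 3         2 0.0771 0.923 0.499            232.       0.0518            234
#> 4         3 0.0776 0.921 0.499            225.       0.0540            236
```

Three iterations lift SSIM against the clean edge from 0.36 to 0.82: the
total variation more than halves as the noise is removed, the intensity
range stays inside the input's, and the count of "intermediate" pixels
(values in (0.25, 0.75), i.e. unsharpened transition zones) shrinks as
the edge is re-sharpened. Residual maps (`ss$residuals`) show what each
iterate removed.

Robustness comparison of the standard filter bank on the fixture set:

```r
imgs <- fixture_set(64)
ladder <- noise_ladder(c(5, 10, 15, 20, 25), seed = 1)
run_robustness_experiment(standard_filter_bank(nit = 3), imgs, ladder)
#> <robustness_experiment> ranking by ascending alpha:
#>          filter       alpha sigma_at_alpha
#>  smoothed_shock 0.002316368             15
#>          median 0.019203432             10
#>   classic_shock 0.034114873              5
#>        identity 0.046916770              5
```

The smoothed shock filter has both the lowest α (mildest worst-case
quality drop per unit of noise) and a higher σ than the classic shock
filter (its worst drop only sets in at stronger noise) — the "low α,
high σ" signature of a robust denoiser.

Command line:

```sh
Rscript inst/cli/shockfilter.R filter --input in.png --output out.png \
    --rho 0.1 --sigma-w 3 --nit 3 --save-scale-space
Rscript inst/cli/shockfilter.R robustness --config experiment.yaml --outdir results/
```

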