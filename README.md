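# lagbias

Removing hidden eye-motion artifacts from the reference frames of
raster-scanned retinal images.

## The problem

Adaptive-optics scanning ophthalmoscopes (AO-SLO) and OCT systems build
images line by line, so fixational eye movements warp every frame: shear
along the fast scanner, compression/expansion along the slow scanner, and
axial displacement in volumes. Strip-based registration — cutting target
frames into narrow rigid strips and registering each to a reference frame
by normalized cross-correlation — removes the warp of the *targets*, but
the warp hidden in the *reference frame itself* propagates into every
registered average and every measurement made from it.

`lagbias` corrects the reference frame from the statistics of the
registration itself. The reference is cut into strips and each strip is
registered against each whole target frame. Writing the matched position of
reference strip `r` in target `f` as lags `s_x(f, r), s_y(f, r)`, and using
the fact that eye motion is uncorrelated across targets, the per-row mean
over frames

    x_hat(r) = mean_f s_x(f, r),    y_hat(r) = mean_f s_y(f, r)

is an estimate (up to a constant) of the eye's position while reference
row `r` was being acquired. After Tukey-fence outlier removal
(`[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`), the reference is dewarped by
interpolating the intensities observed at the displaced per-row coordinates
back onto the ideal pixel grid, and the series is re-registered to the
corrected reference. The same machinery applied to fast-axis projections
corrects axial motion in volume series.

The package also ships the simulators needed to validate the whole chain
against known ground truth — a particle-system cone-mosaic phantom, a
self-avoiding-walk model of fixational drift, a virtual raster scanner and
a two-band outer-retina volume generator — plus validation metrics: trace
R², overlap-normalized whole-image cross-correlation, and power-spectrum
shear detection.

## Worked example

```r
library(lagbias)

sim <- standard_simulation(seed = 1)      # phantom + 100 warped frames
cfg <- pipeline_config(W = 9, k = 3, increment = 2, f_c = sim$f_c,
                       averages = FALSE)
res <- run_pipeline(sim$series, cfg)
res
#> <lagbias_result> reference frame 18 of 100, bias RMS (4.31, 3.15) oversampled px

truth <- sim$series$traces[[res$reference_index]]
est <- bias_to_trace(res$bias, cfg$k, sim$scan$px_per_arcmin,
                     sim$scan$n_rows)
r_squared(truth, est)
#> <fit_quality> R^2 x = 0.9984, y = 0.9941

obj <- fourier_oversample(motion_free_crop(sim$phantom, sim$scan), cfg$k)
whole_image_xcorr(res$reference, obj)$peak             # warped reference
#> [1] 0.421
whole_image_xcorr(res$corrected_reference, obj)$peak   # corrected
#> [1] 0.970
```

Reading: the lag biases reconstruct the eye trace during the reference
frame with R² ≈ 0.99 in both axes, and dewarping lifts the reference's
peak correlation with the motion-free object from 0.42 to 0.97 — the
mosaic's characteristic correlation side lobes, destroyed by the warp,
reappear after correction.

A thin command-line wrapper covers the same pipeline from a shell
(`inst/cli/lagbias`): subcommands `simulate-mosaic`, `simulate-series`,
`register`, `dewarp`, `validate` and `oct-correct`, each writing its
outputs together with a provenance JSON.

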