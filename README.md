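# dirqa — ground-truth benchmarking of deformable image registration

Deformable image registration (DIR) maps every voxel of one CT onto another
through a deformation vector field (DVF), and adaptive radiotherapy leans on
it: dose computed on end-of-treatment (EOT) anatomy is pulled back through
the DVF onto the start-of-treatment (SOT) planning CT. Commercial DIR
engines are black boxes, and on real patients there is no ground truth to
score them against. dirqa gives clinical physicists and algorithm developers
a complete commissioning loop in R:

* **virtual head-and-neck phantoms** — paired SOT/EOT CT-like volumes linked
  by a known, smooth, invertible DVF composed of head rotation/translation,
  spine flexion, mandible rotation, parotid shrinkage, weight loss and a
  thin-plate-spline residual; six organ masks (brainstem, cord, mandible,
  both parotids, external); and a single-fraction 2 Gy dose distribution
  whose gradient can be placed at a chosen distance from any organ at risk;
* **test DVFs** — a built-in multi-resolution demons registration, plus
  parametric error injection (constant bias, spatially correlated noise, an
  isolated local misregistration) so every metric has a planted truth;
* **scoring** — voxel-wise target registration error (TRE) maps, per-ROI
  statistics, the TG-132 goal check, DICE, TRE histograms, dose propagation
  error, cumulative DVHs, the mean DVH difference, the two-SD registration
  failure rule, and Pearson correlation of spatial versus dosimetric error
  across a benchmark suite.

The central metrics, per ROI with ground-truth field `u_gt` and test field
`u_test`:

    TRE(x)   = || u_test(x) - u_gt(x) ||            (mm, per voxel)
    TRE_mu   = mean TRE over ROI voxels;  TRE_max = max
    TG-132 goal: at least 95% of ROI voxels with TRE <= 2 mm
    dose errors: |ΔD_mean| (Gy and % of ground-truth mean), |ΔD_max| (Gy),
    ΔDVH_mean = mean over v in {1..99}% of |D_test(v) - D_gt(v)|  (Gy)
    failure rule: TRE_mu at least 2 pooled SDs above the pooled average

## Worked example

Generate a phantom (here on a coarse 32³ grid of 6 mm voxels so it builds in
a couple of seconds; the study grid is 64³ at 3 mm), make a deliberately
wrong test DVF by adding a 3 mm anterior bias to the ground truth, and score
it:

```r
library(dirqa)

cfg <- phantom_config(grid = image_grid(c(32, 32, 32), c(6, 6, 6)),
                      build_tol = 0.05)
ph <- generate_phantom(cfg, seed = 42)
ph
#> dir_phantom (seed 42) on 32x32x32 @ 6x6x6 mm
#>   ground-truth |u| inside body: mean 3.05 mm, max 5.70 mm
#>   round-trip NRMSE: 0.0307

test_dvf <- inject_error(ph$gt_field,
                         error_model("bias", magnitude = 3,
                                     direction = c(0, -1, 0)))
res <- evaluate_field(ph, test_dvf)
res[, c("roi", "tre_mean", "tre_max", "frac_within_2mm", "tg132_pass",
        "d_mean_gy", "dvh_mean_gy")]
#>        roi tre_mean tre_max frac_within_2mm tg132_pass d_mean_gy dvh_mean_gy
#>  brainstem        3       3               0      FALSE  2.65e-01    0.264339
#>       cord        3       3               0      FALSE  1.44e-03    0.001010
#>   mandible        3       3               0      FALSE  1.58e-02    0.016262
#>  parotid_l        3       3               0      FALSE  1.03e-03    0.000716
#>  parotid_r        3       3               0      FALSE  1.02e-03    0.000579
#>   external        3       3               0      FALSE  9.86e-05    0.001937
```

Every organ sees the same 3 mm spatial error, but its dosimetric consequence
spans three orders of magnitude: the brainstem abuts the dose gradient (the
50% isodose sits 2 mm away by default) and absorbs a 0.26 Gy mean-dose
error, while the cord sits in the flat low-dose bath and barely notices.
That interplay between error location and gradient proximity is the
phenomenon the package exists to quantify.

The built-in demons registration recovers most of the simulated anatomical
change:

```r
tre <- tre_map(ph$gt_field, demons_register(ph$sot, ph$eot))
roi_tre_stats(tre, ph$masks$external)
#> external: TRE 1.87 +/- 0.90 mm (max 4.45), 59.9% <= 2 mm, n = 8696
```

(on the 3 mm study grid the demons TRE_mu over the body is about 1 mm
against a 3.7 mm identity baseline). `run_suite()` executes the whole loop —
n phantoms × m registration sources, TRE and dose scoring per ROI — and
`assemble_report()` renders the per-ROI TRE tables, failure flags, TG-132
pass rates, dose-error table and the TRE-versus-dose correlation table;
`write_report()` serializes everything as CSV plus JSON. A thin command-line
wrapper for the same steps ships in `inst/cli/dirqa.R`
(`generate` / `register` / `evaluate` / `dose` / `run-suite`).

## Documentation

The methods vignette (`vignettes/dirqa-methods.Rmd`) describes the phantom
and dose models, the numerical conventions (voxel-center grids, pull-back
warping, out-of-hull policies, fixed-point field inversion), the metric
definitions the benchmark leaves open and the choices made here, and the
reasoning behind the default suite design.
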