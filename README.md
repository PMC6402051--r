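# pc4dflow

Quantification and validation of 4D phase-contrast MRI flow and kinetic
energy, in R.

Time-resolved, three-directional phase-contrast MRI ("4D flow") measures a
velocity vector in every voxel of the chest over the cardiac cycle. Before
any physiology can be read off, the raw phase images must be decoded and
cleaned, and the resulting velocity fields reduced to clinically meaningful
numbers. `pc4dflow` implements that chain:

* **Velocity decoding** from phase images: `v = VENC · φ / π`, with values
  aliasing (wrapping) at the velocity-encoding limit VENC.
* **Background phase correction**: eddy currents add a slowly varying
  offset; an affine model `b(x) = a0 + ax·x + ay·y + az·z` is fitted per
  component by least squares on stationary tissue and subtracted
  (`fit_background()`, `subtract_background()`, `auto_stationary_mask()`).
* **Temporal phase unwrapping** (`unwrap_velocity()`): inter-phase jumps
  larger than VENC are corrected by multiples of 2·VENC, scanning cyclically
  from the quietest cardiac phase; unfixable voxels are counted, not hidden.
* **Flow quantification** (`extract_plane()`, `integrate_flow()`):
  through-plane velocity on an oblique analysis plane, integrated over an
  ROI contour into a flow curve (mL/s) and a per-beat flow volume (mL);
  contours can be transferred between acquisitions (`transfer_contour()`);
  `qp_qs()` gives the pulmonary-to-systemic flow ratio.
* **Kinetic energy** (`compute_ke()`, `ke_summary()`): `KE = Σ ½ m v²` over
  a ventricular segmentation per cardiac phase, in mJ.
* **Agreement statistics** (`bland_altman()`, `pearson_regression()`,
  `wilcoxon_signed_rank()`, `build_comparison_table()`): the
  bias ± SD / limits-of-agreement machinery used to compare 4D flow against
  2D flow and across scanners, with an exact paired Wilcoxon test.

Because no real scanner data can ship with the package, it includes a
**synthetic phantom generator** with analytic ground truth — Womersley
pulsatile tube flow driven by a programmable pump waveform, and Hill's
spherical vortex for KE — plus a forward model of the acquisition
(VENC wrapping, affine background, phase noise; `encode_acquisition()`).
The per-beat volume of the generated tube field equals the programmed
stroke volume *exactly by construction*, which is what makes end-to-end
validation possible. See `vignette("pc4dflow-methods")` for the science and
the numerical choices.

## Worked example

Simulate a pump phantom at 25 mL/beat under study conditions (2.9 mm
voxels, 40 cardiac phases, VENC 150 cm/s), corrupt it with a random affine
background and 5%-of-VENC noise, then run the full correction and
quantification chain:

```r
library(pc4dflow)

spec <- phantom_spec("tube")              # 2.9 mm, 40 phases, R = 12 mm
prog <- pump_program(stroke_volume = 25)  # 25 mL/beat, RR 1000 ms
sim  <- simulate_tube_dataset(spec, prog)

bg <- random_background_model(seed = 1)   # |a0| ≤ 5 cm/s, |grad| ≤ 0.05 cm/s/mm
ph <- encode_acquisition(sim$field, background = bg,
                         noise_sd = 0.05 * 150, venc = 150, seed = 2)

dec <- decode_velocity(ph)
fit <- fit_background(dec, sim$truth$stationary_mask)
unw <- unwrap_velocity(subtract_background(dec, fit))
fc  <- integrate_flow(extract_plane(unw, sim$truth$plane), sim$truth$contour)
fc
#> <flow_curve> 40 phases, RR 1000 ms
#>   flow volume 24.82 mL/beat; peak rate 116.6 mL/s
```

The recovered volume is 24.82 mL against a construction truth of 25 mL
(−0.7%), and the fitted background matches the injected one:

```r
round(fit$coefficients, 4)
#>         a0      ax     ay      az
#> vx -2.3383  0.0408 0.0444 -0.0433
#> vy -1.2846 -0.0295 0.0162 -0.0298
#> vz  0.7146  0.0403 0.0125 -0.0315
round(bg$coefficients, 4)   # injected truth
#>         a0      ax     ay      az
#> vx -2.3449  0.0408 0.0445 -0.0438
#> vy -1.2788 -0.0298 0.0161 -0.0294
#> vz  0.7285  0.0398 0.0129 -0.0323
```

Method agreement on a synthetic 10-subject cohort with a prescribed
4D−2D offset of −4 mL (SD 10 mL):

```r
m <- simulate_cohort_measurements(seed = 42)
design <- tibble::tibble(label = "4D vs 2D", factor = "method",
                         test = "4D", ref = "2D")
build_comparison_table(m, design)
#> # A tibble: 3 × 12
#>   label    metric     n n_dropped  bias    sd loa_low loa_high     r slope
#> 1 4D vs 2D AAo       10         0 -3.99  7.14   -18.0     10.0 0.856 0.744
#> 2 4D vs 2D DAo       10         0 -7.17  8.99   -24.8     10.4 0.798 0.963
#> 3 4D vs 2D PA        10         0 -3.61 14.8    -32.7     25.5 0.682 1.08

bland_altman(c(10, 20, 30), c(12, 18, 33))   # bias -1, SD sqrt(7)
#> $bias
#> [1] -1
#> $sd
#> [1] 2.645751
```

## Command-line interface

A thin CLI wraps the same functions (requires `optparse`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "pc4dflow.R", package = "pc4dflow"))')
Rscript $CLI simulate --geometry tube --sv 25 --noise 0.05 \
        --background random --seed 17 --out ds
Rscript $CLI correct --in ds --stationary ds/stationary.nii.gz --out corr
Rscript $CLI unwrap  --in corr --out unw
Rscript $CLI flow    --in unw --plane ds/plane.json --contour ds/roi.json \
        --out curve.csv
```

Datasets on disk are three per-component NIfTI series (`vx/vy/vz.nii.gz`,
cm/s) plus a `sidecar.json` with VENC, RR interval and phase count; planes,
contours and background models are JSON; curves are CSV with `#`-prefixed
metadata lines.

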