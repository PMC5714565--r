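# sirtdose

Voxel-based patient dosimetry for yttrium-90 selective internal radiation
treatment (SIRT, radioembolization), computed from quantitative ⁹⁰Y PET
imaging, with linear-quadratic radiobiology on top.

⁹⁰Y microspheres delivered through the hepatic artery act as a permanent
radioactive implant: the dose rate decays with the 2.67-day physical
half-life (λ = 0.2596 d⁻¹) and the spatial distribution is highly
inhomogeneous. `sirtdose` turns a post-treatment ⁹⁰Y PET count-rate image
into a 3D absorbed-dose map and the derived clinical quantities:

- **Calibration**: scanner sensitivity (cps/MBq) fitted from a
  sphere-insert phantom; count rate → activity concentration (Bq/ml).
- **Dosimetry**: dose-rate map `Ṙ(r) = A(r) ⊗ S(r)` by FFT convolution of
  per-voxel activity with a voxel S-value kernel; total dose by
  integrating the decaying dose rate to infinity, `D = R₀/λ`; export as
  DICOM RT Dose.
- **Kernels**: loading, validation (symmetry, energy check
  `Σ S·m = E_per_decay`), and energy-conserving resampling of voxel
  S-value tables; a self-contained analytic test kernel.
- **DVH**: differential/cumulative histograms per structure with
  volume-weighted statistics.
- **Radiobiology**: per-bin `BED = D(1 + Dλ/((μ+λ)(α/β)))` for the
  permanent-implant dose-rate pattern, `EQ2 = BED/(1 + 2/(α/β))`, and the
  Poisson tumor control probability
  `TCP = Π exp(−ρVᵢ e^{−αDᵢ})` (log-domain safe).
- **Partition model**: the classical two-compartment estimate
  `Dt = 49.8 (A/M) r/(1+(Mt/M)(r−1))`, `Dl = Dt/r`, for comparison with
  the voxel-based result.
- **Synthetic data**: a calibration phantom (four spheres 0.22–65.45 cm³
  at 2.996 MBq/ml in a cold background) and a virtual SIRT patient with
  voxel ground truth, so the whole pipeline runs without clinical data.

Formats: NIfTI (via RNifti) and a minimal DICOM subset (RT Dose
write/read, flat image series) implemented in-package and cross-checked
against pydicom in the tests. See the methods vignette
(`vignettes/sirt-dosimetry.Rmd`) for the model, assumptions, parameter
defaults and limitations.

## Worked example

```r
library(sirtdose)

# virtual patient: 1.2 GBq, 1500 cm^3 liver, 60 cm^3 tumor, uptake ratio 4,
# imaged 5 h after administration
vp <- make_virtual_patient(seed = 7)

# forward-model the PET count-rate image at 0.32 cps/MBq, then run the
# full pipeline: counts -> activity -> convolution -> decay integration
sens <- 0.32
counts <- image_grid(
  vp$activity_truth$values * 1e-6 * voxel_volume_cm3(vp$activity_truth) * sens,
  vp$activity_truth$spacing, vp$activity_truth$origin,
  quantity = "COUNT_RATE", reference_time = vp$t_image_h)
res <- run_dose_pipeline(counts, sens, vp$kernel)

gtv   <- compute_dvh(res$dose, vp$masks$tumor_01)
liver <- compute_dvh(res$dose, vp$masks$normal_liver)
mean_dose_table(list(
  list(curve = gtv,   params = radiobio_params("tumor")),
  list(curve = liver, params = radiobio_params("liver"))))
#>      structure volume_cm3 mean_dose_Gy mean_bed_Gy mean_eq2_Gy
#> 1     tumor_01      59.99       114.57      135.27      112.72
#> 2 normal_liver    1441.21        33.21       43.86       24.37
```

The tumor receives a mean physical dose of 114.6 Gy; bin-wise LQ
conversion of its differential DVH gives a mean BED of 135.3 Gy
(tumor α/β = 10 Gy, repair T½ = 1 h) — more than `bed_from_dose(114.6)`,
because BED is convex in dose — and an EQ2 of 112.7 Gy, the equivalent
total dose in 2 Gy fractions. The normal liver (α/β = 2.5 Gy) sits at
33.2 Gy physical / 24.4 Gy EQ2, the number one would hold against
external-beam liver dose limits.

```r
tcp_from_dvh(gtv, radiobio_params("tumor"))
#> [1] 0.9999199
```

This well-covered synthetic tumor is controlled; add a cold core
(`make_virtual_patient(cold_core_fraction = 0.2)`) and the Poisson TCP
collapses to an exact 0 — one cold cubic centimetre at clonogen density
10⁷ cm⁻³ is unsalvageable, which is why inhomogeneous sphere
distributions show "effectively zero" TCP despite high mean doses.

```r
inp <- partition_inputs(A = 1.2, M = mask_volume_cm3(vp$masks$liver) / 1000,
                        Mt = mask_volume_cm3(vp$masks$tumor_01) / 1000, r = 4)
compare_with_voxel_dose(inp, gtv, liver)
#>    compartment partition_Gy voxel_Gy pct_diff
#> 1       target       142.19   114.57   24.105
#> 2 normal_liver        35.55    33.21    7.032
```

The partition model overestimates the tumor dose by 24% here (it assumes
all tumor activity is uniformly in the tumor compartment, while the voxel
dose map loses energy across the tumor boundary) — the same kind of
discrepancy seen when comparing partition planning with PET-based
dosimetry in patients.

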