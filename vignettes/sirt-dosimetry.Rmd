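---
title: "Voxel-based dosimetry and radiobiology for 90Y radioembolization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based dosimetry and radiobiology for 90Y radioembolization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtdose)
```

## The problem

Selective internal radiation treatment (SIRT) delivers ⁹⁰Y-loaded
microspheres through the hepatic artery. The spheres lodge permanently in
the tumor microvasculature, so the patient receives a continuously
decaying, spatially very inhomogeneous irradiation: a permanent-implant
brachytherapy with no biological clearance. Classical planning uses a
two-compartment *partition model* — one number for the tumor, one for the
normal liver — which ignores both the spatial dose gradients and the
changing dose rate. Because ⁹⁰Y has a tiny internal-pair-production branch,
post-treatment PET imaging shows where the spheres actually went, and a
voxel-level dose map can be computed from it.

`sirtdose` implements that pipeline end to end:

1. **Calibration** — a sphere-insert phantom scan converts the scanner's
   observed count rate into a sensitivity in cps/MBq.
2. **Quantification** — each PET voxel's count rate becomes an activity
   concentration in Bq/ml.
3. **Convolution dosimetry** — the per-voxel activity is convolved with a
   voxel S-value kernel (dose to a target voxel per unit cumulated
   activity in a source voxel, homogeneous unit-density medium) to give
   the instantaneous dose-rate map.
4. **Time integration** — the mono-exponentially decaying dose rate is
   integrated to infinity: `D = R0 / lambda`.
5. **DVH + radiobiology** — differential DVHs per structure are converted
   bin-wise to biologically effective dose (BED), equivalent dose at
   2 Gy/fraction (EQ2), and a Poisson tumor control probability (TCP).

## Physical model and assumptions

*Grid convention.* Voxel index `(i, j, k)` (0-based) sits at
`origin + index * spacing`, axis order (x, y, z) everywhere. One fixed
convention removes the easiest way to get a flipped kernel in the
convolution.

*Dose kernel.* The S-value table is a data input (e.g. the published
6 mm ⁹⁰Y voxel S values); the package validates it (non-negative, central
maximum, reflection symmetry, and the energy check
`sum(S * voxel mass) ≈ E_per_decay` with E = 0.9337 MeV for ⁹⁰Y) and
resamples it to the PET grid pitch. For self-contained tests,
`generate_test_kernel()` builds an analytic kernel by integrating a
normalized exponential point-dose profile `phi(r) = mu^3 e^(-mu r)/(8 pi)`
over voxel volumes. This profile is bounded at the origin, radially
monotone, and trivially normalized; with the default
`mu = 0.35 mm^-1` its ~3 mm mean deposition distance is comparable to ⁹⁰Y
beta transport, but it is *not* the true ⁹⁰Y radial dose profile and is
flagged `synthetic = TRUE`.

*Kernel resampling.* Published kernels come at one pitch (6 mm); PET
grids do not match it (e.g. 5.47 × 5.47 × 3.27 mm). Plain value
interpolation does not conserve energy across anisotropic pitch changes,
so `resample_kernel()` interpolates the deposition density and then
renormalizes so that `sum(S * mass)` is preserved exactly. Trilinear
interpolation was chosen over higher-order schemes because it keeps the
interpolant non-negative (cubic overshoot can produce negative S values
near the steep center), and any residual interpolation bias is absorbed by
the renormalization, which is what the conservation guarantee rests on.

*Convolution.* Zero-padded FFT convolution (activity outside the field of
view is air or absent tissue, i.e. zero). Exactness is not taken on
faith: the test suite compares against a literal direct-summation oracle
on 20³ grids to 1e-10 relative.

*Time integration.* The dose rate at the imaging time `t_ref` is
decay-corrected back to administration
(`R0 = R(t_ref) e^{+lambda (t_ref - t_admin)}`) by default, so the
reported dose is the full delivered dose. Imaging ~5 h after
administration makes this a ~5.6% effect. The correction can be switched
off, which instead reports dose delivered from imaging time onward; the
published workflow does not state which convention it used, so both are
provided with the physically complete one as default.

*Radiobiology.* For a permanent implant with initial dose rate
`R0 = D * lambda` and first-order sublethal-damage repair at rate `mu`,

```
BED = D * (1 + R0 / ((mu + lambda) * (alpha/beta)))
EQ2 = BED / (1 + d / (alpha/beta)),  d = 2 Gy
```

This is the standard Dale permanent-implant form; it is dimensionally
consistent (some published statements of it garble `alpha/beta` and the
direction of the `R0`–`D` relation, and the per-patient BED/EQ2 tables are
only consistent with the form above). The closed form is cross-checked in
the tests against numeric quadrature of the Lea–Catcheside protraction
factor. Because BED is strictly convex in D, applying it to the *mean*
dose understates the mean BED of an inhomogeneous distribution; the
package therefore always transforms the differential DVH bin by bin
(within a 0.5 Gy bin the dose and dose rate are effectively constant) and
averages afterwards.

*TCP.* `TCP = prod_i exp(-rho V_i e^{-alpha D_i})` over dDVH bins, with
`alpha = 0.33 /Gy` and clonogen density `rho = 1e7 /cm^3` (per cm³ is the
only reading that makes `rho V` dimensionless). Accumulation is in the log
domain: `exp(-1e7)` underflows a double, and the product must come out as
an exact 0.0, not NaN. A single cold cubic centimetre of tumor therefore
forces TCP ≈ 0 — which is exactly the clinically observed geographic-miss
behavior this model is meant to expose. By default the physical bin dose
enters the surviving fraction (as the model is usually printed); a BED- or
EQ2-based curve can be passed instead.

*Partition model.* `Dt = 49.8 (A/M) r / (1 + (Mt/M)(r-1))` and
`Dl = 49.8 (A/M) / (1 + (Mt/M)(r-1))` (Gy; A in GBq, masses in kg). The
constant 49.8 Gy·kg/GBq is used as conventionally printed rather than
recomputed from nuclear data (≈49.7); the mass-weighted closure
`Mt Dt + (M-Mt) Dl = 49.8 A` then holds to rounding. The uptake ratio `r`
is consumed as a scalar; planar-scintigraphy ROI counting is out of scope.

## Default parameters

| parameter | default | units | why |
|---|---|---|---|
| ⁹⁰Y half-life | 2.67 | d | physical constant; `lambda = ln2/T = 0.2596/d` |
| mean energy per decay | 0.9337 | MeV | kernel energy bookkeeping |
| scanner sensitivity | 0.32 | cps/MBq | a published clinical PET/CT value for ⁹⁰Y; always refit for your scanner |
| alpha/beta tumor / liver | 10 / 2.5 | Gy | standard LQ values for tumor and late-reacting liver |
| repair T½ tumor / liver | 1.0 / 1.5 | h | standard sublethal-damage repair half-times |
| alpha | 0.33 | 1/Gy | TCP radiosensitivity |
| rho | 1e7 | 1/cm³ | clonogen density |
| d | 2 | Gy | reference fraction size for EQ2 |
| DVH bin width | 0.5 | Gy | ≤1% mean-dose discretization error at SIRT dose scales |
| RT Dose scaling | max/(0.9·65535) | Gy/int | ≥90% of the 16-bit range used; 32-bit optional |

## The synthetic data

No public image data exists for this workflow, so the `synthetic` module
generates the two study objects:

- `make_calibration_phantom()` — four hot spheres (0.22, 2, 16,
  65.45 cm³; the two interior volumes are interpolated within the
  published 0.22–65.45 cm³ range, which only states its extremes) at
  2.996 MBq/ml in a cold background, rasterized on a 4 mm grid (2 mm in
  the resolution test, where the 0.22 cm³ sphere spans 27 voxels).
  Optional isotropic Gaussian blur (default would be ~6 mm FWHM for a
  clinical PET) stands in for the scanner PSF, and Poisson noise is formed
  over a 1800 s acquisition (a 30-minute bed position).
- `make_virtual_patient()` — an ellipsoidal liver (defaults 1500 cm³,
  within the reported 1070–1949 cm³ patient range) with spherical tumors
  (default 60 cm³, range 51.6–350.7 cm³), tumor:normal uptake ratio 4,
  administered activity 1.2 GBq (reported range 1.0–1.3 GBq), imaged 5 h
  after administration. Activity bookkeeping closes exactly on the
  voxelized volumes. Optional cold cores reproduce geographic misses.
  Ground-truth dose is forward-computed with the same kernel machinery and
  flagged as such.

What passing tests on these fixtures shows: unit correctness, energy
conservation, exact linear-systems behavior, and the radiobiological
mechanisms (Jensen gap, TCP collapse). What it does not show: accuracy on
real reconstructed PET (no scatter, randoms, reconstruction artifacts, or
partial-volume bias beyond the Gaussian surrogate), registration error, or
tissue heterogeneity.

## Numerical choices

- FFT convolution with zero padding; negative round-off clipped at 0.
- Trilinear resampling for intensive quantities; nearest-neighbour
  mandatory for masks (output stays binary); `volume_preserving` mode
  renormalizes the interpolated field so the integral over the common
  extent is conserved (for energy-like quantities).
- DVH bins are half-open `[lo, hi)` with the top bin closed; bin-center
  doses enter all transforms (unbiased for uniform bins).
- Kernels are stored center-aligned with odd dimensions; asymmetric input
  tables are symmetrized by mirror averaging (warning above 1%), since
  Monte Carlo tables carry sampling noise.
- TCP log-domain accumulation; the returned value underflows cleanly to 0
  while the `log_tcp` attribute stays finite.
- Problem sizes: tests run at 20³–56³ voxel grids; the end-to-end energy
  conservation check runs a 128³ virtual patient, which completes in a few
  seconds with the FFT path.

## Scope and limitations

- DICOM support is a deliberately minimal explicit-VR-little-endian
  subset: RT Dose write/read and flat single-frame series, written
  in-package because no DICOM toolkit is available to R here; files are
  cross-checked against pydicom in the test suite. No sequences, no
  compressed transfer syntaxes, no RT Structure Set parsing (masks arrive
  as NIfTI volumes).
- NRRD input is not supported (NIfTI and DICOM series are).
- Homogeneous unit-density soft tissue only; no density-scaled kernels,
  no partial-volume recovery of patient images, no registration.
- The scanner sensitivity is a single scalar per protocol; phantom decay
  during acquisition is neglected (⁹⁰Y T½ ≫ scan time, <1%).
- Published per-patient dose tables depend on clinical images that were
  never deposited; the package reproduces the closed-form relations (BED →
  EQ2, partition closure, TCP behavior) and all mechanism-level claims,
  not the patient-specific physical doses.
- NTCP/RILD risk modelling is intentionally absent; the liver EQ2 output
  is what one would compare against external-beam dose limits.
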