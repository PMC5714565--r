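#' Physical decay model for a permanent implant
#'
#' 90Y microspheres have essentially no biological clearance, so the dose
#' rate decays with the physical half-life alone: 2.67 days, giving a decay
#' constant of 0.2596 per day.
#'
#' @param half_life_days physical half-life in days (default 2.67).
#' @return object of class `decay_model` with fields `half_life_days` and
#'   `lambda_per_day = ln 2 / half-life`.
#' @export
decay_model <- function(half_life_days = 2.67) {
  stopifnot(is.numeric(half_life_days), half_life_days > 0)
  structure(list(half_life_days = half_life_days,
                 lambda_per_day = log(2) / half_life_days),
            class = "decay_model")
}

# 3D linear convolution via zero-padded FFT; k center-aligned (odd dims).
# out[i] = sum_m a[m] * k[i - m + center]
conv3d_fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  dp <- da + dk - 1L
  pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(dp)
  c0 <- (dk + 1L) %/% 2L
  full[c0[1]:(c0[1] + da[1] - 1L),
       c0[2]:(c0[2] + da[2] - 1L),
       c0[3]:(c0[3] + da[3] - 1L)]
}

#' Instantaneous dose-rate map from an activity image
#'
#' Converts each voxel's activity concentration (Bq/ml) to activity
#' (Bq = concentration x voxel volume in ml) and convolves with the voxel
#' S-value kernel (Gy per Bq s) to give the absorbed dose rate in Gy/s at
#' the image's reference time. Activity outside the field of view is taken
#' as zero (zero-padded convolution).
#'
#' @param activity an [image_grid()] with quantity `"ACTIVITY_CONC"`.
#' @param kernel a [voxel_kernel()] whose pitch matches the grid spacing
#'   within 0.1% per axis (use [resample_kernel()] first otherwise).
#' @return an [image_grid()] with quantity `"DOSE_RATE"` (Gy/s).
#' @export
dose_rate_map <- function(activity, kernel) {
  stopifnot(inherits(activity, "image_grid"), inherits(kernel, "voxel_kernel"))
  if (activity$quantity != "ACTIVITY_CONC")
    stop("dose_rate_map() expects an ACTIVITY_CONC image", call. = FALSE)
  if (any(activity$values < 0))
    stop("negative activity concentration", call. = FALSE)
  if (any(abs(kernel$pitch - activity$spacing) > 1e-3 * activity$spacing))
    stop(sprintf(
      "kernel pitch (%.4g, %.4g, %.4g) mm does not match grid spacing (%.4g, %.4g, %.4g) mm; resample the kernel first",
      kernel$pitch[1], kernel$pitch[2], kernel$pitch[3],
      activity$spacing[1], activity$spacing[2], activity$spacing[3]),
      call. = FALSE)
  a_bq <- activity$values * voxel_volume_cm3(activity)   # Bq per voxel
  rate <- conv3d_fft(a_bq, kernel$svalues)               # Gy/s
  rate[rate < 0] <- 0                                    # FFT round-off
  image_grid(rate, spacing = activity$spacing, origin = activity$origin,
             quantity = "DOSE_RATE", reference_time = activity$reference_time)
}

#' Integrate a decaying dose rate to total absorbed dose
#'
#' For a permanent implant the dose rate decays as `R(t) = R0 exp(-lambda t)`
#' and the total dose is the integral to infinity, `D = R0 / lambda`. With
#' `decay_correct = TRUE` (default) the measured rate at the imaging time is
#' first corrected back to administration,
#' `R0 = R(t_ref) exp(+lambda (t_ref - t_admin))`, so `D` is the full dose
#' delivered from administration onward; with `FALSE`, `D` is the dose
#' delivered from imaging time onward.
#'
#' @param dose_rate an [image_grid()] with quantity `"DOSE_RATE"` (Gy/s),
#'   whose `reference_time` is in hours since administration.
#' @param decay a [decay_model()].
#' @param t_admin_h administration time, hours, on the same clock as
#'   `reference_time` (default 0).
#' @param decay_correct correct the rate back to administration first.
#' @return an [image_grid()] with quantity `"DOSE"` (Gy).
#' @export
integrate_to_total_dose <- function(dose_rate, decay, t_admin_h = 0,
                                    decay_correct = TRUE) {
  stopifnot(inherits(dose_rate, "image_grid"), inherits(decay, "decay_model"))
  if (dose_rate$quantity != "DOSE_RATE")
    stop("integrate_to_total_dose() expects a DOSE_RATE image", call. = FALSE)
  dt_h <- dose_rate$reference_time - t_admin_h
  if (dt_h < 0)
    stop("reference time precedes administration time", call. = FALSE)
  lambda_s <- decay$lambda_per_day / 86400
  corr <- if (decay_correct) exp(decay$lambda_per_day * dt_h / 24) else 1
  dose <- dose_rate$values * corr / lambda_s
  image_grid(dose, spacing = dose_rate$spacing, origin = dose_rate$origin,
             quantity = "DOSE", reference_time = t_admin_h)
}

#' End-to-end dose pipeline: PET counts to DICOM RT Dose
#'
#' Chains the stages: counts to activity concentration (scanner
#' sensitivity), kernel resampling to the PET pitch, convolution to an
#' instantaneous dose-rate map, optional resampling onto a target (CT)
#' geometry, integration of the decaying dose rate to total dose, and
#' optional DICOM RT Dose export. Dose-rate resampling uses linear
#' interpolation (intensive quantity); because both resampling and time
#' integration are linear, their order does not affect the result.
#'
#' @param pet an [image_grid()] with quantity `"COUNT_RATE"` and
#'   `reference_time` in hours since administration.
#' @param sensitivity scanner sensitivity, cps/MBq.
#' @param kernel a [voxel_kernel()] (any pitch; resampled internally).
#' @param decay a [decay_model()].
#' @param t_admin_h administration time in hours (default 0).
#' @param target_geometry optional `list(spacing=, origin=, dim=)` to
#'   resample the result onto (e.g. a 2.5 mm CT grid); `NULL` keeps the PET
#'   grid.
#' @param rtdose_path optional path: write the final dose as DICOM RT Dose.
#' @param decay_correct see [integrate_to_total_dose()].
#' @return list with `dose` (an [image_grid()], Gy), `activity`,
#'   `dose_rate`, and `summary` (per-stage totals).
#' @export
run_dose_pipeline <- function(pet, sensitivity, kernel, decay = decay_model(),
                              t_admin_h = 0, target_geometry = NULL,
                              rtdose_path = NULL, decay_correct = TRUE) {
  activity <- counts_to_activity(pet, sensitivity)
  k <- resample_kernel(kernel, pet$spacing)
  rate <- dose_rate_map(activity, k)
  if (!is.null(target_geometry)) {
    rate <- resample_to_grid(rate, spacing = target_geometry$spacing,
                             origin = target_geometry$origin,
                             dim = target_geometry$dim, mode = "linear")
  }
  dose <- integrate_to_total_dose(rate, decay, t_admin_h = t_admin_h,
                                  decay_correct = decay_correct)
  total_activity_MBq <- sum(activity$values) * voxel_volume_cm3(activity) * 1e-6
  summary <- list(
    total_activity_at_tref_MBq = total_activity_MBq,
    kernel_energy_J = kernel_energy_j(k),
    max_dose_rate_Gy_per_s = max(rate$values),
    max_dose_Gy = max(dose$values),
    mean_dose_Gy = mean(dose$values),
    total_energy_J = sum(dose$values) * voxel_volume_cm3(dose) / 1000 *
      kernel$medium_density
  )
  if (!is.null(rtdose_path)) write_rtdose(dose, rtdose_path)
  list(dose = dose, activity = activity, dose_rate = rate, summary = summary)
}
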