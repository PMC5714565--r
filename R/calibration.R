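#' Specification of a sphere-insert calibration phantom
#'
#' Describes the physical phantom used to calibrate a PET scanner for 90Y:
#' hot spherical inserts in a cold background. Defaults follow a rectangular
#' phantom with four spheres between 0.22 and 65.45 cm^3 filled at
#' 2.996 MBq/ml in an 8.26 litre cold background.
#'
#' @param insert_volumes sphere volumes in cm^3.
#' @param insert_concentration activity concentration in the inserts, MBq/ml.
#' @param background_volume_l background volume in litres.
#' @param background_concentration background concentration, MBq/ml (0 = cold).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(insert_volumes = c(0.22, 2.0, 16.0, 65.45),
                         insert_concentration = 2.996,
                         background_volume_l = 8.26,
                         background_concentration = 0) {
  if (any(insert_volumes <= 0) || background_volume_l <= 0)
    stop("volumes must be positive", call. = FALSE)
  if (insert_concentration < 0 || background_concentration < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  structure(list(insert_volumes = as.numeric(insert_volumes),
                 insert_concentration = insert_concentration,
                 background_volume_l = background_volume_l,
                 background_concentration = background_concentration),
            class = "phantom_spec")
}

#' Fit scanner sensitivity from a phantom count-rate image
#'
#' For each insert, the mean observed count rate per voxel is divided by the
#' true activity per voxel (true concentration times voxel volume, in MBq)
#' to give a per-insert sensitivity in cps/MBq. The headline sensitivity is
#' the volume-weighted mean over inserts at or above `volume_threshold`;
#' the per-insert values expose the partial-volume roll-off that small
#' spheres show when the image is resolution-blurred.
#'
#' @param count_image an [image_grid()] with quantity `"COUNT_RATE"` (cps
#'   per voxel).
#' @param insert_masks list of [structure_mask()]s, one per insert, ordered
#'   as `spec$insert_volumes`.
#' @param spec a [phantom_spec()].
#' @param volume_threshold include only inserts with true volume >= this
#'   (cm^3) in the combined estimate; default 0 includes all.
#' @return an object of class `calibration_result` with fields
#'   `sensitivity` (cps/MBq, volume-weighted), `sensitivity_mean`
#'   (unweighted), `sensitivity_largest` (largest insert only),
#'   `fit_residuals` (per-insert relative deviation from the combined
#'   value), and `insert_summaries` (data.frame).
#' @export
fit_sensitivity <- function(count_image, insert_masks, spec,
                            volume_threshold = 0) {
  stopifnot(inherits(count_image, "image_grid"), inherits(spec, "phantom_spec"))
  if (count_image$quantity != "COUNT_RATE")
    stop("count_image must have quantity COUNT_RATE", call. = FALSE)
  if (spec$insert_concentration <= 0)
    stop("true insert concentration must be positive", call. = FALSE)
  if (length(insert_masks) != length(spec$insert_volumes))
    stop("one mask per insert volume required", call. = FALSE)
  vv_ml <- voxel_volume_cm3(count_image)
  true_mbq_per_voxel <- spec$insert_concentration * vv_ml
  per <- lapply(seq_along(insert_masks), function(i) {
    m <- insert_masks[[i]]
    stopifnot(inherits(m, "structure_mask"))
    if (!same_geometry(m$grid, count_image))
      stop("insert mask '", m$name, "' is not co-registered to the image",
           call. = FALSE)
    idx <- m$grid$values == 1
    if (!any(idx)) stop("empty insert mask '", m$name, "'", call. = FALSE)
    mean_cps <- mean(count_image$values[idx])
    s <- mean_cps / true_mbq_per_voxel
    data.frame(name = m$name, true_volume_cm3 = spec$insert_volumes[i],
               mask_volume_cm3 = sum(idx) * vv_ml,
               mean_count_rate_cps = mean_cps,
               true_concentration_MBq_ml = spec$insert_concentration,
               sensitivity_cps_per_MBq = s)
  })
  per <- do.call(rbind, per)
  use <- per$true_volume_cm3 >= volume_threshold
  if (!any(use)) stop("volume_threshold excludes every insert", call. = FALSE)
  w <- per$true_volume_cm3[use]
  sens <- sum(w * per$sensitivity_cps_per_MBq[use]) / sum(w)
  per$observed_concentration_MBq_ml <-
    per$mean_count_rate_cps / (sens * vv_ml)
  res <- list(sensitivity = sens,
              sensitivity_mean = mean(per$sensitivity_cps_per_MBq[use]),
              sensitivity_largest =
                per$sensitivity_cps_per_MBq[which.max(per$true_volume_cm3)],
              fit_residuals = per$sensitivity_cps_per_MBq / sens - 1,
              insert_summaries = per)
  class(res) <- "calibration_result"
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> sensitivity %.4g cps/MBq (volume-weighted; unweighted %.4g, largest insert %.4g)\n",
              x$sensitivity, x$sensitivity_mean, x$sensitivity_largest))
  print(x$insert_summaries, row.names = FALSE)
  invisible(x)
}

#' Convert a PET count-rate image to activity concentration
#'
#' Each voxel's activity concentration in Bq/ml is
#' `count rate (cps) / (sensitivity (cps/MBq) * 1e-6 (MBq/Bq) * voxel
#' volume (ml))`. The reference time of the image is propagated.
#'
#' @param count_image an [image_grid()] with quantity `"COUNT_RATE"`.
#' @param sensitivity scanner sensitivity in cps/MBq (> 0).
#' @return an [image_grid()] with quantity `"ACTIVITY_CONC"` (Bq/ml).
#' @export
counts_to_activity <- function(count_image, sensitivity) {
  stopifnot(inherits(count_image, "image_grid"))
  if (count_image$quantity != "COUNT_RATE")
    stop("counts_to_activity() expects a COUNT_RATE image", call. = FALSE)
  if (!is.numeric(sensitivity) || length(sensitivity) != 1 || sensitivity <= 0)
    stop("sensitivity must be a positive scalar (cps/MBq)", call. = FALSE)
  vv_ml <- voxel_volume_cm3(count_image)
  conc <- count_image$values / (sensitivity * 1e-6 * vv_ml)
  image_grid(conc, spacing = count_image$spacing, origin = count_image$origin,
             quantity = "ACTIVITY_CONC",
             reference_time = count_image$reference_time)
}
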