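# Synthetic fixtures: a sphere-insert calibration phantom and a virtual
# SIRT patient with voxel ground truth, so every pipeline stage is testable
# without clinical data.

# Gaussian blur via separable FFT convolution; fwhm in mm, zero-padded edges
gauss_blur <- function(values, fwhm_mm, spacing) {
  if (fwhm_mm <= 0) return(values)
  out <- values
  for (ax in 1:3) {
    sigma_vox <- fwhm_mm / 2.354820045 / spacing[ax]
    n <- max(3L, 2L * as.integer(ceiling(4 * sigma_vox)) + 1L)
    x <- seq_len(n) - (n + 1) / 2
    g <- exp(-x^2 / (2 * sigma_vox^2))
    g <- g / sum(g)
    kd <- c(1L, 1L, 1L); kd[ax] <- n
    out <- conv3d_fft(out, array(g, kd))
  }
  out[out < 0] <- 0
  out
}

# rasterize a sphere on a grid geometry: 1 where the voxel center is within
# `radius_mm` of `center_mm`
rasterize_sphere <- function(spacing, origin, dim, center_mm, radius_mm) {
  tc <- target_coords(spacing, origin, dim)
  inside <- (tc$px - center_mm[1])^2 + (tc$py - center_mm[2])^2 +
    (tc$pz - center_mm[3])^2 <= radius_mm^2
  array(as.numeric(inside), dim)
}

sphere_radius_mm <- function(volume_cm3) (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)

#' Simulate a PET acquisition of the calibration phantom
#'
#' Rasterizes the phantom's hot spheres on the grid (sphere centers snapped
#' to voxel centers, spaced along x), converts the activity map to an
#' expected count-rate image through the given scanner sensitivity,
#' optionally applies a Gaussian point-spread surrogate and Poisson counting
#' noise, and returns the image together with the true geometric insert
#' masks.
#'
#' @param spec a [phantom_spec()].
#' @param spacing,dim grid geometry (mm, voxels); origin is centered on the
#'   grid.
#' @param sensitivity scanner sensitivity, cps/MBq.
#' @param noise `"none"` or `"poisson"`.
#' @param blur_fwhm_mm PSF surrogate FWHM in mm (0 = no blur).
#' @param acq_time_s acquisition time used to form Poisson counts
#'   (default 1800 s, a 30-minute bed position).
#' @param seed RNG seed for the noise path.
#' @return list with `count_image` (an [image_grid()], cps per voxel),
#'   `insert_masks` (list of [structure_mask()]), `activity_truth`
#'   (MBq/ml), and `seed`.
#' @export
make_calibration_phantom <- function(spec = phantom_spec(),
                                     spacing = c(4, 4, 4),
                                     dim = c(80, 80, 60),
                                     sensitivity = 0.32,
                                     noise = c("none", "poisson"),
                                     blur_fwhm_mm = 0,
                                     acq_time_s = 1800,
                                     seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "phantom_spec"))
  spacing <- as.numeric(spacing); dim <- as.integer(dim)
  extent_mm <- dim * spacing
  origin <- -extent_mm / 2 + spacing / 2
  radii <- sphere_radius_mm(spec$insert_volumes)
  n <- length(radii)
  # spread centers along x with margin, snapped to voxel centers
  slots <- (seq_len(n) - (n + 1) / 2) * (extent_mm[1] / (n + 0.5))
  snap <- function(x, ax) origin[ax] + round((x - origin[ax]) / spacing[ax]) *
    spacing[ax]
  centers <- lapply(seq_len(n), function(i)
    c(snap(slots[i], 1), snap(0, 2), snap(0, 3)))
  masks <- vector("list", n)
  conc <- array(0, dim)                               # MBq/ml
  for (i in seq_len(n)) {
    if (2 * radii[i] > min(extent_mm) * 0.9)
      stop("insert ", i, " does not fit in the grid", call. = FALSE)
    m <- rasterize_sphere(spacing, origin, dim, centers[[i]], radii[i])
    if (i > 1) {
      prev <- Reduce(`+`, lapply(masks[seq_len(i - 1)],
                                 function(s) s$grid$values))
      if (any(m * prev > 0)) stop("overlapping inserts", call. = FALSE)
    }
    conc <- conc + m * spec$insert_concentration
    masks[[i]] <- structure_mask(
      sprintf("insert_%02d", i),
      image_grid(m, spacing, origin, quantity = "MASK"))
  }
  conc[conc == 0] <- spec$background_concentration
  vv_ml <- prod(spacing) / 1000
  rate <- conc * vv_ml * sensitivity                  # cps per voxel
  if (blur_fwhm_mm > 0) rate <- gauss_blur(rate, blur_fwhm_mm, spacing)
  if (noise == "poisson") {
    if (!is.null(seed)) set.seed(seed)
    rate <- array(stats::rpois(length(rate), rate * acq_time_s) / acq_time_s,
                  dim)
  }
  list(count_image = image_grid(rate, spacing, origin,
                                quantity = "COUNT_RATE"),
       insert_masks = masks,
       activity_truth = image_grid(conc, spacing, origin,
                                   quantity = "ACTIVITY_CONC"),
       seed = seed)
}

#' Build a virtual SIRT patient with voxel ground truth
#'
#' An ellipsoidal liver containing spherical tumors on a regular grid.
#' Activity is distributed so the tumor:normal-liver concentration ratio
#' equals `ratio`, the total in-liver activity at the imaging time equals
#' the administered activity decayed from administration (minus any
#' extrahepatic fraction), with activity bookkeeping closing exactly on the
#' voxelized volumes. Optional cold cores inside the tumors reproduce the
#' geographic misses that drive the Poisson TCP to zero. The ground-truth
#' dose is forward-computed with the supplied kernel (decay-corrected to
#' administration).
#'
#' @param liver_volume_cm3 liver volume (default 1500).
#' @param tumor_volumes_cm3 one volume per tumor (default 60).
#' @param ratio tumor:normal activity concentration ratio (default 4).
#' @param admin_activity_GBq administered activity (default 1.2).
#' @param kernel a [voxel_kernel()]; resampled to the grid pitch
#'   internally.
#' @param spacing,dim grid geometry (default 3 mm, 96^3); origin centered.
#' @param t_image_h imaging time, hours after administration (default 5).
#' @param cold_core_fraction fraction of each tumor's volume made cold
#'   (0 = none).
#' @param extrahepatic_fraction activity fraction assumed outside the liver
#'   (not imaged; default 0).
#' @param decay a [decay_model()].
#' @param seed RNG seed controlling tumor placement.
#' @return object of class `virtual_patient`: `activity_truth` (Bq/ml at
#'   `t_image_h`), `dose_truth` (Gy, from administration), `masks` (named
#'   list: `liver`, `tumor_01`..., plus `normal_liver`), `admin_activity_GBq`,
#'   `t_image_h`, `ratio`, `seed`.
#' @export
make_virtual_patient <- function(liver_volume_cm3 = 1500,
                                 tumor_volumes_cm3 = 60,
                                 ratio = 4,
                                 admin_activity_GBq = 1.2,
                                 kernel = generate_test_kernel(pitch = c(3, 3, 3),
                                                               extent = 15),
                                 spacing = c(3, 3, 3),
                                 dim = c(96, 96, 96),
                                 t_image_h = 5,
                                 cold_core_fraction = 0,
                                 extrahepatic_fraction = 0,
                                 decay = decay_model(),
                                 seed = 1) {
  stopifnot(liver_volume_cm3 > 0, all(tumor_volumes_cm3 > 0), ratio > 0,
            admin_activity_GBq > 0, cold_core_fraction >= 0,
            cold_core_fraction < 1,
            extrahepatic_fraction >= 0, extrahepatic_fraction < 1)
  spacing <- as.numeric(spacing); dim <- as.integer(dim)
  set.seed(seed)
  extent_mm <- dim * spacing
  origin <- -extent_mm / 2 + spacing / 2
  # ellipsoid semi-axes with 1.4 : 1 : 0.8 aspect, volume = liver volume
  s0 <- (3 * liver_volume_cm3 * 1000 / (4 * pi * 1.4 * 1 * 0.8))^(1 / 3)
  semi <- s0 * c(1.4, 1, 0.8)
  if (any(2 * semi > 0.95 * extent_mm))
    stop("liver does not fit in the grid", call. = FALSE)
  tc <- target_coords(spacing, origin, dim)
  liver <- array(as.numeric((tc$px / semi[1])^2 + (tc$py / semi[2])^2 +
                              (tc$pz / semi[3])^2 <= 1), dim)
  tumor_all <- array(0, dim)
  cold_all <- array(0, dim)
  tumor_masks <- list()
  for (i in seq_along(tumor_volumes_cm3)) {
    rad <- sphere_radius_mm(tumor_volumes_cm3[i])
    placed <- FALSE
    for (try in 1:200) {
      u <- stats::runif(3, -0.6, 0.6)
      ctr <- u * semi
      # tumor fully inside the liver ellipsoid?
      if (sum(((abs(ctr) + rad) / semi)^2) > 1) next
      m <- rasterize_sphere(spacing, origin, dim, ctr, rad)
      if (any(m * tumor_all > 0)) next
      tumor_all <- tumor_all + m
      if (cold_core_fraction > 0) {
        crad <- rad * cold_core_fraction^(1 / 3)
        cold_all <- cold_all + rasterize_sphere(spacing, origin, dim, ctr,
                                                crad) * m
      }
      tumor_masks[[sprintf("tumor_%02d", i)]] <- structure_mask(
        sprintf("tumor_%02d", i), image_grid(m, spacing, origin,
                                             quantity = "MASK"))
      placed <- TRUE
      break
    }
    if (!placed) stop("could not place tumor ", i, " inside the liver",
                      call. = FALSE)
  }
  cold_all <- pmin(cold_all, 1)
  liver <- pmax(liver, tumor_all)                     # tumors count as liver
  normal <- liver * (1 - tumor_all)
  hot_tumor <- tumor_all * (1 - cold_all)
  vv_ml <- prod(spacing) / 1000
  v_hot_t <- sum(hot_tumor) * vv_ml                   # ml
  v_norm <- sum(normal) * vv_ml
  # total activity present at the imaging time, Bq
  a_img <- admin_activity_GBq * 1e9 *
    exp(-decay$lambda_per_day * t_image_h / 24) * (1 - extrahepatic_fraction)
  c_norm <- a_img / (ratio * v_hot_t + v_norm)        # Bq/ml
  conc <- c_norm * (normal + ratio * hot_tumor)
  activity <- image_grid(conc, spacing, origin, quantity = "ACTIVITY_CONC",
                         reference_time = t_image_h)
  k <- resample_kernel(kernel, spacing)
  rate <- dose_rate_map(activity, k)
  dose <- integrate_to_total_dose(rate, decay, t_admin_h = 0,
                                  decay_correct = TRUE)
  masks <- c(list(liver = structure_mask("liver",
                    image_grid(liver, spacing, origin, quantity = "MASK")),
                  normal_liver = structure_mask("normal_liver",
                    image_grid(normal, spacing, origin, quantity = "MASK"))),
             tumor_masks)
  structure(list(activity_truth = activity, dose_truth = dose, masks = masks,
                 admin_activity_GBq = admin_activity_GBq,
                 t_image_h = t_image_h, ratio = ratio,
                 extrahepatic_fraction = extrahepatic_fraction,
                 decay = decay, kernel = k, seed = seed),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("<virtual_patient> %.3g GBq administered, imaged at %.3g h, ratio %.3g\n",
              x$admin_activity_GBq, x$t_image_h, x$ratio))
  for (m in x$masks) print(m)
  invisible(x)
}
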