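.quantities <- c("COUNT_RATE", "ACTIVITY_CONC", "DOSE_RATE", "DOSE", "MASK")

#' 3D image grid
#'
#' The common container for every volumetric quantity in the pipeline: PET
#' count-rate maps (cps per voxel), activity concentration (Bq/ml), dose rate
#' (Gy/s), absorbed dose (Gy), and binary structure masks. Voxel index
#' `(i, j, k)` (0-based) maps to the physical position
#' `origin + index * spacing`; axis order is (x, y, z) throughout,
#' independent of on-disk layout.
#'
#' @param values 3D numeric array, all finite. For `quantity = "MASK"` only
#'   values 0 and 1 are allowed.
#' @param spacing voxel pitch (dx, dy, dz) in mm, strictly positive.
#' @param origin physical position of voxel (0,0,0) in mm.
#' @param quantity one of `"COUNT_RATE"` (cps), `"ACTIVITY_CONC"` (Bq/ml),
#'   `"DOSE_RATE"` (Gy/s), `"DOSE"` (Gy), `"MASK"`.
#' @param reference_time time the values refer to, in hours relative to
#'   administration of the activity.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(values, spacing, origin = c(0, 0, 0),
                       quantity = c("COUNT_RATE", "ACTIVITY_CONC",
                                    "DOSE_RATE", "DOSE", "MASK"),
                       reference_time = 0) {
  quantity <- match.arg(quantity)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite numbers (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("grid values must all be finite", call. = FALSE)
  if (quantity == "MASK" && !all(values %in% c(0, 1)))
    stop("MASK grids may contain only 0 and 1", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         quantity = quantity, reference_time = reference_time),
    class = "image_grid"
  )
}

#' Voxel volume of a grid in cm^3
#' @param grid an `image_grid`.
#' @return scalar voxel volume in cm^3 (equivalently ml).
#' @export
voxel_volume_cm3 <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  prod(grid$spacing) / 1000
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_grid> %s  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$quantity, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, t_ref %.3g h, range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3], x$reference_time,
              min(x$values), max(x$values)))
  invisible(x)
}

# geometry equality to a relative tolerance on spacing and an absolute
# tolerance (fraction of a voxel) on origin
same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing - b$spacing) <= tol * a$spacing) &&
    all(abs(a$origin - b$origin) <= tol * pmax(a$spacing, 1))
}

# physical coordinates of voxel centers along one axis
axis_coords <- function(grid, axis) {
  n <- dim(grid$values)[axis]
  grid$origin[axis] + (seq_len(n) - 1) * grid$spacing[axis]
}

#' Named binary structure mask
#'
#' A structure (e.g. `"GTV"`, `"normal_liver"`) represented as a binary
#' `image_grid` co-registered to the grid it annotates.
#'
#' @param name structure label.
#' @param grid an `image_grid` with `quantity = "MASK"`.
#' @return an object of class `structure_mask`.
#' @export
structure_mask <- function(name, grid) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(grid, "image_grid") || grid$quantity != "MASK")
    stop("`grid` must be an image_grid with quantity MASK", call. = FALSE)
  structure(list(name = name, grid = grid), class = "structure_mask")
}

#' Volume of a structure mask in cm^3
#' @param mask a `structure_mask`.
#' @return volume in cm^3 (count of 1-voxels times the voxel volume).
#' @export
mask_volume_cm3 <- function(mask) {
  stopifnot(inherits(mask, "structure_mask"))
  sum(mask$grid$values) * voxel_volume_cm3(mask$grid)
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> '%s': %.3g cm^3 (%d voxels)\n",
              x$name, mask_volume_cm3(x), sum(x$grid$values)))
  invisible(x)
}
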