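# Trilinear sampling of a 3D array at arbitrary physical points.
# Points outside the span of voxel centers get `fill`.
trilinear_sample <- function(values, spacing, origin, px, py, pz, fill = 0) {
  d <- dim(values)
  fx <- (px - origin[1]) / spacing[1]
  fy <- (py - origin[2]) / spacing[2]
  fz <- (pz - origin[3]) / spacing[3]
  ok <- fx >= 0 & fx <= d[1] - 1 & fy >= 0 & fy <= d[2] - 1 &
        fz >= 0 & fz <= d[3] - 1
  i0 <- pmin(pmax(floor(fx), 0), max(d[1] - 2, 0))
  j0 <- pmin(pmax(floor(fy), 0), max(d[2] - 2, 0))
  k0 <- pmin(pmax(floor(fz), 0), max(d[3] - 2, 0))
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  tz <- pmin(pmax(fz - k0, 0), 1)
  i1 <- pmin(i0 + 1, d[1] - 1); j1 <- pmin(j0 + 1, d[2] - 1)
  k1 <- pmin(k0 + 1, d[3] - 1)
  g <- function(i, j, k) values[cbind(i + 1, j + 1, k + 1)]
  out <- (1 - tx) * (1 - ty) * (1 - tz) * g(i0, j0, k0) +
         tx       * (1 - ty) * (1 - tz) * g(i1, j0, k0) +
         (1 - tx) * ty       * (1 - tz) * g(i0, j1, k0) +
         tx       * ty       * (1 - tz) * g(i1, j1, k0) +
         (1 - tx) * (1 - ty) * tz       * g(i0, j0, k1) +
         tx       * (1 - ty) * tz       * g(i1, j0, k1) +
         (1 - tx) * ty       * tz       * g(i0, j1, k1) +
         tx       * ty       * tz       * g(i1, j1, k1)
  out[!ok] <- fill
  out
}

nearest_sample <- function(values, spacing, origin, px, py, pz, fill = 0) {
  d <- dim(values)
  i <- round((px - origin[1]) / spacing[1])
  j <- round((py - origin[2]) / spacing[2])
  k <- round((pz - origin[3]) / spacing[3])
  ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
  i <- pmin(pmax(i, 0), d[1] - 1)
  j <- pmin(pmax(j, 0), d[2] - 1)
  k <- pmin(pmax(k, 0), d[3] - 1)
  out <- values[cbind(i + 1, j + 1, k + 1)]
  out[!ok] <- fill
  out
}

# flattened (x fastest) physical coordinates of all voxel centers of a target
# geometry; returns list(px, py, pz) each of length prod(dim)
target_coords <- function(spacing, origin, dim) {
  xs <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  list(px = rep(xs, times = dim[2] * dim[3]),
       py = rep(rep(ys, each = dim[1]), times = dim[3]),
       pz = rep(zs, each = dim[1] * dim[2]))
}

#' Resample an image grid onto a new geometry
#'
#' Intensive quantities (Bq/ml, Gy/s, Gy, counts) are interpolated
#' trilinearly (`mode = "linear"`); masks must use `"nearest"` so that the
#' output stays binary. `"volume_preserving"` treats `value * voxel volume`
#' as an extensive quantity: values are interpolated linearly, then globally
#' rescaled so the integral over the common extent is conserved.
#' Target voxels outside the source extent are set to 0 (absent tissue
#' carries no activity or dose).
#'
#' @param src an [image_grid()].
#' @param spacing,origin,dim target geometry (mm, mm, voxel counts).
#' @param mode `"linear"`, `"nearest"`, or `"volume_preserving"`.
#' @return an [image_grid()] on the target geometry.
#' @export
resample_to_grid <- function(src, spacing, origin, dim,
                             mode = c("linear", "nearest",
                                      "volume_preserving")) {
  stopifnot(inherits(src, "image_grid"))
  mode <- match.arg(mode)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  dim <- as.integer(dim)
  if (src$quantity == "MASK" && mode != "nearest")
    stop("MASK grids must be resampled with mode = \"nearest\"", call. = FALSE)
  # overlap check on bounding boxes of voxel centers
  src_lo <- src$origin
  src_hi <- src$origin + (base::dim(src$values) - 1) * src$spacing
  tgt_lo <- origin
  tgt_hi <- origin + (dim - 1) * spacing
  if (any(tgt_hi < src_lo) || any(tgt_lo > src_hi))
    stop("target geometry does not overlap the source grid", call. = FALSE)
  tc <- target_coords(spacing, origin, dim)
  out <- if (mode == "nearest") {
    nearest_sample(src$values, src$spacing, src$origin,
                   tc$px, tc$py, tc$pz, fill = 0)
  } else {
    trilinear_sample(src$values, src$spacing, src$origin,
                     tc$px, tc$py, tc$pz, fill = 0)
  }
  out <- array(out, dim = dim)
  if (mode == "volume_preserving") {
    # conserve the integral over the common extent: source voxels whose
    # centers fall inside the target bounding box vs all target voxels
    sc <- target_coords(src$spacing, src$origin, base::dim(src$values))
    inside <- sc$px >= tgt_lo[1] - spacing[1] / 2 &
              sc$px <= tgt_hi[1] + spacing[1] / 2 &
              sc$py >= tgt_lo[2] - spacing[2] / 2 &
              sc$py <= tgt_hi[2] + spacing[2] / 2 &
              sc$pz >= tgt_lo[3] - spacing[3] / 2 &
              sc$pz <= tgt_hi[3] + spacing[3] / 2
    total_src <- sum(src$values[inside]) * prod(src$spacing)
    total_out <- sum(out) * prod(spacing)
    if (total_out > 0) out <- out * (total_src / total_out)
  }
  image_grid(out, spacing = spacing, origin = origin,
             quantity = src$quantity, reference_time = src$reference_time)
}
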