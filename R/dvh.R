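#' Differential dose-volume histogram of a structure
#'
#' Histograms the voxel doses inside the mask; every voxel contributes its
#' full volume to the bin containing its dose (bins are half-open
#' `[lo, hi)`, top bin closed). Voxel-wise mean, volume-weighted SD, min and
#' max are attached.
#'
#' @param dose an [image_grid()] with quantity `"DOSE"` (or a transformed
#'   dose quantity on the same grid).
#' @param mask a [structure_mask()] co-registered to `dose`.
#' @param bin_width bin width in Gy (default 0.5).
#' @param dose_quantity label of the histogrammed quantity:
#'   `"PHYSICAL"`, `"BED"` or `"EQ2"`.
#' @return object of class `dvh_curve`: `bin_edges` (length nbins + 1),
#'   `diff_volume` (cm^3 per bin), `structure`, `total_volume`,
#'   `dose_quantity`, `mean`, `sd`, `min`, `max`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.5,
                        dose_quantity = "PHYSICAL") {
  stopifnot(inherits(dose, "image_grid"), inherits(mask, "structure_mask"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  if (!same_geometry(mask$grid, dose))
    stop("mask '", mask$name, "' is not co-registered to the dose grid",
         call. = FALSE)
  inside <- mask$grid$values == 1
  if (!any(inside)) stop("empty mask '", mask$name, "'", call. = FALSE)
  v <- dose$values[inside]
  vv <- voxel_volume_cm3(dose)
  nbins <- max(1L, as.integer(ceiling((max(v) + 1e-12) / bin_width)))
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), nbins)
  counts <- tabulate(idx, nbins = nbins)
  m <- mean(v)
  structure(list(bin_edges = edges, diff_volume = counts * vv,
                 structure = mask$name, total_volume = sum(inside) * vv,
                 dose_quantity = dose_quantity,
                 mean = m, sd = sqrt(mean((v - m)^2)),
                 min = min(v), max = max(v)),
            class = "dvh_curve")
}

dvh_bin_centers <- function(curve) {
  e <- curve$bin_edges
  (e[-1] + e[-length(e)]) / 2
}

#' Cumulative DVH from a differential curve
#'
#' @param curve a `dvh_curve`.
#' @return data.frame with `dose` (lower bin edges) and `volume_cm3`, the
#'   volume receiving at least that dose: non-increasing, starting at the
#'   total volume.
#' @export
cumulative_dvh <- function(curve) {
  stopifnot(inherits(curve, "dvh_curve"))
  v <- rev(cumsum(rev(curve$diff_volume)))
  data.frame(dose = curve$bin_edges[-length(curve$bin_edges)],
             volume_cm3 = v)
}

#' Summary statistics of a DVH curve
#'
#' Statistics recomputed from bin centers weighted by per-bin volume (the
#' histogram-level view; `curve$mean` etc. retain the voxel-exact values
#' where the curve came from [compute_dvh()]).
#'
#' @param curve a `dvh_curve`.
#' @param v_thresholds optional numeric vector of dose thresholds x; for
#'   each, Vx = volume (cm^3) with dose >= x is reported (bin centers
#'   compared inclusively).
#' @return list with `mean`, `sd` (volume-weighted population SD), `dmin`,
#'   `dmax`, `total_volume`, and `vx` (named numeric vector, cm^3).
#' @export
dvh_statistics <- function(curve, v_thresholds = NULL) {
  stopifnot(inherits(curve, "dvh_curve"))
  ctr <- dvh_bin_centers(curve)
  w <- curve$diff_volume
  tw <- sum(w)
  m <- sum(w * ctr) / tw
  occ <- which(w > 0)
  vx <- NULL
  if (!is.null(v_thresholds)) {
    vx <- vapply(v_thresholds, function(x) sum(w[ctr >= x]), numeric(1))
    names(vx) <- sprintf("V%g", v_thresholds)
  }
  list(mean = m,
       sd = sqrt(sum(w * (ctr - m)^2) / tw),
       dmin = curve$bin_edges[min(occ)],
       dmax = curve$bin_edges[max(occ) + 1L],
       total_volume = tw,
       vx = vx)
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s '%s': %.4g cm^3, mean %.4g +/- %.4g Gy, range [%.4g, %.4g]\n",
              x$dose_quantity, x$structure, x$total_volume, x$mean, x$sd,
              x$min, x$max))
  invisible(x)
}

#' Export a DVH as CSV
#'
#' Columns: `bin_lo`, `bin_hi`, `diff_cm3`, `cum_cm3`.
#'
#' @param curve a `dvh_curve`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dvh_csv <- function(curve, path) {
  stopifnot(inherits(curve, "dvh_curve"))
  e <- curve$bin_edges
  df <- data.frame(bin_lo = e[-length(e)], bin_hi = e[-1],
                   diff_cm3 = curve$diff_volume,
                   cum_cm3 = rev(cumsum(rev(curve$diff_volume))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a DVH written by [write_dvh_csv()]
#' @param path CSV file.
#' @param structure structure name for the curve (default: file stem).
#' @param dose_quantity quantity label (default `"PHYSICAL"`).
#' @return a `dvh_curve`.
#' @export
read_dvh_csv <- function(path, structure = NULL, dose_quantity = "PHYSICAL") {
  df <- utils::read.csv(path)
  if (is.null(structure))
    structure <- sub("\\.csv$", "", basename(path))
  edges <- c(df$bin_lo, df$bin_hi[nrow(df)])
  ctr <- (edges[-1] + edges[-length(edges)]) / 2
  w <- df$diff_cm3
  m <- sum(w * ctr) / sum(w)
  base::structure(list(bin_edges = edges, diff_volume = w,
                       structure = structure, total_volume = sum(w),
                       dose_quantity = dose_quantity,
                       mean = m, sd = sqrt(sum(w * (ctr - m)^2) / sum(w)),
                       min = edges[min(which(w > 0))],
                       max = edges[max(which(w > 0)) + 1L]),
                  class = "dvh_curve")
}
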