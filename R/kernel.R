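# physical constants for the default nuclide
.y90_mean_energy_MeV <- 0.9337     # mean emitted energy per decay
.mev_to_joule <- 1.602176634e-13

#' Voxel S-value kernel
#'
#' A center-aligned 3D table of S values: the absorbed dose (Gy) to the
#' target voxel per unit cumulated activity (Bq s) in the source voxel, for
#' a homogeneous unit-density medium. Dimensions are odd on every axis so
#' that the central entry is the self-dose S(0,0,0).
#'
#' @param svalues 3D array with odd dimensions, non-negative, maximum at the
#'   center.
#' @param pitch voxel pitch (dx, dy, dz) in mm.
#' @param nuclide label, default `"Y90"`.
#' @param medium_density g/cm^3 (default 1, soft tissue).
#' @param mean_energy_MeV mean emitted energy per decay used by the energy
#'   check.
#' @param synthetic flag marking analytically generated (non-tabulated)
#'   kernels.
#' @param truncation_tol allowed relative deficit of `sum(S * voxel mass)`
#'   against the energy per decay, to absorb the finite table extent
#'   (default 5%).
#' @return an object of class `voxel_kernel`.
#' @export
voxel_kernel <- function(svalues, pitch, nuclide = "Y90", medium_density = 1,
                         mean_energy_MeV = .y90_mean_energy_MeV,
                         synthetic = FALSE, truncation_tol = 0.05) {
  if (!is.array(svalues) || length(dim(svalues)) != 3L)
    stop("svalues must be a 3D array", call. = FALSE)
  d <- dim(svalues)
  if (any(d %% 2 == 0))
    stop("kernel dimensions must be odd (center-aligned)", call. = FALSE)
  pitch <- as.numeric(pitch)
  if (length(pitch) != 3L || any(pitch <= 0))
    stop("pitch must be three positive numbers (mm)", call. = FALSE)
  if (any(svalues < 0) || any(!is.finite(svalues)))
    stop("S values must be finite and non-negative", call. = FALSE)
  ctr <- (d + 1) %/% 2
  if (svalues[ctr[1], ctr[2], ctr[3]] < max(svalues) * (1 - 1e-12))
    stop("central S(0,0,0) must be the kernel maximum", call. = FALSE)
  k <- structure(list(svalues = svalues, pitch = pitch, nuclide = nuclide,
                      medium_density = medium_density,
                      mean_energy_MeV = mean_energy_MeV,
                      synthetic = synthetic),
                 class = "voxel_kernel")
  # reflection symmetry
  asym <- kernel_asymmetry(k)
  if (asym > 1e-9)
    stop(sprintf("kernel not reflection-symmetric (relative asymmetry %.3g)",
                 asym), call. = FALSE)
  # energy check: sum S * voxel mass ~ mean energy per decay
  e <- kernel_energy_j(k)
  e_decay <- mean_energy_MeV * .mev_to_joule
  if (abs(e - e_decay) > truncation_tol * e_decay)
    stop(sprintf(
      "kernel energy check failed: sum(S*mass) = %.4g J vs %.4g J per decay (tolerance %.3g)",
      e, e_decay, truncation_tol), call. = FALSE)
  k
}

#' Total energy represented by a kernel
#'
#' `sum(S * voxel mass)` in joules per decay; for an untruncated kernel this
#' equals the nuclide's mean emitted energy per decay.
#' @param k a [voxel_kernel()].
#' @return energy in J.
#' @export
kernel_energy_j <- function(k) {
  mass_kg <- prod(k$pitch) / 1000 * k$medium_density / 1000
  sum(k$svalues) * mass_kg
}

# max relative deviation under reflection of each axis
kernel_asymmetry <- function(k) {
  s <- k$svalues
  mx <- max(s)
  if (mx == 0) return(0)
  rev1 <- s[rev(seq_len(dim(s)[1])), , ]
  rev2 <- s[, rev(seq_len(dim(s)[2])), ]
  rev3 <- s[, , rev(seq_len(dim(s)[3]))]
  max(abs(s - rev1), abs(s - rev2), abs(s - rev3)) / mx
}

#' @export
print.voxel_kernel <- function(x, ...) {
  d <- dim(x$svalues)
  cat(sprintf("<voxel_kernel> %s%s  %dx%dx%d @ %.3g x %.3g x %.3g mm\n",
              x$nuclide, if (isTRUE(x$synthetic)) " (synthetic)" else "",
              d[1], d[2], d[3], x$pitch[1], x$pitch[2], x$pitch[3]))
  cat(sprintf("  S(0,0,0) = %.4g Gy/(Bq s); sum S*mass = %.4g J (E per decay %.4g J)\n",
              max(x$svalues), kernel_energy_j(x),
              x$mean_energy_MeV * .mev_to_joule))
  invisible(x)
}

#' Load a voxel S-value kernel from a text table
#'
#' Format: optional `#`-prefixed header lines `# nuclide: Y90`,
#' `# pitch_mm: 6 6 6`, `# density_g_cm3: 1`, then whitespace-separated rows
#' `i j k S` giving the S value (Gy per Bq s) at integer voxel offset
#' `(i, j, k)`. Offsets may cover all octants or only one (expanded by
#' reflection symmetry); missing far offsets are filled with zero. Tables
#' carrying Monte Carlo noise are symmetrized by averaging mirror pairs,
#' with a warning above 1% asymmetry.
#'
#' @param path table file.
#' @param pitch pitch override (mm) when the file has no header.
#' @param truncation_tol passed to [voxel_kernel()].
#' @return a [voxel_kernel()].
#' @export
load_kernel <- function(path, pitch = NULL, truncation_tol = 0.05) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  get_hdr <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) == 0) return(NULL)
    trimws(sub(paste0("^\\s*#\\s*", key, "\\s*:"), "", m[1]))
  }
  nuclide <- get_hdr("nuclide"); if (is.null(nuclide)) nuclide <- "Y90"
  p <- get_hdr("pitch_mm")
  if (!is.null(p)) pitch <- as.numeric(strsplit(p, "\\s+")[[1]])
  if (is.null(pitch)) stop("kernel file has no pitch header and no pitch ",
                           "argument was given", call. = FALSE)
  dens <- get_hdr("density_g_cm3")
  dens <- if (is.null(dens)) 1 else as.numeric(dens)
  en <- get_hdr("mean_energy_MeV")
  en <- if (is.null(en)) .y90_mean_energy_MeV else as.numeric(en)
  body <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(body) == 0) stop("empty kernel table", call. = FALSE)
  tab <- utils::read.table(text = body, col.names = c("i", "j", "k", "S"))
  if (any(tab$S < 0)) stop("negative S value in kernel table", call. = FALSE)
  if (!any(tab$i == 0 & tab$j == 0 & tab$k == 0))
    stop("kernel table does not cover the center offset (0,0,0)",
         call. = FALSE)
  half <- c(max(abs(tab$i)), max(abs(tab$j)), max(abs(tab$k)))
  d <- 2L * half + 1L
  acc <- array(0, d); cnt <- array(0L, d)
  # accumulate every octant reflection of every row, then average: this both
  # expands octant-only tables and symmetrizes noisy full tables
  signs <- expand.grid(sx = c(-1, 1), sy = c(-1, 1), sz = c(-1, 1))
  raw <- array(NA_real_, d)
  idx0 <- cbind(tab$i + half[1] + 1, tab$j + half[2] + 1, tab$k + half[3] + 1)
  raw[idx0] <- tab$S
  for (r in seq_len(nrow(signs))) {
    ii <- tab$i * signs$sx[r] + half[1] + 1
    jj <- tab$j * signs$sy[r] + half[2] + 1
    kk <- tab$k * signs$sz[r] + half[3] + 1
    idx <- cbind(ii, jj, kk)
    acc[idx] <- acc[idx] + tab$S
    cnt[idx] <- cnt[idx] + 1L
  }
  s <- array(0, d)
  nz <- cnt > 0
  s[nz] <- acc[nz] / cnt[nz]
  # warn if the supplied (pre-symmetrization) values disagreed noticeably
  have <- !is.na(raw)
  if (any(have)) {
    rel <- abs(raw[have] - s[have]) / max(s)
    if (max(rel) > 0.01)
      warning(sprintf("kernel table asymmetry up to %.2g%% averaged out",
                      100 * max(rel)), call. = FALSE)
  }
  voxel_kernel(s, pitch = pitch, nuclide = nuclide, medium_density = dens,
               mean_energy_MeV = en, truncation_tol = truncation_tol)
}

#' Write a kernel in the text format read by [load_kernel()]
#' @param k a [voxel_kernel()].
#' @param path output file.
#' @param octant_only write only offsets with i,j,k >= 0 (the symmetric
#'   expansion restores the rest).
#' @return the path, invisibly.
#' @export
write_kernel <- function(k, path, octant_only = FALSE) {
  stopifnot(inherits(k, "voxel_kernel"))
  d <- dim(k$svalues); half <- (d - 1L) %/% 2L
  off <- expand.grid(i = -half[1]:half[1], j = -half[2]:half[2],
                     k = -half[3]:half[3])
  s <- as.vector(k$svalues)
  keep <- if (octant_only) off$i >= 0 & off$j >= 0 & off$k >= 0 else s > 0 |
    (off$i == 0 & off$j == 0 & off$k == 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# nuclide:", k$nuclide),
               paste("# pitch_mm:", paste(sprintf("%.10g", k$pitch),
                                          collapse = " ")),
               paste("# density_g_cm3:", sprintf("%.10g", k$medium_density)),
               paste("# mean_energy_MeV:", sprintf("%.10g", k$mean_energy_MeV))),
             con)
  writeLines(sprintf("%d %d %d %.12e", off$i[keep], off$j[keep], off$k[keep],
                     s[keep]), con)
  invisible(path)
}

#' Generate an analytic test kernel
#'
#' Builds a radially decreasing voxel S-value table by integrating a
#' normalized exponential point-dose profile
#' `phi(r) = mu^3 exp(-mu r) / (8 pi)` (unit integral over all space) over
#' voxel volumes with a midpoint rule, then rescaling so that
#' `sum(S * voxel mass)` equals the mean emitted energy per decay exactly at
#' the generated extent. This is a self-contained stand-in for tabulated
#' Monte Carlo kernels: correct units, symmetry, monotonicity and energy
#' bookkeeping, but not the true 90Y radial dose profile.
#'
#' @param pitch voxel pitch (mm), scalar or length 3.
#' @param mean_energy_MeV mean emitted energy per decay (default 0.9337 for
#'   90Y).
#' @param attenuation_per_mm apparent attenuation coefficient mu of the
#'   exponential profile (default 0.35/mm, giving a ~3 mm mean deposition
#'   distance comparable to 90Y beta transport).
#' @param extent odd number of voxels per axis (default 11).
#' @param nsub midpoint subdivisions per axis per voxel for the numeric
#'   integration (default 5).
#' @param medium_density g/cm^3.
#' @return a [voxel_kernel()] with `synthetic = TRUE`.
#' @export
generate_test_kernel <- function(pitch = c(6, 6, 6),
                                 mean_energy_MeV = .y90_mean_energy_MeV,
                                 attenuation_per_mm = 0.35,
                                 extent = 11L, nsub = 5L,
                                 medium_density = 1) {
  if (length(pitch) == 1) pitch <- rep(pitch, 3)
  pitch <- as.numeric(pitch)
  stopifnot(all(pitch > 0), mean_energy_MeV > 0, attenuation_per_mm > 0)
  extent <- as.integer(extent)
  if (extent %% 2 == 0) stop("extent must be odd", call. = FALSE)
  mu <- attenuation_per_mm
  half <- (extent - 1L) %/% 2L
  # fraction of emitted energy absorbed in the voxel at offset (i,j,k):
  # integral of phi over the voxel, midpoint rule with nsub^3 points
  sub <- (seq_len(nsub) - 0.5) / nsub - 0.5            # in voxel units
  offs <- -half:half
  xs <- outer(offs, sub * 1, `+`) * pitch[1]           # extent x nsub, mm
  ys <- outer(offs, sub * 1, `+`) * pitch[2]
  zs <- outer(offs, sub * 1, `+`) * pitch[3]
  d <- rep(extent, 3)
  frac <- array(0, d)
  dv <- prod(pitch) / nsub^3                           # mm^3 per sample
  # loop z-offset (small count) and vectorize the xy plane
  xg <- as.vector(xs); yg <- as.vector(ys)
  x2 <- matrix(xg^2, nrow = length(xg), ncol = length(yg))
  y2 <- matrix(yg^2, nrow = length(xg), ncol = length(yg), byrow = TRUE)
  ix <- rep(seq_len(extent), times = nsub)             # voxel index of sample
  for (kk in seq_len(extent)) {
    for (sz in seq_len(nsub)) {
      z <- zs[kk, sz]
      r <- sqrt(x2 + y2 + z^2)
      phi <- mu^3 * exp(-mu * r) / (8 * pi)
      contrib <- phi * dv
      # sum samples into voxel cells
      plane <- rowsum(t(rowsum(contrib, ix)), ix)      # extent x extent (y,x)
      frac[, , kk] <- frac[, , kk] + t(plane)
    }
  }
  total <- sum(frac)
  if (total < 0.99)
    warning(sprintf(
      "kernel extent captures only %.1f%% of emitted energy; increase extent",
      100 * total), call. = FALSE)
  e_decay_j <- mean_energy_MeV * .mev_to_joule
  mass_kg <- prod(pitch) / 1000 * medium_density / 1000
  s <- frac * e_decay_j / mass_kg          # Gy per decay's worth in source
  s <- s * (e_decay_j / (sum(s) * mass_kg))  # exact energy closure at extent
  voxel_kernel(s, pitch = pitch, nuclide = "Y90",
               medium_density = medium_density,
               mean_energy_MeV = mean_energy_MeV, synthetic = TRUE,
               truncation_tol = 1e-9)
}

#' Resample a kernel to a new voxel pitch, conserving energy
#'
#' The dose-deposition density (S values viewed as samples of a continuous
#' deposition profile per unit source activity) is interpolated trilinearly
#' at the new offset lattice, scaled by the voxel-volume ratio, and then
#' renormalized so that `sum(S * voxel mass)` is exactly preserved. The
#' output extent covers the same physical radius as the input and keeps odd
#' dimensions.
#'
#' @param k a [voxel_kernel()].
#' @param pitch target pitch (mm), scalar or length 3.
#' @return a [voxel_kernel()] at the target pitch.
#' @export
resample_kernel <- function(k, pitch) {
  stopifnot(inherits(k, "voxel_kernel"))
  if (length(pitch) == 1) pitch <- rep(pitch, 3)
  pitch <- as.numeric(pitch)
  if (any(pitch <= 0)) stop("target pitch must be positive", call. = FALSE)
  if (all(abs(pitch - k$pitch) < 1e-12 * k$pitch)) return(k)
  d <- dim(k$svalues); half <- (d - 1L) %/% 2L
  phys_half <- half * k$pitch
  if (any(pitch > 2 * phys_half + k$pitch))
    stop("target pitch exceeds the kernel's physical extent", call. = FALSE)
  new_half <- pmax(1L, as.integer(ceiling(phys_half / pitch)))
  nd <- 2L * new_half + 1L
  tc <- target_coords(pitch, -new_half * pitch, nd)
  vals <- trilinear_sample(k$svalues, k$pitch, -half * k$pitch,
                           tc$px, tc$py, tc$pz, fill = 0)
  s <- array(vals, nd) * (prod(pitch) / prod(k$pitch))
  # renormalize: conserve total represented energy exactly
  e_src <- kernel_energy_j(k)
  mass_kg <- prod(pitch) / 1000 * k$medium_density / 1000
  e_new <- sum(s) * mass_kg
  if (e_new <= 0) stop("resampled kernel is empty", call. = FALSE)
  s <- s * (e_src / e_new)
  # symmetrize away interpolation round-off
  s <- (s + s[rev(seq_len(nd[1])), , ]) / 2
  s <- (s + s[, rev(seq_len(nd[2])), ]) / 2
  s <- (s + s[, , rev(seq_len(nd[3]))]) / 2
  voxel_kernel(s, pitch = pitch, nuclide = k$nuclide,
               medium_density = k$medium_density,
               mean_energy_MeV = k$mean_energy_MeV,
               synthetic = isTRUE(k$synthetic),
               truncation_tol = 1e-6 + abs(1 - e_src /
                 (k$mean_energy_MeV * .mev_to_joule)))
  }
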