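# Independent oracles and small fixture builders shared across tests.

# Direct-summation 3D convolution: literally out[i] += a[m] * k[i - m],
# implemented by shifting the activity array once per kernel offset. No FFT.
conv3d_direct <- function(a, k) {
  da <- dim(a); dk <- dim(k); half <- (dk - 1L) %/% 2L
  out <- array(0, da)
  for (oi in -half[1]:half[1]) for (oj in -half[2]:half[2])
    for (ok in -half[3]:half[3]) {
      kv <- k[oi + half[1] + 1L, oj + half[2] + 1L, ok + half[3] + 1L]
      if (kv == 0) next
      # target index = source index + offset
      si <- max(1L, 1L - oi):min(da[1], da[1] - oi)
      sj <- max(1L, 1L - oj):min(da[2], da[2] - oj)
      sk <- max(1L, 1L - ok):min(da[3], da[3] - ok)
      out[si + oi, sj + oj, sk + ok] <-
        out[si + oi, sj + oj, sk + ok] + kv * a[si, sj, sk]
    }
  out
}

# numeric quadrature of the total dose from an exponentially decaying dose
# rate R0 * exp(-lambda t), integrated over n_half_lives
quad_total_dose <- function(r0, lambda_per_day, n_half_lives = 10) {
  t_end <- n_half_lives * log(2) / lambda_per_day
  stats::integrate(function(t) r0 * exp(-lambda_per_day * t), 0, t_end,
                   rel.tol = 1e-10)$value
}

# Lea-Catcheside dose-protraction factor for mono-exponential delivery with
# first-order repair, by outer numeric quadrature (inner integral analytic)
lea_catcheside_g <- function(lambda, mu, n_half_lives = 40) {
  t_end <- n_half_lives * log(2) / lambda
  f <- function(t) exp(-lambda * t) *
    (exp(-lambda * t) - exp(-mu * t)) / (mu - lambda)
  2 * lambda^2 * stats::integrate(f, 0, t_end, rel.tol = 1e-12)$value
}

# compact test kernel: steeper profile so small extents still contain >99%
# of the emitted energy
test_kernel <- function(pitch_mm, extent) {
  generate_test_kernel(pitch = rep(pitch_mm, 3), extent = extent,
                       attenuation_per_mm = 0.6)
}

# uniform grid helper
const_grid <- function(value, dim = c(8, 8, 8), spacing = c(4, 4, 4),
                       quantity = "DOSE", reference_time = 0) {
  image_grid(array(value, dim), spacing = spacing, quantity = quantity,
             reference_time = reference_time)
}

# mask covering a box of voxel indices (1-based inclusive)
box_mask <- function(grid, i, j, k, name = "box") {
  m <- array(0, dim(grid$values))
  m[i, j, k] <- 1
  structure_mask(name, image_grid(m, grid$spacing, grid$origin,
                                  quantity = "MASK"))
}

# two-level dose grid + mask: half the masked voxels at d1, half at d2
two_level_dvh <- function(d1, d2, volume_cm3 = 100, bin_width = 0.5) {
  n <- 250
  vox <- volume_cm3 / (2 * n)                  # cm^3 per voxel
  sp <- rep((vox * 1000)^(1 / 3), 3)
  vals <- array(c(rep(d1, n), rep(d2, n)), dim = c(2 * n, 1, 1))
  g <- image_grid(vals, sp, quantity = "DOSE")
  m <- box_mask(g, seq_len(2 * n), 1, 1)
  compute_dvh(g, m, bin_width = bin_width)
}
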