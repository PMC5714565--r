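test_that("parameter presets carry the standard tumor/liver values", {
  pt <- radiobio_params("tumor")
  pl <- radiobio_params("liver")
  expect_equal(pt$alpha_beta, 10)
  expect_equal(pl$alpha_beta, 2.5)
  expect_equal(pt$mu_per_day, log(2) * 24, tolerance = 1e-12)
  expect_equal(pl$mu_per_day, log(2) * 16, tolerance = 1e-12)
  expect_gt(pt$mu_per_day, pt$lambda_per_day)
  expect_error(radiobio_params("tumor", alpha = -1), "positive")
})

test_that("BED closed form matches the Lea-Catcheside quadrature oracle", {
  p <- radiobio_params("tumor")
  expect_equal(bed_from_dose(0, p), 0)
  # worked value: D = 112.5 Gy, tumor parameters
  expect_equal(bed_from_dose(112.5, p), 131.9, tolerance = 1e-3)
  # oracle: BED = D (1 + G * D / (alpha/beta)) with G from numeric quadrature
  for (D in c(25, 112.5, 300)) {
    G <- lea_catcheside_g(p$lambda_per_day, p$mu_per_day)
    oracle <- D * (1 + G * D / p$alpha_beta)
    expect_equal(bed_from_dose(D, p), oracle, tolerance = 1e-6)
  }
  # BED >= D, equality only at 0; convex increasing
  D <- seq(0, 200, by = 5)
  bed <- bed_from_dose(D, p)
  expect_true(all(bed[-1] > D[-1]))
  expect_true(all(diff(bed) > 0))
  expect_true(all(diff(diff(bed)) > 1e-12))            # strictly convex
  # alpha/beta -> infinity recovers the physical dose
  p_inf <- radiobio_params("tumor", alpha_beta = 1e9)
  expect_equal(bed_from_dose(112.5, p_inf), 112.5, tolerance = 1e-6)
  expect_error(bed_from_dose(-1, p), "non-negative")
})

test_that("EQ2 conversion reproduces the published per-patient table rows", {
  pt <- radiobio_params("tumor")
  pl <- radiobio_params("liver")
  # tumor rows: mean BED -> mean EQ2 at alpha/beta = 10, d = 2
  bed_t <- c(139.3, 140.3, 62.0, 151.7, 195.6)
  eq2_t <- c(116.1, 116.9, 51.7, 126.4, 163.0)
  expect_equal(round(eq2_from_bed(bed_t, pt), 1), eq2_t)
  # normal liver at alpha/beta = 2.5: BED 54.4 -> EQ2 30.2
  expect_equal(round(eq2_from_bed(54.4, pl), 1), 30.2)
  expect_equal(eq2_from_bed(0, pt), 0)
})

test_that("dDVH transform preserves volume and shows the Jensen gap", {
  p <- radiobio_params("tumor")
  # single-bin curve at 112.5 Gy maps to a single bin near 131.9 Gy
  g <- const_grid(112.5, dim = c(5, 5, 4), spacing = rep(10, 3))
  m <- box_mask(g, 1:5, 1:5, 1:4)
  c1 <- compute_dvh(g, m, bin_width = 0.5)
  b1 <- transform_dvh(c1, p, "BED")
  expect_equal(sum(b1$diff_volume), c1$total_volume, tolerance = 1e-10)
  expect_equal(b1$mean, bed_from_dose(c1$mean, p), tolerance = 0.4)
  expect_equal(sum(b1$diff_volume > 0), 1)
  # volume conservation on random curves
  set.seed(13)
  for (i in 1:5) {
    vals <- array(rgamma(512, 4, 1 / 25), c(8, 8, 8))
    gg <- image_grid(vals, c(4, 4, 4), quantity = "DOSE")
    cc <- compute_dvh(gg, box_mask(gg, 1:8, 1:8, 1:8), bin_width = 0.5)
    for (target in c("BED", "EQ2")) {
      tt <- transform_dvh(cc, p, target)
      expect_equal(sum(tt$diff_volume), cc$total_volume, tolerance = 1e-10)
    }
  }
  # Jensen: mean BED over an inhomogeneous dDVH exceeds BED of the mean
  two <- two_level_dvh(40, 180)
  bt <- transform_dvh(two, p, "BED")
  expect_gt(bt$mean, bed_from_dose(two$mean, p))
  # direct-summation check of the same inequality
  ctr <- (two$bin_edges[-1] + two$bin_edges[-length(two$bin_edges)]) / 2
  manual <- sum(two$diff_volume * bed_from_dose(ctr, p)) /
    sum(two$diff_volume)
  expect_equal(bt$mean, manual, tolerance = 1e-10)
  # degenerate (uniform) structure: means coincide
  expect_equal(transform_dvh(c1, p, "BED")$mean, bed_from_dose(112.5, p),
               tolerance = 0.4)
  expect_error(transform_dvh(b1, p, "BED"), "PHYSICAL")
})

test_that("mean_dose_table reports the EQ2 = BED/(1 + d/(a/b)) relation", {
  p <- radiobio_params("tumor")
  two <- two_level_dvh(40, 180)
  tab <- mean_dose_table(list(list(curve = two, params = p)))
  expect_equal(tab$mean_eq2_Gy, tab$mean_bed_Gy / 1.2, tolerance = 1e-10)
  expect_gt(tab$mean_bed_Gy, bed_from_dose(tab$mean_dose_Gy, p))
})

test_that("a cold bin drives TCP to exact zero; TCP crossing at ~49.95 Gy", {
  p <- radiobio_params("tumor")          # rho 1e7 /cm^3, alpha 0.33 /Gy
  cold <- two_level_dvh(0, 150, volume_cm3 = 20)  # 10 cm^3 at 0 Gy
  tcp <- tcp_from_dvh(cold, p)
  expect_identical(as.numeric(tcp), 0)
  expect_lt(attr(tcp, "log_tcp"), -690)  # underflow threshold of a double
  # single bin with rho*V = 1e7: closed-form TCP = 0.5 crossing
  d_half <- log(p$rho * 1 / log(2)) / p$alpha
  expect_equal(d_half, 49.95, tolerance = 0.01)
  mk <- function(D) {
    g <- const_grid(D, dim = c(10, 10, 10), spacing = rep(10, 3))
    compute_dvh(g, box_mask(g, 1, 1, 1), bin_width = 1e-3)  # 1 cm^3
  }
  expect_equal(as.numeric(tcp_from_dvh(mk(d_half), p)), 0.5, tolerance = 1e-3)
  # monotonicity: increasing dose raises TCP; increasing rho lowers it
  expect_gt(as.numeric(tcp_from_dvh(mk(60), p)),
            as.numeric(tcp_from_dvh(mk(50), p)))
  p_dense <- radiobio_params("tumor", rho = 1e9)
  expect_lt(as.numeric(tcp_from_dvh(mk(50), p_dense)),
            as.numeric(tcp_from_dvh(mk(50), p)))
})

test_that("binned TCP converges to the voxel-exact product", {
  set.seed(55)
  p <- radiobio_params("tumor")
  vals <- array(runif(216, 30, 90), c(6, 6, 6))
  g <- image_grid(vals, rep(10, 3), quantity = "DOSE")  # 1 ml voxels
  m <- box_mask(g, 1:6, 1:6, 1:6)
  curve <- compute_dvh(g, m, bin_width = 1e-3)          # near voxel-exact bins
  log_direct <- -sum(p$rho * 1 * exp(-p$alpha * vals))
  expect_equal(attr(tcp_from_dvh(curve, p), "log_tcp"), log_direct,
               tolerance = 1e-3)
})
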