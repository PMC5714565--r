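test_that("decay model ties lambda to the half-life", {
  dm <- decay_model(2.67)
  expect_equal(dm$lambda_per_day, log(2) / 2.67, tolerance = 1e-12)
  expect_lt(abs(dm$lambda_per_day - 0.2596) / 0.2596, 0.001)
})

test_that("a single-voxel source reproduces the kernel around it", {
  k <- test_kernel(4, 7)
  a <- array(0, c(15, 13, 11)); a[8, 7, 6] <- 1 / (4^3 / 1000)  # 1 Bq voxel
  g <- image_grid(a, c(4, 4, 4), quantity = "ACTIVITY_CONC")
  r <- dose_rate_map(g, k)
  half <- (dim(k$svalues) - 1) %/% 2
  sub <- r$values[(8 - half[1]):(8 + half[1]),
                  (7 - half[2]):(7 + half[2]),
                  (6 - half[3]):(6 + half[3])]
  expect_equal(sub, k$svalues, tolerance = 1e-10)
})

test_that("dose_rate_map is linear and matches direct summation to 1e-10", {
  set.seed(17)
  k <- test_kernel(4, 9)
  a <- array(runif(18 * 16 * 14) * 1e5, c(18, 16, 14))
  g <- image_grid(a, c(4, 4, 4), quantity = "ACTIVITY_CONC")
  r <- dose_rate_map(g, k)
  # linearity
  g2 <- image_grid(2 * a, c(4, 4, 4), quantity = "ACTIVITY_CONC")
  expect_equal(dose_rate_map(g2, k)$values, 2 * r$values, tolerance = 1e-12)
  # brute-force oracle
  oracle <- conv3d_direct(a * voxel_volume_cm3(g), k$svalues)
  expect_lt(max(abs(r$values - oracle)) / max(oracle), 1e-10)
})

test_that("uniform activity reaches the equilibrium dose rate", {
  # region large vs kernel support: central rate = C * voxvol * sum(S),
  # equivalently C (Bq/ml) * E per decay / density
  k <- test_kernel(4, 9)
  conc <- 2e6                       # Bq/ml
  g <- const_grid(conc, dim = c(25, 25, 25), spacing = c(4, 4, 4),
                  quantity = "ACTIVITY_CONC")
  r <- dose_rate_map(g, k)
  expected <- conc * voxel_volume_cm3(g) * sum(k$svalues)
  expect_equal(r$values[13, 13, 13], expected, tolerance = 1e-10)
  # physical equilibrium: C[Bq/cm^3] * E[J] / density[kg/cm^3]
  equil <- conc * 0.9337 * 1.602176634e-13 / 1e-3
  expect_equal(expected, equil, tolerance = 1e-6)
})

test_that("kernel/grid pitch mismatch and bad inputs are rejected", {
  k <- generate_test_kernel(pitch = c(6, 6, 6), extent = 7)
  g <- const_grid(1, spacing = c(4, 4, 4), quantity = "ACTIVITY_CONC")
  expect_error(dose_rate_map(g, k), "pitch")
  gn <- image_grid(array(-1, c(3, 3, 3)), c(6, 6, 6),
                   quantity = "ACTIVITY_CONC")
  expect_error(dose_rate_map(gn, generate_test_kernel(pitch = c(6, 6, 6),
                                                      extent = 7)),
               "negative")
})

test_that("integrating the decaying dose rate matches quadrature", {
  dm <- decay_model(2.67)
  lam <- dm$lambda_per_day
  # 4 Gy/h imaged at administration time
  r0_gy_s <- 4 / 3600
  g <- const_grid(r0_gy_s, quantity = "DOSE_RATE", reference_time = 0)
  d <- integrate_to_total_dose(g, dm)
  expect_equal(d$values[1], r0_gy_s * 86400 / lam, tolerance = 1e-12)
  expect_equal(d$values[1], 4 / (lam / 24), tolerance = 1e-6)  # ~369.8 Gy
  oracle <- quad_total_dose(r0_gy_s * 86400, lam)              # Gy, t in days
  expect_lt(abs(d$values[1] - oracle) / oracle, 0.001)

  # property: agreement with quadrature for lambda in [0.1, 1] /day
  set.seed(8)
  for (l in runif(5, 0.1, 1)) {
    dml <- decay_model(log(2) / l)
    dd <- integrate_to_total_dose(g, dml)
    expect_lt(abs(dd$values[1] - quad_total_dose(r0_gy_s * 86400, l)) /
                dd$values[1], 0.001)
  }
})

test_that("decay correction to administration applies exp(+lambda dt)", {
  dm <- decay_model(2.67)
  g <- const_grid(1e-3, quantity = "DOSE_RATE", reference_time = 5)
  d_on <- integrate_to_total_dose(g, dm, t_admin_h = 0)
  d_off <- integrate_to_total_dose(g, dm, t_admin_h = 0, decay_correct = FALSE)
  fac <- exp(dm$lambda_per_day * 5 / 24)
  expect_equal(fac, 1.0556, tolerance = 1e-4)
  expect_equal(d_on$values, d_off$values * fac, tolerance = 1e-12)
  expect_error(integrate_to_total_dose(g, dm, t_admin_h = 6), "precedes")
  z <- const_grid(0, quantity = "DOSE_RATE")
  expect_true(all(integrate_to_total_dose(z, dm)$values == 0))
})

test_that("pipeline recovers forward-simulated dose and commutes with resampling", {
  vp <- make_virtual_patient(dim = c(48, 48, 48), spacing = c(4, 4, 4),
                             kernel = test_kernel(4, 9),
                             liver_volume_cm3 = 800, tumor_volumes_cm3 = 40,
                             seed = 12)
  sens <- 0.5
  counts <- image_grid(
    vp$activity_truth$values * 1e-6 * voxel_volume_cm3(vp$activity_truth) *
      sens,
    vp$activity_truth$spacing, vp$activity_truth$origin,
    quantity = "COUNT_RATE", reference_time = vp$t_image_h)
  res <- run_dose_pipeline(counts, sens, vp$kernel)
  rmse <- sqrt(mean((res$dose$values - vp$dose_truth$values)^2))
  expect_lt(rmse / max(vp$dose_truth$values), 0.02)

  # zero counts -> zero dose everywhere
  z <- image_grid(array(0, c(8, 8, 8)), c(4, 4, 4), quantity = "COUNT_RATE")
  rz <- run_dose_pipeline(z, sens, vp$kernel)
  expect_true(all(rz$dose$values == 0))

  # resample-then-integrate equals integrate-then-resample (both linear)
  tg <- list(spacing = c(2.5, 2.5, 2.5), origin = vp$dose_truth$origin,
             dim = c(60, 60, 60))
  res_a <- run_dose_pipeline(counts, sens, vp$kernel, target_geometry = tg)
  dose_b <- resample_to_grid(res$dose, tg$spacing, tg$origin, tg$dim,
                             "linear")
  expect_equal(res_a$dose$values, dose_b$values, tolerance = 1e-9)
})
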