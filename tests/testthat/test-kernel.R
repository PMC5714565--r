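test_that("generated test kernel satisfies the kernel invariants", {
  k <- generate_test_kernel(pitch = c(6, 6, 6), extent = 11)
  s <- k$svalues
  d <- dim(s)
  expect_true(all(d %% 2 == 1))
  expect_true(all(s >= 0))
  ctr <- (d + 1) %/% 2
  expect_equal(s[ctr[1], ctr[2], ctr[3]], max(s))
  # exact energy closure by construction
  expect_equal(kernel_energy_j(k), 0.9337 * 1.602176634e-13,
               tolerance = 1e-12)
  # radial monotonicity along each axis
  prof <- s[ctr[1]:d[1], ctr[2], ctr[3]]
  expect_true(all(diff(prof) <= 1e-15))
  # doubling the energy per decay doubles every S value
  k2 <- generate_test_kernel(pitch = c(6, 6, 6), extent = 11,
                             mean_energy_MeV = 2 * 0.9337)
  expect_equal(k2$svalues, 2 * k$svalues, tolerance = 1e-12)
})

test_that("central self-dose matches a Monte Carlo integration oracle", {
  mu <- 0.35; pitch <- 6
  k <- generate_test_kernel(pitch = rep(pitch, 3), extent = 15,
                            attenuation_per_mm = mu)
  # MC: fraction of emitted energy absorbed in the source voxel itself
  set.seed(99)
  n <- 2e5
  x <- runif(n, -pitch / 2, pitch / 2)
  y <- runif(n, -pitch / 2, pitch / 2)
  z <- runif(n, -pitch / 2, pitch / 2)
  r <- sqrt(x^2 + y^2 + z^2)
  frac_mc <- mean(mu^3 * exp(-mu * r) / (8 * pi)) * pitch^3
  e_j <- 0.9337 * 1.602176634e-13
  mass_kg <- pitch^3 / 1000 / 1000                     # mm^3 -> kg at 1 g/cm^3
  s_mc <- e_j * frac_mc / mass_kg                      # Gy per Bq s
  ctr <- (dim(k$svalues) + 1) %/% 2
  expect_equal(k$svalues[ctr[1], ctr[2], ctr[3]], s_mc, tolerance = 0.01)
})

test_that("kernel text round-trip and octant expansion are exact", {
  k <- generate_test_kernel(pitch = c(6, 6, 6), extent = 7)
  f_full <- tempfile(fileext = ".tsv")
  f_oct <- tempfile(fileext = ".tsv")
  write_kernel(k, f_full)
  write_kernel(k, f_oct, octant_only = TRUE)
  kf <- load_kernel(f_full)
  ko <- load_kernel(f_oct)
  expect_equal(kf$svalues, k$svalues, tolerance = 1e-10)
  expect_equal(ko$svalues, kf$svalues, tolerance = 1e-10)
  expect_equal(kf$pitch, k$pitch)
})

test_that("malformed kernel tables are rejected", {
  f <- tempfile()
  writeLines(c("# pitch_mm: 6 6 6", "1 0 0 1e-11"), f)   # no center
  expect_error(load_kernel(f), "center")
  writeLines(c("# pitch_mm: 6 6 6", "0 0 0 -1e-11"), f)
  expect_error(load_kernel(f), "negative")
})

test_that("noisy asymmetric tables are symmetrized with a warning", {
  k <- test_kernel(6, 5)
  d <- dim(k$svalues); half <- (d - 1) %/% 2
  off <- expand.grid(i = -half[1]:half[1], j = -half[2]:half[2],
                     k = -half[3]:half[3])
  s <- as.vector(k$svalues)
  s[off$i == 1 & off$j == 0 & off$k == 0] <-
    s[off$i == 1 & off$j == 0 & off$k == 0] * 1.2       # 20% lopsided
  f <- tempfile()
  writeLines(c("# pitch_mm: 6 6 6",
               sprintf("%d %d %d %.12e", off$i, off$j, off$k, s)), f)
  expect_warning(kk <- load_kernel(f, truncation_tol = 0.1), "asymmetry")
  expect_lt(sirtdose:::kernel_asymmetry(kk), 1e-12)
})

test_that("kernel resampling conserves energy and symmetry", {
  k <- generate_test_kernel(pitch = c(6, 6, 6), extent = 11)
  e0 <- kernel_energy_j(k)
  # identity
  expect_identical(resample_kernel(k, c(6, 6, 6)), k)
  # 6 mm -> 3 mm isotropic and 6 mm -> PET-like anisotropic pitch
  for (pitch in list(c(3, 3, 3), c(5.47, 5.47, 3.27))) {
    kr <- resample_kernel(k, pitch)
    expect_lt(abs(kernel_energy_j(kr) - e0) / e0, 0.01)
    expect_lt(sirtdose:::kernel_asymmetry(kr), 1e-9)
    d <- dim(kr$svalues); ctr <- (d + 1) %/% 2
    expect_equal(kr$svalues[ctr[1], ctr[2], ctr[3]], max(kr$svalues))
    # physical radius covered
    expect_true(all((d - 1) / 2 * pitch >= (dim(k$svalues) - 1) / 2 * 6 - 1e-9))
  }
  # property: random pitches in [2, 8] mm conserve energy
  set.seed(31)
  for (i in 1:5) {
    pitch <- runif(3, 2, 8)
    kr <- resample_kernel(k, pitch)
    expect_lt(abs(kernel_energy_j(kr) - e0) / e0, 0.01)
  }
  expect_error(resample_kernel(k, c(200, 200, 200)), "extent")
})
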