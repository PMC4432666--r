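test_that("eigenvalues_for_fa inverts the FA formula", {
  # FA = 0 forces an isotropic triple
  expect_equal(eigenvalues_for_fa(0, 2.1e-3), rep(0.7e-3, 3))
  # round-trip identity over the working FA range, trace preserved
  for (fa in seq(0.1, 0.9, by = 0.1)) {
    l <- eigenvalues_for_fa(fa, 2.1e-3)
    expect_equal(sum(l), 2.1e-3, tolerance = 1e-12)
    expect_equal(l[2], l[3])
    expect_true(l[1] >= l[2])
    expect_equal(fa_from_eigenvalues(l), fa, tolerance = 1e-9)
  }
  expect_error(eigenvalues_for_fa(1.0), "target_fa")
  expect_error(eigenvalues_for_fa(-0.1), "target_fa")
  expect_error(eigenvalues_for_fa(0.5, trace = -1), "trace")
})

test_that("eigenvalues_for_fa matches a 1-D root-finding oracle", {
  # independently solve FA(lambda1/lambda3) = target with uniroot on the
  # closed-form FA expression for axial tensors of fixed trace
  target <- 0.80; trace <- 2.1e-3
  f <- function(ratio) {
    l3 <- trace / (ratio + 2)
    fa_reference(c(ratio * l3, l3, l3)) - target
  }
  ratio_oracle <- uniroot(f, c(1, 1e3), tol = 1e-14)$root
  l <- eigenvalues_for_fa(target, trace)
  expect_equal(l[1] / l[3], ratio_oracle, tolerance = 1e-8)
})

test_that("gradient schemes enforce their invariants", {
  sch <- default_gradient_scheme()
  expect_equal(length(sch$bvalues), 30L)
  expect_equal(sum(sch$bvalues == 0), 5L)
  nrm <- sqrt(rowSums(sch$directions[sch$bvalues > 0, ]^2))
  expect_true(all(abs(nrm - 1) < 1e-6))
  expect_error(gradient_scheme(c(1000, 1000), rbind(c(1, 0, 0), c(0, 1, 0))),
               "b = 0")
  expect_error(gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(2, 0, 0))),
               "unit")
  expect_error(gradient_scheme(c(0, 1000), rbind(c(0, 0, 0))), "equal length")
})

test_that("rasterized straight bundle has axis-aligned eigenvectors and exact FA", {
  ph <- noiseless_phantom()
  # straight bundle: principal eigenvector is +/- x everywhere inside
  idx <- which(ph$ras$bundle_mask == 1)
  v1 <- matrix(ph$eig$vectors, ncol = 9)[idx, 1:3]
  expect_true(all(abs(abs(v1[, 1]) - 1) < 1e-9))
  expect_true(all(abs(v1[, 2:3]) < 1e-9))
  # noiseless FA equals the target inside every bundle
  fa_in <- ph$fa$fa[ph$ras$bundle_mask > 0]
  expect_true(all(abs(fa_in - 0.45) < 1e-9))
  # background is isotropic
  fa_bg <- ph$fa$fa[ph$ras$bundle_mask == 0]
  expect_true(all(fa_bg < 1e-6))
})

test_that("rasterized arc eigenvectors match the analytic tangent", {
  ph <- noiseless_phantom()
  geom <- ph$geom
  arc <- ph$bundles$arc
  idx <- which(ph$ras$bundle_mask == 2)
  centers <- voxel_centers(geom)[idx, , drop = FALSE]
  # brute-force nearest centerline sample, re-derived in-test
  tg <- seq(0, 1, length.out = 400)
  P <- arc$curve(tg)
  v1 <- matrix(ph$eig$vectors, ncol = 9)[idx, 1:3]
  for (q in seq(1, length(idx), by = 7)) {
    j <- which.min(colSums((t(P) - centers[q, ])^2))
    tan_ref <- arc$tangent(tg[j])
    tan_ref <- tan_ref / sqrt(sum(tan_ref^2))
    expect_lt(min(sqrt(sum((v1[q, ] - tan_ref)^2)),
                  sqrt(sum((v1[q, ] + tan_ref)^2))), 1e-6)
  }
})

test_that("centerlines leaving the grid are rejected", {
  geom <- vol_geometry(c(10, 10, 5), c(2, 2, 2))
  bad <- curve_bundle_spec(function(t) cbind(40 * t - 10, 10 + 0 * t, 5 + 0 * t),
                           radius = 2, seed_label = 1, target_label = 2)
  expect_error(rasterize_tensor_field(bad, geom, eigenvalues_for_fa(0.4)),
               "exits the grid")
})

test_that("simulated DWI follows the monoexponential closed form", {
  geom <- vol_geometry(c(3, 3, 3), c(2, 2, 2))
  tens <- array(0, c(3, 3, 3, 6))
  tens[, , , 1:3] <- 0.7e-3  # isotropic, trace 2.1e-3
  sch <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0) ))
  dwi <- simulate_dwi(tens, geom, sch, s0 = 100, snr = Inf)
  expect_equal(unique(as.vector(dwi$data[, , , 1])), 100)
  expect_equal(as.vector(dwi$data[, , , 2]),
               rep(100 * exp(-0.7), 27), tolerance = 1e-12)
  # direction does not matter for an isotropic tensor
  sch2 <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(0, 1, 0)))
  dwi2 <- simulate_dwi(tens, geom, sch2, s0 = 100, snr = Inf)
  expect_equal(dwi$data[, , , 2], dwi2$data[, , , 2], tolerance = 1e-12)
  expect_error(simulate_dwi(tens, geom, sch, s0 = -5), "s0")
})

test_that("very high SNR converges to the noiseless signal and seeds reproduce", {
  geom <- vol_geometry(c(4, 4, 2), c(2, 2, 4))
  tens <- array(0, c(4, 4, 2, 6))
  tens[, , , 1:3] <- 0.7e-3
  sch <- default_gradient_scheme()
  clean <- simulate_dwi(tens, geom, sch, snr = Inf)
  near <- simulate_dwi(tens, geom, sch, snr = 1e9, rng_seed = 3)
  expect_equal(near$data, clean$data, tolerance = 1e-6)
  a <- simulate_dwi(tens, geom, sch, snr = 20, rng_seed = 11)
  b <- simulate_dwi(tens, geom, sch, snr = 20, rng_seed = 11)
  expect_identical(a$data, b$data)
  c2 <- simulate_dwi(tens, geom, sch, snr = 20, rng_seed = 12)
  expect_false(identical(a$data, c2$data))
})

test_that("Rician noise has the analytic Rician mean", {
  # mean of sqrt((nu+n1)^2+n2^2) with n ~ N(0, sigma):
  # sigma*sqrt(pi/2)*L_{1/2}(-nu^2/(2 sigma^2)) via Bessel functions
  s0 <- 100; snr <- 20; sigma <- s0 / snr
  nvox <- 10000
  geom <- vol_geometry(c(100, 100, 1), c(1, 1, 1))
  tens <- array(0, c(100, 100, 1, 6))
  tens[, , , 1:3] <- 0.7e-3
  sch <- gradient_scheme(c(0, 1000), rbind(c(0, 0, 0), c(1, 0, 0)))
  dwi <- simulate_dwi(tens, geom, sch, s0 = s0, snr = snr, rng_seed = 5)
  rician_mean <- function(nu, sigma) {
    x <- -nu^2 / (2 * sigma^2)
    l_half <- exp(x / 2) * ((1 - x) * besselI(-x / 2, 0) -
                              x * besselI(-x / 2, 1))
    sigma * sqrt(pi / 2) * l_half
  }
  for (vol in 1:2) {
    nu <- if (vol == 1) s0 else s0 * exp(-0.7)
    expect_equal(mean(dwi$data[, , , vol]), rician_mean(nu, sigma),
                 tolerance = 0.01)
  }
})

test_that("cohort ground truth honours the null model and determinism", {
  spec0 <- phantom_cohort_spec(n_subjects = 4, waves = 3,
                               annual_decline_pct = 0,
                               annual_decline_sd = 0, snr = 25, rng_seed = 2)
  tr <- cohort_truth(spec0, 2)
  expect_true(all(tapply(tr$true_fa, tr$bundle,
                         function(v) length(unique(v)) == 1L)))
  # positive decline, noise-free rates: FA monotone non-increasing in wave
  spec1 <- phantom_cohort_spec(n_subjects = 5, waves = 3,
                               annual_decline_pct = 1.5,
                               annual_decline_sd = 0, rng_seed = 2)
  tr1 <- cohort_truth(spec1, 1)
  for (s in unique(tr1$subject)) {
    v <- tr1$true_fa[tr1$subject == s][order(tr1$wave[tr1$subject == s])]
    expect_true(all(diff(v) <= 0))
  }
  # same seed, bit-identical cohort (including simulated volumes)
  spec <- phantom_cohort_spec(n_subjects = 2, waves = 2, rng_seed = 9)
  geom <- vol_geometry(c(12, 10, 6), c(2, 2, 2))
  bnd <- list(curve_bundle_spec(function(t) cbind(4 + 16 * t, 10 + 0 * t, 6 + 0 * t),
                                radius = 3, seed_label = 1, target_label = 2))
  c1 <- simulate_cohort(spec, bnd, geom)
  c2 <- simulate_cohort(spec, bnd, geom)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$scans[[1]]$dwi$data, c2$scans[[1]]$dwi$data)
  expect_identical(c1$scans[[4]]$dwi$data, c2$scans[[4]]$dwi$data)
})

test_that("a written cohort round-trips through NIfTI and bval/bvec", {
  spec <- phantom_cohort_spec(n_subjects = 2, waves = 2, rng_seed = 4)
  geom <- vol_geometry(c(12, 10, 6), c(2, 2, 2))
  bnd <- list(curve_bundle_spec(function(t) cbind(4 + 16 * t, 10 + 0 * t, 6 + 0 * t),
                                radius = 3, seed_label = 1, target_label = 2))
  co <- simulate_cohort(spec, bnd, geom)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  dwi <- read_dwi(file.path(dir, "sub-01_wave-1_dwi.nii.gz"),
                  file.path(dir, "sub-01_wave-1.bval"),
                  file.path(dir, "sub-01_wave-1.bvec"))
  expect_equal(dwi$geom$dim, geom$dim)
  expect_equal(dwi$geom$voxel_size, geom$voxel_size)
  expect_equal(as.vector(dwi$data), as.vector(co$scans[[1]]$dwi$data),
               tolerance = 1e-6)
  expect_equal(dwi$scheme$bvalues, co$scheme$bvalues)
  expect_equal(dwi$scheme$directions, co$scheme$directions,
               ignore_attr = TRUE, tolerance = 1e-12)
})
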