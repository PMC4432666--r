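test_that("resampling gives exactly n equidistant on-polyline points", {
  # straight 99 mm segment -> points at 0, 1, ..., 99 mm
  s <- cbind(c(0, 99), 5, 5)
  r <- resample_streamline(s, 100)
  expect_equal(r[, 1], 0:99)
  expect_equal(r[, 2], rep(5, 100))
  # idempotence on an already-equidistant line
  r2 <- resample_streamline(r, 100)
  expect_equal(r2, r, tolerance = 1e-9)
  # duplicated points are collapsed first
  rdup <- resample_streamline(s[c(1, 1, 2, 2), ], 100)
  expect_equal(rdup, r, tolerance = 1e-12)
  expect_error(resample_streamline(cbind(1, 1, 1)), "degenerate")
  expect_error(resample_streamline(rbind(c(1, 1, 1), c(1, 1, 1))),
               "degenerate")
})

test_that("resampled arc points stay on the circle with uniform spacing", {
  r <- 20
  th <- seq(0, pi / 2, length.out = 200)
  poly <- cbind(r * cos(th), r * sin(th), 0)
  out <- resample_streamline(poly, 100)
  # chord error bound for 200-point polygonal approximation
  chord_err <- r * (1 - cos((pi / 2) / 199 / 2))
  expect_true(all(abs(sqrt(out[, 1]^2 + out[, 2]^2) - r) < chord_err + 1e-9))
  # chord gaps are uniform up to the vertex-crossing chord-vs-arc error
  gaps <- sqrt(rowSums(diff(out)^2))
  vertex_err <- 2 * r * (1 - cos((pi / 2) / 199))
  expect_lt(diff(range(gaps)), vertex_err + 1e-9)
  expect_equal(out[1, ], poly[1, ])
  expect_equal(out[100, ], poly[200, ])
})

test_that("orient_bundle makes every streamline seed-first", {
  geom <- vol_geometry(c(20, 10, 10), c(2, 2, 2))
  seed_mask <- array(FALSE, geom$dim)
  seed_mask[1:2, 4:6, 4:6] <- TRUE
  fwd <- lapply(1:10, function(i) cbind(seq(3, 37, by = 1), 9 + 0.1 * i, 10))
  rev_ <- lapply(1:10, function(i) cbind(seq(37, 3, by = -1), 11 + 0.1 * i, 10))
  bd <- structure(list(streamlines = c(fwd, rev_), seed_label = 1L,
                       target_label = 2L, n_fibers = 20L, geom = geom,
                       name = "mix"), class = "bundle")
  ob <- orient_bundle(bd, seed_mask)
  expect_equal(ob$n_fibers, 20L)
  # distance-to-mask oracle: first endpoint closer to the seed centroid
  cm <- colMeans(which(seed_mask, arr.ind = TRUE))
  cm <- (cm - 0.5) * geom$voxel_size  # approximate mask centre, world mm
  for (s in ob$streamlines) {
    expect_lt(sum((s[1, ] - cm)^2), sum((s[nrow(s), ] - cm)^2))
  }
  # already-oriented input is a no-op
  ob2 <- orient_bundle(ob, seed_mask)
  expect_identical(ob2$streamlines, ob$streamlines)
  # streamlines near the seed at neither end are flagged and excluded
  far <- structure(list(streamlines = c(fwd, list(cbind(seq(20, 37), 15, 15))),
                        seed_label = 1L, target_label = 2L, n_fibers = 11L,
                        geom = geom, name = "far"), class = "bundle")
  expect_warning(of <- orient_bundle(far, seed_mask), "excluded")
  expect_equal(of$n_fibers, 10L)
})

test_that("two-ROI profiles are flat on constant fields and track ramps", {
  geom <- vol_geometry(c(30, 8, 8), c(2, 2, 2))
  const <- structure(list(fa = array(0.45, geom$dim),
                          mask = array(TRUE, geom$dim), geom = geom),
                     class = "fa_volume")
  bd <- synthetic_straight_bundle(geom, 4, 56, n = 12)
  pr <- profile_two_roi(bd, const)
  expect_equal(nrow(pr), 100L)
  expect_equal(pr$mean_fa, rep(0.45, 100), tolerance = 1e-9)
  expect_equal(pr$se, rep(0, 100))
  expect_equal(pr$n, rep(12L, 100))

  # generative linear ramp 0.2 -> 0.4 along x
  ramp <- const
  xs <- (seq_len(geom$dim[1]) - 0.5) * geom$voxel_size[1]
  ramp$fa[] <- rep(0.2 + (0.4 - 0.2) * (xs - 4) / (56 - 4), times = 64)
  prr <- profile_two_roi(bd, ramp)
  expect_true(all(diff(prr$mean_fa) > -1e-9))
  expect_equal(prr$mean_fa[1], 0.2, tolerance = 0.02)
  expect_equal(prr$mean_fa[100], 0.4, tolerance = 0.02)

  # single-streamline bundle: SE 0 by convention, mean = sampled values
  one <- synthetic_straight_bundle(geom, 4, 56, n = 1)
  pr1 <- profile_two_roi(one, const)
  expect_equal(pr1$se, rep(0, 100))
  expect_equal(pr1$n, rep(1L, 100))
  # empty bundle: all-missing profile
  empty <- structure(list(streamlines = list(), n_fibers = 0L, geom = geom),
                     class = "bundle")
  pre <- profile_two_roi(empty, const)
  expect_true(all(is.na(pre$mean_fa)))
})

test_that("reversing every streamline reverses the profile exactly", {
  geom <- vol_geometry(c(30, 8, 8), c(2, 2, 2))
  set.seed(5)
  vol <- structure(list(fa = array(runif(prod(geom$dim), 0.2, 0.6), geom$dim),
                        mask = array(TRUE, geom$dim), geom = geom),
                   class = "fa_volume")
  bd <- synthetic_straight_bundle(geom, 4, 56, n = 6)
  rev_bd <- bd
  rev_bd$streamlines <- lapply(bd$streamlines, function(s)
    s[rev(seq_len(nrow(s))), , drop = FALSE])
  a <- profile_two_roi(bd, vol)
  b <- profile_two_roi(rev_bd, vol)
  expect_equal(a$mean_fa, rev(b$mean_fa), tolerance = 1e-12)
  expect_equal(a$se, rev(b$se), tolerance = 1e-12)
})

test_that("profile mean approximates the tract mean FA on uniform tubes", {
  geom <- vol_geometry(c(30, 8, 8), c(2, 2, 2))
  xs <- (seq_len(geom$dim[1]) - 0.5) * geom$voxel_size[1]
  vol <- structure(list(fa = array(rep(0.3 + 0.2 * (xs - 4) / 52, times = 64),
                                   geom$dim),
                        mask = array(TRUE, geom$dim), geom = geom),
                   class = "fa_volume")
  bd <- synthetic_straight_bundle(geom, 4, 56, n = 10, spread = 1)
  pr <- profile_two_roi(bd, vol)
  expect_equal(mean(pr$mean_fa), tract_mean_fa(bd, vol), tolerance = 0.02)
})

test_that("single-ROI profiles anchor at the defining region", {
  geom <- vol_geometry(c(30, 8, 8), c(2, 2, 2))
  const <- structure(list(fa = array(0.45, geom$dim),
                          mask = array(TRUE, geom$dim), geom = geom),
                     class = "fa_volume")
  bd <- synthetic_straight_bundle(geom, 4, 56, n = 8, spread = 1)
  # ROI block at the seed end: equivalent to the two-ROI profile
  roi <- array(FALSE, geom$dim)
  roi[2:3, 3:6, 3:6] <- TRUE
  ps <- profile_single_roi(bd, const, roi)
  pt <- profile_two_roi(bd, const)
  expect_equal(ps$mean_fa, pt$mean_fa, tolerance = 1e-9)

  # ROI in the exact middle of a symmetric bundle anchors segment 1 there
  roi_mid <- array(FALSE, geom$dim)
  roi_mid[15:16, 3:6, 3:6] <- TRUE  # centred on x = 30 mm
  pm <- profile_single_roi(bd, const, roi_mid)
  expect_equal(pm$n, rep(8L, 100))
  # streamlines that miss the ROI are excluded with a warning
  stray <- bd
  stray$streamlines <- c(stray$streamlines, list(cbind(seq(4, 56), 15, 15)))
  stray$n_fibers <- 9L
  expect_warning(profile_single_roi(stray, const, roi), "excluded")
})

test_that("a generative FA step 30% along the tract lands at segment 30", {
  geom <- vol_geometry(c(40, 8, 8), c(2, 2, 2))
  x0 <- 4; x1 <- 74
  step_x <- x0 + 0.30 * (x1 - x0)
  xs <- (seq_len(geom$dim[1]) - 0.5) * geom$voxel_size[1]
  vol <- structure(list(fa = array(rep(ifelse(xs < step_x, 0.45, 0.30),
                                       times = 64), geom$dim),
                        mask = array(TRUE, geom$dim), geom = geom),
                   class = "fa_volume")
  bd <- synthetic_straight_bundle(geom, x0, x1, n = 10, spread = 1)
  roi <- array(FALSE, geom$dim)
  roi[2:3, 3:6, 3:6] <- TRUE
  pr <- profile_single_roi(bd, vol, roi)
  crossing <- which(pr$mean_fa < mean(c(0.45, 0.30)))[1]
  expect_gte(crossing, 28)
  expect_lte(crossing, 32)
})

test_that("midline-split profiles mirror a symmetric U-phantom", {
  geom <- vol_geometry(c(40, 20, 8), c(2, 2, 2))
  mid <- 40
  # symmetric bundle crossing the midline: x from 10 to 70, apex at 40
  mkv <- function(off) cbind(seq(10, 70, by = 0.5), 20 + off, 8)
  bd <- structure(list(streamlines = lapply(1:6, function(i) mkv(i * 0.2)),
                       seed_label = 1L, target_label = 2L, n_fibers = 6L,
                       geom = geom, name = "u"), class = "bundle")
  # FA symmetric about the midline with a depression at the crossing
  xs <- (seq_len(geom$dim[1]) - 0.5) * geom$voxel_size[1]
  prof <- 0.45 - 0.15 * exp(-((xs - mid) / 6)^2)
  vol <- structure(list(fa = array(rep(prof, times = prod(geom$dim[2:3])),
                                   geom$dim),
                        mask = array(TRUE, geom$dim), geom = geom),
                   class = "fa_volume")
  pa <- profile_acf(bd, vol, midline_x = mid)
  expect_equal(pa$left$mean_fa, pa$right$mean_fa, tolerance = 1e-6)
  # depression shows at segment 1 (the midline end) on both sides
  expect_equal(which.min(pa$left$mean_fa), 1L)
  expect_equal(which.min(pa$right$mean_fa), 1L)
  expect_lt(pa$left$mean_fa[1], 0.35)
  expect_gt(pa$left$mean_fa[100], 0.42)
  # non-crossing streamlines are excluded; empty side is all-missing
  left_only <- structure(list(streamlines = list(cbind(seq(10, 35), 20, 8)),
                              seed_label = 1L, target_label = 2L,
                              n_fibers = 1L, geom = geom, name = "l"),
                         class = "bundle")
  pe <- profile_acf(left_only, vol, midline_x = mid)
  expect_true(all(is.na(pe$left$mean_fa)))
  expect_true(all(is.na(pe$right$mean_fa)))
})
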