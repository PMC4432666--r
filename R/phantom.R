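#' Gradient scheme (diffusion-encoding protocol)
#'
#' B-values and unit gradient directions defining a DWI acquisition. The
#' default protocol mirrors a 1.5 T clinical scheme: 25 directions at
#' b = 1000 s/mm^2 plus 5 b = 0 volumes.
#'
#' @param bvalues numeric vector of b-values (s/mm^2).
#' @param directions n x 3 matrix of gradient directions; rows for b > 0
#'   entries must have unit Euclidean norm (tolerance 1e-6), b = 0 rows may
#'   be zero.
#' @return An object of class \code{gradient_scheme}.
#' @export
gradient_scheme <- function(bvalues, directions) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  if (length(bvalues) != nrow(directions))
    stop("bvalues and directions must have equal length")
  if (!any(bvalues == 0)) stop("scheme must contain at least one b = 0 entry")
  nrm <- sqrt(rowSums(directions^2))
  bad <- bvalues > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop("directions for b > 0 entries must be unit vectors (tolerance 1e-6)")
  structure(list(bvalues = bvalues, directions = directions),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("Gradient scheme: %d volumes (%d b=0, %d diffusion-weighted, b = %s s/mm^2)\n",
              length(x$bvalues), sum(x$bvalues == 0), sum(x$bvalues > 0),
              paste(unique(x$bvalues[x$bvalues > 0]), collapse = "/")))
  invisible(x)
}

#' Default 25-direction scheme
#'
#' Deterministic, well-spread directions on the sphere (Fibonacci lattice),
#' prefixed by the b = 0 volumes.
#'
#' @param n_directions number of diffusion-weighted directions.
#' @param n_b0 number of b = 0 volumes.
#' @param bvalue diffusion weighting (s/mm^2).
#' @return a [gradient_scheme()].
#' @export
default_gradient_scheme <- function(n_directions = 25L, n_b0 = 5L,
                                    bvalue = 1000) {
  i <- seq_len(n_directions) - 0.5
  phi <- acos(1 - 2 * i / n_directions)
  theta <- pi * (1 + sqrt(5)) * i
  dirs <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  gradient_scheme(c(rep(0, n_b0), rep(bvalue, n_directions)),
                  rbind(matrix(0, n_b0, 3), dirs))
}

#' Axially symmetric eigenvalues for a target FA
#'
#' Inverts the FA formula under the axially symmetric constraint
#' lambda1 >= lambda2 = lambda3 with fixed trace. Writing the eigenvalues as
#' \code{m(1+2x), m(1-x), m(1-x)} with \code{m = trace/3}, FA reduces to
#' \code{sqrt(3 x^2 / (1 + 2 x^2))}, which inverts in closed form to
#' \code{x = FA / sqrt(3 - 2 FA^2)}.
#'
#' @param target_fa desired FA in \[0, 1).
#' @param trace tensor trace (mm^2/s), default typical adult white matter.
#' @return numeric triple (lambda1, lambda2, lambda3), descending.
#' @export
eigenvalues_for_fa <- function(target_fa, trace = 2.1e-3) {
  if (!is.finite(target_fa) || target_fa < 0 || target_fa >= 1)
    stop("target_fa must lie in [0, 1)")
  if (!is.finite(trace) || trace <= 0) stop("trace must be positive")
  m <- trace / 3
  x <- target_fa / sqrt(3 - 2 * target_fa^2)
  c(m * (1 + 2 * x), m * (1 - x), m * (1 - x))
}

#' Curved fiber-bundle specification
#'
#' A tube of given radius around a parametric 3D centerline, with integer
#' labels painted as spherical caps at the two curve ends (the seed and
#' target regions used for bundle extraction).
#'
#' @param curve function of t in \[0,1\] returning a length-3 mm coordinate
#'   (or an n x 3 matrix for vector t), or an m x 3 matrix of control points
#'   (m >= 2) interpolated by natural cubic splines.
#' @param radius bundle radius (mm), > 0.
#' @param seed_label,target_label integer ROI label ids.
#' @param n_streamlines nominal streamline count when constructing synthetic
#'   streamline sets directly from this bundle specification (tracking
#'   itself seeds per voxel).
#' @param tangent optional function of t returning the (not necessarily unit)
#'   centerline tangent; defaults to a central finite difference of
#'   \code{curve}.
#' @param name connection name used in report tables.
#' @return An object of class \code{curve_bundle_spec}.
#' @export
curve_bundle_spec <- function(curve, radius, seed_label, target_label,
                              n_streamlines = 50L, tangent = NULL,
                              name = NULL) {
  if (is.matrix(curve)) {
    cp <- curve
    if (nrow(cp) < 2L) stop("need at least 2 control points")
    tt <- seq(0, 1, length.out = nrow(cp))
    fx <- stats::splinefun(tt, cp[, 1], method = "natural")
    fy <- stats::splinefun(tt, cp[, 2], method = "natural")
    fz <- stats::splinefun(tt, cp[, 3], method = "natural")
    curve <- function(t) cbind(fx(t), fy(t), fz(t))
    if (is.null(tangent))
      tangent <- function(t) cbind(fx(t, deriv = 1), fy(t, deriv = 1),
                                   fz(t, deriv = 1))
  }
  if (!is.function(curve)) stop("curve must be a function or control-point matrix")
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  if (n_streamlines < 1L) stop("n_streamlines must be >= 1")
  if (is.null(tangent)) {
    h <- 1e-5
    tangent <- function(t) {
      (rbind(curve(pmin(t + h, 1))) - rbind(curve(pmax(t - h, 0)))) /
        (pmin(t + h, 1) - pmax(t - h, 0))
    }
  }
  structure(list(curve = curve, tangent = tangent, radius = radius,
                 seed_label = as.integer(seed_label),
                 target_label = as.integer(target_label),
                 n_streamlines = as.integer(n_streamlines),
                 name = name %||% sprintf("%d-%d", seed_label, target_label)),
            class = "curve_bundle_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in phantom bundle fixtures
#'
#' Three bundles exercising straight, curved, and inflected tangent fields
#' inside the default 40 x 40 x 20 voxel grid at 2 mm isotropic resolution:
#' a straight tube along x, a C-shaped quarter arc, and an S-curve.
#'
#' @param geom a [vol_geometry()]; default the 40 x 40 x 20 / 2 mm grid.
#' @param which subset of \code{c("straight", "arc", "scurve")}.
#' @param radius bundle radius (mm).
#' @return named list of [curve_bundle_spec()]s.
#' @export
bundle_fixtures <- function(geom = default_geometry(),
                            which = c("straight", "arc", "scurve"),
                            radius = 4) {
  fov <- geom$dim * geom$voxel_size
  out <- list()
  # each fixture built inside local() so its closures capture private
  # coordinates rather than this function's (reused) locals
  if ("straight" %in% which) {
    out$straight <- local({
      y0 <- 0.25 * fov[2]; z0 <- 0.35 * fov[3]
      x0 <- 0.12 * fov[1]; x1 <- 0.88 * fov[1]
      curve_bundle_spec(
        curve = function(t) cbind(x0 + t * (x1 - x0), y0 + 0 * t, z0 + 0 * t),
        tangent = function(t) cbind(rep(x1 - x0, length(t)), 0 * t, 0 * t),
        radius = radius, seed_label = 10L, target_label = 11L,
        name = "straight")
    })
  }
  if ("arc" %in% which) {
    out$arc <- local({
      # quarter circle in the x-y plane
      r <- 0.32 * min(fov[1], fov[2])
      cx <- 0.30 * fov[1]; cy <- 0.52 * fov[2]; z0 <- 0.65 * fov[3]
      curve_bundle_spec(
        curve = function(t) cbind(cx + r * cos(pi / 2 * t),
                                  cy + r * sin(pi / 2 * t), z0 + 0 * t),
        tangent = function(t) cbind(-sin(pi / 2 * t), cos(pi / 2 * t), 0 * t),
        radius = radius, seed_label = 20L, target_label = 21L, name = "arc")
    })
  }
  if ("scurve" %in% which) {
    out$scurve <- local({
      x0 <- 0.12 * fov[1]; x1 <- 0.88 * fov[1]
      y0 <- 0.72 * fov[2]; amp <- 0.10 * fov[2]; z0 <- 0.35 * fov[3]
      curve_bundle_spec(
        curve = function(t) cbind(x0 + t * (x1 - x0),
                                  y0 + amp * sin(2 * pi * t), z0 + 0 * t),
        tangent = function(t) cbind(rep(x1 - x0, length(t)),
                                    amp * 2 * pi * cos(2 * pi * t), 0 * t),
        radius = radius, seed_label = 30L, target_label = 31L,
        name = "scurve")
    })
  }
  out[intersect(c("straight", "arc", "scurve"), which)]
}

#' Default phantom geometry
#' @return 40 x 40 x 20 voxel grid at 2 mm isotropic.
#' @export
default_geometry <- function() vol_geometry(c(40L, 40L, 20L), c(2, 2, 2))

#' Rasterize bundle specs into a tensor field and label volume
#'
#' Voxels within \code{radius} of a bundle centerline carry an axially
#' symmetric tensor whose principal eigenvector is the local curve tangent;
#' background voxels carry isotropic tensors of the same trace. Seed and
#' target labels are painted as spheres of the bundle radius at the two
#' curve ends.
#'
#' @param specs a [curve_bundle_spec()] or list of them.
#' @param geom a [vol_geometry()].
#' @param eigenvalues descending triple (per bundle: a list of triples, or a
#'   single triple recycled), e.g. from [eigenvalues_for_fa()].
#' @param n_samples centerline sampling density for nearest-point queries.
#' @return list with \code{tensors} (nx x ny x nz x 6 array, components
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), \code{labels} (integer array) and
#'   \code{bundle_mask} (integer array: bundle index per voxel, 0 outside).
#' @export
rasterize_tensor_field <- function(specs, geom, eigenvalues,
                                   n_samples = 400L) {
  if (inherits(specs, "curve_bundle_spec")) specs <- list(specs)
  if (is.numeric(eigenvalues)) eigenvalues <- rep(list(eigenvalues),
                                                  length(specs))
  stopifnot(length(eigenvalues) == length(specs))
  d <- geom$dim
  fov <- d * geom$voxel_size
  nvox <- prod(d)
  trace_bg <- mean(vapply(eigenvalues, sum, 0))
  tens <- matrix(0, nvox, 6)
  tens[, 1:3] <- trace_bg / 3
  labels <- integer(nvox)
  bmask <- integer(nvox)
  centers <- voxel_centers(geom)
  tgrid <- seq(0, 1, length.out = n_samples)
  for (bi in seq_along(specs)) {
    sp <- specs[[bi]]
    ev <- sort(eigenvalues[[bi]], decreasing = TRUE)
    P <- rbind(sp$curve(tgrid))
    if (any(P < 0) || any(sweep(P, 2, fov, ">")))
      stop("bundle centerline exits the grid")
    Tg <- rbind(sp$tangent(tgrid))
    Tg <- Tg / sqrt(rowSums(Tg^2))
    # restrict candidate voxels to the curve bounding box +/- radius
    lo <- apply(P, 2, min) - sp$radius - max(geom$voxel_size)
    hi <- apply(P, 2, max) + sp$radius + max(geom$voxel_size)
    cand <- which(centers[, 1] >= lo[1] & centers[, 1] <= hi[1] &
                    centers[, 2] >= lo[2] & centers[, 2] <= hi[2] &
                    centers[, 3] >= lo[3] & centers[, 3] <= hi[3])
    if (length(cand) == 0) next
    cc <- centers[cand, , drop = FALSE]
    # nearest centerline sample per candidate voxel (chunked distance scan)
    nearest <- integer(length(cand))
    ndist2 <- numeric(length(cand))
    chunk <- 4000L
    for (s0 in seq(1L, length(cand), by = chunk)) {
      s1 <- min(s0 + chunk - 1L, length(cand))
      block <- cc[s0:s1, , drop = FALSE]
      d2 <- outer(rowSums(block^2), rowSums(P^2), "+") -
        2 * block %*% t(P)
      j <- max.col(-d2, ties.method = "first")
      nearest[s0:s1] <- j
      ndist2[s0:s1] <- d2[cbind(seq_len(nrow(block)), j)]
    }
    inside <- ndist2 <= sp$radius^2
    vidx <- cand[inside]
    tg <- Tg[nearest[inside], , drop = FALSE]
    # D = lambda3 I + (lambda1 - lambda3) t t^T  (axially symmetric)
    dl <- ev[1] - ev[3]
    tens[vidx, 1] <- ev[3] + dl * tg[, 1]^2
    tens[vidx, 2] <- ev[3] + dl * tg[, 2]^2
    tens[vidx, 3] <- ev[3] + dl * tg[, 3]^2
    tens[vidx, 4] <- dl * tg[, 1] * tg[, 2]
    tens[vidx, 5] <- dl * tg[, 1] * tg[, 3]
    tens[vidx, 6] <- dl * tg[, 2] * tg[, 3]
    bmask[vidx] <- bi
    for (end in list(c(sp$curve(0), sp$seed_label),
                     c(sp$curve(1), sp$target_label))) {
      d2e <- (centers[, 1] - end[1])^2 + (centers[, 2] - end[2])^2 +
        (centers[, 3] - end[3])^2
      labels[d2e <= sp$radius^2] <- as.integer(end[4])
    }
  }
  list(tensors = array(tens, c(d, 6L)),
       labels = array(labels, d),
       bundle_mask = array(bmask, d))
}

#' Simulate a DWI series from a tensor field
#'
#' Monoexponential Stejskal-Tanner signal \code{S = S0 exp(-b g' D g)} with
#' Rician noise built from two independent Gaussian quadrature channels of
#' standard deviation \code{s0/snr} (SNR defined on the b = 0 signal).
#'
#' @param tensors nx x ny x nz x 6 tensor array (see
#'   [rasterize_tensor_field()]).
#' @param geom a [vol_geometry()].
#' @param scheme a [gradient_scheme()].
#' @param s0 baseline signal (arbitrary units), > 0.
#' @param snr b0 signal-to-noise ratio; \code{Inf} for noiseless data.
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return An object of class \code{dwi_series}: list with \code{data}
#'   (4D array), \code{geom}, \code{scheme}.
#' @export
simulate_dwi <- function(tensors, geom, scheme, s0 = 100, snr = Inf,
                         rng_seed = 1L) {
  if (!is.finite(s0) || s0 <= 0) stop("s0 must be positive")
  if (is.na(snr) || snr <= 0) stop("snr must be positive (Inf for noiseless)")
  d <- geom$dim
  nvox <- prod(d)
  tmat <- matrix(tensors, nvox, 6)
  g <- scheme$directions
  b <- scheme$bvalues
  # per-volume quadratic-form weights on the 6 unique components
  W <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             2 * g[, 2] * g[, 3]) * b
  S <- s0 * exp(-tmat %*% t(W))  # nvox x nvol
  if (is.finite(snr)) {
    sigma <- s0 / snr
    S <- with_seed(rng_seed, {
      n1 <- matrix(rnorm(length(S), 0, sigma), nrow(S))
      n2 <- matrix(rnorm(length(S), 0, sigma), nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
  }
  structure(list(data = array(S, c(d, length(b))), geom = geom,
                 scheme = scheme), class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("DWI series: %s voxels, %d volumes\n",
              paste(x$geom$dim, collapse = " x "), length(x$scheme$bvalues)))
  invisible(x)
}

#' Phantom cohort specification
#'
#' Design of a synthetic longitudinal cohort: sample size, number of waves,
#' inter-wave intervals, per-bundle baseline FA, the distribution of true
#' per-subject annual percentage FA change, and the acquisition noise level.
#' Defaults emulate the study design this pipeline targets: 3.6-year mean
#' intervals, baseline age 59 +/- 7 years, and per-tract declines of order
#' 0-2 %/year with inter-individual variability.
#'
#' @param n_subjects cohort size (>= 2).
#' @param waves number of study waves (2 or 3).
#' @param interval_years mean inter-wave interval (years).
#' @param interval_sd per-subject jitter (SD, years) of each interval.
#' @param baseline_fa per-bundle baseline FA target(s), each in (0, 1).
#' @param annual_decline_pct mean true decline rate (percent FA lost per
#'   year, positive = decline); recycled per bundle.
#' @param annual_decline_sd between-subject SD of the true rate.
#' @param age_mean,age_sd baseline age distribution (years).
#' @param snr b0 signal-to-noise ratio of the simulated DWI.
#' @param s0 baseline signal.
#' @param trace tensor trace (mm^2/s).
#' @param rng_seed integer master seed.
#' @return An object of class \code{phantom_cohort_spec}.
#' @export
phantom_cohort_spec <- function(n_subjects = 10L, waves = 2L,
                                interval_years = 3.6, interval_sd = 0.3,
                                baseline_fa = 0.45,
                                annual_decline_pct = 1.5,
                                annual_decline_sd = 0.5,
                                age_mean = 59, age_sd = 7,
                                snr = 25, s0 = 100, trace = 2.1e-3,
                                rng_seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (!waves %in% 2:3) stop("waves must be 2 or 3")
  if (any(baseline_fa <= 0 | baseline_fa >= 1))
    stop("baseline_fa must lie in (0, 1)")
  if (is.na(snr) || snr <= 0) stop("snr must be positive")
  structure(list(n_subjects = as.integer(n_subjects),
                 waves = as.integer(waves),
                 interval_years = interval_years, interval_sd = interval_sd,
                 baseline_fa = baseline_fa,
                 annual_decline_pct = annual_decline_pct,
                 annual_decline_sd = annual_decline_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 snr = snr, s0 = s0, trace = trace,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_cohort_spec")
}

#' Ground-truth design of a phantom cohort
#'
#' Draws the per-subject quantities (age, intervals, true annual FA change
#' rates) and tabulates the true per-bundle FA at every wave:
#' \code{FA(w) = baseline * (1 - rate/100 * years_since_baseline)}. The
#' decline is later applied to the generative eigenvalues, so noisy FA
#' estimates vary around this known truth.
#'
#' @param spec a [phantom_cohort_spec()].
#' @param n_bundles number of bundles (baseline FA and decline means are
#'   recycled to this length).
#' @param bundle_names optional character names.
#' @return data.frame with one row per (subject, wave, bundle): subject,
#'   wave, bundle, age, interval (years since previous wave; NA at wave 1),
#'   years (since baseline), true_fa, true_rate (percent per year, positive
#'   = decline).
#' @export
cohort_truth <- function(spec, n_bundles = 1L, bundle_names = NULL) {
  base_fa <- rep_len(spec$baseline_fa, n_bundles)
  decl <- rep_len(spec$annual_decline_pct, n_bundles)
  if (is.null(bundle_names)) bundle_names <- paste0("bundle", seq_len(n_bundles))
  with_seed(spec$rng_seed, {
    age <- rnorm(spec$n_subjects, spec$age_mean, spec$age_sd)
    ints <- matrix(pmax(rnorm(spec$n_subjects * (spec$waves - 1L),
                              spec$interval_years, spec$interval_sd), 0.5),
                   spec$n_subjects)
    rates <- matrix(rnorm(spec$n_subjects * n_bundles, rep(decl, each = spec$n_subjects),
                          spec$annual_decline_sd), spec$n_subjects)
    out <- do.call(rbind, lapply(seq_len(spec$n_subjects), function(s) {
      yrs <- c(0, cumsum(ints[s, ]))
      do.call(rbind, lapply(seq_len(spec$waves), function(w) {
        fa_w <- pmin(pmax(base_fa * (1 - rates[s, ] / 100 * yrs[w]), 0.01), 0.99)
        data.frame(subject = s, wave = w, bundle = bundle_names,
                   age = age[s] + yrs[w],
                   interval = if (w == 1L) NA_real_ else ints[s, w - 1L],
                   years = yrs[w], true_fa = fa_w, true_rate = rates[s, ])
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate one subject-wave acquisition
#'
#' Rasterizes the bundles at the subject's true per-bundle FA for the given
#' wave and simulates the DWI series, with a deterministic per-subject,
#' per-wave noise seed derived from the master seed.
#'
#' @param spec a [phantom_cohort_spec()].
#' @param truth the [cohort_truth()] table for this cohort.
#' @param subject,wave indices.
#' @param bundles list of [curve_bundle_spec()]s (same order as the truth
#'   table's bundles).
#' @param geom a [vol_geometry()].
#' @param scheme a [gradient_scheme()].
#' @return list with \code{dwi} (a \code{dwi_series}), \code{labels},
#'   \code{bundle_mask}, \code{truth} (that subject-wave's truth rows).
#' @export
simulate_subject_wave <- function(spec, truth, subject, wave, bundles, geom,
                                  scheme = default_gradient_scheme()) {
  rows <- truth[truth$subject == subject & truth$wave == wave, ]
  if (nrow(rows) != length(bundles))
    stop("truth table does not match bundle list")
  ev <- lapply(rows$true_fa, eigenvalues_for_fa, trace = spec$trace)
  ras <- rasterize_tensor_field(bundles, geom, ev)
  dwi <- simulate_dwi(ras$tensors, geom, scheme, s0 = spec$s0,
                      snr = spec$snr,
                      rng_seed = derive_seed(spec$rng_seed, subject, wave))
  list(dwi = dwi, labels = ras$labels, bundle_mask = ras$bundle_mask,
       truth = rows)
}

#' Simulate a full longitudinal phantom cohort
#'
#' Materializes every subject-wave acquisition (intended for small n; the
#' streaming [run_pipeline()] processes subject-waves one at a time).
#'
#' @inheritParams simulate_subject_wave
#' @param bundles list of [curve_bundle_spec()]s.
#' @return list with \code{truth} (ground-truth table), \code{scans} (list
#'   of per-(subject, wave) entries as in [simulate_subject_wave()]),
#'   \code{spec}, \code{geom}, \code{scheme}.
#' @export
simulate_cohort <- function(spec, bundles, geom = default_geometry(),
                            scheme = default_gradient_scheme()) {
  if (inherits(bundles, "curve_bundle_spec")) bundles <- list(bundles)
  truth <- cohort_truth(spec, length(bundles),
                        vapply(bundles, function(b) b$name, ""))
  scans <- list()
  for (s in seq_len(spec$n_subjects)) for (w in seq_len(spec$waves)) {
    scans[[sprintf("sub-%02d_wave-%d", s, w)]] <-
      simulate_subject_wave(spec, truth, s, w, bundles, geom, scheme)
  }
  list(truth = truth, scans = scans, spec = spec, geom = geom,
       scheme = scheme)
}

#' Write a simulated cohort to disk
#'
#' Per subject-wave: a 4D DWI NIfTI, a 3D integer label NIfTI and FSL-style
#' bval/bvec text files; plus one ground-truth TSV for the whole cohort.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(cohort$scans)) {
    sc <- cohort$scans[[nm]]
    write_dwi(sc$dwi, file.path(dir, paste0(nm, "_dwi.nii.gz")),
              file.path(dir, paste0(nm, ".bval")),
              file.path(dir, paste0(nm, ".bvec")))
    write_label_volume(sc$labels, cohort$geom,
                       file.path(dir, paste0(nm, "_labels.nii.gz")))
  }
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
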