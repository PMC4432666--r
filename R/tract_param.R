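#' Resample a streamline to n equidistant points
#'
#' Arc-length-uniform resampling: the output points lie on the input
#' polyline, consecutive spacing equals total length / (n - 1), and the
#' endpoints are preserved exactly. Duplicate consecutive input points are
#' collapsed first, so point duplication does not change the result.
#'
#' @param s n x 3 point matrix (mm).
#' @param n number of output points, default 100.
#' @return n x 3 matrix.
#' @export
resample_streamline <- function(s, n = 100L) {
  s <- rbind(s)
  if (nrow(s) >= 2L) {
    dup <- c(FALSE, rowSums(abs(diff(s))) == 0)
    s <- s[!dup, , drop = FALSE]
  }
  if (nrow(s) < 2L) stop("cannot resample a degenerate (zero-length) streamline")
  seglen <- sqrt(rowSums(diff(s)^2))
  cum <- c(0, cumsum(seglen))
  L <- cum[length(cum)]
  if (L <= 0) stop("cannot resample a degenerate (zero-length) streamline")
  xout <- seq(0, L, length.out = n)
  out <- cbind(approx(cum, s[, 1], xout)$y,
               approx(cum, s[, 2], xout)$y,
               approx(cum, s[, 3], xout)$y)
  out[1, ] <- s[1, ]
  out[n, ] <- s[nrow(s), ]
  out
}

#' Orient every streamline of a bundle seed-first
#'
#' Orders each streamline so its first point is the seed-proximal end,
#' judged by the distance from each endpoint to the nearest seed-mask voxel
#' centre. Streamlines with neither endpoint near the seed mask (beyond
#' \code{max_dist}) are flagged and excluded with a warning.
#'
#' @param b a \code{bundle}.
#' @param seed_mask logical 3D array (or integer labels with
#'   \code{seed_label} taken from the bundle).
#' @param max_dist exclusion distance in mm; default twice the largest
#'   voxel dimension.
#' @return the re-oriented \code{bundle}.
#' @export
orient_bundle <- function(b, seed_mask, max_dist = NULL) {
  geom <- b$geom
  if (!is.logical(seed_mask)) seed_mask <- seed_mask == b$seed_label
  if (!any(seed_mask)) stop("seed mask is empty")
  max_dist <- max_dist %||% (2 * max(geom$voxel_size))
  idx <- which(seed_mask, arr.ind = TRUE) - 1L
  centers <- sweep(idx + 0.5, 2, geom$voxel_size, "*")
  mindist <- function(p) {
    sqrt(min((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 +
               (centers[, 3] - p[3])^2))
  }
  out <- list()
  dropped <- 0L
  for (s in b$streamlines) {
    d1 <- mindist(s[1, ])
    d2 <- mindist(s[nrow(s), ])
    if (min(d1, d2) > max_dist) {
      dropped <- dropped + 1L
      next
    }
    if (d2 < d1) s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
    out[[length(out) + 1L]] <- s
  }
  if (dropped > 0L)
    warning(sprintf("%d streamline(s) touch the seed mask at neither end; excluded",
                    dropped))
  b$streamlines <- out
  b$n_fibers <- length(out)
  b
}

new_tract_profile <- function(segment, mean_fa, se, n, side = NULL) {
  df <- data.frame(segment = segment, mean_fa = mean_fa, se = se, n = n)
  if (!is.null(side)) df$side <- side
  class(df) <- c("tract_profile", "data.frame")
  df
}

profile_from_matrix <- function(vals) {
  # vals: streamlines x segments matrix of sampled FA
  nseg <- ncol(vals)
  n <- colSums(!is.na(vals))
  mu <- colMeans(vals, na.rm = TRUE)
  mu[n == 0] <- NA_real_
  se <- apply(vals, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(0)
    sd(v) / sqrt(length(v))
  })
  se[n == 0] <- NA_real_
  new_tract_profile(seq_len(nseg), mu, se, n)
}

#' Two-ROI along-tract FA profile
#'
#' Each member streamline (oriented and trimmed seed-to-target) is
#' resampled to \code{n} equidistant points — data point 1 at the seed,
#' data point \code{n} at the target — and the FA map is sampled at every
#' point by trilinear interpolation. Segment mean and standard error are
#' taken across streamlines at fixed segment index.
#'
#' @param b an oriented, trimmed \code{bundle}.
#' @param fa a \code{fa_volume}.
#' @param n number of segments, default 100.
#' @param method FA sampling, "trilinear" (default) or "nearest".
#' @return a \code{tract_profile} data.frame: segment, mean_fa, se, n. For
#'   a single-streamline bundle the SE is 0 by convention. An empty bundle
#'   yields an all-missing profile.
#' @export
profile_two_roi <- function(b, fa, n = 100L, method = "trilinear") {
  if (b$n_fibers == 0L)
    return(new_tract_profile(seq_len(n), NA_real_, NA_real_, 0L))
  vals <- t(vapply(b$streamlines, function(s) {
    sample_volume(fa$fa, resample_streamline(s, n), b$geom, method)
  }, numeric(n)))
  profile_from_matrix(vals)
}

#' Single-defining-ROI along-tract FA profile
#'
#' For tracts anchored by one region (corticospinal-style): each streamline
#' is parameterized by arc distance from its point nearest the defining-ROI
#' centroid, running toward the distal cut (its farther end). Distances are
#' normalized over the bundle's common extent (the shortest distal reach
#' among member streamlines), so segment 1 sits at the ROI anchor and
#' segment \code{n} at the common distal cut.
#'
#' @param b a \code{bundle}.
#' @param fa a \code{fa_volume}.
#' @param roi_mask logical 3D array of the defining ROI.
#' @param n segments, default 100.
#' @param method FA sampling method.
#' @return a \code{tract_profile}; streamlines missing the ROI are excluded
#'   with a warning.
#' @export
profile_single_roi <- function(b, fa, roi_mask, n = 100L,
                               method = "trilinear") {
  geom <- b$geom
  if (!any(roi_mask)) stop("defining ROI mask is empty")
  ridx <- which(roi_mask, arr.ind = TRUE) - 1L
  centroid <- colMeans(sweep(ridx + 0.5, 2, geom$voxel_size, "*"))
  anchored <- list()
  extents <- numeric()
  dropped <- 0L
  for (s in b$streamlines) {
    vidx <- points_to_voxels(s, geom)
    ok <- !is.na(vidx[, 1])
    inroi <- rep(FALSE, nrow(s))
    inroi[ok] <- roi_mask[vidx[ok, , drop = FALSE] + 1L]
    if (!any(inroi)) {
      dropped <- dropped + 1L
      next
    }
    d2 <- (s[, 1] - centroid[1])^2 + (s[, 2] - centroid[2])^2 +
      (s[, 3] - centroid[3])^2
    anchor <- which.min(d2)
    cum <- c(0, cumsum(sqrt(rowSums(diff(s)^2))))
    # distal side: the end with the greater arc distance from the anchor
    ext_start <- cum[anchor]
    ext_end <- cum[length(cum)] - cum[anchor]
    if (ext_start > ext_end) {
      s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
      cum <- c(0, cumsum(sqrt(rowSums(diff(s)^2))))
      anchor <- nrow(s) - anchor + 1L
    }
    anchored[[length(anchored) + 1L]] <- list(s = s, cum = cum,
                                              anchor = anchor)
    extents <- c(extents, cum[length(cum)] - cum[anchor])
  }
  if (dropped > 0L)
    warning(sprintf("%d streamline(s) miss the defining ROI; excluded", dropped))
  if (length(anchored) == 0L)
    return(new_tract_profile(seq_len(n), NA_real_, NA_real_, 0L))
  common <- min(extents)
  vals <- t(vapply(anchored, function(a) {
    darc <- a$cum[a$anchor] + common * (seq_len(n) - 1) / (n - 1)
    pts <- cbind(approx(a$cum, a$s[, 1], darc)$y,
                 approx(a$cum, a$s[, 2], darc)$y,
                 approx(a$cum, a$s[, 3], darc)$y)
    sample_volume(fa$fa, pts, geom, method)
  }, numeric(n)))
  profile_from_matrix(vals)
}

#' Hemisphere-split (callosal-style) along-tract FA profiles
#'
#' For bundles crossing the midsagittal plane: each streamline is split at
#' its midline crossing and each half profiled from the midline (segment 1,
#' the genu in the anatomical case) outward to the cortical end (segment
#' \code{n}), as two two-ROI-style profiles tagged left/right. Streamlines
#' that never cross the midline are excluded.
#'
#' @param b a \code{bundle}.
#' @param fa a \code{fa_volume}.
#' @param n segments per hemisphere, default 100 (2 x 100 total).
#' @param midline_x world x-coordinate of the midsagittal plane; default
#'   the volume centre.
#' @param method FA sampling method.
#' @return list with elements \code{left} and \code{right}, each a
#'   \code{tract_profile} (all-missing when no streamline contributes to
#'   that side).
#' @export
profile_acf <- function(b, fa, n = 100L, midline_x = NULL,
                        method = "trilinear") {
  geom <- b$geom
  mid <- midline_x %||% (geom$dim[1] * geom$voxel_size[1] / 2)
  halves <- list(left = list(), right = list())
  for (s in b$streamlines) {
    side <- sign(s[, 1] - mid)
    cross <- which(side[-1] * side[-length(side)] < 0)
    if (length(cross) == 0L && !any(side == 0)) next
    ci <- if (length(cross)) cross[1] else which(side == 0)[1]
    # midline point by linear interpolation along the crossing segment
    if (side[ci] == 0) {
      pmidl <- s[ci, ]
      i_before <- ci
    } else {
      a <- s[ci, ]; bb <- s[ci + 1, ]
      tfrac <- (mid - a[1]) / (bb[1] - a[1])
      pmidl <- a + tfrac * (bb - a)
      i_before <- ci
    }
    first_half <- rbind(s[seq_len(i_before), , drop = FALSE], pmidl)
    second_half <- rbind(pmidl, s[seq(i_before + 1, nrow(s)), , drop = FALSE])
    # order each half from the midline outward
    first_half <- first_half[rev(seq_len(nrow(first_half))), , drop = FALSE]
    for (h in list(first_half, second_half)) {
      if (nrow(h) < 2L || streamline_length(h) <= 0) next
      key <- if (mean(h[, 1]) < mid) "left" else "right"
      halves[[key]][[length(halves[[key]]) + 1L]] <- h
    }
  }
  one_side <- function(hs, side) {
    if (length(hs) == 0L) {
      pr <- new_tract_profile(seq_len(n), NA_real_, NA_real_, 0L, side)
      return(pr)
    }
    vals <- t(vapply(hs, function(h) {
      sample_volume(fa$fa, resample_streamline(h, n), geom, method)
    }, numeric(n)))
    pr <- profile_from_matrix(vals)
    pr$side <- side
    pr
  }
  list(left = one_side(halves$left, "left"),
       right = one_side(halves$right, "right"))
}

#' @export
print.tract_profile <- function(x, ...) {
  cat(sprintf("Along-tract FA profile: %d segments, mean FA %.3f (range %.3f-%.3f), max n = %d\n",
              nrow(x), mean(x$mean_fa, na.rm = TRUE),
              suppressWarnings(min(x$mean_fa, na.rm = TRUE)),
              suppressWarnings(max(x$mean_fa, na.rm = TRUE)),
              max(x$n)))
  invisible(x)
}

#' Plot an along-tract FA profile
#'
#' Mean segment-wise FA with a +/- 1 SE band.
#'
#' @param x a \code{tract_profile}.
#' @param ... passed to \code{plot}.
#' @export
plot.tract_profile <- function(x, ...) {
  graphics::plot(x$segment, x$mean_fa, type = "l", xlab = "segment",
                 ylab = "mean FA", ...)
  graphics::lines(x$segment, x$mean_fa + x$se, lty = 3)
  graphics::lines(x$segment, x$mean_fa - x$se, lty = 3)
  invisible(x)
}
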