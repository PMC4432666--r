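#' FACT tracking parameters
#'
#' Termination and propagation settings for deterministic streamline
#' tractography. Defaults follow common FACT practice: FA stop 0.15,
#' maximum turning angle 35 degrees per step, one seed per voxel (at the
#' voxel centre), and a fixed advance of half the smallest voxel dimension
#' with trilinearly interpolated, sign-aligned directions.
#'
#' @param fa_stop FA termination threshold, in \[0, 1).
#' @param angle_stop maximum turning angle per step (degrees), in (0, 90\].
#' @param step step length in mm; \code{NULL} = half the smallest voxel
#'   dimension.
#' @param seeds_per_voxel seeds per eligible voxel (currently 1 supported).
#' @param max_steps per-direction step cap (guards against loops).
#' @return An object of class \code{tracking_params}.
#' @export
tracking_params <- function(fa_stop = 0.15, angle_stop = 35, step = NULL,
                            seeds_per_voxel = 1L, max_steps = 2000L) {
  stopifnot(fa_stop >= 0, fa_stop < 1, angle_stop > 0, angle_stop <= 90,
            seeds_per_voxel == 1L, max_steps >= 1L)
  structure(list(fa_stop = fa_stop, angle_stop = angle_stop, step = step,
                 seeds_per_voxel = as.integer(seeds_per_voxel),
                 max_steps = as.integer(max_steps)),
            class = "tracking_params")
}

#' Whole-volume deterministic FACT tractography
#'
#' From every voxel whose FA meets the threshold, a streamline is
#' propagated bidirectionally along the principal eigenvector
#' (sign-aligned with the previous direction at every step) and the two
#' half-tracks are concatenated. Propagation terminates on leaving the
#' volume, FA below \code{fa_stop}, or a turning angle above
#' \code{angle_stop} (an exact 90-degree flip terminates). Tracking is
#' fully deterministic: identical inputs give an identical streamline set
#' in identical order (seed voxels in column-major order).
#'
#' @param eig a \code{tensor_eigensystem}, or an nx x ny x nz x 3 principal
#'   eigenvector array.
#' @param fa a \code{fa_volume} sharing the same geometry.
#' @param params a [tracking_params()].
#' @param geom required when \code{eig} is a bare array.
#' @return An object of class \code{streamline_set}: a list of n x 3 point
#'   matrices (voxel-mm coordinates), each carrying its seed voxel (0-based
#'   triplet) as attribute \code{"seed"}; attributes \code{geom} and
#'   \code{params}.
#' @export
fact_track <- function(eig, fa, params = tracking_params(), geom = NULL) {
  if (inherits(eig, "tensor_eigensystem")) {
    v1 <- principal_direction(eig)
    geom <- eig$geom
  } else {
    v1 <- eig
    if (is.null(geom)) stop("geom required for a bare eigenvector array")
  }
  if (!identical(fa$geom$dim, geom$dim) ||
      !isTRUE(all.equal(fa$geom$voxel_size, geom$voxel_size)))
    stop("eigenvector field and FA volume must share geometry")
  step <- params$step %||% (min(geom$voxel_size) / 2)
  famap <- fa$fa
  famap[is.na(famap)] <- 0
  seed_lin <- which(famap >= params$fa_stop)  # column-major, deterministic
  if (length(seed_lin) == 0L) {
    return(structure(list(), class = "streamline_set", geom = geom,
                     params = params))
  }
  d <- geom$dim
  k <- (seed_lin - 1L) %/% (d[1] * d[2])
  j <- ((seed_lin - 1L) %/% d[1]) %% d[2]
  i <- (seed_lin - 1L) %% d[1]
  seeds <- cbind(i, j, k)
  storage.mode(seeds) <- "integer"
  v1c <- v1
  v1c[is.na(v1c)] <- 0
  raw <- fact_track_cpp(as.numeric(v1c), as.numeric(famap), d,
                        geom$voxel_size, seeds, params$fa_stop,
                        params$angle_stop, step, params$max_steps)
  keep <- !vapply(raw, is.null, TRUE)
  out <- raw[keep]
  sd <- seeds[keep, , drop = FALSE]
  for (q in seq_along(out)) attr(out[[q]], "seed") <- sd[q, ]
  structure(out, class = "streamline_set", geom = geom, params = params)
}

#' @export
print.streamline_set <- function(x, ...) {
  if (length(x) == 0) {
    cat("Streamline set: 0 streamlines\n")
    return(invisible(x))
  }
  len <- vapply(x, streamline_length, 0)
  cat(sprintf("Streamline set: %d streamlines, length %.1f-%.1f mm (median %.1f)\n",
              length(x), min(len), max(len), stats::median(len)))
  invisible(x)
}

#' Streamline arc length
#'
#' @param s n x 3 point matrix (mm).
#' @return total polyline length (mm): the sum of consecutive-point
#'   Euclidean distances.
#' @export
streamline_length <- function(s) {
  if (nrow(s) < 2L) return(0)
  sum(sqrt(rowSums(diff(s)^2)))
}
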