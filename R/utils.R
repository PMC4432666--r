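#' Volume geometry
#'
#' Minimal geometry descriptor shared by all volumes in the pipeline: grid
#' dimensions and voxel sizes in mm. All synthetic data live in one common
#' space (co-registered by construction), with world coordinates in
#' "voxel-mm": the centre of voxel \code{(i,j,k)} (0-based) is at
#' \code{((i+0.5)*vx, (j+0.5)*vy, (k+0.5)*vz)} mm, the TrackVis convention.
#'
#' @param dim integer vector of length 3, grid dimensions (voxels).
#' @param voxel_size numeric vector of length 3, voxel edge lengths (mm).
#' @return An object of class \code{vol_geom}.
#' @export
vol_geometry <- function(dim, voxel_size) {
  dim <- as.integer(dim)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(dim) == 3L, length(voxel_size) == 3L,
            all(dim >= 1L), all(voxel_size > 0))
  structure(list(dim = dim, voxel_size = voxel_size), class = "vol_geom")
}

#' @export
print.vol_geom <- function(x, ...) {
  cat(sprintf("Volume geometry: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$dim[1], x$dim[2], x$dim[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Voxel centres of a geometry
#'
#' @param geom a [vol_geometry()].
#' @return n-voxel x 3 matrix of voxel-centre world coordinates (mm), in
#'   column-major voxel order.
#' @export
voxel_centers <- function(geom) {
  d <- geom$dim; v <- geom$voxel_size
  idx <- voxel_index_grid(d)
  sweep(idx + 0.5, 2, v, "*")
}

# 0-based voxel index grid in column-major order, n x 3
voxel_index_grid <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
        rep(seq_len(d[3]) - 1L, each = d[1] * d[2]))
}

#' Map world points to voxel indices
#'
#' @param pts n x 3 matrix of voxel-mm world coordinates.
#' @param geom a [vol_geometry()].
#' @return n x 3 integer matrix of 0-based voxel indices; points outside the
#'   grid get NA rows.
#' @export
points_to_voxels <- function(pts, geom) {
  pts <- rbind(pts)  # tolerate a bare length-3 vector
  idx <- floor(sweep(pts, 2, geom$voxel_size, "/"))
  for (a in 1:3) idx[idx[, a] < 0 | idx[, a] > geom$dim[a] - 1L, a] <- NA
  bad <- rowSums(is.na(idx)) > 0
  idx[bad, ] <- NA
  storage.mode(idx) <- "integer"
  idx
}

# linear (1-based, column-major) index from 0-based voxel triplets
voxel_linear_index <- function(idx, dim) {
  1L + idx[, 1] + dim[1] * (idx[, 2] + dim[2] * idx[, 3])
}

#' Sample a scalar volume at world points
#'
#' Trilinear (default) or nearest-neighbour interpolation of a 3D scalar
#' field at arbitrary voxel-mm coordinates.
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of world coordinates (voxel-mm).
#' @param geom a [vol_geometry()] matching \code{vol}.
#' @param method "trilinear" or "nearest".
#' @return numeric vector of sampled values; NA outside the grid.
#' @export
sample_volume <- function(vol, pts, geom, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  pts <- rbind(pts)
  d <- geom$dim
  f <- sweep(pts, 2, geom$voxel_size, "/") - 0.5
  if (method == "nearest") {
    i <- round(f)
    ok <- i[, 1] >= 0 & i[, 1] <= d[1] - 1 & i[, 2] >= 0 & i[, 2] <= d[2] - 1 &
      i[, 3] >= 0 & i[, 3] <= d[3] - 1
    out <- rep(NA_real_, nrow(pts))
    if (any(ok)) out[ok] <- vol[cbind(i[ok, 1] + 1, i[ok, 2] + 1, i[ok, 3] + 1)]
    return(out)
  }
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 & f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
    f[, 3] >= 0 & f[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE]
  i0 <- floor(fo)
  for (a in 1:3) i0[, a] <- pmin(pmax(i0[, a], 0), max(d[a] - 2, 0))
  fr <- fo - i0
  acc <- numeric(nrow(fo))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    ii <- pmin(i0[, 1] + dx, d[1] - 1)
    jj <- pmin(i0[, 2] + dy, d[2] - 1)
    kk <- pmin(i0[, 3] + dz, d[3] - 1)
    acc <- acc + w * vol[cbind(ii + 1, jj + 1, kk + 1)]
  }
  out[ok] <- acc
  out
}

#' Otsu threshold of a scalar sample
#'
#' Histogram-based two-class threshold (maximising between-class variance),
#' used to derive a brain mask from the mean b=0 signal. Degenerate inputs
#' (near-zero variance) return \code{-Inf} so that every voxel is kept.
#'
#' @param x numeric vector (non-finite values dropped).
#' @param nbins number of histogram bins.
#' @return threshold value; voxels with \code{x > threshold} are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0 || diff(range(x)) < 1e-12 * max(abs(x), 1)) return(-Inf)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = nbins + 1L),
            plot = FALSE)
  w <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # ties (an empty valley between modes) resolve to the valley midpoint
  best <- sigma_b >= max(sigma_b) * (1 - 1e-12)
  mean(mids[best])
}

# run a block of code with a locally-seeded RNG, restoring global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a per-subject/per-wave substream seed below 2^31
derive_seed <- function(base, subject, wave) {
  as.integer((as.numeric(base) * 48271 + subject * 7919 + wave * 104729) %%
               2147483629)
}
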