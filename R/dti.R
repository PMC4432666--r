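#' Fit diffusion tensors by log-linear least squares
#'
#' Voxel-wise ordinary least squares on the log signal,
#' \code{ln S = ln S0 - b g' D g}, with 7 unknowns (6 tensor components and
#' \code{ln S0}). This is the classical estimator of the era's tensor
#' tools; on noiseless monoexponential data it is exact. Non-positive
#' signals are clamped to \code{1e-6 * s0} (per-voxel mean b0) before the
#' log.
#'
#' @param dwi a \code{dwi_series}.
#' @param mask optional logical 3D array restricting the fit; \code{"otsu"}
#'   thresholds the mean b0 signal with [otsu_threshold()]; \code{NULL}
#'   fits every voxel.
#' @return An object of class \code{tensor_volume}: list with
#'   \code{tensors} (nx x ny x nz x 6 array: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz),
#'   \code{s0} (fitted S0 map), \code{mask}, \code{geom}. Voxels outside
#'   the mask are NA.
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  b <- dwi$scheme$bvalues
  g <- dwi$scheme$directions
  ndir <- sum(b > 0 & !duplicated(round(g, 8)) )
  if (sum(b == 0) < 1L || ndir < 6L || length(b) < 7L)
    stop("insufficient data: need >= 6 distinct non-zero-b directions and >= 1 b = 0 volume")
  d <- dwi$geom$dim
  nvox <- prod(d)
  S <- matrix(dwi$data, nvox, length(b))
  s0_obs <- rowMeans(S[, b == 0, drop = FALSE])
  if (identical(mask, "otsu")) {
    thr <- otsu_threshold(s0_obs)
    mask <- array(s0_obs > thr, d)
  }
  keep <- if (is.null(mask)) rep(TRUE, nvox) else as.logical(mask)
  keep <- keep & is.finite(s0_obs) & s0_obs > 0
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("insufficient data: gradient design matrix is rank-deficient")
  Sk <- S[keep, , drop = FALSE]
  eps <- 1e-6 * s0_obs[keep]
  Sk <- pmax(Sk, eps)  # clamp non-positive / tiny noisy signals
  beta <- qr.coef(qrX, t(log(Sk)))  # 7 x nkept
  tens <- matrix(NA_real_, nvox, 6)
  tens[keep, ] <- t(beta[-1, , drop = FALSE])
  s0 <- rep(NA_real_, nvox)
  s0[keep] <- exp(beta[1, ])
  structure(list(tensors = array(tens, c(d, 6L)),
                 s0 = array(s0, d),
                 mask = array(keep, d),
                 geom = dwi$geom,
                 template = dwi$template),
            class = "tensor_volume")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("Diffusion tensor volume: %s voxels (%d fitted)\n",
              paste(x$geom$dim, collapse = " x "), sum(x$mask)))
  invisible(x)
}

#' Voxel-wise eigensystem of a tensor volume
#'
#' Eigenvalues sorted descending with orthonormal eigenvectors; negative
#' eigenvalues are additionally provided clamped to 1e-12 for FA (raw
#' values retained for diagnostics). Non-finite tensors are flagged invalid
#' and excluded from the mask.
#'
#' @param tv a \code{tensor_volume}, or an nx x ny x nz x 6 array with
#'   \code{geom} supplied.
#' @param geom required when \code{tv} is a bare array.
#' @return An object of class \code{tensor_eigensystem}: \code{values}
#'   (nx x ny x nz x 3, descending), \code{values_clamped},
#'   \code{vectors} (nx x ny x nz x 3 x 3; \code{[, , , , j]} is the
#'   eigenvector of eigenvalue j), \code{mask}, \code{geom}.
#' @export
tensor_eigensystem <- function(tv, geom = NULL) {
  if (inherits(tv, "tensor_volume")) {
    arr <- tv$tensors; geom <- tv$geom; mask <- as.logical(tv$mask)
  } else {
    arr <- tv
    if (is.null(geom)) stop("geom required for a bare tensor array")
    mask <- rep(TRUE, prod(geom$dim))
  }
  d <- geom$dim
  nvox <- prod(d)
  tmat <- matrix(arr, nvox, 6)
  res <- eig3_batch(tmat)
  valid <- mask & apply(is.finite(res$values), 1, all)
  res$values[!valid, ] <- NA_real_
  res$vectors[!valid, ] <- NA_real_
  clamped <- pmax(res$values, 1e-12)
  structure(list(values = array(res$values, c(d, 3L)),
                 values_clamped = array(clamped, c(d, 3L)),
                 vectors = array(res$vectors, c(d, 3L, 3L)),
                 mask = array(valid, d), geom = geom),
            class = "tensor_eigensystem")
}

#' Fractional anisotropy from eigenvalues
#'
#' \code{FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||}. The
#' all-zero triple is undefined and returns NA.
#'
#' @param values length-3 vector, or n x 3 matrix of eigenvalue triples.
#' @return FA value(s) in \[0, 1\] (NA where undefined).
#' @export
fa_from_eigenvalues <- function(values) {
  m <- rbind(values)
  mu <- rowMeans(m)
  num <- (m[, 1] - mu)^2 + (m[, 2] - mu)^2 + (m[, 3] - mu)^2
  den <- m[, 1]^2 + m[, 2]^2 + m[, 3]^2
  fa <- sqrt(1.5 * num / den)
  fa[den == 0] <- NA_real_
  fa <- pmin(fa, 1)
  if (is.vector(values)) fa[[1]] else fa
}

#' FA map from a tensor volume or eigensystem
#'
#' Computes FA from the clamped eigenvalues, so values lie in \[0, 1\].
#' Masked/invalid voxels are NA (distinct from a true FA of 0).
#'
#' @param x a \code{tensor_volume} or \code{tensor_eigensystem}.
#' @return An object of class \code{fa_volume}: \code{fa} (3D array),
#'   \code{mask}, \code{geom}.
#' @export
fa_map <- function(x) {
  if (inherits(x, "tensor_volume")) x <- tensor_eigensystem(x)
  if (!inherits(x, "tensor_eigensystem")) stop("unsupported input")
  d <- x$geom$dim
  vals <- matrix(x$values_clamped, prod(d), 3)
  fa <- fa_from_eigenvalues(vals)
  fa[!as.logical(x$mask)] <- NA_real_
  structure(list(fa = array(fa, d), mask = x$mask, geom = x$geom),
            class = "fa_volume")
}

#' @export
print.fa_volume <- function(x, ...) {
  cat(sprintf("FA volume: %s voxels; FA range %.3f-%.3f\n",
              paste(x$geom$dim, collapse = " x "),
              min(x$fa, na.rm = TRUE), max(x$fa, na.rm = TRUE)))
  invisible(x)
}

#' Principal diffusion direction field
#'
#' @param eig a \code{tensor_eigensystem}.
#' @return nx x ny x nz x 3 array of unit principal eigenvectors.
#' @export
principal_direction <- function(eig) {
  eig$vectors[, , , , 1, drop = TRUE]
}

#' Write an FA map (and optionally the principal eigenvector volume)
#'
#' @param fa a \code{fa_volume}.
#' @param path NIfTI output path.
#' @param eig optional \code{tensor_eigensystem}; when given, the principal
#'   eigenvector field is written next to the FA map as \code{*_v1.nii.gz}.
#' @param template optional RNifti template whose affine is preserved.
#' @export
write_fa <- function(fa, path, eig = NULL, template = NULL) {
  arr <- fa$fa
  arr[is.na(arr)] <- 0
  write_volume(arr, fa$geom, path, template)
  if (!is.null(eig)) {
    v1 <- principal_direction(eig)
    v1[is.na(v1)] <- 0
    write_volume(v1, fa$geom, sub("(\\.nii(\\.gz)?)$", "_v1\\1", path),
                 template)
  }
  invisible(path)
}
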