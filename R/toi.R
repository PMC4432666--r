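#' Extract a seed-to-target fiber bundle
#'
#' A streamline is retained iff it has at least one point inside the seed
#' mask and at least one inside the target mask (any-point membership;
#' endpoint-only membership available as an option). Retained streamlines
#' are trimmed to the maximal sub-polyline between their last seed-mask
#' point and first target-mask point; streamlines running target-to-seed
#' are reversed first, so every member leaves seed-first.
#'
#' When the seed and target labels coincide, a streamline is retained only
#' if it visits the mask in two separate passes (enters, leaves, and
#' re-enters).
#'
#' @param streamlines a \code{streamline_set}.
#' @param labels integer 3D label array sharing the tracking geometry.
#' @param seed_label,target_label integer ROI ids.
#' @param geom a [vol_geometry()]; defaults to the set's attribute.
#' @param trim trim retained streamlines to the seed-target sub-polyline.
#' @param endpoint_only require the membership points to be streamline
#'   endpoints rather than any point.
#' @return An object of class \code{bundle}: list with \code{streamlines},
#'   \code{seed_label}, \code{target_label}, \code{n_fibers}, \code{name},
#'   \code{geom}.
#' @export
extract_bundle <- function(streamlines, labels, seed_label, target_label,
                           geom = attr(streamlines, "geom"), trim = TRUE,
                           endpoint_only = FALSE, name = NULL) {
  if (is.null(geom)) stop("geom required")
  empty <- function() structure(list(streamlines = list(),
                                     seed_label = seed_label,
                                     target_label = target_label,
                                     n_fibers = 0L, geom = geom,
                                     name = name %||% sprintf("%d-%d", seed_label, target_label)),
                                class = "bundle")
  if (!any(labels == seed_label)) {
    warning(sprintf("seed label %d absent from label volume", seed_label))
    return(empty())
  }
  if (!any(labels == target_label)) {
    warning(sprintf("target label %d absent from label volume", target_label))
    return(empty())
  }
  same <- seed_label == target_label
  kept <- list()
  for (s in streamlines) {
    idx <- points_to_voxels(s, geom)
    lab <- rep(0L, nrow(s))
    ok <- !is.na(idx[, 1])
    lab[ok] <- labels[idx[ok, , drop = FALSE] + 1L]
    in_seed <- lab == seed_label
    in_target <- lab == target_label
    if (endpoint_only) {
      ends <- c(1L, nrow(s))
      in_seed[-ends] <- FALSE
      in_target[-ends] <- FALSE
    }
    if (same) {
      r <- rle(in_seed)
      runs <- which(r$values)
      if (length(runs) < 2L) next
      if (trim) {
        ends_cum <- cumsum(r$lengths)
        first_run_end <- ends_cum[runs[1]]
        last_run_start <- ends_cum[runs[length(runs)]] -
          r$lengths[runs[length(runs)]] + 1L
        s <- s[first_run_end:last_run_start, , drop = FALSE]
      }
      kept[[length(kept) + 1L]] <- s
      next
    }
    if (!any(in_seed) || !any(in_target)) next
    if (trim) {
      if (min(which(in_seed)) > min(which(in_target))) {
        s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
        in_seed <- rev(in_seed)
        in_target <- rev(in_target)
      }
      ft <- min(which(in_target))
      seed_before <- which(in_seed & seq_along(in_seed) <= ft)
      start <- if (length(seed_before)) max(seed_before) else min(which(in_seed))
      end <- min(which(in_target & seq_along(in_target) >= start))
      if (end <= start) next
      s <- s[start:end, , drop = FALSE]
    }
    kept[[length(kept) + 1L]] <- s
  }
  structure(list(streamlines = kept, seed_label = seed_label,
                 target_label = target_label, n_fibers = length(kept),
                 geom = geom,
                 name = name %||% sprintf("%d-%d", seed_label, target_label)),
            class = "bundle")
}

#' @export
print.bundle <- function(x, ...) {
  cat(sprintf("Bundle %s: %d streamlines (seed %d -> target %d)\n",
              x$name, x$n_fibers, x$seed_label, x$target_label))
  invisible(x)
}

#' Minimum-fiber-count recognition criterion
#'
#' A bundle is recognized as a proper tract iff it contains at least
#' \code{min_fibers} continuous fibers (boundary inclusive).
#'
#' @param b a \code{bundle} (or a fiber count).
#' @param min_fibers threshold, default 20.
#' @return logical.
#' @export
bundle_passes_threshold <- function(b, min_fibers = 20L) {
  n <- if (inherits(b, "bundle")) b$n_fibers else as.integer(b)
  n >= min_fibers
}

#' Cohort-level detection filter
#'
#' A connection qualifies for analysis iff it was detected (bundle passing
#' the fiber threshold) in at least \code{fraction} of the cohort, i.e.
#' subject count >= \code{ceiling(fraction * cohort_size)}.
#'
#' @param counts detection counts: a numeric vector, or a matrix/data.frame
#'   of counts (seeds x targets, NA = never detected).
#' @param cohort_size number of subjects.
#' @param fraction required detection fraction, default 0.9.
#' @return logical of the same shape as \code{counts} (NA counts are
#'   \code{FALSE}).
#' @export
cohort_detection_filter <- function(counts, cohort_size, fraction = 0.9) {
  stopifnot(cohort_size >= 1)
  need <- ceiling(fraction * cohort_size)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  q <- counts >= need
  q[is.na(q)] <- FALSE
  q
}

#' Tract mean FA (grand average over the intersected FA-map region)
#'
#' Mean FA over the set of unique voxels visited by at least one member
#' streamline, each voxel counted once (the "FA map region" reading of the
#' grand average). A per-streamline-point mean is available as an
#' alternative weighting.
#'
#' @param b a \code{bundle}.
#' @param fa a \code{fa_volume}.
#' @param mode "voxel" (unique-voxel mean, default) or "point"
#'   (per-streamline-point mean).
#' @return mean FA; NA for an empty bundle.
#' @export
tract_mean_fa <- function(b, fa, mode = c("voxel", "point")) {
  mode <- match.arg(mode)
  if (b$n_fibers == 0L) return(NA_real_)
  pts <- do.call(rbind, b$streamlines)
  idx <- points_to_voxels(pts, b$geom)
  idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
  if (nrow(idx) == 0L) return(NA_real_)
  if (mode == "point") {
    return(mean(fa$fa[idx + 1L], na.rm = TRUE))
  }
  lin <- voxel_linear_index(idx, b$geom$dim)
  mean(fa$fa[unique(lin)], na.rm = TRUE)
}

#' Voxels visited by a bundle
#'
#' @param b a \code{bundle}.
#' @return matrix of unique 0-based voxel triplets visited by any member
#'   streamline.
#' @export
bundle_voxels <- function(b) {
  if (b$n_fibers == 0L) return(matrix(integer(), 0, 3))
  pts <- do.call(rbind, b$streamlines)
  idx <- points_to_voxels(pts, b$geom)
  idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
  unique(idx)
}

#' Read a detection-count table
#'
#' Table of per-connection subject counts: first column seed-region names,
#' remaining columns one per target region; \code{NA} where a connection
#' was never detected.
#'
#' @param path TSV path.
#' @return numeric matrix with seed rownames and target colnames.
#' @export
read_detection_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}

#' Build a detection matrix from per-subject bundle counts
#'
#' A subject counts as detected for a connection when the bundle passes the
#' fiber threshold at every wave recorded for that subject (a bundle usable
#' for longitudinal analysis).
#'
#' @param fibers long data.frame with columns \code{subject},
#'   \code{connection}, \code{n_fibers} (and optionally \code{wave}).
#' @param min_fibers recognition threshold per subject, default 20.
#' @return named integer vector: per connection, the number of subjects in
#'   whom the bundle passed the fiber threshold.
#' @export
detection_counts <- function(fibers, min_fibers = 20L) {
  pass <- bundle_passes_threshold(fibers$n_fibers, min_fibers)
  agg <- stats::aggregate(pass,
                          by = list(connection = fibers$connection,
                                    subject = fibers$subject),
                          FUN = all)
  tab <- tapply(agg$x, agg$connection, sum)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
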