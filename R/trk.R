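#' Write streamlines as a TrackVis .trk file
#'
#' Little-endian .trk (version 2) with the standard 1000-byte header:
#' dimensions, voxel sizes, voxel order "LPS"-agnostic raw voxel-mm points
#' (this pipeline's native coordinate convention), and the streamline
#' count. Round-trips bit-exact through [read_trk()] up to float32 point
#' precision (points are stored as float32 by the format).
#'
#' @param streamlines a \code{streamline_set} (or plain list of n x 3
#'   matrices with \code{geom} supplied).
#' @param path output path.
#' @param geom a [vol_geometry()]; defaults to the set's attribute.
#' @export
write_trk <- function(streamlines, path, geom = attr(streamlines, "geom")) {
  if (is.null(geom)) stop("geom required")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("TRACK"), raw(1)), con)     # id_string, zero padded
  writeBin(as.integer(geom$dim), con, size = 2, endian = "little")
  writeBin(as.numeric(geom$voxel_size), con, size = 4, endian = "little")
  writeBin(rep(0, 3), con, size = 4, endian = "little")      # origin
  writeBin(0L, con, size = 2, endian = "little")             # n_scalars
  writeBin(raw(200), con)                                    # scalar_name
  writeBin(0L, con, size = 2, endian = "little")             # n_properties
  writeBin(raw(200), con)                                    # property_name
  aff <- diag(4)
  aff[1, 1] <- geom$voxel_size[1]
  aff[2, 2] <- geom$voxel_size[2]
  aff[3, 3] <- geom$voxel_size[3]
  writeBin(as.numeric(t(aff)), con, size = 4, endian = "little")  # vox_to_ras
  writeBin(raw(444), con)                                    # reserved
  writeBin(c(charToRaw("RAS"), raw(1)), con)                 # voxel_order
  writeBin(raw(4), con)                                      # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4, endian = "little")  # img orient
  writeBin(raw(2), con)                                      # pad1
  writeBin(raw(6), con)                                      # invert/swap flags
  writeBin(length(streamlines), con, size = 4, endian = "little")  # n_count
  writeBin(2L, con, size = 4, endian = "little")             # version
  writeBin(1000L, con, size = 4, endian = "little")          # hdr_size
  for (s in streamlines) {
    writeBin(nrow(s), con, size = 4, endian = "little")
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a TrackVis .trk file
#'
#' @param path .trk path.
#' @return a \code{streamline_set} with \code{geom} reconstructed from the
#'   header (dimensions and voxel sizes).
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  id <- readBin(con, "raw", 6)
  if (!identical(rawToChar(id[1:5]), "TRACK"))
    stop("not a TrackVis .trk file")
  dm <- readBin(con, "integer", 3, size = 2, endian = "little")
  vox <- readBin(con, "numeric", 3, size = 4, endian = "little")
  invisible(readBin(con, "raw", 12))   # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  invisible(readBin(con, "raw", 200))
  invisible(readBin(con, "raw", 64))   # vox_to_ras
  invisible(readBin(con, "raw", 444))  # reserved
  invisible(readBin(con, "raw", 4))    # voxel_order
  invisible(readBin(con, "raw", 4))    # pad2
  invisible(readBin(con, "raw", 24))   # image_orientation_patient
  invisible(readBin(con, "raw", 2))    # pad1
  invisible(readBin(con, "raw", 6))    # invert/swap
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr != 1000L) stop("unexpected .trk header size")
  out <- vector("list", max(n_count, 0L))
  q <- 0L
  repeat {
    npts <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(npts) == 0L) break
    vals <- readBin(con, "numeric", npts * (3L + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0)
      invisible(readBin(con, "numeric", n_props, size = 4, endian = "little"))
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    q <- q + 1L
    out[[q]] <- m
  }
  out <- out[seq_len(q)]
  structure(out, class = "streamline_set",
            geom = vol_geometry(dm, vox), params = NULL)
}
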