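#' Read a DWI series from NIfTI + FSL bval/bvec files
#'
#' @param nifti_path path to a 4D NIfTI volume.
#' @param bval_path,bvec_path FSL-dialect gradient table: bvals as one
#'   whitespace-separated row, bvecs as three rows (x, y, z).
#' @return a \code{dwi_series}; the source NIfTI header is kept so that
#'   derived volumes can be written with the input affine preserved.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D DWI NIfTI volume")
  tab <- read_bval_bvec(bval_path, bvec_path)
  if (length(tab$bvalues) != dim(arr)[4])
    stop("gradient table length does not match 4th NIfTI dimension")
  vox <- RNifti::pixdim(img)[1:3]
  geom <- vol_geometry(dim(arr)[1:3], vox)
  structure(list(data = arr, geom = geom,
                 scheme = gradient_scheme(tab$bvalues, tab$directions),
                 template = img), class = "dwi_series")
}

#' Read an FSL-style gradient table
#' @param bval_path,bvec_path text files (whitespace-separated rows).
#' @return list with \code{bvalues} and n x 3 \code{directions}.
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) != 3L) stop("bvec file must have exactly 3 rows")
  if (ncol(bv) != length(bvals)) stop("bval/bvec length mismatch")
  list(bvalues = bvals, directions = t(bv))
}

#' Write an FSL-style gradient table
#' @param scheme a [gradient_scheme()].
#' @param bval_path,bvec_path output paths.
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bvalues, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$directions), 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(NULL)
}

#' Write a DWI series (NIfTI + bval/bvec)
#' @param dwi a \code{dwi_series}.
#' @param nifti_path,bval_path,bvec_path output paths.
#' @export
write_dwi <- function(dwi, nifti_path, bval_path, bvec_path) {
  write_volume(dwi$data, dwi$geom, nifti_path, template = dwi$template)
  write_bval_bvec(dwi$scheme, bval_path, bvec_path)
  invisible(nifti_path)
}

#' Write a scalar or vector volume as NIfTI
#'
#' When a template image (from [read_dwi()]) is available its header and
#' affine are reused bit-exact; otherwise a diagonal voxel-size affine is
#' constructed.
#'
#' @param arr 3D or 4D array.
#' @param geom a [vol_geometry()].
#' @param path output path (.nii or .nii.gz).
#' @param template optional RNifti image to inherit the header from.
#' @export
write_volume <- function(arr, geom, path, template = NULL) {
  if (!is.null(template)) {
    img <- RNifti::asNifti(arr, reference = template)
  } else {
    hdr <- RNifti::niftiHeader(RNifti::asNifti(arr))
    hdr$pixdim[2:4] <- geom$voxel_size
    img <- RNifti::asNifti(arr, reference = hdr)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an integer label volume as NIfTI
#' @param labels 3D integer array.
#' @param geom a [vol_geometry()].
#' @param path output path.
#' @param template optional RNifti image to inherit the header from.
#' @export
write_label_volume <- function(labels, geom, path, template = NULL) {
  storage.mode(labels) <- "integer"
  write_volume(labels, geom, path, template)
}

#' Read an integer label volume
#' @param path NIfTI path.
#' @return list with \code{labels} (integer 3D array) and \code{geom}.
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  storage.mode(arr) <- "integer"
  list(labels = arr, geom = vol_geometry(dim(arr)[1:3],
                                         RNifti::pixdim(img)[1:3]),
       template = img)
}

#' Read a label lookup table
#'
#' Two-column TSV mapping integer label ids to names (FreeSurfer-style).
#'
#' @param path TSV with columns \code{id} and \code{name}.
#' @return data.frame.
#' @export
read_label_lookup <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
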