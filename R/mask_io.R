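#' Read a binary structure mask
#'
#' Reads a NIfTI image (e.g. a model-based subcortical segmentation output in
#' standard space) and binarizes it: cells with stored intensity strictly
#' greater than `threshold` become 1, all others 0. Voxel dimensions are taken
#' from the image header; the orientation/affine matrix is otherwise ignored,
#' since the dimension estimator operates in stored voxel space and needs no
#' world coordinates.
#'
#' @param path path to a readable NIfTI file (`.nii` or `.nii.gz`).
#' @param threshold binarization threshold (default 0: any positive intensity
#'   is structure, the convention for boundary-corrected label images).
#' @param label structure name; defaults to the file name without extensions.
#' @return a [binary_lattice()]. An all-zero mask is returned with a warning;
#'   dimension estimation on it will fail with an empty-structure error.
#' @seealso [write_mask()], [lattice_volume()]
#' @export
read_mask <- function(path, threshold = 0, label = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("mask file not found: ", path, call. = FALSE)
  if (!is.numeric(threshold) || threshold < 0)
    stop("'threshold' must be a non-negative number", call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  a <- as.array(img)
  nd <- length(dim(a))
  if (nd > 3L) { # squeeze trailing singleton dims (4D files with one volume)
    dim(a) <- dim(a)[dim(a) > 1L]
    nd <- length(dim(a))
  }
  vox <- RNifti::pixdim(img)[seq_len(nd)]
  if (is.null(label))
    label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lat <- binary_lattice(array(as.integer(a > threshold), dim = dim(a)),
                        cell_size = vox, label = label)
  if (!any(lat == 1L))
    warning("mask '", label, "' is empty after thresholding", call. = FALSE)
  lat
}

#' Write a binary lattice as a NIfTI mask
#'
#' @param lat a [binary_lattice()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(lat, path) {
  stopifnot(is_binary_lattice(lat))
  img <- RNifti::asNifti(unclass(lat) + 0L)
  RNifti::pixdim(img) <- attr(lat, "cell_size")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Tabulate volumes for a set of masks
#'
#' @param lats a list of [binary_lattice()] objects.
#' @param subject_id optional subject identifiers (recycled).
#' @return a data.frame with columns subject_id, structure, voxels, mm3.
#' @export
volume_table <- function(lats, subject_id = NA_character_) {
  stopifnot(length(lats) > 0L)
  subject_id <- rep_len(subject_id, length(lats))
  rows <- lapply(seq_along(lats), function(i) {
    v <- lattice_volume(lats[[i]])
    data.frame(subject_id = subject_id[i],
               structure = attr(lats[[i]], "label"),
               voxels = v$voxels, mm3 = v$mm3,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
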