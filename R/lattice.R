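#' Binary lattice objects
#'
#' A `binary_lattice` is a rectangular 2D or 3D array of 0/1 cells together
#' with the physical edge length of a cell along each axis (in mm; use 1 for
#' abstract phantoms) and a free-text label. It is the "set" whose information
#' dimension is estimated: a structure formed by occupied voxels.
#'
#' @param cells a 2D or 3D array (or matrix) of values coercible to 0/1.
#'   Logical arrays and numeric arrays containing only 0 and 1 are accepted.
#' @param cell_size physical cell edge length per axis in mm; recycled to the
#'   number of axes. All entries must be positive.
#' @param label free-text structure name.
#'
#' @return an object of class `binary_lattice`: the integer 0/1 array with
#'   attributes `cell_size` and `label`.
#' @examples
#' m <- matrix(0L, 8, 8); m[3:5, 4] <- 1L
#' lat <- binary_lattice(m, cell_size = 1.5, label = "toy")
#' lattice_volume(lat)
#' @export
binary_lattice <- function(cells, cell_size = 1, label = "") {
  nd <- length(dim(cells))
  if (nd < 2L || nd > 3L)
    stop("'cells' must be a 2D or 3D array, got ", nd, " dimensions",
         call. = FALSE)
  if (is.logical(cells)) {
    storage.mode(cells) <- "integer"
  } else {
    v <- as.vector(cells)
    if (anyNA(v) || !all(v == 0 | v == 1))
      stop("'cells' must contain only 0 and 1 (use read_mask() to binarize)",
           call. = FALSE)
    storage.mode(cells) <- "integer"
  }
  cell_size <- rep_len(as.numeric(cell_size), nd)
  if (any(!is.finite(cell_size)) || any(cell_size <= 0))
    stop("'cell_size' entries must be positive and finite", call. = FALSE)
  structure(cells,
            cell_size = cell_size,
            label = as.character(label)[1L],
            class = "binary_lattice")
}

#' @rdname binary_lattice
#' @param x object to test or coerce.
#' @export
is_binary_lattice <- function(x) inherits(x, "binary_lattice")

#' @rdname binary_lattice
#' @param ... passed to [binary_lattice()].
#' @export
as_binary_lattice <- function(x, ...) {
  if (is_binary_lattice(x)) return(x)
  binary_lattice(x, ...)
}

#' @export
print.binary_lattice <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("binary_lattice '%s': %s cells (%s mm), %d occupied\n",
              attr(x, "label"), paste(d, collapse = "x"),
              paste(format(attr(x, "cell_size")), collapse = "x"),
              sum(x == 1L)))
  invisible(x)
}

# indices (1-based, n x d matrix) of occupied cells
occupied_indices <- function(lat) {
  which(lat == 1L, arr.ind = TRUE)
}

#' Volume of a binary lattice
#'
#' Counts occupied cells and converts to a physical volume (or area in 2D)
#' using the per-axis cell size, as computed upstream for segmentation masks
#' by voxel-count volumetry.
#'
#' @param lat a [binary_lattice()].
#' @return a list with `voxels` (integer count of 1-cells) and `mm3` (count
#'   times the product of the cell edge lengths; mm^2 for 2D lattices).
#' @examples
#' m <- array(0L, c(4, 4, 4)); m[1:10] <- 1L
#' lattice_volume(binary_lattice(m, cell_size = 1.5))  # 10 voxels, 33.75 mm3
#' @export
lattice_volume <- function(lat) {
  stopifnot(is_binary_lattice(lat))
  n <- sum(lat == 1L)
  list(voxels = as.integer(n), mm3 = n * prod(attr(lat, "cell_size")))
}

#' Tight bounding box of the occupied cells
#'
#' @param lat a [binary_lattice()] with at least one occupied cell.
#' @return an integer matrix with one row per axis and columns `min`, `max`
#'   (1-based cell indices).
#' @export
bounding_box <- function(lat) {
  stopifnot(is_binary_lattice(lat))
  idx <- occupied_indices(lat)
  if (nrow(idx) == 0L)
    stop("empty structure: lattice has no occupied cells", call. = FALSE)
  out <- cbind(min = apply(idx, 2L, min), max = apply(idx, 2L, max))
  rownames(out) <- c("x", "y", "z")[seq_len(nrow(out))]
  out
}

#' Pad a lattice with empty margins
#'
#' Embeds the lattice in a larger empty image. Because the counting grid is
#' anchored to the structure itself, padding (or translating) a structure
#' never changes its occupancy histograms; only the default box-size range,
#' which depends on the image extent, may change.
#'
#' @param lat a [binary_lattice()].
#' @param before,after number of empty cells to add on each side, per axis
#'   (recycled).
#' @return a padded [binary_lattice()].
#' @export
lattice_pad <- function(lat, before = 0L, after = 0L) {
  stopifnot(is_binary_lattice(lat))
  d <- dim(lat)
  nd <- length(d)
  before <- rep_len(as.integer(before), nd)
  after <- rep_len(as.integer(after), nd)
  out <- array(0L, dim = d + before + after)
  idx <- occupied_indices(lat)
  if (nrow(idx) > 0L)
    out[sweep(idx, 2L, before, "+")] <- 1L
  binary_lattice(out, cell_size = attr(lat, "cell_size"),
                 label = attr(lat, "label"))
}
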