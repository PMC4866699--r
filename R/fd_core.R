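#' Default box-size range for an image
#'
#' The smallest box is 2 cells; the largest defaults to 25% of the shortest
#' image side, capped at 30 cells. Unsuitably small or large boxes bias
#' dimension estimates, so the range is restricted before any fitting. For
#' small structures a tighter cap of 15% of the shortest side (`frac = 0.15`)
#' is adequate and cheaper; it is advisory, not enforced.
#'
#' @param lat a [binary_lattice()] (only its image dimensions are used).
#' @param frac largest box as a fraction of the shortest image side.
#' @param cap absolute cap on the largest box, in cells.
#' @return a list with integer `min_r`, `max_r` and `step` (always 1).
#' @examples
#' lat <- binary_lattice(array(1L, c(12, 12, 12)))
#' default_box_range(lat)  # 2..3
#' @export
default_box_range <- function(lat, frac = 0.25, cap = 30L) {
  d <- dim(lat)
  max_r <- min(as.integer(cap), floor(frac * min(d)))
  if (max_r <= 2L)
    stop("image too small for box counting: largest box size would be ",
         max_r, " cells", call. = FALSE)
  list(min_r = 2L, max_r = as.integer(max_r), step = 1L)
}

#' Box-occupancy histogram at one box size
#'
#' Partitions space into cubes (squares in 2D) of side `r` cells, anchored at
#' the minimal corner of the structure's bounding box, with half-open
#' intervals so every occupied cell falls in exactly one box; partial boxes at
#' the far edge are included. Returns the occupancy counts of the boxes that
#' contain part of the structure.
#'
#' Anchoring the grid to the structure (rather than the image edge) makes the
#' histogram — and everything derived from it — invariant under translation
#' of the structure and under padding of the image.
#'
#' @param lat a [binary_lattice()] with at least one occupied cell.
#' @param r box side length in cells (>= 1).
#' @param offset non-negative integer grid shift (cells, recycled per axis);
#'   the grid anchor is moved back by `offset` relative to the bounding-box
#'   corner. 0 is the canonical anchored grid.
#' @return an object of class `occupancy_histogram`: a list with `r`,
#'   `counts` (positive integers, one per occupied box) and `total` (number
#'   of occupied cells). `sum(counts) == total` always.
#' @examples
#' m <- array(0L, c(4, 4, 4))
#' m[c(1, 4), 1, 1] <- 1L; m[c(1, 4), 4, 1] <- 1L
#' m[c(1, 4), 1, 4] <- 1L; m[c(1, 4), 4, 4] <- 1L
#' occupancy(binary_lattice(m), 2)  # 8 corner cells -> 8 boxes of count 1
#' @export
occupancy <- function(lat, r, offset = 0L) {
  stopifnot(is_binary_lattice(lat))
  r <- as.integer(r)
  if (r < 1L) stop("box size 'r' must be >= 1 cell", call. = FALSE)
  idx <- occupied_indices(lat)
  if (nrow(idx) == 0L)
    stop("empty structure: lattice has no occupied cells", call. = FALSE)
  anchor <- apply(idx, 2L, min)
  off <- rep_len(as.integer(offset), ncol(idx))
  if (any(off < 0L) || any(off >= r))
    stop("'offset' must lie in [0, r)", call. = FALSE)
  counts <- box_counts(sweep(idx, 2L, anchor - off), r)
  structure(list(r = r, counts = counts, total = nrow(idx)),
            class = "occupancy_histogram")
}

# core counting kernel: idx is a matrix of non-negative 0-based cell offsets;
# boxes are [k*r, (k+1)*r) per axis; returns counts of non-empty boxes
box_counts <- function(idx, r) {
  b <- idx %/% r
  dims <- apply(b, 2L, max) + 1L
  key <- b[, 1L]
  if (ncol(b) >= 2L) key <- key + dims[1L] * b[, 2L]
  if (ncol(b) == 3L) key <- key + dims[1L] * dims[2L] * b[, 3L]
  cnt <- tabulate(key + 1L, nbins = prod(dims))
  cnt[cnt > 0L]
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("occupancy at r = %d: %d boxes, %d cells (max count %d)\n",
              x$r, length(x$counts), x$total, max(x$counts)))
  invisible(x)
}

#' Shannon entropy of a box-occupancy histogram
#'
#' Computes `I(r) = -sum(p_i * log(p_i))` with `p_i = N_i / N_all`, using the
#' natural logarithm. Empty boxes never contribute (the `0 * log 0 = 0`
#' convention). The entropy is 0 exactly when a single box contains the whole
#' structure, and is bounded above by the log of the number of occupied boxes.
#'
#' @param hist an `occupancy_histogram` from [occupancy()], or a bare vector
#'   of positive box counts.
#' @return the entropy in nats.
#' @examples
#' box_entropy(c(5, 5))  # log(2)
#' @export
box_entropy <- function(hist) {
  counts <- if (inherits(hist, "occupancy_histogram")) hist$counts else hist
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no occupied boxes", call. = FALSE)
  n <- sum(counts)
  log(n) - sum(counts * log(counts)) / n
}

#' Entropy curve over a box-size range
#'
#' Evaluates the box-occupancy entropy `I(r)` for every box size in the range,
#' from the smallest upward in 1-cell increments. The scaling behaviour
#' `I(r) ~ D1 * log(1/r) + c` over the linear regime of this curve defines
#' the information dimension.
#'
#' @param lat a [binary_lattice()].
#' @param box_range a list as returned by [default_box_range()] (the default),
#'   or `NULL` to use the default for this image.
#' @param n_offsets number of grid placements per box size. 1 (default) uses
#'   the canonical structure-anchored grid; larger values average `I(r)` over
#'   `n_offsets` diagonal grid shifts in `[0, r)`, a variance-reduction option
#'   that smooths grid-quantization artifacts on very small objects. All
#'   placements remain anchored relative to the structure, so translation
#'   invariance is preserved.
#' @return a data.frame of class `entropy_curve` with columns `r`, `I` and
#'   `log_inv_r = log(1/r)`, and attribute `n_all` (occupied-cell count).
#' @export
entropy_curve <- function(lat, box_range = NULL, n_offsets = 1L) {
  stopifnot(is_binary_lattice(lat))
  if (is.null(box_range)) box_range <- default_box_range(lat)
  rs <- seq.int(box_range$min_r, box_range$max_r, by = box_range$step)
  idx <- occupied_indices(lat)
  if (nrow(idx) == 0L)
    stop("empty structure: lattice has no occupied cells", call. = FALSE)
  idx <- sweep(idx, 2L, apply(idx, 2L, min))
  n <- nrow(idx)
  nd <- ncol(idx)
  I <- vapply(rs, function(r) {
    offs <- if (n_offsets > 1L)
      unique(floor(seq(0, r - 1L, length.out = n_offsets)))
    else 0L
    mean(vapply(offs, function(o) {
      cnt <- box_counts(sweep(idx, 2L, rep.int(as.integer(o), nd), "+"), r)
      log(n) - sum(cnt * log(cnt)) / n
    }, numeric(1L)))
  }, numeric(1L))
  structure(data.frame(r = rs, I = I, log_inv_r = log(1 / rs)),
            n_all = n,
            class = c("entropy_curve", "data.frame"))
}

#' Fit the information dimension to an entropy curve
#'
#' Ordinary least squares of `I(r)` on `log(1/r)` over a contiguous sub-range
#' of box sizes. Entropy estimates at large box sizes oscillate rather than
#' scale, so the fit is chosen over candidate sub-ranges: the lower end may be
#' raised by at most `bottom_trim` points and the upper end trimmed freely,
#' keeping at least `min_points` points. Among candidates the fit with the
#' largest R-squared wins; candidates whose R-squared is within `tie_tol` of
#' the best are treated as equivalent, and the one retaining the most points
#' (then the smaller largest box) is preferred, so that the final line
#' includes as much of the scaling regime as the data allow.
#'
#' Setting `bottom_trim = Inf` and `tie_tol = 0` gives the strict exhaustive
#' search over all contiguous sub-ranges, maximizing R-squared alone.
#'
#' Points with `I(r) = 0` (a single box covers the structure, so the box size
#' carries no scaling information) are excluded from candidate windows.
#'
#' @param curve an `entropy_curve` (or any data.frame with columns `r`, `I`).
#' @param min_points minimum points retained in the fit (>= 3).
#' @param bottom_trim maximum number of points the lower end may be raised by.
#' @param tie_tol R-squared tolerance within which candidate fits are treated
#'   as equivalent.
#' @return an object of class `fd_fit`: a list with `d1` (the slope),
#'   `intercept`, `r_squared`, `retained_range` (smallest and largest retained
#'   box size), `breakpoint` (largest retained box size, or `NA` when nothing
#'   was trimmed from the top), `n_points_used`, and the annotated `curve`
#'   (with a logical `used` column).
#' @examples
#' ## exact power law: I = 2.5 * log(1/r) + 10
#' cv <- data.frame(r = 2:30, I = 10 + 2.5 * log(1 / (2:30)))
#' fit_information_dimension(cv)$d1  # 2.5, R^2 = 1, nothing excluded
#' @export
fit_information_dimension <- function(curve, min_points = 5L,
                                      bottom_trim = 2L, tie_tol = 1e-3) {
  stopifnot(is.data.frame(curve), all(c("r", "I") %in% names(curve)))
  if (min_points < 3L) stop("'min_points' must be >= 3", call. = FALSE)
  ok <- is.finite(curve$I) & curve$I > 0
  fitable <- curve[ok, , drop = FALSE]
  n <- nrow(fitable)
  if (n < min_points)
    stop("only ", n, " informative points (positive entropy); need at least ",
         min_points, call. = FALSE)
  if (length(unique(fitable$r)) < 2L)
    stop("zero variance in box size: cannot fit a slope", call. = FALSE)
  x <- log(1 / fitable$r)
  y <- fitable$I
  i_max <- min(bottom_trim + 1L, n - min_points + 1L)
  cand <- vector("list", i_max * n)
  k <- 0L
  for (i in seq_len(i_max)) {
    for (j in seq.int(i + min_points - 1L, n)) {
      st <- window_ols(x, y, i, j)
      if (is.null(st)) next
      k <- k + 1L
      cand[[k]] <- c(i = i, j = j, slope = st$slope, intercept = st$intercept,
                     r2 = st$r2, np = j - i + 1L)
    }
  }
  cand <- do.call(rbind, cand[seq_len(k)])
  if (is.null(cand))
    stop("no admissible fitting window (entropy curve degenerate)",
         call. = FALSE)
  best_r2 <- max(cand[, "r2"])
  tied <- cand[cand[, "r2"] >= best_r2 - tie_tol, , drop = FALSE]
  pick <- tied[order(-tied[, "np"], tied[, "j"])[1L], ]
  i <- pick[["i"]]; j <- pick[["j"]]
  used_r <- fitable$r[i:j]
  curve$used <- curve$r %in% used_r
  structure(list(
    d1 = pick[["slope"]],
    intercept = pick[["intercept"]],
    r_squared = pick[["r2"]],
    retained_range = c(min_r = min(used_r), max_r = max(used_r)),
    breakpoint = if (max(used_r) < max(fitable$r)) max(used_r) else NA_integer_,
    n_points_used = as.integer(pick[["np"]]),
    min_points = as.integer(min_points),
    bottom_trim = bottom_trim,
    tie_tol = tie_tol,
    curve = curve
  ), class = "fd_fit")
}

# OLS on x[i:j], y[i:j]; returns NULL for zero y-variance windows
window_ols <- function(x, y, i, j) {
  xi <- x[i:j]; yi <- y[i:j]
  my <- mean(yi)
  syy <- sum((yi - my)^2)
  if (syy < 1e-300) return(NULL)
  mx <- mean(xi)
  sxx <- sum((xi - mx)^2)
  sxy <- sum((xi - mx) * (yi - my))
  slope <- sxy / sxx
  list(slope = slope,
       intercept = my - slope * mx,
       r2 = (sxy * sxy) / (sxx * syy))
}

#' Information dimension of a binary structure
#'
#' The main estimator: composes the default box-size range, the entropy curve
#' and the breakpoint fit, and attaches voxel-count volumetry. The information
#' dimension D1 is the slope of the Shannon box-occupancy entropy `I(r)`
#' against `log(1/r)` over the linear scaling regime; for solid 3D structures
#' it typically lies between 2 and 3, and for plane curves between 1 and 2.
#'
#' A single-cell structure has no scale dependence at all; it is returned with
#' `d1 = 0` and a warning rather than an error.
#'
#' @param x a [binary_lattice()], a plain 0/1 array, or a path to a NIfTI
#'   mask file.
#' @param box_range box-size range (see [default_box_range()]); `NULL` for the
#'   image default.
#' @param min_points,bottom_trim,tie_tol fitting controls passed to
#'   [fit_information_dimension()].
#' @param n_offsets grid placements per box size (see [entropy_curve()]).
#' @param ... passed between methods.
#' @return an object of class `fd_d1` (which extends `fd_fit`) with the fit
#'   fields plus `label`, `voxel_count`, `volume_mm3` and the entropy curve.
#'   Methods: `print`, `summary`, `coef`, `plot`, `residuals`, `predict`.
#' @examples
#' fit <- fd_d1(phantom_circle(8))
#' coef(fit)
#' @export
fd_d1 <- function(x, ...) UseMethod("fd_d1")

#' @rdname fd_d1
#' @export
fd_d1.binary_lattice <- function(x, box_range = NULL, min_points = 5L,
                                 bottom_trim = 2L, tie_tol = 1e-3,
                                 n_offsets = 1L, ...) {
  vol <- lattice_volume(x)
  if (vol$voxels == 0L)
    stop("empty structure: lattice has no occupied cells", call. = FALSE)
  if (vol$voxels == 1L) {
    warning("single-cell structure: returning d1 = 0", call. = FALSE)
    out <- list(d1 = 0, intercept = NA_real_, r_squared = NA_real_,
                retained_range = c(min_r = NA_integer_, max_r = NA_integer_),
                breakpoint = NA_integer_, n_points_used = 0L,
                curve = NULL, label = attr(x, "label"),
                voxel_count = 1L, volume_mm3 = vol$mm3)
    class(out) <- c("fd_d1", "fd_fit")
    return(out)
  }
  cv <- entropy_curve(x, box_range = box_range, n_offsets = n_offsets)
  fit <- fit_information_dimension(cv, min_points = min_points,
                                   bottom_trim = bottom_trim,
                                   tie_tol = tie_tol)
  fit$label <- attr(x, "label")
  fit$voxel_count <- vol$voxels
  fit$volume_mm3 <- vol$mm3
  class(fit) <- c("fd_d1", "fd_fit")
  fit
}

#' @rdname fd_d1
#' @param cell_size,label passed to [binary_lattice()] for array input.
#' @export
fd_d1.array <- function(x, cell_size = 1, label = "", ...) {
  fd_d1(binary_lattice(x, cell_size = cell_size, label = label), ...)
}

#' @rdname fd_d1
#' @param threshold binarization threshold for file input (see [read_mask()]).
#' @export
fd_d1.character <- function(x, threshold = 0, ...) {
  fd_d1(read_mask(x, threshold = threshold), ...)
}

#' @export
print.fd_fit <- function(x, digits = 4L, ...) {
  if (!is.null(x$label) && nzchar(x$label))
    cat("structure:", x$label, "\n")
  cat(sprintf("information dimension D1 = %.*f  (R^2 = %.*f)\n",
              digits, x$d1, digits, x$r_squared))
  if (!any(is.na(x$retained_range)))
    cat(sprintf("retained box range: %d-%d cells (%d points%s)\n",
                x$retained_range[["min_r"]], x$retained_range[["max_r"]],
                x$n_points_used,
                if (!is.na(x$breakpoint))
                  sprintf(", breakpoint at r = %d", x$breakpoint) else ""))
  if (!is.null(x$voxel_count))
    cat(sprintf("structure size: %d voxels, %.2f mm^3\n",
                x$voxel_count, x$volume_mm3))
  invisible(x)
}

#' @export
summary.fd_fit <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$curve)) {
    cat("\nentropy curve:\n")
    print(object$curve, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.fd_fit <- function(object, ...) {
  c(d1 = object$d1, intercept = object$intercept)
}

#' @export
predict.fd_fit <- function(object, r = NULL, ...) {
  if (is.null(r)) r <- object$curve$r[object$curve$used]
  object$intercept + object$d1 * log(1 / r)
}

#' @export
residuals.fd_fit <- function(object, ...) {
  used <- object$curve[object$curve$used, , drop = FALSE]
  used$I - predict(object, used$r)
}

#' @export
fitted.fd_fit <- function(object, ...) {
  predict(object)
}

#' @export
plot.fd_fit <- function(x, ...) {
  cv <- x$curve
  if (is.null(cv)) stop("degenerate fit has no curve to plot", call. = FALSE)
  graphics::plot(cv$log_inv_r, cv$I, xlab = "ln(1/r)", ylab = "I(r)  [nats]",
                 main = if (nzchar(x$label %||% "")) x$label else "entropy scaling",
                 pch = ifelse(cv$used, 19, 1), ...)
  graphics::abline(a = x$intercept, b = x$d1, lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c(sprintf("D1 = %.4f", x$d1),
                              sprintf("R^2 = %.4f", x$r_squared),
                              sprintf("r = %d..%d", x$retained_range[1L],
                                      x$retained_range[2L])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
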