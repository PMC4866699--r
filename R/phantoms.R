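#' Validation phantoms of known dimension
#'
#' Generators for synthetic binary objects used to validate the information
#' dimension estimator: a rasterized circle outline (theoretical dimension 1),
#' the Koch curve (log 4 / log 3), 3D random Cantor sets (3 + log2(p)),
#' voxelized solid spheres and cubes (3), and roughened solid ellipsoids.
#' All stochastic generators are deterministic given their seed.
#'
#' @name phantoms
#' @seealso [fd_d1()], [koch_dimension()], [cantor_dimension()]
NULL

#' Rasterized circle outline
#'
#' A closed, 1-cell-wide circle outline centered in the image: a cell is set
#' when its center lies within half a cell of the ideal circle of the given
#' radius. The raster is 4-fold symmetric under 90-degree rotation of the
#' image.
#'
#' @param radius circle radius in cells.
#' @param image_size image extent, `c(nx, ny)`.
#' @return a [binary_lattice()] with unit cell size.
#' @export
phantom_circle <- function(radius = 8, image_size = c(120L, 120L)) {
  nx <- image_size[1L]; ny <- image_size[2L]
  if (2 * (radius + 0.5) > min(nx, ny))
    stop("radius ", radius, " does not fit in a ", nx, "x", ny, " image",
         call. = FALSE)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  d <- sqrt(outer(((1:nx) - cx)^2, ((1:ny) - cy)^2, "+"))
  binary_lattice(array(as.integer(d >= radius - 0.5 & d < radius + 0.5),
                       dim = c(nx, ny)),
                 label = sprintf("circle_r%g", radius))
}

#' Koch curve vertices
#'
#' Vertex list of the standard Koch curve on the unit baseline: at each
#' iteration every segment is replaced by 4 segments at scale 1/3 with an
#' outward equilateral peak. After `n` iterations there are `4^n + 1`
#' vertices; the curve spans width 1 and height `sqrt(3)/6`.
#'
#' @param iterations number of replacement iterations (>= 0).
#' @return a two-column matrix of (x, y) vertices.
#' @export
koch_vertices <- function(iterations) {
  stopifnot(iterations >= 0)
  v <- matrix(c(0, 0, 1, 0), ncol = 2L, byrow = TRUE)
  for (k in seq_len(iterations)) {
    ns <- nrow(v) - 1L
    out <- matrix(0, nrow = ns * 4L + 1L, ncol = 2L)
    for (s in seq_len(ns)) {
      a <- v[s, ]; b <- v[s + 1L, ]
      d <- (b - a) / 3
      p1 <- a + d
      p3 <- a + 2 * d
      peak <- p1 + c(d[1L] * 0.5 - d[2L] * sqrt(3) / 2,
                     d[1L] * sqrt(3) / 2 + d[2L] * 0.5)
      out[(4L * s - 3L):(4L * s), ] <- rbind(a, p1, peak, p3)
    }
    out[nrow(out), ] <- v[nrow(v), ]
    v <- out
  }
  v
}

# mark cells along a segment (dense sampling + rounding; 1-cell-wide line)
raster_segment <- function(mat, x0, y0, x1, y1) {
  steps <- max(ceiling(2 * max(abs(x1 - x0), abs(y1 - y0))), 1L)
  t <- seq(0, 1, length.out = steps + 1L)
  xi <- pmin(pmax(round(x0 + t * (x1 - x0)), 1L), nrow(mat))
  yi <- pmin(pmax(round(y0 + t * (y1 - y0)), 1L), ncol(mat))
  mat[cbind(xi, yi)] <- 1L
  mat
}

#' Rasterized Koch curve
#'
#' Scales the Koch curve to the image width and rasterizes each segment as a
#' 1-cell-wide line. With iteration count 0 this is a straight horizontal
#' line spanning the image width. If the smallest segment falls below one
#' cell a warning is issued and rasterization proceeds.
#'
#' @param iterations number of Koch iterations (>= 0).
#' @param image_size image extent, `c(nx, ny)`; the curve height is
#'   `width * sqrt(3) / 6`, so `ny` should be at least ~0.29 `nx`.
#' @return a [binary_lattice()] with unit cell size.
#' @export
phantom_koch <- function(iterations = 4, image_size = c(283L, 84L)) {
  nx <- image_size[1L]; ny <- image_size[2L]
  if ((nx - 1) / 3^iterations < 1)
    warning("smallest Koch segment is below one cell at this image size",
            call. = FALSE)
  v <- koch_vertices(iterations)
  vx <- 1 + v[, 1L] * (nx - 1)
  vy <- 1 + v[, 2L] * (nx - 1)
  if (max(vy) > ny)
    warning("image height ", ny, " clips the Koch curve (needs ",
            ceiling(max(vy)), ")", call. = FALSE)
  mat <- matrix(0L, nx, ny)
  for (s in seq_len(nrow(v) - 1L))
    mat <- raster_segment(mat, vx[s], vy[s], vx[s + 1L], vy[s + 1L])
  binary_lattice(mat, label = sprintf("koch_n%d", iterations))
}

#' 3D random Cantor set
#'
#' Top-down octree construction: starting from one full cube of side
#' `2^levels`, each surviving cube is split into 2x2x2 subcubes and each
#' subcube survives independently with probability `survival_p`. After
#' `levels` steps the surviving unit cells are set. The theoretical dimension
#' of the construction is `3 + log2(survival_p)` (see [cantor_dimension()]);
#' the expected cell count is `(8 * survival_p)^levels`.
#'
#' @param levels number of subdivision levels; the lattice side is `2^levels`.
#' @param survival_p per-subcube survival probability in (0, 1].
#' @param seed integer seed; the construction is deterministic given the seed.
#' @return a [binary_lattice()] of side `2^levels` with unit cell size.
#' @export
phantom_cantor3d <- function(levels = 7L, survival_p = 0.7, seed = 1L) {
  stopifnot(levels >= 1L)
  if (survival_p <= 0 || survival_p > 1)
    stop("'survival_p' must be in (0, 1]", call. = FALSE)
  side <- 2L^levels
  set.seed(seed)
  corner_off <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  orig <- matrix(0L, 1L, 3L)
  size <- side
  for (l in seq_len(levels)) {
    size <- size %/% 2L
    n <- nrow(orig)
    child <- orig[rep(seq_len(n), each = 8L), , drop = FALSE] +
      corner_off[rep(1:8, n), , drop = FALSE] * size
    orig <- child[stats::runif(nrow(child)) < survival_p, , drop = FALSE]
    if (nrow(orig) == 0L) break
  }
  arr <- array(0L, dim = rep(side, 3L))
  if (nrow(orig) > 0L) arr[orig + 1L] <- 1L
  binary_lattice(arr, label = sprintf("cantor3d_p%g_seed%d", survival_p, seed))
}

#' Voxelized solid sphere
#'
#' A solid ball: a cell is set iff its center lies within `diameter_mm / 2`
#' of the image center. The image side is twice the diameter in cells, so a
#' 60 mm sphere at 1.5 mm cells sits in an 80x80x80 image.
#'
#' @param diameter_mm sphere diameter in mm.
#' @param cell_mm cubic cell edge in mm.
#' @return a [binary_lattice()] with `cell_size = cell_mm`.
#' @export
phantom_sphere <- function(diameter_mm = 60, cell_mm = 1.5) {
  if (diameter_mm <= cell_mm)
    stop("'diameter_mm' must exceed 'cell_mm'", call. = FALSE)
  side <- as.integer(round(2 * diameter_mm / cell_mm))
  ctr <- side * cell_mm / 2
  x2 <- (((1:side) - 0.5) * cell_mm - ctr)^2
  d2 <- outer(outer(x2, x2, "+"), x2, "+")
  binary_lattice(array(as.integer(d2 <= (diameter_mm / 2)^2),
                       dim = rep(side, 3L)),
                 cell_size = cell_mm,
                 label = sprintf("sphere_d%gmm", diameter_mm))
}

#' Voxelized solid cube
#'
#' @param side_mm cube edge in mm.
#' @param cell_mm cubic cell edge in mm.
#' @param image_cells image side in cells; defaults to twice the cube side.
#' @return a [binary_lattice()].
#' @export
phantom_cube <- function(side_mm = 60, cell_mm = 1.5, image_cells = NULL) {
  k <- as.integer(round(side_mm / cell_mm))
  if (is.null(image_cells)) image_cells <- 2L * k
  if (image_cells < k) stop("cube does not fit in the image", call. = FALSE)
  arr <- array(0L, dim = rep(as.integer(image_cells), 3L))
  lo <- (image_cells - k) %/% 2L + 1L
  arr[lo:(lo + k - 1L), lo:(lo + k - 1L), lo:(lo + k - 1L)] <- 1L
  binary_lattice(arr, cell_size = cell_mm,
                 label = sprintf("cube_%gmm", side_mm))
}

#' Sliced cube (equal volume, altered structure)
#'
#' Cuts a solid cube into `n_slices` lateral slabs separated by one-cell
#' gaps, shifting alternate slabs by one cell. Total occupied volume is
#' preserved up to the removed gap planes while the surface structure — and
#' hence the estimated dimension — changes, demonstrating that volume and
#' complexity are dissociable.
#'
#' @param side_mm cube edge in mm.
#' @param n_slices number of lateral slices (>= 2).
#' @param cell_mm cubic cell edge in mm.
#' @return a [binary_lattice()].
#' @export
phantom_sliced_cube <- function(side_mm = 60, n_slices = 10L, cell_mm = 1.5) {
  stopifnot(n_slices >= 2L)
  k <- as.integer(round(side_mm / cell_mm))
  img <- as.integer(2L * k)
  arr <- array(0L, dim = rep(img, 3L))
  lo <- (img - k) %/% 2L + 1L
  rng <- lo:(lo + k - 1L)
  cut_at <- unique(round(seq(1, k, length.out = n_slices + 1L)))[-c(1L, n_slices + 1L)]
  slab_id <- findInterval(seq_len(k), cut_at + 1L)  # 0-based slab index
  keep <- !(seq_len(k) %in% cut_at)                  # one-cell gaps
  for (i in seq_len(k)) {
    if (!keep[i]) next
    shift <- slab_id[i] %% 2L
    arr[rng + shift, rng, lo + i - 1L] <- 1L
  }
  binary_lattice(arr, cell_size = cell_mm,
                 label = sprintf("sliced_cube_%gmm_%d", side_mm, n_slices))
}

#' Roughened solid ellipsoid
#'
#' A solid ellipsoid whose radius is modulated by a smooth random angular
#' bump field: `bump_count` unit directions are drawn, each contributing a
#' spherical Gaussian lobe, and the summed field is scaled so its maximum
#' equals `bump_amplitude` (mm) and added to the ellipsoid radius. Amplitude
#' 0 reproduces the smooth ellipsoid exactly for any seed. A stand-in for
#' millimeter-level surface protrusions on subcortical structures.
#'
#' @param semi_axes_mm ellipsoid semi-axes in mm (length 3).
#' @param bump_amplitude maximum radial protrusion in mm (>= 0).
#' @param bump_count number of bump centers.
#' @param cell_mm cubic cell edge in mm.
#' @param seed integer seed for the bump directions.
#' @param bump_width angular width (SD, radians) of each bump lobe.
#' @param image_cells image side in cells; default 64 leaves room for the
#'   default box-size range.
#' @return a [binary_lattice()].
#' @export
phantom_bumpy_ellipsoid <- function(semi_axes_mm = c(20, 10, 8),
                                    bump_amplitude = 0, bump_count = 40L,
                                    cell_mm = 1.5, seed = 1L,
                                    bump_width = 0.25, image_cells = 64L) {
  stopifnot(length(semi_axes_mm) == 3L, bump_amplitude >= 0)
  if (any(semi_axes_mm < 3 * cell_mm))
    stop("semi-axes must be at least 3 cells", call. = FALSE)
  n <- as.integer(image_cells)
  if (2 * (max(semi_axes_mm) + bump_amplitude) >= n * cell_mm)
    stop("ellipsoid does not fit in the image", call. = FALSE)
  set.seed(seed)
  u <- matrix(stats::rnorm(3L * bump_count), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  ctr <- (n + 1) / 2
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  x <- sweep(g, 2L, rep(ctr, 3L)) * cell_mm
  rr <- sqrt(rowSums(x^2))
  rr[rr == 0] <- 1e-9
  d <- x / rr
  radius <- 1 / sqrt(rowSums(sweep(d, 2L, semi_axes_mm, "/")^2))
  if (bump_amplitude > 0) {
    f <- numeric(nrow(d))
    for (k in seq_len(bump_count)) {
      ang <- acos(pmin(pmax(d %*% u[k, ], -1), 1))
      f <- f + exp(-ang^2 / (2 * bump_width^2))
    }
    radius <- radius + bump_amplitude * f / max(f)
  }
  arr <- array(0L, dim = rep(n, 3L))
  arr[g[rr <= radius, , drop = FALSE]] <- 1L
  binary_lattice(arr, cell_size = cell_mm,
                 label = sprintf("bumpy_ellipsoid_a%g_seed%d",
                                 bump_amplitude, seed))
}

#' Closed-form similarity dimension of the Koch curve
#'
#' The Koch construction replaces each segment by 4 copies at scale 1/3, so
#' its similarity dimension is `log(4) / log(3)`.
#'
#' @return `log(4) / log(3)` (~1.2619).
#' @export
koch_dimension <- function() log(4) / log(3)

#' Theoretical dimension of a random Cantor set
#'
#' A `d`-dimensional random Cantor set built by halving each axis and keeping
#' subcubes with probability `p` has dimension `d + log2(p)` (almost surely,
#' conditional on non-extinction).
#'
#' @param survival_p survival probability in (0, 1].
#' @param d embedding dimension (default 3).
#' @return `d + log(survival_p) / log(2)`.
#' @export
cantor_dimension <- function(survival_p, d = 3) {
  if (any(survival_p <= 0 | survival_p > 1))
    stop("'survival_p' must be in (0, 1]", call. = FALSE)
  d + log(survival_p) / log(2)
}

#' Synthetic two-group FD cohort
#'
#' Simulates per-subject fractal-dimension values for a patient (SCZ) and a
#' control (HC) group, with an optional group effect and group-by-age
#' interaction:
#' `fd = baseline - effect * [SCZ] - interaction_slope * age * [SCZ] + noise`.
#' Ages are uniform on `age_range`, sexes are assigned with probability
#' `male_prop`, and structure volumes are generated positively correlated
#' with fd. One row per subject and structure.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param effect group effect on fd (positive values lower the SCZ group).
#' @param interaction_slope additional fd change per year of age in the SCZ
#'   group.
#' @param noise_sd SD of the Gaussian fd noise (> 0).
#' @param seed integer seed.
#' @param structures character vector of structure names.
#' @param baseline fd level of the control group.
#' @param age_range uniform age range in years.
#' @param male_prop probability of male sex.
#' @return a data.frame with columns subject_id, group, age, sex, structure,
#'   fd, volume_mm3.
#' @export
simulate_cohort <- function(n_per_group = 19L, effect = 0,
                            interaction_slope = 0, noise_sd = 0.015,
                            seed = 1L, structures = "Left.Hippocampus",
                            baseline = 2.17, age_range = c(23, 54),
                            male_prop = 0.79) {
  stopifnot(n_per_group >= 3L, noise_sd > 0)
  set.seed(seed)
  n <- 2L * n_per_group
  subj <- sprintf("S%03d", seq_len(n))
  group <- rep(c("SCZ", "HC"), each = n_per_group)
  age <- stats::runif(n, age_range[1L], age_range[2L])
  sex <- ifelse(stats::runif(n) < male_prop, "M", "F")
  rows <- lapply(structures, function(st) {
    is_scz <- as.numeric(group == "SCZ")
    fd <- baseline - effect * is_scz - interaction_slope * age * is_scz +
      stats::rnorm(n, 0, noise_sd)
    volume <- 3200 + 25000 * (fd - baseline) + stats::rnorm(n, 0, 120)
    data.frame(subject_id = subj, group = group, age = age, sex = sex,
               structure = st, fd = fd, volume_mm3 = volume,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
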