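# Independent oracles and fixture generators used across the suite.
# These deliberately use naive loops / enumeration, not the package kernels.

# random sparse binary lattice (array), density in (0,1)
random_lattice <- function(dims, density = 0.1, seed = 1) {
  set.seed(seed)
  arr <- array(0L, dim = dims)
  arr[runif(prod(dims)) < density] <- 1L
  if (!any(arr == 1L)) arr[1L] <- 1L
  arr
}

# brute-force occupancy: loop over every box of the structure-anchored grid
# and count occupied cells inside it by scanning all cells
oracle_box_counts <- function(arr, r) {
  idx <- which(arr == 1L, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  nb <- ceiling((hi - lo + 1) / r)
  counts <- integer(0)
  if (length(dim(arr)) == 3) {
    for (bx in seq_len(nb[1])) for (by in seq_len(nb[2])) for (bz in seq_len(nb[3])) {
      x0 <- lo[1] + (bx - 1) * r; y0 <- lo[2] + (by - 1) * r; z0 <- lo[3] + (bz - 1) * r
      n <- sum(idx[, 1] >= x0 & idx[, 1] < x0 + r &
               idx[, 2] >= y0 & idx[, 2] < y0 + r &
               idx[, 3] >= z0 & idx[, 3] < z0 + r)
      if (n > 0) counts <- c(counts, n)
    }
  } else {
    for (bx in seq_len(nb[1])) for (by in seq_len(nb[2])) {
      x0 <- lo[1] + (bx - 1) * r; y0 <- lo[2] + (by - 1) * r
      n <- sum(idx[, 1] >= x0 & idx[, 1] < x0 + r &
               idx[, 2] >= y0 & idx[, 2] < y0 + r)
      if (n > 0) counts <- c(counts, n)
    }
  }
  counts
}

# brute-force best window: all contiguous sub-ranges, strict max R^2,
# ties by more points then smaller max r (mirrors the documented tie-break)
oracle_best_window <- function(r, I, min_points) {
  keep <- I > 0
  r <- r[keep]; I <- I[keep]
  x <- log(1 / r)
  n <- length(x)
  best <- NULL
  for (i in 1:(n - min_points + 1)) for (j in (i + min_points - 1):n) {
    xi <- x[i:j]; yi <- I[i:j]
    if (var(yi) == 0) next
    f <- lm(yi ~ xi)
    r2 <- summary(f)$r.squared
    cand <- list(slope = unname(coef(f)[2]), r2 = r2,
                 lo = r[i], hi = r[j], np = j - i + 1)
    if (is.null(best) || r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 &&
         (cand$np > best$np || (cand$np == best$np && cand$hi < best$hi))))
      best <- cand
  }
  best
}

# exact two-tailed Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(first_idx) {
    x <- pooled[first_idx]; y <- pooled[-first_idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(combn(n1 + n2, n1), 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(all_u - mu) >= abs(u_obs - mu) - 1e-9)
}

# mean and variance of the cell count of a random Cantor set after L levels
# (branching process with offspring ~ Binomial(8, p))
cantor_count_moments <- function(levels, p) {
  m <- 8 * p
  v <- 8 * p * (1 - p)
  mean_l <- m^levels
  # var(Z_L) for a Galton-Watson process started from one individual
  var_l <- if (m == 1) levels * v else v * m^(levels - 1) * (m^levels - 1) / (m - 1)
  list(mean = mean_l, var = var_l)
}

# surface-shell occupied-cell count: occupied cells with at least one
# face-neighbour unoccupied (or on the image border)
shell_count <- function(lat) {
  arr <- unclass(lat)
  d <- dim(arr)
  idx <- which(arr == 1L, arr.ind = TRUE)
  on_shell <- logical(nrow(idx))
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    nb <- sweep(idx, 2, shifts[s, ], "+")
    inside <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
              nb[, 2] >= 1 & nb[, 2] <= d[2] &
              nb[, 3] >= 1 & nb[, 3] <= d[3]
    val <- rep(0L, nrow(idx))
    val[inside] <- arr[nb[inside, , drop = FALSE]]
    on_shell <- on_shell | val == 0L
  }
  sum(on_shell)
}
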