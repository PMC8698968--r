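# Internal numeric helpers shared across modules: trilinear sampling of
# regular voxel grids, separable Gaussian smoothing, and unit conversions.
# All world coordinates are in mm; voxel centers sit at
# world = (index - 1) * spacing + origin (1-based array indexing).

#' Convert world coordinates (mm) to continuous 1-based voxel indices
#' @noRd
world_to_index <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/") + 1
}

#' Precompute trilinear interpolation stencils
#'
#' Returns the 8 corner linear indices and weights for each query point so
#' that repeated interpolation of many arrays (e.g. one per cardiac frame)
#' on the same points costs only a gather and a weighted sum.
#'
#' @param dim integer vector (nx, ny, nz)
#' @param idx n x 3 matrix of continuous 1-based voxel-center coordinates
#' @return list with `corners` (n x 8 linear indices), `weights` (n x 8),
#'   and `inside` (logical, all 8 corners within the array)
#' @noRd
trilinear_prep <- function(dim, idx) {
  n <- nrow(idx)
  i0 <- floor(idx)
  f <- idx - i0
  inside <- i0[, 1] >= 1 & i0[, 1] <= dim[1] - 1 &
    i0[, 2] >= 1 & i0[, 2] <= dim[2] - 1 &
    i0[, 3] >= 1 & i0[, 3] <= dim[3] - 1
  # clamp so indexing stays legal; out-of-bounds points are flagged instead
  i0[, 1] <- pmin(pmax(i0[, 1], 1), dim[1] - 1)
  i0[, 2] <- pmin(pmax(i0[, 2], 1), dim[2] - 1)
  i0[, 3] <- pmin(pmax(i0[, 3], 1), dim[3] - 1)
  nx <- dim[1]; nxy <- dim[1] * dim[2]
  base <- (i0[, 3] - 1) * nxy + (i0[, 2] - 1) * nx + i0[, 1]
  corners <- cbind(
    base,             base + 1,
    base + nx,        base + nx + 1,
    base + nxy,       base + nxy + 1,
    base + nxy + nx,  base + nxy + nx + 1
  )
  wx0 <- 1 - f[, 1]; wx1 <- f[, 1]
  wy0 <- 1 - f[, 2]; wy1 <- f[, 2]
  wz0 <- 1 - f[, 3]; wz1 <- f[, 3]
  weights <- cbind(
    wx0 * wy0 * wz0, wx1 * wy0 * wz0,
    wx0 * wy1 * wz0, wx1 * wy1 * wz0,
    wx0 * wy0 * wz1, wx1 * wy0 * wz1,
    wx0 * wy1 * wz1, wx1 * wy1 * wz1
  )
  list(corners = corners, weights = weights, inside = inside)
}

#' Apply a precomputed trilinear stencil to one 3D array
#' @noRd
trilinear_apply <- function(arr, prep, outside_value = 0) {
  vals <- arr[prep$corners]
  dim(vals) <- dim(prep$corners)
  out <- rowSums(vals * prep$weights)
  out[!prep$inside] <- outside_value
  out
}

#' Trilinear interpolation of a 3D array at world points (one shot)
#' @noRd
interp3 <- function(arr, pts, spacing, origin, outside_value = 0) {
  prep <- trilinear_prep(dim(arr), world_to_index(pts, spacing, origin))
  trilinear_apply(arr, prep, outside_value)
}

#' Fraction of each trilinear stencil lying inside a binary mask
#'
#' Used to decide whether a velocity sample is supported entirely by
#' in-lumen voxels (fraction 1) or contaminated by zero-filled exterior.
#' @noRd
stencil_mask_fraction <- function(mask, prep) {
  vals <- mask[prep$corners]
  dim(vals) <- dim(prep$corners)
  out <- rowSums((vals > 0) * prep$weights)
  out[!prep$inside] <- 0
  out
}

#' Mask-aware trilinear sample: weights of exterior voxels renormalized away
#' @noRd
trilinear_apply_masked <- function(arr, mask, prep) {
  vals <- arr[prep$corners]
  dim(vals) <- dim(prep$corners)
  m <- mask[prep$corners] > 0
  dim(m) <- dim(prep$corners)
  w <- prep$weights * m
  tot <- rowSums(w)
  out <- rowSums(vals * w)
  out <- ifelse(tot > 0, out / tot, 0)
  out[!prep$inside] <- 0
  out
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param arr 3D numeric array
#' @param sigma kernel SD in voxels (scalar); kernel truncated at 3 sigma.
#'   Implemented as shifted-array sums per axis with edge replication.
#' @noRd
gaussian_smooth3 <- function(arr, sigma = 1) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (ax in 1:3) {
    out <- array(0, d)
    n <- d[ax]
    for (s in seq(-r, r)) {
      src <- pmin(pmax(seq_len(n) + s, 1L), n)  # replicate edges
      w <- k[s + r + 1]
      out <- out + w * switch(ax,
        arr[src, , , drop = FALSE],
        arr[, src, , drop = FALSE],
        arr[, , src, drop = FALSE]
      )
    }
    arr <- out
  }
  arr
}

#' Central-difference gradient of a 3D array (per-axis spacing, mm)
#' @return list of three arrays, units value/mm
#' @noRd
gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    fwd <- pmin(seq_len(n) + 1L, n)
    bwd <- pmax(seq_len(n) - 1L, 1L)
    step <- (fwd - bwd) * spacing[ax]
    diffed <- switch(ax,
      arr[fwd, , , drop = FALSE] - arr[bwd, , , drop = FALSE],
      arr[, fwd, , drop = FALSE] - arr[, bwd, , drop = FALSE],
      arr[, , fwd, drop = FALSE] - arr[, , bwd, drop = FALSE]
    )
    g[[ax]] <- switch(ax,
      diffed / step,
      sweep(diffed, 2, step, "/"),
      sweep(diffed, 3, step, "/")
    )
  }
  g
}

#' Normalize rows of a matrix to unit length
#' @noRd
normalize_rows <- function(m) {
  len <- sqrt(rowSums(m^2))
  len[len == 0] <- 1
  m / len
}

#' Row-wise cross product of two n x 3 matrices
#' @noRd
cross_rows <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# unit conversions used at module boundaries (internal computation is SI)
CMS_TO_MS <- 0.01       # cm/s -> m/s
MM3S_TO_MLMIN <- 0.06   # mm^3/s -> mL/min

`%||%` <- function(a, b) if (is.null(a)) b else a
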