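# 2D (z, theta) projection maps: unwrap per-node wall values onto a
# regular cylindrical grid. Interpolation is two-stage bilinear-style:
# nodes are grouped into thin arc-length slabs, each slab is linearly
# interpolated around the (periodic) angle axis, and the slab profiles
# are then linearly interpolated along z. Cells with no node within a
# cutoff box are marked invalid (branch ostia, missing coverage).

#' Construct a regular (z, theta) projection map from per-node values
#'
#' @param values numeric vector, one scalar per node (Pa or percent)
#' @param frames a `wall_frames` carrying (z, theta) per node
#' @param theta_step angular grid step (degrees, default 0.5)
#' @param z_step longitudinal grid step (mm, default 0.001, i.e. 1 um)
#' @param z_range optional c(min, max) in mm; defaults to the node range
#' @param slab_mm width of the z slabs used in the two-stage
#'   interpolation (default 0.08)
#' @param valid_theta,valid_z half-widths of the validity cutoff box: a
#'   cell is valid if a (finite-valued) node lies within +/- these
#'   distances (defaults 3 degrees, 0.06 mm)
#' @return object of class `projection_map`: `values` (nz x ntheta
#'   matrix), `valid` (logical matrix), `grid_z`, `grid_theta`
#' @export
project_to_map <- function(values, frames, theta_step = 0.5, z_step = 0.001,
                           z_range = NULL, slab_mm = 0.08,
                           valid_theta = 3, valid_z = 0.06) {
  stopifnot(inherits(frames, "wall_frames"), theta_step > 0, z_step > 0)
  ok <- is.finite(values)
  z <- frames$z[ok]; th <- frames$theta[ok] %% 360; val <- values[ok]
  if (length(val) < 3) stop("fewer than 3 valid nodes to project")
  if (is.null(z_range)) z_range <- range(z)
  grid_z <- seq(z_range[1], z_range[2], by = z_step)
  grid_theta <- seq(0, 360 - theta_step, by = theta_step)

  # slab the nodes in z; interpolate each slab periodically in theta
  nb <- max(1L, ceiling(diff(range(z)) / slab_mm))
  edges <- seq(min(z), max(z) + 1e-9, length.out = nb + 1)
  bin <- findInterval(z, edges, rightmost.closed = TRUE)
  prof <- matrix(NA_real_, nb, length(grid_theta))
  zbar <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    sel <- bin == b
    if (sum(sel) < 2) next
    zbar[b] <- mean(z[sel])
    tb <- th[sel]; vb <- val[sel]
    # collapse duplicate angles, replicate for periodic wrap
    ta <- sort(unique(tb))
    g <- match(tb, ta)
    va <- rowsum(vb, g)[, 1] / tabulate(g, length(ta))
    tw <- c(ta - 360, ta, ta + 360)
    vw <- rep(va, 3)
    prof[b, ] <- stats::approx(tw, vw, xout = grid_theta, rule = 2)$y
  }
  okb <- !is.na(zbar)
  if (sum(okb) < 2) stop("too few populated z slabs to build a map")
  vals <- apply(prof[okb, , drop = FALSE], 2, function(col)
    stats::approx(zbar[okb], col, xout = grid_z, rule = 2)$y)

  valid <- validity_mask(z, th, grid_z, grid_theta, valid_z, valid_theta)
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid, grid_z = grid_z,
                 grid_theta = grid_theta), class = "projection_map")
}

#' @export
print.projection_map <- function(x, ...) {
  cat("projection_map:", length(x$grid_z), "x", length(x$grid_theta),
      "(z x theta),", round(100 * mean(x$valid), 1), "% valid, range",
      paste(signif(range(x$values[x$valid]), 4), collapse = " .. "), "\n")
  invisible(x)
}

# validity by coarse binning: a cell is valid if a node lies within the
# (valid_z x valid_theta) box; evaluated via a presence matrix dilated by
# the cutoff, with periodic wrap in theta
validity_mask <- function(z, th, grid_z, grid_theta, valid_z, valid_theta) {
  bz <- valid_z / 2; bt <- valid_theta / 2
  nzb <- max(1L, ceiling(diff(range(grid_z)) / bz) + 2L)
  ntb <- max(1L, ceiling(360 / bt))
  izn <- pmin(pmax(floor((z - grid_z[1]) / bz) + 1L, 1L), nzb)
  itn <- (floor(th / bt)) %% ntb + 1L
  pres <- matrix(FALSE, nzb, ntb)
  pres[cbind(izn, itn)] <- TRUE
  # dilate presence by +/-2 bins (= cutoff) with theta wrap
  dil <- pres
  for (dz in -2:2) for (dt in -2:2) {
    if (dz == 0 && dt == 0) next
    zi <- pmin(pmax(seq_len(nzb) + dz, 1L), nzb)
    ti <- (seq_len(ntb) + dt - 1L) %% ntb + 1L
    dil <- dil | pres[zi, ti]
  }
  izc <- pmin(pmax(floor((grid_z - grid_z[1]) / bz) + 1L, 1L), nzb)
  itc <- (floor(grid_theta / bt)) %% ntb + 1L
  dil[izc, , drop = FALSE][, itc, drop = FALSE]
}

#' Align projection maps to a common landmark-centered window
#'
#' Resamples each map so its landmark row sits `prox_mm` into a common
#' window of `prox_mm + dist_mm` total length, giving identical grid
#' shapes for pixel-wise group statistics.
#'
#' @param maps list of `projection_map`s on the same grid steps
#' @param landmark_zs landmark arc position (mm) per map
#' @param prox_mm,dist_mm window extent around the landmark (defaults 3, 4)
#' @return list of aligned `projection_map`s (z axis re-zeroed at the
#'   proximal window edge)
#' @export
align_maps <- function(maps, landmark_zs, prox_mm = 3, dist_mm = 4) {
  stopifnot(length(maps) == length(landmark_zs))
  out <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    z_step <- m$grid_z[2] - m$grid_z[1]
    lo <- landmark_zs[i] - prox_mm
    hi <- landmark_zs[i] + dist_mm
    if (lo < m$grid_z[1] - 1e-9 || hi > m$grid_z[length(m$grid_z)] + 1e-9)
      stop(sprintf("map %d: window [%.3f, %.3f] mm exceeds its z extent", i, lo, hi))
    new_z <- seq(0, prox_mm + dist_mm, by = z_step)
    src <- lo + new_z
    # linear row interpolation; a target row is valid only if both
    # flanking source rows are valid
    idx <- (src - m$grid_z[1]) / z_step + 1
    i0 <- pmin(pmax(floor(idx), 1L), length(m$grid_z) - 1L)
    f <- idx - i0
    v0 <- m$values[i0, , drop = FALSE]
    v1 <- m$values[i0 + 1, , drop = FALSE]
    vals <- v0 * (1 - f) + v1 * f
    valid <- m$valid[i0, , drop = FALSE] & m$valid[i0 + 1, , drop = FALSE]
    vals[!valid] <- NA_real_
    out[[i]] <- structure(list(values = vals, valid = valid, grid_z = new_z,
                               grid_theta = m$grid_theta),
                          class = "projection_map")
  }
  out
}

#' Spatial mean of a map over an angular strip and z interval
#'
#' The histology-correlation readout: averages valid cells with theta in
#' `center_theta +/- half_width` (periodic) and z in `z_range`.
#'
#' @param map a `projection_map`
#' @param center_theta strip center (degrees), e.g. 270 for the inner
#'   curvature
#' @param half_width angular half width (degrees, default 30)
#' @param z_range c(min, max) in mm; default covers the whole map
#' @return scalar mean over the strip's valid cells
#' @export
extract_strip <- function(map, center_theta, half_width = 30,
                          z_range = NULL) {
  stopifnot(inherits(map, "projection_map"))
  if (is.null(z_range)) z_range <- range(map$grid_z)
  dth <- (map$grid_theta - center_theta + 180) %% 360 - 180
  tc <- abs(dth) <= half_width
  zc <- map$grid_z >= z_range[1] - 1e-9 & map$grid_z <= z_range[2] + 1e-9
  sel <- map$valid[zc, tc, drop = FALSE]
  if (!any(sel)) stop("strip contains no valid cells")
  mean(map$values[zc, tc, drop = FALSE][sel])
}

#' Sample a projection map at arbitrary (z, theta) points (bilinear)
#' @param map a `projection_map`
#' @param z,theta coordinate vectors (mm, degrees)
#' @return sampled values (NA outside valid cells)
#' @export
sample_map <- function(map, z, theta) {
  z_step <- map$grid_z[2] - map$grid_z[1]
  th_step <- map$grid_theta[2] - map$grid_theta[1]
  iz <- pmin(pmax((z - map$grid_z[1]) / z_step + 1, 1), length(map$grid_z))
  it <- (theta %% 360) / th_step + 1
  nt <- length(map$grid_theta)
  i0 <- pmin(floor(iz), length(map$grid_z) - 1L); fz <- iz - i0
  j0 <- floor(it); ft <- it - j0
  j0w <- (j0 - 1L) %% nt + 1L
  j1w <- j0 %% nt + 1L
  v00 <- map$values[cbind(i0, j0w)]; v01 <- map$values[cbind(i0, j1w)]
  v10 <- map$values[cbind(i0 + 1L, j0w)]; v11 <- map$values[cbind(i0 + 1L, j1w)]
  (1 - fz) * ((1 - ft) * v00 + ft * v01) + fz * ((1 - ft) * v10 + ft * v11)
}

#' Write a projection map as CSV (values) plus a JSON sidecar (grid spec)
#' @param map a `projection_map`
#' @param path CSV path; the sidecar is `<path>.json`
#' @export
write_map <- function(map, path) {
  utils::write.table(round(map$values, 8), path, sep = ",",
                     row.names = FALSE, col.names = FALSE, na = "")
  jsonlite::write_json(list(
    grid_z_mm = range(map$grid_z), z_step_mm = map$grid_z[2] - map$grid_z[1],
    theta_step_deg = map$grid_theta[2] - map$grid_theta[1],
    n_z = length(map$grid_z), n_theta = length(map$grid_theta),
    invalid_encoding = "empty cell"
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a projection map written by [write_map()]
#' @param path CSV path (expects `<path>.json` sidecar)
#' @return a `projection_map`
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ",", na.strings = "",
                                      header = FALSE))
  dimnames(vals) <- NULL
  structure(list(values = vals, valid = !is.na(vals),
                 grid_z = seq(meta$grid_z_mm[1], by = meta$z_step_mm,
                              length.out = meta$n_z),
                 grid_theta = seq(0, by = meta$theta_step_deg,
                                  length.out = meta$n_theta)),
            class = "projection_map")
}

#' Coarsen a projection map by block averaging of valid cells
#' @param map a `projection_map`
#' @param fz,ft integer block sizes along z and theta
#' @return a `projection_map` on the coarser grid
#' @export
coarsen_map <- function(map, fz = 10L, ft = 4L) {
  nz <- floor(length(map$grid_z) / fz) * fz
  nt <- floor(length(map$grid_theta) / ft) * ft
  v <- map$values[seq_len(nz), seq_len(nt), drop = FALSE]
  ok <- map$valid[seq_len(nz), seq_len(nt), drop = FALSE]
  v[!ok] <- 0
  gz <- rep(seq_len(nz %/% fz), each = fz)
  gt <- rep(seq_len(nt %/% ft), each = ft)
  sums <- rowsum(t(rowsum(v, gz)), gt)            # nt' x nz'
  cnts <- rowsum(t(rowsum(ok + 0, gz)), gt)
  vals <- t(sums / pmax(cnts, 1))
  valid <- t(cnts) > 0
  vals[!valid] <- NA_real_
  structure(list(values = vals, valid = valid,
                 grid_z = colMeans(matrix(map$grid_z[seq_len(nz)], fz)),
                 grid_theta = colMeans(matrix(map$grid_theta[seq_len(nt)], ft))),
            class = "projection_map")
}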