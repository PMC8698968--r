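# Centerline extraction for tubular lumen masks. Strategy: find the two
# geodesically most distant lumen voxels (double breadth-first search),
# slice the lumen into geodesic-distance slabs and take slab centroids as
# an initial axis estimate, then refine by re-slabbing voxels according to
# their projection onto the current centerline (which makes the slicing
# planes perpendicular to the axis, removing the end bias of the BFS
# metric), smooth each coordinate with a smoothing spline, and resample at
# even arc-length spacing.

#' Extract a centerline with arc length from a tubular lumen mask
#'
#' @param mask a [lumen_mask()]; the time-averaged occupancy thresholded
#'   at 0.5 is used.
#' @param resample_mm spacing of the densely resampled output points (mm,
#'   default 0.05).
#' @param refine_iter projection-refinement iterations (default 2).
#' @param smooth_mm window (mm) of the local quadratic regression used
#'   to smooth slab centroids into a curve (default 1.5).
#' @return object of class `centerline`: `points` (m x 3, world mm,
#'   ordered proximal to distal), `arc` (mm, 0 at the proximal end),
#'   `tangents` (m x 3 unit vectors).
#' @export
extract_centerline <- function(mask, resample_mm = 0.05, refine_iter = 2,
                               smooth_mm = 1.5) {
  stopifnot(inherits(mask, "lumen_mask"))
  bin <- array(as.integer(mask_average(mask) >= 0.5), mask$dim)
  if (sum(bin) < 8) stop("mask too small / degenerate for centerline extraction")
  bin <- largest_component(bin)

  vox <- which(bin > 0, arr.ind = TRUE)
  world <- sweep(sweep(vox - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")

  # double BFS to find the two tube ends
  d0 <- bfs_geodesic(bin, which(bin > 0)[1])
  e1 <- which.max(ifelse(is.finite(d0), d0, -1))
  d1 <- bfs_geodesic(bin, e1)
  dv <- d1[bin > 0]
  if (max(dv) < 4) stop("mask too small / degenerate for centerline extraction")

  h <- min(mask$spacing)
  # initial curve from BFS-level slab centroids. BFS level sets are
  # diamond shells around the seed corners, so plain centroids bend
  # toward the corners near the ends; weighting voxels by (erosion
  # depth)^2 concentrates the centroids on the tube core and largely
  # removes that bias before refinement even starts.
  wgt <- as.numeric(erosion_depth(bin)[bin > 0])^2
  curve <- spline_resample(slab_centroids(world, dv, width = 1, weights = wgt),
                           resample_mm, smooth_mm)
  # refinement cycle: (1) slab the lumen perpendicular to the current
  # curve, mirroring end voxels across the estimated cap planes so the
  # end slabs are complete cross-sections; (2) refit the curve; (3) cut
  # the last ~2.5 lumen radii, which inherit whatever bias the previous
  # curve had near the caps, and regrow each end as the circle fitted to
  # the adjacent clean interior. Two cycles reach voxel-level accuracy;
  # more mainly lets the end estimates wander.
  for (it in seq_len(refine_iter)) {
    nn <- nearest_point_index(world, curve$points)
    proj <- curve$arc[nn]
    dist <- sqrt(rowSums((world - curve$points[nn, , drop = FALSE])^2))
    r_est <- as.numeric(stats::quantile(dist, 0.95))  # ~ lumen radius
    ends <- robust_proj_ends(proj)
    margin <- min(1.5 * r_est, 0.3 * diff(ends))
    mirror <- function(end_arc, sel) {
      i <- which.min(abs(curve$arc - end_arc))
      p0 <- curve$points[i, ]; tg <- curve$tangents[i, ]
      s <- (world[sel, , drop = FALSE] - rep(p0, each = sum(sel))) %*% tg
      list(w = world[sel, , drop = FALSE] - 2 * as.vector(s) %o% tg,
           proj = 2 * end_arc - proj[sel])
    }
    lo_sel <- proj < ends[1] + margin
    hi_sel <- proj > ends[2] - margin
    mlo <- mirror(ends[1], lo_sel)
    mhi <- mirror(ends[2], hi_sel)
    allw <- rbind(world, mlo$w, mhi$w)
    allp <- c(proj, mlo$proj, mhi$proj)
    allwgt <- c(wgt, wgt[lo_sel], wgt[hi_sel])
    cent <- slab_centroids(allw, allp,
                           width = max(h, diff(range(allp)) / 180),
                           weights = allwgt)
    curve <- spline_resample(cent, resample_mm, smooth_mm)
    cap_lo <- ends[1] - min(allp)
    cap_hi <- ends[2] - min(allp)
    cut <- min(2.5 * r_est, 0.35 * (cap_hi - cap_lo))
    sel <- curve$arc >= cap_lo + cut & curve$arc <= cap_hi - cut
    if (sum(sel) < 8)
      stop("mask too small / degenerate for centerline extraction")
    curve <- list(points = curve$points[sel, , drop = FALSE],
                  arc = curve$arc[sel] - min(curve$arc[sel]),
                  tangents = curve$tangents[sel, , drop = FALSE])
    curve <- circle_extend(curve, cut + 4 * h, TRUE, resample_mm)
    curve <- circle_extend(curve, cut + 4 * h, FALSE, resample_mm)
  }
  # crop to the arc range actually occupied by lumen voxels
  nn <- nearest_point_index(world, curve$points)
  proj <- curve$arc[nn]
  keep <- curve$arc >= min(proj) - 1e-9 & curve$arc <= max(proj) + 1e-9
  structure(list(points = curve$points[keep, , drop = FALSE],
                 arc = curve$arc[keep] - min(curve$arc[keep]),
                 tangents = curve$tangents[keep, , drop = FALSE]),
            class = "centerline")
}

# prolong one end of a resampled curve along the circle fitted (in its
# local PCA plane) to the adjacent window of the curve; falls back to a
# straight tangent extension where the window is effectively straight
circle_extend <- function(curve, ext, at_start, resample_mm,
                          window_mm = 1.5) {
  if (ext < resample_mm) return(curve)
  n <- nrow(curve$points)
  s <- seq(resample_mm, ext, by = resample_mm)
  w <- max(8L, min(round(window_mm / resample_mm), n))
  ix <- if (at_start) seq_len(w) else (n - w + 1L):n
  p <- curve$points[ix, , drop = FALSE]
  iend <- if (at_start) 1L else n
  tg3 <- curve$tangents[iend, ] * (if (at_start) -1 else 1)
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  ev <- eigen(crossprod(pc), symmetric = TRUE)$vectors
  u <- pc %*% ev[, 1]; v <- pc %*% ev[, 2]
  A <- cbind(2 * u, 2 * v, 1)
  sol <- tryCatch(qr.coef(qr(A), u^2 + v^2), error = function(e) NULL)
  q <- curve$points[iend, ]
  straight <- TRUE
  if (!is.null(sol) && !anyNA(sol)) {
    r2 <- sol[3] + sol[1]^2 + sol[2]^2
    if (r2 > 0 && sqrt(r2) < 50) {
      rc <- sqrt(r2)
      qu <- sum((q - ctr) * ev[, 1]); qv <- sum((q - ctr) * ev[, 2])
      qw <- q - ctr - qu * ev[, 1] - qv * ev[, 2]  # out-of-plane offset
      alpha <- atan2(qv - sol[2], qu - sol[1])
      dirv <- c(-sin(alpha), cos(alpha))
      t2d <- c(sum(tg3 * ev[, 1]), sum(tg3 * ev[, 2]))
      sgn <- if (sum(t2d * dirv) >= 0) 1 else -1
      ang <- alpha + sgn * s / rc
      pts_ext <- sweep(outer(sol[1] + rc * cos(ang), ev[, 1]) +
                         outer(sol[2] + rc * sin(ang), ev[, 2]),
                       2, ctr + qw, "+")
      tng_ext <- sgn * (outer(-sin(ang), ev[, 1]) + outer(cos(ang), ev[, 2]))
      straight <- FALSE
    }
  }
  if (straight) {
    pts_ext <- sweep(outer(s, tg3), 2, q, "+")
    tng_ext <- matrix(tg3, length(s), 3, byrow = TRUE)
  }
  if (at_start) {
    rev_ix <- rev(seq_along(s))
    list(points = rbind(pts_ext[rev_ix, , drop = FALSE], curve$points),
         arc = c(-rev(s), curve$arc) + max(s),
         tangents = rbind(-tng_ext[rev_ix, , drop = FALSE], curve$tangents))
  } else {
    list(points = rbind(curve$points, pts_ext),
         arc = c(curve$arc, max(curve$arc) + s),
         tangents = rbind(curve$tangents, tng_ext))
  }
}

#' @export
print.centerline <- function(x, ...) {
  cat("centerline:", nrow(x$points), "points, arc length",
      signif(max(x$arc), 4), "mm\n")
  invisible(x)
}

# robust arc positions of the two tube ends: inner quantiles extrapolated
# outward, immune to stray projections onto overshooting extensions
robust_proj_ends <- function(proj) {
  q <- as.numeric(stats::quantile(proj, c(0.02, 0.98)))
  span <- (q[2] - q[1]) / 0.96
  c(q[1] - 0.02 * span, q[2] + 0.02 * span)
}

# geodesic (6-connected BFS) distance from a seed linear index; Inf outside
bfs_geodesic <- function(bin, seed) {
  d <- array(Inf, dim(bin))
  inmask <- bin > 0
  frontier <- array(FALSE, dim(bin))
  frontier[seed] <- TRUE
  d[seed] <- 0
  level <- 0
  while (any(frontier)) {
    level <- level + 1
    grown <- dilate6(frontier)
    frontier <- grown & inmask & !is.finite(d)
    d[frontier] <- level
  }
  d
}

# (optionally weighted) centroids of voxels binned by a scalar
# coordinate; rows ordered by bin
slab_centroids <- function(world, coord, width, weights = NULL) {
  b <- as.integer(floor((coord - min(coord)) / width))
  if (is.null(weights)) weights <- rep(1, nrow(world))
  tot <- rowsum(weights, b)  # rowsum orders rows by sort(unique(b))
  rowsum(world * weights, b) / as.vector(tot)
}

# approximate distance-to-boundary in voxels (iterative 6-erosion), capped
erosion_depth <- function(bin, cap = 5L) {
  depth <- array(0L, dim(bin))
  cur <- bin > 0
  for (k in seq_len(cap)) {
    depth[cur] <- k
    # erode: keep voxels whose 6 neighbors are all set
    nb <- !dilate6(!cur)
    cur <- cur & nb
    if (!any(cur)) break
  }
  depth
}

# index of nearest point in `ref` for each row of `pts`
nearest_point_index <- function(pts, ref) {
  # chunked distance computation to bound memory
  n <- nrow(pts)
  out <- integer(n)
  step <- max(1L, floor(2e6 / nrow(ref)))
  for (s in seq(1, n, by = step)) {
    ix <- s:min(n, s + step - 1)
    d2 <- outer(rowSums(pts[ix, , drop = FALSE]^2), rep(1, nrow(ref))) -
      2 * pts[ix, , drop = FALSE] %*% t(ref) +
      outer(rep(1, length(ix)), rowSums(ref^2))
    out[ix] <- max.col(-d2, ties.method = "first")
  }
  out
}

# smooth fit of each coordinate against cumulative chord length by local
# quadratic regression (robust loess), then resampling at even arc
# spacing with finite-difference tangents. Local fitting tracks
# arch-like curvature without boundary-condition artifacts, and its
# bisquare weights shrug off the occasional contaminated slab centroid.
spline_resample <- function(ctr, resample_mm, smooth_mm = 1.5) {
  n <- nrow(ctr)
  if (n < 4) stop("too few centerline support points (degenerate mask)")
  chord <- c(0, cumsum(sqrt(rowSums(diff(ctr)^2))))
  # span: aim for a smooth_mm-wide window, but keep >= 10 support points
  span <- min(1, max(smooth_mm / max(chord), 10 / n))
  sfine <- seq(0, max(chord), length.out = max(400L, n * 4L))
  pfine <- vapply(1:3, function(k) {
    fit <- stats::loess(ctr[, k] ~ chord, span = span, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, sfine)
  }, numeric(length(sfine)))
  arcf <- c(0, cumsum(sqrt(rowSums(diff(pfine)^2))))
  s_even <- seq(0, max(arcf), by = resample_mm)
  pts <- vapply(1:3, function(k)
    stats::spline(arcf, pfine[, k], xout = s_even, method = "fmm")$y,
    numeric(length(s_even)))
  tang <- apply(pts, 2, function(v) {
    n2 <- length(v)
    c(v[2] - v[1], (v[3:n2] - v[1:(n2 - 2)]) / 2, v[n2] - v[n2 - 1])
  })
  list(points = pts, arc = s_even, tangents = normalize_rows(tang))
}

#' Arc-length position and foot point of mesh nodes on a centerline
#'
#' Nearest-point lookup over the densely resampled centerline; ties take
#' the smaller arc length.
#'
#' @param mesh a `surface_mesh`
#' @param centerline a `centerline`
#' @return list: `z` (mm per node), `foot` (index into centerline points)
#' @export
node_arc_positions <- function(mesh, centerline) {
  foot <- nearest_point_index(mesh$nodes, centerline$points)
  list(z = centerline$arc[foot], foot = foot)
}

#' Clip centerline and mesh to the analysis extent around a landmark
#'
#' Reproduces the length normalization used for inter-animal comparison:
#' a fixed window of `prox_mm` proximal and `dist_mm` distal of a
#' landmark arc position (7 mm total by default), with arc length
#' re-zeroed at the proximal cut.
#'
#' @param centerline a `centerline`
#' @param mesh a `surface_mesh`
#' @param landmark_z landmark arc-length position (mm) on `centerline`
#' @param prox_mm extent kept proximal of the landmark (default 3)
#' @param dist_mm extent kept distal of the landmark (default 4)
#' @return list with clipped `centerline` and `mesh`; the mesh keeps only
#'   faces whose three nodes all lie in the window
#' @export
normalize_extent <- function(centerline, mesh, landmark_z,
                             prox_mm = 3, dist_mm = 4) {
  stopifnot(inherits(centerline, "centerline"))
  tol <- 1e-6
  lo <- landmark_z - prox_mm
  hi <- landmark_z + dist_mm
  if (lo < min(centerline$arc) - tol || hi > max(centerline$arc) + tol)
    stop(sprintf(
      "requested extent [%.2f, %.2f] mm exceeds the centerline range [%.2f, %.2f] mm",
      lo, hi, min(centerline$arc), max(centerline$arc)))
  keep_c <- centerline$arc >= lo - tol & centerline$arc <= hi + tol
  cl <- structure(list(
    points = centerline$points[keep_c, , drop = FALSE],
    arc = centerline$arc[keep_c] - lo,
    tangents = centerline$tangents[keep_c, , drop = FALSE]
  ), class = "centerline")

  pos <- node_arc_positions(mesh, centerline)
  keep_n <- pos$z >= lo - tol & pos$z <= hi + tol
  newid <- cumsum(keep_n)
  fkeep <- keep_n[mesh$faces[, 1]] & keep_n[mesh$faces[, 2]] &
    keep_n[mesh$faces[, 3]]
  m <- structure(list(
    nodes = mesh$nodes[keep_n, , drop = FALSE],
    faces = matrix(newid[mesh$faces[fkeep, , drop = FALSE]], ncol = 3),
    normals = mesh$normals[keep_n, , drop = FALSE],
    spacing = mesh$spacing
  ), class = "surface_mesh")
  list(centerline = cl, mesh = m)
}
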