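# Through-plane flow along the centerline, transit-time pulse wave
# velocity from systolic upstroke feet, and time-resolved lumen volume.

#' Through-plane flow curves at arc-length positions
#'
#' At each position a plane orthogonal to the centerline tangent is
#' rasterized at half-voxel pitch; flow(t) is the sum over in-lumen plane
#' pixels of (velocity . plane normal) x pixel area, reported in mL/min.
#'
#' @param velocity a [velocity_field()] (cm/s)
#' @param mask a [lumen_mask()]
#' @param centerline a `centerline`
#' @param positions arc-length positions (mm); see [pwv_plane_positions()]
#' @param max_radius plane half-extent (mm); default: 1.5 x the lumen
#'   radius estimated from the mask
#' @return object of class `flow_curves`: `flow` (n_planes x n_frames
#'   matrix, mL/min), `positions` (mm), `frame_times` (ms)
#' @export
through_plane_flow <- function(velocity, mask, centerline, positions,
                               max_radius = NULL) {
  stopifnot(inherits(velocity, "velocity_field"), inherits(mask, "lumen_mask"),
            inherits(centerline, "centerline"))
  if (any(positions < min(centerline$arc) - 1e-9 |
          positions > max(centerline$arc) + 1e-9))
    stop("plane position outside the centerline extent")
  h <- min(velocity$spacing)
  if (is.null(max_radius)) {
    # generous bound from the lumen cross-section area per unit length
    vol <- sum(mask$frames[[1]]) * prod(mask$spacing)
    max_radius <- 1.5 * sqrt(vol / max(diff(range(centerline$arc)), h) / pi)
  }
  pitch <- h / 2
  offs <- seq(-max_radius, max_radius, by = pitch)
  grid2 <- as.matrix(expand.grid(u = offs, v = offs))
  maskbin <- array(as.integer(mask_average(mask) >= 0.5), mask$dim)
  static_mask <- mask$n_frames == 1

  nfr <- velocity$n_frames
  flow <- matrix(0, length(positions), nfr)
  for (pi_ in seq_along(positions)) {
    i <- which.min(abs(centerline$arc - positions[pi_]))
    p0 <- centerline$points[i, ]
    tg <- centerline$tangents[i, ]
    a <- c(0, 0, 0); a[which.min(abs(tg))] <- 1
    e1 <- a - sum(a * tg) * tg; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(tg[2] * e1[3] - tg[3] * e1[2],
            tg[3] * e1[1] - tg[1] * e1[3],
            tg[1] * e1[2] - tg[2] * e1[1])
    pts <- sweep(grid2[, 1] %o% e1 + grid2[, 2] %o% e2, 2, p0, "+")
    prep <- trilinear_prep(velocity$dim,
                           world_to_index(pts, velocity$spacing,
                                          velocity$origin))
    inlum <- trilinear_apply(maskbin + 0, prep) >= 0.5
    if (!any(inlum)) stop(sprintf(
      "plane at %.2f mm misses the lumen entirely", positions[pi_]))
    # velocity in cm/s -> mm/s (x10); area mm^2 -> flow mm^3/s -> mL/min
    for (k in seq_len(nfr)) {
      fr <- velocity$frames[[k]]
      vn <- (trilinear_apply(fr[[1]], prep) * tg[1] +
             trilinear_apply(fr[[2]], prep) * tg[2] +
             trilinear_apply(fr[[3]], prep) * tg[3]) * 10
      sel <- if (static_mask) inlum else
        (trilinear_apply(mask$frames[[min(k, mask$n_frames)]] + 0, prep) >= 0.5)
      flow[pi_, k] <- sum(vn[sel]) * pitch^2 * MM3S_TO_MLMIN
    }
  }
  structure(list(flow = flow, positions = positions,
                 frame_times = velocity$frame_times),
            class = "flow_curves")
}

#' @export
print.flow_curves <- function(x, ...) {
  cat("flow_curves:", nrow(x$flow), "planes,", ncol(x$flow),
      "frames, peak", signif(max(x$flow), 4), "mL/min\n")
  invisible(x)
}

#' Equidistant plane positions over a centerline
#' @param centerline a `centerline`
#' @param n number of planes (default 50)
#' @param margin_mm end margin kept free of planes (default 0.1)
#' @return arc positions (mm)
#' @export
pwv_plane_positions <- function(centerline, n = 50, margin_mm = 0.1) {
  seq(min(centerline$arc) + margin_mm, max(centerline$arc) - margin_mm,
      length.out = n)
}

#' Detect the systolic upstroke foot of one flow curve
#'
#' Two-line intersection: a baseline line fitted to the frames preceding
#' the foot candidate and an upstroke line fitted to the rising limb
#' between 20% and 80% of (peak - baseline); the foot is where the two
#' lines cross.
#'
#' The curve is treated as one period of a cyclic signal: it is rotated
#' so the peak sits past mid-cycle (guaranteeing pre-foot baseline
#' frames even when the upstroke falls at the start of the cycle) and
#' the detected time is mapped back modulo the cycle length.
#'
#' @param flow flow samples over one cycle (any units)
#' @param times frame times (ms), uniformly spaced
#' @param flat_tol minimum relative amplitude (peak - min vs |peak|)
#'   below which the curve is rejected as flat (default 0.05)
#' @return foot time (ms), within `[times[1], times[1] + period)`
#' @export
detect_upstroke <- function(flow, times, flat_tol = 0.05) {
  stopifnot(length(flow) == length(times), length(flow) >= 5)
  if (abs(min(flow)) > abs(max(flow))) flow <- -flow  # sign convention free
  n <- length(flow)
  dtau <- times[2] - times[1]
  period <- n * dtau
  rot <- round(0.6 * n) - which.max(flow)
  flow <- flow[((seq_len(n) - 1 - rot) %% n) + 1]
  b0 <- min(flow)
  amp <- max(flow) - b0
  if (amp <= flat_tol * max(abs(max(flow)), 1e-12))
    stop("flow curve has no discernible systolic upstroke (flat)")
  ip <- which.max(flow)
  # rising limb between the 20% and 80% amplitude crossings before the
  # peak (threshold crossings, robust to sample-level noise)
  th20 <- b0 + 0.2 * amp; th80 <- b0 + 0.8 * amp
  i80 <- which(flow[1:ip] >= th80)[1]
  if (is.na(i80)) i80 <- ip
  below20 <- which(flow[1:i80] <= th20)
  i20 <- if (length(below20)) max(below20) else 1L
  up <- i20:i80
  if (length(up) < 2) up <- max(1L, i80 - 1L):i80
  fu <- stats::lm.fit(cbind(1, times[up]), flow[up])$coefficients
  # baseline: frames preceding the foot candidate (last sub-10% sample
  # before the rising limb)
  th10 <- b0 + 0.1 * amp
  below10 <- which(flow[1:max(i20, 1)] <= th10)
  cand <- if (length(below10)) max(below10) + 1L else i20
  nb <- max(2L, round(0.1 * n))
  bidx <- seq(max(1L, cand - nb), max(2L, cand - 1L))
  fb <- stats::lm.fit(cbind(1, times[bidx]), flow[bidx])$coefficients
  if (anyNA(c(fu, fb)) || abs(fu[2] - fb[2]) < 1e-12)
    stop("upstroke and baseline lines are indistinguishable")
  foot <- as.numeric((fb[1] - fu[1]) / (fu[2] - fb[2]))
  times[1] + (foot - rot * dtau - times[1]) %% period
}

#' Transit-time pulse wave velocity from multi-plane flow curves
#'
#' Upstroke feet are detected per plane and arrival time is regressed on
#' plane position (errors live in the time estimates); PWV = 1/slope,
#' reported in m/s (mm/ms).
#'
#' @param curves a `flow_curves` (>= 3 planes)
#' @param min_slope_ms_per_mm slopes below this are reported as
#'   unresolvable rather than as a (near-infinite) PWV; default 1e-3
#'   ms/mm, i.e. 1000 m/s
#' @return object of class `pwv_fit`: `pwv` (m/s), `fit_r2`,
#'   `upstroke_times` (ms), `positions` (mm)
#' @export
estimate_pwv <- function(curves, min_slope_ms_per_mm = 1e-3) {
  stopifnot(inherits(curves, "flow_curves"))
  if (nrow(curves$flow) < 3) stop("PWV needs at least 3 planes")
  dt <- vapply(seq_len(nrow(curves$flow)), function(i)
    detect_upstroke(curves$flow[i, ], curves$frame_times), numeric(1))
  # arrival times are modulo the cycle; transit across the vessel is a
  # small fraction of it, so recenter all times circularly around their
  # mean direction before fitting
  period <- length(curves$frame_times) *
    (curves$frame_times[2] - curves$frame_times[1])
  ang <- 2 * pi * dt / period
  center <- atan2(mean(sin(ang)), mean(cos(ang))) * period / (2 * pi)
  dt <- dt - period * round((dt - center) / period)
  fit <- stats::lm(dt ~ curves$positions)
  slope <- stats::coef(fit)[2]
  if (!is.finite(slope) || slope < min_slope_ms_per_mm)
    stop("transit times do not increase along the vessel: wave speed ",
         "unresolvable at this temporal resolution")
  r2 <- summary(fit)$r.squared
  structure(list(pwv = as.numeric(1 / slope), fit_r2 = r2,
                 upstroke_times = dt, positions = curves$positions),
            class = "pwv_fit")
}

#' @export
print.pwv_fit <- function(x, ...) {
  cat("pwv_fit:", signif(x$pwv, 4), "m/s over", length(x$positions),
      "planes (R^2 =", round(x$fit_r2, 4), ")\n")
  invisible(x)
}

#' Orient a centerline along the net flow direction
#'
#' The extraction itself cannot know which tube end is proximal; this
#' flips the centerline, if needed, so that the net through-plane flow
#' at its midpoint is positive along increasing arc length - i.e. arc
#' length grows downstream.
#'
#' @param centerline a `centerline`
#' @param velocity a [velocity_field()]
#' @param mask a [lumen_mask()]
#' @return the (possibly reversed) `centerline`
#' @export
orient_by_flow <- function(centerline, velocity, mask) {
  mid <- (min(centerline$arc) + max(centerline$arc)) / 2
  fc <- through_plane_flow(velocity, mask, centerline, mid)
  if (mean(fc$flow) >= 0) return(centerline)
  m <- nrow(centerline$points)
  structure(list(points = centerline$points[m:1, , drop = FALSE],
                 arc = max(centerline$arc) - rev(centerline$arc),
                 tangents = -centerline$tangents[m:1, , drop = FALSE]),
            class = "centerline")
}

#' Time-resolved lumen volume by voxel counting
#'
#' @param mask a [lumen_mask()] (cropped to the analysis extent, branches
#'   flagged via `branch_flags` where applicable)
#' @return object of class `volume_series`: `volume` (mm^3 per frame),
#'   `mean`, `max`, `min`, `max_minus_min`
#' @export
volume_series <- function(mask) {
  stopifnot(inherits(mask, "lumen_mask"))
  vv <- prod(mask$spacing)
  excl <- if (!is.null(mask$branch_flags)) mask$branch_flags > 0 else FALSE
  vols <- vapply(mask$frames, function(m) {
    n <- sum(m[!excl])
    if (n == 0) stop("empty mask frame in volume computation")
    n * vv
  }, numeric(1))
  structure(list(volume = vols, mean = mean(vols), max = max(vols),
                 min = min(vols), max_minus_min = max(vols) - min(vols)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  cat("volume_series:", length(x$volume), "frames, mean",
      signif(x$mean, 4), "mm^3 (min", signif(x$min, 4), ", max",
      signif(x$max, 4), ")\n")
  invisible(x)
}

#' Crop a mask to the arc-length window of a (normalized) centerline
#'
#' Voxels whose nearest-centerline arc position falls outside
#' `[z_min, z_max]` are cleared in every frame.
#'
#' @param mask a [lumen_mask()]
#' @param centerline a `centerline` (arc already windowed, e.g. from
#'   [normalize_extent()])
#' @param z_min,z_max window (mm); defaults to the centerline range
#' @return a cropped [lumen_mask()]
#' @export
crop_mask_to_extent <- function(mask, centerline, z_min = NULL, z_max = NULL) {
  stopifnot(inherits(mask, "lumen_mask"), inherits(centerline, "centerline"))
  z_min <- z_min %||% min(centerline$arc)
  z_max <- z_max %||% max(centerline$arc)
  occ <- mask_average(mask) > 0
  vox <- which(occ, arr.ind = TRUE)
  world <- sweep(sweep(vox - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  nn <- nearest_point_index(world, centerline$points)
  # signed arc: the tangential offset extends the coordinate past the
  # window ends, where nearest-point projection alone would clamp
  zv <- centerline$arc[nn] +
    rowSums((world - centerline$points[nn, , drop = FALSE]) *
              centerline$tangents[nn, , drop = FALSE])
  drop <- which(occ)[zv < z_min - 1e-9 | zv > z_max + 1e-9]
  frames <- lapply(mask$frames, function(m) { m[drop] <- 0L; m })
  flags <- mask$branch_flags
  lumen_mask(frames, mask$spacing, mask$origin, branch_flags = flags)
}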