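# Per-node orthonormal wall frames in the centerline-based cylindrical
# coordinate system: l_hat along the local centerline tangent, r_hat from
# the wall node toward its centerline foot point (inward positive), c_hat
# completing the right-handed frame. The circumferential angle theta uses
# a reference direction parallel-transported along the centerline so the
# angular origin does not twist through curved segments; with the default
# reference (+y, the arch plane normal / anatomical posterior axis) the
# convention is theta = 0 posterior, 90 outer curvature, 180 anterior,
# 270 inner curvature.

#' Build orthonormal wall frames and (z, theta) coordinates for mesh nodes
#'
#' @param mesh a `surface_mesh`
#' @param centerline a `centerline` covering the mesh extent
#' @param reference direction defining theta = 0 (default `c(0, 1, 0)`);
#'   transported along the centerline by projecting out the tangent.
#' @return object of class `wall_frames`: `node_id`, `z` (mm), `theta`
#'   (degrees in [0, 360)), unit-vector matrices `l_hat`, `c_hat`,
#'   `r_hat`, and `foot` (centerline point index per node).
#' @export
build_wall_frames <- function(mesh, centerline, reference = c(0, 1, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"), inherits(centerline, "centerline"))
  pos <- node_arc_positions(mesh, centerline)
  foot <- pos$foot
  tang <- centerline$tangents

  # parallel transport of the reference direction along the centerline
  m <- nrow(tang)
  eref <- matrix(0, m, 3)
  e <- reference - sum(reference * tang[1, ]) * tang[1, ]
  if (sqrt(sum(e^2)) < 1e-8)
    stop("reference direction is parallel to the centerline start tangent")
  e <- e / sqrt(sum(e^2))
  eref[1, ] <- e
  for (i in 2:m) {
    e <- e - sum(e * tang[i, ]) * tang[i, ]
    nrm <- sqrt(sum(e^2))
    if (nrm < 1e-8) stop("reference transport degenerated (kinked centerline)")
    e <- e / nrm
    eref[i, ] <- e
  }

  l_hat <- tang[foot, , drop = FALSE]
  d <- mesh$nodes - centerline$points[foot, , drop = FALSE]  # outward offset
  # radial: node -> foot (inward), orthogonalized against the tangent
  r_raw <- -d
  r_hat <- normalize_rows(r_raw - rowSums(r_raw * l_hat) * l_hat)
  c_hat <- cross_rows(l_hat, r_hat)

  e1 <- eref[foot, , drop = FALSE]
  e2 <- cross_rows(l_hat, e1)   # theta grows from reference toward t x e
  theta <- atan2(rowSums(d * e2), rowSums(d * e1)) * 180 / pi
  theta <- theta %% 360

  structure(list(node_id = seq_len(nrow(mesh$nodes)), z = pos$z,
                 theta = theta, l_hat = l_hat, c_hat = c_hat,
                 r_hat = r_hat, foot = foot),
            class = "wall_frames")
}

#' @export
print.wall_frames <- function(x, ...) {
  cat("wall_frames:", length(x$node_id), "nodes, z in [",
      signif(min(x$z), 3), ",", signif(max(x$z), 3), "] mm\n")
  invisible(x)
}
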