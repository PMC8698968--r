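# Lumen surface extraction: marching tetrahedra on the (optionally
# time-averaged, lightly smoothed) segmentation, with deduplicated
# vertices, consistent outward orientation from the field gradient, and
# per-node outward normals. The Kuhn 6-tetrahedra cube subdivision keeps
# the triangulation consistent between neighboring cubes, so the mesh is
# watertight away from the array boundary.

# Kuhn subdivision: local cube corner offsets (x, y, z)
.cube_offsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
)
# six tetrahedra sharing the main diagonal corner1-corner7 (1-based ids)
.tet_corners <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7)
)

# per-case triangle table: local tet corners are A=1..D=4; each triangle is
# three edges, an edge being an ordered pair of corner ids. Case id is the
# bitmask of corners above the iso-level (A=1, B=2, C=4, D=8).
.tet_cases <- {
  e <- function(i, j) c(i, j)
  tri <- function(...) list(...)
  cases <- vector("list", 16)
  cases[[1 + 1]]  <- tri(list(e(1, 2), e(1, 3), e(1, 4)))
  cases[[2 + 1]]  <- tri(list(e(2, 1), e(2, 3), e(2, 4)))
  cases[[4 + 1]]  <- tri(list(e(3, 1), e(3, 2), e(3, 4)))
  cases[[8 + 1]]  <- tri(list(e(4, 1), e(4, 2), e(4, 3)))
  cases[[14 + 1]] <- cases[[1 + 1]]
  cases[[13 + 1]] <- cases[[2 + 1]]
  cases[[11 + 1]] <- cases[[4 + 1]]
  cases[[7 + 1]]  <- cases[[8 + 1]]
  cases[[3 + 1]]  <- tri(list(e(1, 3), e(1, 4), e(2, 4)),
                         list(e(1, 3), e(2, 4), e(2, 3)))
  cases[[5 + 1]]  <- tri(list(e(1, 2), e(1, 4), e(3, 4)),
                         list(e(1, 2), e(3, 4), e(3, 2)))
  cases[[9 + 1]]  <- tri(list(e(1, 2), e(1, 3), e(4, 3)),
                         list(e(1, 2), e(4, 3), e(4, 2)))
  cases[[6 + 1]]  <- tri(list(e(2, 1), e(2, 4), e(3, 4)),
                         list(e(2, 1), e(3, 4), e(3, 1)))
  cases[[10 + 1]] <- tri(list(e(2, 1), e(2, 3), e(4, 3)),
                         list(e(2, 1), e(4, 3), e(4, 1)))
  cases[[12 + 1]] <- tri(list(e(3, 1), e(3, 2), e(4, 2)),
                         list(e(3, 1), e(4, 2), e(4, 1)))
  cases
}

#' Extract the lumen surface mesh from a segmentation
#'
#' Triangulates the 0.5-level isosurface of the (optionally time-averaged)
#' mask after mild Gaussian smoothing, which removes voxelization
#' staircase artifacts so mesh area and node positions track the
#' underlying smooth surface. Only the largest connected component is
#' meshed; a second component holding more than `component_tol` of the
#' foreground is treated as a segmentation problem.
#'
#' @param mask a [lumen_mask()]
#' @param frame integer frame index, or `"average"` for the time-averaged
#'   occupancy (the default, matching how per-cycle surfaces are analysed).
#' @param smooth_sigma Gaussian smoothing SD in voxels (default 1).
#' @param level iso-level in the smoothed occupancy (default 0.5).
#' @param component_tol secondary components above this fraction of the
#'   foreground voxel count raise an error (default 0.1).
#' @return object of class `surface_mesh`: `nodes` (n x 3, world mm),
#'   `faces` (m x 3 node indices, outward-wound), `normals` (n x 3 unit
#'   outward vectors).
#' @export
extract_surface <- function(mask, frame = "average", smooth_sigma = 1,
                            level = 0.5, component_tol = 0.1) {
  stopifnot(inherits(mask, "lumen_mask"))
  occ <- if (identical(frame, "average")) mask_average(mask)
         else mask$frames[[frame]]
  if (sum(occ >= 0.5) == 0) stop("empty mask: no lumen voxels")
  bin <- array(as.integer(occ >= 0.5), dim(occ))
  comp <- largest_component(bin, component_tol = component_tol)
  occ <- occ * comp
  f <- gaussian_smooth3(occ, smooth_sigma)
  mt <- marching_tetrahedra(f, level, mask$spacing, mask$origin)
  if (nrow(mt$nodes) < 4) stop("mask too small to extract a surface")
  # outward normals / winding from the smoothed occupancy gradient
  g <- gradient3(f, mask$spacing)
  gn <- cbind(
    interp3(g[[1]], mt$nodes, mask$spacing, mask$origin),
    interp3(g[[2]], mt$nodes, mask$spacing, mask$origin),
    interp3(g[[3]], mt$nodes, mask$spacing, mask$origin)
  )
  normals <- normalize_rows(-gn)  # occupancy decreases outward
  faces <- orient_faces(mt$faces, mt$nodes, normals)
  structure(list(nodes = mt$nodes, faces = faces, normals = normals,
                 spacing = mask$spacing),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$nodes), "nodes,", nrow(x$faces),
      "faces, area", signif(mesh_area(x), 4), "mm^2\n")
  invisible(x)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `surface_mesh`
#' @export
mesh_area <- function(mesh) {
  a <- mesh$nodes[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$nodes[mesh$faces[, 2], , drop = FALSE]
  c_ <- mesh$nodes[mesh$faces[, 3], , drop = FALSE]
  sum(0.5 * sqrt(rowSums(cross_rows(b - a, c_ - a)^2)))
}

# flip faces whose geometric normal opposes the field-derived node normal
orient_faces <- function(faces, nodes, normals) {
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE]
  c_ <- nodes[faces[, 3], , drop = FALSE]
  fn <- cross_rows(b - a, c_ - a)
  ref <- (normals[faces[, 1], , drop = FALSE] +
          normals[faces[, 2], , drop = FALSE] +
          normals[faces[, 3], , drop = FALSE])
  flip <- rowSums(fn * ref) < 0
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  faces
}

#' Marching tetrahedra isosurface of a 3D scalar field
#' @return list(nodes, faces) with nodes in world mm
#' @noRd
marching_tetrahedra <- function(f, level, spacing, origin) {
  d <- dim(f)
  inside <- f > level
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # active cubes: corner in/out status differs
  sub <- function(a, dx, dy, dz)
    a[(1 + dx):(nx - 1 + dx), (1 + dy):(ny - 1 + dy), (1 + dz):(nz - 1 + dz)]
  s <- sub(inside, 0, 0, 0)
  cnt <- s + sub(inside, 1, 0, 0) + sub(inside, 1, 1, 0) + sub(inside, 0, 1, 0) +
    sub(inside, 0, 0, 1) + sub(inside, 1, 0, 1) + sub(inside, 1, 1, 1) +
    sub(inside, 0, 1, 1)
  act <- which(cnt > 0 & cnt < 8, arr.ind = TRUE)
  if (nrow(act) == 0) return(list(nodes = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))

  ngrid <- as.double(nx) * ny * nz
  gid_of <- function(i, j, k) (as.double(k) - 1) * (nx * ny) + (j - 1) * nx + i
  corner_gid <- matrix(0, nrow(act), 8)
  for (c in 1:8)
    corner_gid[, c] <- gid_of(act[, 1] + .cube_offsets[c, 1],
                              act[, 2] + .cube_offsets[c, 2],
                              act[, 3] + .cube_offsets[c, 3])
  fv <- matrix(f[corner_gid], nrow(act), 8)

  # collect all triangles as (edge gid pairs)
  tris_a1 <- tris_b1 <- tris_a2 <- tris_b2 <- tris_a3 <- tris_b3 <- list()
  for (t in seq_len(nrow(.tet_corners))) {
    tc <- .tet_corners[t, ]
    tg <- corner_gid[, tc, drop = FALSE]
    tf <- fv[, tc, drop = FALSE]
    caseid <- (tf[, 1] > level) + 2 * (tf[, 2] > level) +
      4 * (tf[, 3] > level) + 8 * (tf[, 4] > level)
    for (cs in which(!vapply(.tet_cases, is.null, TRUE)) - 1) {
      rows <- which(caseid == cs)
      if (!length(rows)) next
      for (tri in .tet_cases[[cs + 1]]) {
        tris_a1 <- c(tris_a1, list(tg[rows, tri[[1]][1]]))
        tris_b1 <- c(tris_b1, list(tg[rows, tri[[1]][2]]))
        tris_a2 <- c(tris_a2, list(tg[rows, tri[[2]][1]]))
        tris_b2 <- c(tris_b2, list(tg[rows, tri[[2]][2]]))
        tris_a3 <- c(tris_a3, list(tg[rows, tri[[3]][1]]))
        tris_b3 <- c(tris_b3, list(tg[rows, tri[[3]][2]]))
      }
    }
  }
  ea <- cbind(unlist(tris_a1), unlist(tris_a2), unlist(tris_a3))
  eb <- cbind(unlist(tris_b1), unlist(tris_b2), unlist(tris_b3))
  if (!length(ea)) return(list(nodes = matrix(0, 0, 3), faces = matrix(0L, 0, 3)))

  # deduplicate edge-intersection vertices via ordered-pair keys
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- lo * ngrid + hi
  ukey <- unique(as.vector(key))
  vid <- matrix(match(key, ukey), nrow(ea), 3)
  ulo <- floor((ukey - 1) / ngrid)  # keys stay below 2^53, exact in doubles
  uhi <- ukey - ulo * ngrid
  gid_to_ijk <- function(g) {
    g0 <- g - 1
    k <- floor(g0 / (nx * ny))
    rem <- g0 - k * (nx * ny)
    j <- floor(rem / nx)
    i <- rem - j * nx
    cbind(i + 1, j + 1, k + 1)
  }
  pa <- gid_to_ijk(ulo); pb <- gid_to_ijk(uhi)
  fa <- f[cbind(pa[, 1], pa[, 2], pa[, 3])]
  fb <- f[cbind(pb[, 1], pb[, 2], pb[, 3])]
  tt <- (level - fa) / (fb - fa)
  tt[!is.finite(tt)] <- 0.5
  tt <- pmin(pmax(tt, 0), 1)
  idx <- pa + tt * (pb - pa)  # continuous 1-based voxel coords
  nodes <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")
  # drop degenerate triangles (two identical vertices)
  keep <- vid[, 1] != vid[, 2] & vid[, 1] != vid[, 3] & vid[, 2] != vid[, 3]
  list(nodes = nodes, faces = vid[keep, , drop = FALSE])
}

#' Largest 6-connected component of a binary array
#'
#' @param bin integer 0/1 array
#' @param component_tol error if a secondary component exceeds this
#'   fraction of foreground voxels; `Inf` disables the check
#' @return 0/1 array keeping only the largest component
#' @noRd
largest_component <- function(bin, component_tol = Inf) {
  lab <- array(0L, dim(bin))
  remaining <- bin > 0
  comp_sizes <- integer(0)
  cur <- 0L
  while (any(remaining)) {
    cur <- cur + 1L
    seedpos <- which(remaining)[1]
    frontier <- array(FALSE, dim(bin))
    frontier[seedpos] <- TRUE
    member <- frontier
    while (any(frontier)) {
      grown <- dilate6(frontier)
      frontier <- grown & remaining & !member
      member <- member | frontier
    }
    lab[member] <- cur
    remaining <- remaining & !member
    comp_sizes[cur] <- sum(member)
  }
  if (cur == 0L) return(array(0L, dim(bin)))
  big <- which.max(comp_sizes)
  if (cur > 1L && is.finite(component_tol)) {
    second <- max(comp_sizes[-big])
    if (second > component_tol * sum(comp_sizes))
      stop("segmentation has multiple large connected components")
  }
  array(as.integer(lab == big), dim(bin))
}

# one step of 6-neighborhood binary dilation
dilate6 <- function(a) {
  d <- dim(a)
  out <- a
  out[-1, , ] <- out[-1, , ] | a[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | a[-1, , ]
  out[, -1, ] <- out[, -1, ] | a[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | a[, -1, ]
  out[, , -1] <- out[, , -1] | a[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | a[, , -1]
  out
}

#' Write a surface mesh as ASCII PLY
#' @param mesh a `surface_mesh`
#' @param path output file
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "ply", "format ascii 1.0",
    paste("element vertex", nrow(mesh$nodes)),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    paste("element face", nrow(mesh$faces)),
    "property list uchar int vertex_indices", "end_header"
  ), con)
  utils::write.table(format(cbind(mesh$nodes, mesh$normals), digits = 8,
                            trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
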