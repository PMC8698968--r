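# Surface extraction, centerline, extent normalization, wall frames.

test_that("cylinder surface nodes sit at the analytic radius within one voxel", {
  fx <- fixture_cylinder()
  mid <- fx$mesh$nodes[, 1] > 1 & fx$mesh$nodes[, 1] < 8
  r <- sqrt(fx$mesh$nodes[mid, 2]^2 + fx$mesh$nodes[mid, 3]^2)
  expect_true(all(abs(r - 0.6) <= 0.1))
  # outward normals: radial component positive away from the axis
  nr <- rowSums(fx$mesh$normals[mid, 2:3] *
                  cbind(fx$mesh$nodes[mid, 2], fx$mesh$nodes[mid, 3]) /
                  pmax(r, 1e-9))
  expect_true(all(nr > 0.8))
})

test_that("empty and multi-component masks are rejected", {
  m0 <- lumen_mask(array(0L, c(8, 8, 8)), spacing = rep(0.1, 3))
  expect_error(extract_surface(m0), "empty")
  two <- array(0L, c(20, 8, 8))
  two[2:8, 3:6, 3:6] <- 1L
  two[12:18, 3:6, 3:6] <- 1L
  expect_error(extract_surface(lumen_mask(two, rep(0.1, 3))),
               "multiple large connected components")
})

test_that("sphere mesh area is within 5% of the closed form", {
  h <- 0.1; r0 <- 1
  n <- 27
  ax <- (seq_len(n) - 1) * h - (n - 1) * h / 2
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  sph <- array(as.integer(sqrt(X^2 + Y^2 + Z^2) < r0), c(n, n, n))
  mesh <- extract_surface(lumen_mask(sph, rep(h, 3)))
  expect_lt(abs(mesh_area(mesh) / (4 * pi * r0^2) - 1), 0.05)
})

test_that("cylinder centerline recovers the axis and total length", {
  spec <- phantom_spec("straight_cylinder", radius = 0.6, length = 7,
                       voxel_size = 0.1, n_frames = 1)
  ph <- generate_phantom(spec)
  cl <- extract_centerline(ph$mask)
  dev <- sqrt(rowSums(cl$points[, 2:3, drop = FALSE]^2))
  expect_lt(max(dev), 0.05)                     # within half a voxel
  expect_lt(abs(max(cl$arc) - 7), 0.2)
  expect_true(all(diff(cl$arc) > 0))            # arc strictly increasing
  expect_true(all(abs(sqrt(rowSums(cl$tangents^2)) - 1) < 1e-9))
})

test_that("arch centerline arc length matches the analytic semicircle", {
  spec <- phantom_spec("torus_arch", radius = 0.6, arch_radius = 1.5,
                       voxel_size = 0.1, n_frames = 1)
  ph <- generate_phantom(spec)
  cl <- extract_centerline(ph$mask)
  expect_lt(abs(max(cl$arc) / (pi * 1.5) - 1), 0.05)
  rho <- sqrt(cl$points[, 1]^2 + cl$points[, 3]^2)
  dev <- sqrt((rho - 1.5)^2 + cl$points[, 2]^2)
  expect_lt(max(dev), 0.2)  # two voxels off the analytic circle at worst
})

test_that("degenerate masks are rejected by centerline extraction", {
  one <- array(0L, c(8, 8, 8)); one[4, 4, 4] <- 1L
  expect_error(extract_centerline(lumen_mask(one, rep(0.1, 3))),
               "degenerate")
})

test_that("re-extraction from the voxelized analysis window is stable", {
  fx <- fixture_cylinder()
  arc1 <- max(fx$cl$arc)
  cropped <- crop_mask_to_extent(fx$ph$mask, fx$cl,
                                 z_min = 1, z_max = arc1 - 1)
  cl2 <- extract_centerline(cropped)
  expect_lt(abs(max(cl2$arc) / (arc1 - 2) - 1), 0.05)
})

test_that("normalize_extent crops to the 7 mm landmark window and re-zeroes arc", {
  spec <- phantom_spec("straight_cylinder", radius = 0.6, length = 10,
                       voxel_size = 0.1, n_frames = 1)
  ph <- generate_phantom(spec)
  mesh <- extract_surface(ph$mask)
  cl <- extract_centerline(ph$mask)
  ne <- normalize_extent(cl, mesh, landmark_z = 5, prox_mm = 3, dist_mm = 4)
  expect_equal(max(ne$centerline$arc), 7, tolerance = 1e-6)
  expect_equal(min(ne$centerline$arc), 0)
  pos <- node_arc_positions(ne$mesh, ne$centerline)
  expect_true(all(pos$z >= -1e-6 & pos$z <= 7 + 1e-6))
  # landmark too close to the proximal end
  expect_error(normalize_extent(cl, mesh, landmark_z = 1, prox_mm = 3),
               "exceeds the centerline range")
  # clipping again relative to the new coordinates is idempotent
  ne2 <- normalize_extent(ne$centerline, ne$mesh, landmark_z = 3,
                          prox_mm = 3, dist_mm = 4)
  expect_equal(ne2$centerline$arc, ne$centerline$arc)
  expect_equal(nrow(ne2$mesh$nodes), nrow(ne$mesh$nodes))
})

test_that("wall frames are orthonormal and right-handed at every node", {
  fx <- fixture_cylinder()
  fr <- fx$frames
  expect_true(all(abs(rowSums(fr$l_hat * fr$r_hat)) < 1e-6))
  expect_true(all(abs(rowSums(fr$l_hat * fr$c_hat)) < 1e-6))
  expect_true(all(abs(rowSums(fr$c_hat * fr$r_hat)) < 1e-6))
  for (m in list(fr$l_hat, fr$c_hat, fr$r_hat))
    expect_true(all(abs(sqrt(rowSums(m^2)) - 1) < 1e-6))
  expect_true(all(abs(archflow:::cross_rows(fr$l_hat, fr$r_hat) - fr$c_hat) < 1e-6))
})

test_that("cylinder theta equals the analytic azimuth about the axis", {
  fx <- fixture_cylinder()
  nodes <- fx$ne$mesh$nodes
  r <- sqrt(nodes[, 2]^2 + nodes[, 3]^2)
  ok <- r > 0.2  # azimuth ill-defined near the axis
  az <- (atan2(nodes[ok, 3], nodes[ok, 2]) * 180 / pi) %% 360
  dth <- abs((fx$frames$theta[ok] - az + 180) %% 360 - 180)
  expect_lt(max(dth), 2)
})

test_that("arch theta follows the anatomical convention (outer 90, inner 270)", {
  spec <- phantom_spec("torus_arch", radius = 0.6, arch_radius = 1.5,
                       voxel_size = 0.1, n_frames = 1, v_max_axial = 100)
  ph <- generate_phantom(spec)
  mesh <- extract_surface(ph$mask)
  cl <- orient_by_flow(extract_centerline(ph$mask), ph$velocity, ph$mask)
  fr <- build_wall_frames(mesh, cl, reference = c(0, 1, 0))
  rho <- sqrt(mesh$nodes[, 1]^2 + mesh$nodes[, 3]^2)
  top <- mesh$nodes[, 3] > 0.5 & abs(mesh$nodes[, 2]) < 0.15
  outer_n <- which(rho > 1.95 & top)
  inner_n <- which(rho < 1.05 & top)
  post_n <- which(mesh$nodes[, 2] > 0.45 & abs(rho - 1.5) < 0.2 &
                    mesh$nodes[, 3] > 0.5)
  expect_lt(abs(median(fr$theta[outer_n]) - 90), 10)
  expect_lt(abs(median(fr$theta[inner_n]) - 270), 10)
  dpost <- abs((fr$theta[post_n] + 180) %% 360 - 180)
  expect_lt(median(dpost), 30)
})

test_that("radial axis points from node toward the centerline (inward positive)", {
  fx <- fixture_cylinder()
  nodes <- fx$ne$mesh$nodes
  inward <- -cbind(0, nodes[, 2], nodes[, 3])
  agree <- rowSums(fx$frames$r_hat * archflow:::normalize_rows(inward))
  r <- sqrt(nodes[, 2]^2 + nodes[, 3]^2)
  expect_true(all(agree[r > 0.2] > 0.95))
})
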