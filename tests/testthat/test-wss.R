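# WSS vectors from velocity gradients, component decomposition, OSI.

test_that("deformation tensor vanishes for a uniform velocity field", {
  vel <- make_uniform_field(c(20, -7, 4))
  eps <- deformation_tensor_at(node = c(0.8, 0.8, 0.8),
                               normal = c(0, 1, 0), vel)
  expect_lt(max(abs(eps)), 1e-9)
})

test_that("planar shear v_x = k y yields eps_xy = k/2 and tau = 2 eta eps n", {
  k <- 100  # 1/s
  vel <- make_shear_field(k)
  eps <- deformation_tensor_at(node = c(0.8, 0.9, 0.8),
                               normal = c(0, 1, 0), vel)
  expect_equal(eps[1, 2], k / 2, tolerance = 1e-6)
  expect_equal(eps[2, 1], k / 2, tolerance = 1e-6)
  expect_lt(max(abs(eps[-c(2, 4)])), 1e-6)
  expect_equal(eps, t(eps))
  tau <- wss_vector(eps, c(0, 1, 0), eta = 0.004)
  expect_equal(tau, c(0.4, 0, 0), tolerance = 1e-6)
})

test_that("rigid rotation has zero deformation (antisymmetric gradient cancels)", {
  vel <- make_rotation_field(c(0, 0, 50))
  eps <- deformation_tensor_at(node = c(0.75, 0.75, 0.75),
                               normal = c(1, 0, 0), vel)
  expect_lt(max(abs(eps)), 1e-6)
})

test_that("wss_vector validates inputs and handles the zero tensor", {
  expect_equal(wss_vector(matrix(0, 3, 3), c(1, 0, 0)), c(0, 0, 0))
  expect_error(wss_vector(matrix(0, 3, 3), c(1, 1, 0)), "unit length")
  expect_error(wss_vector(matrix(0, 3, 3), c(1, 0, 0), eta = 0))
})

test_that("temporal average is the frame-wise vector mean", {
  const <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  expect_equal(temporal_average(const), c(1, 2, 3))
  alt <- rbind(matrix(rep(c(1, 0, 0), 10), 10, 3, byrow = TRUE),
               matrix(rep(c(-1, 0, 0), 10), 10, 3, byrow = TRUE))
  expect_equal(temporal_average(alt), c(0, 0, 0))
  m <- rbind(matrix(rep(c(1, 0, 0), 15), 15, 3, byrow = TRUE),
             matrix(rep(c(-1, 0, 0), 5), 5, 3, byrow = TRUE))
  expect_equal(temporal_average(m), c(0.5, 0, 0))
})

test_that("OSI matches closed-form cases and stays within [0, 50] under fuzzing", {
  a <- c(0.7, -0.2, 0.1)
  const <- matrix(rep(a, 20), 20, 3, byrow = TRUE)
  expect_equal(osi(const), 0)
  bal <- rbind(matrix(rep(a, 10), 10, 3, byrow = TRUE),
               matrix(rep(-a, 10), 10, 3, byrow = TRUE))
  expect_equal(osi(bal), 50)
  split <- rbind(matrix(rep(a, 15), 15, 3, byrow = TRUE),
                 matrix(rep(-a, 5), 5, 3, byrow = TRUE))
  expect_equal(osi(split), 25)  # 0.5 (1 - 10|a|/20|a|) * 100
  expect_equal(osi(matrix(0, 20, 3)), 0)  # no flow: non-oscillatory
  expect_error(osi(matrix(1, 1, 3)), "at least 2 frames")
  set.seed(42)
  for (i in 1:1000) {
    m <- matrix(rnorm(3 * sample(2:30, 1)), ncol = 3)
    v <- osi(m)
    expect_true(v >= 0 && v <= 50)
  }
})

test_that("decomposition projects onto the frame and conserves the norm", {
  fx <- fixture_cylinder()
  fr <- fx$frames
  n <- length(fr$node_id)
  # tau parallel to l_hat
  tau <- 2 * fr$l_hat
  d <- decompose_wss(tau, fr)
  expect_equal(d$long_wss, rep(2, n), tolerance = 1e-9)
  expect_equal(d$circ_wss, rep(0, n), tolerance = 1e-9)
  # tau toward the centerline: positive radial strain
  d2 <- decompose_wss(0.5 * fr$r_hat, fr)
  expect_true(all(d2$rad_strain > 0.499))
  # Parseval for random vectors
  set.seed(7)
  tau3 <- matrix(rnorm(3 * n), n, 3)
  d3 <- decompose_wss(tau3, fr)
  lhs <- d3$long_wss^2 + d3$circ_wss^2 + d3$rad_strain^2
  expect_lt(max(abs(lhs - rowSums(tau3^2)) / rowSums(tau3^2)), 1e-9)
})

test_that("Poiseuille phantom wall |tau| matches 2 eta v_max / R within 10%", {
  fx <- fixture_cylinder()
  ws <- compute_wall_shear(fx$ph$velocity, fx$ph$mask, fx$ne$mesh)
  mag <- sqrt(rowSums(ws$tau_mean^2))
  expect_lt(abs(mean(mag[ws$valid]) / 13.3333 - 1), 0.1)
  # direction: along +x (flow direction) at the wall
  dirs <- ws$tau_mean[ws$valid, ] / mag[ws$valid]
  expect_gt(median(dirs[, 1]), 0.97)
})

test_that("WSS scales linearly with the velocity field", {
  fx <- fixture_cylinder()
  vel2 <- fx$ph$velocity
  for (k in seq_len(vel2$n_frames))
    vel2$frames[[k]] <- lapply(vel2$frames[[k]], function(a) 2 * a)
  ws1 <- compute_wall_shear(fx$ph$velocity, fx$ph$mask, fx$ne$mesh)
  ws2 <- compute_wall_shear(vel2, fx$ph$mask, fx$ne$mesh)
  expect_equal(ws2$tau_mean, 2 * ws1$tau_mean, tolerance = 1e-12)
})

test_that("helical phantom: circumferential and longitudinal components match their oracles", {
  spec <- phantom_spec("straight_cylinder", radius = 0.6, length = 9,
                       voxel_size = 0.1, n_frames = 1, v_max_axial = 100,
                       helical_v_c = 50)
  ph <- generate_phantom(spec)
  mesh <- extract_surface(ph$mask)
  cl <- orient_by_flow(extract_centerline(ph$mask), ph$velocity, ph$mask)
  ne <- normalize_extent(cl, mesh, landmark_z = 4, prox_mm = 3, dist_mm = 4)
  fr <- build_wall_frames(ne$mesh, ne$centerline)
  ws <- compute_wall_shear(ph$velocity, ph$mask, ne$mesh)
  d <- decompose_wss(ws$tau_mean, fr)
  expect_lt(abs(mean(abs(d$circ_wss[ws$valid])) / 3.3333 - 1), 0.15)
  expect_lt(abs(mean(d$long_wss[ws$valid]) / 13.3333 - 1), 0.1)
})

test_that("nodes with insufficient in-lumen support are flagged invalid", {
  vel <- make_uniform_field(c(10, 0, 0), n = 12)
  # mask only a thin slab: nodes above it cannot gather enough samples
  m <- array(0L, c(12, 12, 12)); m[, , 5:6] <- 1L
  mask <- lumen_mask(m, rep(0.1, 3))
  mesh <- structure(list(nodes = matrix(c(0.6, 0.6, 1.05), 1, 3),
                         faces = matrix(integer(0), 0, 3),
                         normals = matrix(c(0, 0, 1), 1, 3),
                         spacing = rep(0.1, 3)), class = "surface_mesh")
  ws <- compute_wall_shear(vel, mask, mesh)
  expect_false(ws$valid[1])
  expect_true(all(is.na(ws$tau[1, , 1])))
  expect_error(deformation_tensor_at(c(0.6, 0.6, 1.05), c(0, 0, 1), vel,
                                     mask = mask),
               "too few in-lumen samples")
})
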