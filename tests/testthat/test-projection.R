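# (z, theta) projection maps: interpolation accuracy, periodicity,
# alignment, strip extraction.

test_that("analytic wall field sin(theta) z is reconstructed with small RMSE", {
  fx <- fixture_cylinder()
  fr <- fx$frames
  f <- sin(fr$theta * pi / 180) * fr$z
  mp <- project_to_map(f, fr, theta_step = 2, z_step = 0.02, z_range = c(0, 7))
  truth <- outer(mp$grid_z, sin(mp$grid_theta * pi / 180))
  err <- (mp$values - truth)[mp$valid]
  expect_lt(sqrt(mean(err^2)) / diff(range(truth)), 0.02)
  expect_gt(mean(mp$valid), 0.95)
})

test_that("a constant field maps to exactly that constant on valid cells", {
  fx <- fixture_cylinder()
  mp <- project_to_map(rep(2.5, length(fx$frames$node_id)), fx$frames,
                       theta_step = 2, z_step = 0.02, z_range = c(0, 7))
  expect_equal(max(abs(mp$values[mp$valid] - 2.5)), 0)
})

test_that("default grid steps are 0.5 degrees and 1 um", {
  fx <- fixture_cylinder()
  f <- fx$frames$z
  mp <- project_to_map(f, fx$frames, z_range = c(0, 1))
  expect_equal(mp$grid_theta[2] - mp$grid_theta[1], 0.5)
  expect_equal(mp$grid_z[2] - mp$grid_z[1], 0.001)
  expect_equal(length(mp$grid_theta), 720)
})

test_that("theta periodicity: shifting node angles by 360 leaves the map unchanged", {
  fx <- fixture_cylinder()
  fr <- fx$frames
  f <- cos(fr$theta * pi / 180) + 0.1 * fr$z
  m1 <- project_to_map(f, fr, theta_step = 2, z_step = 0.05, z_range = c(0, 7))
  fr2 <- fr
  fr2$theta <- fr$theta + 360
  m2 <- project_to_map(f, fr2, theta_step = 2, z_step = 0.05, z_range = c(0, 7))
  expect_equal(m1$values, m2$values)
})

test_that("project -> sample back reproduces node values", {
  fx <- fixture_cylinder()
  fr <- fx$frames
  f <- sin(fr$theta * pi / 180) * fr$z
  mp <- project_to_map(f, fr, theta_step = 1, z_step = 0.01, z_range = c(0, 7))
  back <- sample_map(mp, fr$z, fr$theta)
  ok <- is.finite(back)
  rmse <- sqrt(mean((back[ok] - f[ok])^2))
  expect_lt(rmse / diff(range(f)), 0.05)
})

test_that("fewer than 3 valid nodes is an error", {
  fx <- fixture_cylinder()
  vals <- rep(NA_real_, length(fx$frames$node_id))
  vals[1:2] <- 1
  expect_error(project_to_map(vals, fx$frames), "fewer than 3")
})

test_that("align_maps shifts landmark rows into correspondence", {
  mk <- function(zmax) {
    gz <- seq(0, zmax, by = 0.02)
    gt <- seq(0, 358, by = 2)
    vals <- outer(gz, rep(1, length(gt)))  # value = z
    structure(list(values = vals, valid = vals > -1, grid_z = gz,
                   grid_theta = gt), class = "projection_map")
  }
  m1 <- mk(9); m2 <- mk(9)
  al <- align_maps(list(m1, m2), landmark_zs = c(4, 4.5),
                   prox_mm = 3, dist_mm = 4)
  expect_identical(dim(al[[1]]$values), dim(al[[2]]$values))
  # the aligned value fields are the source z values shifted by the
  # landmark offset: al2 - al1 = 0.5 everywhere
  expect_equal(al[[2]]$values - al[[1]]$values,
               matrix(0.5, nrow(al[[1]]$values), ncol(al[[1]]$values)),
               tolerance = 1e-9)
  # maps already aligned: output equals the window of the input
  expect_equal(al[[1]]$values[1, 1], 1)  # z = landmark - 3
  expect_error(align_maps(list(m1), landmark_zs = 1, prox_mm = 3),
               "exceeds")
})

test_that("strip extraction averages the requested wedge", {
  gz <- seq(0, 2, by = 0.02)
  gt <- seq(0, 359, by = 1)
  const <- structure(list(values = matrix(3, length(gz), length(gt)),
                          valid = matrix(TRUE, length(gz), length(gt)),
                          grid_z = gz, grid_theta = gt),
                     class = "projection_map")
  expect_equal(extract_strip(const, 270, 30), 3)
  ind <- const
  band <- abs((gt - 270 + 180) %% 360 - 180) <= 30
  ind$values <- outer(rep(1, length(gz)), ifelse(band, 1, 0))
  expect_equal(extract_strip(ind, 270, 30), 1)
  ramp <- const
  ramp$values <- outer(gz, rep(1, length(gt)))  # linear in z
  expect_equal(extract_strip(ramp, 90, 20, z_range = c(0, 2)), 1,
               tolerance = 1e-9)  # midpoint of the ramp
  empty <- const
  empty$valid[] <- FALSE
  expect_error(extract_strip(empty, 270, 30), "no valid cells")
})

test_that("coarsening averages valid cells and preserves constants", {
  gz <- seq(0, 1, by = 0.01)
  gt <- seq(0, 358, by = 2)
  m <- structure(list(values = matrix(4, length(gz), length(gt)),
                      valid = matrix(TRUE, length(gz), length(gt)),
                      grid_z = gz, grid_theta = gt),
                 class = "projection_map")
  cm <- coarsen_map(m, 10L, 4L)
  expect_true(all(cm$values[cm$valid] == 4))
  expect_equal(length(cm$grid_z), length(gz) %/% 10)
})

test_that("map CSV round trip preserves values and grid", {
  fx <- fixture_cylinder()
  f <- fx$frames$z * 0.3
  mp <- project_to_map(f, fx$frames, theta_step = 4, z_step = 0.1,
                       z_range = c(0, 7))
  path <- tempfile(fileext = ".csv")
  write_map(mp, path)
  mp2 <- read_map(path)
  expect_equal(mp2$values[mp2$valid], mp$values[mp$valid], tolerance = 1e-7)
  expect_equal(mp2$grid_theta, mp$grid_theta)
  expect_equal(mp2$grid_z, mp$grid_z, tolerance = 1e-9)
})
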