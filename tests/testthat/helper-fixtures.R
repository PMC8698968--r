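# Shared fixtures, built once per test run. Sizes are kept small: the
# suite favors short cylinders at 100 um and checks finer resolutions
# only in the dedicated accuracy tests.

# steady Poiseuille cylinder with mesh, centerline and analysis window
fixture_cylinder <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- phantom_spec("straight_cylinder", radius = 0.6, length = 9,
                         voxel_size = 0.1, n_frames = 1,
                         v_max_axial = 100, waveform = "steady")
    ph <- generate_phantom(spec)
    mesh <- extract_surface(ph$mask)
    cl <- orient_by_flow(extract_centerline(ph$mask), ph$velocity, ph$mask)
    ne <- normalize_extent(cl, mesh, landmark_z = 4, prox_mm = 3, dist_mm = 4)
    frames <- build_wall_frames(ne$mesh, ne$centerline)
    cache <<- list(spec = spec, ph = ph, mesh = mesh, cl = cl,
                   ne = ne, frames = frames)
    cache
  }
})

# uniform-velocity field filling the whole array (for gradient tests)
make_uniform_field <- function(v = c(10, -5, 3), n = 16, h = 0.1,
                               n_frames = 1) {
  mk <- function(val) array(val, c(n, n, n))
  frames <- replicate(n_frames, list(mk(v[1]), mk(v[2]), mk(v[3])),
                      simplify = FALSE)
  velocity_field(frames, spacing = rep(h, 3))
}

# planar shear v_x = k * y (k in 1/s); velocities stored in cm/s
make_shear_field <- function(k = 100, n = 16, h = 0.1) {
  yw <- (seq_len(n) - 1) * h  # mm
  vx <- array(rep(0.1 * k * yw, each = n), c(n, n, n))  # cm/s = 0.1*k*y_mm
  z0 <- array(0, c(n, n, n))
  velocity_field(list(list(vx, z0, z0)), spacing = rep(h, 3))
}

# rigid rotation v = omega x x about the domain center
make_rotation_field <- function(omega = c(0, 0, 50), n = 16, h = 0.1) {
  ax <- (seq_len(n) - 1) * h - (n - 1) * h / 2
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  # v (m/s) = omega x r (r in m); store cm/s: 100 * omega x (r_mm/1000)
  f <- 0.1
  vx <- f * (omega[2] * Z - omega[3] * Y)
  vy <- f * (omega[3] * X - omega[1] * Z)
  vz <- f * (omega[1] * Y - omega[2] * X)
  velocity_field(list(list(vx, vy, vz)), spacing = rep(h, 3))
}

# numerical derivative of a radial profile at the wall (independent
# oracle for the analytic WSS truth values)
numeric_wall_shear <- function(profile, R, eta, delta = 1e-6) {
  -eta * (profile(R) - profile(R - delta)) / (delta * 1e-3)  # Pa (SI)
}
# four-animal phantom manifest for pipeline-level tests
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mk <- function(v_max, seed) generate_phantom(
      phantom_spec("straight_cylinder", radius = 0.6, length = 9,
                   voxel_size = 0.1, n_frames = 6, v_max_axial = v_max,
                   waveform = "half_sine_pulse", noise_sd = 1, seed = seed))
    objects <- list(
      a1 = mk(100, 11), a2 = mk(100, 12),
      b1 = mk(70, 13), b2 = mk(70, 14))
    objects <- lapply(objects, function(p)
      list(velocity = p$velocity, mask = p$mask))
    manifest <- data.frame(animal = c("a1", "a2", "b1", "b2"),
                           group = c("ctrl", "ctrl", "dis", "dis"))
    cfg <- pipeline_config(grid_theta_step = 2, grid_z_step = 0.02,
                           seed = 5L)
    cache <<- list(objects = objects, manifest = manifest, cfg = cfg)
    cache
  }
})
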