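# Ermak-McCammon propagation: start sampling, noise laws, drift, torques,
# trajectory and ensemble contracts

test_that("start poses live on the truncated b-sphere with uniform cap z", {
  params <- bd_params()
  set.seed(4)
  zs <- numeric(500)
  for (i in 1:500) {
    st <- sample_start(params)
    expect_equal(sqrt(sum(st$position^2)), 100, tolerance = 1e-9)
    expect_gt(st$position[3], 60)
    expect_equal(sum(st$orientation^2), 1, tolerance = 1e-9)
    zs[i] <- st$position[3]
  }
  # Archimedes: area-uniform on the cap means z ~ U(60, 100)
  ks <- suppressWarnings(ks.test(zs, "punif", 60, 100))
  expect_gt(ks$p.value, 0.01)
})

test_that("random orientations give the sin(theta) axis distribution", {
  set.seed(8)
  cosang <- replicate(10000, {
    u <- quat_rotate(quat_random(), c(0, 0, 1))
    u[3]
  })
  # axis angle density ~ sin(theta) <=> cos(theta) ~ U(-1, 1)
  ks <- suppressWarnings(ks.test(cosang, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("free-diffusion translational noise follows <|dr|^2> = 6 D dt", {
  p <- toy_ph()
  Dt <- p$D_trans * 1e4               # A^2/ps
  dt <- 10
  params <- bd_params(dt_near = dt, dt_far = dt, dt_switch_height = -1e9,
                      max_time = dt, sample_interval = dt, q_radius = 1e9)
  set.seed(42)
  n <- 20000
  msd <- 0
  st0 <- bd_state(c(0, 0, 1000))
  for (i in seq_len(n)) {
    st <- bd_step(st0, p, NULL, params)
    msd <- msd + sum((st$position - st0$position)^2)
  }
  expect_equal(msd / n, 6 * Dt * dt, tolerance = 0.02)
})

test_that("rotational free diffusion decays the axis autocorrelation", {
  p <- toy_ph()
  Dr <- p$D_rot / 1e12                # rad^2/ps
  dt <- 400
  nstep <- 13                         # t up to ~1/(2 D_rot)
  params <- bd_params(dt_near = dt, dt_far = dt, dt_switch_height = -1e9,
                      max_time = dt, sample_interval = dt, q_radius = 1e9)
  set.seed(9)
  nrep <- 600
  acc <- matrix(0, nrep, nstep)
  for (r in seq_len(nrep)) {
    st <- bd_state(c(0, 0, 1000))
    u0 <- quat_rotate(st$orientation, c(0, 0, 1))
    for (k in seq_len(nstep)) {
      st <- bd_step(bd_state(c(0, 0, 1000), st$orientation), p, NULL, params)
      acc[r, k] <- sum(quat_rotate(st$orientation, c(0, 0, 1)) * u0)
    }
  }
  t <- dt * seq_len(nstep)
  keep <- t <= 1 / (2 * Dr)
  expect_true(any(keep))
  # fitted decay rate of <u(0).u(t)> = exp(-2 D_rot t) within 5%
  cbar <- colMeans(acc)[keep]
  w <- cbar^2 / (1 - cbar^2)          # inverse variance of log(cbar)
  rate <- -coef(lm(log(cbar) ~ 0 + t[keep], weights = w))[[1]]
  expect_equal(rate, 2 * Dr, tolerance = 0.05)
})

test_that("deterministic drift and dipole alignment in a linear field", {
  p <- toy_ph()                        # +8 e, p_z = 40 e A
  Dt <- p$D_trans * 1e4
  c0 <- -0.02                          # Phi = c z, downhill for a cation
  dims <- c(31, 31, 61)
  org <- c(-15, -15, 900)
  z <- org[3] + rep(0:60, each = 31 * 31)
  gz <- steerBD:::.new_grid(array(c0 * z, dims), org, 1, dims, "potential")
  st <- bd_state(c(0, 0, 930))
  ft <- compute_force_torque(st, p, gz)
  expect_equal(ft$force, c(0, 0, -8 * c0), tolerance = 1e-6)
  params <- bd_params(dt_near = 10, dt_far = 10, dt_switch_height = -1e9,
                      max_time = 10, sample_interval = 10, q_radius = 1e9,
                      noise_scale = 0)
  st1 <- bd_step(st, p, gz, params)
  expect_equal(st1$position[3] - st$position[3], Dt * (-8 * c0) * 10,
               tolerance = 1e-6)
  expect_equal(st1$position[1:2], st$position[1:2], tolerance = 1e-9)

  # torque on a tilted dipole in a uniform field E = -grad(Phi) = (0,0,-c0):
  # T = p x E, perpendicular to both dipole and z; FD matches within 1%
  q45 <- c(cos(pi / 8), sin(pi / 8), 0, 0)  # dipole tilted 45 deg about x
  st45 <- bd_state(c(0, 0, 930), q45)
  ft45 <- compute_force_torque(st45, p, gz, delta_trans = 0.2, delta_rot = 0.5)
  p_lab <- quat_rotate(q45, c(0, 0, 40))    # dipole in lab frame, e A
  E <- c(0, 0, -c0)
  T_exact <- c(p_lab[2] * E[3] - p_lab[3] * E[2],
               p_lab[3] * E[1] - p_lab[1] * E[3],
               p_lab[1] * E[2] - p_lab[2] * E[1])
  expect_equal(ft45$torque, T_exact, tolerance = 0.01)
  expect_lt(abs(sum(ft45$torque * p_lab)), 1e-6 * sqrt(sum(T_exact^2)))
  expect_lt(abs(ft45$torque[3]), 1e-6 + 1e-6 * sqrt(sum(T_exact^2)))

  # noise off: dipole-z angle strictly decreases step over step
  st <- st45
  ang <- function(s) acos(-quat_rotate(s$orientation, c(0, 0, 1))[3])
  # field pushes p toward +z here (E_z > 0 since c0 < 0): angle to +z shrinks
  a_prev <- acos(quat_rotate(st$orientation, c(0, 0, 1))[3])
  for (k in 1:5) {
    st <- bd_step(st, p, gz, params)
    a_new <- acos(quat_rotate(st$orientation, c(0, 0, 1))[3])
    expect_lt(a_new, a_prev)
    a_prev <- a_new
  }
})

test_that("finite-difference force matches the analytic DH gradient", {
  b <- small_patch()
  keep <- b$pip3_index
  b$sites <- b$sites[keep, , drop = FALSE]  # single -7 e source at (0,0,20)
  b$pip3_index <- 1
  g <- compute_potential_grid(b, spacing = 0.5, xy_half = 15, z_range = c(25, 55))
  src <- as.matrix(b$sites[, c("x", "y", "z")])
  p1 <- load_structure(c(
    "ATOM      1  Q   ION A   1       0.000   0.000   0.000   1.0000  1.000"),
    "file")                                  # unit point charge
  st <- bd_state(c(0, 0, 40))                # 20 A above the source
  ft <- compute_force_torque(st, p1, g, delta_trans = 1, delta_rot = 1)
  F_exact <- -dh_oracle_grad(src, b$sites$charge, st$position, g$kappa_inv)
  expect_equal(ft$force, F_exact, tolerance = 0.01)
})

test_that("trajectory contracts: timeout, determinism, strong capture", {
  p <- toy_ph()
  b <- small_patch()
  g <- small_grid(b)
  params <- small_params(max_time = 0)
  set.seed(1)
  tr <- run_trajectory(p, b, g, params)
  expect_equal(nrow(tr$samples), 1)
  expect_equal(tr$termination, "timeout")

  params <- small_params(max_time = 5000, seed = 3)
  set.seed(31); tr1 <- run_trajectory(p, b, g, params)
  set.seed(31); tr2 <- run_trajectory(p, b, g, params)
  expect_identical(tr1$samples, tr2$samples)
  expect_identical(tr1$termination, tr2$termination)

  # strong attraction, damped noise: nearly every trajectory encounters
  ba <- assign_charges(small_patch(),
                       charge_scheme("fractional", fractional_charge = -1))
  ga <- small_grid(ba)
  enc <- 0
  params <- small_params(max_time = 2e4, noise_scale = 0.1)
  for (i in 1:40) {
    set.seed(1000 + i)
    tr <- run_trajectory(p, ba, ga, params)
    enc <- enc + (tr$termination == "encounter")
  }
  expect_gt(enc / 40, 0.9)
})

test_that("ensemble bookkeeping, determinism and wall invariant", {
  p <- toy_ph()
  b <- small_patch()
  g <- small_grid(b)
  params <- small_params(n_trajectories = 60, max_time = 5000, seed = 5)
  e <- run_ensemble(p, b, g, params)
  expect_equal(sum(e$terminations), 60)
  expect_equal(nrow(e$first_encounters), e$terminations[["encounter"]])
  expect_identical(e$samples, run_ensemble(p, b, g, params)$samples)
  # extending the ensemble preserves earlier trajectories
  params2 <- small_params(n_trajectories = 80, max_time = 5000, seed = 5)
  e2 <- run_ensemble(p, b, g, params2)
  expect_identical(e2$samples[e2$samples$traj <= 60, ], e$samples)

  # reflecting wall: a single-bead protein's COM never dips below the
  # upper-leaflet plane (d is measured from the PIP3 plane = wall plane)
  p1 <- load_structure(c(
    "ATOM      1  Q   ION A   1       0.000   0.000   0.000   8.0000  1.000"),
    "file")
  ba <- assign_charges(small_patch(),
                       charge_scheme("fractional", fractional_charge = -1))
  ga <- small_grid(ba)
  eb <- run_ensemble(p1, ba, ga,
                     small_params(n_trajectories = 20, max_time = 1e4, seed = 2))
  expect_true(all(eb$samples$d >= -1e-9))
})

test_that("zero-field ensemble matches a pure-diffusion control (KS)", {
  p <- toy_ph()
  b <- small_patch(pip3_charge = 0)          # completely uncharged bilayer
  g <- small_grid(b)
  expect_true(all(g$values == 0))
  params_a <- small_params(n_trajectories = 200, max_time = 5000, seed = 21)
  params_b <- small_params(n_trajectories = 200, max_time = 5000, seed = 77)
  ea <- run_ensemble(p, b, g, params_a)            # forces from zero grid
  eb <- run_ensemble(p, b, NULL, params_b)         # free-diffusion control
  # samples within a trajectory are autocorrelated, so compare one
  # independent draw per trajectory: d at a fixed elapsed time
  at_t <- function(e, t) e$samples$d[e$samples$time == t]
  ks <- suppressWarnings(ks.test(at_t(ea, 500), at_t(eb, 500)))
  expect_gt(ks$p.value, 0.01)
  expect_gt(min(length(at_t(ea, 500)), length(at_t(eb, 500))), 50)
})
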