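# Rigid-body Brownian dynamics over the static bilayer. Trajectories start
# on a truncated b-sphere (|x| = b, z > z_min_start), propagate with the
# Ermak-McCammon update using grid-derived forces and torques, and
# terminate at the q-surface (escape) or at max_time (timeout); close
# approach to the upper-leaflet plane records a first encounter without
# terminating.

#' BD run parameters
#'
#' @param dt_near timestep in ps used below `dt_switch_height`.
#' @param dt_far timestep in ps used above `dt_switch_height`.
#' @param dt_switch_height protein COM height (Angstrom) separating the two
#'   timesteps.
#' @param b_radius start-surface radius in Angstrom.
#' @param q_radius termination-surface radius in Angstrom (> b_radius).
#' @param z_min_start trajectories start on the spherical cap z >
#'   `z_min_start` of the b-sphere.
#' @param contact_height lowest protein bead within this distance (Angstrom)
#'   of the upper-leaflet plane counts as a bilayer encounter.
#' @param max_time trajectory time cap in ps.
#' @param n_trajectories ensemble size.
#' @param temperature Kelvin.
#' @param seed master RNG seed; per-trajectory streams are derived from it,
#'   so extending an ensemble never changes earlier trajectories.
#' @param sample_interval steering-coordinate recording interval in ps.
#' @param delta_trans finite-difference displacement for forces, Angstrom.
#' @param delta_rot finite-difference rotation for torques, degrees.
#' @param noise_scale multiplier on the stochastic displacement (1 =
#'   physical; 0 = deterministic drift, for tests).
#' @return object of class `bd_params`.
#' @export
bd_params <- function(dt_near = 1, dt_far = 10, dt_switch_height = 90,
                      b_radius = 100, q_radius = 105, z_min_start = 60,
                      contact_height = 4.5, max_time = 2e7,
                      n_trajectories = 5000, temperature = 300, seed = 1L,
                      sample_interval = 100, delta_trans = 0.5,
                      delta_rot = 2, noise_scale = 1) {
  if (q_radius <= b_radius) stop("q_radius must exceed b_radius", call. = FALSE)
  if (z_min_start >= b_radius)
    stop("z_min_start must be below b_radius", call. = FALSE)
  if (dt_near > dt_far) stop("dt_near must be <= dt_far", call. = FALSE)
  if (dt_near <= 0 || max_time < 0 || sample_interval <= 0)
    stop("time parameters must be positive", call. = FALSE)
  structure(list(dt_near = dt_near, dt_far = dt_far,
                 dt_switch_height = dt_switch_height, b_radius = b_radius,
                 q_radius = q_radius, z_min_start = z_min_start,
                 contact_height = contact_height, max_time = max_time,
                 n_trajectories = as.integer(n_trajectories),
                 temperature = temperature, seed = as.integer(seed),
                 sample_interval = sample_interval,
                 delta_trans = delta_trans, delta_rot = delta_rot,
                 noise_scale = noise_scale),
            class = "bd_params")
}

#' Instantaneous rigid-body pose
#' @param position lab-frame protein COM, Angstrom.
#' @param orientation unit quaternion (w, x, y, z), body-to-lab.
#' @param time ps.
#' @return object of class `bd_state`.
#' @export
bd_state <- function(position, orientation = c(1, 0, 0, 0), time = 0) {
  stopifnot(length(position) == 3, length(orientation) == 4)
  n <- sqrt(sum(orientation^2))
  if (abs(n - 1) > 1e-9) orientation <- orientation / n
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation), time = time),
            class = "bd_state")
}

#' Sample a start pose on the truncated b-sphere
#'
#' Position uniform with respect to area on the spherical cap |x| = b,
#' z > z_min_start (by Archimedes, z is uniform on (z_min_start, b\]);
#' orientation uniform on the rotation group. Uses the current R RNG stream.
#'
#' @param params a [bd_params()].
#' @return a `bd_state`.
#' @export
sample_start <- function(params) {
  z <- stats::runif(1, params$z_min_start, params$b_radius)
  phi <- stats::runif(1, 0, 2 * pi)
  rho <- sqrt(max(params$b_radius^2 - z^2, 0))
  bd_state(c(rho * cos(phi), rho * sin(phi), z), quat_random())
}

.D_pair <- function(protein) {
  list(Dt = .D_trans_A2ps(protein$D_trans), Dr = .D_rot_rad2ps(protein$D_rot))
}

.as_grids <- function(grids) {
  if (inherits(grids, "potential_grid")) grids <- list(potential = grids)
  if (is.null(grids$potential)) stop("grids$potential is required", call. = FALSE)
  grids
}

#' Force and torque on the protein from the grids
#'
#' Central finite differences of [interaction_energy()]: +/- `delta_trans`
#' along each lab axis for the force, +/- `delta_rot` about each lab axis
#' through the COM for the torque.
#'
#' @param state a `bd_state`.
#' @param protein a `protein_model`.
#' @param grids a `potential_grid` or list with elements `potential` and
#'   optionally `desolvation`.
#' @param delta_trans displacement in Angstrom.
#' @param delta_rot rotation in degrees.
#' @return list with `force` (kT/Angstrom) and `torque` (kT/rad), lab frame.
#' @export
compute_force_torque <- function(state, protein, grids, delta_trans = 0.5,
                                 delta_rot = 2) {
  grids <- .as_grids(grids)
  d <- .grid_args(grids$desolvation)
  p <- grids$potential
  cpp_force_torque(state$position, state$orientation, protein$coords,
                   protein$charges, as.numeric(p$values), p$origin,
                   p$spacing, p$dims, d$values, d$origin, d$spacing, d$dims,
                   delta_trans, delta_rot * pi / 180)
}

.traj_args <- function(state, protein, bilayer, grids, params,
                       forces_on = TRUE) {
  D <- .D_pair(protein)
  pot <- if (is.null(grids)) NULL else .as_grids(grids)$potential
  des <- if (is.null(grids)) NULL else .as_grids(grids)$desolvation
  pa <- .grid_args(pot); da <- .grid_args(des)
  pip3 <- if (is.null(bilayer)) c(0, 0, 0) else
    as.numeric(bilayer$sites[bilayer$pip3_index, c("x", "y", "z")])
  wall <- if (is.null(bilayer)) -1e30 else bilayer$leaflet_z[["upper"]]
  list(pos0 = state$position, quat0 = state$orientation,
       coords = protein$coords, charges = protein$charges,
       pot_values = pa$values, pot_origin = pa$origin,
       pot_spacing = pa$spacing, pot_dims = pa$dims,
       des_values = da$values, des_origin = da$origin,
       des_spacing = da$spacing, des_dims = da$dims,
       pip3_pos = pip3, ref_vec = protein$ref_vector,
       D_trans = D$Dt, D_rot = D$Dr,
       dt_near = params$dt_near, dt_far = params$dt_far,
       dt_switch_height = params$dt_switch_height,
       q_radius = params$q_radius, wall_z = wall,
       contact_height = params$contact_height,
       max_time = params$max_time,
       sample_interval = params$sample_interval,
       delta_trans = params$delta_trans,
       delta_rot = params$delta_rot * pi / 180,
       noise_scale = params$noise_scale,
       forces_on = forces_on && !is.null(grids))
}

#' Advance a pose by one Ermak-McCammon step
#'
#' dr = (D dt) F + R with R Gaussian, var 2 D dt per axis (energies in kT,
#' so D/kT = D); rotation by w = (D_rot dt) T + W, var(W) = 2 D_rot dt,
#' applied as an axis-angle rotation about the COM. The timestep is
#' `dt_near` below `dt_switch_height`, else `dt_far`. A move placing the
#' lowest bead below the upper-leaflet plane is reflected in z. Draws from
#' the current R RNG stream.
#'
#' @param state a `bd_state`.
#' @param protein a `protein_model`.
#' @param grids grids as in [compute_force_torque()], or `NULL` for free
#'   diffusion.
#' @param params a [bd_params()].
#' @param bilayer optional `bilayer_model` (reflecting wall and steering
#'   coordinates); `NULL` disables the wall.
#' @return the new `bd_state`.
#' @export
bd_step <- function(state, protein, grids = NULL, params = bd_params(),
                    bilayer = NULL) {
  dt <- if (state$position[3] < params$dt_switch_height) params$dt_near
        else params$dt_far
  a <- .traj_args(state, protein, bilayer, grids, params)
  a$max_time <- dt
  a$dt_near <- a$dt_far <- dt
  a$q_radius <- 1e30
  a$sample_interval <- 2 * dt
  res <- do.call(cpp_run_trajectory, a)
  bd_state(res$final_pos, res$final_quat, state$time + dt)
}

#' Run one BD trajectory
#'
#' Propagates from `state0` (or a fresh [sample_start()]) until escape
#' through the q-surface or `max_time`. The first time the lowest bead
#' comes within `contact_height` of the upper-leaflet plane, the steering
#' coordinates are recorded as the first encounter; the trajectory then
#' continues (surface-reflected) and keeps the encounter label. Steering
#' coordinates (r, d, theta) are sampled every `sample_interval`.
#'
#' @param protein a `protein_model`.
#' @param bilayer a `bilayer_model`.
#' @param grids grids as in [compute_force_torque()].
#' @param params a [bd_params()].
#' @param state0 optional starting `bd_state`.
#' @return object of class `bd_trajectory`: list with `samples` (data.frame
#'   time, r, d, theta), `termination` ("encounter", "escape" or "timeout"),
#'   `first_encounter` (named vector or NULL) and `n_steps`.
#' @export
run_trajectory <- function(protein, bilayer, grids, params = bd_params(),
                           state0 = NULL) {
  if (is.null(state0)) state0 <- sample_start(params)
  a <- .traj_args(state0, protein, bilayer, grids, params)
  res <- do.call(cpp_run_trajectory, a)
  term <- c("encounter", "escape", "timeout")[res$termination]
  structure(list(samples = as.data.frame(res$samples),
                 termination = term,
                 first_encounter = res$first_encounter,
                 n_steps = res$n_steps,
                 final_state = bd_state(res$final_pos, res$final_quat)),
            class = "bd_trajectory")
}

.derive_seed <- function(master, i) {
  as.integer((as.numeric(master) + as.numeric(i) * 104729) %% 2147483647)
}

#' Run an ensemble of independent BD trajectories
#'
#' Each trajectory uses an RNG stream seeded from the master seed and the
#' trajectory index, so the ensemble is reproducible and extending
#' `n_trajectories` never changes earlier trajectories.
#'
#' @param protein a `protein_model`.
#' @param bilayer a `bilayer_model`.
#' @param grids grids as in [compute_force_torque()].
#' @param params a [bd_params()] (`n_trajectories`, `seed`).
#' @param progress print a progress line every 100 trajectories.
#' @return object of class `ensemble_record`: list with `samples`
#'   (data.frame traj, time, r, d, theta), `first_encounters` (data.frame
#'   traj, r, d, theta), `terminations` (named counts), `params`.
#' @export
run_ensemble <- function(protein, bilayer, grids, params = bd_params(),
                         progress = FALSE) {
  n <- params$n_trajectories
  if (n < 1) stop("n_trajectories must be >= 1", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  samples <- vector("list", n)
  fe <- vector("list", n)
  term <- character(n)
  for (i in seq_len(n)) {
    set.seed(.derive_seed(params$seed, i))
    tr <- run_trajectory(protein, bilayer, grids, params)
    s <- tr$samples
    s$traj <- i
    samples[[i]] <- s
    term[i] <- tr$termination
    if (!is.null(tr$first_encounter))
      fe[[i]] <- data.frame(traj = i, r = tr$first_encounter[["r"]],
                            d = tr$first_encounter[["d"]],
                            theta = tr$first_encounter[["theta"]])
    if (progress && i %% 100 == 0)
      message(sprintf("  trajectory %d / %d", i, n))
  }
  fe <- fe[!vapply(fe, is.null, logical(1))]
  structure(list(
    samples = do.call(rbind, samples)[, c("traj", "time", "r", "d", "theta")],
    first_encounters = if (length(fe)) do.call(rbind, fe) else
      data.frame(traj = integer(0), r = numeric(0), d = numeric(0),
                 theta = numeric(0)),
    terminations = c(encounter = sum(term == "encounter"),
                     escape = sum(term == "escape"),
                     timeout = sum(term == "timeout")),
    params = params), class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf("ensemble_record: %d trajectories, %d samples\n",
              sum(x$terminations), nrow(x$samples)))
  cat(sprintf("  terminations: %d encounter / %d escape / %d timeout\n",
              x$terminations[["encounter"]], x$terminations[["escape"]],
              x$terminations[["timeout"]]))
  invisible(x)
}
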