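# steering coordinates, Jacobian reweighting, HWHM fits, pose search,
# fingerprints

test_that("steering coordinates: 3-4-5 geometry and rotations", {
  p <- toy_ph()                       # ref_vector = +z (dipole axis)
  b <- small_patch()
  pip3 <- as.numeric(b$sites[b$pip3_index, c("x", "y", "z")])
  # orientation flipping the ref vector onto -z: 180 deg about x
  qflip <- c(0, 1, 0, 0)
  st <- bd_state(pip3 + c(3, 4, 18), qflip)
  sc <- compute_coordinates(st, p, b)
  expect_equal(sc[["r"]], 5)
  expect_equal(sc[["d"]], 18)
  expect_equal(sc[["theta"]], 0, tolerance = 1e-9)
  # rotate the pose 90 deg about a lateral axis: theta -> 90, r/d unchanged
  q90 <- quat_multiply(c(cos(pi / 4), sin(pi / 4), 0, 0), qflip)
  sc90 <- compute_coordinates(bd_state(pip3 + c(3, 4, 18), q90), p, b)
  expect_equal(sc90[["theta"]], 90, tolerance = 1e-9)
  expect_equal(sc90[["r"]], 5)
  expect_equal(sc90[["d"]], 18)
})

test_that("radial reweighting flattens uniform-disc samples", {
  set.seed(12)
  n <- 1e5
  R <- 40
  r <- R * sqrt(runif(n))             # uniform on a disc
  h <- reweight_radial(make_histogram(r, seq(0, R, 2), "r"))
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)
  # chi-square against flat density on the disc
  exp_counts <- n * diff((h$bin_edges / R)^2)
  chi <- sum((h$raw_counts - exp_counts)^2 / exp_counts)
  expect_gt(pchisq(chi, df = length(exp_counts) - 1, lower.tail = FALSE), 0.01)
  # flat means all reweighted bins within a few % of 1/R
  expect_lt(max(abs(h$density - 1 / R)) / (1 / R), 0.2)

  # all mass in one bin
  h1 <- reweight_radial(make_histogram(rep(5, 100), seq(0, 10, 2), "r"))
  expect_equal(h1$density[3], 1 / 2)
  expect_equal(sum(h1$density > 0), 1)

  # 2D Gaussian positions: reweighted density proportional to exp(-r^2/200)
  sg <- 10
  rg <- sqrt(rnorm(n, sd = sg)^2 + rnorm(n, sd = sg)^2)
  hg <- reweight_radial(make_histogram(rg, seq(0, 50, 2), "r"))
  rc <- (hg$bin_edges[-1] + hg$bin_edges[-26]) / 2
  target <- exp(-rc^2 / (2 * sg^2))
  target <- target / sum(target * 2)
  expect_equal(hg$density[rc < 30], target[rc < 30], tolerance = 0.05)
})

test_that("angular reweighting flattens uniform orientations", {
  set.seed(13)
  n <- 1e5
  theta <- acos(runif(n, -1, 1)) * 180 / pi     # isotropic directions
  h <- reweight_angular(make_histogram(theta, seq(0, 180, 2), "theta"))
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)
  edges_rad <- h$bin_edges * pi / 180
  exp_counts <- n * diff(-cos(edges_rad)) / 2
  chi <- sum((h$raw_counts - exp_counts)^2 / exp_counts)
  expect_gt(pchisq(chi, df = length(exp_counts) - 1, lower.tail = FALSE), 0.01)

  # counts exactly proportional to sin(theta) reweight to exactly uniform
  hs <- make_histogram(numeric(0) + 90, seq(0, 180, 2), "theta")
  centres <- (hs$bin_edges[-1] + hs$bin_edges[-91]) / 2
  hs$raw_counts <- 1000 * sin(centres * pi / 180)
  hs <- reweight_angular(hs)
  expect_equal(hs$density, rep(1 / 180, 90), tolerance = 1e-12)

  # all mass near the pole: single nonzero bin survives reweighting
  hp <- reweight_angular(make_histogram(runif(100, 0, 2), seq(0, 180, 2),
                                        "theta"))
  expect_equal(sum(hp$density > 0), 1)
  expect_gt(hp$density[1], 0)
})

test_that("reweighting is the inverse of Jacobian weighting (involution)", {
  edges <- seq(0, 40, 2)
  centres <- (edges[-1] + edges[-21]) / 2
  h <- make_histogram(numeric(0) + 1, edges, "r")
  h$raw_counts <- 2 * pi * centres * 7.3       # flat density, forward-weighted
  h <- reweight_radial(h)
  expect_equal(h$density, rep(1 / 40, 20), tolerance = 1e-9)
})

test_that("HWHM of zero-centred Gaussian fits", {
  edges <- seq(0, 50, 2)
  rc <- (edges[-1] + edges[-26]) / 2
  mk <- function(sigma) {
    h <- make_histogram(numeric(0) + 1, edges, "r")
    h$raw_counts <- 1e4 * 2 * pi * rc * exp(-rc^2 / (2 * sigma^2))
    reweight_radial(h)
  }
  expect_equal(as.numeric(fit_hwhm(mk(10))), 11.774, tolerance = 1e-3)
  expect_equal(as.numeric(fit_hwhm(mk(5))), 5.887, tolerance = 1e-3)

  # sampled recovery within 3%
  set.seed(14)
  r <- sqrt(rnorm(1e5, sd = 10)^2 + rnorm(1e5, sd = 10)^2)
  h <- reweight_radial(make_histogram(r, edges, "r"))
  expect_equal(as.numeric(fit_hwhm(h)), 11.774, tolerance = 0.03)

  # scale equivariance: r -> c r scales HWHM by c
  h2 <- reweight_radial(make_histogram(2 * r, seq(0, 100, 2), "r"))
  expect_equal(as.numeric(fit_hwhm(h2)) / as.numeric(fit_hwhm(h)), 2,
               tolerance = 0.02)

  expect_error(fit_hwhm(reweight_radial(
    make_histogram(rep(5, 10), seq(0, 10, 5), "r"))), "3 nonzero bins")
})

test_that("2D (r, theta) histogram: flatness, delta, marginals", {
  set.seed(15)
  n <- 1e5
  r <- 30 * sqrt(runif(n))
  theta <- acos(runif(n, -1, 1)) * 180 / pi
  h2 <- histogram2d_r_theta(r, theta, seq(0, 30, 2), seq(0, 180, 10))
  dr <- diff(h2$r_edges); dt <- diff(h2$theta_edges)
  expect_equal(sum(h2$density * outer(dr, dt)), 1, tolerance = 1e-9)
  # chi-square of raw counts against the product oracle
  exp_counts <- n * outer(diff((h2$r_edges / 30)^2),
                          diff(-cos(h2$theta_edges * pi / 180)) / 2)
  chi <- sum((h2$raw_counts - exp_counts)^2 / exp_counts)
  expect_gt(pchisq(chi, df = length(exp_counts) - 1, lower.tail = FALSE), 0.01)

  hd <- histogram2d_r_theta(5, 45, seq(0, 10, 2), seq(0, 180, 10))
  expect_equal(sum(hd$density > 0), 1)

  # exactly separable sample: 2D marginals equal the 1D reweighted densities
  rs <- c(3, 9, 15); ts <- c(25, 95, 155)
  wr <- c(2, 5, 3); wt <- c(1, 4, 2)
  r_sep <- rep(rep(rs, wr), times = sum(wt))
  t_sep <- rep(rep(ts, wt), each = sum(wr))
  h2s <- histogram2d_r_theta(r_sep, t_sep, seq(0, 20, 2), seq(0, 180, 10))
  m <- marginals_r_theta(h2s)
  h1r <- reweight_radial(make_histogram(r_sep, seq(0, 20, 2), "r"))
  h1t <- reweight_angular(make_histogram(t_sep, seq(0, 180, 10), "theta"))
  expect_equal(m$r, h1r$density, tolerance = 1e-9)
  expect_equal(m$theta, h1t$density, tolerance = 1e-9)
})

test_that("first-encounter distribution and pose selection contracts", {
  fake <- structure(list(
    samples = data.frame(traj = 1:5, time = 0,
                         r = c(9, 3, 12, 8, 2), d = c(18, 25, 10, 19, 5),
                         theta = c(27, 10, 40, 29, 50)),
    first_encounters = data.frame(traj = 1:3, r = c(4, 9, 14),
                                  d = 0, theta = 20)),
    class = "ensemble_record")
  h <- first_encounter_distribution(fake, seq(0, 16, 4))
  expect_equal(sum(h$raw_counts), 3)
  expect_equal(sum(h$density * diff(h$bin_edges)), 1, tolerance = 1e-9)

  empty <- structure(list(samples = fake$samples,
                          first_encounters = fake$first_encounters[0, ]),
                     class = "ensemble_record")
  expect_error(first_encounter_distribution(empty), "no encounters")

  # (10, 20, 30) admits the (9, 18, 27) pose; sort is by r^2 + d^2
  sel <- select_optimal_pose(fake, 10, 20, 30)
  expect_true(any(sel$r == 9 & sel$d == 18 & sel$theta == 27))
  expect_true(all(diff(sel$r^2 + sel$d^2) >= 0))
  # zero thresholds: empty selection, not an error
  expect_equal(nrow(select_optimal_pose(fake, 0, 0, 0)), 0)
  expect_error(select_optimal_pose(fake, -1, 10, 10), "non-negative")

  # uniform-disc encounters reweight flat
  set.seed(16)
  unif <- structure(list(
    samples = fake$samples,
    first_encounters = data.frame(traj = 1:2e4, r = 20 * sqrt(runif(2e4)),
                                  d = 0, theta = 0)),
    class = "ensemble_record")
  hu <- first_encounter_distribution(unif, seq(0, 20, 2))
  expect_lt(max(abs(hu$density - 1 / 20)) / (1 / 20), 0.2)
})

test_that("average_histograms is the bin-wise mean of densities", {
  e <- seq(0, 10, 2)
  h1 <- reweight_radial(make_histogram(c(1, 3, 5), e, "r"))
  h2 <- reweight_radial(make_histogram(c(7, 9), e, "r"))
  hm <- average_histograms(list(h1, h2))
  expect_equal(hm$density, (h1$density + h2$density) / 2)
  expect_error(average_histograms(list(h1, reweight_radial(
    make_histogram(c(1), seq(0, 8, 2), "r")))), "share bin edges")
})

test_that("fingerprint distances: closed form, invariance, ranking", {
  one <- data.frame(label = "A1", x = 0, y = 0, z = 0)
  p1 <- data.frame(label = "P1", x = 3, y = 0, z = 0)
  expect_equal(fingerprint_contacts(one, p1), matrix(3, 1, 1,
               dimnames = list("A1", "P1")))

  set.seed(17)
  ra <- data.frame(label = rep(c("A1", "A2"), each = 3),
                   x = rnorm(6), y = rnorm(6), z = rnorm(6))
  ph <- data.frame(label = c("P1", "P4"), x = c(5, -2), y = c(1, 3),
                   z = c(0, 2))
  m0 <- fingerprint_contacts(ra, ph)
  shift <- c(11, -4, 7)
  ra2 <- ra; ra2$x <- ra$x + shift[1]; ra2$y <- ra$y + shift[2]
  ra2$z <- ra$z + shift[3]
  ph2 <- ph; ph2$x <- ph$x + shift[1]; ph2$y <- ph$y + shift[2]
  ph2$z <- ph$z + shift[3]
  expect_equal(fingerprint_contacts(ra2, ph2), m0, tolerance = 1e-12)
  expect_error(fingerprint_contacts(ra[0, ], ph), "rows")

  # synthetic complex: the binding-site lysine ranks closest to the
  # phosphorus set, the distal glutamate farthest
  fp <- fingerprint_from_pdb(synthetic_complex_pdb(), "IP4")
  mins <- apply(fp, 1, min)
  expect_equal(names(which.min(mins)), "A10")
  expect_equal(names(which.max(mins)), "A20")
})

test_that("scaled-down steering runs show the charge direction-of-effect", {
  # tiny end-to-end: more leaflet charge pulls the protein to the surface
  p <- toy_ph()
  params <- small_params(n_trajectories = 80, max_time = 2e4, seed = 6)
  frac_d20 <- vapply(c(0, -1), function(q) {
    b <- small_patch()
    if (q != 0)
      b <- assign_charges(b, charge_scheme("fractional", fractional_charge = q))
    e <- run_ensemble(p, b, small_grid(b), params)
    mean(e$samples$d < 20)
  }, numeric(1))
  expect_gt(frac_d20[2], frac_d20[1])
})
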