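# Steering statistics: the (r, d, theta) coordinates of a pose relative to
# the PIP3 headgroup, Jacobian-reweighted histograms over those
# coordinates, Gaussian half-width fits, first-encounter distributions,
# optimal-pose search and residue-phosphorus contact fingerprints.
#
# Raw occupancy counts over r (plane-polar radius) overweight large radii
# by the annulus area 2 pi r; counts over theta overweight mid angles by
# the spherical band area ~ sin(theta). Densities divide these Jacobian
# factors out, so an unbiased (uniform) sample reweights to a flat density.

#' Steering coordinates of a pose
#'
#' r = in-plane distance from the protein COM to the PIP3 site; d = COM
#' height above the PIP3 plane; theta = angle in degrees between the
#' body-fixed binding-site reference vector (rotated to the lab frame) and
#' the downward bilayer normal -z, so theta = 0 is "binding face toward the
#' membrane".
#'
#' @param state a [bd_state()].
#' @param protein a `protein_model`.
#' @param bilayer a `bilayer_model`.
#' @return named numeric vector (r, d, theta).
#' @export
compute_coordinates <- function(state, protein, bilayer) {
  pip3 <- as.numeric(bilayer$sites[bilayer$pip3_index, c("x", "y", "z")])
  p <- state$position
  ref_lab <- quat_rotate(state$orientation, protein$ref_vector)
  cosang <- max(-1, min(1, -ref_lab[3]))
  c(r = sqrt((p[1] - pip3[1])^2 + (p[2] - pip3[2])^2),
    d = p[3] - pip3[3],
    theta = acos(cosang) * 180 / pi)
}

#' Bin values into a steering histogram
#'
#' @param x numeric values (r or d in Angstrom, theta in degrees).
#' @param breaks bin edges; default 2-Angstrom (or 2-degree) bins spanning
#'   the data from 0 (r, theta) or the data minimum (d).
#' @param variable one of "r", "d", "theta".
#' @return object of class `steering_histogram` with `bin_edges`,
#'   `raw_counts`, `density` (NULL until reweighted/normalised), `variable`.
#' @export
make_histogram <- function(x, breaks = NULL, variable = c("r", "d", "theta")) {
  variable <- match.arg(variable)
  x <- x[is.finite(x)]
  if (is.null(breaks)) {
    w <- 2
    lo <- if (variable == "d") w * floor(min(x) / w) else 0
    hi <- if (variable == "theta") 180 else w * ceiling(max(x) / w + 1e-9)
    breaks <- seq(lo, max(hi, lo + w), by = w)
  }
  x <- x[x >= breaks[1] & x <= breaks[length(breaks)]]  # out-of-range dropped
  h <- graphics::hist(x, breaks = breaks, plot = FALSE, right = FALSE)
  structure(list(bin_edges = h$breaks, raw_counts = h$counts,
                 density = NULL, variable = variable),
            class = "steering_histogram")
}

.bin_centres <- function(h) (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
.bin_widths <- function(h) diff(h$bin_edges)

.normalise <- function(h, w) {
  tot <- sum(w * .bin_widths(h))
  if (tot <= 0) stop("zero-total histogram: nothing to normalise", call. = FALSE)
  h$density <- w / tot
  h
}

#' Plain normalised density (no Jacobian), e.g. for d histograms
#' @param h a `steering_histogram`.
#' @return the histogram with unit-integral `density`.
#' @export
normalize_histogram <- function(h) .normalise(h, h$raw_counts)

#' Jacobian-reweight a radial histogram
#'
#' density proportional to counts / (2 pi r_centre), renormalised to unit
#' integral; the bin containing r = 0 uses its bin-centre radius.
#'
#' @param h a `steering_histogram` over r.
#' @return the histogram with `density` filled in.
#' @export
reweight_radial <- function(h) {
  stopifnot(inherits(h, "steering_histogram"))
  if (any(h$bin_edges < 0)) stop("radial bins must cover r >= 0", call. = FALSE)
  .normalise(h, h$raw_counts / (2 * pi * .bin_centres(h)))
}

#' Jacobian-reweight an angular histogram
#'
#' density proportional to counts / sin(theta_centre), renormalised; the
#' polar bins use their bin-centre sine.
#'
#' @param h a `steering_histogram` over theta (degrees in \[0, 180\]).
#' @return the histogram with `density` filled in.
#' @export
reweight_angular <- function(h) {
  stopifnot(inherits(h, "steering_histogram"))
  if (any(h$bin_edges < -1e-9) || any(h$bin_edges > 180 + 1e-9))
    stop("theta bins must lie within [0, 180] degrees", call. = FALSE)
  .normalise(h, h$raw_counts / sin(.bin_centres(h) * pi / 180))
}

#' Half width at half maximum of a zero-centred Gaussian fit
#'
#' Least-squares fit of A exp(-r^2 / (2 sigma^2)) to the reweighted radial
#' density, centre pinned at r = 0; HWHM = sigma sqrt(2 ln 2).
#'
#' @param h a `steering_histogram` over r with `density` present (run
#'   [reweight_radial()] first), or raw (then reweighted internally).
#' @return HWHM in Angstrom, with the fit as attribute "fit".
#' @export
fit_hwhm <- function(h) {
  stopifnot(inherits(h, "steering_histogram"))
  if (is.null(h$density)) h <- reweight_radial(h)
  r <- .bin_centres(h)
  y <- h$density
  if (sum(y > 0) < 3)
    stop("need at least 3 nonzero bins for a Gaussian fit", call. = FALSE)
  s0 <- sqrt(sum(y * r^2) / sum(y) / 2)
  fit <- tryCatch(
    stats::nls(y ~ A * exp(-r^2 / (2 * sigma^2)),
               start = list(A = max(y), sigma = max(s0, 1e-3)),
               lower = c(A = 0, sigma = 1e-6), algorithm = "port",
               control = stats::nls.control(maxiter = 200)),
    error = function(e)
      stop("Gaussian HWHM fit failed to converge: ", conditionMessage(e),
           "\n  bins = ", length(r), ", density range = [",
           signif(min(y), 3), ", ", signif(max(y), 3), "]", call. = FALSE))
  sigma <- abs(stats::coef(fit)[["sigma"]])
  structure(sigma * sqrt(2 * log(2)), fit = fit)
}

#' Two-dimensional reweighted (r, theta) histogram
#'
#' Counts over r and theta bins, divided by both Jacobian factors
#' (2 pi r_centre and sin theta_centre) and normalised so the density
#' integrates to 1 over (r, theta).
#'
#' @param r,theta paired sample vectors.
#' @param r_breaks,theta_breaks bin edges (defaults: 2 Angstrom / 2 degree).
#' @return object of class `steering_histogram2d` with `r_edges`,
#'   `theta_edges`, `raw_counts` (r rows x theta cols) and `density`.
#' @export
histogram2d_r_theta <- function(r, theta, r_breaks = NULL,
                                theta_breaks = NULL) {
  keep <- is.finite(r) & is.finite(theta)
  r <- r[keep]; theta <- theta[keep]
  if (is.null(r_breaks)) r_breaks <- seq(0, 2 * ceiling(max(r) / 2 + 1e-9), by = 2)
  if (is.null(theta_breaks)) theta_breaks <- seq(0, 180, by = 2)
  ri <- cut(r, r_breaks, right = FALSE, labels = FALSE)
  ti <- cut(theta, theta_breaks, right = FALSE, labels = FALSE)
  # theta = 180 exactly falls on the last edge; fold into the last bin
  ti[is.na(ti) & theta >= theta_breaks[length(theta_breaks)]] <-
    length(theta_breaks) - 1
  keep <- !is.na(ri) & !is.na(ti)
  counts <- matrix(0, length(r_breaks) - 1, length(theta_breaks) - 1)
  for (k in which(keep)) counts[ri[k], ti[k]] <- counts[ri[k], ti[k]] + 1
  rc <- (r_breaks[-1] + r_breaks[-length(r_breaks)]) / 2
  tc <- (theta_breaks[-1] + theta_breaks[-length(theta_breaks)]) / 2
  w <- counts / outer(2 * pi * rc, sin(tc * pi / 180))
  dr <- diff(r_breaks); dt <- diff(theta_breaks)
  tot <- sum(w * outer(dr, dt))
  if (tot <= 0) stop("zero-total histogram", call. = FALSE)
  structure(list(r_edges = r_breaks, theta_edges = theta_breaks,
                 raw_counts = counts, density = w / tot),
            class = "steering_histogram2d")
}

#' Marginal densities of a 2D (r, theta) histogram
#' @param h2 a `steering_histogram2d`.
#' @return list of numeric vectors `r` and `theta` (unit-integral each).
#' @export
marginals_r_theta <- function(h2) {
  dr <- diff(h2$r_edges); dt <- diff(h2$theta_edges)
  mr <- as.numeric(h2$density %*% dt)
  mt <- as.numeric(dr %*% h2$density)
  list(r = mr / sum(mr * dr), theta = mt / sum(mt * dt))
}

#' Radial distribution of first-encounter locations
#'
#' @param ensemble an `ensemble_record` with at least one encounter.
#' @param breaks optional r bin edges.
#' @return a reweighted `steering_histogram` over r.
#' @export
first_encounter_distribution <- function(ensemble, breaks = NULL) {
  fe <- ensemble$first_encounters
  if (!nrow(fe)) stop("no encounters in ensemble", call. = FALSE)
  reweight_radial(make_histogram(fe$r, breaks, "r"))
}

#' Search an ensemble for binding-competent poses
#'
#' Returns all recorded samples with r <= r_max, d <= d_max and theta <=
#' theta_max simultaneously (small in-plane offset, close to the surface,
#' binding face down), sorted by r^2 + d^2 with ties broken on theta: the
#' head of the list is the natural hand-off configuration for atomistic
#' refinement.
#'
#' @param ensemble an `ensemble_record`.
#' @param r_max,d_max,theta_max selection thresholds (Angstrom, Angstrom,
#'   degrees).
#' @return data.frame of samples (possibly empty), sorted as described.
#' @export
select_optimal_pose <- function(ensemble, r_max = 10, d_max = 20,
                                theta_max = 30) {
  if (any(c(r_max, d_max, theta_max) < 0))
    stop("thresholds must be non-negative", call. = FALSE)
  s <- ensemble$samples
  sel <- s[s$r <= r_max & s$d <= d_max & s$theta <= theta_max, , drop = FALSE]
  sel[order(sel$r^2 + sel$d^2, sel$theta), , drop = FALSE]
}

#' Average reweighted densities over equal-size ensembles
#'
#' Unweighted mean of per-configuration densities on a shared binning, for
#' comparing a set of discrete-charge configurations with a single
#' mean-field (fractional) run.
#'
#' @param hists list of `steering_histogram`s with identical bin edges and
#'   `density` present.
#' @return a `steering_histogram` whose density is the bin-wise mean.
#' @export
average_histograms <- function(hists) {
  stopifnot(length(hists) >= 1)
  e <- hists[[1]]$bin_edges
  for (h in hists) {
    if (!isTRUE(all.equal(h$bin_edges, e)))
      stop("histograms must share bin edges", call. = FALSE)
    if (is.null(h$density)) stop("densities missing: reweight first", call. = FALSE)
  }
  out <- hists[[1]]
  out$density <- rowMeans(vapply(hists, `[[`, numeric(length(e) - 1), "density"))
  out$raw_counts <- rowSums(vapply(hists, `[[`, numeric(length(e) - 1),
                                   "raw_counts"))
  out
}

#' Residue-phosphorus minimum-distance fingerprint
#'
#' Entry (i, j) is the minimum distance from any atom of residue i to
#' phosphorus atom j: the contact fingerprint characterising a
#' protein-phosphoinositide binding geometry.
#'
#' @param residue_atoms data.frame with columns `label`, `x`, `y`, `z`
#'   (one row per atom; `label` groups atoms into residues).
#' @param phosphorus data.frame with columns `label`, `x`, `y`, `z`
#'   (one row per phosphorus atom, e.g. P1, P3, P4, P5).
#' @return matrix of minimum distances in Angstrom, residues x phosphorus.
#' @export
fingerprint_contacts <- function(residue_atoms, phosphorus) {
  need <- c("label", "x", "y", "z")
  if (!nrow(residue_atoms) || !all(need %in% names(residue_atoms)))
    stop("residue_atoms must have rows and columns label, x, y, z",
         call. = FALSE)
  if (!nrow(phosphorus) || !all(need %in% names(phosphorus)))
    stop("phosphorus must have rows and columns label, x, y, z",
         call. = FALSE)
  res <- unique(residue_atoms$label)
  out <- matrix(NA_real_, length(res), nrow(phosphorus),
                dimnames = list(res, phosphorus$label))
  for (i in seq_along(res)) {
    a <- residue_atoms[residue_atoms$label == res[i], c("x", "y", "z")]
    for (j in seq_len(nrow(phosphorus))) {
      d2 <- (a$x - phosphorus$x[j])^2 + (a$y - phosphorus$y[j])^2 +
        (a$z - phosphorus$z[j])^2
      out[i, j] <- sqrt(min(d2))
    }
  }
  out
}

#' Fingerprint straight from a PDB record stream
#'
#' Extracts protein residues (ATOM records) and the phosphorus atoms of a
#' named ligand residue, then calls [fingerprint_contacts()].
#'
#' @param pdb_text PDB lines or file path.
#' @param ligand_resname residue name of the phosphoinositide ligand.
#' @return minimum-distance matrix, residues x phosphorus atoms.
#' @export
fingerprint_from_pdb <- function(pdb_text, ligand_resname) {
  atoms <- parse_pdb_atoms(pdb_text)
  prot <- atoms[atoms$record == "ATOM" & atoms$resname %in% .aa3, ]
  lig <- atoms[atoms$resname == ligand_resname & atoms$element == "P", ]
  if (!nrow(prot)) stop("no protein atoms", call. = FALSE)
  if (!nrow(lig)) stop("no ligand phosphorus atoms", call. = FALSE)
  fingerprint_contacts(
    data.frame(label = paste0(prot$chain, prot$resseq),
               x = prot$x, y = prot$y, z = prot$z),
    data.frame(label = lig$name, x = lig$x, y = lig$y, z = lig$z))
}
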