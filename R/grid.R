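# Electrostatic potential and desolvation grids over the bilayer.
# Potentials are screened-Coulomb (Debye-Hueckel) superpositions of the
# bilayer point charges, exact for the point-charge membrane model; grids
# are in kT/e on a regular cubic lattice and interpolated trilinearly.

.new_grid <- function(values, origin, spacing, dims, kind,
                      kappa_inv = Inf, temperature = 300,
                      ionic_strength = NA_real_, eps_r = 78.5) {
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = spacing, dims = as.integer(dims), kind = kind,
                 kappa_inv = kappa_inv, temperature = temperature,
                 ionic_strength = ionic_strength, eps_r = eps_r),
            class = "potential_grid")
}

#' @export
print.potential_grid <- function(x, ...) {
  cat(sprintf("potential_grid (%s): %d x %d x %d at %.2f A, origin (%g, %g, %g)\n",
              x$kind, x$dims[1], x$dims[2], x$dims[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  kappa_inv = %.2f A, range [%.3g, %.3g]\n",
              x$kappa_inv, min(x$values), max(x$values)))
  invisible(x)
}

.grid_geometry <- function(bilayer, spacing, xy_half, z_range) {
  if (is.null(xy_half)) xy_half <- max(bilayer$patch_dims) / 2
  nx <- 2 * ceiling(xy_half / spacing) + 1
  nz <- ceiling((z_range[2] - z_range[1]) / spacing) + 1
  list(origin = c(-(nx - 1) / 2 * spacing, -(nx - 1) / 2 * spacing, z_range[1]),
       dims = c(nx, nx, nz))
}

#' Screened-Coulomb potential grid of a bilayer
#'
#' Phi(x) = sum_i q_i C / (eps_r |x - x_i|) exp(-|x - x_i| / kappa_inv) in
#' kT/e, with C = [coulomb_kt()] at `T`. Source singularities are capped at
#' `cap_radius`. `kappa_inv = Inf` gives the unscreened Coulomb sum.
#'
#' @param bilayer a `bilayer_model` providing the charge sites.
#' @param spacing grid spacing in Angstrom.
#' @param xy_half lateral half-extent in Angstrom (default: half the patch).
#' @param z_range vertical extent, default from the bilayer mid-plane (z = 0)
#'   to 120 Angstrom.
#' @param ionic_strength mol/L; used with `T`, `eps_r` to derive
#'   `kappa_inv` when that is not given directly.
#' @param kappa_inv Debye length in Angstrom (overrides `ionic_strength`).
#' @param eps_r solvent relative permittivity.
#' @param T temperature in K.
#' @param cap_radius singularity cap in Angstrom.
#' @param cutoff source-node distance beyond which contributions are dropped
#'   (exp(-cutoff/kappa) is negligible at the default).
#' @return a `potential_grid`.
#' @export
compute_potential_grid <- function(bilayer, spacing = 1, xy_half = NULL,
                                   z_range = c(0, 120),
                                   ionic_strength = 0.1, kappa_inv = NULL,
                                   eps_r = 78.5, T = 300, cap_radius = 2,
                                   cutoff = 150) {
  stopifnot(inherits(bilayer, "bilayer_model"))
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  if (is.null(kappa_inv)) kappa_inv <- debye_length(ionic_strength, T, eps_r)
  geo <- .grid_geometry(bilayer, spacing, xy_half, z_range)
  src <- as.matrix(bilayer$sites[, c("x", "y", "z")])
  xmax <- geo$origin[1] + (geo$dims[1] - 1) * spacing
  if (any(abs(src[, 1]) > xmax + 1e-9) || any(abs(src[, 2]) > xmax + 1e-9) ||
      any(src[, 3] > geo$origin[3] + (geo$dims[3] - 1) * spacing + 1e-9))
    stop("grid does not cover the bilayer charges laterally", call. = FALSE)
  vals <- cpp_dh_grid(geo$origin, spacing, as.integer(geo$dims), src,
                      bilayer$sites$charge, kappa_inv, eps_r,
                      coulomb_kt(T), cap_radius,
                      if (is.finite(kappa_inv)) cutoff else Inf)
  .new_grid(vals, geo$origin, spacing, geo$dims, "potential",
            kappa_inv, T, ionic_strength, eps_r)
}

#' Electrostatic desolvation penalty grid
#'
#' Penalty field g(x) >= 0 such that a protein charge q at x pays q^2 g(x)
#' kT for displacing high-dielectric solvent near the low-dielectric bilayer
#' slab. The slab between the two leaflet planes is discretised into volume
#' elements of side `element_spacing` and each contributes
#' `alpha * C * (eps_s - eps_p) / (eps_s (2 eps_s + eps_p)) * a^3
#'  (1 + kr)^2 exp(-2 kr) / r^4` (Elcock-style image-charge protocol).
#'
#' @param bilayer a `bilayer_model` (defines slab extent).
#' @param spacing output grid spacing in Angstrom.
#' @param xy_half,z_range grid extent as in [compute_potential_grid()].
#' @param alpha dimensionless scaling factor (1.67 in the SDA protocol).
#' @param ionic_strength,kappa_inv,T screening as in
#'   [compute_potential_grid()].
#' @param eps_p,eps_s protein/membrane interior and solvent permittivities.
#' @param element_spacing side of the slab volume elements in Angstrom.
#' @return a `potential_grid` with kind "desolvation" (values in kT/e^2).
#' @export
compute_desolvation_grid <- function(bilayer, spacing = 1, xy_half = NULL,
                                     z_range = c(0, 120), alpha = 1.67,
                                     ionic_strength = 0.1, kappa_inv = NULL,
                                     T = 300, eps_p = 4, eps_s = 78.5,
                                     element_spacing = 4) {
  stopifnot(inherits(bilayer, "bilayer_model"))
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (eps_s <= eps_p)
    stop("eps_s must exceed eps_p (penalty presupposes high-dielectric solvent)",
         call. = FALSE)
  if (is.null(kappa_inv)) kappa_inv <- debye_length(ionic_strength, T, eps_s)
  geo <- .grid_geometry(bilayer, spacing, xy_half, z_range)
  a <- element_spacing
  zr <- range(bilayer$leaflet_z)
  xs <- seq(-bilayer$patch_dims[1] / 2 + a / 2, bilayer$patch_dims[1] / 2, by = a)
  ys <- seq(-bilayer$patch_dims[2] / 2 + a / 2, bilayer$patch_dims[2] / 2, by = a)
  zs <- seq(zr[1] + a / 2, zr[2], by = a)
  el <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  K <- alpha * coulomb_kt(T) * (eps_s - eps_p) / (eps_s * (2 * eps_s + eps_p))
  vals <- cpp_desolv_grid(geo$origin, spacing, as.integer(geo$dims), el,
                          rep(a^3, nrow(el)), 1 / kappa_inv, K,
                          a / 2, 10 * kappa_inv + 20)
  .new_grid(vals, geo$origin, spacing, geo$dims, "desolvation",
            kappa_inv, T, ionic_strength, eps_s)
}

#' Evaluate a grid at arbitrary points by trilinear interpolation
#' @param grid a `potential_grid`.
#' @param pts 3-vector or n x 3 matrix of lab-frame points (Angstrom).
#' @return numeric vector of interpolated values.
#' @export
grid_value <- function(grid, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3, byrow = TRUE)
  cpp_trilinear(grid$values, grid$origin, grid$spacing, grid$dims, pts)
}

.empty_grid_args <- function() {
  list(values = numeric(0), origin = numeric(3), spacing = 1,
       dims = integer(3))
}

.grid_args <- function(grid) {
  if (is.null(grid)) return(.empty_grid_args())
  list(values = as.numeric(grid$values), origin = grid$origin,
       spacing = grid$spacing, dims = grid$dims)
}

#' Protein-bilayer interaction free energy on the grids
#'
#' U = sum_i q_i Phi(x_i) + sum_i q_i^2 g(x_i) in kT, with bead positions
#' x_i obtained from the body-frame coordinates via the pose, and both
#' fields trilinearly interpolated. Errors (naming the bead) if any bead
#' falls outside a grid.
#'
#' @param protein a `protein_model`.
#' @param pose a [bd_state()] (position + orientation).
#' @param potential a `potential_grid` of kind "potential".
#' @param desolvation optional `potential_grid` of kind "desolvation".
#' @return energy in kT.
#' @export
interaction_energy <- function(protein, pose, potential, desolvation = NULL) {
  d <- .grid_args(desolvation)
  cpp_energy(pose$position, pose$orientation, protein$coords, protein$charges,
             as.numeric(potential$values), potential$origin,
             potential$spacing, potential$dims,
             d$values, d$origin, d$spacing, d$dims)
}

# --- OpenDX scalar I/O (APBS-compatible) -----------------------------------

#' Write a grid in OpenDX scalar format
#' @param grid a `potential_grid`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field written by steerBD",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6e %.6e %.6e", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", grid$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  # DX stores with z fastest; our array is x fastest
  v <- aperm(array(grid$values, d), c(3, 2, 1))
  n <- length(v)
  vv <- format(v, scientific = TRUE, digits = 7)
  pad <- ceiling(n / 3) * 3 - n
  m <- matrix(c(vv, rep("", pad)), ncol = 3, byrow = TRUE)
  writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar grid (APBS output compatible)
#' @param path input file path.
#' @param kind "potential" or "desolvation".
#' @return a `potential_grid` (screening metadata unknown: `kappa_inv = NA`).
#' @export
read_dx <- function(path, kind = "potential") {
  lines <- readLines(path)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX grid: no gridpositions object", call. = FALSE)
  dims <- as.integer(strsplit(sub(".*counts +", "", gp), "\\s+")[[1]])
  org <- as.numeric(strsplit(sub("^origin +", "",
                                 grep("^origin", lines, value = TRUE)[1]),
                             "\\s+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(sub("^delta +", "", l), "\\s+")[[1]]), numeric(3)))
  spacing <- max(dmat)
  start <- grep("data follows", lines)[1] + 1
  end <- grep("attribute|^object \"", lines)
  end <- if (any(end > start)) min(end[end > start]) - 1 else length(lines)
  v <- as.numeric(unlist(strsplit(trimws(lines[start:end]), "\\s+")))
  v <- v[!is.na(v)]
  if (length(v) != prod(dims)) stop("DX data length mismatch", call. = FALSE)
  vals <- aperm(array(v, rev(dims)), c(3, 2, 1))  # z fastest -> x fastest
  .new_grid(array(vals, dims), org, spacing, dims, kind, kappa_inv = NA_real_)
}
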