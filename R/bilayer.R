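# Model bilayers: planar square lattices of headgroup charge sites in two
# leaflets, with a single central PIP3 site in the upper (cytoplasmic)
# leaflet. The bilayer is the static "receptor" of every BD run: the
# mid-plane sits at z = 0, the leaflet headgroup planes at +/- separation/2.

#' Construct a charge-scheme descriptor
#'
#' Declares how decoy (non-PIP3) charge is distributed over the upper
#' leaflet. Schemes:
#' \describe{
#'   \item{zwitterionic}{all decoy sites neutral; only the PIP3 site carries
#'     charge.}
#'   \item{fractional}{every decoy site in the upper leaflet gets the same
#'     fractional charge `fractional_charge` (e.g. -0.2 e), mimicking the
#'     time-averaged field of mobile anionic lipids.}
#'   \item{random_subset}{a seeded uniform random subset of
#'     `anionic_fraction` of the upper-leaflet decoy sites is set to -1.0 e.}
#'   \item{clustered}{like random_subset but selection grows preferentially
#'     next to already-selected sites, emulating anionic-lipid demixing in
#'     coarse-grained membrane snapshots; `cluster_strength = 0` reduces to
#'     random_subset.}
#'   \item{explicit}{charges are supplied externally (via
#'     [read_bilayer_sites()]); `assign_charges` leaves the model unchanged.}
#' }
#'
#' @param kind one of "zwitterionic", "fractional", "random_subset",
#'   "clustered", "explicit".
#' @param fractional_charge per-lipid charge in e, in \[-1, 0\]
#'   (fractional scheme).
#' @param anionic_fraction fraction of upper-leaflet decoy sites set to
#'   -1.0 e, in \[0, 1\] (random_subset / clustered).
#' @param cluster_strength non-negative; 0 = uniform selection, larger values
#'   bias selection toward lattice neighbours of selected sites.
#' @param seed integer RNG seed for the stochastic schemes.
#' @return object of class `charge_scheme`.
#' @export
charge_scheme <- function(kind = c("zwitterionic", "fractional",
                                   "random_subset", "clustered", "explicit"),
                          fractional_charge = NULL, anionic_fraction = NULL,
                          cluster_strength = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "fractional") {
    if (is.null(fractional_charge))
      stop("fractional scheme needs fractional_charge", call. = FALSE)
    if (fractional_charge > 0 || fractional_charge < -1)
      stop("fractional_charge must lie in [-1, 0] e", call. = FALSE)
  }
  if (kind %in% c("random_subset", "clustered")) {
    if (is.null(anionic_fraction))
      stop(kind, " scheme needs anionic_fraction", call. = FALSE)
    if (anionic_fraction < 0 || anionic_fraction > 1)
      stop("anionic_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cluster_strength < 0)
    stop("cluster_strength must be >= 0", call. = FALSE)
  structure(list(kind = kind,
                 fractional_charge = fractional_charge,
                 anionic_fraction = anionic_fraction,
                 cluster_strength = cluster_strength,
                 seed = as.integer(seed)),
            class = "charge_scheme")
}

#' Build a two-leaflet headgroup lattice with a central PIP3 site
#'
#' Headgroup sites are laid out on a (near-)square lattice per leaflet; the
#' number of sites per leaflet is `floor(patch area / area_per_lipid)`. The
#' upper-leaflet site closest to the lateral patch centre is replaced by the
#' PIP3 site carrying `pip3_charge`; all other sites start neutral
#' (zwitterionic). The default geometry (220 x 220 Angstrom at 62
#' Angstrom^2/lipid, 40 Angstrom leaflet separation) gives 780 sites per
#' leaflet, about 1560 lipids total.
#'
#' @param patch_dims lateral patch dimensions in Angstrom (length-2, or a
#'   scalar for a square patch).
#' @param area_per_lipid area per lipid in Angstrom^2.
#' @param leaflet_separation distance between the two headgroup planes in
#'   Angstrom (bilayer thickness).
#' @param pip3_charge net charge of the PIP3 headgroup site in e.
#' @return object of class `bilayer_model`: a list with `sites` (data.frame
#'   x, y, z, charge, leaflet, species), `patch_dims`, `leaflet_z`,
#'   `area_per_lipid`, `pip3_index` and `scheme`.
#' @export
build_patch <- function(patch_dims = c(220, 220), area_per_lipid = 62,
                        leaflet_separation = 40, pip3_charge = -7) {
  if (length(patch_dims) == 1) patch_dims <- rep(patch_dims, 2)
  if (any(!is.finite(patch_dims)) || any(patch_dims <= 0))
    stop("patch_dims must be positive", call. = FALSE)
  if (!is.finite(area_per_lipid) || area_per_lipid <= 0)
    stop("area_per_lipid must be positive", call. = FALSE)
  if (!is.finite(leaflet_separation) || leaflet_separation <= 0)
    stop("leaflet_separation must be positive", call. = FALSE)

  n_sites <- floor(prod(patch_dims) / area_per_lipid)
  if (n_sites < 1)
    stop("patch too small to host a PIP3 site (0 lattice sites)", call. = FALSE)

  # near-square grid holding exactly n_sites points, row-major fill
  nx <- ceiling(sqrt(n_sites))
  ny <- ceiling(n_sites / nx)
  dx <- patch_dims[1] / nx
  dy <- patch_dims[2] / ny
  ix <- (seq_len(nx) - 0.5) * dx - patch_dims[1] / 2
  iy <- (seq_len(ny) - 0.5) * dy - patch_dims[2] / 2
  g <- expand.grid(x = ix, y = iy)[seq_len(n_sites), , drop = FALSE]

  zu <- leaflet_separation / 2
  sites <- data.frame(
    x = c(g$x, g$x), y = c(g$y, g$y),
    z = c(rep(zu, n_sites), rep(-zu, n_sites)),
    charge = 0,
    leaflet = rep(c("upper", "lower"), each = n_sites),
    species = "zwitterionic",
    stringsAsFactors = FALSE)

  up <- which(sites$leaflet == "upper")
  cen <- up[which.min(sites$x[up]^2 + sites$y[up]^2)]
  sites$charge[cen] <- pip3_charge
  sites$species[cen] <- "pip3"

  structure(list(sites = sites,
                 patch_dims = as.numeric(patch_dims),
                 leaflet_z = c(lower = -zu, upper = zu),
                 area_per_lipid = area_per_lipid,
                 pip3_index = cen,
                 scheme = charge_scheme("zwitterionic")),
            class = "bilayer_model")
}

#' @export
print.bilayer_model <- function(x, ...) {
  up <- sum(x$sites$leaflet == "upper")
  cat(sprintf(
    "bilayer_model: %.0f x %.0f A patch, %d sites/leaflet, scheme '%s'\n",
    x$patch_dims[1], x$patch_dims[2], up, x$scheme$kind))
  cat(sprintf("  PIP3 site at (%.1f, %.1f, %.1f), charge %+.2f e; decoy charge %+.2f e\n",
              x$sites$x[x$pip3_index], x$sites$y[x$pip3_index],
              x$sites$z[x$pip3_index], x$sites$charge[x$pip3_index],
              total_decoy_charge(x)))
  invisible(x)
}

#' Total decoy (non-PIP3) charge of a bilayer
#' @param model a `bilayer_model`.
#' @return scalar charge in e.
#' @export
total_decoy_charge <- function(model) {
  sum(model$sites$charge[-model$pip3_index])
}

#' Equivalent overall anionic-lipid fraction of a fractional scheme
#'
#' A uniform fractional charge of `q` e on every upper-leaflet lipid carries
#' the same total charge as a fraction `|q| * N_upper / N_total` of all
#' lipids in the bilayer being monovalent anionic: -0.2 e on the upper
#' leaflet of a symmetric bilayer is equivalent to 10% anionic lipids
#' overall.
#'
#' @param model a `bilayer_model` (used for the leaflet site counts).
#' @param fractional_charge per-lipid charge in e.
#' @return equivalent overall anionic fraction in \[0, 1\].
#' @export
equivalent_anionic_fraction <- function(model, fractional_charge) {
  n_up <- sum(model$sites$leaflet == "upper")
  abs(fractional_charge) * n_up / nrow(model$sites)
}

.upper_decoy_idx <- function(model) {
  setdiff(which(model$sites$leaflet == "upper"), model$pip3_index)
}

#' Apply a charge scheme to the upper leaflet
#'
#' Decoy charges are placed on upper-leaflet headgroup sites only; the lower
#' leaflet stays neutral and the PIP3 site is never modified. Identical
#' (scheme, seed) pairs give identical site lists.
#'
#' @param model a `bilayer_model`.
#' @param scheme a [charge_scheme()].
#' @return a new `bilayer_model` with charges assigned.
#' @export
assign_charges <- function(model, scheme) {
  stopifnot(inherits(model, "bilayer_model"), inherits(scheme, "charge_scheme"))
  idx <- .upper_decoy_idx(model)
  s <- model$sites
  # reset decoys before applying
  s$charge[idx] <- 0
  s$species[idx] <- "zwitterionic"

  sel <- integer(0)
  if (scheme$kind == "zwitterionic" || scheme$kind == "explicit") {
    if (scheme$kind == "explicit") return(model)
  } else if (scheme$kind == "fractional") {
    s$charge[idx] <- scheme$fractional_charge
    if (scheme$fractional_charge < 0) s$species[idx] <- "anionic"
  } else {
    n_sel <- round(scheme$anionic_fraction * length(idx))
    if (n_sel > 0) {
      strength <- if (scheme$kind == "clustered") scheme$cluster_strength else 0
      sel <- .select_sites(model, idx, n_sel, strength, scheme$seed)
      s$charge[sel] <- -1.0
      s$species[sel] <- "anionic"
    }
  }
  model$sites <- s
  model$scheme <- scheme
  model
}

# Seeded site selection on the upper leaflet. strength = 0 is uniform
# sampling without replacement; strength > 0 multiplies a site's selection
# weight by (1 + strength * n_selected_neighbours), a growth process that
# aggregates the anionic phase.
.select_sites <- function(model, idx, n_sel, strength, seed) {
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  if (strength == 0) return(sample(idx, n_sel))

  xs <- model$sites$x[idx]; ys <- model$sites$y[idx]
  # lattice neighbours: within 1.5 * typical spacing
  spac <- sqrt(model$area_per_lipid)
  nb <- .lattice_neighbours(xs, ys, 1.5 * spac)
  n <- length(idx)
  selected <- logical(n)
  nsel_nb <- integer(n)  # selected-neighbour count per site
  for (k in seq_len(n_sel)) {
    w <- ifelse(selected, 0, 1 + strength * nsel_nb)
    pick <- sample.int(n, 1, prob = w)
    selected[pick] <- TRUE
    for (j in nb[[pick]]) nsel_nb[j] <- nsel_nb[j] + 1L
  }
  idx[selected]
}

.lattice_neighbours <- function(xs, ys, cutoff) {
  n <- length(xs)
  d2max <- cutoff^2
  lapply(seq_len(n), function(i) {
    d2 <- (xs - xs[i])^2 + (ys - ys[i])^2
    setdiff(which(d2 <= d2max), i)
  })
}

# preserve caller's RNG state around seeded internals
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate a spatially clustered anionic configuration
#'
#' Stand-in for anionic-lipid configurations extracted from coarse-grained
#' membrane simulations: exactly `round(f * N_upper_decoy)` sites are set to
#' -1.0 e by a seeded growth process that, for `cluster_strength > 0`,
#' preferentially selects lattice neighbours of already-selected sites.
#' `cluster_strength = 0` reproduces uniform random selection.
#'
#' @param model a `bilayer_model`.
#' @param anionic_fraction fraction of upper-leaflet decoy sites in \[0, 1\].
#' @param cluster_strength non-negative clustering bias.
#' @param seed integer RNG seed.
#' @return a new `bilayer_model`.
#' @export
generate_clustered_configuration <- function(model, anionic_fraction,
                                             cluster_strength = 5, seed = 1L) {
  assign_charges(model,
                 charge_scheme("clustered",
                               anionic_fraction = anionic_fraction,
                               cluster_strength = cluster_strength,
                               seed = seed))
}

#' Mean nearest-neighbour distance among anionic sites
#'
#' Summary statistic used to quantify spatial aggregation of the anionic
#' phase (smaller = more clustered).
#'
#' @param model a `bilayer_model` with at least two anionic sites.
#' @return mean over anionic sites of the distance to the nearest other
#'   anionic site, in Angstrom.
#' @export
anionic_nn_distance <- function(model) {
  a <- model$sites[model$sites$species == "anionic", c("x", "y")]
  if (nrow(a) < 2) stop("need at least two anionic sites", call. = FALSE)
  d <- as.matrix(stats::dist(a))
  diag(d) <- Inf
  mean(apply(d, 1, min))
}

#' Write bilayer sites as PQR-like text
#'
#' One line per site: `x y z charge leaflet species`, whitespace-separated
#' with a comment header. Read back with [read_bilayer_sites()].
#'
#' @param model a `bilayer_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bilayer_sites <- function(model, path) {
  hdr <- c("# steerBD bilayer sites",
           sprintf("# patch_dims %g %g", model$patch_dims[1], model$patch_dims[2]),
           sprintf("# leaflet_z %g %g", model$leaflet_z[["lower"]],
                   model$leaflet_z[["upper"]]),
           sprintf("# area_per_lipid %g", model$area_per_lipid),
           "# x y z charge leaflet species")
  body <- sprintf("%.4f %.4f %.4f %.6f %s %s",
                  model$sites$x, model$sites$y, model$sites$z,
                  model$sites$charge, model$sites$leaflet, model$sites$species)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read bilayer sites written by [write_bilayer_sites()]
#' @param path input file path.
#' @return a `bilayer_model` with scheme "explicit".
#' @export
read_bilayer_sites <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  .hdr_num <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(ln)) stop("missing header: ", key, call. = FALSE)
    as.numeric(strsplit(trimws(sub(paste0("^# ", key), "", ln[1])), "\\s+")[[1]])
  }
  pd <- .hdr_num("patch_dims"); lz <- .hdr_num("leaflet_z")
  apl <- .hdr_num("area_per_lipid")
  f <- strsplit(trimws(body), "\\s+")
  sites <- data.frame(
    x = as.numeric(vapply(f, `[`, "", 1)),
    y = as.numeric(vapply(f, `[`, "", 2)),
    z = as.numeric(vapply(f, `[`, "", 3)),
    charge = as.numeric(vapply(f, `[`, "", 4)),
    leaflet = vapply(f, `[`, "", 5),
    species = vapply(f, `[`, "", 6),
    stringsAsFactors = FALSE)
  pip3 <- which(sites$species == "pip3")
  if (length(pip3) != 1) stop("file must contain exactly one pip3 site", call. = FALSE)
  structure(list(sites = sites, patch_dims = pd,
                 leaflet_z = c(lower = lz[1], upper = lz[2]),
                 area_per_lipid = apl, pip3_index = pip3,
                 scheme = charge_scheme("explicit")),
            class = "bilayer_model")
}

#' Write a minimal PDB of the charge sites for visualisation
#'
#' Decoy sites become pseudo-atoms N (zwitterionic/anionic) of residue POP;
#' the PIP3 site becomes atom P of residue PIP. Coordinates only; occupancy
#' carries the site charge.
#'
#' @param model a `bilayer_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bilayer_pdb <- function(model, path) {
  s <- model$sites
  is_pip <- s$species == "pip3"
  lines <- sprintf(
    "ATOM  %5d %4s %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(s)) %% 100000,
    ifelse(is_pip, " P  ", " N  "),
    ifelse(is_pip, "PIP", "POP"),
    seq_len(nrow(s)) %% 10000,
    s$x, s$y, s$z, pmax(pmin(s$charge, 99), -9), 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
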