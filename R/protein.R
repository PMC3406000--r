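# Rigid-body protein models: bead coordinates in a body frame with origin at
# the centre of mass, point charges, a body-fixed binding-site reference
# vector, and isotropic translational/rotational diffusion constants.

# default GRP1-PH-like hydrodynamic constants (bead-model estimates)
.default_D_trans <- 1.042e-6  # cm^2 / s
.default_D_rot   <- 1.656e7   # rad^2 / s

.new_protein <- function(coords, charges, labels, ref_vector,
                         D_trans, D_rot, hydrodynamic_radius) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  stopifnot(ncol(coords) == 3, length(charges) == nrow(coords),
            length(labels) == nrow(coords))
  nv <- sqrt(sum(ref_vector^2))
  if (nv > 0) ref_vector <- ref_vector / nv else ref_vector <- c(0, 0, 1)
  structure(list(coords = coords,
                 charges = as.numeric(charges),
                 labels = as.character(labels),
                 ref_vector = as.numeric(ref_vector),
                 D_trans = D_trans, D_rot = D_rot,
                 hydrodynamic_radius = hydrodynamic_radius),
            class = "protein_model")
}

#' @export
print.protein_model <- function(x, ...) {
  cat(sprintf("protein_model: %d beads, net charge %+.3f e, |p| = %.2f D\n",
              nrow(x$coords), sum(x$charges), compute_dipole(x)$magnitude_debye))
  cat(sprintf("  D_trans = %.3e cm^2/s, D_rot = %.3e rad^2/s, a = %.1f A\n",
              x$D_trans, x$D_rot, x$hydrodynamic_radius))
  invisible(x)
}

#' Net charge of a protein model
#' @param model a `protein_model`.
#' @return total charge in e.
#' @export
net_charge <- function(model) sum(model$charges)

#' Build a toy dipolar bead protein
#'
#' Test fixture standing in for a real peripheral protein: `n_beads` beads
#' placed inside a sphere (seeded layout), with the minimum-norm charge set
#' satisfying the requested net charge and dipole moment about the centre of
#' mass. The binding-site reference vector points along the dipole axis.
#'
#' @param n_beads number of beads (>= 2).
#' @param radius sphere radius in Angstrom; also used as the hydrodynamic
#'   radius for Stokes-Einstein diffusion constants.
#' @param net_charge total charge in e.
#' @param dipole_moment dipole vector in e*Angstrom (length-3, or scalar for
#'   a dipole along +z).
#' @param seed RNG seed for the bead layout.
#' @param T temperature in K for the diffusion constants.
#' @return a `protein_model`.
#' @export
make_toy_protein <- function(n_beads = 8, radius = 12, net_charge = 0,
                             dipole_moment = c(0, 0, 0), seed = 1L, T = 300) {
  if (n_beads < 2) stop("n_beads must be >= 2", call. = FALSE)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (length(dipole_moment) == 1) dipole_moment <- c(0, 0, dipole_moment)
  stopifnot(length(dipole_moment) == 3)

  old <- .save_rng(); on.exit(.restore_rng(old), add = TRUE)
  set.seed(seed)
  # rejection-sample beads in the sphere, min separation for conditioning
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n_beads) {
    p <- stats::runif(3, -radius, radius)
    if (sum(p^2) <= radius^2 &&
        (nrow(pts) == 0 || min(colSums((t(pts) - p)^2)) > (0.3 * radius)^2))
      pts <- rbind(pts, p)
  }
  pts <- sweep(pts, 2, colMeans(pts))  # equal-mass COM at origin
  rmax <- sqrt(max(rowSums(pts^2)))    # recentring can push beads out; rescale
  if (rmax > radius) pts <- pts * (radius / rmax)

  # minimum-norm q with sum(q) = Q and t(pts) %*% q = p (pseudo-inverse,
  # so degenerate layouts, e.g. 2 collinear beads, are handled when feasible)
  A <- rbind(rep(1, n_beads), t(pts))
  b <- c(net_charge, dipole_moment)
  sv <- svd(A)
  pos <- sv$d > 1e-10 * max(sv$d)
  q <- drop(sv$v[, pos, drop = FALSE] %*%
              ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos]))
  if (max(abs(A %*% q - b)) > 1e-8)
    stop("infeasible net_charge / dipole combination for this bead layout",
         call. = FALSE)

  se <- stokes_einstein(radius, T = T)
  ref <- if (sqrt(sum(dipole_moment^2)) > 0) dipole_moment else c(0, 0, 1)
  .new_protein(pts, q, paste0("B", seq_len(n_beads)), ref,
               se$D_trans, se$D_rot, radius)
}

# --- PDB parsing -----------------------------------------------------------

.atomic_mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38)

#' Parse ATOM/HETATM records from PDB text
#'
#' Fixed-column parser for the coordinate section; returns one row per atom.
#'
#' @param pdb_text character vector of PDB lines, or a file path.
#' @return data.frame with record, serial, name, resname, chain, resseq,
#'   x, y, z, element columns.
#' @export
parse_pdb_atoms <- function(pdb_text) {
  if (length(pdb_text) == 1 && file.exists(pdb_text))
    pdb_text <- readLines(pdb_text)
  keep <- grepl("^(ATOM  |HETATM)", pdb_text)
  lines <- pdb_text[keep]
  if (!length(lines)) stop("no ATOM/HETATM records found", call. = FALSE)
  fx <- function(l, a, b) substr(l, a, b)
  num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)))
    if (length(bad))
      stop(sprintf("malformed %s field at PDB line %d", what,
                   which(keep)[bad[1]]), call. = FALSE)
    v
  }
  el <- trimws(fx(lines, 77, 78))
  # fall back to first letter of the atom name when the element column is blank
  name <- trimws(fx(lines, 13, 16))
  el[!nzchar(el)] <- gsub("[^A-Za-z].*$", "", name[!nzchar(el)])
  data.frame(
    record = trimws(fx(lines, 1, 6)),
    serial = num(fx(lines, 7, 11), "serial"),
    name = name,
    resname = trimws(fx(lines, 18, 20)),
    chain = fx(lines, 22, 22),
    resseq = num(fx(lines, 23, 26), "resseq"),
    x = num(fx(lines, 31, 38), "x"),
    y = num(fx(lines, 39, 46), "y"),
    z = num(fx(lines, 47, 54), "z"),
    element = toupper(el),
    stringsAsFactors = FALSE)
}

.aa3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE","LEU",
          "LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

.mass_weighted_com <- function(atoms) {
  m <- .atomic_mass[atoms$element]
  m[is.na(m)] <- 12.011  # unknown elements counted as carbon
  c(sum(m * atoms$x), sum(m * atoms$y), sum(m * atoms$z)) / sum(m)
}

# formal charge site for one residue's atoms: (charge, x, y, z) or NULL
.formal_site <- function(res_atoms) {
  rn <- res_atoms$resname[1]
  pick <- function(names) {
    sel <- res_atoms[res_atoms$name %in% names, , drop = FALSE]
    if (!nrow(sel)) sel <- res_atoms
    colMeans(sel[, c("x", "y", "z")])
  }
  switch(rn,
         ASP = c(-1, pick(c("OD1", "OD2"))),
         GLU = c(-1, pick(c("OE1", "OE2"))),
         LYS = c(+1, pick("NZ")),
         ARG = c(+1, pick(c("NE", "NH1", "NH2", "CZ"))),
         c(0, pick(character(0))))
}

#' Load a rigid-body protein model from PDB text
#'
#' Builds one bead per protein residue. Under the "formal" charge rule,
#' Asp/Glu get -1 e at the carboxylate centroid, Lys/Arg +1 e at the
#' amine/guanidinium centroid, His 0, and each chain's termini get +1/-1 e;
#' uncharged residues sit at their atom centroid with charge 0. Coordinates
#' are recentred on the mass-weighted centre of mass of all protein atoms.
#' Under the "file" rule, supply PQR text instead: one bead per atom with
#' the charge column.
#'
#' @param pdb_text character vector of PDB (or PQR) lines, or a file path.
#' @param charge_rule "formal" or "file".
#' @param binding_residues optional character vector of residue labels (as
#'   `"<chain><resseq>"`, e.g. `"A279"`) whose centroid defines the
#'   binding-site reference vector from the centre of mass. Default: the
#'   most positively charged residue.
#' @param D_trans,D_rot diffusion constants; defaults are bead-model
#'   estimates for a GRP1-PH-sized domain.
#' @param hydrodynamic_radius effective radius in Angstrom.
#' @return a `protein_model`.
#' @export
load_structure <- function(pdb_text, charge_rule = c("formal", "file"),
                           binding_residues = NULL,
                           D_trans = .default_D_trans, D_rot = .default_D_rot,
                           hydrodynamic_radius = 20.9) {
  charge_rule <- match.arg(charge_rule)
  if (charge_rule == "file") {
    pqr <- parse_pqr(pdb_text)
    com <- colMeans(pqr[, c("x", "y", "z")])  # PQR carries no masses
    coords <- sweep(as.matrix(pqr[, c("x", "y", "z")]), 2, com)
    labels <- paste0(pqr$chain, pqr$resseq)
    mdl <- .new_protein(coords, pqr$charge, labels, c(0, 0, 1),
                        D_trans, D_rot, hydrodynamic_radius)
    return(.set_ref_vector(mdl, binding_residues))
  }
  atoms <- parse_pdb_atoms(pdb_text)
  prot <- atoms[atoms$record == "ATOM" & atoms$resname %in% .aa3, , drop = FALSE]
  if (!nrow(prot)) stop("no protein atoms found", call. = FALSE)
  com <- .mass_weighted_com(prot)

  key <- paste0(prot$chain, prot$resseq)
  res_keys <- unique(key)
  sites <- t(vapply(res_keys, function(k) {
    .formal_site(prot[key == k, , drop = FALSE])
  }, numeric(4)))
  coords <- sites[, 2:4, drop = FALSE]
  charges <- sites[, 1]
  labels <- res_keys

  # chain termini: +1 at first residue's N, -1 at last residue's O/OXT
  for (ch in unique(prot$chain)) {
    ck <- res_keys[startsWith(res_keys, ch)]
    first <- prot[key == ck[1], , drop = FALSE]
    last <- prot[key == ck[length(ck)], , drop = FALSE]
    natm <- first[first$name == "N", , drop = FALSE]
    oatm <- last[last$name %in% c("OXT", "O"), , drop = FALSE]
    if (nrow(natm)) {
      coords <- rbind(coords, as.numeric(natm[1, c("x", "y", "z")]))
      charges <- c(charges, +1); labels <- c(labels, paste0(ch, "_NTER"))
    }
    if (nrow(oatm)) {
      coords <- rbind(coords, as.numeric(oatm[1, c("x", "y", "z")]))
      charges <- c(charges, -1); labels <- c(labels, paste0(ch, "_CTER"))
    }
  }
  coords <- sweep(coords, 2, com)
  mdl <- .new_protein(coords, charges, labels, c(0, 0, 1),
                      D_trans, D_rot, hydrodynamic_radius)
  .set_ref_vector(mdl, binding_residues)
}

.set_ref_vector <- function(model, binding_residues) {
  if (is.null(binding_residues)) {
    i <- which.max(model$charges)
    v <- model$coords[i, ]
  } else {
    sel <- model$labels %in% binding_residues
    if (!any(sel)) stop("binding_residues not found: ",
                        paste(binding_residues, collapse = ", "), call. = FALSE)
    v <- colMeans(model$coords[sel, , drop = FALSE])
  }
  nv <- sqrt(sum(v^2))
  model$ref_vector <- if (nv > 0) v / nv else c(0, 0, 1)
  model
}

#' Parse whitespace-delimited PQR records
#' @param pqr_text character vector of PQR lines, or a file path.
#' @return data.frame with name, resname, chain, resseq, x, y, z, charge,
#'   radius.
#' @export
parse_pqr <- function(pqr_text) {
  if (length(pqr_text) == 1 && file.exists(pqr_text))
    pqr_text <- readLines(pqr_text)
  lines <- pqr_text[grepl("^(ATOM|HETATM)", pqr_text)]
  if (!length(lines)) stop("no ATOM/HETATM records found", call. = FALSE)
  f <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(f)
  # chain id column is optional in PQR
  has_chain <- nf >= 11
  g <- function(i, off = 0) vapply(seq_along(f), function(k)
    f[[k]][i + if (has_chain[k]) off else 0], "")
  data.frame(
    name = g(3), resname = g(4),
    chain = ifelse(has_chain, g(5), "A"),
    resseq = as.integer(g(5, 1)),
    x = as.numeric(g(6, 1)), y = as.numeric(g(7, 1)), z = as.numeric(g(8, 1)),
    charge = as.numeric(g(9, 1)), radius = as.numeric(g(10, 1)),
    stringsAsFactors = FALSE)
}

#' Write a protein model as PQR-like text
#' @param model a `protein_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_protein_pqr <- function(model, path) {
  lines <- sprintf(
    "ATOM %6d  Q   BEA A %4d %11.4f %10.4f %10.4f %8.4f %7.3f",
    seq_along(model$charges), seq_along(model$charges),
    model$coords[, 1], model$coords[, 2], model$coords[, 3],
    model$charges, 1.0)
  writeLines(c("REMARK steerBD protein beads", lines, "END"), path)
  invisible(path)
}

#' Dipole moment of a protein model
#'
#' p = sum q_i r_i about the centre of mass (the body-frame origin). The
#' angle is measured between the dipole, rotated into the lab frame by
#' `orientation`, and `lab_axis`.
#'
#' @param model a `protein_model`.
#' @param orientation unit quaternion (w, x, y, z) giving the body-to-lab
#'   rotation; default identity.
#' @param lab_axis lab-frame axis against which the angle is reported.
#' @return list with `vector` (e*Angstrom, lab frame), `magnitude_debye`,
#'   and `angle_deg` (NaN with a warning for a zero dipole).
#' @export
compute_dipole <- function(model, orientation = c(1, 0, 0, 0),
                           lab_axis = c(0, 0, 1)) {
  p <- drop(crossprod(model$coords, model$charges))
  p_lab <- quat_rotate(orientation, p)
  mag <- sqrt(sum(p_lab^2))
  if (mag < 1e-12) {
    warning("zero dipole moment: angle undefined")
    ang <- NaN
  } else {
    u <- lab_axis / sqrt(sum(lab_axis^2))
    ang <- acos(max(-1, min(1, sum(p_lab * u) / mag))) * 180 / pi
  }
  list(vector = p_lab, magnitude_debye = mag * .const$debye_per_eA,
       angle_deg = ang)
}

#' Zero or change the charge of one residue site
#'
#' Models point mutations that remove or alter a charged side chain (e.g.
#' K279A, R284A: +1 -> 0). Geometry is untouched and the centre of mass is
#' not recomputed, preserving the rigid-body frame of the wild type.
#'
#' @param model a `protein_model`.
#' @param residue_label label of the bead to change.
#' @param new_charge new charge in e (0 for a charge-deleting mutation).
#' @return a new `protein_model`.
#' @export
mutate_charge <- function(model, residue_label, new_charge = 0) {
  i <- which(model$labels == residue_label)
  if (!length(i)) stop("unknown residue: ", residue_label, call. = FALSE)
  model$charges[i] <- new_charge
  model
}
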