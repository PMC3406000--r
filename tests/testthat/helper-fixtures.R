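# Shared fixtures, all built in code. Geometries are scaled down from the
# production defaults (220 A patch, b = 100) where a test only needs the
# mechanics, not the stated world.

# small bilayer patch: ~58 sites/leaflet, cheap grids
small_patch <- function(pip3_charge = -7) {
  build_patch(c(60, 60), 62, 40, pip3_charge)
}

# production-geometry patch under a fractional charge scheme
scheme_patch <- function(q) {
  b <- build_patch()
  if (q == 0) b else
    assign_charges(b, charge_scheme("fractional", fractional_charge = q))
}

# toy cationic dipolar protein standing in for a PH domain
toy_ph <- function(seed = 3) {
  make_toy_protein(n_beads = 8, radius = 12, net_charge = 8,
                   dipole_moment = c(0, 0, 40), seed = seed)
}

# BD parameters for scaled-down runs over the small patch
small_params <- function(max_time = 2e4, sample_interval = 50, ...) {
  bd_params(b_radius = 50, q_radius = 55, z_min_start = 40,
            max_time = max_time, sample_interval = sample_interval, ...)
}

# grid covering the small-patch BD volume (q = 55, protein radius 12)
small_grid <- function(bilayer, spacing = 2) {
  compute_potential_grid(bilayer, spacing = spacing, xy_half = 70,
                         z_range = c(0, 70))
}

# fixed-column PDB ATOM line
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     record = "ATOM", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, resname, chain, resseq, x, y, z, 1, 0, element)
}

# synthetic mini-protein: Lys + Asp with free termini (net formal charge 0)
mini_pdb <- function(shift = c(0, 0, 0)) {
  s <- shift
  c(pdb_line(1, "N",   "LYS", "A", 1, 0 + s[1], 0 + s[2], 0 + s[3]),
    pdb_line(2, "CA",  "LYS", "A", 1, 1.5 + s[1], 0 + s[2], 0 + s[3]),
    pdb_line(3, "NZ",  "LYS", "A", 1, 3.0 + s[1], 2.0 + s[2], 1.0 + s[3]),
    pdb_line(4, "N",   "ASP", "A", 2, 1.5 + s[1], -3.0 + s[2], 0 + s[3]),
    pdb_line(5, "CA",  "ASP", "A", 2, 2.5 + s[1], -4.0 + s[2], 0 + s[3]),
    pdb_line(6, "OD1", "ASP", "A", 2, 4.0 + s[1], -5.0 + s[2], 1.0 + s[3]),
    pdb_line(7, "OD2", "ASP", "A", 2, 4.0 + s[1], -5.0 + s[2], -1.0 + s[3]),
    pdb_line(8, "O",   "ASP", "A", 2, 2.0 + s[1], -5.5 + s[2], 0 + s[3]),
    "END")
}

# synthetic protein-ligand complex (labelled synthetic: stands in for a
# phosphoinositide-bound PH domain): LYS A10 sits next to the ligand
# phosphorus atoms, GLU A20 far away
synthetic_complex_pdb <- function() {
  c(pdb_line(1, "N",  "LYS", "A", 10, 0, 0, 0),
    pdb_line(2, "CA", "LYS", "A", 10, 1.4, 0, 0),
    pdb_line(3, "NZ", "LYS", "A", 10, 3.0, 1.0, 0.5),
    pdb_line(4, "N",  "GLY", "A", 15, 8, 4, 2),
    pdb_line(5, "CA", "GLY", "A", 15, 9, 4, 2),
    pdb_line(6, "N",  "GLU", "A", 20, 18, 10, 5),
    pdb_line(7, "CA", "GLU", "A", 20, 19, 10, 5),
    pdb_line(8, "OE1","GLU", "A", 20, 20, 11, 6),
    pdb_line(9, "O",  "GLU", "A", 20, 19, 12, 5),
    pdb_line(10, "P1", "IP4", "A", 99, 4.5, 1.5, 0.5, record = "HETATM",
             element = "P"),
    pdb_line(11, "P3", "IP4", "A", 99, 6.0, 2.5, 1.0, record = "HETATM",
             element = "P"),
    pdb_line(12, "P4", "IP4", "A", 99, 6.5, 0.5, -0.5, record = "HETATM",
             element = "P"),
    pdb_line(13, "P5", "IP4", "A", 99, 5.0, -0.5, -1.5, record = "HETATM",
             element = "P"),
    "END")
}

# two opposite unit charges 1 A apart along z, as PQR text (for dipole
# closed forms through the file-charge loading route)
unit_dipole_pqr <- function() {
  c("ATOM      1  Q1  ION A   1       0.000   0.000   0.500   1.0000  1.000",
    "ATOM      2  Q2  ION A   2       0.000   0.000  -0.500  -1.0000  1.000")
}

# analytic screened-Coulomb oracle: potential of point charges at pts
dh_oracle_phi <- function(src, q, pts, kappa_inv, eps_r = 78.5, T = 300) {
  pref <- steerBD::coulomb_kt(T)
  unname(apply(pts, 1, function(p) {
    r <- sqrt(colSums((t(src) - p)^2))
    sc <- if (is.finite(kappa_inv)) exp(-r / kappa_inv) else 1
    sum(q * pref * sc / (eps_r * r))
  }))
}

# analytic gradient of the screened-Coulomb potential (kT/e per Angstrom)
dh_oracle_grad <- function(src, q, pt, kappa_inv, eps_r = 78.5, T = 300) {
  pref <- steerBD::coulomb_kt(T)
  g <- c(0, 0, 0)
  for (i in seq_len(nrow(src))) {
    dv <- pt - src[i, ]
    r <- sqrt(sum(dv^2))
    sc <- if (is.finite(kappa_inv)) exp(-r / kappa_inv) else 1
    # d/dr [exp(-r/k)/r] = -exp(-r/k) (1/r^2 + 1/(k r))
    dphidr <- -pref * q[i] / eps_r * sc * (1 / r^2 +
      if (is.finite(kappa_inv)) 1 / (kappa_inv * r) else 0)
    g <- g + dphidr * dv / r
  }
  unname(g)
}
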