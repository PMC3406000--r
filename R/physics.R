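# Physical constants (CODATA 2018) and small closed forms shared across the
# package. Internal unit system: length in Angstrom, time in ps, energy in kT,
# charge in elementary charges.

.const <- list(
  kB_J      = 1.380649e-23,     # J / K
  e_C       = 1.602176634e-19,  # C
  N_A       = 6.02214076e23,    # 1 / mol
  eps0      = 8.8541878128e-12, # F / m
  kB_kcal   = 1.987204259e-3,   # kcal / (mol K)
  coul_kcal = 332.0637133,      # e^2 / Angstrom in kcal / mol (e^2 / 4 pi eps0)
  debye_per_eA = 4.80320425     # 1 e * Angstrom in Debye
)

#' Coulomb prefactor in kT units
#'
#' Energy of two unit charges 1 Angstrom apart in vacuum, expressed in units
#' of kT at temperature `T`. Divide by the relative permittivity and the
#' separation in Angstrom to get an interaction energy in kT.
#'
#' @param T temperature in Kelvin.
#' @return scalar, kT * Angstrom / e^2.
#' @export
coulomb_kt <- function(T = 300) {
  stopifnot(is.numeric(T), T > 0)
  .const$coul_kcal / (.const$kB_kcal * T)
}

#' Debye screening length
#'
#' kappa^-1 = sqrt(eps_r eps0 kB T / (2 NA e^2 * 1000 I)) for a 1:1
#' electrolyte of ionic strength `I` (mol/L).
#'
#' @param ionic_strength ionic strength in mol/L.
#' @param T temperature in Kelvin.
#' @param eps_r relative permittivity of the solvent.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(0.1, 300, 78.5) # about 10 Angstrom
#' @export
debye_length <- function(ionic_strength, T = 300, eps_r = 78.5) {
  if (!is.numeric(ionic_strength) || ionic_strength <= 0)
    stop("ionic_strength must be > 0", call. = FALSE)
  if (!is.numeric(T) || T <= 0) stop("T must be > 0", call. = FALSE)
  if (!is.numeric(eps_r) || eps_r <= 0) stop("eps_r must be > 0", call. = FALSE)
  num <- eps_r * .const$eps0 * .const$kB_J * T
  den <- 2 * .const$N_A * .const$e_C^2 * 1000 * ionic_strength
  sqrt(num / den) * 1e10
}

#' Stokes-Einstein diffusion constants for a sphere
#'
#' D = kB T / (6 pi eta a) and D_rot = kB T / (8 pi eta a^3). A fallback for
#' bead-model hydrodynamic calculations when only an effective radius is
#' known.
#'
#' @param radius hydrodynamic radius in Angstrom.
#' @param T temperature in Kelvin.
#' @param viscosity solvent viscosity in Pa s.
#' @return list with `D_trans` (cm^2/s) and `D_rot` (rad^2/s).
#' @examples
#' stokes_einstein(20.9, 300, 1e-3)$D_trans # about 1.05e-6 cm^2/s
#' @export
stokes_einstein <- function(radius, T = 300, viscosity = 1e-3) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (!is.numeric(T) || T <= 0) stop("T must be > 0", call. = FALSE)
  if (!is.numeric(viscosity) || viscosity <= 0)
    stop("viscosity must be > 0", call. = FALSE)
  a <- radius * 1e-10
  kT <- .const$kB_J * T
  list(D_trans = kT / (6 * pi * viscosity * a) * 1e4,
       D_rot   = kT / (8 * pi * viscosity * a^3))
}

#' Characteristic diffusion time over a length scale
#'
#' t = L^2 / (2 n D) with n the dimensionality (L^2/6D in 3D, L^2/4D in 2D).
#'
#' @param L length scale in Angstrom.
#' @param D diffusion constant in cm^2/s.
#' @param dimensionality 2 or 3.
#' @return time in ns.
#' @examples
#' diffusion_time(50, 1.042e-6, 3) # about 40 ns
#' @export
diffusion_time <- function(L, D, dimensionality = 3) {
  if (!is.numeric(L) || L < 0) stop("L must be >= 0", call. = FALSE)
  if (!is.numeric(D) || D <= 0) stop("D must be > 0", call. = FALSE)
  if (!dimensionality %in% c(2, 3))
    stop("dimensionality must be 2 or 3", call. = FALSE)
  L_cm <- L * 1e-8
  (L_cm^2 / (2 * dimensionality * D)) * 1e9
}

# unit conversions used by the BD engine
.D_trans_A2ps <- function(D_cm2s) D_cm2s * 1e16 / 1e12   # cm^2/s -> A^2/ps
.D_rot_rad2ps <- function(D_rads) D_rads / 1e12          # rad^2/s -> rad^2/ps
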