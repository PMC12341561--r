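#' @title Unit conventions and physical constants
#'
#' @description
#' All numerical APIs in this package use a single internal unit system:
#' energies in Hartree, lengths in Angstrom, times in femtoseconds and
#' masses in unified atomic mass units (amu).  Conversion to reporting
#' units (kcal/mol, cm^-1) happens only at reporting boundaries.
#'
#' `dd_units()` returns the conversion-constant table (CODATA 2018 based)
#' declared once here and used everywhere else.
#'
#' @return A named list of conversion constants:
#' \describe{
#'   \item{hartree_to_kcalmol}{627.5094740631}
#'   \item{hartree_joule}{Hartree in J}
#'   \item{amu_kg}{atomic mass unit in kg}
#'   \item{acc_factor}{(Hartree/Angstrom)/amu expressed in Angstrom/fs^2}
#'   \item{mass_vel2_to_hartree}{amu (Angstrom/fs)^2 expressed in Hartree}
#'   \item{kB_hartree}{Boltzmann constant in Hartree/K}
#'   \item{h_hartree_fs}{Planck constant in Hartree fs}
#'   \item{c_cm_fs}{speed of light in cm/fs}
#'   \item{freq_to_cm1}{sqrt(Hartree/(Angstrom^2 amu)) to cm^-1 factor}
#' }
#' @examples
#' u <- dd_units()
#' u$hartree_to_kcalmol * 0.001  # 1 mHartree in kcal/mol
#' @export
dd_units <- function() .dd_units

# built once at load; everything is derived from four base constants
.make_units <- function() {
  hartree_joule <- 4.3597447222071e-18
  amu_kg <- 1.66053906660e-27
  h_joule_s <- 6.62607015e-34
  kB_joule <- 1.380649e-23
  c_m_s <- 299792458
  # 1 (Hartree/Angstrom)/amu in Angstrom/fs^2:
  #   (Eh / 1e-10 m) / amu = m/s^2 ; 1 m/s^2 = 1e-20 Angstrom/fs^2
  acc_factor <- hartree_joule / (1e-10 * amu_kg) * 1e-20
  # 1 amu Angstrom^2/fs^2 in Hartree (inverse of acc_factor)
  mass_vel2_to_hartree <- 1 / acc_factor
  # angular frequency: omega^2 [fs^-2] = lambda [Eh/(A^2 amu)] * acc_factor
  # wavenumber = omega/(2 pi c),  c in cm/fs
  c_cm_fs <- c_m_s * 100 * 1e-15
  freq_to_cm1 <- sqrt(acc_factor) / (2 * pi * c_cm_fs)
  list(
    hartree_to_kcalmol = 627.5094740631,
    hartree_joule = hartree_joule,
    amu_kg = amu_kg,
    acc_factor = acc_factor,
    mass_vel2_to_hartree = mass_vel2_to_hartree,
    kB_hartree = kB_joule / hartree_joule,
    h_hartree_fs = h_joule_s / hartree_joule * 1e15,
    c_cm_fs = c_cm_fs,
    freq_to_cm1 = freq_to_cm1
  )
}

.dd_units <- .make_units()

#' Convert internal Hartree values to reported kcal/mol
#'
#' @param x numeric vector in Hartree
#' @return numeric vector in kcal/mol
#' @export
hartree_to_kcalmol <- function(x) x * .dd_units$hartree_to_kcalmol

#' Convert kcal/mol values to internal Hartree
#'
#' @param x numeric vector in kcal/mol
#' @return numeric vector in Hartree
#' @export
kcalmol_to_hartree <- function(x) x / .dd_units$hartree_to_kcalmol

#' Standard atomic masses (amu) for the supported elements
#'
#' @param elements character vector of element symbols
#' @return numeric vector of masses in amu
#' @examples
#' atomic_masses(c("C", "H", "O"))
#' @export
atomic_masses <- function(elements) {
  tab <- c(H = 1.00794, C = 12.011, N = 14.007, O = 15.999,
           F = 18.998403, S = 32.06, Cl = 35.45)
  unknown <- setdiff(unique(elements), names(tab))
  if (length(unknown) > 0L)
    stop("no tabulated mass for element(s): ", paste(unknown, collapse = ", "))
  unname(tab[elements])
}
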