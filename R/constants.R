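#' Unit conversions and physical constants
#'
#' Every cross-module unit conversion in the package goes through this one
#' table. Energies are stored in hartree on records, wavenumbers in cm^-1,
#' coordinates in angstrom, dipoles in debye; downstream modules convert to
#' kcal/mol (the reporting scale) using these factors.
#'
#' @format A named list:
#' \describe{
#'   \item{hartree_kcal}{kcal/mol per hartree (627.5095)}
#'   \item{cm1_kcal}{kcal/mol per cm^-1 (2.8591e-3), i.e. h*c*N_A}
#'   \item{hc_kB}{h*c/k_B in cm*K (1.43877): u = hc*nu/(k_B*T) = hc_kB*nu/T}
#'   \item{kB_h}{k_B/h in s^-1 K^-1 (2.08366e10), the TST prefactor per kelvin}
#'   \item{eA_debye}{debye per e*angstrom (4.80321)}
#'   \item{VA_au}{atomic units of field per V/angstrom (1.94469e-2)}
#'   \item{DVA_kcal}{kcal/mol per (debye * V/angstrom) (4.8032)}
#'   \item{coulomb_VA}{V/angstrom at 1 angstrom from 1 e, e/(4 pi eps0 A^2) = 14.3996}
#'   \item{R_kcal}{gas constant in kcal/(mol K)}
#'   \item{R_cal}{gas constant in cal/(mol K)}
#'   \item{hess_cm1}{cm^-1 per sqrt(hartree/(bohr^2 amu)): converts
#'     mass-weighted Hessian eigenvalues to wavenumbers}
#'   \item{version}{constants-table version string embedded in reports}
#' }
#' @export
oxo_constants <- local({
  # SI values used to derive the composite factors that are not quoted above
  h   <- 6.62607015e-34      # J s
  kB  <- 1.380649e-23        # J/K
  c_m <- 2.99792458e8        # m/s
  NA_ <- 6.02214076e23       # 1/mol
  Eh  <- 4.3597447222071e-18 # J
  a0  <- 0.529177210903e-10  # m
  amu <- 1.66053906660e-27   # kg
  list(
    hartree_kcal = 627.5095,
    cm1_kcal     = 2.8591e-3,
    hc_kB        = 1.43877,
    kB_h         = 2.08366e10,
    eA_debye     = 4.80321,
    VA_au        = 1.94469e-2,
    DVA_kcal     = 4.8032,
    coulomb_VA   = 14.3996,
    R_kcal       = 1.98720425e-3,
    R_cal        = 1.98720425,
    hess_cm1     = sqrt(Eh / (a0^2 * amu)) / (2 * pi * c_m * 100),
    # SI constants kept for Sackur-Tetrode / rotational partition functions
    si = list(h = h, kB = kB, c = c_m, NA_ = NA_, amu = amu),
    version = "oxoscope-constants-1"
  )
})

# Most-abundant-isotope masses (amu) and atomic numbers for the elements the
# package's fixtures and enzyme models touch. Isotope substitution is done by
# overriding per-atom masses, never by editing this table.
.element_table <- data.frame(
  symbol = c("H", "He", "B", "C", "N", "O", "F", "Na", "Mg", "Al", "Si",
             "P", "S", "Cl", "K", "Ca", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
             "Se", "Br", "I"),
  Z = c(1, 2, 5, 6, 7, 8, 9, 11, 12, 13, 14,
        15, 16, 17, 19, 20, 25, 26, 27, 28, 29, 30,
        34, 35, 53),
  mass = c(1.00782503207, 4.00260325, 11.00930536, 12.0, 14.0030740048,
           15.99491461956, 18.99840316, 22.9897692809, 23.98504170,
           26.98153853, 27.97692653, 30.97376163, 31.97207100, 34.96885268,
           38.96370668, 39.96259098, 54.9380451, 55.9349375, 58.9331950,
           57.9353429, 62.9295975, 63.9291422, 79.9165218, 78.9183376,
           126.9044719),
  stringsAsFactors = FALSE
)

#' Most-abundant-isotope mass of an element
#'
#' @param symbol character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @examples
#' element_mass(c("Fe", "O"))
#' @export
element_mass <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .element_table$mass[i]
}

#' Atomic number of an element
#' @param symbol character vector of element symbols.
#' @return integer vector of atomic numbers.
#' @export
element_Z <- function(symbol) {
  i <- match(symbol, .element_table$symbol)
  if (anyNA(i)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  .element_table$Z[i]
}

#' Mass of the deuteron (amu), for H -> D substitution
#' @export
mass_deuterium <- 2.01410177785

#' Mass of oxygen-18 (amu), for 16O -> 18O substitution
#' @export
mass_oxygen18 <- 17.9991610
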