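# Transition-state-theory kinetics, kinetic isotope effects and Boltzmann
# branching. The Eyring prefactor uses kappa = 1; tunnelling enters only
# through the Wigner factor computed from the transition state's imaginary
# wavenumber.

#' Activation free energy from a first-order rate constant
#'
#' Inverts the Eyring equation k = (k_B T / h) exp(-dG/RT) with unit
#' transmission coefficient.
#'
#' @param k rate constant in s^-1 (must be positive).
#' @param T temperature in K.
#' @return activation free energy in kcal/mol.
#' @examples
#' dg_from_rate(13, 278.15)  # 14.83 kcal/mol
#' @export
dg_from_rate <- function(k, T = 298.15) {
  if (any(k <= 0)) stop("rate constant must be positive")
  if (T <= 0) stop("T must be positive")
  cst <- oxo_constants
  -cst$R_kcal * T * log(k / (cst$kB_h * T))
}

#' Rate constant from an activation free energy
#'
#' Inverse of [dg_from_rate()]; the pair round-trips to better than 1e-10
#' relative over many orders of magnitude in k.
#'
#' @param dG activation free energy in kcal/mol.
#' @param T temperature in K.
#' @param kappa transmission coefficient (default 1).
#' @return rate constant in s^-1.
#' @export
rate_from_dg <- function(dG, T = 298.15, kappa = 1) {
  if (T <= 0) stop("T must be positive")
  cst <- oxo_constants
  kappa * cst$kB_h * T * exp(-dG / (cst$R_kcal * T))
}

#' Eyring (semiclassical) kinetic isotope effect
#'
#' KIE = exp((dG_D - dG_H) / RT): the rate ratio k_H/k_D implied by the
#' difference between the deuterated and protiated activation free energies.
#'
#' @param dG_H,dG_D activation free energies (kcal/mol) for the H and D
#'   reactions.
#' @param T temperature in K.
#' @return dimensionless KIE (> 1 iff the D barrier is higher).
#' @export
kie_eyring <- function(dG_H, dG_D, T = 298.15) {
  if (T <= 0) stop("T must be positive")
  exp((dG_D - dG_H) / (oxo_constants$R_kcal * T))
}

#' Wigner tunnelling factor
#'
#' Q_t = 1 + (h c nu / k_B T)^2 / 24 evaluated with the magnitude of the
#' transition state's imaginary wavenumber.
#'
#' @param nu imaginary-mode magnitude in cm^-1 (>= 0; a negative encoded
#'   wavenumber may be passed, its magnitude is used).
#' @param T temperature in K.
#' @return dimensionless factor >= 1.
#' @examples
#' wigner_qt(1495, 298.15)  # ~3.17
#' @export
wigner_qt <- function(nu, T = 298.15) {
  if (T <= 0) stop("T must be positive")
  u <- oxo_constants$hc_kB * abs(nu) / T
  1 + u^2 / 24
}

#' Wigner-corrected kinetic isotope effect
#'
#' Combines the Eyring KIE with the ratio of Wigner tunnelling factors for
#' the protiated and deuterated transition states:
#' KIE_Wigner = KIE_Eyring * Q_t(H) / Q_t(D).
#'
#' @param dG_H,dG_D activation free energies (kcal/mol).
#' @param nu_H,nu_D imaginary-mode magnitudes (cm^-1); typically `nu_D` comes
#'   from [isotope_frequencies()] with all abstractable H replaced by D.
#' @param T temperature in K.
#' @return an object of class `oxo_kie` with fields `dG_H`, `dG_D`, `nu_H`,
#'   `nu_D`, `KIE_eyring`, `Qt_H`, `Qt_D`, `KIE_wigner`, `T`.
#' @export
kie_wigner <- function(dG_H, dG_D, nu_H, nu_D, T = 298.15) {
  nu_H <- abs(nu_H)
  nu_D <- abs(nu_D)
  if (nu_D > nu_H) {
    warning("nu_D > nu_H is unphysical for H-transfer; result returned as-is")
  }
  ke <- kie_eyring(dG_H, dG_D, T)
  qh <- wigner_qt(nu_H, T)
  qd <- wigner_qt(nu_D, T)
  structure(
    list(dG_H = dG_H, dG_D = dG_D, nu_H = nu_H, nu_D = nu_D,
         KIE_eyring = ke, Qt_H = qh, Qt_D = qd,
         KIE_wigner = ke * qh / qd, T = T),
    class = "oxo_kie"
  )
}

#' @export
print.oxo_kie <- function(x, ...) {
  cat(sprintf(
    "<KIE at %g K> Eyring %.3f  Qt(H) %.3f  Qt(D) %.3f  Wigner %.3f\n",
    x$T, x$KIE_eyring, x$Qt_H, x$Qt_D, x$KIE_wigner))
  invisible(x)
}

#' Boltzmann branching over competing pathways
#'
#' Under the Curtin-Hammett assumption (common rapidly-equilibrating
#' reactant, irreversible first step) the product fraction of pathway i is
#' proportional to exp(-dG_i / RT). Fractions are invariant to adding a
#' constant to all barriers.
#'
#' @param dG named numeric vector of activation energies per pathway
#'   (kcal/mol); names are the pathway labels.
#' @param T temperature in K.
#' @param scale_label which energy scale the barriers are on (recorded in
#'   the result, e.g. `"G"` or `"E+ZPE"`).
#' @return an object of class `oxo_branching`: list with `pathways`, `dG`,
#'   `fractions` (summing to 1), `T`, `scale`.
#' @examples
#' branching(c(C1S = 14.5, C1R = 15.8, C2S = 21.2, C2R = 23.1))
#' @export
branching <- function(dG, T = 298.15, scale_label = "G") {
  if (length(dG) < 2L) stop("branching needs at least two pathways")
  if (is.null(names(dG))) names(dG) <- paste0("path", seq_along(dG))
  w <- exp(-(dG - min(dG)) / (oxo_constants$R_kcal * T))
  structure(
    list(pathways = names(dG), dG = dG, fractions = w / sum(w),
         T = T, scale = scale_label),
    class = "oxo_branching"
  )
}

#' @export
print.oxo_branching <- function(x, ...) {
  cat("<branching at ", x$T, " K, barriers on ", x$scale, " scale>\n", sep = "")
  for (i in seq_along(x$pathways)) {
    cat(sprintf("  %-5s dG %6.2f kcal/mol  fraction %.4f\n",
                x$pathways[i], x$dG[i], x$fractions[i]))
  }
  invisible(x)
}
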