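# RRHO thermochemistry, composite energy assembly and isotope shifts.
#
# Conventions: harmonic wavenumbers in cm^-1 with imaginary modes negative;
# ZPE and thermal corrections use unscaled frequencies unless a scale factor
# is passed explicitly; the standard state is 1 atm at the requested
# temperature; symmetry number is fixed at 1 (enzyme-model species carry no
# symmetry).

# Moment-of-inertia tensor (amu A^2) about the centre of mass.
.inertia <- function(geom) {
  m <- geom$masses
  r <- sweep(geom$coords, 2, colSums(geom$coords * m) / sum(m))
  I <- matrix(0, 3, 3)
  for (i in seq_along(m)) {
    ri <- r[i, ]
    I <- I + m[i] * (sum(ri^2) * diag(3) - tcrossprod(ri))
  }
  I
}

# TRUE when the smallest principal moment is below the linearity threshold.
.is_linear <- function(geom, tol = 1e-4) {
  ev <- eigen(.inertia(geom), symmetric = TRUE, only.values = TRUE)$values
  min(ev) < tol
}

# Orthonormal mass-weighted translation/rotation basis (3N x k matrix).
.tr_basis <- function(geom) {
  m <- geom$masses
  n <- length(m)
  r <- sweep(geom$coords, 2, colSums(geom$coords * m) / sum(m))
  sq <- sqrt(m)
  vecs <- matrix(0, 3 * n, 6)
  for (a in 1:3) vecs[seq(a, 3 * n, by = 3), a] <- sq     # translations
  cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                            u[3] * v[1] - u[1] * v[3],
                            u[1] * v[2] - u[2] * v[1])
  for (a in 1:3) {                                         # rotations
    e <- diag(3)[, a]
    for (i in 1:n) {
      vecs[(3 * i - 2):(3 * i), 3 + a] <- sq[i] * cross(e, r[i, ])
    }
  }
  q <- qr(vecs)
  rank <- sum(abs(diag(qr.R(q))) > 1e-8 * max(abs(vecs)))
  qr.Q(q)[, seq_len(rank), drop = FALSE]
}

# Frequencies (cm^-1, imaginary negative, descending) from a Cartesian
# Hessian (hartree/bohr^2) and geometry, with translations/rotations
# projected out. Returns the 3N - n_tr internal modes.
.freqs_from_hessian <- function(hessian, geom, masses = NULL) {
  m <- if (is.null(masses)) geom$masses else masses
  n <- length(m)
  if (nrow(hessian) != 3L * n) stop("hessian dimension mismatch: ",
                                    nrow(hessian), " vs 3N = ", 3L * n)
  if (any(m <= 0)) stop("masses must be positive")
  gm <- geom
  gm$masses <- m
  invsq <- rep(1 / sqrt(m), each = 3L)
  fmw <- hessian * tcrossprod(invsq)
  Q <- .tr_basis(gm)
  P <- diag(3L * n) - tcrossprod(Q)
  fproj <- P %*% fmw %*% P
  fproj <- (fproj + t(fproj)) / 2
  ev <- eigen(fproj, symmetric = TRUE, only.values = TRUE)$values
  n_tr <- ncol(Q)
  keep <- order(abs(ev), decreasing = TRUE)[seq_len(3L * n - n_tr)]
  lam <- ev[sort(keep)]
  nu <- sign(lam) * sqrt(abs(lam)) * oxo_constants$hess_cm1
  sort(nu, decreasing = TRUE)
}

#' Vibrational frequencies after isotope substitution
#'
#' Recomputes harmonic wavenumbers from a Cartesian Hessian with some atomic
#' masses replaced — the route by which 16O -> 18O and H -> D shifts are
#' obtained without touching the force field. Translations and rotations are
#' projected out; imaginary modes come back negative; ordering is descending.
#'
#' @param hessian 3N x 3N Cartesian Hessian (hartree/bohr^2).
#' @param geometry an [geometry()] object (supplies default masses).
#' @param substitutions named list/vector mapping atom index to new mass in
#'   amu, e.g. `list("2" = mass_oxygen18)`. Empty means no substitution.
#' @return numeric vector of wavenumbers (cm^-1).
#' @examples
#' # see gen_harmonic_system() for building a Hessian with known spectrum
#' @export
isotope_frequencies <- function(hessian, geometry, substitutions = list()) {
  stopifnot(inherits(geometry, "oxo_geometry"))
  m <- geometry$masses
  if (length(substitutions)) {
    idx <- as.integer(names(substitutions))
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(m))) {
      stop("substitution atom index out of range")
    }
    m[idx] <- as.numeric(unlist(substitutions))
    if (any(m <= 0)) stop("substituted masses must be positive")
  }
  .freqs_from_hessian(hessian, geometry, masses = m)
}

#' Apply a frequency scaling factor
#'
#' Real modes are multiplied by `scale`; imaginary modes (negative entries)
#' are reported with unchanged magnitude, matching the convention that
#' scaling factors calibrate observable fundamentals only.
#'
#' @param frequencies numeric vector of wavenumbers (cm^-1), imaginary
#'   negative.
#' @param scale scaling factor in (0, 1.2].
#' @return scaled wavenumbers.
#' @examples
#' scale_frequencies(860, 0.95)  # 817 cm^-1
#' @export
scale_frequencies <- function(frequencies, scale) {
  if (!is.numeric(scale) || scale <= 0 || scale > 1.2) {
    stop("scale must lie in (0, 1.2]")
  }
  ifelse(frequencies >= 0, frequencies * scale, frequencies)
}

#' Rigid-rotor harmonic-oscillator thermochemistry
#'
#' Computes ZPE, the thermal enthalpy correction, entropy and the
#' free-energy correction from the record's harmonic frequencies (or from
#' its Hessian + geometry). Imaginary modes are excluded from all sums and
#' counted in `n_imag`; more than one imaginary mode flags a warning but the
#' computation proceeds. Translational and rotational contributions require
#' a geometry; without one the result is vibration-only, which is sufficient
#' whenever only differences between species with matching frames are taken.
#'
#' @param record an [qc_record()] with `frequencies` or `hessian`+`geometry`.
#' @param T temperature in K (default 298.15).
#' @param P pressure in atm (default 1).
#' @param scale frequency scaling factor (default 1: unscaled, the package's
#'   protocol for ZPE and thermal corrections).
#' @return an object of class `oxo_thermo`: list with `ZPE`, `H_corr`
#'   (thermal enthalpy correction excluding ZPE, kcal/mol), `S`
#'   (cal/(mol K)), `G_corr` (= H_corr - T*S, kcal/mol), `T`, `P`, `n_imag`,
#'   and `modes` (the real wavenumbers used).
#' @examples
#' r <- qc_record("m", 0, 1, E_high = -1, frequencies = 1000)
#' rrho(r)$ZPE  # 1.4296 kcal/mol
#' @export
rrho <- function(record, T = 298.15, P = 1, scale = 1.0) {
  stopifnot(inherits(record, "oxo_qc_record"))
  if (T <= 0) stop("T must be positive")
  cst <- oxo_constants
  if (!is.null(record$frequencies)) {
    nu <- record$frequencies
  } else if (!is.null(record$hessian) && !is.null(record$geometry)) {
    nu <- .freqs_from_hessian(record$hessian, record$geometry)
  } else if (!is.null(record$geometry) && length(record$geometry$elements) == 1L) {
    nu <- numeric(0)  # single atom: translation only
  } else {
    stop("record '", record$label,
         "' has neither frequencies nor hessian+geometry; ",
         "thermochemistry needs exactly one of them")
  }
  if (scale != 1.0) nu <- scale_frequencies(nu, scale)
  n_imag <- sum(nu < 0)
  if (n_imag > 1L) {
    warning("record '", record$label, "' has ", n_imag,
            " imaginary modes; all excluded from thermochemistry")
  }
  nu <- nu[nu > 0]
  ZPE <- sum(0.5 * nu * cst$cm1_kcal)
  u <- cst$hc_kB * nu / T
  H_vib <- cst$R_kcal * T * sum(u / expm1(u))
  S_vib <- cst$R_cal * sum(u / expm1(u) - log1p(-exp(-u)))
  H_tr <- 0
  S_tr <- 0
  if (!is.null(record$geometry)) {
    g <- record$geometry
    si <- cst$si
    M <- sum(g$masses) * si$amu                       # kg per molecule
    kT <- si$kB * T
    P_pa <- P * 101325
    q_trans <- (2 * pi * M * kT / si$h^2)^1.5 * kT / P_pa
    S_tr <- S_tr + cst$R_cal * (log(q_trans) + 2.5)
    H_tr <- H_tr + 2.5 * cst$R_kcal * T               # 3/2 RT + PV
    n <- length(g$elements)
    if (n > 1L) {
      Ivals <- eigen(.inertia(g), symmetric = TRUE, only.values = TRUE)$values
      Ivals <- Ivals * si$amu * 1e-20                 # kg m^2
      if (.is_linear(g)) {
        qr_ <- 8 * pi^2 * max(Ivals) * kT / si$h^2    # sigma = 1
        S_tr <- S_tr + cst$R_cal * (log(qr_) + 1)
        H_tr <- H_tr + cst$R_kcal * T
      } else {
        qr_ <- sqrt(pi) * (8 * pi^2 * kT / si$h^2)^1.5 * sqrt(prod(Ivals))
        S_tr <- S_tr + cst$R_cal * (log(qr_) + 1.5)
        H_tr <- H_tr + 1.5 * cst$R_kcal * T
      }
    }
  }
  H_corr <- H_vib + H_tr
  S <- S_vib + S_tr
  structure(
    list(ZPE = ZPE, H_corr = H_corr, S = S,
         G_corr = H_corr - T * S / 1000, T = T, P = P,
         n_imag = n_imag, modes = nu),
    class = "oxo_thermo"
  )
}

#' @export
print.oxo_thermo <- function(x, ...) {
  cat(sprintf(
    "<thermo %g K, %g atm> ZPE %.4f kcal/mol  H_corr %.4f kcal/mol  S %.4f cal/(mol K)  G_corr %.4f kcal/mol  n_imag %d\n",
    x$T, x$P, x$ZPE, x$H_corr, x$S, x$G_corr, x$n_imag))
  invisible(x)
}

.schemes <- c("E+ZPE", "E+ZPE+solv", "E+ZPE+solv+disp", "G")

#' Assemble a composite energy for one species
#'
#' Combines the record's electronic energy with ZPE, solvation, dispersion
#' and (for the free-energy scheme) thermal and entropy terms, all on the
#' kcal/mol scale. Schemes:
#' \describe{
#'   \item{`E+ZPE`}{E_high + ZPE}
#'   \item{`E+ZPE+solv`}{adds the solvation correction (errors if absent)}
#'   \item{`E+ZPE+solv+disp`}{adds the dispersion correction too}
#'   \item{`G`}{free energy: E_high + ZPE + thermal + (-T*S), plus solvation
#'     and dispersion whenever the record carries them}
#' }
#'
#' @param record an [qc_record()].
#' @param thermo an `oxo_thermo` from [rrho()]; computed on the fly when
#'   `NULL`.
#' @param scheme one of the labels above.
#' @param T,P passed to [rrho()] when `thermo` is `NULL`.
#' @return an object of class `oxo_energy`: list with `E_total` (kcal/mol),
#'   `components` (named kcal/mol contributions summing to `E_total`) and
#'   `scheme`.
#' @export
assemble <- function(record, thermo = NULL,
                     scheme = c("E+ZPE+solv+disp", "E+ZPE+solv", "E+ZPE", "G"),
                     T = 298.15, P = 1) {
  stopifnot(inherits(record, "oxo_qc_record"))
  scheme <- match.arg(scheme)
  if (is.null(thermo)) thermo <- rrho(record, T = T, P = P)
  h2k <- oxo_constants$hartree_kcal
  comp <- c(E_high = record$E_high * h2k, ZPE = thermo$ZPE)
  need_solv <- scheme %in% c("E+ZPE+solv", "E+ZPE+solv+disp")
  need_disp <- scheme == "E+ZPE+solv+disp"
  if (need_solv) {
    if (is.null(record$E_solv)) {
      stop("scheme '", scheme, "' needs component E_solv, missing on record '",
           record$label, "'")
    }
    comp["E_solv"] <- record$E_solv * h2k
  }
  if (need_disp) {
    if (is.null(record$E_disp)) {
      stop("scheme '", scheme, "' needs component E_disp, missing on record '",
           record$label, "'")
    }
    comp["E_disp"] <- record$E_disp * h2k
  }
  if (scheme == "G") {
    if (!is.null(record$E_solv)) comp["E_solv"] <- record$E_solv * h2k
    if (!is.null(record$E_disp)) comp["E_disp"] <- record$E_disp * h2k
    comp["thermal"] <- thermo$H_corr
    comp["-TS"] <- -thermo$T * thermo$S / 1000
  }
  structure(
    list(E_total = sum(comp), components = as.list(comp), scheme = scheme),
    class = "oxo_energy"
  )
}

#' @export
print.oxo_energy <- function(x, ...) {
  cat(sprintf("<assembled energy, scheme %s> %.4f kcal/mol\n",
              x$scheme, x$E_total))
  invisible(x)
}
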