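# Bond dissociation free energies and their response to uniform external
# electric fields. BDFE is the homolysis free energy
# G(R.) + G(H.) - G(RH); the field response is first order in the dipole
# difference by default (-(dmu . u) F), with an optional quadratic
# polarizability term.

#' Bond dissociation free energy from species free energies
#'
#' @param G_RH free energy of the parent (kcal/mol), or an `oxo_energy`.
#' @param G_R free energy of the radical R. (same scale/scheme).
#' @param G_H free energy of the hydrogen atom.
#' @param bond bond label (e.g. `"C1-H pro-R"`).
#' @param medium `"gas"` or `"solvated"`, propagated to the result.
#' @return an object of class `oxo_bdfe`: list with `bond`, `BDFE`
#'   (kcal/mol), `components` (G_R, G_H, G_RH), `medium`.
#' @examples
#' bdfe(G_RH = -100, G_R = -30, G_H = 15.8, bond = "C1-H")
#' @export
bdfe <- function(G_RH, G_R, G_H, bond = "C-H", medium = "gas") {
  pull <- function(x, nm) {
    if (inherits(x, "oxo_energy")) {
      list(val = x$E_total, scheme = x$scheme)
    } else if (is.numeric(x) && length(x) == 1L) {
      list(val = x, scheme = NA_character_)
    } else stop(nm, " must be a number or an assembled energy")
  }
  g <- lapply(list(G_RH = G_RH, G_R = G_R, G_H = G_H), pull, nm = "G")
  schemes <- unique(stats::na.omit(vapply(g, `[[`, "", "scheme")))
  if (length(schemes) > 1L) {
    stop("mixed assembly schemes in BDFE components: ",
         paste(schemes, collapse = " vs "))
  }
  vals <- vapply(g, `[[`, 0, "val")
  structure(
    list(bond = bond, BDFE = vals[["G_R"]] + vals[["G_H"]] - vals[["G_RH"]],
         components = list(G_R = vals[["G_R"]], G_H = vals[["G_H"]],
                           G_RH = vals[["G_RH"]]),
         medium = medium),
    class = "oxo_bdfe"
  )
}

#' @export
print.oxo_bdfe <- function(x, ...) {
  cat(sprintf("<BDFE %s, %s> %.2f kcal/mol\n", x$bond, x$medium, x$BDFE))
  invisible(x)
}

#' Stark (field-perturbed) BDFE
#'
#' First-order response of a homolysis free energy to a uniform field F
#' along axis u: BDFE(F) = BDFE(0) - (dmu . u) F, with dmu the dipole of
#' the dissociated fragments minus the parent (debye) and F in V/angstrom
#' (1 debye * V/angstrom = 4.8032 kcal/mol). The quadratic model adds
#' -1/2 dalpha F^2 when a polarizability difference is supplied
#' (dalpha in debye angstrom/V, converted with the same factor).
#'
#' @param bdfe0 zero-field BDFE (kcal/mol).
#' @param dmu dipole difference, a 3-vector in debye (or a scalar already
#'   projected on the axis).
#' @param F signed field strength in V/angstrom (|F| <= 1).
#' @param axis unit 3-vector of the field direction (ignored for scalar
#'   `dmu`); default +z.
#' @param model `"linear"` or `"quadratic"`.
#' @param dalpha polarizability difference (debye angstrom/V), required for
#'   the quadratic model.
#' @return BDFE(F) in kcal/mol (vectorized over `F`).
#' @export
stark_bdfe <- function(bdfe0, dmu, F, axis = c(0, 0, 1),
                       model = c("linear", "quadratic"), dalpha = NULL) {
  model <- match.arg(model)
  if (any(abs(F) > 1)) stop("|F| must be <= 1 V/angstrom")
  proj <- if (length(dmu) == 3L) {
    u <- axis / sqrt(sum(axis^2))
    sum(dmu * u)
  } else as.numeric(dmu)
  out <- bdfe0 - proj * F * oxo_constants$DVA_kcal
  if (model == "quadratic") {
    if (is.null(dalpha)) stop("quadratic model requires dalpha")
    out <- out - 0.5 * dalpha * F^2 * oxo_constants$DVA_kcal
  }
  out
}

#' BDFE field scan over several bonds
#'
#' Evaluates the linear Stark model for each named bond over a signed field
#' grid along one molecular axis (axes pass through the centre of mass;
#' +u means the field vector points along +u).
#'
#' @param bonds list of `list(label =, bdfe0 =, dmu =)` entries, `dmu` a
#'   3-vector in debye or a projected scalar.
#' @param axis `"x"`, `"y"` or `"z"`, or a unit 3-vector.
#' @param fields numeric vector of signed field values in V/angstrom.
#' @return an object of class `oxo_field_scan`: list with `fields`, `axis`,
#'   `bdfe` (matrix fields x bonds), `slopes` (kcal/mol per V/angstrom).
#' @export
field_scan <- function(bonds, axis = "y",
                       fields = seq(-0.5, 0.5, by = 0.05)) {
  if (is.character(axis)) {
    axis <- switch(match.arg(axis, c("x", "y", "z")),
                   x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  }
  labels <- vapply(bonds, `[[`, "", "label")
  vals <- sapply(bonds, function(b) stark_bdfe(b$bdfe0, b$dmu, fields, axis))
  vals <- matrix(vals, nrow = length(fields),
                 dimnames = list(NULL, labels))
  slopes <- (vals[nrow(vals), ] - vals[1, ]) /
    (fields[length(fields)] - fields[1])
  structure(
    list(fields = fields, axis = axis, bdfe = vals, slopes = slopes),
    class = "oxo_field_scan"
  )
}

#' Field at which two linear BDFE responses cross
#'
#' @param bondA,bondB numeric `c(bdfe0, slope)` pairs describing
#'   BDFE(F) = bdfe0 + slope * F.
#' @return list with `type` (`"crossing"`, `"degenerate"` for identical
#'   lines, `"none"` for parallel distinct lines) and `field` (V/angstrom,
#'   `NA` unless a single crossing exists).
#' @examples
#' crossing_field(c(80, -2), c(76, 1))  # F* = 4/3
#' @export
crossing_field <- function(bondA, bondB) {
  d0 <- bondA[1] - bondB[1]
  ds <- bondA[2] - bondB[2]
  if (abs(ds) < 1e-12) {
    if (abs(d0) < 1e-12) return(list(type = "degenerate", field = NA_real_))
    return(list(type = "none", field = NA_real_))
  }
  list(type = "crossing", field = -d0 / ds)
}

#' Weakest bond at each field of a scan
#'
#' @param scan an [field_scan()] object.
#' @return data frame with `field` and `weakest` (bond label at the BDFE
#'   argmin); transition fields (where the label switches between adjacent
#'   grid points) are in attribute `"transitions"`.
#' @export
weakest_bond_map <- function(scan) {
  stopifnot(inherits(scan, "oxo_field_scan"))
  if (ncol(scan$bdfe) < 1L) stop("scan has no bonds")
  lab <- colnames(scan$bdfe)[apply(scan$bdfe, 1, which.min)]
  out <- data.frame(field = scan$fields, weakest = lab,
                    stringsAsFactors = FALSE)
  sw <- which(lab[-1] != lab[-length(lab)])
  attr(out, "transitions") <- (scan$fields[sw] + scan$fields[sw + 1L]) / 2
  out
}

#' Alignment of a dipole with a bond axis
#'
#' @param mu dipole 3-vector (any units).
#' @param bond_axis direction 3-vector.
#' @return cosine of the angle, with attribute `"class"` one of
#'   `"aligned"` (cos > 0.5), `"anti-aligned"` (cos < -0.5) or
#'   `"orthogonal"`.
#' @export
dipole_alignment <- function(mu, bond_axis) {
  nm <- sqrt(sum(mu^2))
  nb <- sqrt(sum(bond_axis^2))
  if (nm == 0 || nb == 0) stop("zero vector in dipole_alignment")
  ct <- sum(mu * bond_axis) / (nm * nb)
  attr(ct, "class") <- if (ct > 0.5) "aligned" else if (ct < -0.5)
    "anti-aligned" else "orthogonal"
  ct
}
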