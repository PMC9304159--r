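#' Molecular geometry
#'
#' A light container for atomic positions: element symbols, per-atom masses
#' (amu) and Cartesian coordinates in angstrom. Masses default to the most
#' abundant isotope of each element and can be overridden atom by atom, which
#' is how isotope substitution (e.g. 16O -> 18O, H -> D) enters the package.
#'
#' @param elements character vector of element symbols.
#' @param coords numeric N x 3 matrix of Cartesian coordinates (angstrom).
#' @param masses optional numeric vector of per-atom masses (amu); default
#'   most-abundant-isotope masses from [element_mass()].
#' @return an object of class `oxo_geometry`.
#' @examples
#' geometry(c("Fe", "O"), rbind(c(0, 0, 0), c(0, 0, 1.62)))
#' @export
geometry <- function(elements, coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("geometry needs at least one atom")
  if (ncol(coords) != 3L || nrow(coords) != length(elements)) {
    stop("coords must be an N x 3 matrix matching length(elements)")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (is.null(masses)) masses <- element_mass(elements)
  masses <- as.numeric(masses)
  if (length(masses) != length(elements)) {
    stop("masses must have one entry per atom")
  }
  if (any(!is.finite(masses) | masses <= 0)) stop("masses must be positive")
  element_Z(elements)  # errors on symbols not in the periodic table
  structure(
    list(elements = as.character(elements), masses = masses,
         coords = unname(coords)),
    class = "oxo_geometry"
  )
}

#' @export
print.oxo_geometry <- function(x, ...) {
  cat("<geometry> ", length(x$elements), " atoms: ",
      paste(x$elements, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Quantum-chemistry result record for one species
#'
#' Holds, for a single stationary point, the quantities an electronic
#' structure code prints: electronic energies at the optimization and
#' single-point levels (hartree), solvation and dispersion corrections
#' (hartree), harmonic wavenumbers (cm^-1, imaginary modes encoded as
#' negative values), the Cartesian Hessian (hartree/bohr^2), dipole vector
#' (debye), per-atom spin densities and the geometry. All downstream
#' thermochemistry requires exactly one of `frequencies` or
#' `hessian` + `geometry`.
#'
#' `E_solv` and `E_disp` are kept absent (`NULL`) unless supplied; an energy
#' assembly scheme that names a missing component fails loudly rather than
#' silently assuming zero.
#'
#' @param label species label (string).
#' @param charge total charge in e (integer).
#' @param multiplicity spin multiplicity 2S+1 (integer >= 1).
#' @param E_high electronic energy at the single-point level (hartree).
#' @param E_low optional energy at the geometry-optimization level (hartree).
#' @param E_solv optional solvation correction (hartree).
#' @param E_disp optional dispersion correction (hartree).
#' @param frequencies optional numeric vector of harmonic wavenumbers
#'   (cm^-1); imaginary modes negative.
#' @param hessian optional 3N x 3N Cartesian Hessian (hartree/bohr^2).
#' @param dipole optional length-3 dipole vector (debye).
#' @param spin_densities optional per-atom unpaired-spin populations.
#' @param geometry optional [geometry()] object.
#' @return an object of class `oxo_qc_record`.
#' @examples
#' qc_record("5Re", charge = 0, multiplicity = 5, E_high = -100.0,
#'           frequencies = c(860, 1200))
#' @export
qc_record <- function(label, charge, multiplicity, E_high,
                      E_low = NULL, E_solv = NULL, E_disp = NULL,
                      frequencies = NULL, hessian = NULL, dipole = NULL,
                      spin_densities = NULL, geometry = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  charge <- as.integer(charge)
  multiplicity <- as.integer(multiplicity)
  if (is.na(multiplicity) || multiplicity < 1L) {
    stop("multiplicity must be an integer >= 1")
  }
  for (nm in c("E_high", "E_low", "E_solv", "E_disp")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !is.finite(v))) {
      stop("non-numeric energy for ", nm)
    }
  }
  if (!is.null(frequencies)) {
    frequencies <- as.numeric(frequencies)
    if (any(!is.finite(frequencies))) stop("frequencies must be finite")
  }
  if (!is.null(geometry) && !inherits(geometry, "oxo_geometry")) {
    stop("geometry must be built with geometry()")
  }
  if (!is.null(hessian)) {
    hessian <- as.matrix(hessian)
    if (nrow(hessian) != ncol(hessian)) stop("hessian must be square")
    if (max(abs(hessian - t(hessian))) > 1e-6 * max(1, max(abs(hessian)))) {
      stop("hessian must be symmetric within tolerance")
    }
    if (!is.null(geometry) && nrow(hessian) != 3L * length(geometry$elements)) {
      stop("hessian dimension must be 3N x 3N for the N-atom geometry")
    }
  }
  if (!is.null(dipole)) {
    dipole <- as.numeric(dipole)
    if (length(dipole) != 3L) stop("dipole must be a 3-vector (debye)")
  }
  if (!is.null(spin_densities)) spin_densities <- as.numeric(spin_densities)
  # Spin/electron-count parity is only checkable when both charge and
  # geometry (hence element identities) are present.
  if (!is.null(geometry)) {
    n_elec <- sum(element_Z(geometry$elements)) - charge
    if ((n_elec + multiplicity) %% 2L != 1L) {
      stop("multiplicity ", multiplicity, " inconsistent with ", n_elec,
           " electrons (needs ", ifelse(n_elec %% 2L == 0L, "odd", "even"),
           " multiplicity)")
    }
  }
  structure(
    list(label = label, charge = charge, multiplicity = multiplicity,
         E_high = E_high, E_low = E_low, E_solv = E_solv, E_disp = E_disp,
         frequencies = frequencies, hessian = hessian, dipole = dipole,
         spin_densities = spin_densities, geometry = geometry),
    class = "oxo_qc_record"
  )
}

#' @export
print.oxo_qc_record <- function(x, ...) {
  cat("<qc_record> ", x$label, "  charge ", x$charge, "  2S+1 ",
      x$multiplicity, "\n", sep = "")
  cat("  E_high ", format(x$E_high), " hartree",
      if (!is.null(x$E_solv)) paste0("  E_solv ", format(x$E_solv)),
      if (!is.null(x$E_disp)) paste0("  E_disp ", format(x$E_disp)), "\n",
      sep = "")
  if (!is.null(x$frequencies)) {
    cat("  ", length(x$frequencies), " frequencies, ",
        sum(x$frequencies < 0), " imaginary\n", sep = "")
  }
  if (!is.null(x$hessian)) {
    cat("  hessian ", nrow(x$hessian), "x", ncol(x$hessian), "\n", sep = "")
  }
  invisible(x)
}

# --- record file format -----------------------------------------------------
# One species per file, human-readable YAML with an explicit format/units
# header so fixtures can be audited by eye.

.record_format <- "oxoscope-qc-record"
.record_version <- 1L
.record_units <- list(energies = "hartree", frequencies = "cm-1",
                      coordinates = "angstrom", hessian = "hartree/bohr2",
                      dipole = "debye", masses = "amu")

#' Write a QC record to its text format
#'
#' The on-disk format is a YAML document with a format/version/units header;
#' [read_qc_record()] reproduces the record field-for-field (floats to
#' better than 1e-12 relative).
#'
#' @param record an [qc_record()] object.
#' @param path file path to write.
#' @return invisibly, `path`.
#' @export
write_qc_record <- function(record, path) {
  stopifnot(inherits(record, "oxo_qc_record"))
  doc <- list(format = .record_format, version = .record_version,
              units = .record_units,
              label = record$label, charge = record$charge,
              multiplicity = record$multiplicity, E_high = record$E_high)
  for (nm in c("E_low", "E_solv", "E_disp")) {
    if (!is.null(record[[nm]])) doc[[nm]] <- record[[nm]]
  }
  if (!is.null(record$frequencies)) doc$frequencies <- as.list(record$frequencies)
  if (!is.null(record$hessian)) {
    doc$hessian <- lapply(seq_len(nrow(record$hessian)),
                          function(i) as.list(record$hessian[i, ]))
  }
  if (!is.null(record$dipole)) doc$dipole <- as.list(record$dipole)
  if (!is.null(record$spin_densities)) {
    doc$spin_densities <- as.list(record$spin_densities)
  }
  if (!is.null(record$geometry)) {
    g <- record$geometry
    doc$geometry <- lapply(seq_along(g$elements), function(i) {
      list(element = g$elements[i], mass = g$masses[i],
           xyz = as.list(g$coords[i, ]))
    })
  }
  txt <- yaml::as.yaml(doc, precision = 17L)
  ok <- try(writeLines(txt, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write record to ", path)
  invisible(path)
}

#' Read a QC record from its text format
#'
#' @param path file path of a record written by [write_qc_record()] (or by
#'   the synthetic generators, which emit the same format).
#' @return an [qc_record()] object. Unknown keys are preserved in the
#'   `"extra"` attribute but otherwise ignored.
#' @export
read_qc_record <- function(path) {
  if (!file.exists(path)) stop("no such record file: ", path)
  doc <- yaml::yaml.load_file(path)
  if (!identical(doc$format, .record_format)) {
    stop("not an ", .record_format, " file: ", path)
  }
  for (nm in c("label", "charge", "multiplicity", "E_high")) {
    if (is.null(doc[[nm]])) stop("missing mandatory field '", nm, "' in ", path)
  }
  for (nm in c("E_high", "E_low", "E_solv", "E_disp")) {
    if (!is.null(doc[[nm]]) && !is.numeric(doc[[nm]])) {
      stop("non-numeric energy for key '", nm, "' in ", path)
    }
  }
  geom <- NULL
  if (!is.null(doc$geometry)) {
    geom <- geometry(
      elements = vapply(doc$geometry, `[[`, "", "element"),
      coords = t(vapply(doc$geometry,
                        function(a) as.numeric(unlist(a$xyz)), numeric(3))),
      masses = vapply(doc$geometry, function(a) as.numeric(a$mass), 0)
    )
  }
  hess <- NULL
  if (!is.null(doc$hessian)) {
    hess <- do.call(rbind, lapply(doc$hessian, function(r) as.numeric(unlist(r))))
  }
  known <- c("format", "version", "units", "label", "charge", "multiplicity",
             "E_high", "E_low", "E_solv", "E_disp", "frequencies", "hessian",
             "dipole", "spin_densities", "geometry")
  rec <- qc_record(
    label = doc$label, charge = doc$charge, multiplicity = doc$multiplicity,
    E_high = doc$E_high, E_low = doc$E_low, E_solv = doc$E_solv,
    E_disp = doc$E_disp,
    frequencies = if (!is.null(doc$frequencies)) as.numeric(unlist(doc$frequencies)),
    hessian = hess,
    dipole = if (!is.null(doc$dipole)) as.numeric(unlist(doc$dipole)),
    spin_densities = if (!is.null(doc$spin_densities))
      as.numeric(unlist(doc$spin_densities)),
    geometry = geom
  )
  extra <- doc[setdiff(names(doc), known)]
  if (length(extra)) attr(rec, "extra") <- extra
  rec
}

# --- XYZ --------------------------------------------------------------------

#' Write a geometry as a standard XYZ file (angstrom)
#' @param geom an [geometry()] object.
#' @param path file path.
#' @param comment second-line comment.
#' @return invisibly, `path`.
#' @export
write_xyz <- function(geom, path, comment = "") {
  stopifnot(inherits(geom, "oxo_geometry"))
  n <- length(geom$elements)
  lines <- c(as.character(n), comment,
             sprintf("%-3s %18.10f %18.10f %18.10f", geom$elements,
                     geom$coords[, 1], geom$coords[, 2], geom$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a standard XYZ file (angstrom)
#' @param path file path.
#' @return an [geometry()] object with default isotope-pure masses.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ: first line must be the atom count")
  if (length(lines) < n + 2L) stop("malformed XYZ: fewer lines than declared")
  body <- lines[seq(3L, 2L + n)]
  parts <- strsplit(trimws(body), "\\s+")
  el <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (any(!is.finite(xyz))) stop("malformed XYZ coordinate line")
  geometry(el, xyz)
}

# --- PDB --------------------------------------------------------------------

#' Read a protein structure from a PDB file
#'
#' Thin wrapper over `bio3d::read.pdb()` that applies the package's
#' conventions: ATOM/HETATM records of the first model only, with altloc
#' 'A' or blank preferred when alternate conformers are present. Residue
#' numbering is preserved exactly as read.
#'
#' @param path path to a PDB-format text file.
#' @return an object of class `oxo_protein`, a data frame with columns
#'   `type`, `resid`, `resno`, `chain`, `atom`, `element`, `x`, `y`, `z`,
#'   `alt`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e))
  )
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("empty structure: no ATOM/HETATM records in ", path)
  keep <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("empty structure after altloc filtering in ", path)
  out <- data.frame(
    type = a$type, resid = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    atom = a$elety,
    element = ifelse(is.na(a$elesy) | a$elesy == "",
                     substr(trimws(a$elety), 1, 1), trimws(a$elesy)),
    x = a$x, y = a$y, z = a$z,
    alt = ifelse(is.na(a$alt), "", a$alt),
    stringsAsFactors = FALSE
  )
  class(out) <- c("oxo_protein", "data.frame")
  out
}

#' @export
print.oxo_protein <- function(x, ...) {
  cat("<protein structure> ", nrow(x), " atoms, ",
      nrow(unique(x[x$type == "ATOM", c("chain", "resno")])),
      " protein residues\n", sep = "")
  invisible(x)
}
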