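# Protein-level point-charge electrostatics: charged-residue census, formal
# charges at side-chain representative atoms, dipole vector and Coulomb
# field at a site. Formal charges follow the standard pH-7 assignment
# (Asp/Glu -1, Arg/Lys +1, His neutral unless flagged doubly protonated);
# termini are ignored.

.amino3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")

# "A:70" -> chain A residue 70; bare numbers match any chain
.parse_resids <- function(ids) {
  if (!length(ids)) return(data.frame(chain = character(), resno = integer()))
  parts <- strsplit(as.character(ids), ":", fixed = TRUE)
  data.frame(
    chain = vapply(parts, function(p) if (length(p) == 2L) p[1] else "", ""),
    resno = vapply(parts, function(p) as.integer(p[length(p)]), 1L),
    stringsAsFactors = FALSE
  )
}

.his_flagged <- function(chain, resno, flags) {
  if (!nrow(flags)) return(rep(FALSE, length(resno)))
  mapply(function(ch, rn) any((flags$chain == "" | flags$chain == ch) &
                                flags$resno == rn), chain, resno)
}

#' Charged-residue census of a protein structure
#'
#' Counts residue types over unique (chain, residue number) of the first
#' model, ATOM records only (HETATM groups are excluded from the
#' amino-acid tally). Negative = Asp + Glu; positive = Arg + Lys plus any
#' His flagged as doubly protonated.
#'
#' @param structure an `oxo_protein` from [read_pdb()].
#' @param his_protonated character vector of doubly-protonated His ids,
#'   `"chain:resno"` or bare residue numbers.
#' @return an object of class `oxo_census`: list with `counts` (named per
#'   residue type), `n_negative`, `n_positive`, `net` (e).
#' @export
residue_census <- function(structure, his_protonated = character()) {
  stopifnot(inherits(structure, "oxo_protein"))
  aa <- structure[structure$type == "ATOM" & structure$resid %in% .amino3, ]
  if (!nrow(aa)) stop("empty structure: no amino-acid ATOM records")
  res <- unique(aa[, c("chain", "resno", "resid")])
  counts <- table(factor(res$resid, levels = .amino3))
  flags <- .parse_resids(his_protonated)
  his <- res[res$resid == "HIS", , drop = FALSE]
  n_hisp <- sum(.his_flagged(his$chain, his$resno, flags))
  n_neg <- sum(counts[c("ASP", "GLU")])
  n_pos <- sum(counts[c("ARG", "LYS")]) + n_hisp
  structure(
    list(counts = c(counts), n_negative = n_neg, n_positive = n_pos,
         n_his_protonated = n_hisp, net = n_pos - n_neg),
    class = "oxo_census"
  )
}

#' @export
print.oxo_census <- function(x, ...) {
  cat("<residue census> ", sum(x$counts), " residues; ",
      x$n_negative, " negative (ASP ", x$counts[["ASP"]], " + GLU ",
      x$counts[["GLU"]], "), ", x$n_positive, " positive (ARG ",
      x$counts[["ARG"]], " + LYS ", x$counts[["LYS"]],
      if (x$n_his_protonated) paste0(" + HIS+ ", x$n_his_protonated) else "",
      "); net ", x$net, " e\n", sep = "")
  invisible(x)
}

# side-chain charge-bearing representative atoms
.rep_atoms <- c(ASP = "CG", GLU = "CD", ARG = "CZ", LYS = "NZ")

#' Point-charge model of a protein's charged residues
#'
#' Places a formal charge (+1/-1 e) at the side-chain representative atom
#' of each charged residue: CG for Asp, CD for Glu, CZ for Arg, NZ for
#' Lys, and the ND1/NE2 midpoint for His flagged protonated. Falls back to
#' the residue centroid when the representative atom is missing.
#'
#' @param structure an `oxo_protein`.
#' @param his_protonated as in [residue_census()].
#' @param overrides optional data frame (`chain`, `resno`, `q`) applied
#'   after the default assignment.
#' @return an object of class `oxo_charges`: data frame with `chain`,
#'   `resno`, `resid`, `q` (e), `x`, `y`, `z` (angstrom).
#' @export
charge_model <- function(structure, his_protonated = character(),
                         overrides = NULL) {
  stopifnot(inherits(structure, "oxo_protein"))
  aa <- structure[structure$type == "ATOM", ]
  res <- unique(aa[, c("chain", "resno", "resid")])
  flags <- .parse_resids(his_protonated)
  rows <- list()
  for (i in seq_len(nrow(res))) {
    rs <- res$resid[i]
    q <- if (rs %in% c("ASP", "GLU")) -1
         else if (rs %in% c("ARG", "LYS")) +1
         else if (rs == "HIS" &&
                  .his_flagged(res$chain[i], res$resno[i], flags)) +1
         else 0
    if (q == 0) next
    at <- aa[aa$chain == res$chain[i] & aa$resno == res$resno[i], ]
    pos <- if (rs == "HIS") {
      ring <- at[trimws(at$atom) %in% c("ND1", "NE2"), ]
      if (nrow(ring)) colMeans(ring[, c("x", "y", "z")])
      else colMeans(at[, c("x", "y", "z")])
    } else {
      hit <- at[trimws(at$atom) == .rep_atoms[[rs]], ]
      if (nrow(hit)) unlist(hit[1, c("x", "y", "z")])
      else colMeans(at[, c("x", "y", "z")])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chain = res$chain[i], resno = res$resno[i], resid = rs, q = q,
      x = pos[[1]], y = pos[[2]], z = pos[[3]], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(), resno = integer(), resid = character(),
               q = numeric(), x = numeric(), y = numeric(), z = numeric())
  if (!is.null(overrides)) {
    for (j in seq_len(nrow(overrides))) {
      hit <- out$resno == overrides$resno[j] &
        (overrides$chain[j] == "" | out$chain == overrides$chain[j])
      out$q[hit] <- overrides$q[j]
    }
  }
  class(out) <- c("oxo_charges", "data.frame")
  out
}

#' Dipole vector of a point-charge model
#'
#' mu = sum q_i (r_i - origin), in debye. Translation-invariant for
#' net-neutral charge sets; for net-charged systems the origin dependence
#' is mu(O1) - mu(O2) = q_net (O2 - O1) (converted to debye), so always
#' state the origin — `"com"` uses the unweighted charge-site centroid.
#'
#' @param model an `oxo_charges` data frame.
#' @param origin length-3 origin in angstrom, or `"com"`.
#' @return dipole 3-vector in debye.
#' @export
dipole_from_charges <- function(model, origin = c(0, 0, 0)) {
  if (!nrow(model) || all(model$q == 0)) return(c(0, 0, 0))
  r <- as.matrix(model[, c("x", "y", "z")])
  if (identical(origin, "com")) origin <- colMeans(r)
  mu_eA <- colSums(model$q * sweep(r, 2, origin))
  unname(mu_eA * oxo_constants$eA_debye)
}

#' Coulomb field of a point-charge model at a site
#'
#' Vacuum point-charge sum E = sum q_i (p - r_i)/|p - r_i|^3 in V/angstrom
#' (14.3996 V/angstrom at 1 angstrom from 1 e), optionally divided by a
#' uniform dielectric.
#'
#' @param model an `oxo_charges` data frame.
#' @param point length-3 evaluation point (angstrom); must be at least
#'   0.5 angstrom from every charge.
#' @param dielectric uniform relative permittivity divisor (default 1).
#' @return field 3-vector in V/angstrom.
#' @export
field_at_point <- function(model, point, dielectric = 1) {
  point <- as.numeric(point)
  stopifnot(length(point) == 3L)
  if (!nrow(model)) return(c(0, 0, 0))
  r <- as.matrix(model[, c("x", "y", "z")])
  d <- sweep(-r, 2, point, FUN = "+")     # p - r_i
  dist <- sqrt(rowSums(d^2))
  if (any(dist[model$q != 0] < 0.5)) {
    stop("evaluation point within 0.5 angstrom of a charge")
  }
  e <- colSums(model$q * d / dist^3)
  unname(e * oxo_constants$coulomb_VA / dielectric)
}
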