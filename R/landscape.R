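# Reaction-landscape bookkeeping: stationary points tagged with mechanistic
# role, pathway and spin state; relative-energy tables against a common
# reactant; spin-state ordering; selectivity verdicts; spin-density grouping
# and hydrogen-bond censuses.

.roles <- c("Re", "TS1_HA", "IM1", "TS2_reb", "P")
.pathways <- c("C1R", "C1S", "C2R", "C2S", "none")

#' Tag a QC record as a stationary point of a mechanism
#'
#' Roles follow the hydrogen-atom-abstraction / rebound nomenclature:
#' reactant complex `Re`, abstraction transition state `TS1_HA`, radical
#' intermediate `IM1`, rebound transition state `TS2_reb`, product complex
#' `P`. When the record carries frequencies, TS roles must show exactly one
#' imaginary mode and minima none. Points whose energy was estimated rather
#' than obtained from a located transition state (e.g. rebound barriers from
#' constraint scans) are flagged `estimated` and excluded from
#' rate-determining-step calls.
#'
#' @param record an [qc_record()].
#' @param role one of `"Re"`, `"TS1_HA"`, `"IM1"`, `"TS2_reb"`, `"P"`.
#' @param pathway one of `"C1R"`, `"C1S"`, `"C2R"`, `"C2S"`, `"none"`.
#' @param spin multiplicity; defaults to the record's.
#' @param model model label (e.g. `"B"`, `"C"`, `"DA"`).
#' @param config_label optional electronic-configuration string (sigma- or
#'   pi-pathway).
#' @param estimated logical; `TRUE` for scan-estimated energies.
#' @return an object of class `oxo_point`.
#' @export
stationary_point <- function(record, role, pathway = "none",
                             spin = record$multiplicity, model = "A",
                             config_label = NULL, estimated = FALSE) {
  stopifnot(inherits(record, "oxo_qc_record"))
  role <- match.arg(role, .roles)
  pathway <- match.arg(pathway, .pathways)
  if (!is.null(record$frequencies) && !isTRUE(estimated)) {
    n_imag <- sum(record$frequencies < 0)
    is_ts <- role %in% c("TS1_HA", "TS2_reb")
    if (is_ts && n_imag != 1L) {
      stop("role ", role, " requires exactly one imaginary frequency; '",
           record$label, "' has ", n_imag)
    }
    if (!is_ts && n_imag != 0L) {
      stop("role ", role, " requires zero imaginary frequencies; '",
           record$label, "' has ", n_imag)
    }
  }
  structure(
    list(record = record, role = role, pathway = pathway,
         spin = as.integer(spin), model = model,
         config_label = config_label, estimated = isTRUE(estimated)),
    class = "oxo_point"
  )
}

#' Assemble stationary points into a reaction landscape
#'
#' Validates the collection (one reference reactant; every pathway with a
#' located rebound TS also carries its radical intermediate), assembles each
#' point under the requested scheme and under the free-energy scheme, and
#' stores energies relative to the reference.
#'
#' @param points list of [stationary_point()] objects.
#' @param scheme the electronic-energy assembly scheme for the
#'   "E+ZPE"-style column (see [assemble()]).
#' @param T temperature in K.
#' @param reference label of the reference `Re` record; default the
#'   lowest-energy `Re` (the ground spin state).
#' @return an object of class `oxo_landscape`.
#' @export
landscape <- function(points, scheme = "E+ZPE+solv+disp", T = 298.15,
                      reference = NULL) {
  stopifnot(length(points) >= 1L,
            all(vapply(points, inherits, TRUE, "oxo_point")))
  labels <- vapply(points, function(p) p$record$label, "")
  if (anyDuplicated(labels)) stop("duplicate point labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  E <- numeric(length(points))
  G <- rep(NA_real_, length(points))
  for (i in seq_along(points)) {
    rec <- points[[i]]$record
    th <- rrho(rec, T = T)
    a <- tryCatch(assemble(rec, th, scheme = scheme),
                  error = function(e) stop("point '", rec$label, "': ",
                                           conditionMessage(e), call. = FALSE))
    E[i] <- a$E_total
    G[i] <- tryCatch(assemble(rec, th, scheme = "G")$E_total,
                     error = function(e) NA_real_)
  }
  roles <- vapply(points, `[[`, "", "role")
  if (is.null(reference)) {
    re_idx <- which(roles == "Re")
    if (!length(re_idx)) stop("landscape has no Re (reference) point")
    reference <- labels[re_idx[which.min(E[re_idx])]]
  }
  ref_i <- match(reference, labels)
  if (is.na(ref_i)) stop("reference '", reference, "' not among the points")
  # every pathway with a located TS2 must also carry an IM1 (C1R/C1S may
  # share one intermediate, so the check is per carbon position)
  pw <- vapply(points, `[[`, "", "pathway")
  est <- vapply(points, `[[`, TRUE, "estimated")
  carbon <- substr(pw, 1, 2)
  for (p in unique(pw[roles == "TS2_reb" & !est])) {
    if (!any(roles == "IM1" & (pw == p | carbon == substr(p, 1, 2)))) {
      stop("pathway ", p, " has a TS2 but no IM1")
    }
  }
  structure(
    list(points = points, labels = labels, reference = reference,
         scheme = scheme, T = T, E = E, G = G, ref_index = ref_i),
    class = "oxo_landscape"
  )
}

#' Relative-energy table for a landscape
#'
#' @param ls an [landscape()] object.
#' @return data frame with one row per point: `label`, `role`, `pathway`,
#'   `spin`, `estimated`, `dE_zpe` (kcal/mol on the landscape's scheme,
#'   reference row exactly 0) and `dG` (kcal/mol, `NA` where the free-energy
#'   scheme is not computable).
#' @export
relative_table <- function(ls) {
  stopifnot(inherits(ls, "oxo_landscape"))
  data.frame(
    label = ls$labels,
    role = vapply(ls$points, `[[`, "", "role"),
    pathway = vapply(ls$points, `[[`, "", "pathway"),
    spin = vapply(ls$points, function(p) p$spin, 1L),
    estimated = vapply(ls$points, `[[`, TRUE, "estimated"),
    dE_zpe = ls$E - ls$E[ls$ref_index],
    dG = ls$G - ls$G[ls$ref_index],
    stringsAsFactors = FALSE
  )
}

#' @export
print.oxo_landscape <- function(x, ...) {
  cat("<landscape> ", length(x$points), " points, reference '",
      x$reference, "', scheme ", x$scheme, ", T ", x$T, " K\n", sep = "")
  print(relative_table(x))
  invisible(x)
}

#' Spin-state ordering of a species across multiplicities
#'
#' @param points list of [stationary_point()] objects sharing model and
#'   role (typically the reactant complex at several multiplicities).
#' @param scheme assembly scheme for the comparison.
#' @param T temperature in K.
#' @return data frame sorted ascending in energy with columns
#'   `multiplicity`, `E` (kcal/mol, absolute assembled) and `gap` (kcal/mol
#'   above the ground state); the ground multiplicity is in attribute
#'   `"ground"`.
#' @export
spin_ordering <- function(points, scheme = "E+ZPE+solv+disp", T = 298.15) {
  stopifnot(length(points) >= 1L,
            all(vapply(points, inherits, TRUE, "oxo_point")))
  mult <- vapply(points, function(p) p$spin, 1L)
  if (anyDuplicated(mult)) {
    stop("duplicate multiplicity in spin_ordering: ",
         paste(mult[duplicated(mult)], collapse = ", "))
  }
  E <- vapply(points, function(p) assemble(p$record, scheme = scheme,
                                           T = T)$E_total, 0)
  o <- order(E)
  out <- data.frame(multiplicity = mult[o], E = E[o], gap = E[o] - min(E))
  attr(out, "ground") <- mult[o][1L]
  out
}

#' Selectivity verdict from a set of abstraction barriers
#'
#' Boltzmann-branches the pathways and classifies the carbon preference:
#' summed fraction > 0.9 on one carbon is "dominant", 0.5-0.9 "preferred",
#' otherwise "unselective".
#'
#' @param barriers named numeric vector of activation energies (kcal/mol);
#'   names must be pathway labels (`C1R`, `C1S`, `C2S`, `C2R`).
#' @param T temperature in K.
#' @param scale_label energy scale annotation (see [branching()]).
#' @return an object of class `oxo_selectivity`: list with `lowest` (label),
#'   `window` (max - min, kcal/mol), `branching`, `carbon_fractions`
#'   (named C1/C2), `carbon` (the favoured carbon or `NA`), `call`.
#' @examples
#' selectivity_from_barriers(c(C1R = 17.1, C1S = 16.3, C2S = 26.6, C2R = 28.6))
#' @export
selectivity_from_barriers <- function(barriers, T = 298.15,
                                      scale_label = "G") {
  if (length(barriers) < 2L || is.null(names(barriers))) {
    stop("need >= 2 named pathway barriers")
  }
  br <- branching(barriers, T = T, scale_label = scale_label)
  carbon <- substr(names(barriers), 1, 2)
  cf <- vapply(split(br$fractions, carbon), sum, 0)
  top <- names(cf)[which.max(cf)]
  eps <- 1e-6  # a numerically exact 50/50 split must read as unselective
  call <- if (max(cf) > 0.9 + eps) "dominant"
          else if (max(cf) > 0.5 + eps) "preferred"
          else "unselective"
  structure(
    list(lowest = names(barriers)[which.min(barriers)],
         window = max(barriers) - min(barriers),
         branching = br, carbon_fractions = cf,
         carbon = if (call == "unselective") NA_character_ else top,
         call = call, T = T),
    class = "oxo_selectivity"
  )
}

#' @export
print.oxo_selectivity <- function(x, ...) {
  cat(sprintf(
    "<selectivity at %g K> lowest %s, window %.2f kcal/mol, %s%s\n",
    x$T, x$lowest, x$window, x$call,
    if (!is.na(x$carbon)) paste0(" ", x$carbon, " (fraction ",
                                 sprintf("%.3f", max(x$carbon_fractions)), ")")
    else ""))
  invisible(x)
}

#' Selectivity report for a landscape
#'
#' Extracts the abstraction (TS1) barrier per pathway — free energies when
#' available on every TS1, otherwise the landscape's electronic scheme —
#' and applies [selectivity_from_barriers()].
#'
#' @param ls an [landscape()] object with TS1 points on >= 2 pathways.
#' @param T temperature in K (default: the landscape's).
#' @return an `oxo_selectivity` object.
#' @export
selectivity_report <- function(ls, T = NULL) {
  stopifnot(inherits(ls, "oxo_landscape"))
  if (is.null(T)) T <- ls$T
  tab <- relative_table(ls)
  ts1 <- tab[tab$role == "TS1_HA", , drop = FALSE]
  if (nrow(ts1) < 2L) stop("selectivity needs TS1 points on >= 2 pathways")
  use_G <- !anyNA(ts1$dG)
  b <- if (use_G) ts1$dG else ts1$dE_zpe
  names(b) <- ts1$pathway
  selectivity_from_barriers(b, T = T,
                            scale_label = if (use_G) "G" else ls$scheme)
}

#' Rate-determining step of a pathway
#'
#' The located (non-estimated) transition state with the highest energy
#' relative to the reference. Ties resolve toward the earlier mechanistic
#' step and are flagged in attribute `"tie"`.
#'
#' @param ls an [landscape()] object.
#' @param pathway pathway label.
#' @return the label of the rate-determining TS (character), with
#'   attributes `"role"` and `"tie"`.
#' @export
rds <- function(ls, pathway) {
  stopifnot(inherits(ls, "oxo_landscape"))
  tab <- relative_table(ls)
  ts <- tab[tab$pathway == pathway & !tab$estimated &
              tab$role %in% c("TS1_HA", "TS2_reb"), , drop = FALSE]
  if (!nrow(ts)) stop("no located TS on pathway ", pathway)
  e <- ifelse(is.na(ts$dG), ts$dE_zpe, ts$dG)
  hi <- which(abs(e - max(e)) < 1e-9)
  tie <- length(hi) > 1L
  if (tie) hi <- hi[order(match(ts$role[hi], .roles))]
  out <- ts$label[hi[1L]]
  attr(out, "role") <- ts$role[hi[1L]]
  attr(out, "tie") <- tie
  out
}

#' Group spin densities
#'
#' Sums per-atom spin densities over named, disjoint atom-index groups;
#' anything not covered is reported as the `rest` group.
#'
#' @param record an [qc_record()] carrying `spin_densities`.
#' @param groups named list of integer atom-index vectors (disjoint).
#' @return named numeric vector of per-group sums, plus `rest`.
#' @export
group_spin <- function(record, groups) {
  stopifnot(inherits(record, "oxo_qc_record"))
  if (is.null(record$spin_densities)) {
    stop("record '", record$label, "' has no spin densities")
  }
  rho <- record$spin_densities
  idx <- unlist(groups, use.names = FALSE)
  if (length(idx) && (any(idx < 1L) || any(idx > length(rho)))) {
    stop("group atom index out of range (1..", length(rho), ")")
  }
  if (anyDuplicated(idx)) stop("groups must be disjoint")
  out <- vapply(groups, function(g) sum(rho[g]), 0)
  c(out, rest = sum(rho[setdiff(seq_along(rho), idx)]))
}

#' Hydrogen-bond census
#'
#' Enumerates donor-acceptor contacts. With hydrogens present and
#' `mode = "angle"`, reports D-H...A triples with H...A distance at most
#' `d_max` and D-H-A angle at least `angle_min`; in distance-only mode,
#' reports donor/acceptor pairs within `d_max`. Requesting the angle
#' criterion on a structure without hydrogens is an error that suggests
#' distance-only mode.
#'
#' @param x an [geometry()] or `oxo_protein` object.
#' @param donors integer atom indices of donor heavy atoms.
#' @param acceptors integer atom indices of acceptor atoms.
#' @param d_max maximum H...A (or D...A in distance mode) distance in
#'   angstrom (default 2.5).
#' @param angle_min minimum D-H-A angle in degrees (default 120).
#' @param mode `"auto"` (angle when hydrogens exist), `"angle"`, or
#'   `"distance"`.
#' @return data frame of contacts with columns `donor`, `h` (NA in distance
#'   mode), `acceptor`, `dist` (angstrom), `angle` (degrees or NA).
#' @export
hbond_census <- function(x, donors, acceptors, d_max = 2.5, angle_min = 120,
                         mode = c("auto", "angle", "distance")) {
  mode <- match.arg(mode)
  if (inherits(x, "oxo_geometry")) {
    coords <- x$coords
    el <- x$elements
  } else if (inherits(x, "oxo_protein")) {
    coords <- as.matrix(x[, c("x", "y", "z")])
    el <- x$element
  } else stop("x must be a geometry or protein structure")
  donors <- as.integer(donors)
  acceptors <- as.integer(acceptors)
  if (any(c(donors, acceptors) < 1L) || any(c(donors, acceptors) > nrow(coords))) {
    stop("donor/acceptor index out of range")
  }
  hyd <- which(el == "H")
  if (mode == "auto") mode <- if (length(hyd)) "angle" else "distance"
  if (mode == "angle" && !length(hyd)) {
    stop("no hydrogens present but the angle criterion was requested; ",
         "use mode = 'distance'")
  }
  out <- data.frame(donor = integer(), h = integer(), acceptor = integer(),
                    dist = numeric(), angle = numeric())
  dvec <- function(i, j) coords[j, ] - coords[i, ]
  if (mode == "distance") {
    for (d in donors) for (a in acceptors) {
      if (d == a) next
      r <- sqrt(sum(dvec(d, a)^2))
      if (r <= d_max) {
        out <- rbind(out, data.frame(donor = d, h = NA_integer_,
                                     acceptor = a, dist = r,
                                     angle = NA_real_))
      }
    }
  } else {
    for (d in donors) {
      dh <- hyd[vapply(hyd, function(h) sqrt(sum(dvec(d, h)^2)) < 1.25, TRUE)]
      for (h in dh) for (a in acceptors) {
        if (a == d || a == h) next
        r_ha <- sqrt(sum(dvec(h, a)^2))
        if (r_ha > d_max) next
        v1 <- dvec(h, d)
        v2 <- dvec(h, a)
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang >= angle_min) {
          out <- rbind(out, data.frame(donor = d, h = h, acceptor = a,
                                       dist = r_ha, angle = ang))
        }
      }
    }
  }
  out
}
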