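# Seeded synthetic generators for every input class the pipeline consumes:
# harmonic systems with prescribed spectra, stationary-point ensembles with
# prescribed barrier/intermediate profiles, and toy PDB files with
# prescribed residue compositions. Changing the seed changes nuisance
# structure (mixing matrices, component splits, coordinates) but never the
# prescribed observables, which is what makes the generators usable as
# ground truth.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Prescription for a synthetic harmonic system
#'
#' @param elements element symbols.
#' @param freqs target real wavenumbers in cm^-1 (3N-6 of them, 3N-5 for a
#'   linear/diatomic system, counted together with `imag`).
#' @param imag optional single imaginary wavenumber magnitude (cm^-1),
#'   encoded into the spectrum as a negative mode.
#' @param masses optional per-atom masses (amu); default isotope-pure.
#' @param geom optional [geometry()]; random non-linear coordinates are
#'   generated when absent.
#' @param label,charge,E_high record metadata passed through.
#' @return a list of class `oxo_harmonic_rx` to feed [gen_harmonic_system()].
#' @export
harmonic_prescription <- function(elements, freqs, imag = NULL, masses = NULL,
                                  geom = NULL, label = "harmonic",
                                  charge = 0, E_high = -100) {
  if (any(freqs <= 0)) stop("target real wavenumbers must be positive")
  if (!is.null(imag) && (length(imag) != 1L || imag <= 0)) {
    stop("imag must be a single positive magnitude")
  }
  structure(list(elements = elements, freqs = freqs, imag = imag,
                 masses = masses, geom = geom, label = label,
                 charge = charge, E_high = E_high),
            class = "oxo_harmonic_rx")
}

#' Generate a QC record with a prescribed harmonic spectrum
#'
#' Builds a Cartesian Hessian H = M^(1/2) B diag(lambda) B' M^(1/2) with B
#' an orthonormal basis of the internal (translation/rotation-free)
#' subspace mixed by a seeded random rotation, so that the projected
#' eigenfrequencies reproduce the prescription to ~1e-6 cm^-1 while
#' translations and rotations are exactly null.
#'
#' @param rx an [harmonic_prescription()].
#' @param seed integer seed; the same seed gives a bitwise-identical record.
#' @return an [qc_record()] with `hessian` and `geometry` (no frequency
#'   list: the spectrum is recomputed, not copied).
#' @examples
#' rx <- harmonic_prescription(c("Fe", "O"), freqs = 860)
#' rec <- gen_harmonic_system(rx, seed = 1)
#' isotope_frequencies(rec$hessian, rec$geometry)  # 860
#' @export
gen_harmonic_system <- function(rx, seed = 1) {
  stopifnot(inherits(rx, "oxo_harmonic_rx"))
  .with_seed(seed, {
    n <- length(rx$elements)
    m <- if (is.null(rx$masses)) element_mass(rx$elements) else rx$masses
    geom <- rx$geom
    if (is.null(geom)) {
      if (n == 1L) {
        geom <- geometry(rx$elements, matrix(0, 1, 3), masses = m)
      } else if (n == 2L) {
        geom <- geometry(rx$elements, rbind(c(0, 0, 0), c(0, 0, 1.6)),
                         masses = m)
      } else {
        repeat {
          xyz <- matrix(stats::runif(3 * n, -2, 2), n, 3)
          g <- geometry(rx$elements, xyz, masses = m)
          ev <- eigen(.inertia(g), symmetric = TRUE, only.values = TRUE)$values
          if (min(ev) > 0.5) { geom <- g; break }
        }
      }
    } else {
      geom$masses <- m
    }
    Q <- .tr_basis(geom)
    n_int <- 3L * n - ncol(Q)
    targets <- c(rx$freqs, if (!is.null(rx$imag)) -rx$imag)
    if (length(targets) != n_int) {
      stop("prescription has ", length(targets), " target modes but the ",
           n, "-atom system has ", n_int, " internal degrees of freedom")
    }
    lam <- sign(targets) * (targets / oxo_constants$hess_cm1)^2
    A <- matrix(stats::rnorm(3 * n * n_int), 3 * n, n_int)
    A <- A - Q %*% (t(Q) %*% A)
    B <- qr.Q(qr(A))
    fmw <- B %*% (lam * t(B))
    sqm <- rep(sqrt(geom$masses), each = 3L)
    H <- fmw * tcrossprod(sqm)
    H <- (H + t(H)) / 2
    n_elec <- sum(element_Z(rx$elements)) - rx$charge
    mult <- if (n_elec %% 2L == 0L) 1L else 2L
    qc_record(label = rx$label, charge = rx$charge, multiplicity = mult,
              E_high = rx$E_high, hessian = H, geometry = geom)
  })
}

# --- landscape generator ----------------------------------------------------

#' Prescription for a synthetic reaction landscape
#'
#' Energies are all relative to the ground-spin reactant complex, in
#' kcal/mol; `*_e` values live on the electronic E+ZPE+solv+disp scale and
#' `*_g` on the free-energy scale. The generator reproduces both scales
#' exactly through the assembled records.
#'
#' @param model model label.
#' @param barriers_e,barriers_g named vectors (pathways among C1R, C1S,
#'   C2S, C2R) of abstraction (TS1) barriers; `barriers_g` defaults to
#'   `barriers_e + 2` when omitted.
#' @param im1_e,im1_g named vectors of radical-intermediate energies, named
#'   by carbon position (`C1`, `C2`); C1R/C1S share the C1 intermediate.
#' @param ts2_e,ts2_g named-by-pathway rebound TS energies (absolute,
#'   relative to Re).
#' @param ts2_estimated character vector of pathways whose rebound barrier
#'   is a scan estimate (stored, excluded from rate-determining-step calls).
#' @param products_e,products_g named-by-pathway product energies.
#' @param spin_gaps named numeric: reactant spin-state gaps (kcal/mol) by
#'   multiplicity, ground state 0; default quintet ground only.
#' @param imag named-by-pathway imaginary wavenumber magnitudes (cm^-1) for
#'   the TS1 records.
#' @param imag_ts2 like `imag`, for located TS2 records (default 500).
#' @param T temperature (K) at which the free-energy scale is defined.
#' @return a list of class `oxo_landscape_rx`.
#' @export
landscape_prescription <- function(model = "B",
                                   barriers_e,
                                   barriers_g = NULL,
                                   im1_e = NULL, im1_g = NULL,
                                   ts2_e = NULL, ts2_g = NULL,
                                   ts2_estimated = character(),
                                   products_e = NULL, products_g = NULL,
                                   spin_gaps = c("5" = 0),
                                   imag = NULL, imag_ts2 = NULL,
                                   T = 298.15) {
  pw <- names(barriers_e)
  if (is.null(pw) || !all(pw %in% c("C1R", "C1S", "C2R", "C2S"))) {
    stop("barriers_e must be named with pathways among C1R, C1S, C2R, C2S")
  }
  if (is.null(barriers_g)) barriers_g <- barriers_e + 2
  if (!setequal(names(barriers_g), pw)) {
    stop("barriers_g must name the same pathways as barriers_e")
  }
  if (is.null(imag)) imag <- stats::setNames(rep(1300, length(pw)), pw)
  if (!all(pw %in% names(imag))) stop("imag must cover every pathway")
  if (any(imag <= 0)) stop("imaginary wavenumber magnitudes must be positive")
  if (!is.null(im1_e) && is.null(im1_g)) im1_g <- im1_e
  if (!is.null(ts2_e) && is.null(ts2_g)) ts2_g <- ts2_e + 2
  if (!is.null(products_e) && is.null(products_g)) products_g <- products_e
  if (is.null(imag_ts2) && !is.null(ts2_e)) {
    imag_ts2 <- stats::setNames(rep(500, length(ts2_e)), names(ts2_e))
  }
  if (!("0" %in% names(spin_gaps)) && !any(spin_gaps == 0)) {
    stop("spin_gaps must contain a zero (ground-state) entry")
  }
  structure(list(model = model, barriers_e = barriers_e,
                 barriers_g = barriers_g[pw], im1_e = im1_e, im1_g = im1_g,
                 ts2_e = ts2_e, ts2_g = ts2_g,
                 ts2_estimated = ts2_estimated,
                 products_e = products_e, products_g = products_g,
                 spin_gaps = spin_gaps, imag = imag, imag_ts2 = imag_ts2,
                 T = T),
            class = "oxo_landscape_rx")
}

# Invert the per-mode vibrational free-energy tail w(nu) = RT ln(1 - e^-u).
# Used to steer G - (E+ZPE) per record; closed form, so recovery is exact
# to float rounding.
.nu_from_w <- function(w, T) {
  RT <- oxo_constants$R_kcal * T
  if (w >= 0) stop("vibrational free-energy tail must be negative")
  u <- -log1p(-exp(w / RT))
  u * T / oxo_constants$hc_kB
}

.w_of_nu <- function(nu, T) {
  oxo_constants$R_kcal * T * log1p(-exp(-oxo_constants$hc_kB * nu / T))
}

# Build one record hitting relative targets d_e (E+ZPE+solv+disp scale) and
# d_g (G scale) against a common base, by splitting the total into
# E_high/ZPE/E_solv/E_disp randomly and steering 12 low modes.
.gen_profile_record <- function(label, d_e, d_g, imag = NULL, mult = 5L,
                                base_kcal, T) {
  n_low <- 12L
  nu0 <- 80
  w_t <- .w_of_nu(nu0, T) + (d_g - d_e) / n_low
  if (w_t >= 0) {
    stop("prescribed G - E gap of ", round(d_g - d_e, 2),
         " kcal/mol exceeds the generator's low-mode headroom")
  }
  nu_low <- .nu_from_w(w_t, T)
  freqs <- c(if (!is.null(imag)) -abs(imag), 3000, rep(nu_low, n_low))
  E_solv <- stats::runif(1, -0.05, 0)
  E_disp <- stats::runif(1, -0.02, 0)
  rec0 <- qc_record(label, charge = 0L, multiplicity = mult, E_high = 0,
                    E_solv = E_solv, E_disp = E_disp, frequencies = freqs)
  zpe <- rrho(rec0, T = T)$ZPE
  h2k <- oxo_constants$hartree_kcal
  E_high <- (base_kcal + d_e - zpe) / h2k - E_solv - E_disp
  qc_record(label, charge = 0L, multiplicity = mult, E_high = E_high,
            E_solv = E_solv, E_disp = E_disp, frequencies = freqs)
}

#' Generate a stationary-point ensemble from a landscape prescription
#'
#' Emits reactant complexes (one per prescribed spin state), TS1 records
#' (one per pathway, each with exactly one imaginary mode of the prescribed
#' magnitude), shared radical intermediates, rebound transition states and
#' products, whose assembled energies reproduce the prescription on both
#' the E+ZPE+solv+disp and free-energy scales. The split of each total into
#' E_high/ZPE/E_solv/E_disp is randomized under the seed.
#'
#' @param rx an [landscape_prescription()].
#' @param seed integer seed.
#' @param dir optional directory; when given, records are written there
#'   (one file per species, [write_qc_record()] format) together with a
#'   `manifest.yaml`, and the directory can be re-read with
#'   [read_landscape()].
#' @return invisibly, a list with `points` (list of [stationary_point()])
#'   and `rx`.
#' @export
gen_landscape <- function(rx, seed = 1, dir = NULL) {
  stopifnot(inherits(rx, "oxo_landscape_rx"))
  .with_seed(seed, {
    base <- -oxo_constants$hartree_kcal * stats::runif(1, 2000, 3000)
    mults <- as.integer(names(rx$spin_gaps))
    ground <- mults[which.min(rx$spin_gaps)]
    pts <- list()
    add <- function(p) pts[[length(pts) + 1L]] <<- p
    for (i in seq_along(mults)) {
      gap <- rx$spin_gaps[[i]]
      rec <- .gen_profile_record(sprintf("%dRe_%s", mults[i], rx$model),
                                 gap, gap, mult = mults[i],
                                 base_kcal = base, T = rx$T)
      add(stationary_point(rec, "Re", "none", spin = mults[i],
                           model = rx$model))
    }
    for (p in names(rx$barriers_e)) {
      rec <- .gen_profile_record(sprintf("%dTS1_%s_%s", ground, p, rx$model),
                                 rx$barriers_e[[p]], rx$barriers_g[[p]],
                                 imag = rx$imag[[p]], mult = ground,
                                 base_kcal = base, T = rx$T)
      add(stationary_point(rec, "TS1_HA", p, spin = ground, model = rx$model))
    }
    for (cpos in names(rx$im1_e)) {
      rec <- .gen_profile_record(sprintf("%dIM1_%s_%s", ground, cpos, rx$model),
                                 rx$im1_e[[cpos]], rx$im1_g[[cpos]],
                                 mult = ground, base_kcal = base, T = rx$T)
      pwy <- paste0(cpos, "S")
      if (!pwy %in% names(rx$barriers_e)) pwy <- paste0(cpos, "R")
      if (!pwy %in% names(rx$barriers_e)) pwy <- "none"
      add(stationary_point(rec, "IM1", pwy, spin = ground, model = rx$model))
    }
    for (p in names(rx$ts2_e)) {
      est <- p %in% rx$ts2_estimated
      rec <- .gen_profile_record(sprintf("%dTS2_%s_%s", ground, p, rx$model),
                                 rx$ts2_e[[p]], rx$ts2_g[[p]],
                                 imag = if (!est) rx$imag_ts2[[p]],
                                 mult = ground, base_kcal = base, T = rx$T)
      add(stationary_point(rec, "TS2_reb", p, spin = ground,
                           model = rx$model, estimated = est))
    }
    for (p in names(rx$products_e)) {
      rec <- .gen_profile_record(sprintf("%dP_%s_%s", ground, p, rx$model),
                                 rx$products_e[[p]], rx$products_g[[p]],
                                 mult = ground, base_kcal = base, T = rx$T)
      add(stationary_point(rec, "P", p, spin = ground, model = rx$model))
    }
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      entries <- lapply(pts, function(p) {
        f <- paste0(p$record$label, ".yml")
        write_qc_record(p$record, file.path(dir, f))
        list(file = f, role = p$role, pathway = p$pathway,
             spin = p$spin, model = p$model, estimated = p$estimated)
      })
      yaml::write_yaml(list(model = rx$model, T = rx$T, points = entries),
                       file.path(dir, "manifest.yaml"))
    }
    invisible(list(points = pts, rx = rx))
  })
}

#' Read a generated landscape directory back into a landscape object
#'
#' @param dir directory written by [gen_landscape()].
#' @param scheme,T passed to [landscape()]; `T` defaults to the manifest's.
#' @return an [landscape()] object.
#' @export
read_landscape <- function(dir, scheme = "E+ZPE+solv+disp", T = NULL) {
  mf <- yaml::yaml.load_file(file.path(dir, "manifest.yaml"))
  if (is.null(T)) T <- mf$T
  pts <- lapply(mf$points, function(e) {
    stationary_point(read_qc_record(file.path(dir, e$file)),
                     role = e$role, pathway = e$pathway, spin = e$spin,
                     model = e$model, estimated = isTRUE(e$estimated))
  })
  landscape(pts, scheme = scheme, T = T)
}

#' Draw a random landscape prescription
#'
#' Used in recovery sweeps: barriers, intermediates and spin gaps are drawn
#' in realistic enzyme-model windows; the prescribed observables are the
#' sweep's ground truth.
#'
#' @param seed integer seed.
#' @return an [landscape_prescription()].
#' @export
random_landscape_prescription <- function(seed = 1) {
  .with_seed(seed, {
    pw <- c("C1R", "C1S", "C2S", "C2R")
    be <- stats::setNames(round(stats::runif(4, 5, 25), 3), pw)
    bg <- be + round(stats::runif(4, -2, 3.5), 3)
    ime <- stats::setNames(round(stats::runif(2, -12, -2), 3), c("C1", "C2"))
    img <- ime + round(stats::runif(2, -1, 2), 3)
    gaps <- c("5" = 0, "3" = round(stats::runif(1, 2, 15), 3),
              "7" = round(stats::runif(1, 2, 15), 3))
    nu <- stats::setNames(round(stats::runif(4, 1000, 1700), 1), pw)
    landscape_prescription(model = "S", barriers_e = be, barriers_g = bg,
                           im1_e = ime, im1_g = img, spin_gaps = gaps,
                           imag = nu)
  })
}

# --- presets ----------------------------------------------------------------

#' Activation free energies of the four abstraction pathways per model
#'
#' The study's summary table of DFT-cluster and QM/MM free energies of
#' activation (kcal/mol) for the pro-R C1-H, pro-S C1-H, pro-S C2-H and
#' pro-R C2-H pathways; these printed values are inputs for selectivity
#' worked examples.
#'
#' @return named list of named numeric vectors (pathways C1R, C1S, C2S,
#'   C2R) for models A, B, B2, C, C2, DA, DB, plus `experiment` (the
#'   TST-converted experimental barrier).
#' @export
table1_barriers <- function() {
  pw <- c("C1R", "C1S", "C2S", "C2R")
  mk <- function(v) stats::setNames(v, pw)
  list(
    A  = mk(c(4.2, 18.1, 13.8, 15.0)),
    B  = mk(c(15.4, 14.2, 13.1, 14.5)),
    B2 = mk(c(27.8, 26.8, 24.4, 30.5)),
    C  = mk(c(17.1, 16.3, 26.6, 28.6)),
    C2 = mk(c(30.9, 25.7, 24.9, 28.6)),
    DA = mk(c(6.7, 8.3, 26.4, 24.9)),
    DB = mk(c(22.6, 21.8, 13.3, 9.4)),
    experiment = 14.83
  )
}

#' Named landscape prescriptions encoding the study's profiles
#'
#' `"tauD-modelB-fig5"` carries the medium cluster model's full profile
#' (abstraction barriers 9.3/10.9/11.8/12.2 kcal/mol on the E+ZPE scale,
#' shared radical intermediates at -8.8/-8.1, rebound steps with the
#' C1R/C2R barriers scan-estimated, and the quintet-ground spin ladder
#' 0/10.4/10.9/19.2). `"tauD-modelC"` carries the large cluster model
#' (C1-selective: 14.5/15.8 vs 21.2/23.1 on E+ZPE, free energies
#' 16.3/17.1/26.6/28.6, TS1 imaginary modes i1495/i1534). The remaining
#' models (`"tauD-modelA"`, `"tauD-modelB2"`, `"tauD-modelC2"`,
#' `"tauD-modelDA"`, `"tauD-modelDB"`) encode their barrier rows; where
#' only free energies are printed, the electronic scale sits 2 kcal/mol
#' below by convention (documented in the methods vignette).
#'
#' @param name preset name.
#' @return an [landscape_prescription()].
#' @export
preset_prescription <- function(name = c("tauD-modelB-fig5", "tauD-modelC",
                                         "tauD-modelA", "tauD-modelB2",
                                         "tauD-modelC2", "tauD-modelDA",
                                         "tauD-modelDB")) {
  name <- match.arg(name)
  t1 <- table1_barriers()
  pw <- c("C1R", "C1S", "C2S", "C2R")
  gaps_re <- c("5" = 0, "3" = 10.4, "1" = 19.2, "7" = 10.9)
  switch(
    name,
    "tauD-modelB-fig5" = landscape_prescription(
      model = "B",
      barriers_e = c(C1R = 12.2, C1S = 11.8, C2S = 9.3, C2R = 10.9),
      barriers_g = t1$B,
      im1_e = c(C1 = -8.8, C2 = -8.1),
      ts2_e = c(C1S = -6.8, C2S = -5.6, C1R = -1.5, C2R = 1.2),
      ts2_estimated = c("C1R", "C2R"),
      products_e = c(C1S = -50.0, C1R = -47.0, C2S = -48.0, C2R = -46.0),
      spin_gaps = gaps_re,
      imag = c(C1R = 1300, C1S = 1350, C2S = 1250, C2R = 1280)),
    "tauD-modelC" = landscape_prescription(
      model = "C",
      barriers_e = c(C1R = 15.8, C1S = 14.5, C2S = 21.2, C2R = 23.1),
      barriers_g = t1$C,
      im1_e = c(C1 = -6.0),
      spin_gaps = c("5" = 0),
      imag = c(C1R = 1534, C1S = 1495, C2S = 1100, C2R = 1150)),
    "tauD-modelDA" = landscape_prescription(
      model = "DA",
      barriers_e = c(C1R = 8.3, C1S = 8.5, C2S = 24.6, C2R = 23.8),
      barriers_g = t1$DA,
      imag = c(C1R = 1400, C1S = 1380, C2S = 506, C2R = 870)),
    landscape_prescription(
      model = sub("tauD-model", "", name),
      barriers_e = t1[[sub("tauD-model", "", name)]] - 2,
      barriers_g = t1[[sub("tauD-model", "", name)]],
      imag = stats::setNames(c(1300, 1350, 1100, 1150), pw))
  )
}

# --- toy PDB ----------------------------------------------------------------

#' Generate a toy PDB file with a prescribed residue composition
#'
#' Writes a valid fixed-width single-chain PDB whose residues sit on a
#' cubic lattice with 5 angstrom spacing (no accidental contacts). Each
#' residue gets a CA atom plus its side-chain charge-bearing atom (CG/CD/
#' CZ/NZ; ND1 and NE2 for His) so that [charge_model()] finds its
#' representative sites. The structure is synthetic: composition, not
#' conformation, is the ground truth.
#'
#' @param composition named integer vector of residue-type counts, e.g.
#'   `c(GLU = 19, ASP = 14, ARG = 19, LYS = 9)`.
#' @param path output file path.
#' @param seed integer seed (residue order and small coordinate jitter).
#' @param chain chain identifier.
#' @return invisibly, `path`.
#' @export
gen_toy_pdb <- function(composition, path, seed = 1, chain = "A") {
  if (length(composition) && (is.null(names(composition)) ||
                              !all(names(composition) %in% .amino3))) {
    stop("composition must be named with 3-letter amino-acid codes")
  }
  .with_seed(seed, {
    res <- sample(rep(names(composition), times = composition))
    lines <- character()
    serial <- 0L
    side <- c(.rep_atoms, HIS = "ND1")
    for (i in seq_along(res)) {
      k <- i - 1L
      origin <- 5 * c(k %% 10L, (k %/% 10L) %% 10L, k %/% 100L) +
        stats::runif(3, -0.3, 0.3)
      atoms <- list(c("CA", "C"))
      if (res[i] %in% names(side)) {
        atoms <- c(atoms, list(c(side[[res[i]]],
                                 substr(side[[res[i]]], 1, 1))))
        if (res[i] == "HIS") atoms <- c(atoms, list(c("NE2", "N")))
      }
      for (j in seq_along(atoms)) {
        serial <- serial + 1L
        pos <- origin + (j - 1L) * c(1.5, 0, 0)
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, atoms[[j]][1], res[i], chain, i,
          pos[1], pos[2], pos[3], 1.0, 0.0, atoms[[j]][2]))
      }
    }
    writeLines(c(lines, "END"), path)
  })
  invisible(path)
}
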