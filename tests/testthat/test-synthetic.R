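test_that("harmonic generation round-trips its target spectrum", {
  rec <- feo_fixture(860)
  expect_equal(isotope_frequencies(rec$hessian, rec$geometry), 860,
               tolerance = 1e-6)
  rx <- harmonic_prescription(c("C", "N", "O", "H"),
                              freqs = c(3300, 2100, 1700, 900, 450),
                              imag = 1495)
  rec4 <- gen_harmonic_system(rx, seed = 13)
  f <- isotope_frequencies(rec4$hessian, rec4$geometry)
  expect_equal(f, c(3300, 2100, 1700, 900, 450, -1495), tolerance = 1e-6)
})

test_that("generation is deterministic under a seed and spectrum-invariant under target order", {
  rx <- harmonic_prescription(c("O", "H", "H"), freqs = c(3700, 3600, 1600))
  a <- gen_harmonic_system(rx, seed = 5)
  b <- gen_harmonic_system(rx, seed = 5)
  expect_identical(a$hessian, b$hessian)
  expect_identical(a$geometry, b$geometry)
  c <- gen_harmonic_system(rx, seed = 6)
  expect_false(identical(a$hessian, c$hessian))  # nuisance structure moves
  rx_shuf <- harmonic_prescription(c("O", "H", "H"),
                                   freqs = c(1600, 3700, 3600))
  d <- gen_harmonic_system(rx_shuf, seed = 5)
  expect_equal(isotope_frequencies(d$hessian, d$geometry),
               isotope_frequencies(a$hessian, a$geometry), tolerance = 1e-6)
})

test_that("a wrong internal-mode count is rejected", {
  expect_error(gen_harmonic_system(
    harmonic_prescription(c("O", "H", "H"), freqs = c(3700, 3600)), 1),
    "internal degrees of freedom")
  expect_error(gen_harmonic_system(
    harmonic_prescription(c("Fe", "O"), freqs = c(860, 400)), 1),
    "internal degrees of freedom")
})

test_that("landscape generation writes records that recover the prescription", {
  tmp <- withr::local_tempdir()
  for (seed in c(7, 8, 9)) {
    rx <- random_landscape_prescription(seed)
    d <- file.path(tmp, paste0("ls", seed))
    gen_landscape(rx, seed = seed, dir = d)
    ls <- read_landscape(d)
    tab <- relative_table(ls)
    ts1 <- tab[tab$role == "TS1_HA", ]
    expect_equal(setNames(ts1$dE_zpe, ts1$pathway)[names(rx$barriers_e)],
                 rx$barriers_e, tolerance = 1e-9)
    expect_equal(setNames(ts1$dG, ts1$pathway)[names(rx$barriers_g)],
                 rx$barriers_g, tolerance = 1e-9)
    re <- tab[tab$role == "Re", ]
    expect_equal(sort(re$dE_zpe), sort(unname(rx$spin_gaps)),
                 tolerance = 1e-9)
    # each TS1 record carries exactly one imaginary mode of the prescribed size
    for (p in ls$points) {
      if (p$role == "TS1_HA") {
        expect_equal(sum(p$record$frequencies < 0), 1L)
        expect_equal(-min(p$record$frequencies), rx$imag[[p$pathway]])
      }
    }
  }
})

test_that("the component split moves with the seed but the observables do not", {
  rx <- random_landscape_prescription(21)
  g1 <- gen_landscape(rx, seed = 1)
  g2 <- gen_landscape(rx, seed = 2)
  e_solv1 <- vapply(g1$points, function(p) p$record$E_solv, 0)
  e_solv2 <- vapply(g2$points, function(p) p$record$E_solv, 0)
  expect_false(any(e_solv1 == e_solv2))
  t1 <- relative_table(landscape(g1$points))
  t2 <- relative_table(landscape(g2$points))
  expect_equal(t1$dE_zpe, t2$dE_zpe, tolerance = 1e-9)
  expect_equal(t1$dG, t2$dG, tolerance = 1e-9)
})

test_that("the large-model preset yields dominant C1 through the pipeline", {
  g <- gen_landscape(preset_prescription("tauD-modelC"), seed = 4)
  s <- selectivity_report(landscape(g$points))
  expect_equal(s$carbon, "C1")
  expect_equal(s$call, "dominant")
})

test_that("a flat prescription gives an unselective verdict", {
  rx <- landscape_prescription(
    model = "flat",
    barriers_e = c(C1R = 10, C1S = 10, C2S = 10, C2R = 10),
    barriers_g = c(C1R = 10, C1S = 10, C2S = 10, C2R = 10))
  s <- selectivity_report(landscape(gen_landscape(rx, seed = 2)$points))
  expect_equal(s$call, "unselective")
  expect_equal(unname(s$branching$fractions), rep(0.25, 4), tolerance = 1e-9)
})

test_that("toy PDB composition is the census ground truth", {
  f <- withr::local_tempfile(fileext = ".pdb")
  gen_toy_pdb(c(GLU = 19, ASP = 14, ARG = 19, LYS = 9), f, seed = 1)
  cen <- residue_census(read_pdb(f))
  expect_equal(cen$counts[["GLU"]], 19)
  expect_equal(cen$counts[["ASP"]], 14)
  expect_equal(cen$counts[["ARG"]], 19)
  expect_equal(cen$counts[["LYS"]], 9)
  expect_equal(cen$net, 28 - 33)
  # deterministic under the seed
  f2 <- withr::local_tempfile(fileext = ".pdb")
  gen_toy_pdb(c(GLU = 19, ASP = 14, ARG = 19, LYS = 9), f2, seed = 1)
  expect_identical(readLines(f), readLines(f2))
})

test_that("an empty composition fails downstream as an empty structure", {
  f <- withr::local_tempfile(fileext = ".pdb")
  gen_toy_pdb(setNames(integer(), character()), f, seed = 1)
  expect_error(read_pdb(f), "empty structure|parse error")
})
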