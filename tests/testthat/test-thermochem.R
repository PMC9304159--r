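test_that("ZPE follows the half-sum of real modes", {
  expect_equal(rrho(freq_record(1000))$ZPE, 0.5 * 1000 * cst$cm1_kcal)
  expect_equal(rrho(freq_record(1000))$ZPE, 1.4296, tolerance = 1e-4)
  # imaginary mode excluded and counted
  th <- rrho(freq_record(c(-1495, 1000, 2000)))
  expect_equal(th$n_imag, 1L)
  expect_equal(th$ZPE, 0.5 * 3000 * cst$cm1_kcal)
  # two imaginary modes warn but are still excluded
  expect_warning(th2 <- rrho(freq_record(c(-1495, -300, 1000))), "imaginary")
  expect_equal(th2$ZPE, 0.5 * 1000 * cst$cm1_kcal)
})

test_that("a single atom has zero ZPE and translational terms only", {
  g <- geometry("C", matrix(0, 1, 3), masses = 39.948)
  th <- rrho(qc_record("atom", 0, 1, E_high = 0, geometry = g))
  expect_equal(th$ZPE, 0)
  # Sackur-Tetrode at 298.15 K, 1 atm for mass 39.948 amu
  expect_equal(th$S, 36.98, tolerance = 1e-3)
  expect_equal(th$H_corr, 2.5 * cst$R_kcal * 298.15, tolerance = 1e-12)
})

test_that("G_corr is internally consistent with H_corr and S", {
  for (fr in list(c(100, 500, 3000), c(-1200, 40, 900))) {
    th <- rrho(freq_record(fr), T = 310)
    expect_equal(th$G_corr, th$H_corr - 310 * th$S / 1000, tolerance = 1e-9)
  }
})

test_that("energy assembly sums its components on the kcal/mol scale", {
  z <- qc_record("z", 0, 1, E_high = 0, E_solv = 0, E_disp = 0,
                 frequencies = numeric(0))
  expect_equal(assemble(z, scheme = "E+ZPE+solv+disp")$E_total, 0)
  r <- freq_record(numeric(0), E_high = -0.1)
  th <- rrho(r)
  a <- assemble(r, th, scheme = "E+ZPE")
  expect_equal(a$E_total + 5, -0.1 * cst$hartree_kcal + 5, tolerance = 1e-9)
  expect_equal(-0.1 * cst$hartree_kcal + 5, -57.751, tolerance = 1e-3)
  # relative energies track E_high differences exactly
  r2 <- freq_record(numeric(0), E_high = -0.1 + 0.016573, label = "hi")
  d <- assemble(r2, scheme = "E+ZPE")$E_total - assemble(r, scheme = "E+ZPE")$E_total
  expect_equal(d, 10.4, tolerance = 1e-3)
  # every assembled energy equals the sum of its listed components
  full <- freq_record(c(500, 1500), E_high = -2, E_solv = -0.01,
                      E_disp = -0.002)
  for (s in c("E+ZPE", "E+ZPE+solv", "E+ZPE+solv+disp", "G")) {
    a <- assemble(full, scheme = s)
    expect_equal(a$E_total, sum(unlist(a$components)), tolerance = 1e-9)
  }
})

test_that("schemes name their missing components", {
  r <- freq_record(500, E_high = -1)
  expect_error(assemble(r, scheme = "E+ZPE+solv"), "E_solv")
  r2 <- freq_record(500, E_high = -1, E_solv = -0.01)
  expect_error(assemble(r2, scheme = "E+ZPE+solv+disp"), "E_disp")
})

test_that("isotope substitution reproduces the diatomic reduced-mass law", {
  rec <- feo_fixture(860, masses = c(56, 16))
  f0 <- isotope_frequencies(rec$hessian, rec$geometry)
  expect_equal(f0, 860, tolerance = 1e-6)
  f18 <- isotope_frequencies(rec$hessian, rec$geometry, list("2" = 18))
  mu16 <- 56 * 16 / 72
  mu18 <- 56 * 18 / 74
  expect_equal(f18, 860 * sqrt(mu16 / mu18), tolerance = 1e-6)
  expect_equal(f0 - f18, 38.0, tolerance = 0.05)
  # empty substitution map is the identity
  expect_equal(isotope_frequencies(rec$hessian, rec$geometry, list()), f0,
               tolerance = 1e-8)
})

test_that("H -> D substitution scales stretches within harmonic bounds", {
  rx <- harmonic_prescription(c("C", "C", "H", "H", "H", "H"),
                              freqs = c(3100, 3050, 3000, 2950,
                                        seq(1500, 300, length.out = 8)))
  rec <- gen_harmonic_system(rx, seed = 11)
  f <- isotope_frequencies(rec$hessian, rec$geometry)
  subs <- as.list(rep(mass_deuterium, 4))
  names(subs) <- 3:6
  fD <- isotope_frequencies(rec$hessian, rec$geometry, subs)
  ratio <- fD / f
  expect_true(all(ratio >= 1 / sqrt(2) - 1e-9 & ratio <= 1 + 1e-9))
})

test_that("heavier isotopes never raise a real frequency", {
  for (seed in 1:5) {
    rx <- harmonic_prescription(c("O", "H", "C", "N"),
                                freqs = sort(runif(6, 200, 3500), TRUE))
    rec <- gen_harmonic_system(rx, seed = seed)
    f <- isotope_frequencies(rec$hessian, rec$geometry)
    i <- sample(4, 1)
    fh <- isotope_frequencies(rec$hessian, rec$geometry,
                              setNames(list(rec$geometry$masses[i] * 1.5), i))
    expect_true(all(fh[fh > 0] <= f[f > 0] + 1e-8))
  }
})

test_that("frequency scaling leaves imaginary modes unscaled", {
  expect_equal(scale_frequencies(860, 0.95), 817)
  expect_equal(scale_frequencies(c(200, 3000), 1.0), c(200, 3000))
  expect_equal(scale_frequencies(c(-1495, 3000), 0.95), c(-1495, 2850))
  expect_error(scale_frequencies(100, 1.5), "scale")
})

test_that("frequency-list and hessian inputs agree in G_corr", {
  rx <- harmonic_prescription(c("O", "H", "H"), freqs = c(3700, 3600, 1600))
  rec <- gen_harmonic_system(rx, seed = 3)
  f <- isotope_frequencies(rec$hessian, rec$geometry)
  twin <- qc_record("twin", 0, rec$multiplicity, E_high = rec$E_high,
                    frequencies = f, geometry = rec$geometry)
  expect_lt(abs(rrho(rec)$G_corr - rrho(twin)$G_corr), 0.01)
})

test_that("vibrational entropy reaches its high-temperature limit", {
  T <- 298.15
  nu <- 0.04 * T / cst$hc_kB  # hc nu / kB T = 0.04
  th <- rrho(freq_record(nu), T = T)
  S_limit <- cst$R_cal * (1 + log(T / (cst$hc_kB * nu)))
  expect_equal(th$S, S_limit, tolerance = 0.01)
})

test_that("projection leaves 3N-6 (3N-5 linear) finite modes", {
  rec3 <- gen_harmonic_system(
    harmonic_prescription(c("O", "H", "H"), freqs = c(3700, 3600, 1600)),
    seed = 2)
  expect_length(isotope_frequencies(rec3$hessian, rec3$geometry), 3L)
  rec2 <- feo_fixture()
  expect_length(isotope_frequencies(rec2$hessian, rec2$geometry), 1L)
})
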