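toy_structure <- function(composition, seed = 1) {
  f <- withr::local_tempfile(fileext = ".pdb", .local_envir = parent.frame())
  gen_toy_pdb(composition, f, seed = seed)
  read_pdb(f)
}

test_that("the residue census counts charges by type", {
  s <- toy_structure(c(ASP = 3, ARG = 2, HIS = 1))
  cen <- residue_census(s)
  expect_equal(cen$n_negative, 3)
  expect_equal(cen$n_positive, 2)
  expect_equal(cen$net, -1)
  # flagging the His as doubly protonated adds one positive charge
  his_no <- unique(s$resno[s$resid == "HIS"])
  cen2 <- residue_census(s, his_protonated = paste0("A:", his_no))
  expect_equal(cen2$net, 0)
  expect_equal(cen2$n_his_protonated, 1)
})

test_that("census is invariant to atom order and duplicated atoms", {
  s <- toy_structure(c(GLU = 4, LYS = 2, ALA = 3))
  base <- residue_census(s)
  shuffled <- s[sample(nrow(s)), ]
  class(shuffled) <- class(s)
  expect_equal(residue_census(shuffled)$counts, base$counts)
  doubled <- rbind(s, s)
  class(doubled) <- class(s)
  expect_equal(residue_census(doubled)$counts, base$counts)
  expect_equal(base$net, 2 - 4)
})

test_that("HETATM groups stay out of the amino-acid tally", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ASP A   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2 FE    FE A 501       5.000   5.000   5.000  1.00  0.00          FE",
    "END"), f)
  cen <- residue_census(read_pdb(f))
  expect_equal(sum(cen$counts), 1)
  expect_equal(cen$n_negative, 1)
})

test_that("point-charge dipoles convert e*A to debye", {
  m <- data.frame(chain = "A", resno = 1:2, resid = c("P", "M"),
                  q = c(1, -1), x = c(1, -1), y = 0, z = 0)
  class(m) <- c("oxo_charges", "data.frame")
  expect_equal(dipole_from_charges(m), c(2 * 4.80321, 0, 0),
               tolerance = 1e-9)
  # net-neutral: translation invariant
  expect_equal(dipole_from_charges(m, origin = c(13, -4, 7)),
               dipole_from_charges(m), tolerance = 1e-9)
  # all-zero charges
  m0 <- m
  m0$q <- 0
  expect_equal(dipole_from_charges(m0), c(0, 0, 0))
})

test_that("net-charged dipoles shift with the origin by q_net * dO", {
  m <- data.frame(chain = "A", resno = 1:3, resid = "X", q = c(1, 1, -1),
                  x = rnorm(3), y = rnorm(3), z = rnorm(3))
  class(m) <- c("oxo_charges", "data.frame")
  o1 <- c(0, 0, 0)
  o2 <- c(2, -1, 5)
  d <- dipole_from_charges(m, o1) - dipole_from_charges(m, o2)
  expect_equal(d, 1 * (o2 - o1) * 4.80321, tolerance = 1e-9)
})

test_that("the Coulomb field obeys the unit case and superposition", {
  one <- data.frame(chain = "A", resno = 1, resid = "X", q = 1,
                    x = 0, y = 0, z = 0)
  class(one) <- c("oxo_charges", "data.frame")
  E <- field_at_point(one, c(1, 0, 0))
  expect_equal(E, c(14.3996, 0, 0), tolerance = 1e-9)
  # symmetric +/- pair, midpoint: along the axis, doubled magnitude
  pair <- data.frame(chain = "A", resno = 1:2, resid = "X", q = c(1, -1),
                     x = c(-1, 1), y = 0, z = 0)
  class(pair) <- c("oxo_charges", "data.frame")
  Em <- field_at_point(pair, c(0, 0, 0))
  expect_equal(Em, c(2 * 14.3996, 0, 0), tolerance = 1e-9)
  # superposition on random charge sets
  set.seed(3)
  for (i in 1:5) {
    mk <- function(n) {
      d <- data.frame(chain = "A", resno = seq_len(n), resid = "X",
                      q = sample(c(-1, 1), n, TRUE),
                      x = runif(n, 2, 9), y = runif(n, 2, 9),
                      z = runif(n, 2, 9))
      class(d) <- c("oxo_charges", "data.frame")
      d
    }
    a <- mk(4)
    b <- mk(3)
    ab <- rbind(a, b)
    class(ab) <- class(a)
    p <- c(-5, -5, -5)
    expect_equal(field_at_point(ab, p),
                 field_at_point(a, p) + field_at_point(b, p),
                 tolerance = 1e-9)
  }
  expect_error(field_at_point(one, c(0.3, 0, 0)), "0.5 angstrom")
  none <- one[one$q > 99, ]
  class(none) <- class(one)
  expect_equal(field_at_point(none, c(1, 1, 1)), c(0, 0, 0))
})

test_that("charge placement uses side-chain representative atoms", {
  s <- toy_structure(c(ASP = 1, ARG = 1, LYS = 1, GLU = 1, ALA = 2))
  cm <- charge_model(s)
  expect_equal(nrow(cm), 4L)
  expect_setequal(cm$q[cm$resid %in% c("ASP", "GLU")], -1)
  expect_setequal(cm$q[cm$resid %in% c("ARG", "LYS")], 1)
  # representative atom, not the CA: x-offset 1.5 A on the lattice
  asp <- cm[cm$resid == "ASP", ]
  ca <- s[s$resno == asp$resno & trimws(s$atom) == "CA", ]
  expect_equal(asp$x - ca$x, 1.5, tolerance = 0.7)  # plus lattice jitter
})

test_that("environment field projects onto a Stark bond-weakening whose sign flips with the charges", {
  s <- toy_structure(c(GLU = 5, ARG = 2, LYS = 1), seed = 6)
  cm <- charge_model(s)
  site <- c(-8, -8, -8)
  E <- field_at_point(cm, site)
  u <- c(0, 1, 0)
  dmu <- c(0.2, 1.5, -0.1)
  shift <- stark_bdfe(80, dmu, sum(E * u), axis = u) - 80
  cm_neg <- cm
  cm_neg$q <- -cm_neg$q
  E2 <- field_at_point(cm_neg, site)
  shift2 <- stark_bdfe(80, dmu, sum(E2 * u), axis = u) - 80
  expect_equal(shift2, -shift, tolerance = 1e-9)
  expect_gt(abs(shift), 0)
})
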