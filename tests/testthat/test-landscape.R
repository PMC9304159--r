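test_that("a lone reactant gives a single zero row", {
  ls <- landscape(list(bare_point("re", -100, "Re")), scheme = "E+ZPE+solv+disp")
  tab <- relative_table(ls)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$dE_zpe, 0)
  expect_equal(tab$dG, 0)
})

test_that("a generated profile reproduces its prescribed energetics", {
  g <- gen_landscape(preset_prescription("tauD-modelB-fig5"), seed = 3)
  ls <- landscape(g$points, T = 298.15)
  tab <- relative_table(ls)
  ts1 <- tab[tab$role == "TS1_HA", ]
  b <- setNames(ts1$dE_zpe, ts1$pathway)
  expect_equal(b[c("C2S", "C2R", "C1S", "C1R")],
               c(C2S = 9.3, C2R = 10.9, C1S = 11.8, C1R = 12.2),
               tolerance = 1e-9)
  im <- tab[tab$role == "IM1", ]
  expect_setequal(round(im$dE_zpe, 6), c(-8.8, -8.1))
  expect_equal(setNames(ts1$dG, ts1$pathway)[names(table1_barriers()$B)],
               table1_barriers()$B, tolerance = 1e-9)
})

test_that("relative tables are gauge-invariant in E_high", {
  rx <- random_landscape_prescription(5)
  g <- gen_landscape(rx, seed = 5)
  tab0 <- relative_table(landscape(g$points))
  shifted <- lapply(g$points, function(p) {
    r <- p$record
    r$E_high <- r$E_high + 0.5  # +0.5 hartree on every species
    p$record <- r
    p
  })
  tab1 <- relative_table(landscape(shifted))
  expect_equal(tab1$dE_zpe, tab0$dE_zpe, tolerance = 1e-9)
  expect_equal(tab1$dG, tab0$dG, tolerance = 1e-9)
})

test_that("spin ordering sorts multiplicities by assembled energy", {
  mk <- function(mult, gap) bare_point(paste0(mult, "Re"), -1000 + gap / cst$hartree_kcal,
                                       "Re", spin = mult)
  pts <- list(mk(1, 19.2), mk(3, 10.4), mk(5, 0), mk(7, 10.9))
  ord <- spin_ordering(pts)
  expect_equal(attr(ord, "ground"), 5)
  expect_equal(ord$multiplicity, c(5, 3, 7, 1))
  expect_equal(ord$gap, c(0, 10.4, 10.9, 19.2), tolerance = 1e-9)
  # input order must not matter
  for (perm in list(c(4, 2, 3, 1), c(2, 1, 4, 3))) {
    expect_equal(spin_ordering(pts[perm])$multiplicity, ord$multiplicity)
  }
  expect_equal(spin_ordering(pts[2])$gap, 0)
  expect_error(spin_ordering(list(mk(5, 0), mk(5, 1))), "duplicate")
})

test_that("selectivity verdicts reproduce the model-by-model reversal", {
  t1 <- table1_barriers()
  sC <- selectivity_from_barriers(t1$C)
  expect_equal(sC$carbon, "C1")
  expect_equal(sC$call, "dominant")
  sDA <- selectivity_from_barriers(t1$DA)
  expect_equal(sDA$carbon, "C1")
  expect_equal(sDA$call, "dominant")
  sB <- selectivity_from_barriers(t1$B)
  expect_equal(sB$lowest, "C2S")
  expect_equal(sB$window, 2.3, tolerance = 1e-9)
  expect_equal(names(which.max(sB$carbon_fractions)), "C2")
  sDB <- selectivity_from_barriers(t1$DB)
  expect_equal(sDB$lowest, "C2R")
  expect_equal(names(which.max(sDB$carbon_fractions)), "C2")
})

test_that("equal barriers give an unselective quarter split", {
  s <- selectivity_from_barriers(
    c(C1R = 15, C1S = 15, C2S = 15, C2R = 15))
  expect_equal(s$call, "unselective")
  expect_true(is.na(s$carbon))
  expect_equal(unname(s$branching$fractions), rep(0.25, 4))
})

test_that("selectivity_report extracts TS1 barriers from a landscape", {
  g <- gen_landscape(preset_prescription("tauD-modelC"), seed = 9)
  s <- selectivity_report(landscape(g$points))
  expect_equal(s$carbon, "C1")
  expect_equal(s$call, "dominant")
  expect_equal(s$lowest, "C1S")
})

test_that("the rate-determining step is the highest located TS", {
  pts <- list(
    bare_point("re", -1000, "Re"),
    bare_point("ts1", -1000 + 9.3 / cst$hartree_kcal, "TS1_HA", "C1S"),
    bare_point("im", -1000 - 8 / cst$hartree_kcal, "IM1", "C1S"),
    bare_point("ts2", -1000 + 2.0 / cst$hartree_kcal, "TS2_reb", "C1S"))
  ls <- landscape(pts)
  expect_equal(as.character(rds(ls, "C1S")), "ts1")
  expect_false(attr(rds(ls, "C1S"), "tie"))
  # single TS
  ls1 <- landscape(pts[1:2])
  expect_equal(as.character(rds(ls1, "C1S")), "ts1")
  expect_error(rds(ls1, "C2R"), "no located TS")
  # exact tie resolves to the earlier mechanistic step and is flagged
  pts[[4]] <- bare_point("ts2", -1000 + 9.3 / cst$hartree_kcal,
                         "TS2_reb", "C1S")
  tie <- rds(landscape(pts), "C1S")
  expect_equal(as.character(tie), "ts1")
  expect_true(attr(tie, "tie"))
})

test_that("TS roles demand exactly one imaginary mode", {
  expect_error(
    stationary_point(freq_record(c(500, 1000)), "TS1_HA", "C1R"),
    "exactly one imaginary")
  expect_error(
    stationary_point(freq_record(c(-100, 500)), "Re"),
    "zero imaginary")
})

test_that("group spin densities conserve the total", {
  rec <- qc_record("ts", 0, 5, E_high = -1,
                   spin_densities = c(3.05, 0.55, -0.35, -0.25, 0.0))
  gs <- group_spin(rec, list(FeO = 1:2, substrate = 3:4))
  expect_equal(unname(gs["substrate"]), -0.60)
  expect_equal(sum(gs), sum(rec$spin_densities))
  all_in_one <- group_spin(rec, list(all = 1:5))
  expect_equal(unname(all_in_one["all"]), sum(rec$spin_densities))
  expect_equal(unname(group_spin(rec, list(none = integer()))["none"]), 0)
  expect_error(group_spin(rec, list(a = 1:2, b = 2:3)), "disjoint")
  expect_error(group_spin(rec, list(a = 99)), "out of range")
})

test_that("hydrogen-bond census honours distance and angle criteria", {
  pair <- geometry(c("N", "O"), rbind(c(0, 0, 0), c(0, 0, 1.961)))
  hits <- hbond_census(pair, 1, 2, d_max = 2.5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$dist, 1.961, tolerance = 1e-9)
  expect_equal(nrow(hbond_census(pair, 1, 2, d_max = 1.5)), 0L)
  expect_error(hbond_census(pair, 1, 2, mode = "angle"), "distance")
  # with an explicit hydrogen the angle criterion filters
  trio <- geometry(c("N", "H", "O"),
                   rbind(c(0, 0, 0), c(0, 0, 1.0), c(0, 0, 2.9)))
  h <- hbond_census(trio, 1, 3, d_max = 2.5, angle_min = 120)
  expect_equal(nrow(h), 1L)
  expect_equal(h$angle, 180, tolerance = 1e-6)
  bent <- geometry(c("N", "H", "O"),
                   rbind(c(0, 0, 0), c(0, 0, 1.0), c(1.8, 0, 1.2)))
  expect_equal(nrow(hbond_census(bent, 1, 3, d_max = 2.5, angle_min = 120)), 0L)
})

test_that("census on a synthetic lattice matches brute-force enumeration", {
  set.seed(8)
  n <- 12
  xyz <- matrix(runif(3 * n, 0, 6), n, 3)
  g <- geometry(rep(c("N", "O"), each = 6), xyz)
  donors <- 1:6
  acceptors <- 7:12
  hits <- hbond_census(g, donors, acceptors, d_max = 3.0, mode = "distance")
  brute <- sum(outer(donors, acceptors, Vectorize(function(i, j)
    sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= 3.0)))
  expect_equal(nrow(hits), brute)
})

test_that("a pathway with a located TS2 requires its intermediate", {
  pts <- list(bare_point("re", -1000, "Re"),
              bare_point("ts2", -999.9, "TS2_reb", "C1S"))
  expect_error(landscape(pts), "no IM1")
})
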