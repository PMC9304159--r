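#!/usr/bin/env Rscript
# Iron(IV)-oxo stretch diagnostics: a diatomic Fe-O harmonic fixture tuned
# to 860 cm^-1 is pushed through the mass-weighted Hessian machinery to get
# the 18O isotope shift and the 0.95-scaled fundamental, the two numbers
# that anchor the oxidant's vibrational assignment.

suppressPackageStartupMessages(library(oxoscope))
cfg <- run_config(seed = 1L)

feo <- gen_harmonic_system(
  harmonic_prescription(c("Fe", "O"), freqs = 860, masses = c(56, 16)),
  seed = cfg$seed)
nu16 <- isotope_frequencies(feo$hessian, feo$geometry)
nu18 <- isotope_frequencies(feo$hessian, feo$geometry, list("2" = 18))

tab <- data.frame(
  quantity = c("Fe-16O stretch", "Fe-18O stretch", "18O shift",
               "Fe-16O stretch, scaled 0.95"),
  value_cm1 = c(nu16, nu18, nu16 - nu18, scale_frequencies(nu16, 0.95)))
write_report(tab, file.path(cfg$out_dir, "feo_stretch.tsv"), cfg)
print(tab, digits = 6)

# RRHO bookkeeping for the same fixture at standard conditions
th <- rrho(feo, T = cfg$temperature, P = cfg$pressure)
cat(sprintf("\nRRHO at %.2f K: ZPE %.4f kcal/mol, S %.3f cal/(mol K), G_corr %.4f kcal/mol\n",
            cfg$temperature, th$ZPE, th$S, th$G_corr))
cat("The 38 cm^-1 isotope drop and the 817 cm^-1 scaled fundamental match",
    "the resonance-Raman fingerprint of the ferryl oxidant.\n")
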