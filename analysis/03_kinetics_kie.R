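#!/usr/bin/env Rscript
# Kinetics: converts the experimental abstraction rate (13 s^-1 at 5 C)
# into a free energy of activation, then maps Eyring and Wigner-corrected
# kinetic isotope effects over a grid of barrier differences and TS
# imaginary modes.

suppressPackageStartupMessages(library(oxoscope))
cfg <- run_config(seed = 1L)

dg_exp <- dg_from_rate(13, T = 278.15)
tst <- data.frame(k_s1 = 13, T_K = 278.15, dG_act_kcal_mol = dg_exp,
                  k_roundtrip_s1 = rate_from_dg(dg_exp, T = 278.15))
write_report(tst, file.path(cfg$out_dir, "tst_experiment.tsv"), cfg)
cat(sprintf("k = 13 s^-1 at 278.15 K  ->  dG_act = %.2f kcal/mol\n", dg_exp))

grid <- expand.grid(ddG_kcal_mol = c(0.5, 1.0, 1.5, 2.0),
                    nu_H_cm1 = c(1495, 1534), nu_D_cm1 = c(1050, 1150))
rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
  k <- kie_wigner(dg_exp, dg_exp + grid$ddG_kcal_mol[i],
                  grid$nu_H_cm1[i], grid$nu_D_cm1[i], T = cfg$temperature)
  data.frame(grid[i, ], KIE_eyring = k$KIE_eyring, Qt_H = k$Qt_H,
             Qt_D = k$Qt_D, KIE_wigner = k$KIE_wigner)
}))
write_report(rows, file.path(cfg$out_dir, "kie_grid.tsv"), cfg)
print(rows, digits = 4)
cat(sprintf(
  "\nQt(i1495, %.2f K) = %.3f: the large imaginary modes of the C1-H\n",
  cfg$temperature, wigner_qt(1495, cfg$temperature)),
  "abstraction TSs triple the semiclassical KIE through tunnelling.\n")
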