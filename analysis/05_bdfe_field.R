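#!/usr/bin/env Rscript
# Bond strengths under external electric fields: zero-field BDFE bookkeeping
# for the substrate C-H bonds and linear Stark scans along the three
# molecular axes, locating the field that flips which bond is weakest.

suppressPackageStartupMessages(library(oxoscope))
cfg <- run_config(seed = 1L)

# gas-phase component fixture: C2-H is the weaker bond by 11.1 kcal/mol
c1 <- bdfe(G_RH = -372640.0, G_R = -372244.2, G_H = -310.0, bond = "C1-H")
c2 <- bdfe(G_RH = -372640.0, G_R = -372255.3, G_H = -310.0, bond = "C2-H")
cat(sprintf("gas-phase BDFE: %s %.1f vs %s %.1f kcal/mol\n",
            c1$bond, c1$BDFE, c2$bond, c2$BDFE))

# solvated-like fixture: all four bonds within 2 kcal/mol, C1-H weakest;
# dipole differences chosen so the y-axis (along the pro-R C1-H bond) is
# the responsive direction and z (molecular skeleton) is inert.
bonds_y <- list(list(label = "C1-H", bdfe0 = 74.0, dmu = 0.6),
                list(label = "C2-H", bdfe0 = 75.2, dmu = -0.4))
bonds_z <- list(list(label = "C1-H", bdfe0 = 74.0, dmu = 0.02),
                list(label = "C2-H", bdfe0 = 75.2, dmu = -0.02))
grid <- seq(-0.5, 0.5, by = 0.05)
scan_y <- field_scan(bonds_y, axis = "y", fields = grid)
scan_z <- field_scan(bonds_z, axis = "z", fields = grid)

tab <- data.frame(field_V_per_A = grid,
                  C1_y = scan_y$bdfe[, "C1-H"], C2_y = scan_y$bdfe[, "C2-H"],
                  weakest_y = weakest_bond_map(scan_y)$weakest,
                  weakest_z = weakest_bond_map(scan_z)$weakest)
write_report(tab, file.path(cfg$out_dir, "bdfe_field_scan.tsv"), cfg)
print(tab, digits = 4)

cr <- crossing_field(c(74.0, -0.6 * 4.8032), c(75.2, 0.4 * 4.8032))
cat(sprintf(
  "\ny-axis crossing at %+.3f V/A: a negative y-field makes C2-H the weakest\n",
  cr$field),
  "bond, while any field along z leaves C1-H weakest across the grid -\n",
  "the protein's electrostatics pick the regiochemistry.\n")
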