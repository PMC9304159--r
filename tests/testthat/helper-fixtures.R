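# Shared fixture builders. Everything is generated in code; no binary data.

cst <- oxoscope::oxo_constants

# minimal record with frequencies
freq_record <- function(freqs, label = "m", E_high = -1, mult = 1, ...) {
  qc_record(label, charge = 0, multiplicity = mult, E_high = E_high,
            frequencies = freqs, ...)
}

# diatomic Fe-O fixture with integer masses, tuned to a target stretch
feo_fixture <- function(nu = 860, masses = c(56, 16), seed = 1) {
  gen_harmonic_system(
    harmonic_prescription(c("Fe", "O"), freqs = nu, masses = masses),
    seed = seed)
}

# a stationary point with a bare (frequency-free) record at a given
# assembled-total offset; used where thermochemistry is irrelevant
bare_point <- function(label, E_high, role, pathway = "none", spin = 5,
                       model = "T", E_solv = 0, E_disp = 0) {
  freqs <- if (role %in% c("TS1_HA", "TS2_reb")) c(-1300, 100) else 100
  stationary_point(
    qc_record(label, 0, spin, E_high = E_high, E_solv = E_solv,
              E_disp = E_disp, frequencies = freqs),
    role = role, pathway = pathway, spin = spin, model = model)
}
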