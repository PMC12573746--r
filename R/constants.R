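# CODATA 2018 values.  All internal math runs in reduced (dimensionless)
# normal coordinates with energies in cm^-1; these constants appear only at
# the unit boundaries (mass-weighted steps, excitation wavelength).
.const <- list(
  h       = 6.62607015e-34,    # Planck constant, J s (exact)
  c_cm    = 2.99792458e10,     # speed of light, cm s^-1 (exact)
  amu     = 1.66053906660e-27, # unified atomic mass unit, kg
  c_au    = 137.035999084,     # speed of light, atomic units
  # hc/E_h: 1 hartree in cm^-1
  hartree_cm = 219474.6313632,
  # angular frequency in a.u. for light of wavelength 1 nm is nm_to_au / 1
  nm_to_omega_au = 45.56335252907657
)
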