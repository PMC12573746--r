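# anharmvoa

Anharmonic IR, VCD, Raman and ROA spectra from quartic vibrational force
fields, by generalized second-order vibrational perturbation theory
(GVPT2) with automatic Fermi/Darling–Dennison resonance handling — plus a
brute-force variational oracle that makes every stage of the pipeline
testable on synthetic model systems.

## Who this is for

Overtone and combination ("anharmonic") bands of chiral molecules are now
routinely measurable in VCD and ROA, but simulating them requires both
*mechanical* anharmonicity (cubic/quartic force constants) and
*electrical* anharmonicity (second and third derivatives of the
electromagnetic tensors μ, m, α, G′, A).  This package is for people who
work on that machinery itself: it implements the full GVPT2 intensity
pipeline in a self-contained, oracle-validated form, with a generator of
synthetic vibrational problems (controlled anharmonicity, contrived
near-resonances, enantiomer pairs) standing in for quantum-chemistry
output.

## The model in brief

Potential, in reduced normal coordinates (everything cm⁻¹):

    V = ½ Σ ωᵢ qᵢ² + ⅙ Σ f_ijk qᵢqⱼq_k + 1/24 Σ f_ijkl qᵢqⱼq_kq_l

Second-order perturbation theory turns this into anharmonic constants
χ_ij and level energies E(v) = Σ ωᵢvᵢ + Σ χ_ij[(vᵢ+½)(vⱼ+½)−¼].
Near-degeneracies ω_k ≈ ωᵢ+ωⱼ (Fermi) and ωᵢ ≈ ωⱼ (Darling–Dennison)
make perturbative denominators diverge; they are detected by energy- and
intensity-based criteria, the resonant pieces are removed from the sums,
and the interactions are reinstated by diagonalizing small variational
blocks ("generalized" VPT2).  Transition moments of the five property
surfaces are assembled through second order with an eleven-term
decomposition separating mechanical, electrical and mixed contributions,
rotated by the block eigenvectors, and convolved into Lorentzian bands.
A spectral similarity statistic s(a) with optimal frequency scaling
compares computed against measured two-column spectra.

The methods vignette (`vignettes/anharmonic-voa.Rmd`) documents the
closed-form χ expressions, the deperturbation bookkeeping, phase and
normalization conventions, and all numerical choices.

## Worked example

The one-mode Morse system is the closed-form benchmark: VPT2 on its
quartic Taylor truncation reproduces the exact Morse levels.

```r
library(anharmvoa)

sys <- make_morse_system(3000, 50)     # omega, omega_x in cm^-1
chi <- anharmonic_constants(sys$force_field)
chi$chi[1, 1]                          # -50   (= -omega_x, exactly)
state_energy(chi, 1L)                  # 2900  (omega - 2 omega_x)
state_energy(chi, 2L)                  # 5700  (2 omega - 6 omega_x)
```

A generated Fermi dyad (ω₁ ≈ 2ω₂, detuning 25 cm⁻¹, f₁₂₂ = 31.2 cm⁻¹)
shows the whole resonance pipeline:

```r
dy <- make_random_system(generator_spec(
  n_modes = 2, omega_range = c(1400, 1550), seed = 105,
  resonance_plan = list(list(type = "fermi", i = 2, j = 2, k = 1,
                             detuning = 25, f = 31.2))))
gv <- gvpt2_solve(dy)
gv$resonances
#> <resonance_set> flagged: 1 Fermi, 0 DD 1-1, 0 DD 2-2
gv$states[, c("label", "energy_vpt2", "energy", "block")]
#>   label energy_vpt2   energy block
#> 1     G       0.000    0.000    NA
#> 2    F1    3074.702 3072.536     1
#> 3    F2    1550.112 1550.112    NA
#> 4    O1    6150.047 6150.047    NA
#> 5    O2    3100.623 3102.789     1
#> 6  C1,2    4625.550 4625.550    NA
```

The fundamental F1 and the overtone O2 form the variational block; their
deperturbed VPT2 energies (3074.7, 3100.6) repel to the GVPT2 eigenvalues
(3072.5, 3102.8).  The independent variational solver — exact
diagonalization of the same Hamiltonian in a harmonic-oscillator product
basis — puts the dyad at (3072.538, 3102.778), within 0.011 cm⁻¹:

```r
sol <- variational_solve(dy$force_field, max_quanta = 30)
sort(c(oracle_level(sol, c(1, 0)), oracle_level(sol, c(0, 2))))
#> 3072.538 3102.778
```

Transition observables, with dissymmetry factors g = 4R/D and circular
intensity differences (ROA/Raman):

```r
tr <- assign_bands(vpt2_transitions(dy))
tr$table[, c("label", "energy", "D", "R", "g", "cid", "assignment")]
#>   label energy        D         R      g       cid assignment
#> 1    F1   3073 2.24e-03  5.45e-04  0.972 -0.000747         F1
#> 2    F2   1550 1.55e-02 -3.99e-03 -1.027 -0.003996         F2
#> 3    O1   6150 5.59e-05  8.12e-05  5.808  0.012472         O1
#> 4    O2   3103 2.04e-04 -2.85e-04 -5.586 -0.007724         O2
#> 5  C1,2   4626 8.76e-04  3.48e-04  1.587  0.012362       C1,2
```

(D, R and the g/CID magnitudes are in the generator's atomic-unit scales,
not those of any real molecule.)  `vpt2_spectra()` convolves the sticks
into the four band spectra; `similarity()` scores them against reference
spectra.  A thin command-line front end over these functions lives in
`inst/scripts/anharmvoa.R` (`generate`, `vpt2`, `numdiff`, `simulate`,
`oracle`, `compare`).

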