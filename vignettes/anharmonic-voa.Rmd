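---
title: "Anharmonic vibrational optical activity with GVPT2: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anharmonic vibrational optical activity with GVPT2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anharmvoa)
```

## The problem

Overtone and combination bands in IR, VCD, Raman and ROA spectra of rigid
chiral molecules are one to two orders of magnitude weaker than the
fundamentals, yet modern spectrometers resolve them routinely.  Simulating
them requires going beyond the double-harmonic approximation in two ways at
once: *mechanical* anharmonicity (cubic and quartic terms of the potential
deform the vibrational wavefunctions and shift the levels) and *electrical*
anharmonicity (second and third derivatives of the electromagnetic property
tensors light up transitions that are dark in the harmonic picture).

This package implements the generalized second-order vibrational
perturbation theory (GVPT2) pipeline for that problem: from a quartic
normal-coordinate force field and property surfaces to anharmonic stick
spectra and Lorentzian bands, with automatic detection and variational
correction of Fermi and Darling-Dennison resonances.  Because no deposited
quartic force fields with full chiroptical surfaces exist as a convenient
test bed, a synthetic-system generator is a first-class module: every
downstream stage is validated against a brute-force variational solver on
generated systems.

## Model and conventions

The vibrational potential is the quartic normal-coordinate expansion

$$V = \tfrac12\sum_i \omega_i q_i^2 + \tfrac16\sum_{ijk} f_{ijk}\,
q_i q_j q_k + \tfrac1{24}\sum_{ijkl} f_{ijkl}\, q_i q_j q_k q_l ,$$

with $\omega_i$, $f_{ijk}$, $f_{ijkl}$ in cm$^{-1}$ and $q_i$ dimensionless
reduced coordinates.  Only *semidiagonal* quartics (at least two equal
indices) are stored -- the set obtainable from single-mode displacement
differencing; fully off-diagonal quartics read as zero.

**Normalization of the reduced coordinate.** The literature is ambiguous
about a $\sqrt2$ in the definition of $q$.  We fix
$\langle 0 | q | 1 \rangle = 1/\sqrt2$, i.e.
$q = (a + a^\dagger)/\sqrt2$, so the harmonic potential is
$(\omega/2)q^2$ and the harmonic levels are $\omega(v + \tfrac12)$.  All
matrix elements, force constants, and property derivatives in the package
are consistent with this single choice.

**Property surfaces.** Five tensors are expanded to third derivative order
in atomic units per power of $q$: the electric dipole $\mu$ and
polarizability $\alpha$ (and the dipole-quadrupole tensor $A$) as ordinary
Taylor series with $1, 1, \tfrac12, \tfrac16$ prefactors, and the magnetic
dipole $m$ and electric-magnetic polarizability $G'$ as *momentum
expansions*: their series run over $p_i$ in the first slot with prefactors
$1, 1, 1, \tfrac12$.  With $p = i(a^\dagger - a)/\sqrt2 = iP$, matrix
elements of the momentum-expanded tensors between real vibrational states
are purely imaginary; the package stores the real factor $M$ of the
physical moment $iM$ throughout.  The rotational strength is then the real
number $R = \langle\mu\rangle \cdot M$ and ROA cross invariants are real
products, with the correct parity: negating the $m$, $G'$ and $A$ surfaces
(an enantiomer, `mirror_image()`) flips $R$ and the ROA invariants and
leaves $D$ and the Raman invariants untouched.

Two details of the momentum expansion are worth stating because they are
silent in most presentations:

* mixed same-mode products $p_i q_i$ are operator-ordering ambiguous; we
  symmetrize, $\tfrac12(p_i q_i + q_i p_i)$, in both the VPT2 engine and
  the variational oracle (so the cross-check is of independent
  implementations of the *same* operator);
* the constant (equilibrium) value of a momentum-expanded tensor is
  excluded from transition moments: a static magnetic moment has the wrong
  phase to interfere with the $iP$ expansion and cannot drive a vibrational
  transition.  For electric tensors the constant term is kept; its formal
  contribution through wavefunction nonorthogonality cancels order by
  order.

## VPT2 energies and the resonance problem

The anharmonic constants $\chi_{ij}$ follow the standard second-order
closed forms for the quartic potential.  We evaluate them in
partial-fraction form, which makes the resonance bookkeeping exact:

$$\chi_{ii} = \frac{f_{iiii}}{16} - \frac{1}{16}\sum_j f_{iij}^2
\left[\frac{2}{\omega_j} - \frac{1/2}{2\omega_i - \omega_j}
+ \frac{1/2}{2\omega_i + \omega_j}\right],$$

$$\chi_{ij} = \frac{f_{iijj}}{4} - \frac14\sum_k
\frac{f_{iik}f_{jjk}}{\omega_k} - \frac18\sum_k f_{ijk}^2
\left[\frac{1}{D_1} + \frac{1}{D_2} + \frac{1}{D_3} -
\frac{1}{D_4}\right] + \chi_{ij}^{\mathrm{Cor}},$$

with $D_1 = \omega_i{+}\omega_j{+}\omega_k$,
$D_2 = \omega_j{+}\omega_k{-}\omega_i$,
$D_3 = \omega_i{+}\omega_k{-}\omega_j$,
$D_4 = \omega_i{+}\omega_j{-}\omega_k$, and an optional Coriolis term
$\chi_{ij}^{\mathrm{Cor}} = \sum_a B_a (\zeta^a_{ij})^2
(\omega_i/\omega_j + \omega_j/\omega_i)$ that enters energies only, never
intensities.  Levels follow
$E(v) - E(0) = \sum_i \omega_i v_i + \sum_{i\le j}
\chi_{ij}[(v_i{+}\tfrac12)(v_j{+}\tfrac12) - \tfrac14]$.

Each $1/D$ piece corresponds to exactly one Fermi triple
($\omega_k \approx \omega_i + \omega_j$, including the overtone case
$i = j$ through the $1/(2\omega_i - \omega_j)$ piece of $\chi_{ii}$).  When
a triple is flagged, its piece is dropped from every $\chi$ element it
touches (*deperturbation*), and the coupling is reinstated variationally:
the flagged states form blocks (transitive closure, so chained resonances
become polyads) with deperturbed energies on the diagonal and the
first-order cubic elements $f_{ijk}/(2\sqrt2)$ (combination) or
$f_{iik}/4$ (overtone) off the diagonal.  The bookkeeping is exactly
balanced: the removed second-order piece equals the second-order expansion
of the block eigenvalue shift, which is why GVPT2 energies are continuous
(to $\sim W^4/\Delta^3$) as a coupling crosses the detection threshold --
a property the test suite checks numerically.

The closed-form $\chi$ route was validated against the package's
variational oracle: the one-mode Morse construction
($f_{iii} = -3\sqrt{2\omega\omega_x}$, $f_{iiii} = 14\omega_x$) gives
$\chi_{11} = -\omega_x$ *exactly*, reproducing the analytic Morse levels,
and random two-mode fields agree with converged variational energies to
fractions of the residual fourth-order terms.

### Detection criteria

Fermi triples are screened by three conditions: a 200 cm$^{-1}$ proximity
gate on the detuning; the strength test $f_{ijk}^4 \ge 64 (1+\delta)^2
\Delta^2$; and an intensity-oriented test $|f_{ijk}| \ge 0.02\,\Delta^2
(1+\delta)$.  The Kronecker $\delta$ is applied to the doubled combination
index ($i=j$, the overtone case) -- the only placement that changes the
overtone/combination weighting; a config switch restores the literal
printed placement (which never fires).  The third criterion mixes cm$^{-1}$
against cm$^{-2}$ in its conventional printed form; it is implemented
verbatim, with `use_5c = FALSE` as an escape hatch.

Darling-Dennison resonances (1-1 between fundamentals, 2-2 among
two-quanta states) use a 200 cm$^{-1}$ gate, a 10 cm$^{-1}$ threshold on
the contact-transformed coupling, and (1-1 only) a 0.03 threshold on the
second-order wavefunction coefficient linking the two fundamentals.  The
coupling itself is evaluated as the explicit second-order Van Vleck matrix
element

$$K_{ab} = \langle a|V_4|b\rangle + \tfrac12\sum_c \langle a|V_3|c\rangle
\langle c|V_3|b\rangle\left[\frac{1}{E_a - E_c} + \frac{1}{E_b -
E_c}\right]$$

with exact ladder matrix elements (the sums are finite), rather than as a
transcribed closed form; the two are the same object, and the
implementation is cross-checked against the oracle by inverting the
effective $2\times2$ block of a contrived near-degenerate pair.

## Transition moments and the eleven-term decomposition

VPT2 wavefunctions are kept to second order in intermediate normalization,
$\psi = \psi^{(0)} + \psi^{(1)} + \psi^{(2)}$, with cubic terms first order
and quartic terms second order; coefficients of deperturbed partners are
exactly zero.  A property operator splits by derivative order into
$X^{(0)}$ (constant + first derivatives), $X^{(1)}$ (second), $X^{(2)}$
(third), and the normalized transition moment expands into eleven terms:
the harmonic term, six terms feeding the harmonic property through
anharmonic wavefunctions (including the second-order normalization
correction, term 11), two mixed terms, and the two pure electrical terms
(2 and 5).

The **reported moment is the sum of the eleven terms** -- the consistent
through-second-order expansion, for which "terms sum to the moment" is an
exact identity.  The full nonlinear ratio (complete numerator over
$\sqrt{\langle\psi_F|\psi_F\rangle\langle\psi_I|\psi_I\rangle}$) is kept
alongside as `full_ratio`; it differs by beyond-second-order cross products
(e.g. $\langle F^{(1)}|X^{(2)}|I^{(0)}\rangle$) and is the quantity
compared against exact variational matrix elements in the oracle tests,
where it agrees to a few parts in $10^3$.  For states in a variational
block, moments of the deperturbed states are rotated by the block
eigenvectors before observables are formed.

Observables follow the standard far-from-resonance conventions:
$D = |\langle\mu\rangle|^2$, $R = \langle\mu\rangle\cdot M$, dissymmetry
$g = 4R/D$; Raman/ROA invariants $a^2$, $\beta(\alpha)^2$, $aG'$,
$\beta(G')^2$, $\beta(A)^2$ contracted from the transition tensors, with
SCP(180$^\circ$) backscattering sticks
$4(45a^2 + 7\beta(\alpha)^2)$ and
$(96/c)(\beta(G')^2 + \beta(A)^2/3)$ and their ratio as the circular
intensity difference.  Overall Raman/ROA scales are arbitrary units
(instrument-specific); only ratios and relative intensities are
contract-bearing.  A $((\nu_0-\nu)/\nu_0)^4$ scattered-frequency factor is
applied by default (it cancels in the CID) and thermal populations are not
(0 K sticks); both are switchable.  Excitation defaults to 532 nm.

## Finite differencing

The two-step protocol displaces each mode by $\pm 0.01$ amu$^{1/2}$ Å
(converted per mode to the reduced coordinate via
$\delta q = \delta Q\sqrt{4\pi^2 c\,\omega/h}$; 0.0545 at 1000 cm$^{-1}$):
central differences of analytic Hessians give $f_{ijk}$, symmetric second
differences give the semidiagonal $f_{iijk}$; the same stencils applied to
analytic first-derivative property tensors give the full second and
semidiagonal third property derivatives.  Estimates of one constant from
different displaced modes are averaged, and the pre-symmetrization spread
is reported as a diagnostic.  Fully off-diagonal third derivatives are not
obtainable from single-mode displacements and are not computed.  Because
generated surfaces are exact polynomials, the round trip generator →
evaluator → differencing recovers stored constants to roundoff ($10^{-11}$
relative or better), and on smooth non-polynomial surfaces the error falls
fourfold when the step is halved.

## The synthetic generator as the study conditions

`make_random_system()` draws harmonic wavenumbers uniformly from 600--3200
cm$^{-1}$ (the mid-infrared span of rigid organic molecules), zero-mean
cubic constants with a default scale of 25 cm$^{-1}$ clamped to
$|f_{ijk}| \le 0.1\,\omega_{\min}$ (the perturbative regime), semidiagonal
quartics at 8 cm$^{-1}$ with positive diagonals (bounded single-mode
truncations), and property surfaces that are exact polynomials with scales
0.1 / 0.02 / 0.005 a.u. for first/second/third derivatives -- mimicking
the typical order-of-magnitude decay of real property derivatives.
Resonance plans are realized exactly: a requested Fermi detuning
constructs $\omega_k = \omega_i + \omega_j - \Delta$; a requested 1-1
coupling $K$ is injected through $f_{iiij} = 8K$, whose direct contact
element is exactly $K$.

`ensure_nonresonant = TRUE` defines what "resonance-free" has to mean for
validation studies: all pairwise and two-quanta proximity gates cleared by
a 220 cm$^{-1}$ margin, three-quanta near-degeneracies (1:3 and 1:2+1,
which enter the perturbative sums at fourth order) cleared by 150
cm$^{-1}$, and every cubic capped at half the Fermi strength threshold for
its actual detuning -- a system sitting *at* the detection boundary is not
meaningfully non-resonant.

**What the generator does not emulate:** real correlations between force
constants (e.g. Morse-like $f_{iii}$--$f_{iiii}$ relations along bond
stretches), mode-localized property derivatives, degenerate modes of
symmetric molecules, or solvent-perturbed surfaces.  Passing tests
therefore demonstrate the correctness of the perturbative machinery, the
resonance logic, the tensor algebra and parity behaviour -- not the
fidelity of any electronic-structure input.

### The oracle-equivalence ensemble

The acceptance comparison against the variational oracle uses
`cubic_scale = 20`, `quartic_scale = 0.5`.  The quartic suppression is a
*validity-regime* requirement, not a tuning convenience: VPT2 treats the
quartic potential at first order only, so its deviation from the exact
(variational) result is dominated by the second-order quartic
contribution, of order $f_4^2/\omega$.  At Morse-realistic quartics this
intrinsic deviation reaches tens of percent of the anharmonic shift (the
quartic-truncated Morse fundamental lies 14.6 cm$^{-1}$ above the VPT2
value, which coincides with the exact Morse level); a sub-1% comparison is
only meaningful where the quartics are subdominant.  Agreement is measured
per system -- every level within 1% of the system's largest anharmonic
shift -- because individual shifts can cancel to $\sim 0.01$ cm$^{-1}$,
far below the oracle's own convergence resolution, making per-state ratios
degenerate.  Under these conditions the observed worst deviation is
$\approx 0.5\%$ for energies and $\approx 0.5\%$ for transition moments.

## The variational oracle

The oracle diagonalizes the same quartic Hamiltonian exactly in a
harmonic-oscillator product basis truncated by total quanta (default 20;
convergence asserted by a $\le 0.1$ cm$^{-1}$ plateau on +5 quanta), and
computes operator matrix elements between its eigenvectors, with
eigenvector phases fixed by the dominant configuration.  It deliberately
shares no matrix-element code with the engine: one-dimensional operators
are built as explicit tridiagonal matrices raised to powers by matrix
multiplication, against the engine's ladder-recursion route.  It is
limited to three modes and refuses negative diagonal quartics (unbounded
truncations show variational collapse instead of convergence).

## Numerical choices and degenerate inputs

* Denominator guards: an exact zero resonant denominator not covered by a
  flagged resonance is a hard error instructing a threshold review, never
  a silent large number; block sizes are capped (default 30 states).
* Degenerate harmonic frequencies are accepted as input; no symmetry
  blocking is attempted (asymmetric molecules are the target).
* Similarity: the overlap functional is *maximized* over the scaling
  factor $a \in [0.95, 1.05]$ by golden-section search (tolerance
  $10^{-4}$), consistent with $s = 1$ for identical spectra; the unscaled
  $s(1)$ is always reported alongside.  Sign-carrying spectra use the same
  formula without absolute values, so wrong signs penalize $s$.
* Convolution: each stick becomes a Lorentzian of area equal to the stick
  intensity, FWHM 8 cm$^{-1}$ by default, on a uniform 1 cm$^{-1}$ grid;
  integration is by trapezoid.
* Serialization writes 17 significant digits, so model-system documents
  round-trip bit exactly.

## Problem sizes

The validation suite runs entirely on systems of 1--3 modes: oracle bases
of a few hundred to ~2000 product states diagonalize in seconds, and
twenty-system ensembles complete in well under a minute.  The engine
itself has no such limit -- states through two quanta and their moments
scale polynomially with mode count -- but oracle-checked claims are only
made where the oracle converges.

## Known limitations

* States above two quanta are outside the manifold; transitions borrowing
  intensity from triply excited states are absent by construction.
* Coriolis data affect energies only; no rovibrational fine structure.
* The far-from-resonance (transparent-molecule) approximation underlies
  the Raman/ROA invariants; resonance-Raman effects are out of scope.
* Wrong-sign band counting against experimental band lists is a
  documented recipe (compare signs of matched `vcd_stick`/`roa_stick`
  entries between a transition table and a curated experimental list),
  not an operation: it requires curated experimental data the package
  does not ship.
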