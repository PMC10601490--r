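---
title: "Models and methods behind vibronica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vibronica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibronica)
```

vibronica simulates the photophysics workflow that in production codes
spans an electronic-structure engine, a sampling tool, a surface-hopping
driver and a spectroscopy post-processor — but entirely on analytic model
potentials, so that every quantity has a closed form or an independent
numerical oracle to test against. This vignette records the models, the
conventions, and the design decisions that were genuinely open.

## Units and coordinates

Everything internal is in Hartree atomic units ($\hbar = m_e = e = a_0 =
1$); `unit_convert()` handles Å, amu, cm$^{-1}$, eV and fs at the
boundaries. Three coordinate layers appear:

* **Cartesian** positions $x$ (bohr) and momenta $p$;
* **mass-weighted normal coordinates** $q = L^T M^{1/2}(x - x_{eq})$ with
  conjugate momenta, in which a mode's energy is
  $(p_i^2 + \omega_i^2 q_i^2)/2$ — this is the layer all sampling works
  in;
* **dimensionless model coordinates** $Q_\alpha = \sqrt{\omega_\alpha}\,
  q_\alpha$, $P_\alpha = p_\alpha/\sqrt{\omega_\alpha}$, in which the
  vibronic Hamiltonian takes its standard form with kinetic energy
  $\sum_\alpha (\omega_\alpha/2) P_\alpha^2$ and ground-surface baseline
  $\sum_\alpha (\omega_\alpha/2) Q_\alpha^2$.

The dimensionless convention was an open choice; we adopted the
mass-frequency-scaled form because it makes the linear-coupling
parameters directly comparable across modes and matches common practice
for vibronic-coupling models.

## Normal modes

`compute_modes()` mass-weights the Cartesian Hessian, projects out the
external subspace, and diagonalizes. The projection builds the six (five
for linear molecules, three for a free atom) translation/rotation
generator vectors explicitly in mass-weighted coordinates,
orthonormalizes them by Gram–Schmidt, and applies $P = I - BB^T$ from
both sides. Doing the projection by explicit generators — rather than by
eigenvalue shifting — gives a testable null-space property: a rigid
translation must see exactly zero restoring force.

Numerical choices: residual external modes below **10 cm$^{-1}$**
(configurable) are discarded as projection zeros; negative eigenvalues
are kept, flagged imaginary, and excluded from sampling with a warning;
eigenvector signs follow a deterministic convention (largest-magnitude
component positive, first index on ties) so repeated runs are bitwise
identical.

## Initial conditions

**Normal-mode sampling (NMS).** Each vibrational mode receives an energy
drawn from the classical Boltzmann law, $E_i = -k_B T \ln u$, and a
uniform phase $\phi$: $A_i = \sqrt{2E_i}/\omega_i$, $Q_i = A_i\cos\phi$,
$P_i = -A_i\omega_i\sin\phi$, which makes the mode energy exactly $E_i$
for every phase. After the Cartesian transform the center-of-mass
momentum is removed and the whole phase-space point is rescaled to match
$\sum_i E_i$.

Two decisions here were open and are worth recording. First, the rescale
applies **one common scalar** $s = \sqrt{E_{target}/E_{current}}$ to both
positions and momenta — the minimal choice, which preserves each mode's
kinetic/potential split. Second, only the center-of-mass *translation*
is removed by default; rigid-body angular momentum is left untouched
(an optional `zero_rotation` flag removes it), since spurious rotation is
a much smaller artifact and zeroing it changes the sampled ensemble.

**Wigner sampling.** The harmonic ground-state Wigner density is a
product of Gaussians, $W_i \propto e^{-\omega_i Q_i^2/\hbar}
e^{-P_i^2/\hbar\omega_i}$; thermal dependence enters through
$\alpha_i(T) = \tanh(\hbar\omega_i/2k_BT)$ multiplying the exponent, so
$\alpha \to 1$ recovers the ground state and high temperature recovers
the classical limit. Closed-form moments used as oracles:
$\mathrm{Var}(Q) = 1/(2\omega\alpha)$, $\mathrm{Var}(P) =
\omega/(2\alpha)$, $\langle E\rangle = (\omega/2)\coth(\hbar\omega/2k_B
T)$. Two sampling schemes are provided: `"reject"` draws uniformly on
$\pm 5\sigma$ boxes and accepts against $W/W_{max}$ (truncation error
below $10^{-5}$ of the mass), and `"direct"` draws the equivalent
Gaussians; they agree in distribution and the tests assert it.

Wigner ensembles are **not** energy-rescaled: the rescale is a classical
bookkeeping step, and applying it would destroy the quantum width and
zero-point energy that are the method's point. This is why Wigner
ensembles come out broader and centered at higher energy than NMS — the
package asserts exactly that on a 2000 cm$^{-1}$ mode at 300 K.

## The vibronic model

`lvc_model()` holds the standard linear vibronic coupling Hamiltonian in
dimensionless coordinates,
$$V_{ii}(Q) = \epsilon_i + \sum_\alpha \kappa_{i,\alpha} Q_\alpha +
  \sum_\alpha \tfrac{\omega_\alpha}{2} Q_\alpha^2, \qquad
  V_{ij}(Q) = \eta_{ij} + \sum_\alpha \lambda_{ij,\alpha} Q_\alpha,$$
with constant state and transition dipoles. `evaluate_adiabatic()`
diagonalizes $V$, then applies Hellmann–Feynman for gradients and
couplings: $d_{ab,\alpha} = [U^T \partial_\alpha V\, U]_{ab}/(E_b -
E_a)$. Gaps below a **degeneracy floor of $10^{-10}$ E$_h$** have the
denominator floored and the point flagged, rather than raising — a
trajectory passing a conical intersection should not die with an
exception.

`build_lvc()` parameterizes the model from single-point reference data:
$\epsilon_i = E_i - E_0$; $\kappa$ is the Cartesian state gradient
projected through $M^{-1/2}L$ and the $\omega^{-1/2}$ scaling; and
$\lambda_{ij,\alpha}$ is the energy gap times the equally-projected
nonadiabatic coupling vector. The gap-times-projection rule for
$\lambda$ is a convention (no unique formula exists once the model is an
approximation); because coupling vectors diverge near degeneracies, the
raw coupling-gradient input is supported as a first-class, formula-free
alternative, and the degenerate-reference case errors out with that
advice.

Eigenvector **phase is only meaningful between frames**, so sign fixing
and state tracking live in `frame_overlap()`, not in the eigensolver:
the overlap $S = U_{prev}^T U_{curr}$ is computed, columns are permuted
by maximal-overlap assignment when a diagonal entry falls below
$1/\sqrt2$ (trivially avoided crossings), and signs are flipped until
the diagonal is non-negative. The trajectory engine applies the sign
correction every step; it does not re-permute states, because on the
smooth model systems the package targets, adiabatic energy ordering and
diabatic character never exchange silently between steps.

## Surface hopping

Nuclear motion is velocity Verlet on the active adiabatic surface of the
model Hamiltonian ($\dot Q = \omega P$, $\dot P = -\partial E_a/\partial
Q$). The electronic coefficients follow the adiabatic-basis TDSE,
$\dot c_k = -iE_kc_k - \sum_i T_{ki} c_i$, integrated by 25 (default)
exponential-midpoint substeps per nuclear step with linear interpolation
of $E$ and $T$ — each substep is exactly unitary, so the norm is
conserved to machine precision by construction.

Time-derivative couplings come from either source:

* `"nac"` — analytic coupling vectors contracted with the velocity,
  $T_{ik} = \sum_\alpha d_{ik,\alpha}\dot Q_\alpha$;
* `"hst"` — the wave-function-overlap formula $T_{ik} = (S_{ik} -
  S_{ki})/2\Delta t$, the midpoint-antisymmetrized form, which is
  $O(\Delta t^2)$ accurate; the tests assert the quadratic convergence
  (error drops $\ge 3.5\times$ on halving the step) and that the two
  sources give statistically identical hop counts.

Hopping follows the fewest-switches prescription with
$g_{a\to k} = \max[0,\, 2\Delta t\, T_{ak}\mathrm{Re}(c_a^*c_k)/|c_a|^2]$
— the sign convention is pinned by differentiating $|c_a|^2$ under the
TDSE, and a test checks that $g$ equals the measured population outflow.
Open choices, fixed as follows:

* hops are attempted **after the full nuclear step**, using couplings
  averaged over the step (no mid-step hop geometry) — simple and
  reproducible bit-for-bit;
* velocity rescaling at a hop happens **along the nonadiabatic coupling
  direction** when it is finite and well-conditioned, else by uniform
  scaling; an energetically forbidden hop is frustrated and leaves state
  and momentum untouched (no velocity reversal);
* **no decoherence correction** is applied by default — the method is
  plain fewest-switches hopping; decoherence-corrected variants are out
  of scope;
* each trajectory of an ensemble gets its own seed (`master + index`),
  so swarms are reproducible and order-independent.

Energy is conserved to the symplectic integrator's bounded oscillation
(below $10^{-6}$ E$_h$ over 1000 steps of 0.5 fs on smooth surfaces) and
is bookkept exactly across hops; through the high-curvature kink of a
tight avoided crossing the bounded oscillation can reach a few
$10^{-6}$ E$_h$ at a 2 a.u. step, which is an integrator property, not a
leak — running the same trajectory backwards retraces it to $10^{-6}$.

## Spectra and kinetics

**Steady-state spectra** follow the nuclear-ensemble recipe: sample
geometries, compute vertical gaps $\Delta E$ and oscillator strengths
$f = \tfrac23\Delta E|\mu|^2$ through the model, then average
unit-area Gaussian or Lorentzian lineshapes centered at $\Delta E$,
weighted by $f$. The empirical width $\delta$ is interpreted as the
**full width at half maximum** for both shapes (the convention had to be
pinned; FWHM is what experimentalists quote). The absolute scale is the
standard constant $C = e^2h/4\varepsilon_0m_ec \approx 1.098\times
10^{-16}\,\mathrm{cm^2\,eV}$, exposed via `sigma_prefactor()` and
overridable; the sum rule $\int\sigma\,dE = C\bar f$ independent of
$\delta$ is asserted in the tests. The default energy grid spans
$[\min\Delta E - 3\delta,\ \max\Delta E + 3\delta]$ with 1000 points.

**Transient maps** extract snapshots along trajectory swarms at a
stride, evaluate the manifold of higher states at each geometry, and
accumulate excited-state absorption (positive) and stimulated emission
(negative) from the active state only — a classical
ensemble-over-trajectories picture with no coherence contributions. A
temporal Gaussian instrument response is available as an opt-in flag
rather than a default, since it is a property of an experiment, not of
the dynamics.

**Photolysis rates** integrate $J = \int\phi(\lambda)\sigma_{abs}
(\lambda)F(\lambda)\,d\lambda$ by composite trapezoid on the merged grid
of all three curves; cross sections are pointwise functions of photon
energy, so the wavelength view is a direct re-expression
($\lambda = 1239.841984/E$), with the lineshape's unit area defined on
the energy axis.

**Kinetics** solve $\dot p = Kp$ as $p(t) = e^{Kt}p(0)$ by
eigendecomposition, falling back to scaling-and-squaring when the rate
matrix is defective (equal consecutive rates in a chain). The canonical
check: a 0.01 fs$^{-1}$ decay reaches $1/e$ of the initial population at
exactly 100 fs.

## What the synthetic systems do and do not cover

The generators produce harmonic diatomics with chosen force constants, a
bent triatomic built backwards from chosen frequencies (so the answer is
known exactly), one-mode two-state crossing models with controllable
gap, slope and couplings, random multimode vibronic models, and
piecewise flux/yield curves. They emulate the *structure* of real
problems — zero-point motion, avoided crossings, bright and dark states,
overlapping bands — with magnitudes typical of small organic
chromophores (frequencies 500–3000 cm$^{-1}$, couplings $10^{-3}$–
$10^{-2}$ E$_h$).

They do not emulate anharmonicity, true conical-intersection topography
(the one-mode models have avoided crossings only), geometry-dependent
dipoles or spin–orbit couplings, or solvent. Passing tests therefore
demonstrate that the machinery is correct on its stated model class, not
that harmonic/LVC assumptions hold for any particular molecule.

Problem sizes in the shipped tests and acceptance script — $10^5$-sample
moment checks, 2000-trajectory hopping ensembles, 400-trajectory
transient maps — were chosen so the closed-form comparisons sit at
3-standard-error resolution while the whole suite completes in a few
minutes on one core.

## Known limitations

* The trajectory engine tracks states by energy ordering with per-step
  phase correction; genuinely diabatic passage through *exact* crossings
  (trivially avoided, gap $\to 0$) would need the maximal-overlap
  re-assignment that `frame_overlap()` provides at the API level.
* Hessians are inputs; there is no finite-difference Hessian builder or
  interface to an electronic-structure engine.
* No quadratic vibronic couplings, geometry-dependent dipoles, or
  decoherence/ISC extensions beyond what constant couplings induce.
* Ensemble archives are plain JSON: human-readable and lossless (17
  significant digits), but not compact for very large swarms.
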