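# vibronica

Semiclassical nonadiabatic photodynamics and ensemble spectroscopy on
analytic model potentials, in R.

Photochemists who simulate what happens after a molecule absorbs light
face a pipeline problem: vibrational analysis feeds phase-space sampling,
sampling feeds trajectory surface hopping, and trajectories feed spectra
and kinetics — and each stage normally hides inside a different program
wrapped around an electronic-structure engine. vibronica implements that
whole pipeline self-contained, replacing the quantum-chemistry engine
with linear vibronic coupling (LVC) model Hamiltonians that are cheap,
analytic, and exactly testable. It is aimed at method developers and
teachers who need a transparent, reproducible reference implementation,
and at anyone prototyping sampling/hopping/spectroscopy protocols before
paying for ab initio surfaces.

## What it computes

**Normal modes.** From a Cartesian Hessian: mass weighting
H̃ = M^(−1/2) H M^(−1/2), explicit projection of translations/rotations,
frequencies ω_i and orthonormal mass-weighted eigenvectors L_i.

**Initial conditions.** Classical normal-mode sampling — per-mode
Boltzmann energies E_i = −k_B T ln u, amplitude A_i = √(2E_i)/ω_i, random
phase, center-of-mass cleanup and common-factor rescaling to ΣE_i — and
quantum Wigner sampling, ground-state or thermal:

    W_i ∝ exp(−α_i ω_i Q_i²/ħ) · exp(−α_i P_i²/(ħω_i)),   α_i = tanh(ħω_i / 2k_B T)

**LVC models.** Diabatic potentials V_ii = ε_i + Σ κ_iα Q_α + Σ (ω_α/2)Q_α²
coupled by V_ij = η_ij + Σ λ_ijα Q_α, with constant dipoles; adiabatic
energies, analytic Hellmann–Feynman gradients and nonadiabatic couplings,
inter-step eigenvector overlaps with phase correction.

**Surface hopping.** Tully's fewest-switches algorithm: velocity-Verlet
nuclei, exactly-unitary electronic propagation, hop probabilities
g_{a→k} = max[0, 2Δt T_ak Re(c_a* c_k)/|c_a|²], energy-conserving velocity
rescaling along the coupling vector, frustrated hops. Time-derivative
couplings from analytic vectors (d·velocity) or from wave-function
overlaps, T_ik = (S_ik − S_ki)/2Δt.

**Spectra and kinetics.** Nuclear-ensemble absorption spectra (broadened
ΔE/f pairs with f = (2/3)ΔE|μ|²), trajectory-resolved transient maps
(excited-state absorption positive, stimulated emission negative),
photolysis rates J = ∫ φ(λ) σ_abs(λ) F(λ) dλ, and rate-equation
population kinetics p(t) = exp(Kt) p(0).

## Worked example

```r
library(vibronica)

# a 2000 cm^-1 diatomic oscillator and its thermal Wigner ensemble
w <- 2000 * au_constants$cm1_to_hartree
dia <- make_diatomic(c(1, 1), k = 911.444243 * w^2)
modes <- compute_modes(dia$hessian, dia$molecule)
#> <normal_modes> 1 vibrational mode(s), 5 external projected
#>     2000.0  cm-1

ens <- sample_wigner(modes, temperature = 300, n = 5000, scheme = "reject", seed = 7)
mean(mode_energies(ens))
#> 4.5124e-03      # E_h; the zero-point energy w/2 is 4.5563e-03

# one surface-hopping passage through an avoided crossing
model <- make_two_state_crossing(gap = 0, slope = 0.01,
                                 coupling_const = 0.005, omega = 0.002)
traj <- run_trajectory(model, Q0 = -8, P0 = 10, state = 1,
                       dt = 2, n_steps = 400, tdc = "hst", seed = 1)
traj
#> <sh_trajectory> 401 records, dt = 0.04838 fs, tdc = hst, 0 hop(s), completed

# rate-equation kinetics: a 0.01 fs^-1 decay reaches 1/e at 100 fs
K <- matrix(c(-0.01, 0.01, 0, 0), 2, 2)
kinetics_propagate(K, c(1, 0), c(0, 50, 100, 200))
#>   time     P1     P2
#> 1    0 1.0000 0.0000
#> 2   50 0.6065 0.3935
#> 3  100 0.3679 0.6321
#> 4  200 0.1353 0.8647
```

The ensemble's mean energy sits just below the zero-point energy because
at 300 K a 2000 cm⁻¹ mode is almost entirely in its ground state —
exactly the quantum effect that distinguishes Wigner from classical
sampling. This particular trajectory seed survives the crossing
diabatically (it ends on the upper adiabat with zero accepted hops);
across a 2000-trajectory swarm the surviving fraction reproduces the
Landau–Zener closed form within statistical error.

A thin command-line front end over the same functions lives in
`inst/cli/vibronica.R` (subcommands `freqs`, `sample`, `propagate`,
`spectrum`, `photolysis`, `fixture`).

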