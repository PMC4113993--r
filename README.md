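# flagsync

Analysis toolkit for **hydrodynamic synchronization of eukaryotic
flagella**. When two flagellated cells are held close together with no
physical or chemical connection, their flagella can still phase-lock —
the only possible coupling is the flow each beating flagellum drives
through the fluid. This package implements the computational chain used
to quantify that phenomenon:

1. **Stokeslet flow analysis** — a beating flagellum's far field is the
   flow of a point force in Stokes flow,
   `u_i(x) = (F_j / 8πμr)(δ_ij + r̂_i r̂_j)`, decaying as `1/r`.
   `fit_stokeslet()` fits the force position `x0` and reduced force
   `G = F/8πμ` to gridded planar velocity snapshots (PIV-like data);
   `fit_force_modulation()` extracts the within-beat modulation
   `F(t)/8πμ = A0 (1 + A1 sin 2πt/T)`; `radial_decay()` verifies the
   `1/r` law; `rotational_stiffness_bound()` converts the interflagellar
   torque estimate `C⊥ u l²/2` into a lower bound on the cell-body
   rotational stiffness.
2. **Resistive force theory (RFT)** — from tracked waveform polylines,
   the local drag force density `f = C⊥ u⊥ + C∥ u∥` with Lighthill's
   slender-body coefficients
   (`C⊥ = 4πμ/(ln(0.18 λ/a) + 1/2)`, `C∥ = 2πμ/(ln(0.18 λ/a) − 1/2)`),
   integrated force `F(t) = ∫ f ds`, force-weighted centre of mass, and
   tangent angles at three arclength stations.
3. **Phase dynamics** — beat phases by Poincaré sectioning of
   interrogation-region signals (`poincare_phase()`), the interflagellar
   phase difference `Δ(t) = (φ1 − φ2)/2π`, phase-locked segments, slips,
   and the `√L`-rescaled fluctuation statistics.
4. **Stochastic Adler model** — the phase difference obeys
   `Δ̇ = δν − 2πε sin(2πΔ) + ξ(t)`, `⟨ξ(t)ξ(t′)⟩ = 2 T_eff δ(t − t′)`:
   Brownian motion in a tilted washboard potential. `simulate_adler()`
   integrates it; `infer_adler()` recovers `(ε, δν, T_eff)` from a
   measured `Δ(t)`; `fit_coupling_law()` fits the Stokeslet-mediated
   scaling `|κ| = k/L` of the dimensionless coupling `κ = ε/ω̄` against
   the scaled separation `L = d/l`; `predicted_freq_diff()` and
   `noisy_freq_diff()` give the frequency-difference bifurcation
   `δω/δω_far = √(1 − (2πε/δν)²)` without and with noise.
5. **Minimal two-sphere model** — two spheres driven along compliant
   circular orbits by a phase-dependent tangential force and coupled
   through the Oseen tensor (`simulate_pair()`, `run_rower_grid()`),
   with geometric-phase rescaling `Φ(φ)` to isolate genuine
   synchronization, and the closed form
   `κ_spheres = (27 μ π a² l² ω̄ / 2R) · L⁻¹` (`kappa_spheres()`).

A seeded synthetic-data module (`generate_piv_frames()`,
`generate_waveforms()`, `generate_pair_phases()`,
`generate_section_signal()`) produces all of these inputs with known
ground truth, so every stage is testable end to end without any
external data.

## Worked example

Generate a synthetic pair of noisy coupled phase oscillators at the
study's typical parameter scale (`ε/ω̄ = 0.016`, `δν/ω̄ = 0.058`,
`T_eff/ω̄ = 0.005`, `ω̄ = 33 Hz`) and recover the model triple from the
phase-difference series alone:

```r
library(flagsync)
omega <- 33
cfg  <- synthetic_config(seed = 11, duration = 100)
par  <- adler_params(eps = 0.016 * omega, delta_nu = 0.058 * omega,
                     T_eff = 0.005 * omega, omega_bar = omega)
pair <- generate_pair_phases(cfg, par, omega_bar = omega, L = 1)
infer_adler(pair)
#> Stochastic Adler model fit (IP pair)
#>   eps = 0.5424 /s, delta_nu = 1.922 /s, T_eff = 0.1635 /s
#>   Delta0 = 0.102 beats, kappa = eps/omega_bar = 0.01644 (omega_bar = 33.000 Hz)
#>   locked fraction 1.00, tau_sync = 2.43 s, 39 slips
```

The generating values were `eps = 0.528`, `delta_nu = 1.914` and
`T_eff = 0.165` (all in 1/s): each is recovered within a few percent.
`Delta0` is the locked phase lag in beats; `tau_sync` the mean duration
of a phase-locked stretch between slips. The closed-form quantities of
the minimal model print as:

```r
signif(kappa_spheres(L = 1), 2)
#> [1] 0.014
rotational_stiffness_bound(l = 20, r = 5, G = 2e3, alpha_star = 0.01)$k_bound
#> [1] 31740.99
```

i.e. a predicted dimensionless coupling of 0.014 at one flagellar
length of separation, and a rotational-stiffness lower bound of
~3 × 10⁴ pN·μm for an angular displacement bound of 0.01 rad.

`run_demo(seed = 1, out_dir = "results")` runs the whole chain —
synthetic flow movie → per-frame Stokeslet fits → force-modulation
recovery, radial decay, RFT forces, coupling-law recovery across four
separations, the bifurcation curve, and a two-sphere simulation — and
writes a JSON + text report.

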