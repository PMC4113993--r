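---
title: "Models and methods behind flagsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flagsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagsync)
```

flagsync quantifies how two flagella, coupled only through the fluid
between them, synchronize their beating. This vignette explains the
models the package implements, the assumptions behind them, the choices
made where the design was genuinely open, and what the synthetic-data
generators do and do not emulate.

## The flow of a beating flagellum

At zero Reynolds number the far field of a localized force distribution
is dominated by its net force: the Stokeslet,
$$u_i(\mathbf{x}) = \frac{F_j}{8\pi\mu r}\left(\delta_{ij} +
\hat r_i \hat r_j\right), \qquad \mathbf{r} = \mathbf{x} -
\mathbf{x}_0 ,$$
which decays as $1/r$ and is anisotropic: the speed on the force axis is
exactly twice the speed at the same distance perpendicular to it. The
package works throughout with the *reduced* force
$G = F/8\pi\mu$ (µm²/s), the combination every flow measurement
constrains directly; conversion to pN happens only at reporting, via
$\mu$ in Pa·s (1 Pa·s·µm³/s = 1 pN·µm is asserted in the tests).

`fit_stokeslet()` fits $(\mathbf{x}_0, G)$ to one gridded planar
snapshot. For fixed $\mathbf{x}_0$ the model is linear in $G$, so that
sub-problem is solved exactly; the remaining 2-D search over
$\mathbf{x}_0$ is a Nelder–Mead descent started at the grid point of
maximum speed (offset by a quarter grid spacing so the $1/r$ kernel is
evaluable), with a restart to escape stalls. A brute-force grid search
with the same exact linear solve serves as an independent oracle in the
tests. Frames are fitted independently — nothing constrains
$\mathbf{x}_0(t)$ to a smooth trajectory, which matches how per-frame
scatter is usually presented.

The treatment is planar: the kernel is evaluated in the beating plane
and out-of-plane flow is ignored, as is appropriate for planar PIV
sections of a planar beat. No wall or pipette image systems are
included; the package's scope is the free-space kernel.

`fit_force_modulation()` fits $|G|(t) = A_0(1 + A_1\sin(2\pi t/T +
\phi_0))$ at known beat period $T$. The model is linear in
$(A_0, A_0A_1\cos\phi_0, A_0A_1\sin\phi_0)$, so the fit is exact least
squares; $A_1$ is reported non-negative with $\phi_0$ adjusted. At
least two full periods of samples are required.

`rotational_stiffness_bound()` implements the torque argument that
rules out cell-body rocking as the synchronization mechanism: the flow
$u = G/r$ of a neighbouring flagellum acting along a flagellum of
length $l$ exerts a torque of order $C_\perp u l^2/2$; equating to a
rotational spring $k\alpha$ with an observed displacement bound
$\alpha^*$ gives $k > C_\perp u l^2 / 2\alpha^*$. The Lighthill
$C_\perp$ at aspect ratio 80 is used, the same coefficient as the RFT
stage.

## Resistive force theory

For a slender filament the local drag model
$$\mathbf{f} = C_\perp \mathbf{u}_\perp + C_\parallel
\mathbf{u}_\parallel$$
relates the force density (pN/µm) to the local velocity components
normal and tangential to the filament, with Lighthill's coefficients
$C_\perp = 4\pi\mu/(\ln(0.18\,\lambda/a) + 1/2)$ and
$C_\parallel = 2\pi\mu/(\ln(0.18\,\lambda/a) - 1/2)$ at
wavelength-to-radius ratio $\lambda/a = 80$ (default). The tangential
coefficient diverges at $\lambda/a = e^{1/2}/0.18 \approx 9.2$; smaller
aspect ratios are rejected. Node velocities come from central
differences across frames (one-sided at the ends), tangents from
central differences along the filament; total force is a trapezoidal
quadrature over arclength.

RFT is local: it is known to overestimate force production during the
recovery stroke, where the filament folds back on itself and non-local
hydrodynamic screening matters. The package documents this and does not
correct for it — no slender-body or non-local theory is attempted.

Waveform-shape changes are summarised by signed tangent angles at three
arclength stations. The stations sit at arclength fractions 1/6, 1/2
and 5/6 (proximal, mid, distal): fixed fractions make the quantity
reproducible across filaments of different length, and on a circular
arc they give exactly $\pi/12$, $\pi/4$, $5\pi/12$ — the analytic check
used in the tests.

## Phase extraction and locked-state statistics

Beat phases are extracted by Poincaré sectioning: upward threshold
crossings of a scalar interrogation signal, one crossing per beat, with
crossing times refined by linear sub-sample interpolation and the phase
advancing exactly $2\pi$ between crossings. Two guards enforce the
once-per-beat rule on noisy signals:

* a **hysteresis band** — a new crossing only arms after the signal has
  retreated below the threshold by 25 % of the signal amplitude. This
  guards the half-period point, where the signal re-crosses the
  threshold downwards and a fluctuation of a few percent can otherwise
  fake an upward passage;
* a **refractory window** of half the median beat period (estimated
  from an initial pass), which suppresses residual double counts.

The phase difference $\Delta(t) = (\varphi_1-\varphi_2)/2\pi$ (beats)
is kept unwrapped. `detect_locked()` segments it by the integer winding
number $n(t) = \operatorname{round}(\Delta - \Delta_{\mathrm{ref}})$,
with $\Delta_{\mathrm{ref}}$ the circular mean of the fractional part:
a slip is a change of $n$ sustained for at least the *hold* time,
segments are maximal constant-$n$ stretches. The hold default is three
mean beat periods — long enough that an excursion which immediately
re-traps is not counted as a slip, short enough that genuine wells are
resolved. The choice is declared, not inferred from any dataset.

Locked fluctuations rescaled as $(\Delta-\Delta_0)/\sqrt{L}$ collapse
across separations when the coupling scales as $1/L$; this follows
from the stationary variance of the linearised dynamics (next section)
being proportional to $1/\varepsilon \propto L$ at fixed noise.

## The stochastic Adler model

The phase difference obeys
$$\dot\Delta = \delta\nu - 2\pi\varepsilon\sin(2\pi\Delta) + \xi(t),
\qquad \langle\xi(t)\xi(t')\rangle = 2T_{\mathrm{eff}}\,
\delta(t-t'),$$
Brownian motion in the tilted washboard potential
$V(\Delta) = -\delta\nu\,\Delta - \varepsilon\cos(2\pi\Delta)$. Minima
are phase-locked states ($\Delta_0 \approx 0$ in phase for
$\varepsilon>0$, $\Delta_0 \approx 1/2$ antiphase for
$\varepsilon<0$); noise drives inter-minima hops (slips). Without
noise the observed frequency difference bifurcates at
$2\pi\varepsilon = |\delta\nu|$:
$$\frac{\delta\omega}{\delta\omega_{\mathrm{far}}} =
\sqrt{1 - (2\pi\varepsilon/\delta\nu)^2}$$
on the drifting branch and 0 on the locked branch. The square root is
the standard result for the mean winding rate of the deterministic
equation; the package verifies it against direct integration to within
1 % in its tests, which settles the functional form internally. With
noise the sharp bifurcation rounds and shifts; the package reproduces
this by simulation (`noisy_freq_diff()`), not by a Fokker–Planck
solver.

Integration is Euler–Maruyama in compiled code with R's RNG, so
`set.seed()` gives bit-reproducible paths. The default step is
$10^{-4}$ s at $\bar\omega = 33$ Hz; steps with
$\mathrm{d}t\cdot\max(|\delta\nu|, 2\pi|\varepsilon|) > 0.01$ are
rejected as under-resolved. Halving the step does not change reported
statistics beyond their confidence intervals.

### Parameter inference

`infer_adler()` offers two routes.

The default, `method = "increment"`, exploits that the drift is linear
in $(\delta\nu, \varepsilon)$ with regressor $\sin(2\pi\Delta)$:
ordinary least squares of the sampled increments
$\mathrm{d}\Delta/\mathrm{d}t$ on $\sin(2\pi\Delta)$ recovers both
parameters, and the residual variance gives
$T_{\mathrm{eff}} = \widehat{\mathrm{Var}}(\text{resid})\,
\mathrm{d}t/2$. This uses every sample — locked stretches, slip
transients and free drift alike — requires no linearisation about the
locked state, and returns the signed coupling without an orientation
tag. It is the package's default because its accuracy is uniform
across the coupling range, which matters when the same estimator feeds
the $1/L$ law at several separations.

The alternative, `method = "autocorrelation"`, follows the classical
locked-state route: within locked segments the fluctuations are
approximately Ornstein–Uhlenbeck with relaxation rate
$r = 4\pi^2\varepsilon\cos(2\pi(\Delta_0 - \Delta_{\min}))$, so an
exponential fit $C(\tau) = C_0 e^{-\tau/\tau_r}$ to their
autocovariance (window $[0, 3\tau_r]$, iterated) yields
$T_{\mathrm{eff}} = C_0/\tau_r$,
$|\varepsilon| = (1/\tau_r)/(4\pi^2\cos\theta)$ and
$\delta\nu = 2\pi|\varepsilon|\sin\theta$ from the locked offset
$\theta = 2\pi(\Delta_0-\Delta_{\min})$. Two refinements proved
necessary: the barrier-bound excursions around each slip are neither
Gaussian nor harmonic, so each segment is trimmed by four relaxation
times at both ends (iterated once from an untrimmed pass), and the
per-segment $\Delta_0$ is the median rather than the mean, which the
one-sided pre-slip excursions would bias. Even so, the OU
linearisation softens differently at different
$T_{\mathrm{eff}}/\varepsilon$, which tilts the apparent $1/L$
exponent; this residual bias is why the increment regression is the
default. Both routes are exercised against the generating ground truth
in the test suite.

A series with no locked segment returns a drift-only $\delta\nu$
estimate from the autocorrelation route ($\varepsilon$ unresolved); the
increment route handles the drifting regime natively.

`teff_from_periods()` estimates single-oscillator phase diffusion from
beat-period statistics via the first-passage identity
$\mathrm{Var}(T_{\mathrm{beat}}) = 2D/\bar f^{\,3}$ for a
constant-drift diffusion crossing unit phase distance; the pair-level
$T_{\mathrm{eff}}$ is the sum of the two single-cell $D$'s. This
estimator is validated against a first-passage simulation oracle.

## The minimal two-sphere model

Each flagellum is abstracted as a sphere of radius $a$ driven along a
circular orbit of radius $r_0$ by a tangential force
$F(\varphi)/8\pi\mu = A_0(1 + A_1\sin(\nu\varphi + \phi_0))$, held by a
radial spring of stiffness $\lambda$; the two spheres are coupled
through the Oseen tensor (the same kernel as the Stokeslet stage,
point-force level: no reflections, no Faxén corrections). The dynamics
are overdamped and integrated by a fixed-step classical 4th-order
scheme; the default resolution is 1000–2000 steps per revolution, and
step halving changes the final phase difference by less than
$10^{-4}$ rad on the default runs.

$\lambda = \infty$ (rigid prescribed orbits) is treated as a genuine
holonomic constraint: the radial reaction forces on both spheres are
solved from a 2×2 linear system at every stage evaluation so that each
radial velocity vanishes exactly, and those reaction forces participate
in the coupling flow. This is cleaner than a very stiff spring, which
would force the explicit integrator to tiny steps.

Because the driving force depends on phase, an isolated oscillator's
geometric phase $\varphi$ does not advance uniformly; the rescaled
phase
$$\Phi(\varphi) = 2\pi\,
\frac{\int_0^\varphi \mathrm{d}\varphi'/F(\varphi')}
     {\int_0^{2\pi} \mathrm{d}\varphi'/F(\varphi')}$$
does (checked to $10^{-3}\cdot2\pi$ per period on an isolated rower).
Synchronization is therefore always judged on
$\delta_{\mathrm{resc}} = \Phi(\varphi_1)-\Phi(\varphi_2)$.

`run_rower_grid()` runs the full factorial: $\lambda \in
\{1, 5, \infty\}$ pN/µm against five forcing sets $(\nu, \phi_0) \in
\{(0,0), (1,0), (1,\pi/2), (2,0), (2,\pi/2)\}$ at $a = 0.75$ µm,
$r_0 = 8$ µm, $d = 20$ µm, $A_0 = 1076$ µm²/s, $A_1 = 0.56$, plus a
flagella-inspired re-run at $\lambda = R/l^3 = 0.05$ pN/µm,
$a = 0.1$ µm, $A_0 = 143$ µm²/s. Runs last 500 beats from
$\delta(0) = 0.5$ rad. Both rowers orbit counterclockwise (the
relative handedness is an open choice; the co-rotating case is the
one with a clean $\pi$-rotation exchange symmetry, which the tests
exploit). Initial radial excursions are zero.

**"Converges" is defined as at least three e-folds of decay of
$|\delta_{\mathrm{resc}}|$ with a tail mean below 0.05 rad.** The
definition matters: with rigid orbits and force modulation
$(\nu = 1, \phi_0 = \pi/2)$ the pair *does* synchronize slowly through
the force-modulation pathway — a real effect, stable under step
refinement — but over 500 beats it remains orders of magnitude away
from the compliance-driven runs, which reach numerical zero. The
3-e-fold criterion separates the two mechanisms cleanly; an endpoint
threshold alone would not, because the rigid-orbit
$\delta_{\mathrm{resc}}$ oscillates and can alias near zero.

`measure_sync_rate()` converts the exponential decay rate $\rho$ of
$|\delta_{\mathrm{resc}}|$ into the equivalent Adler coupling via the
small-angle identity $\rho = 4\pi^2\varepsilon$, so
$\kappa_{\mathrm{sim}} = \rho/(4\pi^2 f)$, comparable with the closed
form $\kappa_{\mathrm{spheres}} = (27\mu\pi a^2l^2\bar\omega/2R)/L$.
With constant forcing the isolated revolution frequency has the Stokes
drag closed form $f = 2A_0/(3\pi a r_0)$, which gives $\approx 38$ Hz
at the grid parameters rather than the 33 Hz the sphere radius was
said to reproduce experimentally; the package reports its own closed
form and flags the discrepancy rather than adjusting any parameter.
With modulated forcing the period follows the quadrature
$T = (3ar_0/4A_0)\,2\pi/\sqrt{1-A_1^2}$, also verified in the tests.

## The synthetic-data generators

The generators produce the package's only inputs, with ground truth
attached to every dataset:

* `generate_piv_frames()` — a moving point force on a closed loop with
  sinusoidally modulated magnitude, evaluated on a regular grid with
  additive isotropic Gaussian velocity noise (a stated fraction of the
  per-frame RMS speed). Points within 5 µm of the trajectory are
  excluded: the Stokeslet description only holds in the far field, and
  the cutoff also guards the $1/r$ singularity. Real PIV error is
  correlated between interrogation windows and heteroscedastic; the
  generator makes no attempt to emulate that, so passing tests show
  robustness to white velocity noise only.
* `generate_waveforms()` — a single-harmonic tangent-angle travelling
  wave $\psi(s,t) = \psi_0(s) + A(s)\sin(2\pi(s/\Lambda - t/T))$ with
  distally growing amplitude, integrated along arclength so the
  filament is inextensible by construction (chord length equals $l$ to
  $10^{-6}$ relative at the default 1024 nodes). Defaults:
  $l = 19.9$ µm, $T = 1/33$ s, $\Lambda = l$, tip amplitude 0.6 rad,
  mean tangent angle 0.25 rad — a generic flagellar scale chosen to
  produce a clearly propulsive (asymmetric) beat. It is a stand-in
  with a power/recovery asymmetry, not a fit to any measured beat; in
  particular it cannot test RFT's recovery-stroke overestimate.
* `generate_pair_phases()` — integrates the Adler dynamics and splits
  $\Delta$ symmetrically: $\varphi_{1,2} = 2\pi\bar\omega t \pm
  \pi\Delta$. The common-mode phase is irrelevant to every downstream
  statistic, so this loses no generality.
* `generate_section_signal()` — maps each phase through a periodic
  waveshape (default sine) with optional white noise, rejecting
  waveshapes that cross their section level more than once per period.
  Real interrogation signals derive from pixel intensities with
  structured noise; only the functional role (one section passage per
  beat) is emulated.

Sampling defaults to 1000 frames/s, the standard high-speed imaging
rate for flagellar work.

### Study conditions used in the validation suite

The end-to-end checks run at fixed, realistic parameter scales:
parameter recovery at $(\varepsilon/\bar\omega, \delta\nu/\bar\omega,
T_{\mathrm{eff}}/\bar\omega) = (0.016, 0.058, 0.005)$ with
$\bar\omega = 33$ Hz and 100 s per pair (20 seeds); the coupling-law
and fluctuation-collapse checks at $\kappa = 0.016/L$ on
$L \in \{0.85, 1.22, 1.69, 2.27\}$ with $\delta\nu/\bar\omega = 0.02$
and $T_{\mathrm{eff}}/\bar\omega = 0.005$. The smaller detuning for
the separation sweep keeps all four separations inside the locked
regime ($2\pi\varepsilon > \delta\nu$ even at $L = 2.27$), which is
the regime the locked-fluctuation statistics are defined in; at the
larger detuning the two widest separations would drift
deterministically. The bead-spring grid runs 500 beats per
configuration at 1000 steps per period. These sizes keep the complete
suite at a few minutes on one core while leaving every tolerance
comfortably non-marginal.

## Known limitations

* Planar, free-space hydrodynamics only: no walls, pipettes, or
  out-of-plane flow; no three-Stokeslet body model.
* RFT is local and overestimates recovery-stroke forces; no
  slender-body correction.
* The Adler inference assumes the phase difference is well sampled
  (many samples per relaxation time); with once-per-beat phase
  reconstruction the within-beat fluctuations of $\Delta$ are
  irrecoverable in principle, so signal-level round trips are judged
  at beat resolution.
* The two-sphere model is a minimal abstraction: Oseen-level coupling,
  no near-field corrections, circular orbits. Its closed-form
  $\kappa_{\mathrm{spheres}}$ derives from a small-compliance,
  quasi-static argument; at the flagella-inspired stiffness the radial
  relaxation time is comparable to the beat period, so simulation and
  closed form are expected to agree only within a factor of order one
  (the tests require a factor of two).
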