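---
title: "Methods: electrolyte structure in a charged cylindrical nanopore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrolyte structure in a charged cylindrical nanopore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The physical model

The package simulates NaCl solution confined in an infinite cylindrical pore
of radius $R_n$ (default 30 Å), periodic along the pore axis $z$ with period
$L_z$. The wall is smooth and structureless: its dispersion interaction with
each fluid particle is the Steele 10-4-3 potential, which depends on
position only through the wall distance $z_w = R_n - r$,

$$u_{wf}(r) = 2\pi\rho_w\,\varepsilon_{wf}\,\sigma_{wf}^2\,\Delta\left[
  \frac{2}{5}\Big(\frac{\sigma_{wf}}{R_n-r}\Big)^{10}
  - \Big(\frac{\sigma_{wf}}{R_n-r}\Big)^{4}
  - \frac{\sigma_{wf}^4}{3\Delta\,(R_n-r+0.61\Delta)^3}\right],$$

with interlayer spacing $\Delta = 2.709$ Å, wall site density
$\rho_w = 42.76\ \mathrm{nm^{-3}}$ (converted to Å$^{-3}$ internally), and
wall LJ constants $\sigma_w = 3.0$ Å, $\varepsilon_w/k_B = 230$ K typical of
bulk silica. Wall–fluid parameters are mixed with Lorentz–Berthelot, the
same rule used for all unlike fluid pairs. The surface carries $n$ frozen
point charges of $-1$ e each, placed exactly on the cylinder $r = R_n$ at
equal $z$ spacing; their implied surface charge density
$\sigma_s = n e / (2\pi R_n L_z)$ normalises the screening factor.

Water is rigid SPC/E: one LJ site on oxygen, charges $-0.8476$ e (O) and
$+0.4238$ e (H), O–H bond 1.0 Å, H–O–H angle 109.47°. Only the model's
*name* fixes these numbers; they are the standard SPC/E definition, and H
carries no LJ term, as usual for that model. Ion and oxygen LJ parameters
are the pure pairs σ(O–O) = 3.169 Å / 0.6502 kJ mol⁻¹,
σ(Na⁺–Na⁺) = 2.583 Å / 0.4184, σ(Cl⁻–Cl⁻) = 4.401 Å / 0.4184; the mixing
rules regenerate every unlike pair.

Electrostatics is point-charge Coulomb. Two evaluation methods are
provided. `ewald` is a conventional 3D Ewald summation (tin-foil boundary,
neutrality enforced); because the pore is periodic only along $z$, the
quasi-1D system is embedded in a 3D box with lateral vacuum padding (box
edge $4R_n$), a background-neutral treatment chosen because the original
boundary handling in such studies is rarely reported. `cutoff_rf` is a
reaction-field cutoff with conducting boundary, zero value *and* zero slope
at the cutoff, so truncated dynamics still conserve energy; it is the
default for dynamics. Intramolecular water pairs are excluded in both
methods (under Ewald the interaction of a molecule with its own periodic
images survives, as it should).

The wall charges interact with the fluid through Coulomb forces only. They
carry no LJ parameters, so nothing stops a counterion from approaching them
except the Steele repulsion — a deliberate reading of a point the model
description leaves open, recorded here rather than silently assumed.

# System construction (the synthetic-data generator)

`build_system()` is the package's data generator and defines the study
conditions: concentrations 0.6, 1.3 or 2.0 mol/L with 1045 water molecules
in the default pore. Ion counts come from the molarity ratio against water,
$n_\mathrm{pairs} = \mathrm{round}(c \cdot n_\mathrm{water}/55.345)$, i.e.
the stated concentrations are treated as a nominal ion/water ratio (the
pore-accessible-volume alternative is not used; the convention is a design
choice). Each $-1$ e wall charge adds one Na⁺, making total charge exactly
zero by integer bookkeeping — electroneutrality is an invariant of every
build, not a statistical property.

Two parameters of the original setup are not derivable from the stated
conditions and are fixed once here: the periodic length $L_z = 60$ Å,
chosen so that 1045 waters plus ions at 2 M occupy the 3 nm pore near
liquid density, and the number of wall charges $n = 8$, a moderate surface
charge density ($\sigma_s \approx 7.1\times10^{-4}$ e/Å² ≈ 0.011 C/m²).
Both are configurable, and $\sigma_s$ is always recorded in the built
system and threaded through to the screening analysis, never hard-coded.

Particles are placed by rejection sampling inside $r < R_n - 1$ Å with a
minimum-separation rule of $0.8\,\sigma_{ij}$ between LJ sites (close
enough to pack, far enough to avoid force blow-ups; equilibration relaxes
the rest), waters at random rigid orientations. Velocities are
Maxwell–Boltzmann at 298 K with the centre-of-mass drift removed. A build
is a pure function of its spec including the seed. What the generator does
*not* emulate: the bulk reservoirs flanking a real membrane pore (the pore
here is fully periodic; reservoir dimensions for the original geometry are
not available), wall atomic structure, and surface-charge mobility.
Conclusions from these runs therefore concern the *interior* double layer,
not entrance effects or reservoir exchange.

# Sampling

**Explicit dynamics.** Velocity Verlet with a 2 fs step integrates all
mobile sites; rigid waters are maintained by iterative SHAKE (positions,
against the pre-step geometry) and RATTLE (velocities), converged to
$10^{-10}$ Å — far below the $10^{-6}$ Å contract. An analytic three-point
solver would also do; the iterative projection was chosen because it is
exactly momentum-conserving by construction, deterministic, and easy to
verify term by term. Temperature uses only unconstrained degrees of freedom
($3N - 3$ per rigid water). The Berendsen thermostat rescales all mobile
velocities jointly each step by
$\lambda = \sqrt{1 + (\delta t/\tau)(T_0/T - 1)}$ with $T_0 = 298.0$ K and
$\tau = 0.1$ ps (whether the original runs coupled water and ions
separately is unknown; joint coupling is the simplest defensible choice).
Setting $\tau = \infty$ gives NVE dynamics, used by the energy-conservation
checks. A fresh build should be passed through `minimize_config()`
(capped steepest descent) before dynamics; rejection-sampled contacts at
$0.8\,\sigma_{ij}$ otherwise inject enough potential energy to destabilise
a 2 fs step.

**Implicit-solvent Monte Carlo.** The `mc_primitive` mode is an addition
beyond the original explicit-water protocol, included so that equilibrium
double-layer properties are testable at desk scale: waters are removed and
replaced by a uniform relative permittivity $\varepsilon_r = 78.4$ scaling
every Coulomb term, while ions keep their LJ cores, the Steele wall, and
the frozen wall charges. Sampling is Metropolis single-particle
displacement (uniform in a cube of half-width `mc_step`, default 1 Å, ~80%
acceptance at 2 M), which obeys detailed balance; a sweep is one attempted
move per ion. Runs are bitwise reproducible given the seed in both modes.

The strongest direct check of the wall potential couples the two layers:
a single Na⁺ in an uncharged pore must sample the cylindrical Boltzmann
law $p(r) \propto r\,e^{-\beta u_{wf}(r)}$, and the test suite holds every
radial bin to within 3σ of the quadrature of that law.

# Analysis definitions and numerical choices

**Radial densities.** Counts per cylindrical shell
$V = \pi(r_\mathrm{out}^2 - r_\mathrm{in}^2)L_z$, averaged over frames,
converted to mol/L. The closure $\sum_k C_k V_k N_A$ = mean per-frame count
holds to round-off and is asserted on every profile test. The default bin
width is 0.25 Å, which places ≥ 6 bins between the counterion and coion
peak features; the trend and acceptance analyses use 0.5 Å bins, trading
resolution for per-bin statistics at the ion counts these runs use.

**Screening factor.** The cumulative mobile net charge between the wall
and radius $r$, expressed per unit wall area and normalised by $\sigma_s$:

$$S_f(r) = \frac{1}{\sigma_s}\int_r^{R_n} F\,[C_{Na}(r') - C_{Cl}(r')]\,
\frac{r'}{R_n}\,dr'.$$

The factor $r'/R_n$ is the cylindrical area Jacobian. A literal planar
integral (no Jacobian) does not close to 1 at the axis in a cylinder, which
would make global electroneutrality untestable, so the cylindrical form is
the default and a `planar = TRUE` switch reproduces the planar reading.
Because the profiles are histograms, each bin's integral is evaluated
exactly for piecewise-constant concentration
($\rho_k (r_{out}^2 - r_{in}^2)/2R_n$) rather than by trapezoid on bin
centres — this is what makes $S_f(0) = 1$ exact to round-off, with
$S_f(R_n) = 0$ by construction. `first_overscreening_radius()` reports the
largest radius at which $S_f \ge 1$.

**Radial potential.** Coulomb's law with point-charge superposition,
referenced to the pore axis:
$\phi(r) = C\sum_i q_i\,(1/|x - x_i| - 1/|x_0 - x_i|)$ over all mobile and
wall charges with minimum image along $z$. The difference form is the only
dimensionally consistent reading of an axis-referenced potential, and it
anchors $\phi(r_0) = 0$ identically. Each radius is averaged over 64
azimuthal × 8 axial probe positions by default (the coarse CLI/acceptance
settings use 16 × 4 with frame striding); probe samples within 0.5 Å of
any charge are excluded and counted in `n_excluded`. In implicit-solvent
trajectories the sum is divided by $\varepsilon_r$.

**Peaks.** The peak is the global-maximum bin centre, reported as wall
distance $R_n - r$; the first valley is the nearest local minimum inward
(axis-ward) of the peak. All-zero profiles return a flagged no-peak result
rather than an error; monotone profiles report a boundary peak and no
valley.

# Problem sizes and what the tests show

The full explicit-water protocol (4 ns equilibration + 4 ns production at
2 fs) is cluster-scale and remains a configuration choice, not a default.
The shipped tests and the acceptance script use sizes chosen to give each
check real statistical teeth while keeping a complete run on one CPU in
minutes: implicit-solvent production of 500–600 equilibration + 2500–3000
sweeps (≈ 500–600 frames) per concentration and seed for the structural
trends; $2\times10^5$ single-ion moves for the Boltzmann law; a ~50-site
explicit-water system, minimised and pre-equilibrated, for the $10^4$-step
NVE drift, reversibility, thermostat and constraint checks; Ewald
validation against the Evjen-summed Madelung constant of a rock-salt
lattice and against bare Coulomb for an isolated pair.

These runs demonstrate the concentration *trends*: non-decreasing Na⁺ and
Cl⁻ peak heights across 0.6/1.3/2.0 M, faster proportional growth of the
coion peak, wallward motion of the first-overscreening radius, a negative
potential adjacent to the charged wall turning positive inward. They are
not converged estimates of the explicit-water peak *heights*, and the
continuum solvent removes hydration-shell structure entirely.

# Known limitations

- **Counterion contact distance.** With the stated wall constants the
  Steele well for Na⁺ sits 2.77 Å from the wall, and the $(R_n-r)^{-10}$
  repulsion dominates any electrostatic pull well before 2 Å at this
  surface-charge scale. Desk-scale runs here accordingly put the Na⁺
  maximum ≈ 2.7 Å from the wall and the Cl⁻ maximum ≈ 3.7 Å (in the first
  Na⁺ valley). Reports of a 1.5 Å contact layer under nominally these
  constants are not reproducible from the potential as written; hydration
  effects absent from the primitive model may contribute, but cannot move
  a maximum inside the wall repulsion.
- The implicit-solvent mode has no molecular water, hence no hydration
  peaks in the ion profiles and a concentration-independent dielectric.
- The Berendsen thermostat does not generate a canonical ensemble; it is
  used here (as in the original protocol) for temperature control, with
  NVE checks guarding the integrator itself.
- Reaction-field electrostatics in a quasi-1D geometry is an
  approximation; the Ewald path is available for validation but is slow in
  pure R for large systems.
- The pore is infinite and periodic: no entrance effects, no reservoir
  exchange, no applied field or ionic current.
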