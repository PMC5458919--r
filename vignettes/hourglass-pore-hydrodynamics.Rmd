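---
title: "Hydrodynamics of hourglass-shaped nanopores: models, numerics and synthetic trajectories"
author: "porehydro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamics of hourglass-shaped nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(porehydro)
```

## The problem

Aquaporin water channels conduct water in single file at remarkable
rates, and their conducting pathway is hourglass-shaped: two conical
vestibules meeting at a sub-nanometre constriction. Biomimetic
solid-state nanopores copy this geometry because the conical mouths
reduce the *access* (entrance) resistance that dominates transport
through short pores. `porehydro` implements the quantitative framework
for this problem: an analytical hydrodynamic-resistance model for
hourglass pores with slipping walls, an axisymmetric Stokes solver for
the dimensionless access-resistance factor, osmotic-permeability
estimation, and trajectory statistics for single-file transport,
together with a seeded synthetic-trajectory generator that makes the
whole analysis chain testable against known ground truth.

The study conditions used throughout are a constriction diameter
$d = 3$ Å (the aquaporin scale), total pore lengths $L = 30$ and
$60$ Å, cone half-opening angles $\alpha = 1,3,\dots,13^\circ$,
hydrophobic walls with Navier slip length $b = 72$ nm and contact angle
$95^\circ$, bulk water viscosity $\eta = 10^{-3}$ Pa s at $T = 300$ K,
and external pressures of 6.04 and 10.03 katm.

## Geometry

The pore axis is $z$, the pore spans $[0, L]$ and the centre plane is
$z = L/2$. The cone angle $\alpha$ is measured between the conical wall
and the axis, so the diameter law is piecewise linear,

$$d(z) = d_c + 2\tan\alpha\,\bigl(L/2 - \min(z, L - z)\bigr),$$

minimal at the centre with $d(L/2) = d_c$ and maximal at the mouths
with $d(0) = d_c + L\tan\alpha$. This convention makes the entrance
factor of the resistance model come out as $(1 + (L/d_c)\tan\alpha)$.
`build_structure()` realizes the wall model as stacked carbon rings of
radius $d(z)/2$ plus two rectangular-lattice wall plates closing the
reservoirs, with 2 Å spacings — narrower than a water molecule, so the
wall is water-tight; the atom count for the default geometries exceeds
500. A filled pore is meaningful only if the applied pressure exceeds
the capillary entry pressure of the hydrophobic aperture,
$-4\gamma\cos\theta/d \approx 8.4\times 10^7$ Pa at
$\theta = 95^\circ$; both study pressures are an order of magnitude
above it.

## The analytical resistance model

The hydrodynamic resistance of a pore is $R_h = \Delta p/Q$. For a
zero-thickness circular orifice of radius $a$ the exact Stokes-flow
result (Sampson) is $\Delta p = 3\eta Q/a^3$, i.e.

$$R_h = \frac{C\,\eta}{(d/2)^3}, \qquad C = 3 \text{ (orifice)},$$

which defines the dimensionless factor $C$. For an hourglass pore the
total resistance is assembled from an access/apex bracket scaled by the
partial-slip factor $C_{pa}$ and a slip-corrected Poiseuille integral
over the two cones:

$$R_\mathrm{total} = C_{pa}\,\eta\left(\frac{d_c}{2}\right)^{-3}
  \left[\Bigl(1 + \frac{L}{d_c}\tan\alpha\Bigr)^{-3} + \sin\alpha\right]
  + 2\int_0^{L/2}
  \frac{8\eta}{\pi\,(d(z)/2)^4}\,
  \Bigl(1 + \frac{4b}{d(z)/2}\Bigr)^{-1}\,dz.$$

The bracket's first summand is the access term $R_e$, suppressed as the
mouths widen; the $\sin\alpha$ summand is the apex (cone-to-cylinder)
term $R_{cy}$, growing with angle because an ever blunter cone meets
the constriction; the integral is the viscous cone term $R_{co}$. The
printed bracket does not itself label the split between $R_e$ and
$R_{cy}$; the attribution used by `total_resistance()` is the natural
one and affects only the reported breakdown, never the total. The
competition of $R_e$ (falling in $\alpha$) and $R_{cy}$ (rising)
produces an optimal cone angle.

The cone integral has a closed form: substituting $r = d(z)/2$ turns it
into $\int dr/(r^3(r + 4b))$, which partial fractions reduce to

$$F(r) = \frac{1}{B^3}\ln\frac{r}{r+B} + \frac{1}{B^2 r}
 - \frac{1}{2Br^2}, \qquad B = 4b,$$

so $R_{co} = \tfrac{16\eta}{\pi\tan\alpha}\,[F(r_0) - F(a)]$ with $r_0$
the mouth radius and $a = d_c/2$. `cone_resistance()` also computes the
integral by adaptive quadrature (`stats::integrate` at
`rel.tol = 1e-12`); the two routes agree to $10^{-9}$ relative over
randomized geometries and the quadrature route is kept as an
independent numerical check. Degenerate inputs take explicit branches
rather than limits of the general formula: $\alpha = 0$ is the straight
pore ($R_{co} = L$ times the slip-Poiseuille density), $b = 0$ is the
plain $1/r^4$ integral, and $b = \infty$ gives $R_{co} = 0$.

```{r}
fl <- fluid_properties()           # eta = 1e-3 Pa s, b = 72 nm, 300 K
total_resistance(pore_geometry(3, 60, 5), fl, C_pa = 3.85)
```

`optimal_angle()` minimizes $R_\mathrm{total}$ over $\alpha$ either on
the exact study grid or continuously (bounded scalar minimization to
$10^{-3}$ degree, with a fine-grid fallback and warning if the curve is
not unimodal on the range). The viscosity scales every term equally, so
the argmin never depends on it. For $L = 60$ Å with $C_{pa} = 3.85$ the
grid optimum is $5^\circ$. For $L = 30$ Å the analytical curve is
minimized at $7^\circ$, whereas dynamical (molecular) estimates for
this geometry put the optimum at $9^\circ$; the two grid points differ
in analytical resistance by under one percent, and the package reports
both curves without forcing agreement.

## The Stokes solver and the factor C

$C_{pa}$ cannot be taken from the orifice solution: finite pore length
and wall slip change the access flow. `stokes_solve()` computes it from
first principles by solving the incompressible creeping-flow (Stokes)
equations in an axisymmetric reservoir–pore–reservoir domain:

* staggered finite-volume (MAC) discretization in cylindrical
  coordinates $(r, z)$, pressure in cell centres, velocities on faces,
  on a tensor-product mesh graded towards the walls and the sharp
  pore-mouth corners;
* Navier slip on all solid walls, implemented through the wall flux
  $\partial u_t/\partial n = -u_t/(b + \delta)$ at half-cell distance
  $\delta$, which reduces to the standard half-cell no-slip flux at
  $b = 0$ and to a shear-free wall as $b \to \infty$;
* the pressure difference imposed through pressure conditions on the
  far reservoir faces (with vanishing normal velocity gradient), and
  shear-free lateral reservoir boundaries;
* all lengths nondimensionalized by the pore radius $a$, so the solve
  returns $C = (\Delta p/Q)\,a^3/\eta$ directly and no Å-scale
  underflow can occur.

The sparse saddle-point system is solved directly (`Matrix`), and $Q$
is obtained by integrating the axial velocity over pore cross-sections;
the flow-rate imbalance between cross-sections is below $10^{-12}$
relative, and doubling the default reservoir extent (25 pore radii)
changes $C$ by about $10^{-4}$. Pore lengths shorter than the finest
mesh spacing are modelled as a zero-thickness orifice plate, the
Sampson configuration. A length of 0.003 Å, the bottom of the study
sweep, falls in this regime.

The sharp mouth corner carries a stress singularity which, on slipping
walls, reduces the raw convergence order of $Q$ to about $0.55$ in the
mesh spacing (about $0.9$ for the no-slip orifice). `c_factor()`
therefore solves on three uniformly refined meshes (the production
sequence has roughly $12\,000$, $28\,000$ and $80\,000$ unknowns for a
30 Å pore) and extrapolates to zero mesh size with the *observed*
order, the standard grid-convergence procedure; a non-contracting
refinement sequence raises a convergence error. The extrapolated
values at $b = 72$ nm are

| configuration | C |
|---|---|
| orifice (0.003 Å) | 3.008 |
| $L = 20$ Å | 3.800 |
| $L = 30$ Å | 3.810 |
| $L = 60$ Å | 3.839 |
| $L = 1200$ Å | 4.850 |

The orifice value reproduces Sampson's $C = 3$ to 0.3 % — a genuine
validation, because the Sampson field happens to exert no shear on the
wall, so the orifice value is independent of the slip length. The 30
and 60 Å values are the access factors $C_{pa}$ used by the analytical
model. $C(L)$ is monotone non-decreasing, rises steeply over the first
few radii, passes a quasi-plateau near $C \approx 3.9$ around
$L \sim 100$–$300$ Å, and then grows linearly with the slip-corrected
channel term: at $L = 1200$ Å the converged value is
$C \approx 4.85 = C_\mathrm{access} + (8/\pi)(L/a)/(1 + 4b/a)$. A
plateau value of $\sim 3.9$ is sometimes quoted for the top of this
length range; that number is consistent with the quasi-plateau region
but not with the channel friction that any finite slip length must
contribute by 1200 Å, and the package reports what the converged solver
(and, equivalently, the analytical channel term) gives. The solver
inherits the continuum treatment at sub-nanometre radii from the model
it serves; it makes no molecular correction.

## Osmotic permeability

The hydrodynamic permeability is the number flux per unit pressure,
$K = j_v/\Delta p$, and the osmotic permeability is

$$p_f = \frac{RT}{V_w}\,\frac{j_v}{\Delta p} = \frac{RT}{V_w}\,K,$$

with $V_w = 18$ cm³/mol the molar volume of water; the prefactor
$RT/V_w$ is $1.386\times 10^8$ Pa at 300 K. With $j_v$ a *number* flux
this convention carries units of s⁻¹; because the conventional
single-channel permeability is volumetric, `osmotic_permeability()`
reports both $p_f$ and $p_f\,v_w$ (m³/s), where $v_w = V_w/N_A$ is the
volume of one molecule. The trajectory-side resistance is the
reciprocal volumetric permeability, $\Delta p/Q = 1/(K v_w)$.

## Trajectory statistics

Trajectories are ordered frames of water-oxygen positions (hydrogens
are ignored; the oxygen is the standard proxy for the molecular
centre) in pore-local coordinates, read and written as multi-frame XYZ
(and read from DL_POLY-style HISTORY files, positions only). All
statistics are deterministic given a trajectory.

*Membership.* A molecule is inside the pore if $0 \le z \le L$ and its
radial distance is at most $d(z)/2 + 1.4$ Å, one water van der Waals
radius of tolerance for centres near the geometric wall.

*Density profile.* Time-averaged histogram of in-pore $z$ on half-open
1 Å bins tiling $[0, L)$. Binning is configurable since no canonical
width exists at this scale.

*Gap series.* Per frame the in-pore molecules are sorted by $z$ and
consecutive differences taken; the maximum gap, minimum gap and the
midpoint of the maximum-gap pair (ties to the smallest-$z$ pair) trace
the pulsatile, burst-like "shooting" advancement of the single-file
chain. Frames with fewer than two in-pore molecules are flagged
invalid, not zeroed. The minimum-gap series is reported raw, without
smoothing.

*Crossing flux.* Transport events are signed crossings of the centre
plane with hysteresis: a forward event requires the molecule to be seen
below $L/2 - \delta$ and later above $L/2 + \delta$ ($\delta = 1$ Å by
default), which suppresses double counting of thermal recrossings.
Tracking state is kept only while the molecule is inside the pore and
reset outside it; this makes the count robust to reservoir
recirculation — a molecule recycled from the downstream to the upstream
reservoir around the pore (as under periodic boundaries) cannot
register a spurious backward event.

*Permeability estimation.* $K$ is defined as a ratio, so the fit of
$j_v$ against $\Delta p$ over one or more runs is least squares through
the origin. Uncertainty comes from a seeded block bootstrap over frames
(20 contiguous blocks per run, 1000 resamples by default), which
respects the strong serial correlation of burst transport.

## The synthetic-trajectory generator

Molecular-dynamics observables for this system are not reproducible at
desk scale, so the analysis stages are tested against a *kinematic*
generator (`generate_trajectory()`) that reproduces the statistical
structure the analysis assumes — not water physics. Its mechanism:

* a single-file chain of molecules spans the pore at site spacing
  2.8 Å (a hydrogen-bonded water-water distance);
* transport events arrive as a Poisson process (default rate
  40 ns⁻¹, the 10–100 ps pulse scale of single-file bursts); each event
  advances the chain by a geometric number of site spacings whose mean
  is calibrated so the mean flux equals the programmed
  $K^*\,\Delta p$ exactly;
* advancement is supply-limited at the entrance: per frame the chain
  advances at most until its tail reaches a ceiling kept below the
  crossing band, the remainder of a burst carrying over — so large
  bursts spread over a few frames, every transported molecule enters
  low in the vestibule, and no programmed flux is ever lost;
* the entrance refills from an accumulated vestibule crowd (10
  molecules by default) at three times the mean chain speed, so a burst
  leaves a visible transient gap that closes over the following frames;
* past the constriction an escape factor of 2 stretches the spacing,
  thinning the downstream density — together with the crowd this
  produces the asymmetric, upstream-biased axial density profile;
* reservoir molecules diffuse in the pools ($D = 0.2$ Å²/ps) and the
  downstream pool recycles its excess back upstream, so the particle
  count (default 1700) is conserved indefinitely;
* thermal jitter (0.25 Å axial) is applied at recording time.

Every stochastic ingredient draws from its own seeded substream
(events, burst sizes, placement, jitter, reservoir diffusion), so
adding or consuming one stream never perturbs another, identical
configurations and seeds give bit-identical trajectories, and — because
the event schedule is pre-generated — runs that share a seed share
their burst realization. The last property is used deliberately: the
angle-ranking experiment (trajectory-derived resistance across the
seven-angle grid) runs all angles with a common seed, a paired
common-random-numbers design under which the estimated fluxes are a
monotone transform of the programmed ones and the recovered resistance
ranking matches the analytical ranking exactly, at run lengths where
independent seeds would drown the sub-percent spacing of the grid
points near the optimum in compound-Poisson noise.

What the generator does *not* emulate: intermolecular forces, hydrogen
bonding and dipole orientation, thermostats, wall flexibility (a
flexible pore is emulated only as a permeability multiplier, which
raises the estimated $p_f$ in the expected direction), and any
dependence of burst statistics on geometry beyond the programmed flux.
Tests passing on synthetic data therefore validate the *estimators* —
their calibration, determinism and ranking behaviour — not the physics
of any particular simulation.

The burst rate, refill factor, escape factor and crowd size are free
phenomenological knobs: no quantitative burst-size or waiting-time
statistics exist for this system, only the qualitative pulse picture.
The defaults above were chosen once as a plausible emulation of that
picture and are not fitted to anything.

## Problem sizes

The test suite and the analysis scripts use synthetic runs of 2–25 ns
at 2–5 ps stride with 300–500 molecules, and Stokes meshes up to about
$3\times 10^5$ unknowns at the finest refinement; these sizes give
sub-percent mesh convergence for $C$ and 3–10 % sampling noise for
single-run fluxes (the compound-Poisson relative standard error is
$\sqrt{2/(\lambda T)}$), which the statistical tests account for
explicitly. The full end-to-end comparison (`analysis/05_compare.R`)
covers both lengths, all seven angles and both pressures.

## Known limitations

* The continuum Stokes treatment at $d = 3$ Å is an idealization
  inherited from the model; real single-file transport is molecular,
  and the analytical optimum can differ from dynamical estimates (the
  30 Å case above).
* Water viscosity is treated as constant; confined-water viscosity
  models are deliberately out of scope.
* The generator's burst phenomenology is a modelling choice, not a
  fitted process; only its programmed flux, determinism and qualitative
  contracts are guaranteed.
* The resistance breakdown's attribution of the bracket terms to
  access and apex contributions is a labelling convention.
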