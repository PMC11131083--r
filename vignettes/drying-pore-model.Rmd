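---
title: "Pore formation in a drying core-shell hydrogel sphere: model and solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pore formation in a drying core-shell hydrogel sphere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drygel)
```

## The physical problem

During drying, many fruits and vegetables form a dense stiff outer layer
("case hardening").  Continued moisture loss from the soft interior then
builds tension under the skin, and pre-existing gas-filled pores --
intercellular spaces -- can grow substantially instead of collapsing.
`drygel` models the minimal system that exhibits this behaviour: a spherical
hydrogel with

* a central spherical cavity (initial radius $R_{in}$) filled with air and
  water vapour,
* a soft hydrogel core (shear modulus $G_{core}$),
* a stiffer hydrogel skin of thickness $t_{skin}$ ($G_{skin} \ge G_{core}$),

immersed in a medium of osmotic pressure $\Pi_{ext}$ (equivalently a relative
humidity $RH_{ext} = e^{-\Pi_{ext}\nu_w/R T}$).

## Constitutive model

**Kinematics.** The reference frame is the stress-free, free-swollen state
$B_0$, in which the polymer network carries a uniform isotropic pre-stretch
$\lambda_0$ with $\lambda_0^3 = 3/2$ relative to the elastically relaxed
(unstretched) configuration.  In spherical symmetry the deformation is
described by the radial and hoop stretches $\lambda_r = 1 + u'(R)$ and
$\lambda_\theta = 1 + u/R$, with volume ratio
$J = \lambda_r\lambda_\theta^2 = \phi_0/\phi$ tied to the polymer volume
fraction $\phi$ (incompressible constituents).

**Stress.** The network is Neo-Hookean.  With
$\hat\varphi = \phi/(\phi_0\lambda_0)$,
$$\sigma_{i} = \hat\varphi\, G\, \lambda_i^2 - p_{liq},$$
so $\sigma_{rr} = G\lambda_r/(\lambda_\theta^2\lambda_0) - p_{liq}$ and
$\sigma_{\theta\theta} = G/(\lambda_r \lambda_0) - p_{liq}$.  The liquid
pressure $p_{liq}$ is the Lagrange multiplier of incompressibility and
couples mechanics to moisture transport.

**Osmotic pressure.**  Mixing thermodynamics follows the scaling (c*-theorem)
form
$$\Pi_{mix} = \alpha\, G\, \tilde\varphi^{9/4}, \qquad
  \tilde\varphi = \phi/\phi_{ref},$$
which collapses the osmotic response of biopolymer gels onto a single master
curve scaled by the elastic modulus.  The chemical potential of water (per
unit volume) is $\mu_w = -\Pi_{mix} + p_{liq}$, and the diffusive flux is
$j_w = -(D_s \nu_w / R T)\nabla\mu_w$.

**Layers.**  The skin is a denser network: its reference polymer fraction
follows from the same scaling law,
$\phi_{skin} = \phi_{core}(G_{skin}/G_{core})^{4/9}$ with
$\phi_{core} = 0.05$.

**Cavity.**  The bubble holds a fixed amount of insoluble air
($N_{air}$, set by the saturated initial state at ambient pressure) plus
water vapour in local equilibrium with the gel at the cavity wall:
$$p_{gas} = -\sigma_{rr}(r_{in}) = p_{air} + p_{vap}, \qquad
  p_{air} V_{gas} = N_{air} R T, \qquad
  p_{vap} = a_w\, p_{sat}(T),$$
with $a_w = \exp[(\mu_w(r_{in}) - p_{gas})\nu_w/R T]$ and $p_{sat}$ from the
Tetens relation.

## Parameters, defaults and why

| parameter | default | role |
|---|---|---|
| $\beta$ | $9/4$ | scaling exponent (c*-theorem) |
| $\lambda_0^3$ | $3/2$ | universal free-swelling ratio for food gels |
| $\alpha$ | $\lambda_0^{23/4} \approx 2.175$ | osmotic prefactor; see below |
| $G_{core}$ | $1.89\times10^5$ Pa | sets $p_0/G$; chosen so $\Pi_{ext}/G_{core}=2000$ corresponds to $a_w \approx 0.07$ at 308 K |
| $\phi_{core}$ | 0.05 | reference polymer fraction of the core |
| $\nu_w$ | $1.8\times10^{-5}$ m$^3$/mol | water molar volume |
| $D_s$ | $10^{-9}$ m$^2$/s | water self-diffusivity (sets the time scale only) |
| $R_{out}$ | 5 mm | absolute size (cancels from scaled outputs) |
| $T$, $p_0$ | 308 K, 101325 Pa | ambient conditions |
| $h_{air}$ | 20 W/m$^2$K | outer boundary layer, via the Lewis relation $\beta_{air} = h_{air}/(\rho_{air}c_{p,air})$ |
| $D_{vap}$ | $2.5\times10^{-5}$ m$^2$/s | cavity boundary layer, $\beta_{cav} = D_{vap}/(r_{cav}/5)$ |

**The prefactor $\alpha$ deserves emphasis.**  It is defined in external
work on the osmotic master curve and is not printed in the study this
package models.  We fix $\alpha = \lambda_0^{23/4}$, the unique value for
which the free-swollen state ($a_w = 1$, $\lambda_i = 1$,
$p = G/\lambda_0 + p_0$) is *exactly* stationary under the model's own
constitutive laws -- a sphere left in pure water does not drift, in any
solver, to machine precision.  Several headline numbers are sensitive to
$\alpha$; most notably the critical stiffness ratio for pore opening moves
from $\approx 11.2$ at $\alpha = 2.175$ to $\approx 10.3$ at $\alpha = 2.5$
and $\approx 9.3$ at $\alpha = 3$.  Reported results should therefore be
read as conditional on this choice.

All headline outputs are reported in the dimensionless groups
$\Pi_{ext}/G_{core}$, $p_{gas}/p_0$, $r/R_{out}$, so the absolute defaults
($G_{core}$, $R_{out}$, $D_s$) cancel except through $p_0/G_{core}$ (a weak
dependence: the critical stiffness ratio changes by about 1% when
$p_0/G_{core}$ varies tenfold).

## Three solvers

### Analytical steady state

Assuming uniform swelling within each layer, the radial momentum balance
integrates in closed form across a layer: with elastic hoop stretch
$\Lambda = \lambda_0\lambda_\theta$ and $\tilde\varphi$ the layer's uniform
swelling, $\sigma_{rr} = F(\Lambda) + C$ with
$F(\Lambda) = \tfrac{G}{2}\,(1 + 4\tilde\varphi\Lambda^3)/(\tilde\varphi\Lambda^4)$,
so the cavity pressure decomposes as
$p_{gas} - p_0 = \Delta p_{skin} + \Delta p_{core}$ with each
$\Delta p = F(\Lambda_{outer}) - F(\Lambda_{inner})$
(`shell_pressure_drop()`).  The layer swellings follow from chemical
equilibrium at the outer surface and at the interface; the outer stretch is
iterated (secant with a bracketed fallback) until the mechanical pressure
matches the cavity gas law (`core_shell_steady()`).

*A design decision that was genuinely open*: the boundary-equilibrium
relation can be written with the hoop stretch (as a thin-shell
simplification) or with the radial stretch
$\lambda_{e,r} = J_e/\lambda_e^2$ implied by uniform swelling.  The radial
form is the mechanically consistent one ($\sigma_{rr} = -p_0$ fixes
$p_{liq}$ through $\lambda_r$), and empirically it reproduces the two grid
solvers to 0.01--0.2% across stiffness ratios 1--20, where the hoop form
deviates by up to 9% in $p_{gas}$ already at ratio 5.  The radial form is
the default; `stretch = "hoop"` retains the simplified variant.  With the
radial form the analytical solution is, for this spherically symmetric
problem, essentially exact whenever each layer's swelling is near-uniform;
it degrades when strong intralayer gradients develop (very small pores,
extreme drying).

### Finite volumes on a co-moving mesh

`run_transient_fv()` discretises the current configuration into spherical
shells whose polymer content is fixed (the mesh co-moves with the network):
only the water volume per cell evolves, driven by central-difference fluxes
of $\mu_w$; cell boundaries are rebuilt each step from the cavity volume and
the cumulative cell volumes.  The momentum balance is integrated inward from
$\sigma_{rr}(r_{out}) = -p_0$; the outer boundary imposes
$\mu_w = p_0 - \Pi_{ext}$ through a ghost value (or zero flux in the
closed-system variant used for conservation checks).  Polymer volume, air
moles and (in closed mode) total water are conserved to machine precision by
construction.

Two numerical choices matter:

* **Cavity coupling.**  The bubble is in local equilibrium at all times.
  Updating it as a lagged fixed point (momentum, then activity, then gas
  volume from the isotherm) has amplification factor of order
  $G/p_{air} > 1$ and diverges within a few steps for any realistic gel
  stiffness; the equilibrium gas volume is therefore solved *implicitly*
  each step (warm-started secant on $V_{gas}$, bracketed fallback).  This is
  the same model, integrated stably.
* **Step size.**  Explicit Euler with
  $\Delta t = C\, d^2 / D_{e\!f\!f}$, where
  $D_{e\!f\!f} = D_s (\nu_w/RT)\, \partial\Pi_{mix}/\partial\phi_w$ per
  cell, $d$ is the smallest gap between adjacent chemical-potential
  evaluation points bounding the cell (half a cell at the outer ghost), and
  $C = 0.2$ by default.  A halve-and-retry guard absorbs the residual
  nonlinearity of $\Pi_{mix}$.

Steady state is declared when the per-cell water rate has decayed below a
set fraction (default $10^{-8}$) of the largest rate seen during the run --
a scale-free criterion that reaches machine-accurate fixed points; absolute
rate thresholds tied to the global diffusion time proved unattainable at the
stable explicit step.

`steady_state_fv()` solves the steady problem directly: for a trial outer
stretch, each cell's polymer fraction is the root of the combined local
chemical equilibrium and momentum relation (bracketed on the physical
branch), marching inward; the outer stretch is then iterated until the
vapour pressure from the cavity gas law matches the equilibrium expression.

### Mixed finite elements on the initial frame

`run_transient_fe()` solves the weak formulation on the fixed free-swollen
frame: quadratic displacement, linear Lagrange pressure and linear molar
water concentration (per layer, on a shared mesh), an inf-sup-stable pair.
The pressure and concentration carry a doubled node at the core/skin
interface because $\lambda_r$ -- and with it $p$ -- jumps there; the two
water fields are coupled by an interface permeance flux
$D_\mu(\mu_{w,c} - \mu_{w,s})$.  The momentum weak form uses the
divergence-consistent spherical operator
$\partial_R S_{RR} + (2/R)(S_{RR} - S_{\theta\theta}) = 0$ (the sign of the
hoop term follows from the referential divergence and is cross-validated
against the current-frame finite-volume integration).  Boundary tractions
are $S_{RR} = -p_0\lambda_\theta^2$ outside and
$S_{RR} = -p_{gas}\lambda_\theta^2$ at the cavity; moisture exchange uses
Robin fluxes ($\beta_{cav}$, $\beta_{air}$ above) and the cavity vapour
content evolves as a scalar ODE, all assembled monolithically.

Time stepping is backward Euler with damped Newton on a finite-difference
Jacobian (reused across iterations while convergence is fast), row/column
equilibration of the linear systems, adaptive step growth and halving on
failure.  The interface permeance is a penalty: $D_\mu$ is chosen so the
chemical-potential jump stays below 0.1% of its scale, and reported
pressures change by less than 0.1% under a tenfold stiffer coupling (a
tested property).  A literal "small" permeance would throttle the flux
rather than enforce continuity.

## Numerical choices and degenerate inputs

* The per-cell equilibrium residual of the steady FV solver is non-monotone
  in $\phi$ (positive at both ends of the admissible range); the physical
  root lies on the rising branch past the minimum and is bracketed there.
* At $\Pi_{ext}/G_{core} \gtrsim 1830$ (for $\alpha = 2.175$) the mixing law
  cannot balance the external osmotic pressure below $\phi = 1$: the model
  has no steady state and the solvers raise a capacity error, which the
  experiment runners record per grid point.  At such drying intensities the
  equilibrium water activity is below 0.1 and a constant-modulus hydrogel
  stops being a sensible description anyway (the material would be glassy).
* $\Pi_{ext} = 0$ with saturated surroundings is an exact fixed point of all
  three solvers (tested to $10^{-9}$).
* Element inversion ($J \le 0$), water depletion in a cell, and
  vapour-above-total-pressure states raise descriptive errors.

## Validation and what it does (not) show

The three solvers are mutually validating: they share no discretisation, no
frame, and no time integrator, yet agree at steady state to five significant
figures on moderate problems (e.g. stiffness ratio 20,
$\Pi_{ext}/G_{core} = 10$, $R_{in} = 0.7 R_{out}$:
$p_{gas}/p_0 = 0.86119$, $r_{in}/R_{in} = 1.05407$ from all three).  This
agreement is a strong check of the *equations as implemented*, and it did
catch a real sign error during development.  It does not validate the model
against real tissue: the synthetic "experiments" are parameter studies of
the idealised sphere, with a sharp two-layer structure, constant moduli,
no viscoelasticity, and isothermal conditions.  Quantitative claims about
actual fruit/vegetable drying would additionally need moisture- and
temperature-dependent properties.

Headline behaviour reproduced by the package (see `scripts/acceptance.R`
and the test suite for the computations):

* Without a stiff skin the pore only shrinks; pore opening requires
  $G_{skin}/G_{core}$ above a threshold near 10 (our solvers place it at
  11.2 for the default $\alpha$; its $\alpha$-sensitivity is quantified
  above).
* A pore of 10% of the sphere radius grows about fivefold under severe
  drying ($\Pi_{ext}/G_{core}$ of several hundred, stiffness ratio 50).
* Steady $p_{gas}$ decreases monotonically with initial pore size towards a
  small positive limit, essentially attained at $R_{in}/R_{out} \approx 0.05$.
* During slow drying the gas pressure is quasi-steady: the instantaneous
  $p_{gas}(t)$ of the finite-element transient matches the analytical layer
  decomposition evaluated at the instantaneous radii to better than 1%
  after the initial boundary shock.

## Problem sizes used in the shipped tests

The tests and the acceptance script run on deliberately modest meshes --
40--72 finite-volume cells, 14--22 finite elements, transients of order
$10^5$ explicit steps or a few hundred implicit steps -- chosen as the
coarsest resolutions at which the cross-solver agreements above hold with
an order of magnitude to spare.  Mesh-refinement tests confirm the steady
finite-volume solution is converged to five digits at these sizes.

## Known limitations

* The uniform-swelling analytical solution has no radial profiles within a
  layer and degrades for very small pores or extreme drying.
* The explicit finite-volume transient becomes expensive for thick, highly
  swollen cores (stability-bound step); the finite-element solver is the
  intended tool for long transients.
* The finite-element transient takes small steps through the rapid
  pore-expansion phase (Newton on the monolithic system with an adaptive
  step); runs to full steady state at very small $R_{in}$ are slow, and the
  steady finite-volume solver is preferred there.
* No wrinkling, fracture, embolism, viscoelasticity, or thermal coupling;
  the temperature enters only through $p_{sat}(T)$ and the gas laws.
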