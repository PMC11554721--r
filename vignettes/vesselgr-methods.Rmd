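---
title: "Coupled bio-chemo-mechanical growth and remodeling of an artery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled bio-chemo-mechanical growth and remodeling of an artery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselgr)
```

`vesselgr` simulates how an artery adapts its geometry and composition to
sustained changes in blood pressure, blood flow, and biochemical
environment. Three submodels are coupled: (i) homogenized constrained
mixture mechanics of the wall, (ii) logic-gated ordinary-differential-
equation models of intracellular signaling evaluated at every material
point, and (iii) continuum-scale reaction-diffusion of the paracrine
messengers nitric oxide (NO) and endothelin-1 (ET1) released by the
endothelium. This vignette states the model, the numerical methods, the
design decisions taken where choices were open, and the known
limitations. All empirical statements below are reproduced by the test
suite or by `scripts/acceptance.R`.

## Mechanics: homogenized constrained mixture

The wall is a mixture of an elastin matrix, four collagen fiber families
(at 0°, 90° and ±29.91° from the circumferential direction) and
circumferential smooth muscle, all constrained to deform together. For
each constituent $i$ the deformation gradient splits multiplicatively,

$$\mathbf F_e^i = \mathbf F \, \mathbf F_g^{-1} \, (\mathbf F_r^i)^{-1},$$

where $\mathbf F_g$ is a transversely isotropic growth tensor with the
radial direction as growth direction and determinant equal to the
referential density ratio $\rho_0(s)/\rho_0(0)$, and $\mathbf F_r^i$ is
an isochoric remodeling tensor with the fiber-direction remodeling
stretch $\lambda_r^i$ as its only unknown. Only the elastic part stores
energy: elastin is a compressible neo-Hookean solid with an
isochoric/volumetric split (shear parameter $\mu^e$, penalty $\kappa =
10\mu^e$), and the fibers are quasi-one-dimensional Fung-type solids
$W = \tfrac{c_1}{4 c_2}\left[e^{c_2 (I_{4e}-1)^2} - 1\right]$. The
fiber-direction Cauchy stress used throughout is $\sigma = 2 I_{4e}\,
\partial W/\partial I_{4e}$ per unit reference mass; the homeostatic
target $\sigma_h$ is this function evaluated at the squared deposition
stretch $\lambda_h^2$, which makes the remodeling law exactly zero at
initialization.

Remodeling evolves by the scalar law

$$\dot\lambda_r = \Big(\frac{\dot\rho_0}{\rho_0} + \frac 1T\Big)
\frac{\lambda_r}{2 I_{4e}}
\Big(\frac{\partial\sigma}{\partial I_{4e}}\Big)^{-1} (\sigma - \sigma_h),$$

integrated with forward Euler at the growth-and-remodeling (G&R) step
$\Delta s$ (7 days by default), the same scheme used for the density
updates. The initial remodeling stretch is $1/\lambda_h$, so the fibers
carry their deposition stretch elastically in the reference state.

Active smooth muscle stress is optional. Its reference configuration
remodels fast, tracking the current stretch, so the active stretch is
identically 1 at every converged quasi-static equilibrium while its
derivative with respect to the total stretch remains $1/\lambda$; the
resulting circumferential stress is linear in the contraction level
$y_{con}$ and the normalized muscle density. The density $\rho_0(0)$ in
the active energy is taken as the initial *mixture* density (the symbol
used elsewhere in the formulation); since the active term is linear in
this normalization, the choice only rescales $\sigma_{max}$.

### Reduced-order equilibrium solver

Instead of a 3D finite element model, the quasi-static equilibrium
$\mathrm{div}\,\boldsymbol\sigma = 0$ is solved on an axisymmetric
thick-walled cylinder with fixed axial stretch
($\mathbf F = \mathrm{diag}(\partial r/\partial R,\, r/R,\, 1)$). The
unknowns are the current radii of `n_radial` nodes (default 5) spanning
the wall; material points live at the 4 cell midpoints. The radial
equilibrium is discretized in conservative finite-volume form (control
volumes around nodes, cell-centered stresses, traction boundary
conditions $\sigma_{rr} = -\gamma p_0$ inside and $0$ outside), so the
discrete residuals telescope and the global force balance
$\int \sigma_{\theta\theta}\, dr = p\, a$ holds to Newton tolerance.
Newton iteration uses a finite-difference tangent (central differences
at a fixed strain perturbation of $10^{-4}$, because the thin-wall
tangent is ill-conditioned and forward differences corrupt the search
direction), a step cap of $0.1 A$ and a backtracking line search. The
default residual tolerance is $5\times 10^{-11}$ relative to $p_0 A$,
just above the double-precision noise floor of the stress evaluations.
Doubling the radial resolution changes the reported inner radius and
thickness by less than 0.1% (tested), which is why 5 nodes are the
default problem size.

### Prestress initialization

The reference configuration is the loaded in-vivo state, so elastin must
be deposited with a prestretch that equilibrates the mixture at identity
deformation under the baseline pressure while collagen and muscle sit at
their homeostatic stretches. The elastin prestretch is the incompressible
uniaxial guess $\mathrm{diag}(\lambda_z^{-1/2}, \lambda_z^{-1/2},
\lambda_z)$ composed with an accumulated correction. Because every
equilibrium correction in the classical fixed-point iteration is the
gradient of a radial map, the accumulated correction is itself the
gradient of one radial "deposition map" $\rho(R)$; `prestress_vessel()`
solves for the nodal values of that map directly by Newton iteration on
the condition that the equilibrium residual vanishes at $\mathbf F =
\mathbf I$. Pressure and all deposition stretches are applied gradually
(5 load increments by default, refined adaptively when a Newton solve
fails). The plain fixed-point iteration converges here too but with a
contraction factor around 0.975 — hundreds of iterations — whereas the
Newton formulation needs a few dozen residual evaluations; both produce
the same state. Convergence is verified by re-solving the equilibrium
from the reference configuration: the mean nodal displacement normalized
by wall thickness is below $10^{-6}$ (machine-zero in practice).

## Intracellular signaling

Each species is a node $y_i \in [0, y_{max,i}]$ of a directed graph
evolving by $\dot y_i = (f_i(\mathbf y)\, y_{max,i} - y_i)/\tau_i$.
Activating influences are normalized Hill functions

$$f^+(y) = W\,\frac{B\, y^n}{(B-1) + y^n},\qquad
B = \frac{EC_{50}^n - 1}{2\,EC_{50}^n - 1},$$

which satisfy $f^+(0)=0$, $f^+(EC_{50})=W/2$, $f^+(1)=W$ exactly;
inhibition is $f^- = 1 - f^+$. $B$ is positive only for $EC_{50}^n <
0.5$, validated at construction and at network load time. Multiple
influences combine through scaled logic gates
($\mathrm{AND}(a,b) = 2ab/(a+b)$, $\mathrm{OR}(a,b) = a+b-ab$,
$\mathrm{AND\ NOT}(a,b) = 2a(1-b)/(a+(1-b))$, with the $0/0$ case defined
as 0). Gate composition is not associative across gate types, so each
node declares an explicit ordered gate tree in the JSON interchange
format; nothing is inferred.

Steady states are defined by residual, $\max_i |f_i y_{max,i} - y_i| <
10^{-8}$, not by a fixed horizon; the integration (deSolve, `lsoda`)
aborts with an explicit error if no steady state is found within
$1000\,\max\tau$, so oscillatory networks surface instead of being
silently truncated. For acyclic networks — all shipped fixtures — the
fixed point is obtained exactly by propagating activations in
topological order; tests verify agreement with the ODE route to
$10^{-8}$ and independence of the initial condition.

Continuum quantities $q$ enter as node inputs through the sigmoid
$y(\Delta q) = 1/(1 + e^{\beta - s_q \Delta q})$ with $\Delta q =
(q-q_h)/q_h$ and $\beta$ fixed by the baseline input $y_{i0}$. Network
outputs act on the tissue only through their normalized deviations
$\Delta\psi = (y - y_0)/y_0$ from the baseline steady state, so
homeostasis is exact by construction at $s = 0$. The smooth muscle
stress input is the passive fiber Cauchy stress (the quantity the
remodeling law regulates), with $q_h = \sigma_h^m$.

## Continuum-scale biochemistry

Structural constituents do not diffuse. Smooth muscle mass follows
$\dot\rho_0^m = (\rho_0^m/T^m)\,\Delta\psi^m$ and collagen
$\dot\rho_0^c = \tfrac{1}{T^c}\tfrac{\rho_0^c(0)}{\rho_0^m(0)}
\rho_0^m (1+\Delta\psi^c) - \rho_0^c/T^c$ (production scales with the
intramural cell density; the prefactor makes $s=0$ homeostatic). Elastin
neither deposits nor degrades. The four collagen families share a
constant relative distribution: each family receives the same relative
rate, and the family fractions provably never drift. The uncoupled
model replaces these by the phenomenological rate
$\dot\rho = \rho\, k\, (\sigma - \sigma_h)/\sigma_h$.

NO and ET1 diffuse from the endothelium through the wall with
first-order decay. Their kinetics (survival times 15 s and 120 s) are
4–5 orders of magnitude faster than the G&R step of 7 days, so each step
solves the quasi-steady elliptic problem $D\nabla^2 c = c/T$ on the
referential wall domain (an open choice; consistent with the referential
densities of the transport equations) with an endothelial influx
$-D\,\partial c/\partial r = \eta\,\dot Q_0 (1+\Delta\psi)$ and an
outer-wall outflux equal to $\xi$ times the instantaneous influx per
unit area. The solver is a conservative finite-volume tridiagonal solve
(101 cells by default) including cylindrical curvature, with a flag to
disable curvature; the planar cosh/sinh and cylindrical Bessel closed
forms serve as independent oracles in the tests, and the
influx–outflux–degradation balance holds to machine precision by
construction. With the default parameters the NO and ET1 profiles are
nearly linear across the 40 µm wall with concentrations on the order of
$10^2$ nM; the curvature term matters — per unit axial length the outer
surface is about 6% larger than the inner one, which at $\xi = 0.9$
roughly triples the net retention compared to a planar slab.

## Staggered coupling

Each G&R step executes, in order: (1) mechanical equilibrium under the
current load with the previous constituent state; (2) signaling steady
states at every material point using the step-1 stresses and the
previous concentrations (plus the endothelial network driven by the
wall-shear-stress ratio $\varepsilon/(a/A)^3$); (3) reaction-diffusion
and turnover rates using the step-1 mechanics and step-2 signaling.
Remodeling stretches and densities then advance by forward Euler, with
$\dot\rho/\rho$ in the remodeling law taken from the step-3 rates. The
ordering is an argument of `staggered_step()` solely so a regression
test can assert it is load-bearing. Load perturbations are sustained
steps at $s = 0^+$; time-varying schedules are also accepted.

Reported quantities (normalized mixture-stress trace, smooth muscle
stress, thickness, inner radius, wall-shear ratio, node activations,
concentrations) are evaluated at the mid-wall point by linear
interpolation between the two adjacent material points and normalized by
their $s=0$ values; the first record of every run is the homeostatic
baseline with all normalized quantities equal to 1.

## Scenario presets and the stand-in networks

The published intramural network (50 nodes, 82 reactions) is not
reproduced here; its parametrization lives in other work. The package
ships *stand-ins* with the same input/output signature so every coupling
pathway is exercised end-to-end:

* `ec_standin` — wall shear stress in; NO out (activated by WSS), ET1
  out (inhibited by WSS).
* `intramural_standin` — inputs: stress, NO, ET1, AngII, integrins,
  stretch-activated channels; outputs: colI, colIII (averaged into one
  fibrillar-collagen signal before the deviation is taken),
  proliferation, actomyosin activity.
* `three_node` — the minimal stability probe: one stress input
  activating proliferation and collagen ($\tau=1$, $W=1$, $EC_{50}=0.5$,
  $n=1.4$); its baseline input is 0.5 (the sigmoid midpoint — any
  consistent choice preserves homeostasis because outputs act through
  deviations).
* `five_node` — two inputs, three outputs; used for
  steady-state-uniqueness and gate-composition tests.

The intramural stand-in's internals are a deliberate design, documented
here because the choice was genuinely open. A single Hill edge from the
stress input (baseline 0.2) has a maximal relative gain
$f'/f \approx n/y \approx 6$, which, multiplied by the input-sigmoid
slope $y_0(1-y_0) s_\sigma = 0.16\, s_\sigma$, is comparable to the
three-node network's effective gain of $0.56\, s_\sigma$ per unit
relative stress deviation — the minimum the stability analysis shows is
needed for a stable adaptive response at $s_\sigma = 0.5$. The stand-in
therefore amplifies the stress input through a two-stage cascade
(`mapk`, `tgfb`; generic edge defaults $EC_{50}=0.5$, $n=1.4$) before it
reaches the synthetic outputs, giving collagen and proliferation stress
gains of roughly $1.1\, s_\sigma$ and $0.5\, s_\sigma$. Side influences
modulate rather than drown this pathway: NO inhibits at the top of the
cascade (its vasoprotective suppression of mechanosensitive signaling),
ET1 promotes proliferation through a steep high-$EC_{50}$ edge
($n = 2$, $EC_{50} = 0.65$, $W = 0.5$: low baseline contribution, strong
relative slope around a 0.5 input), AngII enters the collagen-III and
proliferation gates with weight 0.1, and the integrin/SAC pair
contributes through an AND gate with weight 0.25. Actomyosin activity is
ET1 AND-NOT NO at full weight. Exogenous AngII is applied as a step at
$s=0^+$ while the network is baselined at AngII $=0$: an accelerated
response to AngII is only possible if AngII perturbs the network away
from its baselined state (production scales with $1+\Delta\psi$, and a
re-baselined network would have $\Delta\psi \equiv 0$).

The NO and ET1 input baselines of the intramural network are set to 0.5
(sigmoid midpoints); like the three-node baseline this is a free,
consequence-light choice because inputs are scaled relative to their
homeostatic concentrations and outputs act through deviations. The
uncoupled preset's default gain is $k = 0.01\,$/day, in the stable range
of the phenomenological law for the default geometry (the tests also
exercise $k = 0.05$).

## What the simulations show — and what they do not

Zero-perturbation runs of every preset hold the homeostatic state to
machine precision for 20 turnover times: homeostasis is an exact fixed
point of the discrete scheme, not an approximate one. A 15% pressure
step thickens the wall toward the ideal marker $\gamma \varepsilon^{1/3}
H$; exogenous AngII accelerates the approach, produces a transient
stress undershoot and a smaller adapted radius. A 10% flow step dilates
the lumen toward $\varepsilon^{1/3} A$ at nearly unchanged thickness
while wall shear stress recovers. Lowering the stress sensitivity to
$s_\sigma = 0.25$ produces mechanobiological instability — monotone,
accelerating growth of lumen and mass (continuous distension) — while
$s_\sigma \ge 0.75$ converges to bounded equilibria, for 5, 10 and 15%
pressure steps alike.

Two quantitative offsets of the reduced-order model are documented
rather than hidden. First, adaptation is incomplete at finite time:
because elastin neither remodels nor turns over, the adapted equilibrium
retains a permanent elastin stress offset, and in the pressure scenario
(which has no wall-shear feedback) the inner radius drifts outward, so
at 10 turnover times the thickness reaches about 1.05–1.09 of its
initial value rather than the ideal 1.15, and the mixture-stress trace
retains a 3–10% offset; pushing the network gain arbitrarily high
saturates these at about 1.094 and 1.027 respectively. Second, the flow
response is pace-limited by the double sigmoid between wall shear stress
and the intramural inputs at the configured sensitivities, reaching
$r/A \approx 1.018$ at 10 turnover times with the fixed point at 1.032
still being approached. Both are properties of this single-layer,
radially averaged formulation with reduced stand-in networks; they are
the same kind of residual offsets the full-scale formulation reports,
but larger.

The synthetic scenarios emulate an idealized, axisymmetric, one-layered
murine aorta with deterministic signaling. They do not represent
layer-specific (media/adventitia) behavior, fiber reorientation,
viscoelasticity, damage, convective transport, measurement noise, or
inter-animal variability — so passing tests demonstrate internal
consistency of the model and faithfulness to its equations, not
predictive accuracy for any particular vessel.

## Problem sizes and runtime choices

Default runs use 5 radial nodes (4 material points), a 7-day step, 100
steps to reach 10 turnover times, and 101 diffusion cells; a full
coupled run takes about a second on one core, and the 15-run stability
sweep well under a minute. These sizes are grid-converged for the
reported quantities (see the resolution tests) and keep the whole suite
fast enough to run routinely.

## Reproducing the headline numbers

```r
run <- run_scenario("ec_communication",
                    overrides = list(epsilon = 1.1, gamma = 1),
                    t_end_norm = 10)
glance(run)
autoplot(run)
```

`scripts/acceptance.R` recomputes the headline quantities from scratch
(see the README).
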