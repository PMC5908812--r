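---
title: "Computing saddle slow manifolds and canard orbits in four dimensions"
author: "canard4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing saddle slow manifolds and canard orbits in four dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Slow--fast systems with two fast and two slow variables,
$$\dot{\mathbf{x}} = f(\mathbf{x}, \mathbf{y}, \lambda), \qquad
  \dot{\mathbf{y}} = \varepsilon\, g(\mathbf{x}, \mathbf{y}, \lambda),$$
organize their dynamics around two-dimensional *slow manifolds*: Fenichel
perturbations of normally hyperbolic sheets of the critical manifold
$S = \{f = 0\}$.  When an attracting sheet meets a saddle sheet at a fold
curve carrying a *folded node*, trajectories can cross from the attracting
to the saddle slow manifold and follow it for $O(1)$ slow time before
leaving along its unstable fast directions.  These *canard orbits* are the
organizing centers of the small-amplitude oscillations (SAOs) of
mixed-mode oscillations (MMOs).

A saddle slow manifold cannot be computed by forward or backward
integration: it has both contracting and expanding fast normal directions,
so errors grow at the fast rate $e^{ct/\varepsilon}$ in *either* time
direction.  The package therefore represents every invariant object as a
family of *orbit segments* solving two-point boundary-value problems
(2PBVPs): the vector field is rescaled to
$\dot{u} = T\,H(u, \lambda)$ on $s \in [0,1]$ with the total time $T$ a
free parameter, and the endpoints are constrained to hypersurfaces
$\Xi_0$ (codimension $i$) and $\Xi_1$ (codimension $j$).  With $i+j=4$ and
$T$ free this yields a well-posed problem with a one-parameter family of
solutions — a two-dimensional manifold swept out by pseudo-arclength
continuation.  The boundary-value formulation distributes the error
control over the whole orbit, which is what makes orbits exponentially
close to a saddle slow manifold computable at all.

## Discretization and continuation

Orbit segments are discretized by piecewise-polynomial collocation:
degree-4 polynomials on each of $N$ mesh intervals (default
$N = 60{-}200$ depending on the task), collocated at the 4 Gauss--Legendre
points per interval, with the polynomial represented by its values on the
fine grid of $4N+1$ points.  The nonlinear collocation system is solved by
a damped Newton iteration (line search, minimum damping $10^{-4}$) on a
sparse Jacobian; boundary conditions contribute $i + j$ rows, and one
anchor row (a fixed boundary coordinate, or the pseudo-arclength
constraint during continuation) closes the system.

Pseudo-arclength continuation uses a secant-free bordered tangent, step
adaptation ($\times 1.5$ growth after fast convergence, $\times 0.5$ on
failure, step bounds $[10^{-8}, 4]$), and monitor functions evaluated at
every accepted solution.  A sign change of a monitor is refined by
bisection on the arclength, re-solving the corrector at interior steps,
until the monitor magnitude is below $10^{-8}$.  The arclength metric
averages the state components and measures $T$ relative to its magnitude
at the start of the run, so that slow drift of long periods does not
throttle the parameter steps.

Backward-time families are solved with $T < 0$ rather than by negating the
vector field, keeping a single code path.  Canard branches in
$\varepsilon$ are continued in $\log \varepsilon$, since the approach to
the singular limit spans several decades.  No randomness is used anywhere;
identical configurations reproduce results bit for bit.

### Validation against closed forms and a stiff integrator

Two analytic fixtures calibrate the solver: a linear diagonal system whose
endpoint map is $\mathrm{diag}(e^{a_i T})$ (reproduced to $10^{-10}$), and
a decoupled slow--fast system with an exactly known critical manifold and
one repelling normal direction, which demonstrates that forward
integration leaves the manifold while the boundary-value solve does not.
Attracting orbits are additionally cross-checked against a high-accuracy
stiff initial-value integration (`deSolve::lsoda` at tolerance
$10^{-12}$): full-interval agreement to $10^{-4}$ relative.  For saddle
slow-manifold orbits only subinterval checks apply — the divergence of the
forward integration from the collocation solution is itself asserted in
the tests as evidence of the saddle normal structure.

## The two case studies

### Extended folded-node normal form

The folded-node normal form with one fast variable is extended by a second
fast variable $w$ with a stable direction ($\dot w = z - w$), giving a
four-dimensional test case whose critical manifold
$\{x = -z^2,\, z = w\}$, reduced flow, and desingularized flow are all
explicit.  The folded node at the origin has desingularized eigenvalues
$-\mu$ and $-1$ exactly, which the package's generic finite-difference
linearization reproduces to $10^{-8}$, and the symmetry
$(x,y,z,w) \mapsto (x,-y,-z,-w)$ maps the desingularized flow on the
attracting sheet to the saddle sheet; both serve as machine-precision
oracles in the tests.

Slow-manifold recipes follow the geometry of the fast eigendirections: on
the saddle sheet the stable eigendirection is the $w$-axis and the
unstable one is spanned by $(2z+1, 1)$ in $(z,w)$, so saddle-manifold
orbit segments enter through the $w$-nullcline $\{w = z\}$ and exit
through the $z$-nullcline $\{x = -z^2\}$, with constraint sections
$\{z = 0.1\}$, $\{z = 30\}$, $\{y = 0\}$ selecting the individual
submanifolds.

### Nondimensionalized Hodgkin--Huxley model

The four-dimensional Hodgkin--Huxley model in its singularly perturbed
nondimensional form has fast variables $(v, m)$ (voltage scaled by
$k_v = 100$ mV, activation gate) and slow gates $(h, n)$, with
$\tau_m = 1$, $\tau_h = 2$, $\tau_n = 1$, $\bar E_{Na} = 0.5$,
$\bar E_K = -0.77$, $\bar E_L = -0.544$, $g = 120$, $\bar g_k = 0.3$,
$\bar g_l = 0.0025$, and default operating point $I = 9.74$,
$\varepsilon = 0.0083$.

The gating steady states and time functions are the classical squid-axon
expressions, $x_\infty = \alpha_x/(\alpha_x + \beta_x)$ and
$1/(\alpha_x + \beta_x)$.  Their normalization deserves a precise
statement, because it fixes every number downstream.  The slow gates are
measured against the 1 ms reference of the slow time scale:
$t_h(v) = 1/(\alpha_h + \beta_h)$, $t_n(v) = 1/(\alpha_n + \beta_n)$ with
the rates in 1/ms.  The fast gate is measured against the fast reference
time, i.e. $t_m(v) = 1/(0.0083\,(\alpha_m + \beta_m))$, so that at the
default $\varepsilon$ the $m$-kinetics on the fast time scale coincide
with the dimensional model ($\varepsilon \approx C/(g_{Na}\cdot 1\,
\mathrm{ms}) = 1/120$).  Under this normalization the equilibrium branch
reproduces the reference Hopf locations of this parameterization
($I = 9.700092$ and $I = 170.6094$) to six significant digits, which we
treat as the defining cross-check of the transcription.

One caveat is documented rather than hidden: the folded-node computation
on the desingularized reduced system is sensitive to the *relative* speed
of the $h$ and $n$ gates, and the combination above yields a folded node
at $v = -0.599058$ with eigenvalues $(-0.0039641, -0.00018385)$, ratio
$21.56$, hence $2$ primary and $10$ predicted secondary canards by the
odd-integer resonance rule ($k \ge 1$ with $2k+1 < \mu_{fs}$).  A
reference value of $31.56$ (15 secondary canards) for this ratio is
reproduced only if the $h$-gate is slowed by a further factor
$\approx 1.47 \approx \max_v t_h / \max_v t_n$, a normalization that is
inconsistent with the Hopf locations above; no single convention
reproduces both, and the package follows the one validated by the full
system's bifurcation structure.  The two tested eigenvalue quantities that
are insensitive to this choice — the folded-node position along $v$ and
the strong eigenvalue — agree with the reference values to $5\times
10^{-4}$ and $0.5\%$ respectively.  The same sensitivity shifts the
canard geometry on the start line $\{v = -0.754\}$ by about $2\%$ in $h$,
while the deep-following exit voltage of the representative canard is
insensitive to it (the tests recover $v \approx -0.28$).

### Desingularized reduced systems

On the critical manifold the reduced flow is singular along fold curves;
rescaling time by the fold-vanishing factor (the determinant of the fast
Jacobian, sign-adjusted so that orientation is preserved on the attracting
sheet) removes the singularity and reverses the flow on the saddle sheet.
For Hodgkin--Huxley the package works on the $(v, h)$ chart: $m =
m_\infty(v)$ eliminates the fast gate and $n$ is the unique real positive
fourth root of the voltage equation (the sign of $v - E_K$ is positive
throughout the operating range), which avoids any two-dimensional root
solving.  Folded singularities are located by 1D bracketing along the fold
curve followed by bisection, and their eigenvalues come from a central
finite-difference linearization of the 2D chart field (step $10^{-6}$).

## Canard detection

In $\mathbb{R}^4$ the attracting and saddle slow manifolds are
two-dimensional surfaces whose intersections are not structurally stable,
so canard orbits are *not* intersections of manifolds; they are orbit
segments on the attracting slow manifold that stay close to the saddle
slow manifold for a long time before exiting along its unstable manifold.
The canard 2PBVP starts on a line $L^a$ on the attracting sheet (codimension
3) and ends on the intersection of an exit section transverse to the
unstable fast direction with a far constraint section (codimension 2);
with $T$ free this pins isolated canard orbits, and freeing one system
parameter yields canard branches.

Detection proceeds by a homotopy along $L^a$: the family of orbit
segments starting on $L^a$ has an SAO count that is a step function of
the start coordinate, and the boundaries of the $i$-SAO window are the
twin canards $\xi_i$, $\xi'_i$ that bound the ribbon $R_i$.  The package
locates these boundaries by bisection on event-classified shooting (the
observable switch of the exit side of the unstable manifold), which
resolves the window edges to $10^{-8}$; the representative canard is the
deeper-following edge, and can optionally be re-converged under the full
canard 2PBVP by collocation.  Shooting is usable here — despite the
exponential instability that rules it out for computing the manifolds
themselves — because bisection only needs the *sign* of the exit
classification, which the instability amplifies rather than destroys.

SAO counting thresholds are configured per model: for Hodgkin--Huxley an
oscillation is large-amplitude when its $v$-maximum exceeds $-0.2$, SAO
extrema are counted in the fold window $v \in [-0.75, -0.25]$ with a
prominence cutoff of $10^{-4}$ (to discard sub-resolution wiggles); for
the normal form, rotations are counted as local minima of $z$ in
$[-0.5, 0.5]$.  Counts are validated under sampling refinement; an
unresolved count raises an error rather than returning silently.

## Bifurcation workbench

Equilibria of Hodgkin--Huxley reduce to a scalar equation in $v$ (all
gates at steady state), so the equilibrium branch is tracked by direct
root solving per parameter value; Hopf points are refined to $10^{-6}$ in
$I$ by bisection on the real part of the leading complex pair.  Periodic
orbits are solved with periodic boundary conditions plus the standard
integral phase condition (orthogonality to the previous solution's
derivative) with the period free; Floquet multipliers come from the
monodromy matrix assembled by interval-wise condensation of the linearized
collocation system.  The trivial multiplier reproduces 1 to $10^{-6}$ and
serves as a per-step sanity check.  Period doubling is detected by the
continuous test function $\prod (\mu_i + 1)$ over the nontrivial
multipliers; branch points by a sign change of the bordered continuation
Jacobian's determinant.  There is no automatic branch switching: the
period-doubled branch is started explicitly from the PD orbit traversed
twice and perturbed along the period-doubling mode.

## Problem sizes and tolerances

The default tolerances are: Newton residual $10^{-9}$ ($10^{-8}$ for
periodic runs), boundary and event residuals $10^{-8}$, stiff-integrator
tolerances $10^{-10}$ to $10^{-13}$, fold tolerance $10^{-8}$ on the fast
Jacobian determinant.  The shipped analyses use deliberately moderate
problem sizes chosen as the smallest that leave the reported quantities
mesh-independent at their quoted precision: $N = 40$ collocation intervals
for small periodic orbits, $N = 80$ for the period-doubled branch,
$N = 60{-}150$ for manifold and canard families, and equilibrium scans at
201 parameter values.  Halving any mesh changes the reported endpoint
quantities by less than $10^{-6}$ (asserted in the tests).

## What the computations do and do not show

The synthetic fixtures and the two case studies exercise every code path
on problems with known structure, and the reference values of the
case studies are reproduced at the stated precision wherever the model
convention is unambiguous.  This does not certify behavior on systems
outside the class (more than two fast variables, no explicit
$\varepsilon$), for folded singularities other than nodes (folded saddles
and foci are classified but their unfoldings are not computed), or for
multi-parameter continuation and automatic branch switching, all of which
are out of scope.  Canard counts at finite $\varepsilon$ exceed the
singular-limit predictions (the resonance rule applies near
$\varepsilon = 0$); the package reports the resonance count as a
prediction, never as a census of detected canards.
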