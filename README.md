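# canard4d

Saddle slow manifolds, canard orbits and mixed-mode oscillations in
four-dimensional slow–fast systems.

## The problem

Conductance-based neuron models often evolve on two well-separated time
scales.  In the four-dimensional Hodgkin–Huxley model, the voltage `v` and
the activation gate `m` are fast while the gates `h` and `n` are slow,
with an explicit ratio ε:

```
v' = I/(k_v g) − m³h(v−E_Na) − g_k n⁴(v−E_K) − g_l(v−E_L)
m' = (m∞(v) − m)/(τ_m t_m(v))
h' = ε (h∞(v) − h)/(τ_h t_h(v))
n' = ε (n∞(v) − n)/(τ_n t_n(v))
```

The slow dynamics organize around two-dimensional *slow manifolds* —
perturbations of the normally hyperbolic sheets of the critical manifold
`S = {f = 0}`.  Where an attracting sheet meets a saddle sheet at a fold
curve carrying a *folded node*, trajectories cross onto the saddle slow
manifold and follow it before escaping along its unstable fast
directions.  These *canard orbits* organize the small-amplitude
oscillations (SAOs) of mixed-mode oscillations (MMOs), the alternation of
subthreshold oscillations and action potentials seen at currents near the
onset of firing.

A saddle slow manifold cannot be computed by integration in either time
direction.  `canard4d` computes every invariant object as a family of
orbit segments solving two-point boundary-value problems: the vector
field is rescaled to `du/ds = T·H(u)` on `s ∈ [0,1]` with the total time
`T` free, endpoints are constrained to hypersurfaces of codimensions `i`
and `j` with `i+j=4`, the segments are discretized by degree-4 Gauss
collocation, and families are swept by pseudo-arclength continuation with
event detection.  The package ships two fully parameterized case
studies — an extended folded-node normal form `(x,y,z,w)` with explicit
critical manifold `{x=−z², z=w}`, and the nondimensionalized 4D
Hodgkin–Huxley model — plus a singular-limit (GSPT) toolbox:
desingularized reduced systems, fold curves, folded singularities with
eigenvalues and predicted canard counts, equilibrium/periodic-orbit
continuation with Hopf, period-doubling and branch-point detection,
Floquet multipliers, canard detection and continuation, ribbons, and MMO
signature extraction.

## Worked example

```r
library(canard4d)

hh <- hodgkin_huxley_model()        # I = 9.74, eps = 0.0083, Table defaults

# Singular-limit analysis: folded node on the lower fold curve
fs <- folded_singularities(hh)
fs[[1]]
#> <folded node> at (-0.5990580,  0.0946152,  0.3309020,  0.3957049)
#>   eigenvalues: -0.00396413, -0.00018385  ratio: 21.562
#>   predicted canards: primary 2 secondary 10

# Bifurcation diagram in the injected current
eb <- continue_equilibria(hh, "I", c(0, 200))
eb
#> <equilibrium_branch in I> 201 points, 2 Hopf events
#>   Hopf at I = 9.700092 (omega = 0.0047276)
#>   Hopf at I = 170.609422 (omega = 0.0082349)

# Periodic orbits from the first Hopf point, with Floquet monitoring
po <- hopf_start(hh, "I", eb$hopf[[1]], amplitude = 2e-3)
br <- continue_periodic(hh, po, "I", c(8.6, 9.8), direction = -1,
                        h_max = 4, detect = "PD")
br$events[[1]]$par      # period-doubling at I = 8.805144

# The stable mixed-mode oscillation at I = 9.74
sig <- attractor_signature(hh)
format(sig)             # "1^6": one action potential, six SAOs per period
```

The first Hopf point at `I ≈ 9.7001` marks the subcritical onset of
oscillation; between it and the period-doubling at `I ≈ 8.8051` the model
carries the families of unstable periodic orbits whose interplay with the
slow manifolds produces the `1^6` MMO — six subthreshold oscillations per
action potential.

The normal-form case study works the same way:

```r
nf <- normal_form_model(mu = 9.2, eps = 0.01)
fam <- saddle_slow_manifold(nf, "nf_black", n = 20)   # orbit family on S^s_eps
slow_proximity(nf, family_orbits(fam)[[1]])            # distance to S, middle 80%
```

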