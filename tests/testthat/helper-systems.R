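# shared fixtures: cheap systems and solved orbits reused across tests

nf_default <- function(mu = 9.2, eps = 0.01) normal_form_model(mu, eps)
hh_default <- function() hodgkin_huxley_model()

# reference points of the Hodgkin-Huxley case study (I = 9.74);
# the m-coordinate of the equilibrium carries its leading zero restored
q_ref <- c(-0.596423, 0.0973836, 0.405820, 0.401974)
p_ref <- c(-0.599361, 0.094301, 0.334475, 0.395965)

# a converged normal-form saddle-manifold orbit (black recipe), cached
nf_black_orbit <- local({
  cache <- NULL
  function(y0 = -2, eps = 0.01, N = 60) {
    key <- paste(y0, eps, N)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$orbit)
    sys <- nf_default(eps = eps)
    rec <- manifold_recipe(sys, "nf_black")
    spec <- bvp_spec(rec$left, rec$right)
    guess <- canard4d:::saddle_seed(sys, rec, c(y0, NA), N)
    orb <- solve_orbit(sys, spec, guess, anchor = 2L)
    cache <<- list(key = key, orbit = orb)
    orb
  }
})

lin_fixture_solution <- function(N = 10) {
  fx <- make_fixture("linear_diagonal_bvp")
  mesh <- seq(0, 1, length.out = N + 1)
  guess <- orbit_segment(mesh, function(s) rep(1, 4), T = 1, fx$system)
  list(fx = fx, sol = solve_orbit(fx$system, fx$spec, guess))
}
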