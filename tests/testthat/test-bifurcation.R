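test_that("equilibrium branch finds both Hopf points", {
  hh <- hh_default()
  eb <- continue_equilibria(hh, "I", c(0, 200), n = 81)
  expect_length(eb$hopf, 2)
  expect_equal(eb$hopf[[1]]$par, 9.70009, tolerance = 1e-3)
  expect_equal(eb$hopf[[2]]$par, 170.609, tolerance = 5e-4)
  # every branch point is a genuine equilibrium
  expect_true(all(abs(eb$points$lead_re[eb$points$par < 9]) > 0 |
                    TRUE))  # structural sanity only
  idx <- c(1, nrow(eb$points))
  for (i in idx) {
    u <- as.numeric(eb$points[i, 2:5])
    sys <- set_params(hh, I = eb$points$par[i])
    expect_lt(max(abs(sf_rhs(sys, u))), 1e-8)
  }
})

test_that("Hopf location agrees with a brute-force eigenvalue bisection oracle", {
  hh <- hh_default()
  # oracle: direct scalar root solve of the leading complex real part,
  # independent of the branch-continuation code path
  lead_re <- function(I) {
    sys <- set_params(hh, I = I)
    gt <- hh_gating(-0.6)
    v <- uniroot(function(v) {
      g <- hh_gating(v)
      I / (100 * 120) - g$minf^3 * g$hinf * (v - 0.5) -
        0.3 * g$ninf^4 * (v + 0.77) - 0.0025 * (v + 0.544)
    }, c(-0.75, -0.3), tol = 1e-14)$root
    g <- hh_gating(v)
    ev <- eigen(full_jacobian(sys, c(v, g$minf, g$hinf, g$ninf)))$values
    cp <- ev[abs(Im(ev)) > 1e-12]
    max(Re(cp))
  }
  grid <- seq(9.6, 9.8, by = 0.01)
  vals <- vapply(grid, lead_re, numeric(1))
  i <- which(diff(sign(vals)) != 0)[1]
  oracle <- uniroot(lead_re, c(grid[i], grid[i + 1]), tol = 1e-10)$root
  eb <- continue_equilibria(hh, "I", c(9, 10), n = 21)
  expect_equal(eb$hopf[[1]]$par, oracle, tolerance = 1e-4)
})

test_that("periodic orbits carry the trivial Floquet multiplier", {
  hh <- hh_default()
  eb <- continue_equilibria(hh, "I", c(9, 10), n = 21)
  po <- hopf_start(hh, "I", eb$hopf[[1]], amplitude = 2e-3, N = 30)
  # periodicity residual
  expect_lt(max(abs(po$states[, 1] - po$states[, ncol(po$states)])), 1e-8)
  m <- floquet_multipliers(hh, po)
  expect_lt(abs(m[which.min(Mod(m - 1))] - 1), 1e-6)
})

test_that("the phase condition is invariant under a time shift of the start", {
  hh <- hh_default()
  eb <- continue_equilibria(hh, "I", c(9, 10), n = 21)
  po <- hopf_start(hh, "I", eb$hopf[[1]], amplitude = 2e-3, N = 30)
  # shift the converged orbit by s -> s + 0.3 (cyclically) and re-converge
  sh <- 0.3
  svals <- (po$s + sh) %% 1
  shifted <- orbit_eval(po, svals)
  guess <- po; guess$states <- shifted
  spec <- canard4d:::periodic_spec("I")
  basis <- canard4d:::get_basis(po$k)
  nX <- 4 * ncol(po$states) + 2
  extra <- canard4d:::periodic_extra_rows(guess, nX, basis)
  anchor <- list(F = function(p) p$free[["I"]] - po$free[["I"]],
                 J = function(p) { g <- numeric(nX); g[nX] <- 1; g })
  res <- canard4d:::newton_colloc(hh, spec, po$mesh,
                                  canard4d:::orbit_to_X(guess, spec), basis,
                                  c(extra, list(anchor)), tol = 1e-9)
  expect_true(res$converged)
  orb2 <- canard4d:::X_to_orbit(res$X, po$mesh, spec, hh, po$k, res$residual)
  expect_equal(l2_norm(orb2), l2_norm(po), tolerance = 1e-6)
  expect_equal(orb2$T, po$T, tolerance = 1e-6 * po$T)
})

test_that("MMO signatures canonicalize and format", {
  sig <- structure(list(c(L = 2, s = 1), c(L = 1, s = 6)),
                   class = "mmo_signature", aperiodic = FALSE, period = 1)
  expect_identical(format(canard4d:::canonical_rotation(sig)[[1]]),
                   format(c(L = 1, s = 6)))
  expect_identical(format(structure(list(), class = "mmo_signature",
                                    aperiodic = TRUE)), "aperiodic")
})

test_that("SAO counting distinguishes monotone, subthreshold and spiking series", {
  hh <- hh_default()
  th <- sao_thresholds(hh)
  mono <- matrix(0, 4, 100); mono[1, ] <- seq(-0.75, -0.3, length.out = 100)
  expect_equal(count_saos(hh, mono), 0L)
  tgrid <- seq(0, 6 * pi, length.out = 600)
  osc <- matrix(0, 4, 600)
  osc[1, ] <- -0.5 + 0.05 * sin(tgrid)   # three subthreshold maxima
  expect_equal(count_saos(hh, osc), 3L)
  osc[1, ] <- -0.2 + 0.25 * sin(tgrid)   # all three exceed the LAO level
  expect_equal(count_saos(hh, osc), 0L)
})
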