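test_that("collocation reproduces the linear closed-form endpoint map", {
  ls <- lin_fixture_solution(N = 10)
  endpoint <- ls$sol$states[, ncol(ls$sol$states)]
  expect_equal(endpoint, exp(-(1:4)), tolerance = 1e-10)
  # interior values match the flow too
  mid <- orbit_eval(ls$sol, 0.5)
  expect_equal(drop(mid), exp(-(1:4) * 0.5), tolerance = 1e-9)
})

test_that("well-posedness counting rejects inconsistent boundary codimensions", {
  l3 <- hypersurface(function(u) u[1], function(u) u[2], function(u) u[3])
  r2 <- hypersurface(function(u) u[1], function(u) u[3] - 1)
  expect_error(bvp_spec(l3, NULL), "underdetermined")          # i+j = 3
  expect_error(bvp_spec(hs_and(l3, r2), r2), "overdetermined") # i+j = 7
  expect_silent(spec <- bvp_spec(l3, hs_coord(3, 1)))          # i+j = 4
  expect_equal(spec$family_dim, 1L)
  expect_equal(bvp_spec(l3, r2,
                        free = c("T", "eps"))$family_dim, 1L)  # i+j = 5, 2 free
  expect_error(bvp_spec(l3, hs_coord(3, 1), free = character(0)),
               "T_fixed")
})

test_that("orbit segments validate their invariants", {
  expect_error(orbit_segment(c(0, 0.5, 0.4, 1), function(s) rep(1, 4), 1),
               "diff")
  expect_error(orbit_segment(seq(0, 1, 0.25), function(s) rep(1, 4), 0),
               "nonzero")
})

test_that("high-accuracy IVP oracle matches collocation on a saddle orbit subinterval", {
  nf <- nf_default()
  orb <- nf_black_orbit(y0 = -2)
  # short mid-orbit subinterval: long subintervals are meaningless on a
  # saddle orbit because deviations grow at the unstable fast rate
  s0 <- 0.5; ds <- 0.1 / abs(orb$T)
  u0 <- drop(orbit_eval(orb, s0))
  short <- ivp_endpoint(nf, u0, ds * orb$T)$endpoint
  expect_equal(short, drop(orbit_eval(orb, s0 + ds)),
               tolerance = 1e-5)
})

test_that("forward integration diverges from the saddle slow manifold while the BVP does not", {
  nf <- nf_default()
  orb <- nf_black_orbit(y0 = -2)
  # full-interval IVP from u(0) leaves the manifold through the unstable
  # fast direction; the collocation solution stays on it
  full <- tryCatch(ivp_endpoint(nf, orb$states[, 1], orb$T)$endpoint,
                   error = function(e) NULL)
  bvp_prox <- slow_proximity(nf, orb)
  expect_lt(bvp_prox, 0.1)
  diverged <- is.null(full) || any(!is.finite(full)) ||
    abs(full[1] + full[3]^2) > 10 * bvp_prox
  expect_true(diverged)
})

test_that("mesh refinement leaves the endpoint unchanged", {
  nf <- nf_default()
  orb60 <- nf_black_orbit(y0 = -2, N = 60)
  sys <- nf_default()
  rec <- manifold_recipe(sys, "nf_black")
  spec <- bvp_spec(rec$left, rec$right)
  guess120 <- adapt_mesh(orb60, N = 120)
  orb120 <- solve_orbit(sys, spec, guess120, anchor = 2L)
  expect_equal(orb120$states[, ncol(orb120$states)],
               orb60$states[, ncol(orb60$states)], tolerance = 1e-6)
  expect_equal(orb120$T, orb60$T, tolerance = 1e-6 * abs(orb60$T))
})

test_that("pseudo-arclength continuation sweeps the family and finds events", {
  nf <- nf_default()
  first <- nf_black_orbit(y0 = -2)
  sys <- nf_default()
  rec <- manifold_recipe(sys, "nf_black")
  spec <- bvp_spec(rec$left, rec$right)
  run <- continue_family(sys, spec, first,
                         monitors = list(ycross = function(o) o$states[2, 1] + 1.5),
                         n_max = 12, h0 = 0.5, h_max = 2, direction = 1,
                         tangent_coord = list(what = "u0", index = 2))
  y0s <- vapply(run$solutions, function(o) o$states[2, 1], numeric(1))
  expect_gt(length(run$solutions), 5)
  expect_gt(abs(y0s[length(y0s)] - y0s[1]), 0.5)   # the family is swept
  if (length(run$events)) {
    ev <- run$events[[1]]
    expect_lt(abs(ev$orbit$states[2, 1] + 1.5), 1e-8)
  }
  # all family members satisfy their boundary conditions
  for (o in run$solutions[c(1, length(run$solutions))]) {
    u1 <- o$states[, ncol(o$states)]
    expect_lt(abs(u1[1] + u1[3]^2), 1e-8)
    expect_lt(abs(u1[3] - 30), 1e-8)
  }
})

test_that("flow extension lands exactly on the stop surface", {
  nf <- nf_default()
  orb <- nf_black_orbit(y0 = -2)
  ext <- extend_by_flow(nf, orb, "forward", hs_coord(3, 35), tmax = 500)
  u1 <- ext$states[, ncol(ext$states)]
  expect_lt(abs(u1[3] - 35), 1e-6)
  expect_gt(ext$T, orb$T)
  # backward extension beyond the entry section leaves the slow manifold
  # along the stable fast direction: |w - z| grows monotonically
  back <- extend_by_flow(nf, orb, "backward",
                         hypersurface(function(u) u[4] - u[3] - 2), tmax = 20)
  sfine <- seq(0, 0.05, length.out = 40)
  wz <- abs(apply(orbit_eval(back, sfine), 2, function(u) u[4] - u[3]))
  expect_gt(wz[1], 1.9)                      # far from the manifold at the tail
  expect_lt(wz[length(wz)], wz[1] / 10)      # decaying toward the manifold
})

test_that("time-normalized L2 norm is exact on constants and mesh-invariant", {
  cst <- orbit_segment(seq(0, 1, length.out = 11),
                       function(s) c(3, -4, 0, 0), T = 2)
  expect_equal(l2_norm(cst), 5, tolerance = 1e-12)
  orb <- nf_black_orbit(y0 = -2)
  expect_equal(l2_norm(orb), l2_norm(adapt_mesh(orb, N = 120)),
               tolerance = 1e-5)
})
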