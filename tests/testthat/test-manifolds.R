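test_that("saddle-manifold orbits satisfy their recipe boundary conditions", {
  orb <- nf_black_orbit(y0 = -2)
  u0 <- orb$states[, 1]; u1 <- orb$states[, ncol(orb$states)]
  expect_lt(abs(u0[4] - u0[3]), 1e-8)   # entry on the w-nullcline
  expect_lt(abs(u0[3] - 0.1), 1e-8)     # at z = 0.1
  expect_lt(abs(u1[1] + u1[3]^2), 1e-8) # exit on the z-nullcline
  expect_lt(abs(u1[3] - 30), 1e-8)      # at z = 30
})

test_that("slow-manifold proximity obeys the 10*eps bound and scales linearly", {
  prox <- vapply(c(1e-2, 5e-3, 1e-3), function(eps)
    slow_proximity(nf_default(eps = eps), nf_black_orbit(y0 = -2, eps = eps)),
    numeric(1))
  expect_true(all(prox <= 10 * c(1e-2, 5e-3, 1e-3)))
  # roughly linear-in-eps scaling: a tenfold eps drop shrinks the proximity
  # by about tenfold
  expect_equal(prox[1] / prox[3], 10, tolerance = 0.5)
})

test_that("attracting family sweeps its start line and stays near the sheet", {
  nf <- nf_default()
  fam <- attracting_slow_manifold(nf, "nf_attracting_1", n = 6,
                                  seed_chart = c(-3, -30), N = 60,
                                  h0 = 0.5, h_max = 2)
  orbs <- family_orbits(fam)
  expect_gte(length(orbs), 4)
  y0s <- vapply(orbs, function(o) o$states[2, 1], numeric(1))
  expect_true(all(diff(y0s) > 0) || all(diff(y0s) < 0))
  for (o in orbs) {
    expect_lt(abs(o$states[3, 1] + 30), 1e-8)                 # on L_a1
    expect_lt(abs(o$states[3, ncol(o$states)] + 0.1), 1e-8)   # ends at z=-0.1
    expect_lt(slow_proximity(nf, o), 0.1)
  }
})

test_that("attracting-orbit full-interval IVP oracle agrees with collocation", {
  nf <- nf_default()
  fam <- attracting_slow_manifold(nf, "nf_attracting_1", n = 2,
                                  seed_chart = c(-10, -30), N = 100)
  o <- family_orbits(fam)[[1]]
  ivp <- ivp_endpoint(nf, o$states[, 1], o$T)$endpoint
  u1 <- o$states[, ncol(o$states)]
  expect_lt(sqrt(sum((ivp - u1)^2)) / sqrt(sum(u1^2)), 1e-4)
})

test_that("transversality guard rejects a tangent entry section", {
  nf <- nf_default()
  rec <- manifold_recipe(nf, "nf_black")
  # replace the entry section by one parallel to the stable eigendirection
  rec$left <- hs_and(hypersurface(function(u) u[3] - 0.1, desc = "z=0.1"),
                     hs_coord(2, -2))
  rec$seed$chart_from <- 0.1
  expect_error(saddle_slow_manifold(nf, rec, n = 2, seed_chart = c(-2, NA)),
               "tangent")
})

test_that("Hodgkin-Huxley attracting family follows its recipe", {
  hh <- hh_default()
  fam <- attracting_slow_manifold(hh, "hh_attracting_1", n = 4,
                                  seed_chart = c(-0.75, 0.1), N = 80,
                                  h0 = 0.01, h_max = 0.2)
  orbs <- family_orbits(fam)
  expect_gte(length(orbs), 3)
  for (o in orbs) {
    expect_lt(abs(o$states[3, 1] - 0.1), 1e-8)                # h = 0.1
    expect_lt(abs(o$states[1, ncol(o$states)] + 0.6), 1e-8)   # ends at v=-0.6
  }
})

test_that("section curves of the two manifolds do not intersect", {
  nf <- nf_default()
  # attracting family ending exactly on the section {y = 0}
  fam_a <- attracting_slow_manifold(nf, "nf_attracting_2", n = 8,
                                    seed_chart = c(-3, -30), N = 60,
                                    h0 = 0.5, h_max = 2)
  # saddle family ending on {y = 0} (cut of S^s_eps by the section)
  left <- hs_and(hypersurface(function(u) u[4] - u[3]), hs_coord(3, 0.1))
  right <- hs_and(hypersurface(function(u) u[1] + u[3]^2), hs_coord(2, 0))
  spec <- bvp_spec(left, right)
  rec <- manifold_recipe(nf, "nf_black")
  guess <- canard4d:::saddle_seed(nf, list(seed = list(chart_from = 0.1,
                                                       chart_to = NA,
                                                       y_to = 0)),
                                  c(-1.5, NA), 60)
  first <- solve_orbit(nf, spec, guess, anchor = 2L)
  fam_s <- structure(list(role = "saddle_slow", spec = spec,
                          run = continue_family(nf, spec, first, n_max = 8,
                                                h0 = 0.3, h_max = 1),
                          recipe = "nf_saddle_to_section"),
                     class = "manifold_family")
  sec <- hs_coord(2, 0)
  ca <- section_intersection(fam_a, sec, end = "right")
  cs <- section_intersection(fam_s, sec, end = "right")
  gap <- min_gap(ca, cs)
  expect_gt(gap, 0)
  # determinism: identical configuration reproduces the curve bit-for-bit
  fam_a2 <- attracting_slow_manifold(nf, "nf_attracting_2", n = 8,
                                     seed_chart = c(-3, -30), N = 60,
                                     h0 = 0.5, h_max = 2)
  ca2 <- section_intersection(fam_a2, sec, end = "right")
  expect_identical(ca$points, ca2$points)
})

test_that("section intersection rejects off-section endpoints", {
  nf <- nf_default()
  fam <- attracting_slow_manifold(nf, "nf_attracting_1", n = 3,
                                  seed_chart = c(-3, -30), N = 60)
  expect_error(section_intersection(fam, hs_coord(2, 0)), "off the section")
})
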