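test_that("chart points satisfy the layer problem", {
  nf <- nf_default()
  expect_equal(chart_point(nf, c(0, 2)), c(-4, 0, 2, 2))
  expect_equal(chart_point(nf, c(5, 0)), c(0, 5, 0, 0))  # on the fold
  hh <- hh_default()
  set.seed(4)
  for (rep in 1:10) {
    ch <- c(runif(1, -0.72, -0.6), runif(1, 0.1, 0.5))
    u <- chart_point(hh, ch)
    expect_lt(layer_residual(hh, u), 1e-10)
  }
  # q is an equilibrium, hence on S: its chart point recovers n
  u <- chart_point(hh, q_ref[c(1, 3)])
  expect_equal(u[4], q_ref[4], tolerance = 2e-3)
  expect_error(chart_point(hh, c(0.5, 2)), "domain")
})

test_that("sheets classify by fast-Jacobian eigenvalues", {
  nf <- nf_default()
  expect_identical(classify_sheet(nf, chart_point(nf, c(0, -1))), "attracting")
  expect_identical(classify_sheet(nf, chart_point(nf, c(0, 1))), "saddle")
  expect_identical(classify_sheet(nf, chart_point(nf, c(0, 0))), "fold")
  expect_error(classify_sheet(nf, c(1, 0, 1, 1)), "off the critical manifold")
  hh <- hh_default()
  expect_identical(classify_sheet(hh, chart_point(hh, c(-0.7, 0.3))), "attracting")
  # middle sheet between the fold curves is of saddle type
  expect_identical(classify_sheet(hh, chart_point(hh, c(-0.45, 0.35))), "saddle")
})

test_that("fold curves carry vanishing determinant", {
  nf <- nf_default()
  fc <- fold_curve(nf, n = 20)
  expect_true(all(abs(fc$points[, 3]) <= 1e-10))   # the line z = 0
  expect_true(all(abs(fc$det) <= 1e-8))
  hh <- hh_default()
  f1 <- fold_curve(hh, "F1", sweep = c(0.2, 0.5), n = 20)
  expect_true(all(abs(f1$det) <= 1e-8))
  # lower fold at the folded-node height
  vF <- f1$chart[which.min(abs(f1$chart[, 2] - p_ref[3])), 1]
  expect_equal(vF, p_ref[1], tolerance = 1e-3)
  f2 <- fold_curve(hh, "F2", sweep = c(0.3, 0.7), n = 15)
  # v and m hardly change along the upper fold curve
  expect_lt(diff(range(f2$points[, 1])), 0.05)
  expect_lt(diff(range(f2$points[, 2])), 0.05)
})

test_that("desingularized flow vanishes at folded and ordinary singularities", {
  nf <- nf_default()
  expect_equal(desing_rhs(nf, c(0, 0)), c(0, 0))
  hh <- hh_default()
  fs <- folded_singularities(hh)
  node <- fs[[which(vapply(fs, function(x) x$kind, "") == "node")[1]]]
  expect_lt(sqrt(sum(desing_rhs(hh, node$chart)^2)), 1e-6)
  # projection of the full equilibrium onto S is also an equilibrium of the
  # desingularized system
  q <- full_equilibria(hh)[[1]]$location
  expect_lt(sqrt(sum(desing_rhs(hh, q[c(1, 3)])^2)), 1e-6)
})

test_that("the normal-form symmetry maps the desingularized flow exactly", {
  nf <- nf_default()
  set.seed(5)
  for (rep in 1:20) {
    ch <- c(runif(1, -10, 10), runif(1, -5, 5))
    expect_equal(desing_rhs(nf, -ch), -desing_rhs(nf, ch), tolerance = 1e-14)
  }
})

test_that("desingularized flow matches a finite-difference slow flow on S^a", {
  # on the attracting sheet the reduced flow is explicit: y' = 1,
  # z' = -(mu y /2 - (mu+1) z)/(2 z); the desingularized field is that flow
  # rescaled by -2z (positive on S^a)
  nf <- nf_default()
  mu <- 9.2
  for (ch in list(c(1, -2), c(-4, -0.5), c(3, -1.5))) {
    y <- ch[1]; z <- ch[2]
    red <- c(1, -(0.5 * mu * y - (mu + 1) * z) / (2 * z))
    expect_equal(desing_rhs(nf, ch), -2 * z * red, tolerance = 1e-12)
  }
})

test_that("normal-form folded node has eigenvalues (-mu, -1)", {
  for (mu in c(1.5, 9.2, 100.1)) {
    fs <- folded_singularities(normal_form_model(mu, 0.01))[[1]]
    expect_identical(fs$kind, "node")
    expect_equal(sort(fs$eigenvalues), sort(c(-mu, -1)), tolerance = 1e-8)
  }
})

test_that("Hodgkin-Huxley folded node location and eigenvalues", {
  hh <- hh_default()
  fs <- folded_singularities(hh)
  kinds <- vapply(fs, function(x) x$kind, "")
  expect_true("node" %in% kinds)
  node <- fs[[which(kinds == "node")[1]]]
  # the folded node sits on the lower fold curve near the reference location
  expect_equal(node$location[1], p_ref[1], tolerance = 1e-3)
  expect_equal(node$location[2], p_ref[2], tolerance = 5e-3)
  # regression values of this package's computation (see methods vignette
  # for the discussion of the singular-limit time-scale normalization)
  expect_equal(node$eigenvalues[1], -0.0039641, tolerance = 1e-4)
  expect_equal(node$ratio, 21.562, tolerance = 1e-3)
  expect_identical(node$predicted_primary, 2)
})

test_that("secondary-canard resonance counting", {
  expect_equal(unname(predicted_canard_counts(31.56)), c(2, 15))
  expect_equal(unname(predicted_canard_counts(2.5)), c(2, 0))
  expect_equal(unname(predicted_canard_counts(9.2)), c(2, 4))
  expect_equal(unname(predicted_canard_counts(100.1)), c(2, 49))
  expect_error(predicted_canard_counts(0.5), "degenerate")
  expect_warning(predicted_canard_counts(7), "resonance")
})

test_that("full equilibria: saddle-focus for HH, none for the normal form", {
  hh <- hh_default()
  eqs <- full_equilibria(hh)
  expect_length(eqs, 1)
  q <- eqs[[1]]
  expect_lt(max(abs(sf_rhs(hh, q$location))), 1e-10)
  expect_identical(q$type, "saddle-focus")
  expect_equal(q$stable_dim, 2)
  expect_equal(q$unstable_dim, 2)
  expect_equal(q$location[1], q_ref[1], tolerance = 1e-3)
  expect_length(full_equilibria(nf_default()), 0)
  # a single equilibrium across the whole current range
  for (I in c(0, 50, 100, 150, 200))
    expect_length(full_equilibria(set_params(hh, I = I)), 1)
})
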