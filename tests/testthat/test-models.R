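test_that("normal-form vector field matches its closed form", {
  nf <- nf_default(mu = 9.2, eps = 0.01)
  expect_equal(sf_rhs(nf, c(0, 0, 0, 0)), c(0, 0.01, 0, 0))
  # on the critical manifold the fast components vanish identically
  set.seed(1)
  for (rep in 1:20) {
    y <- runif(1, -20, 20); z <- runif(1, -6, 6)
    u <- c(-z^2, y, z, z)
    du <- sf_rhs(nf, u)
    expect_equal(du[3:4], c(0, 0), tolerance = 1e-14)
    expect_equal(du[2], 0.01)
  }
  # singular limit at a point on the critical manifold
  nf0 <- normal_form_model(9.2, eps = 0)
  expect_equal(nf0$rhs(c(-1, 0, 1, 1), nf0$params, 0), c(0, 0, 0, 0))
})

test_that("slow components of the fast-time field scale linearly in eps", {
  set.seed(2)
  for (sys_name in c("normal_form", "hodgkin_huxley")) {
    mk <- if (sys_name == "normal_form") function(e) normal_form_model(9.2, e)
          else function(e) hodgkin_huxley_model(eps = e)
    u <- if (sys_name == "normal_form") c(-0.3, 1.2, 0.4, 0.1)
         else c(-0.6, 0.1, 0.4, 0.4)
    for (eps in c(1e-2, 1e-3)) {
      s1 <- mk(eps); s0 <- mk(0)
      d <- s1$rhs(u, s1$params, eps) - s0$rhs(u, s0$params, 0)
      slow_rate <- s1$rhs(u, s1$params, eps)[s1$slow] / eps
      expect_equal(d[s1$slow], eps * slow_rate, tolerance = 1e-13)
      expect_equal(d[s1$fast], c(0, 0), tolerance = 1e-14)
    }
  }
})

test_that("fast Jacobian of the normal form is [[2z,0],[1,-1]] everywhere", {
  nf <- nf_default()
  set.seed(3)
  for (rep in 1:10) {
    u <- runif(4, -5, 5)
    expect_equal(fast_jacobian(nf, u),
                 matrix(c(2 * u[3], 1, 0, -1), 2, 2), tolerance = 1e-12)
  }
  ev <- eigen(fast_jacobian(nf, c(0, 0, 1, 0)))$values
  expect_setequal(round(ev, 10), c(2, -1))
})

test_that("slow-time evaluation divides by eps and rejects the singular limit", {
  nf <- nf_default(eps = 0.01)
  u <- c(-1, 2, 1, 1)
  expect_equal(sf_rhs(nf, u, "slow")[1:2],
               c(0.5 * 9.2 * 2 - 10.2 * 1, 1))
  nf0 <- normal_form_model(eps = 0)
  expect_error(sf_rhs(nf0, u, "slow"), "desing_rhs")
  expect_error(sf_rhs(nf, c(NA, 0, 0, 0)), "non-finite")
})

test_that("Hodgkin-Huxley right-hand side nearly vanishes at the reference equilibrium", {
  hh <- hh_default()
  expect_lt(max(abs(sf_rhs(hh, q_ref))), 1e-5)
})

test_that("gating functions have the qualitative Hodgkin-Huxley structure", {
  v <- seq(-0.9, 0.6, length.out = 1000)
  g <- hh_gating(v)
  for (nm in c("minf", "hinf", "ninf")) {
    expect_true(all(g[[nm]] >= 0 & g[[nm]] <= 1))
  }
  for (nm in c("tm", "th", "tn")) expect_true(all(g[[nm]] > 0))
  expect_true(all(diff(g$minf) > 0))   # activation increasing
  expect_true(all(diff(g$hinf) < 0))   # inactivation decreasing
  expect_warning(hh_gating(5), "extrapolat")
})

test_that("m-gate steady state matches the equilibrium m-coordinate", {
  expect_equal(hh_gating(q_ref[1])$minf, q_ref[2], tolerance = 1e-4)
})

test_that("gating sextet regression at the folded-node voltage", {
  g <- hh_gating(-0.599361)
  # frozen one-time evaluation of the transcribed rate functions
  expect_equal(g$minf, 0.09430126, tolerance = 1e-6)
  expect_equal(g$hinf, 0.41593844, tolerance = 1e-6)
  expect_equal(g$ninf, 0.39728719, tolerance = 1e-6)
  expect_equal(g$tm,   36.143049, tolerance = 1e-5)
  expect_equal(g$th,   7.654066, tolerance = 1e-5)
  expect_equal(g$tn,   5.136777, tolerance = 1e-5)
})

test_that("fast Jacobian is singular on the lower fold curve", {
  hh <- hh_default()
  u <- chart_point(hh, p_ref[c(1, 3)])
  expect_lt(abs(det(fast_jacobian(hh, u))), 1e-4)
})

test_that("analytic fast Jacobians agree with finite differences", {
  hh <- hh_default()
  u <- c(-0.55, 0.2, 0.4, 0.38)
  Ja <- fast_jacobian(hh, u)
  Jn <- matrix(0, 2, 2)
  for (j in 1:2) {
    d <- 1e-6
    up <- u; up[j] <- up[j] + d
    um <- u; um[j] <- um[j] - d
    Jn[, j] <- (hh$rhs(up, hh$params, hh$eps)[1:2] -
                hh$rhs(um, hh$params, hh$eps)[1:2]) / (2 * d)
  }
  expect_equal(Ja, Jn, tolerance = 1e-5)
})
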