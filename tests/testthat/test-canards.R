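test_that("SAO counting is stable under refinement on an orbit segment", {
  nf <- nf_default()
  orb <- nf_black_orbit(y0 = -2)
  expect_equal(count_saos(nf, orb), 0L)  # monotone saddle-sheet passage
  # an artificial rotating segment around the fold
  tt <- seq(0, 1, length.out = 401)
  z <- 0.2 * sin(8 * pi * tt) * exp(-tt)
  U <- rbind(-z^2, tt, z, z)
  th <- sao_thresholds(nf)
  expect_equal(canard4d:::count_series_saos(z, th), 4L)
})

test_that("funnel shooting classifies rotation sectors of the normal form", {
  nf <- normal_form_model(mu = 20, eps = 0.01)
  # deep in the jump region: immediate escape with no rotation
  r0 <- canard4d:::funnel_shot(nf, -2.95)
  expect_identical(r0$exit, "up")
  expect_equal(r0$saos, 0L)
  # inside the first rotation sector
  r1 <- canard4d:::funnel_shot(nf, -3.05)
  expect_identical(r1$exit, "up")
  expect_equal(r1$saos, 1L)
  # deeper sector rotates more and escapes later
  r2 <- canard4d:::funnel_shot(nf, -3.15)
  expect_equal(r2$saos, 2L)
  expect_gt(r2$t_exit, r1$t_exit)
})

test_that("canard detection brackets the rotation-sector windows", {
  nf <- normal_form_model(mu = 20, eps = 0.01)
  cd <- detect_canard(nf, 2, scan = c(-3.3, -2.95), n_scan = 25, tol = 1e-7)
  expect_equal(cd$i, 2)
  # frozen regression of this package's window (mu = 20, eps = 0.01)
  expect_equal(cd$window[1], -3.17918, tolerance = 1e-4)
  expect_equal(cd$window[2], -3.08125, tolerance = 1e-4)
  # every interior start shoots with exactly 2 rotations
  mid <- mean(cd$window)
  expect_equal(canard4d:::funnel_shot(nf, mid)$saos, 2L)
})

test_that("ribbons consist of orbits with the bounding twins' SAO count", {
  nf <- normal_form_model(mu = 20, eps = 0.01)
  rb <- compute_ribbon(nf, 2, window = c(-3.165, -3.115), n = 5, N = 80)
  expect_length(rb$orbits, 5)
  expect_true(all(rb$saos == 2L))
  for (o in rb$orbits) expect_s3_class(o, "orbit_segment")
})

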