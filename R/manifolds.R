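#' Named boundary-condition recipes for the built-in models
#'
#' Each recipe fixes the boundary hypersurfaces of one slow-manifold family:
#' the normal-form saddle families start on the w-nullcline (transverse to
#' the stable fast direction) and end on the z-nullcline (transverse to the
#' unstable one), with constraint sections selecting the black, green or
#' orange submanifold; the attracting families run from a line on the
#' attracting sheet to a terminal section.  Hodgkin-Huxley recipes use the
#' m- and v-nullclines and the reference constraint values.
#'
#' @param system a built-in [slow_fast_system()].
#' @param name recipe name: one of `"nf_black"`, `"nf_green"`, `"nf_orange"`,
#'   `"nf_attracting_1"`, `"nf_attracting_2"`, `"nf_attracting_3"`,
#'   `"hh_attracting_1"`, `"hh_attracting_2"`, `"hh_saddle_green"`,
#'   `"hh_saddle_black"`.
#' @return list with `left`, `right` ([hypersurface()]s), `role`, and the
#'   sweep information used for seeding.
#' @export
manifold_recipe <- function(system, name) {
  nf_S0hat <- hypersurface(function(u) u[4] - u[3], desc = "w-nullcline")
  nf_S1hat <- hypersurface(function(u) u[1] + u[3]^2, desc = "z-nullcline")
  hh_f1 <- hypersurface(function(u) system$rhs(u, system$params, system$eps)[1],
                        desc = "v-nullcline")
  hh_f2 <- hypersurface(function(u) system$rhs(u, system$params, system$eps)[2],
                        desc = "m-nullcline")
  onS <- function(u) u[1] + u[3]^2      # normal form: x = -z^2
  switch(name,
    nf_black = list(role = "saddle_slow", anchor = 2L,
      left = hs_and(nf_S0hat, hs_coord(3, 0.1)),
      right = hs_and(nf_S1hat, hs_coord(3, 30)),
      seed = list(chart_from = 0.1, chart_to = 30)),
    nf_green = list(role = "saddle_slow", anchor = 3L,
      left = hs_and(nf_S0hat, hs_coord(2, 0)),
      right = hs_and(nf_S1hat, hs_coord(3, 30)),
      seed = list(chart_from = NA, chart_to = 30)),
    nf_orange = list(role = "saddle_slow", anchor = 3L,
      left = hs_and(nf_S0hat, hs_coord(2, 0)),
      right = hs_and(nf_S1hat, hs_coord(3, 0.1)),
      seed = list(chart_from = NA, chart_to = 0.1)),
    nf_attracting_1 = list(anchor = 2L, role = "attracting_slow",
      left = hypersurface(function(u) u[3] + 30, function(u) onS(u),
                          function(u) u[4] - u[3], desc = "L_a1 on S^a"),
      right = hs_coord(3, -0.1),
      seed = list(z0 = -30)),
    nf_attracting_2 = list(anchor = 2L, role = "attracting_slow",
      left = hypersurface(function(u) u[3] + 30, function(u) onS(u),
                          function(u) u[4] - u[3], desc = "L_a1 on S^a"),
      right = hs_coord(2, 0),
      seed = list(z0 = -30)),
    nf_attracting_3 = list(anchor = 2L, role = "attracting_slow",
      left = hypersurface(function(u) u[3] + 0.1, function(u) onS(u),
                          function(u) u[4] - u[3], desc = "L_a2 on S^a"),
      right = hs_coord(2, 0),
      seed = list(z0 = -0.1)),
    hh_attracting_1 = list(anchor = 1L, role = "attracting_slow",
      left = hypersurface(function(u) u[3] - 0.1,
                          function(u) system$rhs(u, system$params, system$eps)[2],
                          function(u) system$rhs(u, system$params, 0)[1],
                          desc = "L_a1 = {h=0.1} on S^a"),
      right = hs_coord(1, -0.6),
      seed = list(h0 = 0.1)),
    hh_attracting_2 = list(anchor = 3L, role = "attracting_slow",
      left = hypersurface(function(u) u[1] + 0.754,
                          function(u) system$rhs(u, system$params, system$eps)[2],
                          function(u) system$rhs(u, system$params, 0)[1],
                          desc = "L_a2 = {v=-0.754} on S^a"),
      right = hs_coord(1, -0.6),
      seed = list(v0 = -0.754)),
    hh_saddle_green = list(anchor = 3L, role = "saddle_slow",
      left = hs_and(hh_f1, hs_coord(1, -0.55)),
      right = hs_and(hh_f1, hs_coord(1, -0.28)),
      seed = list(v_from = -0.55, v_to = -0.28)),
    hh_saddle_black = list(anchor = 1L, role = "saddle_slow",
      left = hs_and(hh_f2, hs_coord(3, 0.55)),
      right = hs_and(hh_f1, hs_coord(1, -0.28)),
      seed = list(h_from = 0.55, v_to = -0.28)),
    stop("unknown recipe: ", name))
}

# reduced-flow seed on the critical manifold (both models), integrating the
# desingularized chart flow and converting to an orbit segment guess
seed_on_sheet <- function(system, chart0, stop_fn, slow_time_max = 500,
                          N = 100, k = 4, direction = 1) {
  f <- function(t, ch, p) {
    d <- desing_rhs(system, ch)
    # convert desingularized time to slow time where possible: divide by the
    # rescaling factor (positive on the attracting sheet); for seeding only
    # the path matters, so use the desingularized parameterization directly.
    list(direction * d)
  }
  times <- seq(0, slow_time_max, length.out = 20000)
  root <- function(t, ch, p) stop_fn(ch)
  out <- deSolve::lsoda(chart0, times, f, NULL, rtol = 1e-10, atol = 1e-12,
                        rootfunc = root)
  if (nrow(out) < 3) stop("seed path did not develop")
  ch <- out[, 2:3, drop = FALSE]
  pts <- t(apply(ch, 1, function(cc) chart_point(system, cc)))
  # reparameterize by true slow time: dt_slow = |factor| dtau; recover the
  # slow time from the slow components' own equations
  uu <- t(pts)
  ss <- seq(0, 1, length.out = ncol(uu))
  # crude total-time estimate from the slow equation of the first slow var
  islow <- system$slow[1]
  dslow <- diff(uu[islow, ])
  gs <- vapply(seq_len(ncol(uu)), function(i)
    system$rhs(uu[, i], system$params, system$eps)[islow], numeric(1))
  gs[abs(gs) < 1e-12] <- sign(gs[abs(gs) < 1e-12] + 1e-15) * 1e-12
  dt <- dslow / ((gs[-1] + gs[-length(gs)]) / 2)
  dt[dt <= 0 | !is.finite(dt)] <- min(dt[dt > 0 & is.finite(dt)], na.rm = TRUE)
  tt <- c(0, cumsum(dt))
  remesh_series(tt / max(tt), uu, max(tt), system, N = N, k = k)
}

#' Compute an attracting slow manifold as a family of orbit segments
#'
#' Orbit segments start on a line on the attracting sheet of the critical
#' manifold sufficiently far from the fold curve and end on a terminal
#' section transverse to the flow.  The first orbit is seeded by an
#' initial-value solve (attraction makes the seeding trivial); the rest of
#' the family is obtained by pseudo-arclength continuation.
#'
#' @param system a built-in [slow_fast_system()].
#' @param recipe recipe name (see [manifold_recipe()]) or a recipe list.
#' @param n number of continuation steps (family size).
#' @param seed_chart chart coordinates of the seed point on the start line.
#' @param N mesh intervals.
#' @param h0,h_max continuation step sizes.
#' @param ... passed to [continue_family()].
#' @return object of class `manifold_family`.
#' @export
attracting_slow_manifold <- function(system, recipe, n = 20,
                                     seed_chart = NULL, N = 100,
                                     h0 = 0.05, h_max = 2, ...) {
  rec <- if (is.character(recipe)) manifold_recipe(system, recipe) else recipe
  stopifnot(rec$role == "attracting_slow")
  spec <- bvp_spec(rec$left, rec$right)
  if (is.null(seed_chart)) {
    seed_chart <- if (system$name == "normal_form") c(-5, rec$seed$z0)
    else c(rec$seed$v0 %||% -0.7, rec$seed$h0 %||% 0.15)
  }
  u0 <- chart_point(system, seed_chart)
  stop_hs <- rec$right
  ext <- ivp_to_surface(system, u0, stop_hs, tmax = 1e5, direction = 1)
  guess <- remesh_series(abs(ext$t) / max(abs(ext$t)), ext$states,
                         max(abs(ext$t)), system, N = N)
  first <- solve_orbit(system, spec, guess, anchor = rec$anchor %||% 2L)
  run <- continue_family(system, spec, first, n_max = n, h0 = h0,
                         h_max = h_max, ...)
  structure(list(role = "attracting_slow", spec = spec, run = run,
                 recipe = if (is.character(recipe)) recipe else "custom"),
            class = "manifold_family")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# choose the boundary coordinate that varies most freely for anchoring:
# the slow coordinate of u(0) not fixed by the left conditions
best_anchor <- function(guess) 2L

#' Compute a saddle slow manifold as a family of orbit segments
#'
#' Orbit segments enter along the stable fast direction through a section
#' transverse to the stable manifold of the saddle slow manifold and leave
#' along the unstable direction through a section transverse to its unstable
#' manifold; constraint sections select the computed submanifold.  The first
#' orbit is seeded by a singular-limit concatenation (reduced-flow path on
#' the saddle sheet) corrected by Newton.
#'
#' @inheritParams attracting_slow_manifold
#' @param check_transversality verify that the entry/exit sections are
#'   transverse to the fast eigendirections (angle bounded away from 90
#'   degrees by 10 degrees).
#' @return object of class `manifold_family`.
#' @export
saddle_slow_manifold <- function(system, recipe, n = 20, seed_chart = NULL,
                                 N = 100, h0 = 0.05, h_max = 2,
                                 check_transversality = TRUE, ...) {
  rec <- if (is.character(recipe)) manifold_recipe(system, recipe) else recipe
  stopifnot(rec$role == "saddle_slow")
  spec <- bvp_spec(rec$left, rec$right)
  guess <- saddle_seed(system, rec, seed_chart, N)
  if (check_transversality) check_saddle_transversality(system, guess, rec)
  first <- solve_orbit(system, spec, guess, anchor = rec$anchor %||% 2L)
  run <- continue_family(system, spec, first, n_max = n, h0 = h0,
                         h_max = h_max, ...)
  structure(list(role = "saddle_slow", spec = spec, run = run,
                 recipe = if (is.character(recipe)) recipe else "custom"),
            class = "manifold_family")
}

saddle_seed <- function(system, rec, seed_chart, N) {
  if (system$name == "normal_form") {
    z0 <- if (!is.na(rec$seed$chart_from %||% NA)) rec$seed$chart_from else 0.5
    z1 <- rec$seed$chart_to
    y_to <- rec$seed$y_to %||% NULL
    y0 <- if (is.null(seed_chart)) -5 else seed_chart[1]
    # reduced flow on S^s chart (y, z)
    f <- function(t, ch, p) list(slow_chart_rhs(system, ch))
    root <- if (is.null(y_to)) function(t, ch, p) ch[2] - z1
            else function(t, ch, p) ch[1] - y_to
    out <- deSolve::lsoda(c(y0, z0), seq(0, 5000, length.out = 50000), f, NULL,
                          rtol = 1e-10, atol = 1e-12, rootfunc = root)
    ch <- out[, 2:3, drop = FALSE]
    pts <- t(apply(ch, 1, function(cc) chart_point(system, cc)))
    tt <- (out[, 2] - out[1, 2]) / system$eps     # slow y-time over eps
    remesh_series((tt - tt[1]) / (tt[length(tt)] - tt[1]), t(pts),
                  tt[length(tt)] - tt[1], system, N = N)
  } else {
    # HH: reduced (v,h) chart path on the saddle sheet
    ch0 <- seed_chart %||% c(-0.45, 0.35)
    v1 <- rec$seed$v_to
    f <- function(t, ch, p) {
      d <- desing_rhs(system, ch)
      list(-d)   # orientation reversed on the saddle sheet
    }
    root <- function(t, ch, p) ch[1] - v1
    out <- deSolve::lsoda(ch0, seq(0, 5e4, length.out = 50000), f, NULL,
                          rtol = 1e-10, atol = 1e-12, rootfunc = root)
    ch <- out[, 2:3, drop = FALSE]
    pts <- t(apply(ch, 1, function(cc) chart_point(system, cc)))
    uu <- t(pts)
    # recover slow time from the h-equation
    g1 <- vapply(seq_len(ncol(uu)), function(i)
      system$rhs(uu[, i], system$params, system$eps)[3], numeric(1))
    dh <- diff(uu[3, ])
    dt <- dh / ((g1[-1] + g1[-length(g1)]) / 2)
    dt[dt <= 0 | !is.finite(dt)] <- median(abs(dt[is.finite(dt)]))
    tt <- c(0, cumsum(abs(dt)))
    remesh_series(tt / max(tt), uu, max(tt), system, N = N)
  }
}

# true slow flow on the normal-form saddle-sheet chart (y, z)
slow_chart_rhs <- function(system, ch) {
  mu <- system$params[["mu"]]
  y <- ch[1]; z <- ch[2]
  c(1, -(0.5 * mu * y - (mu + 1) * z) / (2 * z))
}

check_saddle_transversality <- function(system, guess, rec, min_angle = 10) {
  M <- ncol(guess$states)
  for (side in c("left", "right")) {
    u <- if (side == "left") guess$states[, 1] else guess$states[, M]
    J <- fast_jacobian(system, u)
    ev <- eigen(J)
    which_dir <- if (side == "left") which.min(Re(ev$values)) else which.max(Re(ev$values))
    vec2 <- Re(ev$vectors[, which_dir])
    vec4 <- numeric(4); vec4[system$fast] <- vec2
    hs <- rec[[side]]
    nrm <- vapply(1:4, function(l) {
      d <- 1e-6 * max(1, abs(u[l]))
      up <- u; up[l] <- up[l] + d
      um <- u; um[l] <- um[l] - d
      (hs$residuals[[1]](up) - hs$residuals[[1]](um)) / (2 * d)
    }, numeric(1))
    ca <- abs(sum(nrm * vec4)) / sqrt(sum(nrm^2) * sum(vec4^2))
    ang <- asin(min(1, ca)) * 180 / pi
    if (ang < min_angle)
      stop(sprintf("%s section nearly tangent to the fast eigendirection (angle %.1f deg)",
                   side, ang))
  }
  invisible(TRUE)
}

#' Family of orbit segments sweeping a fast (un)stable manifold
#'
#' Computes a one-parameter family of orbit segments representing a
#' two-dimensional submanifold of the three-dimensional stable or unstable
#' manifold of the saddle slow manifold, using entry/exit sections
#' constrained by a constant `w` (stable side) or `z` (unstable side), as
#' in the normal-form recipes.
#'
#' @param system the normal-form [slow_fast_system()].
#' @param which `"stable"` or `"unstable"`.
#' @param constant the constraint constant (`w_s` or `z_u`).
#' @param n family size.
#' @param N mesh intervals.
#' @param seed_y y-coordinate used for the seed trajectory.
#' @param ... passed to [continue_family()].
#' @return a `manifold_family`.
#' @export
fast_manifold_slices <- function(system, which = c("stable", "unstable"),
                                 constant, n = 20, N = 120, seed_y = -5, ...) {
  which <- match.arg(which)
  stopifnot(system$name == "normal_form")
  if (which == "stable") {
    left <- hs_and(hypersurface(function(u) u[4] - u[3], desc = "w-nullcline"),
                   hs_coord(4, constant))
    right <- hs_and(hypersurface(function(u) u[1] + u[3]^2, desc = "z-nullcline"),
                    hs_coord(3, 30))
  } else {
    left <- hs_and(hypersurface(function(u) u[4] - u[3], desc = "w-nullcline"),
                   hs_coord(4, 1))
    right <- hs_and(hypersurface(function(u) u[1] + u[3]^2, desc = "z-nullcline"),
                    hs_coord(3, constant))
  }
  spec <- bvp_spec(left, right)
  # seed: saddle-manifold orbit extended backward along the stable direction
  base_rec <- manifold_recipe(system, "nf_black")
  base <- saddle_seed(system, base_rec, c(seed_y, NA), N)
  first <- tryCatch({
    g <- fast_slice_seed(system, which, constant, N)
    solve_orbit(system, spec, g, anchor = 2L)
  }, error = function(e)
    stop("slice constraint appears outside the computed manifold extent: ",
         conditionMessage(e)))
  run <- continue_family(system, spec, first, n_max = n, ...)
  structure(list(role = paste0(which, "_fast"), spec = spec, run = run,
                 recipe = sprintf("nf_%s_slice_%g", which, constant)),
            class = "manifold_family")
}

fast_slice_seed <- function(system, which, constant, N) {
  # integrate from a point displaced from S^s along the fast eigendirection
  if (which == "stable") {
    # backward from near S^s at z in the middle of the range toward w = constant
    z0 <- 5; y0 <- -5
    u0 <- chart_point(system, c(y0, z0))
    u0[4] <- u0[4] + 1e-3 * sign(constant - u0[4])
    stop_w <- hypersurface(function(u) u[4] - constant)
    ext <- ivp_to_surface(system, u0, stop_w, tmax = 50, direction = -1)
    ss <- rev(abs(ext$t)); uu <- ext$states[, rev(seq_len(ncol(ext$states))), drop = FALSE]
    pre <- remesh_series((ss - ss[1]) / (max(ss) - ss[1]), uu, max(ss), system,
                         N = max(10, N %/% 4))
    # then forward along S^s to z = 30
    rec <- manifold_recipe(system, "nf_black")
    main <- saddle_seed(system, list(seed = list(chart_from = z0, chart_to = 30)),
                        c(y0, NA), N)
    glue_orbits(pre, main, system, N)
  } else {
    z1 <- 5; y0 <- -5
    main <- saddle_seed(system, list(seed = list(chart_from = 1, chart_to = z1)),
                        c(y0, NA), N)
    uM <- main$states[, ncol(main$states)]
    uM[1] <- uM[1] + 1e-3
    stop_z <- hypersurface(function(u) u[3] - constant)
    ext <- ivp_to_surface(system, uM, stop_z, tmax = 50, direction = 1)
    post <- remesh_series(abs(ext$t) / max(abs(ext$t)), ext$states,
                          max(abs(ext$t)), system, N = max(10, N %/% 4))
    glue_orbits(main, post, system, N)
  }
}

glue_orbits <- function(a, b, system, N) {
  ta <- a$s * abs(a$T); tb <- abs(a$T) + b$s * abs(b$T)
  tt <- c(ta, tb[-1])
  uu <- cbind(a$states, b$states[, -1, drop = FALSE])
  remesh_series(tt / max(tt), uu, max(tt), system, N = N)
}

#' @export
print.manifold_family <- function(x, ...) {
  cat(sprintf("<manifold_family: %s> recipe '%s', %d orbits, termination %s\n",
              x$role, x$recipe, length(x$run$solutions), x$run$termination))
  invisible(x)
}

#' Orbits of a manifold family
#' @param family a `manifold_family`.
#' @return list of [orbit_segment()]s.
#' @export
family_orbits <- function(family) family$run$solutions

#' Slow-manifold proximity diagnostic
#'
#' Maximum, over the middle portion of an orbit, of the distance-to-critical-
#' manifold residuals.  For the normal form this is
#' \eqn{\max(|x + z^2|, |w - z|)}; for Hodgkin-Huxley the norm of the fast
#' equations' residual.
#'
#' @param system a built-in [slow_fast_system()].
#' @param orbit an [orbit_segment()].
#' @param middle fraction of the orbit (centered) over which to take the max.
#' @return nonnegative scalar.
#' @export
slow_proximity <- function(system, orbit, middle = 0.8) {
  lo <- (1 - middle) / 2; hi <- 1 - lo
  sel <- orbit$s >= lo & orbit$s <= hi
  U <- orbit$states[, sel, drop = FALSE]
  if (system$name == "normal_form") {
    max(pmax(abs(U[1, ] + U[3, ]^2), abs(U[4, ] - U[3, ])))
  } else {
    max(vapply(seq_len(ncol(U)), function(i)
      sqrt(sum(system$rhs(U[, i], system$params, 0)[system$fast]^2)),
      numeric(1)))
  }
}

#' Intersect a family with a section
#'
#' Collects the chosen endpoints of all family orbits, checks that they lie
#' on the section, and returns the ordered section curve.
#'
#' @param family a `manifold_family`.
#' @param section a codimension-one [hypersurface()].
#' @param end `"right"` (u(1), default) or `"left"` (u(0)).
#' @param tol endpoint-on-section tolerance.
#' @return object of class `section_curve` with a `points` matrix (one row
#'   per orbit).
#' @export
section_intersection <- function(family, section, end = c("right", "left"),
                                 tol = 1e-8) {
  end <- match.arg(end)
  pts <- t(vapply(family_orbits(family), function(o) {
    u <- if (end == "right") o$states[, ncol(o$states)] else o$states[, 1]
    u
  }, numeric(4)))
  res <- apply(pts, 1, function(u) abs(section$residuals[[1]](u)))
  if (any(res > tol))
    stop(sprintf("family endpoints are off the section (max residual %.3g); recompute the family with the section as terminal surface",
                 max(res)))
  structure(list(section = section, points = pts, end = end),
            class = "section_curve")
}

#' Minimum gap between two section curves
#'
#' Minimum 4D Euclidean distance between two [section_intersection()]
#' curves, refined by dense linear interpolation along both curves.
#'
#' @param a,b `section_curve` objects.
#' @param refine number of interpolated samples per segment.
#' @return nonnegative scalar.
#' @export
min_gap <- function(a, b, refine = 10) {
  dense <- function(P) {
    if (nrow(P) < 2 || refine <= 1) return(P)
    out <- list()
    for (i in seq_len(nrow(P) - 1)) {
      tfrac <- seq(0, 1, length.out = refine + 1)[-(refine + 1)]
      out[[i]] <- outer(1 - tfrac, P[i, ]) + outer(tfrac, P[i + 1, ])
    }
    rbind(do.call(rbind, out), P[nrow(P), , drop = FALSE])
  }
  A <- dense(a$points); B <- dense(b$points)
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}
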