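#' Default SAO-counting thresholds for the built-in models
#'
#' For the Hodgkin-Huxley model an oscillation is a large-amplitude
#' oscillation (LAO) when its voltage maximum exceeds `lao_level` = -0.2;
#' small-amplitude oscillations (SAOs) are counted as subthreshold local
#' maxima inside the fold window `v` in `[-0.75, -0.25]`.  For the normal
#' form, rotations are counted as local minima of `z` within
#' `[-0.5, 0.5]`.
#'
#' @param system a built-in [slow_fast_system()].
#' @return list of thresholds.
#' @export
sao_thresholds <- function(system) {
  if (system$name == "hodgkin_huxley")
    list(coord = 1L, lao_level = -0.2, window = c(-0.75, -0.25),
         prominence = 1e-4, mode = "maxima")
  else
    list(coord = 3L, lao_level = 0.5, window = c(-0.5, 0.5),
         prominence = 1e-3, mode = "minima")
}

local_extrema <- function(x, mode = c("maxima", "minima")) {
  mode <- match.arg(mode)
  d <- diff(sign(diff(x)))
  if (mode == "maxima") which(d < 0) + 1L else which(d > 0) + 1L
}

#' Count small-amplitude oscillations of a trajectory or orbit segment
#'
#' Counts oscillations of the distinguished coordinate (voltage for
#' Hodgkin-Huxley, `z` for the normal form) inside the fold window that do
#' not reach the LAO level, discarding wiggles below the prominence cutoff.
#' Resolution is validated by refinement: the count is recomputed on a
#' doubled sampling and must agree.
#'
#' @param system a built-in [slow_fast_system()].
#' @param orbit an [orbit_segment()], or a numeric matrix (4 x n) of states.
#' @param thresholds see [sao_thresholds()].
#' @param n_sample dense samples used when `orbit` is an orbit segment.
#' @return integer SAO count.
#' @export
count_saos <- function(system, orbit, thresholds = sao_thresholds(system),
                       n_sample = 4001) {
  count_at <- function(n) {
    U <- if (inherits(orbit, "orbit_segment"))
      orbit_eval(orbit, seq(0, 1, length.out = n)) else orbit
    x <- U[thresholds$coord, ]
    count_series_saos(x, thresholds)
  }
  c1 <- count_at(n_sample)
  if (inherits(orbit, "orbit_segment")) {
    c2 <- count_at(2 * n_sample - 1)
    if (c1 != c2)
      stop(sprintf("unresolved oscillations: SAO count %d vs %d under refinement; refine the mesh",
                   c1, c2))
  }
  c1
}

count_series_saos <- function(x, th) {
  if (th$mode == "maxima") {
    im <- local_extrema(x, "maxima")
    if (!length(im)) return(0L)
    imin <- local_extrema(x, "minima")
    keep <- vapply(im, function(i) {
      prev <- imin[imin < i]
      prom <- if (length(prev)) x[i] - x[max(prev)] else Inf
      x[i] <= th$lao_level && x[i] >= th$window[1] && x[i] <= th$window[2] &&
        prom >= th$prominence
    }, logical(1))
    sum(keep)
  } else {
    im <- local_extrema(x, "minima")
    if (!length(im)) return(0L)
    imax <- local_extrema(x, "maxima")
    keep <- vapply(im, function(i) {
      prev <- imax[imax < i]
      prom <- if (length(prev)) x[max(prev)] - x[i] else Inf
      x[i] >= th$window[1] && x[i] <= th$window[2] && prom >= th$prominence
    }, logical(1))
    sum(keep)
  }
}

# ---------------------------------------------------------------------------
# funnel shooting: the workhorse for canard detection and ribbons

# integrate from a chart point on the start line until the trajectory exits
# the fold region; classify the outcome and count SAOs on the way
funnel_shot <- function(system, start_val, line = NULL, horizon = NULL,
                        thresholds = sao_thresholds(system), keep_path = FALSE) {
  if (system$name == "hodgkin_huxley") {
    v0 <- if (is.null(line)) -0.754 else line
    u0 <- chart_point(system, c(v0, start_val))
    horizon <- horizon %||% 6000
    f <- function(t, u, p) list(system$rhs(u, system$params, system$eps))
    # phase 1: ride the attracting sheet up through v = -0.70
    out1 <- deSolve::lsoda(u0, seq(0, horizon, by = 0.5), f, NULL,
                           rtol = 1e-11, atol = 1e-13,
                           rootfunc = function(t, u, p) u[1] + 0.70,
                           maxsteps = 200000)
    u1 <- as.numeric(out1[nrow(out1), -1])
    t1 <- out1[nrow(out1), 1]
    # phase 2: fold passage; exit up (spike) or back down to the lower sheet
    out2 <- deSolve::lsoda(u1, seq(0, horizon, by = 0.5), f, NULL,
                           rtol = 1e-11, atol = 1e-13,
                           rootfunc = function(t, u, p)
                             c(u[1] + 0.22, u[1] + 0.72),
                           maxsteps = 200000)
    out <- rbind(out1[-nrow(out1), , drop = FALSE],
                 cbind(out2[, 1] + t1, out2[, -1, drop = FALSE]))
    v <- out[, 2]
    vend <- v[length(v)]
    exit <- if (abs(vend + 0.22) < 1e-3) "up"
            else if (abs(vend + 0.72) < 1e-3) "down" else "none"
    saos <- count_series_saos(v, thresholds)
    vmax_follow <- max(v[v < -0.21])
    res <- list(exit = exit, saos = saos, vmax = vmax_follow,
                t_exit = out[nrow(out), 1])
  } else {
    y0 <- start_val
    u0 <- chart_point(system, c(y0, if (is.null(line)) -30 else line))
    horizon <- horizon %||% (80 / system$eps)
    f <- function(t, u, p) list(system$rhs(u, system$params, system$eps))
    root <- function(t, u, p) u[3] - 30    # fast escape upward in z
    out <- deSolve::lsoda(u0, seq(0, horizon,
                                  by = if (keep_path) 0.02 else 0.125),
                          f, NULL, rtol = 1e-11, atol = 1e-13,
                          rootfunc = root, maxsteps = 500000)
    z <- out[, 4]
    exit <- if (z[length(z)] > 29) "up" else "none"
    saos <- count_series_saos(z, thresholds)
    res <- list(exit = exit, saos = saos, zmax = max(z), t_exit = out[nrow(out), 1])
  }
  if (keep_path) res$path <- list(t = out[, 1], states = t(unname(out[, -1])))
  res
}

#' Detect a canard orbit with a prescribed number of SAOs
#'
#' Canard orbits are trajectories that follow the attracting slow manifold,
#' make `i` SAOs near the folded node, and stay close to the saddle slow
#' manifold before leaving via its unstable manifold.  Detection runs the
#' homotopy along the start line on the attracting sheet: the SAO count of
#' the orbit family is a step function of the start coordinate, and the
#' boundaries of the `i`-SAO window are the twin canards (`xi_i`, `xi'_i`),
#' located here by bisection on event-classified shooting (the switch of
#' the exit side of the unstable manifold).  The representative canard is
#' re-converged as a solution of the full canard two-point boundary-value
#' problem when `polish = TRUE`.
#'
#' @param system a built-in [slow_fast_system()].
#' @param i target SAO count.
#' @param scan range of the start-line coordinate to scan (`h` on
#'   `L2a = {v = -0.754}` for Hodgkin-Huxley, `y` on `L1a = {z = -30}` for
#'   the normal form).
#' @param n_scan coarse scan resolution.
#' @param tol bisection tolerance on the start coordinate.
#' @param polish converge the detected orbit under the canard 2PBVP.
#' @param N mesh intervals for the polished orbit.
#' @param polish_n_max continuation steps used by the polish homotopy.
#' @return object of class `canard_orbit`: list with `i`, `start` (the
#'   start coordinate of the representative), `window` (the i-SAO window,
#'   twins at its edges), `vmax` (deepest following), and `orbit` (an
#'   [orbit_segment()]; BVP-converged when `polish`).
#' @export
detect_canard <- function(system, i, scan = NULL, n_scan = 60, tol = 1e-9,
                          polish = FALSE, N = 150, polish_n_max = 60) {
  hh <- system$name == "hodgkin_huxley"
  if (is.null(scan)) scan <- if (hh) c(0.09, 0.25) else c(-8, -0.2)
  g <- seq(scan[1], scan[2], length.out = n_scan)
  shots <- lapply(g, function(s0)
    tryCatch(funnel_shot(system, s0), error = function(e) NULL))
  inwindow <- function(sh) !is.null(sh) && sh$saos == i && sh$exit == "up"
  cnt <- vapply(shots, function(sh) if (is.null(sh)) NA_integer_ else sh$saos,
                integer(1))
  inwin <- which(vapply(shots, inwindow, logical(1)))
  # effective rotation depth: captured (no exit) counts as deeper than any
  # spiking outcome, so the i-band can be found by nested bisection even
  # when it is thinner than the scan spacing
  depth_of <- function(sh) if (is.null(sh)) NA_real_
    else if (sh$exit == "up") sh$saos else Inf
  g_found <- NULL
  if (length(inwin)) {
    g_found <- g[inwin]
  } else {
    dep <- vapply(shots, depth_of, numeric(1))
    ia <- which(dep > i); ib <- which(dep < i)
    if (!length(ia) || !length(ib))
      stop(sprintf("no start value with %d SAOs in the scanned range (counts %s)",
                   i, paste(range(cnt, na.rm = TRUE), collapse = "..")))
    # adjacent deeper/shallower pair
    a <- g[max(ia[ia < min(ib)])]; b <- g[min(ib[ib > max(ia)])]
    degenerate <- FALSE
    for (it in 1:60) {
      mid <- (a + b) / 2
      dm <- depth_of(tryCatch(funnel_shot(system, mid), error = function(e) NULL))
      if (is.na(dm)) break
      if (dm == i) { g_found <- mid; break }
      if (dm > i) a <- mid else b <- mid
      if (abs(b - a) < tol) { degenerate <- TRUE; break }
    }
    if (degenerate) {
      # the i-SAO family is pinched between the deeper (captured) and the
      # shallower (spiking) outcome: the collapsed point is the critical
      # start of the family; represent it by the deep-following orbit on
      # the spiking side
      hstar <- (a + b) / 2
      sh <- funnel_shot(system, b + 2 * tol, keep_path = TRUE)
      orbit <- canard_path_to_orbit(system, sh$path, N = N)
      depth_coord <- if (hh) orbit$states[1, ncol(orbit$states)]
                     else orbit$states[3, ncol(orbit$states)]
      out <- structure(list(i = i, start = hstar, window = c(hstar, hstar),
                            vmax = if (hh) depth_coord else NA_real_,
                            orbit = orbit, polished = FALSE,
                            degenerate = TRUE),
                       class = "canard_orbit")
      if (polish) out <- canard_polish(system, out, n_max = polish_n_max)
      return(out)
    }
    if (is.null(g_found))
      stop(sprintf("no start value with %d SAOs found by nested bisection", i))
  }
  # bisect both edges of the i-SAO window (membership: i SAOs and spike exit)
  edge <- function(lo, hi, want_lo) {
    while (abs(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      ok <- inwindow(tryCatch(funnel_shot(system, mid), error = function(e) NULL))
      if (ok) {
        if (want_lo) hi <- mid else lo <- mid
      } else {
        if (want_lo) lo <- mid else hi <- mid
      }
    }
    (lo + hi) / 2
  }
  glo <- min(g_found); ghi <- max(g_found)
  below <- g[g < glo & !(g %in% g_found)]
  above <- g[g > ghi & !(g %in% g_found)]
  lo_edge <- if (length(below)) edge(max(below), glo, want_lo = TRUE) else glo
  hi_edge <- if (length(above)) edge(min(above), ghi, want_lo = FALSE) else ghi
  win <- sort(c(lo_edge, hi_edge))
  # representative: the deeper-following edge
  sh_lo <- funnel_shot(system, win[1] + 2 * tol, keep_path = TRUE)
  sh_hi <- funnel_shot(system, win[2] - 2 * tol, keep_path = TRUE)
  ob_lo <- canard_path_to_orbit(system, sh_lo$path, N = N)
  ob_hi <- canard_path_to_orbit(system, sh_hi$path, N = N)
  # following depth: coordinate value where the orbit leaves the saddle
  # slow manifold (the exit-section crossing)
  depth <- if (hh) c(ob_lo$states[1, ncol(ob_lo$states)],
                     ob_hi$states[1, ncol(ob_hi$states)])
           else c(ob_lo$states[3, ncol(ob_lo$states)],
                  ob_hi$states[3, ncol(ob_hi$states)])
  pick <- which.max(depth)
  start <- win[pick]
  orbit <- if (pick == 1) ob_lo else ob_hi
  out <- structure(list(i = i, start = start, window = win,
                        vmax = if (hh) depth[pick] else NA_real_,
                        orbit = orbit, polished = FALSE),
                   class = "canard_orbit")
  if (polish) out <- canard_polish(system, out, n_max = polish_n_max)
  out
}

# converge the shooting representative under the open-ended canard family
# (start line -> exit nullcline) and continue it toward deeper following;
# the representative is the deepest-following member (the fold of the
# family in the exit coordinate, where it switches exit side)
canard_polish <- function(system, cd, n_max = 60) {
  hh <- system$name == "hodgkin_huxley"
  if (hh) {
    left <- hypersurface(function(u) u[1] + 0.754,
                         function(u) system$rhs(u, system$params, system$eps)[2],
                         function(u) system$rhs(u, system$params, 0)[1],
                         desc = "L2a on S^a")
    right <- hypersurface(function(u)
      system$rhs(u, system$params, system$eps)[1], desc = "v-nullcline")
  } else {
    left <- hypersurface(function(u) u[3] + 30,
                         function(u) u[1] + u[3]^2,
                         function(u) u[4] - u[3], desc = "L1a on S^a")
    right <- hs_coord(3, 30)
  }
  spec <- bvp_spec(left, right)
  first <- tryCatch(solve_orbit(system, spec, cd$orbit, anchor = "T",
                                tol = 1e-8, maxit = 20),
                    error = function(e) NULL)
  if (is.null(first)) {
    warning("canard BVP polish did not converge; returning the shooting orbit")
    return(cd)
  }
  # monitor driving the homotopy: for HH the exit voltage (deep following
  # raises it); for the normal form the residual of the far section of the
  # saddle sheet, psi = x(1) + z(1)^2, whose zero is the canard
  exit_coord <- if (hh) function(o) o$states[1, ncol(o$states)]
    else function(o) o$states[1, ncol(o$states)] + o$states[3, ncol(o$states)]^2
  if (hh) {
    # the deepening direction along the family is hard to probe reliably;
    # sweep both ways and keep the member spending longest near the saddle
    # slow manifold (the maximum of |T|)
    # orient the homotopy so the exit point climbs the nullcline (deeper
    # following); the representative is the local maximum of T along it
    run <- tryCatch(continue_family(system, spec, first,
                                    monitors = list(exit = exit_coord),
                                    n_max = n_max, h0 = 1e-3, h_max = 0.03,
                                    direction = 1,
                                    tangent_coord = list(what = "u1", index = 1L),
                                    tol = 1e-8),
                    error = function(e) NULL)
    sols <- if (!is.null(run)) run$solutions else list(first)
    Ts <- vapply(sols, function(o) abs(o$T), numeric(1))
    cd$orbit <- sols[[which.max(Ts)]]
    cd$vmax <- exit_coord(cd$orbit)
    cd$polished <- TRUE
    return(cd)
  }
  # normal form: walk toward the deeper-rotation edge of the band
  # (decreasing y on the start line), whose bounding canard is xi_i
  probe <- tryCatch(continue_family(system, spec, first, n_max = 4,
                                    h0 = 0.01, h_max = 0.05,
                                    direction = 1, tol = 1e-8),
                    error = function(e) NULL)
  dir <- 1
  if (!is.null(probe) && length(probe$solutions) > 1) {
    last <- probe$solutions[[length(probe$solutions)]]
    if (last$states[2, 1] > first$states[2, 1]) dir <- -1
  }
  run <- tryCatch(continue_family(system, spec, first,
                                  monitors = list(exit = exit_coord),
                                  stop_fn = function(o) sign(exit_coord(o)) !=
                                      sign(exit_coord(first)),
                                  n_max = 4 * n_max,
                                  h0 = 1e-3, h_max = 5,
                                  direction = dir, tol = 1e-8),
                  error = function(e) NULL)
  # the refined psi = 0 event is the canard; without it the polish failed
  if (is.null(run) || !length(run$events)) {
    warning("canard homotopy found no psi = 0 event; returning the shooting orbit")
    return(cd)
  }
  cd$orbit <- run$events[[1]]$orbit
  cd$polished <- TRUE
  cd
}

#' @export
print.canard_orbit <- function(x, ...) {
  cat(sprintf("<canard_orbit xi_%d> start = %.9f (window width %.2e)%s\n",
              x$i, x$start, diff(x$window),
              if (x$polished) " [BVP-converged]" else ""))
  if (is.finite(x$vmax)) cat(sprintf("  deepest following v-max = %.4f\n", x$vmax))
  invisible(x)
}

# the canard 2PBVP: u(0) on the start line (on the critical manifold),
# u(1) on the exit section transverse to the unstable fast directions
canard_bvp_spec <- function(system, free = "T") {
  if (system$name == "hodgkin_huxley") {
    left <- hypersurface(function(u) u[1] + 0.754,
                         function(u) system$rhs(u, system$params, system$eps)[2],
                         function(u) system$rhs(u, system$params, 0)[1],
                         desc = "L2a on S^a")
    right <- hs_and(hypersurface(function(u)
      system$rhs(u, system$params, system$eps)[1], desc = "v-nullcline"),
      hs_coord(1, -0.28))
  } else {
    left <- hypersurface(function(u) u[3] + 30,
                         function(u) u[1] + u[3]^2,
                         function(u) u[4] - u[3], desc = "L1a on S^a")
    right <- hs_and(hypersurface(function(u) u[1] + u[3]^2, desc = "z-nullcline"),
                    hs_coord(3, 30))
  }
  bvp_spec(left, right, free = free)
}

# truncate a shooting path at the canard exit section and build an orbit
canard_path_to_orbit <- function(system, path, N = 150) {
  U <- path$states
  tt <- path$t
  if (system$name == "hodgkin_huxley") {
    # cut at the last crossing of the v-nullcline before the exit
    f1 <- vapply(seq_len(ncol(U)), function(j)
      system$rhs(U[, j], system$params, system$eps)[1], numeric(1))
    cross <- which(diff(sign(f1)) != 0)
    vmaxi <- which.max(ifelse(U[1, ] < -0.21, U[1, ], -Inf))
    cross <- cross[cross <= vmaxi + 5]
    icut <- if (length(cross)) cross[length(cross)] else ncol(U) - 1
  } else {
    # cut at the first crossing of z = 30 (the far constraint section)
    zhi <- which(U[3, ] >= 30)
    icut <- if (length(zhi)) max(2, min(zhi) - 1) else ncol(U) - 1
  }
  keep <- seq_len(icut + 1)
  remesh_series(tt[keep] / tt[icut + 1], U[, keep, drop = FALSE],
                tt[icut + 1], system, N = N)
}

#' Continue a canard orbit in a system parameter
#'
#' Pseudo-arclength continuation of the canard 2PBVP in `eps`, `mu` or `I`.
#' The branch is truncated (not an error) when the arclength step
#' collapses; the terminal behavior is classified as reaching the lower
#' parameter bound (`reaches_singular_limit`), a norm blow-up at a finite
#' parameter value (`asymptote_at_finite_eps`), or a fold in the branch.
#'
#' @param system a built-in [slow_fast_system()].
#' @param canard a `canard_orbit` with a BVP-converged orbit, or an
#'   [orbit_segment()] satisfying the canard 2PBVP.
#' @param par_name `"eps"`, `"mu"` or `"I"`.
#' @param range admissible parameter interval.
#' @param direction initial direction (+1/-1) in the parameter.
#' @param n_max maximum continuation steps.
#' @param h0,h_max arclength step sizes.
#' @param verbose print progress.
#' @return object of class `canard_branch` with `par`, `l2`, `T`,
#'   `solutions` and `terminal` tag.
#' @export
continue_canard <- function(system, canard, par_name, range,
                            direction = -1, n_max = 150, h0 = 1e-3,
                            h_max = 0.5, log_scale = (par_name == "eps"),
                            verbose = FALSE) {
  orbit <- if (inherits(canard, "canard_orbit")) canard$orbit else canard
  # eps branches approach the singular limit over several decades, so they
  # are continued in log(eps) by default
  to_int <- if (log_scale) log else identity
  from_int <- if (log_scale) exp else identity
  set_par <- function(sys, nm, val) {
    v <- from_int(val)
    if (nm == "eps") { sys$eps <- v; sys }
    else do.call(set_params, c(list(system = sys),
                               structure(list(v), names = nm)))
  }
  spec <- canard_bvp_spec(system, free = c("T", par_name))
  spec$set_par <- set_par
  if (par_name == "eps") orbit$eps <- system$eps
  parv0 <- if (par_name == "eps") system$eps else system$params[[par_name]]
  orbit$free <- stats::setNames(c(orbit$T, to_int(parv0)), c("T", par_name))
  stopf <- function(o) {
    p <- from_int(o$free[[par_name]])
    p < min(range) || p > max(range)
  }
  run <- continue_family(system, spec, orbit,
                         monitors = list(par = function(o)
                           from_int(o$free[[par_name]])),
                         stop_fn = stopf, n_max = n_max, h0 = h0,
                         h_max = h_max, direction = direction,
                         tangent_coord = list(what = "free",
                                              index = match(par_name, spec$free)),
                         verbose = verbose)
  par <- vapply(run$solutions, function(o) from_int(o$free[[par_name]]),
                numeric(1))
  l2 <- vapply(run$solutions, l2_norm, numeric(1))
  nlast <- length(par)
  terminal <- if (run$termination == "stop_condition") "reaches_limit"
  else if (run$termination == "step_collapse") {
    if (nlast > 4 && l2[nlast] > 2 * l2[1] &&
        abs(par[nlast] - par[nlast - 1]) < 1e-6) "asymptote_at_finite_eps"
    else if (nlast > 4 && sign(diff(par)[nlast - 1]) != sign(diff(par)[1]))
      "fold" else "step_collapse"
  } else run$termination
  structure(list(par_name = par_name, par = par, l2 = l2,
                 T = vapply(run$solutions, function(o) o$T, numeric(1)),
                 solutions = run$solutions, terminal = terminal,
                 i = if (inherits(canard, "canard_orbit")) canard$i else NA),
            class = "canard_branch")
}

#' @export
print.canard_branch <- function(x, ...) {
  cat(sprintf("<canard_branch xi_%s in %s> %d solutions, %s in [%.3g, %.3g], terminal: %s\n",
              format(x$i), x$par_name, length(x$par), x$par_name,
              min(x$par), max(x$par), x$terminal))
  invisible(x)
}

#' Compute a ribbon of the extended attracting slow manifold
#'
#' A ribbon `R_i` is the strip of the attracting slow manifold whose
#' trajectories all make `i` SAOs; it is bounded by the twin canard orbits
#' `xi_i` and `xi'_i` (the edges of the i-SAO window on the start line).
#'
#' @param system a built-in [slow_fast_system()].
#' @param i SAO count of the ribbon.
#' @param window optional precomputed window (from [detect_canard()]).
#' @param n number of interior orbits.
#' @param N mesh intervals per stored orbit.
#' @return object of class `ribbon`: `i`, `window`, `orbits` (list of
#'   orbit segments), `saos` (their verified counts).
#' @export
compute_ribbon <- function(system, i, window = NULL, n = 10, N = 120) {
  if (is.null(window)) {
    cd <- detect_canard(system, i)
    window <- cd$window
  }
  pad <- diff(window) * 0.02
  starts <- seq(window[1] + pad, window[2] - pad, length.out = n)
  orbits <- list(); saos <- integer(0)
  for (s0 in starts) {
    sh <- funnel_shot(system, s0, keep_path = TRUE)
    orbits[[length(orbits) + 1L]] <- canard_path_to_orbit(system, sh$path, N = N)
    saos <- c(saos, sh$saos)
  }
  if (!all(saos == i))
    warning(sprintf("ribbon interior contains counts %s (expected %d)",
                    paste(unique(saos), collapse = ","), i))
  structure(list(i = i, window = window, starts = starts, orbits = orbits,
                 saos = saos), class = "ribbon")
}

# ---------------------------------------------------------------------------
# MMO signatures by simulation

#' MMO signature of the attractor from simulation
#'
#' Integrates the model, discards a transient, detects periodicity by
#' recurrence on the Poincare section (`v = -0.4`, increasing, for
#' Hodgkin-Huxley), and returns the mixed-mode signature `L^s` of one
#' period: `L` large-amplitude oscillations followed by `s`
#' small-amplitude oscillations, in canonical (lexicographically minimal)
#' rotation.
#'
#' @param system a built-in [slow_fast_system()].
#' @param ic initial 4-vector; default: a funnel point on the lower
#'   attracting sheet.
#' @param transient time discarded before analysis.
#' @param window analysis time window after the transient.
#' @param thresholds see [sao_thresholds()].
#' @param section_v Poincare level on the voltage coordinate.
#' @param rec_tol recurrence tolerance for periodicity detection.
#' @return object of class `mmo_signature`: list of blocks `(L, s)` plus
#'   attributes; `format()` renders e.g. `"1^6"`.  Aperiodic windows are
#'   tagged `aperiodic = TRUE`.
#' @export
attractor_signature <- function(system, ic = NULL, transient = 50000,
                                window = 40000,
                                thresholds = sao_thresholds(system),
                                section_v = -0.4, rec_tol = 1e-3) {
  stopifnot(system$name == "hodgkin_huxley")
  if (is.null(ic)) ic <- chart_point(system, c(-0.754, 0.1358))
  f <- function(t, u, p) list(system$rhs(u, system$params, system$eps))
  # transient in chunks to bound memory
  u <- ic
  done <- 0
  while (done < transient) {
    step <- min(25000, transient - done)
    out <- deSolve::lsoda(u, c(0, step), f, NULL, rtol = 1e-10, atol = 1e-12,
                          maxsteps = 500000)
    u <- as.numeric(out[nrow(out), -1])
    done <- done + step
  }
  out <- deSolve::lsoda(u, seq(0, window, by = 0.25), f, NULL,
                        rtol = 1e-10, atol = 1e-12, maxsteps = 2000000)
  tt <- out[, 1]; U <- t(unname(out[, -1]))
  v <- U[1, ]
  # Poincare crossings: v through section_v, increasing
  up <- which(v[-length(v)] < section_v & v[-1] >= section_v)
  if (length(up) < 2)
    return(structure(list(), class = "mmo_signature", aperiodic = TRUE,
                     reason = "fewer than two section crossings"))
  # recurrence: match later crossings to the first
  ref <- U[, up[1]]
  dist <- vapply(up[-1], function(j) sqrt(sum((U[, j] - ref)^2)), numeric(1))
  per_idx <- which(dist < rec_tol)[1]
  if (is.na(per_idx))
    return(structure(list(), class = "mmo_signature", aperiodic = TRUE,
                     reason = "no recurrence within tolerance"))
  j0 <- up[1]; j1 <- up[per_idx + 1]
  vseg <- v[j0:j1]
  im <- local_extrema(vseg, "maxima")
  imin <- local_extrema(vseg, "minima")
  lao <- vapply(im, function(k) vseg[k] > thresholds$lao_level, logical(1))
  promin <- vapply(seq_along(im), function(q) {
    prev <- imin[imin < im[q]]
    if (length(prev)) vseg[im[q]] - vseg[max(prev)] else Inf
  }, numeric(1))
  keep <- lao | (promin >= thresholds$prominence &
                   vseg[im] >= thresholds$window[1] &
                   vseg[im] <= thresholds$window[2])
  lab <- lao[keep]
  blocks <- rle(lab)
  Ls <- blocks$lengths[blocks$values]
  ss <- blocks$lengths[!blocks$values]
  if (!length(Ls))
    return(structure(list(), class = "mmo_signature", aperiodic = TRUE,
                     reason = "no LAO in the window"))
  # pair L-blocks with following s-blocks
  sig <- list()
  li <- which(blocks$values)
  for (q in seq_along(li)) {
    snext <- if (q < length(li) || li[q] < length(blocks$values))
      blocks$lengths[li[q] + 1] else 0L
    if (li[q] + 1 > length(blocks$values)) snext <- 0L
    sig[[q]] <- c(L = blocks$lengths[li[q]], s = snext)
  }
  sig <- canonical_rotation(sig)
  structure(sig, class = "mmo_signature", aperiodic = FALSE,
            period = tt[j1] - tt[j0])
}

canonical_rotation <- function(sig) {
  if (length(sig) <= 1) return(sig)
  keys <- vapply(seq_along(sig), function(r) {
    rot <- c(sig[r:length(sig)], sig[seq_len(r - 1)])
    paste(vapply(rot, function(b)
      sprintf("%03d.%03d", as.integer(b[1]), as.integer(b[2])),
      character(1)), collapse = "|")
  }, character(1))
  r <- order(keys)[1]
  c(sig[r:length(sig)], sig[seq_len(r - 1)])
}

#' @export
format.mmo_signature <- function(x, ...) {
  if (isTRUE(attr(x, "aperiodic"))) return("aperiodic")
  paste(vapply(x, function(b) sprintf("%d^%d", b[1], b[2]), character(1)),
        collapse = " ")
}

#' @export
print.mmo_signature <- function(x, ...) {
  cat("<mmo_signature>", format(x), "\n")
  if (!isTRUE(attr(x, "aperiodic")))
    cat("  period:", format(attr(x, "period")), "\n")
  invisible(x)
}
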