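#' Continue the equilibrium branch in a parameter
#'
#' Tracks the equilibrium of the system over a parameter range, computing
#' the four eigenvalues at each point, and locates Hopf bifurcations by
#' refining sign changes of the real part of the leading complex pair to
#' `1e-6` in the parameter by bisection.
#'
#' @param system a [slow_fast_system()].
#' @param par_name continuation parameter (must exist in `system$params`).
#' @param range numeric length-2 parameter interval.
#' @param n number of scan points.
#' @return object of class `equilibrium_branch`: data frame `points` with
#'   the parameter, state, eigenvalues and leading complex real part, and a
#'   data frame `hopf` with refined Hopf events (`par`, `omega`, `state`).
#' @export
continue_equilibria <- function(system, par_name = "I", range = c(0, 200),
                                n = 201) {
  eq_at <- function(val) {
    sys <- do.call(set_params, c(list(system = system),
                                 structure(list(val), names = par_name)))
    eqs <- full_equilibria(sys)
    if (!length(eqs)) return(NULL)
    eqs[[1]]
  }
  lead_re <- function(eq) {
    cp <- eq$eigenvalues[abs(Im(eq$eigenvalues)) > 1e-12]
    if (!length(cp)) return(NA_real_)
    Re(cp[which.max(Re(cp))])
  }
  vals <- seq(range[1], range[2], length.out = n)
  eqs <- lapply(vals, eq_at)
  keep <- !vapply(eqs, is.null, logical(1))
  vals <- vals[keep]; eqs <- eqs[keep]
  lre <- vapply(eqs, lead_re, numeric(1))
  hopf <- list()
  idx <- which(diff(sign(lre)) != 0 & is.finite(lre[-length(lre)]) &
                 is.finite(lre[-1]))
  for (i in idx) {
    lo <- vals[i]; hi <- vals[i + 1]
    flo <- lre[i]
    while (hi - lo > 1e-7) {
      mid <- (lo + hi) / 2
      fm <- lead_re(eq_at(mid))
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    par_star <- (lo + hi) / 2
    eq <- eq_at(par_star)
    cp <- eq$eigenvalues[abs(Im(eq$eigenvalues)) > 1e-12]
    omega <- abs(Im(cp[which.max(Re(cp))]))
    hopf[[length(hopf) + 1L]] <-
      list(par = par_star, omega = omega, state = eq$location)
  }
  pts <- data.frame(par = vals,
                    t(vapply(eqs, function(e) e$location, numeric(4))),
                    lead_re = lre)
  names(pts)[2:5] <- system$var_names
  structure(list(par_name = par_name, points = pts, hopf = hopf),
            class = "equilibrium_branch")
}

#' @export
print.equilibrium_branch <- function(x, ...) {
  cat(sprintf("<equilibrium_branch in %s> %d points, %d Hopf events\n",
              x$par_name, nrow(x$points), length(x$hopf)))
  for (h in x$hopf)
    cat(sprintf("  Hopf at %s = %.6f (omega = %.5g)\n", x$par_name, h$par,
                h$omega))
  invisible(x)
}

# ---------------------------------------------------------------------------
# periodic orbits by collocation

# internal spec for periodic problems: no boundary hypersurfaces; the
# periodicity and phase conditions are supplied as extra rows
periodic_spec <- function(par_name, set_par = NULL) {
  structure(list(left = NULL, right = NULL,
                 free = c("T", par_name), family_dim = 1L,
                 set_par = set_par, periodic = TRUE),
            class = "bvp_spec")
}

periodic_extra_rows <- function(ref, nX, basis) {
  M <- ncol(ref$states)
  k <- ref$k
  mesh <- ref$mesh
  # derivative of the reference orbit on the fine grid (per ds)
  refp <- matrix(0, 4, M)
  lm <- lagrange_matrices(seq(0, 1, length.out = k + 1),
                          seq(0, 1, length.out = k + 1))
  N <- length(mesh) - 1
  for (i in seq_len(N)) {
    h <- mesh[i + 1] - mesh[i]
    cols <- ((i - 1) * k + 1):(i * k + 1)
    dU <- ref$states[, cols, drop = FALSE] %*% t(lm$D) / h
    refp[, cols] <- dU   # right-end value overwritten by next interval
  }
  # trapezoid weights on the fine grid
  w <- numeric(M)
  ds <- diff(ref$s)
  w[1] <- ds[1] / 2; w[M] <- ds[M - 1] / 2
  if (M > 2) w[2:(M - 1)] <- (ds[-1] + ds[-(M - 1)]) / 2
  phase_coef <- as.numeric(refp * rep(w, each = 4))
  rows <- list()
  for (d in 1:4) {
    local({
      dd <- d
      rows[[length(rows) + 1L]] <<- list(
        F = function(p) p$u1[dd] - p$u0[dd],
        J = function(p) {
          g <- numeric(nX)
          g[dd] <- -1
          g[(p$M - 1) * 4 + dd] <- 1
          g
        })
    })
  }
  ref_states <- ref$states
  rows[[length(rows) + 1L]] <- list(
    F = function(p) sum(phase_coef * as.numeric(p$states - ref_states)),
    J = function(p) c(phase_coef, numeric(nX - length(phase_coef))))
  rows
}

#' Floquet multipliers of a periodic collocation solution
#'
#' Computes the monodromy matrix by interval-wise condensation of the
#' linearized collocation equations and returns its eigenvalues.  One
#' multiplier equals 1 up to discretization error.
#'
#' @param system a [slow_fast_system()].
#' @param orbit a converged periodic [orbit_segment()] (period `T`).
#' @return complex eigenvalues sorted by decreasing modulus.
#' @export
floquet_multipliers <- function(system, orbit) {
  basis <- get_basis(orbit$k)
  k <- orbit$k
  mesh <- orbit$mesh
  N <- length(mesh) - 1
  Mmat <- diag(4)
  P <- basis$P; D <- basis$D
  for (i in seq_len(N)) {
    h <- mesh[i + 1] - mesh[i]
    cols <- ((i - 1) * k + 1):(i * k + 1)
    U <- orbit$states[, cols, drop = FALSE]
    Ug <- U %*% t(P)
    A <- matrix(0, 4 * k, 4 * k)
    B <- matrix(0, 4 * k, 4)
    for (g in seq_len(k)) {
      Jg <- full_jacobian(sys_of(system, orbit), Ug[, g])
      rbase <- (g - 1) * 4
      for (j in 1:(k + 1)) {
        Blk <- -orbit$T * P[g, j] * Jg
        diag(Blk) <- diag(Blk) + D[g, j] / h
        if (j == 1) B[rbase + 1:4, ] <- -Blk
        else A[rbase + 1:4, (j - 2) * 4 + 1:4] <- Blk
      }
    }
    Y <- solve(A, B)
    Mi <- Y[(k - 1) * 4 + 1:4, , drop = FALSE]
    Mmat <- Mi %*% Mmat
  }
  ev <- eigen(Mmat, only.values = TRUE)$values
  ev[order(-Mod(ev))]
}

# system with the orbit's parameter snapshot applied
sys_of <- function(system, orbit) {
  sys <- system
  if (!is.null(orbit$params)) sys$params <- orbit$params
  if (is.finite(orbit$eps)) sys$eps <- orbit$eps
  sys
}

#' Start a small-amplitude periodic orbit near a Hopf point
#'
#' Builds the analytic small-amplitude predictor from the Hopf eigenvector
#' and converges it to a genuine periodic solution with the parameter free.
#'
#' @param system a [slow_fast_system()].
#' @param par_name bifurcation parameter name.
#' @param hopf one Hopf event from [continue_equilibria()].
#' @param amplitude initial amplitude of the predictor.
#' @param N mesh intervals.
#' @return converged periodic [orbit_segment()] with `free` containing the
#'   parameter value.
#' @export
hopf_start <- function(system, par_name, hopf, amplitude = 1e-3, N = 40) {
  sys <- do.call(set_params, c(list(system = system),
                               structure(list(hopf$par), names = par_name)))
  J <- full_jacobian(sys, hopf$state)
  e <- eigen(J)
  icx <- which(abs(Im(e$values)) > 1e-12)
  icx <- icx[which.max(Re(e$values[icx]))]
  q <- e$vectors[, icx]
  q <- q / sqrt(sum(Mod(q)^2))
  omega <- abs(Im(e$values[icx]))
  Tper <- 2 * pi / omega
  mesh <- seq(0, 1, length.out = N + 1)
  sfine <- fine_grid(mesh, 4)
  states <- vapply(sfine, function(s)
    hopf$state + amplitude * (Re(q) * cos(2 * pi * s) - Im(q) * sin(2 * pi * s)),
    numeric(4))
  guess <- orbit_segment(mesh, states, Tper, sys)
  spec <- periodic_spec(par_name)
  basis <- get_basis(4)
  nX <- 4 * ncol(states) + 2
  extra <- periodic_extra_rows(guess, nX, basis)
  # anchor the amplitude: fix the first state component of u(0)
  amp_row <- list(F = function(p) p$u0[1] - states[1, 1],
                  J = function(p) { g <- numeric(nX); g[1] <- 1; g })
  res <- newton_colloc(sys, spec, mesh, orbit_to_X(guess, spec), basis,
                       c(extra, list(amp_row)), tol = 1e-9, maxit = 15)
  if (!res$converged)
    stop(sprintf("Hopf predictor did not converge (residual %.3g)", res$residual))
  X_to_orbit(res$X, mesh, spec, sys, 4, res$residual)
}

#' Continue a branch of periodic orbits in a parameter
#'
#' Pseudo-arclength continuation of the periodic two-point boundary-value
#' problem (periodicity conditions plus integral phase condition, period
#' free) with Floquet multipliers computed from the collocation monodromy at
#' every step.  Period-doubling events (a real multiplier crossing -1) and
#' branch points (sign change of the bordered-Jacobian determinant) are
#' detected and refined on the arclength.
#'
#' @param system a [slow_fast_system()].
#' @param start a converged periodic [orbit_segment()] (e.g. from
#'   [hopf_start()] or [double_period_start()]).
#' @param par_name continuation parameter.
#' @param par_range admissible parameter interval; the run stops on exit.
#' @param n_max maximum continuation steps.
#' @param direction initial branch direction (+1/-1) along the parameter.
#' @param h0,h_min,h_max arclength step bounds.
#' @param detect events to watch: subset of `c("PD", "BP")`.
#' @param adapt re-mesh every this many steps (0 = never).
#' @param stop_fn optional `function(orbit, par_history)` returning `TRUE`
#'   to terminate the run early.
#' @param verbose print progress.
#' @return object of class `periodic_branch` with `solutions`, `par`
#'   values, `period`, `l2`, `multipliers`, `stable` flags and `events`.
#' @export
continue_periodic <- function(system, start, par_name, par_range,
                              n_max = 200, direction = -1,
                              h0 = 1e-3, h_min = 1e-10, h_max = 0.5,
                              detect = c("PD"), adapt = 0, stop_fn = NULL,
                              verbose = FALSE) {
  spec <- periodic_spec(par_name)
  basis <- get_basis(start$k)
  mesh <- start$mesh
  M <- ncol(start$states)
  nX <- 4 * M + 2
  wts <- c(rep(1 / sqrt(4 * M), 4 * M), 1 / max(1, abs(start$T)), 1)
  sol <- start
  X <- orbit_to_X(sol, spec)
  par_idx <- 4 * M + 2

  solve_step <- function(Xpred, tau, Xbase, h, ref) {
    extra <- periodic_extra_rows(ref, nX, basis)
    arc <- list(
      F = function(p) sum((c(as.numeric(p$states), p$free) - Xbase) *
                            tau * wts^2) - h,
      J = function(p) tau * wts^2)
    newton_colloc(system, spec, mesh, Xpred, basis, c(extra, list(arc)),
                  tol = 1e-8, maxit = 10)
  }
  tangent <- function(X, ref, tau_prev = NULL) {
    extra <- periodic_extra_rows(ref, nX, basis)
    as_ <- assemble_colloc(system, spec, mesh, X, basis, extra)
    norm_row <- if (is.null(tau_prev)) {
      g <- numeric(nX); g[par_idx] <- 1; g
    } else tau_prev * wts^2
    Jb <- rbind(as_$J,
                Matrix::sparseMatrix(i = rep(1, sum(norm_row != 0)),
                                     j = which(norm_row != 0),
                                     x = norm_row[norm_row != 0],
                                     dims = c(1, nX)))
    tau <- as.numeric(Matrix::solve(Jb, c(rep(0, nrow(as_$J)), 1)))
    tau / sqrt(sum((tau * wts)^2))
  }
  bordered_det_sign <- function(X, ref, tau) {
    extra <- periodic_extra_rows(ref, nX, basis)
    as_ <- assemble_colloc(system, spec, mesh, X, basis, extra)
    Jb <- rbind(as_$J,
                Matrix::sparseMatrix(i = rep(1, nX), j = seq_len(nX),
                                     x = tau * wts^2, dims = c(1, nX)))
    dd <- Matrix::determinant(Jb, logarithm = TRUE)
    as.numeric(dd$sign)
  }
  pd_test <- function(mults) {
    # continuous period-doubling test function: product of (mu + 1) over the
    # nontrivial multipliers; changes sign exactly when a real multiplier
    # crosses -1 (complex pairs contribute |mu+1|^2 > 0)
    nontriv <- mults[-which.min(Mod(mults - 1))]
    Re(prod(nontriv + 1))
  }

  tau <- tangent(X, sol)
  if (sign(tau[par_idx]) != sign(direction)) tau <- -tau
  sols <- list(sol)
  mults <- list(floquet_multipliers(system, sol))
  pdv <- pd_test(mults[[1]])
  bps <- if ("BP" %in% detect) bordered_det_sign(X, sol, tau) else NA
  events <- list()
  h <- h0
  termination <- "n_max"
  for (step in seq_len(n_max)) {
    accepted <- FALSE
    while (!accepted) {
      res <- tryCatch(solve_step(X + h * tau, tau, X, h, sols[[length(sols)]]),
                      error = function(e) NULL)
      if (!is.null(res) && res$converged) { accepted <- TRUE; break }
      h <- h / 2
      if (h < h_min) break
    }
    if (!accepted) { termination <- "step_collapse"; break }
    Xn <- res$X
    orb <- X_to_orbit(Xn, mesh, spec, system, start$k, res$residual)
    mu_n <- floquet_multipliers(system, orb)
    pdv_n <- pd_test(mu_n)
    sols[[length(sols) + 1L]] <- orb
    mults[[length(mults) + 1L]] <- mu_n
    # event: period doubling
    if ("PD" %in% detect && is.finite(pdv) && is.finite(pdv_n) &&
        sign(pdv) != sign(pdv_n)) {
      ev <- refine_periodic_event(system, spec, mesh, basis, X, tau, h, wts,
                                  function(o) pd_test(floquet_multipliers(system, o)),
                                  sols[[length(sols) - 1L]], start$k)
      if (!is.null(ev))
        events[[length(events) + 1L]] <- list(type = "PD", orbit = ev,
                                              par = ev$free[[2]])
    }
    tau_n <- tryCatch(tangent(Xn, orb, tau), error = function(e) tau)
    if (sum(tau_n * tau * wts^2) < 0) tau_n <- -tau_n
    # event: branch point via determinant sign of the bordered Jacobian
    if ("BP" %in% detect) {
      bps_n <- bordered_det_sign(Xn, orb, tau_n)
      if (is.finite(bps) && is.finite(bps_n) && bps_n != bps) {
        ev <- refine_periodic_event(system, spec, mesh, basis, X, tau, h, wts,
                                    function(o) {
                                      Xo <- orbit_to_X(o, spec)
                                      bordered_det_sign(Xo, o, tau)
                                    }, sols[[length(sols) - 1L]], start$k,
                                    max_iter = 12)
        events[[length(events) + 1L]] <-
          list(type = "BP", orbit = ev %||% orb,
               par = (ev %||% orb)$free[[2]])
      }
      bps <- bps_n
    }
    X <- Xn; tau <- tau_n; pdv <- pdv_n
    parv <- orb$free[[2]]
    if (verbose)
      message(sprintf("step %d: %s = %.6f, T = %.4f, h = %.3g", step,
                      par_name, parv, orb$T, h))
    if (parv < min(par_range) || parv > max(par_range)) {
      termination <- "range"; break
    }
    if (!is.null(stop_fn) &&
        isTRUE(stop_fn(orb, vapply(sols, function(o) o$free[[2]], numeric(1))))) {
      termination <- "stop_condition"; break
    }
    if (res$iter <= 4) h <- min(h * 1.5, h_max)
    if (adapt > 0 && step %% adapt == 0) {
      orb2 <- adapt_mesh(orb)
      # keep the same mesh object size; refit X on the new mesh
      mesh <- orb2$mesh
      X <- orbit_to_X(orb2, spec)
      X[4 * M + 1:2] <- c(orb$T, parv)
      res2 <- tryCatch(newton_colloc(system, spec, mesh, X, basis,
                                     c(periodic_extra_rows(orb2, nX, basis),
                                       list(list(F = function(p) p$free[[2]] - parv,
                                                 J = function(p) { g <- numeric(nX); g[par_idx] <- 1; g }))),
                                     tol = 1e-8, maxit = 8),
                       error = function(e) NULL)
      if (!is.null(res2) && res2$converged) {
        X <- res2$X
        sols[[length(sols)]] <- X_to_orbit(X, mesh, spec, system, start$k,
                                           res2$residual)
        tau <- tangent(X, sols[[length(sols)]])
        if (sign(tau[par_idx]) * sign(tau_n[par_idx]) < 0) tau <- -tau
      } else mesh <- orb$mesh
    }
  }
  par <- vapply(sols, function(o) o$free[[2]], numeric(1))
  structure(list(par_name = par_name, solutions = sols, par = par,
                 period = vapply(sols, function(o) o$T, numeric(1)),
                 l2 = vapply(sols, l2_norm, numeric(1)),
                 multipliers = mults,
                 stable = vapply(mults, function(m) all(Mod(m)[-1] < 1 + 1e-6),
                                 logical(1)),
                 events = events, termination = termination),
            class = "periodic_branch")
}

refine_periodic_event <- function(system, spec, mesh, basis, Xbase, tau, h,
                                  wts, testfun, ref, k, max_iter = 40) {
  nX <- length(Xbase)
  solve_at <- function(hh) {
    extra <- periodic_extra_rows(ref, nX, basis)
    arc <- list(
      F = function(p) sum((c(as.numeric(p$states), p$free) - Xbase) *
                            tau * wts^2) - hh,
      J = function(p) tau * wts^2)
    res <- newton_colloc(system, spec, mesh, Xbase + hh * tau, basis,
                         c(extra, list(arc)), tol = 1e-8, maxit = 10)
    if (!res$converged) return(NULL)
    orb <- X_to_orbit(res$X, mesh, spec, system, k, res$residual)
    list(orb = orb, m = testfun(orb))
  }
  lo <- 0; hi <- h
  flo <- solve_at(1e-10); fhi <- solve_at(h)
  if (is.null(flo) || is.null(fhi) || !is.finite(flo$m) || !is.finite(fhi$m))
    return(NULL)
  best <- fhi
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- solve_at(mid)
    if (is.null(fm) || !is.finite(fm$m)) break
    best <- fm
    if (abs(fm$m) < 1e-7) break
    if (sign(fm$m) == sign(flo$m)) { lo <- mid; flo <- fm } else hi <- mid
    if (hi - lo < 1e-12) break
  }
  best$orb
}

#' @export
print.periodic_branch <- function(x, ...) {
  cat(sprintf("<periodic_branch in %s> %d solutions, %s = [%.5g, %.5g], termination %s\n",
              x$par_name, length(x$solutions), x$par_name, min(x$par),
              max(x$par), x$termination))
  for (e in x$events)
    cat(sprintf("  %s at %s = %.6f\n", e$type, x$par_name, e$par))
  invisible(x)
}

#' Predictor on the period-doubled branch at a period-doubling point
#'
#' Builds the doubled-period orbit (the PD orbit traversed twice) perturbed
#' along the period-doubling mode and converges it with the parameter free.
#'
#' @param system a [slow_fast_system()].
#' @param pd_orbit the refined PD orbit from [continue_periodic()].
#' @param par_name continuation parameter.
#' @param amplitude size of the symmetry-breaking perturbation.
#' @param N mesh intervals of the doubled orbit.
#' @return converged periodic [orbit_segment()] on the doubled branch.
#' @export
double_period_start <- function(system, pd_orbit, par_name,
                                amplitude = 1e-3, N = 2 * (length(pd_orbit$mesh) - 1)) {
  k <- pd_orbit$k
  # PD eigenvector of the monodromy (multiplier -1)
  basis <- get_basis(k)
  mesh1 <- pd_orbit$mesh
  Nm <- length(mesh1) - 1
  # propagate the PD mode along the orbit: v(s) from interval maps
  P <- basis$P; D <- basis$D
  mono <- diag(4)
  maps <- vector("list", Nm)
  sys <- sys_of(system, pd_orbit)
  for (i in seq_len(Nm)) {
    h <- mesh1[i + 1] - mesh1[i]
    cols <- ((i - 1) * k + 1):(i * k + 1)
    U <- pd_orbit$states[, cols, drop = FALSE]
    Ug <- U %*% t(P)
    A <- matrix(0, 4 * k, 4 * k); B <- matrix(0, 4 * k, 4)
    for (g in seq_len(k)) {
      Jg <- full_jacobian(sys, Ug[, g])
      for (j in 1:(k + 1)) {
        Blk <- -pd_orbit$T * P[g, j] * Jg
        diag(Blk) <- diag(Blk) + D[g, j] / h
        if (j == 1) B[(g - 1) * 4 + 1:4, ] <- -Blk
        else A[(g - 1) * 4 + 1:4, (j - 2) * 4 + 1:4] <- Blk
      }
    }
    Y <- solve(A, B)
    maps[[i]] <- Y
    mono <- Y[(k - 1) * 4 + 1:4, , drop = FALSE] %*% mono
  }
  e <- eigen(mono)
  ipd <- which.min(Mod(e$values + 1))
  v0 <- Re(e$vectors[, ipd]); v0 <- v0 / sqrt(sum(v0^2))
  # PD mode on the fine grid of the single orbit
  mode <- matrix(0, 4, ncol(pd_orbit$states))
  mode[, 1] <- v0
  vcur <- v0
  for (i in seq_len(Nm)) {
    Y <- maps[[i]] %*% vcur
    cols <- ((i - 1) * k + 1):(i * k + 1)
    mode[, cols[-1]] <- matrix(Y, 4, k)
    vcur <- Y[(k - 1) * 4 + 1:4]
  }
  # doubled orbit: two copies, with antisymmetric perturbation
  s1 <- pd_orbit$s
  sfull <- c(s1 / 2, 0.5 + s1[-1] / 2)
  ufull <- cbind(pd_orbit$states + amplitude * mode,
                 (pd_orbit$states - amplitude * mode)[, -1, drop = FALSE])
  guess <- remesh_series(sfull, ufull, 2 * pd_orbit$T, sys, N = N, k = k)
  spec <- periodic_spec(par_name)
  nX <- 4 * ncol(guess$states) + 2
  extra <- periodic_extra_rows(guess, nX, basis)
  amp_row <- list(F = function(p) p$u0[1] - guess$states[1, 1],
                  J = function(p) { g <- numeric(nX); g[1] <- 1; g })
  res <- newton_colloc(sys, spec, guess$mesh, orbit_to_X(guess, spec), basis,
                       c(extra, list(amp_row)), tol = 1e-8, maxit = 15)
  if (!res$converged)
    stop(sprintf("doubled-period predictor did not converge (residual %.3g)",
                 res$residual))
  X_to_orbit(res$X, guess$mesh, spec, sys, k, res$residual)
}
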