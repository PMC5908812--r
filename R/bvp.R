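#' @importFrom Matrix sparseMatrix
#' @importFrom stats approx uniroot spline
NULL

# ---------------------------------------------------------------------------
# collocation machinery
#
# Orbit segments are rescaled to s in [0,1] with free total time T:
#     du/ds = T * H(u, lambda).
# Discretization: piecewise polynomials of degree k on N mesh intervals,
# represented by their values on the fine grid of N*k+1 equally spaced
# representation points per interval (endpoints shared), collocated at the
# k Gauss-Legendre points of each interval.

gauss_legendre <- function(k) {
  # Golub-Welsch on [0,1]
  i <- seq_len(k - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, k, k)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  x <- (e$values + 1) / 2
  w <- (e$vectors[1, ])^2
  ord <- order(x)
  list(nodes = x[ord], weights = w[ord])
}

# Lagrange basis values and derivatives at points x for given nodes
lagrange_matrices <- function(nodes, x) {
  m <- length(nodes); n <- length(x)
  P <- matrix(0, n, m); D <- matrix(0, n, m)
  for (j in seq_len(m)) {
    others <- nodes[-j]
    denom <- prod(nodes[j] - others)
    for (g in seq_len(n)) {
      P[g, j] <- prod(x[g] - others) / denom
      s <- 0
      for (l in seq_along(others)) s <- s + prod((x[g] - others)[-l])
      D[g, j] <- s / denom
    }
  }
  list(P = P, D = D)
}

colloc_basis <- function(k = 4) {
  gl <- gauss_legendre(k)
  rep_nodes <- seq(0, 1, length.out = k + 1)
  lm <- lagrange_matrices(rep_nodes, gl$nodes)
  list(k = k, gauss = gl$nodes, weights = gl$weights, P = lm$P, D = lm$D)
}

.basis_cache <- new.env(parent = emptyenv())
get_basis <- function(k) {
  key <- as.character(k)
  if (is.null(.basis_cache[[key]])) .basis_cache[[key]] <- colloc_basis(k)
  .basis_cache[[key]]
}

fine_grid <- function(mesh, k) {
  N <- length(mesh) - 1
  s <- numeric(N * k + 1)
  for (i in seq_len(N)) {
    idx <- ((i - 1) * k + 1):(i * k)
    s[idx] <- mesh[i] + (mesh[i + 1] - mesh[i]) * (0:(k - 1)) / k
  }
  s[N * k + 1] <- mesh[N + 1]
  s
}

# ---------------------------------------------------------------------------
# orbit segments

#' Create an orbit segment
#'
#' An orbit segment is a trajectory rescaled to `s` in `[0, 1]` with free
#' total time `T` (negative `T` encodes a backward-time run), stored as
#' states on the fine collocation grid of its mesh.
#'
#' @param mesh strictly increasing mesh `0 = s_0 < ... < s_N = 1`.
#' @param states 4 x (N*k+1) matrix of states on the fine grid, or a
#'   function of `s` used to fill it.
#' @param T total true time (nonzero).
#' @param system the [slow_fast_system()] the orbit belongs to (parameters
#'   and `eps` are snapshotted).
#' @param k collocation degree.
#' @return an object of class `orbit_segment`.
#' @export
orbit_segment <- function(mesh, states, T, system = NULL, k = 4) {
  stopifnot(all(diff(mesh) > 0), abs(mesh[1]) < 1e-14, abs(mesh[length(mesh)] - 1) < 1e-14)
  if (T == 0) stop("total time T must be nonzero")
  s <- fine_grid(mesh, k)
  if (is.function(states)) states <- vapply(s, states, numeric(4))
  stopifnot(nrow(states) == 4, ncol(states) == length(s))
  structure(list(mesh = mesh, k = k, s = s, states = states, T = T,
                 eps = if (!is.null(system)) system$eps else NA_real_,
                 params = if (!is.null(system)) system$params else NULL,
                 residual_norm = NA_real_),
            class = "orbit_segment")
}

#' @export
print.orbit_segment <- function(x, ...) {
  cat(sprintf("<orbit_segment> N=%d k=%d  T=%.6g  residual=%.3g\n",
              length(x$mesh) - 1, x$k, x$T, x$residual_norm))
  cat("  u(0) =", paste(format(x$states[, 1], digits = 6), collapse = ", "), "\n")
  cat("  u(1) =", paste(format(x$states[, ncol(x$states)], digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate an orbit segment at arbitrary s
#'
#' Piecewise-polynomial evaluation of the collocation solution.
#'
#' @param orbit an [orbit_segment()].
#' @param s points in `[0, 1]`.
#' @return 4 x length(s) matrix.
#' @export
orbit_eval <- function(orbit, s) {
  k <- orbit$k
  mesh <- orbit$mesh
  N <- length(mesh) - 1
  out <- matrix(0, 4, length(s))
  iv <- pmin(pmax(findInterval(s, mesh, rightmost.closed = TRUE), 1), N)
  for (j in seq_along(s)) {
    i <- iv[j]
    h <- mesh[i + 1] - mesh[i]
    sigma <- (s[j] - mesh[i]) / h
    cols <- ((i - 1) * k + 1):(i * k + 1)
    lm <- lagrange_matrices(seq(0, 1, length.out = k + 1), sigma)
    out[, j] <- orbit$states[, cols, drop = FALSE] %*% drop(lm$P)
  }
  out
}

#' Initial-value endpoint with a stiff high-accuracy integrator
#'
#' Integrates the fast-time vector field from `u0` over true time `T`
#' (possibly negative) with `deSolve::lsoda` at tolerance `1e-12`.
#'
#' @param system a [slow_fast_system()].
#' @param u0 initial state.
#' @param T integration time.
#' @param n_out number of output samples.
#' @param rtol,atol integrator tolerances.
#' @return list with `endpoint` (4-vector), `t`, `states` (4 x n_out).
#' @export
ivp_endpoint <- function(system, u0, T, n_out = 2L, rtol = 1e-12, atol = 1e-12) {
  f <- function(t, u, p) list(system$rhs(u, system$params, system$eps))
  times <- seq(0, T, length.out = max(2L, n_out))
  out <- deSolve::lsoda(u0, times, f, NULL, rtol = rtol, atol = atol,
                        maxsteps = 100000)
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times))
    stop(sprintf("ivp blow-up or failure near t = %.6g", out[nrow(out), 1]))
  list(endpoint = as.numeric(out[nrow(out), -1]), t = out[, 1],
       states = t(unname(out[, -1, drop = FALSE])))
}

# integrate until a hypersurface crossing (root finding via deSolve)
ivp_to_surface <- function(system, u0, surface, tmax, direction = 1,
                           rtol = 1e-10, atol = 1e-12, n_dense = 2000) {
  f <- function(t, u, p) list(direction * system$rhs(u, system$params, system$eps))
  root <- function(t, u, p)
    vapply(surface$residuals, function(r) r(u), numeric(1))
  times <- seq(0, tmax, length.out = n_dense)
  out <- deSolve::lsoda(u0, times, f, NULL, rtol = rtol, atol = atol,
                        rootfunc = root, maxsteps = 100000)
  tr <- attr(out, "troot")
  if (is.null(tr) || !length(tr))
    stop("no crossing of the stop surface before t = ", tmax)
  list(t = out[, 1] * direction, states = t(unname(out[, -1, drop = FALSE])),
       t_cross = tr[1] * direction)
}

# ---------------------------------------------------------------------------
# hypersurfaces and BVP specifications

#' Define a boundary hypersurface
#'
#' A hypersurface is the common zero set of one or more scalar residual
#' functions of the state; its codimension is the number of residuals.
#'
#' @param ... scalar residual functions `function(u)`.
#' @param desc description tag.
#' @return object of class `hypersurface`.
#' @export
hypersurface <- function(..., desc = "") {
  res <- list(...)
  stopifnot(length(res) >= 1, all(vapply(res, is.function, logical(1))))
  structure(list(residuals = res, codim = length(res), desc = desc),
            class = "hypersurface")
}

#' @rdname hypersurface
#' @param index state index, `value` the fixed coordinate value.
#' @param value coordinate value.
#' @export
hs_coord <- function(index, value) {
  force(index); force(value)
  hypersurface(function(u) u[index] - value,
               desc = sprintf("u[%d]=%g", index, value))
}

#' @rdname hypersurface
#' @param system system whose nullcline is used.
#' @param comp component index whose fast-time derivative vanishes.
#' @export
hs_nullcline <- function(system, comp) {
  force(system); force(comp)
  hypersurface(function(u) system$rhs(u, system$params, system$eps)[comp],
               desc = sprintf("nullcline[%d]", comp))
}

#' @rdname hypersurface
#' @param a,b hypersurfaces to intersect.
#' @export
hs_and <- function(a, b) {
  structure(list(residuals = c(a$residuals, b$residuals),
                 codim = a$codim + b$codim,
                 desc = paste(a$desc, "&", b$desc)),
            class = "hypersurface")
}

hs_residual <- function(hs, u)
  vapply(hs$residuals, function(r) r(u), numeric(1))

#' Two-point boundary-value problem specification
#'
#' Well-posedness bookkeeping for orbit-segment families: with boundary
#' hypersurfaces of codimension `i` and `j` and free scalars beyond the
#' states, the family dimension is `4 + n_free - (i + j)`.  The
#' one-parameter families used throughout require `i + j = 4` when `T` is
#' the only free parameter.
#'
#' @param left,right [hypersurface()]s for `u(0)` and `u(1)`; `right` may be
#'   `NULL` (codimension 0, initial-value case).
#' @param free character vector of free scalars; always contains `"T"`
#'   unless `T` is fixed.  A name other than `"T"` must be resolvable by
#'   `set_par`.
#' @param set_par optional `function(system, name, value)` used during
#'   continuation in a system parameter.
#' @param T_fixed total time, required when `"T"` is not among `free`.
#' @return object of class `bvp_spec` with the computed `family_dim`.
#' @export
bvp_spec <- function(left, right = NULL, free = "T", set_par = NULL,
                     T_fixed = NULL) {
  i <- left$codim
  j <- if (is.null(right)) 0L else right$codim
  fam <- 4L + length(free) - (i + j)
  if (fam < 0L)
    stop(sprintf("overdetermined 2PBVP: i + j = %d exceeds 4 + %d free scalars",
                 i + j, length(free)))
  if (fam > 1L)
    stop(sprintf("underdetermined 2PBVP (family dimension %d): i + j must equal %d",
                 fam, 4L + length(free) - 1L))
  if (!("T" %in% free) && is.null(T_fixed))
    stop("T_fixed must be given when T is not a free parameter")
  structure(list(left = left, right = right, free = free,
                 family_dim = fam, set_par = set_par),
            class = "bvp_spec", T_fixed = T_fixed)
}

# ---------------------------------------------------------------------------
# nonlinear solver

# Assemble residual and sparse Jacobian of the collocation system.
# X layout: [vec(states) (4*M), free scalars in spec$free order]
# rows: collocation (4*N*k), then left BCs, right BCs.
# extra_rows: list of list(F=function(X_parts) scalar, J=function(X_parts)
# dense gradient vector) appended at the end (anchor / arclength / phase).
assemble_colloc <- function(system, spec, mesh, X, basis, extra_rows = list()) {
  k <- basis$k
  N <- length(mesh) - 1
  M <- N * k + 1
  nfree <- length(spec$free)
  states <- matrix(X[seq_len(4 * M)], 4, M)
  freev <- X[4 * M + seq_len(nfree)]
  names(freev) <- spec$free
  T <- if ("T" %in% spec$free) freev[["T"]] else attr(spec, "T_fixed")
  sys <- system
  for (nm in setdiff(spec$free, "T")) {
    sys <- if (is.null(spec$set_par))
      do.call(set_params, c(list(system = sys),
                            structure(list(freev[[nm]]), names = nm)))
    else spec$set_par(sys, nm, freev[[nm]])
  }
  P <- basis$P; D <- basis$D
  nrow_coll <- 4 * N * k
  Fv <- numeric(nrow_coll)
  trip_i <- vector("list", N); trip_j <- vector("list", N); trip_x <- vector("list", N)
  Tcol <- numeric(nrow_coll)
  parcol <- if (nfree > 1) matrix(0, nrow_coll, nfree - 1) else NULL
  dpar <- 1e-7
  for (i in seq_len(N)) {
    h <- mesh[i + 1] - mesh[i]
    cols <- ((i - 1) * k + 1):(i * k + 1)       # k+1 fine-grid indices
    U <- states[, cols, drop = FALSE]           # 4 x (k+1)
    Ug <- U %*% t(P)                            # 4 x k states at gauss pts
    dUg <- U %*% t(D) / h                       # 4 x k derivative
    Hg <- matrix(0, 4, k); Jg <- vector("list", k)
    for (g in seq_len(k)) {
      Hg[, g] <- sys$rhs(Ug[, g], sys$params, sys$eps)
      Jg[[g]] <- full_jacobian(sys, Ug[, g])
    }
    rows0 <- (i - 1) * 4 * k
    # scale each collocation row by the local field magnitude so residuals
    # are comparable across slow segments and fast blow-up tails
    rsc <- 1 / (1 + abs(T * Hg))
    Fv[rows0 + seq_len(4 * k)] <- as.numeric((dUg - T * Hg) * rsc)
    # Jacobian blocks: for gauss g, dim d: row = rows0 + (g-1)*4 + d
    # wrt U[, j]: D[g,j]/h * I4 - T * P[g,j] * Jg[[g]]
    nb <- 4 * k * (k + 1) * 4
    ii <- integer(nb); jj <- integer(nb); xx <- numeric(nb)
    pos <- 0L
    for (g in seq_len(k)) {
      rbase <- rows0 + (g - 1) * 4
      B0 <- -T * Jg[[g]]
      for (j in seq_len(k + 1)) {
        B <- P[g, j] * B0
        diag(B) <- diag(B) + D[g, j] / h
        B <- B * rsc[, g]
        cbase <- (cols[j] - 1) * 4
        idx <- pos + seq_len(16)
        ii[idx] <- rbase + rep(1:4, 4)
        jj[idx] <- cbase + rep(1:4, each = 4)
        xx[idx] <- as.numeric(B)
        pos <- pos + 16L
      }
      Tcol[rbase + 1:4] <- -Hg[, g] * rsc[, g]
      if (nfree > 1) {
        for (pp in seq_len(nfree - 1)) {
          nm <- setdiff(spec$free, "T")[pp]
          sp <- if (is.null(spec$set_par))
            do.call(set_params, c(list(system = sys),
                                  structure(list(freev[[nm]] + dpar), names = nm)))
          else spec$set_par(sys, nm, freev[[nm]] + dpar)
          parcol[rbase + 1:4, pp] <-
            -T * (sp$rhs(Ug[, g], sp$params, sp$eps) - Hg[, g]) * rsc[, g] / dpar
        }
      }
    }
    trip_i[[i]] <- ii; trip_j[[i]] <- jj; trip_x[[i]] <- xx
  }
  # boundary conditions
  u0 <- states[, 1]; u1 <- states[, M]
  bcL <- hs_residual(spec$left, u0)
  bcR <- if (is.null(spec$right)) numeric(0) else hs_residual(spec$right, u1)
  nbc <- length(bcL) + length(bcR)
  bc_i <- integer(0); bc_j <- integer(0); bc_x <- numeric(0)
  d <- 1e-7
  fdgrad <- function(res, u) {
    vapply(1:4, function(l) {
      up <- u; up[l] <- up[l] + d * max(1, abs(u[l]))
      um <- u; um[l] <- um[l] - d * max(1, abs(u[l]))
      (res(up) - res(um)) / (up[l] - um[l])
    }, numeric(1))
  }
  rown <- nrow_coll
  for (r in seq_along(spec$left$residuals)) {
    rown <- rown + 1L
    gr <- fdgrad(spec$left$residuals[[r]], u0)
    bc_i <- c(bc_i, rep(rown, 4)); bc_j <- c(bc_j, 1:4); bc_x <- c(bc_x, gr)
  }
  if (!is.null(spec$right)) {
    for (r in seq_along(spec$right$residuals)) {
      rown <- rown + 1L
      gr <- fdgrad(spec$right$residuals[[r]], u1)
      bc_i <- c(bc_i, rep(rown, 4))
      bc_j <- c(bc_j, (M - 1) * 4 + 1:4)
      bc_x <- c(bc_x, gr)
    }
  }
  nX <- 4 * M + nfree
  nrows <- nrow_coll + nbc + length(extra_rows)
  Fall <- c(Fv, bcL, bcR)
  parts <- list(states = states, u0 = u0, u1 = u1, T = T, free = freev,
                mesh = mesh, system = sys, M = M)
  ex_F <- numeric(0); ex_i <- integer(0); ex_j <- integer(0); ex_x <- numeric(0)
  if (length(extra_rows)) {
    for (e in seq_along(extra_rows)) {
      er <- extra_rows[[e]]
      ex_F <- c(ex_F, er$F(parts))
      gr <- er$J(parts)            # dense length-nX gradient
      nzi <- which(gr != 0)
      ex_i <- c(ex_i, rep(nrow_coll + nbc + e, length(nzi)))
      ex_j <- c(ex_j, nzi)
      ex_x <- c(ex_x, gr[nzi])
    }
    Fall <- c(Fall, ex_F)
  }
  ii <- c(unlist(trip_i), bc_i, ex_i)
  jj <- c(unlist(trip_j), bc_j, ex_j)
  xx <- c(unlist(trip_x), bc_x, ex_x)
  # free-parameter columns (dense over collocation rows)
  if ("T" %in% spec$free) {
    tj <- 4 * M + match("T", spec$free)
    nz <- which(Tcol != 0)
    ii <- c(ii, nz); jj <- c(jj, rep(tj, length(nz))); xx <- c(xx, Tcol[nz])
  }
  if (nfree > 1) {
    off <- 0
    for (pp in seq_len(nfree - 1)) {
      nm <- setdiff(spec$free, "T")[pp]
      cj <- 4 * M + match(nm, spec$free)
      nz <- which(parcol[, pp] != 0)
      ii <- c(ii, nz); jj <- c(jj, rep(cj, length(nz))); xx <- c(xx, parcol[nz, pp])
    }
  }
  J <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nrows, nX))
  list(F = Fall, J = J, parts = parts)
}

newton_colloc <- function(system, spec, mesh, X0, basis, extra_rows = list(),
                          tol = 1e-10, maxit = 12, min_damp = 1e-4,
                          verbose = FALSE) {
  X <- X0
  for (it in seq_len(maxit)) {
    as_ <- assemble_colloc(system, spec, mesh, X, basis, extra_rows)
    nf <- max(abs(as_$F))
    if (verbose) message(sprintf("  newton %d: |F| = %.3e", it, nf))
    if (nf < tol)
      return(list(X = X, converged = TRUE, residual = nf, iter = it,
                  parts = as_$parts))
    dx <- tryCatch(as.numeric(Matrix::solve(as_$J, -as_$F)),
                   error = function(e) NULL)
    if (is.null(dx) || any(!is.finite(dx)))
      return(list(X = X, converged = FALSE, residual = nf, iter = it,
                  singular = TRUE, parts = as_$parts))
    lam <- 1
    repeat {
      Xn <- X + lam * dx
      fn <- tryCatch(max(abs(assemble_colloc(system, spec, mesh, Xn, basis,
                                             extra_rows)$F)),
                     error = function(e) Inf)
      if (fn < nf * (1 - 0.25 * lam) || fn < tol) break
      lam <- lam / 2
      if (lam < min_damp) break
    }
    X <- X + lam * dx
    if (lam < min_damp && it > 3)
      return(list(X = X, converged = fn < tol * 100, residual = fn, iter = it,
                  parts = as_$parts))
  }
  as_ <- assemble_colloc(system, spec, mesh, X, basis, extra_rows)
  list(X = X, converged = max(abs(as_$F)) < tol * 100,
       residual = max(abs(as_$F)), iter = maxit, parts = as_$parts)
}

orbit_to_X <- function(orbit, spec) {
  fv <- vapply(spec$free, function(nm) {
    if (!is.null(orbit$free) && nm %in% names(orbit$free)) orbit$free[[nm]]
    else if (nm == "T") orbit$T
    else if (!is.null(orbit$params) && nm %in% names(orbit$params))
      orbit$params[[nm]]
    else if (nm == "eps") orbit$eps
    else stop("free parameter ", nm, " not found in orbit snapshot")
  }, numeric(1))
  c(as.numeric(orbit$states), fv)
}

X_to_orbit <- function(X, mesh, spec, system, k, residual = NA_real_) {
  M <- (length(mesh) - 1) * k + 1
  states <- matrix(X[seq_len(4 * M)], 4, M)
  fv <- X[4 * M + seq_along(spec$free)]
  names(fv) <- spec$free
  T <- if ("T" %in% spec$free) fv[["T"]] else attr(spec, "T_fixed")
  sys <- system
  for (nm in setdiff(spec$free, "T")) {
    sys <- if (is.null(spec$set_par))
      do.call(set_params, c(list(system = sys),
                            structure(list(fv[[nm]]), names = nm)))
    else spec$set_par(sys, nm, fv[[nm]])
  }
  ob <- orbit_segment(mesh, states, T, sys, k)
  ob$residual_norm <- residual
  ob$free <- fv
  ob
}

#' Solve an orbit segment as a two-point boundary-value problem
#'
#' Newton iteration on the collocation equations with the boundary residuals
#' of `spec`; `T` (and any other declared scalar) is solved for as an
#' unknown.  When the family dimension is 1, one anchor condition closes the
#' system; by default the anchor fixes the coordinate of `u(0)` that varies
#' most along the family, at its value in the guess.
#'
#' @param system a [slow_fast_system()].
#' @param spec a [bvp_spec()].
#' @param guess an [orbit_segment()] roughly satisfying the boundary
#'   conditions (Newton basin).
#' @param anchor `NULL`, `"T"` (fix `T` at the guess value), an integer
#'   `1:4` (fix that coordinate of `u(0)`), or a list `list(F=, J=)` of
#'   functions of the assembled parts.
#' @param tol Newton tolerance on the maximum residual.
#' @param maxit maximum Newton iterations.
#' @return converged [orbit_segment()] (with `residual_norm` set), or an
#'   error carrying the final residual.
#' @export
solve_orbit <- function(system, spec, guess, anchor = NULL, tol = 1e-10,
                        maxit = 12) {
  basis <- get_basis(guess$k)
  X0 <- orbit_to_X(guess, spec)
  extra <- list()
  if (spec$family_dim == 1L) {
    extra <- list(make_anchor(anchor, guess, spec))
  }
  res <- newton_colloc(system, spec, guess$mesh, X0, basis, extra,
                       tol = tol, maxit = maxit)
  if (!res$converged)
    stop(sprintf("Newton did not converge (max residual %.3e after %d iterations)%s",
                 res$residual, res$iter,
                 if (isTRUE(res$singular)) "; singular Jacobian (boundary tangency?)" else ""))
  X_to_orbit(res$X, guess$mesh, spec, system, guess$k, res$residual)
}

make_anchor <- function(anchor, guess, spec) {
  M <- ncol(guess$states)
  nX <- 4 * M + length(spec$free)
  if (is.null(anchor)) anchor <- "T"
  if (identical(anchor, "T")) {
    tj <- 4 * M + match("T", spec$free)
    T0 <- guess$T
    list(F = function(p) p$T - T0,
         J = function(p) { g <- numeric(nX); g[tj] <- 1; g })
  } else if (is.numeric(anchor) && length(anchor) == 1) {
    idx <- as.integer(anchor)
    val <- guess$states[idx, 1]
    list(F = function(p) p$u0[idx] - val,
         J = function(p) { g <- numeric(nX); g[idx] <- 1; g })
  } else anchor
}

# ---------------------------------------------------------------------------
# pseudo-arclength continuation

#' Continue a one-parameter family of orbit segments
#'
#' Pseudo-arclength continuation of the solutions of a well-posed 2PBVP.
#' Named monitor functions are evaluated for every accepted solution; each
#' sign change is refined on the arclength until the monitor magnitude is
#' below `event_tol`.
#'
#' @param system a [slow_fast_system()].
#' @param spec a [bvp_spec()] with family dimension 1.
#' @param first a converged [orbit_segment()] (from [solve_orbit()]).
#' @param monitors named list of functions `function(orbit)` returning a
#'   scalar.
#' @param stop_fn optional `function(orbit)` returning `TRUE` to terminate.
#' @param n_max maximum number of continuation steps.
#' @param h0,h_min,h_max initial, minimal and maximal arclength steps.
#' @param direction +1 or -1, selects the branch direction of the initial
#'   tangent.
#' @param tangent_coord coordinate used to orient the initial tangent: a
#'   list `list(what = "u0"|"free", index)`; by default the first free
#'   scalar.
#' @param event_tol refinement tolerance for monitor events.
#' @param tol Newton tolerance.
#' @param verbose print per-step diagnostics.
#' @return object of class `continuation_run`: list with `solutions` (list
#'   of orbit segments), `monitors` (matrix), `events` (data frame), and
#'   `termination`.
#' @export
continue_family <- function(system, spec, first, monitors = list(),
                            stop_fn = NULL, n_max = 100,
                            h0 = 1e-2, h_min = 1e-8, h_max = 1.0,
                            direction = 1, tangent_coord = NULL,
                            event_tol = 1e-8, tol = 1e-9, verbose = FALSE) {
  if (spec$family_dim != 1L)
    stop("continuation requires family dimension 1")
  basis <- get_basis(first$k)
  mesh <- first$mesh
  M <- ncol(first$states)
  nX <- 4 * M + length(spec$free)
  # arclength metric: averaged state components; T measured relative to its
  # current magnitude so long orbits do not throttle the steps
  T_idx <- match("T", spec$free)
  make_wts <- function(X) {
    free_w <- vapply(spec$free, function(nm)
      if (nm == "T") 1 / max(1, abs(X[4 * M + T_idx])) else 1, numeric(1))
    c(rep(1 / sqrt(4 * M), 4 * M), free_w)
  }
  wts <- make_wts(orbit_to_X(first, spec))
  X <- orbit_to_X(first, spec)

  tangent_at <- function(X, tau_prev = NULL) {
    as_ <- assemble_colloc(system, spec, mesh, X, basis)
    nr <- nrow(as_$J)
    norm_row <- if (is.null(tau_prev)) {
      g <- numeric(nX)
      if (is.null(tangent_coord)) g[4 * M + 1] <- 1
      else if (tangent_coord$what == "u0") g[tangent_coord$index] <- 1
      else if (tangent_coord$what == "u1")
        g[(M - 1) * 4 + tangent_coord$index] <- 1
      else g[4 * M + tangent_coord$index] <- 1
      g
    } else tau_prev * wts^2
    Jb <- rbind(as_$J, Matrix::sparseMatrix(i = rep(1, sum(norm_row != 0)),
                                            j = which(norm_row != 0),
                                            x = norm_row[norm_row != 0],
                                            dims = c(1, nX)))
    rhs <- c(rep(0, nr), 1)
    tau <- tryCatch(as.numeric(Matrix::solve(Jb, rhs)), error = function(e) NULL)
    if (is.null(tau)) stop("tangent computation failed (singular Jacobian)")
    tau / sqrt(sum((tau * wts)^2))
  }

  tau <- direction * tangent_at(X)
  sols <- list(first)
  monv <- if (length(monitors))
    matrix(vapply(monitors, function(m) m(first), numeric(1)), nrow = 1,
           dimnames = list(NULL, names(monitors))) else NULL
  events <- list()
  h <- h0
  termination <- "n_max"
  step <- 1L

  corrector <- function(Xpred, tau, Xbase, h) {
    arc <- list(
      F = function(p) {
        Xc <- c(as.numeric(p$states), p$free)
        sum((Xc - Xbase) * tau * wts^2) - h
      },
      J = function(p) tau * wts^2)
    newton_colloc(system, spec, mesh, Xpred, basis, list(arc),
                  tol = tol, maxit = 10)
  }

  while (step <= n_max) {
    accepted <- FALSE
    while (!accepted) {
      Xpred <- X + h * tau
      res <- tryCatch(corrector(Xpred, tau, X, h), error = function(e) NULL)
      if (!is.null(res) && res$converged) { accepted <- TRUE; break }
      h <- h / 2
      if (h < h_min) break
    }
    if (!accepted) { termination <- "step_collapse"; break }
    Xn <- res$X
    orb <- X_to_orbit(Xn, mesh, spec, system, first$k, res$residual)
    sols[[length(sols) + 1L]] <- orb
    if (length(monitors)) {
      mv <- vapply(monitors, function(m) m(orb), numeric(1))
      prev <- monv[nrow(monv), ]
      for (q in seq_along(mv)) {
        if (is.finite(mv[q]) && is.finite(prev[q]) &&
            sign(mv[q]) != sign(prev[q]) && prev[q] != 0) {
          ev <- refine_event(system, spec, mesh, basis, X, tau, h, wts,
                             monitors[[q]], event_tol, tol, first$k)
          if (!is.null(ev))
            events[[length(events) + 1L]] <-
              list(index = length(sols), name = names(monitors)[q],
                   orbit = ev)
        }
      }
      monv <- rbind(monv, mv)
    }
    if (!is.null(stop_fn) && isTRUE(stop_fn(orb))) {
      termination <- "stop_condition"; break
    }
    tau_new <- tryCatch(tangent_at(Xn, tau), error = function(e) tau)
    if (sum(tau_new * tau * wts^2) < 0) tau_new <- -tau_new
    X <- Xn; tau <- tau_new
    if (!is.na(T_idx)) {
      wts_new <- make_wts(X)
      tau <- tau / sqrt(sum((tau * wts_new)^2))
      wts <- wts_new
    }
    if (res$iter <= 4) h <- min(h * 1.5, h_max)
    if (verbose) message(sprintf("step %d: h = %.3g, T = %.6g", step, h, orb$T))
    step <- step + 1L
  }
  structure(list(solutions = sols, monitors = monv,
                 events = events, termination = termination,
                 spec = spec),
            class = "continuation_run")
}

# secant/bisection on the arclength step for a monitor sign change in (0, h]
refine_event <- function(system, spec, mesh, basis, Xbase, tau, h, wts,
                         monitor, event_tol, tol, k) {
  solve_at <- function(hh) {
    arc <- list(
      F = function(p) {
        Xc <- c(as.numeric(p$states), p$free)
        sum((Xc - Xbase) * tau * wts^2) - hh
      },
      J = function(p) tau * wts^2)
    res <- newton_colloc(system, spec, mesh, Xbase + hh * tau, basis,
                         list(arc), tol = tol, maxit = 10)
    if (!res$converged) return(NULL)
    orb <- X_to_orbit(res$X, mesh, spec, system, k, res$residual)
    list(orb = orb, m = monitor(orb))
  }
  lo <- 0; hi <- h
  flo <- solve_at(1e-12); fhi <- solve_at(h)
  if (is.null(flo) || is.null(fhi)) return(NULL)
  best <- NULL
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    fm <- solve_at(mid)
    if (is.null(fm)) return(if (is.null(best)) NULL else best$orb)
    best <- fm
    if (abs(fm$m) <= event_tol) return(fm$orb)
    if (sign(fm$m) == sign(flo$m)) { lo <- mid; flo <- fm }
    else { hi <- mid; fhi <- fm }
    if (hi - lo < 1e-14 * max(1, h)) break
  }
  best$orb
}

#' @export
print.continuation_run <- function(x, ...) {
  cat(sprintf("<continuation_run> %d solutions, termination: %s\n",
              length(x$solutions), x$termination))
  if (length(x$events))
    for (e in x$events)
      cat(sprintf("  event '%s' near solution %d\n", e$name, e$index))
  invisible(x)
}

# ---------------------------------------------------------------------------
# flow extension and remeshing

#' Extend an orbit segment by the flow
#'
#' Integrates from the requested endpoint until an event-located crossing of
#' the stop hypersurface, concatenates, and re-meshes the result on `[0, 1]`
#' with updated total time.
#'
#' @param system a [slow_fast_system()].
#' @param orbit an [orbit_segment()].
#' @param direction `"forward"` (extend past `u(1)`) or `"backward"`
#'   (prepend before `u(0)`).
#' @param stop_at a [hypersurface()] (codimension 1) at which to stop.
#' @param tmax maximum extension time before failure.
#' @param N mesh intervals of the re-meshed result.
#' @return a new [orbit_segment()] whose endpoint lies on `stop_at`.
#' @export
extend_by_flow <- function(system, orbit, direction = c("forward", "backward"),
                           stop_at, tmax = 1000, N = length(orbit$mesh) - 1) {
  direction <- match.arg(direction)
  M <- ncol(orbit$states)
  fwd <- direction == "forward"
  u_end <- if (fwd) orbit$states[, M] else orbit$states[, 1]
  sgn <- if (fwd) sign(orbit$T) else -sign(orbit$T)
  ext <- ivp_to_surface(system, u_end, stop_at, tmax, direction = sgn)
  te <- abs(ext$t)
  # combined true-time series
  t_orig <- orbit$s * abs(orbit$T)
  if (fwd) {
    tt <- c(t_orig, abs(orbit$T) + te[-1])
    uu <- cbind(orbit$states, ext$states[, -1, drop = FALSE])
  } else {
    tt <- c(rev(te[-1] * -1), t_orig) + max(te)
    uu <- cbind(ext$states[, rev(seq_len(ncol(ext$states))[-1]), drop = FALSE],
                orbit$states)
  }
  Ttot <- max(tt)
  ss <- tt / Ttot
  remesh_series(ss, uu, sign(orbit$T) * Ttot, system, N = N, k = orbit$k)
}

# build an orbit segment from a (s, states) series by interpolation,
# equidistributing arclength of the trajectory
remesh_series <- function(ss, uu, T, system, N = 100, k = 4,
                          alpha = 0.95) {
  stopifnot(length(ss) == ncol(uu))
  keep <- c(TRUE, diff(ss) > 0)
  ss <- ss[keep]; uu <- uu[, keep, drop = FALSE]
  scale <- pmax(apply(abs(uu), 1, max), 1e-8)
  du <- sqrt(rowSums((diff(t(uu / scale)))^2))
  w <- alpha * du / sum(du) + (1 - alpha) * diff(ss) / (max(ss) - min(ss))
  cw <- c(0, cumsum(w)); cw <- cw / cw[length(cw)]
  targets <- seq(0, 1, length.out = N + 1)
  mesh <- stats::approx(cw, ss, xout = targets, ties = "ordered")$y
  mesh[1] <- 0; mesh[N + 1] <- 1
  mesh <- cummax(mesh)
  # guard against collapsed intervals
  for (i in seq_len(N)) if (mesh[i + 1] <= mesh[i]) mesh[i + 1] <- mesh[i] + 1e-12
  mesh <- mesh / mesh[N + 1]
  sfine <- fine_grid(mesh, k)
  states <- matrix(0, 4, length(sfine))
  for (d in 1:4)
    states[d, ] <- stats::approx(ss, uu[d, ], xout = sfine, ties = "ordered")$y
  orbit_segment(mesh, states, T, system, k)
}

#' Re-mesh an orbit segment by error equidistribution
#'
#' @param orbit an [orbit_segment()].
#' @param N new number of mesh intervals.
#' @param n_dense dense sampling used for the redistribution.
#' @return re-meshed [orbit_segment()] (not re-converged).
#' @export
adapt_mesh <- function(orbit, N = length(orbit$mesh) - 1, n_dense = 2000) {
  sd <- seq(0, 1, length.out = n_dense)
  ud <- orbit_eval(orbit, sd)
  ob <- remesh_series(sd, ud, orbit$T, NULL, N = N, k = orbit$k)
  ob$eps <- orbit$eps; ob$params <- orbit$params
  ob
}

#' Time-normalized L2 norm of an orbit segment
#'
#' Square root of the integral over `s` in `[0,1]` of the squared state
#' norm, by Gauss quadrature on the collocation representation.
#'
#' @param orbit an [orbit_segment()].
#' @return nonnegative scalar.
#' @export
l2_norm <- function(orbit) {
  basis <- get_basis(orbit$k)
  mesh <- orbit$mesh
  N <- length(mesh) - 1
  k <- orbit$k
  total <- 0
  for (i in seq_len(N)) {
    h <- mesh[i + 1] - mesh[i]
    cols <- ((i - 1) * k + 1):(i * k + 1)
    Ug <- orbit$states[, cols, drop = FALSE] %*% t(basis$P)
    total <- total + h * sum(basis$weights * colSums(Ug^2))
  }
  sqrt(total)
}
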