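#' Slow-fast vector fields in R^4
#'
#' A `slow_fast_system` describes a four-dimensional vector field with two
#' fast and two slow variables,
#' \deqn{\dot x = f(x, y, \lambda), \qquad \dot y = \varepsilon g(x, y, \lambda),}
#' written on the fast time scale \eqn{t}.  The slow components of the
#' right-hand side vanish identically at \eqn{\varepsilon = 0} (the layer
#' problem); dividing them by \eqn{\varepsilon} and rescaling time gives the
#' reduced (slow) system.
#'
#' @param rhs function `(u, params, eps)` returning the 4-vector derivative
#'   on the fast time scale.
#' @param fast,slow integer index sets partitioning `1:4` into fast and slow
#'   variables.
#' @param eps time-scale ratio, `eps >= 0`.
#' @param params named numeric parameter vector.
#' @param name model label used for dispatch of chart-based operations.
#' @param var_names names of the four state variables.
#' @param fast_jac optional function `(u, params)` returning the 2x2 Jacobian
#'   of the fast right-hand side with respect to the fast variables.
#' @param jac optional function `(u, params, eps)` returning the full 4x4
#'   Jacobian on the fast time scale.
#'
#' @return An object of class `slow_fast_system`.
#' @export
slow_fast_system <- function(rhs, fast = c(1L, 2L), slow = c(3L, 4L),
                             eps, params = numeric(), name = "custom",
                             var_names = c("u1", "u2", "u3", "u4"),
                             fast_jac = NULL, jac = NULL) {
  stopifnot(is.function(rhs), eps >= 0,
            setequal(c(fast, slow), 1:4), length(fast) == 2L)
  structure(list(rhs = rhs, fast = as.integer(fast), slow = as.integer(slow),
                 eps = eps, params = params, name = name,
                 var_names = var_names, fast_jac = fast_jac, jac = jac),
            class = "slow_fast_system")
}

#' @export
print.slow_fast_system <- function(x, ...) {
  cat(sprintf("<slow_fast_system: %s>\n", x$name))
  cat("  state:", paste(x$var_names, collapse = ", "),
      " (fast:", paste(x$var_names[x$fast], collapse = ","),
      "| slow:", paste(x$var_names[x$slow], collapse = ","), ")\n")
  cat("  eps:", format(x$eps), "\n")
  if (length(x$params))
    cat("  params:", paste(names(x$params), format(x$params), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate the vector field of a slow-fast system
#'
#' On the fast time scale the slow components are proportional to
#' \eqn{\varepsilon}; on the slow time scale they are divided by
#' \eqn{\varepsilon}, which requires \eqn{\varepsilon > 0}.  At
#' \eqn{\varepsilon = 0} use [desing_rhs()] for the reduced flow.
#'
#' @param system a [slow_fast_system()].
#' @param u state 4-vector (finite).
#' @param timescale `"fast"` (default) or `"slow"`.
#' @return derivative 4-vector on the requested time scale.
#' @export
sf_rhs <- function(system, u, timescale = c("fast", "slow")) {
  timescale <- match.arg(timescale)
  if (!all(is.finite(u))) stop("non-finite state")
  du <- system$rhs(u, system$params, system$eps)
  if (timescale == "slow") {
    if (system$eps <= 0)
      stop("slow time scale undefined at eps = 0; use desing_rhs() for the reduced flow")
    du <- du / system$eps
  }
  du
}

#' Jacobian of the fast subsystem
#'
#' Partial derivatives of the fast components of the right-hand side with
#' respect to the fast variables only, evaluated at `u`.  Uses the model's
#' closed form when available, otherwise central finite differences with
#' relative step `1e-6`.
#'
#' @inheritParams sf_rhs
#' @return 2x2 matrix.
#' @export
fast_jacobian <- function(system, u) {
  if (!all(is.finite(u))) stop("non-finite state")
  if (!is.null(system$fast_jac)) return(system$fast_jac(u, system$params))
  fidx <- system$fast
  J <- matrix(0, 2, 2)
  for (j in seq_len(2)) {
    d <- 1e-6 * max(1, abs(u[fidx[j]]))
    up <- u; up[fidx[j]] <- up[fidx[j]] + d
    um <- u; um[fidx[j]] <- um[fidx[j]] - d
    J[, j] <- (system$rhs(up, system$params, system$eps)[fidx] -
               system$rhs(um, system$params, system$eps)[fidx]) / (2 * d)
  }
  J
}

#' Full Jacobian of the vector field on the fast time scale
#'
#' @inheritParams sf_rhs
#' @return 4x4 matrix.
#' @export
full_jacobian <- function(system, u) {
  if (!is.null(system$jac)) return(system$jac(u, system$params, system$eps))
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    d <- 1e-7 * max(1, abs(u[j]))
    up <- u; up[j] <- up[j] + d
    um <- u; um[j] <- um[j] - d
    J[, j] <- (system$rhs(up, system$params, system$eps) -
               system$rhs(um, system$params, system$eps)) / (2 * d)
  }
  J
}

# ---------------------------------------------------------------------------
# Extended folded-node normal form

#' Extended normal form of a folded node
#'
#' The three-dimensional folded-node normal form with slow variables
#' \eqn{(x, y)} and fast variable \eqn{z}, extended by a second fast variable
#' \eqn{w} with a stable fast direction:
#' \deqn{\dot x = \varepsilon(\tfrac12 \mu y - (\mu + 1) z), \quad
#'       \dot y = \varepsilon, \quad
#'       \dot z = x + z^2, \quad
#'       \dot w = z - w.}
#' The critical manifold is the parabolic surface
#' \eqn{S = \{x = -z^2,\; z = w\}} with attracting sheet \eqn{z < 0}, fold
#' curve \eqn{z = 0} and saddle sheet \eqn{z > 0}.  The origin is a folded
#' node for \eqn{\mu > 0}; the desingularized reduced flow has eigenvalues
#' \eqn{-\mu} and \eqn{-1} there.
#'
#' @param mu folded-node eigenvalue-ratio parameter, `mu > 0`.
#' @param eps time-scale ratio.
#' @return a [slow_fast_system()] with state ordering `(x, y, z, w)`
#'   (slow, slow, fast, fast).
#' @export
normal_form_model <- function(mu = 9.2, eps = 0.01) {
  rhs <- function(u, params, eps) {
    mu <- params[["mu"]]
    c(eps * (0.5 * mu * u[2] - (mu + 1) * u[3]),
      eps,
      u[1] + u[3]^2,
      u[3] - u[4])
  }
  fast_jac <- function(u, params) matrix(c(2 * u[3], 1, 0, -1), 2, 2)
  jac <- function(u, params, eps) {
    mu <- params[["mu"]]
    matrix(c(0,                 0, 1,          0,
             eps * 0.5 * mu,    0, 0,          0,
             -eps * (mu + 1),   0, 2 * u[3],   1,
             0,                 0, 0,         -1),
           4, 4)
  }
  slow_fast_system(rhs, fast = c(3L, 4L), slow = c(1L, 2L), eps = eps,
                   params = c(mu = mu), name = "normal_form",
                   var_names = c("x", "y", "z", "w"),
                   fast_jac = fast_jac, jac = jac)
}

# ---------------------------------------------------------------------------
# Nondimensionalized four-dimensional Hodgkin-Huxley model

# Standard squid-axon rate functions (modern voltage convention, mV).
# Removable singularities at V = -40 and V = -55 are filled by their limits.
hh_rate_functions <- function(V) {
  dm <- V + 40
  am <- ifelse(abs(dm) < 1e-8, 1, 0.1 * dm / (1 - exp(-dm / 10)))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  dn <- V + 55
  an <- ifelse(abs(dn) < 1e-8, 0.1, 0.01 * dn / (1 - exp(-dn / 10)))
  bn <- 0.125 * exp(-(V + 65) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

#' Gating functions of the nondimensionalized Hodgkin-Huxley model
#'
#' Steady-state activation/inactivation curves and voltage-dependent time
#' functions for the `m`, `h` and `n` gates, as functions of the
#' nondimensional voltage `v` (membrane potential divided by `k_v` = 100 mV).
#' The steady states are \eqn{x_\infty = \alpha_x/(\alpha_x+\beta_x)} with
#' the classical squid-axon rate functions.  The slow-gate time functions
#' `t_h`, `t_n` are \eqn{1/(\alpha+\beta)} relative to the 1 ms reference of
#' the slow time scale; the fast-gate time function `t_m` is normalized by
#' the reference time-scale ratio 0.0083, so that the `m` kinetics on the
#' fast time scale match the dimensional model.
#'
#' @param v nondimensional voltage (operating range about `[-0.9, 0.6]`;
#'   values far outside trigger an extrapolation warning).
#' @return named list with components `minf`, `hinf`, `ninf`, `tm`, `th`,
#'   `tn`, each a numeric vector along `v`.
#' @export
hh_gating <- function(v) {
  if (any(v < -1.5 | v > 1.2))
    warning("voltage far outside the operating range [-0.9, 0.6]; extrapolating")
  r <- hh_rate_functions(100 * v)
  list(minf = r$am / (r$am + r$bm),
       hinf = r$ah / (r$ah + r$bh),
       ninf = r$an / (r$an + r$bn),
       tm = 1 / (0.0083 * (r$am + r$bm)),
       th = 1 / (r$ah + r$bh),
       tn = 1 / (r$an + r$bn))
}

# derivative of minf with respect to v (analytic)
hh_dminf <- function(v) {
  V <- 100 * v
  dm <- V + 40
  e1 <- exp(-dm / 10)
  am <- ifelse(abs(dm) < 1e-8, 1, 0.1 * dm / (1 - e1))
  damdV <- ifelse(abs(dm) < 1e-8, 0.05,
                  (0.1 * (1 - e1) - 0.1 * dm * e1 / 10) / (1 - e1)^2)
  bm <- 4 * exp(-(V + 65) / 18)
  dbmdV <- -bm / 18
  (damdV * bm - am * dbmdV) / (am + bm)^2 * 100
}

#' Nondimensionalized four-dimensional Hodgkin-Huxley model
#'
#' The singularly perturbed form of the classical squid-axon model with
#' state `(v, m, h, n)`, fast variables `(v, m)` and slow gating variables
#' `(h, n)`:
#' \deqn{\dot v = I/(k_v g) - m^3 h (v - E_{Na}) - g_k n^4 (v - E_K) - g_l (v - E_L),}
#' \deqn{\dot m = (m_\infty(v) - m) / (\tau_m t_m(v)),}
#' \deqn{\dot h = \varepsilon (h_\infty(v) - h) / (\tau_h t_h(v)),}
#' \deqn{\dot n = \varepsilon (n_\infty(v) - n) / (\tau_n t_n(v)),}
#' with voltages scaled by `k_v` = 100 mV and conductances by `g` = 120.
#' Default parameters: `tau_m` = 1, `tau_h` = 2, `tau_n` = 1,
#' `E_Na` = 0.5, `E_K` = -0.77, `E_L` = -0.544, `g` = 120, `g_k` = 0.3,
#' `g_l` = 0.0025, `k_v` = 100.  The default operating point is `I` = 9.74,
#' `eps` = 0.0083.
#'
#' @param I injected current (nondimensional).
#' @param eps time-scale ratio.
#' @param tau_m,tau_h,tau_n gating time-scale factors.
#' @param E_Na,E_K,E_L reversal potentials (nondimensional).
#' @param g,g_k,g_l conductance constants.
#' @param k_v voltage scale (mV).
#' @return a [slow_fast_system()] with state ordering `(v, m, h, n)`.
#' @export
hodgkin_huxley_model <- function(I = 9.74, eps = 0.0083,
                                 tau_m = 1, tau_h = 2, tau_n = 1,
                                 E_Na = 0.5, E_K = -0.77, E_L = -0.544,
                                 g = 120, g_k = 0.3, g_l = 0.0025,
                                 k_v = 100) {
  params <- c(I = I, tau_m = tau_m, tau_h = tau_h, tau_n = tau_n,
              E_Na = E_Na, E_K = E_K, E_L = E_L,
              g = g, g_k = g_k, g_l = g_l, k_v = k_v)
  rhs <- function(u, p, eps) {
    v <- u[1]; m <- u[2]; h <- u[3]; n <- u[4]
    r <- hh_rate_functions(p[["k_v"]] * v)
    minf <- r$am / (r$am + r$bm)
    hinf <- r$ah / (r$ah + r$bh)
    ninf <- r$an / (r$an + r$bn)
    c(p[["I"]] / (p[["k_v"]] * p[["g"]]) -
        m^3 * h * (v - p[["E_Na"]]) -
        p[["g_k"]] * n^4 * (v - p[["E_K"]]) -
        p[["g_l"]] * (v - p[["E_L"]]),
      (minf - m) * (0.0083 * (r$am + r$bm)) / p[["tau_m"]],
      eps * (hinf - h) * (r$ah + r$bh) / p[["tau_h"]],
      eps * (ninf - n) * (r$an + r$bn) / p[["tau_n"]])
  }
  fast_jac <- function(u, p) {
    v <- u[1]; m <- u[2]; h <- u[3]; n <- u[4]
    r <- hh_rate_functions(p[["k_v"]] * v)
    minf <- r$am / (r$am + r$bm)
    inv_tm <- 0.0083 * (r$am + r$bm) / p[["tau_m"]]
    d <- 1e-7
    rp <- hh_rate_functions(p[["k_v"]] * (v + d))
    rm <- hh_rate_functions(p[["k_v"]] * (v - d))
    df2v <- ((rp$am / (rp$am + rp$bm) - m) * 0.0083 * (rp$am + rp$bm) -
             (rm$am / (rm$am + rm$bm) - m) * 0.0083 * (rm$am + rm$bm)) /
            (2 * d * p[["tau_m"]])
    matrix(c(-(m^3 * h + p[["g_k"]] * n^4 + p[["g_l"]]), df2v,
             -3 * m^2 * h * (v - p[["E_Na"]]), -inv_tm),
           2, 2)
  }
  slow_fast_system(rhs, fast = c(1L, 2L), slow = c(3L, 4L), eps = eps,
                   params = params, name = "hodgkin_huxley",
                   var_names = c("v", "m", "h", "n"),
                   fast_jac = fast_jac)
}

#' Update parameters or epsilon of a system
#'
#' @param system a [slow_fast_system()].
#' @param ... named parameter values to replace; `eps` updates the
#'   time-scale ratio.
#' @return the modified system.
#' @export
set_params <- function(system, ...) {
  upd <- list(...)
  for (nm in names(upd)) {
    if (nm == "eps") system$eps <- upd[[nm]]
    else if (nm %in% names(system$params)) system$params[[nm]] <- upd[[nm]]
    else stop("unknown parameter: ", nm)
  }
  system
}
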