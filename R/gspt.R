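#' Point on the critical manifold from chart coordinates
#'
#' The critical manifold \eqn{S} is the set of equilibria of the fast
#' subsystem at \eqn{\varepsilon = 0}.  For the normal form it is the
#' parabolic surface \eqn{\{x = -z^2, z = w\}} charted by \eqn{(y, z)}.
#' For the Hodgkin-Huxley model it is the cubic-shaped surface charted by
#' \eqn{(v, h)}: the `m` equation gives \eqn{m = m_\infty(v)} and `n` is the
#' real positive fourth root of the voltage equation.
#'
#' @param system a [slow_fast_system()] (one of the built-in models).
#' @param chart numeric length-2 chart coordinates: `(y, z)` for the normal
#'   form, `(v, h)` for Hodgkin-Huxley.
#' @return 4-vector on `S`, or an error if the chart point lies outside the
#'   manifold domain (no real positive root).
#' @export
chart_point <- function(system, chart) {
  switch(system$name,
    normal_form = {
      y <- chart[1]; z <- chart[2]
      c(-z^2, y, z, z)
    },
    hodgkin_huxley = {
      v <- chart[1]; h <- chart[2]
      p <- system$params
      gt <- hh_gating(v)
      m <- gt$minf
      num <- p[["I"]] / (p[["k_v"]] * p[["g"]]) -
        m^3 * h * (v - p[["E_Na"]]) - p[["g_l"]] * (v - p[["E_L"]])
      den <- p[["g_k"]] * (v - p[["E_K"]])
      q4 <- num / den
      if (!is.finite(q4) || q4 < 0)
        stop("chart point outside the critical-manifold domain (no real positive root)")
      c(v, m, h, q4^0.25)
    },
    stop("chart_point is defined for the built-in models only"))
}

#' Classify a sheet of the critical manifold
#'
#' Labels a point of the critical manifold by the signs of the real parts of
#' the fast-Jacobian eigenvalues: `attracting` (both negative), `repelling`
#' (both positive), `saddle` (opposite signs), or `fold` when the
#' determinant is below `fold_tol`.
#'
#' @param system a [slow_fast_system()].
#' @param u 4-vector; must satisfy the layer-problem residual.
#' @param fold_tol determinant tolerance distinguishing a fold point.
#' @param residual_tol tolerance for membership of the critical manifold.
#' @return one of `"attracting"`, `"repelling"`, `"saddle"`, `"fold"`.
#' @export
classify_sheet <- function(system, u, fold_tol = 1e-8, residual_tol = 1e-8) {
  res <- layer_residual(system, u)
  if (res > residual_tol)
    stop(sprintf("point is off the critical manifold (residual %.3g)", res))
  J <- fast_jacobian(system, u)
  if (abs(det(J)) <= fold_tol) return("fold")
  re <- Re(eigen(J, only.values = TRUE)$values)
  if (all(re < 0)) "attracting" else if (all(re > 0)) "repelling" else "saddle"
}

#' Layer-problem residual
#'
#' Norm of the fast components of the vector field at `eps = 0`; zero on the
#' critical manifold.
#'
#' @inheritParams classify_sheet
#' @return nonnegative scalar.
#' @export
layer_residual <- function(system, u) {
  du0 <- system$rhs(u, system$params, 0)
  sqrt(sum(du0[system$fast]^2))
}

#' Compute a fold curve of the critical manifold
#'
#' Sweeps one chart coordinate and, per slice, locates the zero of
#' \eqn{\det D_x f} along the other chart coordinate by bracketing and
#' bisection.  For the normal form the fold curve is the line \eqn{z = 0};
#' for the Hodgkin-Huxley model `label` selects the lower (`"F1"`) or upper
#' (`"F2"`) fold curve.
#'
#' @param system a built-in [slow_fast_system()].
#' @param label `"F"` (normal form), `"F1"` or `"F2"` (Hodgkin-Huxley).
#' @param sweep range of the swept chart coordinate (`y` for the normal
#'   form, `h` for Hodgkin-Huxley).
#' @param n number of samples along the curve.
#' @return object of class `fold_curve`: list with `label`, `points`
#'   (n x 4 matrix), `chart` (n x 2), and `det` (residual determinants).
#' @export
fold_curve <- function(system, label = NULL, sweep = NULL, n = 50) {
  if (system$name == "normal_form") {
    if (is.null(sweep)) sweep <- c(-20, 20)
    y <- seq(sweep[1], sweep[2], length.out = n)
    pts <- t(vapply(y, function(yy) chart_point(system, c(yy, 0)), numeric(4)))
    out <- list(label = if (is.null(label)) "F" else label,
                points = pts, chart = cbind(y, 0),
                det = vapply(seq_len(n),
                             function(i) det(fast_jacobian(system, pts[i, ])),
                             numeric(1)))
  } else if (system$name == "hodgkin_huxley") {
    if (is.null(label)) label <- "F1"
    vint <- if (label == "F1") c(-0.68, -0.5) else c(-0.45, 0.2)
    if (is.null(sweep)) sweep <- c(0.05, 0.8)
    h <- seq(sweep[1], sweep[2], length.out = n)
    detS <- function(v, hh) det(fast_jacobian(system, chart_point(system, c(v, hh))))
    rows <- lapply(h, function(hh) {
      br <- tryCatch({
        vg <- seq(vint[1], vint[2], length.out = 60)
        dg <- vapply(vg, detS, numeric(1), hh = hh)
        i <- which(diff(sign(dg)) != 0)
        if (!length(i)) return(NULL)
        # pick the fold adjacent to the lower attracting sheet for F1
        i <- if (label == "F1") i[1] else i[length(i)]
        stats::uniroot(detS, c(vg[i], vg[i + 1]), hh = hh, tol = 1e-13)$root
      }, error = function(e) NULL)
      if (is.null(br)) return(NULL)
      c(br, hh)
    })
    keep <- !vapply(rows, is.null, logical(1))
    if (!any(keep)) {
      warning("no bracketing of det = 0 in the sweep range; empty fold curve")
      return(structure(list(label = label, points = matrix(0, 0, 4),
                            chart = matrix(0, 0, 2), det = numeric(0)),
                       class = "fold_curve"))
    }
    ch <- do.call(rbind, rows[keep])
    pts <- t(apply(ch, 1, function(cc) chart_point(system, cc)))
    out <- list(label = label, points = pts, chart = ch,
                det = vapply(seq_len(nrow(pts)),
                             function(i) det(fast_jacobian(system, pts[i, ])),
                             numeric(1)))
  } else stop("fold_curve is defined for the built-in models only")
  structure(out, class = "fold_curve")
}

#' Desingularized reduced system on the critical manifold
#'
#' Returns the two-dimensional desingularized reduced vector field on the
#' chart of the critical manifold.  The reduced slow flow is singular along
#' fold curves; rescaling time by the (signed) determinant factor removes
#' the singularity at the price of reversing the flow on the saddle sheet.
#' The sign convention preserves orientation on the attracting sheet.
#'
#' For the normal form on chart `(y, z)`:
#' \deqn{y' = -2z, \qquad z' = \tfrac12\mu y - (\mu+1) z.}
#' For Hodgkin-Huxley on chart `(v, h)`:
#' \deqn{v' = \partial_h f_1 \, g_1 + \partial_n f_1 \, g_2, \qquad
#'       h' = -(\partial_v f_1 - \partial_m f_1 \,
#'              \partial_v f_2/\partial_m f_2)\, g_1.}
#'
#' @param system a built-in [slow_fast_system()].
#' @param chart numeric length-2 chart point.
#' @return 2-vector: chart derivative with respect to the desingularized
#'   time.
#' @export
desing_rhs <- function(system, chart) {
  switch(system$name,
    normal_form = {
      mu <- system$params[["mu"]]
      y <- chart[1]; z <- chart[2]
      c(-2 * z, 0.5 * mu * y - (mu + 1) * z)
    },
    hodgkin_huxley = {
      v <- chart[1]; h <- chart[2]
      p <- system$params
      u <- chart_point(system, chart)
      m <- u[2]; n <- u[4]
      gt <- hh_gating(v)
      g1 <- (gt$hinf - h) / (p[["tau_h"]] * gt$th)
      g2 <- (gt$ninf - n) / (p[["tau_n"]] * gt$tn)
      df1v <- -(m^3 * h + p[["g_k"]] * n^4 + p[["g_l"]])
      df1m <- -3 * m^2 * h * (v - p[["E_Na"]])
      df1h <- -m^3 * (v - p[["E_Na"]])
      df1n <- -4 * p[["g_k"]] * n^3 * (v - p[["E_K"]])
      # on S, d(f2)/dv / d(f2)/dm = -minf'(v)
      A <- df1v + df1m * hh_dminf(v)
      c(df1h * g1 + df1n * g2, -A * g1)
    },
    stop("desing_rhs is defined for the built-in models only"))
}

desing_jacobian <- function(system, chart, step = 1e-6) {
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    d <- step * max(1, abs(chart[j]))
    cp <- chart; cp[j] <- cp[j] + d
    cm <- chart; cm[j] <- cm[j] - d
    J[, j] <- (desing_rhs(system, cp) - desing_rhs(system, cm)) / (2 * d)
  }
  J
}

#' Locate folded singularities
#'
#' Folded singularities are equilibria of the desingularized reduced system
#' that lie on a fold curve.  Along each fold curve the transverse component
#' of the desingularized flow vanishes automatically, so candidates are
#' located by bracketing the remaining component and refining by bisection.
#' Eigenvalues are computed from the finite-difference linearization of the
#' desingularized system on its 2D chart.
#'
#' @param system a built-in [slow_fast_system()].
#' @param sweep sweep range passed to [fold_curve()] (Hodgkin-Huxley).
#' @return list of `folded_singularity` objects with fields `location`
#'   (4-vector), `chart`, `eigenvalues` (sorted by magnitude, strong first),
#'   `ratio` (strong/weak), `kind`, `predicted_primary`,
#'   `predicted_secondary`.
#' @export
folded_singularities <- function(system, sweep = c(0.05, 0.8)) {
  mk <- function(chartpt) {
    loc <- chart_point(system, chartpt)
    ev <- eigen(desing_jacobian(system, chartpt), only.values = TRUE)$values
    if (all(Im(ev) == 0)) {
      ev <- Re(ev)
      ev <- ev[order(-abs(ev))]
      kind <- if (prod(sign(ev)) > 0) "node" else "saddle"
      ratio <- ev[1] / ev[2]
    } else {
      kind <- "focus"
      ratio <- NA_real_
    }
    counts <- if (kind == "node" && is.finite(ratio) && ratio > 1)
      predicted_canard_counts(ratio) else c(primary = NA, secondary = NA)
    structure(list(location = loc, chart = chartpt, eigenvalues = ev,
                   ratio = ratio, kind = kind,
                   predicted_primary = counts[[1]],
                   predicted_secondary = counts[[2]]),
              class = "folded_singularity")
  }
  if (system$name == "normal_form") return(list(mk(c(0, 0))))
  if (system$name != "hodgkin_huxley")
    stop("folded_singularities is defined for the built-in models only")
  out <- list()
  for (lab in c("F1", "F2")) {
    fc <- tryCatch(fold_curve(system, lab, sweep = sweep, n = 60),
                   error = function(e) NULL)
    if (is.null(fc) || nrow(fc$chart) < 2) next
    vfold <- function(hh, vlo, vhi)
      stats::uniroot(function(v)
        det(fast_jacobian(system, chart_point(system, c(v, hh)))),
        c(vlo, vhi), tol = 1e-13, extendInt = "yes")$root
    # transverse flow component of the desing system along the curve
    val <- vapply(seq_len(nrow(fc$chart)),
                  function(i) desing_rhs(system, fc$chart[i, ])[1], numeric(1))
    sgn <- which(diff(sign(val)) != 0)
    for (i in sgn) {
      root <- tryCatch({
        vlo <- min(fc$chart[i:(i + 1), 1]) - 0.02
        vhi <- max(fc$chart[i:(i + 1), 1]) + 0.02
        hstar <- stats::uniroot(function(hh)
          desing_rhs(system, c(vfold(hh, vlo, vhi), hh))[1],
          c(fc$chart[i, 2], fc$chart[i + 1, 2]), tol = 1e-12)$root
        c(vfold(hstar, vlo, vhi), hstar)
      }, error = function(e) NULL)
      if (!is.null(root)) out <- c(out, list(mk(root)))
    }
  }
  out
}

#' @export
print.folded_singularity <- function(x, ...) {
  cat(sprintf("<folded %s> at (%s)\n", x$kind,
              paste(format(x$location, digits = 6), collapse = ", ")))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 5), collapse = ", "),
      " ratio:", format(x$ratio, digits = 5), "\n")
  if (!is.na(x$predicted_primary))
    cat("  predicted canards: primary", x$predicted_primary,
        "secondary", x$predicted_secondary, "\n")
  invisible(x)
}

#' Predicted canard counts from the folded-node eigenvalue ratio
#'
#' For a folded node with eigenvalue ratio \eqn{\mu_{fs} > 1} (not an odd
#' integer), folded-node theory predicts two primary canard orbits and
#' \eqn{k} secondary canards where \eqn{k} is the number of integers
#' \eqn{k \ge 1} with \eqn{2k + 1 < \mu_{fs}}.
#'
#' @param ratio eigenvalue ratio (strong over weak), `> 1`.
#' @return named vector `c(primary = 2, secondary = k)`.
#' @export
predicted_canard_counts <- function(ratio) {
  if (!is.finite(ratio) || ratio <= 1)
    stop("degenerate folded node: eigenvalue ratio must exceed 1")
  if (abs(ratio - round(ratio)) < 1e-12 && round(ratio) %% 2 == 1)
    warning("odd-integer resonance: canard counts are degenerate")
  c(primary = 2, secondary = max(0L, floor((ratio - 1) / 2 - 1e-12)))
}

#' Equilibria of the full system
#'
#' Newton root solving of the full right-hand side, seeded from
#' critical-manifold chart points.  For the Hodgkin-Huxley model the
#' equilibrium condition reduces to a scalar equation in `v` (all gates at
#' steady state), which is solved by bracketing and polished by Newton on
#' the full 4D system.
#'
#' @param system a [slow_fast_system()].
#' @param v_range search interval in `v` (Hodgkin-Huxley).
#' @return list of `full_equilibrium` objects with `location`,
#'   `eigenvalues`, `type`, `stable_dim`, `unstable_dim`.
#' @export
full_equilibria <- function(system, v_range = c(-0.78, 0.4)) {
  if (system$name == "normal_form") return(list())  # dy/dt = eps never vanishes
  if (system$name != "hodgkin_huxley")
    stop("full_equilibria is implemented for the built-in models")
  p <- system$params
  fv <- function(v) {
    gt <- hh_gating(v)
    p[["I"]] / (p[["k_v"]] * p[["g"]]) -
      gt$minf^3 * gt$hinf * (v - p[["E_Na"]]) -
      p[["g_k"]] * gt$ninf^4 * (v - p[["E_K"]]) -
      p[["g_l"]] * (v - p[["E_L"]])
  }
  vg <- seq(v_range[1], v_range[2], length.out = 400)
  fg <- vapply(vg, fv, numeric(1))
  idx <- which(diff(sign(fg)) != 0)
  out <- lapply(idx, function(i) {
    v0 <- stats::uniroot(fv, c(vg[i], vg[i + 1]), tol = 1e-14)$root
    gt <- hh_gating(v0)
    u <- c(v0, gt$minf, gt$hinf, gt$ninf)
    u <- newton_solve(function(x) sf_rhs(system, x),
                      function(x) full_jacobian(system, x), u)$x
    ev <- eigen(full_jacobian(system, u), only.values = TRUE)$values
    ev <- ev[order(-Re(ev))]
    ns <- sum(Re(ev) < 0); nu <- sum(Re(ev) > 0)
    type <- if (ns == 4) "stable" else if (nu == 4) "unstable"
    else if (any(abs(Im(ev)) > 1e-10)) "saddle-focus" else "saddle"
    structure(list(location = u, eigenvalues = ev, type = type,
                   stable_dim = ns, unstable_dim = nu),
              class = "full_equilibrium")
  })
  out
}

#' @export
print.full_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium: %s> at (%s)\n", x$type,
              paste(format(x$location, digits = 6), collapse = ", ")))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# damped Newton for small dense systems
newton_solve <- function(f, jac, x0, tol = 1e-12, maxit = 50) {
  x <- x0
  for (it in seq_len(maxit)) {
    fx <- f(x)
    nf <- sqrt(sum(fx^2))
    if (nf < tol) return(list(x = x, iter = it, residual = nf, converged = TRUE))
    dx <- tryCatch(solve(jac(x), -fx), error = function(e) NULL)
    if (is.null(dx)) break
    lam <- 1
    repeat {
      xn <- x + lam * dx
      if (sqrt(sum(f(xn)^2)) < nf || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- x + lam * dx
  }
  list(x = x, iter = maxit, residual = sqrt(sum(f(x)^2)), converged = FALSE)
}
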