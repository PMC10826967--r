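# Fast/slow analysis of the 3-variable spiker (V fast; n, c slow):
# critical manifold, fold curve, desingularized reduced flow, folded-node
# location, eigenvalue ratio, and secondary-canard count.

#' Reduced model for fast/slow analysis
#'
#' The intrinsic spiker (`g_BK = 0`) has three variables: fast `V` and slow
#' `n`, `c`. An optional constant-partner input adds `g_c (V - V_fix)` to the
#' voltage equation, emulating gap-junction coupling to a cell clamped at
#' `V_fix`.
#'
#' @param params `cell_params` with `g_BK = 0`.
#' @param input optional list `list(g_c = , V_fix = )`.
#' @return object of class `reduced_model`.
#' @export
reduced_model <- function(params = spiker_params(), input = NULL) {
  if (params$g_BK != 0)
    stop("the fast/slow reduction applies to the spiker (g_BK = 0)")
  if (!is.null(input)) {
    stopifnot(is.numeric(input$g_c), input$g_c >= 0, is.numeric(input$V_fix))
  }
  structure(list(params = params, input = input), class = "reduced_model")
}

# V-only membrane currents S(V) = I_Ca + I_L + I_input and derivatives
fs_S <- function(V, m) {
  p <- m$params
  mm <- activation_inf(V, p$nu_m, p$l_m)
  s <- p$g_Ca * mm * (V - p$V_Ca) + p$g_L * (V - p$V_L)
  if (!is.null(m$input)) s <- s + m$input$g_c * (V - m$input$V_fix)
  s
}
fs_Sp <- function(V, m) {
  p <- m$params
  mm <- activation_inf(V, p$nu_m, p$l_m)
  s <- p$g_Ca * (mm * (1 - mm) / p$l_m * (V - p$V_Ca) + mm) + p$g_L
  if (!is.null(m$input)) s <- s + m$input$g_c
  s
}

# fast nullcline function F = dV/dt on the V equation (with m at equilibrium)
fs_F <- function(V, n, c, m) {
  p <- m$params
  -(p$g_Kdr * n * (V - p$V_K) + p$g_SK * sk_activation(c, p$k_SK) * (V - p$V_K) +
      fs_S(V, m)) / p$C_m
}
fs_FV <- function(V, n, c, m) {
  p <- m$params
  -(p$g_Kdr * n + p$g_SK * sk_activation(c, p$k_SK) + fs_Sp(V, m)) / p$C_m
}
fs_Fn <- function(V, m) -m$params$g_Kdr * (V - m$params$V_K) / m$params$C_m
fs_Fc <- function(V, c, m) {
  p <- m$params
  dd <- 2 * c * p$k_SK^2 / (c^2 + p$k_SK^2)^2
  -p$g_SK * dd * (V - p$V_K) / p$C_m
}

# slow derivatives on the manifold chart
fs_ndot <- function(V, n, m) (activation_inf(V, m$params$nu_n, m$params$l_n) - n) / m$params$tau_n
fs_cdot <- function(V, c, m) {
  p <- m$params
  ICa <- p$g_Ca * activation_inf(V, p$nu_m, p$l_m) * (V - p$V_Ca)
  -p$f_c * (p$alpha * ICa + p$k_c * c)
}

#' Critical-manifold value of n
#'
#' Solves the fast nullcline `F(V, n, c) = 0` for `n`, in which `F` is linear:
#' `n = -(I_Ca + I_SK + I_L + I_input) / (g_Kdr (V - V_K))`.
#'
#' @param V membrane potential (mV), not equal to `V_K`.
#' @param c cytosolic calcium (uM).
#' @param model a `reduced_model`.
#' @return the `n` value on the critical manifold.
#' @export
critical_manifold_n <- function(V, c, model) {
  p <- model$params
  den <- p$g_Kdr * (V - p$V_K)
  if (abs(den) < 1e-12) stop("V = V_K makes the manifold solve singular")
  -(p$g_SK * sk_activation(c, p$k_SK) * (V - p$V_K) + fs_S(V, model)) / den
}

#' Fold curve of the critical manifold
#'
#' On the critical manifold, the fold (loss of normal hyperbolicity of the fast
#' subsystem, `dF/dV = 0` with `F = 0`) occurs along lines of constant voltage:
#' both conditions depend on `n` and `c` only through the combination
#' `g_Kdr n + g_SK d_inf(c)`, so eliminating it leaves the scalar equation
#' `S(V) - S'(V) (V - V_K) = 0` in `V` alone. Returns all solutions in the
#' physiological voltage range.
#'
#' @param model a `reduced_model`.
#' @param V_range search interval (mV).
#' @return numeric vector of fold voltages (possibly empty).
#' @export
fold_voltages <- function(model, V_range = c(-74.9, 59.9)) {
  phi <- function(V) fs_S(V, model) - fs_Sp(V, model) * (V - model$params$V_K)
  Vg <- seq(V_range[1], V_range[2], length.out = 2000)
  ph <- vapply(Vg, phi, numeric(1))
  sgn <- which(diff(sign(ph)) != 0)
  roots <- vapply(sgn, function(i)
    stats::uniroot(phi, c(Vg[i], Vg[i + 1]), tol = 1e-13)$root, numeric(1))
  # Newton polish for tight residuals
  for (k in seq_along(roots)) {
    for (it in 1:3) {
      h <- 1e-6
      dphi <- (phi(roots[k] + h) - phi(roots[k] - h)) / (2 * h)
      roots[k] <- roots[k] - phi(roots[k]) / dphi
    }
  }
  sort(roots)
}

#' Desingularized reduced flow
#'
#' The slow flow on the critical manifold, written in the `(V, c)` chart by
#' total differentiation of the constraint `F(V, n, c) = 0` and rescaled by
#' `-dF/dV` (desingularization), which makes the field regular across the fold:
#' `V' = F_n ndot + F_c cdot`, `c' = -F_V cdot`, with `n` evaluated on the
#' manifold. Folded singularities are its equilibria on the fold.
#'
#' @param V membrane potential (mV).
#' @param c cytosolic calcium (uM).
#' @param model a `reduced_model`.
#' @return numeric vector `c(dV, dc)`.
#' @export
desingularized_rhs <- function(V, c, model) {
  n <- critical_manifold_n(V, c, model)
  nd <- fs_ndot(V, n, model)
  cd <- fs_cdot(V, c, model)
  c(dV = fs_Fn(V, model) * nd + fs_Fc(V, c, model) * cd,
    dc = -fs_FV(V, n, c, model) * cd)
}

#' Jacobian of the desingularized flow
#'
#' Richardson-extrapolated central finite differences of
#' [desingularized_rhs()].
#'
#' @param V,c evaluation point.
#' @param model a `reduced_model`.
#' @param h base step.
#' @return 2 x 2 Jacobian matrix.
#' @export
desingularized_jacobian <- function(V, c, model, h = 1e-4) {
  col_fd <- function(hh) {
    cbind((desingularized_rhs(V + hh, c, model) -
             desingularized_rhs(V - hh, c, model)) / (2 * hh),
          (desingularized_rhs(V, c + hh, model) -
             desingularized_rhs(V, c - hh, model)) / (2 * hh))
  }
  A1 <- col_fd(h); A2 <- col_fd(h / 2)
  (4 * A2 - A1) / 3
}

#' Locate and classify the folded singularity
#'
#' Solves the three defining conditions -- point on the critical manifold
#' (`F = 0`), on the fold (`dF/dV = 0`), and equilibrium of the desingularized
#' reduced flow (`F_n ndot + F_c cdot = 0`) -- by a scalar solve for the fold
#' voltage followed by a scalar solve along the fold line in `c`, then
#' classifies the singularity through the eigenvalues of the desingularized
#' Jacobian. A folded node has real eigenvalues of the same sign; its
#' eigenvalue ratio `mu = lambda_w / lambda_s` (weak over strong) lies in
#' (0, 1) and bounds the number of secondary canards.
#'
#' @param model a `reduced_model`.
#' @param box physiological search box, `list(V = c(lo, hi), c = c(lo, hi))`.
#' @return object of class `folded_node`: list with `found`, and when found
#'   `V`, `c`, `n`, `eigenvalues` (strong, weak), `mu`, `k` (secondary-canard
#'   count, `NA` at resonance), `type`, `residuals`.
#' @export
find_folded_node <- function(model,
                             box = list(V = c(-75, 60), c = c(0, 2))) {
  p <- model$params
  Vf <- fold_voltages(model, V_range = box$V + c(0.01, -0.01))
  candidates <- list()
  for (V0 in Vf) {
    G <- function(cc) {
      n <- critical_manifold_n(V0, cc, model)
      p$g_Kdr * fs_ndot(V0, n, model) +
        p$g_SK * (2 * cc * p$k_SK^2 / (cc^2 + p$k_SK^2)^2) * fs_cdot(V0, cc, model)
    }
    cg <- seq(max(box$c[1], 1e-4), box$c[2], length.out = 1000)
    gv <- vapply(cg, G, numeric(1))
    sgn <- which(diff(sign(gv)) != 0)
    for (i in sgn) {
      cs <- stats::uniroot(G, c(cg[i], cg[i + 1]), tol = 1e-14)$root
      ns <- critical_manifold_n(V0, cs, model)
      J <- desingularized_jacobian(V0, cs, model)
      ev <- eigen(J, only.values = TRUE)$values
      real_node <- all(abs(Im(ev)) < 1e-12) && prod(Re(ev)) > 0
      type <- if (!all(abs(Im(ev)) < 1e-12)) "folded focus"
              else if (prod(Re(ev)) < 0) "folded saddle"
              else "folded node"
      lam <- Re(ev)
      lam <- lam[order(abs(lam), decreasing = TRUE)]  # strong, weak
      mu <- if (real_node) abs(lam[2] / lam[1]) else NA_real_
      res <- c(F = abs(fs_F(V0, ns, cs, model)),
               F_V = abs(fs_FV(V0, ns, cs, model)),
               G = abs(G(cs)))
      candidates[[length(candidates) + 1L]] <- list(
        found = TRUE, V = V0, c = cs, n = ns,
        eigenvalues = lam, mu = mu,
        k = if (real_node) secondary_canard_count(mu) else NA_integer_,
        type = type, residuals = res)
    }
  }
  nodes <- Filter(function(x) x$type == "folded node", candidates)
  out <- if (length(nodes)) nodes[[1]]
         else if (length(candidates)) candidates[[1]]
         else list(found = FALSE, type = "no folded singularity")
  structure(out, class = "folded_node")
}

#' @export
print.folded_node <- function(x, ...) {
  if (!isTRUE(x$found)) {
    cat("<folded_node> no folded singularity found\n")
    return(invisible(x))
  }
  cat(sprintf("<%s> V* = %.4f mV, c* = %.5f uM, n* = %.5f\n",
              x$type, x$V, x$c, x$n))
  cat(sprintf("  eigenvalues (strong, weak) = (%.4g, %.4g), mu = %.5f\n",
              x$eigenvalues[1], x$eigenvalues[2], x$mu))
  if (!is.na(x$k)) cat(sprintf("  secondary canards (asymptotic bound): %d\n", x$k))
  invisible(x)
}

#' Secondary-canard count from the eigenvalue ratio
#'
#' For a folded node with eigenvalue ratio `mu` in (0, 1), the maximal number
#' of secondary canards is the integer `k` with `2k + 1 < 1/mu < 2k + 3`
#' (equivalently `k = floor((1/mu - 1) / 2)`). An odd-integer `1/mu` is a
#' resonance, at which the count is undefined.
#'
#' @param mu eigenvalue ratio, weak over strong, in (0, 1).
#' @param tol resonance detection tolerance on `1/mu`.
#' @return integer canard count (`NA` with a warning at resonance).
#' @export
secondary_canard_count <- function(mu, tol = 1e-9) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) ||
      mu <= 0 || mu >= 1)
    stop("mu must be a scalar in (0, 1)")
  inv <- 1 / mu
  near_odd <- abs(inv - (2 * round((inv - 1) / 2) + 1)) < tol
  if (near_odd) {
    warning("1/mu is an odd integer (resonance); canard count undefined")
    return(NA_integer_)
  }
  as.integer(floor((inv - 1) / 2))
}
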