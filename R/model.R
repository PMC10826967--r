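# Single-cell model: gating equilibria, ionic currents, right-hand side,
# and the secretion readout.

#' Voltage-dependent activation equilibrium
#'
#' Boltzmann sigmoid `1 / (1 + exp((nu - V) / l))`, the equilibrium value of a
#' voltage-gated activation variable with half-activation voltage `nu` and
#' slope factor `l`. Strictly increasing in `V`.
#'
#' @param V membrane potential (mV); vectorized.
#' @param nu half-activation voltage (mV).
#' @param l slope factor (mV), positive.
#' @return activation fraction in (0, 1).
#' @examples
#' activation_inf(-5, -5, 10)   # 0.5 at the midpoint
#' @export
activation_inf <- function(V, nu, l) {
  if (!all(is.finite(V))) stop("V must be finite")
  if (!is.finite(nu)) stop("nu must be finite")
  if (!is.finite(l) || l <= 0) stop("slope factor l must be positive")
  1 / (1 + exp((nu - V) / l))
}

#' Calcium-dependent SK channel activation
#'
#' Hill function of order 2, `c^2 / (c^2 + k_SK^2)`; increasing in `c` and
#' saturating at 1.
#'
#' @param c cytosolic calcium concentration (uM), non-negative; vectorized.
#' @param k_SK half-activation calcium (uM), positive.
#' @return activation fraction in \[0, 1).
#' @export
sk_activation <- function(c, k_SK = 0.4) {
  if (!all(is.finite(c))) stop("c must be finite")
  if (any(c < 0)) stop("calcium concentration must be non-negative")
  if (!is.finite(k_SK) || k_SK <= 0) stop("k_SK must be positive")
  c^2 / (c^2 + k_SK^2)
}

#' Cell state constructor
#'
#' @param V membrane potential (mV).
#' @param n delayed-rectifier activation, in \[0, 1\].
#' @param c cytosolic calcium (uM), non-negative.
#' @param b BK channel activation, in \[0, 1\].
#' @return named numeric vector of class `cell_state`.
#' @export
cell_state <- function(V = -60, n = 0.1, c = 0.1, b = 0.1) {
  if (!all(is.finite(c(V, n, c, b)))) stop("state components must be finite")
  if (n < 0 || n > 1 || b < 0 || b > 1) stop("gating variables must lie in [0, 1]")
  if (c < 0) stop("calcium concentration must be non-negative")
  structure(c(V = V, n = n, c = c, b = b), class = "cell_state")
}

#' Ionic currents of one cell
#'
#' Evaluates the five membrane currents at a given state, with the fast Ca2+
#' activation at quasi-equilibrium, `m = m_inf(V)`:
#' `I_Kdr = g_Kdr n (V - V_K)`, `I_Ca = g_Ca m_inf(V) (V - V_Ca)`,
#' `I_BK = g_BK b (V - V_K)`, `I_SK = g_SK d_inf(c) (V - V_K)`,
#' `I_L = g_L (V - V_L)`. Units are pA (nS times mV).
#'
#' @param state a `cell_state` (or named vector with `V`, `n`, `c`, `b`).
#' @param p a `cell_params` object.
#' @return named numeric vector `c(I_Kdr, I_Ca, I_BK, I_SK, I_L)` in pA.
#' @export
ionic_currents <- function(state, p) {
  V <- unname(state["V"]); n <- unname(state["n"])
  cc <- unname(state["c"]); b <- unname(state["b"])
  if (!all(is.finite(c(V, n, cc, b)))) stop("state components must be finite")
  m <- activation_inf(V, p$nu_m, p$l_m)
  c(I_Kdr = p$g_Kdr * n * (V - p$V_K),
    I_Ca  = p$g_Ca * m * (V - p$V_Ca),
    I_BK  = p$g_BK * b * (V - p$V_K),
    I_SK  = p$g_SK * sk_activation(cc, p$k_SK) * (V - p$V_K),
    I_L   = p$g_L * (V - p$V_L))
}

#' Right-hand side of the single-cell ODEs
#'
#' Time derivatives of the state `(V, n, c, b)` given a total gap-junction
#' current `I_c` flowing into the cell:
#' `dV/dt = -(I_Kdr + I_Ca + I_BK + I_SK + I_L + I_c) / C_m`,
#' `dn/dt = (n_inf(V) - n) / tau_n`,
#' `dc/dt = -f_c (alpha I_Ca + k_c c)`,
#' `db/dt = (b_inf(V) - b) / tau_b`.
#' For `g_BK = 0` the `b` component is dynamically inert (`I_BK = 0`).
#'
#' @param state a `cell_state`.
#' @param p a `cell_params` object.
#' @param I_c total coupling current into the cell (pA).
#' @return named numeric vector of derivatives (mV/ms, 1/ms, uM/ms, 1/ms).
#' @export
cell_rhs <- function(state, p, I_c = 0) {
  if (!is.finite(I_c)) stop("I_c must be finite")
  I <- ionic_currents(state, p)
  V <- unname(state["V"]); n <- unname(state["n"])
  cc <- unname(state["c"]); b <- unname(state["b"])
  c(dV = -(sum(I) + I_c) / p$C_m,
    dn = (activation_inf(V, p$nu_n, p$l_n) - n) / p$tau_n,
    dc = -p$f_c * (p$alpha * I["I_Ca"][[1]] + p$k_c * cc),
    db = (activation_inf(V, p$nu_b, p$l_b) - b) / p$tau_b)
}

#' Secretion readout
#'
#' Dimensionless secretion surrogate, an increasing sigmoid of the cytosolic
#' calcium concentration:
#' `s = 1 / (1 + exp(-5 ((c - 0.27) / 0.082 - 0.6)))`.
#' Its midpoint lies at `c = 0.3192` uM, between the calcium ranges typical of
#' spiking and bursting cells, so `s` rises substantially during each burst.
#'
#' @param c cytosolic calcium (uM), non-negative; vectorized.
#' @return secretion value in (0, 1).
#' @export
secretion <- function(c) {
  if (!all(is.finite(c))) stop("c must be finite")
  if (any(c < 0)) stop("calcium concentration must be non-negative")
  1 / (1 + exp(-5 * ((c - 0.27) / 0.082 - 0.6)))
}
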