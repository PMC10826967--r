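# Coupled-network simulation: gap-junction currents, fixed-step RK4
# integration (compiled core), and the voltage-clamped-partner protocol.

#' Simulation configuration
#'
#' @param dt integration step (ms). The reference protocol uses 0.5 ms.
#' @param t_end total simulated time (ms).
#' @param t_transient initial span discarded from analyses (ms).
#' @param g_c gap-junction coupling conductance (nS), applied to every edge.
#' @param seed RNG seed for the initial-condition jitter.
#' @param init optional explicit per-cell initial states: an `n x 4` matrix
#'   with columns `V`, `n`, `c`, `b`. When `NULL`, each cell starts from
#'   `V = -60` mV, `n = 0.1`, `c = 0.1` uM, `b = 0.1` with seeded jitter
#'   (uniform +-1 mV on `V`, +-5\% on `c`) to break artificial symmetry.
#' @param stride record every `stride`-th step (1 keeps every sample).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.5, t_end = 20000, t_transient = 10000,
                       g_c = 0.05, seed = 1L, init = NULL, stride = 1L) {
  stopifnot(dt > 0, t_end > 0, t_transient >= 0, t_transient < t_end, g_c >= 0)
  structure(list(dt = dt, t_end = t_end, t_transient = t_transient,
                 g_c = g_c, seed = seed, init = init, stride = as.integer(stride)),
            class = "sim_config")
}

default_init <- function(n_cells, seed = NULL, jitter = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  V <- rep(-60, n_cells); cc <- rep(0.1, n_cells)
  if (jitter && n_cells > 0) {
    V <- V + stats::runif(n_cells, -1, 1)
    cc <- cc * (1 + stats::runif(n_cells, -0.05, 0.05))
  }
  cbind(V = V, n = rep(0.1, n_cells), c = cc, b = rep(0.1, n_cells))
}

#' Total gap-junction current into a cell
#'
#' Ohmic bidirectional coupling: `sum_j g_c (V_i - V_j)` over the neighbors of
#' cell `i`. Pairwise antisymmetric: the current into the partner has the same
#' magnitude and opposite sign, so coupling currents cancel over the network.
#'
#' @param V_i membrane potential of the cell (mV).
#' @param neighbor_Vs potentials of its structural neighbors (mV).
#' @param g_c coupling conductance (nS).
#' @return current in pA.
#' @export
coupling_current <- function(V_i, neighbor_Vs, g_c) {
  stopifnot(g_c >= 0)
  if (!length(neighbor_Vs)) return(0)
  sum(g_c * (V_i - neighbor_Vs))
}

#' Generic fixed-step RK4 integrator (reference implementation)
#'
#' Classic 4th-order Runge-Kutta with a fixed step. This pure-R stepper is the
#' reference against which the compiled network integrator is cross-checked;
#' it is also usable for arbitrary small ODE systems.
#'
#' @param rhs function `(t, y) -> dy` returning the derivative vector.
#' @param y0 initial state vector.
#' @param dt step size.
#' @param n_steps number of steps.
#' @return list with `times` (length `n_steps + 1`) and `states`
#'   (`(n_steps + 1) x length(y0)` matrix).
#' @export
integrate_rk4 <- function(rhs, y0, dt, n_steps) {
  stopifnot(dt > 0, n_steps >= 1)
  y <- as.numeric(y0)
  out <- matrix(NA_real_, n_steps + 1, length(y))
  out[1, ] <- y
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * dt
    k1 <- rhs(t, y)
    k2 <- rhs(t + dt / 2, y + dt / 2 * k1)
    k3 <- rhs(t + dt / 2, y + dt / 2 * k2)
    k4 <- rhs(t + dt, y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(y)))
      stop("non-finite state at step ", i)
    out[i + 1, ] <- y
  }
  list(times = seq(0, n_steps * dt, by = dt), states = out)
}

make_trajectory <- function(raw, cfg, net = NULL) {
  s <- secretion(raw$c)
  dim(s) <- dim(raw$c)
  structure(list(times = as.numeric(raw$times),
                 V = raw$V, n = raw$n, c = raw$c, b = raw$b, s = s,
                 dt = cfg$dt * cfg$stride,
                 window = c(cfg$t_transient, cfg$t_end),
                 g_c = cfg$g_c, net = net),
            class = "pitnet_traj")
}

#' @export
print.pitnet_traj <- function(x, ...) {
  cat(sprintf("<pitnet_traj> %d cells, %.1f s at %.2g ms resolution (analysis window %.1f-%.1f s)\n",
              ncol(x$V), max(x$times) / 1000, x$dt,
              x$window[1] / 1000, x$window[2] / 1000))
  invisible(x)
}

# row indices of the analysis window
window_idx <- function(traj, window = traj$window) {
  which(traj$times >= window[1] & traj$times <= window[2])
}

#' Simulate a coupled cell network
#'
#' Integrates the full network with fixed-step RK4 (compiled core): every cell
#' follows the single-cell ODEs plus the gap-junction current
#' `sum_j g_c (V_i - V_j)` over its structural neighbors. Per-cell parameters
#' default to the reference burster/spiker sets selected by the node labels.
#'
#' @param net a labelled `cell_network`.
#' @param cfg a `sim_config`.
#' @param params optional list of `cell_params`, one per cell, overriding the
#'   label-derived defaults.
#' @return a `pitnet_traj`: uniform time grid plus per-cell `V`, `n`, `c`, `b`
#'   matrices and the derived secretion `s`.
#' @export
run_network <- function(net, cfg = sim_config(), params = NULL) {
  if (is.null(params)) {
    if (is.null(net$types)) stop("unlabelled network and no explicit params")
    params <- lapply(net$types, function(tp)
      if (tp == "b") burster_params() else spiker_params())
  }
  if (length(params) != net$n) stop("params must have one entry per cell")
  par <- params_matrix(params)
  init <- if (is.null(cfg$init)) default_init(net$n, cfg$seed) else cfg$init
  if (nrow(init) != net$n) stop("init must have one row per cell")
  n_steps <- round(cfg$t_end / cfg$dt)
  raw <- rk4_network_cpp(par, net$edges, init, cfg$dt, n_steps, cfg$g_c,
                         cfg$stride, -1L, 0, 0,
                         matrix(numeric(0), ncol = 2))
  make_trajectory(raw, cfg, net)
}

#' Simulate one uncoupled cell
#'
#' @param p a `cell_params` object.
#' @param cfg a `sim_config` (`g_c` is ignored; the cell has no neighbors).
#' @param init optional 1 x 4 initial state matrix.
#' @return single-cell `pitnet_traj`.
#' @export
run_single_cell <- function(p, cfg = sim_config(), init = NULL) {
  net <- cell_network(1L, matrix(integer(0), ncol = 2),
                      types = if (is_burster(p)) "b" else "s")
  if (!is.null(init)) cfg$init <- init
  run_network(net, cfg, params = list(p))
}

#' Clamped-partner protocol
#'
#' Simulates a single cell that receives the coupling current
#' `g_c (V - V_fix)` only inside given time windows, emulating a partner cell
#' voltage-clamped at `V_fix` during each of its burst active phases.
#'
#' @param p `cell_params` of the simulated cell (typically a spiker).
#' @param proto list with `V_fix` (mV), `windows` (k x 2 matrix of ms, ordered,
#'   non-overlapping) and `g_c` (nS).
#' @param cfg a `sim_config` (its `g_c` is not used; there are no edges).
#' @return single-cell `pitnet_traj`.
#' @export
run_with_clamped_partner <- function(p, proto, cfg = sim_config()) {
  windows <- proto$windows
  if (is.null(windows) || !nrow(windows))
    windows <- matrix(numeric(0), ncol = 2)
  else {
    windows <- matrix(as.numeric(windows), ncol = 2)
    if (any(diff(as.vector(t(windows))) < 0))
      stop("windows must be ordered and non-overlapping")
  }
  init <- if (is.null(cfg$init)) default_init(1L, cfg$seed) else cfg$init
  n_steps <- round(cfg$t_end / cfg$dt)
  raw <- rk4_network_cpp(params_matrix(list(p)),
                         matrix(integer(0), ncol = 2), init,
                         cfg$dt, n_steps, 0, cfg$stride,
                         0L, proto$g_c, proto$V_fix, windows)
  make_trajectory(raw, cfg)
}

#' Clamp protocol from a reference burster trace
#'
#' Detects the active phases of a reference (uncoupled burster) voltage trace
#' and returns a clamp protocol whose windows are those active phases and whose
#' clamp voltage is the mean voltage over the supra-threshold samples (the
#' plateau mean).
#'
#' @param traj single-cell `pitnet_traj` of the reference burster.
#' @param g_c coupling conductance for the emulated partner (nS).
#' @param cell column index of the reference cell (default 1).
#' @param ... passed to [detect_events()].
#' @return list with `V_fix`, `windows`, `g_c` suitable for
#'   [run_with_clamped_partner()].
#' @export
clamp_protocol_from_burster <- function(traj, g_c = 0.05, cell = 1L, ...) {
  V <- traj$V[, cell]
  ev <- detect_events(V, traj$dt, ...)
  if (!nrow(ev)) stop("no events detected in the reference trace")
  idx <- rep(FALSE, length(V))
  for (k in seq_len(nrow(ev)))
    idx[traj$times >= ev$t_start[k] & traj$times <= ev$t_end[k]] <- TRUE
  list(V_fix = mean(V[idx]),
       windows = as.matrix(ev[, c("t_start", "t_end")]),
       g_c = g_c)
}

#' Export a trajectory as a wide CSV
#'
#' Columns: `time`, then `cell<i>_V`, `cell<i>_n`, `cell<i>_c`, `cell<i>_b`,
#' `cell<i>_s` for each cell `i` (0-based ids).
#'
#' @param traj a `pitnet_traj`.
#' @param path output file.
#' @param stride optional extra down-sampling of rows.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path, stride = 1L) {
  rows <- seq(1, length(traj$times), by = stride)
  out <- data.frame(time = traj$times[rows])
  for (i in seq_len(ncol(traj$V))) {
    out[[sprintf("cell%d_V", i - 1)]] <- traj$V[rows, i]
    out[[sprintf("cell%d_n", i - 1)]] <- traj$n[rows, i]
    out[[sprintf("cell%d_c", i - 1)]] <- traj$c[rows, i]
    out[[sprintf("cell%d_b", i - 1)]] <- traj$b[rows, i]
    out[[sprintf("cell%d_s", i - 1)]] <- traj$s[rows, i]
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
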