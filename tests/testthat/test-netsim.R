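# coupling current, RK4 integrators (R reference and compiled network core),
# conservation/determinism/symmetry invariants, clamped-partner protocol

test_that("coupling current follows the ohmic pairwise form", {
  expect_equal(coupling_current(-50, c(-50, -50), 0.05), 0)
  expect_equal(coupling_current(-20, -60, 0.05), 2)          # 0.05 * 40
  expect_equal(coupling_current(-60, -20, 0.05),
               -coupling_current(-20, -60, 0.05))            # antisymmetric
  expect_equal(coupling_current(-20, numeric(0), 0.05), 0)
})

test_that("RK4 reference stepper is 4th order on the exponential", {
  rhs <- function(t, y) -y
  err <- function(dt) {
    out <- integrate_rk4(rhs, 1, dt, round(5 / dt))
    max(abs(out$states[, 1] - exp(-out$times)))
  }
  e1 <- err(0.1); e2 <- err(0.05)
  expect_lt(e1, 1e-6)
  expect_equal(e1 / e2, 16, tolerance = 0.1)                 # halving dt: ~2^4
  # constant field stays constant
  flat <- integrate_rk4(function(t, y) 0 * y, c(2, -3), 0.1, 50)
  expect_true(all(flat$states[, 1] == 2 & flat$states[, 2] == -3))
  expect_error(suppressWarnings(integrate_rk4(function(t, y) sqrt(y - 2),
                                              1, 0.1, 10)), "step")
})

test_that("compiled network integrator matches the pure-R RK4 oracle", {
  net <- pair_network()
  params <- list(burster_params(), spiker_params())
  init <- cbind(V = c(-60, -55), n = c(0.1, 0.12), c = c(0.1, 0.11),
                b = c(0.1, 0.1))
  cfg <- sim_config(dt = 0.5, t_end = 500, t_transient = 0, g_c = 0.05,
                    init = init)
  traj <- run_network(net, cfg, params)
  # independent route: generic R stepper on the assembled 8-dim system
  rhs8 <- function(t, y) {
    s1 <- y[1:4]; s2 <- y[5:8]
    names(s1) <- names(s2) <- c("V", "n", "c", "b")
    I12 <- coupling_current(s1["V"], s2["V"], 0.05)
    c(cell_rhs(s1, params[[1]], I12), cell_rhs(s2, params[[2]], -I12))
  }
  ref <- integrate_rk4(rhs8, c(init[1, ], init[2, ]), 0.5, 1000)
  expect_lt(max(abs(traj$V[, 1] - ref$states[, 1])), 1e-9)
  expect_lt(max(abs(traj$V[, 2] - ref$states[, 5])), 1e-9)
  expect_lt(max(abs(traj$c[, 1] - ref$states[, 3])), 1e-12)
})

test_that("decoupled network equals per-cell single runs, and is deterministic", {
  net <- path_network(3, types = c("b", "s", "b"))
  cfg <- sim_config(t_end = 2000, t_transient = 0, g_c = 0, seed = 4)
  traj <- run_network(net, cfg)
  init <- pitnet:::default_init(3, seed = 4)
  for (i in 1:3) {
    p <- if (net$types[i] == "b") burster_params() else spiker_params()
    single <- run_single_cell(p, sim_config(t_end = 2000, t_transient = 0,
                                            g_c = 0,
                                            init = init[i, , drop = FALSE]))
    expect_identical(traj$V[, i], single$V[, 1])
  }
  again <- run_network(net, cfg)
  expect_identical(traj$V, again$V)     # bit-identical rerun
  expect_identical(traj$c, again$c)
})

test_that("gap-junction currents cancel over the network at every step", {
  net <- cell_network(4, rbind(c(0, 1), c(1, 2), c(2, 3), c(0, 3), c(0, 2)),
                      types = c("b", "s", "s", "b"))
  cfg <- sim_config(t_end = 1000, t_transient = 0, g_c = 0.05, seed = 2)
  traj <- run_network(net, cfg)
  nb <- pitnet:::neighbor_list(net)
  total <- sapply(seq_along(traj$times), function(t) {
    sum(sapply(1:4, function(i)
      coupling_current(traj$V[t, i], traj$V[t, nb[[i]]], 0.05)))
  })
  expect_lt(max(abs(total)), 1e-10)
})

test_that("identical coupled bursters with identical initial states stay exactly synchronous", {
  net <- pair_network(c("b", "b"))
  init <- cbind(V = c(-60, -60), n = c(0.1, 0.1), c = c(0.1, 0.1), b = c(0.1, 0.1))
  cfg <- sim_config(t_end = 5000, t_transient = 0, g_c = 0.05, init = init)
  traj <- run_network(net, cfg)
  expect_identical(traj$V[, 1], traj$V[, 2])
  expect_identical(traj$c[, 1], traj$c[, 2])
})

test_that("event classification is stable under step halving for the coupled pair", {
  net <- pair_network()
  init <- pitnet:::default_init(2, seed = 1)
  mk <- function(dt) {
    cfg <- sim_config(dt = dt, t_end = 12000, t_transient = 6000, g_c = 0.05,
                      init = init)
    traj <- run_network(net, cfg)
    event_train(traj, 2)$label
  }
  lab1 <- mk(0.5)
  lab2 <- mk(0.25)
  expect_gt(length(lab1), 3)
  expect_identical(lab1, lab2)
})

test_that("clamped-partner protocol reduces to the plain run at g_c = 0 and induces bursts with burst-phase windows", {
  p <- spiker_params()
  cfg <- sim_config(t_end = 20000, t_transient = 8000, g_c = 0, seed = 6)
  plain <- run_single_cell(p, cfg)
  off <- run_with_clamped_partner(
    p, list(V_fix = -20, windows = rbind(c(1000, 2000)), g_c = 0), cfg)
  expect_identical(plain$V[, 1], off$V[, 1])
  # reference burster's active phases as windows, plateau mean as clamp level
  ref <- run_single_cell(burster_params(), cfg)
  proto <- clamp_protocol_from_burster(ref, g_c = 0.05)
  expect_true(proto$V_fix > -40 && proto$V_fix < 0)
  clamped <- run_with_clamped_partner(p, proto, cfg)
  ev <- event_train(clamped, 1)
  expect_gt(nrow(ev), 3)
  # pulses of elevated voltage induce bursting during a majority of the
  # input windows (between windows the cell spikes freely)
  win <- proto$windows[proto$windows[, 1] >= cfg$t_transient, , drop = FALSE]
  hit <- apply(win, 1, function(w) {
    ov <- ev$t_end > w[1] & ev$t_start < w[2]
    any(ev$n_peaks[ov] >= 2)
  })
  expect_gt(mean(hit), 0.5)
})

test_that("trajectory CSV export has the wide per-cell layout", {
  net <- pair_network()
  traj <- run_network(net, sim_config(t_end = 200, t_transient = 0, seed = 1))
  f <- tempfile(fileext = ".csv")
  export_trajectory(traj, f)
  x <- utils::read.csv(f)
  expect_equal(names(x)[1:6],
               c("time", "cell0_V", "cell0_n", "cell0_c", "cell0_b", "cell0_s"))
  expect_equal(nrow(x), length(traj$times))
  expect_equal(x$cell1_V, traj$V[, 2])
})
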