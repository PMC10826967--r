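# single-cell model: gating equilibria, currents, right-hand side, secretion

test_that("activation equilibrium is the Boltzmann sigmoid", {
  expect_equal(activation_inf(-5, -5, 10), 0.5)
  expect_equal(activation_inf(-20, -20, 12), 0.5)
  expect_equal(activation_inf(-75, -5, 10), 1 / (1 + exp(7)))
  # strictly increasing in V
  V <- seq(-80, 40, by = 5)
  expect_true(all(diff(activation_inf(V, -5, 10)) > 0))
  expect_error(activation_inf(NaN, -5, 10), "finite")
  expect_error(activation_inf(-5, -5, -1), "positive")
})

test_that("SK activation is a Hill function of calcium", {
  expect_equal(sk_activation(0.4, 0.4), 0.5)
  expect_equal(sk_activation(0), 0)
  expect_equal(sk_activation(0.8, 0.4), 0.8)  # 0.64 / (0.64 + 0.16)
  cc <- seq(0, 3, by = 0.1)
  expect_true(all(diff(sk_activation(cc)) > 0))
  expect_lt(1 - sk_activation(1e4), 1e-6)
  expect_error(sk_activation(-0.1), "non-negative")
})

test_that("ionic currents follow their defining expressions", {
  p <- burster_params()
  st <- cell_state(V = p$V_L, n = 0.3, c = 0.2, b = 0.2)
  expect_equal(unname(ionic_currents(st, p)["I_L"]), 0)
  st0 <- cell_state(V = 0, n = 0, c = 0.2, b = 0.2)
  expect_equal(unname(ionic_currents(st0, p)["I_Kdr"]), 0)
  st1 <- cell_state(V = 0, n = 0.5, c = 0.2, b = 0.2)
  expect_equal(unname(ionic_currents(st1, p)["I_Kdr"]), 93.75)  # 2.5*0.5*(0-(-75))
  # current units: nS * mV = pA; I_Ca is inward (negative) below V_Ca
  expect_lt(unname(ionic_currents(st1, p)["I_Ca"]), 0)
})

test_that("cell_rhs assembles the ODE right-hand side", {
  p0 <- cell_params(g_Kdr = 0, g_Ca = 0, g_L = 0, g_SK = 0, g_BK = 0)
  st <- cell_state(V = -40, n = 0.2, c = 0.2, b = 0.2)
  expect_equal(unname(cell_rhs(st, p0)["dV"]), 0)
  p <- burster_params()
  st_eq <- cell_state(V = -40, n = activation_inf(-40, p$nu_n, p$l_n),
                      c = 0.2, b = 0.2)
  expect_equal(unname(cell_rhs(st_eq, p)["dn"]), 0)
  expect_error(cell_rhs(st, p, I_c = Inf), "finite")
})

test_that("the spiker right-hand side vanishes at its numerically located rest state", {
  # scalar reduction oracle: at equilibrium n = n_inf(V), c = -alpha I_Ca / k_c,
  # and V solves the resulting current balance
  p <- spiker_params()
  bal <- function(V) {
    ICa <- p$g_Ca * activation_inf(V, p$nu_m, p$l_m) * (V - p$V_Ca)
    cc <- max(-p$alpha * ICa / p$k_c, 0)
    n <- activation_inf(V, p$nu_n, p$l_n)
    ICa + p$g_Kdr * n * (V - p$V_K) +
      p$g_SK * sk_activation(cc, p$k_SK) * (V - p$V_K) + p$g_L * (V - p$V_L)
  }
  Vg <- seq(-70, 0, by = 0.5)
  sgn <- which(diff(sign(sapply(Vg, bal))) != 0)[1]
  Veq <- uniroot(bal, c(Vg[sgn], Vg[sgn + 1]), tol = 1e-14)$root
  ICa <- p$g_Ca * activation_inf(Veq, p$nu_m, p$l_m) * (Veq - p$V_Ca)
  st <- cell_state(V = Veq, n = activation_inf(Veq, p$nu_n, p$l_n),
                   c = -p$alpha * ICa / p$k_c,
                   b = activation_inf(Veq, p$nu_b, p$l_b))
  expect_lt(max(abs(cell_rhs(st, p))), 1e-10)
})

test_that("secretion readout is the calibrated sigmoid of calcium", {
  expect_equal(secretion(0.27 + 0.6 * 0.082), 0.5)
  expect_equal(secretion(0), 1 / (1 + exp(5 * (0.27 / 0.082 + 0.6))), tolerance = 1e-12)
  expect_lt(secretion(0), 1e-8)
  expect_gt(secretion(10), 1 - 1e-10)
  cc <- seq(0, 0.6, by = 0.02)   # double precision saturates above ~0.7 uM
  expect_true(all(diff(secretion(cc)) > 0))
  expect_error(secretion(-0.1), "non-negative")
})

test_that("uncoupled burster bursts, uncoupled spiker spikes, with higher calcium and secretion in the burster", {
  cfg <- sim_config(t_end = 30000, t_transient = 10000, g_c = 0, seed = 3)
  trb <- run_single_cell(burster_params(), cfg)
  trs <- run_single_cell(spiker_params(), cfg)
  evb <- event_train(trb, 1)
  evs <- event_train(trs, 1)
  expect_gt(nrow(evb), 5)
  expect_gt(nrow(evs), 5)
  expect_true(all(evb$n_peaks >= 2))          # pseudo-plateau bursts
  expect_true(all(evs$n_peaks == 1))          # tonic spikes
  idx <- pitnet:::window_idx(trb)
  expect_gt(mean(trb$c[idx, 1]), mean(trs$c[idx, 1]))
  expect_gt(mean(trb$s[idx, 1]), mean(trs$s[idx, 1]))
  # state-space invariants along both trajectories
  for (tr in list(trb, trs)) {
    expect_true(all(tr$n >= 0 & tr$n <= 1))
    expect_true(all(tr$b >= 0 & tr$b <= 1))
    expect_true(all(tr$c > 0))
  }
})

test_that("cell parameters validate and round-trip through JSON", {
  expect_error(cell_params(g_BK = -1), "conductances")
  expect_error(cell_params(f_c = 0), "f_c")
  expect_error(cell_params(nonsense = 1), "unknown")
  p <- cell_params(g_BK = 0, g_SK = 1.7)
  f <- tempfile(fileext = ".json")
  write_cell_params(p, f)
  expect_equal(unclass(read_cell_params(f)), unclass(p))
  # missing keys fall back to reference values
  jsonlite::write_json(list(g_BK = 0), f, auto_unbox = TRUE)
  q <- read_cell_params(f)
  expect_equal(q$g_BK, 0)
  expect_equal(q$g_Kdr, 2.5)
  expect_false(is_burster(q))
  expect_true(is_burster(cell_params()))
})
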