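# event detection, classification, conversion, periodicity, synchrony

# synthetic supra-threshold envelope with k peaks 40 ms apart: gaussian bumps
# to -10 mV whose overlap stays above V_off = -45 between peaks
multi_peak_event <- function(center, k, sep = 40) {
  force(center); force(k); force(sep)
  function(t) {
    v <- 0
    for (j in seq_len(k) - 1)
      v <- v + 50 * exp(-((t - center - j * sep) / 15)^2)
    v
  }
}

test_that("hysteresis detector finds isolated events and counts prominent peaks", {
  dt <- 0.5
  t <- seq(0, 2000, by = dt)
  flat <- rep(-60, length(t))
  expect_equal(nrow(detect_events(flat, dt)), 0)
  one <- -60 + 45 * exp(-((t - 800) / 40)^2)
  ev <- detect_events(one, dt)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_peaks, 1L)
  expect_lt(abs((ev$t_start + ev$t_end) / 2 - 800), 25)
  # two-peak envelope -> one event, two peaks
  V2 <- -60 + multi_peak_event(1000, 2)(t)
  ev2 <- detect_events(V2, dt)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$n_peaks, 2L)
  expect_error(detect_events(one, dt, V_on = -45, V_off = -35), "hysteresis")
})

test_that("classification covers spikes, doublets, k-spike bursts and long bursts", {
  ev <- data.frame(t_start = c(100), t_end = c(130), n_peaks = 1L)
  expect_equal(classify_events(ev)$label, "spike")
  ev <- data.frame(t_start = c(100, 160), t_end = c(130, 190),
                   n_peaks = c(1L, 1L))
  cl <- classify_events(ev)            # 30 ms gap < 40 ms: merged doublet
  expect_equal(nrow(cl), 1)
  expect_equal(cl$label, "doublet")
  expect_equal(cl$n_peaks, 2L)
  ev$t_start[2] <- 200                 # 70 ms gap: two separate spikes
  expect_equal(classify_events(ev)$label, c("spike", "spike"))
  expect_equal(classify_events(data.frame(t_start = 0, t_end = 80,
                                          n_peaks = 2L))$label, "2-spike burst")
  expect_equal(classify_events(data.frame(t_start = 0, t_end = 150,
                                          n_peaks = 4L))$label, "4-spike burst")
  # a burst much longer than the median burst is relabelled
  ev <- data.frame(t_start = c(0, 300, 600), t_end = c(100, 400, 900),
                   n_peaks = c(2L, 2L, 3L))
  expect_equal(classify_events(ev)$label,
               c("2-spike burst", "2-spike burst", "long burst"))
})

test_that("classification is invariant to sub-threshold noise and time reversal preserves event count", {
  set.seed(42)
  dt <- 0.5
  t <- seq(0, 4000, by = dt)
  V <- -60 + multi_peak_event(1000, 2)(t) + multi_peak_event(2500, 3)(t)
  clean <- classify_events(detect_events(V, dt))
  noisy <- classify_events(detect_events(V + runif(length(t), -0.25, 0.25), dt))
  expect_identical(noisy$label, clean$label)
  expect_equal(nrow(detect_events(rev(V), dt)), nrow(detect_events(V, dt)))
})

test_that("conversion flag reflects the burst fraction", {
  spikes <- classify_events(data.frame(t_start = c(0, 300), t_end = c(30, 330),
                                       n_peaks = c(1L, 1L)))
  r <- is_converted_burster(spikes)
  expect_false(r$converted)
  expect_equal(r$burst_fraction, 0)
  mixed <- classify_events(data.frame(t_start = c(0, 300, 600),
                                      t_end = c(100, 400, 700),
                                      n_peaks = c(2L, 2L, 1L)))
  r <- is_converted_burster(mixed)
  expect_true(r$converted)
  expect_equal(r$burst_fraction, 2 / 3)
  empty <- classify_events(data.frame(t_start = numeric(0), t_end = numeric(0),
                                      n_peaks = integer(0)))
  expect_true(is.na(is_converted_burster(empty)$converted))
})

test_that("minimal period is found by exact symbol matching", {
  expect_equal(minimal_period(c("a", "b", "a", "b")), 2L)
  expect_equal(minimal_period(rep("a", 4)), 1L)
  cyc <- letters[1:12]
  expect_equal(minimal_period(rep(cyc, 3)), 12L)
  expect_true(is.na(minimal_period(c("a", "b", "c", "a", "b", "d"))))
  # any other detected period is a multiple of the minimal one
  set.seed(1)
  for (rep_i in 1:20) {
    k <- sample(1:4, 1)
    s <- rep(sample(letters[1:3], k, replace = TRUE), 6)
    k0 <- minimal_period(s)
    n <- length(s)
    others <- Filter(function(kk) all(s[seq_len(n - kk)] == s[seq_len(n - kk) + kk]),
                     seq_len(n %/% 2))
    expect_true(all(others %% k0 == 0))
  }
})

test_that("synchrony index: identical traces 1, independent noise ~0, constant trace excluded", {
  set.seed(7)
  x <- cumsum(rnorm(4000))
  expect_equal(synchrony_index(cbind(x, x), max_lag_ms = 0), 1)
  wn <- matrix(rnorm(2 * 20000), ncol = 2)
  expect_lt(abs(synchrony_index(wn, max_lag_ms = 0)), 0.05)
  expect_lt(abs(synchrony_index(wn, max_lag_ms = 10, lag_step_ms = 1)), 0.05)
  cst <- cbind(x, rep(1, length(x)))
  expect_warning(r <- synchrony_index(cst, max_lag_ms = 0), "constant")
  expect_true(is.na(r))
})
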