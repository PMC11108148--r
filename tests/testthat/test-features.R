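# Feature extraction: spike detection, firing frequency, latency,
# depolarization-block onset, resting QoIs.

# rendered trace with three clean spikes
three_spike_trace <- function(dt = 1e-3) {
  t <- seq(0, 2, by = dt)
  v <- rep(-70, length(t))
  for (ts in c(0.5, 0.8, 1.4)) {
    seg <- t >= ts & t <= ts + 0.004
    v[seg] <- -70 + 80 * (t[seg] - ts) / 0.004
    seg2 <- t > ts + 0.004 & t <= ts + 0.008
    v[seg2] <- 10 - 80 * (t[seg2] - ts - 0.004) / 0.004
  }
  list(t = t, v = v)
}

test_that("spike detection counts threshold-crossing bumps with refractoriness", {
  tr <- three_spike_trace()
  sp <- detect_aps(tr)
  expect_length(sp$times, 3)
  # crossing time is interpolated on the linear upstroke: exact to float
  expect_equal(sp$times, c(0.5, 0.8, 1.4) + 0.004 * 50 / 80, tolerance = 1e-9)
  # flat subthreshold trace: no spikes
  expect_length(detect_aps(list(t = tr$t, v = rep(-70, length(tr$t))))$times, 0)
  # non-uniform grids are rejected
  expect_error(detect_aps(list(t = cumsum(runif(100)), v = rnorm(100))),
               "uniform")
})

test_that("final frequency is the window count over 1.5 s, exactly", {
  mk <- function(times) structure(list(times = times), class = "spike_train")
  expect_equal(final_frequency(mk(seq(4.05, 5.45, length.out = 13))), 13 / 1.5)
  expect_equal(final_frequency(mk(numeric(0))), 0)
  # doubling the in-window count doubles the value
  expect_equal(final_frequency(mk(seq(4.05, 5.45, length.out = 26))),
               2 * final_frequency(mk(seq(4.05, 5.45, length.out = 13))))
  # spikes outside (4, 5.5) s do not count
  expect_equal(final_frequency(mk(c(1, 2, 3))), 0)
})

test_that("first-spike latency propagates the undefined marker", {
  mk <- function(times) structure(list(times = times), class = "spike_train")
  expect_equal(time_before_first_ap(mk(0.2078), 0.2), 7.8, tolerance = 1e-9)
  expect_equal(time_before_first_ap(mk(0.2), 0.2), 0)
  expect_true(is.na(time_before_first_ap(mk(numeric(0)), 0.2)))
  # spikes before onset are ignored
  expect_equal(time_before_first_ap(mk(c(0.1, 0.3)), 0.2), 100)
})

test_that("depolarization-block onset finds sustained depolarized plateaus", {
  dt <- 1e-3
  t <- seq(0, 3, by = dt)
  v <- rep(-70, length(t))
  for (ts in seq(0.3, 1.9, by = 0.1)) {  # spikes until ~2 s
    seg <- t >= ts & t <= ts + 0.004
    v[seg] <- -70 + 80 * (t[seg] - ts) / 0.004
    seg2 <- t > ts + 0.004 & t <= ts + 0.008
    v[seg2] <- 10 - 80 * (t[seg2] - ts - 0.004) / 0.004
  }
  v[t >= 2.0] <- -30  # constant depolarized plateau
  onset <- depolarization_block_onset(list(t = t, v = v))
  expect_lt(abs(onset - 2.0), 2 * dt + 1e-9)
  # a trace that never stops spiking yields the undefined marker
  vv <- rep(-70, length(t))
  for (ts in seq(0.3, 2.9, by = 0.1)) {
    seg <- t >= ts & t <= ts + 0.004
    vv[seg] <- -70 + 80 * (t[seg] - ts) / 0.004
    seg2 <- t > ts + 0.004 & t <= ts + 0.008
    vv[seg2] <- 10 - 80 * (t[seg2] - ts - 0.004) / 0.004
  }
  expect_true(is.na(depolarization_block_onset(list(t = t, v = vv))))
  # no spikes at all: undefined
  expect_true(is.na(depolarization_block_onset(list(t = t, v = rep(-70, length(t))))))
})

test_that("feature extraction is grid-convergent", {
  for (dt in c(1e-3, 5e-4)) {
    tr <- three_spike_trace(dt)
    expect_length(detect_aps(tr)$times, 3)
  }
  # halving the grid moves the interpolated spike times by < one coarse step
  t1 <- detect_aps(three_spike_trace(1e-3))$times
  t2 <- detect_aps(three_spike_trace(5e-4))$times
  expect_lt(max(abs(t1 - t2)), 1e-3)
})

test_that("resting QoIs at rest equal the calibration values", {
  p <- nominal_parameters()
  y0 <- resting_state()
  cfg <- solver_config(dt_max = 5000, t_end = 30, grid_dt = 30000)
  q <- resting_qois(edneg_simulate(p, y0, NULL, cfg))
  phi <- solve_potentials(y0, p)
  expect_equal(q[["phi_msn"]], phi[["phi_msn"]], tolerance = 1e-4)
  expect_equal(q[["K_se"]], y0[["K_se"]] / y0[["V_se"]], tolerance = 1e-4)
  # spike-generating conductances have negligible resting influence ...
  for (nm in c("g_Na", "g_DR", "g_C")) {
    args <- as.list(setNames(edneg_nominal("all")[nm] * 1.15, nm))
    qq <- resting_qois(edneg_simulate(do.call(edneg_parameters, args), y0, NULL, cfg))
    expect_true(all(abs(qq - q) / abs(q) < 1e-3), label = nm)
  }
  # ... while a leak conductance moves the resting state measurably
  qk <- resting_qois(edneg_simulate(edneg_parameters(g_K_leak_n = 0.0245 * 1.15),
                                    y0, NULL, cfg))
  expect_gt(max(abs(qk - q) / abs(q)), 1e-3)
})
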