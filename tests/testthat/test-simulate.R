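# Integration: trajectory well-formedness, resting stability, conservation
# along trajectories, stimulus delivery, convergence.

test_that("stimulus delivery converts current to a conserved K+ rate pair", {
  stim <- stimulus_protocol(8e-5, 0.2, 5.5)
  # outside the window: nothing
  expect_equal(unname(apply_stimulus(stim, 100)), c(0, 0))
  expect_equal(unname(apply_stimulus(stim, 5600)), c(0, 0))
  inside <- apply_stimulus(stim, 1000)
  # source and sink cancel exactly at all times
  expect_equal(sum(inside), 0)
  # current / F with z = +1: 8e-5 uA = 8e-14 C/ms -> amol/ms
  expect_equal(inside[["soma_neuron"]], 8e-5 * 1e9 / 96480, tolerance = 1e-12)
  # amplitude scaling is linear: 20e-5 uA is exactly 2.5x the 8e-5 rate
  stim2 <- stimulus_protocol(20e-5, 0.2, 5.5)
  expect_equal(apply_stimulus(stim2, 1000)[["soma_neuron"]],
               2.5 * inside[["soma_neuron"]])
  expect_error(stimulus_protocol(-1, 0.2, 5.5), "non-negative")
  expect_error(stimulus_protocol(1e-5, 2, 1), "onset")
})

test_that("trajectories are well-formed on the analysis grid", {
  tr <- physiological_trajectory()
  expect_s3_class(tr, "edneg_trajectory")
  expect_true(all(diff(tr$time) > 0))
  expect_equal(length(tr$time), 6001)
  expect_false(any(!is.finite(tr$state)))
  expect_false(any(!is.finite(tr$phi)))
  expect_true(all(tr$state[, 29:34] > 0))
  expect_true(all(tr$state[, 23:28] >= -1e-9 & tr$state[, 23:28] <= 1 + 1e-9))
})

test_that("calibrated rest is stable: 240 s stimulus-free drift below 0.1%", {
  p <- nominal_parameters()
  y0 <- resting_state()
  cfg <- solver_config(dt_max = 5000, t_end = 240, grid_dt = 240000)
  tr <- edneg_simulate(p, y0, NULL, cfg)
  q0 <- resting_qois(tr)  # final time
  phi0 <- solve_potentials(y0, p)
  ref <- c(phi0[["phi_msn"]], phi0[["phi_mdn"]], phi0[["phi_msg"]],
           phi0[["phi_mdg"]], y0[["K_se"]] / y0[["V_se"]],
           y0[["K_de"]] / y0[["V_de"]])
  expect_true(all(abs(q0 - ref) / abs(ref) < 1e-3))
})

test_that("per-species totals and volume are conserved along trajectories", {
  tots <- function(state) {
    cbind(Na = rowSums(state[, 1:6]), K = rowSums(state[, 7:12]),
          Cl = rowSums(state[, 13:18]), Ca = rowSums(state[, 19:22]),
          V = rowSums(state[, 29:34]))
  }
  for (tr in list(physiological_trajectory(), pathological_trajectory())) {
    tt <- tots(tr$state)
    rel <- abs(sweep(tt, 2, tt[1, ], "-")) / matrix(tt[1, ], nrow(tt), 5, byrow = TRUE)
    # total K+ is conserved *during* stimulation (matched source/sink)
    expect_lt(max(rel), 1e-9)
  }
})

test_that("grid outputs are solver-step independent below convergence", {
  p <- nominal_parameters()
  y0 <- resting_state()
  stim <- stimulus_protocol(8e-5, 0.2, 5.5)
  tr10 <- edneg_simulate(p, y0, stim,
                         solver_config(t_end = 2, dt_max = 10, rtol = 1e-9))
  tr5 <- edneg_simulate(p, y0, stim,
                        solver_config(t_end = 2, dt_max = 5, rtol = 1e-9))
  n10 <- length(detect_aps(tr10)$times)
  n5 <- length(detect_aps(tr5)$times)
  expect_equal(n10, n5)
  expect_lt(max(abs(concentration(tr10, "K", "se") -
                    concentration(tr5, "K", "se"))), 1e-3)
})

test_that("convergence scan reports comparable rows against the reference", {
  p <- nominal_parameters()
  y0 <- resting_state()
  stim <- stimulus_protocol(8e-5, 0.2, 5.5)
  cfg <- solver_config(t_end = 1.5)
  sc <- convergence_scan(p, y0, stim, methods = c("radau", "radau"),
                         dt_max = 10, cfg = cfg)
  # identical configurations give identical rows
  expect_equal(sc$n_ap[1], sc$n_ap[2])
  expect_equal(sc$K_se_end[1], sc$K_se_end[2])
  # the default configuration matches the tightened reference spike count
  expect_equal(sc$d_n_ap[1], 0)
  expect_true(sc$reference[nrow(sc)])
})
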