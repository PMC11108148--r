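# Forward-model operations: dimensions, electrochemistry, flux structure,
# the algebraic potential solve, gating kinetics, water flow, Jacobian.

test_that("state and output dimensions decompose as 22 + 6 + 6 and 10", {
  nm <- edneg_state_names()
  expect_length(nm, 34)
  expect_length(grep("^(Na|K|Cl|Ca)_", nm), 22)
  expect_length(grep("^Ca_", nm), 4)         # Ca absent from glia
  expect_identical(nm[23:28], c("n", "h", "s", "c", "q", "z"))
  expect_length(grep("^V_", nm), 6)
  expect_length(edneg_phi_names(), 10)
})

test_that("Nernst potential follows (RT/zF) ln(cout/cin)", {
  expect_equal(nernst_potential(1, 5, 5), 0)
  # concentration ratio e gives exactly RT/F (in mV)
  psi <- 8.314 * 309.14 / 96480 * 1000
  expect_equal(nernst_potential(1, 1, exp(1)), psi, tolerance = 1e-12)
  # divalent ion: half the monovalent value
  expect_equal(nernst_potential(2, 3, 12), nernst_potential(1, 3, 12) / 2)
  expect_error(nernst_potential(1, 0, 5), "positive")
  expect_error(nernst_potential(0, 5, 5), "valence")
})

test_that("membrane flux breakdown respects channel inventory and stoichiometry", {
  p <- nominal_parameters()
  y <- perturbed_state(1)
  for (mem in c("neuron-soma", "neuron-dendrite")) {
    fl <- membrane_fluxes(y, p, mem)
    # pump moves 3 Na out per 2 K in
    expect_equal(fl[["Na_pump"]] / fl[["K_pump"]], -3 / 2, tolerance = 1e-12)
    # KCC2 carries K and Cl 1:1, NKCC1 carries Na:K:Cl = 1:1:2
    expect_equal(fl[["K_kcc2"]], fl[["Cl_kcc2"]])
    expect_equal(fl[["Cl_nkcc1"]], 2 * fl[["Na_nkcc1"]], tolerance = 1e-12)
    expect_equal(fl[["K_nkcc1"]], fl[["Na_nkcc1"]])
    # Ca/2Na exchanger: 2 Na in per Ca out
    expect_equal(fl[["Na_cadec"]], -2 * fl[["Ca_cadec"]], tolerance = 1e-12)
  }
  # soma has the transient Na / delayed-rectifier pair, dendrite the Ca set
  expect_true("Na_active" %in% names(membrane_fluxes(y, p, "neuron-soma")))
  expect_true("Ca_channel" %in% names(membrane_fluxes(y, p, "neuron-dendrite")))
  # glial membranes carry no Ca flux at all
  for (mem in c("glia-soma", "glia-dendrite")) {
    expect_length(grep("^Ca", names(membrane_fluxes(y, p, mem))), 0)
  }
  expect_error(membrane_fluxes(y, p, "axon"), "arg")
})

test_that("passive leak flux vanishes at its reversal potential", {
  p <- nominal_parameters()
  y <- resting_state()
  phi <- solve_potentials(y, p)
  fl <- membrane_fluxes(y, p, "neuron-soma")
  conv <- edneg_rescale(1, "conductance")
  EK <- nernst_potential(1, y[["K_sn"]] / y[["V_sn"]], y[["K_se"]] / y[["V_se"]])
  # implementation equals the constitutive law g (phi_m - E): zero iff at E
  expect_equal(fl[["K_leak"]],
               0.0245 * conv * (phi[["phi_msn"]] - EK), tolerance = 1e-12)
  ENa <- nernst_potential(1, y[["Na_sn"]] / y[["V_sn"]], y[["Na_se"]] / y[["V_se"]])
  expect_equal(fl[["Na_leak"]],
               0.0246 * conv * (phi[["phi_msn"]] - ENa), tolerance = 1e-12)
})

test_that("potential solve is linear and satisfies its defining relations", {
  p <- nominal_parameters()
  y <- resting_state()
  phi <- solve_potentials(y, p)
  # membrane potential = intracellular minus extracellular absolute potential
  expect_equal(phi[["phi_msn"]], phi[["phi_sn"]] - phi[["phi_se"]],
               tolerance = 1e-10)
  expect_equal(phi[["phi_mdg"]], phi[["phi_dg"]] - phi[["phi_de"]],
               tolerance = 1e-10)
  expect_equal(phi[["phi_de"]], 0)  # gauge
  # moving charge across the dendritic membrane: doubling the charge
  # deviation doubles the membrane-potential deviation (capacitor linearity)
  delta <- 5
  y1 <- y; y1[["K_dn"]] <- y[["K_dn"]] + delta; y1[["K_de"]] <- y[["K_de"]] - delta
  y2 <- y; y2[["K_dn"]] <- y[["K_dn"]] + 2 * delta; y2[["K_de"]] <- y[["K_de"]] - 2 * delta
  d1 <- solve_potentials(y1, p)[["phi_mdn"]] - phi[["phi_mdn"]]
  d2 <- solve_potentials(y2, p)[["phi_mdn"]] - phi[["phi_mdn"]]
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
  expect_error(solve_potentials(replace(y, 29, -1), p), "volume")
})

test_that("gating dynamics relax towards the voltage fixed point inside [0,1]", {
  p <- nominal_parameters()
  g <- gate_dynamics(-65, -65, 0.01, p = p)
  # at x_inf all derivatives vanish
  d0 <- gate_dynamics(-65, -65, 0.01, x = g$x_inf, p = p)
  expect_true(all(abs(d0$dx) < 1e-14))
  # flow points into the unit interval at its ends
  expect_true(all(gate_dynamics(-65, -65, 0.02, x = rep(0, 6), p = p)$dx >= 0))
  expect_true(all(gate_dynamics(-65, -65, 0.02, x = rep(1, 6), p = p)$dx <= 0))
  # clamped first-order kinetics: x(t) = xinf + (x0 - xinf) exp(-t/tau)
  x0 <- 0.9; tt <- 4
  f <- function(t, x, parms) {
    list(gate_dynamics(-65, -65, 0.01, x = x, p = p)$dx)
  }
  num <- deSolve::ode(y = setNames(rep(x0, 6), letters[1:6]),
                      times = c(0, tt), func = f, parms = NULL)[2, 1 + 1:6]
  closed <- g$x_inf + (x0 - g$x_inf) * exp(-tt / g$tau)
  expect_equal(unname(num), unname(closed), tolerance = 1e-6)
  expect_error(gate_dynamics(-65, -65, 0.01, x = rep(2, 6), p = p), "0, 1")
})

test_that("axial flux obeys Fick direction, drift sign and antisymmetry", {
  D <- 1.96e-9; lam <- 1.6; dx <- 667
  expect_equal(axial_flux(5, 5, -70, -70, 1, D, lam, dx), 0)
  # pure diffusion runs down the concentration gradient (a -> b)
  expect_gt(axial_flux(6, 5, -70, -70, 1, D, lam, dx), 0)
  # swapping ends negates the flux
  expect_equal(axial_flux(6, 5, -65, -70, 1, D, lam, dx),
               -axial_flux(5, 6, -70, -65, 1, D, lam, dx))
  # positive ion drifts down the potential gradient
  expect_gt(axial_flux(5, 5, -60, -70, 1, D, lam, dx), 0)
  expect_error(axial_flux(5, 5, 0, 0, 1, D, lam, 0), "distance")
})

test_that("osmotic water flow conserves volume and follows osmolarity", {
  p <- nominal_parameters()
  y <- resting_state()
  w <- water_flow(y, p)
  # calibrated rest is osmotically balanced
  expect_true(all(abs(w) < 1e-6))
  # any state: the six volume derivatives sum to zero (pairwise exchange)
  for (s in 1:5) {
    ww <- water_flow(perturbed_state(s), p)
    expect_lt(abs(sum(ww)), 1e-12 * max(abs(ww), 1))
  }
  # adding osmolytes to soma-neuron draws water in
  y2 <- y; y2[["Cl_sn"]] <- y2[["Cl_sn"]] * 1.05
  expect_gt(water_flow(y2, p)[["V_sn"]], 0)
})

test_that("right-hand side conserves matter with and without stimulus", {
  p <- nominal_parameters()
  tot <- function(dy) c(sum(dy[1:6]), sum(dy[7:12]), sum(dy[13:18]),
                        sum(dy[19:22]), sum(dy[29:34]))
  for (s in 1:5) {
    y <- perturbed_state(s)
    dy <- edneg_rhs(0, y, p)$dy
    expect_true(all(abs(tot(dy)) < 1e-10 * max(abs(dy))))
    # stimulation injects K+ into soma-neuron and removes it from soma-ECS,
    # so every total is still conserved
    stim <- stimulus_protocol(8e-5, 0, 1)
    dys <- edneg_rhs(100, y, p, stim)$dy
    expect_true(all(abs(tot(dys)) < 1e-10 * max(abs(dys))))
    expect_gt(dys[["K_sn"]] - dy[["K_sn"]], 0)
  }
})

test_that("exact Jacobian agrees with central finite differences", {
  p <- nominal_parameters()
  for (s in 1:10) {
    y <- perturbed_state(s)
    J <- edneg_jacobian(0, y, p)
    Jfd <- fd_jacobian(y, p)
    scale <- max(abs(J))
    rel <- abs(J - Jfd) / pmax(abs(J), scale * 1e-7)
    expect_lt(max(rel), 1e-4)  # FD truncation-limited agreement
    big <- abs(J) > scale * 1e-6
    expect_lt(max(abs(J - Jfd)[big] / abs(J)[big]), 1e-5)
  }
})

test_that("Jacobian has the gating-block sparsity of first-order kinetics", {
  p <- nominal_parameters()
  J <- edneg_jacobian(0, perturbed_state(3), p)
  gates <- 23:28
  for (i in gates) {
    # each gate's rate involves itself but no other gating variable
    others <- setdiff(gates, i)
    expect_true(all(J[i, others] == 0))
  }
})

test_that("unit rescaling is a bijection with the documented factors", {
  vals <- edneg_nominal("all")
  for (q in c("conductance", "pump_strength", "current", "diffusion")) {
    x <- c(0.1, 30, 1e-4)
    expect_equal(edneg_rescale(edneg_rescale(x, q), q, "to_external"), x)
  }
  # 30 mS/cm^2 converts through 10/F and back
  expect_equal(edneg_rescale(30, "conductance"), 30 * 10 / 96480)
  expect_error(edneg_rescale(1, "parsec"), "unknown unit")
  # rescaled resting state magnitudes lie within the documented window
  y <- resting_state()
  expect_true(all(abs(y[y != 0]) > 1e-5 & abs(y) < 1e6))
})
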