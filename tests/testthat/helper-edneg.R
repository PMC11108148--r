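# Shared fixtures: computed lazily once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

nominal_parameters <- function() cached("p", edneg_parameters())

resting_state <- function() cached("y0", edneg_resting_state(nominal_parameters()))

physiological_trajectory <- function() {
  cached("tr_phys", edneg_simulate(
    nominal_parameters(), resting_state(),
    stimulus_protocol(8e-5, 0.2, 5.5), solver_config(t_end = 6)))
}

pathological_trajectory <- function() {
  cached("tr_path", edneg_simulate(
    nominal_parameters(), resting_state(),
    stimulus_protocol(20e-5, 0.2, 5.5), solver_config(t_end = 6)))
}

# A physically admissible state away from rest, for Jacobian and
# conservation property tests. Ion moves are (near-)electroneutral —
# K+/Na+ swaps and KCl additions within compartments, Ca2+ against 2 Na+ —
# plus a small charge transfer across each membrane (mV-scale membrane
# potential shifts); arbitrary independent amount changes would put
# unphysically large charges on the capacitors. Ca is nudged above its
# baseline so the Ca-activity branch is differentiable.
perturbed_state <- function(seed) {
  y <- resting_state()
  set.seed(seed)
  iNa <- 1:6; iK <- 7:12; iCl <- 13:18
  for (c_ in 1:6) {
    swap <- y[iK[c_]] * runif(1, -0.02, 0.02)   # K+ <-> Na+
    y[iK[c_]] <- y[iK[c_]] + swap
    y[iNa[c_]] <- y[iNa[c_]] - swap
    kcl <- y[iCl[c_]] * runif(1, -0.02, 0.02)   # neutral KCl addition
    y[iK[c_]] <- y[iK[c_]] + kcl
    y[iCl[c_]] <- y[iCl[c_]] + kcl
  }
  # Ca2+ against 2 Na+ (electroneutral), biased upwards
  ca_slots <- 19:22
  ca_comp <- c(1, 2, 4, 5)
  for (k in 1:4) {
    dca <- y[ca_slots[k]] * runif(1, 0.05, 0.3)
    y[ca_slots[k]] <- y[ca_slots[k]] + dca
    y[iNa[ca_comp[k]]] <- y[iNa[ca_comp[k]]] - 2 * dca
  }
  # small charge transfers across the four membranes (a few mV each)
  mem <- list(c(7, 8), c(10, 11), c(9, 8), c(12, 11)) # K: sn|se dn|de sg|se dg|de
  for (m_ in mem) {
    dq <- runif(1, -0.5, 0.5)
    y[m_[1]] <- y[m_[1]] + dq
    y[m_[2]] <- y[m_[2]] - dq
  }
  y[23:28] <- pmin(pmax(y[23:28] * runif(6, 0.8, 1.2), 1e-4), 0.999)
  dv <- y[29:34] * runif(6, -0.01, 0.01)
  y[29:34] <- y[29:34] + dv - rep(tapply(dv, rep(1:2, each = 3), mean), each = 3)
  y
}

# central-difference Jacobian with block-scaled steps: amount steps are in
# absolute charge units (0.5e-3 amol ~ 3e-3 mV on a membrane capacitor) so
# that the potential-mediated nonlinearities stay in their linear range
fd_jacobian <- function(y, p, stim = NULL) {
  h <- c(rep(5e-4, 22), rep(1e-6, 6), pmax(abs(y[29:34]) * 1e-7, 1e-5))
  J <- matrix(0, 34, 34)
  for (j in 1:34) {
    yp <- y; yp[j] <- yp[j] + h[j]
    ym <- y; ym[j] <- ym[j] - h[j]
    J[, j] <- (edneg_rhs(0, yp, p, stim)$dy - edneg_rhs(0, ym, p, stim)$dy) /
      (2 * h[j])
  }
  J
}
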