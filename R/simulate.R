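# Stiff integration of the model under stimulus protocols, producing
# trajectories on a uniform analysis grid.

#' Stimulus protocol
#'
#' A constant K+ injection current delivered to the soma-neuron compartment
#' between onset and offset. To conserve ions, an equal amount of K+ is
#' removed from the soma-ECS compartment at every instant, so the total K+
#' amount is unchanged by stimulation.
#'
#' @param amplitude stimulus current in uA (>= 0).
#' @param onset,offset stimulus window in s, `0 <= onset < offset`.
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(amplitude = 8e-5, onset = 0.2, offset = 5.5) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (!(onset >= 0 && onset < offset)) stop("need 0 <= onset < offset")
  structure(list(amplitude = amplitude, onset = onset, offset = offset),
            class = "stimulus_protocol")
}

.stim_amp <- function(stim) {
  if (is.null(stim)) 0 else stim$amplitude * .conv$current # amol/ms of K+
}
.stim_on <- function(stim) if (is.null(stim)) 0 else stim$onset * 1000
.stim_off <- function(stim) if (is.null(stim)) 0 else stim$offset * 1000

#' Instantaneous stimulus delivery
#'
#' Converts the protocol's current into a K+ amount rate via Faraday's
#' constant (z = +1) and reports the source/sink pair: injection into
#' soma-neuron and the exactly opposite removal from soma-ECS.
#'
#' @param stim a [stimulus_protocol()] (or `NULL`).
#' @param t time in ms.
#' @return named numeric vector `c(soma_neuron =, soma_ecs =)` in amol/ms;
#'   the two entries always sum to zero.
#' @export
apply_stimulus <- function(stim, t) {
  amp <- .stim_amp(stim)
  on <- t >= .stim_on(stim) & t < .stim_off(stim) & !is.null(stim)
  r <- ifelse(on, amp, 0)
  c(soma_neuron = r, soma_ecs = -r)
}

#' Solver configuration
#'
#' @param method integration method; the default (and the method used for
#'   all analyses) is the implicit Radau IIA solver with the exact Jacobian.
#'   Other deSolve methods are accepted for the convergence scan.
#' @param dt_max maximum step length in ms.
#' @param rtol relative tolerance.
#' @param atol_amount,atol_gate,atol_volume absolute tolerances for the
#'   three state blocks (amounts are O(1e5) amol, gates O(1), volumes
#'   O(1e3) um^3, hence block-scaled).
#' @param t_end total simulated time in s.
#' @param grid_dt spacing of the uniform analysis grid in ms.
#' @param maxsteps maximum number of internal solver steps per segment.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(method = "radau", dt_max = 10, rtol = 1e-8,
                          atol_amount = 1e-6, atol_gate = 1e-10,
                          atol_volume = 1e-6, t_end = 6, grid_dt = 1,
                          maxsteps = 1e5) {
  if (dt_max <= 0 || grid_dt <= 0 || t_end <= 0) stop("times must be positive")
  if (rtol <= 0 || atol_amount <= 0 || atol_gate <= 0 || atol_volume <= 0) {
    stop("tolerances must be positive")
  }
  structure(list(method = method, dt_max = dt_max, rtol = rtol,
                 atol = c(rep(atol_amount, 22), rep(atol_gate, 6),
                          rep(atol_volume, 6)),
                 t_end = t_end, grid_dt = grid_dt, maxsteps = maxsteps),
            class = "solver_config")
}

# run one solver segment on a fixed time vector (ms)
.integrate_segment <- function(y0, times, parms, cfg) {
  if (identical(cfg$method, "radau")) {
    deSolve::radau(
      y = y0, times = times, func = "edneg_derivs", parms = parms,
      jacfunc = "edneg_jac", jactype = "fullusr",
      dllname = "edneguq", initfunc = "edneg_initmod",
      nout = 10, outnames = .phi_names,
      rtol = cfg$rtol, atol = cfg$atol, hmax = cfg$dt_max,
      maxsteps = cfg$maxsteps
    )
  } else {
    deSolve::ode(
      y = y0, times = times, func = "edneg_derivs", parms = parms,
      method = cfg$method, jacfunc = "edneg_jac", jactype = "fullusr",
      dllname = "edneguq", initfunc = "edneg_initmod",
      nout = 10, outnames = .phi_names,
      rtol = cfg$rtol, atol = cfg$atol, hmax = cfg$dt_max,
      maxsteps = cfg$maxsteps
    )
  }
}

#' Integrate the model
#'
#' Adaptive implicit integration of the 34-dimensional stiff system with
#' the exact Jacobian, split into segments at the stimulus onset and offset
#' (the indicator-function stimulus is discontinuous there, and restarting
#' the integrator at the discontinuity handles it exactly). States are
#' reported on a uniform analysis grid; the ten potentials are evaluated at
#' every grid point.
#'
#' @param p an [edneg_parameters()] object.
#' @param y0 initial state (length 34, internal units); defaults to the
#'   calibrated resting state.
#' @param stim a [stimulus_protocol()] or `NULL` for a stimulus-free run.
#' @param cfg a [solver_config()].
#' @return an object of class `edneg_trajectory`: a list with `time` (s),
#'   `state` (matrix, one row per grid point), `phi` (matrix of the ten
#'   potentials, mV), and the provenance (`parameters`, `stimulus`,
#'   `config`).
#' @export
edneg_simulate <- function(p = edneg_parameters(), y0 = edneg_resting_state(p),
                           stim = NULL, cfg = solver_config()) {
  stopifnot(inherits(p, "edneg_parameters"), inherits(cfg, "solver_config"))
  y0 <- .check_state(y0)
  names(y0) <- .state_names
  parms <- edneg_pack_parms(p, .stim_amp(stim), .stim_on(stim), .stim_off(stim))

  t_end <- cfg$t_end * 1000
  grid <- seq(0, t_end, by = cfg$grid_dt)
  breaks <- c(0, t_end)
  if (!is.null(stim)) {
    breaks <- sort(unique(c(breaks, .stim_on(stim), .stim_off(stim))))
    breaks <- breaks[breaks >= 0 & breaks <= t_end]
  }

  rows <- vector("list", length(breaks) - 1)
  y <- y0
  for (k in seq_len(length(breaks) - 1)) {
    lo <- breaks[k]; hi <- breaks[k + 1]
    tt <- unique(c(lo, grid[grid > lo & grid < hi], hi))
    sol <- .integrate_segment(y, tt, parms, cfg)
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tt)) {
      last_t <- sol[nrow(sol), 1]
      stop(sprintf("integration failed in segment [%g, %g] ms; last valid time %g ms",
                   lo, hi, last_t))
    }
    y <- sol[nrow(sol), 1 + seq_len(34)]
    keep <- sol[, 1] %in% grid & (k == 1 | sol[, 1] > lo)
    rows[[k]] <- sol[keep, , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  state <- out[, 1 + seq_len(34), drop = FALSE]
  colnames(state) <- .state_names
  phi <- out[, 35 + seq_len(10), drop = FALSE]
  colnames(phi) <- .phi_names
  if (any(!is.finite(state))) stop("non-finite state in trajectory")

  structure(list(time = out[, 1] / 1000, state = state, phi = phi,
                 parameters = p, stimulus = stim, config = cfg),
            class = "edneg_trajectory")
}

#' Extract a named concentration trace from a trajectory
#'
#' @param traj an `edneg_trajectory`.
#' @param species one of `"Na"`, `"K"`, `"Cl"`, `"Ca"`.
#' @param compartment one of `"sn"`, `"se"`, `"sg"`, `"dn"`, `"de"`, `"dg"`.
#' @return numeric vector of concentrations (mM) on the analysis grid.
#' @export
concentration <- function(traj, species, compartment) {
  nm <- paste0(species, "_", compartment)
  if (!nm %in% colnames(traj$state)) stop("unknown species/compartment: ", nm)
  traj$state[, nm] / traj$state[, paste0("V_", compartment)]
}

#' @export
print.edneg_trajectory <- function(x, ...) {
  cat(sprintf("edneg trajectory: %d grid points over %.3g s\n",
              length(x$time), max(x$time)))
  if (!is.null(x$stimulus)) {
    cat(sprintf("  stimulus: %.3g uA on (%.3g, %.3g) s\n",
                x$stimulus$amplitude, x$stimulus$onset, x$stimulus$offset))
  } else cat("  stimulus: none\n")
  cat(sprintf("  phi_msn range: [%.1f, %.1f] mV\n",
              min(x$phi[, "phi_msn"]), max(x$phi[, "phi_msn"])))
  invisible(x)
}

#' @export
plot.edneg_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time, x$phi[, "phi_msn"], type = "l", xlab = "time (s)",
       ylab = expression(phi[msn] ~ "(mV)"), ...)
  plot(x$time, concentration(x, "K", "se"), type = "l", xlab = "time (s)",
       ylab = expression("[K+]"[se] ~ "(mM)"), ...)
  plot(x$time, x$state[, "V_se"] - x$state[1, "V_se"], type = "l",
       xlab = "time (s)", ylab = expression(Delta * V[se] ~ (mu * m^3)), ...)
  invisible(x)
}

#' Solver convergence scan
#'
#' Integrates the same problem under several (method, dt_max)
#' configurations and reports, for each, the spiking and slow-variable
#' summaries used to judge convergence: the number of somatic action
#' potentials, the time of the last action potential, and the terminal
#' extracellular K+ concentration and volume deviation in the soma layer,
#' together with their deviations from the tightest (reference)
#' configuration, taken as the last row.
#'
#' @param p,y0,stim as in [edneg_simulate()].
#' @param methods character vector of solver methods.
#' @param dt_max numeric vector of maximum step lengths (ms), recycled
#'   against `methods`.
#' @param cfg base [solver_config()]; the reference row uses
#'   `cfg$dt_max / 10` and `cfg$rtol / 10`.
#' @return data.frame, one row per configuration plus the reference.
#' @export
convergence_scan <- function(p = edneg_parameters(), y0 = edneg_resting_state(p),
                             stim = stimulus_protocol(),
                             methods = "radau", dt_max = 10,
                             cfg = solver_config()) {
  grid <- expand.grid(method = methods, dt_max = dt_max,
                      stringsAsFactors = FALSE)
  grid <- rbind(grid, data.frame(method = "radau", dt_max = cfg$dt_max / 10))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ci <- cfg
    ci$method <- grid$method[i]
    ci$dt_max <- grid$dt_max[i]
    if (i == nrow(grid)) ci$rtol <- cfg$rtol / 10
    tr <- tryCatch(edneg_simulate(p, y0, stim, ci), error = function(e) NULL)
    if (is.null(tr)) {
      return(data.frame(n_ap = NA, last_ap = NA, K_se_end = NA, dV_se_end = NA,
                        failed = TRUE))
    }
    sp <- detect_aps(tr)
    data.frame(
      n_ap = length(sp$times),
      last_ap = if (length(sp$times)) max(sp$times) else NA_real_,
      K_se_end = concentration(tr, "K", "se")[length(tr$time)],
      dV_se_end = tr$state[length(tr$time), "V_se"] - tr$state[1, "V_se"],
      failed = FALSE
    )
  })
  out <- cbind(grid, do.call(rbind, res))
  ref <- out[nrow(out), ]
  out$d_n_ap <- out$n_ap - ref$n_ap
  out$d_last_ap <- out$last_ap - ref$last_ap
  out$d_K_se <- out$K_se_end - ref$K_se_end
  out$reference <- seq_len(nrow(out)) == nrow(out)
  out
}
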