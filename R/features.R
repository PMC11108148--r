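# Extraction of scalar quantities of interest from trajectories: action
# potentials, firing frequency, first-spike latency, depolarization-block
# onset, and resting-state values.

.trace_from <- function(trace) {
  if (inherits(trace, "edneg_trajectory")) {
    list(t = trace$time, v = trace$phi[, "phi_msn"])
  } else if (is.list(trace) && !is.null(trace$t) && !is.null(trace$v)) {
    trace
  } else stop("trace must be an edneg_trajectory or a list(t=, v=)")
}

.check_uniform <- function(t) {
  dt <- diff(t)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    stop("trace must be on a uniform time grid")
  }
  dt[1]
}

#' Detect action potentials in a somatic membrane-potential trace
#'
#' An action potential is an upward crossing of the detection threshold
#' followed by a local maximum; crossings closer than the refractory
#' interval `min_isi` to the previous spike are ignored. The spike time is
#' the threshold-crossing time, obtained by linear interpolation between
#' grid points (robust against depolarization-block plateaus, where peak
#' times are undefined).
#'
#' @param trace an `edneg_trajectory`, or a `list(t =, v =)` with time (s)
#'   and somatic membrane potential (mV) on a uniform grid.
#' @param threshold detection threshold (mV).
#' @param min_isi minimum inter-spike interval (ms).
#' @return an object of class `spike_train`: list with `times` (s),
#'   `threshold`, `min_isi`.
#' @export
detect_aps <- function(trace, threshold = -20, min_isi = 2) {
  tr <- .trace_from(trace)
  .check_uniform(tr$t)
  v <- tr$v; t <- tr$t
  i <- which(v[-length(v)] < threshold & v[-1] >= threshold)
  times <- numeric(0)
  if (length(i)) {
    # linear interpolation of the crossing time
    frac <- (threshold - v[i]) / (v[i + 1] - v[i])
    cand <- t[i] + frac * (t[i + 1] - t[i])
    # enforce refractoriness sequentially
    times <- cand[1]
    for (k in seq_along(cand)[-1]) {
      if ((cand[k] - times[length(times)]) * 1000 >= min_isi) {
        times <- c(times, cand[k])
      }
    }
  }
  structure(list(times = times, threshold = threshold, min_isi = min_isi),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike train: %d APs", length(x$times)))
  if (length(x$times)) cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' Final firing frequency
#'
#' Number of spikes in the final firing window divided by the window
#' length; the default window (4.0, 5.5) s covers the last 1.5 s of firing
#' under the standard protocols.
#'
#' @param spikes a [detect_aps()] spike train.
#' @param window numeric length-2, window in s.
#' @return frequency in Hz (0 if no spikes fall in the window).
#' @export
final_frequency <- function(spikes, window = c(4.0, 5.5)) {
  n <- sum(spikes$times > window[1] & spikes$times < window[2])
  n / diff(window)
}

#' Latency from stimulus onset to the first action potential
#'
#' @param spikes a [detect_aps()] spike train.
#' @param stim_onset stimulus onset in s.
#' @return latency in ms, or `NA_real_` if the train contains no spike at
#'   or after the onset (the undefined marker is propagated, never
#'   silently zero).
#' @export
time_before_first_ap <- function(spikes, stim_onset = 0.2) {
  after <- spikes$times[spikes$times >= stim_onset]
  if (!length(after)) return(NA_real_)
  (after[1] - stim_onset) * 1000
}

#' Depolarization-block onset
#'
#' Earliest time after the first action potential from which the somatic
#' membrane potential is stationary — |d phi/dt| (central differences)
#' stays below `deriv_threshold` throughout the stationarity window — while
#' the trace remains depolarized above the `depolarized_above` guard level.
#' This operationalizes "the first derivative becomes consistently constant
#' and falls below a threshold" for a plateau that outlasts the window.
#'
#' @inheritParams detect_aps
#' @param deriv_threshold derivative threshold in mV/ms (default 1e-1).
#' @param window stationarity window in s.
#' @param depolarized_above guard level (mV); `NULL` uses the trace's
#'   initial (pre-stimulus) value plus 10 mV.
#' @return onset time in s, or `NA_real_` if the criterion is never met.
#' @export
depolarization_block_onset <- function(trace, deriv_threshold = 0.1,
                                       window = 0.1, depolarized_above = NULL,
                                       threshold = -20, min_isi = 2) {
  tr <- .trace_from(trace)
  dt <- .check_uniform(tr$t)
  v <- tr$v; t <- tr$t; n <- length(v)
  sp <- detect_aps(tr, threshold = threshold, min_isi = min_isi)
  if (!length(sp$times)) return(NA_real_)
  if (is.null(depolarized_above)) depolarized_above <- v[1] + 10
  dv <- c(NA, (v[3:n] - v[1:(n - 2)]) / (2 * dt * 1000), NA) # mV/ms
  ok <- abs(dv) < deriv_threshold & v > depolarized_above
  ok[is.na(ok)] <- FALSE
  w <- max(1L, round(window / dt))
  start <- which(t >= sp$times[1])[1]
  run <- 0L
  for (i in seq(start, n)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= w) return(t[i - w + 1L])
  }
  NA_real_
}

#' Resting-state quantities of interest
#'
#' The six variables whose final values characterize the resting state:
#' the four membrane potentials and the extracellular K+ concentrations in
#' the two layers, evaluated at the trajectory's final time.
#'
#' @param traj an `edneg_trajectory`.
#' @return named numeric vector `phi_msn, phi_mdn, phi_msg, phi_mdg, K_se,
#'   K_de` (mV and mM).
#' @export
resting_qois <- function(traj) {
  n <- length(traj$time)
  c(phi_msn = unname(traj$phi[n, "phi_msn"]),
    phi_mdn = unname(traj$phi[n, "phi_mdn"]),
    phi_msg = unname(traj$phi[n, "phi_msg"]),
    phi_mdg = unname(traj$phi[n, "phi_mdg"]),
    K_se = unname(traj$state[n, "K_se"] / traj$state[n, "V_se"]),
    K_de = unname(traj$state[n, "K_de"] / traj$state[n, "V_de"]))
}

#' Extract spiking quantities of interest from a trajectory
#'
#' @param traj an `edneg_trajectory` (or `list(t=, v=)` trace).
#' @param qois character vector among `"n_ap"`, `"f_final"`, `"t_bfap"`,
#'   `"t_sdp"`.
#' @param stim_onset stimulus onset (s); defaults to the trajectory's
#'   protocol.
#' @param ... further arguments to [detect_aps()] and
#'   [depolarization_block_onset()].
#' @return named numeric vector; undefined features are `NA`.
#' @export
extract_qois <- function(traj, qois = c("n_ap", "f_final", "t_bfap"),
                         stim_onset = NULL, ...) {
  if (is.null(stim_onset)) {
    stim_onset <- if (inherits(traj, "edneg_trajectory") &&
                      !is.null(traj$stimulus)) traj$stimulus$onset else 0.2
  }
  sp <- detect_aps(traj, ...)
  out <- c()
  for (q in qois) {
    out[q] <- switch(q,
      n_ap = length(sp$times),
      f_final = final_frequency(sp),
      t_bfap = time_before_first_ap(sp, stim_onset),
      t_sdp = depolarization_block_onset(traj),
      stop("unknown QoI: ", q))
  }
  out
}
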