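# Module-level operations on the forward model: right-hand side, algebraic
# potential solve, per-channel membrane fluxes, gating kinetics, axial flux
# and water flow, and the exact Jacobian.

#' Nernst (reversal) potential
#'
#' @param valence integer ion valence (non-zero).
#' @param conc_in,conc_out intra-/extracellular concentrations (mM, > 0).
#' @param temperature temperature in K.
#' @return reversal potential in mV, `(RT/zF) ln(c_out/c_in)`.
#' @export
nernst_potential <- function(valence, conc_in, conc_out, temperature = 309.14) {
  if (any(valence == 0)) stop("valence must be non-zero")
  if (any(conc_in <= 0) || any(conc_out <= 0)) {
    stop("concentrations must be strictly positive")
  }
  psi <- .RGAS * temperature / .FARADAY * 1000
  psi / valence * log(conc_out / conc_in)
}

.check_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 34L) stop("state must have length 34")
  state
}

#' Model right-hand side
#'
#' Evaluates the 34 time derivatives (ion amounts, gating variables,
#' volumes) and the 10 derived potentials at a given state.
#'
#' @param t time (ms).
#' @param state numeric state vector of length 34 (see
#'   [edneg_state_names()]; internal units).
#' @param p an [edneg_parameters()] object.
#' @param stim optional [stimulus_protocol()]; `NULL` means no stimulus.
#' @return list with `dy` (named, length 34) and `phi` (named, length 10,
#'   mV).
#' @export
edneg_rhs <- function(t, state, p, stim = NULL) {
  state <- .check_state(state)
  parms <- edneg_pack_parms(p, .stim_amp(stim), .stim_on(stim), .stim_off(stim))
  out <- .edneg_rhs_cpp(t, state, parms)
  if (any(!is.finite(out$dy))) {
    bad <- .state_names[!is.finite(out$dy)]
    stop("non-finite derivative in component(s): ", paste(bad, collapse = ", "))
  }
  names(out$dy) <- .state_names
  names(out$phi) <- .phi_names
  out
}

#' Exact Jacobian of the right-hand side
#'
#' The 34 x 34 Jacobian is computed by forward-mode differentiation of the
#' implemented equations (one seeded pass per state variable), so it is
#' exact to floating-point rounding, with no finite-difference truncation
#' error. It is the Jacobian supplied to the implicit solver.
#'
#' @inheritParams edneg_rhs
#' @return 34 x 34 numeric matrix, `d(rhs)/d(state)`.
#' @export
edneg_jacobian <- function(t, state, p, stim = NULL) {
  state <- .check_state(state)
  parms <- edneg_pack_parms(p, .stim_amp(stim), .stim_on(stim), .stim_off(stim))
  J <- .edneg_jac_cpp(t, state, parms)
  dimnames(J) <- list(.state_names, .state_names)
  J
}

#' Algebraic potential solve
#'
#' Solves the linear Kirchhoff-Nernst-Planck system for the six absolute
#' compartment potentials and the four membrane potentials, given ion
#' amounts and volumes. Membrane potentials follow from the capacitor
#' relation (net compartment charge over membrane capacitance); the
#' soma-layer extracellular potential follows from axial current
#' conservation across the soma/dendrite boundary. Gauge: `phi_de = 0`.
#'
#' @inheritParams edneg_rhs
#' @return named numeric vector of length 10 (mV), see [edneg_phi_names()].
#' @export
solve_potentials <- function(state, p) {
  state <- .check_state(state)
  if (any(state[29:34] <= 0)) stop("degenerate geometry: non-positive volume")
  out <- edneg_rhs(0, state, p)
  out$phi
}

.membrane_tags <- c("neuron-soma", "neuron-dendrite", "glia-soma", "glia-dendrite")

#' Per-channel transmembrane flux densities
#'
#' Returns the flux density carried by each membrane mechanism on the
#' selected membrane, in amol um^-2 ms^-1, positive outward. The channel
#' inventory depends on the membrane: both neuronal membranes carry Na+, K+
#' and Cl- leaks, the 3Na+/2K+ pump, KCC2 and NKCC1 cotransporters and the
#' Ca2+/2Na+ exchanger; the soma adds the transient Na+ and delayed-rectifier
#' K+ channels, the dendrite the voltage-gated Ca2+ channel and the
#' Ca2+-dependent K+ currents (AHP and K-C); the glial membranes carry Na+
#' and Cl- leaks, the inward-rectifying K+ channel and the pump. Ca2+ does
#' not enter the glial compartments, so glial membranes report no Ca2+ flux.
#'
#' @inheritParams edneg_rhs
#' @param membrane one of `"neuron-soma"`, `"neuron-dendrite"`,
#'   `"glia-soma"`, `"glia-dendrite"`.
#' @return named numeric vector of per-channel flux densities.
#' @export
membrane_fluxes <- function(state, p, membrane = .membrane_tags) {
  membrane <- match.arg(membrane)
  state <- .check_state(state)
  conc <- state[1:22] / state[28 + c(rep(1:6, 3), c(1, 2, 4, 5))]
  if (any(conc <= 0)) stop("non-positive concentration")
  parms <- edneg_pack_parms(p)
  .edneg_fluxes_cpp(state, parms, match(membrane, .membrane_tags) - 1L)
}

#' Gating-variable dynamics
#'
#' Time derivatives of the six Hodgkin-Huxley gating variables
#' (n, h: somatic, driven by `phi_msn`; s, c, z: dendritic, driven by
#' `phi_mdn`; q: driven by dendritic Ca2+). Each derivative has the
#' first-order form `alpha (1 - x) - beta x`, equivalently
#' `(x_inf - x)/tau`, so trajectories are confined to the unit interval.
#'
#' @param phi_msn,phi_mdn somatic and dendritic membrane potentials (mV).
#' @param ca_conc total dendritic Ca2+ concentration (mM).
#' @param x gating vector of length 6 (`n, h, s, c, q, z`), or `NULL` to
#'   return only `x_inf` and `tau`.
#' @param p an [edneg_parameters()] object.
#' @return list with `dx` (ms^-1), `x_inf`, `tau` (ms), each named.
#' @export
gate_dynamics <- function(phi_msn, phi_mdn, ca_conc, x = NULL, p = edneg_parameters()) {
  if (!is.null(x)) {
    if (length(x) != 6L) stop("x must have length 6")
    if (any(x < 0 | x > 1)) stop("gating variables must lie in [0, 1]")
  }
  parms <- edneg_pack_parms(p)
  out <- .edneg_gates_cpp(phi_msn, phi_mdn, ca_conc,
                          if (is.null(x)) numeric(0) else as.numeric(x), parms)
  gn <- c("n", "h", "s", "c", "q", "z")
  names(out$dx) <- gn; names(out$x_inf) <- gn; names(out$tau) <- gn
  out
}

#' Axial electrodiffusive flux density
#'
#' Flux of one ion species between two compartments of the same domain,
#' driven by diffusion (concentration difference) and electric drift
#' (potential difference acting on the mean concentration), per unit
#' cross-sectional area. Positive from a to b.
#'
#' @param conc_a,conc_b concentrations (mM, > 0).
#' @param pot_a,pot_b absolute potentials (mV).
#' @param valence ion valence.
#' @param diffusion free-solution diffusion constant (m^2 s^-1).
#' @param tortuosity dimensionless tortuosity of the domain.
#' @param dx inter-compartment distance (um, > 0).
#' @param temperature temperature (K).
#' @return flux density in amol um^-2 ms^-1.
#' @export
axial_flux <- function(conc_a, conc_b, pot_a, pot_b, valence, diffusion,
                       tortuosity, dx, temperature = 309.14) {
  if (dx <= 0) stop("inter-compartment distance must be positive")
  if (any(conc_a <= 0) || any(conc_b <= 0)) stop("concentrations must be positive")
  psi <- .RGAS * temperature / .FARADAY * 1000
  D <- diffusion * .conv$diffusion / tortuosity^2
  -D * (conc_b - conc_a) / dx - D * valence * (conc_a + conc_b) / 2 *
    (pot_b - pot_a) / (psi * dx)
}

#' Osmotic water flow
#'
#' Volume derivatives of all six compartments from transmembrane osmotic
#' pressure differences. Water moves towards the hyperosmolar side; each
#' membrane conserves the total volume of its compartment pair, so the six
#' derivatives sum to zero.
#'
#' @inheritParams edneg_rhs
#' @return named numeric vector of six volume derivatives (um^3 ms^-1).
#' @export
water_flow <- function(state, p) {
  state <- .check_state(state)
  if (any(state[29:34] <= 0)) stop("volumes must be positive")
  out <- edneg_rhs(0, state, p)
  out$dy[29:34]
}
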