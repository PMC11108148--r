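# Model parameters: nominal membrane-mechanism values, physical constants,
# geometry, and the static background composition of each compartment.

# Internal unit system: mV, ms, um, amol (1e-18 mol), mM (= amol/um^3).
# I/O units follow the conventional presentation of the model: conductances in
# mS cm^-2, pump/cotransporter strengths in nmol cm^-2 ms^-1, currents in uA,
# diffusion constants in m^2 s^-1, potentials in mV, time in ms (solver) or s
# (protocols).

.FARADAY <- 96480      # C / mol
.RGAS <- 8.314         # J / (mol K)

# conversion factors to internal units
.conv <- list(
  conductance = 10 / .FARADAY,   # mS cm^-2 -> charge-amol um^-2 ms^-1 mV^-1
  capacitance = 10 / .FARADAY,   # uF cm^-2 -> charge-amol um^-2 mV^-1
  pump_strength = 10,            # nmol cm^-2 ms^-1 -> amol um^-2 ms^-1
  current = 1e9 / .FARADAY,      # uA -> charge-amol ms^-1
  diffusion = 1e9,               # m^2 s^-1 -> um^2 ms^-1
  amount = 1e18,                 # mol -> amol
  volume = 1e18                  # m^3 -> um^3
)

#' Convert between I/O and internal units
#'
#' The model integrates in a rescaled unit system (mV, ms, um, amol, mM)
#' chosen so that all state magnitudes lie within a few orders of magnitude,
#' which markedly improves the conditioning of the stiff integration. This
#' helper converts scalar quantities between the conventional I/O units and
#' the internal system. The conversion is a bijection; a round trip is the
#' identity to machine precision.
#'
#' @param x numeric vector to convert.
#' @param quantity one of `"conductance"` (mS cm^-2), `"capacitance"`
#'   (uF cm^-2), `"pump_strength"` (nmol cm^-2 ms^-1), `"current"` (uA),
#'   `"diffusion"` (m^2 s^-1), `"amount"` (mol), `"volume"` (m^3).
#' @param direction `"to_internal"` or `"to_external"`.
#' @return converted numeric vector.
#' @export
edneg_rescale <- function(x, quantity, direction = c("to_internal", "to_external")) {
  direction <- match.arg(direction)
  if (!quantity %in% names(.conv)) {
    stop("unknown unit tag: ", quantity)
  }
  f <- .conv[[quantity]]
  if (direction == "to_internal") x * f else x / f
}

# names of the 11 "non-dynamic" (resting-state) parameters
.nondynamic_names <- c(
  "g_Na_leak_n", "g_K_leak_n", "g_Cl_leak_n", "rho_n", "U_kcc2", "U_nkcc1",
  "U_Cadec", "g_Na_leak_g", "g_K_IR", "g_Cl_leak_g", "rho_g"
)
# names of the 5 "dynamic" (active-conductance) parameters
.dynamic_names <- c("g_Na", "g_DR", "g_Ca", "g_AHP", "g_C")

.nominal_membrane <- c(
  g_Na_leak_n = 0.0246,   # mS cm^-2
  g_K_leak_n = 0.0245,    # mS cm^-2
  g_Cl_leak_n = 0.1,      # mS cm^-2
  rho_n = 1.87e-4,        # nmol cm^-2 ms^-1
  U_kcc2 = 1.49e-5,       # nmol cm^-2 ms^-1
  U_nkcc1 = 2.33e-5,      # nmol cm^-2 ms^-1
  U_Cadec = 0.075,        # ms^-1
  g_Na_leak_g = 0.1,      # mS cm^-2
  g_K_IR = 1.696,         # mS cm^-2
  g_Cl_leak_g = 0.01,     # mS cm^-2
  rho_g = 1.12e-4,        # nmol cm^-2 ms^-1
  g_Na = 30,              # mS cm^-2
  g_DR = 15,              # mS cm^-2
  g_Ca = 11.8,            # mS cm^-2
  g_AHP = 0.8,            # mS cm^-2
  g_C = 15                # mS cm^-2
)

#' Nominal membrane-mechanism parameter values
#'
#' Nominal values of the 11 "non-dynamic" parameters (leak conductances,
#' pump and cotransporter strengths, Ca decay rate) and the 5 "dynamic"
#' parameters (maximum conductances of the active channels), in I/O units
#' (conductances mS cm^-2, strengths nmol cm^-2 ms^-1, decay rate ms^-1).
#'
#' @param group `"all"`, `"non-dynamic"` or `"dynamic"`.
#' @return named numeric vector.
#' @export
edneg_nominal <- function(group = c("all", "non-dynamic", "dynamic")) {
  group <- match.arg(group)
  switch(group,
    "all" = .nominal_membrane,
    "non-dynamic" = .nominal_membrane[.nondynamic_names],
    "dynamic" = .nominal_membrane[.dynamic_names]
  )
}

# Documented baseline composition used to construct the approximate resting
# state from which calibration starts.  Concentrations in mM, volumes in um^3,
# potentials in mV.
.baseline <- list(
  conc = list(
    # sn, se, sg, dn, de, dg
    Na = c(19, 144, 14.6, 19, 144, 14.6),
    K = c(97, 3.5, 101, 97, 3.5, 101),
    Cl = c(8, 132, 6, 8, 132, 6),
    Ca = c(0.01, 1.1, 0.01, 1.1)  # sn, se, dn, de
  ),
  volume = c(1437, 590, 1437, 1437, 590, 1437),
  phi_m_neuron = -67.7,
  phi_m_glia = -83.9,
  osmolarity = 300
)

#' Model parameters for the six-compartment electrodiffusive model
#'
#' Builds the full parameter object: the 16 membrane-mechanism parameters
#' (nominal values unless overridden), physical constants, compartment
#' geometry, diffusion constants, water permeabilities, and the static
#' background composition (impermeant osmolytes and background charge) that
#' fixes the baseline resting configuration.
#'
#' @param ... named overrides for any of the 16 membrane parameters (I/O
#'   units, names as in [edneg_nominal()]).
#' @return an object of class `edneg_parameters`.
#' @export
edneg_parameters <- function(...) {
  overrides <- list(...)
  membrane <- .nominal_membrane
  if (length(overrides)) {
    nm <- names(overrides)
    unknown <- setdiff(nm, names(membrane))
    if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    vals <- unlist(overrides)
    if (any(vals <= 0)) stop("membrane parameters must be strictly positive")
    membrane[nm] <- vals
  }

  physical <- list(temperature = 309.14, faraday = .FARADAY, gas_constant = .RGAS)
  physical$psi <- physical$gas_constant * physical$temperature / physical$faraday * 1000 # mV

  geometry <- list(
    # membrane areas (um^2): soma-neuron, dendrite-neuron, soma-glia, dendrite-glia
    A_m = c(msn = 616, mdn = 616, msg = 200, mdg = 200),
    capacitance = c(neuron = 3, glia = 3),          # uF cm^-2
    # intradomain cross sections (um^2): neuron, ECS, glia
    A_cross = c(n = 150, e = 308, g = 616),
    dx = 667,                                        # um, soma-dendrite distance
    tortuosity = c(n = 3.2, e = 1.6, g = 3.2),
    diffusion = c(Na = 1.33e-9, K = 1.96e-9, Cl = 2.03e-9, Ca = 0.71e-9), # m^2 s^-1
    water_permeability = c(neuron = 0.002, glia = 0.02), # um^3 ms^-1 mM^-1 per membrane
    baseline_volume = .baseline$volume
  )

  kinetics <- list(
    Ca_baseline = c(sn = .baseline$conc$Ca[1], dn = .baseline$conc$Ca[3]),
    K_e_base = 3.5,          # mM, reference extracellular K for the Kir factor
    free_Ca_fraction = 0.01, # fraction of intracellular Ca that is free
    ca_activity_scale = 1e7, # dimensionless Ca activity per mM free Ca excess
    E_K_glia_rest = -85.2,   # mV, reference in the Kir rectification factor
    pump_glia_Km_Na = 10,    # mM
    pump_glia_Km_K = 1.5,    # mM
    z_midpoint = -45,        # mV, dendritic Ca-channel inactivation midpoint
    z_slope = 2,             # mV
    tau_z = 200,             # ms
    beta_q = 3.5e-5,         # ms^-1, AHP gate closing rate
    Ca_activation_threshold = 0.01,  # mM total Ca; AHP/K-C activity reference
    pump_n_Na_half = 25,     # mM, neuronal pump Na half-activation
    s_shift = 0,             # mV, rightward shift of Ca-channel activation
    alpha_q_max = 0.01       # ms^-1, cap on the AHP gate opening rate
  )

  background <- .edneg_background(membrane, physical, geometry, .baseline)

  structure(
    list(membrane = membrane, physical = physical, geometry = geometry,
         kinetics = kinetics, background = background, baseline = .baseline),
    class = "edneg_parameters"
  )
}

# Static background composition: per-compartment impermeant osmolyte amount X
# (amol) and background charge B (charge-amol), chosen so that at the
# documented baseline every compartment is osmotically balanced and the
# membrane potentials equal their target values.
.edneg_background <- function(membrane, physical, geometry, baseline = .baseline) {
  conc <- baseline$conc
  V <- baseline$volume
  ca_full <- c(conc$Ca[1], conc$Ca[2], 0, conc$Ca[3], conc$Ca[4], 0)
  osm_ions <- conc$Na + conc$K + conc$Cl + ca_full
  X <- (baseline$osmolarity - osm_ions) * V
  if (any(X < 0)) stop("baseline osmolarity target below ionic osmolarity")

  cap <- geometry$capacitance * .conv$capacitance   # charge-amol um^-2 mV^-1
  Am <- geometry$A_m
  Q_target <- c(
    sn = cap[["neuron"]] * Am[["msn"]] * baseline$phi_m_neuron,
    se = NA, sg = cap[["glia"]] * Am[["msg"]] * baseline$phi_m_glia,
    dn = cap[["neuron"]] * Am[["mdn"]] * baseline$phi_m_neuron,
    de = NA, dg = cap[["glia"]] * Am[["mdg"]] * baseline$phi_m_glia
  )
  # bulk electroneutrality of each layer fixes the ECS charge
  Q_target[["se"]] <- -(Q_target[["sn"]] + Q_target[["sg"]])
  Q_target[["de"]] <- -(Q_target[["dn"]] + Q_target[["dg"]])

  ion_charge <- (conc$Na + conc$K - conc$Cl + 2 * ca_full) * V
  B <- Q_target - ion_charge
  list(X = unname(X), B = unname(B))
}

#' @export
print.edneg_parameters <- function(x, ...) {
  cat("Six-compartment electrodiffusive model parameters\n")
  cat("  non-dynamic (resting-state) parameters:\n")
  print(signif(x$membrane[.nondynamic_names], 4))
  cat("  dynamic (active-channel) conductances [mS/cm^2]:\n")
  print(signif(x$membrane[.dynamic_names], 4))
  invisible(x)
}

# state variable names, in the canonical ordering
.state_names <- c(
  paste0("Na_", c("sn", "se", "sg", "dn", "de", "dg")),
  paste0("K_", c("sn", "se", "sg", "dn", "de", "dg")),
  paste0("Cl_", c("sn", "se", "sg", "dn", "de", "dg")),
  paste0("Ca_", c("sn", "se", "dn", "de")),
  c("n", "h", "s", "c", "q", "z"),
  paste0("V_", c("sn", "se", "sg", "dn", "de", "dg"))
)

.phi_names <- c(
  paste0("phi_", c("sn", "se", "sg", "dn", "de", "dg")),
  paste0("phi_", c("msn", "mdn", "msg", "mdg"))
)

#' State-vector layout
#'
#' @return character vector of the 34 state-variable names in canonical
#'   order: 22 ion amounts (amol; Ca is absent from the two glial
#'   compartments), 6 gating variables, 6 volumes (um^3).
#' @export
edneg_state_names <- function() .state_names

#' Derived-potential layout
#'
#' @return character vector of the 10 potential names: six absolute
#'   compartment potentials (gauge: `phi_de = 0`) and the four membrane
#'   potentials (intracellular minus extracellular), all in mV.
#' @export
edneg_phi_names <- function() .phi_names

# Pack a parameter object (plus stimulus, internal units) into the flat
# numeric vector consumed by the compiled model core.  Order must match the
# enum in src/edneg.cpp.
edneg_pack_parms <- function(p, stim_amp = 0, stim_on = 0, stim_off = 0) {
  stopifnot(inherits(p, "edneg_parameters"))
  m <- p$membrane
  g <- .conv$conductance
  u <- .conv$pump_strength
  geo <- p$geometry
  kin <- p$kinetics
  c(
    m[["g_Na_leak_n"]] * g, m[["g_K_leak_n"]] * g, m[["g_Cl_leak_n"]] * g,
    m[["rho_n"]] * u, m[["U_kcc2"]] * u, m[["U_nkcc1"]] * u,
    m[["U_Cadec"]],
    m[["g_Na_leak_g"]] * g, m[["g_K_IR"]] * g, m[["g_Cl_leak_g"]] * g,
    m[["rho_g"]] * u,
    m[["g_Na"]] * g, m[["g_DR"]] * g, m[["g_Ca"]] * g, m[["g_AHP"]] * g,
    m[["g_C"]] * g,
    p$physical$psi,
    geo$A_m[["msn"]], geo$A_m[["mdn"]], geo$A_m[["msg"]], geo$A_m[["mdg"]],
    geo$capacitance[["neuron"]] * .conv$capacitance,
    geo$capacitance[["glia"]] * .conv$capacitance,
    geo$A_cross[["n"]], geo$A_cross[["e"]], geo$A_cross[["g"]],
    geo$dx,
    geo$diffusion[["Na"]] * .conv$diffusion, geo$diffusion[["K"]] * .conv$diffusion,
    geo$diffusion[["Cl"]] * .conv$diffusion, geo$diffusion[["Ca"]] * .conv$diffusion,
    geo$tortuosity[["n"]]^2, geo$tortuosity[["e"]]^2, geo$tortuosity[["g"]]^2,
    geo$water_permeability[["neuron"]], geo$water_permeability[["glia"]],
    p$background$X,
    p$background$B,
    kin$Ca_baseline[["sn"]], kin$Ca_baseline[["dn"]],
    kin$K_e_base, kin$free_Ca_fraction, kin$ca_activity_scale,
    kin$E_K_glia_rest, kin$pump_glia_Km_Na, kin$pump_glia_Km_K,
    kin$z_midpoint, kin$z_slope, kin$tau_z, kin$beta_q, kin$alpha_q_max,
    kin$Ca_activation_threshold, kin$pump_n_Na_half, kin$s_shift,
    stim_amp, stim_on, stim_off
  )
}
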