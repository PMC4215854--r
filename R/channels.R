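#' Voltage- and calcium-gated channel specifications
#'
#' A channel specification carries the reversal potential, the section roles
#' that express the channel, and its gating model: one or two gates, each
#' with a Boltzmann steady state, a bell-shaped voltage-dependent time
#' constant, and an integer exponent. The calcium-activated potassium (AHP)
#' channel uses a Hill-type calcium gate instead.
#'
#' @details
#' Voltage gates: `x_inf(V) = 1 / (1 + exp(-(V - vh)/k))` (k < 0 gives an
#' inactivation/hyperpolarization-activated gate) and
#' `tau(V) = tmin + tamp / (exp((V - tv1)/k1) + exp(-(V - tv2)/k2))` ms;
#' `tamp = 0` gives a constant time constant `tmin`. Calcium gates:
#' `z_inf = (Ca/kd)^hill / (1 + (Ca/kd)^hill)` with constant `tau`.
#'
#' @param name Channel name.
#' @param erev Reversal potential (mV).
#' @param regions Character vector of section roles carrying the channel.
#' @param gates List of gates from [voltage_gate()] / [calcium_gate()].
#' @param ca_current Whether the channel current feeds the calcium pool.
#' @return A list of class `olm_channel`.
#' @export
channel_spec <- function(name, erev, regions, gates, ca_current = FALSE) {
  stopifnot(is.character(name), length(gates) >= 1)
  for (g in gates) {
    if (g$exponent < 0) stop("gate exponents must be >= 0")
    if (g$type == 0L && (g$tmin <= 0))
      stop("time-constant functions must be strictly positive")
    if (g$type == 1L && g$tau <= 0)
      stop("time-constant functions must be strictly positive")
  }
  structure(list(name = name, erev = erev, regions = regions,
                 gates = gates, ca_current = ca_current),
            class = "olm_channel")
}

#' @param exponent Integer exponent applied to the gate variable.
#' @param vh,k Boltzmann half-activation (mV) and slope (mV).
#' @param tmin,tamp,tv1,k1,tv2,k2 Time-constant function parameters (ms, mV).
#' @rdname channel_spec
#' @export
voltage_gate <- function(exponent, vh, k, tmin, tamp = 0,
                         tv1 = vh, k1 = 15, tv2 = vh, k2 = 15) {
  list(exponent = exponent, type = 0L, vh = vh, k = k, tmin = tmin,
       tamp = tamp, tv1 = tv1, k1 = k1, tv2 = tv2, k2 = k2)
}

#' @param kd Half-activation calcium concentration (mM).
#' @param hill Hill coefficient.
#' @param tau Constant time constant (ms).
#' @rdname channel_spec
#' @export
calcium_gate <- function(exponent, kd, hill, tau) {
  list(exponent = exponent, type = 1L, kd = kd, hill = hill, tau = tau)
}

#' Default O-LM channel set
#'
#' The nine active conductances expressed by O-LM cells: somatic and
#' dendritic transient sodium (`Na_s`, `Na_d`), fast and slow delayed
#' rectifiers (`KDRf`, `KDRs`), A-type potassium (`A`),
#' hyperpolarization-activated mixed cation current (`h`), L- and T-type
#' calcium (`CaL`, `CaT`), calcium-activated potassium (`AHP`) and the
#' Kv7/KCNQ/M current (`M`). Reversal potentials default to E_Na = 50 mV,
#' E_K = -95 mV, E_h = -32.9 mV, E_Ca = +120 mV. The gating parameter set
#' follows the conventions of the O-LM modelling literature and every value
#' can be overridden via `overrides`.
#'
#' @param e_na,e_k,e_h,e_ca Reversal potentials (mV).
#' @param overrides Named list of `olm_channel` objects replacing the
#'   defaults (matched by name).
#' @return Named list of `olm_channel` objects (class `olm_channel_set`).
#' @export
default_channel_set <- function(e_na = 50, e_k = -95, e_h = -32.9,
                                e_ca = 120, overrides = list()) {
  na_gates <- list(
    voltage_gate(3, vh = -40, k = 7, tmin = 0.04, tamp = 0.2,
                 tv1 = -40, k1 = 12, tv2 = -40, k2 = 12),
    voltage_gate(1, vh = -58, k = -7, tmin = 0.8, tamp = 6,
                 tv1 = -58, k1 = 11, tv2 = -58, k2 = 11))
  chans <- list(
    channel_spec("Na_s", e_na, "soma", na_gates),
    channel_spec("Na_d", e_na, c("dendrite", "axon"), na_gates),
    channel_spec("KDRf", e_k, c("soma", "dendrite", "axon"), list(
      voltage_gate(4, vh = -26, k = 9, tmin = 0.6, tamp = 3,
                   tv1 = -25, k1 = 15, tv2 = -25, k2 = 15))),
    channel_spec("KDRs", e_k, c("soma", "dendrite", "axon"), list(
      voltage_gate(4, vh = -25, k = 11, tmin = 8, tamp = 40,
                   tv1 = -30, k1 = 15, tv2 = -30, k2 = 15))),
    channel_spec("A", e_k, c("soma", "dendrite"), list(
      voltage_gate(1, vh = -32, k = 9, tmin = 0.8, tamp = 3,
                   tv1 = -40, k1 = 15, tv2 = -40, k2 = 15),
      voltage_gate(1, vh = -85, k = -6, tmin = 12, tamp = 40,
                   tv1 = -60, k1 = 15, tv2 = -60, k2 = 15))),
    channel_spec("h", e_h, c("soma", "dendrite"), list(
      voltage_gate(1, vh = -90, k = -5, tmin = 80, tamp = 600,
                   tv1 = -65, k1 = 12, tv2 = -110, k2 = 12))),
    channel_spec("CaL", e_ca, "dendrite", list(
      voltage_gate(2, vh = -10, k = 6, tmin = 1, tamp = 2,
                   tv1 = -20, k1 = 12, tv2 = -20, k2 = 12)),
      ca_current = TRUE),
    channel_spec("CaT", e_ca, "dendrite", list(
      voltage_gate(2, vh = -45, k = 6.5, tmin = 1.5, tamp = 4,
                   tv1 = -50, k1 = 12, tv2 = -50, k2 = 12),
      voltage_gate(1, vh = -85, k = -4, tmin = 15, tamp = 60,
                   tv1 = -75, k1 = 15, tv2 = -75, k2 = 15)),
      ca_current = TRUE),
    channel_spec("AHP", e_k, "dendrite", list(
      calcium_gate(1, kd = 0.05, hill = 2, tau = 40))),
    channel_spec("M", e_k, c("soma", "dendrite"), list(
      voltage_gate(1, vh = -27, k = 7, tmin = 15, tamp = 80,
                   tv1 = -45, k1 = 20, tv2 = -45, k2 = 20))))
  names(chans) <- vapply(chans, `[[`, "", "name")
  for (nm in names(overrides)) {
    if (!nm %in% names(chans)) stop("unknown channel in overrides: ", nm)
    chans[[nm]] <- overrides[[nm]]
  }
  structure(chans, class = "olm_channel_set")
}

#' @export
print.olm_channel_set <- function(x, ...) {
  cat("Channel set:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
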