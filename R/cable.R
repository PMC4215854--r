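#' Build a simulatable cable from a model specification
#'
#' Combines a discretized morphology with a channel set and a model
#' specification's maximum conductance densities, assigning each channel to
#' the compartments whose section role it is expressed in. The h-current is
#' placed on the soma only or uniformly over soma and dendrites according
#' to the spec's `ih_dist` flag.
#'
#' @param spec An `olm_model_spec` (or a named numeric vector of densities
#'   in pS/um^2, in which case `ih_dist` must be given).
#' @param morph An `olm_morphology`.
#' @param passive An `olm_passive`.
#' @param channels An `olm_channel_set`.
#' @param disc An `olm_discretization`.
#' @param ih_dist Overrides the spec's h-distribution flag.
#' @param ca_shell_depth Depth of the submembrane calcium shell (um).
#' @param tau_ca Calcium removal time constant (ms).
#' @param ca_rest Resting calcium concentration (mM).
#' @return A list of class `olm_cable` ready for [simulate_protocol()].
#' @export
build_cable <- function(spec, morph, passive,
                        channels = default_channel_set(),
                        disc = discretization(), ih_dist = NULL,
                        ca_shell_depth = 0.1, tau_ca = 30,
                        ca_rest = 5e-5) {
  if (inherits(spec, "olm_model_spec")) {
    densities <- spec$densities
    if (is.null(ih_dist)) ih_dist <- spec$ih_dist
    model_id <- spec$model_id
  } else {
    densities <- spec
    model_id <- NA_integer_
    if (is.null(ih_dist)) stop("ih_dist required when spec is a plain vector")
  }
  missing <- setdiff(names(channels), names(densities))
  if (length(missing))
    stop("no density assigned for channel(s): ",
         paste(missing, collapse = ", "))
  stopifnot(ih_dist %in% c("soma", "somatodendritic"))

  skel <- discretize(morph, passive, disc)
  comp <- skel$comp
  n <- nrow(comp)
  nchan <- length(channels)
  g_chan <- matrix(0, n, nchan, dimnames = list(NULL, names(channels)))
  has_ca_sink <- logical(n)
  for (j in seq_len(nchan)) {
    ch <- channels[[j]]
    regions <- ch$regions
    if (ch$name == "h")
      regions <- if (ih_dist == "soma") "soma" else c("soma", "dendrite")
    mask <- comp$role %in% regions
    g_chan[mask, j] <- densities[[ch$name]] * comp$area[mask] * 1e-3  # nS
    if (ch$ca_current) has_ca_sink <- has_ca_sink | mask
  }
  # calcium influx factor: phi = 1/(2 F * shell volume) in mM/(pA ms)
  ca_phi <- ifelse(has_ca_sink,
                   1e3 / (2 * 96485 * comp$area * ca_shell_depth), 0)

  chan_payload <- lapply(channels, function(ch)
    list(erev = ch$erev, ca_current = ch$ca_current, gates = ch$gates))

  structure(list(
    parent = ifelse(is.na(comp$parent_comp), -1L,
                    as.integer(comp$parent_comp - 1L)),
    g_ax = ifelse(is.na(comp$g_ax), 0, comp$g_ax),
    cm = comp$cm, g_pas = comp$g_pas, g_kl = comp$g_kl,
    e_pas = passive$el, e_k = channels[[which(names(channels) == "KDRf")]]$erev,
    g_chan = g_chan, channels = unname(chan_payload),
    ca_phi = ca_phi, tau_ca = tau_ca, ca_rest = ca_rest,
    comp = comp, model_id = model_id, ih_dist = ih_dist,
    morph_label = morph$label, densities = densities),
    class = "olm_cable")
}

#' Index of the central somatic compartment
#' @param cable An `olm_cable`.
#' @return Integer compartment index.
#' @export
soma_comp <- function(cable) {
  idx <- which(cable$comp$role == "soma")
  idx[ceiling(length(idx) / 2)]
}

#' Compartment nearest a given path distance from the soma on a dendrite
#'
#' @param cable An `olm_cable`.
#' @param dist Path distance from the soma (um).
#' @return Integer compartment index.
#' @export
dendrite_comp_at <- function(cable, dist) {
  idx <- which(cable$comp$role == "dendrite")
  if (!length(idx)) stop("invalid site: morphology has no dendrite")
  idx[which.min(abs(cable$comp$path_dist[idx] - dist))]
}

#' @export
print.olm_cable <- function(x, ...) {
  cat("Cable (", x$morph_label, "): ", nrow(x$comp), " compartments, ",
      "model_id ", x$model_id, ", I_h ", x$ih_dist, "\n", sep = "")
  invisible(x)
}
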