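#' Current/voltage-clamp protocol specification
#'
#' Timing of a somatic current step with optional bias current, optional
#' ideal somatic voltage clamp and optional dendritic injection.
#'
#' @param pre Pre-step settling duration (ms).
#' @param step_dur Step duration (ms).
#' @param post Post-step recovery duration (ms).
#' @param amp Somatic step amplitude (pA).
#' @param bias Constant somatic bias (holding) current (pA), applied for the
#'   whole protocol.
#' @param vc_level Somatic voltage-clamp command (mV) or `NULL` for current
#'   clamp.
#' @param vc_g Clamp series conductance (nS); the default 10000 nS
#'   (0.1 Mohm series resistance) approximates an ideal clamp even for
#'   high-conductance models.
#' @param dend_site Path distance (um) of a dendritic injection site, or
#'   `NULL`.
#' @param dend_amp Tonic dendritic injection amplitude (pA), applied from
#'   `pre` to the end of the step window.
#' @param target_vm Holding target (mV); metadata only.
#' @return A list of class `olm_protocol`.
#' @export
protocol_spec <- function(pre = 1000, step_dur = 1000, post = 1000,
                          amp = 0, bias = 0, vc_level = NULL,
                          vc_g = 10000,
                          dend_site = NULL, dend_amp = 0,
                          target_vm = -74) {
  if (pre < 0 || step_dur < 0 || post < 0)
    stop("durations must be >= 0")
  structure(list(pre = pre, step_dur = step_dur, post = post, amp = amp,
                 bias = bias, vc_level = vc_level, vc_g = vc_g,
                 dend_site = dend_site, dend_amp = dend_amp,
                 target_vm = target_vm), class = "olm_protocol")
}

#' Simulate a cable under a protocol
#'
#' Integrates the compartmental membrane equation (Crank-Nicolson on the
#' cable terms, exponential gate updates) and returns the voltage sampled
#' every `dt_save` ms at the requested sites. Deterministic for fixed
#' inputs.
#'
#' @param cable An `olm_cable` from [build_cable()].
#' @param proto An `olm_protocol`.
#' @param dt,dt_save Integration and output sampling steps (ms).
#' @param record Compartment indices to record; defaults to the central
#'   somatic compartment. Names are kept as site labels.
#' @param v_init Initial membrane potential (mV); defaults to the leak
#'   reversal.
#' @return An object of class `olm_trace`: list with `t` (ms), `v` (matrix,
#'   one column per site), `sites`, `i_clamp` (pA, when voltage clamped),
#'   `proto`, `model_id`.
#' @export
simulate_protocol <- function(cable, proto, dt = 0.025, dt_save = 0.1,
                              record = NULL, v_init = NULL) {
  stopifnot(inherits(cable, "olm_cable"), inherits(proto, "olm_protocol"))
  soma <- soma_comp(cable)
  if (is.null(record)) record <- c(soma = soma)
  if (is.null(names(record)))
    names(record) <- paste0("comp", record)
  if (is.null(v_init)) v_init <- cable$e_pas
  t_total <- proto$pre + proto$step_dur + proto$post
  inj <- matrix(numeric(0), ncol = 4)
  if (proto$bias != 0)
    inj <- rbind(inj, c(soma, 0, t_total, proto$bias))
  if (proto$amp != 0)
    inj <- rbind(inj, c(soma, proto$pre, proto$pre + proto$step_dur,
                        proto$amp))
  if (!is.null(proto$dend_site) && proto$dend_amp != 0) {
    dcomp <- dendrite_comp_at(cable, proto$dend_site)
    inj <- rbind(inj, c(dcomp, proto$pre, proto$pre + proto$step_dur,
                        proto$dend_amp))
  }
  vc <- if (is.null(proto$vc_level)) list(on = FALSE) else
    list(on = TRUE, comp = soma, level = proto$vc_level,
         g_clamp = proto$vc_g)
  res <- .cpp_simulate(
    unclass(cable),
    list(t_total = t_total, dt = dt, dt_save = dt_save, inj = inj,
         vc = vc, record = as.integer(record), v_init = v_init))
  v <- res$v
  colnames(v) <- names(record)
  structure(list(t = res$t, v = v, sites = names(record),
                 i_clamp = if (vc$on) res$i_clamp else NULL,
                 dt_save = dt_save, dt = dt, proto = proto,
                 model_id = cable$model_id),
            class = "olm_trace")
}

#' Extract one site's voltage from a trace
#' @param trace An `olm_trace`.
#' @param site Site name or column index (default first column).
#' @return Numeric vector of membrane potential (mV).
#' @export
trace_site <- function(trace, site = 1) {
  trace$v[, site]
}

#' @export
print.olm_trace <- function(x, ...) {
  cat("Voltage trace:", length(x$t), "samples x", ncol(x$v), "site(s), ",
      max(x$t), "ms; step", x$proto$amp, "pA, bias",
      round(x$proto$bias, 2), "pA\n")
  invisible(x)
}

#' Period boundaries of a trace (ini / pulse / recovery)
#' @param trace An `olm_trace`.
#' @return Named list of index vectors into `trace$t`.
#' @keywords internal
trace_periods <- function(trace) {
  p <- trace$proto
  t <- trace$t
  list(ini = which(t < p$pre),
       pulse = which(t >= p$pre & t < p$pre + p$step_dur),
       recov = which(t >= p$pre + p$step_dur))
}

#' Run the paired hyperpolarizing/depolarizing step protocol
#'
#' Simulates the same model under -90 pA and +90 pA somatic steps sharing
#' the fitted bias current and identical timing.
#'
#' @param cable An `olm_cable`.
#' @param bias Fitted bias current (pA).
#' @param amps Step amplitudes (pA).
#' @param pre,step_dur,post Timing (ms).
#' @param dt,dt_save Integration steps (ms).
#' @return Named list of two `olm_trace` objects (`"hyp"`, `"dep"`).
#' @export
run_step_pair <- function(cable, bias, amps = c(-90, 90), pre = 1000,
                          step_dur = 1000, post = 1000, dt = 0.025,
                          dt_save = 0.1) {
  stopifnot(length(amps) == 2)
  traces <- lapply(amps, function(a)
    simulate_protocol(cable,
                      protocol_spec(pre = pre, step_dur = step_dur,
                                    post = post, amp = a, bias = bias),
                      dt = dt, dt_save = dt_save))
  names(traces) <- ifelse(amps < 0, "hyp", "dep")
  traces
}

#' Mixed voltage-clamp / current-clamp dendritic protocol
#'
#' Holds the soma at `hold` mV with an ideal (stiff series conductance)
#' voltage clamp while injecting a tonic hyperpolarizing current at a
#' dendritic site, and records the soma plus positions along the injected
#' branch.
#'
#' @param cable An `olm_cable`.
#' @param site_distance Path distance of the injection site from the soma
#'   (um).
#' @param dend_current Tonic dendritic current (nA; negative =
#'   hyperpolarizing).
#' @param hold Somatic clamp command (mV).
#' @param pre,step_dur,post Timing (ms).
#' @param n_sites Number of dendritic recording positions (>= 3) spread
#'   from the injection site outward along the same branch.
#' @param dt,dt_save Integration steps (ms).
#' @return An `olm_trace` with one soma column and `n_sites` dendritic
#'   columns.
#' @export
run_vcic_protocol <- function(cable, site_distance = 30, dend_current = -5,
                              hold = -74, pre = 500, step_dur = 1000,
                              post = 500, n_sites = 3, dt = 0.025,
                              dt_save = 0.1) {
  dcomp <- dendrite_comp_at(cable, site_distance)
  if (cable$comp$role[dcomp] != "dendrite")
    stop("invalid site: injection site must be on a dendrite")
  # recording sites: injection compartment and downstream along its branch
  branch <- which(cable$comp$role == "dendrite" &
                    cable$comp$section == cable$comp$section[dcomp] &
                    seq_len(nrow(cable$comp)) >= dcomp)
  # extend into child sections if the branch is short
  if (length(branch) < n_sites) {
    kids <- which(cable$comp$role == "dendrite" &
                    cable$comp$path_dist > cable$comp$path_dist[dcomp])
    branch <- sort(unique(c(branch, kids)))
  }
  sites <- branch[unique(round(seq(1, length(branch),
                                   length.out = n_sites)))]
  record <- c(soma = soma_comp(cable), setNames(
    sites, paste0("dend_", round(cable$comp$path_dist[sites]), "um")))
  proto <- protocol_spec(pre = pre, step_dur = step_dur, post = post,
                         amp = 0, bias = 0, vc_level = hold,
                         dend_site = site_distance,
                         dend_amp = dend_current * 1000)  # nA -> pA
  simulate_protocol(cable, proto, dt = dt, dt_save = dt_save,
                    record = record, v_init = hold)
}
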