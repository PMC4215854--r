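#' Detect action potentials in a voltage trace
#'
#' Spikes are upward crossings of a fixed voltage threshold separated by at
#' least a refractory gap. Deterministic; an empty result is allowed.
#'
#' @param trace An `olm_trace`, or a list with elements `t` and `v`.
#' @param threshold Crossing threshold (mV).
#' @param refractory Minimum separation between spikes (ms).
#' @param site Recording site to use.
#' @return Numeric vector of spike times (ms).
#' @export
detect_spikes <- function(trace, threshold = -20, refractory = 2,
                          site = 1) {
  v <- if (is.matrix(trace$v)) trace$v[, site] else trace$v
  t <- trace$t
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- t[up]
  keep <- c(TRUE, diff(times) >= refractory)
  # enforce the gap sequentially (a crossing inside the gap of a kept spike
  # is dropped and does not reset the gap)
  out <- numeric(0)
  last <- -Inf
  for (tt in times) {
    if (tt - last >= refractory) {
      out <- c(out, tt)
      last <- tt
    }
  }
  out
}

#' Fit the time constant of the hyperpolarization-induced sag
#'
#' Fits `V(t) = V_ss - A * exp(-(t - t_trough)/tau)` by separable least
#' squares on the interval from the voltage trough to the end of the
#' current step. The linear parameters (V_ss, A) are solved in closed form
#' for each candidate tau; tau is optimized by golden-section search.
#'
#' @param trace A hyperpolarizing `olm_trace`.
#' @param min_sag Minimum trough-to-steady-state amplitude (mV) for a sag
#'   to be declared present.
#' @param site Recording site.
#' @param tau_range Search range for tau (ms).
#' @return A list: `ok` (logical), `tau` (ms), `v_ss`, `amp`, and `reason`
#'   = `"no sag"` for monotonic traces (distinct from a fit failure).
#' @export
fit_sag_tau <- function(trace, min_sag = 0.5, site = 1,
                        tau_range = c(1, 2000)) {
  p <- trace$proto
  per <- trace_periods(trace)
  t <- trace$t[per$pulse]
  v <- (if (is.matrix(trace$v)) trace$v[, site] else trace$v)[per$pulse]
  if (length(t) < 10)
    return(list(ok = FALSE, tau = NA_real_, reason = "fit failure"))
  imin <- which.min(v)
  ss <- mean(v[t >= max(t) - 100])
  sag_amp <- ss - v[imin]
  # a trough in the last 5% of the step, or a negligible rebound, means the
  # response is effectively monotonic
  if (imin > 0.95 * length(v) || sag_amp < min_sag)
    return(list(ok = FALSE, tau = NA_real_, amp = sag_amp,
                reason = "no sag"))
  tt <- t[imin:length(t)] - t[imin]
  vv <- v[imin:length(v)]
  sse <- function(tau) {
    b <- exp(-tt / tau)
    X <- cbind(1, b)
    fit <- tryCatch(qr.solve(X, vv), error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    sum((vv - X %*% fit)^2)
  }
  opt <- optimize(sse, lower = tau_range[1], upper = tau_range[2],
                  tol = 1e-3)
  tau <- opt$minimum
  b <- exp(-tt / tau)
  cf <- qr.solve(cbind(1, b), vv)
  # guard against degenerate fits (tau pinned at the bound, or an
  # exponential component inconsistent with the observed rebound)
  if (tau > 0.95 * tau_range[2] || -cf[2] < min_sag / 2)
    return(list(ok = FALSE, tau = NA_real_, amp = sag_amp,
                reason = "fit failure"))
  list(ok = TRUE, tau = tau, v_ss = unname(cf[1]), amp = -unname(cf[2]),
       reason = NULL)
}

# ---------------------------------------------------------------------------
# measure registry

measure_quantities <- c("SpikeAmplitude", "SpikeMaxVm", "SpikeMinVm",
                        "SpikeThresholdVm", "SpikeHalfWidth",
                        "SpikeBaseWidth", "SpikeMaxRise", "SpikeMaxFall",
                        "SpikeAHPDepth", "SpikeAHPDelay", "SpikeRiseTime",
                        "SpikeFallTime", "SpikeHeight", "ISI")

#' The default electrophysiological measure registry
#'
#' Measures are named with a period prefix (`Ini` before the 1 s step,
#' `Pulse` during it, `Recov` after it) and, for per-spike statistics, a
#' `Mean` or `Mode` suffix. The hyperpolarizing (-90 pA) set holds 11
#' subthreshold measures (trough, steady state, sag amplitude and time
#' constant, period means/extrema). The depolarizing (+90 pA) set holds 92
#' measures: 8 scalar counts/timings plus 14 per-spike quantities x 3
#' periods x \{Mean, Mode\}.
#'
#' @return A data.frame (class `olm_registry`) with columns `name`,
#'   `protocol` (`"hyp"`/`"dep"`), `period`, `quantity`, `statistic`.
#' @export
measure_registry <- function() {
  hyp <- data.frame(
    name = c("IniVmMean", "IniVmSD", "PulseVmMin", "PulseVmMean",
             "PulseVmSS", "PulsePotSag", "PulseSagTau", "RecovVmMean",
             "RecovVmMax", "RecovVmSS", "RecovPotOvershoot"),
    protocol = "hyp",
    period = c("Ini", "Ini", "Pulse", "Pulse", "Pulse", "Pulse", "Pulse",
               "Recov", "Recov", "Recov", "Recov"),
    quantity = c("VmMean", "VmSD", "VmMin", "VmMean", "VmSS", "PotSag",
                 "SagTau", "VmMean", "VmMax", "VmSS", "PotOvershoot"),
    statistic = "")
  scalars <- data.frame(
    name = c("IniSpikes", "PulseSpikes", "RecovSpikes", "PulseFiringFreq",
             "PulseFirstSpikeTime", "PulseLastSpikeTime",
             "RecovFirstSpikeTime", "RecovVmMin"),
    protocol = "dep",
    period = c("Ini", "Pulse", "Recov", "Pulse", "Pulse", "Pulse",
               "Recov", "Recov"),
    quantity = c("Spikes", "Spikes", "Spikes", "FiringFreq",
                 "FirstSpikeTime", "LastSpikeTime", "FirstSpikeTime",
                 "VmMin"),
    statistic = "")
  per <- expand.grid(statistic = c("Mean", "Mode"),
                     quantity = measure_quantities,
                     period = c("Ini", "Pulse", "Recov"),
                     stringsAsFactors = FALSE)
  per <- data.frame(name = paste0(per$period, per$quantity, per$statistic),
                    protocol = "dep", period = per$period,
                    quantity = per$quantity, statistic = per$statistic)
  reg <- rbind(hyp, scalars, per)
  stopifnot(!anyDuplicated(reg$name))
  class(reg) <- c("olm_registry", "data.frame")
  reg
}

#' @export
print.olm_registry <- function(x, ...) {
  cat("Measure registry:", sum(x$protocol == "hyp"), "hyperpolarizing +",
      sum(x$protocol == "dep"), "depolarizing =", nrow(x), "measures\n")
  invisible(x)
}

#' Registry export
#' @param registry An `olm_registry`.
#' @param path JSON file path.
#' @export
registry_to_json <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path, digits = NA)
  invisible(path)
}

# deterministic mode of a small sample (kernel density peak)
stat_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || diff(range(x)) < 1e-12) return(mean(x))
  d <- density(x)
  d$x[which.max(d$y)]
}

# per-spike shape quantities within one period
spike_shape_stats <- function(t, v, spike_times, period_end) {
  n <- length(spike_times)
  out <- matrix(NA_real_, n, length(measure_quantities),
                dimnames = list(NULL, measure_quantities))
  if (n == 0) return(out)
  dt <- t[2] - t[1]
  dvdt <- c(diff(v) / dt, 0)
  bounds <- c(spike_times, period_end)
  for (i in seq_len(n)) {
    win <- which(t >= spike_times[i] & t < bounds[i + 1])
    if (length(win) < 3) next
    vw <- v[win]; tw <- t[win]; dw <- dvdt[win]
    ipk <- which.max(vw)
    # threshold: last point before the peak where dV/dt first reaches
    # 20 mV/ms
    pre <- which(dw[seq_len(ipk)] >= 20)
    ithr <- if (length(pre)) pre[1] else 1L
    vthr <- vw[ithr]
    vmax <- vw[ipk]
    post <- if (ipk < length(vw)) vw[(ipk + 1):length(vw)] else vw[ipk]
    imin <- ipk + which.min(post)
    vmin <- min(post)
    amp <- vmax - vthr
    half <- vthr + amp / 2
    above <- which(vw >= half)
    out[i, "SpikeAmplitude"] <- amp
    out[i, "SpikeMaxVm"] <- vmax
    out[i, "SpikeMinVm"] <- vmin
    out[i, "SpikeThresholdVm"] <- vthr
    out[i, "SpikeHalfWidth"] <- if (length(above)) dt * length(above) else NA
    out[i, "SpikeBaseWidth"] <- dt * sum(vw >= vthr)
    out[i, "SpikeMaxRise"] <- max(dw)
    out[i, "SpikeMaxFall"] <- min(dw)
    out[i, "SpikeAHPDepth"] <- vthr - vmin
    out[i, "SpikeAHPDelay"] <- tw[min(imin, length(tw))] - tw[ipk]
    out[i, "SpikeRiseTime"] <- tw[ipk] - tw[ithr]
    ifall <- which(vw[ipk:length(vw)] <= half)
    out[i, "SpikeFallTime"] <- if (length(ifall)) dt * (ifall[1] - 1) else NA
    out[i, "SpikeHeight"] <- vmax - vmin
  }
  out[, "ISI"] <- c(diff(spike_times), NA)
  out
}

#' Extract the measure vector of a trace
#'
#' Computes every measure in the registry applicable to the trace's
#' protocol. Measures undefined on the trace (e.g. spike-shape statistics
#' of a period with no spikes, or the sag time constant of a monotonic
#' response) are returned as `NA` (invalid), never zero-filled.
#'
#' @param trace An `olm_trace`.
#' @param registry An `olm_registry`.
#' @param protocol `"hyp"` or `"dep"`; inferred from the step sign when
#'   omitted.
#' @param spike_threshold,refractory Spike detection settings.
#' @param ss_window Steady-state window at the end of the step (ms).
#' @param site Recording site.
#' @return Named numeric vector over the registry's measures for this
#'   protocol (class `olm_measures`), with attribute `protocol`.
#' @export
extract_measures <- function(trace, registry = measure_registry(),
                             protocol = NULL, spike_threshold = -20,
                             refractory = 2, ss_window = 100, site = 1) {
  if (is.null(protocol))
    protocol <- if (trace$proto$amp < 0) "hyp" else "dep"
  stopifnot(protocol %in% c("hyp", "dep"))
  reg <- registry[registry$protocol == protocol, , drop = FALSE]
  t <- trace$t
  v <- if (is.matrix(trace$v)) trace$v[, site] else trace$v
  per <- trace_periods(trace)
  p <- trace$proto
  out <- setNames(rep(NA_real_, nrow(reg)), reg$name)

  if (protocol == "hyp") {
    ini_v <- v[per$ini]; pul_v <- v[per$pulse]; rec_v <- v[per$recov]
    pul_t <- t[per$pulse]; rec_t <- t[per$recov]
    ss <- mean(pul_v[pul_t >= max(pul_t) - ss_window])
    out["IniVmMean"] <- mean(ini_v)
    out["IniVmSD"] <- sd(ini_v)
    out["PulseVmMin"] <- min(pul_v)
    out["PulseVmMean"] <- mean(pul_v)
    out["PulseVmSS"] <- ss
    out["PulsePotSag"] <- ss - min(pul_v)
    sagfit <- fit_sag_tau(trace, site = site)
    out["PulseSagTau"] <- if (sagfit$ok) sagfit$tau else NA_real_
    out["RecovVmMean"] <- mean(rec_v)
    out["RecovVmMax"] <- max(rec_v)
    out["RecovVmSS"] <- mean(rec_v[rec_t >= max(rec_t) - ss_window])
    out["RecovPotOvershoot"] <- max(rec_v) - mean(ini_v)
  } else {
    spikes <- detect_spikes(trace, threshold = spike_threshold,
                            refractory = refractory, site = site)
    pend <- c(p$pre, p$pre + p$step_dur, p$pre + p$step_dur + p$post)
    sp <- list(Ini = spikes[spikes < pend[1]],
               Pulse = spikes[spikes >= pend[1] & spikes < pend[2]],
               Recov = spikes[spikes >= pend[2]])
    out["IniSpikes"] <- length(sp$Ini)
    out["PulseSpikes"] <- length(sp$Pulse)
    out["RecovSpikes"] <- length(sp$Recov)
    out["PulseFiringFreq"] <- length(sp$Pulse) / (p$step_dur / 1000)
    out["PulseFirstSpikeTime"] <- if (length(sp$Pulse))
      sp$Pulse[1] - p$pre else NA_real_
    out["PulseLastSpikeTime"] <- if (length(sp$Pulse))
      sp$Pulse[length(sp$Pulse)] - p$pre else NA_real_
    out["RecovFirstSpikeTime"] <- if (length(sp$Recov))
      sp$Recov[1] - pend[2] else NA_real_
    out["RecovVmMin"] <- min(v[per$recov])
    for (period in c("Ini", "Pulse", "Recov")) {
      st <- spike_shape_stats(t, v, sp[[period]], pend[
        match(period, c("Ini", "Pulse", "Recov"))])
      for (q in measure_quantities) {
        vals <- st[, q]
        vals <- vals[is.finite(vals)]
        nm_mean <- paste0(period, q, "Mean")
        nm_mode <- paste0(period, q, "Mode")
        if (length(vals)) {
          out[nm_mean] <- mean(vals)
          out[nm_mode] <- stat_mode(vals)
        }
      }
    }
  }
  structure(out, protocol = protocol, class = "olm_measures")
}
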