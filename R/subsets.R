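#' General (distance-derivative) cutoff of a ranked database
#'
#' Computes first differences of the aggregate distance with respect to
#' rank, estimates the plateau slope as the median difference over the
#' middle 50% of ranks, and returns the first rank after the plateau at
#' which the smoothed difference exceeds `sensitivity` times the plateau
#' slope persistently (for at least `persistence` of the database length).
#' Replaces the original by-eye choice with a logged, overridable detector.
#'
#' @param d Ascending vector of aggregate distances (by rank).
#' @param sensitivity Slope multiple that counts as leaving the plateau.
#' @param persistence Fraction of the database length the excess must
#'   persist for.
#' @param override Manual cutoff rank; when given it is returned with the
#'   detector's diagnostics attached.
#' @return A list of class `olm_cutoff`: `criterion`, `cutoff` (rank, or
#'   `NA` with `verdict = "no cutoff"`), `diagnostics`.
#' @export
general_cutoff <- function(d, sensitivity = 3, persistence = 0.01,
                           override = NULL) {
  n <- length(d)
  stopifnot(n >= 10)
  if (any(diff(d) < -1e-9)) stop("distance sequence must be ascending")
  dd <- diff(d)
  w <- max(1L, round(persistence * n))
  sm <- stats::filter(dd, rep(1 / w, w), sides = 1)
  sm[seq_len(min(w - 1, length(sm)))] <- dd[seq_len(min(w - 1, length(dd)))]
  sm <- as.numeric(sm)
  mid <- seq(floor(n / 4), ceiling(3 * n / 4) - 1)
  plateau <- median(dd[mid])
  thr <- sensitivity * plateau
  diag <- list(plateau_slope = plateau, threshold = thr,
               window = w, sensitivity = sensitivity)
  if (!is.null(override))
    return(structure(list(criterion = "general", cutoff = override,
                          verdict = "override", diagnostics = diag),
                     class = "olm_cutoff"))
  # enter the plateau first (skip the initial steep descent region)
  in_plateau <- which(sm <= 1.5 * plateau)
  start <- if (length(in_plateau)) in_plateau[1] else NA_integer_
  cutoff <- NA_integer_
  if (!is.na(start) && plateau > 0) {
    exceed <- sm > thr
    exceed[seq_len(start)] <- FALSE
    run <- rle(exceed)
    ends <- cumsum(run$lengths)
    hit <- which(run$values & run$lengths >= w)
    if (length(hit))
      cutoff <- ends[hit[1]] - run$lengths[hit[1]] + 1L
  }
  verdict <- if (is.na(cutoff)) "no cutoff" else "detected"
  structure(list(criterion = "general", cutoff = cutoff, verdict = verdict,
                 diagnostics = diag), class = "olm_cutoff")
}

#' Failure-to-fire (restricted) cutoff
#'
#' A model "fails to fire" when it emits no more than `spike_floor` action
#' potentials during the +90 pA step. The restricted cutoff is the rank
#' prior to the first failure-to-fire model.
#'
#' @param pulse_spikes Vector of `PulseSpikes` in rank order.
#' @param spike_floor Maximum spike count that still counts as failure.
#' @return An `olm_cutoff` (cutoff = database size when no model fails).
#' @export
failure_to_fire_cutoff <- function(pulse_spikes, spike_floor = 2) {
  if (anyNA(pulse_spikes))
    stop("PulseSpikes must be available for every ranked model")
  first_fail <- which(pulse_spikes <= spike_floor)
  cutoff <- if (length(first_fail)) first_fail[1] - 1L
            else length(pulse_spikes)
  structure(list(criterion = "failure_to_fire", cutoff = cutoff,
                 verdict = "detected",
                 diagnostics = list(first_failure_rank =
                   if (length(first_fail)) first_fail[1] else NA_integer_,
                   spike_floor = spike_floor)),
            class = "olm_cutoff")
}

#' Sag time-constant (restricted) cutoff
#'
#' Returns the rank before the first persistent run of models whose sag
#' time constant falls outside the range observed in the experimental
#' dataset. Models without a measurable sag count as outside the range.
#'
#' @param sag_tau Vector of model sag time constants in rank order (ms; NA
#'   = no sag).
#' @param exp_tau Experimental sag time constants (the range `[min, max]`
#'   is used).
#' @param persistence Fraction of the database length a run must persist.
#' @return An `olm_cutoff` (cutoff = database size when no exit occurs).
#' @export
sag_tau_cutoff <- function(sag_tau, exp_tau, persistence = 0.01) {
  exp_tau <- exp_tau[is.finite(exp_tau)]
  if (!length(exp_tau)) stop("criterion unavailable: empty experimental ",
                             "sag time-constant set")
  rng <- range(exp_tau)
  n <- length(sag_tau)
  w <- max(1L, round(persistence * n))
  outside <- !is.finite(sag_tau) | sag_tau < rng[1] | sag_tau > rng[2]
  run <- rle(outside)
  ends <- cumsum(run$lengths)
  hit <- which(run$values & run$lengths >= w)
  cutoff <- if (length(hit)) ends[hit[1]] - run$lengths[hit[1]] else n
  structure(list(criterion = "sag_tau", cutoff = as.integer(cutoff),
                 verdict = if (length(hit)) "detected" else "no exit",
                 diagnostics = list(range = rng, window = w,
                                    tau_exit_rank = if (length(hit))
                                      cutoff + 1L else NA_integer_)),
            class = "olm_cutoff")
}

#' Subset report for one ranked (per-morphology) database
#'
#' @param ranked A ranked data.frame (from [rank_models()]).
#' @param cutoff An `olm_cutoff` (or integer rank).
#' @param morphology Morphology label for provenance.
#' @return A list of class `olm_subset_report`: `criterion`, `cutoffs`
#'   (named per morphology), `members` (data.frame `morphology`,
#'   `model_id`, `rank`), `diagnostics`.
#' @export
subset_report <- function(ranked, cutoff, morphology = "morph1") {
  if (inherits(cutoff, "olm_cutoff")) {
    crit <- cutoff$criterion
    diag <- cutoff$diagnostics
    k <- cutoff$cutoff
  } else {
    crit <- "manual"; diag <- list(); k <- cutoff
  }
  if (is.na(k)) stop("cutoff is undefined (verdict: no cutoff)")
  if (k > nrow(ranked)) stop("cutoff exceeds database size")
  members <- if (k >= 1)
    data.frame(morphology = morphology,
               model_id = ranked$model_id[seq_len(k)],
               rank = seq_len(k))
  else data.frame(morphology = character(0), model_id = integer(0),
                  rank = integer(0))
  structure(list(criterion = crit, cutoffs = setNames(k, morphology),
                 members = members, diagnostics = diag),
            class = "olm_subset_report")
}

#' Pool per-morphology subset reports
#'
#' The pooled subset is the union of the per-morphology memberships; its
#' cardinality is the sum of the per-morphology cutoffs.
#'
#' @param reports List of `olm_subset_report` objects sharing a criterion.
#' @return A pooled `olm_subset_report`.
#' @export
pool_subsets <- function(reports) {
  stopifnot(length(reports) >= 1)
  crits <- unique(vapply(reports, `[[`, "", "criterion"))
  if (length(crits) != 1)
    stop("cannot pool subsets with mixed criteria: ",
         paste(crits, collapse = ", "))
  cutoffs <- do.call(c, lapply(reports, `[[`, "cutoffs"))
  members <- do.call(rbind, lapply(reports, `[[`, "members"))
  rep <- structure(list(criterion = crits, cutoffs = cutoffs,
                        members = members,
                        diagnostics = list(pooled_from = length(reports))),
                   class = "olm_subset_report")
  stopifnot(nrow(members) == sum(cutoffs))
  rep
}

#' Size of a subset
#' @param report An `olm_subset_report`.
#' @export
subset_size <- function(report) nrow(report$members)

#' @export
print.olm_subset_report <- function(x, ...) {
  cat("Subset (", x$criterion, "): ", nrow(x$members), " models; cutoffs: ",
      paste(names(x$cutoffs), "=", x$cutoffs, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Subset report serialization (JSON + membership CSV)
#' @param report An `olm_subset_report`.
#' @param path Base path; writes `<path>.json` and `<path>_members.csv`.
#' @export
write_subset_report <- function(report, path) {
  jsonlite::write_json(list(criterion = report$criterion,
                            cutoffs = as.list(report$cutoffs),
                            diagnostics = report$diagnostics),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(report$members, paste0(path, "_members.csv"),
            row.names = FALSE)
  invisible(path)
}
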