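#' Per-measure statistics of the experimental dataset
#'
#' Computes, per protocol and per measure, the sample mean and standard
#' deviation over all valid entries of the experimental measure table.
#' Standard deviations below a floor (degenerate, e.g. constant measures)
#' are replaced by the floor and flagged.
#'
#' @param measures A data.frame with columns `trace_id`, `protocol`
#'   (`"hyp"`/`"dep"`) and one column per measure (NA = invalid), e.g. from
#'   [cohort_report()].
#' @param sd_floor_rel,sd_floor_abs The floor is
#'   `sd_floor_rel * |mean| + sd_floor_abs`.
#' @return A list of class `olm_dataset_stats`: per-protocol data.frames
#'   with `measure`, `mean`, `sd`, `n`, `floored`; plus `n_traces`.
#' @export
dataset_stats <- function(measures, sd_floor_rel = 1e-6,
                          sd_floor_abs = 1e-12) {
  stopifnot(is.data.frame(measures), "protocol" %in% names(measures))
  meta <- intersect(c("trace_id", "protocol", "cell_id", "source"),
                    names(measures))
  if (nrow(measures) < 2) stop("sd undefined: need >= 2 traces")
  stats <- lapply(split(measures, measures$protocol), function(df) {
    cols <- setdiff(names(df), meta)
    do.call(rbind, lapply(cols, function(cl) {
      x <- df[[cl]]
      x <- x[is.finite(x)]
      if (length(x) < 2)
        return(data.frame(measure = cl, mean = if (length(x)) mean(x)
                          else NA_real_, sd = NA_real_, n = length(x),
                          floored = NA))
      m <- mean(x)
      s <- sd(x)
      floor_v <- sd_floor_rel * abs(m) + sd_floor_abs
      data.frame(measure = cl, mean = m, sd = max(s, floor_v),
                 n = length(x), floored = s < floor_v)
    }))
  })
  structure(list(stats = stats, n_traces = nrow(measures)),
            class = "olm_dataset_stats")
}

# fetch the sd vector for a protocol, named by measure
stats_sd <- function(stats, protocol) {
  df <- stats$stats[[protocol]]
  setNames(df$sd, df$measure)
}

#' Normalized z-score distance between two measure vectors
#'
#' `d_xy = sqrt( sum_i ((x_i - y_i)/sigma_i)^2 / N_valid )` over the
#' measures valid (non-NA) in both vectors, with sigma taken from the
#' experimental dataset statistics: the root-mean-square z-score of the
#' model's measures against one experimental trace, all measures equally
#' weighted.
#'
#' @param x,y Named numeric measure vectors sharing a registry (model and
#'   experimental trace).
#' @param stats An `olm_dataset_stats`.
#' @param protocol `"hyp"` or `"dep"`; taken from `x`'s attribute when
#'   omitted.
#' @return Non-negative distance (attribute `n_valid` holds the number of
#'   measures compared).
#' @export
trace_distance <- function(x, y, stats, protocol = NULL) {
  if (is.null(protocol)) protocol <- attr(x, "protocol")
  common <- intersect(names(x), names(y))
  sig <- stats_sd(stats, protocol)
  common <- intersect(common, names(sig)[is.finite(sig)])
  xi <- as.numeric(x[common]); yi <- as.numeric(y[common])
  ok <- is.finite(xi) & is.finite(yi)
  if (!any(ok)) stop("incomparable traces: zero valid shared measures")
  z <- (xi[ok] - yi[ok]) / sig[common][ok]
  d <- sqrt(mean(z^2))
  attr(d, "n_valid") <- sum(ok)
  d
}

#' Aggregate distance of one model against the whole dataset
#'
#' `d_x = (sum_y d_xy) / N_y` over all experimental traces, using the
#' model's measure vector of the matching protocol for each trace.
#'
#' @param model_vectors Named list with elements `hyp` and/or `dep`: the
#'   model's measure vectors.
#' @param exp_measures Experimental measure data.frame (one row per trace,
#'   with `protocol` column).
#' @param stats An `olm_dataset_stats`.
#' @return `d_x` with attribute `per_trace` (the d_xy breakdown).
#' @export
aggregate_distance <- function(model_vectors, exp_measures, stats) {
  meta <- intersect(c("trace_id", "protocol", "cell_id", "source"),
                    names(exp_measures))
  d_xy <- vapply(seq_len(nrow(exp_measures)), function(i) {
    prot <- exp_measures$protocol[i]
    if (is.null(model_vectors[[prot]]))
      stop("pairing error: model lacks a ", prot, " measure vector")
    y <- unlist(exp_measures[i, setdiff(names(exp_measures), meta)])
    as.numeric(trace_distance(model_vectors[[prot]], y, stats,
                              protocol = prot))
  }, 1)
  d <- sum(d_xy) / nrow(exp_measures)
  attr(d, "per_trace") <- d_xy
  d
}

#' Rank a model database by aggregate distance
#'
#' Sorts ascending by `d_x` (rank 1 = best); ties are broken by model id,
#' so the ranking is stable and permutation-invariant. Models with
#' non-finite distance are excluded and reported.
#'
#' @param records A data.frame with columns `model_id` and `d_x` (other
#'   columns are carried along).
#' @return The data.frame sorted by rank with a `rank` column; excluded
#'   rows are kept in attribute `"excluded"`.
#' @export
rank_models <- function(records) {
  stopifnot(all(c("model_id", "d_x") %in% names(records)))
  bad <- !is.finite(records$d_x)
  excluded <- records[bad, , drop = FALSE]
  if (nrow(excluded))
    message(nrow(excluded), " model(s) excluded from ranking ",
            "(non-finite distance)")
  rec <- records[!bad, , drop = FALSE]
  ord <- order(rec$d_x, rec$model_id)
  rec <- rec[ord, , drop = FALSE]
  rec$rank <- seq_len(nrow(rec))
  rownames(rec) <- NULL
  attr(rec, "excluded") <- excluded
  rec
}
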