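#' Plain-text trace store
#'
#' Persists a list of voltage traces as a directory of CSV files (one per
#' trace: a `t` column plus one column per recording site) with JSON
#' metadata sidecars carrying the protocol, model/cell ids and sampling
#' information. The round trip is lossless up to numeric printing
#' precision.
#'
#' @param traces List of `olm_trace` objects.
#' @param dir Output directory (created if needed).
#' @return `write_traces` returns `dir` invisibly; `read_traces` the list
#'   of traces.
#' @export
write_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    df <- data.frame(t = tr$t, tr$v, check.names = FALSE)
    write.csv(df, file.path(dir, sprintf("trace_%04d.csv", i)),
              row.names = FALSE)
    meta <- list(sites = tr$sites, dt_save = tr$dt_save, dt = tr$dt,
                 proto = tr$proto[!vapply(tr$proto, is.null, TRUE)],
                 model_id = tr$model_id, cell_id = tr$cell_id,
                 sweep = tr$sweep, protocol = tr$protocol, role = tr$role)
    jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                         file.path(dir, sprintf("trace_%04d.json", i)),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "^trace_\\d+\\.csv$",
                          full.names = TRUE))
  lapply(csvs, function(f) {
    df <- read.csv(f, check.names = FALSE)
    meta <- jsonlite::read_json(sub("\\.csv$", ".json", f),
                                simplifyVector = TRUE)
    v <- as.matrix(df[, -1, drop = FALSE])
    proto <- do.call(protocol_spec, meta$proto[
      intersect(names(meta$proto), names(formals(protocol_spec)))])
    tr <- structure(list(t = df$t, v = v, sites = colnames(v),
                         i_clamp = NULL, dt_save = meta$dt_save,
                         dt = meta$dt, proto = proto,
                         model_id = meta$model_id),
                    class = "olm_trace")
    for (f2 in c("cell_id", "sweep", "protocol", "role"))
      if (!is.null(meta[[f2]])) tr[[f2]] <- meta[[f2]]
    tr
  })
}

#' Measure table I/O (one CSV row per trace)
#' @param measures Measure data.frame (see [cohort_report()]).
#' @param path CSV path.
#' @export
write_measures <- function(measures, path) {
  write.csv(measures, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measures
#' @export
read_measures <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}
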