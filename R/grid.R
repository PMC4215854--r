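#' Design of the model-variant grid
#'
#' A grid design specifies, for each maximum conductance density, the list
#' of values (pS/um^2) it may take, together with the candidate
#' distributions of the h-current (soma-only and/or somatodendritic) and the
#' candidate morphologies. The model database is the Cartesian product of
#' all of these options.
#'
#' @param values Named list of numeric value vectors (pS/um^2), one per
#'   conductance; every vector must be non-empty with values >= 0.
#' @param ih_dist Character vector from `c("soma", "somatodendritic")`.
#' @param morphologies Character vector of morphology labels.
#' @return An object of class `olm_grid_design`.
#' @export
grid_design <- function(values, ih_dist = c("soma", "somatodendritic"),
                        morphologies = "morph1") {
  if (!is.list(values) || is.null(names(values)) ||
      any(!nzchar(names(values))))
    stop("values must be a named list of numeric vectors")
  for (nm in names(values)) {
    v <- values[[nm]]
    if (length(v) == 0) stop("invalid design: empty value list for ", nm)
    if (any(v < 0)) stop("invalid design: negative density for ", nm)
  }
  if (length(ih_dist) == 0 || length(morphologies) == 0)
    stop("invalid design: empty option list")
  stopifnot(all(ih_dist %in% c("soma", "somatodendritic")))
  structure(list(values = values, ih_dist = ih_dist,
                 morphologies = morphologies), class = "olm_grid_design")
}

#' Reference conductance-density grids
#'
#' The production value lists used for database construction (pS/um^2). The
#' `"v2"` preset uses the five-value h-conductance list
#' \{0.02, 0.05, 0.1, 0.3, 0.5\}; with a single morphology and a single
#' h-distribution it yields 233,280 parameter combinations. The `"v1"`
#' preset retains the earlier four-value h list \{0.5, 16, 53, 90\}.
#'
#' @param version `"v2"` (default) or `"v1"`.
#' @param ih_dist,morphologies Passed to [grid_design()].
#' @return An `olm_grid_design`.
#' @export
grid_presets <- function(version = c("v2", "v1"),
                         ih_dist = c("soma", "somatodendritic"),
                         morphologies = c("morph1", "morph2")) {
  version <- match.arg(version)
  g_h <- if (version == "v2") c(0.02, 0.05, 0.1, 0.3, 0.5)
         else c(0.5, 16, 53, 90)
  grid_design(values = list(
    Na_s = c(60, 107, 220),
    Na_d = c(70, 117, 230),
    KDRf = c(6, 95, 215, 506),
    KDRs = c(2.3, 42, 92, 222),
    A    = c(2.5, 32, 72, 169),
    h    = g_h,
    CaL  = c(12.5, 25, 30),
    CaT  = c(1.25, 2.5, 5),
    AHP  = c(2.75, 5.5, 11),
    M    = c(0.375, 0.75, 1.5)),
    ih_dist = ih_dist, morphologies = morphologies)
}

#' Number of models implied by a grid design (closed form)
#'
#' @param design An `olm_grid_design`.
#' @return Product of all option-list lengths.
#' @export
grid_size <- function(design) {
  stopifnot(inherits(design, "olm_grid_design"))
  prod(vapply(design$values, length, 1L)) * length(design$ih_dist) *
    length(design$morphologies)
}

#' Enumerate the model grid
#'
#' Builds the full Cartesian product of the design's value lists, the
#' h-distribution options and the morphology options, in a deterministic
#' order: the first conductance varies fastest, then subsequent
#' conductances, then `ih_dist`, then `morphology` (slowest). Each row is
#' one model specification with a stable integer `model_id` equal to its
#' row index.
#'
#' @param design An `olm_grid_design`.
#' @return A data.frame (class `olm_grid`) with one row per model:
#'   `model_id`, one column per conductance, `ih_dist`, `morphology`.
#' @export
build_grid <- function(design) {
  stopifnot(inherits(design, "olm_grid_design"))
  cols <- c(design$values,
            list(ih_dist = design$ih_dist,
                 morphology = design$morphologies))
  g <- expand.grid(cols, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- cbind(model_id = seq_len(nrow(g)), g)
  class(g) <- c("olm_grid", "data.frame")
  g
}

#' Extract one model specification from a grid
#'
#' @param grid An `olm_grid` (from [build_grid()]) or compatible data.frame.
#' @param model_id Stable integer id of the model.
#' @return A list of class `olm_model_spec` with fields `model_id`,
#'   `densities` (named numeric, pS/um^2), `ih_dist` and `morphology`.
#' @export
model_spec <- function(grid, model_id) {
  row <- grid[grid$model_id == model_id, , drop = FALSE]
  if (nrow(row) != 1) stop("model_id not found in grid: ", model_id)
  dens_cols <- setdiff(names(row), c("model_id", "ih_dist", "morphology"))
  spec <- list(model_id = model_id,
               densities = unlist(row[dens_cols]),
               ih_dist = row$ih_dist, morphology = row$morphology)
  class(spec) <- "olm_model_spec"
  spec
}

#' @export
print.olm_model_spec <- function(x, ...) {
  cat("Model", x$model_id, "(", x$morphology, ", I_h:", x$ih_dist, ")\n")
  print(x$densities)
  invisible(x)
}

#' Grid serialization
#'
#' `write_grid`/`read_grid` store an enumerated grid as a CSV table (one row
#' per model id, one column per parameter). `design_to_json` /
#' `design_from_json` round-trip the design itself.
#'
#' @param grid An `olm_grid`.
#' @param path File path.
#' @export
write_grid <- function(grid, path) {
  write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  g <- read.csv(path, stringsAsFactors = FALSE)
  class(g) <- c("olm_grid", "data.frame")
  g
}

#' @param design An `olm_grid_design`.
#' @rdname write_grid
#' @export
design_to_json <- function(design, path) {
  jsonlite::write_json(unclass(design), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grid
#' @export
design_from_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid_design(values = as.list(d$values), ih_dist = d$ih_dist,
              morphologies = d$morphologies)
}
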