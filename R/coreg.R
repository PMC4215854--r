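#' Dimensional-stack image of a model database
#'
#' Renders the model grid as a nested two-dimensional image for a given
#' parameter ordering: parameters at odd positions of the ordering are
#' stacked on the x axis, parameters at even positions on the y axis, the
#' earliest (highest-order) parameters varying slowest. Pixel values are
#' the models' aggregate distances; models outside the subset (or missing)
#' are rendered at a fixed background value.
#'
#' @param db A data.frame with one row per model: parameter columns plus
#'   `d_x` (and optionally `retained`).
#' @param order Character vector: parameter ordering (highest order first).
#' @param value Column used as pixel value.
#' @param background Background value; defaults to `max(value) + spread/2`.
#' @return A numeric matrix (class `olm_stack_image`).
#' @export
stack_image <- function(db, order, value = "d_x", background = NULL) {
  stopifnot(all(order %in% names(db)))
  vals <- db[[value]]
  if (!is.null(db$retained)) vals[!db$retained] <- NA
  if (is.null(background)) {
    fin <- vals[is.finite(vals)]
    background <- if (length(fin)) max(fin) + diff(range(fin)) / 2 + 1 else 1
  }
  levs <- lapply(order, function(p) sort(unique(db[[p]])))
  names(levs) <- order
  idx <- lapply(order, function(p) match(db[[p]], levs[[p]]) - 1L)
  xp <- seq_along(order) %% 2L == 1L   # odd positions -> x axis
  xdim <- prod(vapply(levs[xp], length, 1L))
  ydim <- prod(vapply(levs[!xp], length, 1L))
  compose <- function(which_axis) {
    pos <- which(xp == which_axis)
    out <- integer(nrow(db))
    for (p in pos) {                   # highest order first = slowest
      out <- out * length(levs[[p]]) + idx[[p]]
    }
    out
  }
  xi <- compose(TRUE)
  yi <- compose(FALSE)
  img <- matrix(background, nrow = ydim, ncol = xdim)
  img[cbind(yi + 1L, xi + 1L)] <- ifelse(is.finite(vals), vals, background)
  structure(img, class = c("olm_stack_image", "matrix"),
            order = order, background = background)
}

#' Clutter of a stack image
#'
#' Sum over adjacent pixel pairs (horizontal and vertical) of absolute
#' value differences; lower clutter means models with similar distances
#' cluster together more tightly.
#'
#' @param img An `olm_stack_image` (or numeric matrix).
#' @return Scalar clutter score.
#' @export
clutter_score <- function(img) {
  m <- unclass(img)
  s <- 0
  if (ncol(m) > 1) s <- s + sum(abs(m[, -1] - m[, -ncol(m)]))
  if (nrow(m) > 1) s <- s + sum(abs(m[-1, ] - m[-nrow(m), ]))
  s
}

#' Clutter-based dimension reordering (CBDR)
#'
#' Finds the parameter ordering whose dimensional-stack image minimizes
#' clutter: exhaustive search over permutations for up to `exhaustive_max`
#' parameters, greedy insertion beyond. Deterministic: candidate orderings
#' are visited in lexicographic name order and only strict improvements
#' are accepted, so ties resolve to the name-sorted ordering.
#'
#' @param db Data.frame with parameter columns and `d_x` (see
#'   [stack_image()]).
#' @param params Parameter names to order; defaults to every column except
#'   `model_id`, `d_x`, `rank`, `retained`.
#' @param value Pixel value column.
#' @param exhaustive_max Largest parameter count searched exhaustively.
#' @return A list of class `olm_stack_order`: `order` (highest first),
#'   `clutter`, `scores` (per-candidate when exhaustive).
#' @export
cbdr_order <- function(db, params = NULL, value = "d_x",
                       exhaustive_max = 6) {
  if (is.null(params))
    params <- setdiff(names(db), c("model_id", "d_x", "rank", "retained"))
  if (!all(params %in% names(db)) || anyNA(db[params]))
    stop("models missing grid coordinates for some parameters")
  params <- sort(params)
  score <- function(ord) clutter_score(stack_image(db, ord, value))
  if (length(params) <= exhaustive_max) {
    perms <- permutations_of(params)
    scores <- vapply(perms, score, 1)
    best <- which.min(scores)      # which.min takes the first = lexic. order
    structure(list(order = perms[[best]], clutter = scores[best],
                   n_candidates = length(perms)),
              class = "olm_stack_order")
  } else {
    ord <- character(0)
    remaining <- params
    while (length(remaining)) {
      cand_scores <- vapply(remaining, function(p)
        score(c(ord, p, setdiff(remaining, p))), 1)
      pick <- remaining[which.min(cand_scores)]
      ord <- c(ord, pick)
      remaining <- setdiff(remaining, pick)
    }
    structure(list(order = ord, clutter = score(ord),
                   n_candidates = NA_integer_),
              class = "olm_stack_order")
  }
}

# all permutations of a character vector, in lexicographic order
permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(permutations_of(x[-i]), function(p) c(x[i], p)))
  out
}

#' @export
print.olm_stack_order <- function(x, ...) {
  cat("CBDR ordering (highest order first):",
      paste(x$order, collapse = " > "), "\n  clutter:", x$clutter, "\n")
  invisible(x)
}

#' Pairwise conductance histogram of a subset
#'
#' Counts the subset's models for every combination of the two parameters'
#' grid values, normalized as a percentage of the subset size.
#'
#' @param db Model data.frame with parameter columns.
#' @param retained Logical vector: subset membership (defaults to column
#'   `retained`, else all models).
#' @param param_a,param_b Parameter names.
#' @return A list of class `olm_cond_hist`: `counts` (matrix levels_a x
#'   levels_b), `percent`, `levels_a`, `levels_b`, `n_subset`.
#' @export
conductance_histogram <- function(db, param_a, param_b, retained = NULL) {
  for (p in c(param_a, param_b))
    if (!p %in% names(db)) stop("parameter not in grid: ", p)
  if (is.null(retained))
    retained <- if (!is.null(db$retained)) db$retained
                else rep(TRUE, nrow(db))
  la <- sort(unique(db[[param_a]]))
  lb <- sort(unique(db[[param_b]]))
  sub <- db[retained, , drop = FALSE]
  counts <- table(factor(sub[[param_a]], levels = la),
                  factor(sub[[param_b]], levels = lb))
  counts <- matrix(as.numeric(counts), length(la), length(lb),
                   dimnames = list(format(la), format(lb)))
  n <- nrow(sub)
  structure(list(counts = counts,
                 percent = if (n > 0) 100 * counts / n else counts,
                 levels_a = la, levels_b = lb, n_subset = n,
                 param_a = param_a, param_b = param_b),
            class = "olm_cond_hist")
}

#' Classify the interaction of a conductance pair
#'
#' Quantifies the visual categories used for conductance histogram plots:
#' no clear interaction, a local peak/preference of density values, or a
#' co-regulation ("ridge"). The ridge score is the count-weighted Spearman
#' correlation between the two parameters' grid ranks over subset members;
#' co-regulation requires both a large `|score|` and monotone conditional
#' modes across columns.
#'
#' @param h An `olm_cond_hist`.
#' @param ridge_threshold Minimum `|score|` for co-regulation.
#' @param peak_threshold Multiple of the uniform cell share that counts as
#'   a dominant local peak.
#' @return A list of class `olm_interaction`: `label` (one of
#'   `"co-regulation"`, `"local-preference"`, `"no-interaction"`),
#'   `score`, `peak_share`.
#' @export
classify_interaction <- function(h, ridge_threshold = 0.4,
                                 peak_threshold = 2) {
  cnt <- h$counts
  na <- nrow(cnt); nb <- ncol(cnt)
  if (na < 2 || nb < 2)
    stop("incomparable: histogram needs >= 2 levels per axis")
  tot <- sum(cnt)
  if (tot == 0)
    return(structure(list(label = "no-interaction", score = 0,
                          peak_share = 0), class = "olm_interaction"))
  ia <- row(cnt); ib <- col(cnt)
  w <- cnt / tot
  mu_a <- sum(w * ia); mu_b <- sum(w * ib)
  va <- sum(w * (ia - mu_a)^2); vb <- sum(w * (ib - mu_b)^2)
  score <- if (va > 0 && vb > 0)
    sum(w * (ia - mu_a) * (ib - mu_b)) / sqrt(va * vb) else 0
  # conditional modal B level per A level (columns of the stack)
  modes <- apply(cnt, 1, function(r) if (sum(r) > 0) which.max(r)
                 else NA_integer_)
  modes <- modes[!is.na(modes)]
  monotone <- length(modes) >= 2 &&
    (all(diff(modes) >= 0) || all(diff(modes) <= 0)) &&
    any(diff(modes) != 0)
  peak_share <- max(cnt) / tot
  uniform_share <- 1 / (na * nb)
  label <- if (abs(score) >= ridge_threshold && monotone) "co-regulation"
  else if (peak_share >= peak_threshold * uniform_share) "local-preference"
  else "no-interaction"
  structure(list(label = label, score = score, peak_share = peak_share,
                 monotone_modes = monotone),
            class = "olm_interaction")
}

#' @export
print.olm_interaction <- function(x, ...) {
  cat(x$label, " (ridge score ", round(x$score, 3), ")\n", sep = "")
  invisible(x)
}

#' Screen all high-order conductance pairs for co-regulations
#'
#' Classifies every pairwise combination among the `n_high` highest-order
#' parameters of the CBDR stack plus one boundary control parameter (the
#' next parameter in the ordering), and returns the classifications sorted
#' by decreasing `|ridge score|`.
#'
#' @param db Model data.frame with parameter columns and `retained`.
#' @param stack_order An `olm_stack_order` (or character vector of
#'   parameter names, highest order first).
#' @param n_high Number of high-order parameters screened.
#' @param retained Subset membership (defaults to `db$retained`).
#' @param ... Passed to [classify_interaction()].
#' @return A data.frame: `param_a`, `param_b`, `label`, `score`, sorted by
#'   `|score|` descending.
#' @export
coreg_screen <- function(db, stack_order, n_high = 5, retained = NULL,
                         ...) {
  ord <- if (inherits(stack_order, "olm_stack_order")) stack_order$order
         else stack_order
  k <- min(n_high + 1, length(ord))    # top-n plus one boundary control
  params <- ord[seq_len(k)]
  pairs <- utils::combn(params, 2)
  res <- lapply(seq_len(ncol(pairs)), function(j) {
    h <- conductance_histogram(db, pairs[1, j], pairs[2, j],
                               retained = retained)
    cls <- classify_interaction(h, ...)
    data.frame(param_a = pairs[1, j], param_b = pairs[2, j],
               label = cls$label, score = cls$score)
  })
  res <- do.call(rbind, res)
  res[order(-abs(res$score)), , drop = FALSE]
}

#' Plot helpers for stacked images and conductance histograms
#'
#' Base-graphics renderings of the CBDR stack image and of a pairwise
#' conductance histogram.
#'
#' @param x The object to plot.
#' @param ... Further arguments passed to [graphics::image()].
#' @export
plot.olm_stack_image <- function(x, ...) {
  graphics::image(t(unclass(x)), useRaster = TRUE, axes = FALSE,
                  col = grDevices::hcl.colors(64, "Spectral"), ...)
  invisible(x)
}

#' @rdname plot.olm_stack_image
#' @export
plot.olm_cond_hist <- function(x, ...) {
  graphics::image(x$levels_a, x$levels_b, x$percent, xlab = x$param_a,
                  ylab = x$param_b,
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  ...)
  invisible(x)
}
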