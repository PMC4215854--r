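#' Construct a cell morphology from cylindrical sections
#'
#' A morphology is a tree of cylindrical sections rooted at the soma. Each
#' section has a role (`soma`, `dendrite` or `axon`), a length and diameter
#' in micrometres, and attaches to a parent section at a relative position
#' `parent_pos` in \[0, 1\] along the parent.
#'
#' @param sections A data.frame with columns `id` (integer, 1..n, parents
#'   precede children), `role`, `length`, `diam`, `parent` (id of parent
#'   section, `NA` for the root), `parent_pos` (0..1, default 1).
#' @param label Identifier for the morphology.
#' @return An object of class `olm_morphology`.
#' @export
morphology <- function(sections, label = "morph") {
  req <- c("id", "role", "length", "diam", "parent")
  if (!all(req %in% names(sections)))
    stop("sections must have columns: ", paste(req, collapse = ", "))
  if (is.null(sections$parent_pos)) sections$parent_pos <- 1
  sections <- as.data.frame(sections, stringsAsFactors = FALSE)
  n <- nrow(sections)
  if (n < 1) stop("morphology needs at least one section")
  if (!identical(as.integer(sections$id), seq_len(n)))
    stop("section ids must be 1..n in order")
  if (any(sections$length <= 0) || any(sections$diam <= 0))
    stop("section lengths and diameters must be > 0")
  if (!all(sections$role %in% c("soma", "dendrite", "axon")))
    stop("roles must be one of soma, dendrite, axon")
  root <- which(is.na(sections$parent))
  if (length(root) != 1 || sections$role[root] != "soma")
    stop("the section tree must have exactly one root, and it must be the soma")
  nonroot <- which(!is.na(sections$parent))
  if (any(sections$parent[nonroot] >= sections$id[nonroot]))
    stop("parents must precede children (parent id < section id)")
  if (any(sections$parent_pos < 0 | sections$parent_pos > 1))
    stop("parent_pos must lie in [0, 1]")
  structure(list(sections = sections, label = label),
            class = "olm_morphology")
}

#' @export
print.olm_morphology <- function(x, ...) {
  s <- x$sections
  cat("Morphology '", x$label, "': ", nrow(s), " sections (",
      sum(s$role == "soma"), " soma, ", sum(s$role == "dendrite"),
      " dendrite, ", sum(s$role == "axon"), " axon), total membrane area ",
      round(sum(pi * s$diam * s$length)), " um^2\n", sep = "")
  invisible(x)
}

#' Shape family for surrogate morphologies
#'
#' The surrogate family is a soma cylinder plus two symmetric dendritic
#' trunks (each optionally bifurcating once into two daughters) and an
#' optional short axon. The free parameter solved during calibration is the
#' total dendritic path length (trunk + daughter).
#'
#' @param soma_length,soma_diam Soma cylinder dimensions (um).
#' @param n_trunks Number of primary dendritic trunks.
#' @param trunk_diam Trunk diameter (um).
#' @param bifurcate Whether each trunk bifurcates once.
#' @param branch_frac Fraction of the dendritic path length taken by the
#'   trunk before the bifurcation.
#' @param daughter_diam Diameter of daughter branches (um).
#' @param axon_length Axon length (um); 0 suppresses the axon.
#' @param axon_diam Axon diameter (um).
#' @return A list of class `olm_shape`.
#' @export
surrogate_shape <- function(soma_length = 20, soma_diam = 10, n_trunks = 2,
                            trunk_diam = 2.5, bifurcate = TRUE,
                            branch_frac = 0.4, daughter_diam = 1.5,
                            axon_length = 150, axon_diam = 0.7) {
  structure(list(soma_length = soma_length, soma_diam = soma_diam,
                 n_trunks = n_trunks, trunk_diam = trunk_diam,
                 bifurcate = bifurcate, branch_frac = branch_frac,
                 daughter_diam = daughter_diam, axon_length = axon_length,
                 axon_diam = axon_diam), class = "olm_shape")
}

# Realize the shape family at a given dendritic path length (um).
shape_to_morphology <- function(shape, dend_length, label = "surrogate") {
  secs <- list(data.frame(id = 1L, role = "soma", length = shape$soma_length,
                          diam = shape$soma_diam, parent = NA_integer_,
                          parent_pos = 0.5))
  nid <- 1L
  for (tr in seq_len(shape$n_trunks)) {
    if (shape$bifurcate) {
      ltr <- dend_length * shape$branch_frac
      lda <- dend_length * (1 - shape$branch_frac)
      nid <- nid + 1L
      trunk_id <- nid
      secs <- c(secs, list(data.frame(id = trunk_id, role = "dendrite",
                                      length = ltr, diam = shape$trunk_diam,
                                      parent = 1L, parent_pos = 0.5)))
      for (d in 1:2) {
        nid <- nid + 1L
        secs <- c(secs, list(data.frame(id = nid, role = "dendrite",
                                        length = lda,
                                        diam = shape$daughter_diam,
                                        parent = trunk_id, parent_pos = 1)))
      }
    } else {
      nid <- nid + 1L
      secs <- c(secs, list(data.frame(id = nid, role = "dendrite",
                                      length = dend_length,
                                      diam = shape$trunk_diam,
                                      parent = 1L, parent_pos = 0.5)))
    }
  }
  if (shape$axon_length > 0) {
    nid <- nid + 1L
    secs <- c(secs, list(data.frame(id = nid, role = "axon",
                                    length = shape$axon_length,
                                    diam = shape$axon_diam,
                                    parent = 1L, parent_pos = 0.5)))
  }
  morphology(do.call(rbind, secs), label = label)
}

#' Passive somatic input resistance of a morphology
#'
#' Solves the steady-state passive cable system (no active conductances) for
#' a unit current injected at the soma and returns the somatic input
#' resistance.
#'
#' @param morph An `olm_morphology`.
#' @param passive An `olm_passive`.
#' @param disc A [discretization()] spec.
#' @return Input resistance in megaohm.
#' @export
passive_input_resistance <- function(morph, passive,
                                     disc = discretization()) {
  cab <- discretize(morph, passive, disc)
  n <- nrow(cab$comp)
  g_m <- cab$comp$g_pas + cab$comp$g_kl          # nS
  G <- diag(g_m, n, n)
  for (i in which(!is.na(cab$comp$parent_comp))) {
    p <- cab$comp$parent_comp[i]
    g <- cab$comp$g_ax[i]
    G[i, i] <- G[i, i] + g
    G[p, p] <- G[p, p] + g
    G[i, p] <- G[i, p] - g
    G[p, i] <- G[p, i] - g
  }
  inj <- numeric(n)
  inj[1] <- 1                                     # 1 pA at the soma
  v <- solve(G, inj)                              # mV per pA = GOhm
  unname(v[1] * 1000)                             # MOhm
}

#' Build a surrogate morphology calibrated to a target input resistance
#'
#' Solves for the dendritic path length of the [surrogate_shape()] family so
#' that the passive somatic input resistance matches `target_rin` under the
#' given passive properties.
#'
#' @param target_rin Target somatic input resistance (megaohm).
#' @param passive An `olm_passive` object.
#' @param shape A [surrogate_shape()].
#' @param tol Relative tolerance on the achieved input resistance.
#' @param disc Discretization used during calibration.
#' @param label Label for the returned morphology.
#' @return An `olm_morphology` whose passive input resistance is within
#'   `tol` of `target_rin`; the achieved value is stored in attribute
#'   `"rin"`.
#' @export
surrogate_morphology <- function(target_rin, passive,
                                 shape = surrogate_shape(), tol = 0.05,
                                 disc = discretization(), label = "surrogate") {
  stopifnot(target_rin > 0)
  f <- function(log_l) {
    m <- shape_to_morphology(shape, exp(log_l), label)
    passive_input_resistance(m, passive, disc) - target_rin
  }
  lo <- log(10); hi <- log(20000)
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    ach <- if (abs(flo) < abs(fhi)) flo else fhi
    stop(sprintf(paste0("calibration failure: target Rin %.1f MOhm not ",
                        "reachable in this shape family (nearest achieved ",
                        "%.1f MOhm)"), target_rin, target_rin + ach))
  }
  r <- uniroot(f, c(lo, hi), tol = 1e-4)
  m <- shape_to_morphology(shape, exp(r$root), label)
  rin <- passive_input_resistance(m, passive, disc)
  if (abs(rin - target_rin) / target_rin > tol)
    stop(sprintf("calibration failure: achieved %.1f MOhm vs target %.1f",
                 rin, target_rin))
  attr(m, "rin") <- rin
  attr(m, "dend_length") <- exp(r$root)
  m
}

#' Write / read a morphology in a minimal SWC dialect
#'
#' Each section is written as one SWC node (id, type, x, y, z, radius,
#' parent) at the section's distal end, with type 1 = soma, 2 = axon,
#' 3 = dendrite. Section lengths, `parent_pos` and the label are stored in a
#' JSON sidecar (`<path>.json`) so the round trip is lossless.
#'
#' @param morph An `olm_morphology`.
#' @param path Output SWC file path.
#' @return `write_swc` returns `path` invisibly; `read_swc` returns the
#'   morphology.
#' @export
write_swc <- function(morph, path) {
  s <- morph$sections
  type <- c(soma = 1L, axon = 2L, dendrite = 3L)[s$role]
  # synthetic coordinates: lay each section along +x from its parent's end
  x <- numeric(nrow(s))
  for (i in seq_len(nrow(s)))
    x[i] <- if (is.na(s$parent[i])) s$length[i] else
      x[s$parent[i]] * s$parent_pos[i] + s$length[i]
  swc <- data.frame(id = s$id, type = type, x = x, y = 0, z = 0,
                    radius = s$diam / 2,
                    parent = ifelse(is.na(s$parent), -1L, s$parent))
  writeLines(c("# minimal SWC dialect: one node per section (distal end)",
               apply(swc, 1, function(r) paste(format(r, trim = TRUE),
                                               collapse = " "))), path)
  jsonlite::write_json(list(label = morph$label, length = s$length,
                            parent_pos = s$parent_pos),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_swc
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  role <- c("soma", "axon", "dendrite")[m[, 2]]
  sections <- data.frame(id = as.integer(m[, 1]), role = role,
                         length = side$length, diam = 2 * m[, 6],
                         parent = ifelse(m[, 7] < 0, NA_integer_,
                                         as.integer(m[, 7])),
                         parent_pos = side$parent_pos)
  morphology(sections, label = side$label)
}
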