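#' Spatial discretization specification
#'
#' Compartment sizes are set by the fraction of the frequency-dependent
#' length constant at a reference frequency (default 100 Hz): each section
#' is split into the smallest odd number of segments whose length does not
#' exceed `lambda_fraction * lambda_f`.
#'
#' @param lambda_fraction Fraction of lambda_100 per compartment (0, 1].
#' @param f Reference frequency (Hz).
#' @param dt Integration time step (ms).
#' @param dt_save Output sampling interval (ms), `>= dt`.
#' @return An object of class `olm_discretization`.
#' @export
discretization <- function(lambda_fraction = 0.1, f = 100, dt = 0.025,
                           dt_save = 0.1) {
  if (lambda_fraction <= 0 || lambda_fraction > 1)
    stop("lambda_fraction must lie in (0, 1]")
  if (dt <= 0) stop("dt must be > 0")
  if (dt_save < dt) stop("dt_save must be >= dt")
  structure(list(lambda_fraction = lambda_fraction, f = f, dt = dt,
                 dt_save = dt_save), class = "olm_discretization")
}

#' AC length constant at frequency f
#'
#' `lambda_f = (1/2) * sqrt(diam / (pi * f * Ra * Cm))` in consistent units;
#' inputs here are um, Hz, ohm cm and uF/cm^2, and the result is in um.
#'
#' @param diam Diameter (um).
#' @param f Frequency (Hz).
#' @param ra Axial resistivity (ohm cm).
#' @param cm Specific capacitance (uF/cm^2).
#' @return Length constant (um).
#' @export
lambda_f <- function(diam, f, ra, cm) {
  if (any(diam <= 0)) stop("degenerate geometry: zero diameter")
  d_cm <- diam * 1e-4
  cm_f <- cm * 1e-6
  0.5 * sqrt(d_cm / (pi * f * ra * cm_f)) * 1e4
}

#' Discretize a morphology into a passive compartmental cable
#'
#' Splits every section into an odd number of equal segments according to
#' the lambda rule, computes per-compartment membrane areas and passive
#' conductances, and symmetric axial couplings (half-segment resistances in
#' series). Total membrane area is preserved exactly.
#'
#' @param morph An `olm_morphology`.
#' @param passive An `olm_passive`.
#' @param disc An `olm_discretization`.
#' @return A list of class `olm_cable_skeleton` with element `comp`, a
#'   data.frame with one row per compartment: `section`, `role`, `area`
#'   (um^2), `cm` (pF), `g_pas`, `g_kl`, `g_ax` (nS, to parent),
#'   `parent_comp`, `path_dist` (um from soma center along the tree).
#' @export
discretize <- function(morph, passive, disc = discretization()) {
  stopifnot(inherits(morph, "olm_morphology"),
            inherits(passive, "olm_passive"),
            inherits(disc, "olm_discretization"))
  s <- morph$sections
  if (any(s$diam <= 0)) stop("degenerate geometry: zero diameter")
  lam <- lambda_f(s$diam, disc$f, passive$ra, passive$cm)
  nseg <- vapply(seq_len(nrow(s)), function(i) {
    n <- ceiling(s$length[i] / (disc$lambda_fraction * lam[i]))
    n <- max(1L, as.integer(n))
    if (n %% 2L == 0L) n + 1L else n
  }, 1L)

  comp <- list()
  first_comp <- integer(nrow(s))   # index of first compartment per section
  idx <- 0L
  for (i in seq_len(nrow(s))) {
    n <- nseg[i]
    lseg <- s$length[i] / n
    area <- pi * s$diam[i] * lseg                       # um^2
    # axial resistance of one full segment, MOhm -> conductance nS
    r_seg <- passive$ra * (lseg * 1e-4) /
      (pi * (s$diam[i] * 1e-4 / 2)^2)                    # ohm
    first_comp[i] <- idx + 1L
    for (k in seq_len(n)) {
      idx <- idx + 1L
      if (k == 1L) {
        if (is.na(s$parent[i])) {
          parent_comp <- NA_integer_; g_ax <- NA_real_; pdist <- 0
        } else {
          # attach to the parent's segment containing parent_pos
          p <- s$parent[i]
          pseg <- min(nseg[p], max(1L, ceiling(s$parent_pos[i] * nseg[p])))
          parent_comp <- first_comp[p] + pseg - 1L
          # half of parent's segment + half of this segment in series
          r_par <- passive$ra * ((s$length[p] / nseg[p]) * 1e-4) /
            (pi * (s$diam[p] * 1e-4 / 2)^2)
          g_ax <- 1e9 / (0.5 * r_par + 0.5 * r_seg)      # nS
          pdist <- comp[[parent_comp]]$path_dist + 0.5 *
            (s$length[p] / nseg[p]) + 0.5 * lseg
        }
      } else {
        parent_comp <- idx - 1L
        g_ax <- 1e9 / r_seg
        pdist <- comp[[idx - 1L]]$path_dist + lseg
      }
      comp[[idx]] <- list(section = i, role = s$role[i], area = area,
                          cm = passive$cm * area * 1e-2,       # pF
                          g_pas = 10 * area / passive$rm,      # nS
                          g_kl = passive$gkl * 10 * area,      # nS
                          g_ax = g_ax, parent_comp = parent_comp,
                          path_dist = pdist)
    }
  }
  comp <- do.call(rbind.data.frame, comp)
  rownames(comp) <- NULL
  structure(list(comp = comp, nseg = nseg, morph_label = morph$label,
                 passive = passive, disc = disc),
            class = "olm_cable_skeleton")
}
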