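# Shared fixtures, all built in code.

# fitted passive set of reference morphology 1
pas1 <- olm_passive_defaults(1)

# coarse but fast discretization used across simulation tests
disc_fast <- discretization(lambda_fraction = 0.5, dt = 0.05)

# a single-cylinder soma whose area makes the passive input resistance
# close to the reference 474 MOhm (area = Rm / Rin)
soma_only <- morphology(data.frame(id = 1L, role = "soma", length = 65,
                                   diam = 60, parent = NA_integer_,
                                   parent_pos = 0.5), "soma_only")

# mid-grid reference densities (version-2 h list)
ref_densities <- c(Na_s = 107, Na_d = 117, KDRf = 95, KDRs = 42, A = 32,
                   h = 0.1, CaL = 25, CaT = 2.5, AHP = 5.5, M = 0.75)

# densities with every active conductance silenced (passive membrane)
passive_densities <- ref_densities * 0

# cache the calibrated surrogate morphology (built once per test run)
surrogate_cached <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- surrogate_morphology(474, pas1, disc = disc_fast)
    m
  }
})

# build a synthetic trace object from a voltage vector (for feature tests)
fake_trace <- function(t, v, pre = 1000, step_dur = 1000, post = 1000,
                       amp = -90, bias = 0) {
  structure(list(t = t, v = matrix(v, ncol = 1,
                                   dimnames = list(NULL, "soma")),
                 sites = "soma", i_clamp = NULL, dt_save = t[2] - t[1],
                 dt = t[2] - t[1],
                 proto = protocol_spec(pre = pre, step_dur = step_dur,
                                       post = post, amp = amp,
                                       bias = bias),
                 model_id = NA_integer_),
            class = "olm_trace")
}
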