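test_that("grid size equals the product of option-list lengths", {
  set.seed(11)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    vals <- setNames(lapply(seq_len(k), function(i)
      sort(runif(sample(1:4, 1)))), paste0("g", seq_len(k)))
    des <- grid_design(vals,
                       ih_dist = sample(c("soma", "somatodendritic"),
                                        sample(1:2, 1)),
                       morphologies = paste0("m", seq_len(sample(1:2, 1))))
    g <- build_grid(des)
    # explicit enumeration oracle
    expect_identical(nrow(g), as.integer(grid_size(des)))
    expect_identical(nrow(unique(g[-1])), nrow(g))
  }
})

test_that("reference grid reproduces the published combination counts", {
  des1 <- grid_presets("v2", ih_dist = "soma", morphologies = "morph1")
  expect_identical(grid_size(des1), 233280)
  des <- grid_presets("v2")
  expect_identical(grid_size(des), 933120)
  # singleton design
  one <- grid_design(list(a = 1, b = 2), ih_dist = "soma",
                     morphologies = "m")
  expect_identical(nrow(build_grid(one)), 1L)
})

test_that("grid enumeration is deterministic and round-trips", {
  des <- grid_design(list(a = c(1, 2), b = c(3, 4, 5)),
                     ih_dist = "soma", morphologies = "m1")
  g1 <- build_grid(des)
  g2 <- build_grid(des)
  expect_identical(g1, g2)
  # CSV round trip
  tf <- tempfile(fileext = ".csv")
  write_grid(g1, tf)
  g3 <- read_grid(tf)
  expect_equal(as.data.frame(g1), as.data.frame(g3))
  # design JSON round trip
  tj <- tempfile(fileext = ".json")
  design_to_json(des, tj)
  expect_equal(unclass(design_from_json(tj)), unclass(des))
  # model spec extraction keeps every conductance assigned
  sp <- model_spec(g1, 4)
  expect_named(sp$densities, c("a", "b"))
  expect_s3_class(sp, "olm_model_spec")
})

test_that("invalid designs are rejected", {
  expect_error(grid_design(list(a = numeric(0))), "empty value list")
  expect_error(grid_design(list(a = -1)), "negative")
  expect_error(grid_design(list(a = 1), ih_dist = character(0)),
               "empty option list")
})

test_that("passive properties validate and give the reference time constant", {
  expect_equal(round(membrane_time_constant(olm_passive_defaults(1))), 57)
  expect_error(passive_properties(-1, 1, 1, -70), "positive")
  expect_error(passive_properties(300, 1, 1, 10), "\\[-120, 0\\]")
})

test_that("morphology invariants are enforced", {
  expect_error(morphology(data.frame(id = 1L, role = "dendrite", length = 10,
                                     diam = 1, parent = NA_integer_)),
               "soma")
  expect_error(morphology(data.frame(id = 1:2,
                                     role = c("soma", "dendrite"),
                                     length = c(10, 0), diam = c(1, 1),
                                     parent = c(NA, 1L))),
               "> 0")
  m <- shape_to_morphology(surrogate_shape(), 500)
  expect_s3_class(m, "olm_morphology")
  expect_true(all(m$sections$parent[-1] < m$sections$id[-1]))
})

test_that("single-compartment input resistance matches the analytic form", {
  # isopotential limit: G_in = area * (1/Rm + gKL) in matching units
  area <- pi * 60 * 65                                 # um^2
  g_leak <- 10 * area / pas1$rm + pas1$gkl * 10 * area # nS
  rin_analytic <- 1000 / g_leak                        # MOhm
  rin <- passive_input_resistance(soma_only, pas1, disc_fast)
  expect_equal(rin, rin_analytic, tolerance = 1e-6)
})

test_that("surrogate morphology calibrates to the target input resistance", {
  m <- surrogate_cached()
  expect_lt(abs(attr(m, "rin") - 474) / 474, 0.05)
  # idempotent: re-targeting the achieved Rin reproduces it
  m2 <- surrogate_morphology(attr(m, "rin"), pas1, disc = disc_fast)
  expect_lt(abs(attr(m2, "rin") - attr(m, "rin")) / attr(m, "rin"), 0.05)
  # infeasible target reports the achieved value
  expect_error(surrogate_morphology(5, pas1, disc = disc_fast),
               "calibration failure")
})

test_that("morphologies round-trip through the SWC dialect", {
  m <- shape_to_morphology(surrogate_shape(), 420, label = "rt")
  tf <- tempfile(fileext = ".swc")
  write_swc(m, tf)
  m2 <- read_swc(tf)
  expect_equal(m2$sections$length, m$sections$length)
  expect_equal(m2$sections$diam, m$sections$diam, tolerance = 1e-6)
  expect_identical(m2$sections$role, m$sections$role)
  expect_identical(m2$label, "rt")
})

test_that("channel specs validate gating parameters", {
  expect_error(channel_spec("x", 0, "soma",
                            list(voltage_gate(-1, -40, 6, 1))),
               "exponents")
  expect_error(channel_spec("x", 0, "soma",
                            list(voltage_gate(1, -40, 6, 0))),
               "strictly positive")
  ch <- default_channel_set()
  expect_named(ch, c("Na_s", "Na_d", "KDRf", "KDRs", "A", "h", "CaL",
                     "CaT", "AHP", "M"))
  expect_equal(ch$Na_s$erev, 50)
  expect_equal(ch$KDRf$erev, -95)
  expect_equal(ch$h$erev, -32.9)
})
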