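# small helper: measure table from a matrix (rows = traces)
meas_df <- function(m, protocol = "hyp") {
  data.frame(trace_id = seq_len(nrow(m)), protocol = protocol,
             setNames(as.data.frame(m), colnames(m)))
}

test_that("dataset statistics are per-measure sample moments", {
  m <- rbind(c(a = 1, b = 10), c(a = 3, b = 10))
  st <- dataset_stats(meas_df(m))
  df <- st$stats$hyp
  expect_equal(df$mean[df$measure == "a"], 2)
  expect_equal(df$sd[df$measure == "a"], sqrt(2))
  # constant measure: sd replaced by the floor and flagged
  expect_true(df$floored[df$measure == "b"])
  expect_equal(df$sd[df$measure == "b"], 1e-6 * 10 + 1e-12)
  expect_error(dataset_stats(meas_df(m[1, , drop = FALSE])), ">= 2")
})

test_that("the z-score distance matches identity, unit and oracle cases", {
  m <- rbind(c(a = 1, b = 5, c = -2), c(a = 3, b = 6, c = 0),
             c(a = 2, b = 4, c = -1))
  st <- dataset_stats(meas_df(m))
  x <- c(a = 2, b = 5, c = -1)
  expect_equal(as.numeric(trace_distance(x, x, st, "hyp")), 0)
  # single valid measure differing by exactly sigma -> 1
  sig_a <- st$stats$hyp$sd[st$stats$hyp$measure == "a"]
  x1 <- c(a = 2, b = NA, c = NA)
  y1 <- c(a = 2 + sig_a, b = NA, c = NA)
  expect_equal(as.numeric(trace_distance(x1, y1, st, "hyp")), 1)
  # brute-force formula evaluation to 12 decimals
  y <- c(a = 1.4, b = 6.2, c = -1.7)
  sig <- st$stats$hyp$sd[match(c("a", "b", "c"), st$stats$hyp$measure)]
  d_hand <- sqrt(mean(((x - y) / sig)^2))
  expect_equal(as.numeric(trace_distance(x, y, st, "hyp")), d_hand,
               tolerance = 1e-12)
  # incomparable when no shared valid measures
  expect_error(trace_distance(c(a = NA, b = 1, c = NA),
                              c(a = 1, b = NA, c = NA), st, "hyp"),
               "incomparable")
})

test_that("distance is symmetric, unit invariant and monotone", {
  set.seed(5)
  m <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- dataset_stats(meas_df(m))
  x <- c(a = 0.3, b = -1, c = 2)
  y <- c(a = -0.2, b = 0.4, c = 1)
  expect_equal(as.numeric(trace_distance(x, y, st, "hyp")),
               as.numeric(trace_distance(y, x, st, "hyp")))
  # rescale measure "a" by 1000 in data and vectors alike
  m2 <- m
  m2[, "a"] <- m2[, "a"] * 1000
  st2 <- dataset_stats(meas_df(m2))
  x2 <- x; y2 <- y
  x2["a"] <- x["a"] * 1000; y2["a"] <- y["a"] * 1000
  expect_equal(as.numeric(trace_distance(x2, y2, st2, "hyp")),
               as.numeric(trace_distance(x, y, st, "hyp")),
               tolerance = 1e-9)
  # worsening one measure never decreases the distance
  d0 <- as.numeric(trace_distance(x, y, st, "hyp"))
  x_worse <- x
  x_worse["b"] <- y[["b"]] + (x[["b"]] - y[["b"]]) * 3
  expect_gte(as.numeric(trace_distance(x_worse, y, st, "hyp")), d0)
})

test_that("aggregate distance is the mean of per-trace distances", {
  m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  st <- dataset_stats(meas_df(m))
  x <- c(a = 0.1, b = 0.2, c = 0.3)
  exp_meas <- meas_df(m)
  d <- aggregate_distance(list(hyp = x), exp_meas, st)
  per <- attr(d, "per_trace")
  expect_length(per, 4)
  expect_equal(as.numeric(d), mean(per))
  # single trace -> d_x = d_xy
  d1 <- aggregate_distance(list(hyp = x), exp_meas[1, ], st)
  expect_equal(as.numeric(d1), per[1])
  # protocol mismatch -> pairing error
  bad <- exp_meas
  bad$protocol <- "dep"
  expect_error(aggregate_distance(list(hyp = x), bad, st), "pairing")
})

test_that("aggregate distance equals a brute-force oracle on toy databases", {
  set.seed(13)
  for (rep in 1:5) {
    n_mod <- sample(2:10, 1)
    n_tr <- sample(2:6, 1)
    cols <- c("a", "b", "c")
    m <- matrix(rnorm(n_tr * 3), n_tr, 3, dimnames = list(NULL, cols))
    st <- dataset_stats(meas_df(m))
    sig <- setNames(st$stats$hyp$sd[match(cols, st$stats$hyp$measure)],
                    cols)
    models <- lapply(seq_len(n_mod), function(i)
      setNames(rnorm(3), cols))
    d_pkg <- vapply(models, function(x)
      as.numeric(aggregate_distance(list(hyp = x), meas_df(m), st)), 1)
    # independent direct summation of the definition
    d_hand <- vapply(models, function(x) {
      dxy <- vapply(seq_len(n_tr), function(j)
        sqrt(sum(((x - m[j, ]) / sig)^2) / 3), 1)
      sum(dxy) / n_tr
    }, 1)
    expect_equal(d_pkg, d_hand, tolerance = 1e-12)
  }
})

test_that("ranking sorts ascending with documented tie-breaks", {
  rec <- data.frame(model_id = c(7L, 2L, 5L), d_x = c(3, 1, 2))
  r <- rank_models(rec)
  expect_identical(r$model_id, c(2L, 5L, 7L))
  expect_identical(r$rank, 1:3)
  # all-equal distances -> id order
  rec2 <- data.frame(model_id = c(9L, 1L, 4L), d_x = c(2, 2, 2))
  expect_identical(rank_models(rec2)$model_id, c(1L, 4L, 9L))
  # permutation invariance
  set.seed(3)
  rec3 <- data.frame(model_id = 1:50, d_x = rnorm(50)^2)
  r3 <- rank_models(rec3)
  r3p <- rank_models(rec3[sample(50), ])
  expect_equal(as.data.frame(r3), as.data.frame(r3p))
  # non-finite distances are excluded with a message
  rec4 <- data.frame(model_id = 1:3, d_x = c(1, NaN, 2))
  expect_message(r4 <- rank_models(rec4), "excluded")
  expect_identical(nrow(r4), 2L)
  expect_identical(attr(r4, "excluded")$model_id, 2L)
})
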