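# toy model databases on small factorial grids
toy_db <- function(values, d_fun, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- expand.grid(values, KEEP.OUT.ATTRS = FALSE)
  g$model_id <- seq_len(nrow(g))
  g$d_x <- d_fun(g)
  g
}

test_that("stack images place every model and score clutter finitely", {
  db <- toy_db(list(a = 1:3, b = 1:3, c = 1:2),
               function(g) g$a + 10 * g$b + 0.1 * g$c)
  img <- stack_image(db, c("a", "b", "c"))
  expect_identical(length(img), nrow(db))
  expect_true(is.finite(clutter_score(img)))
  expect_error(stack_image(db, c("a", "zzz")))
})

test_that("CBDR puts the only influential parameter first", {
  db <- toy_db(list(a = 1:3, b = 1:3, c = 1:3),
               function(g) as.numeric(g$b) * 2)
  so <- cbdr_order(db, params = c("a", "b", "c"))
  expect_identical(so$order[1], "b")
  # constant distances: every ordering ties, name-sorted order returned
  db0 <- toy_db(list(a = 1:3, b = 1:3, c = 1:3), function(g) 1)
  expect_identical(cbdr_order(db0, params = c("c", "a", "b"))$order,
                   c("a", "b", "c"))
})

test_that("CBDR ranks two additive parameters above noise parameters", {
  db <- toy_db(list(a = 1:3, b = 1:3, c = 1:3, e = 1:3),
               function(g) 10 * as.numeric(g$a) + as.numeric(g$b))
  so <- cbdr_order(db, params = c("a", "b", "c", "e"))
  expect_setequal(so$order[1:2], c("a", "b"))
})

test_that("the returned ordering beats 100 random orderings on clutter", {
  db <- toy_db(list(a = 1:3, b = 1:3, c = 1:2, e = 1:2),
               function(g) as.numeric(g$a) * 3 + as.numeric(g$c),
               seed = 99)
  so <- cbdr_order(db, params = c("a", "b", "c", "e"))
  set.seed(17)
  for (i in 1:100) {
    ord <- sample(c("a", "b", "c", "e"))
    expect_gte(clutter_score(stack_image(db, ord)), so$clutter)
  }
})

test_that("conductance histograms count, normalize and degrade gracefully", {
  db <- toy_db(list(a = 1:4, b = 1:4), function(g) 1)
  # whole grid -> uniform
  h <- conductance_histogram(db, "a", "b")
  expect_true(all(h$counts == 1))
  expect_equal(sum(h$percent), 100)
  # diagonal subset -> all mass on the diagonal
  hd <- conductance_histogram(db, "a", "b", retained = db$a == db$b)
  expect_equal(sum(diag(hd$counts)), hd$n_subset)
  expect_equal(sum(hd$counts) - sum(diag(hd$counts)), 0)
  # empty subset -> all-zero histogram
  he <- conductance_histogram(db, "a", "b",
                              retained = rep(FALSE, nrow(db)))
  expect_true(all(he$counts == 0))
  expect_error(conductance_histogram(db, "a", "nope"), "not in grid")
})

test_that("interaction classification separates the three categories", {
  db <- toy_db(list(a = 1:4, b = 1:4), function(g) 1)
  # diagonal: co-regulation with score +1
  hd <- conductance_histogram(db, "a", "b", retained = db$a == db$b)
  cd <- classify_interaction(hd)
  expect_identical(cd$label, "co-regulation")
  expect_equal(cd$score, 1)
  # anti-diagonal: co-regulation with score -1
  ha <- conductance_histogram(db, "a", "b", retained = db$a == 5 - db$b)
  expect_identical(classify_interaction(ha)$label, "co-regulation")
  expect_equal(classify_interaction(ha)$score, -1)
  # single dominant central cell with symmetric tapering: local preference
  w <- outer(c(1, 4, 16, 4), c(1, 4, 16, 4))
  keep <- unlist(lapply(seq_len(nrow(db)), function(i)
    rep(i, w[db$a[i], db$b[i]])))
  db_rep <- db[keep, ]
  db_rep$model_id <- seq_len(nrow(db_rep))
  hp <- conductance_histogram(db_rep, "a", "b")
  cp <- classify_interaction(hp)
  expect_identical(cp$label, "local-preference")
  # degenerate 1 x N histogram is incomparable
  db1 <- toy_db(list(a = 1, b = 1:4), function(g) 1)
  h1 <- conductance_histogram(db1, "a", "b")
  expect_error(classify_interaction(h1), "incomparable")
})

test_that("uniform sampling stays below the ridge threshold over seeds", {
  scores <- vapply(1:100, function(s) {
    set.seed(s)
    db <- expand.grid(a = 1:4, b = 1:4)
    db <- db[sample(16, 400, replace = TRUE), ]
    h <- conductance_histogram(db, "a", "b")
    classify_interaction(h)$score
  }, 1)
  expect_lt(mean(abs(scores) >= 0.1), 0.05)
  expect_lt(mean(abs(scores)), 0.05)
})

test_that("classification depends only on value ranks, not units", {
  db <- toy_db(list(a = 1:4, b = 1:4), function(g) 1)
  mask <- db$a == db$b
  h1 <- conductance_histogram(db, "a", "b", retained = mask)
  db2 <- db
  db2$a <- db2$a * 1e-3          # relabel units
  db2$b <- db2$b * 40
  h2 <- conductance_histogram(db2, "a", "b", retained = mask)
  c1 <- classify_interaction(h1)
  c2 <- classify_interaction(h2)
  expect_identical(c1$label, c2$label)
  expect_equal(c1$score, c2$score)
})

test_that("coreg_screen recovers a planted co-regulation in >= 95% of runs", {
  hits <- vapply(1:50, function(s) {
    set.seed(s)
    vals <- list(a = 1:3, b = 1:3, c = 1:3, e = 1:3, f = 1:3)
    db <- expand.grid(vals)
    db$model_id <- seq_len(nrow(db))
    # distance driven by the a-b balance plus noise; retention = best 25%
    db$d_x <- abs(db$a - db$b) + 0.5 * abs(db$c - 2) +
      rnorm(nrow(db), 0, 0.3)
    db$retained <- rank(db$d_x, ties.method = "first") <=
      0.25 * nrow(db)
    so <- cbdr_order(db, params = names(vals))
    screen <- coreg_screen(db, so, n_high = 3)
    top <- screen[screen$label == "co-regulation", ]
    nrow(top) >= 1 && setequal(c(top$param_a[1], top$param_b[1]),
                               c("a", "b")) && abs(top$score[1]) >= 0.4
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("screening the full unfiltered grid reports no co-regulations", {
  vals <- list(a = 1:3, b = 1:3, c = 1:3)
  db <- expand.grid(vals)
  db$model_id <- seq_len(nrow(db))
  db$d_x <- rep(1, nrow(db))
  db$retained <- TRUE
  screen <- coreg_screen(db, c("a", "b", "c"), n_high = 3)
  expect_false(any(screen$label == "co-regulation"))
})
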