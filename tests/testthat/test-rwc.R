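# two disconnected triangles with decile labels 1 and 2
two_blocks <- function() {
  g <- graph_from_edges(c("a1", "a2", "a3", "b1", "b2", "b3"),
                        c("a2", "a3", "a1", "b2", "b3", "b1"))
  dec <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                  c("a1", "a2", "a3", "b1", "b2", "b3"))
  list(g = g, dec = dec)
}

test_that("authoritative-node selection takes the top in-degree per decile", {
  g <- graph_from_edges(c("x1", "x2", "x3", "y1"), c("h1", "h1", "h2", "h2"))
  dec <- setNames(c(1L, 1L, 1L, 2L, 1L, 2L),
                  c("x1", "x2", "x3", "h1", "h2", "y1"))
  # decile 1: h2 has in-degree 1, others 0 -> top-1 is h2
  # decile 2: h1 has in-degree 2 -> top-1 is h1
  expect_setequal(select_authoritative_nodes(g, dec, k = 1), c("h1", "h2"))
  # k >= decile size includes whole deciles
  expect_setequal(select_authoritative_nodes(g, dec, k = 10), names(dec))
  # equal in-degrees break ties by user id, deterministically
  gt <- graph_from_edges(c("a", "b"), c("t1", "t2"))
  dt <- setNames(rep(1L, 4), c("a", "b", "t1", "t2"))
  expect_equal(select_authoritative_nodes(gt, dt, k = 1), "t1")
  # fractional k reads as a per-decile fraction
  expect_length(select_authoritative_nodes(g, dec, k = 0.25), 2L)
})

test_that("single walks terminate on dead ends, revisits and length caps", {
  # dead end: no out-neighbours ends where it stands
  g1 <- graph_from_edges("a", "b")
  expect_equal(sample_walk(g1, "b"), "b")
  # forced 2-cycle ends back at the start via revisit
  g2 <- graph_from_edges(c("a", "b"), c("b", "a"))
  expect_equal(sample_walk(g2, "a"), "a")
  # chain with max_len = 2 ends exactly two hops away
  g3 <- graph_from_edges(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
  expect_equal(sample_walk(g3, "a", max_len = 2), "c")
  # arrival at an authoritative node halts the walk
  expect_equal(sample_walk(g3, "a", authoritative = "b", max_len = 10), "b")
  # ... but starting at one does not
  expect_equal(sample_walk(g3, "a", authoritative = "a", max_len = 2), "c")
})

test_that("disconnected blocks give the exact identity pattern", {
  tb <- two_blocks()
  est <- estimate_rwc_matrix(tb$g, tb$dec, walks_per_decile = 200, rng_seed = 3)
  expect_equal(unclass(est), matrix(c(1, 0, 0, 1), 2, 2,
                                    dimnames = list(start = 1:2, end = 1:2)),
               ignore_attr = TRUE)
  ex <- exact_rwc_small(tb$g, tb$dec)
  expect_equal(unclass(ex), unclass(est), ignore_attr = TRUE)
  expect_equal(colSums(ex), c(`1` = 1, `2` = 1))
})

test_that("shared dead-end hub splits column mass equally between deciles", {
  # a1, a2 (decile 1) each point only at hub (decile 2); equal walk budgets
  g <- graph_from_edges(c("a1", "a2"), c("hub", "hub"))
  dec <- setNames(c(1L, 1L, 2L), c("a1", "a2", "hub"))
  est <- estimate_rwc_matrix(g, dec, walks_per_decile = 500, rng_seed = 4)
  expect_equal(est["1", "2"], 0.5)
  expect_equal(est["2", "2"], 0.5)
  expect_true(all(is.na(est[, "1"])))
  expect_equal(attr(est, "undefined_columns"), "1")
  ex <- exact_rwc_small(g, dec)
  expect_equal(ex["1", "2"], 0.5)
})

test_that("columns of the estimated matrix sum to one", {
  run <- pipeline_run("tiny")
  g <- run$graph
  dec <- setNames(run$scores$decile, run$scores$user_id)
  est <- estimate_rwc_matrix(g, dec, walks_per_decile = 300, rng_seed = 5)
  cs <- colSums(unclass(est))
  ok <- !is.na(cs)
  expect_true(all(abs(cs[ok] - 1) < 1e-9))
})

test_that("relabeling deciles permutes the matrix correspondingly", {
  tb <- two_blocks()
  m1 <- exact_rwc_small(tb$g, tb$dec)
  swapped <- setNames(ifelse(tb$dec == 1L, 2L, 1L), names(tb$dec))
  m2 <- exact_rwc_small(tb$g, swapped)
  expect_equal(unclass(m1), unclass(m2)[c("2", "1"), c("2", "1")],
               ignore_attr = TRUE)
})

test_that("monte-carlo estimate converges to the exact oracle", {
  # 6-node graph with cross-block edges and an authoritative node
  g <- graph_from_edges(c("a1", "a2", "a3", "a1", "b1", "b2", "b3", "b1"),
                        c("a2", "a3", "a1", "b1", "b2", "b3", "b1", "a1"))
  dec <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L),
                  c("a1", "a2", "a3", "b1", "b2", "b3"))
  auth <- select_authoritative_nodes(g, dec, k = 1)
  ex <- exact_rwc_small(g, dec, auth)
  budgets <- c(100L, 1000L, 10000L)
  errs <- vapply(budgets, function(B) {
    est <- estimate_rwc_matrix(g, dec, auth, walks_per_decile = B, rng_seed = 6)
    max(abs(unclass(est) - unclass(ex)), na.rm = TRUE)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  # at the largest budget every cell sits within 3 binomial standard errors
  est <- estimate_rwc_matrix(g, dec, auth, walks_per_decile = 10000L,
                             rng_seed = 7)
  nB <- attr(est, "end_counts")
  for (b in colnames(ex)) {
    if (nB[b] == 0) next
    se <- sqrt(unclass(ex)[, b] * (1 - unclass(ex)[, b]) / nB[b])
    expect_true(all(abs(unclass(est)[, b] - unclass(ex)[, b]) <= 3 * se + 1e-9))
  }
})

test_that("the exact enumerator refuses graphs above its guard", {
  ids <- sprintf("n%02d", 1:13)
  g <- graph_from_edges(ids, ids[c(2:13, 1)])
  dec <- setNames(rep(1:2, length.out = 13), ids)
  expect_error(exact_rwc_small(g, dec), "guard")
})
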