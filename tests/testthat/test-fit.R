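test_that("polarity head fits separable seeds perfectly and stays in (0,1)", {
  withr::local_seed(41)
  emb <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(c("left", "right"), each = 20)
  head <- fit_polarity_head(emb, y)
  p <- polarnet:::predict_head(head, emb)
  expect_true(all(p > 0 & p < 1))
  expect_equal(mean((p > 0.5) == (y == "right")), 1.0)
  expect_error(fit_polarity_head(emb, rep("left", 40)), "both classes")
})

test_that("flipping all seed labels flips scores to their complement", {
  withr::local_seed(42)
  emb <- rbind(matrix(rnorm(60, -1), 30, 2), matrix(rnorm(60, 1), 30, 2))
  y <- rep(c("left", "right"), each = 30)
  h1 <- fit_polarity_head(emb, y)
  h2 <- fit_polarity_head(emb, ifelse(y == "left", "right", "left"))
  p1 <- polarnet:::predict_head(h1, emb)
  p2 <- polarnet:::predict_head(h2, emb)
  expect_equal(p1, 1 - p2, tolerance = 1e-6)
})

test_that("decile binning gives balanced bins with the stated tie rule", {
  s <- withr::with_seed(1, runif(20))
  d <- assign_deciles(s, sprintf("u%02d", 1:20))
  expect_equal(as.integer(table(d)), rep(2L, 10))
  # decile 1 holds the two lowest scores
  expect_setequal(names(d)[d == 1], sprintf("u%02d", order(s)[1:2]))

  d23 <- assign_deciles(withr::with_seed(2, runif(23)), sprintf("u%02d", 1:23))
  sz <- as.integer(table(d23))
  expect_equal(sum(sz), 23L)
  expect_lte(max(sz) - min(sz), 1L)

  # all-equal scores still split 10% per bin via the user-id tie rule
  deq <- assign_deciles(rep(0.5, 30), sprintf("u%02d", 1:30))
  expect_equal(as.integer(table(deq)), rep(3L, 10))
  expect_true(all(deq[sprintf("u%02d", 1:3)] == 1))

  expect_error(assign_deciles(runif(9), as.character(1:9)), "at least 10")
})

test_that("cross-validated AUC recovers separation and nulls to one half", {
  withr::local_seed(43)
  emb <- rbind(matrix(rnorm(100, -3), 50, 2), matrix(rnorm(100, 3), 50, 2))
  y <- rep(c("left", "right"), each = 50)
  expect_equal(crossval_auc(emb, y), 1.0)

  # permutation null at n = 500
  emb0 <- matrix(rnorm(1000), 500, 2)
  y0 <- sample(rep(c("left", "right"), each = 250))
  expect_lt(abs(crossval_auc(emb0, y0) - 0.5), 0.1)

  # AUC is a rank statistic: invariant under monotone transforms of scores
  p <- withr::with_seed(9, runif(100))
  yy <- rep(0:1, 50)
  a1 <- as.numeric(pROC::auc(yy, p, direction = "<", quiet = TRUE))
  a2 <- as.numeric(pROC::auc(yy, qlogis(p), direction = "<", quiet = TRUE))
  expect_equal(a1, a2)
})

test_that("predictions are order-invariant and identical for identical profiles", {
  run <- pipeline_run("separable")
  fit <- run$fit
  users <- run$users
  tab1 <- predict(fit, users)
  perm <- users[rev(seq_len(nrow(users))), ]
  tab2 <- predict(fit, perm)
  m <- merge(tab1, tab2, by = "user_id")
  expect_equal(m$score.x, m$score.y)
  expect_equal(m$decile.x, m$decile.y)

  dup <- users[c(1, 1, 2, 3:11), ]
  dup$user_id <- sprintf("d%02d", seq_len(nrow(dup)))
  td <- predict(fit, dup)
  expect_equal(td$score[1], td$score[2])

  bad <- users[1:10, ]; bad$profile_text[1] <- "  "
  expect_error(predict(fit, bad), "empty profiles")
})

test_that("seed scores align with seed labels after fitting", {
  run <- pipeline_run("separable")
  tab <- run$scores
  m <- merge(tab, run$seeds, by = "user_id")
  expect_gt(mean(m$score[m$label == "right"]), mean(m$score[m$label == "left"]))
})

test_that("model object methods print, summarise and expose coefficients", {
  run <- pipeline_run("separable")
  expect_output(print(run$fit), "polarity model")
  co <- coef(run$fit)
  expect_equal(length(co), run$fit$encoder$dim_out + 1L)
  expect_named(co[1], "intercept")
  s <- summary(run$fit)
  expect_s3_class(s, "summary.polarity_fit")
  expect_output(print(s), "cross-validated AUC")
})

test_that("mean word-embedding baseline averages in-vocabulary tokens", {
  wv <- matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("alpha", "beta"), NULL))
  expect_equal(baseline_mean_embedding("alpha", wv)[1, ], c(0, 2))
  expect_equal(baseline_mean_embedding("alpha beta", wv)[1, ], c(1, 1))
  expect_warning(out <- baseline_mean_embedding("zzz qqq", wv), "no in-vocabulary")
  expect_equal(out[1, ], c(0, 0))
})

test_that("label propagation converges to known fixed points and flags isolates", {
  # path L - x - R with unit weights: x settles at 0.5
  g <- interaction_graph(data.frame(source = c("L", "x"), target = c("x", "R"),
                                    weight = 1L))
  seeds <- data.frame(user_id = c("L", "R"), label = c("left", "right"))
  out <- baseline_label_propagation(g, seeds)
  expect_equal(out$score[out$user_id == "x"], 0.5, tolerance = 1e-4)

  # component with only left seeds absorbs to 0
  g2 <- graph_from_edges(c("L", "a"), c("a", "b"))
  out2 <- baseline_label_propagation(g2, data.frame(user_id = "L", label = "left"))
  expect_true(all(abs(out2$score) < 1e-4))

  # unreachable node is flagged unpredicted
  g3 <- interaction_graph(data.frame(source = c("L", "z"), target = c("a", "w"),
                                     weight = 1L))
  out3 <- baseline_label_propagation(g3, data.frame(user_id = "L", label = "left"))
  expect_false(out3$predicted[out3$user_id == "z"])
  expect_true(is.na(out3$score[out3$user_id == "w"]))

  expect_error(baseline_label_propagation(g3, data.frame(user_id = "nope",
                                                         label = "left")),
               "at least one seed")
})

test_that("graph-embedding baselines are explicit interface stubs", {
  expect_error(baseline_node2vec(), "stub")
  expect_error(baseline_graphsage(), "stub")
})
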