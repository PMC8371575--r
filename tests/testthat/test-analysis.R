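test_that("pagerank matches symmetry, normalisation and the dense oracle", {
  cyc <- graph_from_edges(c("a", "b", "c"), c("b", "c", "a"))
  pr <- compute_pagerank(cyc)
  expect_equal(unname(pr), rep(1 / 3, 3), tolerance = 1e-10)
  expect_equal(sum(pr), 1, tolerance = 1e-9)

  withr::local_seed(51)
  ids <- sprintf("n%02d", 1:10)
  el <- data.frame(source = sample(ids, 30, TRUE),
                   target = sample(ids, 30, TRUE),
                   weight = sample(1:3, 30, TRUE))
  el <- el[el$source != el$target, ]
  el <- stats::aggregate(weight ~ source + target, el, sum)
  g <- interaction_graph(el)
  pr2 <- compute_pagerank(g)
  oracle <- pagerank_dense_oracle(g)
  expect_lt(max(abs(pr2 - oracle[names(pr2)])), 1e-8)
  expect_equal(sum(pr2), 1, tolerance = 1e-9)

  # independent cross-check against igraph's implementation
  ig <- igraph::graph_from_data_frame(g$edges, vertices = g$nodes)
  prig <- igraph::page_rank(ig, damping = 0.85,
                            weights = igraph::E(ig)$weight)$vector
  expect_lt(max(abs(pr2[names(prig)] - prig)), 1e-6)
})

test_that("influence flags pick exactly the ceiling of the top fraction", {
  withr::local_seed(52)
  v <- setNames(runif(100), sprintf("u%03d", 1:100))
  f <- influence_flags(v, 0.05)
  expect_equal(sum(f), 5L)
  expect_true(all(v[f] >= max(v[!f])))
  expect_equal(sum(influence_flags(v, 1)), 100L)
  # verified measure passes through
  vf <- setNames(c(TRUE, FALSE), c("a", "b"))
  expect_identical(influence_flags(vf), vf)
  # ties at the cut resolved by user id
  tied <- setNames(rep(1, 10), sprintf("u%02d", 10:1))
  ft <- influence_flags(tied, 0.2)
  expect_setequal(names(ft)[ft], c("u01", "u02"))
})

test_that("per-decile influence fractions behave at the extremes and under nulls", {
  dec <- setNames(rep(1:10, each = 30), sprintf("u%03d", 1:300))
  flags <- setNames(rep(FALSE, 300), names(dec))
  flags[dec == 1][1:5] <- TRUE
  row <- influence_by_decile(flags, dec)
  expect_equal(row$fraction[row$decile == 1], 5 / 30)
  expect_true(all(row$fraction[row$decile != 1] == 0))
  # uniform random flags land near their rate in every decile
  withr::local_seed(53)
  rf <- setNames(runif(300) < 0.3, names(dec))
  rr <- influence_by_decile(rf, dec)
  sigma <- sqrt(0.3 * 0.7 / 30)
  expect_true(all(abs(rr$fraction - 0.3) <= 3 * sigma))
  expect_true(all(rr$fraction >= 0 & rr$fraction <= 1))
})

test_that("polarity groups map deciles 1-2/5-6/9-10 and agree with score order", {
  run <- pipeline_run("separable")
  dec <- setNames(run$scores$decile, run$scores$user_id)
  grp <- polarity_groups(dec)
  expect_true(all(dec[!is.na(grp) & grp == "left"] %in% 1:2))
  expect_true(all(dec[!is.na(grp) & grp == "neutral"] %in% 5:6))
  expect_true(all(dec[!is.na(grp) & grp == "right"] %in% 9:10))
  # each group is ~20% of users (rank binning keeps this exact up to ties)
  n <- length(dec)
  expect_lte(abs(sum(grp == "left", na.rm = TRUE) - 0.2 * n), 1)
  # group membership respects the score ordering
  sc <- setNames(run$scores$score, run$scores$user_id)
  expect_lt(max(sc[grp == "left"], na.rm = TRUE),
            min(sc[grp == "right"], na.rm = TRUE))
})

test_that("audience distributions hit the forced extremes", {
  # all retweeters of v are right-group users
  g <- graph_from_edges(c("r1", "r2", "r3"), rep("v", 3))
  dec <- setNames(c(9L, 10L, 9L, 10L), c("r1", "r2", "r3", "v"))
  grp <- polarity_groups(dec)
  ver <- setNames(rep(FALSE, 4), names(dec))
  aud <- audience_distribution(g, dec, grp, ver)
  r10 <- aud[aud$decile == 10 & !aud$verified, ]
  expect_equal(r10$frac_right, 1.0)
  expect_equal(r10$n_retweeters, 3L)

  # an even three-way split gives thirds
  g2 <- graph_from_edges(c("l", "n", "r"), rep("v", 3))
  dec2 <- setNames(c(1L, 5L, 9L, 5L), c("l", "n", "r", "v"))
  grp2 <- polarity_groups(dec2)
  ver2 <- setNames(rep(FALSE, 4), names(dec2))
  aud2 <- audience_distribution(g2, dec2, grp2, ver2)
  cell <- aud2[aud2$decile == 5 & !aud2$verified, ]
  expect_equal(unlist(cell[c("frac_left", "frac_neutral", "frac_right")]),
               c(frac_left = 1 / 3, frac_neutral = 1 / 3, frac_right = 1 / 3))
  # a cell with no retweeters is NA-flagged
  expect_true(all(is.na(aud2[aud2$decile == 1, c("frac_left", "frac_right")])))
})

test_that("top retweeted users are ranked by unique within-group retweeters", {
  # v retweeted by everyone; u retweeted 7 times by 3 unique users
  src <- c("a", "b", "c", "a", "a", "b", "b", "c", "c", "c")
  dst <- c(rep("v", 3), rep("u", 7))
  g <- build_interaction_graph(rt_records(src, dst), "retweet")
  expect_equal(g$edges$weight[g$edges$source == "c" & g$edges$target == "u"], 3L)
  grp <- setNames(c("left", "left", "left", NA, NA), c("a", "b", "c", "u", "v"))
  top <- top_retweeted_by_group(g, grp, "left", k = 2)
  expect_equal(top$group_retweeters, c(3L, 3L))
  expect_equal(top$total_retweeters, c(3L, 3L))
  expect_equal(top$overall_rank, c(1L, 1L))
  expect_equal(top$frac_left, c(1, 1))
})

test_that("role summaries compute original fractions and detect planted shifts", {
  recs <- tweet_records(tweet_id = c("t1", "t2", "t3", "t4"),
                        author_id = rep("a", 4),
                        kind = c("original", "original", "retweet", "retweet"),
                        retweeted_author_id = c(NA, NA, "b", "b"))
  users <- data.frame(user_id = c("a", "b"), profile_text = c("x", "y"),
                      followers = c(10L, 20L), verified = c(FALSE, FALSE),
                      location = "", bot_score = c(0.1, 0.2))
  g <- build_interaction_graph(recs, "retweet")
  grp <- setNames(c("left", "right"), c("a", "b"))
  ver <- setNames(c(FALSE, FALSE), c("a", "b"))
  out <- user_role_summary(users, recs, g, grp, ver)
  cell <- out$cells[out$cells$group == "left" & !out$cells$verified &
                      out$cells$statistic == "orig_fraction", ]
  expect_equal(cell$mean, 0.5)

  # null: identical follower distributions across groups -> F near 1
  withr::local_seed(54)
  n <- 300
  ids <- sprintf("u%03d", 1:n)
  grp2 <- setNames(rep(c("left", "neutral", "right"), each = n / 3), ids)
  ver2 <- setNames(rep(FALSE, n), ids)
  users2 <- data.frame(user_id = ids, profile_text = "p",
                       followers = rpois(n, 50), verified = FALSE,
                       location = "", bot_score = runif(n))
  recs2 <- tweet_records(tweet_id = ids, author_id = ids, kind = "original")
  g2 <- interaction_graph(NULL)
  null_out <- user_role_summary(users2, recs2, g2, grp2, ver2)
  p_foll <- null_out$anova$p_value[null_out$anova$statistic == "followers"]
  expect_gt(p_foll, 0.001)

  # planted mean shift in one group is detected decisively
  users3 <- users2
  users3$followers[grp2[users3$user_id] == "right"] <-
    users3$followers[grp2[users3$user_id] == "right"] + 40L
  shift_out <- user_role_summary(users3, recs2, g2, grp2, ver2)
  expect_lt(shift_out$anova$p_value[shift_out$anova$statistic == "followers"],
            0.001)
})
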