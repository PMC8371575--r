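test_that("tweet stream reading preserves order and skips malformed lines", {
  path <- system.file("extdata", "toy_tweets.jsonl", package = "polarnet")
  recs <- read_tweet_stream(path)
  expect_equal(nrow(recs), 12L)
  expect_equal(attr(recs, "skipped"), 0L)
  expect_equal(recs$tweet_id, sprintf("t%03d", 1:12))
  expect_true(all(recs$kind == "retweet"))
  expect_equal(recs$author_id[1:3], c("u1", "u1", "u1"))
  expect_equal(recs$retweeted_author_id[1:3], c("u2", "u2", "u3"))

  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id_str":"a","user":{"id_str":"u1"},"text":"hi"}',
               "{not json at all"), tmp)
  expect_warning(recs2 <- read_tweet_stream(tmp), "skipped 1")
  expect_equal(nrow(recs2), 1L)
  expect_equal(attr(recs2, "skipped"), 1L)
  expect_equal(recs2$kind, "original")

  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(), empty)
  expect_equal(nrow(read_tweet_stream(empty)), 0L)
  expect_error(read_tweet_stream("no/such/file.jsonl"), "not found")
})

test_that("records missing the author id are skipped with a warning", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id_str":"a","text":"orphan"}',
               '{"id_str":"b","user":{"id_str":"u9"},"text":"ok"}'), tmp)
  expect_warning(recs <- read_tweet_stream(tmp), "skipped 1")
  expect_equal(recs$author_id, "u9")
})

test_that("retweet graph weights count retweets and edges are directed", {
  recs <- rt_records(c("u", "u"), c("v", "v"))
  g <- build_interaction_graph(recs, "retweet")
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$weight, 2L)

  recs2 <- rt_records(c("u", "v"), c("v", "u"))
  g2 <- build_interaction_graph(recs2, "retweet")
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(g2$edges$weight, c(1L, 1L))

  # edge weights conserve the retweet-event count
  toy <- toy_tweets()
  gt <- build_interaction_graph(toy, "retweet")
  expect_equal(sum(gt$edges$weight), sum(toy$kind == "retweet"))

  # order independence
  perm <- toy[rev(seq_len(nrow(toy))), ]
  expect_identical(build_interaction_graph(perm, "retweet"), gt)
})

test_that("mention graph counts every mentioned id once per tweet", {
  recs <- tweet_records(tweet_id = "t1", author_id = "u", kind = "original",
                        mentioned_ids = list(c("v", "x")))
  g <- build_interaction_graph(recs, "mention")
  expect_equal(sort(g$edges$target), c("v", "x"))
  expect_equal(g$edges$weight, c(1L, 1L))
  # empty input gives an empty graph
  g0 <- build_interaction_graph(recs[0, ], "mention")
  expect_equal(n_distinct <- length(g0$nodes), 0L)
})

test_that("self-retweets are dropped at construction", {
  recs <- rt_records(c("u", "u"), c("u", "v"))
  g <- build_interaction_graph(recs, "retweet")
  expect_equal(g$edges$source, "u")
  expect_equal(g$edges$target, "v")
})

test_that("edge-weight filter keeps nodes and is idempotent", {
  g <- graph_from_edges(c("a", "a"), c("b", "c"), w = c(1L, 2L))
  f <- filter_edges_by_weight(g, 2)
  expect_equal(nrow(f$edges), 1L)
  expect_equal(f$edges$target, "c")
  expect_setequal(f$nodes, c("a", "b", "c"))
  expect_identical(filter_edges_by_weight(g, 1), g)
  g1 <- graph_from_edges(c("a", "b"), c("b", "c"), w = 1L)
  f1 <- filter_edges_by_weight(g1, 2)
  expect_equal(nrow(f1$edges), 0L)
  expect_setequal(f1$nodes, c("a", "b", "c"))
  expect_identical(filter_edges_by_weight(f, 2), f)
})

test_that("degree filter keeps nodes active in either direction, single pass", {
  # star: 12 leaves retweet the hub; hub in-degree 12, leaves out-degree 1
  leaves <- sprintf("l%02d", 1:12)
  g <- graph_from_edges(leaves, rep("hub", 12))
  f <- filter_users_by_degree(g, 10)
  expect_equal(f$nodes, "hub")
  expect_equal(nrow(f$edges), 0L)

  expect_identical(filter_users_by_degree(g, 0), g)

  # 11-node directed cycle: every node has in = out = 1
  ids <- sprintf("c%02d", 1:11)
  cyc <- graph_from_edges(ids, ids[c(2:11, 1)])
  f2 <- filter_users_by_degree(cyc, 2)
  expect_equal(length(f2$nodes), 0L)

  # idempotent when surviving nodes keep their qualifying degrees
  expect_identical(filter_users_by_degree(cyc, 1), cyc)
  expect_identical(filter_users_by_degree(filter_users_by_degree(cyc, 1), 1), cyc)
})

test_that("bot filter removes the top scored fraction with a stable tie rule", {
  u <- data.frame(user_id = sprintf("u%02d", 1:10),
                  bot_score = seq(0, 0.9, by = 0.1))
  out <- remove_top_bot_fraction(u, 0.1)
  expect_equal(nrow(out), 9L)
  expect_false("u10" %in% out$user_id)

  expect_identical(remove_top_bot_fraction(u, 0), u)

  tie <- data.frame(user_id = sprintf("u%02d", 1:10), bot_score = rep(0.5, 10))
  out2 <- remove_top_bot_fraction(tie, 0.1)
  expect_equal(nrow(out2), 9L)
  expect_false("u01" %in% out2$user_id)   # smallest id removed among ties

  mixed <- data.frame(user_id = c("a", "b", "c"), bot_score = c(NA, 0.9, 0.1))
  expect_message(out3 <- remove_top_bot_fraction(mixed, 0.5), "exempt")
  expect_setequal(out3$user_id, c("a", "c"))
})

test_that("US-location filter uses the packaged predicate and is pluggable", {
  u <- data.frame(user_id = c("a", "b", "c", "d"),
                  location = c("Los Angeles, CA", "", "London, UK", "texas"))
  out <- filter_us_location(u)
  expect_setequal(out$user_id, c("a", "d"))
  expect_identical(filter_us_location(u, function(x) rep(TRUE, length(x))), u)
})

test_that("toy corpus filter cascade matches hand-computed counts", {
  g <- build_interaction_graph(toy_tweets(), "retweet")
  expect_equal(length(g$nodes), 6L)
  expect_equal(nrow(g$edges), 7L)

  g2 <- filter_edges_by_weight(g, 2)
  expect_equal(nrow(g2$edges), 5L)
  expect_equal(length(g2$nodes), 6L)

  g3 <- filter_users_by_degree(g2, 1)
  expect_setequal(g3$nodes, c("u1", "u2", "u3", "u4"))
  expect_equal(nrow(g3$edges), 5L)

  users <- toy_users()
  kept <- remove_top_bot_fraction(users[users$user_id %in% g3$nodes, ], 0.25)
  expect_setequal(kept$user_id, c("u1", "u2", "u3"))
  g4 <- induce_subgraph(g3, kept$user_id)
  expect_equal(nrow(g4$edges), 4L)
})

test_that("edge list TSV round-trips", {
  g <- build_interaction_graph(toy_tweets(), "retweet")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, tmp)
  expect_identical(read_edge_list(tmp), g)
})
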