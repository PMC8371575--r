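# shared fixtures and cached pipeline runs (computed once per test session)

.polarnet_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .polarnet_cache))
    assign(key, force(expr), envir = .polarnet_cache)
  get(key, envir = .polarnet_cache)
}

# full pipeline run on a standard fixture; artifacts under a session tempdir
pipeline_run <- function(fixture, rng_seed = 1L, tag = fixture) {
  cached(paste0("run_", tag, "_", rng_seed), {
    out <- file.path(tempdir(), paste0("polarnet_", tag, "_", rng_seed))
    cfg <- pipeline_config(out_dir = out, fixture = fixture, rng_seed = rng_seed)
    run_pipeline(cfg)
    list(
      out = out,
      cfg = cfg,
      scores = utils::read.csv(file.path(out, "scores.csv"),
                               colClasses = c(user_id = "character")),
      seeds = utils::read.csv(file.path(out, "seeds.csv"),
                              colClasses = c(user_id = "character")),
      truth = utils::read.csv(file.path(out, "corpus", "truth.csv"),
                              colClasses = c(user_id = "character")),
      users = read_user_table(file.path(out, "users_filtered.csv")),
      graph = read_edge_list(file.path(out, "graph_retweet.tsv")),
      fit = readRDS(file.path(out, "model.rds")))
  })
}

# quick retweet-record builder: one record per (src, dst) retweet event
rt_records <- function(src, dst) {
  tweet_records(tweet_id = sprintf("t%03d", seq_along(src)),
                author_id = src, kind = "retweet",
                retweeted_author_id = dst,
                mentioned_ids = as.list(dst))
}

graph_from_edges <- function(src, dst, w = 1L, mode = "retweet") {
  interaction_graph(data.frame(source = src, target = dst,
                               weight = rep_len(w, length(src))),
                    mode = mode)
}

# the 12-tweet toy corpus with hand-computed filter outcomes:
#   raw edges: (u1,u2,2) (u1,u3,2) (u2,u1,2) (u3,u1,2) (u4,u1,2)
#              (u5,u1,1) (u6,u5,1)
#   weight >= 2       -> 5 edges, 6 nodes
#   degree >= 1       -> 4 nodes (u1..u4), 5 edges
#   bot top 25%       -> u4 removed (score 0.8), 3 nodes, 4 edges
toy_tweets <- function() {
  src <- c("u1", "u1", "u1", "u2", "u2", "u3", "u3", "u4", "u4", "u5", "u1", "u6")
  dst <- c("u2", "u2", "u3", "u1", "u1", "u1", "u1", "u1", "u1", "u1", "u3", "u5")
  rt_records(src, dst)
}

toy_users <- function() {
  data.frame(
    user_id = paste0("u", 1:6),
    profile_text = c("likes politics", "sports fan", "news junkie",
                     "always posting", "quiet", "lurker"),
    followers = c(100L, 50L, 80L, 10L, 5L, 2L),
    verified = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    location = c("New York, NY", "Los Angeles, CA", "Chicago, IL",
                 "Houston, TX", "Miami, FL", "Seattle, WA"),
    bot_score = c(0.1, 0.2, 0.3, 0.8, 0.4, 0.5),
    stringsAsFactors = FALSE)
}

# brute-force double-loop oracle for the in-batch multiple-negatives loss
mult_neg_oracle <- function(emb, pairs, margin = 1) {
  n <- nrow(pairs)
  tot <- 0
  for (k in seq_len(n)) for (kp in seq_len(n)) {
    if (kp == k) next
    tot <- tot + triplet_loss(emb[pairs[k, 1], ], emb[pairs[k, 2], ],
                              emb[pairs[kp, 2], ], margin)
  }
  tot / (n * (n - 1))
}

# dense linear-solve PageRank oracle (same conventions as compute_pagerank)
pagerank_dense_oracle <- function(graph, damping = 0.85, weighted = TRUE) {
  ids <- graph$nodes
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- graph$edges
  w <- if (weighted) e$weight else rep(1, nrow(e))
  for (r in seq_len(nrow(e)))
    P[e$target[r], e$source[r]] <- P[e$target[r], e$source[r]] + w[r]
  outsum <- colSums(P)
  for (j in seq_len(n)) {
    if (outsum[j] > 0) P[, j] <- P[, j] / outsum[j]
    else P[, j] <- 1 / n           # dangling: uniform redistribution
  }
  x <- solve(diag(n) - damping * P, rep((1 - damping) / n, n))
  stats::setNames(x / sum(x) * 1, ids)  # solve already sums to 1 up to fp
}
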