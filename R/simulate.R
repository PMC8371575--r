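#' Configuration for the synthetic polarized corpus
#'
#' Describes a block-model retweet/mention corpus with known ground truth:
#' partisan communities of stated sizes and polarity centers, a community
#' retweet-rate matrix (the right block is typically smaller and denser,
#' mirroring the asymmetry of real partisan networks), community token
#' distributions with a shared-vocabulary overlap, planted unambiguous
#' partisan profile hashtags on a fraction of users (these become seeds),
#' planted media endorsements, per-community verified rates, heavy-tailed
#' follower counts and community-shifted bot scores.
#'
#' @param communities data.frame `name`, `n`, `center` (polarity centre in
#'   `[0, 1]`), plus optional per-community columns `verified_rate`,
#'   `orig_lambda`, `followers_meanlog`, `bot_shape1`, `bot_shape2`.
#' @param retweet_rates K x K matrix of ordered retweet-pair probabilities
#'   (row retweets column), dimnames = community names.
#' @param stop_prob geometric stopping probability for the per-pair retweet
#'   count (`count = 1 + Geom(stop_prob)`), so both weight-1 and
#'   weight->=2 edges occur.
#' @param seed_rate fraction of left/right-community users carrying
#'   unambiguous partisan profile hashtags.
#' @param endorse_rate fraction of left/right users emitting >= 2 media
#'   endorsements (links to side-matched outlets).
#' @param mention_lambda expected extra direct-mention tweets per user.
#' @param mention_own_prob probability an extra mention targets the
#'   author's own community (mention networks mix more than retweets).
#' @param vocab_shared,vocab_per_community shared / per-community token
#'   pool sizes.
#' @param shared_token_prob probability a profile token comes from the
#'   shared pool.
#' @param tokens_per_profile range (min, max) of tokens per profile.
#' @param non_us_rate fraction of users given a non-US location.
#' @param rng_seed generator seed; a fixed seed gives byte-identical files.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(communities,
                             retweet_rates,
                             stop_prob = 0.55,
                             seed_rate = 0.30,
                             endorse_rate = 0.10,
                             mention_lambda = 2,
                             mention_own_prob = 0.6,
                             vocab_shared = 40L,
                             vocab_per_community = 30L,
                             shared_token_prob = 0.45,
                             tokens_per_profile = c(6L, 10L),
                             non_us_rate = 0.05,
                             rng_seed = 1L) {
  stopifnot(is.data.frame(communities),
            all(c("name", "n", "center") %in% names(communities)),
            all(communities$n > 0),
            all(communities$center >= 0 & communities$center <= 1))
  K <- nrow(communities)
  retweet_rates <- as.matrix(retweet_rates)
  stopifnot(nrow(retweet_rates) == K, ncol(retweet_rates) == K,
            all(retweet_rates >= 0 & retweet_rates <= 1),
            stop_prob > 0, stop_prob <= 1,
            seed_rate >= 0, seed_rate <= 1,
            endorse_rate >= 0, endorse_rate <= 1,
            non_us_rate >= 0, non_us_rate <= 1)
  defaults <- list(verified_rate = rep(0.08, K), orig_lambda = rep(1.5, K),
                   followers_meanlog = rep(4, K),
                   bot_shape1 = rep(2, K), bot_shape2 = rep(8, K))
  for (f in names(defaults))
    if (is.null(communities[[f]])) communities[[f]] <- defaults[[f]]
  structure(list(communities = communities, retweet_rates = retweet_rates,
                 stop_prob = stop_prob, seed_rate = seed_rate,
                 endorse_rate = endorse_rate,
                 mention_lambda = mention_lambda,
                 mention_own_prob = mention_own_prob,
                 vocab_shared = as.integer(vocab_shared),
                 vocab_per_community = as.integer(vocab_per_community),
                 shared_token_prob = shared_token_prob,
                 tokens_per_profile = as.integer(tokens_per_profile),
                 non_us_rate = non_us_rate,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Synthetic media catalog
#'
#' Six synthetic outlets spanning the 1-5 bias scale with invented
#' domains; used by the generator to plant endorsements with known bias.
#'
#' @return a [media_catalog()].
#' @export
synthetic_media_catalog <- function() {
  media_catalog(
    handle = c("synthleftdaily", "synthleanleft", "synthcenterwire",
               "synthleanright", "synthrightpost", "synthfarright"),
    domains = c("leftdaily.example", "leanleft.example", "centerwire.example",
                "leanright.example", "rightpost.example;rightpost-news.example",
                "farright.example"),
    bias = c(1L, 2L, 3L, 4L, 5L, 5L))
}

# sample k distinct ordered pairs between two id vectors at rate p
sample_pairs <- function(ua, ub, p, same) {
  na <- length(ua); nb <- length(ub)
  npairs <- if (same) na * (nb - 1) else na * nb
  if (npairs <= 0 || p <= 0) return(NULL)
  k <- stats::rbinom(1, npairs, p)
  if (k == 0) return(NULL)
  idx <- sample.int(npairs, k) - 1L
  if (same) {
    i <- idx %/% (na - 1L)
    j0 <- idx %% (na - 1L)
    j <- j0 + (j0 >= i)
  } else {
    i <- idx %/% nb
    j <- idx %% nb
  }
  data.frame(source = ua[i + 1L], target = ub[j + 1L],
             stringsAsFactors = FALSE)
}

json_tweet <- function(id, author, rt_author = NA, mentions = character(),
                       urls = character(), text = "") {
  m <- if (length(mentions))
    sprintf("\"user_mentions\":[%s]",
            paste(sprintf("{\"id_str\":\"%s\"}", mentions), collapse = ","))
  else "\"user_mentions\":[]"
  u <- if (length(urls))
    sprintf("\"urls\":[%s]",
            paste(sprintf("{\"expanded_url\":\"%s\"}", urls), collapse = ","))
  else "\"urls\":[]"
  rt <- if (!is.na(rt_author))
    sprintf(",\"retweeted_status\":{\"user\":{\"id_str\":\"%s\"}}", rt_author)
  else ""
  sprintf("{\"id_str\":\"%s\",\"user\":{\"id_str\":\"%s\"}%s,\"entities\":{%s,%s},\"text\":\"%s\"}",
          id, author, rt, m, u, text)
}

#' Generate a synthetic polarized corpus
#'
#' Writes three files to `dir`: `tweets.jsonl` (nested v1-style JSON
#' Lines), `users.csv` (the user table) and `truth.csv` (`user_id`,
#' `community`, `center` — the ground truth).  A fixed `rng_seed` yields
#' byte-identical output.
#'
#' @param cfg a [synthetic_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the three paths and event counts.
#' @export
generate_corpus <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  com <- cfg$communities
  K <- nrow(com)
  res <- withr::with_seed(cfg$rng_seed, {
    ids <- sprintf("u%04d", seq_len(sum(com$n)))
    community <- rep(com$name, com$n)
    members <- split(ids, factor(community, levels = com$name))

    # ---- profiles: community token distributions with shared overlap
    shared_vocab <- sprintf("common%02d", seq_len(cfg$vocab_shared))
    com_vocab <- lapply(seq_len(K), function(k)
      sprintf("%stok%02d", com$name[k], seq_len(cfg$vocab_per_community)))
    ntok <- sample(cfg$tokens_per_profile[1]:cfg$tokens_per_profile[2],
                   length(ids), replace = TRUE)
    ki <- match(community, com$name)
    profiles <- vapply(seq_along(ids), function(i) {
      from_shared <- stats::runif(ntok[i]) < cfg$shared_token_prob
      toks <- ifelse(from_shared,
                     sample(shared_vocab, ntok[i], replace = TRUE),
                     sample(com_vocab[[ki[i]]], ntok[i], replace = TRUE))
      paste(toks, collapse = " ")
    }, character(1))

    # ---- planted partisan hashtags (unambiguous; these become seeds)
    lex <- default_hashtag_lexicon()
    is_left_com <- com$center < 0.4
    is_right_com <- com$center > 0.6
    seeded <- logical(length(ids))
    for (k in seq_len(K)) {
      if (!is_left_com[k] && !is_right_com[k]) next
      mk <- which(community == com$name[k])
      ns <- round(cfg$seed_rate * length(mk))
      if (ns == 0) next
      pick <- sample(mk, ns)
      pool <- if (is_left_com[k]) lex$left else lex$right
      tags <- vapply(seq_len(ns), function(i)
        paste(sample(pool, sample(1:2, 1)), collapse = " "), character(1))
      profiles[pick] <- paste(tags, profiles[pick])
      seeded[pick] <- TRUE
    }

    # ---- user metadata
    verified <- stats::runif(length(ids)) < com$verified_rate[ki]
    followers <- round(stats::rlnorm(length(ids),
                                     meanlog = com$followers_meanlog[ki],
                                     sdlog = 1.2))
    bot_score <- round(stats::rbeta(length(ids), com$bot_shape1[ki],
                                    com$bot_shape2[ki]), 4)
    us_cities <- c("New York, NY", "Los Angeles, CA", "Chicago, IL",
                   "Houston, TX", "Phoenix, AZ", "Philadelphia, PA",
                   "Miami, FL", "Seattle, WA", "Denver, CO", "Atlanta, GA")
    location <- sample(us_cities, length(ids), replace = TRUE)
    non_us <- stats::runif(length(ids)) < cfg$non_us_rate
    location[non_us] <- sample(c("London, UK", "Toronto, Canada", "Paris"),
                               sum(non_us), replace = TRUE)

    # ---- retweet events: block model with geometric repeat counts
    pair_list <- list()
    for (a in seq_len(K)) for (b in seq_len(K)) {
      pl <- sample_pairs(members[[a]], members[[b]], cfg$retweet_rates[a, b],
                         same = a == b)
      if (!is.null(pl)) pair_list[[length(pair_list) + 1L]] <- pl
    }
    pairs <- if (length(pair_list)) do.call(rbind, pair_list)
    else data.frame(source = character(), target = character())
    counts <- if (nrow(pairs)) 1L + stats::rgeom(nrow(pairs), cfg$stop_prob)
    else integer()
    rt_src <- rep(pairs$source, counts)
    rt_dst <- rep(pairs$target, counts)

    # ---- media endorsements: >= 2 links to side-matched outlets
    catalog <- synthetic_media_catalog()
    left_doms <- unlist(catalog$domains[catalog$bias <= 2])
    right_doms <- unlist(catalog$domains[catalog$bias >= 4 &
                                           catalog$handle != "synthleanright"])
    end_src <- character(); end_url <- character()
    for (k in seq_len(K)) {
      if (!is_left_com[k] && !is_right_com[k]) next
      mk <- members[[k]]
      ne <- round(cfg$endorse_rate * length(mk))
      if (ne == 0) next
      pick <- sample(mk, ne)
      doms <- if (is_left_com[k]) left_doms else right_doms
      for (u in pick) {
        nl <- sample(2:3, 1)
        end_src <- c(end_src, rep(u, nl))
        end_url <- c(end_url, sprintf("https://%s/story%d",
                                      sample(doms, nl, replace = TRUE),
                                      sample.int(999, nl)))
      }
    }

    # ---- original tweets and extra direct mentions
    n_orig <- stats::rpois(length(ids), com$orig_lambda[ki])
    orig_src <- rep(ids, n_orig)
    n_ment <- stats::rpois(length(ids), cfg$mention_lambda)
    ment_src <- rep(ids, n_ment)
    ment_dst <- vapply(rep(ki, n_ment), function(k) {
      if (stats::runif(1) < cfg$mention_own_prob)
        sample(members[[k]], 1) else sample(ids, 1)
    }, character(1))
    self <- ment_src == ment_dst
    ment_src <- ment_src[!self]; ment_dst <- ment_dst[!self]

    # ---- assemble JSON lines (retweets, endorsements, originals, mentions)
    lines <- c(
      if (length(rt_src)) vapply(seq_along(rt_src), function(i)
        json_tweet(sprintf("rt%06d", i), rt_src[i], rt_author = rt_dst[i],
                   mentions = rt_dst[i], text = "rt"), character(1)),
      if (length(end_src)) vapply(seq_along(end_src), function(i)
        json_tweet(sprintf("en%06d", i), end_src[i], urls = end_url[i],
                   text = "link"), character(1)),
      if (length(orig_src)) vapply(seq_along(orig_src), function(i)
        json_tweet(sprintf("og%06d", i), orig_src[i], text = "original post"),
        character(1)),
      if (length(ment_src)) vapply(seq_along(ment_src), function(i)
        json_tweet(sprintf("mn%06d", i), ment_src[i], mentions = ment_dst[i],
                   text = "hey"), character(1)))

    tweets_path <- file.path(dir, "tweets.jsonl")
    users_path <- file.path(dir, "users.csv")
    truth_path <- file.path(dir, "truth.csv")
    writeLines(lines, tweets_path, useBytes = TRUE)
    users <- data.frame(user_id = ids, profile_text = profiles,
                        followers = followers, verified = verified,
                        location = location, bot_score = bot_score,
                        stringsAsFactors = FALSE)
    utils::write.csv(users, users_path, row.names = FALSE, quote = TRUE,
                     eol = "\n")
    truth <- data.frame(user_id = ids, community = community,
                        center = com$center[ki], seeded = seeded,
                        stringsAsFactors = FALSE)
    utils::write.csv(truth, truth_path, row.names = FALSE, quote = TRUE,
                     eol = "\n")
    list(tweets = tweets_path, users = users_path, truth = truth_path,
         n_users = length(ids), n_retweet_events = length(rt_src),
         n_tweets = length(lines))
  })
  invisible(res)
}

#' Standard synthetic fixtures
#'
#' Three named study conditions:
#' \describe{
#'   \item{tiny}{12 users in two communities; small enough for the exact
#'     random-walk enumeration oracle.}
#'   \item{separable}{~600 users in two well-separated communities with a
#'     high-signal vocabulary and unambiguous planted seeds; used for
#'     parameter-recovery checks (AUC, rank correlation).}
#'   \item{echo_asym}{600 users in three communities; the right block is
#'     smaller and denser and cross-community edges run mostly between
#'     the left and neutral blocks, planting the asymmetric echo-chamber
#'     structure (an insulated right community).}
#' }
#' The returned config carries a `thresholds` attribute with the
#' preprocessing settings appropriate to the fixture's scale (`tiny`
#' relaxes the corpus-scale weight/degree filters, which a 12-node graph
#' cannot survive).
#'
#' @param name `"tiny"`, `"separable"` or `"echo_asym"`.
#' @param rng_seed generator seed.
#' @return a [synthetic_config()].
#' @export
standard_fixture <- function(name = c("tiny", "separable", "echo_asym"),
                             rng_seed = 1L) {
  name <- match.arg(name)
  cfg <- switch(name,
    tiny = synthetic_config(
      communities = data.frame(name = c("left", "right"), n = c(6, 6),
                               center = c(0.15, 0.85)),
      retweet_rates = matrix(c(0.7, 0.08, 0.08, 0.7), 2, 2,
                             dimnames = list(c("left", "right"),
                                             c("left", "right"))),
      stop_prob = 0.6, seed_rate = 1, endorse_rate = 0,
      mention_lambda = 1, non_us_rate = 0, rng_seed = rng_seed),
    separable = synthetic_config(
      communities = data.frame(
        name = c("left", "right"), n = c(360, 240), center = c(0.15, 0.85),
        verified_rate = c(0.12, 0.04), orig_lambda = c(2, 0.5),
        followers_meanlog = c(4, 4.8),
        bot_shape1 = c(2, 3), bot_shape2 = c(8, 6)),
      retweet_rates = matrix(c(0.10, 0.002, 0.002, 0.18), 2, 2,
                             dimnames = list(c("left", "right"),
                                             c("left", "right"))),
      seed_rate = 0.30, endorse_rate = 0.12, rng_seed = rng_seed),
    echo_asym = synthetic_config(
      communities = data.frame(
        name = c("left", "neutral", "right"), n = c(260, 200, 140),
        center = c(0.15, 0.5, 0.85),
        verified_rate = c(0.12, 0.08, 0.04), orig_lambda = c(2, 1.5, 0.5),
        followers_meanlog = c(4, 3.8, 4.8),
        bot_shape1 = c(2, 2, 3), bot_shape2 = c(8, 8, 6)),
      retweet_rates = matrix(c(0.10, 0.03, 0.002,
                               0.03, 0.10, 0.004,
                               0.002, 0.004, 0.30), 3, 3, byrow = TRUE,
                             dimnames = list(c("left", "neutral", "right"),
                                             c("left", "neutral", "right"))),
      seed_rate = 0.30, endorse_rate = 0.10, mention_lambda = 3,
      mention_own_prob = 0.5, rng_seed = rng_seed))
  thresholds <- if (name == "tiny")
    list(w_min = 1L, d_min = 0L, bot_fraction = 0)
  else list(w_min = 2L, d_min = 10L, bot_fraction = 0.10)
  attr(cfg, "fixture") <- name
  attr(cfg, "thresholds") <- thresholds
  cfg
}
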