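#' PageRank by power iteration
#'
#' Standard PageRank on the directed graph, transition probabilities
#' proportional to edge weights, dangling mass redistributed uniformly.
#' Iterates `x <- (1 - damping)/n + damping * (P'x + dangling)` until the
#' L1 change falls below `tol`.
#'
#' @param graph an [interaction_graph()].
#' @param damping damping factor in (0, 1), default 0.85.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence warns with the residual.
#' @param weighted use edge weights (default TRUE).
#' @return named numeric vector summing to 1.
#' @export
compute_pagerank <- function(graph, damping = 0.85, tol = 1e-12,
                             max_iter = 200L, weighted = TRUE) {
  stopifnot(damping > 0, damping < 1)
  ids <- graph$nodes
  n <- length(ids)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  idx <- stats::setNames(seq_len(n), ids)
  e <- graph$edges
  w <- if (weighted) as.numeric(e$weight) else rep(1, nrow(e))
  outsum <- stats::setNames(numeric(n), ids)
  if (nrow(e)) {
    t1 <- tapply(w, e$source, sum)
    outsum[names(t1)] <- t1
  }
  P <- if (nrow(e))
    Matrix::sparseMatrix(i = idx[e$target], j = idx[e$source],
                         x = w / outsum[e$source], dims = c(n, n))
  else Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(n, n))
  dangling <- outsum[ids] == 0
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    xn <- (1 - damping) / n + damping * (as.numeric(P %*% x) +
                                           sum(x[dangling]) / n)
    delta <- sum(abs(xn - x))
    x <- xn
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("PageRank did not converge; residual ", signif(delta, 3))
  stats::setNames(x, ids)
}

#' Flag influential users by one measure
#'
#' For a numeric measure, flags exactly `ceil(top_frac * n)` users with
#' the highest values (ties at the cut broken by user id, smaller ids
#' flagged first).  For the verified measure the flag itself is returned.
#'
#' @param values named numeric vector (names = user ids) or, for
#'   `verified`, a named logical vector.
#' @param top_frac fraction flagged (default 0.05).
#' @return named logical vector over the same users.
#' @export
influence_flags <- function(values, top_frac = 0.05) {
  if (is.logical(values)) return(values)
  n <- length(values)
  m <- ceiling(top_frac * n)
  ord <- order(-values, names(values))
  out <- stats::setNames(rep(FALSE, n), names(values))
  out[ord[seq_len(min(m, n))]] <- TRUE
  out
}

#' Per-decile fraction of flagged users
#'
#' @param flags named logical vector.
#' @param deciles named integer vector over the same users.
#' @return data.frame `decile`, `fraction`, `n`.
#' @export
influence_by_decile <- function(flags, deciles) {
  ids <- intersect(names(flags), names(deciles))
  d <- deciles[ids]; f <- flags[ids]
  lev <- sort(unique(d))
  data.frame(decile = lev,
             fraction = vapply(lev, function(k) mean(f[d == k]), numeric(1)),
             n = vapply(lev, function(k) sum(d == k), integer(1)))
}

#' Influence report across the five standard measures
#'
#' Proportion of users in each polarity decile flagged influential under:
#' verified status, follower count, retweet in-degree, mention in-degree
#' and PageRank in the retweet network.
#'
#' @param users user table (for `followers`, `verified`).
#' @param retweet_graph,mention_graph [interaction_graph()]s;
#'   `mention_graph` may be `NULL`.
#' @param deciles named integer decile vector.
#' @param top_frac influential cut (default 0.05).
#' @param weighted_degree use weighted in-degrees (default FALSE: unique
#'   retweeters/mentioners).
#' @return data.frame `decile` x one column per measure.
#' @export
influence_report <- function(users, retweet_graph, mention_graph = NULL,
                             deciles, top_frac = 0.05,
                             weighted_degree = FALSE) {
  ids <- names(deciles)
  meas <- list(
    verified = stats::setNames(as.logical(users$verified[match(ids, users$user_id)]), ids),
    followers = stats::setNames(as.numeric(users$followers[match(ids, users$user_id)]), ids),
    retweet_in_degree = graph_degree(retweet_graph, "in", weighted_degree)[ids],
    pagerank = compute_pagerank(retweet_graph)[ids])
  if (!is.null(mention_graph))
    meas$mention_in_degree <- graph_degree(mention_graph, "in", weighted_degree)[ids]
  meas <- lapply(meas, function(v) { v[is.na(v)] <- 0; stats::setNames(v, ids) })
  out <- NULL
  for (m in names(meas)) {
    flags <- influence_flags(meas[[m]], top_frac)
    row <- influence_by_decile(flags, deciles)
    col <- stats::setNames(row["fraction"], m)
    out <- if (is.null(out)) cbind(row["decile"], col) else cbind(out, col)
  }
  out
}

#' Polarity groups from deciles
#'
#' Left = bottom 20% (deciles 1-2), neutral = middle 20% (deciles 5-6),
#' right = top 20% (deciles 9-10) of polarity scores; rank-based so each
#' group is exactly 20% up to tie rounding.  Users in other deciles get
#' `NA` (ungrouped).
#'
#' @param deciles named integer vector (1..10).
#' @return named character vector: `"left"`, `"neutral"`, `"right"` or `NA`.
#' @export
polarity_groups <- function(deciles) {
  g <- rep(NA_character_, length(deciles))
  g[deciles %in% 1:2] <- "left"
  g[deciles %in% 5:6] <- "neutral"
  g[deciles %in% 9:10] <- "right"
  stats::setNames(g, names(deciles))
}

#' Audience polarity distribution per retweeted-user decile
#'
#' For users in each polarity decile (split by verified status), pools
#' their unique retweeters — any `u` with an edge `(u, v)` — and reports
#' the fraction of that audience falling in the left / neutral / right
#' polarity groups (the remainder is ungrouped).  Pooling counts each
#' unique (retweeter, retweeted) pair once; `per_user = TRUE` instead
#' averages per-retweeted-user fractions.
#'
#' @param graph retweet [interaction_graph()].
#' @param deciles named integer decile vector over users.
#' @param groups named character group vector (see [polarity_groups()]).
#' @param verified named logical vector.
#' @param per_user average per-user instead of pooling (default FALSE).
#' @return data.frame `decile`, `verified`, `frac_left`, `frac_neutral`,
#'   `frac_right`, `n_retweeters` (NA fractions when a cell has no
#'   retweeters).
#' @export
audience_distribution <- function(graph, deciles, groups, verified,
                                  per_user = FALSE) {
  e <- unique(graph$edges[c("source", "target")])
  lev <- sort(unique(deciles))
  out <- expand.grid(decile = lev, verified = c(FALSE, TRUE))
  frac_na <- function(u) {
    g <- groups[u]
    n <- length(g)
    c(left = sum(g == "left", na.rm = TRUE) / n,
      neutral = sum(g == "neutral", na.rm = TRUE) / n,
      right = sum(g == "right", na.rm = TRUE) / n)
  }
  res <- t(vapply(seq_len(nrow(out)), function(r) {
    vs <- names(deciles)[deciles == out$decile[r] &
                           verified[names(deciles)] == out$verified[r]]
    ee <- e[e$target %in% vs, , drop = FALSE]
    if (nrow(ee) == 0L) return(c(NA_real_, NA_real_, NA_real_, 0))
    if (per_user) {
      per <- lapply(split(ee$source, ee$target), frac_na)
      f <- colMeans(do.call(rbind, per))
    } else {
      f <- frac_na(ee$source)
    }
    c(f, nrow(ee))
  }, numeric(4)))
  out$frac_left <- res[, 1]; out$frac_neutral <- res[, 2]
  out$frac_right <- res[, 3]; out$n_retweeters <- as.integer(res[, 4])
  out
}

#' Most-retweeted users within a polarity group
#'
#' Ranks users by their number of unique retweeters belonging to the
#' query group, attaching each user's overall unique-retweeter rank and
#' the polarity-group breakdown of their audience.
#'
#' @param graph retweet [interaction_graph()].
#' @param groups named character group vector.
#' @param group `"left"`, `"neutral"` or `"right"`.
#' @param k number of users returned (default 10).
#' @return data.frame `user_id`, `group_retweeters`, `total_retweeters`,
#'   `overall_rank`, `frac_left`, `frac_neutral`, `frac_right`.
#' @export
top_retweeted_by_group <- function(graph, groups, group = c("left", "neutral", "right"),
                                   k = 10L) {
  group <- match.arg(group)
  e <- unique(graph$edges[c("source", "target")])
  total <- table(e$target)
  in_grp <- e[!is.na(groups[e$source]) & groups[e$source] == group, , drop = FALSE]
  gcount <- table(in_grp$target)
  total_v <- stats::setNames(as.integer(total), names(total))
  overall_rank <- stats::setNames(rank(-total_v, ties.method = "min"), names(total_v))
  cand <- names(gcount)[order(-as.integer(gcount), names(gcount))]
  cand <- utils::head(cand, k)
  breakdown <- t(vapply(cand, function(v) {
    u <- e$source[e$target == v]
    g <- groups[u]
    n <- length(u)
    c(sum(g == "left", na.rm = TRUE), sum(g == "neutral", na.rm = TRUE),
      sum(g == "right", na.rm = TRUE)) / n
  }, numeric(3)))
  data.frame(user_id = cand,
             group_retweeters = as.integer(gcount[cand]),
             total_retweeters = total_v[cand],
             overall_rank = overall_rank[cand],
             frac_left = breakdown[, 1], frac_neutral = breakdown[, 2],
             frac_right = breakdown[, 3],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Role statistics per polarity group and verification status
#'
#' Per (group x verified) cell: mean, median and quartiles of the
#' original-tweet fraction, bot score, retweet-graph out- and in-degree
#' and follower count; plus, per statistic, a one-way analysis-of-variance
#' F test across the three polarity groups.
#'
#' @param users user table.
#' @param records tweet records (for original-tweet fractions).
#' @param graph retweet [interaction_graph()].
#' @param groups named character group vector.
#' @param verified named logical vector.
#' @return list with `cells` (data.frame of summaries) and `anova`
#'   (data.frame `statistic`, `F`, `p_value`).
#' @export
user_role_summary <- function(users, records, graph, groups, verified) {
  ids <- names(groups)[!is.na(groups)]
  n_tweets <- table(factor(records$author_id, levels = ids))
  n_orig <- table(factor(records$author_id[records$kind == "original"], levels = ids))
  stat_tab <- data.frame(
    user_id = ids,
    group = groups[ids],
    verified = verified[ids],
    orig_fraction = ifelse(n_tweets[ids] > 0,
                           as.integer(n_orig[ids]) / as.integer(n_tweets[ids]),
                           NA_real_),
    bot_score = users$bot_score[match(ids, users$user_id)],
    out_degree = graph_degree(graph, "out")[ids],
    in_degree = graph_degree(graph, "in")[ids],
    followers = as.numeric(users$followers[match(ids, users$user_id)]),
    stringsAsFactors = FALSE)
  stat_tab$out_degree[is.na(stat_tab$out_degree)] <- 0
  stat_tab$in_degree[is.na(stat_tab$in_degree)] <- 0
  stats_names <- c("orig_fraction", "bot_score", "out_degree", "in_degree",
                   "followers")
  summarize <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(n = 0, mean = NA, q1 = NA, median = NA, q3 = NA))
    q <- stats::quantile(x, c(.25, .5, .75), names = FALSE)
    c(n = length(x), mean = mean(x), q1 = q[1], median = q[2], q3 = q[3])
  }
  cells <- NULL
  for (g in c("left", "neutral", "right")) for (v in c(FALSE, TRUE)) {
    sub <- stat_tab[stat_tab$group == g & stat_tab$verified == v, , drop = FALSE]
    for (s in stats_names) {
      row <- data.frame(group = g, verified = v, statistic = s,
                        t(summarize(sub[[s]])))
      cells <- rbind(cells, row)
    }
  }
  an <- do.call(rbind, lapply(stats_names, function(s) {
    d <- stat_tab[!is.na(stat_tab[[s]]), c(s, "group")]
    if (length(unique(d$group)) < 2L || stats::var(d[[s]]) == 0)
      return(data.frame(statistic = s, F = NA_real_, p_value = NA_real_))
    fit <- stats::aov(stats::reformulate("group", response = s), data = d)
    sm <- summary(fit)[[1]]
    Fv <- sm$`F value`[1]; pv <- sm$`Pr(>F)`[1]
    data.frame(statistic = s,
               F = if (length(Fv)) Fv else NA_real_,
               p_value = if (length(pv)) pv else NA_real_)
  }))
  list(cells = cells, anova = an)
}
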