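#' Pipeline configuration
#'
#' Collects every stage's inputs, thresholds and seeds into one list.
#' Defaults follow the reference analysis: edge weight >= 2, degree >= 10,
#' top 10% bot removal, triplet margin 1, 10,000 walks per decile of
#' maximum length 10, top-5% influence cut.  The authoritative-node count
#' may be an absolute per-decile count (the reference analysis used 1000,
#' about 4% of a decile at its scale) or a fraction of each decile.
#'
#' @param out_dir artifact directory.
#' @param fixture synthetic fixture name for the simulate stage, or `NULL`
#'   when `tweets`/`users` point at real inputs.
#' @param tweets,users input paths (filled by the simulate stage when a
#'   fixture is named).
#' @param lexicon a [hashtag_lexicon()]; `catalog` a [media_catalog()].
#' @param w_min,d_min,bot_fraction preprocessing thresholds.
#' @param filter_location apply the US-location predicate.
#' @param control a [polarity_control()].
#' @param walks_per_decile,max_len,authoritative_k random-walk settings.
#' @param top_frac influence cut.
#' @param rwc_mention also estimate the controversy matrix on the mention
#'   network.
#' @param rng_seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            fixture = "separable",
                            tweets = NULL, users = NULL,
                            lexicon = default_hashtag_lexicon(),
                            catalog = synthetic_media_catalog(),
                            w_min = 2L, d_min = 10L, bot_fraction = 0.10,
                            filter_location = TRUE,
                            control = NULL,
                            walks_per_decile = 10000L, max_len = 10L,
                            authoritative_k = 0.04,
                            top_frac = 0.05,
                            rwc_mention = FALSE,
                            rng_seed = 1L) {
  if (is.null(control)) control <- polarity_control(rng_seed = rng_seed + 1L)
  if (!is.null(fixture)) {
    fx <- standard_fixture(fixture, rng_seed = rng_seed)
    th <- attr(fx, "thresholds")
    w_min <- th$w_min; d_min <- th$d_min; bot_fraction <- th$bot_fraction
  } else fx <- NULL
  structure(list(out_dir = out_dir, fixture = fixture, fixture_cfg = fx,
                 tweets = tweets, users = users,
                 lexicon = lexicon, catalog = catalog,
                 w_min = w_min, d_min = d_min, bot_fraction = bot_fraction,
                 filter_location = filter_location, control = control,
                 walks_per_decile = as.integer(walks_per_decile),
                 max_len = as.integer(max_len),
                 authoritative_k = authoritative_k,
                 top_frac = top_frac, rwc_mention = rwc_mention,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

pipeline_stages <- c("simulate", "ingest", "seed", "train", "predict",
                     "rwc", "analyze")

artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(out_dir, name, stage) {
  p <- artifact(out_dir, name)
  if (!file.exists(p))
    stop("missing artifact '", name, "' — run stage '", stage, "' first")
  p
}

write_manifest <- function(out_dir, stage, inputs, config) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  man <- list(stage = stage,
              package_version = as.character(utils::packageVersion("polarnet")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              rng_seed = config$rng_seed,
              config_summary_hash = unname(tools::md5sum(
                { tf <- tempfile(); writeLines(cfg_txt, tf); tf })),
              input_md5 = hashes)
  jsonlite::write_json(man, artifact(out_dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the polarity/echo-chamber pipeline
#'
#' Executes the requested stages in the fixed order
#' simulate -> ingest -> seed -> train -> predict -> rwc -> analyze,
#' writing each stage's artifact (and a manifest with input hashes and
#' versions) under `config$out_dir`.  Rerunning with unchanged inputs and
#' seed reproduces the artifacts byte-for-byte.
#'
#' Artifacts: `corpus/` (synthetic inputs), `graph_retweet.tsv`,
#' `graph_mention.tsv`, `users_filtered.csv`, `seeds.csv`, `model.rds`,
#' `scores.csv`, `rwc_retweet.csv` (and `rwc_mention.csv` when enabled),
#' `influence_report.csv`, `audience.csv`, `roles_cells.csv`,
#' `roles_anova.csv`, `top_left.csv`, `top_right.csv`.
#'
#' @param config a [pipeline_config()].
#' @param stages subset of the stage names (default: all).
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  paths <- list()

  if ("simulate" %in% stages) {
    if (is.null(config$fixture_cfg))
      stop("simulate stage requested but config names no fixture")
    res <- generate_corpus(config$fixture_cfg, file.path(out, "corpus"))
    paths$tweets <- res$tweets; paths$users <- res$users
    paths$truth <- res$truth
    write_manifest(out, "simulate", character(), config)
  } else {
    paths$tweets <- config$tweets %||% file.path(out, "corpus", "tweets.jsonl")
    paths$users <- config$users %||% file.path(out, "corpus", "users.csv")
  }

  if ("ingest" %in% stages) {
    if (!file.exists(paths$tweets))
      stop("missing artifact '", paths$tweets, "' — run stage 'simulate' first")
    records <- suppressWarnings(read_tweet_stream(paths$tweets))
    users <- read_user_table(paths$users)
    if (config$filter_location) users <- filter_us_location(users)
    users <- filter_empty_profiles(users)
    g_rt <- build_interaction_graph(records, "retweet")
    g_rt <- induce_subgraph(g_rt, users$user_id)
    g_rt <- filter_edges_by_weight(g_rt, config$w_min)
    g_rt <- filter_users_by_degree(g_rt, config$d_min)
    users_kept <- suppressMessages(
      remove_top_bot_fraction(users[users$user_id %in% g_rt$nodes, , drop = FALSE],
                              config$bot_fraction))
    g_rt <- induce_subgraph(g_rt, users_kept$user_id)
    users_kept <- users_kept[users_kept$user_id %in% g_rt$nodes, , drop = FALSE]
    g_mn <- build_interaction_graph(records, "mention")
    g_mn <- induce_subgraph(g_mn, users_kept$user_id)
    write_edge_list(g_rt, artifact(out, "graph_retweet.tsv"))
    write_edge_list(g_mn, artifact(out, "graph_mention.tsv"))
    utils::write.csv(users_kept, artifact(out, "users_filtered.csv"),
                     row.names = FALSE, eol = "\n")
    write_manifest(out, "ingest", c(paths$tweets, paths$users), config)
  }

  if ("seed" %in% stages) {
    up <- require_artifact(out, "users_filtered.csv", "ingest")
    users <- read_user_table(up)
    if (!file.exists(paths$tweets))
      stop("missing tweet stream — run stage 'simulate' or set config$tweets")
    records <- suppressWarnings(read_tweet_stream(paths$tweets))
    seeds <- seed_labels(users, records, config$lexicon, config$catalog)
    utils::write.csv(seeds, artifact(out, "seeds.csv"), row.names = FALSE,
                     eol = "\n")
    write_manifest(out, "seed", up, config)
  }

  if ("train" %in% stages) {
    gp <- require_artifact(out, "graph_retweet.tsv", "ingest")
    up <- require_artifact(out, "users_filtered.csv", "ingest")
    sp <- require_artifact(out, "seeds.csv", "seed")
    graph <- read_edge_list(gp)
    users <- read_user_table(up)
    seeds <- utils::read.csv(sp, colClasses = c(user_id = "character"))
    fit <- polarity_fit(graph, users, seeds, control = config$control)
    saveRDS(fit, artifact(out, "model.rds"))
    write_manifest(out, "train", c(gp, up, sp), config)
  }

  if ("predict" %in% stages) {
    mp <- require_artifact(out, "model.rds", "train")
    fit <- readRDS(mp)
    tab <- predict(fit)
    utils::write.csv(tab, artifact(out, "scores.csv"), row.names = FALSE,
                     eol = "\n")
    write_manifest(out, "predict", mp, config)
  }

  if ("rwc" %in% stages) {
    sp <- require_artifact(out, "scores.csv", "predict")
    gp <- require_artifact(out, "graph_retweet.tsv", "ingest")
    tab <- utils::read.csv(sp, colClasses = c(user_id = "character"))
    graph <- read_edge_list(gp)
    deciles <- stats::setNames(tab$decile, tab$user_id)
    auth <- select_authoritative_nodes(graph, deciles, config$authoritative_k)
    m <- estimate_rwc_matrix(graph, deciles, auth,
                             walks_per_decile = config$walks_per_decile,
                             max_len = config$max_len,
                             rng_seed = config$rng_seed + 2L)
    write_rwc_matrix(m, artifact(out, "rwc_retweet.csv"))
    if (isTRUE(config$rwc_mention)) {
      gm <- read_edge_list(require_artifact(out, "graph_mention.tsv", "ingest"),
                           mode = "mention")
      authm <- select_authoritative_nodes(gm, deciles, config$authoritative_k)
      mm <- estimate_rwc_matrix(gm, deciles, authm,
                                walks_per_decile = config$walks_per_decile,
                                max_len = config$max_len,
                                rng_seed = config$rng_seed + 3L)
      write_rwc_matrix(mm, artifact(out, "rwc_mention.csv"))
    }
    write_manifest(out, "rwc", c(sp, gp), config)
  }

  if ("analyze" %in% stages) {
    sp <- require_artifact(out, "scores.csv", "predict")
    gp <- require_artifact(out, "graph_retweet.tsv", "ingest")
    up <- require_artifact(out, "users_filtered.csv", "ingest")
    tab <- utils::read.csv(sp, colClasses = c(user_id = "character"))
    graph <- read_edge_list(gp)
    gm_path <- artifact(out, "graph_mention.tsv")
    g_mn <- if (file.exists(gm_path)) read_edge_list(gm_path, "mention") else NULL
    users <- read_user_table(up)
    if (!file.exists(paths$tweets))
      stop("missing tweet stream — run stage 'simulate' or set config$tweets")
    records <- suppressWarnings(read_tweet_stream(paths$tweets))
    deciles <- stats::setNames(tab$decile, tab$user_id)
    groups <- polarity_groups(deciles)
    verified <- stats::setNames(as.logical(users$verified), users$user_id)
    rep_inf <- influence_report(users, graph, g_mn, deciles, config$top_frac)
    aud <- audience_distribution(graph, deciles, groups, verified)
    roles <- user_role_summary(users, records, graph, groups, verified)
    tl <- top_retweeted_by_group(graph, groups, "left")
    tr <- top_retweeted_by_group(graph, groups, "right")
    utils::write.csv(rep_inf, artifact(out, "influence_report.csv"),
                     row.names = FALSE, eol = "\n")
    utils::write.csv(aud, artifact(out, "audience.csv"), row.names = FALSE,
                     eol = "\n")
    utils::write.csv(roles$cells, artifact(out, "roles_cells.csv"),
                     row.names = FALSE, eol = "\n")
    utils::write.csv(roles$anova, artifact(out, "roles_anova.csv"),
                     row.names = FALSE, eol = "\n")
    utils::write.csv(tl, artifact(out, "top_left.csv"), row.names = FALSE,
                     eol = "\n")
    utils::write.csv(tr, artifact(out, "top_right.csv"), row.names = FALSE,
                     eol = "\n")
    write_manifest(out, "analyze", c(sp, gp, up), config)
  }
  invisible(c(paths, list(out_dir = out)))
}
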