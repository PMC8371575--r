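#' Field mapping for tweet streams
#'
#' Maps the canonical record fields onto dotted JSON paths in the input.
#' Defaults mirror a Twitter v1-style export.  A path whose prefix resolves
#' to an array of objects (e.g. `entities.user_mentions`) is applied to
#' every element and the results concatenated.
#'
#' @param tweet_id,author_id,retweeted_author_id,quoted_author_id,
#'   in_reply_to,mentioned_ids,urls,text dotted JSON paths.
#' @param kind optional path to an explicit kind field; when `NULL` the
#'   kind is derived: retweet if a retweeted author resolves, else quote if
#'   a quoted author resolves, else reply if `in_reply_to` resolves, else
#'   original.
#' @return A named list of paths, class `tweet_field_mapping`.
#' @export
tweet_field_mapping <- function(tweet_id = "id_str",
                                author_id = "user.id_str",
                                retweeted_author_id = "retweeted_status.user.id_str",
                                quoted_author_id = "quoted_status.user.id_str",
                                in_reply_to = "in_reply_to_status_id_str",
                                mentioned_ids = "entities.user_mentions.id_str",
                                urls = "entities.urls.expanded_url",
                                text = "text",
                                kind = NULL) {
  structure(list(tweet_id = tweet_id, author_id = author_id,
                 retweeted_author_id = retweeted_author_id,
                 quoted_author_id = quoted_author_id,
                 in_reply_to = in_reply_to,
                 mentioned_ids = mentioned_ids, urls = urls,
                 text = text, kind = kind),
            class = "tweet_field_mapping")
}

# resolve a dotted path inside a parsed JSON object; arrays of objects fan out
json_path <- function(obj, path) {
  if (is.null(path)) return(NULL)
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  cur <- obj
  for (i in seq_along(parts)) {
    if (is.null(cur)) return(NULL)
    if (is.list(cur) && is.null(names(cur))) {
      # unnamed array: apply remaining path over elements
      rest <- paste(parts[i:length(parts)], collapse = ".")
      out <- unlist(lapply(cur, json_path, path = rest), use.names = FALSE)
      return(out)
    }
    cur <- cur[[parts[i]]]
  }
  if (is.list(cur) && is.null(names(cur))) cur <- unlist(cur, use.names = FALSE)
  cur
}

#' Read a JSON-Lines tweet stream
#'
#' One JSON object per line.  Malformed lines and records lacking an
#' author id are skipped (with a warning) and counted in the `skipped`
#' attribute of the result.
#'
#' @param path JSON-Lines file, UTF-8.
#' @param mapping a [tweet_field_mapping()].
#' @return data.frame with columns `tweet_id`, `author_id`, `kind`
#'   (original/retweet/quote/reply), `retweeted_author_id` (NA when
#'   absent), list-columns `mentioned_ids` and `urls`, and `text`;
#'   records in file order.  Attribute `skipped` counts dropped lines.
#' @export
read_tweet_stream <- function(path, mapping = tweet_field_mapping()) {
  if (!file.exists(path)) stop("tweet stream not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  skipped <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(obj)) { skipped <- skipped + 1L; next }
    author <- json_path(obj, mapping$author_id)
    if (is.null(author) || !nzchar(author[1])) { skipped <- skipped + 1L; next }
    rt_author <- json_path(obj, mapping$retweeted_author_id)
    q_author <- json_path(obj, mapping$quoted_author_id)
    kind <- json_path(obj, mapping$kind)
    if (is.null(kind)) {
      kind <- if (!is.null(rt_author)) "retweet"
      else if (!is.null(q_author)) "quote"
      else if (!is.null(json_path(obj, mapping$in_reply_to))) "reply"
      else "original"
    }
    if (is.null(rt_author) && kind == "quote") rt_author <- q_author
    mention <- json_path(obj, mapping$mentioned_ids)
    urls <- json_path(obj, mapping$urls)
    txt <- json_path(obj, mapping$text)
    recs[[i]] <- list(
      tweet_id = as.character(json_path(obj, mapping$tweet_id) %||% NA_character_)[1],
      author_id = as.character(author)[1],
      kind = as.character(kind)[1],
      retweeted_author_id = as.character(rt_author %||% NA_character_)[1],
      mentioned_ids = as.character(mention %||% character()),
      urls = as.character(urls %||% character()),
      text = as.character(txt %||% "")[1])
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (skipped > 0L)
    warning(sprintf("skipped %d malformed or author-less line(s) in %s",
                    skipped, path))
  out <- tweet_records(
    tweet_id = vapply(recs, `[[`, character(1), "tweet_id"),
    author_id = vapply(recs, `[[`, character(1), "author_id"),
    kind = vapply(recs, `[[`, character(1), "kind"),
    retweeted_author_id = vapply(recs, `[[`, character(1), "retweeted_author_id"),
    mentioned_ids = lapply(recs, `[[`, "mentioned_ids"),
    urls = lapply(recs, `[[`, "urls"),
    text = vapply(recs, `[[`, character(1), "text"))
  attr(out, "skipped") <- skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct tweet records directly
#'
#' Convenience constructor used by the synthetic generator and tests.
#' @param tweet_id,author_id,kind,retweeted_author_id character vectors.
#' @param mentioned_ids,urls lists of character vectors (recycled if empty).
#' @param text character vector of tweet texts.
#' @return data.frame of tweet records (list-columns for mentions/urls).
#' @export
tweet_records <- function(tweet_id, author_id, kind,
                          retweeted_author_id = NA_character_,
                          mentioned_ids = list(character()),
                          urls = list(character()),
                          text = "") {
  n <- length(author_id)
  if (n == 0L) {
    out <- data.frame(tweet_id = character(), author_id = character(),
                      kind = character(), retweeted_author_id = character(),
                      stringsAsFactors = FALSE)
    out$mentioned_ids <- list()
    out$urls <- list()
    out$text <- character()
    return(out)
  }
  bad <- kind == "retweet" & is.na(retweeted_author_id)
  if (any(bad)) stop("retweet records must carry retweeted_author_id")
  out <- data.frame(tweet_id = rep_len(as.character(tweet_id), n),
                    author_id = as.character(author_id),
                    kind = rep_len(as.character(kind), n),
                    retweeted_author_id = rep_len(as.character(retweeted_author_id), n),
                    stringsAsFactors = FALSE)
  out$mentioned_ids <- rep_len(mentioned_ids, n)
  out$urls <- rep_len(urls, n)
  out$text <- rep_len(as.character(text), n)
  out
}

#' Read a user table
#'
#' CSV with header `user_id, profile_text, followers, verified, location,
#' bot_score`; `bot_score` may be empty (never removed by the bot filter).
#'
#' @param path CSV file.
#' @return data.frame with those columns, `user_id` character.
#' @export
read_user_table <- function(path) {
  if (!file.exists(path)) stop("user table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(user_id = "character"))
  need <- c("user_id", "profile_text", "followers", "verified", "location", "bot_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("user table missing columns: ", paste(miss, collapse = ", "))
  df$profile_text[is.na(df$profile_text)] <- ""
  df$location[is.na(df$location)] <- ""
  df$verified <- as.logical(df$verified)
  df$bot_score <- as.numeric(df$bot_score)
  if (any(!is.na(df$bot_score) & (df$bot_score < 0 | df$bot_score > 1)))
    stop("bot_score outside [0, 1]")
  df
}

#' Remove likely bot accounts
#'
#' Drops the `ceil(fraction * n_scored)` users with the highest bot scores,
#' where `n_scored` counts users carrying a score.  Unscored users are never
#' removed (a message reports how many were exempt).  Ties at the cut are
#' broken by `user_id` order (lexicographically smaller ids removed first).
#'
#' @param users user table (data.frame as from [read_user_table()]).
#' @param fraction fraction of scored users to remove, in `[0, 1)`.
#' @return The user table minus the removed rows.
#' @export
remove_top_bot_fraction <- function(users, fraction = 0.10) {
  stopifnot(fraction >= 0, fraction < 1)
  scored <- which(!is.na(users$bot_score))
  n_unscored <- nrow(users) - length(scored)
  if (n_unscored > 0L)
    message(n_unscored, " user(s) lack a bot score and are exempt from the bot filter")
  m <- ceiling(fraction * length(scored))
  if (m == 0L) return(users)
  ord <- scored[order(-users$bot_score[scored], users$user_id[scored])]
  users[-ord[seq_len(m)], , drop = FALSE]
}

us_states <- c(
  "alabama", "alaska", "arizona", "arkansas", "california", "colorado",
  "connecticut", "delaware", "florida", "georgia", "hawaii", "idaho",
  "illinois", "indiana", "iowa", "kansas", "kentucky", "louisiana", "maine",
  "maryland", "massachusetts", "michigan", "minnesota", "mississippi",
  "missouri", "montana", "nebraska", "nevada", "new hampshire", "new jersey",
  "new mexico", "new york", "north carolina", "north dakota", "ohio",
  "oklahoma", "oregon", "pennsylvania", "rhode island", "south carolina",
  "south dakota", "tennessee", "texas", "utah", "vermont", "virginia",
  "washington", "west virginia", "wisconsin", "wyoming")

us_state_abbr <- c(
  "al", "ak", "az", "ar", "ca", "co", "ct", "de", "fl", "ga", "hi", "id",
  "il", "in", "ia", "ks", "ky", "la", "me", "md", "ma", "mi", "mn", "ms",
  "mo", "mt", "ne", "nv", "nh", "nj", "nm", "ny", "nc", "nd", "oh", "ok",
  "or", "pa", "ri", "sc", "sd", "tn", "tx", "ut", "vt", "va", "wa", "wv",
  "wi", "wy", "dc")

#' Default US-location predicate
#'
#' Case-insensitive test of a free-text location against US state names
#' (substring with word boundaries), state abbreviations (standalone
#' tokens) and common country spellings.  Empty locations fail.
#'
#' @param location character vector of location strings.
#' @return logical vector.
#' @export
is_us_location <- function(location) {
  loc <- tolower(trimws(location))
  out <- logical(length(loc))
  nonempty <- nzchar(loc)
  if (!any(nonempty)) return(out)
  country <- c("usa", "u.s.", "u.s.a.", "united states", "united states of america",
               "america", "d.c.", "washington dc")
  pat_state <- paste0("\\b(", paste(us_states, collapse = "|"), ")\\b")
  hit_state <- grepl(pat_state, loc[nonempty], perl = TRUE)
  toks <- strsplit(loc[nonempty], "[^a-z.]+")
  hit_abbr <- vapply(toks, function(t) any(t %in% us_state_abbr), logical(1))
  hit_country <- vapply(seq_along(toks), function(i) {
    any(vapply(country, function(cn) grepl(cn, loc[nonempty][i], fixed = TRUE), logical(1)))
  }, logical(1))
  out[nonempty] <- hit_state | hit_abbr | hit_country
  out
}

#' Keep users whose location passes a predicate
#'
#' @param users user table.
#' @param predicate function mapping a character vector of locations to a
#'   logical vector; default [is_us_location()].
#' @return Filtered user table.
#' @export
filter_us_location <- function(users, predicate = is_us_location) {
  keep <- predicate(users$location)
  keep[is.na(keep)] <- FALSE
  users[keep, , drop = FALSE]
}

#' Drop users with empty profile text
#' @param users user table.
#' @return Users with non-empty `profile_text` (whitespace-only counts as empty).
#' @export
filter_empty_profiles <- function(users) {
  users[nzchar(trimws(users$profile_text)), , drop = FALSE]
}
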