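#' Hashtag lexicon for weak supervision
#'
#' Two disjoint sets of lowercased partisan profile hashtags.  The packaged
#' default ships only well-known example tags; real analyses should supply
#' a curated lexicon via [read_hashtag_lexicon()].
#'
#' @param left,right character vectors of hashtags (with or without `#`).
#' @return list with `left` and `right` lowercase `#`-prefixed sets,
#'   class `hashtag_lexicon`.
#' @export
hashtag_lexicon <- function(left, right) {
  norm <- function(x) {
    x <- tolower(trimws(x))
    x <- ifelse(startsWith(x, "#"), x, paste0("#", x))
    unique(x[nzchar(x) & x != "#"])
  }
  left <- norm(left); right <- norm(right)
  if (length(intersect(left, right)))
    stop("lexicon left and right sets must be disjoint")
  structure(list(left = left, right = right), class = "hashtag_lexicon")
}

#' @rdname hashtag_lexicon
#' @export
default_hashtag_lexicon <- function() {
  hashtag_lexicon(left = c("#theresistance", "#voteblue", "#resist",
                           "#bluewave"),
                  right = c("#maga", "#kag", "#trump2020", "#wwg1wga"))
}

#' @rdname hashtag_lexicon
#' @param path YAML file with keys `left: [...]` and `right: [...]`.
#' @export
read_hashtag_lexicon <- function(path) {
  y <- yaml::read_yaml(path)
  hashtag_lexicon(unlist(y$left), unlist(y$right))
}

# `#`-prefixed tokens of a profile, NFC-normalized and lowercased
extract_profile_hashtags <- function(text) {
  text <- tolower(stringi::stri_trans_nfc(text))
  m <- gregexpr("#\\w+", text, perl = TRUE)
  regmatches(text, m)
}

#' Most-used hashtags in user profiles
#'
#' Counts `#`-prefixed tokens across all profile descriptions (each
#' occurrence counts), descending by count with lexicographic tie-break.
#'
#' @param users user table.
#' @param n maximum number of hashtags returned (default 50).
#' @return data.frame `hashtag`, `count`, at most `n` rows.
#' @export
top_profile_hashtags <- function(users, n = 50L) {
  tags <- unlist(extract_profile_hashtags(users$profile_text), use.names = FALSE)
  if (length(tags) == 0L)
    return(data.frame(hashtag = character(), count = integer()))
  tab <- table(tags)
  out <- data.frame(hashtag = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$hashtag), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Hashtag-based pseudo label
#'
#' Labels a profile left or right by strict majority of lexicon hashtags
#' in the profile text; ties (including 0-0) give `"none"`.  Only profile
#' text is consulted — hashtags in tweets can be adversarial.
#'
#' @param profile_text character vector of profile descriptions.
#' @param lexicon a [hashtag_lexicon()].
#' @return character vector in `{"left", "right", "none"}`.
#' @export
hashtag_label <- function(profile_text, lexicon) {
  tags <- extract_profile_hashtags(profile_text)
  vapply(tags, function(t) {
    nl <- sum(t %in% lexicon$left)
    nr <- sum(t %in% lexicon$right)
    if (nl > nr) "left" else if (nr > nl) "right" else "none"
  }, character(1))
}

#' Media catalog of outlets with bias ratings
#'
#' @param handle character vector of outlet account ids/handles (no `@`).
#' @param domains list (or `;`-separated strings) of web domains per outlet.
#' @param bias integer 1-5 (left, center-left, neutral, center-right, right).
#' @return data.frame class `media_catalog`.
#' @export
media_catalog <- function(handle, domains, bias) {
  if (is.character(domains)) domains <- strsplit(domains, ";", fixed = TRUE)
  bias <- as.integer(bias)
  if (!all(bias %in% 1:5)) stop("bias must be integers 1..5")
  out <- data.frame(handle = as.character(handle), bias = bias,
                    stringsAsFactors = FALSE)
  out$domains <- lapply(domains, function(d) tolower(trimws(d)))
  class(out) <- c("media_catalog", class(out))
  out
}

#' @rdname media_catalog
#' @param path CSV with columns `handle`, `domains` (`;`-separated), `bias`.
#' @export
read_media_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(handle = "character"))
  media_catalog(df$handle, df$domains, df$bias)
}

# registered domain = last two dot-labels of the URL host, lowercased
registered_domain <- function(url) {
  host <- sub("^[a-z]+://", "", tolower(url))
  host <- sub("[/?#].*$", "", host)
  host <- sub(":\\d+$", "", host)
  vapply(strsplit(host, ".", fixed = TRUE), function(p) {
    n <- length(p)
    if (n >= 2) paste(p[(n - 1):n], collapse = ".") else host[1]
  }, character(1))
}

#' Collect media endorsements per user
#'
#' An endorsement is an explicit retweet of an outlet's account (quote
#' tweets count by default) or a tweet embedding a link whose registered
#' domain belongs to an outlet.  One bias entry is appended per qualifying
#' retweet / URL occurrence.
#'
#' @param records tweet records.
#' @param catalog a [media_catalog()].
#' @param include_quotes count quote tweets of outlet accounts (default TRUE).
#' @return named list: `user_id -> integer vector of bias scores`.
#' @export
extract_endorsements <- function(records, catalog, include_quotes = TRUE) {
  bias_by_handle <- stats::setNames(catalog$bias, catalog$handle)
  dom <- unlist(lapply(seq_len(nrow(catalog)), function(i)
    stats::setNames(rep(catalog$bias[i], length(catalog$domains[[i]])),
                    catalog$domains[[i]])))
  out <- list()
  add <- function(uid, b) out[[uid]] <<- c(out[[uid]], b)
  kinds <- if (include_quotes) c("retweet", "quote") else "retweet"
  for (i in seq_len(nrow(records))) {
    uid <- records$author_id[i]
    if (records$kind[i] %in% kinds && !is.na(records$retweeted_author_id[i])) {
      b <- bias_by_handle[records$retweeted_author_id[i]]
      if (!is.na(b)) add(uid, unname(b))
    }
    urls <- records$urls[[i]]
    if (length(urls)) {
      rd <- registered_domain(urls)
      hit <- dom[rd]
      hit <- hit[!is.na(hit)]
      if (length(hit)) add(uid, unname(hit))
    }
  }
  out
}

#' Media-based pseudo label
#'
#' Requires at least `min_endorsements` endorsements; the mean bias `m`
#' labels the user left when `m <= 2`, right when `m > 4`, none otherwise.
#'
#' @param bias_list integer vector of bias scores for one user.
#' @param min_endorsements minimum endorsement count (default 2).
#' @return `"left"`, `"right"` or `"none"`.
#' @export
media_label <- function(bias_list, min_endorsements = 2L) {
  stopifnot(min_endorsements >= 1L)
  if (length(bias_list) < min_endorsements) return("none")
  m <- mean(bias_list)
  if (m <= 2) "left" else if (m > 4) "right" else "none"
}

#' Combine hashtag and media pseudo labels
#'
#' The hashtag label wins whenever it is decisive; the media label is the
#' fallback.  Both `"none"` yields no seed (`NA`).
#'
#' @param hashtag,media labels in `{"left","right","none"}` (vectorised).
#' @return character vector: `"left"`, `"right"` or `NA` (no seed), with
#'   attribute-free source recoverable from the inputs.
#' @export
combine_seed_labels <- function(hashtag, media) {
  ifelse(hashtag != "none", hashtag, ifelse(media != "none", media, NA_character_))
}

#' Derive seed labels for a user table
#'
#' Runs both weak labelers and combines them (hashtag precedence).
#'
#' @param users user table.
#' @param records tweet records (for endorsements).
#' @param lexicon a [hashtag_lexicon()].
#' @param catalog a [media_catalog()] (optional; `NULL` skips media labels).
#' @return data.frame `user_id`, `label` ("left"/"right"), `source`
#'   ("hashtag"/"media"); one row per seed user.
#' @export
seed_labels <- function(users, records = NULL, lexicon = default_hashtag_lexicon(),
                        catalog = NULL) {
  ht <- hashtag_label(users$profile_text, lexicon)
  md <- rep("none", nrow(users))
  if (!is.null(catalog) && !is.null(records)) {
    ends <- extract_endorsements(records, catalog)
    idx <- match(users$user_id, names(ends))
    md <- vapply(seq_len(nrow(users)), function(i) {
      if (is.na(idx[i])) "none" else media_label(ends[[idx[i]]])
    }, character(1))
  }
  lab <- combine_seed_labels(ht, md)
  keep <- !is.na(lab)
  data.frame(user_id = users$user_id[keep], label = lab[keep],
             source = ifelse(ht[keep] != "none", "hashtag", "media"),
             stringsAsFactors = FALSE)
}
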