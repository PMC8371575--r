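#' Profile encoders
#'
#' An encoder maps profile strings to fixed-dimension real vectors.  The
#' contract is three generics: [encode()] (deterministic at fixed
#' parameters), [is_trainable()] and, for trainable encoders, an internal
#' parameter-gradient hook used by [train_siamese_encoder()].
#'
#' `hash_encoder()` is the packaged trainable encoder: profiles are
#' tokenised (lowercased `#`-friendly word tokens), tokens are hashed into
#' `dim_in` buckets, the bucket-count vector is L2-normalised, and a
#' trainable linear map `W` (`dim_in x dim_out`) produces the embedding.
#' It is fast, deterministic and sufficient for distributional profile
#' signal; it does not model word order or semantics.
#'
#' `sentence_encoder()` adapts any external sentence-embedding function
#' (for example a transformer encoder served out-of-process) to the same
#' contract; such encoders are frozen — training keeps them unchanged.
#'
#' @param dim_in number of hash buckets (input features).
#' @param dim_out embedding dimension `d`.
#' @param seed RNG seed for the linear-map initialisation.
#' @return An object of class `c("hash_encoder", "profile_encoder")`.
#' @export
hash_encoder <- function(dim_in = 512L, dim_out = 16L, seed = 1L) {
  W <- withr::with_seed(seed, matrix(stats::rnorm(dim_in * dim_out, sd = 1 / sqrt(dim_in)),
                                     dim_in, dim_out))
  structure(list(dim_in = as.integer(dim_in), dim_out = as.integer(dim_out),
                 W = W, seed = as.integer(seed)),
            class = c("hash_encoder", "profile_encoder"))
}

#' @rdname hash_encoder
#' @param fun function mapping a character vector of texts to an
#'   `n x dim_out` numeric matrix.
#' @export
sentence_encoder <- function(fun, dim_out) {
  stopifnot(is.function(fun))
  structure(list(fun = fun, dim_out = as.integer(dim_out)),
            class = c("function_encoder", "profile_encoder"))
}

#' Encode texts into embeddings
#' @param encoder a `profile_encoder`.
#' @param texts character vector.
#' @param ... unused.
#' @return numeric matrix, one row per text, `dim_out` columns.
#' @export
encode <- function(encoder, texts, ...) UseMethod("encode")

#' @export
encode.hash_encoder <- function(encoder, texts, ...) {
  hash_features(texts, encoder$dim_in) %*% encoder$W
}

#' @export
encode.function_encoder <- function(encoder, texts, ...) {
  out <- encoder$fun(texts)
  out <- as.matrix(out)
  if (ncol(out) != encoder$dim_out || nrow(out) != length(texts))
    stop("sentence encoder returned wrong dimensions")
  out
}

#' Is an encoder trainable?
#' @param encoder a `profile_encoder`.
#' @return logical.
#' @export
is_trainable <- function(encoder) UseMethod("is_trainable")
#' @export
is_trainable.hash_encoder <- function(encoder) TRUE
#' @export
is_trainable.profile_encoder <- function(encoder) FALSE

tokenize_profile <- function(text) {
  text <- tolower(stringi::stri_trans_nfc(text))
  toks <- strsplit(text, "[^#[:alnum:]_]+")
  lapply(toks, function(t) t[nzchar(t) & t != "#"])
}

# stable polynomial rolling hash of a token into [1, m]
hash_token <- function(tokens, m) {
  vapply(tokens, function(tok) {
    b <- utf8ToInt(tok)
    h <- 0
    for (x in b) h <- (h * 31 + x) %% 2147483647
    (h %% m) + 1L
  }, numeric(1))
}

# n x m L2-row-normalised hashed bag-of-tokens matrix
hash_features <- function(texts, m) {
  toks <- tokenize_profile(texts)
  vocab <- unique(unlist(toks, use.names = FALSE))
  X <- matrix(0, length(texts), m)
  if (length(vocab)) {
    buckets <- hash_token(vocab, m)
    names(buckets) <- vocab
    for (i in seq_along(toks)) {
      if (!length(toks[[i]])) next
      tab <- table(buckets[toks[[i]]])
      X[i, as.integer(names(tab))] <- as.numeric(tab)
    }
    nrm <- sqrt(rowSums(X^2))
    nz <- nrm > 0
    X[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  }
  X
}

#' Mean word-embedding profile baseline
#'
#' Averages per-token word vectors over each profile; out-of-vocabulary
#' tokens are skipped, and a profile with no in-vocabulary token yields a
#' zero vector (with a warning).
#'
#' @param profiles character vector of profile descriptions.
#' @param word_vectors numeric matrix with words as rownames.
#' @return numeric matrix, one row per profile.
#' @export
baseline_mean_embedding <- function(profiles, word_vectors) {
  stopifnot(is.matrix(word_vectors), !is.null(rownames(word_vectors)))
  toks <- tokenize_profile(profiles)
  d <- ncol(word_vectors)
  out <- matrix(0, length(profiles), d)
  empty <- 0L
  for (i in seq_along(toks)) {
    t <- toks[[i]][toks[[i]] %in% rownames(word_vectors)]
    if (length(t) == 0L) { empty <- empty + 1L; next }
    out[i, ] <- colMeans(word_vectors[t, , drop = FALSE])
  }
  if (empty > 0L)
    warning(empty, " profile(s) had no in-vocabulary tokens; zero vectors returned")
  out
}

#' Graph-embedding baseline stubs
#'
#' Interface placeholders for random-walk and inductive graph-embedding
#' baselines; not implemented in this package.
#'
#' @param ... ignored.
#' @export
baseline_node2vec <- function(...) {
  stop("node2vec baseline is an interface stub; not implemented in polarnet")
}

#' @rdname baseline_node2vec
#' @export
baseline_graphsage <- function(...) {
  stop("GraphSAGE baseline is an interface stub; not implemented in polarnet")
}
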