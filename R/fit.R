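#' Training control parameters
#'
#' Collects the tunable knobs of the Siamese triplet training and the
#' polarity head.  Defaults: Euclidean distance with margin 1 (the
#' sentence-embedding convention the model follows), in-batch multiple
#' negatives, batch size 32, 8 epochs, learning rate 0.05, ridge penalty
#' 1e-3 on the head.
#'
#' @param margin triplet margin (> 0).
#' @param sampling `"mult_neg"` (in-batch negatives) or `"one_neg"`
#'   (one uniform negative per anchor).
#' @param batch_size,epochs,learning_rate gradient-descent knobs.
#' @param l2 ridge penalty of the logistic polarity head.
#' @param rng_seed seed governing pair shuffling and negative draws.
#' @return list of class `polarity_control`.
#' @export
polarity_control <- function(margin = 1, sampling = c("mult_neg", "one_neg"),
                             batch_size = 32L, epochs = 8L,
                             learning_rate = 0.05, l2 = 1e-3,
                             rng_seed = 42L) {
  sampling <- match.arg(sampling)
  stopifnot(margin > 0, batch_size >= 1, epochs >= 0, learning_rate > 0, l2 >= 0)
  structure(list(margin = margin, sampling = sampling,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, l2 = l2,
                 rng_seed = as.integer(rng_seed)),
            class = "polarity_control")
}

#' Fit a sigmoid polarity head on seed embeddings
#'
#' Ridge-penalised logistic regression (left -> 0, right -> 1): a linear
#' map of the embedding followed by a sigmoid, fitted by penalised
#' maximum likelihood.
#'
#' @param emb numeric matrix of seed-user embeddings.
#' @param labels character vector `"left"`/`"right"` (or 0/1).
#' @param l2 fixed ridge penalty.
#' @return object of class `polarity_head` with `intercept` and `beta`.
#' @export
fit_polarity_head <- function(emb, labels, l2 = 1e-3) {
  y <- if (is.character(labels) || is.factor(labels))
    as.integer(as.character(labels) == "right") else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("polarity head needs seeds of both classes (left and right)")
  fit <- glmnet::glmnet(emb, y, family = "binomial", alpha = 0,
                        lambda = l2, standardize = FALSE)
  structure(list(intercept = as.numeric(fit$a0),
                 beta = as.numeric(fit$beta), l2 = l2),
            class = "polarity_head")
}

predict_head <- function(head, emb) {
  eta <- head$intercept + as.numeric(emb %*% head$beta)
  1 / (1 + exp(-eta))
}

#' Rank-based decile binning of polarity scores
#'
#' Users are ranked ascending by score (ties broken by user id) and cut
#' into 10 bins whose sizes differ by at most one; decile 1 holds the most
#' left-leaning users.
#'
#' @param scores numeric vector.
#' @param ids character user ids (tie-break); defaults to names of scores.
#' @param n_bins number of bins (default 10).
#' @return integer vector of decile assignments (1..n_bins), named by id.
#' @export
assign_deciles <- function(scores, ids = names(scores), n_bins = 10L) {
  n <- length(scores)
  if (n < n_bins) stop("need at least ", n_bins, " users to bin into deciles")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(scores, ids)
  bounds <- floor(seq_len(n_bins) * n / n_bins)
  sizes <- diff(c(0L, bounds))
  dec <- integer(n)
  dec[ord] <- rep(seq_len(n_bins), times = sizes)
  stats::setNames(dec, ids)
}

#' Stratified k-fold cross-validated AUC of the polarity head
#'
#' Splits seeds into stratified folds, fits the head on the training
#' folds, and averages the held-out area under the ROC curve.
#'
#' @param emb seed embedding matrix.
#' @param labels `"left"`/`"right"` per row.
#' @param k number of folds (default 5).
#' @param l2 head ridge penalty.
#' @param rng_seed fold-assignment seed.
#' @return mean AUC over folds, in `[0, 1]`.
#' @export
crossval_auc <- function(emb, labels, k = 5L, l2 = 1e-3, rng_seed = 42L) {
  stopifnot(k >= 2L)
  y <- as.integer(as.character(labels) == "right")
  if (min(table(y)) < k)
    stop("not enough seeds of each class for ", k, " stratified folds")
  folds <- integer(length(y))
  withr::with_seed(rng_seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  aucs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    head <- fit_polarity_head(emb[tr, , drop = FALSE], y[tr], l2 = l2)
    p <- predict_head(head, emb[!tr, , drop = FALSE])
    as.numeric(pROC::auc(y[!tr], p, direction = "<", quiet = TRUE))
  }, numeric(1))
  mean(aucs)
}

#' Fit the retweet-aware polarity model
#'
#' The central fitting function.  Fine-tunes a profile encoder on the
#' (filtered) retweet graph with the Siamese triplet objective — users who
#' retweet each other are pulled together in embedding space — then fits a
#' sigmoid head on the weak-supervision seed labels.  The fitted object
#' scores any user in `[0, 1]` (0 far-left, 1 far-right) via [predict()].
#'
#' @param graph filtered retweet [interaction_graph()].
#' @param users user table covering all graph nodes (non-empty profiles).
#' @param seeds data.frame `user_id`, `label` from [seed_labels()].
#' @param encoder trainable `profile_encoder` (default [hash_encoder()]).
#' @param control a [polarity_control()].
#' @return object of class `polarity_fit` with components `encoder`
#'   (trained), `head`, `control`, `seeds`, `users`, `graph_nodes` and
#'   `training_log`.
#' @export
polarity_fit <- function(graph, users, seeds, encoder = hash_encoder(),
                         control = polarity_control()) {
  users <- filter_empty_profiles(users)
  missing_prof <- setdiff(graph$nodes, users$user_id)
  if (length(missing_prof))
    stop(length(missing_prof), " graph node(s) lack profile text; filter first")
  seeds <- seeds[seeds$user_id %in% users$user_id, , drop = FALSE]
  if (length(unique(seeds$label)) < 2L)
    stop("need seed users of both classes to fit a polarity model")
  encoder <- train_siamese_encoder(graph, users, encoder, control)
  semb <- encode(encoder, users$profile_text[match(seeds$user_id, users$user_id)])
  head <- fit_polarity_head(semb, seeds$label, l2 = control$l2)
  structure(list(encoder = encoder, head = head, control = control,
                 seeds = seeds, users = users, graph_nodes = graph$nodes,
                 training_log = encoder$log),
            class = "polarity_fit")
}

#' Predict polarity scores and deciles
#'
#' Scores every user (seed and non-seed) in `[0, 1]` and bins the scores
#' into rank deciles (1 = most left).  Scores are invariant to user order
#' and identical profiles receive identical scores.
#'
#' @param object a [polarity_fit()] model.
#' @param newdata user table; defaults to the fitting table.
#' @param ... unused.
#' @return data.frame `user_id`, `score`, `decile` — the polarity table.
#' @export
predict.polarity_fit <- function(object, newdata = NULL, ...) {
  users <- if (is.null(newdata)) object$users else newdata
  if (any(!nzchar(trimws(users$profile_text))))
    stop("users with empty profiles cannot be scored; filter first")
  emb <- encode(object$encoder, users$profile_text)
  score <- predict_head(object$head, emb)
  dec <- assign_deciles(score, users$user_id)
  out <- data.frame(user_id = users$user_id, score = score,
                    decile = as.integer(dec[users$user_id]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.polarity_fit <- function(x, ...) {
  cat("Retweet-aware polarity model\n")
  cat(sprintf("  graph nodes: %d | seeds: %d (left %d / right %d)\n",
              length(x$graph_nodes), nrow(x$seeds),
              sum(x$seeds$label == "left"), sum(x$seeds$label == "right")))
  cat(sprintf("  encoder: %s (d = %d) | sampling: %s | epochs: %d\n",
              class(x$encoder)[1], x$encoder$dim_out,
              x$control$sampling, x$control$epochs))
  if (!is.null(x$training_log) && nrow(x$training_log))
    cat(sprintf("  final epoch mean triplet loss: %.4f\n",
                utils::tail(x$training_log$mean_loss, 1)))
  invisible(x)
}

#' @export
summary.polarity_fit <- function(object, ...) {
  tab <- predict(object)
  auc <- tryCatch({
    semb <- encode(object$encoder,
                   object$users$profile_text[match(object$seeds$user_id,
                                                   object$users$user_id)])
    crossval_auc(semb, object$seeds$label, l2 = object$control$l2,
                 rng_seed = object$control$rng_seed)
  }, error = function(e) NA_real_)
  out <- list(n_users = nrow(tab), n_seeds = nrow(object$seeds),
              seed_balance = table(object$seeds$label),
              cv_auc = auc,
              score_quantiles = stats::quantile(tab$score, c(0, .25, .5, .75, 1)),
              training_log = object$training_log)
  class(out) <- "summary.polarity_fit"
  out
}

#' @export
print.summary.polarity_fit <- function(x, ...) {
  cat("Polarity model summary\n")
  cat(sprintf("  users scored: %d | seeds: %d (left %d / right %d)\n",
              x$n_users, x$n_seeds, x$seed_balance["left"], x$seed_balance["right"]))
  if (!is.na(x$cv_auc))
    cat(sprintf("  5-fold cross-validated AUC on seeds: %.3f\n", x$cv_auc))
  cat("  score quantiles:\n")
  print(round(x$score_quantiles, 3))
  invisible(x)
}

#' @export
coef.polarity_fit <- function(object, ...) {
  c(intercept = object$head$intercept,
    stats::setNames(object$head$beta,
                    paste0("emb", seq_along(object$head$beta))))
}

#' Plot a fitted polarity model
#'
#' `which = 1`: per-epoch mean triplet training loss; `which = 2`:
#' histogram of predicted polarity scores.
#'
#' @param x a [polarity_fit()].
#' @param which plots to draw.
#' @param ... passed to base plotting.
#' @export
plot.polarity_fit <- function(x, which = 1:2, ...) {
  if (1 %in% which && !is.null(x$training_log) && nrow(x$training_log)) {
    plot(x$training_log$epoch, x$training_log$mean_loss, type = "b",
         xlab = "epoch", ylab = "mean triplet loss",
         main = "Siamese training loss", ...)
  }
  if (2 %in% which) {
    tab <- predict(x)
    graphics::hist(tab$score, breaks = 30, xlab = "polarity score (0 = left)",
                   main = "Predicted polarity scores", ...)
  }
  invisible(x)
}
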