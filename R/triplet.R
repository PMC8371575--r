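#' Triplet margin loss
#'
#' For an anchor embedding `s_i`, a positive `s_j` (a retweet partner) and
#' a negative `s_k` (a non-neighbour), the loss is
#' `max(||s_i - s_j|| - ||s_i - s_k|| + margin, 0)` with the Euclidean
#' norm.  Zero exactly when the positive sits at least `margin` closer to
#' the anchor than the negative.
#'
#' @param s_i,s_j,s_k numeric vectors of equal dimension.
#' @param margin positive margin (default 1).
#' @return nonnegative scalar.
#' @export
triplet_loss <- function(s_i, s_j, s_k, margin = 1) {
  if (length(s_i) != length(s_j) || length(s_i) != length(s_k))
    stop("embedding dimension mismatch in triplet")
  stopifnot(margin > 0)
  max(sqrt(sum((s_i - s_j)^2)) - sqrt(sum((s_i - s_k)^2)) + margin, 0)
}

# cross pairwise Euclidean distances between rows of A and rows of B
cross_dist <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  D2 <- outer(an, bn, "+") - 2 * A %*% t(B)
  sqrt(pmax(D2, 0))
}

#' Batch triplet loss with one sampled negative per anchor
#'
#' For each positive pair `(i, j)` one negative `k` is drawn uniformly
#' from the node pool excluding `i` itself and all graph neighbours of
#' `i` (the triplet sum ranges over non-edges).  Anchors with an empty
#' eligible pool are skipped with a warning.
#'
#' @param emb numeric embedding matrix with rownames = node ids.
#' @param pairs two-column character matrix of positive pairs (anchor, positive).
#' @param forbidden named list: for each anchor id, the node ids excluded
#'   from negative sampling (its neighbours; the anchor itself is always
#'   excluded).
#' @param pool character vector of candidate negative ids.
#' @param margin triplet margin.
#' @return mean triplet loss over retained anchors (uses the current RNG
#'   stream; seed it for reproducibility).
#' @export
batch_loss_one_neg <- function(emb, pairs, forbidden, pool = rownames(emb),
                               margin = 1) {
  losses <- numeric(0)
  skipped <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    elig <- setdiff(pool, c(i, forbidden[[i]]))
    if (length(elig) == 0L) { skipped <- skipped + 1L; next }
    k <- elig[sample.int(length(elig), 1L)]
    losses <- c(losses, triplet_loss(emb[i, ], emb[j, ], emb[k, ], margin))
  }
  if (skipped > 0L)
    warning(skipped, " anchor(s) had no eligible negative and were skipped")
  if (length(losses) == 0L) return(NA_real_)
  mean(losses)
}

#' Batch triplet loss with in-batch multiple negatives
#'
#' For a batch of positive pairs `[(i1,j1) ... (in,jn)]` the negatives for
#' pair `k` are all other positives' partners `s_jk'`, `k' != k`.  Returns
#' the mean of the `n (n - 1)` triplet losses.
#'
#' @param emb embedding matrix with rownames = node ids.
#' @param pairs two-column character matrix of positive pairs; `n >= 2`.
#' @param margin triplet margin.
#' @return mean triplet loss.
#' @export
batch_loss_mult_neg <- function(emb, pairs, margin = 1) {
  n <- nrow(pairs)
  if (n < 2L) stop("mult-neg batch needs at least 2 positive pairs")
  A <- emb[pairs[, 1], , drop = FALSE]
  P <- emb[pairs[, 2], , drop = FALSE]
  D <- cross_dist(A, P)            # D[k, k'] = ||s_ik - s_jk'||
  pos <- diag(D)
  L <- pmax(pos - D + margin, 0)
  diag(L) <- 0
  sum(L) / (n * (n - 1))
}

# gradient of the mean mult-neg batch loss w.r.t. the anchor and positive
# embedding rows; returns list(dA, dP) matching rows of pairs
mult_neg_grad <- function(A, P, margin = 1) {
  n <- nrow(A)
  D <- cross_dist(A, P)
  pos <- diag(D)
  act <- (pos - D + margin > 0)
  diag(act) <- FALSE
  denom <- n * (n - 1)
  # unit vector anchor -> positive
  dif <- A - P
  posn <- pmax(pos, .Machine$double.eps)
  U <- dif / posn                       # n x d, u_k
  r <- rowSums(act)                     # active negatives per anchor
  Wg <- ifelse(act & D > 0, 1 / D, 0)   # weights for negative terms
  rw <- rowSums(Wg); cw <- colSums(Wg)
  dA <- (r * U - rw * A + Wg %*% P) / denom
  dP <- (-r * U - cw * P + t(Wg) %*% A) / denom
  list(dA = dA, dP = dP)
}

# gradient of mean one-neg loss; K = matrix of negative embeddings per pair
one_neg_grad <- function(A, P, K, margin = 1) {
  n <- nrow(A)
  dp <- sqrt(rowSums((A - P)^2))
  dn <- sqrt(rowSums((A - K)^2))
  act <- dp - dn + margin > 0
  U <- (A - P) / pmax(dp, .Machine$double.eps)
  V <- (A - K) / pmax(dn, .Machine$double.eps)
  s <- as.numeric(act) / n
  list(dA = s * (U - V), dP = -s * U, dK = s * V)
}

#' Train a Siamese profile encoder on the retweet graph
#'
#' Fine-tunes the encoder so users who retweet each other sit close in
#' embedding space: each (undirected, deduplicated) edge of the filtered
#' retweet graph is a positive pair, optimised under the triplet margin
#' objective by minibatch gradient descent on the shared encoder
#' parameters.  Directionality and edge weights are disregarded (weights
#' only served the edge filter); weight-proportional pair sampling is
#' available via `weight_pairs`.
#'
#' @param graph filtered [interaction_graph()]; must have at least one edge.
#' @param users user table supplying `profile_text` for every graph node.
#' @param encoder a trainable `profile_encoder` (see [hash_encoder()]).
#' @param control a [polarity_control()] list: margin, sampling
#'   (`"mult_neg"` or `"one_neg"`), batch_size, epochs, learning_rate,
#'   rng_seed.
#' @param weight_pairs sample pairs proportionally to edge weight
#'   (default FALSE: each edge once per epoch).
#' @return The encoder with updated parameters and a `log` element: a
#'   data.frame of per-epoch mean training loss.  With a fixed
#'   `control$rng_seed` the run is reproducible.
#' @export
train_siamese_encoder <- function(graph, users, encoder,
                                  control = polarity_control(),
                                  weight_pairs = FALSE) {
  if (nrow(graph$edges) == 0L) stop("cannot train on a graph with zero edges")
  if (!is_trainable(encoder)) {
    warning("encoder is not trainable; returned unchanged")
    return(encoder)
  }
  ids <- graph$nodes
  prof <- users$profile_text[match(ids, users$user_id)]
  if (anyNA(prof)) stop("profile text missing for some graph nodes")
  X <- hash_features(prof, encoder$dim_in)
  rownames(X) <- ids
  # undirected dedup of edges
  e <- graph$edges
  key <- ifelse(e$source < e$target, paste(e$source, e$target),
                paste(e$target, e$source))
  first <- !duplicated(key)
  pairs <- cbind(ifelse(e$source < e$target, e$source, e$target)[first],
                 ifelse(e$source < e$target, e$target, e$source)[first])
  wts <- tapply(e$weight, key, sum)[key[first]]
  # neighbour sets over the undirected view (for one-neg exclusion)
  nb <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
  nb <- lapply(nb, unique)
  idx <- stats::setNames(seq_along(ids), ids)
  W <- encoder$W
  log <- data.frame(epoch = integer(), mean_loss = numeric())
  withr::with_seed(control$rng_seed, {
    for (ep in seq_len(control$epochs)) {
      ord <- if (weight_pairs)
        sample.int(nrow(pairs), nrow(pairs), replace = TRUE, prob = wts)
      else sample.int(nrow(pairs))
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      ep_loss <- numeric(0)
      for (b in batches) {
        pa <- pairs[b, , drop = FALSE]
        ia <- idx[pa[, 1]]; ip <- idx[pa[, 2]]
        S <- X %*% W
        A <- S[ia, , drop = FALSE]; P <- S[ip, , drop = FALSE]
        if (control$sampling == "mult_neg" && nrow(pa) >= 2L) {
          D <- cross_dist(A, P); posd <- diag(D)
          Lm <- pmax(posd - D + control$margin, 0); diag(Lm) <- 0
          ep_loss <- c(ep_loss, sum(Lm) / (nrow(pa) * (nrow(pa) - 1)))
          g <- mult_neg_grad(A, P, control$margin)
          dW <- t(X[ia, , drop = FALSE]) %*% g$dA +
            t(X[ip, , drop = FALSE]) %*% g$dP
        } else {
          ik <- vapply(pa[, 1], function(i) {
            elig <- setdiff(ids, c(i, nb[[i]]))
            if (length(elig) == 0L) NA_character_
            else elig[sample.int(length(elig), 1L)]
          }, character(1))
          ok <- !is.na(ik)
          if (!any(ok)) next
          A <- A[ok, , drop = FALSE]; P <- P[ok, , drop = FALSE]
          K <- S[idx[ik[ok]], , drop = FALSE]
          dp <- sqrt(rowSums((A - P)^2)); dn <- sqrt(rowSums((A - K)^2))
          ep_loss <- c(ep_loss, mean(pmax(dp - dn + control$margin, 0)))
          g <- one_neg_grad(A, P, K, control$margin)
          dW <- t(X[ia[ok], , drop = FALSE]) %*% g$dA +
            t(X[ip[ok], , drop = FALSE]) %*% g$dP +
            t(X[idx[ik[ok]], , drop = FALSE]) %*% g$dK
        }
        W <- W - control$learning_rate * dW
      }
      log <- rbind(log, data.frame(epoch = ep, mean_loss = mean(ep_loss)))
    }
  })
  encoder$W <- W
  encoder$log <- log
  encoder
}
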