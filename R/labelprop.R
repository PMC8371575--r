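#' Label-propagation polarity baseline
#'
#' Deterministically propagates seed polarity (left = 0, right = 1) over
#' the undirected view of the retweet graph: each sweep replaces every
#' non-seed score with the edge-weighted mean of its neighbours' scores,
#' seeds staying clamped.  Nodes with no path to any seed cannot be
#' predicted and are flagged.
#'
#' @param graph an [interaction_graph()].
#' @param seeds data.frame `user_id`, `label` (`"left"`/`"right"`).
#' @param max_iter maximum sweeps (default 500).
#' @param tol max absolute score change declaring convergence.
#' @return data.frame `user_id`, `score` (NA when unpredicted),
#'   `predicted` logical; attribute `iterations`.
#' @export
baseline_label_propagation <- function(graph, seeds, max_iter = 500L, tol = 1e-6) {
  seeds <- seeds[seeds$user_id %in% graph$nodes, , drop = FALSE]
  if (nrow(seeds) == 0L) stop("label propagation needs at least one seed in the graph")
  ids <- graph$nodes
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  e <- graph$edges
  # symmetric weighted adjacency
  A <- Matrix::sparseMatrix(i = c(idx[e$source], idx[e$target]),
                            j = c(idx[e$target], idx[e$source]),
                            x = c(e$weight, e$weight), dims = c(n, n))
  deg <- Matrix::rowSums(A)
  seed_idx <- idx[seeds$user_id]
  seed_val <- as.numeric(seeds$label == "right")
  # reachability from seeds over the undirected view
  ig <- igraph::graph_from_adjacency_matrix(A > 0, mode = "undirected")
  comp <- igraph::components(ig)$membership
  reach <- comp %in% unique(comp[seed_idx])
  x <- rep(0.5, n)
  x[seed_idx] <- seed_val
  it <- 0L
  repeat {
    it <- it + 1L
    xn <- as.numeric(A %*% x)
    xn <- ifelse(deg > 0, xn / deg, x)
    xn[seed_idx] <- seed_val
    delta <- max(abs(xn - x))
    x <- xn
    if (delta < tol || it >= max_iter) break
  }
  if (it >= max_iter && delta >= tol)
    warning("label propagation stopped at max_iter with residual ", signif(delta, 3))
  out <- data.frame(user_id = ids, score = ifelse(reach, x, NA_real_),
                    predicted = reach, stringsAsFactors = FALSE)
  attr(out, "iterations") <- it
  out
}
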