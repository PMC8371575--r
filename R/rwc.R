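#' Authoritative nodes per polarity decile
#'
#' The union over deciles of each decile's top-`k` nodes by in-degree in
#' the given graph (ties at rank `k` broken by user id).  Random walks
#' halt on arrival at these nodes: they proxy well-endorsed information
#' sources.
#'
#' @param graph an [interaction_graph()].
#' @param deciles named integer vector `user_id -> decile`.
#' @param k nodes retained per decile (default 1000), capped at the decile
#'   size; a value below 1 is read as a fraction of each decile
#'   (at least one node per decile).
#' @param weighted rank by weighted in-degree instead of unique-neighbour
#'   count (default FALSE).
#' @return character vector of node ids.
#' @export
select_authoritative_nodes <- function(graph, deciles, k = 1000L,
                                       weighted = FALSE) {
  din <- graph_degree(graph, "in", weighted = weighted)
  ids <- intersect(names(deciles), graph$nodes)
  out <- character(0)
  for (d in sort(unique(deciles[ids]))) {
    members <- ids[deciles[ids] == d]
    members <- members[order(-din[members], members)]
    kk <- if (k < 1) max(1L, round(k * length(members))) else k
    out <- c(out, members[seq_len(min(kk, length(members)))])
  }
  sort(unique(out))
}

# one random walk; returns the id of the node where it terminates.
# rules: step uniformly over out-neighbours; end on arrival at a revisited
# node, an authoritative node, or after max_len edges; a node with no
# out-neighbours ends the walk where it stands.  The start node is never
# checked for authority (a walk may begin at an authoritative node).
walk_once <- function(adj, start, is_auth, max_len) {
  cur <- start
  visited <- start
  for (step in seq_len(max_len)) {
    nbrs <- adj[[cur]]
    if (is.null(nbrs) || length(nbrs) == 0L) return(cur)
    nxt <- nbrs[sample.int(length(nbrs), 1L)]
    if (nxt %in% visited) return(nxt)
    if (isTRUE(is_auth[[nxt]])) return(nxt)
    visited <- c(visited, nxt)
    cur <- nxt
  }
  cur
}

#' Sample a single random walk
#'
#' @param graph an [interaction_graph()].
#' @param start starting node id (must be in the graph).
#' @param authoritative character vector of halting node ids.
#' @param max_len maximum number of edges traversed (default 10).
#' @return the id of the termination node.
#' @export
sample_walk <- function(graph, start, authoritative = character(), max_len = 10L) {
  stopifnot(start %in% graph$nodes, max_len >= 1L)
  adj <- out_adjacency(graph)
  is_auth <- stats::setNames(rep(TRUE, length(authoritative)), authoritative)
  walk_once(adj, start, as.list(is_auth), max_len)
}

#' Monte-Carlo random-walk controversy matrix
#'
#' Estimates `RWC(A, B) = Pr(start in decile A | end in decile B)` by
#' launching an equal budget of random walks from each decile (start
#' nodes uniform within the decile) and column-normalising the
#' start-by-end termination counts.  Conditioning on the end decile
#' controls for the uneven placement of high-degree vertices.
#'
#' @param graph an [interaction_graph()].
#' @param deciles named integer vector `user_id -> decile`; every level
#'   must have at least one member present in the graph.
#' @param authoritative halting node ids (see
#'   [select_authoritative_nodes()]).
#' @param walks_per_decile walks launched per starting decile
#'   (default 10000).
#' @param max_len maximum walk length in edges (default 10).
#' @param rng_seed seed for start draws and steps.
#' @return `rwc_matrix`: a K x K matrix (rows = start decile, columns =
#'   end decile) whose columns each sum to 1; columns in which no walk
#'   terminated are `NA` and listed in attribute `undefined_columns`.
#'   Attribute `end_counts` keeps per-column termination totals.
#' @export
estimate_rwc_matrix <- function(graph, deciles, authoritative = character(),
                                walks_per_decile = 10000L, max_len = 10L,
                                rng_seed = 42L) {
  stopifnot(walks_per_decile >= 1L, max_len >= 1L)
  ids <- intersect(names(deciles), graph$nodes)
  lev <- sort(unique(deciles[names(deciles)]))
  members <- lapply(lev, function(d) ids[deciles[ids] == d])
  if (any(lengths(members) == 0L))
    stop("every decile must contain at least one graph node")
  adj <- out_adjacency(graph)
  is_auth <- as.list(stats::setNames(rep(TRUE, length(authoritative)), authoritative))
  dec_of <- deciles
  K <- length(lev)
  N <- matrix(0, K, K, dimnames = list(start = lev, end = lev))
  withr::with_seed(rng_seed, {
    for (a in seq_len(K)) {
      starts <- members[[a]][sample.int(length(members[[a]]),
                                        walks_per_decile, replace = TRUE)]
      for (s in starts) {
        endn <- walk_once(adj, s, is_auth, max_len)
        b <- match(dec_of[[endn]], lev)
        if (!is.na(b)) N[a, b] <- N[a, b] + 1
      }
    }
  })
  finalize_rwc(N)
}

finalize_rwc <- function(N) {
  cs <- colSums(N)
  M <- sweep(N, 2, ifelse(cs > 0, cs, 1), "/")
  M[, cs == 0] <- NA_real_
  structure(M, class = c("rwc_matrix", "matrix"),
            end_counts = cs,
            undefined_columns = colnames(N)[cs == 0])
}

#' @export
print.rwc_matrix <- function(x, digits = 3, ...) {
  cat("Random-walk controversy matrix  Pr(start = row | end = column)\n")
  print(round(unclass(x), digits))
  und <- attr(x, "undefined_columns")
  if (length(und)) cat("undefined columns (no terminations):",
                       paste(und, collapse = ", "), "\n")
  invisible(x)
}

#' Exact random-walk controversy on a small graph
#'
#' Enumerates every self-avoiding trajectory of at most `max_len` edges
#' under the same termination rules as [estimate_rwc_matrix()] and
#' accumulates exact termination probabilities (uniform start within each
#' decile, uniform steps).  Guard: refuses graphs with more than
#' `max_nodes` nodes.
#'
#' @inheritParams estimate_rwc_matrix
#' @param max_nodes enumeration guard (default 12).
#' @return `rwc_matrix` of exact conditional probabilities.
#' @export
exact_rwc_small <- function(graph, deciles, authoritative = character(),
                            max_len = 10L, max_nodes = 12L) {
  if (length(graph$nodes) > max_nodes)
    stop("exact enumeration guard exceeded: ", length(graph$nodes),
         " nodes > ", max_nodes)
  ids <- intersect(names(deciles), graph$nodes)
  lev <- sort(unique(deciles[names(deciles)]))
  members <- lapply(lev, function(d) ids[deciles[ids] == d])
  if (any(lengths(members) == 0L))
    stop("every decile must contain at least one graph node")
  adj <- out_adjacency(graph)
  is_auth <- as.list(stats::setNames(rep(TRUE, length(authoritative)), authoritative))
  K <- length(lev)
  N <- matrix(0, K, K, dimnames = list(start = lev, end = lev))
  end_mass <- function(cur, visited, steps_left, prob, a) {
    nbrs <- adj[[cur]]
    if (is.null(nbrs) || length(nbrs) == 0L || steps_left == 0L) {
      b <- match(deciles[[cur]], lev)
      N[a, b] <<- N[a, b] + prob
      return(invisible())
    }
    p <- prob / length(nbrs)
    for (nxt in nbrs) {
      if (nxt %in% visited || isTRUE(is_auth[[nxt]])) {
        b <- match(deciles[[nxt]], lev)
        N[a, b] <<- N[a, b] + p
      } else if (steps_left == 1L) {
        b <- match(deciles[[nxt]], lev)
        N[a, b] <<- N[a, b] + p
      } else {
        end_mass(nxt, c(visited, nxt), steps_left - 1L, p, a)
      }
    }
  }
  for (a in seq_len(K)) {
    w <- 1 / length(members[[a]])
    for (s in members[[a]]) end_mass(s, s, max_len, w, a)
  }
  finalize_rwc(N)
}

#' Write an RWC matrix as CSV
#' @param m an `rwc_matrix`.
#' @param path output CSV (decile row/column headers).
#' @export
write_rwc_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m))
  df <- cbind(start_decile = rownames(m), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}
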