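#' Weighted directed interaction graph
#'
#' Container for a retweet or mention network: a set of user-id nodes and a
#' weighted directed edge list where `w(u, v)` counts how many times `u`
#' retweeted (or mentioned) `v`.  Self-loops are dropped at construction;
#' they carry no endorsement signal.
#'
#' @param edges data.frame with character columns `source`, `target` and a
#'   positive integer column `weight`.
#' @param nodes character vector of node ids; defaults to the ids appearing
#'   in `edges`.  Extra isolated nodes may be supplied.
#' @param mode `"retweet"` or `"mention"`.
#' @return An object of class `interaction_graph`: a list with elements
#'   `nodes` (character), `edges` (data.frame, canonically ordered by
#'   source then target) and `mode`.
#' @export
interaction_graph <- function(edges, nodes = NULL, mode = c("retweet", "mention")) {
  mode <- match.arg(mode)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(source = character(), target = character(),
                        weight = integer(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("source", "target", "weight") %in% names(edges)))
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.integer(edges$weight)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  if (any(edges$weight < 1L)) stop("edge weights must be >= 1")
  if (is.null(nodes)) nodes <- unique(c(edges$source, edges$target))
  nodes <- sort(unique(as.character(nodes)))
  if (!all(edges$source %in% nodes) || !all(edges$target %in% nodes))
    stop("edge endpoints must all be in `nodes`")
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, mode = mode),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph mode=%s | %d nodes, %d edges, total weight %d>\n",
              x$mode, length(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

n_nodes <- function(graph) length(graph$nodes)
n_edges <- function(graph) nrow(graph$edges)

#' Node degrees of an interaction graph
#'
#' Unique-neighbour (unweighted) or weight-summed degrees, per direction.
#'
#' @param graph an [interaction_graph()].
#' @param direction `"in"` or `"out"`.
#' @param weighted if `TRUE` sum edge weights instead of counting edges.
#' @return Named numeric vector over all nodes (isolated nodes get 0).
#' @export
graph_degree <- function(graph, direction = c("in", "out"), weighted = FALSE) {
  direction <- match.arg(direction)
  key <- if (direction == "in") graph$edges$target else graph$edges$source
  val <- if (weighted) graph$edges$weight else rep(1L, nrow(graph$edges))
  d <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  if (length(key)) {
    tab <- tapply(val, key, sum)
    d[names(tab)] <- tab
  }
  d
}

#' Build a retweet or mention graph from tweet records
#'
#' In retweet mode each retweet record contributes 1 to the weight of the
#' edge (author, retweeted author): `w(u, v)` is the number of retweets of
#' `v` by `u`.  In mention mode every id mentioned in any tweet (retweets,
#' quotes, replies or direct mentions) contributes 1 per tweet to
#' (author, mentioned id).
#'
#' @param records tweet records as returned by [read_tweet_stream()].
#' @param mode `"retweet"` or `"mention"`.
#' @param include_quotes count quote tweets as retweet edges (default
#'   `FALSE`: the retweet network encodes plain-retweet endorsement).
#' @return An [interaction_graph()].  Construction is order-independent:
#'   permuting records yields an identical graph.
#' @export
build_interaction_graph <- function(records, mode = c("retweet", "mention"),
                                    include_quotes = FALSE) {
  mode <- match.arg(mode)
  if (is.null(records) || nrow(records) == 0L)
    return(interaction_graph(NULL, mode = mode))
  if (mode == "retweet") {
    kinds <- if (include_quotes) c("retweet", "quote") else "retweet"
    keep <- records$kind %in% kinds & !is.na(records$retweeted_author_id)
    src <- records$author_id[keep]
    dst <- records$retweeted_author_id[keep]
  } else {
    reps <- lengths(records$mentioned_ids)
    src <- rep(records$author_id, reps)
    dst <- unlist(records$mentioned_ids, use.names = FALSE)
    if (is.null(dst)) dst <- character()
  }
  if (length(src) == 0L) return(interaction_graph(NULL, mode = mode))
  agg <- stats::aggregate(list(weight = rep(1L, length(src))),
                          by = list(source = src, target = dst), FUN = sum)
  interaction_graph(agg, mode = mode)
}

#' Drop low-weight edges
#'
#' Retains only edges with weight at least `w_min` (default 2: a repeated
#' retweet implies stronger endorsement).  Nodes are kept even if they
#' become isolated; degree filtering is a separate pass.
#'
#' @param graph an [interaction_graph()].
#' @param w_min minimum surviving edge weight (>= 1).
#' @return Filtered [interaction_graph()], same node set.
#' @export
filter_edges_by_weight <- function(graph, w_min = 2L) {
  stopifnot(w_min >= 1L)
  edges <- graph$edges[graph$edges$weight >= w_min, , drop = FALSE]
  interaction_graph(edges, nodes = graph$nodes, mode = graph$mode)
}

#' Drop low-degree nodes
#'
#' Removes nodes whose in-degree AND out-degree (unique-neighbour counts,
#' measured on the input graph) are both below `d_min`; a node active in
#' either direction survives.  Single pass: degrees are not recomputed
#' after removal (no k-core iteration).  Edges incident to removed nodes
#' are dropped.
#'
#' @param graph an [interaction_graph()].
#' @param d_min minimum degree (default 10).
#' @return Filtered [interaction_graph()].
#' @export
filter_users_by_degree <- function(graph, d_min = 10L) {
  stopifnot(d_min >= 0L)
  din <- graph_degree(graph, "in")
  dout <- graph_degree(graph, "out")
  keep <- graph$nodes[pmax(din, dout)[graph$nodes] >= d_min]
  edges <- graph$edges[graph$edges$source %in% keep &
                         graph$edges$target %in% keep, , drop = FALSE]
  interaction_graph(edges, nodes = keep, mode = graph$mode)
}

#' Restrict a graph to a node subset
#' @param graph an [interaction_graph()].
#' @param ids character vector of node ids to keep.
#' @return The induced subgraph (isolated retained ids kept as nodes).
#' @export
induce_subgraph <- function(graph, ids) {
  ids <- intersect(graph$nodes, as.character(ids))
  edges <- graph$edges[graph$edges$source %in% ids &
                         graph$edges$target %in% ids, , drop = FALSE]
  interaction_graph(edges, nodes = ids, mode = graph$mode)
}

#' Write / read an edge list as TSV
#'
#' Plain `source<TAB>target<TAB>weight` with a header row.
#'
#' @param graph an [interaction_graph()].
#' @param path output file.
#' @return `write_edge_list` returns `path` invisibly; `read_edge_list`
#'   returns an [interaction_graph()].
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_edge_list
#' @param mode graph mode recorded on read.
#' @export
read_edge_list <- function(path, mode = c("retweet", "mention")) {
  mode <- match.arg(mode)
  edges <- utils::read.table(path, sep = "\t", header = TRUE,
                             colClasses = c("character", "character", "integer"))
  interaction_graph(edges, mode = mode)
}

# out-neighbour adjacency as a named list of character vectors
out_adjacency <- function(graph, weighted = FALSE) {
  adj <- split(graph$edges$target, factor(graph$edges$source, levels = graph$nodes))
  if (!weighted) return(adj)
  wts <- split(graph$edges$weight, factor(graph$edges$source, levels = graph$nodes))
  list(targets = adj, weights = wts)
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}
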