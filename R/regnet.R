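#' Directed regulatory network
#'
#' A `regnet` holds a directed regulator-to-target edge list together with a
#' per-node transcription-factor (TF) flag.  Only nodes flagged as TFs may
#' appear as edge sources; duplicate directed edges are collapsed (with a
#' count kept); self-loops are permitted but counted and reported by
#' `print()`.
#'
#' @param edges data.frame with columns `regulator`, `target` and optionally
#'   `evidence` (carried opaquely).  May have zero rows.
#' @param is_tf named logical vector mapping node id to TF status.  Every
#'   edge endpoint must be named here; additional nodes are kept as isolated
#'   nodes.
#' @return An object of class `regnet`: a list with elements `nodes`
#'   (character), `is_tf` (named logical), `edges` (data.frame with
#'   `regulator`, `target`, `evidence`), and attributes `n_duplicates` and
#'   `n_self_loops`.
#' @examples
#' net <- regnet(data.frame(regulator = "A", target = "B"),
#'               is_tf = c(A = TRUE, B = FALSE))
#' net
#' @export
regnet <- function(edges, is_tf) {
  stopifnot(is.data.frame(edges), is.logical(is_tf))
  if (is.null(names(is_tf)) && length(is_tf) > 0)
    stop("'is_tf' must be a named logical vector")
  if (anyDuplicated(names(is_tf)))
    stop("duplicate node ids in 'is_tf'")
  if (nrow(edges) > 0) {
    if (!all(c("regulator", "target") %in% names(edges)))
      stop("'edges' needs columns 'regulator' and 'target'")
    edges$regulator <- as.character(edges$regulator)
    edges$target <- as.character(edges$target)
  } else {
    edges <- data.frame(regulator = character(), target = character(),
                        evidence = character(), stringsAsFactors = FALSE)
  }
  if (is.null(edges$evidence)) edges$evidence <- rep(NA_character_, nrow(edges))
  edges <- edges[, c("regulator", "target", "evidence")]

  nodes <- names(is_tf)
  ends <- unique(c(edges$regulator, edges$target))
  missing <- setdiff(ends, nodes)
  if (length(missing) > 0)
    stop("edge endpoint(s) not declared as nodes: ",
         paste(missing, collapse = ", "))
  bad_src <- unique(edges$regulator[!is_tf[edges$regulator]])
  if (length(bad_src) > 0)
    stop("edge regulator(s) not flagged as TF: ",
         paste(bad_src, collapse = ", "))

  key <- paste(edges$regulator, edges$target, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  rownames(edges) <- NULL

  net <- structure(
    list(nodes = nodes, is_tf = is_tf, edges = edges),
    class = "regnet",
    n_duplicates = n_dup,
    n_self_loops = sum(edges$regulator == edges$target))
  net
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("regnet: %d nodes (%d TFs), %d directed edges\n",
              length(x$nodes), sum(x$is_tf), nrow(x$edges)))
  if (attr(x, "n_self_loops") > 0)
    cat(sprintf("  self-loops: %d\n", attr(x, "n_self_loops")))
  if (attr(x, "n_duplicates") > 0)
    cat(sprintf("  duplicate edges collapsed on construction: %d\n",
                attr(x, "n_duplicates")))
  invisible(x)
}

#' Number of nodes / edges of a regulatory network
#' @param net a `regnet`
#' @return integer count
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' TF node ids of a network
#' @param net a `regnet`
#' @return character vector of node ids flagged as transcription factors
#' @export
tf_nodes <- function(net) net$nodes[net$is_tf[net$nodes]]

#' Convert a regulatory network to an igraph graph
#'
#' Node attribute `is_tf` is carried over.  Isolated nodes are preserved.
#'
#' @param net a `regnet`
#' @param directed keep edge direction (default) or drop it
#' @return an `igraph` graph
#' @export
as_igraph <- function(net, directed = TRUE) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("regulator", "target")],
    directed = TRUE,
    vertices = data.frame(name = net$nodes, is_tf = unname(net$is_tf[net$nodes])))
  if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
  g
}

#' Restrict a network to a node subset
#'
#' Keeps the given nodes and every edge with both endpoints retained
#' (induced subgraph).
#'
#' @param net a `regnet`
#' @param keep character vector of node ids (silently intersected with the
#'   network's nodes)
#' @return a `regnet`
#' @export
induced_network <- function(net, keep) {
  keep <- intersect(net$nodes, keep)
  e <- net$edges
  e <- e[e$regulator %in% keep & e$target %in% keep, , drop = FALSE]
  regnet(e, net$is_tf[keep])
}

# incident edge count per node: each stored directed edge touching the node
# counts once (a self-loop counts once, not twice)
incident_counts <- function(net) {
  cnt <- stats::setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges) > 0) {
    self <- net$edges$regulator == net$edges$target
    t1 <- table(c(net$edges$regulator, net$edges$target[!self]))
    cnt[names(t1)] <- as.integer(t1)
  }
  cnt
}
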