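#' Two-level neighborhood of a seed gene
#'
#' Collects the seed, its neighbors and their neighbors — two hops on the
#' undirected projection of the network (regulators of the seed must be
#' reachable even though the seed is usually a target, so direction is
#' ignored by default) — and returns the induced subgraph.
#'
#' @param net a [regnet]
#' @param seed seed node id; must be in `net`
#' @param directed expand along edge direction only (non-default)
#' @return a `subnetwork`: a [regnet] with attributes `seed` and
#'   `provenance` (ordered list of construction/pruning steps with node
#'   counts)
#' @export
two_level_neighborhood <- function(net, seed, directed = FALSE) {
  if (!seed %in% net$nodes)
    stop("seed node '", seed, "' not in network")
  mode <- if (directed) "out" else "all"
  g <- as_igraph(net)
  ball <- igraph::ego(g, order = 2, nodes = seed, mode = mode)[[1]]
  keep <- igraph::V(g)$name[as.integer(ball)]
  sub <- induced_network(net, keep)
  attr(sub, "seed") <- seed
  attr(sub, "provenance") <- list(
    list(step = "two_level_neighborhood", n_nodes = length(sub$nodes),
         n_edges = nrow(sub$edges)))
  class(sub) <- c("subnetwork", class(sub))
  sub
}

#' Prune a seed subnetwork
#'
#' Applies the two pruning steps, in order and each exactly once:
#' (1) remove every node — the seed included — whose incident edge count
#' within the subnetwork is below two; (2) remove every remaining
#' non-transcription-factor node except the seed.  Induced edges are
#' recomputed after each step, and the provenance records both step counts.
#' The result may be empty (e.g. a degree-1 seed is removed at step 1).
#'
#' @param sub a `subnetwork` (see [two_level_neighborhood()])
#' @param min_degree incident-edge threshold of step 1, default 2
#' @param iterate iterate step 1 to a fixed point before step 2 (sensitivity
#'   analysis; not the default recipe)
#' @return the pruned `subnetwork`
#' @export
prune_subnetwork <- function(sub, min_degree = 2, iterate = FALSE) {
  seed <- attr(sub, "seed")
  prov <- attr(sub, "provenance")

  step1 <- function(net) {
    cnt <- incident_counts(net)
    induced_network(net, names(cnt)[cnt >= min_degree])
  }
  out <- step1(sub)
  if (iterate) {
    repeat {
      nxt <- step1(out)
      if (length(nxt$nodes) == length(out$nodes)) break
      out <- nxt
    }
  }
  prov <- c(prov, list(list(step = "degree_prune", n_nodes = length(out$nodes),
                            n_edges = nrow(out$edges))))

  keep <- out$nodes[out$is_tf[out$nodes] | out$nodes == seed]
  out <- induced_network(out, keep)
  prov <- c(prov, list(list(step = "tf_prune", n_nodes = length(out$nodes),
                            n_edges = nrow(out$edges))))

  attr(out, "seed") <- seed
  attr(out, "provenance") <- prov
  class(out) <- c("subnetwork", class(out))
  out
}

#' Build the pruned subnetwork of one seed gene
#'
#' Composition of [two_level_neighborhood()] and [prune_subnetwork()].
#'
#' @inheritParams two_level_neighborhood
#' @inheritParams prune_subnetwork
#' @return a pruned `subnetwork`
#' @export
build_seed_subnetwork <- function(net, seed, directed = FALSE,
                                  min_degree = 2, iterate = FALSE) {
  prune_subnetwork(two_level_neighborhood(net, seed, directed = directed),
                   min_degree = min_degree, iterate = iterate)
}

#' Transcription factors shared by all subnetworks
#'
#' Intersects the node sets of the subnetworks, keeps transcription factors
#' only, and (by default) drops the seed genes themselves — the analysis
#' seeks regulators *of* the seeds, so a seed that happens to be a TF is not
#' counted as evidence of shared regulation.
#'
#' @param subs list of at least two `subnetwork` objects
#' @param exclude_seeds drop the seeds from the intersection (default TRUE;
#'   both variants are easy to compare by flipping this)
#' @return list of class `shared_tf_result` with `seeds`, `shared_tfs`
#'   (sorted character) and `k = length(shared_tfs)`
#' @export
shared_tfs <- function(subs, exclude_seeds = TRUE) {
  if (length(subs) < 2)
    stop("need at least 2 subnetworks to intersect")
  seeds <- vapply(subs, function(s) attr(s, "seed"), "")
  common <- Reduce(intersect, lapply(subs, `[[`, "nodes"))
  is_tf <- subs[[1]]$is_tf   # flags agree across subnetworks of one parent
  for (s in subs[-1]) is_tf <- c(is_tf, s$is_tf[setdiff(names(s$is_tf), names(is_tf))])
  tfs <- common[is_tf[common]]
  if (exclude_seeds) tfs <- setdiff(tfs, seeds)
  structure(list(seeds = seeds, shared_tfs = sort(tfs), k = length(tfs)),
            class = "shared_tf_result")
}

#' @export
print.shared_tf_result <- function(x, ...) {
  cat(sprintf("seeds: %s\nshared TFs (k = %d): %s\n",
              paste(x$seeds, collapse = ", "), x$k,
              if (x$k) paste(x$shared_tfs, collapse = ", ") else "(none)"))
  invisible(x)
}
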