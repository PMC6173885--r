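## Independent oracles used to cross-check the package's graph operations.
## Deliberately naive implementations sharing no code with R/.

# undirected (or directed) breadth-first ball of given radius around a seed,
# computed straight from the edge data.frame
oracle_bfs_ball <- function(edges, nodes, seed, radius, directed = FALSE) {
  frontier <- seed
  seen <- seed
  for (i in seq_len(radius)) {
    nxt <- character(0)
    for (v in frontier) {
      out <- edges$target[edges$regulator == v]
      inn <- edges$regulator[edges$target == v]
      nxt <- c(nxt, out, if (!directed) inn)
    }
    frontier <- setdiff(unique(nxt), seen)
    seen <- union(seen, frontier)
    if (length(frontier) == 0) break
  }
  sort(intersect(seen, nodes))
}

# all-pairs shortest directed path lengths by Floyd-Warshall
oracle_fw <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges)))
    d[edges$regulator[i], edges$target[i]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# literal re-statement of the two pruning steps, operating on plain
# data.frames (no regnet code)
oracle_prune <- function(edges, nodes, is_tf, seed, min_degree = 2) {
  induce <- function(e, keep) e[e$regulator %in% keep & e$target %in% keep, , drop = FALSE]
  deg <- function(e, v) sum(e$regulator == v | e$target == v)
  keep1 <- nodes[vapply(nodes, function(v) deg(edges, v) >= min_degree, TRUE)]
  e1 <- induce(edges, keep1)
  keep2 <- keep1[is_tf[keep1] | keep1 == seed]
  e2 <- induce(e1, keep2)
  list(nodes = sort(keep2), edges = e2)
}

# a reproducible random directed TF->target network for property tests
random_regnet <- function(n_tf, n_nontf, n_edges, seed) {
  withr::with_seed(seed, {
    tfs <- sprintf("T%02d", seq_len(n_tf))
    others <- sprintf("g%02d", seq_len(n_nontf))
    nodes <- c(tfs, others)
    e <- unique(data.frame(regulator = sample(tfs, n_edges, replace = TRUE),
                           target = sample(nodes, n_edges, replace = TRUE),
                           stringsAsFactors = FALSE))
    e <- e[e$regulator != e$target, , drop = FALSE]
    regnet(e, stats::setNames(nodes %in% tfs, nodes))
  })
}

# small expression table around explicit per-group, per-replicate values
toy_expr <- function(values, groups, bio, tech = NULL) {
  if (is.null(tech)) tech <- rep(1L, length(groups))
  ids <- sprintf("%s.%s.%s", groups, bio, tech)
  colnames(values) <- ids
  expr_table(values, data.frame(sample_id = ids, group = groups,
                                bio_rep = bio, tech_rep = tech,
                                stringsAsFactors = FALSE))
}
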