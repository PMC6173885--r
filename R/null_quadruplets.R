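## Empirical null for the shared-TF statistic: enumerate (or uniformly
## sample) quadruplets of seed nodes, rebuild the four pruned subnetworks
## for each, and histogram the number of shared transcription factors.

choose_exact <- function(n, k) round(choose(n, k))

## lexicographic unranking of a k-combination of 1..n (1-based rank)
comb_unrank <- function(rank, n, k) {
  out <- integer(k)
  x <- 1L
  r <- rank - 1
  for (i in seq_len(k - 1L)) {
    repeat {
      block <- choose_exact(n - x, k - i)
      if (r < block) break
      r <- r - block
      x <- x + 1L
    }
    out[i] <- x
    x <- x + 1L
  }
  out[k] <- x + r
  out
}

#' Enumerate seed-node quadruplets of a network
#'
#' `any_nodes` lists all `choose(n, 4)` unordered quadruplets;
#' `one_tf_three_nontf` lists every transcription factor combined with every
#' unordered triple of non-TF nodes (the composition of the observed seed
#' set: one TF among three non-TF genes).  Order is deterministic and
#' lexicographic over the sorted node names.
#'
#' @param net a [regnet]
#' @param mode `"any_nodes"` or `"one_tf_three_nontf"`
#' @param limit hard cap on the number of quadruplets materialised (error
#'   above it; use [shared_tf_distribution()] with `max_quadruplets` to
#'   sample instead)
#' @return character matrix, one row per quadruplet, 4 columns
#' @export
enumerate_quadruplets <- function(net, mode = c("any_nodes", "one_tf_three_nontf"),
                                  limit = 2e6) {
  mode <- match.arg(mode)
  nodes <- sort(net$nodes)
  if (mode == "any_nodes") {
    if (length(nodes) < 4) stop("need at least 4 nodes")
    total <- choose_exact(length(nodes), 4)
    if (total > limit) stop("too many quadruplets (", total, "); sample instead")
    m <- t(utils::combn(nodes, 4))
  } else {
    tfs <- sort(tf_nodes(net))
    non <- sort(setdiff(net$nodes, tfs))
    if (length(tfs) < 1 || length(non) < 3)
      stop("need at least 1 TF and 3 non-TF nodes")
    total <- length(tfs) * choose_exact(length(non), 3)
    if (total > limit) stop("too many quadruplets (", total, "); sample instead")
    triples <- t(utils::combn(non, 3))
    m <- cbind(rep(tfs, each = nrow(triples)),
               triples[rep(seq_len(nrow(triples)), length(tfs)), , drop = FALSE])
  }
  dimnames(m) <- NULL
  m
}

## per-node shared-TF "signature": the TF node set of the pruned seed
## subnetwork, memoised so the null and the observed statistic run through
## build_seed_subnetwork exactly once per distinct seed
subnetwork_tf_sets <- function(net, nodes = net$nodes, ...) {
  sets <- vector("list", length(nodes))
  names(sets) <- nodes
  for (v in nodes) {
    sub <- build_seed_subnetwork(net, v, ...)
    sets[[v]] <- sub$nodes[sub$is_tf[sub$nodes]]
  }
  sets
}

count_shared <- function(tf_sets, quad, exclude_seeds = TRUE) {
  common <- Reduce(intersect, tf_sets[quad])
  if (exclude_seeds) common <- setdiff(common, quad)
  length(common)
}

#' Null distribution of shared-TF counts over seed quadruplets
#'
#' For every quadruplet of the chosen mode (or a uniform sample without
#' replacement of `max_quadruplets` of them when the exhaustive count is
#' larger), builds the four pruned seed subnetworks and records the number
#' of transcription factors shared by all four (seeds excluded, as in
#' [shared_tfs()]).  Exhaustive runs are fully deterministic; sampled runs
#' are reproducible from `rng_seed`, and the provenance always records which
#' ran.
#'
#' @param net a [regnet]
#' @param mode quadruplet composition, see [enumerate_quadruplets()]
#' @param max_quadruplets sample size cap; `Inf` forces exhaustion
#' @param rng_seed integer seed used only when sampling
#' @return object of class `null_distribution`: list with `mode`, `counts`
#'   (named vector, shared-TF count k -> number of quadruplets), `total`,
#'   `sampled`, `rng_seed`
#' @export
shared_tf_distribution <- function(net, mode = c("any_nodes", "one_tf_three_nontf"),
                                   max_quadruplets = Inf, rng_seed = 1L) {
  mode <- match.arg(mode)
  nodes <- sort(net$nodes)
  tfs <- sort(tf_nodes(net))
  non <- sort(setdiff(nodes, tfs))
  total_exh <- if (mode == "any_nodes") choose_exact(length(nodes), 4)
               else length(tfs) * choose_exact(length(non), 3)
  if (mode == "any_nodes" && length(nodes) < 4) stop("need at least 4 nodes")
  if (mode == "one_tf_three_nontf" && (length(tfs) < 1 || length(non) < 3))
    stop("need at least 1 TF and 3 non-TF nodes")

  sampled <- total_exh > max_quadruplets
  unrank <- function(r) {
    if (mode == "any_nodes") nodes[comb_unrank(r, length(nodes), 4)]
    else {
      c3 <- choose_exact(length(non), 3)
      ti <- floor((r - 1) / c3) + 1
      c(tfs[ti], non[comb_unrank(r - (ti - 1) * c3, length(non), 3)])
    }
  }
  if (sampled) {
    ranks <- withr::with_seed(rng_seed, {
      got <- numeric(0)
      while (length(got) < max_quadruplets) {
        need <- max_quadruplets - length(got)
        got <- unique(c(got, ceiling(stats::runif(2 * need) * total_exh)))
      }
      got[seq_len(max_quadruplets)]
    })
    quads <- t(vapply(ranks, unrank, character(4)))
  } else {
    quads <- enumerate_quadruplets(net, mode, limit = Inf)
  }

  tf_sets <- subnetwork_tf_sets(net)
  ks <- vapply(seq_len(nrow(quads)), function(i) count_shared(tf_sets, quads[i, ]),
               integer(1))
  tab <- table(ks)
  counts <- stats::setNames(as.numeric(tab), names(tab))
  structure(list(mode = mode, counts = counts, total = length(ks),
                 sampled = sampled,
                 rng_seed = if (sampled) rng_seed else NA_integer_),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("shared-TF null (%s, %s, %d quadruplets)\n", x$mode,
              if (x$sampled) paste0("sampled, seed ", x$rng_seed) else "exhaustive",
              x$total))
  print(x$counts)
  invisible(x)
}

#' Upper-tail probability of a shared-TF count
#'
#' Fraction of enumerated quadruplets whose shared-TF count is at least
#' `k_obs`; by construction `tail_probability(dist, 0) == 1`.
#'
#' @param dist a `null_distribution`
#' @param k_obs observed shared-TF count (non-negative integer)
#' @return numeric in \[0, 1\]
#' @export
tail_probability <- function(dist, k_obs) {
  stopifnot(k_obs >= 0)
  ks <- as.numeric(names(dist$counts))
  sum(dist$counts[ks >= k_obs]) / dist$total
}
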