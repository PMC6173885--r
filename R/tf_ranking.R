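#' Directed shortest-path distances from every TF to the genes of interest
#'
#' Breadth-first shortest directed path length (in edges) from every
#' transcription factor of the network to each target gene.  A TF with no
#' directed path to a target gets `NA` for that target, and its distance sum
#' is defined only when every target is reachable.  A TF that is itself a
#' target contributes a self-distance of 0 by convention, unless
#' `exclude_self_targets` drops such TFs from the table.
#'
#' @param net a [regnet]
#' @param targets character vector of gene-of-interest ids, all in `net`
#' @param exclude_self_targets drop TFs that are themselves targets
#' @return data.frame of class `distance_table`: one row per TF, one column
#'   `d_<target>` per target, plus `sum` (NA when any target is
#'   unreachable); attribute `targets` keeps the target order
#' @export
directed_distances <- function(net, targets, exclude_self_targets = FALSE) {
  missing <- setdiff(targets, net$nodes)
  if (length(missing) > 0)
    stop("target(s) absent from network: ", paste(missing, collapse = ", "))
  tfs <- sort(tf_nodes(net))
  if (exclude_self_targets) tfs <- setdiff(tfs, targets)
  g <- as_igraph(net)
  d <- igraph::distances(g, v = tfs, to = targets, mode = "out")
  d[is.infinite(d)] <- NA
  tab <- data.frame(tf = tfs, stringsAsFactors = FALSE)
  for (t in targets) tab[[paste0("d_", t)]] <- d[, t]
  tab$sum <- ifelse(apply(d, 1, function(r) all(!is.na(r))), rowSums(d), NA)
  rownames(tab) <- NULL
  attr(tab, "targets") <- targets
  class(tab) <- c("distance_table", "data.frame")
  tab
}

#' Rank transcription factors by summed directed distance
#'
#' Only TFs with a directed path to *every* gene of interest (a defined
#' `sum`) enter the ranking, ordered by ascending sum; ties share a rank
#' (minimum-rank convention) and are listed alphabetically for determinism.
#' TFs missing one or more targets are reported separately when
#' `partial_sums = TRUE` (sum over the reachable targets only), never mixed
#' into the ranking.
#'
#' @param dist a `distance_table` from [directed_distances()]
#' @param partial_sums also return the unranked TFs with partial sums
#' @return data.frame with columns `tf`, the `d_*` columns, `sum`, `rank`;
#'   attribute `n_ranked`; when `partial_sums`, attribute `partial` holds
#'   the excluded rows
#' @export
rank_tfs <- function(dist, partial_sums = FALSE) {
  stopifnot(nrow(dist) > 0)
  full <- dist[!is.na(dist$sum), , drop = FALSE]
  if (nrow(full) == 0)
    warning("no TF reaches every gene of interest; empty ranking")
  full <- full[order(full$sum, full$tf), , drop = FALSE]
  full$rank <- if (nrow(full)) rank(full$sum, ties.method = "min") else integer(0)
  rownames(full) <- NULL
  attr(full, "n_ranked") <- nrow(full)
  if (partial_sums) {
    part <- dist[is.na(dist$sum), , drop = FALSE]
    dcols <- grep("^d_", names(part), value = TRUE)
    part$partial_sum <- rowSums(part[, dcols, drop = FALSE], na.rm = TRUE)
    part$n_reached <- rowSums(!is.na(part[, dcols, drop = FALSE]))
    rownames(part) <- NULL
    attr(full, "partial") <- part
  }
  full
}

#' Trace shortest undirected paths from genes of interest to circuit TFs
#'
#' For each (source gene, circuit TF) pair, finds one shortest path on the
#' undirected projection of the network.  When several shortest paths exist,
#' the lexicographically smallest node sequence is returned and the number
#' of alternatives is reported.  Disconnected pairs are recorded as
#' unreachable, not errors.
#'
#' @param net a [regnet]
#' @param sources gene-of-interest ids
#' @param sinks circuit TF ids
#' @return data.frame: `source`, `sink`, `path` (node sequence joined by
#'   `"->"`, NA if unreachable), `length` (edges, NA if unreachable),
#'   `n_intermediate` (= length - 1), `n_shortest` (number of distinct
#'   shortest paths)
#' @export
trace_undirected_paths <- function(net, sources, sinks) {
  missing <- setdiff(c(sources, sinks), net$nodes)
  if (length(missing) > 0)
    stop("node(s) absent from network: ", paste(missing, collapse = ", "))
  g <- as_igraph(net, directed = FALSE)
  rows <- list()
  for (src in sources) for (snk in sinks) {
    if (src == snk) {
      rows[[length(rows) + 1]] <- data.frame(
        source = src, sink = snk, path = src, length = 0L,
        n_intermediate = 0L, n_shortest = 1L, stringsAsFactors = FALSE)
      next
    }
    ap <- suppressWarnings(
      igraph::all_shortest_paths(g, from = src, to = snk)$vpaths)
    if (length(ap) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        source = src, sink = snk, path = NA_character_, length = NA_integer_,
        n_intermediate = NA_integer_, n_shortest = 0L, stringsAsFactors = FALSE)
      next
    }
    seqs <- lapply(ap, function(p) igraph::V(g)$name[as.integer(p)])
    keys <- vapply(seqs, paste, "", collapse = "\r")
    best <- seqs[[order(keys)[1]]]
    rows[[length(rows) + 1]] <- data.frame(
      source = src, sink = snk, path = paste(best, collapse = "->"),
      length = length(best) - 1L,
      n_intermediate = length(best) - 2L,
      n_shortest = length(ap), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
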