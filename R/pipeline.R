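#' Run the full regulatory-circuit pipeline
#'
#' Executes, in order: background-network filtering against expression and
#' differential-expression evidence; pruned subnetwork construction for the
#' seed quadruplet; shared-TF intersection; the quadruplet null
#' distribution(s) and the observed tail probability; directed-distance TF
#' ranking; undirected path tracing from the genes of interest back to the
#' circuit TFs; and a correlation summary of the genes of interest across
#' biological replicates.  Every intermediate is persisted under `out_dir`
#' and the run is deterministic given the inputs and `rng_seed`.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   \describe{
#'     \item{edges, node_attrs}{background network files ([read_network()]),
#'       or `network`, an in-memory [regnet]}
#'     \item{expr_matrix, samples}{expression files ([read_expression()]),
#'       or `expr`, an [expr_table]}
#'     \item{de}{DE table file ([read_de_table()]) or `de_table` object}
#'     \item{comparison}{character(2): (reference group, test group)}
#'     \item{seeds}{the seed quadruplet (>= 2 gene ids)}
#'     \item{targets}{genes of interest for ranking/tracing (default:
#'       `seeds`)}
#'     \item{circuit_tfs}{sinks for undirected path tracing (default: the
#'       shared TFs found)}
#'     \item{null_modes}{subset of `c("any_nodes", "one_tf_three_nontf")`}
#'     \item{max_quadruplets}{sampling cap per mode (default `Inf` =
#'       exhaustive)}
#'     \item{criteria}{arguments for [filter_criteria()]}
#'     \item{rng_seed}{integer, recorded in the report}
#'     \item{out_dir}{output directory (required)}
#'   }
#' @param quiet suppress per-stage progress lines on stderr
#' @return the run report (list), also written to `out_dir/report.json`
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config[["out_dir"]]), !is.null(config[["seeds"]]))
  dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  stage <- "load"
  bg <- if (!is.null(config[["network"]])) config[["network"]]
        else read_network(config[["edges"]], config[["node_attrs"]])
  expr <- if (!is.null(config[["expr"]])) config[["expr"]]
          else read_expression(config[["expr_matrix"]], config[["samples"]])
  de <- if (!is.null(config[["de_table"]])) config[["de_table"]]
        else read_de_table(config[["de"]])
  comparison <- config[["comparison"]] %||% c("KO-N", "KO-NTD")
  seeds <- config[["seeds"]]
  targets <- config[["targets"]] %||% seeds
  null_modes <- config[["null_modes"]] %||% "any_nodes"
  max_q <- config[["max_quadruplets"]] %||% Inf
  rng_seed <- as.integer(config[["rng_seed"]] %||% 1L)
  crit <- do.call(filter_criteria, config[["criteria"]] %||% list())
  say(stage, "background: %d nodes, %d edges", n_nodes(bg), n_edges(bg))

  stage <- "filter"
  flt <- filter_network(bg, expr, de, comparison, crit)
  gen <- flt$network
  write_network(gen, file.path(config[["out_dir"]], "general_edges.tsv"),
                file.path(config[["out_dir"]], "general_nodes.tsv"))
  utils::write.table(flt$report, file.path(config[["out_dir"]], "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say(stage, "general network: %d nodes, %d edges retained of %d",
      n_nodes(gen), n_edges(gen), attr(flt$report, "n_in"))

  stage <- "subnetworks"
  miss <- setdiff(seeds, gen$nodes)
  if (length(miss) > 0)
    stop("pipeline stage 'subnetworks': seed(s) not in general network: ",
         paste(miss, collapse = ", "))
  subs <- lapply(seeds, function(s) build_seed_subnetwork(gen, s))
  for (i in seq_along(seeds))
    write_sif(subs[[i]], file.path(config[["out_dir"]],
                                   paste0("subnetwork_", seeds[i], ".sif")))
  shared <- shared_tfs(subs)
  say(stage, "shared TFs (k = %d): %s", shared$k,
      paste(shared$shared_tfs, collapse = ", "))

  stage <- "null"
  nulls <- list()
  for (mode in null_modes) {
    nd <- shared_tf_distribution(gen, mode, max_quadruplets = max_q,
                                 rng_seed = rng_seed)
    ks <- as.integer(names(nd$counts))
    utils::write.table(
      data.frame(k = ks, count = as.integer(nd$counts),
                 frequency = as.numeric(nd$counts) / nd$total),
      file.path(config[["out_dir"]], paste0("null_", mode, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    nulls[[mode]] <- list(
      total = nd$total, sampled = nd$sampled,
      rng_seed = if (nd$sampled) nd$rng_seed else NULL,
      tail_probability = tail_probability(nd, shared$k))
    say(stage, "%s: %d quadruplets (%s), P(k >= %d) = %.4g", mode, nd$total,
        if (nd$sampled) "sampled" else "exhaustive", shared$k,
        nulls[[mode]]$tail_probability)
  }

  stage <- "ranking"
  dist <- directed_distances(gen, intersect(targets, gen$nodes))
  ranking <- rank_tfs(dist)
  utils::write.table(ranking, file.path(config[["out_dir"]], "ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  say(stage, "%d TFs reach every gene of interest", nrow(ranking))

  stage <- "paths"
  sinks <- config[["circuit_tfs"]] %||% shared$shared_tfs
  paths <- if (length(sinks) > 0)
    trace_undirected_paths(gen, intersect(targets, gen$nodes),
                           intersect(sinks, gen$nodes))
  else NULL
  if (!is.null(paths))
    utils::write.table(paths, file.path(config[["out_dir"]], "paths.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  stage <- "correlations"
  avg <- average_technical_replicates(expr)
  goi <- intersect(targets, rownames(avg$abundance))
  corr <- if (length(goi) >= 2 && ncol(avg$abundance) >= 4)
    correlation_matrix(avg$abundance[goi, , drop = FALSE])
  else NULL
  if (!is.null(corr))
    utils::write.table(corr$entries,
                       file.path(config[["out_dir"]], "correlations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    package_version = as.character(utils::packageVersion("regcircuit")),
    rng_seed = rng_seed,
    config = list(comparison = comparison, seeds = seeds, targets = targets,
                  null_modes = null_modes, max_quadruplets = max_q,
                  criteria = unclass(crit)),
    counts = list(background_nodes = n_nodes(bg),
                  background_edges = n_edges(bg),
                  general_nodes = n_nodes(gen),
                  general_edges = n_edges(gen)),
    shared_tfs = list(seeds = shared$seeds, tfs = shared$shared_tfs,
                      k = shared$k),
    null = nulls,
    ranking = list(n_ranked = nrow(ranking),
                   top = if (nrow(ranking)) ranking$tf[ranking$rank == 1] else character(0),
                   min_sum = if (nrow(ranking)) min(ranking$sum) else NA),
    paths = if (!is.null(paths))
      list(n_pairs = nrow(paths),
           max_intermediates = suppressWarnings(
             max(paths$n_intermediate, na.rm = TRUE)))
    else NULL,
    correlations = if (!is.null(corr))
      list(n_pairs = nrow(corr$entries),
           n_significant = sum(corr$entries$significant, na.rm = TRUE))
    else NULL)
  jsonlite::write_json(report, file.path(config[["out_dir"]], "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
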