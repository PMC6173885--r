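## Synthetic-data generators.  These emulate the statistical structure the
## pipeline assumes: a sparse directed TF->target background network with a
## planted master-regulator circuit, three embryo groups (WT, KO-N, KO-NTD)
## whose divergent group is driven by a latent master activity that raises
## one gene module (lipid-like) and suppresses the other (neural-tube-like),
## lognormal measurement noise, and Ct-scale qPCR data with amplification
## efficiencies near 2.  All generators are pure functions of
## (configuration, seed): the RNG state is scoped with withr::with_seed and
## never leaks.

#' Planted master-regulator circuit
#'
#' The master TF regulates the integrator TFs and, together with them, every
#' module gene.  A latent per-replicate master activity moves the two
#' modules in opposite directions: `module_up` genes scale as
#' `2^(+effect * activity)` (elevated when activity is high, lipid-like) and
#' `module_down` genes as `2^(-effect * activity)` (suppressed when activity
#' is high, neural-tube-like).
#'
#' @param master master TF id
#' @param integrators character vector (>= 1) of integrator TF ids
#' @param module_up,module_down disjoint character vectors of target-gene
#'   ids
#' @param effect absolute per-unit-activity effect size in log2 units
#'   (default 0.8, a planted per-group shift of 1.2 log2 units under the
#'   default activity means)
#' @param noise_sd lognormal measurement noise, sd on the log2 scale
#'   (default 0.2)
#' @return list of class `circuit_spec`
#' @export
circuit_spec <- function(master = "TF01",
                         integrators = c("TF02", "TF03"),
                         module_up = sprintf("UP%02d", 1:10),
                         module_down = sprintf("DN%02d", 1:10),
                         effect = 0.8, noise_sd = 0.2) {
  if (length(intersect(module_up, module_down)) > 0)
    stop("modules must be disjoint")
  if (length(integrators) < 1) stop("need at least one integrator")
  stopifnot(effect >= 0, noise_sd >= 0)
  structure(list(master = master, integrators = integrators,
                 module_up = module_up, module_down = module_down,
                 effect = effect, noise_sd = noise_sd),
            class = "circuit_spec")
}

#' Simulation configuration
#'
#' Defaults mirror the study design: three groups (wild type, phenotypically
#' normal knockout, knockout with neural-tube defect) with three pooled
#' biological replicates each, and per-group latent master-activity means
#' (0, 0, 1.5) so the defect group is the divergent one.  Activity is drawn
#' per biological replicate with unit standard deviation.
#'
#' @param n_tf,n_nontf node budgets (TF and non-TF), circuit included
#' @param mean_out_degree mean number of random targets per TF (Poisson)
#' @param groups named integer vector: biological replicates per group
#' @param activity_mean named numeric vector: latent master-activity mean
#'   per group
#' @param n_tech_rep technical replicates per biological replicate
#' @param rng_seed integer seed recorded in all outputs
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_tf = 30, n_nontf = 120, mean_out_degree = 5,
                       groups = c(WT = 3, `KO-N` = 3, `KO-NTD` = 3),
                       activity_mean = c(WT = 0, `KO-N` = 0, `KO-NTD` = 1.5),
                       n_tech_rep = 2, rng_seed = 1L) {
  stopifnot(n_tf > 0, n_nontf > 0, mean_out_degree > 0, all(groups > 0),
            n_tech_rep >= 1)
  if (!setequal(names(groups), names(activity_mean)))
    stop("'groups' and 'activity_mean' must name the same groups")
  structure(list(n_tf = as.integer(n_tf), n_nontf = as.integer(n_nontf),
                 mean_out_degree = mean_out_degree, groups = groups,
                 activity_mean = activity_mean,
                 n_tech_rep = as.integer(n_tech_rep),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

sim_node_names <- function(cfg, circuit) {
  tf_extra <- cfg$n_tf - (1 + length(circuit$integrators))
  nontf_extra <- cfg$n_nontf - length(c(circuit$module_up, circuit$module_down))
  if (tf_extra < 0 || nontf_extra < 0)
    stop("circuit larger than the configured node budget")
  tfs <- c(circuit$master, circuit$integrators,
           if (tf_extra > 0) sprintf("TFx%03d", seq_len(tf_extra)))
  nontfs <- c(circuit$module_up, circuit$module_down,
              if (nontf_extra > 0) sprintf("Gx%03d", seq_len(nontf_extra)))
  list(tfs = tfs, nontfs = nontfs)
}

#' Generate a background regulatory network with a planted circuit
#'
#' Random directed TF-to-target edges at the configured density plus the
#' guaranteed circuit edges: master -> each integrator, and master and every
#' integrator -> every module gene.  Each module gene therefore lies within
#' two undirected hops of the master, and every pair of module genes shares
#' at least two TF regulators (the integrators).
#'
#' @param cfg a [sim_config]
#' @param circuit a [circuit_spec]
#' @return a [regnet]
#' @export
generate_network <- function(cfg = sim_config(), circuit = circuit_spec()) {
  nm <- sim_node_names(cfg, circuit)
  nodes <- c(nm$tfs, nm$nontfs)
  module <- c(circuit$module_up, circuit$module_down)
  withr::with_seed(cfg$rng_seed, {
    rand <- lapply(nm$tfs, function(tf) {
      k <- stats::rpois(1, cfg$mean_out_degree)
      k <- min(k, length(nodes) - 1)
      if (k == 0) return(NULL)
      data.frame(regulator = tf,
                 target = sample(setdiff(nodes, tf), k),
                 stringsAsFactors = FALSE)
    })
    circuit_edges <- rbind(
      data.frame(regulator = circuit$master, target = circuit$integrators,
                 stringsAsFactors = FALSE),
      expand.grid(regulator = c(circuit$master, circuit$integrators),
                  target = module, stringsAsFactors = FALSE))
    edges <- rbind(circuit_edges, do.call(rbind, rand))
    edges$evidence <- "simulated"
    regnet(edges, stats::setNames(nodes %in% nm$tfs, nodes))
  })
}

sim_gene_direction <- function(genes, circuit) {
  d <- stats::setNames(numeric(length(genes)), genes)
  d[intersect(genes, circuit$module_up)] <- 1
  d[intersect(genes, circuit$module_down)] <- -1
  d
}

#' Simulate group expression and the matching differential-expression calls
#'
#' Per biological replicate a latent master activity is drawn from
#' `Normal(group mean, 1)`; module genes scale by `2^(direction * effect *
#' activity)` around a lognormal baseline, with multiplicative lognormal
#' noise per technical replicate.  The DE table carries the *planted* group
#' log2 fold changes (significance = |log2FC| >= 0.4): the pipeline under
#' test consumes DE calls, it does not make them.
#'
#' @param net a [regnet] from [generate_network()] (node set reused)
#' @param cfg a [sim_config]
#' @param circuit a [circuit_spec]
#' @param comparison groups of the DE table, (reference, test); default
#'   `c("KO-N", "KO-NTD")`
#' @return list with `expr` (an [expr_table]) and `de` (a `de_table`)
#' @export
simulate_expression <- function(net, cfg = sim_config(),
                                circuit = circuit_spec(),
                                comparison = c("KO-N", "KO-NTD")) {
  genes <- net$nodes
  missing <- setdiff(c(circuit$module_up, circuit$module_down,
                       circuit$master, circuit$integrators), genes)
  if (length(missing) > 0)
    stop("circuit gene(s) absent from network: ", paste(missing, collapse = ", "))
  dir <- sim_gene_direction(genes, circuit)
  withr::with_seed(cfg$rng_seed + 1L, {
    base <- stats::setNames(2^stats::runif(length(genes), 3, 8), genes)
    cols <- list(); sheet <- list()
    for (g in names(cfg$groups)) {
      for (r in seq_len(cfg$groups[[g]])) {
        a <- stats::rnorm(1, cfg$activity_mean[[g]], 1)
        for (tr in seq_len(cfg$n_tech_rep)) {
          id <- sprintf("%s.%d.%d", g, r, tr)
          noise <- stats::rnorm(length(genes), 0, circuit$noise_sd)
          cols[[id]] <- base * 2^(dir * circuit$effect * a + noise)
          sheet[[id]] <- data.frame(sample_id = id, group = g, bio_rep = r,
                                    tech_rep = tr, stringsAsFactors = FALSE)
        }
      }
    }
    ab <- do.call(cbind, cols)
    rownames(ab) <- genes
    expr <- expr_table(ab, do.call(rbind, sheet))

    shift <- cfg$activity_mean[[comparison[2]]] - cfg$activity_mean[[comparison[1]]]
    lfc <- unname(dir * circuit$effect * shift)
    de <- data.frame(gene = genes,
                     comparison = paste(comparison, collapse = "_vs_"),
                     log2fc = lfc, q = NA_real_,
                     significant = abs(lfc) >= 0.4,
                     stringsAsFactors = FALSE)
    class(de) <- c("de_table", "data.frame")
    list(expr = expr, de = de)
  })
}

#' Simulate an individual-embryo expression panel
#'
#' The per-embryo analogue of [simulate_expression()] used for correlation
#' analyses: one latent activity per embryo, module genes responding in
#' opposite directions, lognormal noise.  Defaults give 15 embryos (5 per
#' group), matching a three-genotype panel.
#'
#' @param cfg a [sim_config] (group names and activity means reused)
#' @param circuit a [circuit_spec]
#' @param n_per_group embryos per group, default 5
#' @return numeric gene-by-embryo matrix (module genes only), with the
#'   embryo group in the column name
#' @export
simulate_embryo_panel <- function(cfg = sim_config(), circuit = circuit_spec(),
                                  n_per_group = 5) {
  genes <- c(circuit$module_up, circuit$module_down)
  dir <- sim_gene_direction(genes, circuit)
  withr::with_seed(cfg$rng_seed + 2L, {
    base <- stats::setNames(2^stats::runif(length(genes), 3, 8), genes)
    cols <- list()
    for (g in names(cfg$groups)) {
      for (i in seq_len(n_per_group)) {
        a <- stats::rnorm(1, cfg$activity_mean[[g]], 1)
        noise <- stats::rnorm(length(genes), 0, circuit$noise_sd)
        cols[[sprintf("%s.e%d", g, i)]] <- base * 2^(dir * circuit$effect * a + noise)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- genes
    m
  })
}

#' Simulate Ct-scale qPCR measurements
#'
#' Generates cycle-threshold values consistent with the Pfaffl model: the
#' control group sits at a baseline Ct and the treated group is shifted by
#' `-log(ratio) / log(E)` for each gene, so that on noiseless data
#' [pfaffl_ratio()] recovers the true ratio exactly.  The reference gene has
#' a true ratio of 1.
#'
#' @param true_ratios named positive vector of treated/control expression
#'   ratios per target gene
#' @param E named amplification efficiencies for the target genes and the
#'   reference gene
#' @param ref_gene reference gene id (default `"Tbp"`), must be in `E`
#' @param n_per_group samples per group, default 3
#' @param ct_noise_sd Gaussian Ct noise, default 0 (noiseless)
#' @param ct0 baseline cycle threshold, default 25
#' @param rng_seed seed for the noise draws
#' @return data.frame with `sample_id`, `group` (control/treated), `gene`,
#'   `ct`, `E`
#' @export
simulate_qpcr <- function(true_ratios, E, ref_gene = "Tbp", n_per_group = 3,
                          ct_noise_sd = 0, ct0 = 25, rng_seed = 1L) {
  stopifnot(all(true_ratios > 0), all(E > 1))
  if (!ref_gene %in% names(E)) stop("efficiency missing for reference gene")
  genes <- c(names(true_ratios), ref_gene)
  ratios <- c(true_ratios, stats::setNames(1, ref_gene))
  withr::with_seed(rng_seed, {
    rows <- list()
    for (grp in c("control", "treated")) for (i in seq_len(n_per_group)) {
      id <- sprintf("%s.%d", grp, i)
      for (g in genes) {
        ct <- ct0 - if (grp == "treated") log(ratios[[g]]) / log(E[[g]]) else 0
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = id, group = grp, gene = g,
          ct = ct + stats::rnorm(1, 0, ct_noise_sd), E = E[[g]],
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
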