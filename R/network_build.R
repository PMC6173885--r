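#' Filtering criteria for conditioning a background network on expression
#'
#' An edge of the background network is kept only when its regulator is
#' detected in the embryo expression data, its target is called
#' differentially expressed, and the per-replicate absolute log2 fold change
#' of the target reaches `min_abs_log2fc`.
#'
#' @param min_abs_log2fc minimum |log2 fold change| of the target, default
#'   0.4
#' @param detection_threshold abundance strictly above this counts as
#'   detected, default 0 (any positive FPKM)
#' @param replicate_rule how per-biological-replicate decisions (detection
#'   and fold change) combine: `"any"` (default; at least one replicate) or
#'   `"all"` (every replicate)
#' @param require_regulator_de also require the regulator itself to be
#'   differentially expressed (default FALSE: only detection is required of
#'   the regulator)
#' @param pseudocount added to numerator and denominator of the fold change;
#'   default 0 (division by zero then gives an infinite log2fc, which
#'   compares correctly against the threshold)
#' @return a list of class `filter_criteria`
#' @export
filter_criteria <- function(min_abs_log2fc = 0.4, detection_threshold = 0,
                            replicate_rule = c("any", "all"),
                            require_regulator_de = FALSE, pseudocount = 0) {
  replicate_rule <- match.arg(replicate_rule)
  stopifnot(min_abs_log2fc >= 0, pseudocount >= 0)
  structure(list(min_abs_log2fc = min_abs_log2fc,
                 detection_threshold = detection_threshold,
                 replicate_rule = replicate_rule,
                 require_regulator_de = require_regulator_de,
                 pseudocount = pseudocount),
            class = "filter_criteria")
}

#' Average technical replicates into one column per biological replicate
#'
#' Technical replicates sharing a (group, biological replicate) pair are
#' collapsed by arithmetic mean.  The returned table has one sample per
#' biological replicate, named `<group>.<bio_rep>`, with `tech_rep = 1`.
#'
#' @param expr an [expr_table]
#' @return an [expr_table] with one column per biological replicate
#' @export
average_technical_replicates <- function(expr) {
  s <- expr$samples
  key <- paste(s$group, s$bio_rep, sep = ".")
  groups <- split(seq_len(nrow(s)), key)
  if (any(lengths(groups) == 0))
    stop("biological replicate with zero technical replicates")
  ukey <- unique(key)   # keep first-appearance order
  ab <- vapply(ukey, function(k) rowMeans(expr$abundance[, groups[[k]], drop = FALSE]),
               numeric(nrow(expr$abundance)))
  ab <- matrix(ab, nrow = nrow(expr$abundance),
               dimnames = list(rownames(expr$abundance), ukey))
  first <- vapply(ukey, function(k) groups[[k]][1], integer(1))
  samples <- data.frame(sample_id = ukey,
                        group = s$group[first],
                        bio_rep = s$bio_rep[first],
                        tech_rep = 1L,
                        stringsAsFactors = FALSE)
  expr_table(ab, samples)
}

#' Per-biological-replicate log2 fold changes against a reference group
#'
#' For each gene and each biological replicate of `comparison[2]`, computes
#' `log2((abundance + pseudocount) / (mean reference abundance +
#' pseudocount))`, the reference mean being taken over the biological
#' replicates of `comparison[1]`.  Technical replicates are averaged first.
#'
#' @param expr an [expr_table]
#' @param comparison character of length 2: (reference group, per-replicate
#'   group)
#' @param pseudocount non-negative; with 0 a zero reference yields +/-Inf
#' @return data.frame with columns `gene`, `bio_rep`, `log2fc`
#' @export
per_replicate_log2fc <- function(expr, comparison, pseudocount = 0) {
  stopifnot(length(comparison) == 2)
  avg <- average_technical_replicates(expr)
  s <- avg$samples
  if (!all(comparison %in% s$group))
    stop("group(s) absent from expression table: ",
         paste(setdiff(comparison, s$group), collapse = ", "))
  ref_cols <- s$sample_id[s$group == comparison[1]]
  rep_cols <- s$sample_id[s$group == comparison[2]]
  ref_mean <- rowMeans(avg$abundance[, ref_cols, drop = FALSE])
  out <- lapply(rep_cols, function(cl) {
    data.frame(gene = rownames(avg$abundance),
               bio_rep = s$bio_rep[s$sample_id == cl],
               log2fc = log2((avg$abundance[, cl] + pseudocount) /
                               (ref_mean + pseudocount)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Condition a background regulatory network on expression evidence
#'
#' Reproduces the expression filter that turns the experimentally supported
#' background network into the "general network": an edge is retained iff
#' (a) its regulator's abundance exceeds the detection threshold under the
#' replicate rule, (b) its target is flagged significant in the
#' differential-expression table, and (c) the target's per-replicate
#' |log2 fold change| reaches `crit$min_abs_log2fc` under the replicate
#' rule.  Nodes left without any retained incident edge are dropped.  Genes
#' present in the network but absent from the expression table count as not
#' detected (reported, not an error).
#'
#' @param bg background [regnet]
#' @param expr an [expr_table] containing both comparison groups
#' @param de a `de_table` (see [read_de_table()]); only rows of `comparison`
#'   are used
#' @param comparison character of length 2, (reference group, test group);
#'   must match the comparison labelled in `de`
#' @param crit a [filter_criteria]
#' @return list with `network` (the filtered [regnet]) and `report`
#'   (data.frame with per-edge `regulator`, `target`, `retained`,
#'   `first_failure` in \{"", "regulator-not-detected",
#'   "regulator-not-de", "target-not-de", "fold-change"\}, plus attributes
#'   `n_in`, `n_retained`)
#' @export
filter_network <- function(bg, expr, de, comparison,
                           crit = filter_criteria()) {
  stopifnot(inherits(bg, "regnet"), inherits(expr, "expr_table"))
  comp_label <- paste(comparison, collapse = "_vs_")
  de_use <- de[de$comparison == comp_label, , drop = FALSE]
  if (nrow(de_use) == 0 && nrow(de) > 0 && length(unique(de$comparison)) == 1)
    de_use <- de   # single-comparison table with a different label style
  sig_genes <- de_use$gene[de_use$significant]

  avg <- average_technical_replicates(expr)
  s <- avg$samples
  if (!all(comparison %in% s$group))
    stop("comparison group(s) absent from expression table")
  comb <- if (crit$replicate_rule == "all") all else any

  ## detection per gene over the biological replicates of both groups
  det_cols <- s$sample_id[s$group %in% comparison]
  detected <- apply(avg$abundance[, det_cols, drop = FALSE] >
                      crit$detection_threshold, 1, comb)

  lfc <- per_replicate_log2fc(expr, comparison, crit$pseudocount)
  pass_fc <- tapply(abs(lfc$log2fc) >= crit$min_abs_log2fc, lfc$gene, comb)

  gene_detected <- function(g) {
    ifelse(g %in% names(detected), unname(detected[g]), FALSE)
  }
  gene_fc <- function(g) {
    ifelse(g %in% names(pass_fc), unname(pass_fc[g]), FALSE)
  }

  e <- bg$edges
  reg_det <- gene_detected(e$regulator)
  reg_de <- if (crit$require_regulator_de) e$regulator %in% sig_genes else TRUE
  tgt_de <- e$target %in% sig_genes
  tgt_fc <- gene_fc(e$target)
  retained <- reg_det & reg_de & tgt_de & tgt_fc

  first_failure <- rep("", nrow(e))
  first_failure[!reg_det] <- "regulator-not-detected"
  ff <- first_failure == "" & !retained
  if (crit$require_regulator_de) {
    first_failure[ff & !reg_de] <- "regulator-not-de"
    ff <- first_failure == "" & !retained
  }
  first_failure[ff & !tgt_de] <- "target-not-de"
  ff <- first_failure == "" & !retained
  first_failure[ff & !tgt_fc] <- "fold-change"

  kept <- e[retained, , drop = FALSE]
  keep_nodes <- unique(c(kept$regulator, kept$target))
  net <- regnet(kept, bg$is_tf[keep_nodes])

  report <- data.frame(regulator = e$regulator, target = e$target,
                       retained = retained, first_failure = first_failure,
                       stringsAsFactors = FALSE)
  attr(report, "n_in") <- nrow(e)
  attr(report, "n_retained") <- sum(retained)
  list(network = net, report = report)
}
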