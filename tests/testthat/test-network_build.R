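make_filter_fixture <- function() {
  # 6 TFs, 4 target genes, 10 edges; expression over KO-N/KO-NTD x 3 bio reps
  tfs <- sprintf("T%d", 1:6)
  genes <- sprintf("g%d", 1:4)
  edges <- data.frame(
    regulator = c("T1", "T1", "T2", "T2", "T3", "T4", "T5", "T6", "T6", "T3"),
    target    = c("g1", "g2", "g1", "g3", "g2", "g4", "g1", "g3", "g4", "T1"),
    stringsAsFactors = FALSE)
  net <- regnet(edges, stats::setNames(c(tfs, genes) %in% tfs,
                                       c(tfs, genes)))
  groups <- rep(c("KO-N", "KO-NTD"), each = 3)
  bio <- rep(1:3, 2)
  ab <- matrix(10, 10, 6, dimnames = list(c(tfs, genes), NULL))
  ab["T5", ] <- 0                       # never detected
  ab["g1", 4:6] <- 10 * 2^1.0           # strong planted shift
  ab["g3", 4:6] <- 10 * 2^0.05          # shifted, but below threshold
  ab["g4", 4:6] <- 10 * 2^0.6
  ab["T1", 4:6] <- 10 * 2^0.5
  expr <- toy_expr(ab, groups = groups, bio = bio)
  de <- data.frame(
    gene = c("g1", "g2", "g3", "g4", "T1"),
    comparison = "KO-N_vs_KO-NTD",
    log2fc = c(1.0, 0.0, 0.05, 0.6, 0.5),
    significant = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  list(net = net, expr = expr, de = de)
}

test_that("technical replicate averaging is the elementwise mean", {
  expr <- toy_expr(matrix(c(4, 6), 1), groups = c("WT", "WT"),
                   bio = c(1, 1), tech = c(1, 2))
  avg <- average_technical_replicates(expr)
  expect_equal(unname(avg$abundance[1, 1]), 5)

  # single technical replicate: identity
  one <- toy_expr(matrix(3.25, 1), groups = "WT", bio = 1)
  expect_equal(unname(average_technical_replicates(one)$abundance[1, 1]), 3.25)

  # 3 bio reps x 2 tech reps against an independent per-pair mean
  withr::with_seed(5, vals <- matrix(runif(24, 0, 10), 4))
  expr <- toy_expr(vals, groups = rep("WT", 6), bio = rep(1:3, each = 2),
                   tech = rep(1:2, 3))
  avg <- average_technical_replicates(expr)
  for (b in 1:3)
    expect_equal(unname(avg$abundance[, b]),
                 unname((vals[, 2 * b - 1] + vals[, 2 * b]) / 2))
  expect_equal(avg$samples$group, rep("WT", 3))
})

test_that("per-replicate log2 fold change matches the direct formula", {
  # replicate abundance 8 against reference mean 2 -> log2(4) = 2
  vals <- matrix(c(2, 2, 2, 8), 1)
  expr <- toy_expr(vals, groups = c(rep("A", 3), "B"), bio = c(1:3, 1))
  lfc <- per_replicate_log2fc(expr, c("A", "B"))
  expect_equal(lfc$log2fc, 2)

  # equal abundances -> 0
  eq <- toy_expr(matrix(c(5, 5), 1), groups = c("A", "B"), bio = c(1, 1))
  expect_equal(per_replicate_log2fc(eq, c("A", "B"))$log2fc, 0)

  # random table equals elementwise evaluation of the formula
  withr::with_seed(9, vals <- matrix(runif(60, 0.5, 30), 10))
  expr <- toy_expr(vals, groups = rep(c("A", "B"), each = 3),
                   bio = rep(1:3, 2))
  lfc <- per_replicate_log2fc(expr, c("A", "B"), pseudocount = 0.5)
  ref <- rowMeans(vals[, 1:3])
  for (r in 1:3) {
    got <- lfc$log2fc[lfc$bio_rep == r]
    expect_equal(got, unname(log2((vals[, 3 + r] + 0.5) / (ref + 0.5))))
  }

  expect_error(per_replicate_log2fc(expr, c("A", "missing")), "absent")
})

test_that("edge filtering equals a brute-force per-edge re-check", {
  fx <- make_filter_fixture()
  for (rule in c("any", "all")) {
    crit <- filter_criteria(replicate_rule = rule)
    res <- filter_network(fx$net, fx$expr, fx$de, c("KO-N", "KO-NTD"), crit)

    avg <- average_technical_replicates(fx$expr)
    lfc <- per_replicate_log2fc(fx$expr, c("KO-N", "KO-NTD"))
    comb <- if (rule == "all") all else any
    sig <- fx$de$gene[fx$de$significant]
    expected_keep <- vapply(seq_len(n_edges(fx$net)), function(i) {
      reg <- fx$net$edges$regulator[i]; tgt <- fx$net$edges$target[i]
      det <- reg %in% rownames(avg$abundance) &&
        comb(avg$abundance[reg, ] > 0)
      de_ok <- tgt %in% sig
      fc_ok <- tgt %in% lfc$gene &&
        comb(abs(lfc$log2fc[lfc$gene == tgt]) >= 0.4)
      det && de_ok && fc_ok
    }, TRUE)
    expect_equal(res$report$retained, expected_keep)
    expect_setequal(paste(res$network$edges$regulator, res$network$edges$target),
                    paste(fx$net$edges$regulator, fx$net$edges$target)[expected_keep])
  }
})

test_that("filter drop reasons are informative and conserved", {
  fx <- make_filter_fixture()
  res <- filter_network(fx$net, fx$expr, fx$de, c("KO-N", "KO-NTD"))
  rep <- res$report
  # every edge is either retained or carries a first failed criterion
  expect_equal(sum(rep$retained) + sum(rep$first_failure != ""),
               attr(rep, "n_in"))
  # an undetected regulator is reported as such
  expect_true(all(rep$first_failure[rep$regulator == "T5"] ==
                    "regulator-not-detected"))
  # a flat target fails on fold change (g2 is non-significant -> target-not-de)
  expect_equal(rep$first_failure[rep$target == "g2"],
               rep("target-not-de", 2))
  # g3: significant but |log2fc| < 0.4 in every replicate
  expect_equal(unique(rep$first_failure[rep$target == "g3" & !rep$retained]),
               "fold-change")
})

test_that("filtering is monotone in the threshold and idempotent", {
  fx <- make_filter_fixture()
  comparison <- c("KO-N", "KO-NTD")
  prev <- NULL
  for (thr in c(0, 0.4, 0.8, 1.6)) {
    res <- filter_network(fx$net, fx$expr, fx$de, comparison,
                          filter_criteria(min_abs_log2fc = thr))
    keys <- paste(res$network$edges$regulator, res$network$edges$target)
    # always a subgraph of the background
    expect_true(all(keys %in% paste(fx$net$edges$regulator, fx$net$edges$target)))
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  # idempotence: refiltering the general network changes nothing
  crit <- filter_criteria()
  once <- filter_network(fx$net, fx$expr, fx$de, comparison, crit)$network
  twice <- filter_network(once, fx$expr, fx$de, comparison, crit)$network
  expect_equal(sort(paste(twice$edges$regulator, twice$edges$target)),
               sort(paste(once$edges$regulator, once$edges$target)))
  expect_setequal(twice$nodes, once$nodes)
})

test_that("genes absent from the expression table count as not detected", {
  net <- regnet(data.frame(regulator = "T1", target = "g1"),
                c(T1 = TRUE, g1 = FALSE))
  expr <- toy_expr(matrix(c(5, 5, 9, 9), 1, dimnames = list("g1", NULL)),
                   groups = c("A", "A", "B", "B"), bio = c(1, 2, 1, 2))
  de <- data.frame(gene = "g1", comparison = "A_vs_B", log2fc = 0.85,
                   significant = TRUE, stringsAsFactors = FALSE)
  res <- filter_network(net, expr, de, c("A", "B"))
  expect_equal(n_edges(res$network), 0)
  expect_equal(res$report$first_failure, "regulator-not-detected")
})
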