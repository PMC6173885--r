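#' Efficiency-corrected relative expression (Pfaffl)
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with `dCt` the
#' control-minus-treated difference of mean cycle thresholds, so a ratio
#' above 1 means the gene is up in the treated group.  Efficiencies are the
#' per-primer amplification bases (2 for perfect doubling).
#'
#' @param E_target,E_ref amplification efficiencies, in (1, 2.2]
#' @param dCt_target,dCt_ref mean Ct(control) - mean Ct(treated) for the
#'   target and reference gene
#' @return positive ratio
#' @examples
#' pfaffl_ratio(2, 2, 2, 1)        # 2
#' pfaffl_ratio(1.9, 3, 2.0, 1)    # 1.9^3 / 2
#' @export
pfaffl_ratio <- function(E_target, dCt_target, E_ref, dCt_ref) {
  if (any(c(E_target, E_ref) <= 0))
    stop("amplification efficiency must be positive")
  E_target^dCt_target / E_ref^dCt_ref
}

#' Pair-wise fixed reallocation randomisation test
#'
#' Tests a Pfaffl relative-expression ratio against 1 by randomly
#' reallocating whole samples between the two groups.  Each sample's target
#' and reference Ct move together ("fixed" pairing), group sizes are
#' preserved, and the two-sided statistic is the absolute log ratio.  All
#' `choose(n, n_control)` distinct reallocations are enumerated when that
#' count is at most `n_perm`; otherwise `n_perm` random reallocations are
#' drawn and the observed allocation is included in the null.
#'
#' @param ct data.frame with columns `group`, `ct_target`, `ct_ref`, one row
#'   per sample
#' @param groups character of length 2: (control, treated)
#' @param E_target,E_ref amplification efficiencies
#' @param n_perm permutation budget (default 2000)
#' @param rng_seed seed for the sampled branch
#' @return list with `ratio` (observed), `p`, `n_realloc`, `exhaustive`
#' @export
reallocation_test <- function(ct, groups, E_target = 2, E_ref = 2,
                              n_perm = 2000, rng_seed = 1L) {
  stopifnot(all(c("group", "ct_target", "ct_ref") %in% names(ct)),
            length(groups) == 2)
  ct <- ct[ct$group %in% groups, , drop = FALSE]
  n1 <- sum(ct$group == groups[1])
  n2 <- sum(ct$group == groups[2])
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  if (any(is.na(ct$ct_target)) || any(is.na(ct$ct_ref)))
    stop("missing Ct value(s)")
  n <- n1 + n2

  log_ratio <- function(ctrl_idx) {
    trt_idx <- setdiff(seq_len(n), ctrl_idx)
    dct_t <- mean(ct$ct_target[ctrl_idx]) - mean(ct$ct_target[trt_idx])
    dct_r <- mean(ct$ct_ref[ctrl_idx]) - mean(ct$ct_ref[trt_idx])
    dct_t * log(E_target) - dct_r * log(E_ref)
  }
  obs_ctrl <- which(ct$group == groups[1])
  obs <- log_ratio(obs_ctrl)

  n_alloc <- round(choose(n, n1))
  exhaustive <- n_alloc <= n_perm
  if (exhaustive) {
    allocs <- utils::combn(n, n1, simplify = FALSE)
    stats <- vapply(allocs, log_ratio, numeric(1))
    p <- mean(abs(stats) >= abs(obs) - 1e-12)
    n_used <- n_alloc
  } else {
    stats <- withr::with_seed(rng_seed,
      vapply(seq_len(n_perm), function(i) log_ratio(sample.int(n, n1)),
             numeric(1)))
    p <- (1 + sum(abs(stats) >= abs(obs) - 1e-12)) / (n_perm + 1)
    n_used <- n_perm + 1
  }
  list(ratio = exp(obs), p = p, n_realloc = n_used, exhaustive = exhaustive)
}

#' Pearson correlation matrix with Fisher-z confidence intervals
#'
#' Pairwise-complete Pearson correlations across embryos, with 95%
#' confidence intervals computed on the variance-stabilised scale
#' (`atanh(r) +/- 1.96 / sqrt(n - 3)`, back-transformed) assuming Gaussian
#' data; an entry is flagged significant exactly when its CI excludes zero.
#' Zero-variance genes give undefined (NA) entries.
#'
#' @param values numeric gene-by-embryo matrix with row names
#' @param conf confidence level, default 0.95
#' @return list of class `correlation_matrix` with square matrices `r`,
#'   `lo`, `hi`, `n` (pairwise-complete counts), `significant` (logical),
#'   and a tidy data.frame `entries` (one row per unordered pair)
#' @export
correlation_matrix <- function(values, conf = 0.95) {
  stopifnot(is.matrix(values), nrow(values) >= 2)
  if (ncol(values) < 4) stop("need at least 4 embryos")
  genes <- rownames(values)
  x <- t(values)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  npair <- crossprod(!is.na(x))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(pmax(npair - 3, 0))
  lo <- tanh(atanh(pmin(pmax(r, -1), 1)) - z * se)
  hi <- tanh(atanh(pmin(pmax(r, -1), 1)) + z * se)
  diag(lo) <- 1; diag(hi) <- 1
  sig <- (lo > 0 | hi < 0)
  diag(sig) <- TRUE
  sig[is.na(r)] <- NA

  pairs <- which(upper.tri(r), arr.ind = TRUE)
  entries <- data.frame(
    gene1 = genes[pairs[, 1]], gene2 = genes[pairs[, 2]],
    r = r[pairs], n = npair[pairs], lo = lo[pairs], hi = hi[pairs],
    significant = sig[pairs], stringsAsFactors = FALSE)
  structure(list(r = r, lo = lo, hi = hi, n = npair, significant = sig,
                 entries = entries),
            class = "correlation_matrix")
}

#' Grand-mean centering of log-transformed group means
#'
#' Per gene, log-transforms the group means (with a pseudocount) and
#' subtracts the gene's mean log value across groups — the standard heat-map
#' transform.  Rows of the result sum to zero.
#'
#' @param means non-negative gene-by-group matrix of mean abundances
#' @param pseudocount added before the log, default 1
#' @param base log base, default 2
#' @return centered matrix of the same shape
#' @export
grand_mean_center <- function(means, pseudocount = 1, base = 2) {
  stopifnot(is.matrix(means), all(means >= 0))
  lg <- log(means + pseudocount, base = base)
  lg - rowMeans(lg)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a hit list and a functional category, both drawn from a
#' finite background, with the enrichment fold `observed / expected`.
#'
#' @param hits a [gene_set] (or character vector) of e.g. DE genes
#' @param category a [gene_set] (or character vector), the functional class
#' @param background a [gene_set] (or character vector), the universe; hits
#'   and category are intersected with it
#' @return list of class `enrichment_result`: `category`, `overlap`,
#'   `expected`, `fold`, `p`
#' @export
enrichment_test <- function(hits, category, background) {
  as_genes <- function(x) if (inherits(x, "gene_set")) x$genes else unique(as.character(x))
  bg <- as_genes(background)
  if (length(bg) == 0) stop("empty background")
  h <- intersect(as_genes(hits), bg)
  cat_g <- intersect(as_genes(category), bg)
  ov <- length(intersect(h, cat_g))
  expected <- length(h) * length(cat_g) / length(bg)
  p <- stats::phyper(ov - 1, length(cat_g), length(bg) - length(cat_g),
                     length(h), lower.tail = FALSE)
  structure(list(category = if (inherits(category, "gene_set")) category$name else NA_character_,
                 overlap = ov, expected = expected,
                 fold = if (expected > 0) ov / expected else NA_real_, p = p),
            class = "enrichment_result")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over `p.adjust(method = "BH")`, kept as the module surface
#' for enrichment q-values.
#'
#' @param p numeric vector of p-values
#' @return q-values in the input order
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Genotype-proportion test
#'
#' 2x2 tables use Fisher's exact test (two-sided, summing tables no more
#' probable than the observed one); 2xk tables with k > 2 use Pearson's
#' chi-squared test with k - 1 degrees of freedom (no continuity
#' correction).
#'
#' @param tab non-negative integer matrix, 2 rows
#' @return list with `p`, `method`, and `statistic` (chi-squared only)
#' @export
proportion_test <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2, ncol(tab) >= 2, all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table has an all-zero margin")
  if (ncol(tab) == 2) {
    list(p = stats::fisher.test(tab)$p.value, method = "fisher",
         statistic = NA_real_)
  } else {
    ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(p = unname(ch$p.value), method = "chisq",
         statistic = unname(ch$statistic))
  }
}
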