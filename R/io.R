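## Readers/writers for the pipeline's external representations.
## Dialect: UTF-8, tab-separated, '#' comment lines ignored, no quoting.

read_tsv_lines <- function(path) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  list(lines = raw[keep], lineno = which(keep))
}

#' Read a directed regulatory network from an edge list plus node attributes
#'
#' The edge list is tab-separated with columns
#' `regulator_id<TAB>target_id[<TAB>evidence]` and no header.  The node
#' attribute file is tab-separated `node_id<TAB>is_tf` with `is_tf` in
#' \{0, 1\}.  Nodes present in the attribute file but absent from the edge
#' list are kept as isolated nodes; duplicate edges are collapsed with a
#' warning carrying the count.
#'
#' @param edge_list_path path to the edge-list TSV
#' @param node_attr_path path to the node-attribute TSV
#' @return a validated [regnet]
#' @seealso [write_network()], [write_sif()]
#' @export
read_network <- function(edge_list_path, node_attr_path) {
  ed <- read_tsv_lines(edge_list_path)
  parts <- strsplit(ed$lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 2)
  if (length(bad) > 0)
    stop(sprintf("malformed edge line %d in '%s': expected at least 2 fields",
                 ed$lineno[bad[1]], edge_list_path))
  edges <- data.frame(
    regulator = vapply(parts, `[[`, "", 1),
    target = vapply(parts, `[[`, "", 2),
    evidence = vapply(parts, function(p) if (length(p) >= 3) p[[3]] else NA_character_, ""),
    stringsAsFactors = FALSE)

  at <- read_tsv_lines(node_attr_path)
  aparts <- strsplit(at$lines, "\t", fixed = TRUE)
  abad <- which(lengths(aparts) < 2)
  if (length(abad) > 0)
    stop(sprintf("malformed node attribute line %d in '%s'",
                 at$lineno[abad[1]], node_attr_path))
  node_id <- vapply(aparts, `[[`, "", 1)
  flag <- vapply(aparts, `[[`, "", 2)
  if (!all(flag %in% c("0", "1")))
    stop(sprintf("node attribute line %d in '%s': is_tf must be 0 or 1",
                 at$lineno[which(!flag %in% c("0", "1"))[1]], node_attr_path))
  dup_nodes <- duplicated(node_id)
  node_id <- node_id[!dup_nodes]
  flag <- flag[!dup_nodes]
  is_tf <- stats::setNames(flag == "1", node_id)

  ends <- unique(c(edges$regulator, edges$target))
  missing <- setdiff(ends, node_id)
  if (length(missing) > 0)
    stop("edge endpoint(s) missing from node attribute file: ",
         paste(missing, collapse = ", "))

  key <- paste(edges$regulator, edges$target, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0)
    warning(sprintf("%d duplicate edge(s) collapsed while reading '%s'",
                    ndup, edge_list_path))
  regnet(edges, is_tf)
}

#' Write a network as an edge-list TSV plus node-attribute TSV
#'
#' Inverse of [read_network()]; round-trips nodes (including isolated ones),
#' TF flags and edges.
#'
#' @param net a [regnet]
#' @param edge_list_path,node_attr_path output paths
#' @return invisibly, `net`
#' @export
write_network <- function(net, edge_list_path, node_attr_path) {
  ev <- ifelse(is.na(net$edges$evidence), "", paste0("\t", net$edges$evidence))
  writeLines(paste0(net$edges$regulator, "\t", net$edges$target, ev),
             edge_list_path, useBytes = TRUE)
  writeLines(paste0(net$nodes, "\t", as.integer(net$is_tf[net$nodes])),
             node_attr_path, useBytes = TRUE)
  invisible(net)
}

#' Export a network in Cytoscape SIF format
#'
#' One line `regulator<TAB>regulates<TAB>target` per edge.  SIF cannot
#' represent isolated nodes; these are omitted (write the node-attribute
#' sidecar with [write_network()] to preserve them).
#'
#' @param net a [regnet]
#' @param path output path
#' @return invisibly, the number of lines written
#' @export
write_sif <- function(net, path) {
  writeLines(paste(net$edges$regulator, "regulates", net$edges$target,
                   sep = "\t"), path, useBytes = TRUE)
  invisible(nrow(net$edges))
}

#' Read a SIF file back into an edge data.frame
#'
#' @param path SIF path (interaction type ignored)
#' @return data.frame with columns `regulator`, `target`
#' @export
read_sif <- function(path) {
  sf <- read_tsv_lines(path)
  parts <- strsplit(sf$lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop(sprintf("malformed SIF line %d in '%s'", sf$lineno[bad[1]], path))
  data.frame(regulator = vapply(parts, `[[`, "", 1),
             target = vapply(parts, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

#' Expression table: abundance matrix plus sample sheet
#'
#' @param abundance numeric gene-by-sample matrix, non-negative, with row and
#'   column names
#' @param samples data.frame with columns `sample_id`, `group`, `bio_rep`,
#'   `tech_rep`; `sample_id` must match the matrix columns exactly
#' @return an object of class `expr_table` (list with `abundance`, `samples`)
#' @export
expr_table <- function(abundance, samples) {
  stopifnot(is.matrix(abundance), is.numeric(abundance), is.data.frame(samples))
  if (is.null(rownames(abundance)))
    rownames(abundance) <- sprintf("gene%d", seq_len(nrow(abundance)))
  req <- c("sample_id", "group", "bio_rep", "tech_rep")
  if (!all(req %in% names(samples)))
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in sample sheet")
  only_mat <- setdiff(colnames(abundance), samples$sample_id)
  only_sheet <- setdiff(samples$sample_id, colnames(abundance))
  if (length(only_mat) > 0 || length(only_sheet) > 0)
    stop("sample mismatch between matrix and sheet; only in matrix: {",
         paste(only_mat, collapse = ", "), "}; only in sheet: {",
         paste(only_sheet, collapse = ", "), "}")
  if (any(abundance < 0))
    stop("negative abundance value(s) in expression matrix")
  if (any(is.na(samples$group)) || any(!nzchar(samples$group)))
    stop("every sample needs a group")
  if (any(is.na(samples$bio_rep)))
    stop("every sample needs a biological replicate id")
  samples <- samples[match(colnames(abundance), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(abundance = abundance, samples = samples),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("expr_table: %d genes x %d samples, groups: %s\n",
              nrow(x$abundance), ncol(x$abundance),
              paste(unique(x$samples$group), collapse = ", ")))
  invisible(x)
}

#' Read an expression matrix and sample sheet
#'
#' The matrix is a TSV with a header line (first field a gene-id column
#' name, remaining fields sample ids) and genes in rows.  The sample sheet
#' is a CSV with columns `sample_id`, `group`, `bio_rep`, `tech_rep`.
#' Matrix columns and sheet rows must match exactly.
#'
#' @param matrix_path expression matrix TSV
#' @param samplesheet_path sample sheet CSV
#' @return an [expr_table]
#' @export
read_expression <- function(matrix_path, samplesheet_path) {
  mx <- read_tsv_lines(matrix_path)
  if (length(mx$lines) < 1) stop("empty expression matrix: ", matrix_path)
  header <- strsplit(mx$lines[1], "\t", fixed = TRUE)[[1]]
  sample_ids <- header[-1]
  body <- strsplit(mx$lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(body) != length(header))
  if (length(bad) > 0)
    stop(sprintf("matrix line %d in '%s': expected %d fields, got %d",
                 mx$lineno[-1][bad[1]], matrix_path, length(header),
                 lengths(body)[bad[1]]))
  genes <- vapply(body, `[[`, "", 1)
  vals <- vapply(body, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop(sprintf("non-numeric abundance for gene '%s' in '%s'",
                               p[[1]], matrix_path))
    v
  }, numeric(length(sample_ids)))
  ab <- matrix(t(vals), nrow = length(genes),
               dimnames = list(genes, sample_ids))
  samples <- utils::read.csv(samplesheet_path, stringsAsFactors = FALSE,
                             comment.char = "#")
  expr_table(ab, samples)
}

#' Write an expression table to a matrix TSV and sample sheet CSV
#' @param expr an [expr_table]
#' @param matrix_path,samplesheet_path output paths
#' @return invisibly, `expr`
#' @export
write_expression <- function(expr, matrix_path, samplesheet_path) {
  con <- file(matrix_path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr$abundance)), collapse = "\t"), con)
  writeLines(paste(rownames(expr$abundance),
                   apply(expr$abundance, 1, paste, collapse = "\t"),
                   sep = "\t"), con)
  utils::write.csv(expr$samples, samplesheet_path, row.names = FALSE,
                   quote = FALSE)
  invisible(expr)
}

#' Read a differential-expression table
#'
#' TSV with a header; required columns `gene`, `comparison`, `log2fc`,
#' `significant` (`0`/`1` or `TRUE`/`FALSE`), optional `q`.
#'
#' @param path DE table TSV
#' @return data.frame of class `de_table`, one row per (gene, comparison)
#' @export
read_de_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("gene", "comparison", "log2fc", "significant")
  if (!all(req %in% names(tb)))
    stop("DE table needs columns: ", paste(req, collapse = ", "))
  if (!is.numeric(tb$log2fc))
    stop("non-numeric log2fc in '", path, "'")
  if (any(!is.finite(tb$log2fc)))
    stop("non-finite log2fc in '", path, "'")
  tb$significant <- as.logical(as.integer(as.logical(tb$significant)))
  if (anyNA(tb$significant)) stop("unreadable 'significant' flag in '", path, "'")
  if (anyDuplicated(tb[, c("gene", "comparison")]))
    stop("duplicate (gene, comparison) record(s) in '", path, "'")
  class(tb) <- c("de_table", "data.frame")
  tb
}

#' Write a differential-expression table
#' @param de a `de_table` data.frame
#' @param path output TSV path
#' @return invisibly, `de`
#' @export
write_de_table <- function(de, path) {
  out <- as.data.frame(de)
  out$significant <- as.integer(out$significant)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(de)
}

#' Read a gene set from a plain list or GMT file
#'
#' Plain format: one gene id per line; the set is named after `name` or the
#' file stem.  GMT: `name<TAB>description<TAB>gene1<TAB>gene2...`; the first
#' (or `name`-matching) record is returned.  Repeated ids are deduplicated
#' with a warning.
#'
#' @param path input path
#' @param name optional set name (GMT: selects the record)
#' @return list of class `gene_set` with elements `name`, `genes`
#' @export
read_gene_set <- function(path, name = NULL) {
  gmt <- grepl("\\.gmt$", path, ignore.case = TRUE)
  gl <- read_tsv_lines(path)
  if (gmt) {
    recs <- strsplit(gl$lines, "\t", fixed = TRUE)
    bad <- which(lengths(recs) < 3)
    if (length(bad) > 0)
      stop(sprintf("malformed GMT line %d in '%s'", gl$lineno[bad[1]], path))
    nm <- vapply(recs, `[[`, "", 1)
    i <- if (is.null(name)) 1L else match(name, nm)
    if (is.na(i)) stop("gene set '", name, "' not found in '", path, "'")
    genes <- recs[[i]][-(1:2)]
    name <- nm[i]
  } else {
    genes <- trimws(gl$lines)
    if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  }
  ndup <- sum(duplicated(genes))
  if (ndup > 0)
    warning(sprintf("%d repeated gene id(s) deduplicated in set '%s'",
                    ndup, name))
  structure(list(name = name, genes = unique(genes)), class = "gene_set")
}

#' Construct a gene set in memory
#' @param name set name
#' @param genes character vector of member ids (deduplicated)
#' @return a `gene_set`
#' @export
gene_set <- function(name, genes) {
  structure(list(name = name, genes = unique(as.character(genes))),
            class = "gene_set")
}
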