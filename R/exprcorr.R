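#' Spearman correlation profile of a feature against all genes
#'
#' Rank correlation between one patient-level image feature and every gene
#' in an expression matrix, computed as rank-then-Pearson with average-rank
#' tie handling (identical to the direct Spearman definition). Missing
#' expression values are dropped pairwise per gene. At least 10 patients
#' must be shared between the feature vector and the expression columns.
#'
#' @param feature Named numeric vector (names = patient ids) of one
#'   patient-level feature.
#' @param expression Genes x patients numeric matrix with patient id
#'   colnames.
#' @return data.frame of class `correlation_profile` with columns gene,
#'   rho, n (patients used).
#' @export
spearman_profile <- function(feature, expression) {
  expression <- as.matrix(expression)
  if (is.null(names(feature)) || is.null(colnames(expression)))
    stop("feature names and expression colnames (patient ids) are required")
  shared <- intersect(names(feature), colnames(expression))
  if (length(shared) < 10L)
    stop("fewer than 10 shared patients between feature and expression")
  f <- feature[shared]
  e <- expression[, shared, drop = FALSE]
  rf <- rank(f)
  complete <- !apply(is.na(e), 1, any)
  rho <- rep(NA_real_, nrow(e))
  nn <- rep(length(shared), nrow(e))
  if (any(complete)) {
    re <- t(apply(e[complete, , drop = FALSE], 1, rank))
    rho[complete] <- as.numeric(stats::cor(rf, t(re)))
  }
  for (i in which(!complete)) {
    ok <- !is.na(e[i, ])
    nn[i] <- sum(ok)
    if (nn[i] >= 3L)
      rho[i] <- stats::cor(rank(f[ok]), rank(e[i, ok]))
  }
  structure(data.frame(gene = rownames(e) %||% seq_len(nrow(e)),
                       rho = rho, n = nn, row.names = NULL),
            class = c("correlation_profile", "data.frame"))
}

#' Select the top correlated genes for a feature
#'
#' Genes with `|rho| >= threshold` (or strictly greater with
#' `strict = TRUE`), ranked by `|rho|` descending (ties broken
#' alphabetically by gene id) and truncated at `cap`. If fewer than
#' `min_genes` qualify, the set is flagged `skip_enrichment = TRUE`:
#' enrichment on one or two genes is meaningless and is skipped downstream.
#'
#' @param profile A `correlation_profile` from [spearman_profile()].
#' @param threshold Absolute-correlation cutoff (default 0.3).
#' @param cap Maximum number of genes returned (default 100).
#' @param min_genes Minimum qualifying genes for enrichment (default 10).
#' @param strict Use `|rho| > threshold` instead of `>=`.
#' @return data.frame of gene, rho with attribute `skip_enrichment`.
#' @export
select_top_genes <- function(profile, threshold = 0.3, cap = 100L,
                             min_genes = 10L, strict = FALSE) {
  ok <- !is.na(profile$rho) &
    (if (strict) abs(profile$rho) > threshold else abs(profile$rho) >= threshold)
  sel <- profile[ok, c("gene", "rho")]
  sel <- sel[order(-abs(sel$rho), sel$gene), , drop = FALSE]
  if (nrow(sel) > cap) sel <- sel[seq_len(cap), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "skip_enrichment") <- nrow(sel) < min_genes
  sel
}

#' Hypergeometric gene-set over-representation
#'
#' One-sided hypergeometric test of over-representation of a query gene
#' set in each collection set, against a stated gene universe (by default
#' the sampling frame should be all genes in the expression matrix). Sets
#' are intersected with the universe before testing; p-values are
#' BH-adjusted across sets.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector: the background gene list.
#' @return data.frame of class `enrichment_table`: set, overlap, set_size,
#'   query_size, universe_size, p, q, sorted by p.
#' @export
hypergeometric_enrichment <- function(query, collection, universe) {
  query <- unique(query); universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  if (length(query) == 0L) stop("empty query gene set")
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe")
  if (is.null(names(collection))) stop("collection sets must be named")
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(query, set))
    # P(overlap >= k) drawing |query| genes from the universe
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       length(query), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               query_size = length(query),
               universe_size = length(universe), p = min(max(p, 0), 1))
  })
  out <- do.call(rbind, rows)
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$q <- benjamini_hochberg(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Read and write GMT gene-set collections
#'
#' GMT is the standard tab-separated gene-set format: one set per line as
#' `name <tab> description <tab> gene1 <tab> gene2 ...`. Reading delegates
#' to [fgsea::gmtPathways()] when available and falls back to a direct
#' parse otherwise.
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @return `read_gmt` returns a named list of gene vectors; `write_gmt`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) x[-(1:2)]),
                  vapply(parts, `[`, character(1), 1))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  desc <- descriptions %||% rep("na", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], desc[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Correlate prognostic features with expression and run enrichment
#'
#' For each requested feature: Spearman profile against the expression
#' matrix, top-gene selection, and (unless skipped for too few qualifying
#' genes) hypergeometric enrichment against the supplied collection with
#' the expression matrix's genes as universe.
#'
#' @param features Patients x features matrix (rownames = patient ids).
#' @param expression Genes x patients matrix.
#' @param feature_set Character vector of feature names to analyse.
#' @param collection Named list of gene sets, or `NULL` to skip enrichment.
#' @param threshold,cap,min_genes Passed to [select_top_genes()].
#' @return Named list per feature: `profile`, `top_genes`, `enrichment`
#'   (`NULL` when skipped).
#' @export
run_expression_correlation <- function(features, expression, feature_set,
                                       collection = NULL, threshold = 0.3,
                                       cap = 100L, min_genes = 10L) {
  stopifnot(all(feature_set %in% colnames(features)))
  out <- lapply(feature_set, function(f) {
    prof <- spearman_profile(stats::setNames(features[, f],
                                             rownames(features)), expression)
    top <- select_top_genes(prof, threshold = threshold, cap = cap,
                            min_genes = min_genes)
    enr <- NULL
    if (!is.null(collection) && !attr(top, "skip_enrichment") &&
        nrow(top) > 0)
      enr <- hypergeometric_enrichment(top$gene, collection,
                                       universe = prof$gene)
    list(profile = prof, top_genes = top, enrichment = enr)
  })
  stats::setNames(out, feature_set)
}
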