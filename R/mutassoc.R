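#' Select frequently mutated genes
#'
#' Genes whose non-silent mutation fraction is strictly greater than the
#' threshold (default "more than 15%" of patients), sorted by descending
#' frequency.
#'
#' @param mutations Patients x genes binary matrix (1 = non-silent
#'   mutation, 0 = wild type), with gene column names.
#' @param threshold Mutation-fraction cutoff (strict inequality).
#' @return data.frame with columns `gene` and `frequency`, sorted by
#'   descending frequency.
#' @export
select_frequent_genes <- function(mutations, threshold = 0.15) {
  mutations <- as.matrix(mutations)
  if (!all(mutations %in% c(0, 1)))
    stop("mutation matrix must be binary (0 = wild type, 1 = mutated)")
  freq <- colMeans(mutations)
  keep <- freq > threshold
  out <- data.frame(gene = colnames(mutations)[keep],
                    frequency = unname(freq[keep]))
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test comparing two independent samples. The U statistic is
#' reported for group A (`U = sum of A's ranks - nA(nA+1)/2`, average ranks
#' for ties). The p-value is exact (from the null U distribution) when
#' `nA + nB <= exact_limit` and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' Two identical constant samples have zero rank variance and return p = 1.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Maximum combined sample size for the exact p-value.
#' @return List with `U` (statistic for group `a`) and `p` (two-sided).
#' @export
mann_whitney_two_sided <- function(a, b, exact_limit = 12L) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na == 0L || nb == 0L) stop("both groups must be non-empty")
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && (na + nb) <= exact_limit) {
    p <- if (u < na * nb / 2) 2 * stats::pwilcox(u, na, nb)
         else 2 * stats::pwilcox(u - 1, na, nb, lower.tail = FALSE)
    p <- min(p, 1)
  } else {
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties) / ((na + nb) * (na + nb - 1))
    sigma2 <- (na * nb / 12) * ((na + nb + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = u, p = 1))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(2 * stats::pnorm(-abs(z)), 1)
  }
  list(U = u, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' mapped back to input order. Delegates to [stats::p.adjust()] after
#' validating the input range.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Mutation-morphology association testing
#'
#' For every frequently mutated gene ([select_frequent_genes()]) and every
#' patient-level image feature, compares the feature distribution between
#' mutated and wild-type patients with a two-sided Mann-Whitney U test,
#' reports the fold change (ratio of the mutated-group median to the
#' wild-type median), and adjusts p-values by Benjamini-Hochberg FDR.
#' By default the FDR family is all gene x feature tests jointly;
#' `fdr_family = "per_gene"` adjusts within each gene instead. Genes with
#' fewer than 2 patients in either group are flagged untestable and
#' excluded from the FDR family. A wild-type median of 0 gives a missing
#' fold change rather than infinity.
#'
#' @param features Patients x features numeric matrix (rownames = patient
#'   ids).
#' @param mutations Patients x genes binary matrix (rownames = patient
#'   ids; rows are aligned to `features` by id).
#' @param threshold Mutation-frequency cutoff (strict).
#' @param alpha Significance level on q-values.
#' @param fdr_family `"global"` (all tests jointly) or `"per_gene"`.
#' @return data.frame of class `association_table` with columns gene,
#'   feature, U, p, q, fold_change, significant, untestable.
#' @export
run_association <- function(features, mutations, threshold = 0.15,
                            alpha = 0.05, fdr_family = c("global", "per_gene")) {
  fdr_family <- match.arg(fdr_family)
  features <- as.matrix(features)
  mutations <- as.matrix(mutations)
  if (!is.null(rownames(features)) && !is.null(rownames(mutations))) {
    common <- intersect(rownames(features), rownames(mutations))
    if (length(common) < 4L) stop("too few shared patient ids")
    features <- features[common, , drop = FALSE]
    mutations <- mutations[common, , drop = FALSE]
  } else if (nrow(features) != nrow(mutations)) {
    stop("feature and mutation tables have different patient counts ",
         "and no shared rownames to align by")
  }
  genes <- select_frequent_genes(mutations, threshold)$gene
  if (length(genes) == 0L)
    return(structure(data.frame(gene = character(), feature = character(),
                                U = numeric(), p = numeric(), q = numeric(),
                                fold_change = numeric(),
                                significant = logical(),
                                untestable = logical()),
                     class = c("association_table", "data.frame")))
  res <- do.call(rbind, lapply(genes, function(g) {
    mut <- mutations[, g] == 1
    untestable <- sum(mut) < 2L || sum(!mut) < 2L
    rows <- lapply(colnames(features), function(f) {
      x <- features[mut, f]; y <- features[!mut, f]
      if (untestable)
        return(data.frame(gene = g, feature = f, U = NA_real_, p = NA_real_,
                          fold_change = NA_real_, untestable = TRUE))
      mw <- mann_whitney_two_sided(x, y)
      med_wt <- stats::median(y)
      fc <- if (isTRUE(med_wt == 0)) NA_real_ else stats::median(x) / med_wt
      data.frame(gene = g, feature = f, U = mw$U, p = mw$p,
                 fold_change = fc, untestable = FALSE)
    })
    do.call(rbind, rows)
  }))
  res$q <- NA_real_
  ok <- !res$untestable
  if (any(ok)) {
    if (fdr_family == "global") {
      res$q[ok] <- benjamini_hochberg(res$p[ok])
    } else {
      for (g in unique(res$gene[ok])) {
        sel <- ok & res$gene == g
        res$q[sel] <- benjamini_hochberg(res$p[sel])
      }
    }
  }
  res$significant <- !is.na(res$q) & res$q < alpha
  res <- res[, c("gene", "feature", "U", "p", "q", "fold_change",
                 "significant", "untestable")]
  class(res) <- c("association_table", "data.frame")
  res
}
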