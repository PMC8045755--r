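#' Canonical cell-level and patient-level feature names
#'
#' Ten cell-level features are measured per nucleus: `area`, `major`,
#' `minor`, `ratio`, `rMean`, `gMean`, `bMean`, `distMean`, `distMax`,
#' `distMin`. Each is summarized per patient into 15 values — the ten
#' histogram-bin proportions `F_bin1`..`F_bin10` followed by `F_mean`,
#' `F_std`, `F_skewness`, `F_kurtosis`, `F_entropy` — giving the canonical
#' 150-dimensional patient feature vector.
#'
#' @return `cell_feature_names()` returns the 10 cell-level names;
#'   `feature_names()` the ordered 150 patient-level names.
#' @export
cell_feature_names <- function() {
  c("area", "major", "minor", "ratio", "rMean", "gMean", "bMean",
    "distMean", "distMax", "distMin")
}

#' @rdname cell_feature_names
#' @export
feature_names <- function() {
  unlist(lapply(cell_feature_names(), function(f)
    paste0(f, "_", c(paste0("bin", 1:10),
                     "mean", "std", "skewness", "kurtosis", "entropy"))),
    use.names = FALSE)
}

#' Fit cohort-shared histogram bins
#'
#' Derives, for every cell-level feature, the 11 bin edges (10 bins) that
#' all patients share, so that histogram features are comparable across the
#' cohort. Bins are equal-width over the \[P1, P99\] nearest-rank percentile
#' range of the pooled reference values; the percentile clamp protects the
#' bin width from extreme outliers. Out-of-range cell values are later
#' clamped into the first/last bin.
#'
#' @param pooled Named list (or data.frame) with one numeric vector per
#'   cell-level feature, pooled over all reference-cohort cells. At least
#'   100 non-missing values per feature are required.
#' @param n_bins Number of bins (default 10).
#' @return An object of class `bin_scheme`: a named list of numeric
#'   length-`n_bins + 1` strictly increasing edge vectors.
#' @export
fit_bin_scheme <- function(pooled, n_bins = 10L) {
  if (is.data.frame(pooled)) pooled <- as.list(pooled)
  stopifnot(is.list(pooled), length(names(pooled)) == length(pooled))
  edges <- lapply(names(pooled), function(f) {
    x <- pooled[[f]]
    x <- x[!is.na(x)]
    if (length(x) < 100L)
      stop("need >= 100 pooled values for feature '", f, "'")
    lo <- nearest_rank_percentile(x, 1)
    hi <- nearest_rank_percentile(x, 99)
    if (hi <= lo) stop("degenerate feature range for '", f, "'")
    seq(lo, hi, length.out = n_bins + 1L)
  })
  names(edges) <- names(pooled)
  structure(edges, class = "bin_scheme")
}

#' Serialize / restore a bin scheme
#'
#' The scheme is stored as JSON with full double precision so that a
#' reloaded scheme is bit-identical and downstream cohorts bin their cells
#' against exactly the same edges.
#'
#' @param scheme A `bin_scheme`.
#' @param path JSON file path.
#' @return `read_bin_scheme` returns the `bin_scheme`; the writer returns
#'   `path` invisibly.
#' @export
write_bin_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "bin_scheme"))
  # edges stored as %.17g strings: plain JSON numbers lose the last bits
  jsonlite::write_json(lapply(unclass(scheme), sprintf, fmt = "%.17g"),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_bin_scheme
#' @export
read_bin_scheme <- function(path) {
  edges <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(lapply(edges, as.numeric), class = "bin_scheme")
}

# histogram proportions with out-of-range clamping into the first/last bin
.bin_proportions <- function(x, edges) {
  n_bins <- length(edges) - 1L
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tabulate(idx, nbins = n_bins) / length(x)
}

#' Aggregate one patient's cells into the 150-feature vector
#'
#' Pools the cell tables of all of a patient's slides (treated as one large
#' slide) and summarizes each cell-level feature into ten histogram-bin
#' proportions plus five distribution statistics. Histograms use the shared
#' [fit_bin_scheme()] edges; values below the first or above the last edge
#' count toward the first/last bin. The mean, standard deviation (population
#' form), skewness (g1), kurtosis (non-excess m4/m2^2) and Shannon entropy
#' of the bin proportions (natural log) are computed on the raw, unbinned
#' values. Nuclei with missing distance features (isolated nodes) are
#' excluded from the distance-feature summaries only.
#'
#' @param cells A data.frame of per-nucleus features (one row per cell,
#'   containing the 10 [cell_feature_names()] columns), or a list of such
#'   data.frames (one per slide) which are pooled.
#' @param scheme A `bin_scheme` fitted on the reference cohort.
#' @return Named numeric vector of length 150 in [feature_names()] order.
#' @export
aggregate_patient <- function(cells, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (is.data.frame(cells)) cells <- list(cells)
  cells <- do.call(rbind, lapply(cells, function(d)
    d[, cell_feature_names(), drop = FALSE]))
  if (is.null(cells) || nrow(cells) == 0L) stop("empty patient: no nuclei")
  out <- numeric(0)
  for (f in cell_feature_names()) {
    x <- cells[[f]]
    x <- x[!is.na(x)]
    if (length(x) == 0L) {
      vals <- rep(NA_real_, 15L)
    } else {
      p <- .bin_proportions(x, scheme[[f]])
      st <- moment_stats(x)
      vals <- c(p, st["mean"], st["std"], st["skewness"], st["kurtosis"],
                shannon_entropy(p))
    }
    out <- c(out, vals)
  }
  names(out) <- feature_names()
  out
}

#' Aggregate a whole cohort of patients
#'
#' @param cell_tables Named list: one entry per patient, each a data.frame
#'   (or list of data.frames, one per slide) of per-nucleus features.
#' @param scheme Optional `bin_scheme`; when `NULL`, a scheme is fitted on
#'   the pooled cells of this cohort (which then acts as the reference
#'   cohort).
#' @return List with `features` (patients x 150 matrix, rownames = patient
#'   ids) and `scheme` (the `bin_scheme` used).
#' @export
aggregate_cohort <- function(cell_tables, scheme = NULL) {
  stopifnot(is.list(cell_tables), !is.null(names(cell_tables)))
  flatten <- lapply(cell_tables, function(p) {
    if (is.data.frame(p)) p else do.call(rbind, p)
  })
  if (is.null(scheme)) {
    pooled <- do.call(rbind, lapply(flatten, function(d)
      d[, cell_feature_names(), drop = FALSE]))
    scheme <- fit_bin_scheme(lapply(pooled, function(x) x[!is.na(x)]))
  }
  mat <- t(vapply(cell_tables, aggregate_patient,
                  numeric(150), scheme = scheme))
  rownames(mat) <- names(cell_tables)
  list(features = mat, scheme = scheme)
}
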