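#' Nearest-rank percentile
#'
#' The nearest-rank definition: the p-th percentile of `x` is the value at
#' sorted position `ceiling(p/100 * n)`. Unlike interpolating definitions
#' this always returns an observed value, which makes percentile-based
#' filters exact on small samples.
#'
#' @param x Numeric vector (NAs removed).
#' @param p Percentile in (0, 100].
#' @return A single observed value of `x`.
#' @export
nearest_rank_percentile <- function(x, p) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) stop("no non-missing values")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 100)
    stop("percentile must be in (0, 100]")
  sort(x)[max(1L, ceiling(p / 100 * length(x)))]
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so generators never perturb the global stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Population moments used for the patient-level distribution statistics.
# std divides by n; skewness is g1 = m3 / m2^1.5; kurtosis is m4 / m2^2
# (non-excess, so a normal distribution gives 3).
moment_stats <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(c(mean = NA_real_, std = NA_real_,
                        skewness = NA_real_, kurtosis = NA_real_))
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  if (m2 == 0) return(c(mean = m, std = 0, skewness = 0, kurtosis = 0))
  c(mean = m, std = sqrt(m2),
    skewness = mean(d^3) / m2^1.5, kurtosis = mean(d^4) / m2^2)
}

# Shannon entropy of a proportion vector, natural log, 0 * log(0) == 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}
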