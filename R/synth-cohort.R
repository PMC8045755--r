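#' Specification for a synthetic patient cohort
#'
#' Defines a cohort whose patient-level image features, somatic-mutation
#' labels, survival outcomes, and gene-expression profiles follow the
#' statistical structure the analysis pipeline assumes, with all planted
#' effects recorded as ground truth.
#'
#' Features are drawn i.i.d. Gaussian per patient for each of the 150
#' canonical names (arbitrary units; mean 10, SD 2). Mutation labels are
#' Bernoulli per gene; for mutated patients the affected feature is shifted
#' by `effect` pooled standard deviations. Survival times (months) come
#' from an exponential proportional-hazards model
#' `h(t) = baseline_hazard * exp(sum(beta * z))` on the z-scored features,
#' with independent exponential censoring. The default hazard and censoring
#' rates give roughly 35-40% observed deaths and a median follow-up near
#' one year, matching a typical gastric-adenocarcinoma cohort.
#'
#' @param n_patients Number of patients (>= 2).
#' @param mutation_genes `NULL` or a data.frame with columns `gene`,
#'   `frequency` (in (0,1)), `feature` (one of [feature_names()]), `effect`
#'   (shift in pooled-SD units).
#' @param cox_betas `NULL` or a named numeric vector of planted log-hazard
#'   coefficients on z-scored features.
#' @param baseline_hazard Baseline event rate (1/month).
#' @param censoring_rate Independent censoring rate (1/month); 0 disables
#'   censoring.
#' @param expression_genes `NULL` or a data.frame with columns `gene`,
#'   `feature`, `rho` (target Spearman correlation in \[-1, 1\]).
#' @param n_background_genes Number of undriven noise genes in the
#'   expression matrix.
#' @param seed Integer seed; identical specs are bit-reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 200L, mutation_genes = NULL,
                        cox_betas = NULL, baseline_hazard = 0.02,
                        censoring_rate = 0.035, expression_genes = NULL,
                        n_background_genes = 200L, seed = 1L) {
  n_patients <- stopifnot_scalar_count(n_patients, "n_patients", 2L)
  canon <- feature_names()
  check_feats <- function(x, what) {
    bad <- setdiff(x, canon)
    if (length(bad))
      stop("unknown ", what, " feature name(s): ", paste(bad, collapse = ", "),
           "; valid names are the 150 canonical patient features ",
           "(see feature_names())")
  }
  if (!is.null(mutation_genes)) {
    mutation_genes <- as.data.frame(mutation_genes)
    stopifnot(all(c("gene", "frequency", "feature", "effect") %in%
                    names(mutation_genes)))
    if (any(mutation_genes$frequency <= 0 | mutation_genes$frequency >= 1))
      stop("mutation frequencies must lie in (0, 1)")
    check_feats(mutation_genes$feature, "mutation-affected")
  }
  if (!is.null(cox_betas)) {
    stopifnot(is.numeric(cox_betas), !is.null(names(cox_betas)))
    check_feats(names(cox_betas), "cox_betas")
  }
  if (!is.null(expression_genes)) {
    expression_genes <- as.data.frame(expression_genes)
    stopifnot(all(c("gene", "feature", "rho") %in% names(expression_genes)))
    if (any(abs(expression_genes$rho) > 1))
      stop("target Spearman strength must lie in [-1, 1]")
    check_feats(expression_genes$feature, "expression-driving")
  }
  if (censoring_rate < 0) stop("censoring_rate must be >= 0")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  structure(list(n_patients = n_patients, mutation_genes = mutation_genes,
                 cox_betas = cox_betas, baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 expression_genes = expression_genes,
                 n_background_genes =
                   stopifnot_scalar_count(n_background_genes,
                                          "n_background_genes", 0L),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with planted truth
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort_table` with elements:
#'   `features` (patients x 150 matrix, rownames = patient ids),
#'   `clinical` (data.frame: patient_id, time_months, event, stage, grade,
#'   msi), `mutations` (patients x genes binary matrix, possibly 0 columns),
#'   and `truth` (planted mutation labels, shifts, betas and linear
#'   predictors).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    canon <- feature_names()
    feats <- matrix(stats::rnorm(n * length(canon), mean = 10, sd = 2),
                    nrow = n, dimnames = list(ids, canon))

    genes <- if (is.null(spec$mutation_genes)) character(0) else
      as.character(spec$mutation_genes$gene)
    mut <- matrix(0L, n, length(genes), dimnames = list(ids, genes))
    shifts <- list()
    if (length(genes)) {
      for (k in seq_along(genes)) {
        g <- spec$mutation_genes[k, ]
        mut[, k] <- stats::rbinom(n, 1L, g$frequency)
        pooled_sd <- stats::sd(feats[, g$feature])
        delta <- g$effect * pooled_sd
        feats[mut[, k] == 1L, g$feature] <-
          feats[mut[, k] == 1L, g$feature] + delta
        shifts[[genes[k]]] <- list(feature = g$feature, effect = g$effect,
                                   shift = delta)
      }
    }

    z <- scale(feats)
    lp <- rep(0, n)
    if (!is.null(spec$cox_betas))
      lp <- as.numeric(z[, names(spec$cox_betas), drop = FALSE] %*%
                         spec$cox_betas)
    t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(lp))
    t_cens <- if (spec$censoring_rate > 0)
      stats::rexp(n, rate = spec$censoring_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    clinical <- data.frame(
      patient_id = ids,
      time_months = time,
      event = event,
      stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                     prob = c(0.14, 0.34, 0.43, 0.09)),
      grade = sample(c("G1", "G2", "G3"), n, TRUE, prob = c(0.02, 0.34, 0.64)),
      msi = sample(c("MSS", "MSI-L", "MSI-H"), n, TRUE,
                   prob = c(0.6, 0.2, 0.2)),
      stringsAsFactors = FALSE)

    structure(list(features = feats, clinical = clinical, mutations = mut,
                   truth = list(shifts = shifts,
                                betas = spec$cox_betas,
                                linear_predictor = lp,
                                event_time = t_event,
                                censor_time = t_cens),
                   spec = spec),
              class = "cohort_table")
  })
}

#' Generate a synthetic expression matrix for a cohort
#'
#' Driven genes are noisy monotone transforms of their driving feature: the
#' feature's ranks are mapped to normal scores and mixed with independent
#' Gaussian noise at the weight that gives the target Spearman correlation
#' in expectation (for a bivariate-normal copula, Spearman rho relates to
#' the Pearson mixing weight r by rho = (6/pi) * asin(r/2)). A target of
#' +/-1 uses the noiseless transform, so the realized rank correlation is
#' exactly +/-1. Undriven background genes are independent standard normal
#' noise.
#'
#' @param cohort A `cohort_table` from [generate_cohort()].
#' @param spec The same [cohort_spec()] (supplies `expression_genes`,
#'   `n_background_genes`, and the seed; the expression stream is derived
#'   from `seed + 1000003` so it is independent of the cohort draw).
#' @return Numeric genes x patients matrix with gene rownames and patient
#'   id colnames.
#' @export
generate_expression <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort_table"), inherits(spec, "cohort_spec"))
  with_seed(spec$seed + 1000003L, {
    n <- nrow(cohort$features)
    driven <- spec$expression_genes
    n_drv <- if (is.null(driven)) 0L else nrow(driven)
    gene_ids <- c(if (n_drv) as.character(driven$gene),
                  sprintf("BG%04d", seq_len(spec$n_background_genes)))
    expr <- matrix(stats::rnorm(length(gene_ids) * n),
                   nrow = length(gene_ids),
                   dimnames = list(gene_ids, rownames(cohort$features)))
    if (n_drv) {
      for (k in seq_len(n_drv)) {
        rho <- driven$rho[k]
        f <- cohort$features[, driven$feature[k]]
        zf <- stats::qnorm(rank(f, ties.method = "average") / (n + 1))
        if (abs(rho) >= 1) {
          expr[k, ] <- sign(rho) * zf
        } else {
          r <- 2 * sin(pi * rho / 6)
          expr[k, ] <- r * zf + sqrt(1 - r^2) * stats::rnorm(n)
        }
      }
    }
    expr
  })
}
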