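#' Two-group log-rank test
#'
#' Standard log-rank test: at each distinct event time the observed deaths
#' in group A are compared with the hypergeometric expectation given the
#' at-risk counts; the statistic is `(O - E)^2 / V`, chi-squared with 1
#' degree of freedom. Implemented directly (a single O(n log n) pass) so
#' that the per-feature screening in [logrank_filter()] stays fast; agrees
#' with [survival::survdiff()]. Two groups with identical survival give
#' statistic 0 and p = 1.
#'
#' @param group Logical or 0/1 vector (TRUE/1 = group A); both groups must
#'   be non-empty.
#' @param time Follow-up times (months), positive.
#' @param event Event indicator (1 = death).
#' @return List with `chisq` and `p`.
#' @export
logrank_test <- function(group, time, event) {
  group <- as.logical(group)
  if (!any(group) || all(group)) stop("both groups must be non-empty")
  st <- .logrank_stats(matrix(group), time, event)
  chisq <- if (st$V > 0) (st$O - st$E)^2 / st$V else 0
  list(chisq = as.numeric(chisq),
       p = if (st$V > 0) stats::pchisq(chisq, 1, lower.tail = FALSE) else 1)
}

# O, E, V of the group-A death counts for each column of the logical
# membership matrix G, computed jointly for all columns.
.logrank_stats <- function(G, time, event) {
  n <- length(time)
  o <- order(time)
  t_s <- time[o]; e_s <- event[o]
  G_s <- G[o, , drop = FALSE] * 1
  ut <- unique(t_s)
  first <- match(ut, t_s)              # first index of each distinct time
  n_at <- n - first + 1                # total at risk at each distinct time
  tg <- match(t_s, ut)
  # suffix sums give group-A at-risk counts at each distinct time
  suffix <- apply(G_s, 2, function(col) rev(cumsum(rev(col))))
  NA_at <- suffix[first, , drop = FALSE]
  d <- as.numeric(rowsum(e_s, tg))     # deaths at each distinct time
  dA <- rowsum(G_s * e_s, tg)
  ev <- d > 0
  frac <- NA_at[ev, , drop = FALSE] / n_at[ev]
  dv <- d[ev]; nv <- n_at[ev]
  vmult <- ifelse(nv > 1, dv * (nv - dv) / (nv - 1), 0)
  list(O = colSums(dA[ev, , drop = FALSE]),
       E = colSums(dv * frac),
       V = colSums(vmult * frac * (1 - frac)))
}

#' Median-dichotomized log-rank feature screen
#'
#' For every feature column, patients are split at the feature's median
#' computed on the same (training) data — values greater than or equal to
#' the median form the "high" group — and a two-group log-rank test is
#' run. Features with p < `alpha` are retained. No multiplicity correction
#' is applied at this screening step (the aim is to keep trending
#' features). Constant features, or splits that leave a group empty, are
#' skipped and never retained.
#'
#' @param features Patients x features numeric matrix (training rows only;
#'   the screen must never see held-out patients).
#' @param time,event Training survival data.
#' @param alpha Retention threshold on the per-feature p-value.
#' @return data.frame with columns feature, chisq, p, retained.
#' @export
logrank_filter <- function(features, time, event, alpha = 0.05) {
  features <- as.matrix(features)
  med <- apply(features, 2, stats::median)
  G <- sweep(features, 2, med, ">=")
  n_high <- colSums(G)
  testable <- n_high > 0 & n_high < nrow(features)
  out <- data.frame(feature = colnames(features), chisq = NA_real_,
                    p = NA_real_, retained = FALSE)
  if (any(testable)) {
    st <- .logrank_stats(G[, testable, drop = FALSE], time, event)
    chisq <- ifelse(st$V > 0, (st$O - st$E)^2 / st$V, 0)
    p <- ifelse(st$V > 0, stats::pchisq(chisq, 1, lower.tail = FALSE), 1)
    out$chisq[testable] <- chisq
    out$p[testable] <- p
    out$retained[testable] <- p < alpha
  }
  out
}

#' Fit a lasso-penalized Cox model on a training set
#'
#' Features are z-scored by their training mean and SD, an L1-penalized
#' Cox regularization path is fitted with [glmnet::glmnet()], and the
#' penalty is chosen by `nfolds`-fold cross-validated partial-likelihood
#' deviance (`lambda_rule = "min"` takes the deviance minimizer, `"1se"`
#' the sparsest model within one standard error). With a single candidate
#' feature there is nothing for the lasso to select between, so an
#' unpenalized Cox fit is used. The inner CV fold assignment is drawn from
#' `seed`, making the whole fit deterministic.
#'
#' @param x Training features (patients x features matrix, >= 1 column).
#' @param time,event Training survival data.
#' @param nfolds Inner CV folds (default 10); requires at least `nfolds`
#'   events.
#' @param seed Integer seed for the fold assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param lambda Optional fixed penalty; bypasses the inner CV (used to
#'   force a given shrinkage level).
#' @return List of class `fold_model`: `features` (candidates), `selected`
#'   (nonzero-coefficient features), `coef` (named coefficients on the
#'   z-scored scale), `lambda`, `center`, `scale`.
#' @export
fit_lasso_cox <- function(x, time, event, nfolds = 10L, seed = 1L,
                          lambda_rule = c("min", "1se"), lambda = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  x <- as.matrix(x)
  if (ncol(x) < 1L) stop("at least one feature is required")
  if (is.null(lambda) && ncol(x) > 1L && sum(event) < nfolds)
    stop("need at least ", nfolds, " events for ", nfolds, "-fold inner CV")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xz <- scale(x, center = ctr, scale = scl)
  if (ncol(x) == 1L) {
    fit <- survival::coxph(survival::Surv(time, event) ~ xz)
    cf <- stats::setNames(as.numeric(stats::coef(fit)), colnames(x))
    lam <- 0
  } else if (!is.null(lambda)) {
    fit <- glmnet::glmnet(xz, survival::Surv(time, event), family = "cox",
                          standardize = FALSE)
    cf <- stats::setNames(as.numeric(stats::coef(fit, s = lambda,
                                                 exact = FALSE)),
                          colnames(x))
    lam <- lambda
  } else {
    foldid <- with_seed(seed, sample(rep(seq_len(nfolds), length.out = nrow(x))))
    cv <- glmnet::cv.glmnet(xz, survival::Surv(time, event), family = "cox",
                            foldid = foldid, standardize = FALSE)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    cf_all <- as.numeric(stats::coef(cv, s = lam))
    cf <- stats::setNames(cf_all, colnames(x))
  }
  structure(list(features = colnames(x),
                 selected = names(cf)[cf != 0],
                 coef = cf[cf != 0],
                 lambda = lam, center = ctr, scale = scl),
            class = "fold_model")
}

# risk index of new observations under a fold model (0 for empty models)
.predict_fold <- function(model, x_new) {
  if (length(model$coef) == 0L) return(rep(0, nrow(x_new)))
  z <- sweep(sweep(x_new[, model$features, drop = FALSE], 2, model$center),
             2, model$scale, "/")
  as.numeric(z[, model$selected, drop = FALSE] %*% model$coef)
}

#' Leave-one-out cross-validated risk indices
#'
#' For each patient in turn: the remaining patients form the training set,
#' the median-split log-rank screen ([logrank_filter()]) selects candidate
#' features, a lasso-Cox model with inner 10-fold CV ([fit_lasso_cox()]) is
#' fitted, and the held-out patient's risk index is the dot product of
#' their training-standardized features with the model coefficients.
#' Screening, standardization, and penalty selection all happen strictly
#' inside the training set. Folds whose screen retains no feature emit an
#' empty model and risk index 0. After all folds, patients are split into
#' low-/high-risk groups at the median risk index (ties go to low risk).
#'
#' @param features Patients x features matrix (rownames = patient ids).
#' @param time,event Survival data aligned with `features` rows.
#' @param alpha Screening threshold.
#' @param nfolds Inner CV folds.
#' @param seed Base seed; fold `i` uses `seed + i` for its inner CV
#'   assignment.
#' @param lambda_rule `"min"` or `"1se"`.
#' @return List of class `risk_result`: `risk` (data.frame patient_id,
#'   risk_index, group), `folds` (list of `fold_model`s), `cutoff` (median
#'   risk index), and `logrank` (test of the final two-group split).
#' @export
loocv_risk_indices <- function(features, time, event, alpha = 0.05,
                               nfolds = 10L, seed = 1L,
                               lambda_rule = c("min", "1se")) {
  lambda_rule <- match.arg(lambda_rule)
  features <- as.matrix(features)
  n <- nrow(features)
  ids <- rownames(features) %||% sprintf("P%04d", seq_len(n))
  keep <- time > 0
  if (!all(keep)) {
    warning(sum(!keep), " patient(s) with non-positive follow-up dropped")
    features <- features[keep, , drop = FALSE]
    time <- time[keep]; event <- event[keep]; ids <- ids[keep]
    n <- nrow(features)
  }
  risk <- numeric(n)
  folds <- vector("list", n)
  for (i in seq_len(n)) {
    xtr <- features[-i, , drop = FALSE]
    ttr <- time[-i]; etr <- event[-i]
    scr <- logrank_filter(xtr, ttr, etr, alpha = alpha)
    sel <- scr$feature[scr$retained]
    if (length(sel) == 0L) {
      folds[[i]] <- structure(list(features = character(0),
                                   selected = character(0),
                                   coef = numeric(0), lambda = NA_real_,
                                   center = numeric(0), scale = numeric(0)),
                              class = "fold_model")
      risk[i] <- 0
      next
    }
    m <- fit_lasso_cox(xtr[, sel, drop = FALSE], ttr, etr, nfolds = nfolds,
                       seed = seed + i, lambda_rule = lambda_rule)
    folds[[i]] <- m
    risk[i] <- .predict_fold(m, features[i, , drop = FALSE])
  }
  res <- stratify_risk(risk, ids)
  lr <- logrank_test(res$group == "high-risk", time, event)
  structure(list(risk = res, folds = folds,
                 cutoff = stats::median(risk), logrank = lr),
            class = "risk_result")
}

#' Median split of risk indices
#'
#' Patients with risk index strictly above the median form the high-risk
#' group; patients at or below the median (including median ties) are
#' low-risk. With distinct indices the groups differ in size by at most 1.
#' All-identical indices cannot be stratified and raise an error.
#'
#' @param risk_index Numeric vector of per-patient risk indices.
#' @param ids Optional patient ids.
#' @return data.frame with patient_id, risk_index, group.
#' @export
stratify_risk <- function(risk_index, ids = NULL) {
  if (length(unique(risk_index)) < 2L)
    stop("degenerate risk distribution: all risk indices identical")
  cut <- stats::median(risk_index)
  data.frame(patient_id = ids %||% seq_along(risk_index),
             risk_index = risk_index,
             group = ifelse(risk_index > cut, "high-risk", "low-risk"),
             stringsAsFactors = FALSE)
}

#' Feature selection frequency across LOOCV folds
#'
#' For every feature ever assigned a nonzero lasso coefficient: in how many
#' folds it was selected and its mean coefficient over the selecting folds,
#' sorted by selection count descending.
#'
#' @param folds List of `fold_model`s (e.g. from [loocv_risk_indices()]).
#' @return data.frame with feature, count, n_folds, fraction,
#'   mean_coefficient.
#' @export
summarize_selection <- function(folds) {
  if (length(folds) == 0L) stop("at least one fold model is required")
  all_coef <- unlist(lapply(folds, function(m) m$coef))
  if (length(all_coef) == 0L)
    return(data.frame(feature = character(), count = integer(),
                      n_folds = integer(), fraction = numeric(),
                      mean_coefficient = numeric()))
  tab <- tapply(all_coef, names(all_coef), function(v)
    c(count = length(v), mean = mean(v)))
  tab <- do.call(rbind, tab)
  out <- data.frame(feature = rownames(tab),
                    count = as.integer(tab[, "count"]),
                    n_folds = length(folds),
                    fraction = tab[, "count"] / length(folds),
                    mean_coefficient = tab[, "mean"], row.names = NULL)
  out[order(-out$count, out$feature), , drop = FALSE]
}

#' Univariable and multivariable Cox regression on binary factors
#'
#' Fits Cox proportional-hazards models ([survival::coxph()]) on
#' dichotomized covariates. Each term must be a factor (or coercible) with
#' exactly two levels; the first level is the reference group. In
#' univariable mode every term is fitted alone; in multivariable mode all
#' terms enter jointly. Wald hazard ratios, 95% confidence intervals and
#' p-values are reported per term. Terms with zero events in a level are
#' rejected with a diagnostic.
#'
#' @param time,event Survival data.
#' @param terms data.frame of binary covariates; factor level order defines
#'   the reference (character columns are converted with the first-listed
#'   value as reference after sorting unique values in order of appearance).
#' @param mode `"univariable"` or `"multivariable"`.
#' @return data.frame of class `cox_summary`: term, comparison, reference,
#'   hr, ci_low, ci_high, p.
#' @export
cox_regression <- function(time, event, terms,
                           mode = c("univariable", "multivariable")) {
  mode <- match.arg(mode)
  terms <- as.data.frame(terms)
  for (nm in names(terms)) {
    v <- terms[[nm]]
    if (!is.factor(v)) v <- factor(v, levels = unique(v))
    if (nlevels(v) != 2L)
      stop("term '", nm, "' must have exactly 2 levels")
    for (lev in levels(v))
      if (sum(event[v == lev]) == 0L)
        stop("term '", nm, "', level '", lev,
             "': zero events; hazard ratio not estimable")
    terms[[nm]] <- v
  }
  extract <- function(fit, nms) {
    s <- summary(fit)
    data.frame(term = nms,
               comparison = vapply(nms, function(nm)
                 levels(terms[[nm]])[2], character(1)),
               reference = vapply(nms, function(nm)
                 levels(terms[[nm]])[1], character(1)),
               hr = unname(s$conf.int[, "exp(coef)"]),
               ci_low = unname(s$conf.int[, "lower .95"]),
               ci_high = unname(s$conf.int[, "upper .95"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]),
               row.names = NULL)
  }
  y <- survival::Surv(time, event)
  out <- if (mode == "univariable") {
    do.call(rbind, lapply(names(terms), function(nm) {
      fit <- survival::coxph(y ~ x, data = data.frame(x = terms[[nm]]))
      r <- extract(fit, nm)
      r
    }))
  } else {
    fit <- survival::coxph(y ~ ., data = terms)
    extract(fit, names(terms))
  }
  class(out) <- c("cox_summary", "data.frame")
  out
}

#' Standard clinical dichotomizations
#'
#' Builds the three conventional binary clinical factors from a clinical
#' table: stage I+II (reference) vs III+IV, grade G1+G2 (reference) vs G3,
#' and MSS (reference) vs MSI-L+MSI-H.
#'
#' @param clinical data.frame with columns stage ("I".."IV"), grade
#'   ("G1".."G3"), msi ("MSS", "MSI-L", "MSI-H").
#' @return data.frame of three two-level factors (reference level first):
#'   stage, grade, msi.
#' @export
dichotomize_clinical <- function(clinical) {
  data.frame(
    stage = factor(ifelse(clinical$stage %in% c("I", "II"), "I+II", "III+IV"),
                   levels = c("I+II", "III+IV")),
    grade = factor(ifelse(clinical$grade %in% c("G1", "G2"), "G1+G2", "G3"),
                   levels = c("G1+G2", "G3")),
    msi = factor(ifelse(clinical$msi == "MSS", "MSS", "MSI-L+MSI-H"),
                 levels = c("MSS", "MSI-L+MSI-H")))
}

#' Kaplan-Meier curve data
#'
#' Product-limit survival estimates per group via [survival::survfit()],
#' exported as a plain data.frame for plotting or export.
#'
#' @param time,event Survival data.
#' @param group Group labels.
#' @return data.frame with group, time, n_risk, n_event, surv.
#' @export
km_curve <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, event) ~ g,
                           data = data.frame(g = factor(group)))
  strata <- if (is.null(fit$strata)) rep(levels(factor(group)), length(fit$time))
            else rep(sub("^g=", "", names(fit$strata)), fit$strata)
  data.frame(group = strata, time = fit$time, n_risk = fit$n.risk,
             n_event = fit$n.event, surv = fit$surv, row.names = NULL)
}
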