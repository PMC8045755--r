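test_that("log-rank matches the hand-computed 4-patient example", {
  lr <- logrank_test(c(TRUE, TRUE, FALSE, FALSE), c(1, 2, 3, 4), rep(1, 4))
  expect_equal(lr$chisq, 49 / 17, tolerance = 1e-12)  # O=2, E=5/6, V=17/36
  expect_equal(lr$p, pchisq(49 / 17, 1, lower.tail = FALSE))
})

test_that("identical groups give statistic 0 and p 1", {
  time <- rep(c(2, 5, 9), 2)
  event <- rep(c(1, 0, 1), 2)
  lr <- logrank_test(rep(c(TRUE, FALSE), each = 3), time, event)
  expect_equal(lr$chisq, 0)
  expect_equal(lr$p, 1)
})

test_that("log-rank agrees with survival::survdiff on random data", {
  set.seed(3)
  for (rep in 1:15) {
    n <- sample(20:80, 1)
    time <- rexp(n, 0.1) + 0.01
    event <- rbinom(n, 1, 0.6)
    g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2) next
    mine <- logrank_test(g == 1, time, event)
    ref <- survival::survdiff(survival::Surv(time, event) ~ g)
    expect_equal(mine$chisq, ref$chisq, tolerance = 1e-10)
  }
})

test_that("log-rank p-values are uniform under label permutation", {
  set.seed(11)
  n <- 60
  time <- rexp(n, 0.08); event <- rbinom(n, 1, 0.7)
  ps <- replicate(500, logrank_test(sample(rep(c(TRUE, FALSE), n / 2)),
                                    time, event)$p)
  expect_gt(ks.test(ps, punif)$p.value, 0.01)
})

test_that("the median-split screen matches per-feature log-rank tests", {
  co <- planted_surv_cohort(n = 120, seed = 8)
  scr <- logrank_filter(co$features[, 1:25], co$clinical$time_months,
                        co$clinical$event)
  for (j in c(1, 7, 19)) {
    f <- colnames(co$features)[j]
    g <- co$features[, j] >= median(co$features[, j])
    expect_equal(scr$p[scr$feature == f],
                 logrank_test(g, co$clinical$time_months,
                              co$clinical$event)$p, tolerance = 1e-10)
  }
})

test_that("constant features are never retained by the screen", {
  co <- null_cohort(n = 50, seed = 2)
  x <- cbind(co$features[, 1:3], flat = rep(4, 50))
  scr <- logrank_filter(x, co$clinical$time_months, co$clinical$event)
  expect_false(scr$retained[scr$feature == "flat"])
  expect_true(is.na(scr$p[scr$feature == "flat"]))
})

test_that("a strong planted hazard feature passes the screen", {
  hits <- 0L
  for (s in 1:10) {
    co <- generate_cohort(cohort_spec(n_patients = 200,
                                      cox_betas = c(area_mean = 1),
                                      seed = 300 + s))
    scr <- logrank_filter(co$features[, "area_mean", drop = FALSE],
                          co$clinical$time_months, co$clinical$event)
    hits <- hits + scr$retained
  }
  expect_gte(hits, 9L)
})

test_that("forcing a huge penalty shrinks every coefficient to zero", {
  co <- planted_surv_cohort(n = 100, seed = 4)
  m <- fit_lasso_cox(co$features[, 1:20], co$clinical$time_months,
                     co$clinical$event, lambda = 1e3)
  expect_length(m$selected, 0L)
  m2 <- fit_lasso_cox(co$features[, 1:20], co$clinical$time_months,
                      co$clinical$event, seed = 5)
  expect_true(all(is.finite(m2$coef)))
})

test_that("duplicated columns share the coefficient mass", {
  co <- generate_cohort(cohort_spec(n_patients = 300,
                                    cox_betas = c(area_mean = 0.8),
                                    seed = 19))
  x1 <- co$features[, c("area_mean", "ratio_mean", "minor_bin2")]
  m1 <- fit_lasso_cox(x1, co$clinical$time_months, co$clinical$event,
                      seed = 7)
  x2 <- cbind(x1, area_dup = x1[, "area_mean"])
  m2 <- fit_lasso_cox(x2, co$clinical$time_months, co$clinical$event,
                      seed = 7)
  mass1 <- sum(m1$coef[names(m1$coef) %in% c("area_mean")])
  mass2 <- sum(m2$coef[names(m2$coef) %in% c("area_mean", "area_dup")])
  expect_equal(mass2, mass1, tolerance = 0.2 * abs(mass1))
})

test_that("median split balances groups and rejects degenerate indices", {
  r <- stratify_risk(c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(table(r$group)[c("low-risk", "high-risk")]),
               array(c(2L, 2L)))
  expect_error(stratify_risk(rep(1, 5)), "degenerate")
  # ties at the median go to low risk
  r2 <- stratify_risk(c(1, 2, 2, 3))
  expect_equal(sum(r2$group == "low-risk"), 3L)
})

test_that("selection summary counts folds and averages coefficients", {
  mk <- function(cf) structure(list(features = names(cf), selected = names(cf),
                                    coef = cf, lambda = 0.1,
                                    center = numeric(0), scale = numeric(0)),
                               class = "fold_model")
  folds <- list(mk(c(a = 0.2, b = 0.5)), mk(c(a = 0.3)))
  s <- summarize_selection(folds)
  expect_equal(s$feature, c("a", "b"))
  expect_equal(s$count, c(2L, 1L))
  expect_equal(s$mean_coefficient, c(0.25, 0.5))
  expect_equal(s$fraction, c(1, 0.5))
  expect_false("c" %in% s$feature)
})

test_that("LOOCV risk indices are deterministic and stratify planted signal", {
  co <- planted_surv_cohort(n = 80, seed = 33)
  r1 <- loocv_risk_indices(co$features, co$clinical$time_months,
                           co$clinical$event, seed = 2)
  r2 <- loocv_risk_indices(co$features, co$clinical$time_months,
                           co$clinical$event, seed = 2)
  expect_identical(r1$risk, r2$risk)
  expect_lt(r1$logrank$p, 0.05)
  sizes <- table(r1$risk$group)
  expect_lte(abs(diff(as.integer(sizes))), 1L)
})

test_that("held-out patients are provably unused in their fold", {
  co <- planted_surv_cohort(n = 40, seed = 44)
  time <- co$clinical$time_months; event <- co$clinical$event
  rr <- loocv_risk_indices(co$features, time, event, seed = 9)
  for (i in c(1L, 17L)) {
    scr <- logrank_filter(co$features[-i, ], time[-i], event[-i])
    sel <- scr$feature[scr$retained]
    refit <- if (length(sel) == 0L) NULL else
      fit_lasso_cox(co$features[-i, sel, drop = FALSE], time[-i], event[-i],
                    seed = 9 + i)
    if (is.null(refit)) {
      expect_length(rr$folds[[i]]$coef, 0L)
    } else {
      expect_identical(rr$folds[[i]]$coef, refit$coef)
      expect_identical(rr$folds[[i]]$lambda, refit$lambda)
    }
  }
})

test_that("Cox regression is calibrated on null and known-hazard data", {
  set.seed(12)
  n <- 200
  g <- factor(rep(c("A", "B"), each = n / 2), levels = c("A", "B"))
  time <- rexp(n, 0.1); event <- rbinom(n, 1, 0.8)
  null_fit <- cox_regression(time, event, data.frame(g = g))
  expect_lt(null_fit$ci_low, 1)
  expect_gt(null_fit$ci_high, 1)
  # known hazard ratio 2
  time2 <- c(rexp(n / 2, 0.05), rexp(n / 2, 0.1))
  fit2 <- cox_regression(time2, rep(1, n), data.frame(g = g))
  expect_true(fit2$ci_low < 2 && 2 < fit2$ci_high)
  expect_equal(fit2$reference, "A")
})

test_that("multivariable Cox tolerates an independent null covariate", {
  set.seed(14)
  n <- 300
  g <- rbinom(n, 1, 0.5)
  time <- rexp(n, 0.05 * exp(log(2) * g))
  terms <- data.frame(g = factor(g), z = factor(rbinom(n, 1, 0.5)))
  uni <- cox_regression(time, rep(1, n), terms["g"])
  multi <- cox_regression(time, rep(1, n), terms, mode = "multivariable")
  hr_uni <- uni$hr[uni$term == "g"]
  hr_multi <- multi$hr[multi$term == "g"]
  expect_lt(abs(hr_multi - hr_uni) / hr_uni, 0.1)
})

test_that("zero events in a level raise a diagnostic error", {
  g <- factor(c("A", "A", "B", "B"))
  expect_error(cox_regression(c(1, 2, 3, 4), c(1, 1, 0, 0),
                              data.frame(g = g)),
               "zero events")
})

test_that("KM estimates match a hand-computed product-limit table", {
  # 6 patients, one group: times 1,2,2,4+,5,6+  (+ = censored)
  time <- c(1, 2, 2, 4, 5, 6)
  event <- c(1, 1, 1, 0, 1, 0)
  km <- km_curve(time, event, rep("all", 6))
  # S(1)=5/6; S(2)=5/6*2/4? no: at t=2, n.risk=5, d=2 -> S=5/6*3/5=1/2
  # at t=5, n.risk=2, d=1 -> S=1/2*1/2=1/4
  s_expected <- c(5 / 6, 5 / 6 * 3 / 5, NA, 5 / 6 * 3 / 5 * 1 / 2, NA)
  expect_equal(km$surv[km$time == 1], 5 / 6)
  expect_equal(km$surv[km$time == 2], 1 / 2)
  expect_equal(km$surv[km$time == 5], 1 / 4)
})
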