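test_that("empty tile gives blank background, empty mask and table", {
  tl <- generate_tile(tile_spec(width = 64, height = 64, n_nuclei = 0,
                                noise_sd = 0, seed = 1))
  expect_true(all(tl$mask == 0L))
  expect_equal(nrow(tl$truth), 0L)
  expect_equal(unique(as.vector(tl$image[, , 1])), 243)
})

test_that("tile generation is seed-deterministic and places the exact count", {
  sp <- tile_spec(n_nuclei = 50, min_separation = 30, seed = 7)
  t1 <- generate_tile(sp)
  t2 <- generate_tile(sp)
  expect_identical(t1$image, t2$image)
  expect_identical(t1$mask, t2$mask)
  expect_equal(nrow(t1$truth), 50L)
  expect_equal(sort(unique(t1$mask[t1$mask > 0])), 1:50)
  # independent connected-component count
  cc <- EBImage::bwlabel(EBImage::Image(t1$mask > 0))
  expect_equal(max(cc), 50)
})

test_that("impossible placement raises an overcrowded-tile error", {
  sp <- tile_spec(width = 60, height = 60, n_nuclei = 40,
                  min_separation = 30, seed = 2)
  expect_error(generate_tile(sp), "overcrowded")
})

test_that("cohort generation is seed-reproducible with sane survival", {
  co1 <- null_cohort(n = 200, seed = 11)
  co2 <- null_cohort(n = 200, seed = 11)
  expect_identical(co1$features, co2$features)
  expect_identical(co1$clinical, co2$clinical)
  expect_equal(dim(co1$features), c(200L, 150L))
  expect_identical(colnames(co1$features), feature_names())
  expect_true(all(co1$clinical$time_months > 0))
  co3 <- planted_mut_cohort(n = 200, seed = 11)
  expect_true(sum(co3$mutations[, "GENE1"]) %in% 0:200)
  expect_identical(sum(co3$mutations[, "GENE1"]),
                   sum(generate_cohort(co3$spec)$mutations[, "GENE1"]))
})

test_that("unknown feature names are rejected with guidance", {
  expect_error(cohort_spec(mutation_genes = data.frame(
    gene = "G", frequency = 0.5, feature = "nonesuch", effect = 1)),
    "unknown.*nonesuch")
  expect_error(cohort_spec(cox_betas = c(bogus_feature = 1)), "unknown")
})

test_that("planted mutation effects shift the affected feature", {
  co <- planted_mut_cohort(n = 400, effect = 1.5, seed = 3)
  mut <- co$mutations[, "GENE1"] == 1
  d <- mean(co$features[mut, "area_mean"]) - mean(co$features[!mut, "area_mean"])
  expect_gt(d, 1.5 * 2 * 0.6)  # features have SD 2; allow sampling noise
  # untouched feature stays centred
  d0 <- mean(co$features[mut, "ratio_mean"]) - mean(co$features[!mut, "ratio_mean"])
  expect_lt(abs(d0), 0.8)
})

test_that("univariable Cox recovers a planted log-hazard coefficient", {
  hits <- 0L
  n_seeds <- 20L
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(cohort_spec(n_patients = 300,
                                      cox_betas = c(area_mean = 0.8),
                                      seed = 100 + s))
    z <- as.numeric(scale(co$features[, "area_mean"]))
    fit <- survival::coxph(
      survival::Surv(co$clinical$time_months, co$clinical$event) ~ z)
    se <- sqrt(diag(fit$var))
    if (abs(coef(fit) - 0.8) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 17L)  # ~99.7% coverage expected; generous at 20 seeds
})

test_that("expression generator hits exact and null Spearman targets", {
  spec <- cohort_spec(n_patients = 300,
                      expression_genes = data.frame(
                        gene = c("POS1", "NEG1"),
                        feature = c("area_mean", "ratio_mean"),
                        rho = c(1, -1)),
                      n_background_genes = 200, seed = 5)
  co <- generate_cohort(spec)
  e1 <- generate_expression(co, spec)
  e2 <- generate_expression(co, spec)
  expect_identical(e1, e2)
  expect_equal(cor(e1["POS1", ], co$features[, "area_mean"],
                   method = "spearman"), 1)
  expect_equal(cor(e1["NEG1", ], co$features[, "ratio_mean"],
                   method = "spearman"), -1)
  # undriven genes: null Spearman SE ~ 1/sqrt(n-1) => |rho| < 0.3 almost surely
  rhos <- apply(e1[-(1:2), ], 1, cor, y = co$features[, "area_mean"],
                method = "spearman")
  expect_gte(mean(abs(rhos) < 0.3), 0.95)
})

test_that("moderate Spearman targets are realized approximately", {
  spec <- cohort_spec(n_patients = 400,
                      expression_genes = data.frame(
                        gene = "MID1", feature = "area_mean", rho = 0.5),
                      n_background_genes = 0, seed = 9)
  co <- generate_cohort(spec)
  e <- generate_expression(co, spec)
  rho <- cor(e["MID1", ], co$features[, "area_mean"], method = "spearman")
  expect_lt(abs(rho - 0.5), 0.12)
})
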