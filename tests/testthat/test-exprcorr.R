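mk_expr <- function(mat, ids) {
  colnames(mat) <- ids
  mat
}

test_that("monotone transforms give exactly +/-1", {
  set.seed(2)
  ids <- sprintf("P%02d", 1:20)
  f <- setNames(rnorm(20), ids)
  e <- mk_expr(rbind(up = 2 * f + 5, down = -f,
                     noise = rnorm(20)), ids)
  prof <- spearman_profile(f, e)
  expect_equal(prof$rho[prof$gene == "up"], 1)
  expect_equal(prof$rho[prof$gene == "down"], -1)
})

test_that("rank-then-Pearson equals the direct Spearman oracle", {
  set.seed(4)
  ids <- sprintf("P%02d", 1:30)
  f <- setNames(rnorm(30), ids)
  e <- mk_expr(matrix(c(rnorm(50 * 30),
                        round(rnorm(50 * 30), 1)),  # with ties
                      nrow = 100), ids)
  rownames(e) <- sprintf("G%03d", 1:100)
  prof <- spearman_profile(f, e)
  oracle <- apply(e, 1, cor, y = f, method = "spearman")
  expect_equal(prof$rho, unname(oracle), tolerance = 1e-12)
})

test_that("missing expression values are dropped pairwise per gene", {
  set.seed(6)
  ids <- sprintf("P%02d", 1:25)
  f <- setNames(rnorm(25), ids)
  g1 <- 3 * f; g1[c(2, 9)] <- NA
  e <- mk_expr(rbind(g1 = g1, g2 = rnorm(25)), ids)
  prof <- spearman_profile(f, e)
  expect_equal(prof$rho[prof$gene == "g1"], 1)
  expect_equal(prof$n[prof$gene == "g1"], 23)
})

test_that("fewer than 10 shared patients is an error", {
  ids <- sprintf("P%02d", 1:8)
  f <- setNames(rnorm(8), ids)
  e <- mk_expr(matrix(rnorm(16), 2), ids)
  expect_error(spearman_profile(f, e), "10 shared")
})

test_that("top-gene selection caps at 100 with boundary inclusion", {
  prof <- structure(data.frame(gene = sprintf("G%03d", 1:150),
                               rho = seq(0.95, 0.30, length.out = 150),
                               n = 100),
                    class = c("correlation_profile", "data.frame"))
  top <- select_top_genes(prof)
  expect_equal(nrow(top), 100L)
  expect_equal(top$gene[1], "G001")
  expect_true(all(abs(top$rho) >= sort(abs(prof$rho), decreasing = TRUE)[100]))
  expect_false(attr(top, "skip_enrichment"))
  # exact boundary 0.30 is included by default, excluded under strict
  prof2 <- prof[148:150, ]
  expect_equal(nrow(select_top_genes(prof2, min_genes = 1)), 3L)
  expect_true(all(select_top_genes(prof2, min_genes = 1,
                                   strict = TRUE)$rho > 0.3))
})

test_that("too few qualifying genes flags enrichment to be skipped", {
  prof <- structure(data.frame(gene = c("A", "B", "C"),
                               rho = c(0.9, 0.5, 0.1), n = 50),
                    class = c("correlation_profile", "data.frame"))
  top <- select_top_genes(prof)
  expect_equal(nrow(top), 2L)
  expect_true(attr(top, "skip_enrichment"))
})

test_that("hypergeometric p matches the closed-form toy example", {
  universe <- sprintf("G%02d", 1:10)
  query <- universe[1:5]
  res <- hypergeometric_enrichment(query, list(hit = query), universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  res2 <- hypergeometric_enrichment(query, list(miss = universe[6:10]),
                                    universe)
  expect_equal(res2$p, 1)
})

test_that("enrichment p decreases monotonically with overlap", {
  universe <- sprintf("G%03d", 1:100)
  query <- universe[1:20]
  ps <- vapply(5:15, function(k)
    hypergeometric_enrichment(query,
                              list(s = c(universe[1:k], universe[60:(79 - k)])),
                              universe)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("enrichment p-values are calibrated (super-uniform) under the null", {
  set.seed(10)
  universe <- sprintf("G%04d", 1:400)
  gene_set <- universe[1:60]
  ps <- replicate(400, hypergeometric_enrichment(
    sample(universe, 40), list(s = gene_set), universe)$p)
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= a), a + 0.04)  # Monte-Carlo margin
  expect_gt(mean(ps), 0.4)
})

test_that("invalid enrichment inputs are rejected", {
  expect_error(hypergeometric_enrichment(character(0), list(s = "A"), "A"),
               "empty query")
  expect_error(hypergeometric_enrichment("A", list(s = "A"), character(0)),
               "empty universe")
  expect_error(hypergeometric_enrichment("Z", list(s = "A"), "A"),
               "contained in the universe")
})

test_that("the full correlation stage links planted genes to their feature", {
  spec <- cohort_spec(n_patients = 150,
                      expression_genes = data.frame(
                        gene = sprintf("DRV%02d", 1:12),
                        feature = "area_mean", rho = 0.65),
                      n_background_genes = 100, seed = 21)
  co <- generate_cohort(spec)
  expr <- generate_expression(co, spec)
  sets <- list(DRIVEN = sprintf("DRV%02d", 1:12),
               RANDOM = sprintf("BG%04d", 1:30))
  res <- run_expression_correlation(co$features, expr, "area_mean", sets)
  enr <- res$area_mean$enrichment
  expect_false(is.null(enr))
  expect_equal(enr$set[1], "DRIVEN")
  expect_lt(enr$q[1], 0.05)
})
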