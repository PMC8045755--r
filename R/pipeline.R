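#' Pipeline configuration
#'
#' Collects paths, thresholds and seeds for [run_pipeline()]. Either a
#' tiles manifest (CSV with columns `patient_id`, `tile`, optionally
#' `mask`; paths relative to the manifest's directory) or a precomputed
#' patient-feature CSV must be supplied. All other inputs are optional and
#' enable the corresponding downstream stage.
#'
#' @param tiles_manifest CSV describing the image tiles per patient.
#' @param features Precomputed patient x 150 feature CSV (alternative to
#'   `tiles_manifest`).
#' @param clinical Clinical CSV (patient_id, time_months, event, stage,
#'   grade, msi); enables the prognostic stage.
#' @param mutations Binary mutation CSV (patients x genes); enables the
#'   association stage.
#' @param expression Expression CSV (genes x patients); enables the
#'   correlation stage.
#' @param gmt GMT gene-set file for enrichment (optional).
#' @param out_dir Output directory (created if missing).
#' @param bin_scheme Path to a bin-scheme JSON, or `"fit"` to fit the
#'   scheme on this cohort.
#' @param seed Seed for the inner cross-validation.
#' @param alpha,mutation_threshold,correlation_threshold,gene_cap,percentile
#'   Analysis thresholds (defaults 0.05, 0.15, 0.3, 100, 95).
#' @param selection_fraction Minimum LOOCV selection fraction for a feature
#'   to enter the expression-correlation stage (default 0.8).
#' @param seg Segmentation parameters, see [seg_params()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(tiles_manifest = NULL, features = NULL,
                            clinical = NULL, mutations = NULL,
                            expression = NULL, gmt = NULL,
                            out_dir = "histomorph_out", bin_scheme = "fit",
                            seed = 1L, alpha = 0.05,
                            mutation_threshold = 0.15,
                            correlation_threshold = 0.3, gene_cap = 100L,
                            percentile = 95, selection_fraction = 0.8,
                            seg = seg_params()) {
  if (is.null(tiles_manifest) && is.null(features))
    stop("either 'tiles_manifest' or a precomputed 'features' CSV is required")
  stopifnot(alpha > 0, alpha < 1, mutation_threshold >= 0,
            mutation_threshold < 1, correlation_threshold >= 0,
            correlation_threshold <= 1, percentile > 0, percentile <= 100)
  structure(list(tiles_manifest = tiles_manifest, features = features,
                 clinical = clinical, mutations = mutations,
                 expression = expression, gmt = gmt, out_dir = out_dir,
                 bin_scheme = bin_scheme, seed = as.integer(seed),
                 alpha = alpha, mutation_threshold = mutation_threshold,
                 correlation_threshold = correlation_threshold,
                 gene_cap = gene_cap, percentile = percentile,
                 selection_fraction = selection_fraction, seg = seg),
            class = "pipeline_config")
}

.check_paths <- function(config) {
  paths <- c(config$tiles_manifest, config$features, config$clinical,
             config$mutations, config$expression, config$gmt,
             if (!identical(config$bin_scheme, "fit")) config$bin_scheme)
  for (p in paths)
    if (!file.exists(p)) stop("input file does not exist: ", p)
  invisible(TRUE)
}

# patient feature matrix <-> CSV
write_feature_csv <- function(features, path) {
  df <- data.frame(patient_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Run the full analysis pipeline
#'
#' Orchestrates the workflow: stain normalization, nucleus segmentation and
#' the large-nucleus percentile filter per tile; cell-level morphometry;
#' per-patient aggregation with cohort-shared histogram bins; then, where
#' the inputs are supplied, mutation-morphology association, the LOOCV
#' lasso-Cox prognostic model, and expression correlation with gene-set
#' enrichment. All outputs are plain CSV/JSON in `out_dir` together with a
#' `provenance.json` (config hash, seed, package version). Re-running with
#' identical config and inputs reproduces identical tables.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results (`features`,
#'   `scheme`, `association`, `risk`, `selection`, `cox`, `correlation`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  .check_paths(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  if (!is.null(config$features)) {
    feats <- read_feature_csv(config$features)
    scheme <- if (!identical(config$bin_scheme, "fit"))
      read_bin_scheme(config$bin_scheme) else NULL
  } else {
    manifest <- utils::read.csv(config$tiles_manifest,
                                stringsAsFactors = FALSE)
    base <- dirname(config$tiles_manifest)
    cell_tables <- list()
    for (i in seq_len(nrow(manifest))) {
      img <- read_tile(file.path(base, manifest$tile[i]))
      img <- suppressWarnings(normalize_stain(img))
      seg <- if (!is.null(manifest$mask) && nzchar(manifest$mask[i])) {
        m <- read_mask(file.path(base, manifest$mask[i]))
        structure(.label_table(m), class = "segmentation_result")
      } else {
        segment_nuclei(img, config$seg)
      }
      seg <- filter_large_nuclei(seg, config$percentile)
      cells <- extract_cell_features(img, seg)
      pid <- as.character(manifest$patient_id[i])
      cell_tables[[pid]] <- c(cell_tables[[pid]], list(cells))
    }
    scheme <- if (!identical(config$bin_scheme, "fit"))
      read_bin_scheme(config$bin_scheme) else NULL
    agg <- aggregate_cohort(cell_tables, scheme)
    feats <- agg$features
    scheme <- agg$scheme
    write_bin_scheme(scheme, file.path(config$out_dir, "bin_scheme.json"))
  }
  write_feature_csv(feats, file.path(config$out_dir, "features.csv"))
  results$features <- feats
  results$scheme <- scheme

  if (!is.null(config$mutations)) {
    mdf <- utils::read.csv(config$mutations, check.names = FALSE)
    mut <- as.matrix(mdf[, -1, drop = FALSE])
    rownames(mut) <- mdf[[1]]
    assoc <- run_association(feats, mut, threshold = config$mutation_threshold,
                             alpha = config$alpha)
    utils::write.csv(assoc, file.path(config$out_dir, "association.csv"),
                     row.names = FALSE)
    results$association <- assoc
  }

  sel_features <- NULL
  if (!is.null(config$clinical)) {
    clin <- utils::read.csv(config$clinical, stringsAsFactors = FALSE)
    clin <- clin[match(rownames(feats), clin$patient_id), ]
    rr <- loocv_risk_indices(feats, clin$time_months, clin$event,
                             alpha = config$alpha, seed = config$seed)
    utils::write.csv(rr$risk, file.path(config$out_dir, "risk.csv"),
                     row.names = FALSE)
    sel <- summarize_selection(rr$folds)
    utils::write.csv(sel, file.path(config$out_dir, "selection.csv"),
                     row.names = FALSE)
    km <- km_curve(clin$time_months[clin$time_months > 0],
                   clin$event[clin$time_months > 0],
                   rr$risk$group)
    utils::write.csv(km, file.path(config$out_dir, "km_curves.csv"),
                     row.names = FALSE)
    cox_terms <- cbind(
      risk = factor(rr$risk$group, levels = c("low-risk", "high-risk")),
      dichotomize_clinical(clin[clin$time_months > 0, ]))
    cox <- tryCatch({
      uni <- cox_regression(clin$time_months, clin$event, cox_terms,
                            mode = "univariable")
      mult <- cox_regression(clin$time_months, clin$event, cox_terms,
                             mode = "multivariable")
      rbind(cbind(model = "univariable", uni),
            cbind(model = "multivariable", mult))
    }, error = function(e) {
      warning("Cox regression on clinical factors failed: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(cox))
      utils::write.csv(cox, file.path(config$out_dir, "cox_summary.csv"),
                       row.names = FALSE)
    results$risk <- rr
    results$selection <- sel
    results$cox <- cox
    sel_features <- sel$feature[sel$fraction >= config$selection_fraction]
  }

  if (!is.null(config$expression)) {
    edf <- utils::read.csv(config$expression, check.names = FALSE)
    expr <- as.matrix(edf[, -1, drop = FALSE])
    rownames(expr) <- edf[[1]]
    collection <- if (!is.null(config$gmt)) read_gmt(config$gmt) else NULL
    if (is.null(sel_features) || length(sel_features) == 0L)
      sel_features <- colnames(feats)[seq_len(min(3L, ncol(feats)))]
    corr <- run_expression_correlation(
      feats, expr, sel_features, collection,
      threshold = config$correlation_threshold, cap = config$gene_cap)
    corr_tab <- do.call(rbind, lapply(names(corr), function(f)
      cbind(feature = f, corr[[f]]$profile)))
    utils::write.csv(corr_tab, file.path(config$out_dir, "correlation.csv"),
                     row.names = FALSE)
    enr_tab <- do.call(rbind, lapply(names(corr), function(f)
      if (!is.null(corr[[f]]$enrichment))
        cbind(feature = f, corr[[f]]$enrichment)))
    if (!is.null(enr_tab))
      utils::write.csv(enr_tab, file.path(config$out_dir, "enrichment.csv"),
                       row.names = FALSE)
    results$correlation <- corr
  }

  cfg_serial <- jsonlite::toJSON(config[setdiff(names(config), "seg")],
                                 auto_unbox = TRUE, force = TRUE)
  prov <- list(config_hash = .hash_string(as.character(cfg_serial)),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("histomorph")))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(results)
}

# md5 of a string via a temporary file (tools::md5sum is file-based)
.hash_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Generate a self-contained synthetic demo dataset
#'
#' Writes a small image-level cohort to `dir`: one tile per patient with
#' patient-specific nucleus size and density, a tiles manifest, clinical
#' survival, a binary mutation matrix, an expression matrix, and a toy GMT
#' collection — everything [run_pipeline()] needs, with effects planted at
#' the image level. Patients mutated in the synthetic gene `MUT1` grow
#' larger nuclei; the death hazard increases with the patient's mean
#' nucleus area; the gene `DRV1` expression tracks nucleus area. The
#' pipeline should therefore associate `MUT1` with area features, select
#' area-related features in the prognostic model, and correlate `DRV1`
#' with them.
#'
#' @param dir Output directory.
#' @param n_patients Number of patients.
#' @param tile_px Tile side length in pixels.
#' @param n_nuclei Nuclei per tile.
#' @param seed Integer seed.
#' @return Invisibly, the [pipeline_config()] pointing at the demo files.
#' @export
simulate_demo <- function(dir, n_patients = 30L, tile_px = 192L,
                          n_nuclei = 30L, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n_patients))
    mutated <- stats::rbinom(n_patients, 1L, 0.5)
    area_mean <- stats::rlnorm(n_patients, log(210), 0.18) +
      60 * mutated                               # planted mutation effect
    tiles <- character(n_patients)
    for (i in seq_len(n_patients)) {
      sp <- tile_spec(width = tile_px, height = tile_px, n_nuclei = n_nuclei,
                      area_mean = area_mean[i], area_sd = area_mean[i] * 0.3,
                      min_separation = 2.3 * sqrt(area_mean[i] / pi),
                      seed = seed + 7919L + i)
      tl <- generate_tile(sp)
      tiles[i] <- sprintf("tile_%s.png", ids[i])
      write_tile(tl$image, file.path(dir, tiles[i]))
    }
    utils::write.csv(data.frame(patient_id = ids, tile = tiles),
                     file.path(dir, "tiles.csv"), row.names = FALSE)
    z_area <- as.numeric(scale(area_mean))
    t_event <- stats::rexp(n_patients, 0.03 * exp(0.9 * z_area))
    t_cens <- stats::rexp(n_patients, 0.02)
    utils::write.csv(data.frame(
      patient_id = ids,
      time_months = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      stage = sample(c("I", "II", "III", "IV"), n_patients, TRUE,
                     prob = c(0.14, 0.34, 0.43, 0.09)),
      grade = sample(c("G1", "G2", "G3"), n_patients, TRUE,
                     prob = c(0.02, 0.34, 0.64)),
      msi = sample(c("MSS", "MSI-L", "MSI-H"), n_patients, TRUE,
                   prob = c(0.6, 0.2, 0.2))),
      file.path(dir, "clinical.csv"), row.names = FALSE)
    utils::write.csv(data.frame(patient_id = ids, MUT1 = mutated,
                                MUT2 = stats::rbinom(n_patients, 1L, 0.4)),
                     file.path(dir, "mutations.csv"), row.names = FALSE)
    n_bg <- 40L
    expr <- rbind(DRV1 = 0.9 * z_area + 0.4 * stats::rnorm(n_patients),
                  matrix(stats::rnorm(n_bg * n_patients), n_bg,
                         dimnames = list(sprintf("BG%03d", seq_len(n_bg)), NULL)))
    utils::write.csv(data.frame(gene = rownames(expr), expr,
                                check.names = FALSE) |>
                       stats::setNames(c("gene", ids)),
                     file.path(dir, "expression.csv"), row.names = FALSE)
    write_gmt(list(SET_DRIVEN = c("DRV1", sprintf("BG%03d", 1:9)),
                   SET_RANDOM = sprintf("BG%03d", 10:25)),
              file.path(dir, "genesets.gmt"))
  })
  invisible(pipeline_config(
    tiles_manifest = file.path(dir, "tiles.csv"),
    clinical = file.path(dir, "clinical.csv"),
    mutations = file.path(dir, "mutations.csv"),
    expression = file.path(dir, "expression.csv"),
    gmt = file.path(dir, "genesets.gmt"),
    out_dir = file.path(dir, "out"), seed = seed))
}
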