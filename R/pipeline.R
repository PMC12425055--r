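# Top-level orchestration: simulate -> GPCs -> scan/meta/select -> train ->
# apply -> evaluate -> EWAS, with a checksum manifest for reproducibility.

#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end run. The analysis defaults mirror
#' the method's standard setup: 10 components, FDR threshold 0.05, 85/15
#' stratified train/test split, observation-weight truncation at the 0.90
#' quantile, 10 CV folds, 5 structure adjusters in the EWAS comparison. The
#' simulation defaults describe a small five-cohort design (about 700
#' samples, 2000 CpGs, 1500 variants) that runs in seconds.
#'
#' @param out_dir Output directory.
#' @param seed Master seed; every stage derives its own seed from it.
#' @param n_components Number of genetic PCs / MPSs (K).
#' @param q_threshold FDR threshold for stage-1 CpG selection.
#' @param train_fraction Per-cohort training fraction.
#' @param truncation_quantile Observation-weight truncation quantile.
#' @param cv_folds Cross-validation folds for the Lasso penalty.
#' @param n_adjusters Structure adjusters used in the EWAS comparison.
#' @param pop_model,meth_model Simulation models ([pop_model()],
#'   [meth_model()]).
#' @param cohort_sizes Per-cohort sample counts for the simulation.
#' @param exposure_intercept,exposure_slope Logistic coefficients linking
#'   exposure prevalence to latent ancestry in the EWAS scenario
#'   (`exposure_slope = 0` removes the confounding).
#' @param mpc_scale Whether the PCA comparator scales CpG columns.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("mpscore_run_"),
                            seed = 1L,
                            n_components = 10L,
                            q_threshold = 0.05,
                            train_fraction = 0.85,
                            truncation_quantile = 0.90,
                            cv_folds = 10L,
                            n_adjusters = 5L,
                            pop_model = mpscore::pop_model(n_variants = 1500L),
                            meth_model = mpscore::meth_model(),
                            cohort_sizes = c(90L, 110L, 130L, 230L, 140L),
                            exposure_intercept = -0.5,
                            exposure_slope = 2,
                            mpc_scale = TRUE) {
  check_proportion(q_threshold, "q_threshold")
  check_proportion(train_fraction, "train_fraction")
  check_proportion(truncation_quantile, "truncation_quantile")
  if (!is_count(n_components) || n_components < 1) abort("n_components must be >= 1")
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_components = as.integer(n_components), q_threshold = q_threshold,
         train_fraction = train_fraction,
         truncation_quantile = truncation_quantile,
         cv_folds = as.integer(cv_folds), n_adjusters = as.integer(n_adjusters),
         pop_model = pop_model, meth_model = meth_model,
         cohort_sizes = as.integer(cohort_sizes),
         exposure_intercept = exposure_intercept,
         exposure_slope = exposure_slope, mpc_scale = mpc_scale),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `pop_model` and
#' `meth_model` may be given as nested maps of their constructor arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$pop_model)) y$pop_model <- do.call(pop_model, y$pop_model)
  if (!is.null(y$meth_model)) y$meth_model <- do.call(meth_model, y$meth_model)
  do.call(pipeline_config, y)
}

stage_msg <- function(stage, ...) {
  inform(paste0("[", stage, "] ", sprintf(...)))
}

#' Run the full pipeline on simulated cohorts
#'
#' Executes every stage in order and writes all artifacts under
#' `config$out_dir`: the simulated cohort files, GPC scores/loadings, one
#' meta-analysis table per component, the portable weight file, test-set MPS
#' scores, the evaluation report, the three-way EWAS comparison
#' (unadjusted / MPS-adjusted / GPC-adjusted), and a manifest checksumming
#' every emitted file together with the configuration. Rerunning with the
#' same seed reproduces identical checksums.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list with the trained models, evaluation report,
#'   EWAS summary, split sizes and the manifest tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # --- simulate ------------------------------------------------------------
  stage_msg("simulate", "%d cohorts, %d CpGs, %d variants",
            length(config$cohort_sizes), config$meth_model$n_cpgs,
            config$pop_model$n_variants)
  cohorts <- simulate_cohorts(config$pop_model, config$meth_model,
                              config$cohort_sizes,
                              seed = derive_seed(config$seed, "simulate"))
  ancestry_cpgs <- attr(cohorts, "ancestry_cpgs")
  sim_dir <- file.path(out, "sim")
  for (ds in cohorts) write_cohort(ds, sim_dir)

  # --- split ---------------------------------------------------------------
  split <- split_train_test(cohorts, config$train_fraction,
                            seed = derive_seed(config$seed, "split"))
  split_sizes <- tibble(
    cohort = vapply(cohorts, function(d) d$cohort_id, ""),
    n_train = vapply(split$train, function(d) length(d$sample_ids), 1L),
    n_test = vapply(split$test, function(d) length(d$sample_ids), 1L)
  )
  stage_msg("split", "train %d / test %d at fraction %.2f",
            sum(split_sizes$n_train), sum(split_sizes$n_test),
            config$train_fraction)
  readr::write_tsv(split_sizes, file.path(out, "split_sizes.tsv"))

  # --- gpca (central, on all samples) --------------------------------------
  geno_all <- dplyr::bind_rows(lapply(cohorts, function(d) d$genotypes))
  gpcs <- compute_gpcs(geno_all, config$n_components)
  k <- length(gpcs$eigenvalues)
  stage_msg("gpca", "%d components on %d samples", k, nrow(geno_all))
  write_sample_table(gpcs$scores, file.path(out, "gpc_scores.tsv"))
  readr::write_tsv(tibble(component = paste0("GPC", seq_len(k)),
                          eigenvalue = gpcs$eigenvalues),
                   file.path(out, "gpc_eigenvalues.tsv"))

  # --- select --------------------------------------------------------------
  meta_dir <- file.path(out, "meta")
  dir.create(meta_dir, showWarnings = FALSE)
  selected <- vector("list", k)
  names(selected) <- as.character(seq_len(k))
  for (j in seq_len(k)) {
    assocs <- lapply(split$train, cohort_scan, gpc_scores = gpcs$scores,
                     gpc_index = j)
    meta <- meta_scan(meta_fixed(assocs), config$q_threshold)
    selected[[j]] <- meta$cpg[meta$selected]
    readr::write_tsv(meta, file.path(meta_dir, sprintf("gpc%d.meta.tsv", j)),
                     na = "NA")
  }
  stage_msg("select", "CpGs selected per component: %s",
            paste(lengths(selected), collapse = ", "))

  # --- train ---------------------------------------------------------------
  models <- train_mps(split$train, gpcs, selected,
                      truncation_quantile = config$truncation_quantile,
                      cv_folds = config$cv_folds,
                      seed = derive_seed(config$seed, "train"))
  weights_path <- file.path(out, "weights.tsv")
  write_weights(models, weights_path)
  stage_msg("train", "nonzero weights per component: %s",
            paste(vapply(models, function(m) length(m$weights), 1L),
                  collapse = ", "))

  # --- apply + evaluate on the test split ----------------------------------
  test_agg <- aggregate_cohorts(split$test)
  mps_test <- compute_mps(test_agg$methylation, models)
  write_sample_table(mps_test, file.path(out, "mps_test_scores.tsv"))
  gpc_test <- gpcs$scores[match(test_agg$sample_ids, gpcs$scores$sample_id), ]
  report <- correlation_report(mps_test, gpc_test)
  readr::write_tsv(tidy(report), file.path(out, "eval_correlation.tsv"))
  C_test <- covariate_design(test_agg$covariates, exclude = "alcohol")
  ve <- vapply(seq_len(k), function(j) {
    mj <- mps_test[[paste0("MPS", j)]]
    if (is.null(mj) || sd(mj) == 0) return(NA_real_)
    variance_explained(gpc_test[[paste0("GPC", j)]], mj, C_test)
  }, 1)
  readr::write_tsv(tibble(component = seq_len(k), var_explained = ve),
                   file.path(out, "eval_var_explained.tsv"), na = "NA")
  stage_msg("evaluate", "R2(MPS1, GPC1) = %.3f on %d test samples",
            report$r2_diag[1], report$n_test)

  mpc <- tryCatch(
    pca_on_cpg_subset(test_agg$methylation, ancestry_cpgs,
                      n_components = min(k, 3), scale = config$mpc_scale),
    error = function(e) NULL)
  if (!is.null(mpc)) {
    write_sample_table(mpc$scores, file.path(out, "mpc_scores.tsv"))
  }

  # --- ewas comparison on the test split -----------------------------------
  truth_test <- test_agg$truth
  exposure <- simulate_exposure(truth_test, config$exposure_intercept,
                                config$exposure_slope,
                                seed = derive_seed(config$seed, "exposure"))
  ew_cov <- test_agg$covariates[c("sample_id", "age", "sex", "smoking", "bmi",
                                  grep("^cell", names(test_agg$covariates),
                                       value = TRUE))]
  na <- min(config$n_adjusters, k)
  scans <- list(
    none = run_ewas(test_agg$methylation, exposure, ew_cov,
                    adjustment_mode = "none"),
    mps = run_ewas(test_agg$methylation, exposure, ew_cov,
                   adjusters = mps_test, n_adjusters = na,
                   adjustment_mode = "mps"),
    gpc = run_ewas(test_agg$methylation, exposure, ew_cov,
                   adjusters = gpc_test, n_adjusters = na,
                   adjustment_mode = "gpc")
  )
  ewas_summary <- dplyr::bind_rows(lapply(scans, glance))
  readr::write_tsv(ewas_summary, file.path(out, "ewas_summary.tsv"))
  for (nm in names(scans)) {
    readr::write_tsv(as_tibble(scans[[nm]]),
                     file.path(out, sprintf("ewas_%s.tsv", nm)), na = "NA")
    readr::write_tsv(qq_data(scans[[nm]]),
                     file.path(out, sprintf("ewas_%s.qq.tsv", nm)))
  }
  stage_msg("ewas", "lambda_gc: none=%.3f mps=%.3f gpc=%.3f",
            ewas_summary$lambda_gc[1], ewas_summary$lambda_gc[2],
            ewas_summary$lambda_gc[3])

  # --- manifest ------------------------------------------------------------
  cfg_path <- file.path(out, "config.yaml")
  cfg <- config
  cfg$out_dir <- NULL   # keep the manifest independent of where it was run
  cfg$pop_model <- unclass(cfg$pop_model)
  cfg$meth_model <- lapply(unclass(cfg$meth_model), function(x) {
    if (is.numeric(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(unclass(cfg), cfg_path)
  files <- sort(setdiff(list.files(out, recursive = TRUE), "manifest.tsv"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(out, files)))
  )
  readr::write_tsv(manifest, file.path(out, "manifest.tsv"))
  stage_msg("manifest", "%d files checksummed", nrow(manifest))

  invisible(list(models = models, report = report, var_explained = ve,
                 ewas = ewas_summary, split_sizes = split_sizes,
                 manifest = manifest, selected = selected,
                 out_dir = out))
}
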