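# Stage-2 training: two-stage weighted Lasso per genetic PC, score
# application, portable weight files.

new_mps_model <- function(gpc_index, weights, intercept, stage, lambda,
                          cpg_universe, training_meta = list()) {
  stopifnot(all(names(weights) %in% cpg_universe))
  structure(
    list(gpc_index = as.integer(gpc_index),
         weights = weights, intercept = as.numeric(intercept),
         stage = as.integer(stage), lambda = as.numeric(lambda),
         cpg_universe = cpg_universe, training_meta = training_meta),
    class = "mps_model"
  )
}

#' @export
print.mps_model <- function(x, ...) {
  cat(sprintf("<mps_model> GPC%d stage %d: %d nonzero CpG weights (lambda = %.4g)\n",
              x$gpc_index, x$stage, length(x$weights), x$lambda))
  invisible(x)
}

#' @export
print.mps_model_set <- function(x, ...) {
  cat(sprintf("<mps_model_set> %d models (GPC %s)\n", length(x),
              paste(vapply(x, function(m) m$gpc_index, 1L), collapse = ", ")))
  invisible(x)
}

#' Fit one Lasso stage with unpenalized covariates
#'
#' L1-penalized least squares of a GPC score on selected CpG beta values,
#' with covariates entering as unpenalized predictors (penalty factor 0) and
#' optional per-observation weights in the loss. Predictors are standardized
#' internally; coefficients are returned on the original beta-value scale.
#' When `lambda` is `NULL` it is chosen by V-fold cross-validation minimizing
#' weighted mean squared error, with seeded fold assignment.
#'
#' @param y Numeric outcome vector (a GPC score).
#' @param cpgs Penalized predictor matrix (samples x CpGs) or tibble with
#'   `sample_id`; columns must be named by CpG id.
#' @param covariates Optional unpenalized design: a numeric matrix, or a
#'   covariate tibble passed through [covariate_design()].
#' @param obs_weights Optional positive observation weights (see
#'   [residual_weights()]); default uniform.
#' @param lambda Optional fixed penalty; default cross-validated.
#' @param cv_folds Number of CV folds when `lambda` is `NULL`.
#' @param seed Integer seed for fold assignment.
#' @param gpc_index Component index recorded in the model.
#' @param stage Stage label (1 or 2) recorded in the model.
#'
#' @return An `mps_model`: sparse CpG weight map, intercept, penalty,
#'   CpG universe and training metadata. If the cross-validated fit keeps no
#'   CpG, an empty-weight model is returned with a warning.
#' @export
fit_lasso_stage <- function(y, cpgs, covariates = NULL, obs_weights = NULL,
                            lambda = NULL, cv_folds = 10L, seed = 1L,
                            gpc_index = 1L, stage = 1L) {
  M <- if (is.matrix(cpgs)) cpgs else as_feature_matrix(cpgs, "cpgs")
  if (ncol(M) < 1) abort(sprintf("no selected CpGs for GPC %d", gpc_index))
  n <- length(y)
  stopifnot(nrow(M) == n)
  C <- if (is.null(covariates)) {
    matrix(numeric(0), nrow = n, ncol = 0)
  } else if (is.matrix(covariates)) {
    covariates
  } else {
    covariate_design(covariates)
  }
  w <- obs_weights %||% rep(1, n)
  if (any(w <= 0)) abort("observation weights must be positive")

  x <- cbind(C, M)
  pf <- c(rep(0, ncol(C)), rep(1, ncol(M)))
  pad <- FALSE
  if (ncol(x) < 2) {              # glmnet needs >= 2 columns
    x <- cbind(x, .pad. = 0)
    pf <- c(pf, 1)
    pad <- TRUE
  }

  fit <- glmnet::glmnet(x, y, weights = w, penalty.factor = pf,
                        standardize = TRUE, thresh = 1e-12)
  rule <- "fixed"
  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(cv_folds), n)))
    cv <- glmnet::cv.glmnet(x, y, weights = w, penalty.factor = pf,
                            foldid = foldid, standardize = TRUE,
                            thresh = 1e-12)
    lambda <- cv$lambda.min
    rule <- "cv.min"
  }
  cf <- as.matrix(coef(fit, s = lambda, exact = TRUE, x = x, y = y,
                       weights = w, penalty.factor = pf))
  intercept <- cf[1, 1]
  cpg_cols <- colnames(M)
  beta <- setNames(cf[cpg_cols, 1], cpg_cols)
  nz <- beta[beta != 0]
  if (length(nz) == 0 && rule == "cv.min") {
    warn(sprintf("GPC %d stage %d: cross-validated Lasso kept no CpG; returning empty model",
                 gpc_index, stage))
  }
  new_mps_model(gpc_index, nz, intercept, stage, lambda,
                cpg_universe = cpg_cols,
                training_meta = list(seed = seed, n = n,
                                     cv_folds = if (rule == "cv.min") cv_folds else NA_integer_,
                                     selection_rule = rule,
                                     weighted = !is.null(obs_weights)))
}

#' Apply MPS weights to a methylation matrix
#'
#' Computes each sample's methylation population score as the weighted sum
#' of CpG beta values, `score_s = sum_j w_j beta_sj`, over the CpGs present
#' in the data. The intercept is excluded: downstream uses (correlation,
#' regression adjustment) are location-invariant. CpGs entirely absent from
#' the data are dropped from the sum and the coverage fraction is reported;
#' per-sample missing values are imputed by the data's own per-CpG mean.
#'
#' @param methylation Beta-value tibble (`sample_id` + CpG columns) or
#'   matrix.
#' @param model An `mps_model`, or an `mps_model_set` / list of models.
#'
#' @return Tibble with `sample_id` and one `MPS<k>` column per model, with a
#'   `coverage` attribute giving the fraction of each model's weighted CpGs
#'   found in the data.
#' @export
compute_mps <- function(methylation, model) {
  M <- if (is.matrix(methylation)) methylation else {
    as_feature_matrix(methylation, "methylation")
  }
  models <- if (inherits(model, "mps_model")) list(model) else model
  # mean-impute missing cells using this data's own CpG means
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  scores <- matrix(0, nrow(M), length(models))
  coverage <- numeric(length(models))
  cn <- character(length(models))
  for (i in seq_along(models)) {
    m <- models[[i]]
    cn[i] <- paste0("MPS", m$gpc_index)
    if (length(m$weights) == 0) {
      coverage[i] <- 1
      next
    }
    present <- intersect(names(m$weights), colnames(M))
    if (length(present) == 0) {
      abort(sprintf("no weighted CpG of GPC %d present in the data", m$gpc_index))
    }
    coverage[i] <- length(present) / length(m$weights)
    if (coverage[i] < 1) {
      inform(sprintf("MPS%d: %d of %d weighted CpGs present (coverage %.2f)",
                     m$gpc_index, length(present), length(m$weights), coverage[i]))
    }
    scores[, i] <- M[, present, drop = FALSE] %*% m$weights[present]
  }
  colnames(scores) <- cn
  rownames(scores) <- rownames(M)
  out <- matrix_to_tbl(scores)
  attr(out, "coverage") <- setNames(coverage, cn)
  out
}

#' Observation weights from squared residuals
#'
#' The normalization used for the second Lasso stage: squared residuals are
#' truncated above their empirical `truncation_quantile` (linear
#' interpolation between order statistics, R quantile type 7) to that
#' quantile, floored at a tiny positive value so every weight is strictly
#' positive, and rescaled so the weights sum to the sample size.
#'
#' @param sq_resid Nonnegative squared residuals.
#' @param truncation_quantile Truncation level in `(0, 1)`, default 0.90.
#'
#' @return Numeric weights of class `obs_weights` summing to `n`, with
#'   attributes `cap` (the truncation value on the normalized scale) and
#'   `truncation_quantile`.
#' @export
normalize_obs_weights <- function(sq_resid, truncation_quantile = 0.9) {
  check_proportion(truncation_quantile, "truncation_quantile")
  if (any(sq_resid < 0)) abort("squared residuals must be nonnegative")
  n <- length(sq_resid)
  cap <- unname(quantile(sq_resid, truncation_quantile, type = 7))
  r <- pmin(sq_resid, cap)
  r <- pmax(r, 1e-12 * max(cap, 1))   # strict positivity
  w <- r * n / sum(r)
  structure(w, cap = cap * n / sum(r),
            truncation_quantile = truncation_quantile, class = "obs_weights")
}

#' Individual observation weights from an initial MPS fit
#'
#' Regresses a GPC on its initial MPS without covariate adjustment and turns
#' the squared residuals into observation weights via
#' [normalize_obs_weights()]: truncated at the `truncation_quantile`
#' empirical quantile, normalized to sum to the sample size. Samples whose
#' GPC is poorly predicted by the initial score (typically those from
#' populations with higher GPC variance) get larger weights in the second
#' Lasso stage.
#'
#' @param y GPC score vector.
#' @param mps_initial Initial MPS score vector (same length >= 3, not
#'   constant).
#' @param truncation_quantile Truncation level, default 0.90.
#'
#' @return `obs_weights` vector (see [normalize_obs_weights()]).
#' @export
residual_weights <- function(y, mps_initial, truncation_quantile = 0.9) {
  if (length(y) != length(mps_initial) || length(y) < 3) {
    abort("y and mps_initial must have equal length >= 3")
  }
  if (sd(mps_initial) == 0) abort("mps_initial is constant; slope undefined")
  r <- residuals(lm(y ~ mps_initial))
  normalize_obs_weights(r^2, truncation_quantile)
}

# Stack cohorts on their common CpG universe; covariates gain a `cohort`
# column standing in for study center.
aggregate_cohorts <- function(datasets) {
  if (inherits(datasets, "cohort_dataset")) datasets <- list(datasets)
  common <- Reduce(intersect, lapply(datasets, function(d) names(d$methylation)))
  meth <- dplyr::bind_rows(lapply(datasets, function(d) d$methylation[common]))
  covar <- dplyr::bind_rows(lapply(datasets, function(d) {
    mutate(d$covariates, cohort = d$cohort_id)
  }))
  if (anyDuplicated(meth$sample_id)) abort("duplicate sample_id across cohorts")
  truth <- if (all(!vapply(datasets, function(d) is.null(d$truth), TRUE))) {
    dplyr::bind_rows(lapply(datasets, function(d) d$truth))
  } else NULL
  list(methylation = meth, covariates = covar, truth = truth,
       sample_ids = meth$sample_id)
}

#' Train methylation population scores
#'
#' The full stage-2 procedure, per genetic PC: (1) Lasso with uniform
#' weights on the FDR-selected CpGs, covariates unpenalized (alcohol use is
#' excluded here, reflecting its partial availability); (2) the initial MPS
#' is computed from the stage-1 weights; (3) observation weights are derived
#' from the squared residuals of GPC ~ initial MPS, truncated at the 0.90
#' quantile and normalized to sum to n; (4) a second Lasso with those
#' observation weights produces the final model. All stage seeds derive from
#' one master seed. If stage 1 keeps no CpG (e.g. under a null simulation),
#' a degenerate empty model is returned for that component with a warning.
#'
#' @param train List of training [cohort_dataset()] objects; they are
#'   aggregated on their common CpG universe, with the cohort label entering
#'   the covariates as study center.
#' @param gpcs A `gpc_set` or GPC score tibble covering the training
#'   samples.
#' @param selected List of CpG id vectors, one per component to train (from
#'   [select_cpgs()]); names or positions give the GPC index.
#' @param truncation_quantile Truncation level for the observation weights.
#' @param cv_folds Cross-validation folds for the penalty.
#' @param seed Master seed.
#'
#' @return An `mps_model_set` (list of stage-2 `mps_model` objects).
#' @export
train_mps <- function(train, gpcs, selected, truncation_quantile = 0.9,
                      cv_folds = 10L, seed = 1L) {
  agg <- aggregate_cohorts(train)
  s <- if (inherits(gpcs, "gpc_set")) as_feature_matrix(gpcs$scores) else {
    as_feature_matrix(gpcs, "gpcs")
  }
  s <- align_rows(s, agg$sample_ids, "gpc scores")
  M <- as_feature_matrix(agg$methylation, "methylation")
  C <- covariate_design(agg$covariates, exclude = "alcohol")
  idx <- if (!is.null(names(selected))) as.integer(names(selected)) else {
    seq_along(selected)
  }

  models <- vector("list", length(selected))
  for (i in seq_along(selected)) {
    k <- idx[i]
    cpgs_k <- intersect(selected[[i]], colnames(M))
    y <- s[, k]
    if (length(cpgs_k) == 0) {
      warn(sprintf("GPC %d: empty selection; returning degenerate model", k))
      models[[i]] <- new_mps_model(k, setNames(numeric(0), character(0)),
                                   mean(y), 1L, NA_real_, character(0),
                                   list(seed = seed, n = length(y),
                                        degenerate = TRUE))
      next
    }
    Mk <- M[, cpgs_k, drop = FALSE]
    stage1 <- fit_lasso_stage(y, Mk, C, obs_weights = NULL,
                              cv_folds = cv_folds,
                              seed = derive_seed(seed, paste0("stage1_gpc", k)),
                              gpc_index = k, stage = 1L)
    mps_i <- compute_mps(M, stage1)[[paste0("MPS", k)]]
    if (length(stage1$weights) == 0 || sd(mps_i) == 0) {
      warn(sprintf("GPC %d: stage-1 score is degenerate; returning stage-1 model", k))
      stage1$training_meta$degenerate <- TRUE
      models[[i]] <- stage1
      next
    }
    ow <- residual_weights(y, mps_i, truncation_quantile)
    stage2 <- fit_lasso_stage(y, Mk, C, obs_weights = as.numeric(ow),
                              cv_folds = cv_folds,
                              seed = derive_seed(seed, paste0("stage2_gpc", k)),
                              gpc_index = k, stage = 2L)
    stage2$training_meta$master_seed <- seed
    stage2$training_meta$truncation_quantile <- truncation_quantile
    stage2$training_meta$stage1_support <- names(stage1$weights)
    models[[i]] <- stage2
  }
  structure(models, class = "mps_model_set")
}

#' @rdname fit_lasso_stage
#' @param x An `mps_model` or `mps_model_set`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.mps_model <- function(x, ...) {
  tibble(gpc_index = x$gpc_index, cpg = names(x$weights),
         weight = unname(x$weights))
}

#' @rdname fit_lasso_stage
#' @exportS3Method generics::tidy
tidy.mps_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, tidy))
}

#' @rdname fit_lasso_stage
#' @exportS3Method generics::glance
glance.mps_model <- function(x, ...) {
  tibble(gpc_index = x$gpc_index, stage = x$stage,
         n_weights = length(x$weights), lambda = x$lambda,
         n_train = x$training_meta$n %||% NA_integer_)
}

#' @rdname fit_lasso_stage
#' @exportS3Method generics::glance
glance.mps_model_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, glance))
}
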