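# Stage-1 feature selection: per-cohort covariate-adjusted CpG-GPC scans,
# inverse-variance fixed-effects meta-analysis, BH-FDR selection.

#' Build a covariate design matrix
#'
#' Turns a covariate tibble into a numeric design matrix (no intercept
#' column). Numeric columns enter as-is; character/factor columns
#' (e.g. self-reported group, study cohort) enter as treatment-coded
#' indicators; one cell-proportion column is dropped to avoid the simplex
#' collinearity. Columns that are absent or constant in the data are skipped
#' with a message — the "if applicable" convention for partially available
#' covariates such as alcohol use.
#'
#' @param covariates Tibble with `sample_id` plus covariate columns.
#' @param include Covariate names to use; default: every column present
#'   except `sample_id`.
#' @param exclude Covariate names to drop from `include`.
#'
#' @return Numeric matrix with one row per sample.
#' @export
covariate_design <- function(covariates, include = NULL, exclude = character()) {
  nms <- setdiff(names(covariates), "sample_id")
  include <- include %||% nms
  missing <- setdiff(include, nms)
  if (length(missing) > 0) {
    inform(paste0("covariate(s) not present, skipped: ",
                  paste(missing, collapse = ", ")))
  }
  use <- setdiff(intersect(include, nms), exclude)
  cell_cols <- grep("^cell", use, value = TRUE)
  if (length(cell_cols) > 1) use <- setdiff(use, cell_cols[length(cell_cols)])

  blocks <- list()
  for (v in use) {
    x <- covariates[[v]]
    if (is.numeric(x)) {
      if (length(unique(x)) < 2) {
        inform(paste0("covariate constant, skipped: ", v))
        next
      }
      blocks[[v]] <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      f <- factor(x)
      if (nlevels(f) < 2) {
        inform(paste0("covariate constant, skipped: ", v))
        next
      }
      mm <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(v, levels(f)[-1])
      blocks[[v]] <- mm
    }
  }
  if (length(blocks) == 0) {
    return(matrix(numeric(0), nrow = nrow(covariates), ncol = 0))
  }
  do.call(cbind, blocks)
}

# Residualize y (vector) and M (matrix) on [1, C] via QR; exact OLS by the
# Frisch-Waugh-Lovell theorem, vectorized over the columns of M.
fwl_scan <- function(y, M, C) {
  X <- cbind(`(Intercept)` = 1, C)
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) abort("not enough samples for the covariate design")
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  y_t <- y - Q %*% crossprod(Q, y)
  M_t <- M - Q %*% crossprod(Q, M)
  sxx <- colSums(M_t^2)
  df <- n - qrX$rank - 1L
  ok <- sxx > 1e-12 * n
  beta <- se <- pval <- rep(NA_real_, ncol(M))
  sxy <- as.vector(crossprod(M_t, y_t))
  syy <- sum(y_t^2)
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - beta[ok]^2 * sxx[ok], 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  tt <- beta[ok] / se[ok]
  pval[ok] <- 2 * pt(-abs(tt), df)
  list(beta = beta, se = se, p = pval, df = df, n = n, ok = ok)
}

#' Per-cohort association scan of a genetic PC against every CpG
#'
#' For each CpG `j` fits `GPC = a + b * CpG_j + covariates` by ordinary least
#' squares within one cohort and reports the CpG effect, its standard error
#' and a two-sided p-value from the t distribution with residual degrees of
#' freedom. Constant CpG columns yield NA rows with a message. The fit is
#' computed by residualizing on the covariates once (Frisch-Waugh-Lovell),
#' which is exact OLS and fast enough for epigenome-wide scans.
#'
#' @param dataset A [cohort_dataset()].
#' @param gpc_scores GPC score tibble (`sample_id` + `GPC*` columns) or
#'   matrix; rows are aligned to the cohort by `sample_id`.
#' @param gpc_index Which component to scan (1-based).
#' @param covariates Covariate names to adjust for; default: all available
#'   columns of the cohort covariate table. Absent or constant ones are
#'   skipped with a message.
#'
#' @return A tibble of class `cohort_assoc` with columns `cpg`, `beta`,
#'   `se`, `p`, `n`, `cohort_id`, `gpc_index`.
#' @export
cohort_scan <- function(dataset, gpc_scores, gpc_index = 1L, covariates = NULL) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  s <- as_feature_matrix(gpc_scores, "gpc_scores")
  s <- align_rows(s, dataset$sample_ids, "gpc_scores")
  if (gpc_index > ncol(s)) abort("gpc_index exceeds available components")
  y <- s[, gpc_index]
  M <- as_feature_matrix(dataset$methylation, "methylation")
  C <- covariate_design(dataset$covariates, include = covariates)
  fit <- fwl_scan(y, M, C)
  if (any(!fit$ok)) {
    inform(sprintf("cohort %s: %d constant CpG column(s) set to NA",
                   dataset$cohort_id, sum(!fit$ok)))
  }
  out <- tibble(cpg = colnames(M), beta = fit$beta, se = fit$se, p = fit$p,
                n = fit$n, cohort_id = dataset$cohort_id,
                gpc_index = as.integer(gpc_index))
  class(out) <- c("cohort_assoc", class(out))
  out
}

#' Inverse-variance fixed-effects meta-analysis of cohort scans
#'
#' Pools per-cohort CpG effects with weights `w_i = 1 / se_i^2`:
#' `pooled_beta = sum(w_i b_i) / sum(w_i)`, `pooled_se = sum(w_i)^(-1/2)`,
#' `z = pooled_beta / pooled_se`, `p = 2 * pnorm(-|z|)`. CpGs defined in only
#' some cohorts are pooled over those cohorts, with `n_cohorts` recording how
#' many contributed; CpGs with no defined estimate get an NA row.
#'
#' @param assocs List of `cohort_assoc` tibbles from [cohort_scan()] (one
#'   GPC at a time).
#'
#' @return A tibble with columns `cpg`, `pooled_beta`, `pooled_se`, `z`,
#'   `p`, `n_cohorts`, `gpc_index`.
#' @export
meta_fixed <- function(assocs) {
  if (inherits(assocs, "cohort_assoc")) assocs <- list(assocs)
  all <- dplyr::bind_rows(assocs)
  if (length(unique(all$gpc_index)) > 1) {
    abort("meta_fixed pools one GPC at a time")
  }
  cpg_order <- unique(all$cpg)
  out <- all |>
    group_by(.data$cpg) |>
    summarise(
      n_cohorts = sum(is.finite(.data$se)),
      pooled_beta = if (n_cohorts[1] > 0) {
        sum((.data$beta / .data$se^2)[is.finite(.data$se)]) /
          sum((1 / .data$se^2)[is.finite(.data$se)])
      } else NA_real_,
      pooled_se = if (n_cohorts[1] > 0) {
        1 / sqrt(sum((1 / .data$se^2)[is.finite(.data$se)]))
      } else NA_real_,
      gpc_index = .data$gpc_index[1],
      .groups = "drop"
    ) |>
    mutate(z = .data$pooled_beta / .data$pooled_se,
           p = 2 * pnorm(-abs(.data$z))) |>
    select("cpg", "pooled_beta", "pooled_se", "z", "p", "n_cohorts", "gpc_index")
  out[match(cpg_order, out$cpg), ]
}

#' Benjamini-Hochberg step-up q-values
#'
#' Adjusts p-values by the BH step-up procedure:
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, with the original order
#' restored. NA entries pass through as NA and do not count toward the
#' family size `m`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]` (NA allowed).
#'
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) abort("p-values must be in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  q
}

#' Add q-values and selection flags to a meta-analysis table
#'
#' @param meta Output of [meta_fixed()].
#' @param q_threshold FDR threshold; CpGs with `q < q_threshold` are flagged
#'   selected.
#' @return The input tibble with `q` and `selected` columns.
#' @export
meta_scan <- function(meta, q_threshold = 0.05) {
  meta |>
    mutate(q = bh_fdr(.data$p),
           selected = !is.na(.data$q) & .data$q < q_threshold)
}

#' Selected CpG ids at an FDR threshold
#'
#' @param meta Meta-analysis tibble carrying a `q` column (see
#'   [meta_scan()]).
#' @param q_threshold FDR threshold (default 0.05).
#' @return Character vector of CpG ids with `q < q_threshold`.
#' @export
select_cpgs <- function(meta, q_threshold = 0.05) {
  if (!"q" %in% names(meta)) abort("meta table has no q column; run meta_scan()")
  ids <- meta$cpg[!is.na(meta$q) & meta$q < q_threshold]
  inform(sprintf("selected %d of %d CpGs at q < %g", length(ids), nrow(meta),
                 q_threshold))
  ids
}
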