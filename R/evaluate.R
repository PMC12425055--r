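# Test-set evaluation: MPS-GPC correlations, covariate-adjusted variance
# explained, PCA-on-CpG-subset comparator, group-separation summaries.

#' Correlation report between MPS and GPC score matrices
#'
#' Full Pearson correlation matrix between every MPS and every GPC on
#' aligned samples, plus the squared diagonal correlations. Constant columns
#' yield NA entries with a warning.
#'
#' @param mps_scores Tibble (`sample_id` + `MPS*`) or matrix.
#' @param gpc_scores Tibble (`sample_id` + `GPC*`) or matrix.
#'
#' @return An `eval_report` with elements `correlation` (matrix, MPS rows x
#'   GPC columns), `r2_diag`, and `n_test`. `tidy()` returns the plot-ready
#'   long table.
#' @export
correlation_report <- function(mps_scores, gpc_scores) {
  A <- as_feature_matrix(mps_scores, "mps_scores")
  B <- as_feature_matrix(gpc_scores, "gpc_scores")
  B <- align_rows(B, rownames(A), "gpc_scores")
  const_a <- apply(A, 2, sd) == 0
  const_b <- apply(B, 2, sd) == 0
  if (any(const_a) || any(const_b)) {
    warn("constant score column(s); correlations set to NA")
  }
  r <- suppressWarnings(cor(A, B))
  r[const_a, ] <- NA_real_
  r[, const_b] <- NA_real_
  kk <- min(nrow(r), ncol(r))
  structure(
    list(correlation = r,
         r2_diag = setNames(diag(r[seq_len(kk), seq_len(kk), drop = FALSE])^2,
                            rownames(r)[seq_len(kk)]),
         n_test = nrow(A)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d\n", x$n_test))
  cat("diagonal R2:", paste(sprintf("%s=%.3f", names(x$r2_diag), x$r2_diag),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @rdname correlation_report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  as_tibble(as.data.frame.table(x$correlation, responseName = "r",
                                stringsAsFactors = FALSE)) |>
    rename(mps = "Var1", gpc = "Var2")
}

#' @rdname correlation_report
#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble(n_test = x$n_test,
         mean_r2_diag = mean(x$r2_diag, na.rm = TRUE),
         min_r2_diag = min(x$r2_diag, na.rm = TRUE),
         max_r2_diag = max(x$r2_diag, na.rm = TRUE))
}

#' @rdname correlation_report
#' @param object An `eval_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gpc, y = .data$mps,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Covariate-adjusted variance explained by an MPS for its GPC
#'
#' Partial R-squared of the MPS: the GPC is regressed on covariates alone
#' (reduced model) and on covariates plus the MPS (full model);
#' `partial R2 = (RSS_reduced - RSS_full) / RSS_reduced`. An MPS collinear
#' with the covariates contributes nothing and reports ~0 with a warning.
#'
#' @param gpc GPC score vector.
#' @param mps MPS score vector, aligned.
#' @param covariates Covariate tibble (passed through [covariate_design()])
#'   or numeric design matrix; `NULL` for the unadjusted R-squared.
#'
#' @return Partial R-squared in `[0, 1]`.
#' @export
variance_explained <- function(gpc, mps, covariates = NULL) {
  n <- length(gpc)
  stopifnot(length(mps) == n)
  C <- if (is.null(covariates)) {
    matrix(numeric(0), n, 0)
  } else if (is.matrix(covariates)) covariates else covariate_design(covariates)
  if (n <= ncol(C) + 2) abort("not enough samples for the covariate design")
  fit_red <- lm.fit(cbind(1, C), gpc)
  rss_red <- sum(fit_red$residuals^2)
  fit_full <- lm.fit(cbind(1, C, mps), gpc)
  rss_full <- sum(fit_full$residuals^2)
  if (any(is.na(fit_full$coefficients[length(fit_full$coefficients)]))) {
    warn("MPS collinear with covariates; partial R2 ~ 0")
    return(0)
  }
  max(0, (rss_red - rss_full) / rss_red)
}

#' Methylation principal components on a supplied CpG subset
#'
#' The unsupervised comparator: PCA restricted to a user-supplied list of
#' CpGs (e.g. a published set of genetically informative probes). Missing
#' cells are imputed by the per-CpG mean across samples before PCA; columns
#' are centered and, by default, scaled to unit variance. The number of
#' requested versus found CpGs is reported, since published lists typically
#' overlap the data only partially.
#'
#' @param methylation Beta-value tibble or matrix.
#' @param cpg_list Character vector of requested CpG ids.
#' @param n_components Number of components.
#' @param scale Scale columns to unit variance (default `TRUE`); recorded in
#'   the result so either convention is reproducible.
#'
#' @return An `mpc_set` with `scores` (tibble, `MPC1..K`), `cpg_list_used`,
#'   `n_requested`, `n_found`, `scaled`.
#' @export
pca_on_cpg_subset <- function(methylation, cpg_list, n_components = 10L,
                              scale = TRUE) {
  M <- if (is.matrix(methylation)) methylation else {
    as_feature_matrix(methylation, "methylation")
  }
  found <- intersect(cpg_list, colnames(M))
  if (length(found) < 2) abort("fewer than 2 requested CpGs present")
  X <- M[, found, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  X <- scale(X[, keep, drop = FALSE], center = TRUE, scale = scale)
  sv <- svd(X)
  k <- min(n_components, sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]))
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  s <- u %*% diag(sv$d[seq_len(k)], k, k)
  dimnames(s) <- list(rownames(M), paste0("MPC", seq_len(k)))
  structure(
    list(scores = matrix_to_tbl(s),
         cpg_list_used = colnames(X),
         n_requested = length(cpg_list), n_found = length(found),
         scaled = scale),
    class = "mpc_set"
  )
}

#' @export
print.mpc_set <- function(x, ...) {
  cat(sprintf("<mpc_set> %d components on %d/%d requested CpGs\n",
              ncol(x$scores) - 1L, x$n_found, x$n_requested))
  invisible(x)
}

#' Group-separation table and summary for score matrices
#'
#' Exports scores in long (tidy) form for scatter / parallel-coordinate
#' plots, together with a per-component scalar separation summary: the
#' one-way between-group to within-group sum-of-squares ratio. This summary
#' is a convenience metric of this package for automated comparison of score
#' sets; group separation is usually judged visually.
#'
#' @param scores Score tibble (`sample_id` + components) or matrix.
#' @param labels Per-sample group labels (e.g. self-reported race/ethnicity
#'   or latent population).
#'
#' @return A `group_separation` object: `table` (tibble `sample_id`,
#'   `component`, `value`, `label`) and `summary` (tibble `component`,
#'   `separation_ratio`). With a single group the ratio is NA.
#' @export
group_separation_table <- function(scores, labels) {
  S <- as_feature_matrix(scores, "scores")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(S))
  long <- matrix_to_tbl(S) |>
    mutate(label = labels) |>
    tidyr::pivot_longer(-c("sample_id", "label"),
                        names_to = "component", values_to = "value") |>
    select("sample_id", "component", "value", "label")
  ratio_one <- function(v, g) {
    if (length(unique(g)) < 2) return(NA_real_)
    mu <- mean(v)
    ssb <- sum(tapply(v, g, function(x) length(x) * (mean(x) - mu)^2))
    ssw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2)))
    if (ssw == 0) return(Inf)
    ssb / ssw
  }
  summary <- tibble(
    component = colnames(S),
    separation_ratio = apply(S, 2, ratio_one, g = labels)
  )
  structure(list(table = long, summary = summary), class = "group_separation")
}

#' @export
print.group_separation <- function(x, ...) {
  cat("<group_separation>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname group_separation_table
#' @param x A `group_separation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.group_separation <- function(x, ...) x$table

#' @rdname group_separation_table
#' @param object A `group_separation`.
#' @exportS3Method ggplot2::autoplot
autoplot.group_separation <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(x = .data$component, y = .data$value,
                               colour = .data$label)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "score", colour = NULL) +
    ggplot2::theme_minimal()
}
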