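# Exposure EWAS with selectable population-structure adjustment and the
# genomic inflation factor.

CHISQ1_MEDIAN <- 0.4549364  # median of the 1-df chi-square distribution

#' Epigenome-wide association scan of a binary exposure
#'
#' For each CpG fits `CpG_j ~ exposure + covariates (+ adjusters)` by
#' ordinary least squares (linear model on the beta-value scale, the
#' conventional EWAS orientation) and reports the exposure effect, standard
#' error and two-sided t p-value. `adjusters` carries the
#' population-structure correction — GPC scores, MPS scores, or the latent
#' truth in simulations; `NULL` runs the unadjusted scan. Alongside the
#' per-CpG table the scan records its genomic inflation factor, Bonferroni
#' counts at the family size of tested CpGs, and BH q-values.
#'
#' @param methylation Beta-value tibble or matrix (outcome, one scan per
#'   column).
#' @param exposure Binary 0/1 vector, or a tibble with `sample_id` and
#'   `exposure` columns (aligned by id).
#' @param covariates Optional covariate tibble or design matrix.
#' @param adjusters Optional score tibble/matrix of structure adjusters;
#'   only the first `n_adjusters` columns are used.
#' @param n_adjusters How many adjuster columns to include (default all).
#' @param adjustment_mode Label stored with the result (`"none"`, `"gpc"`,
#'   `"mps"`, ...); defaults to `"none"` when `adjusters` is `NULL` and
#'   `"custom"` otherwise.
#' @param alpha Significance level for the Bonferroni count.
#'
#' @return An `ewas_table`: tibble with columns `cpg`, `beta`, `se`, `p`,
#'   `q`, `sig_bonferroni`, plus attributes `lambda_gc`, `adjustment_mode`,
#'   `n_adjusters`, `n`. `glance()` returns the scan-level summary and
#'   `qq_data()` the observed-vs-expected quantile pairs.
#' @export
run_ewas <- function(methylation, exposure, covariates = NULL,
                     adjusters = NULL, n_adjusters = NULL,
                     adjustment_mode = NULL, alpha = 0.05) {
  M <- if (is.matrix(methylation)) methylation else {
    as_feature_matrix(methylation, "methylation")
  }
  if (is.data.frame(exposure)) {
    e <- exposure$exposure[match(rownames(M), exposure$sample_id)]
  } else {
    e <- exposure
  }
  e <- as.numeric(e)
  if (anyNA(e)) abort("exposure missing for some samples")
  if (!all(e %in% c(0, 1))) abort("exposure must be binary 0/1")
  if (length(unique(e)) < 2) abort("exposure is constant")
  n <- nrow(M)
  C <- if (is.null(covariates)) {
    matrix(numeric(0), n, 0)
  } else if (is.matrix(covariates)) covariates else covariate_design(covariates)
  A <- NULL
  if (!is.null(adjusters)) {
    A <- as_feature_matrix(adjusters, "adjusters")
    A <- align_rows(A, rownames(M), "adjusters")
    if (!is.null(n_adjusters)) {
      A <- A[, seq_len(min(n_adjusters, ncol(A))), drop = FALSE]
    }
  }
  mode <- adjustment_mode %||% if (is.null(A)) "none" else "custom"

  # FWL, swapped orientation: residualize the exposure and all CpG outcomes
  # on [1, covariates, adjusters]; per-CpG slope of outcome on exposure.
  Z <- cbind(`(Intercept)` = 1, C, A)
  qrZ <- qr(Z)
  Q <- qr.Q(qrZ)[, seq_len(qrZ$rank), drop = FALSE]
  e_t <- e - Q %*% crossprod(Q, e)
  sxx <- sum(e_t^2)
  if (sxx < 1e-10) abort("exposure collinear with covariates/adjusters")
  M_t <- M - Q %*% crossprod(Q, M)
  df <- n - qrZ$rank - 1L
  sxy <- as.vector(crossprod(M_t, e_t))
  syy <- unname(colSums(M_t^2))
  beta <- sxy / sxx
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  const <- apply(M, 2, function(x) length(unique(x)) < 2)
  beta[const] <- se[const] <- NA_real_
  tt <- beta / se
  p <- 2 * pt(-abs(tt), df)

  m_tested <- sum(!is.na(p))
  out <- tibble(cpg = colnames(M), beta = beta, se = se, p = p,
                q = bh_fdr(p),
                sig_bonferroni = !is.na(p) & p < alpha / m_tested)
  class(out) <- c("ewas_table", class(out))
  attr(out, "lambda_gc") <- genomic_inflation(p)
  attr(out, "adjustment_mode") <- mode
  attr(out, "n_adjusters") <- if (is.null(A)) 0L else ncol(A)
  attr(out, "n") <- n
  out
}

#' Genomic inflation factor from p-values
#'
#' Converts each p-value to a 1-df chi-square quantile,
#' `chi2 = Q_chisq1(1 - p)`, and returns
#' `lambda = median(chi2) / 0.4549364`, the chi-square-1 median. Lambda near
#' 1 indicates a calibrated scan; values above 1 indicate inflation, e.g.
#' from unadjusted population stratification. Underflowed `p = 0` entries
#' are clamped to the smallest positive double with a warning.
#'
#' @param pvalues Numeric p-values (NA ignored; at least one non-NA).
#'
#' @return The scalar inflation factor.
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0) abort("no non-NA p-values")
  if (any(p == 0)) {
    warn("p-values of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  chi2 <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chi2) / CHISQ1_MEDIAN
}

#' Observed vs expected quantiles for a QQ plot
#'
#' @param ewas An `ewas_table` (or any p-value vector).
#' @return Tibble with sorted `expected` and `observed` `-log10(p)` pairs.
#' @export
qq_data <- function(ewas) {
  p <- if (is.data.frame(ewas)) ewas$p else ewas
  p <- sort(p[!is.na(p)])
  m <- length(p)
  tibble(expected = -log10((seq_len(m) - 0.5) / m),
         observed = -log10(pmax(p, .Machine$double.xmin)))
}

#' @rdname run_ewas
#' @param x An `ewas_table`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.ewas_table <- function(x, ...) {
  tibble(adjustment_mode = attr(x, "adjustment_mode"),
         n_adjusters = attr(x, "n_adjusters"),
         n = attr(x, "n"),
         n_cpgs = nrow(x),
         lambda_gc = attr(x, "lambda_gc"),
         n_significant_bonferroni = sum(x$sig_bonferroni, na.rm = TRUE),
         n_significant_fdr = sum(x$q < 0.05, na.rm = TRUE))
}

#' @rdname run_ewas
#' @param object An `ewas_table`.
#' @exportS3Method ggplot2::autoplot
autoplot.ewas_table <- function(object, ...) {
  df <- qq_data(object)
  lab <- sprintf("%s (lambda = %.2f)", attr(object, "adjustment_mode"),
                 attr(object, "lambda_gc"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(title = lab, x = "expected -log10(p)",
                  y = "observed -log10(p)") +
    ggplot2::theme_minimal()
}

#' Look up EWAS results in a benchmark CpG set
#'
#' Subsets the scan to a user-supplied benchmark list (e.g. previously
#' validated trait-associated CpGs) and recomputes BH q-values with the
#' family size equal to the benchmark subset actually tested, flagging hits
#' at `q < alpha`.
#'
#' @param ewas An `ewas_table` from [run_ewas()].
#' @param benchmark_cpgs Character vector of benchmark CpG ids.
#' @param alpha FDR level for the hit flag.
#'
#' @return Tibble `cpg`, `beta`, `se`, `p`, `q_benchmark`, `hit` (one row
#'   per benchmark CpG found; empty with a warning when none overlap).
#' @export
benchmark_lookup <- function(ewas, benchmark_cpgs, alpha = 0.05) {
  sub <- ewas[ewas$cpg %in% benchmark_cpgs,
              c("cpg", "beta", "se", "p"), drop = FALSE]
  sub <- as_tibble(sub)
  if (nrow(sub) == 0) {
    warn("no benchmark CpG overlaps the tested CpGs")
    return(mutate(sub, q_benchmark = numeric(0), hit = logical(0)))
  }
  sub |>
    mutate(q_benchmark = bh_fdr(.data$p),
           hit = !is.na(.data$q_benchmark) & .data$q_benchmark < alpha)
}
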