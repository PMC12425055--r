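#' Genetic principal components from genotype dosages
#'
#' Standard PCA on a complete dosage matrix: each variant is centered by its
#' mean dosage and scaled by `sqrt(2 p (1 - p))` with `p` the sample allele
#' frequency — the genotype standard deviation under Hardy-Weinberg
#' equilibrium, the convention of genotype PCA. Monomorphic variants are
#' dropped with a message. Scores are the top-K left singular vectors times
#' their singular values; the sign of each component is fixed so that its
#' largest-magnitude loading is positive, making output deterministic across
#' linear-algebra backends.
#'
#' The samples here are unrelated by construction, so plain PCA is used
#' rather than relatedness-aware methods (PC-AiR / PC-Relate) that real
#' cohort studies apply before computing such components.
#'
#' @param genotypes Samples x variants dosage matrix (values in `[0, 2]`), or
#'   a tibble with a `sample_id` column.
#' @param n_components Number of components K to keep; truncated to the
#'   matrix rank with a warning if larger.
#'
#' @return An object of class `gpc_set` with elements `sample_ids`, `scores`
#'   (tibble, `sample_id` + `GPC1..GPCK`), `loadings` (variants x K),
#'   `eigenvalues` (length K, nonincreasing), `variant_means`, `variant_sds`.
#' @export
compute_gpcs <- function(genotypes, n_components = 10L) {
  g <- as_feature_matrix(genotypes, "genotypes")
  if (!is_count(n_components) || n_components < 1) abort("n_components must be >= 1")
  p_hat <- colMeans(g) / 2
  mono <- p_hat <= 0 | p_hat >= 1
  if (all(mono)) abort("all variants are monomorphic")
  if (any(mono)) {
    inform(sprintf("dropping %d monomorphic variant(s)", sum(mono)))
    g <- g[, !mono, drop = FALSE]
    p_hat <- p_hat[!mono]
  }
  means <- 2 * p_hat
  sds <- sqrt(2 * p_hat * (1 - p_hat))
  z <- sweep(sweep(g, 2, means, "-"), 2, sds, "/")

  sv <- svd(z)
  tol <- max(dim(z)) * .Machine$double.eps * sv$d[1]
  rank <- sum(sv$d > tol)
  k <- min(n_components, nrow(z), ncol(z))
  if (k > rank) {
    warn(sprintf("n_components = %d exceeds rank %d; truncating", n_components, rank))
    k <- rank
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  # sign convention: largest-magnitude loading of each component is positive
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  scores <- u %*% diag(d, k, k)
  dimnames(scores) <- list(rownames(g), paste0("GPC", seq_len(k)))
  dimnames(v) <- list(colnames(g), paste0("GPC", seq_len(k)))

  structure(
    list(sample_ids = rownames(g),
         scores = matrix_to_tbl(scores),
         loadings = v,
         eigenvalues = d^2 / (nrow(z) - 1),
         variant_means = setNames(means, colnames(g)),
         variant_sds = setNames(sds, colnames(g))),
    class = "gpc_set"
  )
}

#' @export
print.gpc_set <- function(x, ...) {
  cat(sprintf("<gpc_set> %d samples, %d variants, %d components\n",
              length(x$sample_ids), nrow(x$loadings),
              length(x$eigenvalues)))
  invisible(x)
}

#' Project new samples onto trained genetic principal components
#'
#' Standardizes the new dosages with the training variant means and scales,
#' then multiplies by the stored loadings. The variant universe and order
#' must match training exactly.
#'
#' @param new_genotypes New samples x variants dosage matrix or tibble with
#'   `sample_id`.
#' @param gpcs A `gpc_set` from [compute_gpcs()].
#'
#' @return Tibble of projected scores (`sample_id` + `GPC1..GPCK`).
#' @export
project_gpcs <- function(new_genotypes, gpcs) {
  stopifnot(inherits(gpcs, "gpc_set"))
  g <- as_feature_matrix(new_genotypes, "new_genotypes")
  want <- rownames(gpcs$loadings)
  if (!all(want %in% colnames(g))) {
    bad <- setdiff(want, colnames(g))[1]
    abort(paste0("variant mismatch: ", bad, " absent from new genotypes"))
  }
  g <- g[, want, drop = FALSE]
  z <- sweep(sweep(g, 2, gpcs$variant_means, "-"), 2, gpcs$variant_sds, "/")
  s <- z %*% gpcs$loadings
  matrix_to_tbl(s)
}

#' @rdname compute_gpcs
#' @param x A `gpc_set`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gpc_set <- function(x, ...) {
  tidyr::pivot_longer(x$scores, -"sample_id",
                      names_to = "component", values_to = "score")
}

#' @rdname compute_gpcs
#' @exportS3Method generics::glance
glance.gpc_set <- function(x, ...) {
  tibble(n_samples = length(x$sample_ids),
         n_variants = nrow(x$loadings),
         n_components = length(x$eigenvalues),
         top_eigenvalue = x$eigenvalues[1])
}

#' @rdname compute_gpcs
#' @param object A `gpc_set`.
#' @param components Two components to plot.
#' @param labels Optional per-sample labels for coloring.
#' @exportS3Method ggplot2::autoplot
autoplot.gpc_set <- function(object, components = c(1, 2), labels = NULL, ...) {
  nm <- paste0("GPC", components)
  df <- object$scores
  df$label <- if (is.null(labels)) "all" else as.character(labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nm[1]]], y = .data[[nm[2]]],
                                   colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}
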