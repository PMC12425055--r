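#' Population model for synthetic genotypes
#'
#' Describes the latent population structure used by the synthetic-data
#' generator: a Balding-Nichols allele-frequency model with Dirichlet
#' admixture. Ancestral allele frequencies are drawn uniformly on
#' `maf_range`; each population's frequencies are drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` so that the between-population variance of
#' allele frequency is `F p (1-p)`, i.e. the nominal `fst`.
#'
#' @param n_populations Number of latent populations (>= 1).
#' @param fst Per-population differentiation, in `[0, 1)`. A scalar is
#'   recycled across populations. `fst = 0` collapses every population onto
#'   the ancestral frequency exactly.
#' @param n_variants Number of independent biallelic variants.
#' @param maf_range Interval within `(0, 0.5]` for the ancestral minor allele
#'   frequency.
#' @param admixture_concentration Symmetric Dirichlet concentration for
#'   per-sample ancestry proportions. Values `<= 0` are taken as the
#'   concentration-to-zero limit: each sample belongs entirely to one
#'   population, chosen uniformly.
#'
#' @return An object of class `pop_model`.
#' @export
pop_model <- function(n_populations = 2L, fst = 0.1, n_variants = 2000L,
                      maf_range = c(0.05, 0.5),
                      admixture_concentration = 0.5) {
  if (!is_count(n_populations) || n_populations < 1) abort("n_populations must be >= 1")
  fst <- rep_len(as.numeric(fst), n_populations)
  if (any(fst < 0) || any(fst >= 1)) abort("fst must be in [0, 1)")
  if (!is_count(n_variants) || n_variants < 1) abort("n_variants must be >= 1")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be an interval within (0, 0.5]")
  }
  structure(
    list(n_populations = as.integer(n_populations), fst = fst,
         n_variants = as.integer(n_variants), maf_range = as.numeric(maf_range),
         admixture_concentration = as.numeric(admixture_concentration)),
    class = "pop_model"
  )
}

#' Methylation model for synthetic beta values
#'
#' Controls how latent ancestry and confounding covariates shape simulated
#' CpG beta values. Each CpG has a baseline level drawn uniformly on
#' `(0.05, 0.95)`; a subset of `n_ancestry_cpgs` CpGs receives an mQTL-like
#' ancestry effect of `ancestry_effect_size` beta units per unit ancestry
#' proportion (random sign, random target population); covariates in
#' `covariate_effects` shift a random fraction of CpGs by the stated
#' magnitude per standard deviation of the covariate. Gaussian noise with
#' standard deviation `noise_sd` is added and the result clipped to `[0, 1]`.
#'
#' @param n_cpgs Total number of CpGs.
#' @param n_ancestry_cpgs Number of CpGs carrying ancestry effects
#'   (`<= n_cpgs`).
#' @param ancestry_effect_size Shift in beta value per unit ancestry
#'   proportion at affected CpGs.
#' @param covariate_effects Named numeric vector mapping covariate name
#'   (`age`, `sex`, `smoking`, `alcohol`, `bmi`, `cell1` ... `cell6`) to the
#'   beta shift per covariate standard deviation.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param covariate_affected_fraction Fraction of CpGs affected by each
#'   covariate with a declared effect.
#'
#' @return An object of class `meth_model`.
#' @export
meth_model <- function(n_cpgs = 2000L, n_ancestry_cpgs = 50L,
                       ancestry_effect_size = 0.2,
                       covariate_effects = c(age = 0.01, sex = 0.02,
                                             smoking = 0.02, bmi = 0.01,
                                             cell1 = 0.05, cell2 = 0.03),
                       noise_sd = 0.05,
                       covariate_affected_fraction = 0.2) {
  if (!is_count(n_cpgs) || n_cpgs < 1) abort("n_cpgs must be >= 1")
  if (!is_count(n_ancestry_cpgs) || n_ancestry_cpgs > n_cpgs) {
    abort("n_ancestry_cpgs must be a count <= n_cpgs")
  }
  if (noise_sd <= 0) abort("noise_sd must be positive")
  if (length(covariate_effects) && is.null(names(covariate_effects))) {
    abort("covariate_effects must be named")
  }
  structure(
    list(n_cpgs = as.integer(n_cpgs),
         n_ancestry_cpgs = as.integer(n_ancestry_cpgs),
         ancestry_effect_size = as.numeric(ancestry_effect_size),
         covariate_effects = covariate_effects,
         noise_sd = as.numeric(noise_sd),
         covariate_affected_fraction = as.numeric(covariate_affected_fraction)),
    class = "meth_model"
  )
}

known_sim_covariates <- function() {
  c("age", "sex", "smoking", "alcohol", "bmi", paste0("cell", 1:6))
}

# Dirichlet draws as normalized gammas; concentration <= 0 gives the one-hot
# limit with uniform population assignment.
rdirichlet_mat <- function(n, alpha) {
  k <- length(alpha)
  if (all(alpha <= 0)) {
    z <- sample.int(k, n, replace = TRUE)
    m <- matrix(0, n, k)
    m[cbind(seq_len(n), z)] <- 1
    return(m)
  }
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# Ancestral + per-population allele frequencies under Balding-Nichols.
draw_allele_freqs <- function(pop_model) {
  p <- runif(pop_model$n_variants, pop_model$maf_range[1], pop_model$maf_range[2])
  freqs <- matrix(NA_real_, pop_model$n_populations, pop_model$n_variants)
  for (k in seq_len(pop_model$n_populations)) {
    f <- pop_model$fst[k]
    if (f == 0) {
      freqs[k, ] <- p
    } else {
      freqs[k, ] <- stats::rbeta(pop_model$n_variants,
                                 p * (1 - f) / f, (1 - p) * (1 - f) / f)
    }
  }
  list(ancestral = p, by_population = freqs)
}

simulate_genotypes_given <- function(freqs, pop_model, n_samples, prefix = "s") {
  q <- rdirichlet_mat(n_samples, rep(pop_model$admixture_concentration,
                                     pop_model$n_populations))
  pi_mat <- q %*% freqs$by_population            # n x variants mixed frequency
  g <- matrix(rbinom(length(pi_mat), 2L, pi_mat), nrow = n_samples)
  ids <- sprintf("%s%04d", prefix, seq_len(n_samples))
  dimnames(g) <- list(ids, sprintf("var%05d", seq_len(ncol(g))))
  dimnames(q) <- list(ids, paste0("pop", seq_len(ncol(q))))
  list(genotypes = g, ancestry = q)
}

#' Simulate genotype dosages with latent population structure
#'
#' Draws a Balding-Nichols allele-frequency table, per-sample Dirichlet
#' ancestry proportions, and binomial genotype dosages at each sample's mixed
#' allele frequency. Deterministic given `seed`.
#'
#' @param pop_model A [pop_model()].
#' @param n_samples Number of samples (>= 2).
#' @param seed Integer seed.
#'
#' @return A list with `genotypes` (samples x variants dosage matrix, values
#'   in `[0, 2]`), `ancestry` (samples x populations latent proportions), and
#'   `allele_freqs` (the ancestral and per-population frequencies used).
#' @export
simulate_genotypes <- function(pop_model, n_samples, seed) {
  stopifnot(inherits(pop_model, "pop_model"))
  if (!is_count(n_samples) || n_samples < 2) abort("n_samples must be >= 2")
  with_seed(seed, {
    freqs <- draw_allele_freqs(pop_model)
    out <- simulate_genotypes_given(freqs, pop_model, n_samples)
    c(out, list(allele_freqs = freqs))
  })
}

simulate_covariates <- function(n, ids) {
  cell_alpha <- c(6, 2, 1.5, 1, 0.5, 0.3)
  cells <- rdirichlet_mat(n, cell_alpha)
  colnames(cells) <- paste0("cell", seq_along(cell_alpha))
  dplyr::bind_cols(
    tibble(sample_id = ids,
           age = rnorm(n, 55, 8),
           sex = rbinom(n, 1L, 0.5),
           smoking = rbinom(n, 1L, 0.4),
           alcohol = rbinom(n, 1L, 0.5),
           bmi = rnorm(n, 29, 5)),
    as_tibble(cells)
  )
}

#' Simulate multi-cohort methylation, covariate and genotype data
#'
#' All cohorts share one CpG universe, one allele-frequency table and one set
#' of CpG effect assignments, then draw their samples independently:
#' genotypes and latent ancestry from the population model, covariates from
#' fixed realistic distributions (age ~ N(55, 8), BMI ~ N(29, 5), binary
#' smoking/sex/alcohol, six-part Dirichlet blood cell proportions), and beta
#' values from the methylation model. The self-reported `group` label is the
#' sample's majority latent population, standing in for race/ethnicity.
#'
#' @param pop_model A [pop_model()].
#' @param meth_model A [meth_model()].
#' @param cohort_sizes Integer vector of per-cohort sample counts (each at
#'   least 10).
#' @param seed Integer seed; all randomness derives from it.
#' @param cohort_ids Optional character labels, defaults to `cohort1`, ...
#'
#' @return A list of [cohort_dataset()] objects with attributes
#'   `ancestry_cpgs` (ids of the CpGs given ancestry effects) and
#'   `cpg_baseline` (named baseline beta levels).
#' @export
simulate_cohorts <- function(pop_model, meth_model, cohort_sizes, seed,
                             cohort_ids = NULL) {
  stopifnot(inherits(pop_model, "pop_model"), inherits(meth_model, "meth_model"))
  if (length(cohort_sizes) < 1) abort("need at least one cohort")
  if (any(cohort_sizes < 10)) abort("each cohort must have >= 10 samples")
  unknown <- setdiff(names(meth_model$covariate_effects), known_sim_covariates())
  if (length(unknown) > 0) {
    abort(paste0("covariate_effects names unknown covariates: ",
                 paste(unknown, collapse = ", ")))
  }
  cohort_ids <- cohort_ids %||% paste0("cohort", seq_along(cohort_sizes))
  stopifnot(length(cohort_ids) == length(cohort_sizes))

  m <- meth_model$n_cpgs
  cpg_ids <- sprintf("cg%06d", seq_len(m))

  globals <- with_seed(derive_seed(seed, "sim_global"), {
    baseline <- runif(m, 0.05, 0.95)
    anc_idx <- sort(sample.int(m, meth_model$n_ancestry_cpgs))
    anc_sign <- sample(c(-1, 1), meth_model$n_ancestry_cpgs, replace = TRUE)
    anc_pop <- sample.int(pop_model$n_populations, meth_model$n_ancestry_cpgs,
                          replace = TRUE)
    n_aff <- max(1L, round(meth_model$covariate_affected_fraction * m))
    cov_targets <- lapply(names(meth_model$covariate_effects), function(cv) {
      list(idx = sample.int(m, n_aff),
           sign = sample(c(-1, 1), n_aff, replace = TRUE))
    })
    names(cov_targets) <- names(meth_model$covariate_effects)
    freqs <- draw_allele_freqs(pop_model)
    list(baseline = baseline, anc_idx = anc_idx, anc_sign = anc_sign,
         anc_pop = anc_pop, cov_targets = cov_targets, freqs = freqs)
  })

  datasets <- lapply(seq_along(cohort_sizes), function(ci) {
    n <- cohort_sizes[ci]
    with_seed(derive_seed(seed, paste0("cohort_", cohort_ids[ci])), {
      geno <- simulate_genotypes_given(globals$freqs, pop_model, n,
                                       prefix = paste0(cohort_ids[ci], "_s"))
      ids <- rownames(geno$genotypes)
      covar <- simulate_covariates(n, ids)
      covar$group <- paste0("pop", max.col(geno$ancestry, ties.method = "first"))

      beta <- matrix(rep(globals$baseline, each = n), nrow = n)
      if (length(globals$anc_idx) > 0 && meth_model$ancestry_effect_size != 0) {
        shift <- geno$ancestry[, globals$anc_pop, drop = FALSE] *
          rep(globals$anc_sign * meth_model$ancestry_effect_size, each = n)
        beta[, globals$anc_idx] <- beta[, globals$anc_idx] + shift
      }
      for (cv in names(globals$cov_targets)) {
        x <- covar[[cv]]
        sx <- sd(x)
        if (!is.finite(sx) || sx == 0) next
        z <- (x - mean(x)) / sx
        tg <- globals$cov_targets[[cv]]
        beta[, tg$idx] <- beta[, tg$idx] +
          outer(z, tg$sign * meth_model$covariate_effects[[cv]])
      }
      beta <- beta + matrix(rnorm(n * m, 0, meth_model$noise_sd), nrow = n)
      beta <- pmin(pmax(beta, 0), 1)
      dimnames(beta) <- list(ids, cpg_ids)

      cohort_dataset(
        cohort_id = cohort_ids[ci],
        methylation = matrix_to_tbl(beta),
        covariates = covar,
        genotypes = matrix_to_tbl(geno$genotypes),
        truth = matrix_to_tbl(geno$ancestry)
      )
    })
  })
  attr(datasets, "ancestry_cpgs") <- cpg_ids[globals$anc_idx]
  attr(datasets, "cpg_baseline") <- setNames(globals$baseline, cpg_ids)
  datasets
}

#' Bundle one cohort's matrices and tables
#'
#' Validates and packages a cohort: methylation beta values, covariates,
#' optional genotype dosages and optional latent ancestry truth, all aligned
#' by `sample_id`.
#'
#' @param cohort_id Cohort label.
#' @param methylation Tibble with `sample_id` plus one numeric column per
#'   CpG, values in `[0, 1]`.
#' @param covariates Tibble with `sample_id` plus covariate columns.
#' @param genotypes Optional tibble with `sample_id` plus per-variant dosage
#'   columns in `[0, 2]`.
#' @param truth Optional tibble of latent ancestry proportions (simulation
#'   only).
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(cohort_id, methylation, covariates,
                           genotypes = NULL, truth = NULL) {
  ids <- as.character(methylation$sample_id)
  if (anyDuplicated(ids)) abort("sample_ids must be unique")
  check_rows <- function(tbl, what) {
    if (!is.null(tbl) && !identical(as.character(tbl$sample_id), ids)) {
      if (nrow(tbl) != length(ids) || !setequal(tbl$sample_id, ids)) {
        abort(paste0(what, " rows do not match methylation samples"))
      }
      tbl <- tbl[match(ids, tbl$sample_id), , drop = FALSE]
    }
    tbl
  }
  covariates <- check_rows(covariates, "covariates")
  genotypes <- check_rows(genotypes, "genotypes")
  truth <- check_rows(truth, "truth")
  cell_cols <- grep("^cell", names(covariates), value = TRUE)
  if (length(cell_cols) > 0) {
    s <- rowSums(as.matrix(covariates[cell_cols]))
    if (any(abs(s - 1) > 1e-8)) abort("cell proportions must sum to 1")
  }
  structure(
    list(cohort_id = cohort_id, sample_ids = ids, methylation = methylation,
         covariates = covariates, genotypes = genotypes, truth = truth),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %s: %d samples, %d CpGs, %s variants\n",
              x$cohort_id, length(x$sample_ids),
              ncol(x$methylation) - 1L,
              if (is.null(x$genotypes)) "no" else ncol(x$genotypes) - 1L))
  invisible(x)
}

# Subset a cohort_dataset to a set of sample ids (order preserved).
cohort_subset <- function(ds, ids) {
  keep <- ds$sample_ids %in% ids
  sub <- function(tbl) if (is.null(tbl)) NULL else tbl[keep, , drop = FALSE]
  cohort_dataset(ds$cohort_id, sub(ds$methylation), sub(ds$covariates),
                 sub(ds$genotypes), sub(ds$truth))
}

#' Stratified train/test split of cohorts
#'
#' Splits each cohort independently: `round(n * train_fraction)` samples
#' (ties toward train) are drawn at random into the training set, the rest
#' into the test set. Deterministic given `seed`.
#'
#' @param datasets List of [cohort_dataset()] objects.
#' @param train_fraction Proportion in `(0, 1)` assigned to training within
#'   each cohort.
#' @param seed Integer seed.
#'
#' @return A list with elements `train` and `test`, each a list of
#'   [cohort_dataset()] objects in the input cohort order.
#' @export
split_train_test <- function(datasets, train_fraction = 0.85, seed = 1L) {
  check_proportion(train_fraction, "train_fraction")
  if (inherits(datasets, "cohort_dataset")) datasets <- list(datasets)
  out <- with_seed(seed, lapply(datasets, function(ds) {
    n <- length(ds$sample_ids)
    n_train <- floor(n * train_fraction + 0.5)   # nearest, ties toward train
    if (n_train < 1 || n_train > n - 1) {
      abort(sprintf("cohort %s too small to split at fraction %.2f",
                    ds$cohort_id, train_fraction))
    }
    tr_ids <- sort(sample(ds$sample_ids, n_train))
    te_ids <- setdiff(ds$sample_ids, tr_ids)
    list(train = cohort_subset(ds, tr_ids), test = cohort_subset(ds, te_ids))
  }))
  list(train = lapply(out, `[[`, "train"), test = lapply(out, `[[`, "test"))
}

#' Simulate a binary exposure that depends on latent ancestry
#'
#' Draws exposure status from a logistic model in the first latent ancestry
#' proportion, the scenario used to manufacture stratification-induced
#' inflation in EWAS: `P(E = 1) = plogis(intercept + slope * ancestry1)`.
#' `slope = 0` gives an exposure independent of structure.
#'
#' @param truth Tibble of latent ancestry proportions (`sample_id`, `pop1`,
#'   ...), as stored by [simulate_cohorts()].
#' @param intercept,slope Logistic coefficients.
#' @param seed Integer seed.
#'
#' @return Tibble with `sample_id` and binary `exposure`.
#' @export
simulate_exposure <- function(truth, intercept = -0.5, slope = 2, seed = 1L) {
  q1 <- truth[[2]]
  with_seed(seed, tibble(
    sample_id = as.character(truth$sample_id),
    exposure = rbinom(length(q1), 1L, plogis(intercept + slope * q1))
  ))
}
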