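# Independent oracles and small fixture builders used across test files.

# Hudson-type FST estimator for two populations, ratio of averages, with the
# within-population sampling correction on the numerator.
hudson_fst <- function(genotypes, pop) {
  stopifnot(length(unique(pop)) == 2)
  g1 <- genotypes[pop == unique(pop)[1], , drop = FALSE]
  g2 <- genotypes[pop == unique(pop)[2], , drop = FALSE]
  p1 <- colMeans(g1) / 2
  p2 <- colMeans(g2) / 2
  n1 <- 2 * nrow(g1)
  n2 <- 2 * nrow(g2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

# Literal step-up definition of the BH adjustment, independent of p.adjust:
# sort ascending, q_(i) = min_{j >= i} p_(j) * m / j, cap at 1, restore order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m))
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Small two-population multi-cohort simulation shared by several files.
tiny_sim <- function(seed = 101, sizes = c(60, 80), n_cpgs = 300,
                     n_ancestry = 20, n_variants = 400, effect = 0.2) {
  pm <- pop_model(n_populations = 2, fst = 0.1, n_variants = n_variants)
  mm <- meth_model(n_cpgs = n_cpgs, n_ancestry_cpgs = n_ancestry,
                   ancestry_effect_size = effect)
  suppressMessages(simulate_cohorts(pm, mm, sizes, seed = seed))
}

# Pure-noise methylation tibble: baseline 0.5, sd 0.05, clipped to [0, 1].
noise_meth <- function(n, m, seed = 1, prefix = "s") {
  withr::with_seed(seed, {
    x <- matrix(pmin(pmax(rnorm(n * m, 0.5, 0.05), 0), 1), n, m,
                dimnames = list(sprintf("%s%04d", prefix, seq_len(n)),
                                sprintf("cg%06d", seq_len(m))))
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(x)),
                     tibble::as_tibble(x))
  })
}

expect_quiet <- function(expr) suppressMessages(suppressWarnings(expr))
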