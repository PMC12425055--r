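test_that("genomic inflation follows its definition", {
  # median chi-square equal to the null median gives lambda 1
  p_med <- pchisq(0.4549364, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(rep(p_med, 7)), 1, tolerance = 1e-6)
  # twice the null median gives lambda 2
  p2 <- pchisq(0.9098728, 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(rep(p2, 7)), 2, tolerance = 1e-6)

  withr::with_seed(3, {
    lams <- vapply(1:5, function(i) genomic_inflation(runif(10000)), 1)
  })
  expect_lt(abs(mean(lams) - 1), 0.03)

  expect_warning(l0 <- genomic_inflation(c(0, 0.5)), "clamped")
  expect_true(is.finite(l0))
  expect_error(genomic_inflation(c(NA, NA)), "non-NA")

  # invariant to sample permutation applied jointly to all inputs
  meth <- noise_meth(100, 200, seed = 12)
  expo <- tibble::tibble(sample_id = meth$sample_id,
                         exposure = withr::with_seed(13, rbinom(100, 1, 0.4)))
  e1 <- run_ewas(meth, expo)
  perm <- withr::with_seed(14, sample(nrow(meth)))
  e2 <- run_ewas(meth[perm, ], expo)
  expect_equal(attr(e1, "lambda_gc"), attr(e2, "lambda_gc"), tolerance = 1e-12)
})

test_that("the exposure scan is exact OLS and calibrated under the null", {
  meth <- noise_meth(150, 30, seed = 21)
  withr::with_seed(22, {
    covar <- tibble::tibble(sample_id = meth$sample_id,
                            age = rnorm(150, 55, 8), sex = rbinom(150, 1, 0.5))
    expo <- tibble::tibble(sample_id = meth$sample_id,
                           exposure = rbinom(150, 1, 0.5))
  })
  scan <- run_ewas(meth, expo, covar)
  for (j in c(2, 17)) {
    fit <- summary(lm(meth[[j + 1]] ~ expo$exposure + covar$age + covar$sex))
    expect_equal(scan$beta[j], unname(coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(scan$se[j], unname(coef(fit)[2, 2]), tolerance = 1e-10)
    expect_equal(scan$p[j], unname(coef(fit)[2, 4]), tolerance = 1e-10)
  }
  expect_error(run_ewas(meth, rep(1, 150)), "constant")
  expect_error(run_ewas(meth, rep(0.5, 150)), "binary")

  # Bonferroni never declares more than BH at the same level
  expect_lte(sum(scan$sig_bonferroni), sum(scan$q < 0.05, na.rm = TRUE))

  lams <- vapply(1:10, function(s) {
    pm <- pop_model(n_variants = 50)
    mm <- meth_model(n_cpgs = 2000, n_ancestry_cpgs = 0,
                     ancestry_effect_size = 0, covariate_effects = numeric(0))
    co <- suppressMessages(simulate_cohorts(pm, mm, 500, seed = 100 + s))[[1]]
    ex <- simulate_exposure(co$truth, 0, 0, seed = 200 + s)
    cv <- co$covariates[c("sample_id", "age", "sex", "smoking", "bmi")]
    attr(run_ewas(co$methylation, ex, cv), "lambda_gc")
  }, 1)
  expect_lt(abs(mean(lams) - 1), 0.08)
  expect_lt(max(abs(lams - 1)), 0.2)
})

test_that("adjusting for the true confounder deflates a stratified scan", {
  pm <- pop_model(n_populations = 2, fst = 0.1, n_variants = 100)
  mm <- meth_model(n_cpgs = 1000, n_ancestry_cpgs = 200)
  res <- t(vapply(1:10, function(s) {
    co <- suppressMessages(simulate_cohorts(pm, mm, 400, seed = 300 + s))[[1]]
    ex <- simulate_exposure(co$truth, -0.5, 2, seed = 400 + s)
    cv <- co$covariates[c("sample_id", "age", "sex", "smoking", "bmi",
                          paste0("cell", 1:6))]
    c(none = attr(run_ewas(co$methylation, ex, cv), "lambda_gc"),
      truth = attr(run_ewas(co$methylation, ex, cv, adjusters = co$truth[1:2],
                            adjustment_mode = "truth"), "lambda_gc"))
  }, c(none = 1, truth = 1)))
  expect_gte(sum(res[, "none"] > res[, "truth"]), 9)
})

test_that("a spiked effect ranks at the top of the scan", {
  hits <- vapply(1:10, function(s) {
    meth <- noise_meth(500, 400, seed = 500 + s)
    expo <- tibble::tibble(sample_id = meth$sample_id,
                           exposure = withr::with_seed(600 + s,
                                                       rbinom(500, 1, 0.5)))
    meth$cg000042 <- pmin(pmax(meth$cg000042 + 0.1 * expo$exposure, 0), 1)
    scan <- run_ewas(meth, expo)
    rank(scan$p)[scan$cpg == "cg000042"] <= 0.01 * nrow(scan)
  }, TRUE)
  expect_gte(sum(hits), 9)
})

test_that("benchmark lookup computes FDR over the benchmark family only", {
  meth <- noise_meth(80, 50, seed = 71)
  expo <- tibble::tibble(sample_id = meth$sample_id,
                         exposure = withr::with_seed(72, rbinom(80, 1, 0.5)))
  scan <- run_ewas(meth, expo)

  expect_warning(none <- benchmark_lookup(scan, c("cgX", "cgY")), "no benchmark")
  expect_equal(nrow(none), 0)

  one <- benchmark_lookup(scan, "cg000007")
  expect_equal(one$q_benchmark, one$p)

  sub <- benchmark_lookup(scan, sprintf("cg%06d", 1:20))
  expect_equal(sub$q_benchmark, bh_bruteforce(sub$p), tolerance = 1e-12)

  # spiked benchmark recovery: 10 true effects among 46 nulls
  recovered <- vapply(1:10, function(s) {
    meth <- noise_meth(1000, 200, seed = 800 + s)
    expo <- tibble::tibble(sample_id = meth$sample_id,
                           exposure = withr::with_seed(900 + s,
                                                       rbinom(1000, 1, 0.5)))
    spiked <- sprintf("cg%06d", 1:10)
    bench <- sprintf("cg%06d", 1:56)
    for (cg in spiked) {
      meth[[cg]] <- pmin(pmax(meth[[cg]] + 0.1 * expo$exposure, 0), 1)
    }
    scan <- run_ewas(meth, expo)
    hits <- benchmark_lookup(scan, bench)
    sum(hits$hit[hits$cpg %in% spiked])
  }, 1)
  expect_gte(mean(recovered >= 8), 0.9)
})
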