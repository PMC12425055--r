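test_that("the vectorized scan is exact OLS (lm oracle)", {
  co <- tiny_sim(seed = 41, sizes = 80, n_cpgs = 12, n_ancestry = 4,
                 n_variants = 60)[[1]]
  gp <- expect_quiet(compute_gpcs(co$genotypes, 2))
  sc <- cohort_scan(co, gp$scores, gpc_index = 1)

  C <- covariate_design(co$covariates)
  y <- gp$scores$GPC1
  for (j in c(1, 5, 12)) {
    x <- co$methylation[[j + 1]]
    fit <- summary(lm(y ~ x + C))
    expect_equal(sc$beta[j], unname(coef(fit)["x", "Estimate"]), tolerance = 1e-10)
    expect_equal(sc$se[j], unname(coef(fit)["x", "Std. Error"]), tolerance = 1e-10)
    expect_equal(sc$p[j], unname(coef(fit)["x", "Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("exact linear relation, duplicate-sample SE scaling, constant CpGs", {
  n <- 60
  withr::with_seed(13, {
    cg <- runif(n, 0.2, 0.8)
  })
  meth <- tibble::tibble(sample_id = sprintf("s%03d", 1:n),
                         cg1 = cg, cg2 = 0.5)
  covar <- tibble::tibble(sample_id = meth$sample_id)
  ds <- cohort_dataset("c1", meth, covar)
  scores <- tibble::tibble(sample_id = meth$sample_id, GPC1 = 2 * cg)
  sc <- suppressMessages(cohort_scan(ds, scores, 1))
  expect_equal(sc$beta[1], 2, tolerance = 1e-8)
  expect_lt(sc$p[1], 1e-100)
  expect_true(is.na(sc$beta[2]))   # constant CpG -> NA row

  # doubling the data leaves beta unchanged and shrinks the SE
  withr::with_seed(14, y <- 0.5 * cg + rnorm(n, 0, 0.1))
  meth2 <- dplyr::bind_rows(meth, dplyr::mutate(meth, sample_id = paste0(sample_id, "b")))
  ds2 <- cohort_dataset("c1", meth2, tibble::tibble(sample_id = meth2$sample_id))
  s1 <- suppressMessages(cohort_scan(ds, tibble::tibble(sample_id = meth$sample_id, GPC1 = y), 1))
  s2 <- suppressMessages(cohort_scan(ds2, tibble::tibble(sample_id = meth2$sample_id, GPC1 = c(y, y)), 1))
  expect_equal(s2$beta[1], s1$beta[1], tolerance = 1e-10)
  expect_lt(s2$se[1], s1$se[1])
})

test_that("scan p-values are calibrated under the null", {
  n <- 200
  m <- 1000
  meth <- noise_meth(n, m, seed = 6)
  covar <- tibble::tibble(sample_id = meth$sample_id,
                          age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  ds <- cohort_dataset("c1", meth, covar)
  withr::with_seed(7, y <- rnorm(n))
  sc <- cohort_scan(ds, tibble::tibble(sample_id = meth$sample_id, GPC1 = y), 1)
  expect_lt(abs(mean(sc$p < 0.05) - 0.05), 0.02)
})

test_that("inverse-variance pooling matches its closed forms", {
  mk <- function(beta, se, id) {
    structure(tibble::tibble(cpg = "cg1", beta = beta, se = se, p = 0.5,
                             n = 10L, cohort_id = id, gpc_index = 1L),
              class = c("cohort_assoc", class(tibble::tibble())))
  }
  one <- meta_fixed(list(mk(1.7, 0.3, "a")))
  expect_equal(one$pooled_beta, 1.7)
  expect_equal(one$pooled_se, 0.3)

  two <- meta_fixed(list(mk(1, 1, "a"), mk(3, 1, "b")))
  expect_equal(two$pooled_beta, 2.0)
  expect_equal(two$pooled_se, 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(two$n_cohorts, 2L)

  five <- meta_fixed(lapply(1:5, function(i) mk(0.8, 0.25, paste0("c", i))))
  expect_equal(five$pooled_beta, 0.8, tolerance = 1e-12)
  expect_equal(five$pooled_se, 0.25 / sqrt(5), tolerance = 1e-12)

  # pooled SE never exceeds the smallest cohort SE; partial cohorts pool
  mixed <- meta_fixed(list(mk(1, 0.5, "a"), mk(2, NA, "b")))
  expect_equal(mixed$n_cohorts, 1L)
  expect_equal(mixed$pooled_beta, 1)
  expect_lte(two$pooled_se, 1)
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.5, NA, 0.01)), c(0.5, NA, 0.02))
  expect_error(bh_fdr(c(0.5, 1.2)), "p-values")

  withr::with_seed(55, {
    for (i in 1:50) {
      p <- runif(sample(1:200, 1))^sample(c(1, 2, 4), 1)
      q <- bh_fdr(p)
      expect_equal(q, bh_bruteforce(p), tolerance = 1e-15)
      expect_true(all(q >= p - 1e-15))
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))  # monotone in p
    }
  })
})

test_that("selection flags respect the threshold and recover causal CpGs", {
  meta <- tibble::tibble(cpg = paste0("cg", 1:4), pooled_beta = 1,
                         pooled_se = 1, z = 1,
                         p = c(1e-6, 0.2, 0.8, NA), n_cohorts = 2L,
                         gpc_index = 1L)
  ms <- meta_scan(meta, 0.05)
  expect_identical(suppressMessages(select_cpgs(ms, 0.05)), "cg1")
  expect_true(all(ms$q >= ms$p, na.rm = TRUE))
  expect_identical(suppressMessages(select_cpgs(ms, 1.0)),
                   paste0("cg", 1:3))   # every defined q selected
  ms_none <- meta_scan(dplyr::mutate(meta, p = c(0.9, 0.95, 0.8, 0.7)), 0.05)
  expect_length(suppressMessages(select_cpgs(ms_none, 0.05)), 0)

  # under the global null almost nothing passes the FDR gate
  null_frac <- vapply(1:5, function(s) {
    p <- withr::with_seed(s, runif(2000))
    mean(bh_fdr(p) < 0.05)
  }, 1)
  expect_lt(mean(null_frac), 0.005)
})
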