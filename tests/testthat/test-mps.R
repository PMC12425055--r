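test_that("single-predictor Lasso equals the soft-threshold closed form", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- 100
      x <- rnorm(n)
      x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))  # unit 1/n variance
      y <- runif(1, -1, 1) * x + rnorm(n)
      lam <- runif(1, 0.01, 0.6)
      b_ols <- sum(x * y) / sum(x^2)
      expected <- sign(b_ols) * max(abs(b_ols) - lam, 0)
      m <- fit_lasso_stage(y, matrix(x, ncol = 1, dimnames = list(NULL, "cg1")),
                           lambda = lam)
      got <- if (length(m$weights)) unname(m$weights[["cg1"]]) else 0
      expect_lt(abs(got - expected), 1e-6)
    }
  })
})

test_that("Lasso limits: full shrinkage and the unpenalized OLS end", {
  withr::with_seed(31, {
    n <- 120
    X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("cg", 1:4)))
    y <- as.numeric(X %*% c(1, -2, 0, 0.5) + rnorm(n))
    w <- runif(n, 0.5, 2)
  })
  big <- fit_lasso_stage(y, X, lambda = 100)
  expect_length(big$weights, 0)

  m0 <- fit_lasso_stage(y, X, obs_weights = w, lambda = 0)
  ols <- lm(y ~ X, weights = w)
  expect_lt(max(abs(m0$weights[paste0("cg", 1:4)] - coef(ols)[-1])), 1e-6)
  expect_lt(abs(m0$intercept - coef(ols)[1]), 1e-6)

  expect_error(fit_lasso_stage(y, X[, 0, drop = FALSE]), "no selected CpGs")
  expect_error(fit_lasso_stage(y, X, obs_weights = rep(0, n)), "positive")
})

test_that("score application is a plain weighted sum with documented missing-data policy", {
  meth <- tibble::tibble(sample_id = c("a", "b"),
                         cg1 = c(0.5, 0.1), cg2 = c(0.25, 0.4), cg3 = c(0.9, 0.2))
  m <- mpscore:::new_mps_model(1L, c(cg1 = 2, cg2 = -1), 0.3, 2L, 0.1,
                               c("cg1", "cg2", "cg3"))
  s <- compute_mps(meth, m)
  expect_equal(s$MPS1, c(2 * 0.5 - 0.25, 2 * 0.1 - 0.4))

  ident <- mpscore:::new_mps_model(1L, c(cg2 = 1), 0, 2L, 0.1, "cg2")
  expect_equal(compute_mps(meth, ident)$MPS1, meth$cg2)

  empty <- mpscore:::new_mps_model(2L, setNames(numeric(0), character(0)),
                                   0, 2L, NA_real_, character(0))
  expect_equal(compute_mps(meth, empty)$MPS2, c(0, 0))

  # linearity in the methylation matrix
  M1 <- as.matrix(meth[-1])
  rownames(M1) <- meth$sample_id
  M2 <- withr::with_seed(2, matrix(runif(6), 2, 3, dimnames = dimnames(M1)))
  lhs <- compute_mps(0.3 * M1 + 0.7 * M2, m)$MPS1
  rhs <- 0.3 * compute_mps(M1, m)$MPS1 + 0.7 * compute_mps(M2, m)$MPS1
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # absent CpG dropped with coverage logged; missing cells mean-imputed
  meth_miss <- meth[c("sample_id", "cg1")]
  s2 <- suppressMessages(compute_mps(meth_miss, m))
  expect_equal(s2$MPS1, 2 * meth$cg1)
  expect_equal(unname(attr(s2, "coverage")["MPS1"]), 0.5)
  meth_na <- meth
  meth_na$cg1[2] <- NA
  s3 <- compute_mps(meth_na, m)
  expect_equal(s3$MPS1[2], 2 * 0.5 - 0.4)  # imputed by cg1 column mean (0.5)
  expect_error(compute_mps(meth[c("sample_id", "cg3")], ident), "no weighted CpG")
})

test_that("observation weights obey the truncate-then-normalize contract", {
  w <- normalize_obs_weights(c(1, 1, 1, 4), 0.9)
  expect_equal(as.numeric(w), c(1, 1, 1, 3.1) * 4 / 6.1, tolerance = 1e-12)
  expect_equal(round(as.numeric(w), 4), c(0.6557, 0.6557, 0.6557, 2.0328))
  expect_equal(sum(w), 4, tolerance = 1e-6)

  withr::with_seed(19, {
    for (i in 1:100) {
      n <- sample(10:200, 1)
      sq <- rexp(n)^sample(1:2, 1)
      ww <- normalize_obs_weights(sq, 0.9)
      expect_equal(sum(ww), n, tolerance = 1e-6)
      expect_true(all(ww > 0))
      expect_lte(max(ww), attr(ww, "cap") + 1e-9)
    }
  })

  # equal-magnitude residuals give unit weights through the full path
  y <- c(1, 2, 3, 4) + c(0.1, -0.1, -0.1, 0.1)
  rw <- residual_weights(y, c(1, 2, 3, 4), 0.9)
  expect_equal(as.numeric(rw), rep(1, 4), tolerance = 1e-9)
  expect_error(residual_weights(y, rep(1, 4)), "constant")
  expect_error(residual_weights(1:2, 1:2), "length")
})

test_that("two-stage training keeps support inside the selected universe and handles nulls", {
  co <- tiny_sim(seed = 61, sizes = c(150, 150), n_cpgs = 200, n_ancestry = 30)
  sp <- split_train_test(co, 0.85, seed = 62)
  geno <- dplyr::bind_rows(lapply(co, function(d) d$genotypes))
  gp <- expect_quiet(compute_gpcs(geno, 2))
  assocs <- lapply(sp$train, cohort_scan, gpc_scores = gp$scores, gpc_index = 1)
  sel <- suppressMessages(select_cpgs(meta_scan(meta_fixed(assocs))))
  expect_gt(length(sel), 5)

  mods <- expect_quiet(train_mps(sp$train, gp, list(`1` = sel), seed = 63))
  m1 <- mods[[1]]
  expect_s3_class(m1, "mps_model")
  expect_equal(m1$stage, 2L)
  expect_true(all(names(m1$weights) %in% sel))
  expect_true(all(m1$training_meta$stage1_support %in% sel))

  # the trained score predicts the held-out component
  te <- mpscore:::aggregate_cohorts(sp$test)
  ms <- compute_mps(te$methylation, mods)
  gte <- gp$scores$GPC1[match(te$sample_ids, gp$scores$sample_id)]
  expect_gt(cor(ms$MPS1, gte)^2, 0.5)

  # empty selection yields a degenerate model, not an error
  expect_warning(mods0 <- train_mps(sp$train, gp, list(`2` = character(0)),
                                    seed = 64), "degenerate")
  expect_length(mods0[[1]]$weights, 0)
  expect_equal(mods0[[1]]$gpc_index, 2L)

  # determinism: same master seed, same weights
  mods_b <- expect_quiet(train_mps(sp$train, gp, list(`1` = sel), seed = 63))
  expect_identical(mods[[1]]$weights, mods_b[[1]]$weights)
})

test_that("weight files round-trip losslessly and reject malformed input", {
  m1 <- mpscore:::new_mps_model(1L, c(cg000001 = pi, cg000002 = -exp(1) / 3),
                                0.123456789, 2L, 0.0123, paste0("cg00000", 1:3),
                                list(master_seed = 42L))
  m_empty <- mpscore:::new_mps_model(2L, setNames(numeric(0), character(0)),
                                     0, 1L, NA_real_, character(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_weights(structure(list(m1, m_empty), class = "mps_model_set"), path)
  back <- read_weights(path)
  expect_length(back, 2)
  expect_identical(back[[1]]$weights, m1$weights)
  expect_identical(back[[1]]$intercept, m1$intercept)
  expect_identical(back[[1]]$lambda, m1$lambda)
  expect_length(back[[2]]$weights, 0)
  expect_equal(back[[2]]$gpc_index, 2L)

  # byte-identical rewrite
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_weights(back, path2)
  l1 <- readLines(path)
  l2 <- readLines(path2)
  expect_identical(grep("^[^#]", l1, value = TRUE), grep("^[^#]", l2, value = TRUE))

  dup <- c(readLines(path), "1\tcg000001\t0.5")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(dup, path3)
  expect_error(read_weights(path3), "duplicate CpG")

  bad <- c(readLines(path), "1\tonly_two_fields")
  writeLines(bad, path3)
  expect_error(read_weights(path3), "line")
})
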