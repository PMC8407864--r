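# Fixed-effects meta-analysis engine: pooling formulas, FDR, genomic
# inflation, leave-one-out, meta-regression, sensitivity subsets.

test_that("fixed-effects pooling matches hand oracles", {
  single <- fixed_effects_meta(0.5, 0.1)
  expect_equal(single$pooled_beta, 0.5)
  expect_equal(single$pooled_se, 0.1)
  expect_equal(single$i2, 0)
  expect_equal(single$q_df, 0L)

  m <- fixed_effects_meta(c(1, 3), c(1, 1))
  expect_equal(m$pooled_beta, 2)
  expect_equal(m$pooled_se, 1 / sqrt(2))
  expect_equal(m$q_stat, 2)
  expect_equal(m$q_df, 1L)
  expect_equal(m$i2, 50)
  expect_identical(m$direction, "++")

  hom <- fixed_effects_meta(rep(0.7, 5), c(0.1, 0.2, 0.3, 0.1, 0.2))
  expect_equal(hom$q_stat, 0, tolerance = 1e-12)
  expect_equal(hom$i2, 0)
  expect_equal(hom$pooled_beta, 0.7)

  expect_error(fixed_effects_meta(NA_real_, 0.1), class = "ewasmeta_no_data")
})

test_that("pooling agrees with a brute-force oracle and with metafor", {
  withr::with_seed(61, {
    for (i in 1:100) {
      k <- sample(2:10, 1)
      b <- rnorm(k); s <- runif(k, 0.05, 2)
      ours <- fixed_effects_meta(b, s)
      orc <- oracle_pool(b, s)
      expect_equal(ours$pooled_beta, orc$beta, tolerance = 1e-10)
      expect_equal(ours$pooled_se, orc$se, tolerance = 1e-10)
      expect_equal(ours$q_stat, orc$q, tolerance = 1e-10)
      expect_equal(ours$i2, orc$i2, tolerance = 1e-10)
      expect_equal(ours$p, orc$p, tolerance = 1e-10)
    }
  })
  skip_if_not_installed("metafor")
  withr::with_seed(62, {
    for (i in 1:10) {
      b <- rnorm(6); s <- runif(6, 0.1, 1)
      ours <- fixed_effects_meta(b, s)
      rr <- metafor::rma(yi = b, sei = s, method = "FE")
      expect_equal(ours$pooled_beta, as.numeric(rr$beta), tolerance = 1e-8)
      expect_equal(ours$pooled_se, rr$se, tolerance = 1e-8)
      expect_equal(ours$q_stat, rr$QE, tolerance = 1e-8)
    }
  })
})

test_that("pooled estimates respect convexity and exact-replication shrinkage", {
  withr::with_seed(63, {
    for (i in 1:25) {
      k <- sample(2:8, 1)
      b <- rnorm(k); s <- runif(k, 0.05, 1)
      m <- fixed_effects_meta(b, s)
      expect_gte(m$pooled_beta, min(b)); expect_lte(m$pooled_beta, max(b))
      expect_lte(m$pooled_se, min(s))
    }
    K <- 7
    m <- fixed_effects_meta(rep(1.3, K), rep(0.4, K))
    expect_equal(m$pooled_se, 0.4 / sqrt(K), tolerance = 1e-12)
  })
})

test_that("meta_analyse handles probe unions, missing cohorts and direction strings", {
  r1 <- data.frame(probe_id = c("a", "b"), estimate = c(1, -2), se = c(0.5, 0.4),
                   p = c(0.05, 0.01), n = c(100L, 100L))
  r2 <- data.frame(probe_id = c("a", "c"), estimate = c(3, 0.2), se = c(0.5, 0.3),
                   p = c(0.01, 0.5), n = c(200L, 200L))
  m <- meta_analyse(list(c1 = r1, c2 = r2))
  expect_setequal(m$probe_id, c("a", "b", "c"))
  a <- m[m$probe_id == "a", ]
  expect_equal(a$beta, 2); expect_equal(a$k, 2)
  expect_identical(a$direction, "++")
  expect_identical(m$direction[m$probe_id == "b"], "-?")
  expect_equal(m$k[m$probe_id == "c"], 1)
  expect_equal(m$i2[m$probe_id == "c"], 0)
  expect_equal(m$n[m$probe_id == "a"], 300)
  expect_true(all(m$fdr_p >= m$p))
})

test_that("BH adjustment matches hand step-up oracles and validates input", {
  expect_equal(bh_fdr(1.0), 1.0)
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(c(0.03, 0.01, 0.02)), c(0.03, 0.03, 0.03))
  expect_error(bh_fdr(c(0.5, 0)), class = "ewasmeta_input_error")
  expect_error(bh_fdr(c(0.5, 1.2)), class = "ewasmeta_input_error")
  withr::with_seed(64, {
    for (i in 1:20) {
      p <- runif(sample(1:50, 1))
      expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    }
  })
})

test_that("genomic inflation lambda matches the chi-square quantile definition", {
  expect_equal(genomic_inflation_lambda(rep(0.5, 10)), 1)
  expect_equal(genomic_inflation_lambda(rep(0.05, 7)),
               qchisq(0.95, 1) / qchisq(0.5, 1), tolerance = 1e-10)
  expect_equal(genomic_inflation_lambda(rep(0.05, 7)), 8.445, tolerance = 1e-3)
  withr::with_seed(65, {
    expect_lt(abs(genomic_inflation_lambda(runif(1e5)) - 1), 0.03)
  })
  expect_error(genomic_inflation_lambda(numeric(0)), class = "ewasmeta_input_error")
})

test_that("leave-one-out applies the three survival criteria", {
  hom <- leave_one_out(rep(1, 5), rep(0.1, 5))
  expect_true(hom$survived)
  expect_length(hom$failure_reasons, 0)

  # one driving cohort among four nulls
  drv <- leave_one_out(c(0, 0, 0, 0, 3), c(0.5, 0.5, 0.5, 0.5, 0.1))
  expect_false(drv$survived)
  expect_true(all(c("attenuation_gt_20pct", "ci_crosses_null") %in%
                    drv$failure_reasons))

  # boundary: omitting either of two equal-weight cohorts changes the
  # estimate by exactly 21%
  bnd <- leave_one_out(c(0.79, 1.21), c(0.01, 0.01))
  expect_false(bnd$survived)
  expect_identical(bnd$failure_reasons, "attenuation_gt_20pct")
  expect_equal(bnd$table$pooled_beta, c(1.21, 0.79))

  # 19% change survives
  ok <- leave_one_out(c(0.81, 1.19), c(0.01, 0.01))
  expect_true(ok$survived)

  na <- leave_one_out(1, 0.1)
  expect_true(is.na(na$survived))
})

test_that("leave-one-out re-pooling matches a hand re-pool", {
  b <- c(0.2, 0.4, 0.9); s <- c(0.1, 0.2, 0.3)
  loo <- leave_one_out(b, s)
  for (i in 1:3) {
    orc <- oracle_pool(b[-i], s[-i])
    expect_equal(loo$table$pooled_beta[i], orc$beta, tolerance = 1e-12)
    expect_equal(loo$table$ci_low[i], orc$beta - 1.96 * orc$se, tolerance = 1e-12)
  }
})

test_that("meta-regression on age matches closed-form WLS and is calibrated", {
  # exact linear relation, equal SEs
  ages <- c(4, 7, 9)
  b <- 0.1 + 0.05 * ages
  mr <- meta_regression_age(b, rep(0.2, 3), ages)
  expect_equal(mr$slope, 0.05, tolerance = 1e-10)

  # closed-form 3-point WLS oracle
  s <- c(0.1, 0.3, 0.2); bb <- c(0.5, 0.2, 0.9)
  w <- 1 / s^2
  X <- cbind(1, ages)
  V <- solve(t(X) %*% diag(w) %*% X)
  beta_hat <- V %*% t(X) %*% diag(w) %*% bb
  mr2 <- meta_regression_age(bb, s, ages)
  expect_equal(mr2$slope, beta_hat[2], tolerance = 1e-10)
  expect_equal(mr2$se, sqrt(V[2, 2]), tolerance = 1e-10)

  expect_error(meta_regression_age(b, rep(0.2, 3), rep(5, 3)),
               class = "ewasmeta_degenerate_moderator")

  withr::with_seed(66, {   # null calibration
    rej <- mean(replicate(500, {
      k <- 8; ag <- runif(k, 4, 10); se <- runif(k, 0.1, 0.3)
      bb <- rnorm(k, 0, se)
      meta_regression_age(bb, se, ag)$p < 0.05
    }))
    expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  })
})

test_that("sensitivity subsets re-pool and re-rank FDR correctly", {
  withr::with_seed(67, {
    results <- lapply(1:5, function(i)
      data.frame(probe_id = sprintf("p%02d", 1:20), estimate = rnorm(20, 0, 0.2),
                 se = runif(20, 0.1, 0.2), p = runif(20), n = 100L))
    names(results) <- sprintf("c%d", 1:5)
    full <- meta_analyse(results)
    same <- sensitivity_subset_meta(results, character(0))
    expect_equal(same$beta, full$beta)
    expect_equal(same$fdr_p, full$fdr_p)

    # K identical cohorts: dropping one leaves beta, inflates SE by sqrt(K/(K-1))
    ident <- lapply(1:4, function(i) results[[1]])
    names(ident) <- sprintf("c%d", 1:4)
    fullk <- meta_analyse(ident)
    sub <- sensitivity_subset_meta(ident, "c4")
    expect_equal(sub$beta, fullk$beta, tolerance = 1e-12)
    expect_equal(sub$se, fullk$se * sqrt(4 / 3), tolerance = 1e-12)

    expect_error(sensitivity_subset_meta(results, names(results)),
                 class = "ewasmeta_empty_analysis")
  })
})

test_that("excluding the cohort carrying a single-cohort artefact removes the hit", {
  withr::with_seed(68, {
    results <- lapply(1:5, function(i)
      data.frame(probe_id = sprintf("p%02d", 1:50), estimate = rnorm(50, 0, 0.05),
                 se = rep(0.05, 50), p = runif(50), n = 400L))
    names(results) <- sprintf("c%d", 1:5)
    results$c3$estimate[7] <- 1.5        # artefact probe p07 in cohort 3 only
    full <- meta_analyse(results)
    expect_lt(full$fdr_p[full$probe_id == "p07"], 0.05)
    sub <- sensitivity_subset_meta(results, "c3")
    expect_gt(sub$fdr_p[sub$probe_id == "p07"], 0.05)
  })
})

test_that("cell-association meta-analysis pools per cell type", {
  one <- list(data.frame(cell_type = c("CD4T", "nRBC"), estimate = c(0.01, 0.001),
                         se = c(0.002, 0.0005), p = c(0.1, 0.2), n = 100L))
  m1 <- meta_analyse_cell_associations(one)
  expect_equal(m1$beta, c(0.01, 0.001))
  expect_equal(m1$se, c(0.002, 0.0005))

  many <- lapply(1:13, function(i)
    data.frame(cell_type = "nRBC", estimate = 0.001, se = 0.0004,
               p = 0.01, n = 300L))
  m13 <- meta_analyse_cell_associations(many)
  expect_equal(m13$beta, 0.001)
  expect_equal(m13$q, 0, tolerance = 1e-12)
  expect_equal(m13$k, 13)
})

test_that("meta result table round-trips through the exchange TSV", {
  withr::with_seed(69, {
    results <- lapply(1:3, function(i)
      data.frame(probe_id = sprintf("p%02d", 1:10), estimate = rnorm(10),
                 se = runif(10, 0.1, 0.3), p = runif(10), n = 50L))
    names(results) <- c("a", "b", "c")
    m <- meta_analyse(results)
    path <- file.path(withr::local_tempdir(), "meta.tsv")
    write_meta_result(m, path)
    back <- as.data.frame(data.table::fread(path))
    expect_equal(back$beta, m$beta, tolerance = 1e-12)
    expect_identical(as.character(back$direction), m$direction)
  })
})
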