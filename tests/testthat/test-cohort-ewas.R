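# Cohort-level EWAS: Z-scoring, Tukey outlier removal, deconvolution,
# surrogate variables, per-CpG linear models.

test_that("BMI standardization gives mean-0 SD-1 Z-scores and rejects degenerate input", {
  expect_equal(standardize_bmi(c(20, 25, 30)), c(-1, 0, 1))
  expect_error(standardize_bmi(c(22.6, 22.6)), class = "ewasmeta_degenerate_exposure")
  expect_error(standardize_bmi(c(25, NA)), class = "ewasmeta_degenerate_exposure")

  x <- c(26.6, 27.5, 28.0, 25.2)
  z <- standardize_bmi(x)
  # independent two-pass oracle
  m <- sum(x) / 4; s <- sqrt(sum((x - m)^2) / 3)
  expect_equal(z, (x - m) / s, tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)

  xm <- c(20, NA, 30, 25)
  zm <- standardize_bmi(xm)
  expect_true(is.na(zm[2]))
})

test_that("Tukey outlier removal uses 3xIQR bounds with interpolated quartiles", {
  constant <- matrix(0.5, 1, 10, dimnames = list("p1", NULL))
  expect_equal(remove_methylation_outliers(constant)$n_removed[["p1"]], 0L)

  # hand oracle: Q1=3, Q3=7 (type-7), bounds [-9, 19]
  row <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 1000), 1, dimnames = list("p1", NULL))
  out <- remove_methylation_outliers(row)
  expect_equal(out$n_removed[["p1"]], 1L)
  expect_identical(which(is.na(out$betas[1, ])), 9L)

  withr::with_seed(11, {
    x <- rbeta(1000, 50, 50)        # tight around 0.5
    x[137] <- 0.99
    m <- matrix(x, 1, dimnames = list("p1", NULL))
    res <- remove_methylation_outliers(m)
    expect_equal(res$n_removed[["p1"]], 1L)
    expect_identical(which(is.na(res$betas[1, ])), 137L)
  })

  short <- matrix(c(0.1, 0.2, NA, NA, NA, NA), 1, dimnames = list("p1", NULL))
  expect_warning(res <- remove_methylation_outliers(short),
                 class = "ewasmeta_outlier_skip")
  expect_equal(res$n_skipped, 1L)
})

test_that("fast and slow Tukey paths agree", {
  withr::with_seed(12, {
    m <- matrix(runif(50 * 40), 50)
    rownames(m) <- sprintf("p%02d", 1:50)
    m_na <- m
    m_na[cbind(1:50, sample(40, 50, replace = TRUE))] <- NA  # forces slow path
    fast <- remove_methylation_outliers(m)
    for (j in 1:50) {   # per-row quantile() oracle for the vectorized path
      q <- quantile(m[j, ], c(0.25, 0.75), type = 7, names = FALSE)
      bad <- m[j, ] < q[1] - 3 * (q[2] - q[1]) | m[j, ] > q[2] + 3 * (q[2] - q[1])
      expect_equal(unname(fast$n_removed[j]), sum(bad))
    }
    expect_silent(remove_methylation_outliers(m_na))
  })
})

test_that("cell deconvolution recovers vertices, exact mixtures, and noisy Dirichlet truth", {
  ref <- generate_cell_reference(200, 3, seed = 2)
  v <- matrix(ref$profiles[, 1], dimnames = list(rownames(ref$profiles), NULL))
  colnames(v) <- "s1"
  expect_equal(unname(estimate_cell_proportions(v, ref)[1, ]), c(1, 0, 0),
               tolerance = 1e-8)

  mix <- matrix(0.6 * ref$profiles[, 1] + 0.4 * ref$profiles[, 2],
                dimnames = list(rownames(ref$profiles), "s1"))
  expect_equal(unname(estimate_cell_proportions(mix, ref)[1, ]), c(0.6, 0.4, 0),
               tolerance = 1e-8)

  withr::with_seed(31, {
    n <- 50
    g <- matrix(rgamma(n * 3, shape = 2), n)
    truth <- g / rowSums(g)
    B <- ref$profiles %*% t(truth) + matrix(rnorm(200 * n, 0, 0.01), 200)
    colnames(B) <- sprintf("s%02d", 1:n)
    est <- estimate_cell_proportions(B, ref)
    expect_lt(mean(abs(est - truth)), 0.03)
  })

  # rank-deficient reference on shared probes
  bad_ref <- ref
  bad_ref$profiles[, 2] <- bad_ref$profiles[, 1]
  expect_error(estimate_cell_proportions(v, bad_ref),
               class = "ewasmeta_unidentifiable_reference")
})

test_that("package NNLS agrees with an established Lawson-Hanson implementation", {
  skip_if_not_installed("pracma")
  withr::with_seed(7, {
    for (i in 1:50) {
      A <- matrix(runif(30 * 4), 30)
      b <- runif(30)
      ours <- ewasmeta:::nnls_small(crossprod(A), crossprod(A, b)[, 1])
      theirs <- pracma::lsqnonneg(A, b)$x
      expect_equal(ours, theirs, tolerance = 1e-10)
    }
  })
})

test_that("surrogate variables are orthogonal to the design and recover planted batch", {
  withr::with_seed(41, {
    n <- 200; p <- 500
    design <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
    planted <- rnorm(n)
    load <- rnorm(p, 0, 0.8) * rbinom(p, 1, 0.3)   # batch hits ~30% of probes
    B <- matrix(rnorm(p * n, 0, 0.3), p) + outer(load, planted)
    sv <- estimate_surrogate_variables(B, design, k = 1)
    expect_true(all(abs(crossprod(sv, design)) < 1e-8))
    expect_gt(abs(cor(sv[, 1], planted)), 0.9)

    # SVs never beat matched-dimension random projections on pure noise
    Bnull <- matrix(rnorm(p * n, 0, 0.3), p)
    sv2 <- estimate_surrogate_variables(Bnull, design, k = 2)
    resid <- t(Bnull) - design %*% solve(crossprod(design), crossprod(design, t(Bnull)))
    ev_sv <- sum((crossprod(resid, sv2))^2) / sum(resid^2)
    rand_ev <- replicate(20, {
      Q <- qr.Q(qr(matrix(rnorm(n * 2), n)))
      sum((crossprod(resid, Q))^2) / sum(resid^2)
    })
    # top-2 PCs of iid noise explain little more than random directions
    expect_lt(ev_sv, 3 * max(rand_ev))

    expect_error(estimate_surrogate_variables(B, design, k = n),
                 class = "ewasmeta_invalid_config")
  })
})

test_that("surrogate variables are deterministic with a fixed sign convention", {
  withr::with_seed(42, {
    B <- matrix(rnorm(300 * 50), 300)
    design <- cbind(1, rnorm(50))
    s1 <- estimate_surrogate_variables(B, design, k = 3)
    s2 <- estimate_surrogate_variables(B, design, k = 3)
    expect_identical(s1, s2)
    nz <- which(abs(s1[, 1]) > 1e-8)
    expect_gt(s1[nz[1], 1], 0)
  })
})

test_that("per-CpG estimates, SEs and p-values match an independent lm() oracle", {
  cfg <- tiny_config(seed = 51, n_cohorts = 1, n = 80, n_probes = 40,
                     missing_rate = 0.01)
  ref <- generate_cell_reference(40, 4, seed = 51)
  d <- generate_cohort(cfg, 1, ref)
  model <- ewas_model("paternal", n_surrogate_variables = 0,
                      remove_outliers = FALSE)
  r <- run_ewas(d, model, reference = ref)
  cp <- estimate_cell_proportions(d$betas, ref)
  ph <- d$phenotypes
  ph$z <- standardize_bmi(ph$paternal_bmi)
  for (j in c(1, 7, 20)) {
    pid <- r$probe_id[j]
    y <- d$betas[pid, ]
    ok <- !is.na(y)
    f <- summary(lm(y[ok] ~ ph$z[ok] + ph$paternal_age[ok] + ph$maternal_age[ok] +
                      ph$maternal_smoking[ok] + ph$paternal_smoking[ok] +
                      ph$paternal_sep[ok] + ph$parity[ok] + cp[ok, -1]))
    expect_equal(r$estimate[j], 100 * f$coefficients[2, 1], tolerance = 1e-8)
    expect_equal(r$se[j], 100 * f$coefficients[2, 2], tolerance = 1e-8)
    expect_equal(r$p[j], f$coefficients[2, 4], tolerance = 1e-8)
    expect_equal(r$n[j], sum(ok))
  }
})

test_that("an injected paternal effect is recovered by the full cohort EWAS", {
  cfg <- simulation_config(n_cohorts = 1, cohort_sizes = 1000L, n_probes = 200,
                           n_cell_types = 4, n_batch_factors = 5,
                           effect_specs = effect_spec("cg000099", "paternal", 0.5),
                           seed = 52)
  ref <- generate_cell_reference(200, 4, seed = 52)
  d <- generate_cohort(cfg, 1, ref)
  r <- run_ewas(d, ewas_model("paternal", n_surrogate_variables = 5), reference = ref)
  i <- match("cg000099", r$probe_id)
  expect_lt(abs(r$estimate[i] - 0.5), 3 * r$se[i])
})

test_that("null-probe p-values are uniform", {
  cfg <- simulation_config(n_cohorts = 1, cohort_sizes = 200L, n_probes = 1000,
                           n_cell_types = 4, n_batch_factors = 5, seed = 53)
  ref <- generate_cell_reference(1000, 4, seed = 53)
  d <- generate_cohort(cfg, 1, ref)
  r <- run_ewas(d, ewas_model("paternal", n_surrogate_variables = 5), reference = ref)
  frac <- mean(r$p < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("mutual adjustment is a no-op when the parental exposures are orthogonal in-sample", {
  cfg <- tiny_config(seed = 54, n_cohorts = 1, n = 120, n_probes = 50)
  ref <- generate_cell_reference(50, 4, seed = 54)
  d <- generate_cohort(cfg, 1, ref)
  # rebuild the unadjusted design, then orthogonalize maternal BMI against it
  cp <- estimate_cell_proportions(d$betas, ref)
  ph <- d$phenotypes
  X <- cbind(1, standardize_bmi(ph$paternal_bmi),
             as.matrix(ph[, c("paternal_age", "maternal_age", "maternal_smoking",
                              "paternal_smoking", "paternal_sep", "parity")]),
             cp[, -1])
  m_orth <- ph$maternal_bmi - X %*% solve(crossprod(X), crossprod(X, ph$maternal_bmi))
  d$phenotypes$maternal_bmi <- 25 + as.numeric(m_orth)
  base <- ewas_model("paternal", n_surrogate_variables = 0, remove_outliers = FALSE)
  adj <- ewas_model("paternal", mutual_adjustment = TRUE,
                    n_surrogate_variables = 0, remove_outliers = FALSE)
  r0 <- run_ewas(d, base, cell_proportions = cp)
  r1 <- run_ewas(d, adj, cell_proportions = cp)
  expect_equal(r0$estimate, r1$estimate, tolerance = 1e-8)
})

test_that("undersized sex strata raise a stratum-too-small condition", {
  cfg <- tiny_config(seed = 55, n_cohorts = 1, n = 40, n_probes = 40)
  ref <- generate_cell_reference(40, 4, seed = 55)
  d <- generate_cohort(cfg, 1, ref)
  expect_error(run_ewas(d, ewas_model("paternal", mutual_adjustment = TRUE,
                                      sex_stratum = "female",
                                      n_surrogate_variables = 2),
                        reference = ref),
               class = "ewasmeta_stratum_too_small")
})

test_that("cell-proportion regressions recover a deterministic line and are calibrated", {
  cfg <- tiny_config(seed = 56, n_cohorts = 1, n = 100, n_probes = 20)
  ref <- generate_cell_reference(20, 4, seed = 56)
  d <- generate_cohort(cfg, 1, ref)
  z <- standardize_bmi(d$phenotypes$paternal_bmi)
  est <- cbind(nRBC = 0.2 + 0.001 * z)
  rownames(est) <- d$phenotypes$sample_id
  r <- regress_cell_on_bmi(d, est)
  expect_equal(r$estimate[1], 0.001, tolerance = 1e-12)

  withr::with_seed(57, {   # type-I error calibration at n=500
    n <- 500
    bmi <- rnorm(n, 26, 3)
    dd <- list(cohort_id = "c", phenotypes = data.frame(
      sample_id = sprintf("s%03d", 1:n), paternal_bmi = bmi))
    rej <- mean(replicate(500, {
      pr <- cbind(ct = runif(n, 0.1, 0.3))
      rownames(pr) <- dd$phenotypes$sample_id
      regress_cell_on_bmi(dd, pr)$p[1] < 0.05
    }))
    expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  })
})

test_that("parental BMI Spearman correlation handles monotone and degenerate cases", {
  mono <- list(cohort_id = "c", phenotypes = data.frame(
    sample_id = letters[1:6], paternal_bmi = 20:25, maternal_bmi = c(21, 23, 24, 26, 28, 30)))
  expect_equal(parental_bmi_correlation(mono)$rho, 1)
  anti <- mono
  anti$phenotypes$maternal_bmi <- rev(anti$phenotypes$maternal_bmi)
  expect_equal(parental_bmi_correlation(anti)$rho, -1)
  few <- list(cohort_id = "c", phenotypes = data.frame(
    sample_id = letters[1:3], paternal_bmi = 20:22, maternal_bmi = 23:25))
  expect_error(parental_bmi_correlation(few), class = "ewasmeta_insufficient_data")
})

test_that("EWAS result files round-trip through the exchange format", {
  cfg <- tiny_config(seed = 58, n_cohorts = 1, n = 60, n_probes = 30)
  ref <- generate_cell_reference(30, 4, seed = 58)
  d <- generate_cohort(cfg, 1, ref)
  r <- run_ewas(d, ewas_model("maternal", mutual_adjustment = TRUE,
                              n_surrogate_variables = 2), reference = ref)
  dir <- withr::local_tempdir()
  path <- write_ewas_result(r, dir)
  expect_match(basename(path), "^cohort01_maternal_adjusted_all\\.tsv$")
  back <- read_ewas_result(path)
  expect_equal(back$estimate, r$estimate, tolerance = 1e-12)
  expect_equal(back$p, r$p, tolerance = 1e-12)
})
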