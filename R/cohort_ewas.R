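# Cohort-level EWAS following the shared consortium analysis plan:
# exposure Z-scoring, Tukey outlier removal, reference-based cell-type
# deconvolution, surrogate-variable estimation, per-CpG covariate-adjusted
# linear models.

EWAS_COVARIATES <- c("paternal_age", "maternal_age", "maternal_smoking",
                     "paternal_smoking", "paternal_sep", "parity")

#' Convert BMI values to internal Z-scores
#'
#' Each cohort standardizes its exposure internally: mean 0, sample SD 1
#' (n-1 denominator) over non-missing entries; missing values propagate.
#'
#' @param bmi_values numeric vector (kg/m^2).
#' @return numeric Z-score vector of the same length.
#' @export
standardize_bmi <- function(bmi_values) {
  ok <- !is.na(bmi_values)
  if (sum(ok) < 2)
    em_stop("need at least 2 non-missing BMI values", "ewasmeta_degenerate_exposure")
  s <- stats::sd(bmi_values[ok])
  if (!is.finite(s) || s == 0)
    em_stop("BMI has zero variance; cannot standardize", "ewasmeta_degenerate_exposure")
  (bmi_values - mean(bmi_values[ok])) / s
}

#' Remove per-probe methylation outliers by the Tukey method
#'
#' Values outside [Q1 - 3*IQR, Q3 + 3*IQR] are set missing, probe by probe;
#' quartiles use the linear-interpolation convention (R quantile type 7).
#' Potential outliers are typically introduced by technical error or a rare
#' SNP under the probe. Probes with fewer than 4 non-missing values are
#' skipped (a single aggregated warning is raised).
#'
#' @param betas probes x samples matrix, values in [0,1] or NA.
#' @return list with `betas` (outliers set to NA), `n_removed` (named per
#'   probe) and `n_skipped`.
#' @export
remove_methylation_outliers <- function(betas) {
  stopifnot(is.matrix(betas))
  n_removed <- integer(nrow(betas))
  names(n_removed) <- rownames(betas)
  skipped <- 0L
  n <- ncol(betas)
  has_na <- rowSums(is.na(betas)) > 0L
  if (any(!has_na) && n >= 4) {
    # vectorized fast path: sort complete rows once, interpolate type-7
    # quartiles from the order statistics
    rows <- which(!has_na)
    sub <- betas[rows, , drop = FALSE]
    srt <- matrix(sub[order(row(sub), sub)], nrow = length(rows), byrow = TRUE)
    q7 <- function(h) {
      lo <- floor(h); frac <- h - lo
      srt[, lo] + frac * (srt[, min(lo + 1, n)] - srt[, lo])
    }
    q1 <- q7((n - 1) * 0.25 + 1)
    q3 <- q7((n - 1) * 0.75 + 1)
    iqr <- q3 - q1
    bad <- sub < (q1 - 3 * iqr) | sub > (q3 + 3 * iqr)
    nb <- rowSums(bad)
    if (any(nb > 0)) {
      sub[bad] <- NA_real_
      betas[rows, ] <- sub
      n_removed[rows] <- nb
    }
  }
  for (j in which(has_na | n < 4)) {
    x <- betas[j, ]
    ok <- !is.na(x)
    if (sum(ok) < 4) { skipped <- skipped + 1L; next }
    q <- stats::quantile(x[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    bad <- ok & (x < q[1] - 3 * iqr | x > q[2] + 3 * iqr)
    if (any(bad)) {
      betas[j, bad] <- NA_real_
      n_removed[j] <- sum(bad)
    }
  }
  if (skipped > 0)
    em_warn(sprintf("%d probe(s) had <4 non-missing values; outlier removal skipped", skipped),
            "ewasmeta_outlier_skip")
  list(betas = betas, n_removed = n_removed, n_skipped = skipped)
}

# Lawson-Hanson active-set NNLS on the normal equations; exact for the
# small, full-rank systems arising in reference-based deconvolution
# (k cell types, k << probes).
nnls_small <- function(AtA, Atb, tol = 1e-10) {
  k <- length(Atb)
  x <- numeric(k)
  P <- logical(k)
  w <- Atb - AtA %*% x
  iter <- 0L
  while (any(!P) && max(w[!P]) > tol && iter < 30 * k) {
    iter <- iter + 1L
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      s <- numeric(k)
      s[P] <- solve(AtA[P, P, drop = FALSE], Atb[P])
      if (all(s[P] > tol)) break
      neg <- P & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    x <- s
    w <- Atb - AtA %*% x
  }
  x
}

#' Estimate cell-type proportions by constrained projection
#'
#' Reference-based (Houseman-style) deconvolution: each sample's beta vector,
#' restricted to the probes shared with the reference, is regressed on the
#' reference profiles under a nonnegativity constraint (Lawson--Hanson
#' active-set NNLS); the solution is then renormalized to sum to 1 (or left
#' as-is with row sums <= 1 under `sum_to_one = FALSE`).
#'
#' @param betas probes x samples matrix.
#' @param reference a `cell_reference`.
#' @param sum_to_one renormalize each sample's proportions to sum 1 (default).
#' @return samples x cell-types matrix of proportions.
#' @export
estimate_cell_proportions <- function(betas, reference, sum_to_one = TRUE) {
  stopifnot(inherits(reference, "cell_reference"))
  shared <- intersect(rownames(betas), rownames(reference$profiles))
  k <- ncol(reference$profiles)
  if (length(shared) < k)
    em_stop("fewer shared probes than cell types", "ewasmeta_unidentifiable_reference")
  R <- reference$profiles[shared, , drop = FALSE]
  if (qr(R)$rank < k)
    em_stop("reference profiles are rank-deficient on shared probes",
            "ewasmeta_unidentifiable_reference")
  B <- betas[shared, , drop = FALSE]
  out <- matrix(NA_real_, ncol(B), k,
                dimnames = list(colnames(B), colnames(R)))
  # work on the normal equations: AtA is shared across samples; samples with
  # a few missing probes use a rank-|S| downdate of AtA instead of a fresh
  # crossprod over all shared probes
  AtA <- crossprod(R)
  na_count <- colSums(is.na(B))
  B0 <- B
  B0[is.na(B0)] <- 0
  Atb_all <- crossprod(R, B0)
  for (i in seq_len(ncol(B))) {
    if (na_count[i] == 0L) {
      out[i, ] <- nnls_small(AtA, Atb_all[, i])
    } else {
      S <- which(is.na(B[, i]))
      if (length(shared) - length(S) < k) { out[i, ] <- 1 / k; next }
      out[i, ] <- nnls_small(AtA - crossprod(R[S, , drop = FALSE]), Atb_all[, i])
    }
  }
  if (sum_to_one) {
    s <- rowSums(out)
    bad <- !is.finite(s) | s <= 0
    out[bad, ] <- 1 / k
    out[!bad, ] <- out[!bad, , drop = FALSE] / s[!bad]
  }
  out
}

#' Estimate surrogate variables from covariate-residualized methylation
#'
#' Residualizes each probe on the supplied design, then takes the top-k
#' principal directions of the residual matrix in sample space as surrogate
#' variables. [run_ewas()] passes the covariate design without the exposure:
#' the SVs then capture the latent technical factors in full (including
#' their chance in-sample correlation with the exposure), which keeps the
#' exposure's standard errors calibrated; sparse genuine effects contribute
#' negligibly to the leading factors. Probes with missing values are mean-imputed for this step
#' only. SVs are orthogonal to the covariate column space by construction;
#' signs are fixed so the first non-negligible loading is positive.
#'
#' @param betas probes x samples matrix.
#' @param design samples x q covariate design matrix (include the intercept).
#' @param k number of surrogate variables (default 20).
#' @return samples x k matrix of surrogate variables.
#' @export
estimate_surrogate_variables <- function(betas, design, k = 20L) {
  n <- ncol(betas)
  design <- as.matrix(design)
  stopifnot(nrow(design) == n)
  if (k == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  qrd <- qr(design)
  if (k >= n - qrd$rank)
    em_stop("k must be smaller than samples minus design rank", "ewasmeta_invalid_config")
  B <- betas
  if (anyNA(B)) {
    rm_ <- rowMeans(B, na.rm = TRUE)
    idx <- which(is.na(B), arr.ind = TRUE)
    B[idx] <- rm_[idx[, 1]]
  }
  Q <- qr.Q(qrd)[, seq_len(qrd$rank), drop = FALSE]
  S <- t(B)                       # samples x probes
  S <- S - Q %*% crossprod(Q, S)  # residualize in sample space
  # left singular vectors of S via the (n x n) Gram matrix
  ev <- eigen(tcrossprod(S), symmetric = TRUE)
  sv <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    nz <- which(abs(sv[, j]) > 1e-8)
    if (length(nz) && sv[nz[1], j] < 0) sv[, j] <- -sv[, j]
  }
  colnames(sv) <- sprintf("sv%02d", seq_len(k))
  rownames(sv) <- colnames(betas)
  sv
}

#' Specify an EWAS model variant
#'
#' @param exposure `"paternal"` or `"maternal"` (internally Z-scored BMI).
#' @param mutual_adjustment also adjust for the other parent's BMI Z-score.
#' @param sex_stratum `"all"`, `"female"` or `"male"`.
#' @param n_surrogate_variables number of SVs to estimate and adjust for
#'   (default 20).
#' @param min_stratum_size minimum sample size for a sex stratum (default
#'   30); smaller strata raise a `stratum-too-small` condition so the cohort
#'   is omitted from that stratified meta-analysis.
#' @param remove_outliers apply Tukey 3xIQR outlier removal first (default).
#' @return object of class `ewas_model`.
#' @export
ewas_model <- function(exposure = c("paternal", "maternal"),
                       mutual_adjustment = FALSE,
                       sex_stratum = c("all", "female", "male"),
                       n_surrogate_variables = 20L,
                       min_stratum_size = 30L,
                       remove_outliers = TRUE) {
  exposure <- match.arg(sub("_bmi_z$", "", exposure), c("paternal", "maternal"))
  sex_stratum <- match.arg(sex_stratum)
  if (n_surrogate_variables < 0)
    em_stop("n_surrogate_variables must be >= 0", "ewasmeta_invalid_config")
  structure(list(exposure = exposure, mutual_adjustment = mutual_adjustment,
                 sex_stratum = sex_stratum,
                 n_surrogate_variables = as.integer(n_surrogate_variables),
                 min_stratum_size = as.integer(min_stratum_size),
                 remove_outliers = remove_outliers),
            class = "ewas_model")
}

model_label <- function(model) {
  sprintf("%s_%s_%s", model$exposure,
          if (model$mutual_adjustment) "adjusted" else "unadjusted",
          model$sex_stratum)
}

#' Run one cohort's EWAS
#'
#' For each probe fits ordinary least squares of methylation beta on the
#' exposure Z-score, the fixed covariate set (parental ages, maternal and
#' paternal smoking, paternal socio-economic position, parity), estimated
#' cell proportions (one column dropped to break the sum-to-one constraint),
#' k surrogate variables and, under mutual adjustment, the other parent's
#' BMI Z-score. Analysis is complete-case per probe. The exposure
#' coefficient and its SE are reported in percentage-methylation points per
#' 1 SD of BMI; p-values use the t distribution with residual degrees of
#' freedom.
#'
#' @param dataset a `cohort_dataset` (or compatible list with `betas` and
#'   `phenotypes`).
#' @param model an [ewas_model()].
#' @param reference a `cell_reference` used for deconvolution (ignored if
#'   `cell_proportions` given).
#' @param cell_proportions optional precomputed samples x cell-types matrix.
#' @return data.frame of class `cohort_ewas` with columns probe_id,
#'   estimate, se, p, n; attributes `cohort_id` and `model`.
#' @export
run_ewas <- function(dataset, model, reference = NULL, cell_proportions = NULL) {
  stopifnot(inherits(model, "ewas_model"))
  phen <- dataset$phenotypes
  need <- c("sample_id", "paternal_bmi", "maternal_bmi", EWAS_COVARIATES, "child_sex")
  miss <- setdiff(need, names(phen))
  if (length(miss))
    em_stop(paste("phenotype columns missing:", paste(miss, collapse = ", ")),
            "ewasmeta_invalid_config")

  betas <- dataset$betas
  if (model$remove_outliers) betas <- remove_methylation_outliers(betas)$betas

  # exposure standardized on the full cohort, then stratified
  phen$paternal_bmi_z <- standardize_bmi(phen$paternal_bmi)
  phen$maternal_bmi_z <- standardize_bmi(phen$maternal_bmi)

  if (is.null(cell_proportions)) {
    if (is.null(reference))
      em_stop("either reference or cell_proportions must be supplied",
              "ewasmeta_invalid_config")
    cell_proportions <- estimate_cell_proportions(betas, reference)
  }
  cp <- cell_proportions[phen$sample_id, -1, drop = FALSE]  # drop one column

  keep <- rep(TRUE, nrow(phen))
  if (model$sex_stratum != "all") keep <- phen$child_sex == model$sex_stratum
  if (sum(keep) < model$min_stratum_size)
    em_stop(sprintf("stratum '%s' has %d samples (< %d); cohort omitted from this stratified analysis",
                    model$sex_stratum, sum(keep), model$min_stratum_size),
            "ewasmeta_stratum_too_small")

  expo_col <- paste0(model$exposure, "_bmi_z")
  other_col <- paste0(setdiff(c("paternal", "maternal"), model$exposure), "_bmi_z")
  covar_cols <- c(EWAS_COVARIATES, if (model$mutual_adjustment) other_col)
  sub <- phen[keep, , drop = FALSE]
  cpk <- cp[keep, , drop = FALSE]
  complete <- stats::complete.cases(sub[, c(expo_col, covar_cols)]) &
    stats::complete.cases(cpk)
  sub <- sub[complete, , drop = FALSE]
  cpk <- cpk[complete, , drop = FALSE]
  Bk <- betas[, sub$sample_id, drop = FALSE]

  # SVs are estimated from covariate-only residuals (exposure excluded from
  # the residualizing design): the SVs then track the latent factors in
  # full, including their chance in-sample correlation with the exposure,
  # which keeps the exposure's standard errors calibrated. Genuine exposure
  # effects stay out of the SVs as long as they are sparse relative to the
  # array, as in any realistic EWAS.
  Xcov <- cbind(`(Intercept)` = 1, as.matrix(sub[, covar_cols, drop = FALSE]),
                cpk)
  sv <- estimate_surrogate_variables(Bk, Xcov, k = model$n_surrogate_variables)
  X <- cbind(`(Intercept)` = 1, exposure = sub[[expo_col]],
             as.matrix(sub[, covar_cols, drop = FALSE]), cpk, sv)

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    em_stop(paste("design matrix is rank-deficient; collinear columns:",
                  paste(dropped, collapse = ", ")), "ewasmeta_rank_deficient")
  }

  n_s <- nrow(X); p_x <- ncol(X)
  est <- se <- pval <- rep(NA_real_, nrow(Bk))
  nn <- integer(nrow(Bk))
  cc_full <- !is.na(Bk)
  full_rows <- which(rowSums(cc_full) == n_s)
  part_rows <- setdiff(seq_len(nrow(Bk)), full_rows)

  e_idx <- 2L  # exposure column
  if (length(full_rows)) {
    # multi-response OLS through the QR of X (one factorization, all probes)
    Y <- t(Bk[full_rows, , drop = FALSE])
    Rp <- qr.R(qrx)                       # pivoted column order
    XtXinv <- chol2inv(Rp)
    ep <- which(qrx$pivot == e_idx)
    XtY <- crossprod(X[, qrx$pivot, drop = FALSE], Y)
    coefs <- backsolve(Rp, backsolve(Rp, XtY, transpose = TRUE))
    df <- n_s - p_x
    rss <- colSums(Y^2) - colSums(XtY * coefs)
    rss <- pmax(rss, 0)
    b <- coefs[ep, ]
    s2 <- rss / df
    sej <- sqrt(s2 * XtXinv[ep, ep])
    tt <- b / sej
    est[full_rows] <- 100 * b
    se[full_rows] <- 100 * sej
    pval[full_rows] <- pmax(2 * stats::pt(-abs(tt), df), .Machine$double.xmin)
    nn[full_rows] <- n_s
  }
  if (length(part_rows)) {
    # probes with missing betas: rank-|S| downdate of the normal equations
    XtX <- crossprod(X)
    Y0 <- Bk[part_rows, , drop = FALSE]
    Y0[is.na(Y0)] <- 0
    XtY0 <- crossprod(X, t(Y0))          # p_x x length(part_rows), X' y0
    yy0 <- rowSums(Y0^2)
    for (jj in seq_along(part_rows)) {
      j <- part_rows[jj]
      ok <- cc_full[j, ]
      nj <- sum(ok)
      if (nj <= p_x) next
      S <- which(!ok)
      XtXj <- XtX - crossprod(X[S, , drop = FALSE])
      ch <- tryCatch(chol(XtXj), error = function(e) NULL)
      if (is.null(ch)) next
      bj <- backsolve(ch, backsolve(ch, XtY0[, jj], transpose = TRUE))
      df <- nj - p_x
      rss <- max(yy0[jj] - sum(XtY0[, jj] * bj), 0)
      s2 <- rss / df
      cinv <- chol2inv(ch)
      sej <- sqrt(s2 * cinv[e_idx, e_idx])
      est[j] <- 100 * bj[e_idx]
      se[j] <- 100 * sej
      pval[j] <- max(2 * stats::pt(-abs(bj[e_idx] / sej), df), .Machine$double.xmin)
      nn[j] <- nj
    }
  }

  res <- data.frame(probe_id = rownames(Bk), estimate = est, se = se,
                    p = pval, n = nn, stringsAsFactors = FALSE)
  res <- res[!is.na(res$estimate) & !is.na(res$se) & res$se > 0, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "cohort_id") <- dataset$cohort_id
  attr(res, "model") <- model
  class(res) <- c("cohort_ewas", "data.frame")
  res
}

#' Regress estimated cell proportions on paternal BMI
#'
#' One simple linear regression per cell type (proportion ~ paternal BMI
#' Z-score); slopes are per 1 SD of paternal BMI, for downstream
#' meta-analysis across cohorts.
#'
#' @param dataset a `cohort_dataset`.
#' @param estimates samples x cell-types proportion matrix.
#' @return data.frame with cell_type, estimate, se, p, n.
#' @export
regress_cell_on_bmi <- function(dataset, estimates) {
  phen <- dataset$phenotypes
  if (nrow(phen) < 3) em_stop("need at least 3 samples", "ewasmeta_insufficient_data")
  z <- standardize_bmi(phen$paternal_bmi)
  est <- estimates[phen$sample_id, , drop = FALSE]
  out <- lapply(colnames(est), function(ct) {
    y <- est[, ct]
    ok <- !is.na(y) & !is.na(z)
    if (stats::var(y[ok]) == 0)
      em_warn(sprintf("cell type %s has constant proportion", ct), "ewasmeta_zero_variance")
    f <- stats::lm.fit(cbind(1, z[ok]), y[ok])
    df <- sum(ok) - 2
    s2 <- sum(f$residuals^2) / df
    xtxinv <- chol2inv(qr.R(qr(cbind(1, z[ok]))))
    sej <- sqrt(s2 * xtxinv[2, 2])
    b <- f$coefficients[2]
    p <- if (sej > 0) 2 * stats::pt(-abs(b / sej), df) else NA_real_
    data.frame(cell_type = ct, estimate = b, se = sej, p = p, n = sum(ok),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "cohort_id") <- dataset$cohort_id
  res
}

#' Spearman correlation between paternal and maternal BMI
#'
#' Reported per cohort to gauge assortative mating as an alternative
#' explanation for paternal-exposure associations.
#'
#' @param dataset a `cohort_dataset`.
#' @return list with `rho`, `p` and `n` (complete pairs).
#' @export
parental_bmi_correlation <- function(dataset) {
  phen <- dataset$phenotypes
  ok <- !is.na(phen$paternal_bmi) & !is.na(phen$maternal_bmi)
  if (sum(ok) < 4)
    em_stop("need at least 4 complete parental BMI pairs", "ewasmeta_insufficient_data")
  ct <- suppressWarnings(stats::cor.test(phen$paternal_bmi[ok], phen$maternal_bmi[ok],
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Write a cohort EWAS result to the consortium exchange format
#'
#' TSV with header probe_id, beta, se, p, n, named
#' `{cohort}_{exposure}_{adjusted|unadjusted}_{stratum}.tsv`.
#'
#' @param result a `cohort_ewas`.
#' @param directory output directory.
#' @return invisibly, the file path.
#' @export
write_ewas_result <- function(result, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  model <- attr(result, "model")
  path <- file.path(directory, sprintf("%s_%s.tsv", attr(result, "cohort_id"),
                                       model_label(model)))
  out <- data.frame(probe_id = result$probe_id, beta = result$estimate,
                    se = result$se, p = result$p, n = result$n)
  data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a cohort EWAS result file written by [write_ewas_result()]
#'
#' @param path TSV file path.
#' @return data.frame with probe_id, estimate, se, p, n.
#' @export
read_ewas_result <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t", na.strings = "NA"))
  data.frame(probe_id = d$probe_id, estimate = d$beta, se = d$se, p = d$p,
             n = d$n, stringsAsFactors = FALSE)
}
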