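# Inverse-variance fixed-effects meta-analysis engine: pooling,
# heterogeneity, FDR, genomic inflation, leave-one-out stability,
# meta-regression on cohort age, sensitivity subsets.

#' Fixed-effects inverse-variance meta-analysis of one probe
#'
#' Weights are w_i = 1/se_i^2; the pooled estimate is sum(w b)/sum(w) with
#' SE (sum w)^-1/2; z uses the normal reference (METAL convention);
#' Cochran's Q = sum w (b - pooled)^2 with df = k - 1 and
#' I^2 = max(0, (Q - df)/Q) x 100 (0 when k = 1). Cohorts with missing
#' estimates or non-positive SE are skipped and shown as `?` in the
#' direction string.
#'
#' @param betas numeric vector of cohort estimates.
#' @param ses numeric vector of cohort standard errors.
#' @param cohort_ids optional labels (used only for bookkeeping).
#' @return list with pooled_beta, pooled_se, z, p, q_stat, q_df, i2,
#'   k_cohorts, direction.
#' @export
fixed_effects_meta <- function(betas, ses, cohort_ids = NULL) {
  stopifnot(length(betas) == length(ses))
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  if (!any(ok))
    em_stop("no cohort contributes a finite estimate with positive SE",
            "ewasmeta_no_data")
  direction <- rep("?", length(betas))
  direction[ok] <- ifelse(betas[ok] < 0, "-", "+")
  w <- 1 / ses[ok]^2
  pooled <- sum(w * betas[ok]) / sum(w)
  pse <- 1 / sqrt(sum(w))
  z <- pooled / pse
  q <- sum(w * (betas[ok] - pooled)^2)
  k <- sum(ok)
  df <- k - 1L
  i2 <- if (k <= 1 || q <= 0) 0 else max(0, (q - df) / q) * 100
  # floor at the smallest representable double so p stays in (0, 1]
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  list(pooled_beta = pooled, pooled_se = pse, z = z,
       p = p, q_stat = q, q_df = df, i2 = i2,
       k_cohorts = k, direction = paste(direction, collapse = ""))
}

#' Meta-analyse cohort EWAS results across all probes
#'
#' Vectorized fixed-effects pooling over the union of probes. Probes present
#' in only one cohort are retained with k = 1 and I^2 = 0 (users can filter
#' on `k`). FDR adjustment (Benjamini--Hochberg) is computed within this
#' analysis.
#'
#' @param results list of cohort result data.frames (probe_id, estimate, se,
#'   p, n), e.g. from [run_ewas()]; names are cohort ids.
#' @return data.frame of class `meta_result`: probe_id, beta, se, z, p,
#'   fdr_p, q, q_df, i2, k, direction, n (summed sample size).
#' @export
meta_analyse <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  if (is.null(names(results)) || any(names(results) == ""))
    names(results) <- vapply(seq_along(results), function(i) {
      cid <- attr(results[[i]], "cohort_id")
      if (is.null(cid)) sprintf("cohort%02d", i) else cid
    }, character(1))
  probes <- Reduce(union, lapply(results, function(r) r$probe_id))
  K <- length(results)
  B <- SE <- matrix(NA_real_, length(probes), K,
                    dimnames = list(probes, names(results)))
  N <- matrix(0L, length(probes), K)
  for (i in seq_len(K)) {
    r <- results[[i]]
    idx <- match(r$probe_id, probes)
    B[idx, i] <- r$estimate
    SE[idx, i] <- r$se
    N[idx, i] <- r$n
  }
  ok <- is.finite(B) & is.finite(SE) & SE > 0
  B[!ok] <- NA_real_
  W <- 1 / SE^2
  W[!ok] <- NA_real_
  k <- rowSums(ok)
  keep <- k >= 1
  if (!all(keep))
    message(sprintf("%d probe(s) dropped: no valid cohort estimate", sum(!keep)))
  sw <- rowSums(W, na.rm = TRUE)
  pooled <- rowSums(W * B, na.rm = TRUE) / sw
  pse <- 1 / sqrt(sw)
  z <- pooled / pse
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  q <- rowSums(W * (B - pooled)^2, na.rm = TRUE)
  df <- pmax(k - 1L, 0L)
  i2 <- ifelse(k <= 1 | q <= 0, 0, pmax(0, (q - df) / q) * 100)
  dirmat <- matrix("?", length(probes), K)
  dirmat[ok] <- ifelse(B[ok] < 0, "-", "+")
  direction <- do.call(paste0, as.data.frame(dirmat, stringsAsFactors = FALSE))
  res <- data.frame(probe_id = probes, beta = pooled, se = pse, z = z, p = p,
                    fdr_p = NA_real_, q = q, q_df = df, i2 = i2, k = k,
                    direction = direction, n = rowSums(N),
                    stringsAsFactors = FALSE)
  res <- res[keep, , drop = FALSE]
  res$fdr_p <- bh_fdr(res$p)
  rownames(res) <- NULL
  attr(res, "cohort_ids") <- names(results)
  class(res) <- c("meta_result", "data.frame")
  res
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, monotone in ranked p; ties share
#' the rank minimum.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return adjusted vector of the same length.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    em_stop("p-values must lie in (0, 1]", "ewasmeta_input_error")
  stats::p.adjust(p_values, method = "BH")
}

#' Genomic inflation factor lambda
#'
#' lambda = median of the 1-df chi-square quantiles of the observed p-values
#' divided by the null median (~0.4549364). Gauges bulk inflation of EWAS
#' test statistics; 1 = no inflation.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomic_inflation_lambda <- function(p_values) {
  if (length(p_values) == 0)
    em_stop("empty p-value vector", "ewasmeta_input_error")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    em_stop("p-values must lie in (0, 1]", "ewasmeta_input_error")
  stats::median(stats::qchisq(p_values, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Leave-one-out stability analysis at one probe
#'
#' Re-pools the remaining cohorts after omitting each contributing cohort in
#' turn. An omission fails if the re-pooled estimate (i) flips direction
#' relative to the full pooled estimate, (ii) changes by more than the
#' attenuation threshold (default >20% change-in-estimate, in either
#' direction), or (iii) has a 95% confidence interval crossing the null. The
#' probe survives iff no omission fails any criterion.
#'
#' @param betas,ses per-cohort estimates and SEs (only finite, se > 0
#'   entries contribute).
#' @param cohort_ids optional cohort labels.
#' @param attenuation_threshold relative change-in-estimate limit (0.20).
#' @param ci_z normal quantile for the CI (1.96 for 95%).
#' @return list with `table` (per-omitted-cohort pooled beta, CI and failure
#'   flags), `survived`, `failure_reasons`; `survived = NA` when only one
#'   cohort contributes.
#' @export
leave_one_out <- function(betas, ses, cohort_ids = NULL,
                          attenuation_threshold = 0.20, ci_z = 1.96) {
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  if (is.null(cohort_ids)) cohort_ids <- sprintf("cohort%02d", seq_along(betas))
  betas <- betas[ok]; ses <- ses[ok]; cohort_ids <- cohort_ids[ok]
  k <- length(betas)
  if (k < 2)
    return(list(table = NULL, survived = NA,
                failure_reasons = character(0), k = k))
  full <- fixed_effects_meta(betas, ses)
  rows <- lapply(seq_len(k), function(i) {
    m <- fixed_effects_meta(betas[-i], ses[-i])
    lo <- m$pooled_beta - ci_z * m$pooled_se
    hi <- m$pooled_beta + ci_z * m$pooled_se
    flip <- sign(m$pooled_beta) != sign(full$pooled_beta)
    atten <- if (full$pooled_beta == 0) m$pooled_beta != 0 else
      abs(m$pooled_beta - full$pooled_beta) / abs(full$pooled_beta) > attenuation_threshold
    crosses <- lo <= 0 && hi >= 0
    data.frame(omitted = cohort_ids[i], pooled_beta = m$pooled_beta,
               ci_low = lo, ci_high = hi, direction_flip = flip,
               attenuation_gt_20pct = atten, ci_crosses_null = crosses,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  reasons <- c("direction_flip", "attenuation_gt_20pct", "ci_crosses_null")
  failure_reasons <- reasons[vapply(reasons, function(r) any(tab[[r]]), logical(1))]
  list(table = tab, survived = length(failure_reasons) == 0,
       failure_reasons = failure_reasons, k = k)
}

#' Leave-one-out analysis at the top meta-analysis probes
#'
#' Runs [leave_one_out()] at probes below a reporting threshold: FDR < `fdr`
#' plus a relaxed p-value tier (default p < 1e-5).
#'
#' @param meta a `meta_result`.
#' @param results the cohort result list that produced it.
#' @param fdr FDR threshold (default 0.05).
#' @param p_relaxed relaxed p-value tier (default 1e-5); NULL to disable.
#' @param attenuation_threshold passed to [leave_one_out()].
#' @return named list (probe id -> leave_one_out result), with a `survived`
#'   logical attribute vector.
#' @export
loo_at_top_probes <- function(meta, results, fdr = 0.05, p_relaxed = 1e-5,
                              attenuation_threshold = 0.20) {
  sel <- meta$fdr_p < fdr
  if (!is.null(p_relaxed)) sel <- sel | meta$p < p_relaxed
  probes <- meta$probe_id[sel]
  out <- lapply(probes, function(pr) {
    b <- vapply(results, function(r) {
      i <- match(pr, r$probe_id); if (is.na(i)) NA_real_ else r$estimate[i]
    }, numeric(1))
    s <- vapply(results, function(r) {
      i <- match(pr, r$probe_id); if (is.na(i)) NA_real_ else r$se[i]
    }, numeric(1))
    leave_one_out(b, s, names(results),
                  attenuation_threshold = attenuation_threshold)
  })
  names(out) <- probes
  out
}

#' Inverse-variance weighted meta-regression on cohort mean age
#'
#' Weighted least squares of cohort effect estimates on the cohort mean age
#' at DNA-sample collection, with weights 1/se^2; the slope is per year of
#' age, with a normal-reference two-sided p-value.
#'
#' @param betas,ses per-cohort estimates and SEs.
#' @param ages per-cohort mean ages (years).
#' @return list with slope, se, p, intercept.
#' @export
meta_regression_age <- function(betas, ses, ages) {
  ok <- is.finite(betas) & is.finite(ses) & ses > 0 & is.finite(ages)
  betas <- betas[ok]; ses <- ses[ok]; ages <- ages[ok]
  if (length(betas) < 3 || stats::var(ages) == 0)
    em_stop("need >= 3 cohorts with non-constant mean age",
            "ewasmeta_degenerate_moderator")
  W <- 1 / ses^2
  X <- cbind(1, ages)
  XtWX <- crossprod(X, W * X)
  V <- solve(XtWX)
  coef <- V %*% crossprod(X, W * betas)
  se_slope <- sqrt(V[2, 2])
  z <- coef[2] / se_slope
  list(slope = coef[2], se = se_slope, p = 2 * stats::pnorm(-abs(z)),
       intercept = coef[1])
}

#' Sensitivity meta-analysis excluding named cohorts
#'
#' Re-runs the identical pooling pipeline on the remaining cohorts, with FDR
#' re-ranked within the subset analysis.
#'
#' @param results named list of cohort result data.frames.
#' @param excluded character vector of cohort ids to drop.
#' @return `meta_result` for the subset.
#' @export
sensitivity_subset_meta <- function(results, excluded = character(0)) {
  keep <- setdiff(names(results), excluded)
  if (length(keep) == 0)
    em_stop("all cohorts excluded; nothing to meta-analyse",
            "ewasmeta_empty_analysis")
  meta_analyse(results[keep])
}

#' Meta-analyse per-cohort cell-proportion regressions
#'
#' Fixed-effects pooling of the per-cell-type slopes (proportion per 1 SD of
#' paternal BMI) across cohorts.
#'
#' @param cell_results list of per-cohort data.frames from
#'   [regress_cell_on_bmi()].
#' @return data.frame: cell_type, beta, se, z, p, ci_low, ci_high, q, i2, k.
#' @export
meta_analyse_cell_associations <- function(cell_results) {
  stopifnot(length(cell_results) >= 1)
  cells <- unique(unlist(lapply(cell_results, function(r) r$cell_type)))
  rows <- lapply(cells, function(ct) {
    b <- vapply(cell_results, function(r) {
      i <- match(ct, r$cell_type); if (is.na(i)) NA_real_ else r$estimate[i]
    }, numeric(1))
    s <- vapply(cell_results, function(r) {
      i <- match(ct, r$cell_type); if (is.na(i)) NA_real_ else r$se[i]
    }, numeric(1))
    m <- fixed_effects_meta(b, s)
    data.frame(cell_type = ct, beta = m$pooled_beta, se = m$pooled_se,
               z = m$z, p = m$p,
               ci_low = m$pooled_beta - 1.96 * m$pooled_se,
               ci_high = m$pooled_beta + 1.96 * m$pooled_se,
               q = m$q_stat, i2 = m$i2, k = m$k_cohorts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a meta-analysis result table
#'
#' TSV with METAL-style per-cohort direction string.
#'
#' @param meta a `meta_result`.
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
write_meta_result <- function(meta, path) {
  data.table::fwrite(as.data.frame(meta), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}
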