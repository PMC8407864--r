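# Quality checks of cohort-level and meta-analysed results: genomic
# inflation, precision coordinates, estimate distributions, cross-model
# agreement, extreme-estimate flags.

#' Quality-check a set of cohort EWAS results
#'
#' For each cohort x model result computes the genomic inflation factor
#' lambda, the precision-plot coordinates (x = sqrt(n), y = 1/median SE),
#' and the five-number summary of effect estimates; flags estimates beyond
#' a configurable absolute bound as extreme (such outliers typically occur
#' in small sex-stratified strata and carry little meta-analysis weight).
#' Cross-result Spearman correlations of effect estimates are computed on
#' shared probes.
#'
#' @param results named list of result data.frames (probe_id, estimate, se,
#'   p, n), e.g. from [run_ewas()]; names identify cohort x model.
#' @param extreme_bound absolute effect bound in percentage points per SD
#'   (default 10).
#' @return object of class `qc_report`: list with `table` (per-result
#'   metrics), `correlations` (Spearman matrix), `extremes` (per-result
#'   probe ids flagged).
#' @export
cohort_qc <- function(results, extreme_bound = 10) {
  if (length(results) == 0) em_stop("no results supplied", "ewasmeta_input_error")
  if (is.null(names(results)))
    names(results) <- sprintf("result%02d", seq_along(results))
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    med_se <- stats::median(r$se, na.rm = TRUE)
    n_med <- stats::median(r$n, na.rm = TRUE)
    qs <- stats::quantile(r$estimate, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE,
                          type = 7, names = FALSE)
    data.frame(result = nm, lambda = genomic_inflation_lambda(r$p),
               n = n_med, median_se = med_se,
               precision_x = sqrt(n_med), precision_y = 1 / med_se,
               est_min = qs[1], est_q1 = qs[2], est_median = qs[3],
               est_q3 = qs[4], est_max = qs[5],
               n_extreme = sum(abs(r$estimate) > extreme_bound, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  K <- length(results)
  corr <- matrix(1, K, K, dimnames = list(names(results), names(results)))
  if (K > 1) {
    for (i in 1:(K - 1)) for (j in (i + 1):K) {
      a <- results[[i]]; b <- results[[j]]
      common <- intersect(a$probe_id, b$probe_id)
      corr[i, j] <- corr[j, i] <- if (length(common) >= 3)
        stats::cor(a$estimate[match(common, a$probe_id)],
                   b$estimate[match(common, b$probe_id)],
                   method = "spearman", use = "complete.obs") else NA_real_
    }
  }
  extremes <- lapply(results, function(r)
    r$probe_id[!is.na(r$estimate) & abs(r$estimate) > extreme_bound])
  structure(list(table = tab, correlations = corr, extremes = extremes),
            class = "qc_report")
}

#' QQ-plot coordinates for a p-value vector
#'
#' Emits the plot-ready expected/observed -log10(p) table used for QQ
#' diagnostics (no figure is rendered).
#'
#' @param p_values numeric vector in (0, 1].
#' @return data.frame with expected and observed columns, sorted.
#' @export
qq_coordinates <- function(p_values) {
  p <- sort(p_values)
  n <- length(p)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n), observed = -log10(p))
}
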