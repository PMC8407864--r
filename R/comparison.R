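# Maternal-vs-paternal comparison and candidate-locus enrichment:
# between-parent heterogeneity Q, KS enrichment of p-value sets,
# direction-of-effect concordance, model-estimate comparison summaries.

#' Heterogeneity between paternal and maternal effect estimates
#'
#' Cochran's Q for the difference between two independent estimates:
#' Q = (b_p - b_m)^2 / (se_p^2 + se_m^2), compared against a 1-df
#' chi-square. Also reports the two-estimate I^2 = max(0, (Q - 1)/Q) x 100.
#' Vectorized over probes; symmetric in its two arguments.
#'
#' @param beta_p,se_p paternal estimate(s) and SE(s).
#' @param beta_m,se_m maternal estimate(s) and SE(s).
#' @return data.frame with q, df (= 1), p, i2.
#' @export
parental_heterogeneity_q <- function(beta_p, se_p, beta_m, se_m) {
  if (any(!is.finite(beta_p) | !is.finite(se_p) | !is.finite(beta_m) |
          !is.finite(se_m)) || any(se_p <= 0) || any(se_m <= 0))
    em_stop("estimates and SEs must be finite with SE > 0", "ewasmeta_input_error")
  q <- (beta_p - beta_m)^2 / (se_p^2 + se_m^2)
  i2 <- ifelse(q <= 1, 0, (q - 1) / q * 100)
  data.frame(q = q, df = 1L, p = stats::pchisq(q, df = 1, lower.tail = FALSE),
             i2 = i2)
}

#' Kolmogorov--Smirnov enrichment of a candidate p-value set
#'
#' Tests whether candidate-set p-values deviate from the uniform null. The
#' default is the two-sided one-sample KS test; `alternative = "inflation"`
#' gives the one-sided variant sensitive to an excess of small p-values.
#'
#' @param candidate_p p-values at the candidate probes, in (0, 1].
#' @param alternative `"two.sided"` or `"inflation"`.
#' @param set_name label used in error messages.
#' @return list with `D` (KS statistic), `p` and `n`.
#' @export
ks_enrichment <- function(candidate_p, alternative = c("two.sided", "inflation"),
                          set_name = "candidate set") {
  alternative <- match.arg(alternative)
  if (length(candidate_p) == 0)
    em_stop(paste0("empty candidate set after intersection: ", set_name),
            "ewasmeta_empty_set")
  if (any(!is.finite(candidate_p) | candidate_p <= 0 | candidate_p > 1))
    em_stop("candidate p-values must lie in (0, 1]", "ewasmeta_input_error")
  alt <- if (alternative == "inflation") "greater" else "two.sided"
  kt <- suppressWarnings(stats::ks.test(candidate_p, "punif", alternative = alt))
  list(D = unname(kt$statistic), p = kt$p.value, n = length(candidate_p))
}

#' Direction-of-effect concordance with previously reported signs
#'
#' Counts how many observed effect estimates share the previously reported
#' direction, how many observed p-values fall below 0.05, and how many
#' survive BH-FDR correction within the candidate set (m = set size).
#' Observed estimates of exactly zero are counted as discordant and
#' reported as ties.
#'
#' @param reference data.frame with probe_id and sign (+1/-1, or "+"/"-").
#' @param observed data.frame with probe_id, beta (or estimate) and p.
#' @return list with n_same_direction, n_total, n_ties, n_p_below_0.05,
#'   fdr_survivors and the per-probe table.
#' @export
direction_concordance <- function(reference, observed) {
  if (!"beta" %in% names(observed) && "estimate" %in% names(observed))
    observed$beta <- observed$estimate
  stopifnot(all(c("probe_id", "sign") %in% names(reference)),
            all(c("probe_id", "beta", "p") %in% names(observed)))
  common <- intersect(reference$probe_id, observed$probe_id)
  if (length(common) == 0)
    em_stop("no overlap between reference and observed probe sets",
            "ewasmeta_empty_set")
  ref_sign <- reference$sign[match(common, reference$probe_id)]
  if (is.character(ref_sign)) ref_sign <- ifelse(ref_sign == "-", -1, 1)
  obs <- observed[match(common, observed$probe_id), ]
  same <- sign(obs$beta) == sign(ref_sign) & obs$beta != 0
  ties <- obs$beta == 0
  fdr <- bh_fdr(obs$p)
  list(n_same_direction = sum(same), n_total = length(common),
       n_ties = sum(ties), n_p_below_0.05 = sum(obs$p < 0.05),
       fdr_survivors = sum(fdr < 0.05),
       table = data.frame(probe_id = common, reference_sign = ref_sign,
                          beta = obs$beta, p = obs$p, fdr_p = fdr,
                          concordant = same, stringsAsFactors = FALSE))
}

#' Compare effect estimates from two model variants
#'
#' Summarizes how much an adjustment changes genome-wide effect estimates:
#' Spearman correlation, the per-probe percentage difference
#' |b_a - b_b| / |b_b| x 100 (with the unadjusted model `b` as baseline;
#' probes with b_b = 0 are excluded and counted), and the share of probes
#' with a larger absolute estimate under model a.
#'
#' @param model_a data.frame with probe_id and beta/estimate (e.g. the
#'   mutually adjusted model).
#' @param model_b same, the baseline (unadjusted) model.
#' @return list with spearman_rho, median_pct_diff, iqr_pct_diff (length-2),
#'   share_larger_abs_a, n_common, n_zero_baseline.
#' @export
compare_model_estimates <- function(model_a, model_b) {
  get_beta <- function(d) if ("beta" %in% names(d)) d$beta else d$estimate
  common <- intersect(model_a$probe_id, model_b$probe_id)
  if (length(common) == 0)
    em_stop("model result probe sets are disjoint", "ewasmeta_input_error")
  a <- get_beta(model_a)[match(common, model_a$probe_id)]
  b <- get_beta(model_b)[match(common, model_b$probe_id)]
  rho <- stats::cor(a, b, method = "spearman", use = "complete.obs")
  nz <- b != 0
  pct <- abs(a[nz] - b[nz]) / abs(b[nz]) * 100
  list(spearman_rho = rho,
       median_pct_diff = stats::median(pct),
       iqr_pct_diff = unname(stats::quantile(pct, c(0.25, 0.75), type = 7)),
       share_larger_abs_a = mean(abs(a) > abs(b)),
       n_common = length(common), n_zero_baseline = sum(!nz))
}

#' Candidate-set enrichment report against a meta-analysis
#'
#' Routes candidate sets (probe id vectors, or gene intervals mapped through
#' [map_genes_to_probes()]) through [ks_enrichment()] and, when expected
#' directions are given, [direction_concordance()].
#'
#' @param meta a `meta_result`.
#' @param candidate_sets named list; each element either a character vector
#'   of probe ids or a data.frame of gene intervals (gene, chr, start, end).
#' @param annotation probe annotation (required for gene-interval sets).
#' @param expected_directions optional named list of data.frames (probe_id,
#'   sign) parallel to `candidate_sets`.
#' @param alternative passed to [ks_enrichment()].
#' @return data.frame: set, n_overlap, D, ks_p, n_concordant, n_total.
#' @export
enrichment_report <- function(meta, candidate_sets, annotation = NULL,
                              expected_directions = NULL,
                              alternative = "two.sided") {
  rows <- lapply(names(candidate_sets), function(nm) {
    cs <- candidate_sets[[nm]]
    if (is.data.frame(cs)) {
      if (is.null(annotation))
        em_stop("annotation required to map gene-interval candidate sets",
                "ewasmeta_input_error")
      cs <- unique(unlist(map_genes_to_probes(cs, annotation)))
    }
    probes <- intersect(cs, meta$probe_id)
    pvals <- meta$p[match(probes, meta$probe_id)]
    ks <- ks_enrichment(pvals, alternative = alternative, set_name = nm)
    ncc <- ntt <- NA_integer_
    if (!is.null(expected_directions) && !is.null(expected_directions[[nm]])) {
      dc <- direction_concordance(expected_directions[[nm]],
                                  meta[, c("probe_id", "beta", "p")])
      ncc <- dc$n_same_direction; ntt <- dc$n_total
    }
    data.frame(set = nm, n_overlap = length(probes), D = ks$D, ks_p = ks$p,
               n_concordant = ncc, n_total = ntt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
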