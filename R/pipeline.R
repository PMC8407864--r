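# End-to-end orchestration: configuration, deterministic seeding, stage
# composition (filter -> cohort EWAS -> QC -> meta -> FDR -> leave-one-out
# -> meta-regression -> sensitivity subsets -> comparison/enrichment),
# manifest writing.

#' Pipeline run configuration
#'
#' The machine form of the consortium's pre-specified analysis plan.
#' Cohorts come either from an in-memory simulation config or from
#' directories written by [write_cohort()].
#'
#' @param sim_config a [simulation_config()] (used when `cohort_dirs` NULL).
#' @param cohort_dirs optional character vector of cohort directories.
#' @param annotation probe annotation table (default: clean simulated
#'   autosomal annotation matching the probe count).
#' @param reference optional `cell_reference`.
#' @param n_surrogate_variables SVs per cohort model (default 20).
#' @param sex_strata strata to analyse besides "all" (default both sexes).
#' @param fdr_threshold FDR significance threshold (0.05).
#' @param attenuation_threshold leave-one-out change-in-estimate limit (0.20).
#' @param min_stratum_size minimum sex-stratum size (30).
#' @param loo_p_relaxed relaxed p tier for leave-one-out reporting (1e-5).
#' @param exclusion_sets named list of cohort-id vectors for sensitivity
#'   meta-analyses.
#' @param candidate_sets named list of candidate probe-id vectors or
#'   gene-interval data.frames.
#' @param expected_directions optional named list of (probe_id, sign) tables.
#' @param cohort_ages optional named numeric vector of cohort mean ages for
#'   meta-regression.
#' @param output_dir directory for written artefacts (NULL = in-memory only).
#' @param seed master seed (overrides the simulation config seed).
#' @return object of class `run_config`.
#' @export
run_config <- function(sim_config = NULL, cohort_dirs = NULL,
                       annotation = NULL, reference = NULL,
                       n_surrogate_variables = 20L,
                       sex_strata = c("female", "male"),
                       fdr_threshold = 0.05, attenuation_threshold = 0.20,
                       min_stratum_size = 30L, loo_p_relaxed = 1e-5,
                       exclusion_sets = NULL, candidate_sets = NULL,
                       expected_directions = NULL, cohort_ages = NULL,
                       output_dir = NULL, seed = NULL) {
  if (is.null(sim_config) && is.null(cohort_dirs))
    em_stop("supply either sim_config or cohort_dirs", "ewasmeta_invalid_config")
  if (fdr_threshold <= 0 || fdr_threshold >= 1 ||
      attenuation_threshold <= 0 || min_stratum_size < 2)
    em_stop("thresholds out of range", "ewasmeta_invalid_config")
  if (!is.null(seed) && !is.null(sim_config)) sim_config$seed <- as.integer(seed)
  structure(list(sim_config = sim_config, cohort_dirs = cohort_dirs,
                 annotation = annotation, reference = reference,
                 n_surrogate_variables = as.integer(n_surrogate_variables),
                 sex_strata = sex_strata, fdr_threshold = fdr_threshold,
                 attenuation_threshold = attenuation_threshold,
                 min_stratum_size = as.integer(min_stratum_size),
                 loo_p_relaxed = loo_p_relaxed,
                 exclusion_sets = exclusion_sets,
                 candidate_sets = candidate_sets,
                 expected_directions = expected_directions,
                 cohort_ages = cohort_ages,
                 output_dir = output_dir,
                 seed = if (!is.null(seed)) as.integer(seed)
                        else if (!is.null(sim_config)) sim_config$seed else 1L),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[stage %s] %s", name, conditionMessage(e)),
                        class = c("ewasmeta_stage_error", class(e))))
  })
}

#' Run the full EWAS meta-analysis pipeline
#'
#' Composes every stage of the analysis plan: probe filtering, cohort-level
#' EWAS for the full model grid (paternal/maternal x unadjusted/mutually
#' adjusted x all/female/male strata for the adjusted models), cohort QC,
#' fixed-effects meta-analysis with FDR, meta-level QC, leave-one-out at
#' top probes, optional meta-regression on cohort age, sensitivity subset
#' meta-analyses, model-estimate comparison, cell-proportion meta-analysis
#' and candidate-set enrichment. Reruns with the same configuration are
#' deterministic; when `output_dir` is set every artefact is written as TSV
#' together with a manifest recording the seed and a config hash.
#'
#' @param config a [run_config()].
#' @return list (invisibly when writing) with elements `cohorts` (ids),
#'   `filter`, `cohort_results`, `skipped_strata`, `qc`, `meta` (per model),
#'   `meta_qc`, `loo`, `meta_regression`, `sensitivity`, `comparison`,
#'   `cell_meta`, `enrichment`, `parental_correlations`, `summary`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  consortium <- stage("load", {
    if (!is.null(config$cohort_dirs)) {
      cs <- lapply(config$cohort_dirs, read_cohort)
      names(cs) <- vapply(cs, `[[`, character(1), "cohort_id")
      cs
    } else generate_consortium(config$sim_config)
  })
  reference <- config$reference
  if (is.null(reference)) reference <- attr(consortium, "reference")
  if (is.null(reference))
    reference <- generate_cell_reference(nrow(consortium[[1]]$betas),
                                         6L, seed = child_seed(config$seed, 0))

  annotation <- config$annotation
  if (is.null(annotation))
    annotation <- simulate_probe_annotation(nrow(consortium[[1]]$betas),
                                            seed = child_seed(config$seed, 999))
  filt <- stage("filter", filter_probes(annotation))
  consortium <- lapply(consortium, function(d) {
    d$betas <- d$betas[intersect(rownames(d$betas), filt$retained), , drop = FALSE]
    d
  })

  models <- list(
    paternal_unadjusted_all = ewas_model("paternal", FALSE, "all"),
    paternal_adjusted_all = ewas_model("paternal", TRUE, "all"),
    maternal_unadjusted_all = ewas_model("maternal", FALSE, "all"),
    maternal_adjusted_all = ewas_model("maternal", TRUE, "all")
  )
  for (st in config$sex_strata) {
    models[[paste0("paternal_adjusted_", st)]] <- ewas_model("paternal", TRUE, st)
    models[[paste0("maternal_adjusted_", st)]] <- ewas_model("maternal", TRUE, st)
  }
  models <- lapply(models, function(m) {
    m$n_surrogate_variables <- config$n_surrogate_variables
    m$min_stratum_size <- config$min_stratum_size
    m
  })

  cohort_results <- list()
  skipped <- list()
  cell_props <- list()
  stage("cohort_ewas", {
    for (cid in names(consortium)) {
      d <- consortium[[cid]]
      cp <- estimate_cell_proportions(d$betas, reference)
      cell_props[[cid]] <- cp
      for (mn in names(models)) {
        res <- tryCatch(run_ewas(d, models[[mn]], cell_proportions = cp),
                        ewasmeta_stratum_too_small = function(e) e)
        if (inherits(res, "condition")) {
          skipped[[length(skipped) + 1]] <- data.frame(
            cohort = cid, model = mn, reason = conditionMessage(res))
        } else {
          cohort_results[[mn]][[cid]] <- res
        }
      }
    }
  })
  skipped <- if (length(skipped)) do.call(rbind, skipped) else NULL

  qc <- stage("cohort_qc", {
    flat <- list()
    for (mn in names(cohort_results))
      for (cid in names(cohort_results[[mn]]))
        flat[[paste(cid, mn, sep = ".")]] <- cohort_results[[mn]][[cid]]
    cohort_qc(flat)
  })

  metas <- stage("meta", lapply(cohort_results, meta_analyse))

  meta_qc <- stage("meta_qc", {
    asres <- lapply(metas, function(m)
      data.frame(probe_id = m$probe_id, estimate = m$beta, se = m$se,
                 p = m$p, n = m$n))
    cohort_qc(asres)
  })

  loo <- stage("loo", lapply(names(metas), function(mn)
    loo_at_top_probes(metas[[mn]], cohort_results[[mn]],
                      fdr = config$fdr_threshold,
                      p_relaxed = config$loo_p_relaxed,
                      attenuation_threshold = config$attenuation_threshold)))
  names(loo) <- names(metas)

  metareg <- NULL
  if (!is.null(config$cohort_ages)) {
    metareg <- stage("meta_regression", {
      lapply(names(metas), function(mn) {
        res <- cohort_results[[mn]]
        top <- metas[[mn]]$probe_id[metas[[mn]]$p < config$loo_p_relaxed |
                                      metas[[mn]]$fdr_p < config$fdr_threshold]
        out <- lapply(top, function(pr) {
          b <- vapply(res, function(r) {
            i <- match(pr, r$probe_id); if (is.na(i)) NA_real_ else r$estimate[i]
          }, numeric(1))
          s <- vapply(res, function(r) {
            i <- match(pr, r$probe_id); if (is.na(i)) NA_real_ else r$se[i]
          }, numeric(1))
          ages <- config$cohort_ages[names(res)]
          tryCatch(meta_regression_age(b, s, ages), error = function(e) NULL)
        })
        names(out) <- top
        out
      })
    })
    names(metareg) <- names(metas)
  }

  sensitivity <- NULL
  if (!is.null(config$exclusion_sets)) {
    sensitivity <- stage("sensitivity", {
      out <- lapply(names(config$exclusion_sets), function(sn) {
        lapply(cohort_results, sensitivity_subset_meta,
               excluded = config$exclusion_sets[[sn]])
      })
      names(out) <- names(config$exclusion_sets)
      out
    })
  }

  comparison <- stage("comparison", list(
    paternal = compare_model_estimates(metas$paternal_adjusted_all,
                                       metas$paternal_unadjusted_all),
    maternal = compare_model_estimates(metas$maternal_adjusted_all,
                                       metas$maternal_unadjusted_all)
  ))

  cell_meta <- stage("cell_meta", {
    cellres <- lapply(names(consortium), function(cid)
      regress_cell_on_bmi(consortium[[cid]], cell_props[[cid]]))
    meta_analyse_cell_associations(cellres)
  })

  parental <- stage("parental_correlation",
                    lapply(consortium, parental_bmi_correlation))

  enrich <- NULL
  if (!is.null(config$candidate_sets)) {
    enrich <- stage("enrichment",
                    enrichment_report(metas$paternal_unadjusted_all,
                                      config$candidate_sets, annotation,
                                      config$expected_directions))
  }

  summary_tab <- do.call(rbind, lapply(names(metas), function(mn) {
    m <- metas[[mn]]
    hits <- sum(m$fdr_p < config$fdr_threshold)
    surv <- if (hits > 0) {
      hit_ids <- m$probe_id[m$fdr_p < config$fdr_threshold]
      sum(vapply(loo[[mn]][hit_ids], function(l) isTRUE(l$survived), logical(1)))
    } else NA_integer_
    data.frame(model = mn, n_fdr_hits = hits, n_loo_survivors = surv,
               n = max(m$n), lambda = genomic_inflation_lambda(m$p),
               stringsAsFactors = FALSE)
  }))

  out <- list(cohorts = names(consortium), filter = filt,
              cohort_results = cohort_results, skipped_strata = skipped,
              qc = qc, meta = metas, meta_qc = meta_qc, loo = loo,
              meta_regression = metareg, sensitivity = sensitivity,
              comparison = comparison, cell_meta = cell_meta,
              enrichment = enrich, parental_correlations = parental,
              summary = summary_tab)

  if (!is.null(config$output_dir)) {
    stage("write", write_pipeline_outputs(out, config))
    invisible(out)
  } else out
}

# Serialize pipeline artefacts as TSVs plus a manifest (seed + config hash).
write_pipeline_outputs <- function(out, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$output_dir
  for (mn in names(out$meta))
    write_meta_result(out$meta[[mn]], file.path(od, paste0("meta_", mn, ".tsv")))
  for (mn in names(out$cohort_results))
    for (cid in names(out$cohort_results[[mn]]))
      write_ewas_result(out$cohort_results[[mn]][[cid]], file.path(od, "cohort"))
  data.table::fwrite(out$summary, file.path(od, "summary.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(out$qc$table, file.path(od, "qc_cohort.tsv"), sep = "\t",
                     quote = FALSE)
  data.table::fwrite(out$cell_meta, file.path(od, "cell_meta.tsv"), sep = "\t",
                     quote = FALSE)
  if (!is.null(out$enrichment))
    data.table::fwrite(out$enrichment, file.path(od, "enrichment.tsv"),
                       sep = "\t", quote = FALSE)
  cfg_file <- file.path(od, "config.txt")
  hashed <- setdiff(names(config), c("annotation", "reference", "output_dir"))
  writeLines(utils::capture.output(utils::str(config[hashed])), cfg_file)
  manifest <- c(sprintf("seed\t%d", config$seed),
                sprintf("config_md5\t%s", unname(tools::md5sum(cfg_file))),
                sprintf("n_cohorts\t%d", length(out$cohorts)),
                sprintf("n_probes_retained\t%d", length(out$filter$retained)))
  writeLines(manifest, file.path(od, "MANIFEST.tsv"))
  invisible(od)
}
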