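# Synthetic consortium generator: multi-cohort methylation data with known
# ground truth (cell mixtures, latent batch factors, correlated parental
# BMIs, injectable per-CpG effects).

#' Characteristics of the 13 default birth-cohort data sets
#'
#' Sample sizes and parental BMI distributions emulating a 13-data-set birth
#' consortium (total n = 4894, ~48% female, paternal BMI higher mean / lower
#' SD than maternal). Used as the default cohort table by
#' [simulation_config()].
#'
#' @return data.frame with columns cohort_id, n, paternal_mean, paternal_sd,
#'   maternal_mean, maternal_sd.
#' @export
birth_cohort_table <- function() {
  data.frame(
    cohort_id = c("cohortA", "cohortB", "cohortC", "cohortD", "cohortE",
                  "cohortF", "cohortG", "cohortH", "cohortI", "cohortJ",
                  "cohortK", "cohortL", "cohortM"),
    n = c(531L, 70L, 115L, 158L, 947L, 390L, 352L, 982L, 621L, 212L, 98L, 324L, 94L),
    paternal_mean = c(25.0, 26.6, 27.5, 28.0, 25.2, 25.1, 25.8, 25.6, 25.7, 26.0, 24.9, 26.3, 27.2),
    paternal_sd   = c(3.0, 5.3, 4.7, 4.2, 3.2, 3.1, 3.5, 3.1, 3.1, 3.1, 3.0, 3.6, 4.0),
    maternal_mean = c(22.6, 26.2, 26.7, 26.5, 23.2, 23.4, 23.8, 24.0, 24.3, 24.0, 22.6, 24.3, 25.1),
    maternal_sd   = c(3.3, 5.8, 6.1, 4.5, 3.9, 3.7, 4.5, 4.1, 4.6, 3.9, 3.9, 4.9, 5.5),
    stringsAsFactors = FALSE
  )
}

#' Specify a ground-truth CpG effect to inject
#'
#' @param probe_id probe identifier (must exist in the generated probe set,
#'   ids are `cg` followed by a zero-padded index, e.g. `"cg000001"`).
#' @param parent which parental exposure carries the effect: `"paternal"`,
#'   `"maternal"` or `"both"`.
#' @param effect_size difference in offspring percentage methylation per
#'   1-SD increase in the parental BMI (percentage points; injected
#'   additively on the beta scale so the linear-scale slope equals this
#'   value exactly).
#' @param sex_restriction `"none"`, `"female"` or `"male"`; a restricted
#'   effect is present only in offspring of that sex.
#' @param cohorts optional integer vector of cohort indices carrying the
#'   effect; `NULL` (default) injects it in every cohort.
#' @return one-row data.frame; rbind several to build an effect table.
#' @export
effect_spec <- function(probe_id, parent = c("paternal", "maternal", "both"),
                        effect_size, sex_restriction = c("none", "female", "male"),
                        cohorts = NULL) {
  parent <- match.arg(parent)
  sex_restriction <- match.arg(sex_restriction)
  if (!is.finite(effect_size)) em_stop("effect_size must be finite", "ewasmeta_invalid_config")
  data.frame(probe_id = as.character(probe_id), parent = parent,
             effect_size = effect_size, sex_restriction = sex_restriction,
             cohorts = if (is.null(cohorts)) NA_character_ else paste(cohorts, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Configuration for a simulated consortium
#'
#' Defaults emulate the study conditions of a coordinated birth-cohort
#' consortium: 13 cohorts of 70--982 samples (total 4894), within-cohort
#' paternal--maternal BMI Spearman correlation about 0.2, Dirichlet cell
#' mixtures, 20 latent technical (batch) factors and beta-distributed
#' methylation.
#'
#' @param n_cohorts number of cohorts.
#' @param cohort_sizes integer vector of per-cohort sample sizes
#'   (length `n_cohorts`, all >= 2).
#' @param n_probes number of CpG probes.
#' @param n_cell_types number of cell types in the mixture (>= 2).
#' @param n_batch_factors number of latent technical factors (default 20,
#'   matching the number of surrogate variables estimated downstream).
#' @param parent_bmi_correlation latent Gaussian correlation between paternal
#'   and maternal BMI, in (-1, 1); default 0.2.
#' @param bmi_means_sds data.frame with columns paternal_mean, paternal_sd,
#'   maternal_mean, maternal_sd (one row per cohort); defaults taken from
#'   [birth_cohort_table()] (recycled if needed).
#' @param noise_sd residual SD on the methylation beta scale (default 0.02,
#'   i.e. 2 percentage points, typical for array data).
#' @param batch_sd SD of batch-factor loadings on the latent logistic scale.
#' @param effect_specs data.frame of injected effects (rbind of
#'   [effect_spec()] rows), or NULL for a null consortium.
#' @param missing_rate completely-at-random missingness proportion in [0, 1).
#' @param cohort_ids optional character vector of cohort labels.
#' @param seed master integer seed; each cohort uses [child_seed()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 13L,
                              cohort_sizes = birth_cohort_table()$n,
                              n_probes = 1000L,
                              n_cell_types = 6L,
                              n_batch_factors = 20L,
                              parent_bmi_correlation = 0.2,
                              bmi_means_sds = NULL,
                              noise_sd = 0.02,
                              batch_sd = 0.15,
                              effect_specs = NULL,
                              missing_rate = 0,
                              cohort_ids = NULL,
                              seed = 1L) {
  if (length(cohort_sizes) != n_cohorts)
    em_stop("cohort_sizes length must equal n_cohorts", "ewasmeta_invalid_config")
  if (any(cohort_sizes < 2))
    em_stop("all cohort sizes must be >= 2", "ewasmeta_invalid_config")
  if (!(parent_bmi_correlation > -1 && parent_bmi_correlation < 1))
    em_stop("parent_bmi_correlation must lie in (-1, 1)", "ewasmeta_invalid_config")
  if (missing_rate < 0 || missing_rate >= 1)
    em_stop("missing_rate must lie in [0, 1)", "ewasmeta_invalid_config")
  if (n_cell_types < 2)
    em_stop("n_cell_types must be >= 2", "ewasmeta_invalid_config")
  if (!is.null(effect_specs)) {
    stopifnot(all(c("probe_id", "parent", "effect_size", "sex_restriction") %in% names(effect_specs)))
    if (!"cohorts" %in% names(effect_specs)) effect_specs$cohorts <- NA_character_
    if (n_probes < length(unique(effect_specs$probe_id)))
      em_stop("n_probes must cover all probes named in effect_specs", "ewasmeta_invalid_config")
  }
  if (is.null(bmi_means_sds)) {
    tab <- birth_cohort_table()[, c("paternal_mean", "paternal_sd", "maternal_mean", "maternal_sd")]
    idx <- rep_len(seq_len(nrow(tab)), n_cohorts)
    bmi_means_sds <- tab[idx, , drop = FALSE]
    rownames(bmi_means_sds) <- NULL
  }
  if (is.null(cohort_ids)) cohort_ids <- sprintf("cohort%02d", seq_len(n_cohorts))
  structure(list(
    n_cohorts = as.integer(n_cohorts), cohort_sizes = as.integer(cohort_sizes),
    n_probes = as.integer(n_probes), n_cell_types = as.integer(n_cell_types),
    n_batch_factors = as.integer(n_batch_factors),
    parent_bmi_correlation = parent_bmi_correlation,
    bmi_means_sds = bmi_means_sds, noise_sd = noise_sd, batch_sd = batch_sd,
    effect_specs = effect_specs, missing_rate = missing_rate,
    cohort_ids = cohort_ids, seed = as.integer(seed)
  ), class = "simulation_config")
}

probe_ids_for <- function(n_probes) sprintf("cg%06d", seq_len(n_probes))

#' Generate a synthetic cell-type methylation reference
#'
#' Builds mean beta profiles per cell type with between-cell-type divergence
#' concentrated in an informative probe subset, so that reference-based
#' deconvolution is identifiable. When emulating cord blood the last column
#' is labelled `nRBC` (nucleated red blood cells).
#'
#' @param n_probes number of probes (>= n_cell_types).
#' @param n_cell_types number of cell types (>= 2).
#' @param seed integer seed; output is deterministic given the seed.
#' @param n_informative number of probes with cell-type-specific means;
#'   defaults to all probes when few, else 20% of probes (at least
#'   `n_cell_types`).
#' @return object of class `cell_reference`: list with `profiles`
#'   (probes x cell types, values in [0.02, 0.98]) and `cell_labels`.
#' @export
generate_cell_reference <- function(n_probes, n_cell_types, seed,
                                    n_informative = NULL) {
  if (n_cell_types < 2) em_stop("need at least 2 cell types", "ewasmeta_invalid_config")
  if (n_probes < n_cell_types)
    em_stop("need at least as many probes as cell types", "ewasmeta_invalid_config")
  if (is.null(n_informative))
    n_informative <- min(n_probes, max(n_cell_types, ceiling(0.2 * n_probes)))
  labels <- c("CD4T", "CD8T", "Bcell", "NK", "Gran", "Mono", "nRBC")
  if (n_cell_types <= length(labels)) {
    labels <- labels[seq_len(n_cell_types)]
  } else {
    labels <- c(labels, sprintf("cell%02d", seq_len(n_cell_types - length(labels))))
  }
  withr::with_seed(as.integer(seed %% 2147483647), {
    # bimodal baseline typical of array betas
    comp <- sample(1:3, n_probes, replace = TRUE, prob = c(0.4, 0.4, 0.2))
    base <- numeric(n_probes)
    base[comp == 1] <- stats::rbeta(sum(comp == 1), 1, 8)
    base[comp == 2] <- stats::rbeta(sum(comp == 2), 8, 1)
    base[comp == 3] <- stats::rbeta(sum(comp == 3), 4, 4)
    profiles <- matrix(rep(base, n_cell_types), nrow = n_probes)
    info <- sample.int(n_probes, n_informative)
    profiles[info, ] <- matrix(stats::runif(n_informative * n_cell_types, 0.05, 0.95),
                               nrow = n_informative)
    profiles <- pmin(pmax(profiles, 0.02), 0.98)
    dimnames(profiles) <- list(probe_ids_for(n_probes), labels)
    structure(list(profiles = profiles, cell_labels = labels),
              class = "cell_reference")
  })
}


#' Generate one cohort of a synthetic consortium
#'
#' Parental BMIs are drawn from a bivariate Gaussian with the configured
#' correlation and truncated to plausible bounds (15--60 kg/m^2); per-sample
#' cell proportions come from a Dirichlet; the methylation background is
#' constructed on an unbounded logistic scale as cell-mixture baseline +
#' batch-factor loadings + Gaussian noise, then mapped to [0, 1]. Injected
#' effects are then added on the beta (linear) scale — effect size x
#' standardized BMI, restricted by sex when requested — so the linear-scale
#' slope equals the specified percentage points per SD exactly, on the
#' scale the EWAS estimates (values are clipped to [0, 1] with a warning;
#' effects are only meaningful away from the beta boundaries).
#' Missingness is applied completely at random.
#'
#' @param config a [simulation_config()].
#' @param cohort_index 1-based cohort index.
#' @param reference a [generate_cell_reference()] object with `n_probes` rows.
#' @return object of class `cohort_dataset`: list with `cohort_id`, `betas`
#'   (probes x samples), `phenotypes` (one row per sample),
#'   `true_cell_proportions` (samples x cell types) and `truth` (injected
#'   effects applicable to this cohort).
#' @export
generate_cohort <- function(config, cohort_index, reference) {
  stopifnot(inherits(config, "simulation_config"), inherits(reference, "cell_reference"))
  if (cohort_index < 1 || cohort_index > config$n_cohorts)
    em_stop("cohort_index out of range", "ewasmeta_invalid_config")
  n <- config$cohort_sizes[cohort_index]
  if (n < 2) em_stop("cohort size must be >= 2", "ewasmeta_invalid_config")
  p <- config$n_probes
  if (nrow(reference$profiles) != p)
    em_stop("reference probe count does not match config n_probes", "ewasmeta_invalid_config")
  pid <- rownames(reference$profiles)
  specs <- config$effect_specs
  if (!is.null(specs)) {
    unknown <- setdiff(specs$probe_id, pid)
    if (length(unknown))
      em_stop(paste0("effect probes absent from generated probe set: ",
                     paste(unknown, collapse = ", ")), "ewasmeta_unknown_probe")
  }
  cohort_id <- config$cohort_ids[cohort_index]
  bm <- config$bmi_means_sds[cohort_index, ]

  withr::with_seed(as.integer(child_seed(config$seed, cohort_index)), {
    # correlated parental BMIs, truncated to plausible bounds
    r <- config$parent_bmi_correlation
    z1 <- stats::rnorm(n); z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
    paternal_bmi <- pmin(pmax(bm$paternal_mean + bm$paternal_sd * z1, 15), 60)
    maternal_bmi <- pmin(pmax(bm$maternal_mean + bm$maternal_sd * z2, 15), 60)

    phen <- data.frame(
      sample_id = sprintf("%s_s%04d", cohort_id, seq_len(n)),
      paternal_bmi = paternal_bmi, maternal_bmi = maternal_bmi,
      paternal_age = round(stats::rnorm(n, 31, 5), 1),
      maternal_age = round(stats::rnorm(n, 29, 4.5), 1),
      maternal_smoking = stats::rbinom(n, 1, 0.15),
      paternal_smoking = stats::rbinom(n, 1, 0.30),
      parity = stats::rbinom(n, 1, 0.45),
      paternal_sep = stats::rbinom(n, 1, 0.50),
      child_sex = sample(c("female", "male"), n, replace = TRUE, prob = c(0.48, 0.52)),
      stringsAsFactors = FALSE
    )

    # Dirichlet cell proportions around typical cord-blood composition
    k <- config$n_cell_types
    alpha0 <- c(4, 2, 1.5, 1, 8, 1.5, 1)[seq_len(min(k, 7))]
    if (k > 7) alpha0 <- c(alpha0, rep(1, k - 7))
    g <- matrix(stats::rgamma(n * k, shape = rep(alpha0 * 6, each = n)), nrow = n)
    props <- g / rowSums(g)
    dimnames(props) <- list(phen$sample_id, reference$cell_labels)

    mu <- reference$profiles %*% t(props)          # probes x samples, in (0,1)
    mu <- pmin(pmax(mu, 1e-4), 1 - 1e-4)
    lat <- stats::qlogis(mu)

    if (config$n_batch_factors > 0) {
      b <- config$n_batch_factors
      load <- matrix(stats::rnorm(p * b, 0, config$batch_sd), nrow = p) *
        matrix(stats::rbinom(p * b, 1, 0.3), nrow = p)   # each factor hits ~30% of probes
      scores <- matrix(stats::rnorm(n * b), nrow = n)
      lat <- lat + load %*% t(scores)
    } else {
      scores <- matrix(numeric(0), nrow = n, ncol = 0)
    }

    pat_z <- (paternal_bmi - mean(paternal_bmi)) / stats::sd(paternal_bmi)
    mat_z <- (maternal_bmi - mean(maternal_bmi)) / stats::sd(maternal_bmi)

    if (config$noise_sd > 0) {
      # delta-method scaling so the realized beta-scale residual SD ~ noise_sd
      deriv <- pmax(mu * (1 - mu), 0.05)
      lat <- lat + matrix(stats::rnorm(p * n), nrow = p) * (config$noise_sd / deriv)
    }

    betas <- stats::plogis(lat)
    if (config$noise_sd == 0 && config$n_batch_factors == 0) {
      betas <- mu   # exact cell-mixture expectation in the noise-free limit
    }

    # injected effects are additive on the beta (linear) scale, so the
    # linear-scale slope equals the specified percentage points per SD
    # exactly on the scale the EWAS estimates; clipped to [0, 1]
    truth <- NULL
    n_clipped <- 0L
    if (!is.null(specs)) {
      in_cohort <- is.na(specs$cohorts) |
        vapply(strsplit(specs$cohorts, ","),
               function(s) as.character(cohort_index) %in% s, logical(1))
      truth <- specs[in_cohort, , drop = FALSE]
      for (i in seq_len(nrow(truth))) {
        sp <- truth[i, ]
        j <- match(sp$probe_id, pid)
        sel <- switch(sp$sex_restriction,
                      none = rep(TRUE, n),
                      female = phen$child_sex == "female",
                      male = phen$child_sex == "male")
        for (par in if (sp$parent == "both") c("paternal", "maternal") else sp$parent) {
          zx <- if (par == "paternal") pat_z else mat_z
          shifted <- betas[j, sel] + (sp$effect_size / 100) * zx[sel]
          n_clipped <- n_clipped + sum(shifted < 0 | shifted > 1)
          betas[j, sel] <- pmin(pmax(shifted, 0), 1)
        }
      }
      if (n_clipped > 0)
        em_warn(sprintf(
          "%d injected-effect value(s) clipped to [0,1]; effects at near-boundary probes are attenuated",
          n_clipped), "ewasmeta_effect_clipped")
    }
    if (config$missing_rate > 0) {
      betas[stats::runif(p * n) < config$missing_rate] <- NA_real_
    }
    dimnames(betas) <- list(pid, phen$sample_id)

    structure(list(cohort_id = cohort_id, betas = betas, phenotypes = phen,
                   true_cell_proportions = props, true_batch_scores = scores,
                   truth = truth),
              class = "cohort_dataset")
  })
}

#' Generate every cohort of a configured consortium
#'
#' @param config a [simulation_config()].
#' @param reference optional [generate_cell_reference()]; generated from a
#'   seed derived from the config seed when NULL.
#' @return named list of `cohort_dataset` objects plus the reference as
#'   attribute `reference`.
#' @export
generate_consortium <- function(config, reference = NULL) {
  if (is.null(reference))
    reference <- generate_cell_reference(config$n_probes, config$n_cell_types,
                                         seed = child_seed(config$seed, 0))
  cohorts <- lapply(seq_len(config$n_cohorts), function(i)
    generate_cohort(config, i, reference))
  names(cohorts) <- config$cohort_ids
  attr(cohorts, "reference") <- reference
  cohorts
}

#' Write a cohort dataset to disk as plain-text files
#'
#' Emits `betas.tsv` (first column `probe_id`, remaining columns sample ids,
#' missing values as `NA`), `phenotypes.csv`, and ground-truth sidecars
#' `truth_effects.tsv` / `truth_cell_proportions.tsv`. A read-back with
#' [read_cohort()] reproduces values to full stored precision; repeated
#' writes are byte-identical.
#'
#' @param dataset a `cohort_dataset`.
#' @param directory output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(dataset, directory) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok) em_stop(paste("cannot create directory", directory), "ewasmeta_io_error")
  bt <- data.table::data.table(probe_id = rownames(dataset$betas))
  bt <- cbind(bt, data.table::as.data.table(dataset$betas))
  f1 <- file.path(directory, "betas.tsv")
  data.table::fwrite(bt, f1, sep = "\t", na = "NA", quote = FALSE)
  f2 <- file.path(directory, "phenotypes.csv")
  data.table::fwrite(dataset$phenotypes, f2, na = "NA", quote = FALSE)
  f3 <- file.path(directory, "truth_effects.tsv")
  te <- dataset$truth
  if (is.null(te)) te <- effect_spec("cg000001", "paternal", 0)[0, ]
  data.table::fwrite(te, f3, sep = "\t", na = "NA", quote = FALSE)
  f4 <- file.path(directory, "truth_cell_proportions.tsv")
  cp <- data.table::data.table(sample_id = rownames(dataset$true_cell_proportions))
  cp <- cbind(cp, data.table::as.data.table(dataset$true_cell_proportions))
  data.table::fwrite(cp, f4, sep = "\t", na = "NA", quote = FALSE)
  f5 <- file.path(directory, "cohort_id.txt")
  writeLines(dataset$cohort_id, f5)
  invisible(c(f1, f2, f3, f4, f5))
}

#' Read a cohort dataset written by [write_cohort()]
#'
#' @param directory directory containing the cohort files.
#' @return a `cohort_dataset`.
#' @export
read_cohort <- function(directory) {
  f1 <- file.path(directory, "betas.tsv")
  if (!file.exists(f1)) em_stop(paste("no betas.tsv under", directory), "ewasmeta_io_error")
  bt <- data.table::fread(f1, sep = "\t", na.strings = "NA")
  betas <- as.matrix(bt[, -1])
  rownames(betas) <- bt[[1]]
  phen <- as.data.frame(data.table::fread(file.path(directory, "phenotypes.csv"),
                                          na.strings = "NA"))
  te <- as.data.frame(data.table::fread(file.path(directory, "truth_effects.tsv"),
                                        sep = "\t", na.strings = "NA",
                                        colClasses = list(character = "cohorts")))
  if (nrow(te) == 0) te <- NULL
  cp <- data.table::fread(file.path(directory, "truth_cell_proportions.tsv"), sep = "\t")
  props <- as.matrix(cp[, -1]); rownames(props) <- cp[[1]]
  structure(list(cohort_id = readLines(file.path(directory, "cohort_id.txt"))[1],
                 betas = betas, phenotypes = phen,
                 true_cell_proportions = props, truth = te),
            class = "cohort_dataset")
}
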