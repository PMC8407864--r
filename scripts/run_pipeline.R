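#!/usr/bin/env Rscript

# Thin command-line wrapper over ewasmeta::run_full_pipeline() for simulated
# consortia: generates a consortium of the requested size, runs every
# analysis stage and writes all artefacts (meta TSVs, QC tables, summary,
# manifest) to --out.
#
# Usage: Rscript scripts/run_pipeline.R --out <dir> [--seed 1]
#          [--cohorts 13] [--probes 2000] [--svs 20] [--no-strata]

suppressPackageStartupMessages({
  library(optparse)
  library(ewasmeta)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--cohorts", type = "integer", default = 13L),
  make_option("--probes", type = "integer", default = 2000L),
  make_option("--svs", type = "integer", default = 20L),
  make_option("--no-strata", action = "store_true", default = FALSE,
              dest = "no_strata")
)))
if (is.null(opts$out)) stop("--out is required")

sizes <- rep_len(birth_cohort_table()$n, opts$cohorts)
sim <- simulation_config(n_cohorts = opts$cohorts, cohort_sizes = sizes,
                         n_probes = opts$probes, seed = opts$seed)
cfg <- run_config(sim_config = sim,
                  n_surrogate_variables = opts$svs,
                  sex_strata = if (opts$no_strata) character(0)
                               else c("female", "male"),
                  output_dir = opts$out, seed = opts$seed)
out <- run_full_pipeline(cfg)
print(out$summary)
cat("artefacts written to", opts$out, "\n")
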