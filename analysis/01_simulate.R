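#!/usr/bin/env Rscript
# Stage 1: generate the synthetic faking-ability study.
#
# Draws the full study under the default population: 299 recruited
# respondents (89 failing an attention check), 25-expert panels for three
# jobs (pilot, tour guide, TV/radio announcer), an honest linkage sample of
# 151, faked responses for all six tasks on the 50-point slider, and
# bifactor-structured cognitive parcels. Every table is written as CSV
# under results/data/.

suppressPackageStartupMessages(library(fakability))

STUDY_SEED <- 20260924
spec <- population_spec(seed = STUDY_SEED)
study <- simulate_study(spec)
files <- write_study_csvs(study, "results/data")

cat("Simulated study (seed", spec$seed, ")\n")
cat("  recruited:", spec$n_respondents + spec$n_attention_fail,
    "respondents;", spec$n_attention_fail, "fail an attention check\n")
cat("  honest linkage sample:", spec$n_honest, "\n")
cat("  expert panels:", paste(spec$jobs, collapse = ", "),
    sprintf("(%d experts each)\n", spec$n_experts_per_job))
cat("  faking tasks:", paste(names(study$faked), collapse = ", "), "\n")
cat("  wrote", length(files), "CSV files under results/data/\n")
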