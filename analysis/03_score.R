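#!/usr/bin/env Rscript
# Stage 3: filter the sample and score the six faking tasks.
#
# Drops respondents failing any attention check, rescales the 50-point
# slider responses to the anchor scale (divide by 10), and computes the
# two profile-similarity metrics per task: elevation (absolute mean
# distance to the optimal profile, square-root transformed; lower =
# better) and shape (Pearson correlation with the optimal profile;
# higher = better). Target-instrument tasks are scored per 8-item
# subscale, then averaged over available subscales.

suppressPackageStartupMessages(library(fakability))

STUDY_SEED <- 20260924
spec <- population_spec(seed = STUDY_SEED)
study <- simulate_study(spec)

flt <- filter_attention_checks(study$truth, checks = study$attention)
cat(sprintf("Attention filter: %d of %d retained (%.1f%% excluded)\n",
            flt$report$n_retained, flt$report$n_total,
            100 * flt$report$exclusion_rate))

tasks <- study_tasks(study)
responses <- lapply(study$faked, function(df)
  rescale_responses(df[df$respondent_id %in% flt$data$respondent_id, ]))
scores <- score_battery(responses, tasks)
summary_tab <- summarize_scores(scores)

dir.create("results/scores", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(scores, "results/scores/scores_long.csv",
                 row.names = FALSE, na = "")
utils::write.csv(summary_tab, "results/scores/score_summary.csv",
                 row.names = FALSE, na = "")

cat("\nDescriptive statistics per task and metric:\n")
print(transform(summary_tab,
                m = round(m, 2), sd = round(sd, 2), min = round(min, 2),
                max = round(max, 2), skew = round(skew, 2),
                kurtosis = round(kurtosis, 2)), row.names = FALSE)
n_missing <- sum(is.na(scores$shape))
cat(sprintf("\nShape missing (zero-variance rule): %d of %d values (%.1f%%)\n",
            n_missing, nrow(scores), 100 * n_missing / nrow(scores)))
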