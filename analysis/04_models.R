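#!/usr/bin/env Rscript
# Stage 4: measurement models.
#
# Fits the final single-factor models of elevation (5 indicators; the
# anchor-instrument pilot task is excluded) and shape (6 indicators), each
# with a free error covariance between the two remaining anchor-instrument
# tasks; reports fit (chi-square, CFI, RMSEA) and factor saturation
# (McDonald's omega). Then tests the elevation-shape factor correlation by
# likelihood ratio against an orthogonal two-factor model, and fits the
# cognitive bifactor model (g on all 11 parcels, nested orthogonal gc and
# ep).

suppressPackageStartupMessages(library(fakability))

scores <- utils::read.csv("results/scores/scores_long.csv",
                          check.names = FALSE)
class(scores) <- c("psm_scores", "data.frame")
cog <- utils::read.csv("results/data/cognitive_parcels.csv",
                       check.names = FALSE)
cog <- cog[cog$respondent_id %in% unique(scores$respondent_id), ]

e_wide <- scores_wide(scores, "elevation")
s_wide <- scores_wide(scores, "shape")
zoo <- builtin_model_zoo()

report <- function(label, fit) {
  cat(sprintf("%-22s chisq(%d) = %6.2f, p = %.3f, CFI = %.3f, RMSEA = %.3f\n",
              label, fit$df, fit$chisq, fit$p, fit$cfi, fit$rmsea))
}

fit_e <- fit_model(zoo$elevation_final, e_wide)
fit_s <- fit_model(zoo$shape_final, s_wide)
report("elevation (final)", fit_e)
report("shape (final)", fit_s)
cat(sprintf("  omega: elevation = %.2f, shape = %.2f\n",
            mcdonald_omega(fit_e, "elevation"),
            mcdonald_omega(fit_s, "shape")))

es <- merge(e_wide, s_wide, by = "respondent_id")
fit_two <- fit_model(zoo$two_factor, es)
fit_orth <- fit_model(fm_spec(factors = zoo$two_factor$factors,
                              error_cov = zoo$two_factor$error_cov), es)
r_es <- fit_two$latent_cov["elevation", "shape"] /
  sqrt(prod(diag(fit_two$latent_cov)[c("elevation", "shape")]))
lrt <- boundary_lrt(fit_two, fit_orth, df = 1)
cat(sprintf("elevation-shape factor correlation r = %.3f, LRT chisq = %.3f, p = %.3f\n",
            r_es, lrt$statistic, lrt$p))

fit_bf <- fit_model(zoo$cognitive_bifactor, cog)
report("cognitive bifactor", fit_bf)
cat(sprintf("  omega: g = %.2f, gc = %.2f, ep = %.2f\n",
            mcdonald_omega(fit_bf, "g"), mcdonald_omega(fit_bf, "gc"),
            mcdonald_omega(fit_bf, "ep")))

dir.create("results/models", recursive = TRUE, showWarnings = FALSE)
loadings <- rbind(
  cbind(model = "elevation_final", fit_e$standardized),
  cbind(model = "shape_final", fit_s$standardized),
  cbind(model = "cognitive_bifactor", fit_bf$standardized))
utils::write.csv(loadings, "results/models/standardized_loadings.csv",
                 row.names = FALSE)
fit_stats <- function(f) list(chisq = f$chisq, df = f$df, p = f$p,
                              cfi = f$cfi, rmsea = f$rmsea)
jsonlite::write_json(list(
  elevation_final = c(fit_stats(fit_e),
                      omega = mcdonald_omega(fit_e, "elevation")),
  shape_final = c(fit_stats(fit_s), omega = mcdonald_omega(fit_s, "shape")),
  cognitive_bifactor = c(fit_stats(fit_bf),
                         omega_g = mcdonald_omega(fit_bf, "g"),
                         omega_gc = mcdonald_omega(fit_bf, "gc"),
                         omega_ep = mcdonald_omega(fit_bf, "ep")),
  factor_correlation = list(r = r_es, lrt_chisq = lrt$statistic,
                            p = lrt$p)),
  "results/models/fit_indices.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/models/\n")
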