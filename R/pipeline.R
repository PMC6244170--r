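# End-to-end orchestration: sample filtering, linkage, scoring, latent
# models, structural regressions and correlation-difference tests, with all
# tables written as CSV plus a JSON results manifest.

#' Filter respondents who fail attention checks
#'
#' Drops every respondent failing at least one check (a respondent failing
#' several checks is excluded exactly once) and reports counts and the
#' exclusion rate.
#'
#' @param data Response data frame with a \code{respondent_id} column.
#' @param checks Data frame with \code{respondent_id} and logical
#'   \code{check_*} columns (TRUE = passed). If NULL, \code{check_*}
#'   columns are looked up in \code{data} itself.
#' @param strict Error when no check columns are present (default TRUE);
#'   otherwise pass the data through with a warning.
#' @return List: \code{data} (filtered, check columns removed),
#'   \code{report} (n_total, n_excluded, n_retained, exclusion_rate,
#'   excluded_ids).
#' @export
filter_attention_checks <- function(data, checks = NULL, strict = TRUE) {
  if (is.null(checks)) {
    cc <- grep("^check_", names(data), value = TRUE)
    if (!length(cc)) {
      msg <- "no attention-check columns found"
      if (strict) stop_fmt("%s", msg)
      warning(msg, call. = FALSE)
      return(list(data = data,
                  report = list(n_total = nrow(data), n_excluded = 0L,
                                n_retained = nrow(data),
                                exclusion_rate = 0,
                                excluded_ids = character(0))))
    }
    checks <- data[, c("respondent_id", cc)]
    data <- data[, setdiff(names(data), cc)]
  }
  cc <- grep("^check_", names(checks), value = TRUE)
  if (!length(cc)) stop_fmt("checks table has no check_* columns")
  failed <- rowSums(!as.matrix(checks[, cc, drop = FALSE])) > 0
  excluded_ids <- checks$respondent_id[failed]
  keep <- !(data$respondent_id %in% excluded_ids)
  list(
    data = data[keep, , drop = FALSE],
    report = list(
      n_total = nrow(data), n_excluded = sum(!keep),
      n_retained = sum(keep),
      exclusion_rate = sum(!keep) / nrow(data),
      excluded_ids = excluded_ids)
  )
}

#' Study configuration
#'
#' @param spec A \code{\link{population_spec}} describing the synthetic
#'   population (ignored when \code{study} is passed to
#'   \code{\link{run_study}}).
#' @param scoring_mode "subscale" (score target-type tasks per 8-item
#'   subscale, then average) or "pooled".
#' @param use_linkage Estimate target-instrument optimal profiles through
#'   the linkage stage (default TRUE); otherwise use the generator's true
#'   profiles.
#' @param bootstrap_draws Bootstrap draws for structural-weight confidence
#'   intervals (0 disables the bootstrap).
#' @param alpha Significance threshold.
#' @param power Power used by the sensitivity calculation.
#' @return A \code{study_config} list.
#' @export
study_config <- function(spec = population_spec(),
                         scoring_mode = c("subscale", "pooled"),
                         use_linkage = TRUE, bootstrap_draws = 0,
                         alpha = 0.05, power = 0.80) {
  scoring_mode <- match.arg(scoring_mode)
  structure(list(spec = spec, scoring_mode = scoring_mode,
                 use_linkage = use_linkage,
                 bootstrap_draws = bootstrap_draws, alpha = alpha,
                 power = power),
            class = "study_config")
}

#' Run the full faking-ability analysis
#'
#' Sequences every stage on a (simulated) study: attention-check filtering,
#' optional questionnaire linkage and optimal-profile projection, slider
#' rescaling, profile-similarity scoring, descriptive summaries, the
#' elevation / shape measurement models with reliabilities, the two-factor
#' correlation test, the cognitive bifactor model, the two structural
#' models regressing each ability on g, gc and ep, and Fisher-z
#' correlation-difference tests between the standardized structural
#' weights. Optionally writes every table as CSV plus a JSON manifest.
#'
#' @param config A \code{\link{study_config}}.
#' @param study Optionally a pre-generated \code{\link{simulate_study}}
#'   result (defaults to simulating from \code{config$spec}).
#' @param out_dir Output directory; NULL (default) skips file output.
#' @return A results bundle (list) with elements \code{report},
#'   \code{linkage}, \code{scores}, \code{score_summary}, \code{fits},
#'   \code{omegas}, \code{factor_correlation}, \code{gammas},
#'   \code{r_squared}, \code{corr_diff_tests}, \code{sensitivity_r},
#'   \code{manifest}.
#' @export
run_study <- function(config = study_config(), study = NULL,
                      out_dir = NULL) {
  t0 <- Sys.time()
  spec <- config$spec
  stages <- list()
  log_stage <- function(name, ...) {
    stages[[name]] <<- list(
      seconds = as.numeric(Sys.time() - t0, units = "secs"), ...)
  }

  if (is.null(study)) study <- simulate_study(spec)
  log_stage("simulate", seed = spec$seed)

  # --- filtering -------------------------------------------------------
  flt <- filter_attention_checks(study$truth, checks = study$attention)
  keep_ids <- flt$data$respondent_id
  report <- flt$report
  log_stage("filter", retained = report$n_retained)

  # --- linkage ---------------------------------------------------------
  neo_profiles <- study$true_neo_profiles
  linkage <- NULL
  if (config$use_linkage) {
    linkage <- build_linkage(study$honest$anchor, study$honest$target)
    # profiles are projected for the administered item sets (the items the
    # faking tasks actually contain), via their estimated linking lines
    neo_profiles <- lapply(stats::setNames(spec$jobs, spec$jobs),
                           function(job) {
      means <- expert_panel_means(study$expert_panels[[job]])
      admin <- study$true_neo_profiles[[job]]
      sel <- data.frame(anchor_item = paste0("wsq_", admin$subscale),
                        target_item = admin$item, stringsAsFactors = FALSE)
      fitted <- fit_item_links(study$honest$anchor, study$honest$target,
                               sel)
      prof <- project_optimal_profile(fitted, means,
                                      bounds = spec$anchor_bounds,
                                      job = job)
      data.frame(item = prof$item,
                 subscale = sub("^wsq_", "", prof$subscale),
                 optimal = prof$optimal, stringsAsFactors = FALSE)
    })
    log_stage("linkage",
              subscales_created = sum(attr(linkage, "created")))
  }

  # --- scoring ---------------------------------------------------------
  tasks <- study_tasks(study, neo_profiles = neo_profiles)
  responses <- lapply(study$faked, function(df) {
    df <- df[df$respondent_id %in% keep_ids, , drop = FALSE]
    rescale_responses(df)
  })
  scores <- score_battery(responses, tasks, mode = config$scoring_mode)
  score_summary <- summarize_scores(scores)
  log_stage("scoring", n_scores = nrow(scores))

  # --- measurement models ---------------------------------------------
  e_wide <- scores_wide(scores, "elevation")
  s_wide <- scores_wide(scores, "shape")
  cog <- study$cognitive[study$cognitive$respondent_id %in% keep_ids, ]
  zoo <- builtin_model_zoo()

  fits <- list()
  fits$elevation <- fit_model(zoo$elevation_final, e_wide)
  fits$shape <- fit_model(zoo$shape_final, s_wide)
  omegas <- c(elevation = mcdonald_omega(fits$elevation, "elevation"),
              shape = mcdonald_omega(fits$shape, "shape"))

  es_wide <- merge(e_wide, s_wide, by = "respondent_id")
  fits$two_factor <- fit_model(zoo$two_factor, es_wide)
  two_orth <- fm_spec(factors = zoo$two_factor$factors,
                      error_cov = zoo$two_factor$error_cov)
  fits$two_factor_orth <- fit_model(two_orth, es_wide)
  factor_correlation <- list(
    r = fits$two_factor$latent_cov["elevation", "shape"] /
      sqrt(fits$two_factor$latent_cov["elevation", "elevation"] *
             fits$two_factor$latent_cov["shape", "shape"]),
    lrt = boundary_lrt(fits$two_factor, fits$two_factor_orth, df = 1))

  fits$bifactor <- fit_model(zoo$cognitive_bifactor, cog)
  omegas <- c(omegas,
              g = mcdonald_omega(fits$bifactor, "g"),
              gc = mcdonald_omega(fits$bifactor, "gc"),
              ep = mcdonald_omega(fits$bifactor, "ep"))
  log_stage("measurement")

  # --- structural models ----------------------------------------------
  sem_data <- merge(merge(e_wide, s_wide, by = "respondent_id"), cog,
                    by = "respondent_id")
  fits$sem1 <- fit_model(zoo$sem1, sem_data)
  fits$sem2 <- fit_model(zoo$sem2, sem_data)
  preds <- c("g", "gc", "ep")
  gammas <- data.frame(
    model = rep(c("sem1", "sem2"), each = 3),
    outcome = rep(c("elevation", "shape"), each = 3),
    predictor = rep(preds, 2),
    gamma_std = c(vapply(preds, function(pr)
      gamma_std(fits$sem1, "elevation", pr), 0),
      vapply(preds, function(pr) gamma_std(fits$sem2, "shape", pr), 0)),
    stringsAsFactors = FALSE)
  # per-predictor significance via LRT
  lrt_p <- mapply(function(model, pr) {
    zoo_spec <- if (model == "sem1") zoo$sem1 else zoo$sem2
    out <- if (model == "sem1") "elevation" else "shape"
    restricted <- fm_spec(
      factors = zoo_spec$factors,
      regressions = stats::setNames(list(setdiff(preds, pr)), out),
      error_cov = zoo_spec$error_cov)
    rfit <- fit_model(restricted, sem_data)
    lrt <- boundary_lrt(if (model == "sem1") fits$sem1 else fits$sem2,
                        rfit, df = 1)
    c(lrt$statistic, lrt$p)
  }, gammas$model, gammas$predictor)
  gammas$lrt_chisq <- lrt_p[1, ]
  gammas$lrt_p <- lrt_p[2, ]
  r_squared <- c(elevation = unname(fits$sem1$r_squared["elevation"]),
                 shape = unname(fits$sem2$r_squared["shape"]))
  log_stage("sem")

  if (config$bootstrap_draws > 0) {
    boot <- bootstrap_ci(zoo$sem2, sem_data,
                         draws = config$bootstrap_draws,
                         seed = sub_seed(spec$seed, "bootstrap"))
    log_stage("bootstrap", draws_used = boot$draws_used)
  } else boot <- NULL

  # --- correlation-difference tests ------------------------------------
  n_eff <- report$n_retained
  g1 <- stats::setNames(gammas$gamma_std[gammas$model == "sem1"], preds)
  g2 <- stats::setNames(gammas$gamma_std[gammas$model == "sem2"], preds)
  cd <- list(
    between_g = fisher_z_diff(g2["g"], g1["g"], n_eff),
    between_gc = fisher_z_diff(g2["gc"], g1["gc"], n_eff),
    between_ep = fisher_z_diff(g2["ep"], g1["ep"], n_eff),
    within_gc_g = fisher_z_diff(g2["gc"], g2["g"], n_eff),
    within_gc_ep = fisher_z_diff(g2["gc"], g2["ep"], n_eff),
    within_ep_g = fisher_z_diff(g2["ep"], g2["g"], n_eff))
  sens <- sensitivity_r(n_eff, config$alpha, config$power)
  log_stage("inference")

  manifest <- list(
    seed = spec$seed, alpha = config$alpha,
    scoring_mode = config$scoring_mode,
    use_linkage = config$use_linkage,
    n_recruited = report$n_total, n_retained = report$n_retained,
    stages = stages,
    package_version = as.character(utils::packageVersion("fakability")))

  bundle <- list(report = report, linkage = linkage, scores = scores,
                 score_summary = score_summary, fits = fits,
                 omegas = omegas, factor_correlation = factor_correlation,
                 gammas = gammas, r_squared = r_squared, bootstrap = boot,
                 corr_diff_tests = cd, sensitivity_r = sens,
                 manifest = manifest, study = study)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores_long.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(score_summary,
                     file.path(out_dir, "score_summary.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(gammas, file.path(out_dir, "gammas.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(linkage))
      utils::write.csv(as.data.frame(linkage),
                       file.path(out_dir, "linkage_map.csv"),
                       row.names = FALSE, na = "")
    cd_df <- do.call(rbind, lapply(names(cd), function(nm) {
      x <- cd[[nm]]
      data.frame(test = nm, r1 = x$r1, r2 = x$r2, r_diff = x$r_diff,
                 z = x$z, p_one_tailed = x$p_one_tailed,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(cd_df, file.path(out_dir, "corr_diff_tests.csv"),
                     row.names = FALSE, na = "")
    manifest_out <- c(manifest, list(
      omegas = as.list(omegas), r_squared = as.list(r_squared),
      factor_correlation_r = factor_correlation$r,
      sensitivity_r = sens))
    jsonlite::write_json(manifest_out,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}
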