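# Synthetic-data generator: emulates every input the faking-ability pipeline
# needs — O*NET-style expert panels, an honest linkage sample for two
# questionnaires, faked responses whose proximity/pattern match to optimal
# profiles is driven by two latent abilities (elevation, shape), and
# bifactor-structured cognitive parcel scores.

WORK_STYLES <- c(
  "achievement_effort", "persistence", "initiative", "leadership",
  "cooperation", "concern_for_others", "social_orientation", "self_control",
  "stress_tolerance", "adaptability_flexibility", "dependability",
  "attention_to_detail", "integrity", "independence", "innovation",
  "analytical_thinking"
)

JOBS <- c("pilot", "tour_guide", "tv_radio_announcer")

# Work styles whose honest target-item pool carries real linear links; the
# other four styles get only weakly correlated candidates so no subscale can
# be formed for them.
LINKABLE_STYLES <- setdiff(WORK_STYLES, c(
  "adaptability_flexibility", "attention_to_detail", "independence",
  "analytical_thinking"
))

# Work-style subscales administered in each target-instrument faking task
# (four disjoint 8-item subscales per job, varying in job relevance).
NEO_TASK_SUBSCALES <- list(
  pilot = c("self_control", "persistence", "concern_for_others", "innovation"),
  tour_guide = c("self_control", "cooperation", "leadership",
                 "achievement_effort"),
  tv_radio_announcer = c("integrity", "stress_tolerance", "innovation",
                         "leadership")
)

# True job-specific optimal anchor profiles on the 1-5 expert scale. The
# entries for the work styles used in the target-instrument tasks carry the
# published mean expert ratings for these three jobs; the remaining entries
# are fixed plausible values giving each job a distinct pattern.
default_true_profiles <- function() {
  m <- matrix(
    c(
      # pilot, tour_guide, tv_radio_announcer
      4.2, 3.4, 3.9,  # achievement_effort
      4.1, 3.3, 3.8,  # persistence
      3.9, 3.6, 4.1,  # initiative
      3.6, 3.7, 3.7,  # leadership
      4.0, 4.5, 3.9,  # cooperation
      4.1, 4.3, 3.5,  # concern_for_others
      3.2, 4.4, 4.0,  # social_orientation
      4.7, 4.5, 4.1,  # self_control
      4.6, 4.0, 4.3,  # stress_tolerance
      4.3, 4.2, 4.2,  # adaptability_flexibility
      4.8, 4.0, 4.1,  # dependability
      4.6, 3.5, 3.9,  # attention_to_detail
      4.5, 4.1, 4.4,  # integrity
      3.8, 3.0, 3.6,  # independence
      3.5, 3.2, 4.0,  # innovation
      4.4, 2.8, 3.3   # analytical_thinking
    ),
    ncol = 3, byrow = TRUE,
    dimnames = list(WORK_STYLES, JOBS)
  )
  m
}

#' Declarative population specification for a synthetic faking study
#'
#' Collects every parameter of the generative model in one object: sample
#' sizes, expert-panel size, job-specific true optimal profiles, loadings of
#' the two faking-ability latents (elevation, shape) on each of the six
#' tasks, the standardized structural effects of the cognitive factors
#' (g, gc, ep) on each ability, and residual noise scales.
#'
#' Defaults reflect the study conditions the pipeline is designed around:
#' an analysis sample of 210 respondents (299 recruited, 89 failing at least
#' one attention check), at least 25 experts per job, a 16-item anchor
#' questionnaire on a 1-5 scale answered on a 50-point slider in the faking
#' tasks, 32-item target-questionnaire tasks in four disjoint 8-item
#' subscales, and standardized effects on shape of
#' (g, gc, ep) = (0.218, 0.495, 0.316) with null effects on elevation.
#'
#' @param n_respondents Size of the final analysis sample.
#' @param n_attention_fail Additional recruited respondents who fail at
#'   least one attention check (generated and then filtered out downstream).
#' @param n_honest Size of the honest linkage sample.
#' @param n_experts_per_job Experts rating each job (must be >= 25).
#' @param jobs Job labels.
#' @param true_profiles Work-style-by-job matrix of true optimal anchor
#'   ratings on the expert scale.
#' @param gamma_shape,gamma_elevation Standardized effects of (g, gc, ep) on
#'   the shape and elevation latents; each must satisfy sum(gamma^2) <= 1.
#' @param ability_loadings Data frame with columns \code{task},
#'   \code{shape}, \code{elevation}: loadings of the task-specific latent on
#'   the respective ability, in [0, 1].
#' @param noise_sd Named list of residual scales: \code{rater} (expert
#'   panel), \code{honest} (target-item residual multiplier), \code{faking}
#'   (item-level noise in faked responses, as a multiple of the optimal
#'   pattern's spread).
#' @param blend Named list of constants of the faking-response mechanism:
#'   \code{w0}, \code{w1} (logistic blend weight on the shape latent),
#'   \code{offset_scale}, \code{offset_rate} (negative-exponential mean
#'   offset on the elevation latent).
#' @param seed Integer master seed; fans out deterministically to stages.
#' @return An object of class \code{population_spec}.
#' @export
population_spec <- function(n_respondents = 210,
                            n_attention_fail = 89,
                            n_honest = 151,
                            n_experts_per_job = 25,
                            jobs = JOBS,
                            true_profiles = default_true_profiles(),
                            gamma_shape = c(g = 0.218, gc = 0.495, ep = 0.316),
                            gamma_elevation = c(g = 0, gc = 0, ep = 0),
                            ability_loadings = NULL,
                            noise_sd = list(rater = 0.5, honest = 1,
                                            faking = 1.8),
                            blend = list(w0 = 0.1, w1 = 0.9,
                                         offset_scale = 0.5,
                                         offset_rate = 0.6),
                            seed = 1L) {
  if (n_respondents <= 0 || n_honest <= 0 || n_experts_per_job <= 0)
    stop_fmt("all counts must be positive")
  if (n_experts_per_job < 25)
    stop_fmt("at least 25 experts are required per job (got %d)",
             n_experts_per_job)
  if (sum(gamma_shape^2) > 1 || sum(gamma_elevation^2) > 1)
    stop_fmt("sum of squared gammas must not exceed 1 (orthogonal predictors)")
  stopifnot(all(jobs %in% colnames(true_profiles)),
            all(rownames(true_profiles) == WORK_STYLES),
            all(true_profiles >= 1 & true_profiles <= 5))
  if (is.null(ability_loadings)) {
    tasks <- c(paste0("wsq_", jobs), paste0("neo_", jobs))
    ability_loadings <- data.frame(
      task = tasks,
      shape = c(rep(0.50, length(jobs)), rep(0.70, length(jobs))),
      elevation = c(rep(0.50, length(jobs)), rep(0.70, length(jobs))),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(n_respondents = as.integer(n_respondents),
         n_attention_fail = as.integer(n_attention_fail),
         n_honest = as.integer(n_honest),
         n_experts_per_job = as.integer(n_experts_per_job),
         jobs = jobs,
         true_profiles = true_profiles,
         gamma_shape = gamma_shape,
         gamma_elevation = gamma_elevation,
         ability_loadings = ability_loadings,
         noise_sd = noise_sd,
         blend = blend,
         anchor_bounds = c(1, 5),
         slider_bounds = c(1, 50),
         seed = as.integer(seed)),
    class = "population_spec"
  )
}

# Truncated-normal sampler recentred so that the truncated mean equals
# `target_mean` (plain truncation would bias panel means away from the truth
# near the scale bounds).
rtrunc_centered <- function(n, target_mean, sd, lo, hi) {
  if (sd == 0) return(rep(target_mean, n))
  tn_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    den <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / den
  }
  mu <- stats::uniroot(function(m) tn_mean(m) - target_mean,
                       lower = lo - 4 * sd, upper = hi + 4 * sd,
                       tol = 1e-10)$root
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  u <- stats::runif(n, stats::pnorm(a), stats::pnorm(b))
  mu + sd * stats::qnorm(u)
}

#' Generate an expert rating panel for one job
#'
#' Each expert rates all 16 work styles on the 1-5 anchor scale. Ratings are
#' the job's true optimal profile plus truncated-normal rater noise,
#' recentred so the population panel mean equals the truth; panel means are
#' therefore rational numbers within the scale bounds.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param job Job label declared in \code{spec}.
#' @return An object of class \code{expert_panel}: a data frame
#'   (\code{expert_id} + one column per work style) with attributes
#'   \code{job} and \code{bounds}.
#' @export
generate_expert_panel <- function(spec, job) {
  if (!job %in% spec$jobs)
    stop_fmt("unknown job label '%s' (declared: %s)", job,
             paste(spec$jobs, collapse = ", "))
  set.seed(sub_seed(spec$seed, paste0("expert_panel_", job)))
  truth <- spec$true_profiles[, job]
  n <- spec$n_experts_per_job
  ratings <- vapply(truth, function(mu) {
    rtrunc_centered(n, mu, spec$noise_sd$rater,
                    spec$anchor_bounds[1], spec$anchor_bounds[2])
  }, numeric(n))
  out <- data.frame(expert_id = sprintf("expert_%02d", seq_len(n)), ratings,
                    stringsAsFactors = FALSE)
  names(out) <- c("expert_id", paste0("wsq_", WORK_STYLES))
  structure(out, job = job, bounds = spec$anchor_bounds,
            class = c("expert_panel", "data.frame"))
}

#' Per-item mean ratings of an expert panel
#'
#' @param panel An \code{expert_panel}.
#' @return Data frame with columns \code{item} and \code{mean}.
#' @export
expert_panel_means <- function(panel) {
  items <- setdiff(names(panel), "expert_id")
  data.frame(item = items,
             mean = vapply(items, function(j) mean(panel[[j]]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

# True linear links between honest anchor responses and the honest target
# item pool: per linkable work style, eight "strong" candidate items on a
# known line (two of them reversed) plus two weak ones; per non-linkable
# style, ten weak items only. Deterministic in the work-style index.
true_item_links <- function() {
  rows <- list()
  sd_x <- 0.85  # approximate sd of honest anchor responses
  for (si in seq_along(WORK_STYLES)) {
    ws <- WORK_STYLES[si]
    linkable <- ws %in% LINKABLE_STYLES
    n_cand <- 10L
    for (k in seq_len(n_cand)) {
      strong <- linkable && k <= 8L
      if (strong) {
        b <- c(0.9, 0.8, 0.75, 0.7, 0.65, 0.6, -0.7, -0.55)[k]
        r <- c(0.70, 0.65, 0.62, 0.58, 0.55, 0.50, 0.60, 0.45)[k]
      } else {
        b <- 0.12 * (-1)^k
        r <- 0.10
      }
      sigma <- abs(b) * sd_x * sqrt(1 / r^2 - 1)
      a <- 3 - b * 3 + 0.1 * ((k + si) %% 3 - 1)
      rows[[length(rows) + 1L]] <- data.frame(
        work_style = ws, item = sprintf("neo_%s_%d", ws, k),
        a = a, b = b, sigma = sigma, target_r = r * sign(b),
        in_true_subscale = strong, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate an honest linkage sample for the anchor and target questionnaires
#'
#' Respondents hold Big-Five-style latent traits; each anchor work-style item
#' reflects one trait, and target-pool items are generated from known linear
#' links to the observed anchor responses (eight linkable items per work
#' style for twelve styles; only weakly related items for the remaining
#' four). The true links are returned so that linkage estimates can be
#' validated against them.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param n Sample size (default \code{spec$n_honest}).
#' @param discretize Round responses to integer Likert categories (default
#'   TRUE). Continuous responses with \code{noise = 0} give exact link
#'   recovery.
#' @param noise Multiplier on target-item residual scales (default
#'   \code{spec$noise_sd$honest}).
#' @return List with data frames \code{anchor} (respondent x 16 items),
#'   \code{target} (respondent x 160 pool items) and \code{links} (true
#'   generating lines per target item).
#' @export
generate_honest_sample <- function(spec, n = spec$n_honest, discretize = TRUE,
                                   noise = spec$noise_sd$honest) {
  set.seed(sub_seed(spec$seed, "honest_sample"))
  trait_of <- c(
    achievement_effort = "C", persistence = "C", initiative = "C",
    leadership = "E", cooperation = "A", concern_for_others = "A",
    social_orientation = "E", self_control = "N", stress_tolerance = "N",
    adaptability_flexibility = "O", dependability = "C",
    attention_to_detail = "C", integrity = "C", independence = "O",
    innovation = "O", analytical_thinking = "O")
  trait_sign <- stats::setNames(ifelse(trait_of == "N", -1, 1),
                                names(trait_of))
  traits <- matrix(stats::rnorm(n * 5), n, 5,
                   dimnames = list(NULL, c("N", "E", "O", "A", "C")))
  lam <- 0.65
  anchor <- sapply(WORK_STYLES, function(ws) {
    lat <- lam * trait_sign[ws] * traits[, trait_of[ws]] +
      sqrt(1 - lam^2) * stats::rnorm(n)
    x <- 3 + 0.9 * lat
    x <- clip(x, spec$anchor_bounds[1], spec$anchor_bounds[2])
    if (discretize) round(x) else x
  })
  colnames(anchor) <- paste0("wsq_", WORK_STYLES)

  links <- true_item_links()
  target <- matrix(NA_real_, n, nrow(links),
                   dimnames = list(NULL, links$item))
  for (j in seq_len(nrow(links))) {
    x <- anchor[, paste0("wsq_", links$work_style[j])]
    y <- links$a[j] + links$b[j] * x +
      noise * links$sigma[j] * stats::rnorm(n)
    y <- clip(y, spec$anchor_bounds[1], spec$anchor_bounds[2])
    target[, j] <- if (discretize) round(y) else y
  }
  ids <- sprintf("h%03d", seq_len(n))
  list(
    anchor = data.frame(respondent_id = ids, anchor, check.names = FALSE,
                        stringsAsFactors = FALSE),
    target = data.frame(respondent_id = ids, target, check.names = FALSE,
                        stringsAsFactors = FALSE),
    links = links
  )
}

# Item-level true optimal profile for one target-instrument task: the true
# generating lines evaluated at the true anchor profile, clipped to bounds.
true_neo_profile <- function(spec, job) {
  links <- true_item_links()
  sub <- links[links$in_true_subscale &
                 links$work_style %in% NEO_TASK_SUBSCALES[[job]], ]
  value <- clip(sub$a + sub$b * spec$true_profiles[sub$work_style, job],
                spec$anchor_bounds[1], spec$anchor_bounds[2])
  data.frame(item = sub$item, subscale = sub$work_style, optimal = value,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate faked responses toward an optimal profile
#'
#' Mechanism: a respondent's centred response pattern is a convex blend of
#' the centred optimal pattern and a respondent-specific noise pattern, with
#' blend weight a logistic function of the task-specific shape latent; the
#' response mean overshoots the optimal mean by a scaled negative
#' exponential of the task-specific elevation latent. Higher shape latents
#' therefore yield response vectors more correlated with the optimal
#' pattern, and higher elevation latents yield mean levels closer to the
#' optimal mean. Responses are expressed on the 50-point slider and clipped
#' to its bounds.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param optimal Numeric vector of item-level optimal values (anchor-scale
#'   units), named by item.
#' @param abilities Data frame with columns \code{respondent_id},
#'   \code{elevation}, \code{shape} (standard-normal ability latents).
#' @param task Task label (used for ability-loading lookup and seeding).
#' @param discretize Round to integer slider values (default TRUE); pass
#'   FALSE for exact zero-noise limits.
#' @param zero_noise If TRUE, suppress task-specific and item-level noise so
#'   the ability latents act directly.
#' @return Data frame \code{respondent_id} + one column per item on the
#'   slider scale, with attribute \code{bounds}.
#' @export
generate_faked_responses <- function(spec, optimal, abilities, task,
                                     discretize = TRUE, zero_noise = FALSE) {
  if (is.null(names(optimal)) || anyNA(optimal))
    stop_fmt("optimal profile must be a complete named numeric vector")
  need <- c("respondent_id", "elevation", "shape")
  if (!all(need %in% names(abilities)))
    stop_fmt("abilities must have columns %s", paste(need, collapse = ", "))
  n <- nrow(abilities)
  p <- length(optimal)
  set.seed(sub_seed(spec$seed, paste0("faked_", task)))
  ld <- spec$ability_loadings
  row <- match(task, ld$task)
  l_s <- if (is.na(row)) 0.6 else ld$shape[row]
  l_e <- if (is.na(row)) 0.6 else ld$elevation[row]
  if (zero_noise) {
    s_task <- abilities$shape
    e_task <- abilities$elevation
  } else {
    s_task <- l_s * abilities$shape + sqrt(1 - l_s^2) * stats::rnorm(n)
    e_task <- l_e * abilities$elevation + sqrt(1 - l_e^2) * stats::rnorm(n)
  }
  w <- stats::plogis(spec$blend$w0 + spec$blend$w1 * s_task)
  offset <- spec$blend$offset_scale * exp(-spec$blend$offset_rate * e_task)
  pat <- optimal - mean(optimal)
  sd_pat <- stats::sd(pat)
  noise_sd <- if (zero_noise) 0 else spec$noise_sd$faking * sd_pat
  resp <- matrix(NA_real_, n, p, dimnames = list(NULL, names(optimal)))
  for (i in seq_len(n)) {
    u <- noise_sd * stats::rnorm(p)
    u <- u - mean(u)
    centred <- w[i] * pat + (1 - w[i]) * u
    resp[i, ] <- mean(optimal) + offset[i] + centred
  }
  slider <- clip(resp * 10, spec$slider_bounds[1], spec$slider_bounds[2])
  if (discretize) slider <- round(slider)
  out <- data.frame(respondent_id = abilities$respondent_id, slider,
                    check.names = FALSE, stringsAsFactors = FALSE)
  structure(out, bounds = spec$slider_bounds, task = task)
}

# Default bifactor loadings of the 11 cognitive parcels: fluid parcels mark
# the general factor only; knowledge and emotion-perception parcels load on
# g plus their nested orthogonal specific factor.
default_parcel_loadings <- function() {
  data.frame(
    parcel = c("gf_1", "gf_2", "gf_3", "gc_Sci", "gc_Hum", "gc_Soc",
               "ep_a", "ep_d", "ep_f", "ep_sa", "ep_su"),
    g = c(0.75, 0.75, 0.75, 0.55, 0.55, 0.55, 0.45, 0.45, 0.45, 0.45, 0.45),
    gc = c(0, 0, 0, 0.60, 0.60, 0.60, 0, 0, 0, 0, 0),
    ep = c(0, 0, 0, 0, 0, 0, 0.65, 0.65, 0.65, 0.65, 0.65),
    stringsAsFactors = FALSE
  )
}

#' Generate bifactor-structured cognitive parcel scores
#'
#' Emits 11 parcels: three fluid-reasoning parcels loading on the general
#' factor only, three knowledge-domain parcels loading on g plus a nested
#' crystallized factor, and five emotion-perception parcels loading on g
#' plus a nested emotion-perception factor. Unique variances are
#' 1 - sum(loadings^2) so parcels have unit population variance.
#'
#' @param spec A \code{\link{population_spec}}.
#' @param factor_scores Data frame with columns \code{respondent_id},
#'   \code{g}, \code{gc}, \code{ep} (orthogonal standard-normal factors).
#' @param loadings Parcel loading table (default
#'   \code{default_parcel_loadings()}).
#' @return Data frame \code{respondent_id} + 11 parcel columns.
#' @export
generate_cognitive_scores <- function(spec, factor_scores,
                                      loadings = default_parcel_loadings()) {
  uniq <- 1 - loadings$g^2 - loadings$gc^2 - loadings$ep^2
  if (any(uniq <= 0))
    stop_fmt("loadings imply non-positive unique variance for parcel(s): %s",
             paste(loadings$parcel[uniq <= 0], collapse = ", "))
  set.seed(sub_seed(spec$seed, "cognitive_scores"))
  n <- nrow(factor_scores)
  F <- as.matrix(factor_scores[, c("g", "gc", "ep")])
  L <- t(as.matrix(loadings[, c("g", "gc", "ep")]))
  scores <- F %*% L +
    matrix(stats::rnorm(n * nrow(loadings)), n) %*% diag(sqrt(uniq))
  colnames(scores) <- loadings$parcel
  data.frame(respondent_id = factor_scores$respondent_id, scores,
             check.names = FALSE, stringsAsFactors = FALSE)
}

# Closed-form implied covariance of the default bifactor parcel model
# (used by tests as the convergence target of the generator).
bifactor_implied_cov <- function(loadings = default_parcel_loadings()) {
  L <- as.matrix(loadings[, c("g", "gc", "ep")])
  uniq <- 1 - rowSums(L^2)
  S <- L %*% t(L) + diag(uniq)
  dimnames(S) <- list(loadings$parcel, loadings$parcel)
  S
}

#' Simulate a complete faking-ability study
#'
#' Draws latent cognitive factors (g, gc, ep, orthogonal standard normal),
#' the elevation and shape ability latents from the declared structural
#' effects, expert panels per job, an honest linkage sample, faked responses
#' for all six tasks (anchor- and target-instrument versions of each job),
#' cognitive parcel scores, and attention-check outcomes (a fixed number of
#' recruited respondents fail at least one of three checks).
#'
#' @param spec A \code{\link{population_spec}}.
#' @return List of class \code{simulated_study}: \code{spec},
#'   \code{expert_panels}, \code{honest}, \code{true_neo_profiles},
#'   \code{faked} (six response tables on the slider scale),
#'   \code{cognitive}, \code{attention}, and \code{truth} (per-respondent
#'   latents, aligned one-to-one with respondent identifiers).
#' @export
simulate_study <- function(spec = population_spec()) {
  n_total <- spec$n_respondents + spec$n_attention_fail
  ids <- sprintf("r%03d", seq_len(n_total))

  set.seed(sub_seed(spec$seed, "latents"))
  g <- stats::rnorm(n_total)
  gc_ <- stats::rnorm(n_total)
  ep <- stats::rnorm(n_total)
  gs <- spec$gamma_shape
  ge <- spec$gamma_elevation
  shape <- gs["g"] * g + gs["gc"] * gc_ + gs["ep"] * ep +
    sqrt(1 - sum(gs^2)) * stats::rnorm(n_total)
  elevation <- ge["g"] * g + ge["gc"] * gc_ + ge["ep"] * ep +
    sqrt(1 - sum(ge^2)) * stats::rnorm(n_total)
  truth <- data.frame(respondent_id = ids, g = g, gc = gc_, ep = ep,
                      shape = as.numeric(shape),
                      elevation = as.numeric(elevation),
                      stringsAsFactors = FALSE)

  panels <- lapply(spec$jobs, function(j) generate_expert_panel(spec, j))
  names(panels) <- spec$jobs

  honest <- generate_honest_sample(spec)

  abilities <- truth[, c("respondent_id", "elevation", "shape")]
  faked <- list()
  neo_profiles <- list()
  for (job in spec$jobs) {
    opt_wsq <- spec$true_profiles[, job]
    names(opt_wsq) <- paste0("wsq_", WORK_STYLES)
    faked[[paste0("wsq_", job)]] <- generate_faked_responses(
      spec, opt_wsq, abilities, paste0("wsq_", job))
    prof <- true_neo_profile(spec, job)
    neo_profiles[[job]] <- prof
    opt_neo <- stats::setNames(prof$optimal, prof$item)
    faked[[paste0("neo_", job)]] <- generate_faked_responses(
      spec, opt_neo, abilities, paste0("neo_", job))
  }

  cognitive <- generate_cognitive_scores(
    spec, truth[, c("respondent_id", "g", "gc", "ep")])

  set.seed(sub_seed(spec$seed, "attention"))
  fail_ids <- sample(ids, spec$n_attention_fail)
  checks <- matrix(TRUE, n_total, 3,
                   dimnames = list(NULL, paste0("check_", 1:3)))
  for (id in fail_ids) {
    k <- sample(1:3, sample(1:2, 1))
    checks[match(id, ids), k] <- FALSE
  }
  attention <- data.frame(respondent_id = ids, checks,
                          stringsAsFactors = FALSE)

  structure(
    list(spec = spec, expert_panels = panels, honest = honest,
         true_neo_profiles = neo_profiles, faked = faked,
         cognitive = cognitive, attention = attention, truth = truth),
    class = "simulated_study"
  )
}

#' Write every table of a simulated study as CSV
#'
#' @param study A \code{simulated_study}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_csvs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
    files <<- c(files, path)
  }
  for (job in names(study$expert_panels))
    put(study$expert_panels[[job]], paste0("expert_panel_", job))
  put(study$honest$anchor, "honest_anchor")
  put(study$honest$target, "honest_target")
  put(study$honest$links, "true_item_links")
  for (task in names(study$faked)) put(study$faked[[task]],
                                       paste0("faked_", task))
  for (job in names(study$true_neo_profiles))
    put(study$true_neo_profiles[[job]], paste0("true_profile_neo_", job))
  put(study$cognitive, "cognitive_parcels")
  put(study$attention, "attention_checks")
  put(study$truth, "truth")
  invisible(files)
}
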