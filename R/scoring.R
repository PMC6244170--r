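# Profile-similarity scoring of faking-ability tasks: rescaling from the
# 50-point slider, elevation (absolute mean difference to the optimal
# profile, square-root transformed) and shape (Pearson correlation with the
# optimal profile), per-task aggregation, and descriptive summaries.

#' Rescale 50-point slider responses to the anchor scale
#'
#' Divides each response by 10, so the bounds [1, 50] become [0.1, 5.0].
#'
#' @param raw Response data frame (\code{respondent_id} + item columns) with
#'   values in [1, 50] (missing allowed).
#' @return The data frame with item columns divided by 10.
#' @export
rescale_responses <- function(raw) {
  items <- setdiff(names(raw), "respondent_id")
  m <- as.matrix(raw[, items, drop = FALSE])
  bad <- which(!is.na(m) & (m < 1 | m > 50), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(utils::head(bad, 10), 1, function(ix)
      sprintf("%s[%s, %s] = %g", "raw", rownames(m)[ix[1]] %||% ix[1],
              items[ix[2]], m[ix[1], ix[2]]))
    stop_fmt("values outside [1, 50]: %s%s", paste(cells, collapse = "; "),
             if (nrow(bad) > 10) sprintf(" (and %d more)", nrow(bad) - 10)
             else "")
  }
  raw[items] <- m / 10
  raw
}

#' Elevation: absolute mean distance to the optimal profile
#'
#' |mean(response) - mean(optimal)|, optionally square-root transformed
#' (the transform improves the distributional properties of absolute
#' difference scores, which are typically right-skewed). Lower values mean
#' closer proximity to the optimal profile, i.e. higher faking ability.
#' Missing response entries are excluded together with their optimal
#' counterparts.
#'
#' @param response,optimal Equal-length numeric vectors.
#' @param transform Apply the square root (default TRUE).
#' @return A scalar; NA if no complete pairs remain.
#' @export
elevation_score <- function(response, optimal, transform = TRUE) {
  if (length(response) != length(optimal))
    stop_fmt("response (%d) and optimal (%d) differ in length",
             length(response), length(optimal))
  ok <- !is.na(response) & !is.na(optimal)
  if (!any(ok)) return(NA_real_)
  e <- abs(mean(response[ok]) - mean(optimal[ok]))
  if (transform) sqrt(e) else e
}

#' Shape: pattern correlation with the optimal profile
#'
#' Pearson correlation between the response vector and the optimal profile.
#' Higher values mean a better pattern match, i.e. higher faking ability.
#' A zero-variance response vector makes the correlation undefined and the
#' score is set to missing; a zero-variance optimal profile is also
#' missing, but flagged with a warning since it indicates a degenerate task.
#'
#' @param response,optimal Equal-length numeric vectors with at least 3
#'   complete pairs.
#' @return Correlation in [-1, 1], or NA.
#' @export
shape_score <- function(response, optimal) {
  if (length(response) != length(optimal))
    stop_fmt("response (%d) and optimal (%d) differ in length",
             length(response), length(optimal))
  ok <- !is.na(response) & !is.na(optimal)
  if (sum(ok) < 3)
    stop_fmt("shape needs at least 3 complete pairs (got %d)", sum(ok))
  r <- response[ok]; o <- optimal[ok]
  if (stats::var(o) == 0) {
    warning("optimal profile has zero variance; shape undefined",
            call. = FALSE)
    return(NA_real_)
  }
  if (stats::var(r) == 0) return(NA_real_)
  stats::cor(r, o)
}

#' Define a faking task
#'
#' Anchor-type tasks are scored over all their items at once; target-type
#' tasks carry four disjoint 8-item subscales that are scored separately
#' and then aggregated.
#'
#' @param job Job label.
#' @param instrument "wsq" (anchor-type) or "neo" (target-type).
#' @param optimal Named numeric vector of per-item optimal values on the
#'   anchor scale.
#' @param subscales For target-type tasks, a named list mapping subscale
#'   labels to item-identifier vectors (disjoint).
#' @return A \code{faking_task} object.
#' @export
faking_task <- function(job, instrument = c("wsq", "neo"), optimal,
                        subscales = NULL) {
  instrument <- match.arg(instrument)
  if (instrument == "neo") {
    if (is.null(subscales))
      stop_fmt("target-type tasks need a subscale list")
    all_items <- unlist(subscales, use.names = FALSE)
    if (anyDuplicated(all_items))
      stop_fmt("subscales must be disjoint within a task")
    if (!all(all_items %in% names(optimal)))
      stop_fmt("optimal profile does not cover every task item")
  }
  structure(list(job = job, instrument = instrument, optimal = optimal,
                 subscales = subscales,
                 name = paste0(instrument, "_", job)),
            class = "faking_task")
}

#' Score one task for all respondents
#'
#' @param responses Anchor-scale response data frame covering the task's
#'   items.
#' @param task A \code{\link{faking_task}}.
#' @param mode For target-type tasks: "subscale" (default) scores each
#'   8-item subscale and averages the available subscale values into one
#'   task-level elevation and shape; "pooled" scores all items at once.
#' @return Data frame: \code{respondent_id}, \code{task},
#'   \code{elevation_raw}, \code{elevation}, \code{shape}.
#' @export
score_task <- function(responses, task, mode = c("subscale", "pooled")) {
  mode <- match.arg(mode)
  M <- resp_matrix(responses)
  blocks <- if (task$instrument == "neo" && mode == "subscale")
    task$subscales else list(all = names(task$optimal))
  missing_items <- setdiff(unlist(blocks), colnames(M))
  if (length(missing_items))
    stop_fmt("task %s: response table lacks item(s) %s", task$name,
             paste(utils::head(missing_items, 5), collapse = ", "))
  n <- nrow(M)
  el_raw <- el <- sh <- matrix(NA_real_, n, length(blocks))
  for (b in seq_along(blocks)) {
    items <- blocks[[b]]
    opt <- task$optimal[items]
    for (i in seq_len(n)) {
      resp <- M[i, items]
      el_raw[i, b] <- elevation_score(resp, opt, transform = FALSE)
      el[i, b] <- elevation_score(resp, opt, transform = TRUE)
      sh[i, b] <- shape_score(resp, opt)
    }
  }
  agg <- function(x) {
    v <- rowMeans(x, na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    v
  }
  data.frame(respondent_id = responses$respondent_id, task = task$name,
             elevation_raw = agg(el_raw), elevation = agg(el),
             shape = agg(sh), row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a battery of faking tasks
#'
#' @param responses Named list of anchor-scale response data frames, one per
#'   task, keyed by task name.
#' @param tasks List of \code{\link{faking_task}} objects (six in the
#'   standard battery: anchor- and target-type versions of three jobs).
#' @param mode Passed to \code{\link{score_task}}.
#' @return Long data frame of class \code{psm_scores} stacking the per-task
#'   results.
#' @export
score_battery <- function(responses, tasks, mode = "subscale") {
  out <- lapply(tasks, function(task) {
    if (!task$name %in% names(responses))
      stop_fmt("no response table for task %s", task$name)
    score_task(responses[[task$name]], task, mode = mode)
  })
  structure(do.call(rbind, out), class = c("psm_scores", "data.frame"))
}

#' Reshape battery scores to a respondent-by-task matrix
#'
#' @param scores A \code{psm_scores} long table.
#' @param metric "elevation", "shape" or "elevation_raw".
#' @return Data frame \code{respondent_id} + one column per task, columns
#'   named \code{<metric initial>_<task>}.
#' @export
scores_wide <- function(scores, metric = c("elevation", "shape",
                                           "elevation_raw")) {
  metric <- match.arg(metric)
  tasks <- unique(scores$task)
  ids <- unique(scores$respondent_id)
  out <- data.frame(respondent_id = ids, stringsAsFactors = FALSE)
  for (tk in tasks) {
    sub <- scores[scores$task == tk, ]
    out[[paste0(substr(metric, 1, 1), "_", tk)]] <-
      sub[[metric]][match(ids, sub$respondent_id)]
  }
  out
}

#' Descriptive statistics of battery scores
#'
#' Per task and metric: mean, SD, minimum, maximum, skew, and excess
#' kurtosis (no small-sample bias correction), missing values excluded per
#' cell.
#'
#' @param scores A \code{psm_scores} long table.
#' @return Data frame with columns \code{metric}, \code{task}, \code{m},
#'   \code{sd}, \code{min}, \code{max}, \code{skew}, \code{kurtosis},
#'   \code{n}.
#' @export
summarize_scores <- function(scores) {
  rows <- list()
  for (metric in c("elevation", "shape")) {
    for (tk in unique(scores$task)) {
      x <- scores[[metric]][scores$task == tk]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, task = tk,
        m = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1) stats::sd(x) else NA_real_,
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_,
        skew = moment_skew(x), kurtosis = moment_kurtosis(x),
        n = length(x), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Build the six standard tasks of a simulated study
#'
#' Anchor-type optimal profiles are the expert-panel means; target-type
#' profiles are either the true generating profiles carried by the study or
#' profiles projected through a fitted linkage map.
#'
#' @param study A \code{\link{simulate_study}} result.
#' @param neo_profiles Optional named list (per job) of data frames with
#'   columns \code{item}, \code{subscale}, \code{optimal} to use for the
#'   target-type tasks; defaults to the study's true profiles.
#' @return List of six \code{\link{faking_task}} objects keyed by task name.
#' @export
study_tasks <- function(study, neo_profiles = study$true_neo_profiles) {
  tasks <- list()
  for (job in study$spec$jobs) {
    means <- expert_panel_means(study$expert_panels[[job]])
    opt_wsq <- stats::setNames(means$mean, means$item)
    tasks[[paste0("wsq_", job)]] <-
      faking_task(job, "wsq", optimal = opt_wsq)
    prof <- neo_profiles[[job]]
    subscales <- split(prof$item, prof$subscale)
    tasks[[paste0("neo_", job)]] <-
      faking_task(job, "neo",
                  optimal = stats::setNames(prof$optimal, prof$item),
                  subscales = subscales)
  }
  tasks
}
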