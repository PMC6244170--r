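# Questionnaire linkage: correlate anchor items with a target item pool,
# build k-item subscales under a correlation threshold, fit per-item linking
# regressions, and project expert ratings into optimal profiles for the
# target instrument.

resp_matrix <- function(df) {
  if (!"respondent_id" %in% names(df))
    stop_fmt("response table needs a 'respondent_id' column")
  m <- as.matrix(df[, setdiff(names(df), "respondent_id"), drop = FALSE])
  rownames(m) <- df$respondent_id
  storage.mode(m) <- "double"
  m
}

#' Correlate every anchor item with every target item
#'
#' Pearson correlations on pairwise-complete observations, after aligning
#' the two tables on shared respondent identifiers. Cells with a
#' zero-variance item (or fewer than 3 complete pairs) are NA.
#'
#' @param anchor,target Response data frames (\code{respondent_id} + item
#'   columns).
#' @return Matrix of correlations, anchor items in rows, target items in
#'   columns.
#' @export
correlate_items <- function(anchor, target) {
  A <- resp_matrix(anchor)
  B <- resp_matrix(target)
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) == 0) stop_fmt("no overlapping respondents")
  A <- A[shared, , drop = FALSE]
  B <- B[shared, , drop = FALSE]
  suppressWarnings(r <- stats::cor(A, B, use = "pairwise.complete.obs"))
  # flag cells with < 3 complete pairs as missing
  if (anyNA(A) || anyNA(B)) {
    okA <- !is.na(A); okB <- !is.na(B)
    npair <- t(okA) %*% okB
    r[npair < 3] <- NA_real_
  }
  r
}

#' Select subscale items for each anchor item
#'
#' For each anchor item, ranks candidate target items by the selection
#' statistic (absolute correlation by default, so reversed indicators
#' qualify) and keeps the top \code{k}. If fewer than \code{k} candidates
#' reach the threshold, no subscale is created for that anchor item. Ties at
#' the k-th rank are broken by target-item column order. Items may be shared
#' between subscales.
#'
#' @param corr_table Anchor-by-target correlation matrix from
#'   \code{\link{correlate_items}}.
#' @param k Subscale size (default 8).
#' @param r_min Threshold the selection statistic must reach (default 0.3).
#' @param statistic "abs" (default) ranks and thresholds on |r|; "signed"
#'   uses the raw correlation.
#' @return A \code{linkage_map}: data frame with one row per selected
#'   (anchor item, target item) pair — columns \code{anchor_item},
#'   \code{target_item}, \code{rank}, \code{r} — plus attribute
#'   \code{created}, a named logical over anchor items.
#' @export
select_subscale_items <- function(corr_table, k = 8, r_min = 0.3,
                                  statistic = c("abs", "signed")) {
  statistic <- match.arg(statistic)
  if (k > ncol(corr_table))
    stop_fmt("k = %d exceeds the number of target items (%d)", k,
             ncol(corr_table))
  created <- stats::setNames(logical(nrow(corr_table)), rownames(corr_table))
  rows <- list()
  for (ai in rownames(corr_table)) {
    r <- corr_table[ai, ]
    stat <- if (statistic == "abs") abs(r) else r
    stat[is.na(stat)] <- -Inf      # missing cells are not candidates
    n_pass <- sum(stat >= r_min)
    if (n_pass < k) next
    ord <- order(-stat, seq_along(stat))  # ties: column order
    sel <- ord[seq_len(k)]
    created[ai] <- TRUE
    rows[[ai]] <- data.frame(
      anchor_item = ai, target_item = colnames(corr_table)[sel],
      rank = seq_len(k), r = as.numeric(r[sel]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(anchor_item = character(), target_item = character(),
               rank = integer(), r = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, created = created, k = k, r_min = r_min,
            statistic = statistic, class = c("linkage_map", "data.frame"))
}

#' Fit per-item linking regressions
#'
#' Ordinary least squares of each selected target item on its anchor item,
#' target = a + b * anchor, on pairwise-complete observations. The intercept
#' \code{a} and slope \code{b} are appended to the linkage map.
#'
#' @param anchor,target Response data frames.
#' @param selection A \code{linkage_map} from
#'   \code{\link{select_subscale_items}}.
#' @return The linkage map with columns \code{a}, \code{b}, \code{n} added.
#' @export
fit_item_links <- function(anchor, target, selection) {
  A <- resp_matrix(anchor)
  B <- resp_matrix(target)
  shared <- intersect(rownames(A), rownames(B))
  if (length(shared) == 0) stop_fmt("no overlapping respondents")
  A <- A[shared, , drop = FALSE]
  B <- B[shared, , drop = FALSE]
  a <- b <- nn <- numeric(nrow(selection))
  for (i in seq_len(nrow(selection))) {
    x <- A[, selection$anchor_item[i]]
    y <- B[, selection$target_item[i]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3)
      stop_fmt("fewer than 3 complete pairs for %s ~ %s",
               selection$target_item[i], selection$anchor_item[i])
    x <- x[ok]; y <- y[ok]
    vx <- stats::var(x)
    if (vx == 0)
      stop_fmt("anchor item %s has zero variance", selection$anchor_item[i])
    b[i] <- stats::cov(x, y) / vx
    a[i] <- mean(y) - b[i] * mean(x)
    nn[i] <- sum(ok)
  }
  selection$a <- a
  selection$b <- b
  selection$n <- as.integer(nn)
  selection
}

#' Project expert mean ratings into a target-instrument optimal profile
#'
#' Evaluates each fitted linking line at the job's mean expert rating of the
#' corresponding anchor item: optimal_i = a_i + b_i * expert_mean, clipped
#' to the response-scale bounds. The anchor instrument's own optimal profile
#' is the expert means themselves, unprojected.
#'
#' @param linkage A fitted \code{linkage_map} (with \code{a}, \code{b}).
#' @param expert_means Data frame with columns \code{item} (anchor item) and
#'   \code{mean}, e.g. from \code{\link{expert_panel_means}}.
#' @param bounds Length-2 numeric, the target response-scale bounds used for
#'   clipping (default c(1, 5)).
#' @param job,instrument Labels recorded on the result.
#' @return An \code{optimal_profile}: data frame with columns \code{item},
#'   \code{subscale} (the anchor item), \code{optimal}, \code{raw} (before
#'   clipping), with attributes \code{job}, \code{instrument},
#'   \code{bounds}.
#' @export
project_optimal_profile <- function(linkage, expert_means, bounds = c(1, 5),
                                    job = NA_character_,
                                    instrument = "target") {
  if (!all(c("a", "b") %in% names(linkage)))
    stop_fmt("linkage map has no fitted regressions; run fit_item_links first")
  created <- attr(linkage, "created")
  need <- unique(linkage$anchor_item)
  mu <- stats::setNames(expert_means$mean, expert_means$item)
  missing_items <- setdiff(need, names(mu))
  if (length(missing_items))
    stop_fmt("expert means missing for anchor item(s): %s",
             paste(missing_items, collapse = ", "))
  anchor_bounds <- c(1, 5)
  bad <- mu[need] < anchor_bounds[1] | mu[need] > anchor_bounds[2]
  if (any(bad))
    stop_fmt("expert mean outside anchor bounds for: %s",
             paste(need[bad], collapse = ", "))
  raw <- linkage$a + linkage$b * mu[linkage$anchor_item]
  out <- data.frame(item = linkage$target_item,
                    subscale = linkage$anchor_item,
                    optimal = clip(raw, bounds[1], bounds[2]),
                    raw = as.numeric(raw),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, job = job, instrument = instrument, bounds = bounds,
            class = c("optimal_profile", "data.frame"))
}

#' Run the whole linkage stage
#'
#' Convenience wrapper: correlations, selection, regressions.
#'
#' @inheritParams correlate_items
#' @inheritParams select_subscale_items
#' @return A fitted \code{linkage_map}.
#' @export
build_linkage <- function(anchor, target, k = 8, r_min = 0.3,
                          statistic = "abs") {
  ct <- correlate_items(anchor, target)
  sel <- select_subscale_items(ct, k = k, r_min = r_min,
                               statistic = statistic)
  fit_item_links(anchor, target, sel)
}
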