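# Inference utilities on fitted covariance-structure models: McDonald's
# omega, boundary-adjusted likelihood ratio tests, and nonparametric
# bootstrap confidence intervals.

#' McDonald's omega (factor saturation)
#'
#' omega = (sum lambda)^2 phi / [(sum lambda)^2 phi + sum theta_ii +
#' 2 sum_{i<j} theta_ij], computed over one factor's indicators; error
#' covariances among those indicators enter the denominator.
#'
#' @param fit A \code{fit_result}.
#' @param factor Factor name (defaults to the only factor).
#' @return Omega in [0, 1].
#' @export
mcdonald_omega <- function(fit, factor = NULL) {
  fnames <- names(fit$spec$factors)
  factor <- factor %||% {
    if (length(fnames) > 1)
      stop_fmt("model has several factors; name one of: %s",
               paste(fnames, collapse = ", "))
    fnames[1]
  }
  if (!factor %in% fnames) stop_fmt("unknown factor '%s'", factor)
  ind <- fit$spec$factors[[factor]]
  lam <- fit$mats$Lambda[ind, factor]
  phi <- fit$latent_cov[factor, factor]
  Th <- fit$mats$Theta[ind, ind, drop = FALSE]
  common <- sum(lam)^2 * phi
  denom <- common + sum(diag(Th)) + 2 * sum(Th[upper.tri(Th)])
  if (denom <= 0)
    stop_fmt("inadmissible solution: omega denominator is %g", denom)
  common / denom
}

#' Likelihood ratio test with optional boundary adjustment
#'
#' T = 2 (loglik_full - loglik_restricted), referred to a chi-square with
#' \code{df} degrees of freedom. When a single restricted parameter lies on
#' the boundary of its admissible space (e.g. a variance tested against
#' zero), the null distribution is the 50:50 mixture of a point mass at
#' zero and chi-square(df), so the p-value is halved; a fractional-df
#' chi-square variant is also available.
#'
#' @param full,restricted \code{fit_result}s of nested models on the same
#'   data (restricted nested in full).
#' @param df Degrees of freedom; defaults to the difference in free
#'   parameter counts.
#' @param boundary Is the tested parameter on a boundary? (default FALSE).
#' @param method For boundary tests: "mixture" (default) halves the
#'   chi-square(df) tail; "fractional" refers T to chi-square(df/2).
#' @return List with \code{statistic}, \code{df}, \code{p},
#'   \code{boundary}, \code{method}.
#' @export
boundary_lrt <- function(full, restricted, df = NULL, boundary = FALSE,
                         method = c("mixture", "fractional")) {
  method <- match.arg(method)
  df <- df %||% (full$npar - restricted$npar)
  if (df < 1) stop_fmt("df must be >= 1 (got %g)", df)
  T <- 2 * (full$loglik - restricted$loglik)
  tol <- 1e-6 * max(1, abs(full$loglik))
  if (T < -tol)
    stop_fmt(paste0("negative LRT statistic (%.6g): models are not nested ",
                    "or one fit did not converge"), T)
  T <- max(T, 0)
  p <- if (T == 0) 1 else if (!boundary) {
    stats::pchisq(T, df, lower.tail = FALSE)
  } else if (method == "mixture") {
    0.5 * stats::pchisq(T, df, lower.tail = FALSE)
  } else {
    stats::pchisq(T, df / 2, lower.tail = FALSE)
  }
  list(statistic = T, df = df, p = p, boundary = boundary, method = method)
}

#' Nonparametric bootstrap confidence intervals for model parameters
#'
#' Case resampling: respondents are resampled with replacement, the model
#' is refit from the full-sample solution, and percentile intervals are
#' formed per parameter. Non-converged draws are dropped and counted.
#'
#' @param spec An \code{\link{fm_spec}}.
#' @param data Case-level data (data frame or matrix).
#' @param draws Bootstrap draws (default 1000).
#' @param seed Integer seed (resampling is fully reproducible given it).
#' @param level Confidence level (default 0.95).
#' @param strict Escalate the >20 percent non-convergence warning to an
#'   error.
#' @return List: \code{ci} (data frame name/lower/upper), \code{draws_used},
#'   \code{n_nonconverged}, \code{estimates} (the draws matrix).
#' @export
bootstrap_ci <- function(spec, data, draws = 1000, seed = 1, level = 0.95,
                         strict = FALSE) {
  df <- as.data.frame(data)
  if ("respondent_id" %in% names(df)) df$respondent_id <- NULL
  full <- fit_model(spec, df, n_starts = 3)
  nfree <- sum(spec$params$type == "free")
  start <- full$theta
  names(start) <- c(spec$params$name[spec$params$type == "free"],
                    if (full$fiml) paste0("nu_", spec$observed))
  n <- nrow(df)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  samples <- matrix(sample.int(n, n * draws, replace = TRUE), nrow = draws)
  keep <- list()
  bad <- 0L
  for (d in seq_len(draws)) {
    fit_d <- tryCatch(
      fit_model(spec, df[samples[d, ], , drop = FALSE], n_starts = 1,
                start = start, on_nonconv = "warn"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit_d) || !fit_d$converged) { bad <- bad + 1L; next }
    keep[[length(keep) + 1L]] <- fit_d$estimates$est
  }
  if (!length(keep)) stop_fmt("no bootstrap draw converged")
  if (bad / draws > 0.2) {
    msg <- sprintf("%d of %d bootstrap draws did not converge", bad, draws)
    if (strict) stop_fmt("%s", msg) else warning(msg, call. = FALSE)
  }
  est <- do.call(rbind, keep)
  colnames(est) <- full$estimates$name
  alpha <- (1 - level) / 2
  ci <- data.frame(
    name = colnames(est),
    estimate = full$estimates$est,
    lower = apply(est, 2, stats::quantile, probs = alpha, names = FALSE),
    upper = apply(est, 2, stats::quantile, probs = 1 - alpha,
                  names = FALSE),
    stringsAsFactors = FALSE)
  list(ci = ci, draws_used = nrow(est), n_nonconverged = bad,
       estimates = est, full_fit = full)
}
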