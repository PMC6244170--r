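# Model specification layer of the covariance-structure engine.
#
# A model is a set of latent factors with indicator loading patterns
# (cross-loadings allowed, as in bifactor structures), optional structural
# regressions among latents, named free error covariances, and named free
# factor covariances. Identification uses effects coding by default: each
# factor's loadings are constrained to average 1 (the last loading is
# determined as n_f - sum(others)) and the factor variance is free.

#' Specify a factor / structural-equation model
#'
#' @param factors Named list: factor name -> character vector of indicator
#'   (observed variable) names. An indicator may appear under several
#'   factors (e.g. bifactor general + nested factors).
#' @param regressions Named list: latent outcome -> character vector of
#'   latent predictors (a recursive structure; outcomes acquire a free
#'   residual variance).
#' @param error_cov List of length-2 character vectors naming observed
#'   variable pairs whose error covariance is free.
#' @param factor_cov List of length-2 character vectors naming factor pairs
#'   whose (exogenous) covariance is free; all other factor covariances are
#'   fixed to zero, so orthogonality is the default.
#' @param identification "effects" (effects coding, default) or "marker"
#'   (first loading fixed to 1).
#' @return An object of class \code{fm_spec}.
#' @export
fm_spec <- function(factors, regressions = NULL, error_cov = NULL,
                    factor_cov = NULL,
                    identification = c("effects", "marker")) {
  identification <- match.arg(identification)
  stopifnot(is.list(factors), length(factors) >= 1, !is.null(names(factors)))
  observed <- unique(unlist(factors, use.names = FALSE))
  fnames <- names(factors)
  for (f in fnames) {
    if (length(factors[[f]]) < 2)
      stop_fmt("factor '%s' needs at least 2 indicators", f)
  }
  for (out in names(regressions %||% list())) {
    if (!out %in% fnames) stop_fmt("regression outcome '%s' is not a factor",
                                   out)
    bad <- setdiff(regressions[[out]], fnames)
    if (length(bad)) stop_fmt("unknown predictor(s): %s",
                              paste(bad, collapse = ", "))
  }
  for (pr in error_cov %||% list()) {
    if (length(pr) != 2 || !all(pr %in% observed))
      stop_fmt("error_cov entries must pair two observed variables")
  }
  for (pr in factor_cov %||% list()) {
    if (length(pr) != 2 || !all(pr %in% fnames))
      stop_fmt("factor_cov entries must pair two factors")
  }
  spec <- structure(
    list(factors = factors, regressions = regressions %||% list(),
         error_cov = error_cov %||% list(),
         factor_cov = factor_cov %||% list(),
         identification = identification, observed = observed),
    class = "fm_spec")
  spec$params <- build_param_table(spec)
  spec
}

# Enumerate the free parameters (and effects-coding determined loadings).
# Order: loadings per factor, regressions, factor (co)variances, error
# variances, error covariances. FIML mean parameters are appended at fit
# time.
build_param_table <- function(spec) {
  obs <- spec$observed
  fnames <- names(spec$factors)
  rows <- list()
  add <- function(name, matrix, row, col, type, fixed_value = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, matrix = matrix, row = row, col = col, type = type,
      fixed_value = fixed_value, stringsAsFactors = FALSE)
  }
  for (f in fnames) {
    ind <- spec$factors[[f]]
    for (i in seq_along(ind)) {
      nm <- sprintf("lambda_%s_%s", f, ind[i])
      if (spec$identification == "effects") {
        type <- if (i == length(ind)) "determined" else "free"
        add(nm, "lambda", ind[i], f, type)
      } else {
        if (i == 1) add(nm, "lambda", ind[i], f, "fixed", 1)
        else add(nm, "lambda", ind[i], f, "free")
      }
    }
  }
  for (out in names(spec$regressions)) {
    for (pred in spec$regressions[[out]]) {
      add(sprintf("beta_%s_%s", out, pred), "beta", out, pred, "free")
    }
  }
  for (f in fnames) add(sprintf("psi_%s_%s", f, f), "psi", f, f, "free")
  for (pr in spec$factor_cov) {
    add(sprintf("psi_%s_%s", pr[1], pr[2]), "psi", pr[1], pr[2], "free")
  }
  for (v in obs) add(sprintf("theta_%s_%s", v, v), "theta", v, v, "free")
  for (pr in spec$error_cov) {
    add(sprintf("theta_%s_%s", pr[1], pr[2]), "theta", pr[1], pr[2], "free")
  }
  do.call(rbind, rows)
}

#' Number of free parameters of a specification
#'
#' @param spec An \code{fm_spec}.
#' @param meanstructure Count one mean parameter per observed variable
#'   (FIML fits).
#' @return Integer count.
#' @export
n_free_params <- function(spec, meanstructure = FALSE) {
  sum(spec$params$type == "free") +
    if (meanstructure) length(spec$observed) else 0L
}

# Assemble Lambda, B, Psi, Theta from the free-parameter vector.
build_matrices <- function(spec, theta) {
  obs <- spec$observed
  fnames <- names(spec$factors)
  p <- length(obs)
  m <- length(fnames)
  L <- matrix(0, p, m, dimnames = list(obs, fnames))
  B <- matrix(0, m, m, dimnames = list(fnames, fnames))
  P <- matrix(0, m, m, dimnames = list(fnames, fnames))
  Th <- matrix(0, p, p, dimnames = list(obs, obs))
  pt <- spec$params
  free_idx <- which(pt$type == "free")
  vals <- numeric(nrow(pt))
  vals[free_idx] <- theta[seq_along(free_idx)]
  vals[pt$type == "fixed"] <- pt$fixed_value[pt$type == "fixed"]
  # effects coding: determined loading = n_ind - sum(free loadings of factor)
  for (f in fnames) {
    sel <- which(pt$matrix == "lambda" & pt$col == f)
    det <- sel[pt$type[sel] == "determined"]
    if (length(det)) {
      vals[det] <- length(sel) - sum(vals[setdiff(sel, det)])
    }
  }
  for (i in seq_len(nrow(pt))) {
    v <- vals[i]
    switch(pt$matrix[i],
      lambda = { L[pt$row[i], pt$col[i]] <- v },
      beta = { B[pt$row[i], pt$col[i]] <- v },
      psi = { P[pt$row[i], pt$col[i]] <- v
              P[pt$col[i], pt$row[i]] <- v },
      theta = { Th[pt$row[i], pt$col[i]] <- v
                Th[pt$col[i], pt$row[i]] <- v })
  }
  list(Lambda = L, B = B, Psi = P, Theta = Th)
}

#' Model-implied covariance matrix
#'
#' Sigma(theta) = Lambda (I-B)^-1 Psi (I-B)^-T Lambda^T + Theta.
#'
#' @param spec An \code{fm_spec}.
#' @param parameters Named numeric vector of free parameters (names as in
#'   \code{spec$params$name}), or an unnamed vector in parameter-table
#'   order.
#' @return Covariance matrix of the observed variables.
#' @export
implied_covariance <- function(spec, parameters) {
  free_names <- spec$params$name[spec$params$type == "free"]
  if (!is.null(names(parameters))) {
    missing <- setdiff(free_names, names(parameters))
    if (length(missing))
      stop_fmt("missing parameter(s): %s",
               paste(utils::head(missing, 5), collapse = ", "))
    theta <- as.numeric(parameters[free_names])
  } else {
    if (length(parameters) != length(free_names))
      stop_fmt("expected %d parameters, got %d", length(free_names),
               length(parameters))
    theta <- as.numeric(parameters)
  }
  mats <- build_matrices(spec, theta)
  sigma_of(mats)
}

sigma_of <- function(mats) {
  m <- ncol(mats$B)
  IB <- diag(m) - mats$B
  A <- tryCatch(solve(IB), error = function(e)
    stop_fmt("(I - B) is not invertible: cyclic structural part"))
  C <- A %*% mats$Psi %*% t(A)
  S <- mats$Lambda %*% C %*% t(mats$Lambda) + mats$Theta
  (S + t(S)) / 2
}

# Latent covariance matrix (I-B)^-1 Psi (I-B)^-T
latent_cov <- function(mats) {
  m <- ncol(mats$B)
  A <- solve(diag(m) - mats$B)
  A %*% mats$Psi %*% t(A)
}

# Deterministic start values. kind: "moment", "identity", "perturbed".
start_values <- function(spec, S, ybar = NULL, kind = "moment") {
  pt <- spec$params
  free <- pt[pt$type == "free", ]
  vbar <- mean(diag(S))
  theta <- numeric(nrow(free))
  for (i in seq_len(nrow(free))) {
    theta[i] <- switch(free$matrix[i],
      lambda = 1,
      beta = 0,
      psi = {
        if (free$row[i] == free$col[i]) {
          ind <- spec$factors[[free$row[i]]]
          if (kind == "identity" || length(ind) < 2) 0.5 * vbar
          else {
            cc <- S[ind, ind]
            off <- cc[upper.tri(cc)]
            max(mean(off), 0.05 * vbar)
          }
        } else 0
      },
      theta = {
        if (free$row[i] == free$col[i]) {
          if (kind == "identity") 0.5 * vbar else 0.5 * S[free$row[i],
                                                          free$row[i]]
        } else 0
      })
  }
  if (kind == "perturbed") {
    theta[free$matrix == "lambda"] <- 1.2
    theta[free$matrix == "psi" & free$row == free$col] <-
      0.8 * theta[free$matrix == "psi" & free$row == free$col]
  }
  names(theta) <- free$name
  if (!is.null(ybar)) {
    nu <- stats::setNames(ybar, paste0("nu_", spec$observed))
    theta <- c(theta, nu)
  }
  theta
}
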