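# Maximum-likelihood estimation of covariance-structure models.
#
# Complete data minimize the normal-theory discrepancy
#   F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p          (S with divisor n)
# with analytic gradients in Lambda, B, Psi, Theta. With missing values the
# casewise (full-information) -2 loglik is minimized over the same
# parameters plus saturated means, grouped by missing pattern. Both routes
# report chi-square = (n-1) * F_implied, so they agree exactly on complete
# data; the saturated FIML loglik comes from an EM algorithm for the
# unstructured multivariate normal.

LOG2PI <- log(2 * pi)

chol_or_null <- function(S) tryCatch(chol(S), error = function(e) NULL)

# ---- complete-data objective -------------------------------------------

# Value and gradient of F at theta; returns list(value, grad) or NULL when
# Sigma is not positive definite.
ml_value_grad <- function(spec, theta, S, logdetS, want_grad = TRUE) {
  mats <- build_matrices(spec, theta)
  m <- ncol(mats$B)
  IB <- diag(m) - mats$B
  A <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(A)) return(NULL)
  C <- A %*% mats$Psi %*% t(A)
  Sigma <- mats$Lambda %*% C %*% t(mats$Lambda) + mats$Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  ch <- chol_or_null(Sigma)
  if (is.null(ch)) return(NULL)
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  p <- nrow(S)
  value <- logdet + sum(Sinv * S) - logdetS - p
  if (!want_grad) return(list(value = value))
  E <- Sinv - Sinv %*% S %*% Sinv
  grad <- map_gradient(spec, mats, A, C, E)
  list(value = value, grad = grad, Sigma = Sigma, mats = mats)
}

# Chain tr(E dSigma) onto the free parameters, honoring effects-coding
# determined loadings.
map_gradient <- function(spec, mats, A, C, E, scale = 1) {
  dimnames(E) <- dimnames(mats$Theta)
  GL <- 2 * (E %*% mats$Lambda %*% C)            # d/dLambda
  dimnames(GL) <- dimnames(mats$Lambda)
  M <- t(mats$Lambda) %*% E %*% mats$Lambda
  N <- t(A) %*% M %*% A                          # d/dPsi (full)
  dimnames(N) <- dimnames(mats$Psi)
  GB <- 2 * t(C %*% M %*% A)                     # d/dB
  dimnames(GB) <- dimnames(mats$B)
  pt <- spec$params
  free <- which(pt$type == "free")
  g <- numeric(length(free))
  for (k in seq_along(free)) {
    i <- free[k]
    g[k] <- switch(pt$matrix[i],
      lambda = {
        val <- GL[pt$row[i], pt$col[i]]
        if (spec$identification == "effects") {
          sel <- which(pt$matrix == "lambda" & pt$col == pt$col[i] &
                         pt$type == "determined")
          if (length(sel)) val <- val - GL[pt$row[sel], pt$col[sel]]
        }
        val
      },
      beta = GB[pt$row[i], pt$col[i]],
      psi = if (pt$row[i] == pt$col[i]) N[pt$row[i], pt$col[i]]
            else 2 * N[pt$row[i], pt$col[i]],
      theta = if (pt$row[i] == pt$col[i]) E[pt$row[i], pt$col[i]]
              else 2 * E[pt$row[i], pt$col[i]])
  }
  scale * g
}

# ---- FIML objective -----------------------------------------------------

# Pre-group rows of Y by missing pattern.
fiml_patterns <- function(Y) {
  pat <- apply(!is.na(Y), 1, function(r) paste(as.integer(r), collapse = ""))
  groups <- split(seq_len(nrow(Y)), pat)
  lapply(groups, function(idx) {
    obs <- which(!is.na(Y[idx[1], ]))
    if (length(obs) == 0) return(NULL)
    Yo <- Y[idx, obs, drop = FALSE]
    list(obs = obs, n = length(idx), ybar = colMeans(Yo),
         C = crossprod(Yo) / length(idx))
  })
}

# -2 loglik (and gradient) of the structured model under FIML. theta holds
# free structural parameters followed by p mean parameters.
fiml_value_grad <- function(spec, theta, patterns, p, want_grad = TRUE) {
  nfree <- sum(spec$params$type == "free")
  mu <- theta[(nfree + 1):(nfree + p)]
  mats <- build_matrices(spec, theta[seq_len(nfree)])
  m <- ncol(mats$B)
  A <- tryCatch(solve(diag(m) - mats$B), error = function(e) NULL)
  if (is.null(A)) return(NULL)
  C <- A %*% mats$Psi %*% t(A)
  Sigma <- mats$Lambda %*% C %*% t(mats$Lambda) + mats$Theta
  Sigma <- (Sigma + t(Sigma)) / 2
  val <- 0
  E <- matrix(0, p, p)
  gmu <- numeric(p)
  for (pg in patterns) {
    if (is.null(pg)) next
    o <- pg$obs
    So <- Sigma[o, o, drop = FALSE]
    ch <- chol_or_null(So)
    if (is.null(ch)) return(NULL)
    W <- chol2inv(ch)
    mo <- mu[o]
    d <- pg$ybar - mo
    Sstar <- pg$C - tcrossprod(pg$ybar, mo) - tcrossprod(mo, pg$ybar) +
      tcrossprod(mo)
    val <- val + pg$n * (length(o) * LOG2PI + 2 * sum(log(diag(ch))) +
                           sum(W * Sstar))
    if (want_grad) {
      Eo <- pg$n * (W - W %*% Sstar %*% W)
      E[o, o] <- E[o, o] + Eo
      gmu[o] <- gmu[o] - 2 * pg$n * as.numeric(W %*% d)
    }
  }
  if (!want_grad) return(list(value = val))
  g_struct <- map_gradient(spec, mats, A, C, E)
  list(value = val, grad = c(g_struct, gmu), Sigma = Sigma, mu = mu,
       mats = mats)
}

# FIML -2 loglik of an arbitrary (mu, Sigma) — used for saturated and
# baseline models.
fiml_m2ll <- function(patterns, mu, Sigma) {
  val <- 0
  for (pg in patterns) {
    if (is.null(pg)) next
    o <- pg$obs
    ch <- chol_or_null(Sigma[o, o, drop = FALSE])
    if (is.null(ch)) return(Inf)
    W <- chol2inv(ch)
    mo <- mu[o]
    Sstar <- pg$C - tcrossprod(pg$ybar, mo) - tcrossprod(mo, pg$ybar) +
      tcrossprod(mo)
    val <- val + pg$n * (length(o) * LOG2PI + 2 * sum(log(diag(ch))) +
                           sum(W * Sstar))
  }
  val
}

# EM for the unstructured multivariate normal with missing data; returns
# the saturated-model mean, covariance (divisor n) and loglik.
em_mvn <- function(Y, max_iter = 1000, tol = 1e-10) {
  n <- nrow(Y); p <- ncol(Y)
  mu <- colMeans(Y, na.rm = TRUE)
  Sigma <- stats::cov(Y, use = "pairwise.complete.obs") * (n - 1) / n
  Sigma[is.na(Sigma)] <- 0
  # ensure an admissible start
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) Sigma <- Sigma + diag(1e-6 + abs(min(ev)), p)
  patterns <- fiml_patterns(Y)
  rows_by_pat <- split(seq_len(n),
                       apply(!is.na(Y), 1,
                             function(r) paste(as.integer(r), collapse = "")))
  complete <- !anyNA(Y)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    if (complete) {
      mu <- colMeans(Y)
      Sigma <- crossprod(sweep(Y, 2, mu)) / n
      break
    }
    T1 <- numeric(p)
    T2 <- matrix(0, p, p)
    for (key in names(rows_by_pat)) {
      idx <- rows_by_pat[[key]]
      obs <- which(!is.na(Y[idx[1], ]))
      mis <- setdiff(seq_len(p), obs)
      Yo <- Y[idx, obs, drop = FALSE]
      ng <- length(idx)
      if (length(mis) == 0) {
        T1 <- T1 + colSums(Yo)
        T2[obs, obs] <- T2[obs, obs] + crossprod(Yo)
        next
      }
      if (length(obs) == 0) {
        T1[mis] <- T1[mis] + ng * mu[mis]
        T2[mis, mis] <- T2[mis, mis] + ng * (Sigma[mis, mis] +
                                               tcrossprod(mu[mis]))
        next
      }
      W <- solve(Sigma[obs, obs, drop = FALSE])
      Bmo <- Sigma[mis, obs, drop = FALSE] %*% W
      resid <- sweep(Yo, 2, mu[obs])
      Em <- matrix(mu[mis], ng, length(mis), byrow = TRUE) +
        resid %*% t(Bmo)
      Ccond <- Sigma[mis, mis, drop = FALSE] -
        Bmo %*% Sigma[obs, mis, drop = FALSE]
      T1[obs] <- T1[obs] + colSums(Yo)
      T1[mis] <- T1[mis] + colSums(Em)
      T2[obs, obs] <- T2[obs, obs] + crossprod(Yo)
      T2[obs, mis] <- T2[obs, mis] + crossprod(Yo, Em)
      T2[mis, obs] <- t(T2[obs, mis, drop = FALSE])
      T2[mis, mis] <- T2[mis, mis] + crossprod(Em) + ng * Ccond
    }
    mu <- T1 / n
    Sigma <- T2 / n - tcrossprod(mu)
    Sigma <- (Sigma + t(Sigma)) / 2
    ll <- -0.5 * fiml_m2ll(patterns, mu, Sigma)
    if (abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mu = mu, Sigma = Sigma,
       loglik = -0.5 * fiml_m2ll(patterns, mu, Sigma))
}

# ---- data preparation ---------------------------------------------------

prep_data <- function(spec, data) {
  if (is.list(data) && !is.data.frame(data) && !is.null(data$cov)) {
    S <- as.matrix(data$cov)
    if (is.null(data$n)) stop_fmt("covariance input needs n")
    miss <- setdiff(spec$observed, colnames(S))
    if (length(miss)) stop_fmt("covariance lacks variable(s): %s",
                               paste(miss, collapse = ", "))
    return(list(type = "cov", S = S[spec$observed, spec$observed],
                n = data$n))
  }
  df <- as.data.frame(data)
  if ("respondent_id" %in% names(df)) df$respondent_id <- NULL
  miss <- setdiff(spec$observed, names(df))
  if (length(miss)) stop_fmt("data lacks variable(s): %s",
                             paste(miss, collapse = ", "))
  Y <- as.matrix(df[, spec$observed, drop = FALSE])
  storage.mode(Y) <- "double"
  Y <- Y[rowSums(!is.na(Y)) > 0, , drop = FALSE]
  list(type = if (anyNA(Y)) "fiml" else "complete", Y = Y, n = nrow(Y))
}

# ---- the fitting routine ------------------------------------------------

#' Fit a factor / structural-equation model by maximum likelihood
#'
#' Complete data are fit by minimizing the normal-theory ML discrepancy;
#' data with missing values are fit by casewise full-information maximum
#' likelihood with saturated means. Optimization is quasi-Newton
#' (\code{nlminb}) with analytic gradients from up to three deterministic
#' starts (moment-based, identity-scaled, perturbed); the best converged
#' solution is kept. Heywood cases (negative variance estimates) are
#' reported, not clipped.
#'
#' @param spec An \code{\link{fm_spec}}.
#' @param data A data frame / matrix of observed variables (a
#'   \code{respondent_id} column is ignored), or \code{list(cov = S, n =
#'   n)} for covariance-only input.
#' @param se "none" (default) or "hessian" for standard errors from the
#'   inverse numerical Hessian (finite differences of the analytic
#'   gradient).
#' @param n_starts Number of deterministic starts to use (1-3).
#' @param start Optional named start vector overriding the built-in starts.
#' @param on_nonconv "error" (default) or "warn" when no start converges.
#' @param estimator "auto" (default: FIML only when values are missing),
#'   "ml" (complete data required) or "fiml" (casewise likelihood even on
#'   complete data; equals the ML route there).
#' @return A \code{fit_result}: parameter estimates (free and determined),
#'   log-likelihood, chi-square / df / p against the saturated model, CFI,
#'   RMSEA, the standardized solution, R-squared per latent outcome, and
#'   convergence diagnostics.
#' @export
fit_model <- function(spec, data, se = c("none", "hessian"), n_starts = 3,
                      start = NULL, on_nonconv = c("error", "warn"),
                      estimator = c("auto", "ml", "fiml")) {
  se <- match.arg(se)
  on_nonconv <- match.arg(on_nonconv)
  estimator <- match.arg(estimator)
  pd <- prep_data(spec, data)
  p <- length(spec$observed)
  if (pd$n <= p)
    stop_fmt("n (%d) must exceed the number of observed variables (%d)",
             pd$n, p)

  fiml <- switch(estimator,
                 auto = pd$type == "fiml",
                 ml = if (pd$type == "fiml")
                   stop_fmt("data contain missing values; use FIML")
                 else FALSE,
                 fiml = if (pd$type == "cov")
                   stop_fmt("FIML needs case-level data") else TRUE)
  if (fiml) {
    patterns <- fiml_patterns(pd$Y)
    objfun <- function(th) {
      r <- fiml_value_grad(spec, th, patterns, p, want_grad = FALSE)
      if (is.null(r)) 1e10 else r$value
    }
    gradfun <- function(th) {
      r <- fiml_value_grad(spec, th, patterns, p, want_grad = TRUE)
      if (is.null(r)) numeric(length(th)) else r$grad
    }
    Sfull <- stats::cov(pd$Y, use = "pairwise.complete.obs") *
      (pd$n - 1) / pd$n
    Sfull[is.na(Sfull)] <- 0
    ybar <- colMeans(pd$Y, na.rm = TRUE)
  } else {
    S <- if (pd$type == "cov") pd$S else crossprod(
      sweep(pd$Y, 2, colMeans(pd$Y))) / pd$n
    chS <- chol_or_null(S)
    if (is.null(chS)) stop_fmt("sample covariance is not positive definite")
    logdetS <- 2 * sum(log(diag(chS)))
    objfun <- function(th) {
      r <- ml_value_grad(spec, th, S, logdetS, want_grad = FALSE)
      if (is.null(r)) 1e10 else r$value
    }
    gradfun <- function(th) {
      r <- ml_value_grad(spec, th, S, logdetS, want_grad = TRUE)
      if (is.null(r)) numeric(length(th)) else r$grad
    }
    Sfull <- S
    ybar <- NULL
  }

  kinds <- c("moment", "identity", "perturbed")[seq_len(max(1, min(3,
                                                                n_starts)))]
  starts <- lapply(kinds, function(k)
    start_values(spec, Sfull, ybar = if (fiml) ybar else NULL, kind = k))
  if (!is.null(start)) starts <- c(list(start), starts)

  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::nlminb(as.numeric(s), objfun, gradient = gradfun,
                    control = list(iter.max = 1000, eval.max = 2000,
                                   rel.tol = 1e-12)),
      error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, TRUE)
  fits <- fits[ok]
  if (!length(fits)) stop_fmt("all optimizer starts failed")
  conv <- vapply(fits, function(f) {
    f$convergence == 0 ||
      max(abs(gradfun(f$par))) < 1e-4 * max(1, abs(f$objective))
  }, TRUE)
  vals <- vapply(fits, function(f) f$objective, 0)
  pick <- if (any(conv)) which(conv)[which.min(vals[conv])] else
    which.min(vals)
  best <- fits[[pick]]
  # nlminb's code 7 ("singular convergence") fires at flat optima; accept
  # any solution whose scaled gradient is numerically zero
  grad_at_best <- gradfun(best$par)
  converged <- best$convergence == 0 ||
    max(abs(grad_at_best)) < 1e-4 * max(1, abs(best$objective))
  if (!converged) {
    msg <- sprintf("no start converged (best message: %s)", best$message)
    if (on_nonconv == "error") stop_fmt("%s", msg) else warning(msg,
                                                                call. = FALSE)
  }

  theta <- best$par
  nfree_struct <- sum(spec$params$type == "free")
  theta_struct <- theta[seq_len(nfree_struct)]
  mats <- build_matrices(spec, theta_struct)
  Sigma_hat <- sigma_of(mats)
  n <- pd$n

  if (fiml) {
    sat <- em_mvn(pd$Y)
    ll_model <- -0.5 * best$objective
    ll_sat <- sat$loglik
    Fmin <- 2 * (ll_sat - ll_model) / n
    # baseline: independent normals, free means and variances
    ll_base <- 0
    for (j in seq_len(p)) {
      yj <- pd$Y[, j]
      yj <- yj[!is.na(yj)]
      vj <- mean((yj - mean(yj))^2)
      ll_base <- ll_base + sum(stats::dnorm(yj, mean(yj), sqrt(vj),
                                            log = TRUE))
    }
    F_base <- 2 * (ll_sat - ll_base) / n
    mu_hat <- theta[(nfree_struct + 1):(nfree_struct + p)]
    npar <- nfree_struct + p
    n_moments <- p * (p + 1) / 2 + p
  } else {
    Fmin <- best$objective
    ll_sat <- -n / 2 * (logdetS + p + p * LOG2PI)
    ll_model <- ll_sat - n / 2 * Fmin
    R <- stats::cov2cor(Sfull)
    F_base <- -determinant(R, logarithm = TRUE)$modulus[1]
    mu_hat <- NULL
    npar <- nfree_struct
    n_moments <- p * (p + 1) / 2
  }

  df <- n_moments - npar
  chisq <- max((n - 1) * Fmin, 0)
  chisq_base <- max((n - 1) * F_base, 0)
  df_base <- p * (p - 1) / 2
  p_chisq <- if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE)
  else NA_real_
  cfi <- if (df == 0) 1 else {
    num <- max(chisq - df, 0)
    den <- max(chisq_base - df_base, chisq - df, 0)
    if (den == 0) 1 else clip(1 - num / den, 0, 1)
  }
  rmsea <- if (df == 0) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))

  est <- param_estimates(spec, theta_struct)
  Cl <- latent_cov(mats)
  std <- standardized_solution(spec, mats, Sigma_hat, Cl)
  heywood <- c(
    names(which(diag(mats$Theta) < 0)),
    names(which(diag(mats$Psi) < 0)))

  fit <- structure(list(
    spec = spec, estimates = est, theta = theta, loglik = ll_model,
    loglik_sat = ll_sat, npar = npar, df = df, chisq = chisq, p = p_chisq,
    cfi = cfi, rmsea = rmsea, n = n, fiml = fiml,
    Sigma = Sigma_hat, mu = mu_hat, mats = mats, latent_cov = Cl,
    standardized = std$table, r_squared = std$r_squared,
    converged = converged, objective = best$objective,
    heywood = heywood, start_used = pick), class = "fit_result")

  if (se == "hessian") fit <- add_hessian_se(fit, objfun, gradfun)
  fit
}

# Full parameter table (free, determined and fixed) with estimates.
param_estimates <- function(spec, theta_struct) {
  pt <- spec$params
  vals <- numeric(nrow(pt))
  vals[pt$type == "free"] <- theta_struct
  vals[pt$type == "fixed"] <- pt$fixed_value[pt$type == "fixed"]
  for (f in names(spec$factors)) {
    sel <- which(pt$matrix == "lambda" & pt$col == f)
    det <- sel[pt$type[sel] == "determined"]
    if (length(det)) vals[det] <- length(sel) - sum(vals[setdiff(sel, det)])
  }
  data.frame(pt[, c("name", "matrix", "row", "col", "type")],
             est = vals, stringsAsFactors = FALSE)
}

standardized_solution <- function(spec, mats, Sigma, Cl) {
  sd_lat <- sqrt(pmax(diag(Cl), 0))
  sd_obs <- sqrt(pmax(diag(Sigma), 0))
  names(sd_lat) <- colnames(mats$Psi)
  names(sd_obs) <- rownames(mats$Lambda)
  rows <- list()
  for (f in colnames(mats$Lambda)) {
    for (v in spec$factors[[f]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "loading", outcome = v, predictor = f,
        std = mats$Lambda[v, f] * sd_lat[f] / sd_obs[v],
        stringsAsFactors = FALSE)
    }
  }
  r2 <- stats::setNames(numeric(0), character(0))
  for (out in names(spec$regressions)) {
    for (pred in spec$regressions[[out]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "gamma", outcome = out, predictor = pred,
        std = mats$B[out, pred] * sd_lat[pred] / sd_lat[out],
        stringsAsFactors = FALSE)
    }
    r2[out] <- 1 - mats$Psi[out, out] / Cl[out, out]
  }
  list(table = do.call(rbind, rows), r_squared = r2)
}

# Standard errors from the inverse numerical Hessian (central finite
# differences of the analytic gradient), with delta-method SEs for the
# effects-coding determined loadings.
add_hessian_se <- function(fit, objfun, gradfun) {
  theta <- fit$theta
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (gradfun(tp) - gradfun(tm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  info <- if (fit$fiml) H / 2 else (fit$n - 1) / 2 * H
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(V)) {
    warning("information matrix is singular; no standard errors",
            call. = FALSE)
    return(fit)
  }
  se_free <- sqrt(pmax(diag(V), 0))
  pt <- fit$spec$params
  free_names <- pt$name[pt$type == "free"]
  se_all <- rep(NA_real_, nrow(pt))
  se_all[pt$type == "free"] <- se_free[seq_along(free_names)]
  for (f in names(fit$spec$factors)) {
    sel <- which(pt$matrix == "lambda" & pt$col == f)
    det <- sel[pt$type[sel] == "determined"]
    if (length(det)) {
      fr <- intersect(setdiff(sel, det), which(pt$type == "free"))
      idx <- match(pt$name[fr], free_names)
      se_all[det] <- sqrt(max(sum(V[idx, idx]), 0))
    }
  }
  fit$estimates$se <- se_all
  fit$vcov <- V
  fit$vcov_names <- free_names
  fit
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: %d observed, %d free parameters, n = %d%s\n",
              length(x$spec$observed), x$npar, x$n,
              if (x$fiml) " (FIML)" else ""))
  cat(sprintf("chisq(%d) = %.3f, p = %.4g, CFI = %.3f, RMSEA = %.3f\n",
              x$df, x$chisq, x$p, x$cfi, x$rmsea))
  cat(sprintf("loglik = %.3f, converged: %s\n", x$loglik, x$converged))
  if (length(x$heywood))
    cat("Heywood case(s):", paste(x$heywood, collapse = ", "), "\n")
  if (length(x$r_squared))
    cat("R-squared:", paste(sprintf("%s = %.3f", names(x$r_squared),
                                    x$r_squared), collapse = ", "), "\n")
  invisible(x)
}

#' Extract a named parameter estimate
#'
#' @param fit A \code{fit_result}.
#' @param name Parameter name as in the specification's parameter table.
#' @return The estimate.
#' @export
coef_of <- function(fit, name) {
  i <- match(name, fit$estimates$name)
  if (is.na(i)) stop_fmt("no parameter named '%s'", name)
  fit$estimates$est[i]
}

#' Standardized structural weight
#'
#' @param fit A \code{fit_result}.
#' @param outcome,predictor Latent variable names.
#' @return The fully standardized regression weight.
#' @export
gamma_std <- function(fit, outcome, predictor) {
  s <- fit$standardized
  i <- which(s$type == "gamma" & s$outcome == outcome &
               s$predictor == predictor)
  if (!length(i)) stop_fmt("no gamma %s ~ %s", outcome, predictor)
  s$std[i]
}
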