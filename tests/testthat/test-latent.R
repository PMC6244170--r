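# The ML/FIML covariance-structure engine: implied covariance algebra,
# estimation, fit indices, reliability, LRTs and bootstrap.

two_factor_spec <- function() {
  fm_spec(
    factors = list(f1 = c("y1", "y2", "y3"), f2 = c("y4", "y5", "y6")),
    regressions = list(f2 = "f1"),
    error_cov = list(c("y1", "y4")))
}

random_params <- function(spec, seed) {
  set.seed(seed)
  pt <- spec$params
  free <- pt[pt$type == "free", ]
  v <- numeric(nrow(free))
  for (i in seq_len(nrow(free))) {
    v[i] <- switch(free$matrix[i],
      lambda = stats::runif(1, 0.6, 1.4),
      beta = stats::runif(1, -0.5, 0.5),
      psi = if (free$row[i] == free$col[i]) stats::runif(1, 0.4, 1)
            else stats::runif(1, -0.2, 0.2),
      theta = if (free$row[i] == free$col[i]) stats::runif(1, 0.4, 1)
              else stats::runif(1, -0.1, 0.1))
  }
  stats::setNames(v, free$name)
}

test_that("implied covariance matches hand algebra and a naive oracle", {
  # single factor, loadings (1,1,1), phi = 1, theta = I
  spec <- fm_spec(list(f = c("y1", "y2", "y3")))
  theta <- c(lambda_f_y1 = 1, lambda_f_y2 = 1, psi_f_f = 1,
             theta_y1_y1 = 1, theta_y2_y2 = 1, theta_y3_y3 = 1)
  S <- implied_covariance(spec, theta)
  expect_equal(unname(diag(S)), rep(2, 3))
  expect_equal(unname(S[lower.tri(S)]), rep(1, 3))
  # null model: loadings 0 leaves Sigma = Theta
  theta0 <- theta
  theta0[c("lambda_f_y1", "lambda_f_y2")] <- 0
  # effects coding fixes the determined loading to 3 - 0 - 0 = 3; use a
  # marker spec to express an all-zero loading pattern instead
  spec_m <- fm_spec(list(f = c("y1", "y2", "y3")), identification = "marker")
  mats <- fakability:::build_matrices(
    spec_m, c(lambda_f_y2 = 0, lambda_f_y3 = 0, psi_f_f = 0,
              theta_y1_y1 = 0.7, theta_y2_y2 = 0.8, theta_y3_y3 = 0.9))
  S0 <- fakability:::sigma_of(mats)
  expect_equal(unname(diag(S0)), c(0.7, 0.8, 0.9))
  expect_equal(max(abs(S0[lower.tri(S0)])), 0)
  # random admissible parameters against the element-wise loop oracle
  spec2 <- two_factor_spec()
  for (seed in 1:5) {
    v <- random_params(spec2, seed)
    S2 <- implied_covariance(spec2, v)
    m <- fakability:::build_matrices(spec2, as.numeric(v))
    expect_equal(S2, naive_sigma(m$Lambda, m$B, m$Psi, m$Theta),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("analytic gradients agree with central finite differences", {
  spec <- two_factor_spec()
  v <- random_params(spec, 42)
  set.seed(1)
  Struth <- implied_covariance(spec, v)
  Y <- rmvn(300, Struth)
  colnames(Y) <- spec$observed
  S <- crossprod(sweep(Y, 2, colMeans(Y))) / nrow(Y)
  logdetS <- as.numeric(determinant(S)$modulus)
  th0 <- as.numeric(v) * 0.9
  r <- fakability:::ml_value_grad(spec, th0, S, logdetS)
  num <- vapply(seq_along(th0), function(j) {
    h <- 1e-6
    tp <- th0; tp[j] <- tp[j] + h
    tm <- th0; tm[j] <- tm[j] - h
    (fakability:::ml_value_grad(spec, tp, S, logdetS, FALSE)$value -
       fakability:::ml_value_grad(spec, tm, S, logdetS, FALSE)$value) /
      (2 * h)
  }, 0)
  expect_lt(max(abs(r$grad - num)), 1e-6)
  # FIML gradient, with a missing block
  Y[1:40, 2] <- NA
  pats <- fakability:::fiml_patterns(Y)
  thF <- c(th0, colMeans(Y, na.rm = TRUE))
  rf <- fakability:::fiml_value_grad(spec, thF, pats, ncol(Y))
  numF <- vapply(seq_along(thF), function(j) {
    h <- 1e-5
    tp <- thF; tp[j] <- tp[j] + h
    tm <- thF; tm[j] <- tm[j] - h
    (fakability:::fiml_value_grad(spec, tp, pats, ncol(Y), FALSE)$value -
       fakability:::fiml_value_grad(spec, tm, pats, ncol(Y), FALSE)$value) /
      (2 * h)
  }, 0)
  expect_lt(max(abs(rf$grad - numF)), 1e-3)
})

test_that("a just-identified model fits perfectly", {
  set.seed(2)
  Y <- single_factor_data(200, c(1, 1.1, 0.9), 0.8, c(0.5, 0.5, 0.5))
  fit <- fit_model(fm_spec(list(f = c("y1", "y2", "y3"))), Y)
  expect_equal(fit$df, 0)
  expect_lt(fit$chisq, 1e-6)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$rmsea, 0)
})

test_that("effects coding holds: loadings of each factor average one", {
  set.seed(3)
  Y <- single_factor_data(500, c(0.7, 1.2, 1.0, 1.1), 0.9,
                          rep(0.5, 4))
  spec <- fm_spec(list(f = paste0("y", 1:4)))
  fit <- fit_model(spec, Y)
  lam <- fit$estimates$est[fit$estimates$matrix == "lambda"]
  expect_equal(sum(lam), 4, tolerance = 1e-8)
})

test_that("single-factor parameter recovery attains nominal CI coverage", {
  lam <- c(0.9, 1.0, 1.1, 1.0)   # satisfies the effects-coding constraint
  phi <- 0.8
  th <- c(0.5, 0.6, 0.4, 0.5)
  spec <- fm_spec(list(f = paste0("y", 1:4)))
  free_lam <- paste0("lambda_f_y", 1:3)
  truth <- c(lam[1:3], phi, th)
  names(truth) <- c(free_lam, "psi_f_f", paste0("theta_y", 1:4, "_y", 1:4))
  set.seed(1234)
  hits <- 0L; total <- 0L
  for (rep in 1:100) {
    Y <- single_factor_data(5000, lam, phi, th)
    fit <- fit_model(spec, Y, se = "hessian", n_starts = 1)
    est <- fit$estimates
    for (nm in names(truth)) {
      i <- match(nm, est$name)
      ci <- est$est[i] + c(-1, 1) * 1.96 * est$se[i]
      hits <- hits + (truth[nm] >= ci[1] && truth[nm] <= ci[2])
      total <- total + 1L
    }
  }
  expect_gt(hits / total, 0.90)
})

test_that("a free error covariance is recovered from its generating value", {
  # six-indicator single factor with one error covariance, as in the
  # shape measurement model
  spec <- fm_spec(list(f = paste0("y", 1:6)),
                  error_cov = list(c("y5", "y6")))
  truth <- c(stats::setNames(rep(1, 5), paste0("lambda_f_y", 1:5)),
             psi_f_f = 0.5,
             stats::setNames(rep(0.6, 6), paste0("theta_y", 1:6, "_y", 1:6)),
             theta_y5_y6 = 0.15)
  Struth <- implied_covariance(spec, truth)
  set.seed(21)
  Y <- rmvn(20000, Struth)
  colnames(Y) <- spec$observed
  fit <- fit_model(spec, Y)
  expect_lt(abs(coef_of(fit, "theta_y5_y6") - 0.15), 0.02)
  expect_lt(abs(coef_of(fit, "psi_f_f") - 0.5), 0.03)
})

test_that("FIML equals complete-data ML when nothing is missing", {
  set.seed(6)
  Y <- single_factor_data(400, c(1, 1, 1, 1), 0.7, rep(0.5, 4))
  spec <- fm_spec(list(f = paste0("y", 1:4)))
  f_ml <- fit_model(spec, Y, estimator = "ml")
  f_fi <- fit_model(spec, Y, estimator = "fiml")
  expect_lt(abs(f_ml$chisq - f_fi$chisq), 1e-4)
  expect_lt(abs(f_ml$loglik - f_fi$loglik), 1e-6)
  expect_lt(max(abs(f_ml$estimates$est - f_fi$estimates$est)), 1e-5)
  expect_equal(f_ml$cfi, f_fi$cfi, tolerance = 1e-6)
  expect_equal(f_ml$rmsea, f_fi$rmsea, tolerance = 1e-6)
})

test_that("FIML recovers parameters under random missingness", {
  lam <- c(0.9, 1.0, 1.1, 1.0)
  spec <- fm_spec(list(f = paste0("y", 1:4)))
  set.seed(8)
  Y <- single_factor_data(3000, lam, 0.8, rep(0.5, 4))
  mask <- matrix(stats::runif(length(Y)) < 0.15, nrow(Y))
  Ymiss <- Y
  Ymiss[mask] <- NA
  fit <- fit_model(spec, Ymiss)
  expect_true(fit$fiml)
  expect_true(fit$converged)
  expect_equal(coef_of(fit, "psi_f_f"), 0.8, tolerance = 0.08)
  expect_equal(coef_of(fit, "lambda_f_y1"), 0.9, tolerance = 0.06)
  expect_true(is.finite(fit$cfi) && fit$cfi >= 0 && fit$cfi <= 1)
  expect_gte(fit$rmsea, 0)
})

test_that("McDonald's omega matches the closed formula", {
  # lambda = (1,1,1,1), phi = 1, theta = I: omega = 16/20 = 0.8
  mk_fit <- function(lam, phi, Th) {
    p <- length(lam)
    obs <- paste0("y", seq_len(p))
    list(spec = list(factors = list(f = obs)),
         mats = list(Lambda = matrix(lam, p, 1,
                                     dimnames = list(obs, "f")),
                     Theta = matrix(Th, p, p, dimnames = list(obs, obs))),
         latent_cov = matrix(phi, 1, 1, dimnames = list("f", "f")))
  }
  f1 <- mk_fit(rep(1, 4), 1, diag(4))
  expect_equal(mcdonald_omega(f1, "f"), 0.8)
  # errors shrink to zero: omega approaches 1
  f2 <- mk_fit(rep(1, 4), 1, diag(1e-12, 4))
  expect_equal(mcdonald_omega(f2, "f"), 1, tolerance = 1e-10)
  # random admissible parameters vs an independently coded formula
  set.seed(10)
  for (i in 1:10) {
    p <- sample(3:7, 1)
    lam <- stats::runif(p, 0.5, 1.5)
    phi <- stats::runif(1, 0.3, 1.2)
    Th <- diag(stats::runif(p, 0.3, 1))
    Th[1, 2] <- Th[2, 1] <- stats::runif(1, 0, 0.2)
    num <- 0
    for (a in 1:p) for (b in 1:p) num <- num + lam[a] * lam[b] * phi
    den <- num
    for (a in 1:p) for (b in 1:p) den <- den + Th[a, b]
    expect_equal(mcdonald_omega(mk_fit(lam, phi, Th), "f"), num / den,
                 tolerance = 1e-12)
  }
  # inadmissible denominator errors
  f3 <- mk_fit(rep(1, 3), 0.1, diag(-2, 3))
  expect_error(mcdonald_omega(f3, "f"), "inadmissible")
})

test_that("likelihood ratio tests apply the boundary adjustment", {
  full <- list(loglik = -100, npar = 10)
  restr <- list(loglik = -100, npar = 9)
  expect_equal(boundary_lrt(full, restr)$p, 1)
  expect_equal(boundary_lrt(full, restr, boundary = TRUE)$p, 1)
  # chi-square(1) critical value
  full2 <- list(loglik = -100, npar = 10)
  restr2 <- list(loglik = -100 - 3.841 / 2, npar = 9)
  expect_equal(boundary_lrt(full2, restr2)$p, 0.05, tolerance = 1e-3)
  # boundary halves the tail probability
  expect_equal(boundary_lrt(full2, restr2, boundary = TRUE)$p, 0.025,
               tolerance = 1e-3)
  # fractional-df variant is smaller still
  pf <- boundary_lrt(full2, restr2, boundary = TRUE,
                     method = "fractional")$p
  expect_lt(pf, 0.025)
  # negative statistics indicate broken nesting
  expect_error(boundary_lrt(list(loglik = -105, npar = 10), restr, df = 1),
               "nested|converge")
})

test_that("bootstrap intervals are reproducible and respect fixed parameters", {
  set.seed(14)
  Y <- single_factor_data(150, c(1, 1, 1, 1), 0.7, rep(0.5, 4))
  spec <- fm_spec(list(f = paste0("y", 1:4)), identification = "marker")
  b1 <- bootstrap_ci(spec, Y, draws = 60, seed = 99)
  b2 <- bootstrap_ci(spec, Y, draws = 60, seed = 99)
  expect_identical(b1$ci, b2$ci)
  # the fixed marker loading never varies: interval width exactly zero
  i <- match("lambda_f_y1", b1$ci$name)
  expect_equal(b1$ci$lower[i], 1)
  expect_equal(b1$ci$upper[i], 1)
  # free parameters have positive width
  j <- match("psi_f_f", b1$ci$name)
  expect_gt(b1$ci$upper[j] - b1$ci$lower[j], 0)
})

test_that("the model zoo carries the published topologies", {
  zoo <- builtin_model_zoo()
  expect_named(zoo, c("elevation_final", "shape_final", "two_factor",
                      "cognitive_bifactor", "sem1", "sem2"))
  # the elevation model drops the anchor-instrument pilot indicator
  expect_length(zoo$elevation_final$factors$elevation, 5)
  expect_false("e_wsq_pilot" %in% zoo$elevation_final$factors$elevation)
  expect_length(zoo$shape_final$factors$shape, 6)
  # fluid parcels load on g only
  bf <- zoo$cognitive_bifactor
  expect_true(all(paste0("gf_", 1:3) %in% bf$factors$g))
  expect_false(any(paste0("gf_", 1:3) %in% c(bf$factors$gc,
                                             bf$factors$ep)))
  # predictors are orthogonal: no free psi covariances in the SEMs
  for (s in list(zoo$sem1, zoo$sem2, zoo$cognitive_bifactor)) {
    pt <- s$params
    off <- pt[pt$matrix == "psi" & pt$row != pt$col, ]
    expect_equal(nrow(off), 0)
  }
  # the two-factor model frees exactly the elevation-shape covariance
  pt2 <- zoo$two_factor$params
  off2 <- pt2[pt2$matrix == "psi" & pt2$row != pt2$col, ]
  expect_equal(nrow(off2), 1)
  # both final models free the anchor tour-guide / TV error covariance
  expect_true("theta_s_wsq_tour_guide_s_wsq_tv_radio_announcer" %in%
                zoo$shape_final$params$name)
  expect_true("theta_e_wsq_tour_guide_e_wsq_tv_radio_announcer" %in%
                zoo$elevation_final$params$name)
})

test_that("orthogonal-predictor SEMs satisfy R-squared = sum of squared gammas", {
  zoo <- builtin_model_zoo()
  spec <- zoo$sem2
  truth <- stats::setNames(numeric(sum(spec$params$type == "free")),
                           spec$params$name[spec$params$type == "free"])
  truth[grep("^lambda", names(truth))] <- 1
  truth[c("psi_g_g", "psi_gc_gc", "psi_ep_ep")] <- 0.3
  truth["psi_shape_shape"] <- 0.3 * (1 - 0.393)
  truth[grep("^theta_.*", names(truth))] <- 0.5
  truth["theta_s_wsq_tour_guide_s_wsq_tv_radio_announcer"] <- 0.1
  truth[c("beta_shape_g", "beta_shape_gc", "beta_shape_ep")] <-
    c(0.218, 0.495, 0.316)
  Struth <- implied_covariance(spec, truth)
  set.seed(33)
  Y <- rmvn(500, Struth)
  colnames(Y) <- spec$observed
  fit <- fit_model(spec, Y)
  g <- vapply(c("g", "gc", "ep"), function(p) gamma_std(fit, "shape", p), 0)
  expect_equal(unname(fit$r_squared["shape"]), sum(g^2), tolerance = 1e-8)
  # standardized gammas equal the model-implied latent correlations
  Cl <- fit$latent_cov
  D <- diag(1 / sqrt(diag(Cl)))
  Rl <- D %*% Cl %*% D
  dimnames(Rl) <- dimnames(Cl)
  for (p in c("g", "gc", "ep"))
    expect_equal(unname(g[p]), Rl["shape", p], tolerance = 1e-8)
})
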