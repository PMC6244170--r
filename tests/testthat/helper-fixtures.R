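# Shared fixtures and independent oracles. Studies are generated once per
# test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_env)) assign(key, fn(),
                                                 envir = .fixture_env)
  get(key, envir = .fixture_env)
}

default_study <- function() {
  memo("default_study", function() simulate_study(population_spec(seed = 303)))
}

# large filtered-free study for generator-fidelity and end-to-end recovery
big_study <- function() {
  memo("big_study", function()
    simulate_study(population_spec(n_respondents = 2000,
                                   n_attention_fail = 0, seed = 904)))
}

scored_big_study <- function() {
  memo("scored_big_study", function() {
    st <- big_study()
    tasks <- study_tasks(st)
    resp <- lapply(st$faked, rescale_responses)
    score_battery(resp, tasks)
  })
}

# MVN sampler via Cholesky (no extra dependencies)
rmvn <- function(n, Sigma, mu = rep(0, ncol(Sigma))) {
  L <- chol(Sigma)
  sweep(matrix(stats::rnorm(n * ncol(Sigma)), n) %*% L, 2, -mu)
}

# Independent implied-covariance oracle: element-wise loops, no shared code
# with the engine's matrix path.
naive_sigma <- function(L, B, P, Th) {
  m <- ncol(L)
  p <- nrow(L)
  A <- solve(diag(m) - B)
  C <- matrix(0, m, m)
  for (i in 1:m) for (j in 1:m)
    for (k in 1:m) for (l in 1:m)
      C[i, j] <- C[i, j] + A[i, k] * P[k, l] * A[j, l]
  S <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    for (k in 1:m) for (l in 1:m)
      S[i, j] <- S[i, j] + L[i, k] * C[k, l] * L[j, l]
    S[i, j] <- S[i, j] + Th[i, j]
  }
  S
}

# Independent ML fit: naive discrepancy + restarted Nelder-Mead, never the
# engine's gradient path.
naive_ml_fit <- function(spec, S, start, restarts = 6) {
  p <- nrow(S)
  obj <- function(th) {
    mats <- fakability:::build_matrices(spec, th)
    Sig <- naive_sigma(mats$Lambda, mats$B, mats$Psi, mats$Theta)
    ev <- tryCatch(eigen(Sig, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (min(ev) <= 1e-10) return(1e10)
    as.numeric(determinant(Sig)$modulus) + sum(solve(Sig) * S) -
      as.numeric(determinant(S)$modulus) - p
  }
  best <- list(par = start, value = obj(start))
  cur <- start
  for (r in seq_len(max(restarts, 12))) {
    o <- stats::optim(cur, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-15))
    improved <- o$value < best$value - 1e-13
    if (o$value < best$value) best <- o
    cur <- best$par
    if (r > 2 && !improved) break
  }
  best
}

# data generated from a single-factor model
single_factor_data <- function(n, lam, phi, th, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- stats::rnorm(n, 0, sqrt(phi))
  Y <- vapply(seq_along(lam), function(j)
    lam[j] * f + stats::rnorm(n, 0, sqrt(th[j])), numeric(n))
  colnames(Y) <- paste0("y", seq_along(lam))
  Y
}

# brute-force Pearson correlation from sums (hand-formula oracle)
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
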