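#' Fisher r-to-z test of the difference between two correlations
#'
#' Tests whether two correlations differ, treating them as coming from
#' independent samples of common size \code{n}. Both correlations are mapped
#' through Fisher's variance-stabilizing transform \code{atanh} and the
#' difference is referred to a standard normal. Standardized regression
#' weights of mutually orthogonal latent predictors can be interpreted as
#' correlations and compared with this test.
#'
#' A dependent-correlations variant (\code{method = "dependent"}) applies the
#' Steiger adjustment for two correlations sharing a variable, given their
#' inter-correlation \code{r12}. The independent formula is the default.
#'
#' @param r1,r2 Correlations in (-1, 1).
#' @param n Common sample size (>= 4).
#' @param method "independent" (default) or "dependent".
#' @param r12 Correlation between the two variables being compared
#'   (only used by the dependent variant; default 0).
#' @return An object of class \code{corr_diff} with fields \code{r1},
#'   \code{r2}, \code{r_diff}, \code{n}, \code{z}, \code{p_one_tailed},
#'   \code{p_two_tailed}.
#' @examples
#' fisher_z_diff(0.495, -0.069, n = 210)
#' @export
fisher_z_diff <- function(r1, r2, n, method = c("independent", "dependent"),
                          r12 = 0) {
  method <- match.arg(method)
  if (any(abs(c(r1, r2)) >= 1)) {
    stop_fmt("correlations must lie strictly inside (-1, 1); got r1 = %g, r2 = %g",
             r1, r2)
  }
  if (n < 4) stop_fmt("n must be at least 4 (got %g)", n)
  dz <- atanh(r1) - atanh(r2)
  if (method == "independent") {
    se <- sqrt(2 / (n - 3))
  } else {
    # Steiger's modification: shrink the variance of the difference by the
    # covariance induced by the shared variable.
    rbar <- (r1 + r2) / 2
    cov_term <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
      (1 - 2 * rbar^2 - r12^2)
    h <- cov_term / (1 - rbar^2)^2
    se <- sqrt((2 - 2 * h) / (n - 3))
  }
  z <- dz / se
  structure(
    list(r1 = r1, r2 = r2, r_diff = r1 - r2, n = n, z = z,
         p_one_tailed = stats::pnorm(z, lower.tail = FALSE),
         p_two_tailed = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
         method = method),
    class = "corr_diff"
  )
}

#' @export
print.corr_diff <- function(x, ...) {
  cat(sprintf("r1 = %.3f, r2 = %.3f, r_diff = %.3f (n = %d)\n",
              x$r1, x$r2, x$r_diff, as.integer(x$n)))
  cat(sprintf("z = %.3f, one-tailed p = %.4g, two-tailed p = %.4g [%s]\n",
              x$z, x$p_one_tailed, x$p_two_tailed, x$method))
  invisible(x)
}

#' Power of the test that a correlation is zero
#'
#' Approximate power for H0: rho = 0 against a true correlation \code{r},
#' using the Fisher-z normal approximation.
#'
#' @param r True correlation effect size, 0 < r < 1.
#' @param n Sample size (>= 4).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
power_r <- function(r, n, alpha = 0.05, tails = 2) {
  stopifnot(r > 0, r < 1, n >= 4, alpha > 0, alpha < 1, tails %in% c(1, 2))
  z_crit <- stats::qnorm(1 - alpha / tails)
  stats::pnorm(atanh(r) * sqrt(n - 3) - z_crit)
}

#' Minimal detectable correlation at given power
#'
#' Inverts \code{\link{power_r}} under the Fisher approximation:
#' r = tanh((z_crit + z_power) / sqrt(n - 3)).
#'
#' @inheritParams power_r
#' @param power Target power, must exceed \code{alpha}.
#' @return The smallest correlation detectable with the requested power.
#' @examples
#' sensitivity_r(n = 210, alpha = 0.05, power = 0.80)
#' @export
sensitivity_r <- function(n, alpha = 0.05, power = 0.80, tails = 2) {
  stopifnot(n >= 4, alpha > 0, alpha < 1, tails %in% c(1, 2))
  if (power <= alpha) stop_fmt("power (%g) must exceed alpha (%g)", power, alpha)
  z_crit <- stats::qnorm(1 - alpha / tails)
  z_pow <- stats::qnorm(power)
  tanh((z_crit + z_pow) / sqrt(n - 3))
}
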