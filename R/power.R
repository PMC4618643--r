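#' Analytic power of the two one-sided tests (TOST) procedure
#'
#' Power to conclude equivalence for a within-subject crossover comparison
#' of a log-normal parameter: both one-sided size-`alpha` t-tests of the log
#' geometric-mean ratio against the log equivalence limits must reject. The
#' standard error of the log-ratio is `sigma_w * sqrt(2/n)` with `n - 2`
#' degrees of freedom (the crossover mixed-model convention). The exact
#' bivariate acceptance probability is evaluated by integrating the normal
#' rejection probability over the chi-squared distribution of the variance
#' estimate (equivalent to Owen's Q function).
#'
#' @param n Number of evaluable subjects (>= 3).
#' @param sigma_w Within-subject SD of the log parameter (>= 0). The limit
#'   `sigma_w = 0` gives power 1 strictly inside the limits, else 0.
#' @param limits Equivalence limits on the ratio scale, `0 < lower < 1 <
#'   upper` (default `c(0.8, 1.25)`).
#' @param alpha One-sided significance level of each test (default 0.05,
#'   i.e. a 90% CI).
#' @param true_ratio True geometric mean ratio (default 1).
#' @return Power, a number in \[0, 1\].
#' @examples
#' tost_power_analytic(n = 24, sigma_w = 0.2171)
#' @export
tost_power_analytic <- function(n, sigma_w, limits = c(0.8, 1.25),
                                alpha = 0.05, true_ratio = 1) {
  check_power_spec(n, sigma_w, limits, alpha, true_ratio)
  theta <- log(true_ratio)
  lo <- log(limits[1]); hi <- log(limits[2])
  if (sigma_w == 0) {
    return(as.numeric(theta > lo && theta < hi))
  }
  se <- sigma_w * sqrt(2 / n)
  df <- n - 2
  tcrit <- qt(1 - alpha, df)
  integrand <- function(x) {
    scale <- sqrt(x / df)
    dchisq(x, df) * pmax(
      0,
      pnorm((hi - theta) / se - tcrit * scale) -
        pnorm((lo - theta) / se + tcrit * scale)
    )
  }
  integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
}

#' Simulated power of the TOST procedure
#'
#' Monte-Carlo twin of [tost_power_analytic()]: each replicate draws `n`
#' paired within-subject log-differences from
#' `N(log(true_ratio), 2 sigma_w^2)`, forms the `1 - 2 alpha` two-sided CI
#' from the paired t contrast (the same estimator [ls_mean_ratio()] applies
#' to a one-pattern crossover, vectorized across replicates), and counts the
#' replicates whose CI lies inside the limits.
#'
#' @inheritParams tost_power_analytic
#' @param n_reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Optional integer seed.
#' @return One-row tibble: `power`, `mc_se` (binomial Monte-Carlo standard
#'   error), `n_reps`.
#' @examples
#' tost_power_simulated(n = 24, sigma_w = 0.2171, n_reps = 2000, seed = 1)
#' @export
tost_power_simulated <- function(n, sigma_w, limits = c(0.8, 1.25),
                                 alpha = 0.05, true_ratio = 1,
                                 n_reps = 10000, seed = NULL) {
  check_power_spec(n, sigma_w, limits, alpha, true_ratio)
  if (n_reps < 100) abort("`n_reps` must be >= 100.")
  if (!is.null(seed)) set.seed(seed)
  theta <- log(true_ratio)
  d <- matrix(rnorm(n * n_reps, theta, sqrt(2) * sigma_w), nrow = n)
  est <- colMeans(d)
  s <- sqrt(colSums((d - rep(est, each = n))^2) / (n - 1))
  half <- qt(1 - alpha, n - 1) * s / sqrt(n)
  ok <- (est - half) >= log(limits[1]) & (est + half) <= log(limits[2])
  p <- mean(ok)
  tibble::tibble(power = p, mc_se = sqrt(p * (1 - p) / n_reps),
                 n_reps = n_reps)
}

check_power_spec <- function(n, sigma_w, limits, alpha, true_ratio) {
  if (!is.numeric(n) || n < 3) abort("`n` must be >= 3.")
  if (sigma_w < 0) abort("`sigma_w` must be >= 0.")
  if (length(limits) != 2 || limits[1] <= 0 || limits[1] >= 1 ||
      limits[2] <= 1) {
    abort("`limits` must satisfy 0 < lower < 1 < upper.")
  }
  if (alpha <= 0 || alpha >= 0.5) abort("`alpha` must be in (0, 0.5).")
  if (true_ratio <= 0) abort("`true_ratio` must be positive.")
  invisible(TRUE)
}
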