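# Independent numeric oracles used across tests.

# Adaptive-quadrature AUC of a model curve (independent of the closed-form
# AUC path inside the package).
numeric_auc <- function(f, lower, upper, subdivisions = 2000L) {
  stats::integrate(f, lower, upper, subdivisions = subdivisions,
                   rel.tol = 1e-10)$value
}

# Fine-grid numeric integral of the piecewise lin-up/log-down interpolant,
# used as the oracle for auc_lin_up_log_down.
interpolant_auc <- function(times, concs, t_end = max(times), n_grid = 2e5) {
  interp1 <- function(t) {
    i <- findInterval(t, times, rightmost.closed = TRUE)
    i <- min(max(i, 1L), length(times) - 1L)
    t1 <- times[i]; t2 <- times[i + 1]; c1 <- concs[i]; c2 <- concs[i + 1]
    f <- (t - t1) / (t2 - t1)
    if (c2 < c1 && c1 > 0 && c2 > 0) c1 * (c2 / c1)^f else c1 + f * (c2 - c1)
  }
  g <- seq(times[1], t_end, length.out = n_grid)
  y <- vapply(g, interp1, numeric(1))
  sum((y[-1] + y[-n_grid]) / 2 * diff(g))
}

# Brute-force terminal-slope selection: enumerate all last-k windows, fit
# log-linear OLS directly, return the window with maximal adjusted R^2
# (ties within 1e-4 to the larger window).
brute_force_lambda <- function(times, concs) {
  n <- length(times)
  best <- NULL
  for (k in 3:n) {
    idx <- seq(n - k + 1, n)
    fit <- stats::lm(log(concs[idx]) ~ times[idx])
    r2 <- summary(fit)$r.squared
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (abs(adj - best$adj) <= 1e-4 && k > best$k)) {
      best <- list(k = k, lambda = -unname(coef(fit)[2]), adj = adj, rsq = r2)
    }
  }
  best
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
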