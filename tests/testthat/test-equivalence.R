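paired_obs <- function(log_diffs, ref_log = 0) {
  n <- length(log_diffs)
  tibble::tibble(
    subject = rep(seq_len(n), each = 2),
    period = rep(1:2, n),
    treatment = rep(c("A", "B"), n),
    value = exp(as.vector(rbind(ref_log + log_diffs, ref_log)))
  )
}

test_that("identical values under both treatments give a degenerate 100% ratio", {
  d <- paired_obs(rep(0, 5))
  r <- tidy(ls_mean_ratio(d, "A", "B"))
  expect_equal(r$ratio_percent, 100)
  expect_equal(r$ci_low_percent, 100)
  expect_equal(r$ci_high_percent, 100)
  expect_true(r$within_limits)
})

test_that("the paired contrast matches the closed-form hand computation", {
  d <- paired_obs(c(0.1, -0.1, 0.2, -0.2))
  r <- ls_mean_ratio(d, "A", "B")
  s <- sd(c(0.1, -0.1, 0.2, -0.2))
  expect_equal(s, 0.18257, tolerance = 1e-4)
  expect_equal(r$ratio_percent, 100)
  expect_equal(r$df, 3)
  expect_equal(r$ci_low_percent, 100 * exp(0 - qt(0.95, 3) * s / 2),
               tolerance = 1e-12)
  expect_equal(r$ci_high_percent, 100 * exp(0 + qt(0.95, 3) * s / 2),
               tolerance = 1e-12)
})

test_that("ratios are scale invariant and reciprocal under contrast reversal", {
  set.seed(21)
  d <- paired_obs(rnorm(12, 0.05, 0.25), ref_log = rnorm(12, 3, 0.4))
  r1 <- tidy(ls_mean_ratio(d, "A", "B"))
  scaled <- dplyr::mutate(d, value = value * 37.5)
  r2 <- tidy(ls_mean_ratio(scaled, "A", "B"))
  expect_equal(r1$ratio_percent, r2$ratio_percent, tolerance = 1e-12)
  expect_equal(r1$ci_low_percent, r2$ci_low_percent, tolerance = 1e-12)

  rev <- tidy(ls_mean_ratio(d, "B", "A"))
  expect_equal(rev$ratio_percent, 100^2 / r1$ratio_percent,
               tolerance = 1e-9)
  expect_equal(rev$ci_low_percent, 100^2 / r1$ci_high_percent,
               tolerance = 1e-9)
  expect_equal(rev$ci_high_percent, 100^2 / r1$ci_low_percent,
               tolerance = 1e-9)
})

test_that("subjects lacking either treatment are excluded and counted", {
  d <- paired_obs(c(0.1, -0.1, 0.05, -0.05, 0.2))
  d <- d[-10, ]  # subject 5 loses its reference observation
  r <- tidy(ls_mean_ratio(d, "A", "B"))
  expect_equal(r$n_subjects_used, 4)
  expect_equal(r$n_subjects_excluded, 1)

  expect_error(ls_mean_ratio(paired_obs(c(0.1, 0.2)), "A", "B"),
               "Fewer than 3")
  dup <- dplyr::bind_rows(paired_obs(rep(0.1, 3)), paired_obs(0.1)[1, ])
  expect_error(ls_mean_ratio(dup, "A", "B"), "exactly one")
})

test_that("period adjustment removes an additive period effect", {
  # balanced 2x2 crossover with a large period effect
  set.seed(31)
  n_half <- 10
  delta <- 0.08            # true log treatment effect
  pi2 <- 0.5               # period-2 shift
  subj <- seq_len(2 * n_half)
  rows <- purrr::map(subj, function(i) {
    ab <- i <= n_half      # TRUE: A in period 1, B in period 2
    base <- rnorm(1, 3, 0.3)
    eps <- rnorm(2, 0, 0.15)
    tibble::tibble(
      subject = i, period = 1:2,
      treatment = if (ab) c("A", "B") else c("B", "A"),
      value = exp(base + c(0, pi2) + delta * (treatment == "A") + eps)
    )
  })
  d <- dplyr::bind_rows(rows)
  r <- ls_mean_ratio(d, "A", "B")
  expect_equal(r$n_patterns, 2)
  expect_equal(r$df, 2 * n_half - 2)
  # the naive mean of log-differences is biased by the period effect in an
  # unbalanced subset; the adjusted estimator is not
  expect_lt(abs(r$estimate_log - delta), 0.12)
  # check against lm() with period + treatment + subject fixed effects
  fit <- lm(log(value) ~ factor(subject) + factor(period) + treatment,
            data = d)
  expect_equal(r$estimate_log, unname(coef(fit)["treatmentB"]) * -1,
               tolerance = 1e-9)
})

test_that("interaction decision: closed limits, failure reporting", {
  mk_ddi <- function(lo, hi) {
    structure(list(
      results = tibble::tibble(
        analyte = "a", day = 1, parameter = "cmax",
        test = "T", reference = "R", ratio_percent = sqrt(lo * hi),
        ci_low_percent = lo, ci_high_percent = hi,
        conf_level = 0.9, df = 20, n_subjects_used = 21,
        n_subjects_excluded = 0,
        within_limits = lo >= 80 && hi <= 125
      ),
      limits_percent = c(80, 125), conf_level = 0.9, n_planned = 1L
    ), class = "pk_ddi")
  }
  expect_equal(interaction_decision(mk_ddi(92, 110))$decision,
               "no interaction")
  expect_equal(interaction_decision(mk_ddi(80, 125))$decision,
               "no interaction")  # closed interval
  bad <- interaction_decision(mk_ddi(79.9, 110))
  expect_equal(bad$decision, "interaction not excluded")
  expect_equal(nrow(bad$failing), 1)

  incomplete <- mk_ddi(90, 110)
  incomplete$n_planned <- 2L
  expect_error(interaction_decision(incomplete), "Incomplete")
})

test_that("analytic TOST power: limits, boundary size, and the design point", {
  expect_equal(tost_power_analytic(24, 0, true_ratio = 1), 1)
  expect_equal(tost_power_analytic(24, 0, true_ratio = 1.3), 0)
  expect_lte(tost_power_analytic(24, 0.2171, true_ratio = 1.25), 0.05)
  expect_gte(tost_power_analytic(24, 0.2171, true_ratio = 1), 0.90)
  expect_gte(tost_power_analytic(24, 0.2088, true_ratio = 1), 0.90)
  # power shrinks with variability
  pw <- vapply(c(0.1, 0.2, 0.3, 0.4),
               function(s) tost_power_analytic(24, s), numeric(1))
  expect_true(all(diff(pw) <= 0))
})

test_that("simulated power agrees with the analytic routine", {
  for (tr in c(1, 1.1)) {
    sim <- tost_power_simulated(24, 0.2171, true_ratio = tr,
                                n_reps = 4000, seed = 17)
    ana <- tost_power_analytic(24, 0.2171, true_ratio = tr)
    expect_lt(abs(sim$power - ana), 3 * sim$mc_se + 0.005)
  }
  gross <- tost_power_simulated(24, 0.2171, true_ratio = 2,
                                n_reps = 500, seed = 1)
  expect_lt(gross$power, 0.01)
})

test_that("type-I error at the 1.25 boundary is controlled", {
  sim <- tost_power_simulated(24, 0.2171, true_ratio = 1.25,
                              n_reps = 4000, seed = 23)
  expect_lte(sim$power, 0.05 + 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("the vectorized replicate analysis equals ls_mean_ratio", {
  set.seed(41)
  n <- 12
  d <- rnorm(n, 0.03, sqrt(2) * 0.2)
  obs <- paired_obs(d)
  r <- ls_mean_ratio(obs, "A", "B")
  est <- mean(d); s <- sd(d)
  half <- qt(0.95, n - 1) * s / sqrt(n)
  expect_equal(r$estimate_log, est, tolerance = 1e-12)
  expect_equal(log(r$ci_high_percent / 100), est + half, tolerance = 1e-12)
})

test_that("CI half-width shrinks as 1/sqrt(n)", {
  set.seed(51)
  ns <- c(16, 32, 64, 128)
  mean_log_hw <- vapply(ns, function(n) {
    hw <- replicate(300, {
      d <- rnorm(n, 0, sqrt(2) * 0.2171)
      qt(0.95, n - 1) * sd(d) / sqrt(n)
    })
    mean(log(hw))
  }, numeric(1))
  slope <- unname(coef(lm(mean_log_hw ~ log(ns)))[2])
  expect_lt(abs(slope - (-0.5)), 0.05)
})

test_that("a simulated no-interaction crossover passes the 80-125% window", {
  study <- simulate_crossover(
    design_caz_avi_ddi(n_subjects = 27),
    variability = variability_model(within_subject_sd_log = 0.2171,
                                    residual_cv = 0),
    seed = 61
  )
  nca <- run_nca(study)
  obs <- nca_to_observations(nca)
  r <- tidy(ls_mean_ratio(
    dplyr::filter(obs, analyte == "avibactam", day == 1, parameter == "cmax"),
    test = "caz_avi", reference = "avi"
  ))
  expect_true(r$within_limits)
})
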