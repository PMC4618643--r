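test_that("Cmax/tmax: maximum observed value, earliest-tie rule, BLQ handling", {
  expect_equal(
    compute_cmax_tmax(data.frame(time = 1, concentration = 5)),
    tibble::tibble(cmax = 5, tmax = 1, n_obs = 1L)
  )
  tie <- data.frame(time = c(0, 2, 2.25, 3), concentration = c(0, 9, 9, 4))
  expect_equal(compute_cmax_tmax(tie)$tmax, 2)

  blq <- data.frame(time = 0:3, concentration = c(NA, 8, 10, NA),
                    blq = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(compute_cmax_tmax(blq)$cmax, 10)
  allblq <- data.frame(time = 0:2, concentration = rep(NA_real_, 3),
                       blq = rep(TRUE, 3))
  expect_true(is.na(compute_cmax_tmax(allblq)$cmax))
})

test_that("tmax is at end of infusion on noiseless 2-h-infusion profiles", {
  p <- pk_params(12, 12 * 2.3 / log(2))
  d <- dose_event("avibactam", 500, 0, 2)
  sched <- c(0, 0.5, 1, 1.5, 2, 2.25, 2.5, 2.75, 3, 3.5, 4, 6, 8, 12, 24)
  prof <- data.frame(time = sched,
                     concentration = infusion_concentration(p, d, sched))
  expect_equal(compute_cmax_tmax(prof)$tmax, 2.0)
})

test_that("linear-up/log-down AUC matches hand values and the interpolant oracle", {
  # rectangle
  expect_equal(auc_lin_up_log_down(c(0, 8), c(10, 10)), 80)
  # degenerate log segment falls back to the linear rule
  expect_equal(auc_lin_up_log_down(c(0, 1), c(10, 10)), 10)
  # hand evaluation: linear up then log down
  expect_equal(auc_lin_up_log_down(c(0, 1, 2), c(0, 10, 5)),
               5 + 5 / log(2), tolerance = 1e-12)
  expect_equal(auc_lin_up_log_down(c(0, 1, 2), c(0, 10, 5)), 12.2135,
               tolerance = 1e-4)

  # numeric integration of the same interpolant agrees
  set.seed(7)
  tt <- sort(c(0, cumsum(runif(8, 0.2, 3))))
  cc <- c(0, 40 * exp(-0.3 * tt[-1]) * exp(rnorm(8, 0, 0.15)))
  expect_rel_equal(auc_lin_up_log_down(tt, cc),
                   interpolant_auc(tt, cc), 1e-4)
  # partial last segment by the same rule
  t_end <- mean(tt[8:9])
  expect_rel_equal(auc_lin_up_log_down(tt, cc, t_end = t_end),
                   interpolant_auc(tt, cc, t_end = t_end), 1e-4)

  expect_error(auc_lin_up_log_down(c(0, 2, 1), c(1, 2, 3)), "increasing")
})

test_that("AUC is additive over abutting intervals on the same grid", {
  set.seed(11)
  tt <- sort(c(0, cumsum(runif(10, 0.2, 2.5))))
  cc <- c(0, 30 * exp(-0.25 * tt[-1]) * exp(rnorm(10, 0, 0.2)))
  for (a in c(tt[4], 3.21, tt[7])) {
    lhs <- auc_lin_up_log_down(tt, cc, t_end = a) +
      auc_lin_up_log_down(tt, cc, t_start = a, t_end = max(tt))
    expect_equal(lhs, auc_lin_up_log_down(tt, cc), tolerance = 1e-10)
  }
})

test_that("lambda_z: exact data, gating, and brute-force window selection", {
  exact <- data.frame(time = c(4, 6, 8, 12),
                      concentration = 100 * exp(-0.25 * c(4, 6, 8, 12)))
  # add a rising limb so the terminal points sit strictly after tmax
  prof <- rbind(data.frame(time = c(0, 1, 2),
                           concentration = c(0, 60, 95 * exp(-0.25 * 0))),
                exact)
  prof$concentration[3] <- 100 * exp(-0.25 * 2) * 1.8  # cmax at t = 2
  fit <- fit_lambda_z(prof)
  expect_equal(fit$lambda_z, 0.25, tolerance = 1e-10)
  expect_equal(fit$rsq, 1, tolerance = 1e-12)
  expect_true(fit$lambda_reportable)

  # too few eligible points
  short <- data.frame(time = c(0, 1, 2, 3),
                      concentration = c(0, 10, 8, 6))
  expect_equal(fit_lambda_z(short)$lambda_flag, "not_evaluable")

  # rising terminal data -> nonpositive slope, not reportable
  rising <- data.frame(time = 0:5, concentration = c(0, 10, 2, 3, 4, 5))
  expect_equal(fit_lambda_z(rising)$lambda_flag, "nonpositive_slope")

  # noisy profiles: automatic selection equals exhaustive enumeration
  set.seed(5)
  for (rep in 1:10) {
    tt <- c(3, 4, 6, 8, 10, 12, 16, 24)
    cc <- 80 * exp(-0.28 * tt) * exp(rnorm(8, 0, 0.08))
    prof <- rbind(data.frame(time = c(0, 1, 2),
                             concentration = c(0, 50, 90)),
                  data.frame(time = tt, concentration = cc))
    fit <- fit_lambda_z(prof)
    oracle <- brute_force_lambda(tt, cc)
    expect_equal(fit$n_lambda_points, oracle$k)
    expect_equal(fit$lambda_z, oracle$lambda, tolerance = 1e-10)
  }
})

test_that("AUC extrapolation applies the 20% suppression rule", {
  ok <- extrapolate_auc(98, 1, 0.5)
  expect_equal(ok$auc_inf, 100)
  expect_equal(ok$extrapolated_fraction, 0.02)
  expect_true(ok$auc_inf_reportable)

  over <- extrapolate_auc(7, 0.9, 0.3)
  expect_equal(over$extrapolated_fraction, 0.3, tolerance = 1e-12)
  expect_false(over$auc_inf_reportable)
  # exactly at 20% is retained (rule is "greater than 20%")
  at <- extrapolate_auc(80, 4, 0.2)
  expect_equal(at$extrapolated_fraction, 0.2)
  expect_true(at$auc_inf_reportable)

  expect_false(extrapolate_auc(98, 1, NA_real_)$auc_inf_reportable)
})

test_that("NCA on noiseless model data recovers lambda_z, CL and CLR", {
  cl <- 12; thalf <- 2.7
  p <- pk_params(cl, cl * thalf / log(2), renal_fraction = 1)
  d <- dose_event("drug", 500, 0, 2)
  sched <- c(0, 0.5, 1, 1.5, 2, 2.25, 2.5, 2.75, 3, 3.5, 4, 6, 8, 12, 24)
  prof <- data.frame(time = sched,
                     concentration = infusion_concentration(p, d, sched))
  reg <- regimen(d, tau = 8)
  urine <- tibble::tibble(
    interval_start = c(0, 2, 4, 8, 12), interval_end = c(2, 4, 8, 12, 24),
    amount_excreted = purrr::map2_dbl(
      c(0, 2, 4, 8, 12), c(2, 4, 8, 12, 24),
      ~ cumulative_urine_amount(p, reg, .x, .y)
    )
  )
  res <- nca_profile(prof, dose = 500, tau = 8, urine = urine)
  expect_rel_equal(res$lambda_z, log(2) / thalf, 1e-6)
  expect_rel_equal(res$cl, cl, 0.005)
  expect_lt(res$extrapolated_fraction, 0.01)
  expect_rel_equal(res$auc_inf, 500 / cl, 0.005)
  # renal_fraction 1: CLR/CL = 1 within 2% on 0-24 h urine and AUC
  expect_rel_equal(res$clr / res$cl, 1, 0.02)
  expect_equal(res$half_life, log(2) / res$lambda_z)
})

test_that("bolus-limit sanity: CL = dose/AUCinf identity", {
  p <- pk_params(1, 10)   # k = 0.1/h
  d <- dose_event("drug", 100, 0, 0.01)
  sched <- c(0.01, 0.5, 1, 2, 4, 8, 12, 24, 36, 48)
  prof <- data.frame(time = sched,
                     concentration = infusion_concentration(p, d, sched))
  res <- nca_profile(prof, dose = 100, tau = 8)
  expect_rel_equal(res$cl, 1, 0.01)
})

test_that("rsq and extrapolation gates suppress AUCinf-derived parameters", {
  # sawtooth terminal phase: every candidate window has rsq < 0.8
  prof <- data.frame(
    time = c(0, 1, 2, 3, 4, 6, 8, 12, 24),
    concentration = c(0, 50, 90, 9, 3.5, 7, 2.5, 5, 1.2)
  )
  fit <- fit_lambda_z(prof)
  expect_lt(fit$rsq, 0.8)
  expect_false(fit$lambda_reportable)
  res <- nca_profile(prof, dose = 500)
  expect_true(is.na(res$auc_inf) && is.na(res$half_life) && is.na(res$cl))
  expect_match(res$flags, "rsq")
  expect_false(is.na(res$auc_last))

  # a short profile whose extrapolated area exceeds 20%
  p <- pk_params(12, 40)
  d <- dose_event("drug", 500, 0, 2)
  short_sched <- c(0, 1, 2, 2.5, 3, 3.5, 4)
  sp <- data.frame(time = short_sched,
                   concentration = infusion_concentration(p, d, short_sched))
  res2 <- nca_profile(sp, dose = 500, tau = 8)
  expect_true(is.na(res2$auc_inf) && is.na(res2$cl))
  expect_match(res2$flags, "extrapolation")
})

test_that("accumulation ratio and linearity index follow their definitions", {
  nca <- tibble::tibble(
    subject = c(1, 1), treatment = "t", analyte = "a", day = c(1, 4),
    auc_tau = c(265.0, 294.0), auc_inf = c(289.0, NA), reportable = c(TRUE, NA)
  )
  out <- accumulation_and_linearity(nca, day1 = 1, steady = 4)
  expect_equal(out$accumulation_ratio, 294 / 265)
  expect_equal(round_half_up(out$accumulation_ratio, 1), 1.1)
  expect_equal(out$linearity_index, 294 / 289)
  expect_equal(round_half_up(out$linearity_index, 1), 1.0)

  # identical day-1 / steady-state profiles give ratios of exactly 1
  same <- dplyr::mutate(nca, auc_tau = 265, auc_inf = 289)
  out2 <- accumulation_and_linearity(same, 1, 4)
  expect_equal(out2$accumulation_ratio, 1)

  # non-reportable day-1 AUCinf withholds the linearity index
  gated <- dplyr::mutate(nca, reportable = c(FALSE, NA))
  out3 <- accumulation_and_linearity(gated, 1, 4)
  expect_true(is.na(out3$linearity_index))
  expect_match(out3$flags, "not_reportable")
})

test_that("geometric summaries follow the printed CV formula", {
  all_eq <- geometric_summary(rep(3.7, 5))
  expect_equal(all_eq$geometric_mean, 3.7)
  expect_equal(all_eq$geometric_cv_percent, 0)

  two <- geometric_summary(c(exp(0), exp(2)))  # s = sqrt(2) on log scale
  expect_equal(two$geometric_cv_percent, 100 * sqrt(exp(2) - 1),
               tolerance = 1e-12)
  expect_equal(two$geometric_cv_percent, 252.766, tolerance = 1e-4)

  # Monte-Carlo convergence to the closed form at sigma = 0.2171
  set.seed(1)
  x <- exp(rnorm(1e5, 0, 0.2171))
  mc <- geometric_summary(x)
  expect_rel_equal(mc$geometric_cv_percent,
                   100 * sqrt(exp(0.2171^2) - 1), 0.01)

  expect_error(geometric_summary(c(1, -2)), "positive")
})

test_that("geometric mean CL commutes with dose over geometric mean AUC", {
  set.seed(3)
  auc <- exp(rnorm(20, log(40), 0.2))
  cl <- 500 / auc
  expect_equal(geometric_summary(cl)$geometric_mean,
               500 / geometric_summary(auc)$geometric_mean,
               tolerance = 1e-12)
})

test_that("summary tables drop gated profiles from AUCinf-derived rows", {
  study <- simulate_crossover(design_caz_avi_ddi(n_subjects = 4),
                              variability = no_variability(), seed = 2)
  nca <- run_nca(study)
  # force one profile through the rsq gate
  nca$auc_inf[1] <- NA; nca$half_life[1] <- NA; nca$cl[1] <- NA
  nca$reportable[1] <- FALSE; nca$flags[1] <- "rsq<0.8"
  smry <- summarize_nca(nca)
  grp <- dplyr::filter(smry, analyte == nca$analyte[1],
                       treatment == nca$treatment[1], day == nca$day[1])
  n_auc <- grp$n[grp$parameter == "auc_inf"]
  n_cmax <- grp$n[grp$parameter == "cmax"]
  expect_equal(n_auc, n_cmax - 1L)
})
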