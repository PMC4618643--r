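#' Linear-up/log-down trapezoidal AUC
#'
#' Computes the area under a concentration-time curve by the linear-up/
#' log-down rule: a segment where the concentration rises (or where either
#' endpoint is 0) contributes a linear trapezoid `(C1 + C2)/2 * dt`; a
#' segment where it falls with both endpoints positive contributes the log
#' trapezoid `(C1 - C2)/ln(C1/C2) * dt`. Partial bounds inside a segment are
#' handled by the same interpolant (log-linear on falling segments, linear
#' otherwise).
#'
#' @param times Strictly increasing sampling times (h).
#' @param concs Nonnegative concentrations (ug/mL), same length.
#' @param t_end Upper integration bound (h); must not exceed `max(times)`.
#' @param t_start Lower integration bound (h); defaults to `times[1]`.
#' @return The area (ug.h/mL).
#' @examples
#' auc_lin_up_log_down(c(0, 1, 2), c(0, 10, 5))
#' @export
auc_lin_up_log_down <- function(times, concs, t_end = max(times),
                                t_start = times[1]) {
  if (length(times) != length(concs) || length(times) < 2) {
    abort("`times` and `concs` must have equal length >= 2.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.")
  }
  if (any(concs < 0)) abort("`concs` must be nonnegative.")
  if (t_end > max(times) + 1e-12 || t_start < times[1] - 1e-12 ||
      t_end < t_start) {
    abort("Integration bounds must satisfy times[1] <= t_start <= t_end <= max(times).")
  }
  total <- 0
  for (i in seq_len(length(times) - 1L)) {
    t1 <- times[i]; t2 <- times[i + 1L]
    lo <- max(t1, t_start); hi <- min(t2, t_end)
    if (hi <= lo) next
    c1 <- interp_conc(t1, t2, concs[i], concs[i + 1L], lo)
    c2 <- interp_conc(t1, t2, concs[i], concs[i + 1L], hi)
    total <- total + segment_area(lo, hi, c1, c2)
  }
  total
}

segment_area <- function(t1, t2, c1, c2) {
  if (c2 < c1 && c1 > 0 && c2 > 0) {
    (c1 - c2) / log(c1 / c2) * (t2 - t1)
  } else {
    (c1 + c2) / 2 * (t2 - t1)
  }
}

interp_conc <- function(t1, t2, c1, c2, t) {
  if (t <= t1) return(c1)
  if (t >= t2) return(c2)
  f <- (t - t1) / (t2 - t1)
  if (c2 < c1 && c1 > 0 && c2 > 0) c1 * (c2 / c1)^f else c1 + f * (c2 - c1)
}

# Order a raw profile and resolve BLQ values for numeric use: leading BLQ
# (before the first quantifiable sample) count as 0 on the AUC grid;
# embedded and trailing BLQ samples are dropped from both the AUC grid and
# the terminal fit. Returns the AUC grid plus the quantifiable points.
prepare_profile <- function(profile) {
  stopifnot(is.data.frame(profile),
            all(c("time", "concentration") %in% names(profile)))
  if (!"blq" %in% names(profile)) {
    profile$blq <- is.na(profile$concentration)
  }
  profile <- dplyr::arrange(profile, .data$time)
  obs_idx <- which(!profile$blq & !is.na(profile$concentration))
  if (length(obs_idx) == 0) {
    return(list(grid_t = numeric(), grid_c = numeric(),
                obs = profile[0, ], evaluable = FALSE))
  }
  first_obs <- min(obs_idx)
  leading <- profile[seq_len(first_obs - 1), , drop = FALSE]
  keep <- dplyr::bind_rows(
    dplyr::mutate(leading, concentration = 0),
    profile[obs_idx, , drop = FALSE]
  )
  keep <- dplyr::arrange(keep, .data$time)
  list(
    grid_t = keep$time, grid_c = keep$concentration,
    obs = profile[obs_idx, , drop = FALSE], evaluable = TRUE
  )
}

#' Maximum concentration and its time
#'
#' `cmax` is the largest quantifiable concentration in the profile and
#' `tmax` the time at which it occurs; ties are broken by the earliest time.
#'
#' @param profile Data frame with columns `time`, `concentration` and
#'   optionally `blq` (BLQ samples are ignored).
#' @return One-row tibble with `cmax`, `tmax` and `n_obs` (quantifiable
#'   samples used); all-BLQ profiles give `NA` values.
#' @examples
#' compute_cmax_tmax(data.frame(time = c(0, 1, 2), concentration = c(0, 8, 10)))
#' @export
compute_cmax_tmax <- function(profile) {
  prep <- prepare_profile(profile)
  if (!prep$evaluable) {
    return(tibble::tibble(cmax = NA_real_, tmax = NA_real_, n_obs = 0L))
  }
  obs <- prep$obs
  i <- which(obs$concentration == max(obs$concentration))[1]
  tibble::tibble(cmax = obs$concentration[i], tmax = obs$time[i],
                 n_obs = nrow(obs))
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Fits ordinary least squares of log concentration on time over terminal
#' points strictly after tmax. The number of points is chosen automatically:
#' candidate windows are the last k = 3, 4, ... quantifiable points, and the
#' window with maximal adjusted R-squared wins (ties within 1e-4 go to the
#' larger window). The fit is flagged not reportable when R-squared < 0.8
#' (`rsq_threshold`) or the slope is nonnegative; fewer than 3 eligible
#' points make the profile not evaluable.
#'
#' @inheritParams compute_cmax_tmax
#' @param rsq_threshold Minimum R-squared for a reportable fit (default 0.8).
#' @param max_points Cap on the candidate window size (default all points).
#' @return One-row tibble: `lambda_z` (1/h), `rsq`, `adj_rsq`,
#'   `n_lambda_points`, `lambda_t_first`, `lambda_t_last`, `lambda_reportable`,
#'   `lambda_flag`.
#' @examples
#' pr <- data.frame(time = c(1, 4, 6, 8, 12),
#'                  concentration = c(50, 100 * exp(-0.25 * c(4, 6, 8, 12))))
#' fit_lambda_z(pr)
#' @export
fit_lambda_z <- function(profile, rsq_threshold = 0.8, max_points = Inf) {
  empty <- tibble::tibble(
    lambda_z = NA_real_, rsq = NA_real_, adj_rsq = NA_real_,
    n_lambda_points = 0L, lambda_t_first = NA_real_, lambda_t_last = NA_real_,
    lambda_reportable = FALSE, lambda_flag = "not_evaluable"
  )
  prep <- prepare_profile(profile)
  if (!prep$evaluable) return(empty)
  ct <- compute_cmax_tmax(profile)
  obs <- dplyr::filter(prep$obs, .data$time > ct$tmax, .data$concentration > 0)
  n <- nrow(obs)
  if (n < 3) return(empty)

  best <- NULL
  for (k in 3:min(n, max_points)) {
    idx <- seq(n - k + 1L, n)
    tt <- obs$time[idx]; lc <- log(obs$concentration[idx])
    fit <- lm(lc ~ tt)
    ssr <- sum(fit$residuals^2)
    sst <- sum((lc - mean(lc))^2)
    rsq <- if (sst == 0) 1 else 1 - ssr / sst
    adj <- 1 - (1 - rsq) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (abs(adj - best$adj) <= 1e-4 && k > best$k)) {
      best <- list(k = k, slope = unname(coef(fit)[2]), rsq = rsq, adj = adj,
                   t_first = tt[1], t_last = tt[k])
    }
  }
  lambda <- -best$slope
  reportable <- TRUE
  flag <- NA_character_
  if (lambda <= 0) {
    reportable <- FALSE; flag <- "nonpositive_slope"
  } else if (best$rsq < rsq_threshold) {
    reportable <- FALSE; flag <- sprintf("rsq<%.2g", rsq_threshold)
  }
  tibble::tibble(
    lambda_z = if (lambda > 0) lambda else NA_real_,
    rsq = best$rsq, adj_rsq = best$adj, n_lambda_points = best$k,
    lambda_t_first = best$t_first, lambda_t_last = best$t_last,
    lambda_reportable = reportable, lambda_flag = flag
  )
}

#' Extrapolate AUC to infinity with the 20% suppression rule
#'
#' `AUCinf = AUClast + Clast / lambda_z`. When the extrapolated portion
#' exceeds 20% of AUCinf, AUCinf and parameters derived from it are not
#' reported.
#'
#' @param auc_last AUC to the last quantifiable concentration (ug.h/mL).
#' @param c_last Last quantifiable concentration (ug/mL).
#' @param lambda_z Terminal rate constant (1/h); `NA` propagates.
#' @param max_extrapolated_fraction Suppression threshold (default 0.20).
#' @return One-row tibble: `auc_inf`, `extrapolated_fraction`,
#'   `auc_inf_reportable`.
#' @examples
#' extrapolate_auc(98, 1, 0.5)
#' @export
extrapolate_auc <- function(auc_last, c_last, lambda_z,
                            max_extrapolated_fraction = 0.20) {
  if (is.na(lambda_z)) {
    return(tibble::tibble(auc_inf = NA_real_,
                          extrapolated_fraction = NA_real_,
                          auc_inf_reportable = FALSE))
  }
  if (auc_last <= 0 || c_last <= 0 || lambda_z <= 0) {
    abort("`auc_last`, `c_last` and `lambda_z` must be positive.")
  }
  tail_area <- c_last / lambda_z
  auc_inf <- auc_last + tail_area
  frac <- tail_area / auc_inf
  tibble::tibble(
    auc_inf = auc_inf, extrapolated_fraction = frac,
    auc_inf_reportable = frac <= max_extrapolated_fraction
  )
}

#' Full noncompartmental analysis of one concentration profile
#'
#' Assembles Cmax/tmax, AUC to the last quantifiable sample, AUC over the
#' dosing interval, AUC extrapolated to infinity (with the R-squared >= 0.8
#' and <= 20% extrapolation gates), terminal half-life `ln 2 / lambda_z`,
#' plasma clearance `dose / AUCinf`, and - when urine collections are
#' supplied - renal clearance as the amount excreted over the collection
#' span divided by the plasma AUC over the same span.
#'
#' @inheritParams compute_cmax_tmax
#' @param dose Administered dose (mg) for the profile's day.
#' @param tau Dosing interval (h) for AUC(0-tau); default 8.
#' @param urine Optional data frame with `interval_start`, `interval_end`,
#'   `amount_excreted` (times on the same clock as the profile).
#' @param rsq_threshold,max_extrapolated_fraction Reportability gates.
#' @return One-row tibble of NCA outputs with a semicolon-joined `flags`
#'   column recording every gating event.
#' @export
nca_profile <- function(profile, dose, tau = 8, urine = NULL,
                        rsq_threshold = 0.8,
                        max_extrapolated_fraction = 0.20) {
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0) {
    abort("`dose` must be a single positive number (mg).")
  }
  flags <- character()
  prep <- prepare_profile(profile)
  ct <- compute_cmax_tmax(profile)
  if (!prep$evaluable) {
    flags <- "all_blq"
    return(nca_row(ct, auc_last = NA_real_, auc_tau = NA_real_,
                   lam = fit_lambda_z(profile), ext = NULL,
                   half_life = NA_real_, cl = NA_real_, clr = NA_real_,
                   flags = flags))
  }

  grid_t <- prep$grid_t; grid_c <- prep$grid_c
  t_last <- max(prep$obs$time)
  c_last <- prep$obs$concentration[which.max(prep$obs$time)]
  auc_last <- if (length(grid_t) >= 2) {
    auc_lin_up_log_down(grid_t, grid_c, t_end = t_last)
  } else NA_real_
  auc_tau <- if (length(grid_t) >= 2 && t_last >= tau) {
    auc_lin_up_log_down(grid_t, grid_c, t_end = tau)
  } else {
    if (t_last < tau) flags <- c(flags, "auc_tau_span_short")
    NA_real_
  }

  lam <- fit_lambda_z(profile, rsq_threshold = rsq_threshold)
  if (!lam$lambda_reportable) {
    flags <- c(flags, lam$lambda_flag %||% "lambda_not_reportable")
  }
  ext <- if (lam$lambda_reportable && !is.na(auc_last)) {
    extrapolate_auc(auc_last, c_last, lam$lambda_z,
                    max_extrapolated_fraction = max_extrapolated_fraction)
  } else {
    tibble::tibble(auc_inf = NA_real_, extrapolated_fraction = NA_real_,
                   auc_inf_reportable = FALSE)
  }
  if (lam$lambda_reportable && !ext$auc_inf_reportable) {
    flags <- c(flags, "extrapolation>20%")
  }

  reportable <- lam$lambda_reportable && ext$auc_inf_reportable
  half_life <- if (reportable) log(2) / lam$lambda_z else NA_real_
  cl <- if (reportable) dose / ext$auc_inf else NA_real_
  auc_inf <- if (reportable) ext$auc_inf else NA_real_

  clr <- NA_real_
  if (!is.null(urine) && nrow(urine) > 0) {
    span <- min(max(urine$interval_end), t_last)
    use <- dplyr::filter(urine, .data$interval_end <= span + 1e-9)
    if (nrow(use) > 0 && span > grid_t[1]) {
      ae <- sum(use$amount_excreted)
      auc_span <- auc_lin_up_log_down(grid_t, grid_c, t_end = span)
      if (auc_span > 0) clr <- ae / auc_span
    }
  }

  nca_row(ct, auc_last, auc_tau, lam,
          tibble::tibble(auc_inf = auc_inf,
                         extrapolated_fraction = ext$extrapolated_fraction,
                         auc_inf_reportable = reportable),
          half_life, cl, clr, flags)
}

nca_row <- function(ct, auc_last, auc_tau, lam, ext, half_life, cl, clr,
                    flags) {
  if (is.null(ext)) {
    ext <- tibble::tibble(auc_inf = NA_real_, extrapolated_fraction = NA_real_,
                          auc_inf_reportable = FALSE)
  }
  tibble::tibble(
    cmax = ct$cmax, tmax = ct$tmax, n_obs = ct$n_obs,
    auc_last = auc_last, auc_tau = auc_tau,
    auc_inf = ext$auc_inf, extrapolated_fraction = ext$extrapolated_fraction,
    lambda_z = lam$lambda_z, rsq = lam$rsq,
    n_lambda_points = lam$n_lambda_points,
    half_life = half_life, cl = cl, clr = clr,
    reportable = isTRUE(ext$auc_inf_reportable),
    flags = if (length(flags) == 0) NA_character_ else
      paste(flags, collapse = ";")
  )
}

#' Geometric summary statistics
#'
#' Geometric mean `exp(mean(log x))` and geometric CV%
#' `100 * sqrt(exp(s^2) - 1)` with `s` the sample SD (n-1 denominator) of
#' the natural-log data, alongside arithmetic mean, SD, median and range.
#'
#' @param values Positive numeric vector (NAs dropped).
#' @return One-row tibble: `geometric_mean`, `geometric_cv_percent`,
#'   `arithmetic_mean`, `sd`, `median`, `range_min`, `range_max`, `n`.
#' @examples
#' geometric_summary(c(1, exp(2)))
#' @export
geometric_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) abort("No non-missing values.")
  if (any(values <= 0)) abort("Geometric summaries require positive values.")
  lx <- log(values)
  n <- length(values)
  s <- if (n >= 2) sd(lx) else NA_real_
  tibble::tibble(
    geometric_mean = exp(mean(lx)),
    geometric_cv_percent = if (is.na(s)) NA_real_ else
      100 * sqrt(exp(s^2) - 1),
    arithmetic_mean = mean(values), sd = if (n >= 2) sd(values) else NA_real_,
    median = median(values), range_min = min(values),
    range_max = max(values), n = n
  )
}
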