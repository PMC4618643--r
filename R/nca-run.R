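#' Run noncompartmental analysis over a whole study
#'
#' Applies [nca_profile()] to every subject x period x treatment x analyte x
#' day profile of a simulated or imported study, matching each profile to
#' its dose (the amount administered on that day) and, where available, its
#' urine collections.
#'
#' @param study A `pk_study` from [simulate_crossover()], or a list with
#'   tibbles `concentrations`, `urine` and `doses` in the long CSV layout
#'   (see [write_study_csv()]).
#' @param tau Dosing interval (h) for AUC(0-tau).
#' @param rsq_threshold,max_extrapolated_fraction Reportability gates passed
#'   to [nca_profile()].
#' @return A tibble with one row per profile: identifier columns followed by
#'   the [nca_profile()] outputs.
#' @examples
#' study <- simulate_crossover(design_caz_avi_ddi(n_subjects = 3),
#'                             variability = no_variability(), seed = 1)
#' nca <- run_nca(study)
#' dplyr::select(nca, subject, treatment, analyte, day, cmax, auc_tau)
#' @export
run_nca <- function(study, tau = 8, rsq_threshold = 0.8,
                    max_extrapolated_fraction = 0.20) {
  conc <- study$concentrations
  urine <- study$urine
  doses <- study$doses
  stopifnot(is.data.frame(conc), is.data.frame(doses))

  keys <- c("subject", "period", "treatment", "analyte", "day")
  groups <- dplyr::distinct(
    conc, dplyr::across(dplyr::all_of(c("sequence", keys)))
  )
  out <- purrr::pmap(groups, function(sequence, subject, period, treatment,
                                      analyte, day) {
    prof <- dplyr::filter(
      conc, .data$subject == !!subject, .data$period == !!period,
      .data$analyte == !!analyte, .data$day == !!day
    )
    dose_rows <- dplyr::filter(
      doses, .data$subject == !!subject, .data$period == !!period,
      .data$drug == !!analyte, .data$day == !!day
    )
    if (nrow(dose_rows) == 0) {
      abort(sprintf("No dose event for subject %s, %s, day %s.",
                    subject, analyte, day))
    }
    ur <- NULL
    if (!is.null(urine) && nrow(urine) > 0) {
      ur <- dplyr::filter(
        urine, .data$subject == !!subject, .data$period == !!period,
        .data$analyte == !!analyte, .data$day == !!day
      )
      if (nrow(ur) == 0) ur <- NULL
    }
    res <- nca_profile(
      tibble::tibble(time = prof$actual_time,
                     concentration = prof$concentration, blq = prof$blq),
      dose = dose_rows$amount[1], tau = tau, urine = ur,
      rsq_threshold = rsq_threshold,
      max_extrapolated_fraction = max_extrapolated_fraction
    )
    dplyr::bind_cols(
      tibble::tibble(subject = subject, sequence = sequence, period = period,
                     treatment = treatment, analyte = analyte, day = day,
                     dose = dose_rows$amount[1]),
      res
    )
  })
  dplyr::arrange(dplyr::bind_rows(out), .data$analyte, .data$treatment,
                 .data$subject, .data$day)
}

#' Accumulation ratio and linearity index
#'
#' Pairs each subject's first-day profile with the steady-state day and
#' computes the accumulation ratio `AUC(0-tau, steady) / AUC(0-tau, day 1)`
#' and the linearity index `AUC(0-tau, steady) / AUCinf(day 1)`. The
#' linearity index is only reported when the Day-1 AUCinf passed its
#' reportability gates.
#'
#' @param nca Output of [run_nca()].
#' @param day1 Day index of the first (single-dose) day. Default 1.
#' @param steady Day index of the steady-state day (the design's last day).
#' @return Tibble with one row per subject x treatment x analyte:
#'   `accumulation_ratio`, `linearity_index` and a `flags` column.
#' @export
accumulation_and_linearity <- function(nca, day1 = 1,
                                       steady = max(nca$day)) {
  d1 <- dplyr::filter(nca, .data$day == day1)
  ss <- dplyr::filter(nca, .data$day == steady)
  joined <- dplyr::inner_join(
    dplyr::select(d1, "subject", "treatment", "analyte",
                  auc_tau_d1 = "auc_tau", auc_inf_d1 = "auc_inf",
                  reportable_d1 = "reportable"),
    dplyr::select(ss, "subject", "treatment", "analyte",
                  auc_tau_ss = "auc_tau"),
    by = c("subject", "treatment", "analyte")
  )
  dplyr::transmute(
    joined,
    .data$subject, .data$treatment, .data$analyte,
    accumulation_ratio = .data$auc_tau_ss / .data$auc_tau_d1,
    linearity_index = dplyr::if_else(
      .data$reportable_d1, .data$auc_tau_ss / .data$auc_inf_d1, NA_real_
    ),
    flags = dplyr::if_else(.data$reportable_d1, NA_character_,
                           "day1_auc_inf_not_reportable")
  )
}

#' Study-level summary of NCA parameters
#'
#' Summarises per-profile NCA results the way PK tables are usually
#' presented: geometric mean (geometric CV%) for Cmax and the AUCs, median
#' (range) for tmax, arithmetic mean (SD) for half-life and the clearances.
#' Profiles whose AUCinf failed a reportability gate contribute nothing to
#' the AUCinf/half-life/clearance rows (their `n` drops accordingly).
#'
#' @param nca Output of [run_nca()].
#' @param rounding Apply the table rounding profile to the `formatted`
#'   column (3 significant figures for concentrations/AUCs, 1 decimal for
#'   half-life and clearances, 2 decimals for tmax). Default TRUE.
#' @return Long tibble: `analyte`, `treatment`, `day`, `parameter`, `n`,
#'   summary-statistic columns and a `formatted` display string.
#' @export
summarize_nca <- function(nca, rounding = TRUE) {
  geo_pars <- c("cmax", "auc_last", "auc_tau", "auc_inf")
  arith_pars <- c("half_life", "cl", "clr")

  one_group <- function(df) {
    rows <- list()
    for (p in geo_pars) {
      v <- df[[p]][!is.na(df[[p]])]
      if (length(v) == 0) next
      g <- geometric_summary(v)
      rows[[p]] <- tibble::tibble(
        parameter = p, n = g$n, estimate = g$geometric_mean,
        spread = g$geometric_cv_percent, stat = "geomean (CV%)",
        formatted = sprintf("%s (%s)",
                            fmt_sig3(g$geometric_mean, rounding),
                            fmt_1dp(g$geometric_cv_percent, rounding))
      )
    }
    v <- df$tmax[!is.na(df$tmax)]
    if (length(v) > 0) {
      rows[["tmax"]] <- tibble::tibble(
        parameter = "tmax", n = length(v), estimate = median(v),
        spread = NA_real_, stat = "median (range)",
        formatted = sprintf("%s (%s-%s)", fmt_2dp(median(v), rounding),
                            fmt_2dp(min(v), rounding), fmt_2dp(max(v), rounding))
      )
    }
    for (p in arith_pars) {
      v <- df[[p]][!is.na(df[[p]])]
      if (length(v) == 0) next
      s <- if (length(v) >= 2) sd(v) else NA_real_
      rows[[p]] <- tibble::tibble(
        parameter = p, n = length(v), estimate = mean(v), spread = s,
        stat = "mean (SD)",
        formatted = sprintf("%s (%s)", fmt_1dp(mean(v), rounding),
                            fmt_1dp(s, rounding))
      )
    }
    dplyr::bind_rows(rows)
  }

  nca |>
    dplyr::group_by(.data$analyte, .data$treatment, .data$day) |>
    dplyr::group_modify(~ one_group(.x)) |>
    dplyr::ungroup()
}

#' Half-up rounding
#'
#' Rounds with ties away from zero (0.5 -> 1), the convention of the
#' reporting tables, unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_sig3 <- function(x, rounding = TRUE) {
  if (is.na(x)) return(NA_character_)
  if (!rounding) return(format(x))
  format(signif(x, 3), big.mark = "", trim = TRUE, scientific = FALSE)
}
fmt_1dp <- function(x, rounding = TRUE) {
  if (is.na(x)) return(NA_character_)
  if (!rounding) return(format(x))
  sprintf("%.1f", round_half_up(x, 1))
}
fmt_2dp <- function(x, rounding = TRUE) {
  if (is.na(x)) return(NA_character_)
  if (!rounding) return(format(x))
  sprintf("%.2f", round_half_up(x, 2))
}
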