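#' Reshape NCA results into crossover observations
#'
#' Pivots per-profile NCA results into the long observation layout the
#' equivalence analysis consumes: one row per subject x treatment x analyte
#' x day x parameter, keeping only positive values.
#'
#' @param nca Output of [run_nca()].
#' @param parameters Which NCA columns to carry (default the exposure
#'   parameters used for interaction testing).
#' @return Tibble with columns `subject`, `sequence`, `period`, `treatment`,
#'   `analyte`, `day`, `parameter`, `value`.
#' @export
nca_to_observations <- function(nca,
                                parameters = c("auc_inf", "auc_tau", "cmax")) {
  nca |>
    dplyr::select(dplyr::all_of(c("subject", "sequence", "period",
                                  "treatment", "analyte", "day", parameters))) |>
    tidyr::pivot_longer(dplyr::all_of(parameters), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value), .data$value > 0)
}

#' Geometric LS-mean ratio of two treatments in a crossover
#'
#' Estimates the test/reference geometric mean ratio of a log-normal PK
#' parameter from a crossover study, with a 90% (by default) confidence
#' interval. The estimator is the within-subject period-adjusted contrast on
#' natural-log values: for each subject with both treatments, the
#' log-difference test minus reference is formed; subjects are grouped by
#' the period pattern in which they received the pair, the estimate is the
#' unweighted mean of the pattern-group means (which removes additive period
#' effects), and the variance is pooled within patterns. For complete
#' balanced data this coincides with the treatment LS-mean difference of the
#' usual mixed model with sequence, period and treatment fixed effects and
#' subject-within-sequence random effect. With a single pattern it reduces
#' to the paired t contrast with `n - 1` degrees of freedom; with G patterns
#' the degrees of freedom are `n - G`. Subjects lacking either treatment are
#' excluded and counted.
#'
#' @param data Data frame with columns `subject`, `period`, `treatment`,
#'   `value` (positive). Rows for other treatments are ignored.
#' @param test,reference Treatment labels to contrast.
#' @param conf_level Two-sided confidence level (default 0.90, i.e. two
#'   one-sided 5% tests).
#' @param limits Equivalence limits on the ratio scale as fractions
#'   (default `c(0.8, 1.25)`); the CI is compared against them in percent.
#' @return An object of class `pk_ratio`; see [tidy.pk_ratio()].
#' @examples
#' d <- tibble::tibble(
#'   subject = rep(1:4, each = 2), period = rep(1:2, 4),
#'   treatment = rep(c("A", "B"), 4),
#'   value = exp(c(0.1, 0, -0.1, 0, 0.2, 0, -0.2, 0))
#' )
#' tidy(ls_mean_ratio(d, test = "A", reference = "B"))
#' @export
ls_mean_ratio <- function(data, test, reference, conf_level = 0.90,
                          limits = c(0.8, 1.25)) {
  stopifnot(is.data.frame(data),
            all(c("subject", "period", "treatment", "value") %in% names(data)))
  sub <- dplyr::filter(data, .data$treatment %in% c(test, reference))
  if (any(sub$value <= 0)) abort("`value` must be positive (log scale).")
  dup <- sub |>
    dplyr::count(.data$subject, .data$treatment) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort("Each subject must have exactly one observation per treatment.")
  }
  wide <- sub |>
    dplyr::mutate(role = dplyr::if_else(.data$treatment == test,
                                        "test", "reference")) |>
    tidyr::pivot_wider(id_cols = "subject",
                       names_from = "role",
                       values_from = c("value", "period"))
  n_excluded <- sum(is.na(wide$value_test) | is.na(wide$value_reference))
  wide <- dplyr::filter(wide, !is.na(.data$value_test),
                        !is.na(.data$value_reference))
  n <- nrow(wide)
  if (n < 3) abort("Fewer than 3 subjects with both treatments.")

  d <- log(wide$value_test) - log(wide$value_reference)
  pattern <- paste(wide$period_test, wide$period_reference, sep = ">")
  grp <- split(d, pattern)
  g_means <- vapply(grp, mean, numeric(1))
  g_n <- vapply(grp, length, integer(1))
  G <- length(grp)
  est <- mean(g_means)
  if (G == 1L) {
    df <- n - 1L
    se <- sd(d) / sqrt(n)
  } else {
    df <- n - G
    s2 <- sum(vapply(grp, function(x) sum((x - mean(x))^2), numeric(1))) / df
    se <- sqrt(s2 * sum(1 / g_n)) / G
  }
  alpha2 <- (1 - conf_level) / 2
  half <- if (se == 0 || df < 1) 0 else qt(1 - alpha2, df) * se
  structure(
    list(
      test = test, reference = reference,
      estimate_log = est, se_log = se, df = df,
      ratio_percent = 100 * exp(est),
      ci_low_percent = 100 * exp(est - half),
      ci_high_percent = 100 * exp(est + half),
      conf_level = conf_level, limits_percent = 100 * limits,
      n_subjects_used = n, n_subjects_excluded = n_excluded,
      n_patterns = G
    ),
    class = "pk_ratio"
  )
}

#' @export
print.pk_ratio <- function(x, ...) {
  cat(sprintf("<pk_ratio> %s / %s\n", x$test, x$reference))
  cat(sprintf("  ratio %.1f%% (%.0f%% CI %.1f-%.1f), n = %d, df = %d\n",
              x$ratio_percent, 100 * x$conf_level, x$ci_low_percent,
              x$ci_high_percent, x$n_subjects_used, x$df))
  cat(sprintf("  within %g-%g%% limits: %s\n", x$limits_percent[1],
              x$limits_percent[2], within_limits(x)))
  invisible(x)
}

within_limits <- function(x) {
  x$ci_low_percent >= x$limits_percent[1] &&
    x$ci_high_percent <= x$limits_percent[2]
}

#' Tidy a geometric mean ratio result
#'
#' @param x A `pk_ratio` from [ls_mean_ratio()].
#' @param ... Unused.
#' @return One-row tibble: contrast, ratio (%), CI bounds (%), subjects
#'   used/excluded, degrees of freedom and the within-limits decision
#'   (closed interval: bounds exactly at 80 or 125 count as within).
#' @method tidy pk_ratio
#' @export
tidy.pk_ratio <- function(x, ...) {
  tibble::tibble(
    test = x$test, reference = x$reference,
    ratio_percent = x$ratio_percent,
    ci_low_percent = x$ci_low_percent, ci_high_percent = x$ci_high_percent,
    conf_level = x$conf_level, df = x$df,
    n_subjects_used = x$n_subjects_used,
    n_subjects_excluded = x$n_subjects_excluded,
    within_limits = within_limits(x)
  )
}

#' Drug-drug interaction analysis over a set of contrasts
#'
#' Runs [ls_mean_ratio()] for every requested analyte x day x parameter
#' contrast. Following the usual convention, Day-1 exposure is tested on
#' AUC to infinity and Cmax, steady state on AUC(0-tau) and Cmax.
#'
#' @param observations Output of [nca_to_observations()].
#' @param contrasts Tibble with columns `analyte`, `test`, `reference`
#'   (treatment labels).
#' @param day1,steady Day indices analysed (set either to `NULL` to skip).
#' @param conf_level,limits Passed to [ls_mean_ratio()].
#' @return An object of class `pk_ddi` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
ddi_analysis <- function(observations, contrasts, day1 = 1, steady = 4,
                         conf_level = 0.90, limits = c(0.8, 1.25)) {
  plan <- dplyr::bind_rows(
    if (!is.null(day1)) tidyr::expand_grid(
      contrasts, day = day1, parameter = c("auc_inf", "cmax")
    ),
    if (!is.null(steady)) tidyr::expand_grid(
      contrasts, day = steady, parameter = c("auc_tau", "cmax")
    )
  )
  rows <- purrr::pmap(plan, function(analyte, test, reference, day,
                                     parameter) {
    obs <- dplyr::filter(observations, .data$analyte == !!analyte,
                         .data$day == !!day, .data$parameter == !!parameter)
    if (nrow(obs) == 0) return(NULL)
    res <- tryCatch(
      ls_mean_ratio(obs, test = test, reference = reference,
                    conf_level = conf_level, limits = limits),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(analyte = analyte, day = day, parameter = parameter),
      tidy(res)
    )
  })
  results <- dplyr::bind_rows(rows)
  structure(
    list(results = results, limits_percent = 100 * limits,
         conf_level = conf_level, n_planned = nrow(plan)),
    class = "pk_ddi"
  )
}

#' @method tidy pk_ddi
#' @export
tidy.pk_ddi <- function(x, ...) x$results

#' Overall no-interaction decision for a DDI analysis
#'
#' @param x A `pk_ddi` from [ddi_analysis()].
#' @param ... Unused.
#' @return One-row tibble: number of contrasts evaluated/planned, number
#'   within the limits, and `no_interaction` - `TRUE` only when every
#'   planned contrast was evaluable and every CI lies inside the limits.
#' @method glance pk_ddi
#' @export
glance.pk_ddi <- function(x, ...) {
  tibble::tibble(
    n_contrasts = nrow(x$results),
    n_planned = x$n_planned,
    n_within = sum(x$results$within_limits),
    complete = nrow(x$results) == x$n_planned,
    no_interaction = nrow(x$results) == x$n_planned &&
      all(x$results$within_limits)
  )
}

#' Interaction decision report
#'
#' Declares "no interaction" iff every contrast's CI lies within the
#' equivalence limits (closed interval); otherwise lists the failing
#' contrasts. Errors if any planned contrast is missing.
#'
#' @param x A `pk_ddi` from [ddi_analysis()].
#' @return List with `decision` ("no interaction" or
#'   "interaction not excluded"), `failing` (tibble of failing contrasts)
#'   and the full results.
#' @export
interaction_decision <- function(x) {
  stopifnot(inherits(x, "pk_ddi"))
  g <- glance(x)
  if (!g$complete) {
    abort(sprintf("Incomplete analysis: %d of %d planned contrasts evaluable.",
                  g$n_contrasts, g$n_planned))
  }
  failing <- dplyr::filter(x$results, !.data$within_limits)
  list(
    decision = if (nrow(failing) == 0) "no interaction" else
      "interaction not excluded",
    failing = failing,
    results = x$results,
    limits_percent = x$limits_percent
  )
}

#' @export
print.pk_ddi <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<pk_ddi> %d contrast(s), %d within %g-%g%%\n",
              g$n_contrasts, g$n_within, x$limits_percent[1],
              x$limits_percent[2]))
  print(x$results)
  invisible(x)
}
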