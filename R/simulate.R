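#' Simulate a crossover study dataset
#'
#' Generates seeded plasma-concentration, urine-collection and dose-event
#' records for a [crossover_design()]. Between-subject variability is a
#' log-normal subject-level size multiplier applied jointly to CL and V
#' (so each subject's whole curve scales by its reciprocal); within-subject
#' variability is a log-normal period-level multiplier on the curve,
#' parameterized as (CL, V) -> (CL/m, V/m) so that the within-subject SD of
#' log Cmax and log AUC equals `within_subject_sd_log` exactly while urinary
#' mass balance is preserved. Independent proportional assay noise is then
#' added to each measurement, and concentrations below the analyte's LLOQ
#' are flagged BLQ.
#'
#' Treatment periods are simulated independently: with a washout of at least
#' 48 h (many terminal half-lives for these analytes) carryover is
#' negligible and is not modelled.
#'
#' @param design A [crossover_design()].
#' @param pk Named list of [pk_params()] per analyte (default
#'   [default_pk_parameters()]).
#' @param variability A [variability_model()].
#' @param lloq Named vector of LLOQs (ug/mL) per analyte, or a single number.
#' @param seed Integer master seed; per-subject streams are derived from it,
#'   so the output is reproducible.
#'
#' @return An object of class `pk_study`: a list of tibbles
#'   `concentrations` (subject, sequence, period, treatment, analyte, day,
#'   nominal_time, actual_time, concentration, blq, lloq), `urine` and
#'   `doses`, with the design and settings attached.
#' @examples
#' study <- simulate_crossover(design_caz_avi_ddi(n_subjects = 6), seed = 1)
#' dplyr::count(study$concentrations, analyte)
#' @export
simulate_crossover <- function(design,
                               pk = default_pk_parameters(),
                               variability = variability_model(),
                               lloq = default_lloq(),
                               seed = 1L) {
  stopifnot(inherits(design, "crossover_design"),
            inherits(variability, "variability_model"))
  analytes <- sort(unique(unlist(
    purrr::map(design$treatments, ~ .x$analyte)
  )))
  missing_pk <- setdiff(analytes, names(pk))
  if (length(missing_pk) > 0) {
    abort(sprintf("No PK parameters supplied for analyte(s): %s",
                  paste(missing_pk, collapse = ", ")))
  }
  lloq <- lloq_lookup(lloq, analytes)

  conc_all <- vector("list", design$n_subjects)
  urine_all <- vector("list", design$n_subjects)
  dose_all <- vector("list", design$n_subjects)

  for (i in seq_len(design$n_subjects)) {
    seq_idx <- (i - 1L) %% length(design$sequences) + 1L
    sequence <- design$sequences[[seq_idx]]
    seq_label <- paste(sequence, collapse = "-")
    set.seed((seed + 7919L * i) %% .Machine$integer.max)
    b <- setNames(rnorm(length(analytes), 0, variability$between_subject_sd_log),
                  analytes)

    subj_conc <- list(); subj_urine <- list(); subj_dose <- list()
    for (p in seq_along(sequence)) {
      trt <- sequence[p]
      per <- simulate_period(design, trt, pk, variability, b, lloq)
      ctx <- function(df) {
        dplyr::mutate(df, subject = i, sequence = seq_label, period = p,
                      treatment = trt, .before = 1)
      }
      subj_conc[[p]] <- ctx(per$conc)
      subj_urine[[p]] <- ctx(per$urine)
      subj_dose[[p]] <- ctx(per$doses)
    }
    conc_all[[i]] <- dplyr::bind_rows(subj_conc)
    urine_all[[i]] <- dplyr::bind_rows(subj_urine)
    dose_all[[i]] <- dplyr::bind_rows(subj_dose)
  }

  structure(
    list(
      concentrations = dplyr::bind_rows(conc_all),
      urine = dplyr::bind_rows(urine_all),
      doses = dplyr::bind_rows(dose_all),
      design = design, pk = pk, variability = variability,
      lloq = lloq, seed = seed
    ),
    class = "pk_study"
  )
}

lloq_lookup <- function(lloq, analytes) {
  if (length(lloq) == 1L && is.null(names(lloq))) {
    return(setNames(rep(lloq, length(analytes)), analytes))
  }
  out <- lloq[analytes]
  if (anyNA(out)) {
    abort(sprintf("No LLOQ supplied for analyte(s): %s",
                  paste(analytes[is.na(out)], collapse = ", ")))
  }
  out
}

# Dose events (absolute hours from period start) for one treatment period.
period_dose_events <- function(design, treatment) {
  tmpl <- design$treatments[[treatment]]
  rows <- list()
  for (d in design$single_days) {
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      tmpl, day = d, start_time = (d - 1) * 24 + .data$offset
    )
  }
  for (d in design$q8h_days) {
    for (h in c(0, 8, 16)) {
      rows[[length(rows) + 1L]] <- dplyr::mutate(
        tmpl, day = d, start_time = (d - 1) * 24 + h + .data$offset
      )
    }
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$analyte, .data$start_time)
}

treatment_sampling <- function(design, treatment) {
  design$sampling[[treatment]] %||% design$sampling[["default"]] %||%
    abort(sprintf("No sampling schedule for treatment '%s'.", treatment))
}

# One subject-period for one treatment. `b` holds the subject's per-analyte
# log size effects (already drawn); period-level effects and assay noise are
# drawn here, inside the subject's RNG stream.
simulate_period <- function(design, treatment, pk, var, b, lloq) {
  ev <- period_dose_events(design, treatment)
  sched <- treatment_sampling(design, treatment)
  analytes <- sort(unique(ev$analyte))
  w <- setNames(rnorm(length(analytes), 0, var$within_subject_sd_log), analytes)

  conc_rows <- list(); urine_rows <- list()
  for (a in analytes) {
    params <- pk[[a]]
    reg <- regimen(
      dplyr::transmute(dplyr::filter(ev, .data$analyte == a),
                       drug = .data$analyte, amount = .data$amount,
                       start_time = .data$start_time,
                       infusion_duration = .data$duration),
      tau = design$tau
    )
    curve_factor <- exp(w[[a]] - b[[a]])

    for (d in names(sched)) {
      day <- as.integer(d)
      if (day > design$n_days) next
      t_rel <- sched[[d]]
      t_abs <- (day - 1) * 24 + t_rel
      base <- multi_dose_concentration(params, reg, t_abs)
      meas <- base * curve_factor
      if (var$residual_cv > 0) {
        meas <- pmax(0, meas * (1 + rnorm(length(meas), 0, var$residual_cv)))
      }
      conc_rows[[length(conc_rows) + 1L]] <- tibble::tibble(
        analyte = a, day = day, nominal_time = t_rel, actual_time = t_rel,
        concentration = meas, blq = FALSE, lloq = lloq[[a]]
      )
    }

    if (params$renal_fraction > 0) {
      for (d in design$urine_days) {
        if (d > design$n_days) next
        for (iv in design$urine_intervals) {
          amt <- cumulative_urine_amount(
            params, reg, (d - 1) * 24 + iv[1], (d - 1) * 24 + iv[2]
          )
          if (var$residual_cv > 0) {
            amt <- max(0, amt * (1 + rnorm(1, 0, var$residual_cv)))
          }
          urine_rows[[length(urine_rows) + 1L]] <- tibble::tibble(
            analyte = a, day = d, interval_start = iv[1], interval_end = iv[2],
            amount_excreted = amt
          )
        }
      }
    }
  }

  conc <- apply_lloq(dplyr::bind_rows(conc_rows))
  urine <- if (length(urine_rows) > 0) dplyr::bind_rows(urine_rows) else
    tibble::tibble(analyte = character(), day = integer(),
                   interval_start = numeric(), interval_end = numeric(),
                   amount_excreted = numeric())
  doses <- dplyr::transmute(ev, drug = .data$analyte, day = .data$day,
                            amount = .data$amount, start_time = .data$start_time,
                            infusion_duration = .data$duration)
  list(conc = conc, urine = urine, doses = doses)
}

#' Flag concentrations below the limit of quantification
#'
#' Marks records with concentration strictly below the LLOQ as BLQ and
#' withholds their numeric value (set to `NA`); values exactly at the LLOQ
#' are retained. Downstream NCA treats leading BLQ values as 0 and drops
#' embedded/trailing ones.
#'
#' @param records Tibble of concentration records with columns
#'   `concentration` and either an `lloq` column or the `lloq` argument.
#' @param lloq Optional LLOQ (ug/mL): a single number, or a named vector
#'   keyed by analyte (requires an `analyte` column).
#' @return The records with `blq` and `concentration` updated and an
#'   `lloq` column present.
#' @examples
#' apply_lloq(tibble::tibble(concentration = c(0, 0.039, 0.04)), lloq = 0.04)
#' @export
apply_lloq <- function(records, lloq = NULL) {
  stopifnot(is.data.frame(records), "concentration" %in% names(records))
  if (any(records$concentration < 0, na.rm = TRUE)) {
    abort("Negative concentrations are not valid input.")
  }
  if (!is.null(lloq)) {
    if (length(lloq) > 1L || !is.null(names(lloq))) {
      if (!"analyte" %in% names(records)) {
        abort("A named `lloq` vector requires an `analyte` column.")
      }
      records$lloq <- unname(lloq[records$analyte])
      if (anyNA(records$lloq)) abort("Missing LLOQ for some analytes.")
    } else {
      records$lloq <- lloq
    }
  }
  if (!"lloq" %in% names(records)) {
    abort("Provide `lloq` or an `lloq` column.")
  }
  dplyr::mutate(
    records,
    blq = !is.na(.data$concentration) & .data$concentration < .data$lloq |
      is.na(.data$concentration),
    concentration = dplyr::if_else(.data$blq, NA_real_, .data$concentration)
  )
}

#' Write a simulated study to long-format CSV files
#'
#' Writes `concentrations.csv`, `urine.csv` and `doses.csv` into `dir`.
#' Times are written in hours with 2-decimal precision; concentrations and
#' amounts at full precision. Output is byte-identical for identical input.
#'
#' @param study A `pk_study` from [simulate_crossover()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study_csv <- function(study, dir) {
  stopifnot(inherits(study, "pk_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  conc <- dplyr::mutate(study$concentrations,
                        nominal_time = round(.data$nominal_time, 2),
                        actual_time = round(.data$actual_time, 2))
  paths <- c(
    concentrations = file.path(dir, "concentrations.csv"),
    urine = file.path(dir, "urine.csv"),
    doses = file.path(dir, "doses.csv")
  )
  readr::write_csv(conc, paths["concentrations"])
  readr::write_csv(study$urine, paths["urine"])
  readr::write_csv(study$doses, paths["doses"])
  invisible(paths)
}

#' Read a study previously written by [write_study_csv()]
#'
#' @param dir Directory containing `concentrations.csv`, `urine.csv`,
#'   `doses.csv`.
#' @return A list of tibbles `concentrations`, `urine`, `doses`.
#' @export
read_study_csv <- function(dir) {
  read1 <- function(f) readr::read_csv(file.path(dir, f),
                                       show_col_types = FALSE,
                                       progress = FALSE)
  list(
    concentrations = read1("concentrations.csv"),
    urine = read1("urine.csv"),
    doses = read1("doses.csv")
  )
}

#' @export
print.pk_study <- function(x, ...) {
  cat(sprintf("<pk_study> simulated '%s' (seed %d)\n", x$design$name, x$seed))
  cat(sprintf("  %d concentration records, %d urine records, %d dose events\n",
              nrow(x$concentrations), nrow(x$urine), nrow(x$doses)))
  invisible(x)
}
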