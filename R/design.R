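#' Crossover study design
#'
#' Describes a (possibly single-arm) crossover study of IV-infused treatments:
#' which analytes each treatment delivers and how, the sequence assignments,
#' the dosing calendar (single dose on the first and last study days, q8h on
#' the days between), the blood-sampling schedule per treatment and sampled
#' day, and the urine collection intervals.
#'
#' @param name Design label.
#' @param treatments Named list; each element is a tibble of per-analyte dose
#'   templates with columns `analyte`, `amount` (mg), `offset` (h after the
#'   day's reference start) and `duration` (h).
#' @param sequences List of character vectors; each a permutation of
#'   `names(treatments)` (one period per treatment). Subjects are assigned to
#'   sequences round-robin.
#' @param n_subjects Number of subjects (>= 1).
#' @param n_days Length of a treatment period in days.
#' @param single_days Days with a single morning dose (first and last).
#' @param q8h_days Days dosed every 8 h (three doses).
#' @param sampling Named list keyed by treatment name (or `"default"`);
#'   each element a named list keyed by day number (as character) giving the
#'   nominal blood-sampling times (h after the day's reference start).
#' @param urine_days Days on which urine is collected.
#' @param urine_intervals List of `c(start, end)` collection intervals (h
#'   after the day's reference start).
#' @param tau Dosing interval (h) used for AUC(0-tau).
#' @param washout Washout between periods (h); must be >= 48.
#'
#' @return An object of class `crossover_design`.
#' @seealso [design_caz_avi_pk()], [design_caz_avi_ddi()],
#'   [design_caz_avi_mtz_ddi()] for the built-in study designs.
#' @export
crossover_design <- function(name, treatments, sequences, n_subjects,
                             n_days, single_days, q8h_days,
                             sampling, urine_days = integer(),
                             urine_intervals = list(),
                             tau = 8, washout = 48) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  if (washout < 48) abort("`washout` must be >= 48 h.")
  trt_names <- names(treatments)
  if (is.null(trt_names) || any(trt_names == "")) {
    abort("`treatments` must be a named list.")
  }
  for (s in sequences) {
    if (!setequal(s, trt_names) || length(s) != length(trt_names)) {
      abort(sprintf(
        "Sequence '%s' is not a permutation of the treatments (%s).",
        paste(s, collapse = ","), paste(trt_names, collapse = ",")
      ))
    }
  }
  structure(
    list(
      name = name, treatments = treatments, sequences = sequences,
      n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
      single_days = as.integer(single_days), q8h_days = as.integer(q8h_days),
      sampling = sampling, urine_days = as.integer(urine_days),
      urine_intervals = urine_intervals, tau = tau, washout = washout
    ),
    class = "crossover_design"
  )
}

#' @export
print.crossover_design <- function(x, ...) {
  cat(sprintf("<crossover_design> %s\n", x$name))
  cat(sprintf("  %d subjects, %d treatment(s), %d period(s), %d-day periods\n",
              x$n_subjects, length(x$treatments), length(x$sequences[[1]]),
              x$n_days))
  cat(sprintf("  single dose on days %s; q8h on days %s; washout >= %g h\n",
              paste(x$single_days, collapse = ", "),
              paste(x$q8h_days, collapse = ", "), x$washout))
  invisible(x)
}

# Reference Day-1 blood-sampling schedule for 2-h ceftazidime-avibactam
# infusions (predose through 24 h), and the sparser steady-state day schedule.
caz_avi_day1_sampling <- function() {
  c(0, 0.5, 1, 1.5, 2, 2.25, 2.5, 2.75, 3, 3.5, 4, 6, 8, 12, 24)
}
caz_avi_ss_sampling <- function() c(0, 1, 2, 3, 4, 6, 8)

default_urine_intervals <- function() {
  list(c(0, 2), c(2, 4), c(4, 8), c(8, 12), c(12, 24))
}

caz_template <- function() {
  tibble::tibble(analyte = "ceftazidime", amount = 2000, offset = 0, duration = 2)
}
avi_template <- function() {
  tibble::tibble(analyte = "avibactam", amount = 500, offset = 0, duration = 2)
}
mtz_template <- function(offset = 0) {
  tibble::tibble(analyte = "metronidazole", amount = 500, offset = offset,
                 duration = 1)
}

#' Built-in design: multiple-dose PK of ceftazidime-avibactam
#'
#' Single-arm 11-day study: one 2-h infusion of ceftazidime 2000 mg +
#' avibactam 500 mg on Days 1 and 11, q8h on Days 2-10. Rich sampling on
#' Days 1 and 11, sparse on Day 4; urine collected on Days 1 and 11.
#'
#' @param n_subjects Number of subjects (default 16).
#' @return A [crossover_design()].
#' @export
design_caz_avi_pk <- function(n_subjects = 16) {
  crossover_design(
    name = "caz_avi_pk",
    treatments = list(caz_avi = dplyr::bind_rows(caz_template(), avi_template())),
    sequences = list("caz_avi"),
    n_subjects = n_subjects,
    n_days = 11, single_days = c(1, 11), q8h_days = 2:10,
    sampling = list(default = list(
      `1` = caz_avi_day1_sampling(),
      `4` = caz_avi_ss_sampling(),
      `11` = caz_avi_day1_sampling()
    )),
    urine_days = c(1, 11), urine_intervals = default_urine_intervals()
  )
}

#' Built-in design: ceftazidime / avibactam interaction crossover
#'
#' 3-way crossover (ceftazidime 2000 mg, avibactam 500 mg, or both; all 2-h
#' infusions), 4-day periods with single doses on Days 1 and 4 and q8h dosing
#' on Days 2-3, washout >= 48 h. Blood and urine sampled on Days 1 and 4.
#'
#' @param n_subjects Number of subjects (default 27).
#' @return A [crossover_design()].
#' @export
design_caz_avi_ddi <- function(n_subjects = 27) {
  sched <- list(`1` = caz_avi_day1_sampling(), `4` = caz_avi_day1_sampling())
  crossover_design(
    name = "caz_avi_ddi",
    treatments = list(
      caz = caz_template(),
      avi = avi_template(),
      caz_avi = dplyr::bind_rows(caz_template(), avi_template())
    ),
    sequences = list(
      c("caz", "avi", "caz_avi"),
      c("avi", "caz_avi", "caz"),
      c("caz_avi", "caz", "avi")
    ),
    n_subjects = n_subjects,
    n_days = 4, single_days = c(1, 4), q8h_days = 2:3,
    sampling = list(default = sched),
    urine_days = c(1, 4), urine_intervals = default_urine_intervals()
  )
}

#' Built-in design: ceftazidime-avibactam / metronidazole interaction crossover
#'
#' 3-way crossover: ceftazidime 2000 mg-avibactam 500 mg (2-h infusion),
#' metronidazole 500 mg (1-h infusion), or metronidazole followed by
#' ceftazidime-avibactam (combined treatment: metronidazole over hour 0-1,
#' then the 2-h ceftazidime-avibactam infusion over hours 1-3). Single doses
#' on Days 1 and 4, q8h on Days 2-3, so each component is given 8 times per
#' subject. Sampling times are relative to the start of the first infusion
#' and differ by treatment.
#'
#' @param n_subjects Number of subjects (default 28).
#' @return A [crossover_design()].
#' @export
design_caz_avi_mtz_ddi <- function(n_subjects = 28) {
  samp_caz_avi <- c(0, 0.5, 1, 1.5, 2, 2.25, 2.5, 2.75, 3, 4, 5, 7, 11, 23)
  samp_mtz <- c(0, 0.5, 1, 1.25, 1.5, 2, 3, 4, 6, 8, 12, 24)
  samp_combo <- c(0, 0.5, 1, 1.25, 1.5, 2, 2.5, 3, 3.25, 3.5, 3.75, 4, 5, 6,
                  8, 12, 24)
  crossover_design(
    name = "caz_avi_mtz_ddi",
    treatments = list(
      caz_avi = dplyr::bind_rows(caz_template(), avi_template()),
      mtz = mtz_template(),
      caz_avi_mtz = dplyr::bind_rows(
        mtz_template(offset = 0),
        dplyr::mutate(caz_template(), offset = 1),
        dplyr::mutate(avi_template(), offset = 1)
      )
    ),
    sequences = list(
      c("caz_avi", "mtz", "caz_avi_mtz"),
      c("mtz", "caz_avi_mtz", "caz_avi"),
      c("caz_avi_mtz", "caz_avi", "mtz")
    ),
    n_subjects = n_subjects,
    n_days = 4, single_days = c(1, 4), q8h_days = 2:3,
    sampling = list(
      caz_avi = list(`1` = samp_caz_avi, `4` = samp_caz_avi),
      mtz = list(`1` = samp_mtz, `4` = samp_mtz),
      caz_avi_mtz = list(`1` = samp_combo, `4` = samp_combo)
    ),
    urine_days = c(1, 4), urine_intervals = default_urine_intervals()
  )
}

#' Default disposition parameters per analyte
#'
#' One-compartment calibration choices matched to the reported clearances and
#' terminal half-lives of each analyte (ceftazidime CL 7 L/h, t1/2 2.7 h;
#' avibactam CL 12 L/h, t1/2 2.3 h, fully renally cleared; metronidazole
#' CL 4.35 L/h, t1/2 8.4 h, negligible renal elimination of parent drug at
#' the level modelled here). Volumes are derived as CL * t1/2 / ln 2.
#'
#' @return Named list of [pk_params()] keyed by analyte.
#' @export
default_pk_parameters <- function() {
  vol <- function(cl, thalf) cl * thalf / log(2)
  list(
    ceftazidime = pk_params(7, vol(7, 2.7), renal_fraction = 0.95),
    avibactam = pk_params(12, vol(12, 2.3), renal_fraction = 1),
    metronidazole = pk_params(4.35, vol(4.35, 8.4), renal_fraction = 0)
  )
}

#' Default lower limits of quantification per analyte (ug/mL)
#'
#' Metronidazole 0.040 ug/mL (40.0 ng/mL); ceftazidime and avibactam at the
#' bottom of their low-range plasma calibration curves (0.0446 and 0.010
#' ug/mL).
#'
#' @return Named numeric vector (ug/mL).
#' @export
default_lloq <- function() {
  c(ceftazidime = 0.0446, avibactam = 0.010, metronidazole = 0.040)
}

#' Variability model for the synthetic-data generator
#'
#' @param between_subject_sd_log SD of the subject-level log-scale size
#'   multiplier (applied jointly to CL and V, so concentrations scale by the
#'   reciprocal of the multiplier). Default gives a geometric CV of about
#'   15%.
#' @param within_subject_sd_log SD sigma_w of the period-level log-scale
#'   multiplier on the whole concentration curve; this is the within-subject
#'   SD of log Cmax (and log AUC) the equivalence power calculation uses.
#' @param residual_cv Proportional assay noise on each measured
#'   concentration and urine amount.
#'
#' @return An object of class `variability_model`.
#' @export
variability_model <- function(between_subject_sd_log = sqrt(log(1 + 0.15^2)),
                              within_subject_sd_log = 0.2171,
                              residual_cv = 0.05) {
  if (between_subject_sd_log < 0 || within_subject_sd_log < 0 ||
      residual_cv < 0) {
    abort("Variability SDs must be nonnegative.")
  }
  structure(
    list(
      between_subject_sd_log = between_subject_sd_log,
      within_subject_sd_log = within_subject_sd_log,
      residual_cv = residual_cv
    ),
    class = "variability_model"
  )
}

#' Zero-variability model (noiseless simulation)
#' @return A [variability_model()] with all components 0.
#' @export
no_variability <- function() variability_model(0, 0, 0)
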