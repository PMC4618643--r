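#' Compartmental parameters for an IV-infusion disposition model
#'
#' Bundles the parameters of a one- or two-compartment linear disposition
#' model. The model order is implied by the optional fields: supplying
#' `peripheral_volume` and `intercompartmental_clearance` selects the
#' two-compartment model, omitting both selects the one-compartment model.
#'
#' @param clearance Total plasma clearance CL (L/h). Positive.
#' @param central_volume Volume of the central compartment (L). Positive.
#' @param peripheral_volume Optional peripheral compartment volume (L).
#' @param intercompartmental_clearance Optional distributional clearance
#'   Q (L/h). Must be supplied together with `peripheral_volume`.
#' @param renal_fraction Fraction of clearance that is renal, in \[0, 1\].
#'   Renal clearance is `renal_fraction * clearance`.
#'
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(clearance = 12, central_volume = 40, renal_fraction = 1)
#' @export
pk_params <- function(clearance, central_volume,
                      peripheral_volume = NULL,
                      intercompartmental_clearance = NULL,
                      renal_fraction = 0) {
  if (!is.numeric(clearance) || length(clearance) != 1L || clearance <= 0) {
    abort("`clearance` must be a single positive number (L/h).")
  }
  if (!is.numeric(central_volume) || length(central_volume) != 1L ||
      central_volume <= 0) {
    abort("`central_volume` must be a single positive number (L).")
  }
  two_cpt <- !is.null(peripheral_volume) || !is.null(intercompartmental_clearance)
  if (two_cpt) {
    if (is.null(peripheral_volume) || is.null(intercompartmental_clearance)) {
      abort(paste(
        "Supply both `peripheral_volume` and `intercompartmental_clearance`",
        "for the two-compartment model."
      ))
    }
    if (peripheral_volume <= 0 || intercompartmental_clearance <= 0) {
      abort("Two-compartment parameters must be positive.")
    }
  }
  if (!is.numeric(renal_fraction) || renal_fraction < 0 || renal_fraction > 1) {
    abort("`renal_fraction` must lie in [0, 1].")
  }
  structure(
    list(
      clearance = clearance,
      central_volume = central_volume,
      peripheral_volume = peripheral_volume,
      intercompartmental_clearance = intercompartmental_clearance,
      renal_fraction = renal_fraction
    ),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  n_cpt <- if (is.null(x$peripheral_volume)) 1L else 2L
  cat(sprintf("<pk_params> %d-compartment IV disposition model\n", n_cpt))
  cat(sprintf("  CL = %g L/h, Vc = %g L", x$clearance, x$central_volume))
  if (n_cpt == 2L) {
    cat(sprintf(", Vp = %g L, Q = %g L/h",
                x$peripheral_volume, x$intercompartmental_clearance))
  }
  cat(sprintf(", renal fraction = %g\n", x$renal_fraction))
  invisible(x)
}

# Macro-constants of the unit-bolus response: C_delta(t) = sum coef_i exp(-lambda_i t).
# For the 1-compartment model lambda = CL/V, coef = 1/V; for the 2-compartment
# model (alpha, beta) are the roots of the usual micro-constant quadratic.
macro_constants <- function(params) {
  cl <- params$clearance
  v1 <- params$central_volume
  if (is.null(params$peripheral_volume)) {
    return(list(lambda = cl / v1, coef = 1 / v1))
  }
  v2 <- params$peripheral_volume
  q <- params$intercompartmental_clearance
  k10 <- cl / v1
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  alpha <- (s + sqrt(s^2 - 4 * p)) / 2
  beta <- p / alpha
  list(
    lambda = c(alpha, beta),
    coef = c((alpha - k21) / (v1 * (alpha - beta)),
             (k21 - beta) / (v1 * (alpha - beta)))
  )
}

#' Terminal elimination rate constant of a disposition model
#'
#' The slowest macro-rate constant: CL/V for the one-compartment model, the
#' beta phase rate for the two-compartment model.
#'
#' @param params A [pk_params()] object.
#' @return Rate constant (1/h).
#' @export
terminal_rate_constant <- function(params) {
  min(macro_constants(params)$lambda)
}

#' A single IV-infusion dose event
#'
#' @param drug Analyte label.
#' @param amount Dose amount (mg). Positive.
#' @param start_time Infusion start (h). Nonnegative.
#' @param infusion_duration Infusion duration (h). Positive: doses are
#'   constant-rate infusions, bolus input is not modelled.
#'
#' @return A one-row tibble with columns `drug`, `amount`, `start_time`,
#'   `infusion_duration`.
#' @examples
#' dose_event("avibactam", 500, start_time = 0, infusion_duration = 2)
#' @export
dose_event <- function(drug, amount, start_time = 0, infusion_duration) {
  if (!is.numeric(amount) || any(amount <= 0)) {
    abort("`amount` must be positive (mg).")
  }
  if (!is.numeric(infusion_duration) || any(infusion_duration <= 0)) {
    abort("`infusion_duration` must be positive (h); only IV infusions are modelled.")
  }
  if (any(start_time < 0)) abort("`start_time` must be nonnegative (h).")
  tibble::tibble(
    drug = drug, amount = amount,
    start_time = start_time, infusion_duration = infusion_duration
  )
}

#' A dosing regimen: ordered dose events plus the dosing interval
#'
#' @param dose_events A tibble of dose events as built by [dose_event()]
#'   (rows may be bound together); will be sorted by `start_time`.
#' @param tau Dosing interval tau (h), the interval over which AUC(0-tau) is
#'   computed. Positive.
#'
#' @return An object of class `pk_regimen`.
#' @examples
#' regimen(dose_event("avibactam", 500, 0, 2), tau = 8)
#' @export
regimen <- function(dose_events, tau) {
  if (!is.data.frame(dose_events) || nrow(dose_events) == 0) {
    abort("`dose_events` must be a nonempty data frame of dose events.")
  }
  needed <- c("drug", "amount", "start_time", "infusion_duration")
  if (!all(needed %in% names(dose_events))) {
    abort("`dose_events` must have columns drug, amount, start_time, infusion_duration.")
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    abort("`tau` must be a single positive number (h).")
  }
  structure(
    list(
      dose_events = dplyr::arrange(tibble::as_tibble(dose_events), .data$start_time),
      tau = tau
    ),
    class = "pk_regimen"
  )
}

#' Every-q-hours multiple-dose regimen builder
#'
#' Convenience constructor for `n_doses` identical infusions `q` hours apart.
#'
#' @inheritParams dose_event
#' @param n_doses Number of doses.
#' @param q Inter-dose interval (h); also used as tau.
#' @param first_start Start of the first infusion (h).
#' @return A [regimen()] object.
#' @export
q_regimen <- function(drug, amount, infusion_duration, n_doses, q = 8,
                      first_start = 0) {
  regimen(
    dose_event(drug, amount,
               start_time = first_start + q * (seq_len(n_doses) - 1),
               infusion_duration = infusion_duration),
    tau = q
  )
}

# Closed-form concentration and cumulative AUC for one constant-rate infusion.
# `t` is vectorized; times before the infusion start give 0.
single_infusion_curve <- function(params, amount, start_time, duration, t,
                                  what = c("conc", "auc")) {
  what <- match.arg(what)
  mc <- macro_constants(params)
  r0 <- amount / duration
  tr <- t - start_time
  out <- numeric(length(t))
  for (i in seq_along(mc$lambda)) {
    lam <- mc$lambda[i]
    cf <- mc$coef[i]
    during <- tr > 0 & tr <= duration
    after <- tr > duration
    if (what == "conc") {
      out[during] <- out[during] +
        r0 * cf / lam * (1 - exp(-lam * tr[during]))
      out[after] <- out[after] +
        r0 * cf / lam * (1 - exp(-lam * duration)) *
          exp(-lam * (tr[after] - duration))
    } else {
      out[during] <- out[during] +
        r0 * cf / lam * (tr[during] - (1 - exp(-lam * tr[during])) / lam)
      auc_T <- r0 * cf / lam * (duration - (1 - exp(-lam * duration)) / lam)
      c_T_i <- r0 * cf / lam * (1 - exp(-lam * duration))
      out[after] <- out[after] + auc_T +
        c_T_i / lam * (1 - exp(-lam * (tr[after] - duration)))
    }
  }
  out
}

#' Plasma concentration during and after a single IV infusion
#'
#' Closed-form solution of the one- or two-compartment linear model with
#' constant-rate (zero-order) drug input. Concentration is 0 up to the
#' infusion start, rises during the infusion and decays (mono- or
#' bi-exponentially) afterwards.
#'
#' @param params A [pk_params()] object.
#' @param dose A one-row dose event from [dose_event()].
#' @param t Time (h), vectorized.
#' @return Concentration (ug/mL) at each `t`, for a dose in mg and volumes in L.
#' @examples
#' p <- pk_params(clearance = 7, central_volume = 20)
#' d <- dose_event("ceftazidime", 2000, 0, 2)
#' infusion_concentration(p, d, t = c(0, 1, 2, 4, 8))
#' @export
infusion_concentration <- function(params, dose, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) abort("`t` must be nonnegative.")
  single_infusion_curve(params, dose$amount[1], dose$start_time[1],
                        dose$infusion_duration[1], t, "conc")
}

#' Concentration under a multiple-dose regimen by superposition
#'
#' Linear time-invariant kinetics: the concentration is the sum of
#' single-infusion curves over all dose events that have started by `t`.
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()] object.
#' @param t Time (h), vectorized.
#' @return Concentration (ug/mL) at each `t`.
#' @export
multi_dose_concentration <- function(params, reg, t) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "pk_regimen"))
  if (any(t < 0)) abort("`t` must be nonnegative.")
  ev <- reg$dose_events
  out <- numeric(length(t))
  for (j in seq_len(nrow(ev))) {
    out <- out + single_infusion_curve(
      params, ev$amount[j], ev$start_time[j], ev$infusion_duration[j], t, "conc"
    )
  }
  out
}

# Cumulative plasma AUC of a regimen from 0 to t (closed form).
regimen_auc_to <- function(params, reg, t) {
  ev <- reg$dose_events
  out <- numeric(length(t))
  for (j in seq_len(nrow(ev))) {
    out <- out + single_infusion_curve(
      params, ev$amount[j], ev$start_time[j], ev$infusion_duration[j], t, "auc"
    )
  }
  out
}

#' Amount of drug excreted in urine over a collection interval
#'
#' For a linear model with constant renal fraction fe, the amount excreted
#' over \[t0, t1\] is `fe * CL * AUC(t0, t1)`, evaluated in closed form.
#' Over \[0, Inf) for a single dose this equals `fe * dose` (mass balance).
#'
#' @param params A [pk_params()] object.
#' @param reg A [regimen()] object.
#' @param t0,t1 Interval bounds (h), `0 <= t0 < t1`; `t1` may be `Inf`.
#' @return Excreted amount (mg).
#' @examples
#' p <- pk_params(12, 40, renal_fraction = 1)
#' r <- regimen(dose_event("avibactam", 500, 0, 2), tau = 8)
#' cumulative_urine_amount(p, r, 0, 24)
#' @export
cumulative_urine_amount <- function(params, reg, t0, t1) {
  stopifnot(inherits(params, "pk_params"), inherits(reg, "pk_regimen"))
  if (t0 < 0 || t1 <= t0) abort("Need 0 <= t0 < t1.")
  fe <- params$renal_fraction
  if (fe == 0) return(0)
  auc1 <- if (is.infinite(t1)) {
    sum(reg$dose_events$amount) / params$clearance
  } else {
    regimen_auc_to(params, reg, t1)
  }
  fe * params$clearance * (auc1 - regimen_auc_to(params, reg, t0))
}
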