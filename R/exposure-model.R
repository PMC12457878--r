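#' Allometric breathing rate from body weight
#'
#' Inhalation rate R \[m3/hour\] as a logarithmic function of body weight,
#' R = (5.3 ln(Wb) - 6.9) / 24, i.e. a daily volume 5.3 ln(Wb) - 6.9 m3/day
#' spread over 24 hours. The model is only physiologic for body weights
#' above about 10 kg (below that the numerator goes non-positive), so
#' lighter inputs are rejected rather than extrapolated.
#'
#' @param weight_kg Numeric vector of body weights \[kg\].
#' @param params A [risk_params()] object (supplies the model constants).
#' @param worker_id Optional labels used in error messages.
#' @return Breathing rates \[m3/hour\], same length as `weight_kg`.
#' @examples
#' breathing_rate(63) # 0.627442
#' @export
breathing_rate <- function(weight_kg, params = risk_params(), worker_id = NULL) {
  params <- as_risk_params(params)
  check_numeric(weight_kg, "weight_kg")
  bad <- which(weight_kg < 10)
  if (length(bad)) {
    stop("breathing_rate: body weight below 10 kg for ",
         offender_label(bad, worker_id),
         "; the allometric model is not valid there", call. = FALSE)
  }
  (params$br_slope * log(weight_kg) - params$br_shift) / 24
}

#' Convert an airborne concentration from ppm to mg/m3
#'
#' Uses the ideal-gas conversion C \[mg/m3\] = C \[ppm\] x M / Vm with
#' M the molar mass \[g/mol\] and Vm the molar volume of air \[L/mol\].
#' For benzene at the default 24.5 L/mol the factor is 78.11/24.5 = 3.188.
#'
#' @param concentration_ppm Numeric vector of concentrations \[ppm\], >= 0.
#' @inheritParams breathing_rate
#' @return Concentrations \[mg/m3\].
#' @examples
#' ppm_to_mgm3(1) # 3.1882
#' @export
ppm_to_mgm3 <- function(concentration_ppm, params = risk_params(),
                        worker_id = NULL) {
  params <- as_risk_params(params)
  check_numeric(concentration_ppm, "concentration_ppm")
  bad <- which(concentration_ppm < 0)
  if (length(bad)) {
    stop("ppm_to_mgm3: negative concentration for ",
         offender_label(bad, worker_id), call. = FALSE)
  }
  concentration_ppm * params$molecular_weight / params$molar_volume
}

#' Chronic daily inhalation intake
#'
#' The chronic daily intake of an inhaled contaminant,
#' \deqn{Ink = \frac{C \cdot R \cdot tE \cdot fE \cdot Dt}
#'                  {Wb \cdot t_{avg} \cdot 365}}
#' in mg per kg body weight per day, where C is the airborne concentration
#' \[mg/m3\], R the breathing rate \[m3/h\], tE the daily exposure \[h/day\],
#' fE the exposure frequency \[day/year\], Dt the exposure duration \[years\],
#' Wb the body weight \[kg\] and `t_avg` the averaging time
#' (`params$tavg_intake_years`, 30 years by default). Intake is linear in C
#' and in Dt and is zero for zero tenure.
#'
#' @param concentration_ppm Airborne benzene concentration \[ppm\].
#' @param weight_kg Body weight \[kg\].
#' @param hours_per_day Daily exposure tE \[h/day\], in (0, 24\].
#' @param days_per_year Annual exposure frequency fE \[day/year\], in (0, 365\].
#' @param tenure_years Exposure duration Dt \[years\], >= 0.
#' @inheritParams breathing_rate
#' @return Intake \[mg/kg/day\], vectorised over the inputs.
#' @examples
#' chronic_intake(0.6768, 63, 7, 312, 25) # 0.107155 (a 25-year sprayer)
#' @export
chronic_intake <- function(concentration_ppm, weight_kg, hours_per_day,
                           days_per_year, tenure_years,
                           params = risk_params(), worker_id = NULL) {
  params <- as_risk_params(params)
  validate_exposure_inputs(concentration_ppm, weight_kg, hours_per_day,
                           days_per_year, tenure_years, worker_id)
  c_mgm3 <- ppm_to_mgm3(concentration_ppm, params, worker_id)
  r <- breathing_rate(weight_kg, params, worker_id)
  (c_mgm3 * r * hours_per_day * days_per_year * tenure_years) /
    (weight_kg * params$tavg_intake_years * params$days_per_year_avg)
}

#' Non-carcinogenic Risk Quotient
#'
#' RQ = intake / RfC, rescaled by the ratio of averaging times when the
#' quotient uses a longer (lifetime) averaging period than the intake:
#' RQ = Ink x (tavg_intake / tavg_rq) / RfC. Under the 30/70 defaults this
#' is Ink x (3/7) / RfC; with `tavg_rq_years = tavg_intake_years` it is
#' exactly Ink / RfC. Workers with RQ at or above `params$rq_threshold`
#' (default 1) are considered at risk.
#'
#' @param intake Chronic daily intake \[mg/kg/day\], >= 0.
#' @param rfc Reference dose \[mg/kg/day\], > 0. Defaults to
#'   `params$rfc_default`; pass a vector for per-worker values.
#' @inheritParams breathing_rate
#' @return Dimensionless Risk Quotients.
#' @examples
#' risk_quotient(0.329663, rfc = 0.000313) # 451.39
#' @export
risk_quotient <- function(intake, rfc = NULL, params = risk_params(),
                          worker_id = NULL) {
  params <- as_risk_params(params)
  if (is.null(rfc)) rfc <- params$rfc_default
  check_numeric(intake, "intake")
  check_numeric(rfc, "rfc")
  if (any(intake < 0)) {
    stop("risk_quotient: negative intake for ",
         offender_label(which(intake < 0), worker_id), call. = FALSE)
  }
  if (any(rfc <= 0)) {
    stop("risk_quotient: RfC must be strictly positive (",
         offender_label(which(rfc <= 0), worker_id), ")", call. = FALSE)
  }
  intake * (params$tavg_intake_years / params$tavg_rq_years) / rfc
}

#' Classify workers against the RQ and TLV thresholds
#'
#' Applies the two binary rules of the assessment: a worker is `unsafe`
#' when RQ >= 1 (the boundary itself counts as unsafe) and `safe` otherwise,
#' and their measured air concentration is `above` the threshold limit value
#' when it strictly exceeds 0.5 ppm, `at_or_below` otherwise.
#'
#' @param rq Numeric vector of Risk Quotients.
#' @param concentration_ppm Airborne concentrations \[ppm\].
#' @inheritParams breathing_rate
#' @return A data.frame with factor columns `rq_class`
#'   (levels `unsafe`, `safe`) and `tlv_class` (levels `above`,
#'   `at_or_below`).
#' @export
classify_risk <- function(rq, concentration_ppm, params = risk_params()) {
  params <- as_risk_params(params)
  check_numeric(rq, "rq")
  check_numeric(concentration_ppm, "concentration_ppm")
  data.frame(
    rq_class = factor(ifelse(rq >= params$rq_threshold, "unsafe", "safe"),
                      levels = c("unsafe", "safe")),
    tlv_class = factor(ifelse(concentration_ppm > params$tlv_ppm,
                              "above", "at_or_below"),
                       levels = c("above", "at_or_below"))
  )
}

#' Run the full risk assessment over a worker roster
#'
#' The per-worker computation chain: breathing rate from body weight,
#' ppm to mg/m3 conversion, chronic daily intake, Risk Quotient and the two
#' threshold classifications. The reference dose is taken from the roster's
#' `rfc` column where present (NA falls back) and from
#' `params$rfc_default` otherwise.
#'
#' @param roster A roster data.frame as returned by [read_roster()] or
#'   [generate_cohort()]: columns `worker_id`, `concentration_ppm`,
#'   `weight_kg`, `hours_per_day`, `days_per_year`, `tenure_years`, and
#'   optionally `rfc`.
#' @inheritParams breathing_rate
#' @return A data.frame of class `benz_assessment`: the exposure columns
#'   plus `breathing_rate_m3h`, `concentration_mgm3`, `rfc`, `intake`, `rq`,
#'   `rq_class`, `tlv_class`. Biomarker columns present on the roster are
#'   carried through.
#' @examples
#' r <- table3_roster()
#' a <- assess_cohort(r)
#' head(a[, c("worker_id", "intake", "rq", "rq_class")])
#' @export
assess_cohort <- function(roster, params = risk_params()) {
  params <- as_risk_params(params)
  roster <- validate_roster(roster)
  id <- roster$worker_id
  rfc <- if ("rfc" %in% names(roster)) {
    ifelse(is.na(roster$rfc), params$rfc_default, roster$rfc)
  } else {
    rep(params$rfc_default, nrow(roster))
  }
  br <- breathing_rate(roster$weight_kg, params, id)
  cmg <- ppm_to_mgm3(roster$concentration_ppm, params, id)
  ink <- chronic_intake(roster$concentration_ppm, roster$weight_kg,
                        roster$hours_per_day, roster$days_per_year,
                        roster$tenure_years, params, id)
  rq <- risk_quotient(ink, rfc, params, id)
  cls <- classify_risk(rq, roster$concentration_ppm, params)
  out <- data.frame(
    worker_id = id,
    concentration_ppm = roster$concentration_ppm,
    weight_kg = roster$weight_kg,
    hours_per_day = roster$hours_per_day,
    days_per_year = roster$days_per_year,
    tenure_years = roster$tenure_years,
    breathing_rate_m3h = br,
    concentration_mgm3 = cmg,
    rfc = rfc,
    intake = ink,
    rq = rq,
    rq_class = cls$rq_class,
    tlv_class = cls$tlv_class,
    stringsAsFactors = FALSE
  )
  for (bm in intersect(biomarker_columns(), names(roster))) {
    out[[bm]] <- roster[[bm]]
  }
  class(out) <- c("benz_assessment", "data.frame")
  out
}

#' @export
print.benz_assessment <- function(x, digits = 6, ...) {
  cat(sprintf("Benzene risk assessment: %d workers\n", nrow(x)))
  if (all(c("rq_class", "tlv_class") %in% names(x))) {
    cat(sprintf("  unsafe (RQ >= 1): %d   above TLV: %d\n",
                sum(x$rq_class == "unsafe"), sum(x$tlv_class == "above")))
  }
  print.data.frame(as.data.frame(x), digits = digits, ...)
  invisible(x)
}

# ---- internal validation helpers ------------------------------------------

biomarker_columns <- function() c("mda", "bun", "creatinine")

check_numeric <- function(x, name) {
  if (!is.numeric(x) || anyNA(x)) {
    stop(name, " must be numeric with no missing values", call. = FALSE)
  }
  invisible(x)
}

offender_label <- function(idx, worker_id) {
  lab <- if (is.null(worker_id)) paste0("element ", idx) else
    paste0("worker ", worker_id[idx])
  paste(utils::head(lab, 5), collapse = ", ")
}

validate_exposure_inputs <- function(concentration_ppm, weight_kg,
                                     hours_per_day, days_per_year,
                                     tenure_years, worker_id = NULL) {
  checks <- list(
    "concentration_ppm must be >= 0" = concentration_ppm < 0,
    "weight_kg must be > 0" = weight_kg <= 0,
    "hours_per_day must be in (0, 24]" =
      hours_per_day <= 0 | hours_per_day > 24,
    "days_per_year must be in (0, 365]" =
      days_per_year <= 0 | days_per_year > 365,
    "tenure_years must be >= 0" = tenure_years < 0
  )
  for (msg in names(checks)) {
    bad <- which(checks[[msg]])
    if (length(bad)) {
      stop(msg, " (", offender_label(bad, worker_id), ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

validate_roster <- function(roster) {
  if (!is.data.frame(roster)) {
    stop("roster must be a data.frame (see read_roster())", call. = FALSE)
  }
  needed <- c("worker_id", "concentration_ppm", "weight_kg", "hours_per_day",
              "days_per_year", "tenure_years")
  missing_cols <- setdiff(needed, names(roster))
  if (length(missing_cols)) {
    stop("roster is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(roster) == 0L) stop("roster has no rows", call. = FALSE)
  for (col in setdiff(needed, "worker_id")) check_numeric(roster[[col]], col)
  validate_exposure_inputs(roster$concentration_ppm, roster$weight_kg,
                           roster$hours_per_day, roster$days_per_year,
                           roster$tenure_years, roster$worker_id)
  roster
}
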