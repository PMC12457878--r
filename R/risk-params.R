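#' Risk-model parameters
#'
#' All constants of the chronic inhalation risk model live in one place so
#' that no magic number is buried in a formula. Defaults reproduce the
#' conventional non-carcinogenic assessment for benzene:
#'
#' * `rfc_default`: reference dose \[mg/kg/day\] assumed without appreciable
#'   non-cancer risk; denominator of the Risk Quotient.
#' * `molecular_weight`, `molar_volume`: benzene molar mass \[g/mol\] and the
#'   molar volume of air \[L/mol\] at roughly 25 degrees C; their ratio
#'   (78.11 / 24.5 = 3.188) converts ppm to mg/m3. Set `molar_volume = 24.45`
#'   for the 25 C / 1 atm convention used by some agencies.
#' * `tavg_intake_years`: averaging time for the chronic daily intake
#'   (30 years, the non-carcinogenic convention).
#' * `tavg_rq_years`: averaging time applied inside the Risk Quotient
#'   (70 years, lifetime). With the 30/70 defaults,
#'   RQ = intake x (30/70) / RfC; setting `tavg_rq_years = tavg_intake_years`
#'   degenerates to the plain RQ = intake / RfC.
#' * `days_per_year_avg`: days per year used to annualise the averaging time.
#' * `tlv_ppm`: occupational threshold limit value for airborne benzene
#'   (0.5 ppm).
#' * `rq_threshold`: RQ at or above which a worker is classified unsafe.
#' * `br_slope`, `br_shift`: constants of the allometric breathing-rate model
#'   R = (br_slope x ln(Wb) - br_shift) / 24 \[m3/hour\] for body weight Wb in kg.
#'
#' @param rfc_default Reference dose \[mg/kg/day\].
#' @param molecular_weight Molar mass of benzene \[g/mol\].
#' @param molar_volume Molar volume of air \[L/mol\].
#' @param tavg_intake_years Averaging time for intake \[years\].
#' @param tavg_rq_years Averaging time inside the Risk Quotient \[years\].
#' @param days_per_year_avg Days per year in the averaging denominator.
#' @param tlv_ppm Threshold limit value \[ppm\].
#' @param rq_threshold Unsafe classification boundary for RQ.
#' @param br_slope,br_shift Breathing-rate model constants.
#'
#' @return An object of class `risk_params`: a validated named list.
#' @examples
#' p <- risk_params()
#' p$rfc_default
#' # plain intake / RfC convention:
#' risk_params(tavg_rq_years = 30)
#' @export
risk_params <- function(rfc_default = 0.0003128,
                        molecular_weight = 78.11,
                        molar_volume = 24.5,
                        tavg_intake_years = 30,
                        tavg_rq_years = 70,
                        days_per_year_avg = 365,
                        tlv_ppm = 0.5,
                        rq_threshold = 1.0,
                        br_slope = 5.3,
                        br_shift = 6.9) {
  p <- list(
    rfc_default = rfc_default,
    molecular_weight = molecular_weight,
    molar_volume = molar_volume,
    tavg_intake_years = tavg_intake_years,
    tavg_rq_years = tavg_rq_years,
    days_per_year_avg = days_per_year_avg,
    tlv_ppm = tlv_ppm,
    rq_threshold = rq_threshold,
    br_slope = br_slope,
    br_shift = br_shift
  )
  bad <- names(p)[!vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                            is.finite(x) && x > 0, logical(1))]
  if (length(bad)) {
    stop("risk_params: fields must be single positive numbers: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(p, class = "risk_params")
}

#' @export
print.risk_params <- function(x, ...) {
  cat("Benzene inhalation risk parameters\n")
  cat(sprintf("  RfC default          %g mg/kg/day\n", x$rfc_default))
  cat(sprintf("  ppm -> mg/m3 factor  %g (= %g g/mol / %g L/mol)\n",
              x$molecular_weight / x$molar_volume,
              x$molecular_weight, x$molar_volume))
  cat(sprintf("  averaging time       %g y (intake), %g y (RQ)\n",
              x$tavg_intake_years, x$tavg_rq_years))
  cat(sprintf("  TLV                  %g ppm; unsafe RQ >= %g\n",
              x$tlv_ppm, x$rq_threshold))
  cat(sprintf("  breathing rate       (%g ln(Wb) - %g)/24 m3/h\n",
              x$br_slope, x$br_shift))
  invisible(x)
}

as_risk_params <- function(params) {
  if (inherits(params, "risk_params")) return(params)
  if (is.list(params)) return(do.call(risk_params, params))
  stop("`params` must be a risk_params object (see risk_params())",
       call. = FALSE)
}
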