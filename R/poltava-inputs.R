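#' Published 2016 cost-and-coverage ledger for Poltava oblast
#'
#' The bottom-up unit costs (USD, converted at 26.3138 UAH/USD), estimated
#' 2016 coverage, and estimated spend for each diabetes service line in
#' Poltava region, Ukraine, as published. Displayed unit costs are rounded
#' to two decimals, so recomputed spends differ from the printed spends by
#' up to a few tenths of a percent; see [recompute_ledger()].
#'
#' @return data.frame with columns `name`, `unit_cost_usd`, `people`,
#'   `spend_usd`.
#' @export
poltava_cost_ledger <- function() {
  data.frame(
    name = c("Facility-based blood glucose test",
             "Outreach/community-based blood glucose test",
             "Oral glucose tolerance test",
             "IEC through residential school/courses",
             "IEC through PHC clinic staff",
             "Enhanced adherence counseling at PHC clinic",
             "Enhanced adherence counseling at Feldsher post",
             "Annual co-payments for oral medication",
             "Annual co-payments for insulin"),
    unit_cost_usd = c(0.66, 0.66, 3.80, 5.76, 1.60, 0.62, 0.55, 34.30, 356.56),
    people = c(41833, 3803, 3344, 773, 2318, 2339, 1170, 31067, 8600),
    spend_usd = c(27503, 2500, 12708, 4451, 3712, 1439, 646, 1065523, 3066413)
  )
}

#' Published annual patient-monitoring cost table for Poltava
#'
#' Per-patient annual monitoring unit costs and people counts for the 40,000
#' in-care patients, split by treatment group and glucose-control status.
#'
#' @return A [monitoring_table()].
#' @export
poltava_monitoring_table <- function() {
  monitoring_table(data.frame(
    group = rep(c("non_pharma", "oral", "insulin"), each = 2),
    status = rep(c("controlled", "not_controlled"), 3),
    unit_cost_usd = c(24.48, 28.28, 25.61, 52.85, 48.97, 78.85),
    people = c(960, 2240, 8460, 19740, 1978, 6622)
  ))
}

#' 2016 screening volumes and yield for Poltava
#'
#' Screening-test counts and newly detected cases by modality in 2016:
#' 41,833 facility screens yielding ~3,350 new cases, and 3,803 outreach
#' screens yielding ~300, for 3,650 new cases in total. The implied facility
#' positivity 3350/41833 (~8.0%) is the optimizer's default.
#'
#' @return List with `facility_screens`, `outreach_screens`,
#'   `facility_cases`, `outreach_cases`, and the implied
#'   `facility_positivity` and `outreach_positivity`.
#' @export
poltava_screening_2016 <- function() {
  list(facility_screens = 41833, outreach_screens = 3803,
       facility_cases = 3350, outreach_cases = 300,
       facility_positivity = 3350 / 41833,
       outreach_positivity = 300 / 3803)
}

#' Published inputs for the glucose-control investment arithmetic
#'
#' @return List with the annual oral-medication co-payment per patient
#'   (USD 34.30), the current enhanced-adherence-counselling spend
#'   (USD 2,085/yr) and people reached (2,339 at PHC clinics + 1,170 at
#'   Feldsher posts = 3,509), the in-care total (40,000), and the treatment
#'   mix shares (3,200 / 28,200 / 8,600 of 40,000).
#' @export
poltava_adherence_inputs <- function() {
  list(copay_oral_annual = 34.30,
       counselling_current_spend = 2085,
       counselling_current_people = 2339 + 1170,
       total_in_care = 40000,
       treatment_mix_shares = c(non_pharma = 3200, oral = 28200,
                                insulin = 8600) / 40000)
}
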