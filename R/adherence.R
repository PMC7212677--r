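#' Share of the oral co-payment funded by monitoring-cost savings
#'
#' If subsidizing oral medication improves adherence enough to bring a
#' patient to sustained glucose control, that patient's annual monitoring
#' becomes cheaper by the oral monitoring-cost gap. The offset is the gap
#' expressed as a fraction of the annual per-patient co-payment: the share
#' of the scheme the state recoups through reduced monitoring alone.
#'
#' @param monitoring_gap_oral USD/yr saved in monitoring when an oral
#'   patient attains control (see [monitoring_cost_gap()]).
#' @param copay_oral_annual annual oral-medication co-payment per patient in
#'   USD (> 0).
#' @return List with `offset` (raw fraction) and `offset_presented`
#'   (rounded to the nearest ten percent). An offset above 1 flags a fully
#'   self-funding intervention.
#' @examples
#' copayment_offset(27.24, 34.30) # 0.794, presented as 0.8 (80%)
#' @export
copayment_offset <- function(monitoring_gap_oral, copay_oral_annual) {
  .check(.is_number(copay_oral_annual) && copay_oral_annual > 0,
         "co-payment must be > 0")
  .check(.is_number(monitoring_gap_oral) && monitoring_gap_oral >= 0,
         "monitoring gap must be >= 0")
  offset <- monitoring_gap_oral / copay_oral_annual
  list(offset = offset, offset_presented = round_half_up(offset * 10) / 10)
}

#' Monitoring-cost savings per percentage point of glucose control
#'
#' If one more percentage point of the in-care population attains sustained
#' glucose control, each shifted patient is monitored at the controlled
#' rather than the uncontrolled unit cost. The shifted patients are
#' apportioned across the three treatment groups; two conventions are
#' available:
#' * `"overall_mix"` (default): in proportion to the overall treatment mix
#'   (group counts / total in care);
#' * `"uncontrolled_mix"`: in proportion to the currently uncontrolled
#'   patients in each group.
#'
#' @param table a [monitoring_table()].
#' @param percentage_points size of the control improvement (default 1);
#'   the savings are linear in this.
#' @param convention apportionment convention, see above.
#' @return List with `savings_usd` (raw), `savings_presented` (rounded to
#'   the nearest dollar), `patients_shifted`, and the per-group breakdown.
#' @examples
#' savings_per_control_point(poltava_monitoring_table()) # 10,373 USD/yr
#' @export
savings_per_control_point <- function(table, percentage_points = 1,
                                      convention = c("overall_mix",
                                                     "uncontrolled_mix")) {
  convention <- match.arg(convention)
  t <- monitoring_table(table)
  totals <- tapply(t$people, t$group, sum)[.monitoring_groups]
  total_in_care <- sum(t$people)
  gaps <- vapply(.monitoring_groups,
                 function(g) monitoring_cost_gap(t, g)$difference_usd,
                 numeric(1))
  weights <- if (convention == "overall_mix") {
    totals / total_in_care
  } else {
    unc <- t$people[t$status == "not_controlled"]
    names(unc) <- t$group[t$status == "not_controlled"]
    unc[.monitoring_groups] / sum(unc)
  }
  shifted <- percentage_points / 100 * total_in_care
  by_group <- shifted * weights * gaps
  savings <- sum(by_group)
  list(savings_usd = savings,
       savings_presented = round_half_up(savings),
       patients_shifted = shifted,
       by_group = by_group,
       convention = convention)
}

#' Affordable scale-up of enhanced adherence counselling
#'
#' How far the current counselling programme could be expanded if
#' additional funds (e.g. the monitoring-cost savings from better glucose
#' control) were reinvested in it, assuming the current unit-cost mix.
#'
#' @param current_spend current annual counselling spend in USD (> 0).
#' @param additional_funds extra USD/yr to invest.
#' @param current_people people currently reached (optional; enables the
#'   people-reachable output).
#' @return List with `fold` ((current + additional) / current),
#'   `fold_presented` (nearest whole fold), and -- when `current_people` is
#'   given -- `people_reachable` (raw) and `people_presented` (people at the
#'   presented fold).
#' @examples
#' counselling_scaleup(2085, 10373, 3509) # 5.98-fold, presented as 6-fold
#' @export
counselling_scaleup <- function(current_spend, additional_funds,
                                current_people = NULL) {
  .check(.is_number(current_spend) && current_spend > 0,
         "current_spend must be > 0; scale-up of a zero programme is undefined")
  .check(.is_number(additional_funds) && additional_funds >= 0,
         "additional_funds must be >= 0")
  fold <- (current_spend + additional_funds) / current_spend
  out <- list(fold = fold, fold_presented = round_half_up(fold))
  if (!is.null(current_people)) {
    out$people_reachable <- fold * current_people
    out$people_presented <- round_half_up(out$fold_presented * current_people)
  }
  out
}
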