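#' Bottom-up unit cost of one service
#'
#' A unit cost is assembled from its ingredients -- drugs, other consumables,
#' staff time and overheads -- with value-added tax applied at 7% on drugs
#' and 20% on all other consumables, then converted from hryvnia (UAH) to USD
#' at a fixed exchange rate (default: the mid-2018 rate of 26.3138 UAH/USD).
#'
#' @param ingredients a [cost_ingredients()] object (or list with the same
#'   fields, all in UAH / minutes).
#' @param fx_rate UAH per USD; must be > 0.
#' @return Unit cost in USD per person-service.
#' @examples
#' build_unit_cost(cost_ingredients(drug_cost = 100)) # 107/26.3138
#' @export
build_unit_cost <- function(ingredients, fx_rate = 26.3138) {
  .check(.is_number(fx_rate) && fx_rate > 0, "fx_rate must be > 0")
  ing <- ingredients
  total_uah <- ing$drug_cost * 1.07 +
    ing$other_consumables_cost * 1.20 +
    ing$staff_minutes * ing$salary_rate +
    ing$overhead
  total_uah / fx_rate
}

#' Cost ingredients for one service, in UAH
#'
#' @param drug_cost drug consumables (UAH); 7% VAT is applied downstream.
#' @param other_consumables_cost non-drug consumables (UAH); 20% VAT.
#' @param staff_minutes staff time required to deliver the service (minutes).
#' @param salary_rate average professional salary rate (UAH per minute).
#' @param overhead facility overhead allocation (UAH).
#' @return Object of class `cost_ingredients`.
#' @export
cost_ingredients <- function(drug_cost = 0, other_consumables_cost = 0,
                             staff_minutes = 0, salary_rate = 0,
                             overhead = 0) {
  vals <- c(drug_cost, other_consumables_cost, staff_minutes, salary_rate,
            overhead)
  .check(all(is.finite(vals)) && all(vals >= 0),
         "all cost ingredients must be non-negative")
  structure(list(drug_cost = drug_cost,
                 other_consumables_cost = other_consumables_cost,
                 staff_minutes = staff_minutes, salary_rate = salary_rate,
                 overhead = overhead),
            class = "cost_ingredients")
}

#' Spending on one intervention line
#'
#' Spend = unit cost x people covered, reported to the cent.
#'
#' @param unit_cost USD per person-service (>= 0).
#' @param people number of people covered (>= 0).
#' @return USD, rounded to 2 decimals.
#' @examples
#' compute_spend(0.66, 41833) # 27,609.78
#' @export
compute_spend <- function(unit_cost, people) {
  .check(all(unit_cost >= 0) && all(people >= 0),
         "unit_cost and people must be >= 0")
  round_half_up(unit_cost * people, 2)
}

#' Recompute a spending ledger and flag inconsistencies
#'
#' Takes a Table-1-style ledger (one row per service line) and recomputes
#' each spend from the displayed unit cost and people count. Printed spends
#' usually reflect unrounded unit costs, so small relative differences are
#' expected; rows beyond `tolerance` are flagged.
#'
#' @param ledger data.frame with columns `name`, `unit_cost_usd`, `people`
#'   and optionally `spend_usd` (the printed spend to check against).
#' @param tolerance maximum acceptable relative difference between printed
#'   and recomputed spend (default 0.015, i.e. 1.5%, covering display
#'   rounding of unit costs to two decimals).
#' @return The ledger with `computed_spend_usd`, `rel_diff` and `consistent`
#'   columns added; total spend is in `attr(, "total_spend_usd")`.
#' @export
recompute_ledger <- function(ledger, tolerance = 0.015) {
  .check(all(c("name", "unit_cost_usd", "people") %in% names(ledger)),
         "ledger needs name, unit_cost_usd, people columns")
  .check(all(ledger$unit_cost_usd >= 0) && all(ledger$people >= 0),
         "ledger values must be >= 0")
  out <- as.data.frame(ledger)
  out$computed_spend_usd <- compute_spend(out$unit_cost_usd, out$people)
  if (!is.null(out$spend_usd)) {
    out$rel_diff <- ifelse(out$spend_usd > 0,
                           abs(out$computed_spend_usd - out$spend_usd) /
                             out$spend_usd,
                           abs(out$computed_spend_usd - out$spend_usd))
    out$consistent <- out$rel_diff <= tolerance
  }
  attr(out, "total_spend_usd") <- sum(out$computed_spend_usd)
  out
}

#' Treatment-mix accounting for people in diabetes care
#'
#' Splits the in-care population into non-pharmacological, oral-only and
#' insulin patients, with the insulin group further split into insulin-only
#' and insulin-plus-oral. Everyone taking any oral medication (oral-only plus
#' insulin-plus-oral) is eligible for the oral-drug co-payment scheme.
#' Derived people counts are rounded half-up to whole people.
#'
#' @param total_in_care people linked to care.
#' @param insulin_total people receiving insulin (with or without oral).
#' @param frac_insulin_also_oral fraction of insulin patients who also
#'   receive oral treatment.
#' @param frac_non_pharma fraction of all in-care patients on
#'   non-pharmacological treatment only.
#' @return Object of class `treatment_mix` with fields `total_in_care`,
#'   `insulin_total`, `insulin_only`, `insulin_plus_oral`, `non_pharma`,
#'   `oral_only`, `oral_copay_eligible`.
#' @examples
#' derive_treatment_mix(40000, 8600, 1 / 3, 0.08)
#' @export
derive_treatment_mix <- function(total_in_care, insulin_total,
                                 frac_insulin_also_oral, frac_non_pharma) {
  .check(insulin_total <= total_in_care,
         "insulin_total cannot exceed total_in_care")
  .check(.is_fraction(frac_insulin_also_oral) && .is_fraction(frac_non_pharma),
         "fractions must lie in [0, 1]")
  non_pharma <- round_half_up(frac_non_pharma * total_in_care)
  insulin_plus_oral <- round_half_up(frac_insulin_also_oral * insulin_total)
  oral_only <- total_in_care - insulin_total - non_pharma
  if (oral_only < 0) {
    stop("inconsistent inputs: non-pharma and insulin groups exceed the ",
         "in-care total", call. = FALSE)
  }
  mix <- structure(list(
    total_in_care = total_in_care,
    insulin_total = insulin_total,
    insulin_only = insulin_total - insulin_plus_oral,
    insulin_plus_oral = insulin_plus_oral,
    non_pharma = non_pharma,
    oral_only = oral_only,
    oral_copay_eligible = oral_only + insulin_plus_oral
  ), class = "treatment_mix")
  stopifnot(mix$insulin_only + mix$insulin_plus_oral == mix$insulin_total,
            mix$non_pharma + mix$oral_only + mix$insulin_total ==
              mix$total_in_care)
  mix
}

#' @export
print.treatment_mix <- function(x, ...) {
  cat("<treatment_mix> ", format(x$total_in_care, big.mark = ","),
      " in care\n", sep = "")
  cat(sprintf("  non-pharma %s | oral-only %s | insulin %s (%s also oral)\n",
              format(x$non_pharma, big.mark = ","),
              format(x$oral_only, big.mark = ","),
              format(x$insulin_total, big.mark = ","),
              format(x$insulin_plus_oral, big.mark = ",")))
  cat("  eligible for oral co-payment scheme:",
      format(x$oral_copay_eligible, big.mark = ","), "\n")
  invisible(x)
}

.monitoring_groups <- c("non_pharma", "oral", "insulin")
.monitoring_statuses <- c("controlled", "not_controlled")

#' Annual patient-monitoring cost table
#'
#' Per-patient annual monitoring unit cost (USD) and people count for each
#' of the six cells: treatment group {non_pharma, oral, insulin} crossed
#' with glucose-control status {controlled, not_controlled} (controlled
#' means sustained HbA1c at or below the 7.0% target).
#'
#' @param table data.frame with columns `group`, `status`, `unit_cost_usd`,
#'   `people`; exactly one row per group x status cell.
#' @return Object of class `monitoring_table` (a validated data.frame).
#' @export
monitoring_table <- function(table) {
  t <- as.data.frame(table)
  .check(all(c("group", "status", "unit_cost_usd", "people") %in% names(t)),
         "monitoring table needs group, status, unit_cost_usd, people")
  .check(all(t$group %in% .monitoring_groups) &&
           all(t$status %in% .monitoring_statuses),
         "group must be non_pharma/oral/insulin; status controlled/not_controlled")
  .check(nrow(t) == 6 && !anyDuplicated(paste(t$group, t$status)),
         "all six group x status cells must be present exactly once")
  .check(all(t$unit_cost_usd >= 0) && all(t$people >= 0),
         "unit costs and counts must be >= 0")
  for (g in .monitoring_groups) {
    uc <- t$unit_cost_usd[t$group == g]
    names(uc) <- t$status[t$group == g]
    .check(uc[["not_controlled"]] >= uc[["controlled"]],
           paste0("monitoring cost for uncontrolled ", g,
                  " patients must be >= the controlled cost"))
  }
  t <- t[order(match(t$group, .monitoring_groups),
               match(t$status, .monitoring_statuses)), ]
  rownames(t) <- NULL
  class(t) <- c("monitoring_table", "data.frame")
  t
}

#' Per-cell and total monitoring spend
#'
#' @param table a [monitoring_table()].
#' @return List with `cells` (the table plus a `total_usd` column, rounded
#'   to the cent) and `grand_total_usd` (exact sum of the six cells).
#' @export
monitoring_totals <- function(table) {
  t <- monitoring_table(table)
  t$total_usd <- compute_spend(t$unit_cost_usd, t$people)
  list(cells = t, grand_total_usd = sum(t$total_usd))
}

#' Monitoring-cost gap between uncontrolled and controlled patients
#'
#' How much more it costs per year to monitor a patient who has not attained
#' glucose control, within one treatment group.
#'
#' @param table a [monitoring_table()].
#' @param group one of `"non_pharma"`, `"oral"`, `"insulin"`.
#' @return List with `difference_usd` (not-controlled minus controlled unit
#'   cost) and `ratio` (not-controlled / controlled).
#' @examples
#' monitoring_cost_gap(poltava_monitoring_table(), "oral") # 27.24, ratio 2.06
#' @export
monitoring_cost_gap <- function(table, group) {
  t <- monitoring_table(table)
  .check(group %in% .monitoring_groups, "unknown treatment group")
  ctrl <- t$unit_cost_usd[t$group == group & t$status == "controlled"]
  nctrl <- t$unit_cost_usd[t$group == group & t$status == "not_controlled"]
  if (ctrl == 0) stop("controlled unit cost is 0: ratio undefined", call. = FALSE)
  list(difference_usd = nctrl - ctrl, ratio = nctrl / ctrl)
}
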