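#' New cases identified by a two-modality screening effort
#'
#' Screening happens in facilities (during clinical visits) and via
#' community outreach campaigns. Each modality has a positivity rate: the
#' fraction of its screening tests that identify a new case.
#'
#' @param total_screens total number of screening tests performed.
#' @param outreach_share fraction of screening events done via outreach.
#' @param positivity_outreach,positivity_facility per-modality positivity
#'   fractions.
#' @return Expected newly identified cases:
#'   `total_screens * ((1 - share) * p_facility + share * p_outreach)`.
#' @examples
#' s <- poltava_screening_2016()
#' cases_identified(s$facility_screens + s$outreach_screens,
#'                  s$outreach_screens / (s$facility_screens + s$outreach_screens),
#'                  s$outreach_positivity, s$facility_positivity) # 3650
#' @export
cases_identified <- function(total_screens, outreach_share,
                             positivity_outreach, positivity_facility) {
  .check(all(total_screens >= 0), "total_screens must be >= 0")
  .check(all(outreach_share >= 0 & outreach_share <= 1) &&
           all(positivity_outreach >= 0 & positivity_outreach <= 1) &&
           all(positivity_facility >= 0 & positivity_facility <= 1),
         "shares and positivities must lie in [0, 1]")
  total_screens * ((1 - outreach_share) * positivity_facility +
                     outreach_share * positivity_outreach)
}

#' Screening volumes needed to hit a case-finding target
#'
#' Inverts [cases_identified()]: given a target number of new diagnoses and
#' the outreach share of screening events, how many tests does each modality
#' need to perform?
#'
#' @param target_new_cases new cases to identify (>= 0).
#' @param outreach_share fraction of screening events done via outreach.
#' @param positivity_facility,positivity_outreach per-modality positivities.
#' @return List with `facility_screens`, `outreach_screens`,
#'   `total_screens`, `blended_positivity`.
#' @export
screens_for_target <- function(target_new_cases, outreach_share,
                               positivity_facility, positivity_outreach) {
  .check(all(target_new_cases >= 0), "target must be >= 0")
  blended <- (1 - outreach_share) * positivity_facility +
    outreach_share * positivity_outreach
  if (any(blended <= 0 & target_new_cases > 0)) {
    stop("infeasible target: blended positivity is 0", call. = FALSE)
  }
  total <- ifelse(target_new_cases == 0, 0, target_new_cases / blended)
  list(facility_screens = (1 - outreach_share) * total,
       outreach_screens = outreach_share * total,
       total_screens = total,
       blended_positivity = blended)
}

#' Cost of a screening scale-up scenario
#'
#' Facility screening is costed linearly at its unit cost; outreach
#' screening is costed along a saturating [cost_curve()], so its average
#' cost rises as the implied outreach coverage approaches the maximal
#' attainable level. A scenario whose implied outreach coverage reaches the
#' curve's saturation is infeasible.
#'
#' @param target_new_cases new cases to identify.
#' @param outreach_share fraction of screening events done via outreach.
#' @param positivity_facility,positivity_outreach per-modality positivities.
#' @param facility_unit_cost USD per facility screen (default 0.66).
#' @param outreach_curve a [cost_curve()] for the outreach modality.
#' @return List with `feasible` flag and, when feasible, `facility_cost`,
#'   `outreach_cost`, `total_cost`, `cost_per_case`, the screen volumes and
#'   implied `outreach_coverage`.
#' @export
scenario_cost <- function(target_new_cases, outreach_share,
                          positivity_facility, positivity_outreach,
                          facility_unit_cost = 0.66, outreach_curve) {
  v <- screens_for_target(target_new_cases, outreach_share,
                          positivity_facility, positivity_outreach)
  coverage <- v$outreach_screens / outreach_curve$eligible_population
  if (coverage >= outreach_curve$saturation) {
    return(list(feasible = FALSE, outreach_coverage = coverage,
                facility_screens = v$facility_screens,
                outreach_screens = v$outreach_screens))
  }
  facility_cost <- v$facility_screens * facility_unit_cost
  outreach_cost <- if (v$outreach_screens > 0) {
    spend_from_coverage(coverage, outreach_curve)
  } else 0
  total <- facility_cost + outreach_cost
  list(feasible = TRUE,
       facility_cost = facility_cost, outreach_cost = outreach_cost,
       total_cost = total,
       cost_per_case = total / target_new_cases,
       facility_screens = v$facility_screens,
       outreach_screens = v$outreach_screens,
       outreach_coverage = coverage)
}

#' Optimal outreach share for one (positivity, saturation) assumption
#'
#' Exhaustive grid search over the outreach share of screening events,
#' minimizing the cost per newly identified case; ties break toward the
#' smaller share.
#'
#' @param target_new_cases new cases to identify (e.g. 5,000).
#' @param positivity_outreach assumed outreach positivity.
#' @param saturation assumed maximal attainable outreach coverage.
#' @param share_grid candidate outreach shares (default 101 points, 0..1).
#' @param positivity_facility facility positivity; default is the 2016
#'   Poltava value 3350/41833.
#' @param facility_unit_cost,outreach_unit_cost USD per screen (default 0.66
#'   for both, the published blood-glucose-test unit cost).
#' @param eligible_population denominator for outreach coverage (default
#'   1.4 million, the regional adult population convention).
#' @param curve_form passed to [cost_curve()].
#' @return List with `optimal_share`, `min_cost_per_case`, and the evaluated
#'   `grid` (data.frame of share, cost_per_case, feasible).
#' @export
optimize_share <- function(target_new_cases, positivity_outreach, saturation,
                           share_grid = seq(0, 1, length.out = 101),
                           positivity_facility = 3350 / 41833,
                           facility_unit_cost = 0.66,
                           outreach_unit_cost = 0.66,
                           eligible_population = 1.4e6,
                           curve_form = "logistic") {
  .check(all(share_grid >= 0 & share_grid <= 1), "share grid must be in [0, 1]")
  curve <- cost_curve(outreach_unit_cost, saturation, eligible_population,
                      form = curve_form)
  share_grid <- sort(share_grid)
  cost <- rep(NA_real_, length(share_grid))
  for (i in seq_along(share_grid)) {
    sc <- scenario_cost(target_new_cases, share_grid[i],
                        positivity_facility, positivity_outreach,
                        facility_unit_cost, curve)
    if (sc$feasible) cost[i] <- sc$cost_per_case
  }
  if (all(is.na(cost))) {
    stop("no feasible outreach share on the grid", call. = FALSE)
  }
  best <- which.min(cost) # first minimum on the sorted grid = smaller share
  list(optimal_share = share_grid[best],
       min_cost_per_case = cost[best],
       grid = data.frame(share = share_grid, cost_per_case = cost,
                         feasible = !is.na(cost)))
}

#' Sweep the screening-mix optimization over positivity and saturation
#'
#' Evaluates the cost per newly identified case over a 3-D grid (outreach
#' share x outreach positivity x maximal attainable coverage) and records,
#' for each (positivity, saturation) pair, the optimal outreach share and
#' its minimal cost per case -- the heatmap presentation of the screening
#' scale-up analysis.
#'
#' @param target_new_cases new cases to identify.
#' @param positivity_grid outreach positivities to assess (default 8%..16%).
#' @param saturation_grid maximal coverages to assess (default 10%..20%).
#' @param share_grid candidate outreach shares (default 101 points).
#' @param ... passed on to [optimize_share()].
#' @return Object of class `screening_mix_grid`: list with `grid` (long
#'   data.frame of share, positivity, saturation, cost_per_case, feasible)
#'   and `optima` (one row per positivity x saturation pair with
#'   `optimal_share`, `min_cost_per_case`).
#' @export
sweep_screening_grid <- function(target_new_cases,
                                 positivity_grid = seq(0.08, 0.16, length.out = 9),
                                 saturation_grid = seq(0.10, 0.20, length.out = 6),
                                 share_grid = seq(0, 1, length.out = 101),
                                 ...) {
  .check(length(positivity_grid) >= 1 && length(saturation_grid) >= 1,
         "positivity and saturation grids must be non-empty")
  grids <- list()
  optima <- expand.grid(positivity = positivity_grid,
                        saturation = saturation_grid,
                        KEEP.OUT.ATTRS = FALSE)
  optima$optimal_share <- NA_real_
  optima$min_cost_per_case <- NA_real_
  for (k in seq_len(nrow(optima))) {
    res <- optimize_share(target_new_cases, optima$positivity[k],
                          optima$saturation[k], share_grid, ...)
    optima$optimal_share[k] <- res$optimal_share
    optima$min_cost_per_case[k] <- res$min_cost_per_case
    g <- res$grid
    g$positivity <- optima$positivity[k]
    g$saturation <- optima$saturation[k]
    grids[[k]] <- g
  }
  structure(list(grid = do.call(rbind, grids), optima = optima,
                 target_new_cases = target_new_cases),
            class = "screening_mix_grid")
}

#' @export
print.screening_mix_grid <- function(x, ...) {
  cat("<screening_mix_grid> target ", format(x$target_new_cases, big.mark = ","),
      " new cases; ", length(unique(x$optima$positivity)), " positivity x ",
      length(unique(x$optima$saturation)), " saturation levels\n", sep = "")
  lo <- x$optima[which.min(x$optima$min_cost_per_case), ]
  hi <- x$optima[which.max(x$optima$min_cost_per_case), ]
  cat(sprintf("  cheapest corner: %.2f USD/case at positivity %.0f%%, saturation %.0f%% (share %.0f%%)\n",
              lo$min_cost_per_case, 100 * lo$positivity, 100 * lo$saturation,
              100 * lo$optimal_share))
  cat(sprintf("  dearest corner:  %.2f USD/case at positivity %.0f%%, saturation %.0f%% (share %.0f%%)\n",
              hi$min_cost_per_case, 100 * hi$positivity, 100 * hi$saturation,
              100 * hi$optimal_share))
  invisible(x)
}
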