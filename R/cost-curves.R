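#' Saturating cost-coverage curve
#'
#' Outreach screening gets progressively more expensive per person as its
#' coverage approaches the maximal attainable level: the easy-to-reach are
#' reached first. The relation is parameterized by just two programme-level
#' inputs -- the unit cost at the low-coverage limit and the saturation
#' (maximal attainable coverage) -- plus the eligible-population denominator
#' that converts coverage fractions into people.
#'
#' The default `"logistic"` form is
#' \deqn{coverage(s) = \sigma \tanh\!\big(s / (\sigma N u)\big)}
#' with unit cost \eqn{u}, saturation \eqn{\sigma} and eligible population
#' \eqn{N} (algebraically identical to
#' \eqn{\sigma(2/(1+e^{-2s/(\sigma N u)}) - 1)}). It rises with slope
#' \eqn{1/(Nu)} at the origin -- so the marginal cost per person is exactly
#' the unit cost at zero coverage -- and approaches \eqn{\sigma} as spend
#' grows, with strictly increasing marginal cost in between. The `"linear"`
#' form keeps the average cost constant at the unit cost up to saturation;
#' facility-based screening is modelled this way.
#'
#' @param unit_cost USD per person screened at the low-coverage limit (> 0).
#' @param saturation maximal attainable coverage, a fraction in (0, 1].
#' @param eligible_population people in the coverage denominator (> 0). Two
#'   conventions are in use: the total adult population (the default used
#'   throughout this package) or the undiagnosed prevalent pool; results
#'   should state which was chosen.
#' @param form `"logistic"` (saturating, default) or `"linear"`.
#' @return Object of class `cost_curve`.
#' @seealso [coverage_from_spend()], [spend_from_coverage()], [average_cost()]
#' @export
cost_curve <- function(unit_cost, saturation, eligible_population,
                       form = c("logistic", "linear")) {
  form <- match.arg(form)
  .check(.is_number(unit_cost) && unit_cost > 0, "unit_cost must be > 0")
  .check(.is_number(saturation) && saturation > 0 && saturation <= 1,
         "saturation must lie in (0, 1]")
  .check(.is_number(eligible_population) && eligible_population > 0,
         "eligible_population must be > 0")
  structure(list(unit_cost = unit_cost, saturation = saturation,
                 eligible_population = eligible_population, form = form),
            class = "cost_curve")
}

#' @export
print.cost_curve <- function(x, ...) {
  cat("<cost_curve> form = ", x$form, ", unit cost = ", x$unit_cost,
      " USD, saturation = ", 100 * x$saturation, "% of ",
      format(x$eligible_population, big.mark = ","), " eligible\n", sep = "")
  invisible(x)
}

# characteristic spend scale: saturation * N * unit_cost
.curve_scale <- function(curve) {
  curve$saturation * curve$eligible_population * curve$unit_cost
}

#' Coverage attainable for a given spend
#'
#' @param spend USD (vectorized, >= 0).
#' @param curve a [cost_curve()].
#' @return Coverage fraction(s): 0 at zero spend, strictly increasing and
#'   concave in spend, approaching the curve's saturation as spend grows.
#' @export
coverage_from_spend <- function(spend, curve) {
  .check(all(spend >= 0), "spend must be >= 0")
  if (curve$form == "linear") {
    return(pmin(spend / (curve$eligible_population * curve$unit_cost),
                curve$saturation))
  }
  curve$saturation * tanh(spend / .curve_scale(curve))
}

#' Spend required to attain a given coverage
#'
#' Exact inverse of [coverage_from_spend()].
#'
#' @param coverage fraction(s) in `[0, saturation)`.
#' @param curve a [cost_curve()].
#' @return USD.
#' @export
spend_from_coverage <- function(coverage, curve) {
  .check(all(coverage >= 0), "coverage must be >= 0")
  if (any(coverage >= curve$saturation)) {
    stop("unattainable coverage: at or beyond the curve's saturation of ",
         curve$saturation, call. = FALSE)
  }
  if (curve$form == "linear") {
    return(coverage * curve$eligible_population * curve$unit_cost)
  }
  .curve_scale(curve) * atanh(coverage / curve$saturation)
}

#' Average cost per person reached at a given coverage
#'
#' @param coverage fraction(s) in `(0, saturation)`.
#' @param curve a [cost_curve()].
#' @return USD per person screened: `spend / (coverage * eligible
#'   population)`. Non-decreasing in coverage; tends to the unit cost as
#'   coverage tends to 0.
#' @export
average_cost <- function(coverage, curve) {
  .check(all(coverage > 0), "average cost needs coverage > 0")
  spend_from_coverage(coverage, curve) /
    (coverage * curve$eligible_population)
}

#' Tabulate a cost-coverage curve on a grid
#'
#' Exports (coverage, people, spend, average cost) for plotting the
#' average-total-cost curve of an outreach programme.
#'
#' @param curve a [cost_curve()].
#' @param n number of grid points (default 200), spanning coverage from
#'   just above 0 to just below saturation.
#' @return data.frame with columns `coverage`, `people`, `spend_usd`,
#'   `average_cost_usd`.
#' @export
cost_curve_table <- function(curve, n = 200) {
  .check(n >= 2, "need at least 2 grid points")
  cov <- seq(curve$saturation / n, curve$saturation * (1 - 1e-6),
             length.out = n)
  data.frame(coverage = cov,
             people = cov * curve$eligible_population,
             spend_usd = spend_from_coverage(cov, curve),
             average_cost_usd = average_cost(cov, curve))
}
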