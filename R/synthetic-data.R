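#' Assumed defaults standing in for unpublished regional inputs
#'
#' The published analysis draws several inputs from a supplementary cascade
#' table that is not reproduced here (compartment counts, birth and
#' mortality rates, transition rates). This one place collects the package's
#' stand-in ASSUMPTIONS -- they are not published values:
#'
#' * `prevalent_cases` 60,000 (~4.3% of 1.4 m adults, a realistic adult
#'   type 2 diabetes prevalence for the region);
#' * `annual_incident_cases` 3,750/yr, back-derived from the statement that
#'   identifying 5,000 cases per year is a ~33% increase over annual
#'   incidence;
#' * `background_mortality` 0.015/yr for this predominantly older
#'   population, with `excess_mortality_uncontrolled` 0.01/yr added to the
#'   uncontrolled-treatment compartments;
#' * annual transition rates chosen to be consistent with the observed 2016
#'   flows (about 3,650 confirmations out of ~20,000 undiagnosed prevalent
#'   cases gives a screening rate near 0.2/yr) and with ~25-30% of treated
#'   patients glucose-controlled at equilibrium.
#'
#' @return Named list of default values; see Details.
#' @export
region_defaults <- function() {
  list(
    prevalent_cases = 60000,
    annual_incident_cases = 3750,
    background_mortality = 0.015,
    excess_mortality_uncontrolled = 0.01,
    rates = list(
      screening = 0.20,        # unscreened -> screened (driver: screening)
      confirmation = 0.85,     # screened -> confirmed
      linkage = 0.80,          # confirmed -> linked
      treatment_start = 0.90,  # linked -> on treatment, split by mix shares
      control_gain = c(non_pharma = 0.20, oral = 0.20, insulin = 0.15),
      control_loss = c(non_pharma = 0.45, oral = 0.45, insulin = 0.50)
    ),
    reference_screening_coverage = (41833 + 3803) / 1.4e6
  )
}

#' Specification of a synthetic region
#'
#' Describes a Poltava-like region by its population and the fractions that
#' determine the state of its diabetes care cascade. All counts produced
#' from a spec are deterministic functions of the spec (and, in stochastic
#' mode, of its seed).
#'
#' @param seed integer RNG seed (only used by stochastic generation modes).
#' @param adult_population people (default 1.4 million).
#' @param t2d_prevalence prevalent type 2 diabetes fraction of the adult
#'   population (default 60,000 / 1.4 m; an assumption, see
#'   [region_defaults()]).
#' @param diagnosed_fraction fraction of prevalent cases ever diagnosed
#'   (default 2/3).
#' @param in_care_fraction fraction of diagnosed cases linked to care
#'   (default 1: the published in-care total coincides with its register).
#' @param treatment_mix_shares named fractions for non_pharma / oral /
#'   insulin, summing to 1 (default 8% / 70.5% / 21.5%).
#' @param controlled_fraction_by_group named per-group fractions attaining
#'   sustained glucose control (default 30% / 30% / 23%).
#' @param unit_cost_table data.frame of monitoring unit costs (`group`,
#'   `status`, `unit_cost_usd`); default: the published Poltava costs.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(seed = 1L,
                        adult_population = 1.4e6,
                        t2d_prevalence = 60000 / 1.4e6,
                        diagnosed_fraction = 2 / 3,
                        in_care_fraction = 1,
                        treatment_mix_shares = c(non_pharma = 0.08,
                                                 oral = 0.705,
                                                 insulin = 0.215),
                        controlled_fraction_by_group = c(non_pharma = 0.30,
                                                         oral = 0.30,
                                                         insulin = 0.23),
                        unit_cost_table = NULL) {
  .check(adult_population > 0, "adult_population must be > 0")
  .check(.is_fraction(t2d_prevalence) && .is_fraction(diagnosed_fraction) &&
           .is_fraction(in_care_fraction),
         "prevalence and cascade fractions must lie in [0, 1]")
  .check(setequal(names(treatment_mix_shares), .monitoring_groups) &&
           abs(sum(treatment_mix_shares) - 1) < 1e-9 &&
           all(treatment_mix_shares >= 0),
         "treatment_mix_shares must be named non_pharma/oral/insulin and sum to 1")
  .check(setequal(names(controlled_fraction_by_group), .monitoring_groups) &&
           all(controlled_fraction_by_group >= 0 &
                 controlled_fraction_by_group <= 1),
         "controlled_fraction_by_group must be named fractions in [0, 1]")
  if (is.null(unit_cost_table)) {
    t <- poltava_monitoring_table()
    unit_cost_table <- t[, c("group", "status", "unit_cost_usd")]
  }
  structure(list(seed = as.integer(seed),
                 adult_population = adult_population,
                 t2d_prevalence = t2d_prevalence,
                 diagnosed_fraction = diagnosed_fraction,
                 in_care_fraction = in_care_fraction,
                 treatment_mix_shares = treatment_mix_shares[.monitoring_groups],
                 controlled_fraction_by_group =
                   controlled_fraction_by_group[.monitoring_groups],
                 unit_cost_table = unit_cost_table),
            class = "region_spec")
}

# compartment ids of the default cascade
.cascade_ids <- c("unscreened", "screened", "confirmed", "linked",
                  "np_not", "np_ctrl", "oral_not", "oral_ctrl",
                  "ins_not", "ins_ctrl", "death")

.group_compartments <- function(group) {
  prefix <- c(non_pharma = "np", oral = "oral", insulin = "ins")[[group]]
  c(not = paste0(prefix, "_not"), ctrl = paste0(prefix, "_ctrl"))
}

#' Generate a synthetic region
#'
#' Produces, deterministically from a [region_spec()], the cascade state
#' vector, the monitoring cost table, and a cost ledger of a synthetic
#' Poltava-like region. With `stochastic = TRUE` the treatment mix and
#' control-status splits are drawn multinomially (seeded by the spec's
#' seed) instead of rounded.
#'
#' @param spec a [region_spec()].
#' @param year calendar year stamped on the state vector (default 2016).
#' @param stochastic draw the within-care splits multinomially instead of
#'   deterministic rounding.
#' @return List with `state` (a [cascade_state()] on the default cascade
#'   compartments), `monitoring` (a [monitoring_table()]), `ledger`
#'   (an intervention cost ledger data.frame), and the derived totals
#'   `prevalent`, `diagnosed`, `in_care`.
#' @examples
#' reg <- generate_region(region_spec())
#' sum(reg$monitoring$people) # 40,000 in care
#' @export
generate_region <- function(spec, year = 2016, stochastic = FALSE) {
  .check(inherits(spec, "region_spec"), "spec must be a region_spec")
  pop <- spec$adult_population
  prevalent <- round_half_up(pop * spec$t2d_prevalence)
  diagnosed <- round_half_up(prevalent * spec$diagnosed_fraction)
  in_care <- round_half_up(diagnosed * spec$in_care_fraction)

  if (stochastic) {
    counts_by_group <- .with_seed(spec$seed, {
      as.vector(stats::rmultinom(1, in_care, spec$treatment_mix_shares))
    })
    names(counts_by_group) <- .monitoring_groups
  } else {
    counts_by_group <- c(
      non_pharma = round_half_up(spec$treatment_mix_shares[["non_pharma"]] * in_care),
      insulin = round_half_up(spec$treatment_mix_shares[["insulin"]] * in_care)
    )
    counts_by_group <- c(counts_by_group,
                         oral = in_care - sum(counts_by_group))
    counts_by_group <- counts_by_group[.monitoring_groups]
  }
  .check(all(counts_by_group >= 0), "inconsistent spec: negative group count")

  ctrl <- if (stochastic) {
    .with_seed(spec$seed + 1L, vapply(.monitoring_groups, function(g) {
      stats::rbinom(1, counts_by_group[[g]],
                    spec$controlled_fraction_by_group[[g]])
    }, numeric(1)))
  } else {
    vapply(.monitoring_groups, function(g) {
      round_half_up(spec$controlled_fraction_by_group[[g]] *
                      counts_by_group[[g]])
    }, numeric(1))
  }
  not_ctrl <- counts_by_group - ctrl

  counts <- stats::setNames(numeric(length(.cascade_ids)), .cascade_ids)
  counts["unscreened"] <- prevalent - diagnosed
  counts["confirmed"] <- diagnosed - in_care
  for (g in .monitoring_groups) {
    cc <- .group_compartments(g)
    counts[cc[["ctrl"]]] <- ctrl[[g]]
    counts[cc[["not"]]] <- not_ctrl[[g]]
  }

  monitoring <- monitoring_table(data.frame(
    group = rep(.monitoring_groups, each = 2),
    status = rep(.monitoring_statuses, 3),
    unit_cost_usd = vapply(seq_len(6), function(i) {
      g <- rep(.monitoring_groups, each = 2)[i]
      s <- rep(.monitoring_statuses, 3)[i]
      spec$unit_cost_table$unit_cost_usd[
        spec$unit_cost_table$group == g & spec$unit_cost_table$status == s]
    }, numeric(1)),
    people = as.vector(rbind(ctrl[.monitoring_groups],
                             not_ctrl[.monitoring_groups]))
  ))

  # intervention ledger scaled to the region's size, spends consistent by
  # construction (computed from unit cost x people)
  scale <- pop / 1.4e6
  base <- poltava_cost_ledger()
  ledger <- data.frame(name = base$name,
                       unit_cost_usd = base$unit_cost_usd,
                       people = round_half_up(base$people * scale))
  ledger$spend_usd <- compute_spend(ledger$unit_cost_usd, ledger$people)

  list(state = cascade_state(year, counts),
       monitoring = monitoring,
       ledger = ledger,
       prevalent = prevalent, diagnosed = diagnosed, in_care = in_care)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Default cascade model for a synthetic region
#'
#' Builds the package's default type 2 diabetes care-cascade model:
#' unscreened -> screened -> confirmed -> linked -> on treatment
#' (non-pharmacological / oral / insulin, each with an uncontrolled
#' compartment and a glucose-controlled sibling) plus a death sink.
#' Transition rates and demography come from [region_defaults()] and are
#' assumptions, not published values; the screening flow carries the
#' `"screening"` driver so its rate scales with screening coverage.
#'
#' @param spec a [region_spec()] (sets incidence/mortality scale via the
#'   population).
#' @param defaults overridable list as returned by [region_defaults()].
#' @return A [cascade_model()].
#' @export
default_cascade_model <- function(spec = region_spec(),
                                  defaults = region_defaults()) {
  r <- defaults$rates
  mix <- spec$treatment_mix_shares
  tr <- rbind(
    data.frame(source = "unscreened", target = "screened",
               base_rate = r$screening, driver = "screening"),
    data.frame(source = "screened", target = "confirmed",
               base_rate = r$confirmation, driver = NA),
    data.frame(source = "confirmed", target = "linked",
               base_rate = r$linkage, driver = NA),
    data.frame(source = "linked",
               target = c("np_not", "oral_not", "ins_not"),
               base_rate = r$treatment_start * as.vector(mix),
               driver = NA),
    data.frame(source = c("np_not", "oral_not", "ins_not"),
               target = c("np_ctrl", "oral_ctrl", "ins_ctrl"),
               base_rate = as.vector(r$control_gain[.monitoring_groups]),
               driver = NA),
    data.frame(source = c("np_ctrl", "oral_ctrl", "ins_ctrl"),
               target = c("np_not", "oral_not", "ins_not"),
               base_rate = as.vector(r$control_loss[.monitoring_groups]),
               driver = NA)
  )
  scale <- spec$adult_population / 1.4e6
  uncontrolled <- c("np_not", "oral_not", "ins_not")
  cascade_model(
    compartments = data.frame(
      id = .cascade_ids,
      label = c("Unscreened prevalent", "Screened positive",
                "Confirmed diagnosis", "Linked to care",
                "Non-pharma, not controlled", "Non-pharma, controlled",
                "Oral, not controlled", "Oral, controlled",
                "Insulin, not controlled", "Insulin, controlled",
                "Deceased"),
      terminal = .cascade_ids == "death"),
    transitions = tr,
    demography = list(
      annual_incident_cases = defaults$annual_incident_cases * scale,
      background_mortality = defaults$background_mortality,
      excess_mortality = stats::setNames(
        rep(defaults$excess_mortality_uncontrolled, length(uncontrolled)),
        uncontrolled),
      entry_compartment = "unscreened",
      death_compartment = "death"))
}

#' Simulate a stream of screening events
#'
#' Each screen is an independent Bernoulli draw at the true positivity; a
#' positive screen is a genuinely new case with probability
#' `1 - retester_fraction` (already-diagnosed people using outreach
#' campaigns as free glucose checks dilute the unique-case yield).
#'
#' @param seed integer seed; the stream is a pure function of it.
#' @param n_screens number of screening events.
#' @param true_positivity probability a screen is positive.
#' @param retester_fraction probability a positive is a known case rather
#'   than a new one (default 0).
#' @return data.frame with logical columns `positive` and `new_case`.
#' @export
simulate_screens <- function(seed, n_screens, true_positivity,
                             retester_fraction = 0) {
  .check(n_screens >= 0, "n_screens must be >= 0")
  .check(.is_fraction(true_positivity) && .is_fraction(retester_fraction),
         "positivity and retester fraction must lie in [0, 1]")
  .with_seed(as.integer(seed), {
    positive <- stats::runif(n_screens) < true_positivity
    new_case <- positive & (stats::runif(n_screens) >= retester_fraction)
    data.frame(positive = positive, new_case = new_case)
  })
}

#' Estimate new-case positivity from a screening-event stream
#'
#' Point estimate (new cases / screens) with an exact (Clopper-Pearson)
#' 95% binomial confidence interval.
#'
#' @param events data.frame as produced by [simulate_screens()] (needs a
#'   logical `new_case` column); must contain at least one screen.
#' @param conf_level confidence level (default 0.95).
#' @return List with `estimate`, `conf_low`, `conf_high`, `n_screens`,
#'   `n_new_cases`.
#' @export
recover_positivity <- function(events, conf_level = 0.95) {
  .check(is.data.frame(events) && "new_case" %in% names(events),
         "events must be a data.frame with a new_case column")
  n <- nrow(events)
  if (n == 0) stop("empty screening stream", call. = FALSE)
  k <- sum(events$new_case)
  ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
  list(estimate = k / n, conf_low = ci[1], conf_high = ci[2],
       n_screens = n, n_new_cases = k)
}
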