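#' Read a cascade model definition from a JSON configuration file
#'
#' The configuration holds `compartments` (array of objects with `id`,
#' optional `label`, `terminal`), `transitions` (`source`, `target`,
#' `base_rate`, optional `driver`), `demography`
#' (`annual_incident_cases`, `background_mortality`, optional
#' `excess_mortality` object, `entry_compartment`, `death_compartment`),
#' and optionally `initial_counts` (object mapping compartment id to
#' people) plus `initial_year`.
#'
#' @param path path to the JSON file.
#' @return List with `model` (a [cascade_model()]) and, when initial counts
#'   are present, `initial` (a [cascade_state()]).
#' @export
read_cascade_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  dem <- cfg$demography
  if (!is.null(dem$excess_mortality)) {
    dem$excess_mortality <- unlist(dem$excess_mortality)
  }
  model <- cascade_model(cfg$compartments, cfg$transitions, dem)
  out <- list(model = model)
  if (!is.null(cfg$initial_counts)) {
    counts <- unlist(cfg$initial_counts)
    missing <- setdiff(model$compartments$id, names(counts))
    counts[missing] <- 0
    out$initial <- cascade_state(
      if (is.null(cfg$initial_year)) 0 else cfg$initial_year,
      counts[model$compartments$id])
  }
  out
}

#' Write a projected trajectory to CSV
#'
#' One row per time point, one column per compartment.
#'
#' @param trajectory a `cascade_trajectory` from [cascade_project()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}

#' Read an intervention cost ledger from CSV
#'
#' Expects Table-1-style columns `name`, `unit_cost_usd`, `people` and
#' optionally `spend_usd`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [recompute_ledger()].
#' @export
read_ledger_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check(all(c("name", "unit_cost_usd", "people") %in% names(df)),
         "ledger CSV needs name, unit_cost_usd, people columns")
  df
}

#' Read a monitoring cost table from CSV
#'
#' Expects columns `group`, `status`, `unit_cost_usd`, `people`.
#'
#' @param path CSV path.
#' @return A validated [monitoring_table()].
#' @export
read_monitoring_csv <- function(path) {
  monitoring_table(utils::read.csv(path, stringsAsFactors = FALSE))
}
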