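# Independent oracles used across tests.

# Matrix-power solution of a discrete-time compartmental model: one step is
# s' = s %*% M + b, with M built directly from the transition list. Coded
# independently of cascade_step() (no flow loop, no state objects).
oracle_project <- function(counts, transitions, mort, incidence,
                           entry, death, dt, n_steps) {
  ids <- names(counts)
  M <- diag(length(ids))
  dimnames(M) <- list(ids, ids)
  for (k in seq_len(nrow(transitions))) {
    src <- transitions$source[k]; tgt <- transitions$target[k]
    M[src, src] <- M[src, src] - transitions$base_rate[k] * dt
    M[src, tgt] <- M[src, tgt] + transitions$base_rate[k] * dt
  }
  for (id in ids) {
    M[id, id] <- M[id, id] - mort[id] * dt
    M[id, death] <- M[id, death] + mort[id] * dt
  }
  b <- stats::setNames(numeric(length(ids)), ids)
  b[entry] <- incidence * dt
  s <- counts
  for (i in seq_len(n_steps)) s <- drop(s %*% M) + b
  s
}

# three-compartment toy: A -> B -> C plus a death sink
toy_model <- function(rab = 0.3, rbc = 0.2, incidence = 0, mortality = 0) {
  cascade_model(
    compartments = data.frame(id = c("A", "B", "C", "death"),
                              terminal = c(FALSE, FALSE, FALSE, TRUE)),
    transitions = data.frame(source = c("A", "B"), target = c("B", "C"),
                             base_rate = c(rab, rbc)),
    demography = list(annual_incident_cases = incidence,
                      background_mortality = mortality,
                      entry_compartment = "A", death_compartment = "death"))
}

# monitoring table with arbitrary counts, Poltava unit costs
make_monitoring <- function(people) {
  t <- poltava_monitoring_table()
  t$people <- people
  monitoring_table(t)
}
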