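# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays desk-scale.

tiny_config <- function(horizon_days = 365L, n_agents = 300L, base_seed = 11L) {
  run_config(
    horizon_days = as.integer(horizon_days),
    base_seed = base_seed,
    population_spec = population_spec(n_agents = as.integer(n_agents))
  )
}

# A hand-built ledger with known counts, for recount oracles.
fake_ledger <- function(diag_q, treat_q, death_q, cat_q = integer(0),
                        imp_q = integer(0), person_days = rep(365 * 100, 5),
                        patient = numeric(0), program = numeric(0),
                        horizon_days = 365L, scenario = "fake") {
  mk <- function(q, ...) {
    df <- data.frame(day = seq_along(q) - 1L,
                     agent_id = seq_along(q), quintile = q,
                     stringsAsFactors = FALSE)
    extra <- list(...)
    for (nm in names(extra)) df[[nm]] <- rep(extra[[nm]], length.out = nrow(df))
    df
  }
  n_ex <- max(length(patient), length(program))
  if (n_ex == 0L) {
    ex <- data.frame(day = integer(0), agent_id = integer(0),
                     quintile = integer(0), patient_medical = numeric(0),
                     patient_transport = numeric(0),
                     program_medical = numeric(0),
                     program_transport = numeric(0))
  } else {
    ex <- data.frame(day = seq_len(n_ex) - 1L, agent_id = seq_len(n_ex),
                     quintile = rep_len(1:5, n_ex),
                     patient_medical = rep_len(c(patient, 0), n_ex)[seq_len(n_ex)],
                     patient_transport = 0,
                     program_medical = rep_len(c(program, 0), n_ex)[seq_len(n_ex)],
                     program_transport = 0)
  }
  structure(list(
    scenario = scenario, parameter_set_index = 0L,
    horizon_days = horizon_days,
    diagnoses = mk(diag_q, cancer = "x"),
    treatments = mk(treat_q, cancer = "x", provider_id = "H01",
                    provider_type = "public", level = "district",
                    outcome = "cured", complication = FALSE),
    cancer_deaths = mk(death_q, cancer = "x", perioperative = FALSE),
    background_deaths = mk(integer(0)),
    catastrophic = mk(cat_q),
    impoverishment = mk(imp_q, cause = "expense"),
    expenditures = ex,
    person_days = person_days,
    ticks = data.frame(day = 0:(horizon_days - 1L))
  ), class = "ledger")
}

# Brute-force dominance oracle: strict dominance by exhaustive pairwise
# comparison, then extended dominance by exhaustive ICER screening.
oracle_frontier <- function(pts) {
  if (!"status_quo" %in% pts$scenario)
    pts <- rbind(data.frame(scenario = "status_quo", cost = 0, benefit = 0),
                 pts)
  n <- nrow(pts)
  strict <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && pts$cost[j] <= pts$cost[i] && pts$benefit[j] >= pts$benefit[i] &&
        (pts$cost[j] < pts$cost[i] || pts$benefit[j] > pts$benefit[i])
    }, TRUE))
  }, TRUE)
  keep <- pts[!strict, ]
  keep <- keep[order(keep$benefit, keep$cost), ]
  repeat {
    if (nrow(keep) < 3L) break
    icers <- diff(keep$cost) / diff(keep$benefit)
    drop <- NA
    for (k in seq_len(length(icers) - 1L)) {
      if (icers[k + 1L] <= icers[k]) { drop <- k + 1L; break }
    }
    if (is.na(drop)) break
    keep <- keep[-drop, ]
  }
  keep$scenario
}
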