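test_that("parameter sets are reproducible draws honoring their descriptors", {
  dt <- generate_disease_table()
  tables <- list(disease = dt, choice = choice_model())
  p0 <- draw_parameter_set(tables, 0L, base_seed = 5L)
  p0b <- draw_parameter_set(tables, 0L, base_seed = 5L)
  expect_identical(p0, p0b)
  p1 <- draw_parameter_set(tables, 1L, base_seed = 5L)
  expect_false(identical(p0$disease$medical_cost, p1$disease$medical_cost))
  ## per-cancer draws shared across the three level rows
  for (cn in unique(p0$disease$cancer))
    expect_equal(length(unique(p0$disease$incidence_rate[p0$disease$cancer == cn])), 1L)
  ## supports respected
  expect_true(all(p0$disease$cure_probability >= 0 & p0$disease$cure_probability <= 1))
  expect_true(all(p0$disease$medical_cost > 0))

  ## all-point table: identical set for every index
  pt <- dt
  for (f in c("incidence", "survival", "cure", "periop", "complication", "cost")) {
    pt[[paste0(f, "_family")]] <- "point"
    pt[[paste0(f, "_par1")]] <- pt[[switch(f, incidence = "incidence_rate",
      survival = "untreated_median_survival", cure = "cure_probability",
      periop = "periop_mortality", complication = "complication_rate",
      cost = "medical_cost")]]
  }
  tp <- list(disease = pt, choice = choice_model())
  expect_identical(draw_parameter_set(tp, 0L, 5L)$disease,
                   draw_parameter_set(tp, 3L, 5L)$disease)

  ## a beta(2, 2) descriptor draws with mean 1/2
  one <- data.frame(cancer = "x", level = "district",
    incidence_rate = 10, incidence_family = "point", incidence_par1 = 10,
    incidence_par2 = NA, untreated_median_survival = 100,
    survival_family = "point", survival_par1 = 100, survival_par2 = NA,
    cure_probability = 0.5, cure_family = "beta", cure_par1 = 2, cure_par2 = 2,
    periop_mortality = 0.05, periop_family = "point", periop_par1 = 0.05,
    periop_par2 = NA, complication_rate = 0.1, complication_family = "point",
    complication_par1 = 0.1, complication_par2 = NA, medical_cost = 100,
    cost_family = "point", cost_par1 = 100, cost_par2 = NA,
    transport_cost_per_km = 0.1)
  draws <- vapply(0:999, function(i)
    draw_parameter_set(list(disease = one, choice = choice_model()), i, 7L)$disease$cure_probability,
    0)
  expect_equal(mean(draws), 0.5, tolerance = 0.02)

  bad <- one; bad$cure_family <- "weibull"
  expect_error(draw_parameter_set(list(disease = bad, choice = choice_model()), 0L, 1L),
               "unknown distribution family")
})

test_that("runs are deterministic, tick-complete, and silent without incidence", {
  cfg <- tiny_config(horizon_days = 200L, n_agents = 300L)
  ## zero incidence: no cancer events, no costs
  dt0 <- cfg$disease_table
  dt0$incidence_rate <- 0
  dt0$incidence_family <- "point"; dt0$incidence_par1 <- 0; dt0$incidence_par2 <- NA
  cfg0 <- cfg; cfg0$disease_table <- dt0
  ps0 <- draw_parameter_set(list(disease = dt0, choice = cfg$choice), 0L, cfg$base_seed)
  co <- build_cohort(cfg$population_spec, cfg$density_grid, seed = 1L)
  led0 <- run_simulation(co, policy_scenario("status_quo"), ps0, cfg0)
  expect_equal(nrow(led0$diagnoses), 0L)
  expect_equal(nrow(led0$cancer_deaths), 0L)
  expect_equal(nrow(led0$expenditures), 0L)
  expect_equal(nrow(led0$ticks), 200L)

  ## same seed twice: bit-identical ledgers
  ps <- draw_parameter_set(list(disease = cfg$disease_table, choice = cfg$choice),
                           0L, cfg$base_seed)
  l1 <- run_simulation(co, policy_scenario("UPF"), ps, cfg)
  l2 <- run_simulation(co, policy_scenario("UPF"), ps, cfg)
  expect_identical(l1, l2)
})

test_that("experiment pairing uses common random numbers and closes its accounts", {
  cfg <- tiny_config(horizon_days = 730L, n_agents = 400L, base_seed = 21L)
  ## a do-nothing custom scenario must replicate status quo exactly
  exp <- run_experiment(list(policy_scenario("custom")), 2L, cfg)
  for (i in 1:2) {
    a <- exp$ledgers[["status_quo"]][[i]]
    b <- exp$ledgers[["custom"]][[i]]
    b$scenario <- a$scenario
    expect_identical(a, b)
  }

  exp2 <- run_experiment(c("UPF"), 1L, cfg)
  expect_equal(length(exp2$ledgers$status_quo), 1L)
  ## societal cost = patient + program on every ledger
  for (s in names(exp2$ledgers)) {
    l <- exp2$ledgers[[s]][[1]]
    ol_soc <- outcome_levels(l, "societal")
    ol_moh <- outcome_levels(l, "ministry_of_health")
    expect_equal(ol_soc$cost, ol_soc$patient_cost + ol_soc$program_cost,
                 tolerance = 1e-9)
    expect_equal(ol_moh$cost, ol_moh$program_cost, tolerance = 1e-9)
  }
  ## every cancer death matches a diagnosis
  l <- exp2$ledgers$status_quo[[1]]
  expect_true(all(l$cancer_deaths$agent_id %in% l$diagnoses$agent_id))
  expect_true(all(l$person_days > 0))
})
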