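## The simulation engine.
##
## A daily tick cycles: cancer incidence -> care-seeking for untreated
## cases -> treatment outcomes and cost booking -> financial flagging ->
## untreated progression -> background vital dynamics.  One root seed
## spawns named substreams (incidence, choice, outcome, progression,
## vitals) keyed by parameter-set index but NOT by scenario, so paired
## scenario/status-quo runs share every draw a policy does not touch
## (common random numbers).

#' Construct a run configuration
#'
#' Bundles the simulation inputs and numerical knobs.  Anything not
#' supplied is generated from the default synthetic fixtures.
#'
#' @param horizon_days simulated days (default 18,250 = 50 x 365)
#' @param base_seed root seed; all substreams derive from it
#' @param population_spec a `population_spec`
#' @param density_grid raster from [generate_density_grid()]
#' @param facilities facility table (default generated from `base_seed`)
#' @param disease_table disease-parameter table
#' @param choice a `choice_model`
#' @param platforms named list of `platform_config`s
#' @param reeval_days days between care-seeking re-evaluations while
#'   untreated (default 90)
#' @param complication_cost_factor fraction of the medical price added when
#'   a complication occurs (cost only; no extra mortality)
#' @param transport_round_trip multiplier on one-way transport cost
#' @return an object of class `run_config`
#' @export
run_config <- function(horizon_days = 18250L,
                       base_seed = 0L,
                       population_spec = surgecea::population_spec(),
                       density_grid = generate_density_grid(),
                       facilities = NULL,
                       disease_table = generate_disease_table(),
                       choice = choice_model(),
                       platforms = NULL,
                       reeval_days = 90L,
                       complication_cost_factor = 0.3,
                       transport_round_trip = 2) {
  if (horizon_days < 1L) stop("horizon_days must be >= 1")
  if (is.null(facilities))
    facilities <- generate_facility_table(facility_spec(), density_grid, base_seed)
  if (is.null(platforms)) platforms <- default_platforms(facilities)
  structure(list(
    horizon_days = as.integer(horizon_days), base_seed = base_seed,
    population_spec = population_spec, density_grid = density_grid,
    facilities = facilities, disease_table = disease_table,
    choice = choice, platforms = platforms,
    reeval_days = as.integer(reeval_days),
    complication_cost_factor = complication_cost_factor,
    transport_round_trip = transport_round_trip
  ), class = "run_config")
}

#' Draw one probabilistic parameter set
#'
#' Reproducibly keyed by (base_seed, index).  Per-cancer quantities
#' (incidence, untreated median survival) are drawn once per cancer;
#' per-cancer-per-level quantities (cure, perioperative mortality,
#' complication rate, medical cost) once per row.  Point-mass descriptors
#' return their point, so a degenerate table gives the identical set for
#' every index.
#'
#' @param tables list(disease = disease table, choice = choice_model)
#' @param index parameter-set index (>= 0)
#' @param base_seed root seed
#' @return list of class `parameter_set`: `disease` (table with drawn point
#'   columns), `choice`, `index`
#' @export
draw_parameter_set <- function(tables, index, base_seed = 0L) {
  stopifnot(index >= 0)
  dt <- tables$disease
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(base_seed, paste0("params", index)))
  draw1 <- function(family, p1, p2) {
    draw_dist(list(family = family, par1 = p1, par2 = p2), 1L)
  }
  ## per-cancer fields: one draw shared by all level rows
  for (cn in unique(dt$cancer)) {
    rows <- which(dt$cancer == cn)
    r1 <- rows[1L]
    dt$incidence_rate[rows] <-
      draw1(dt$incidence_family[r1], dt$incidence_par1[r1], dt$incidence_par2[r1])
    dt$untreated_median_survival[rows] <-
      draw1(dt$survival_family[r1], dt$survival_par1[r1], dt$survival_par2[r1])
  }
  ## per-row fields
  for (r in seq_len(nrow(dt))) {
    dt$cure_probability[r] <-
      draw1(dt$cure_family[r], dt$cure_par1[r], dt$cure_par2[r])
    dt$periop_mortality[r] <-
      draw1(dt$periop_family[r], dt$periop_par1[r], dt$periop_par2[r])
    dt$complication_rate[r] <-
      draw1(dt$complication_family[r], dt$complication_par1[r], dt$complication_par2[r])
    dt$medical_cost[r] <-
      draw1(dt$cost_family[r], dt$cost_par1[r], dt$cost_par2[r])
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  structure(list(disease = dt, choice = tables$choice, index = index),
            class = "parameter_set")
}

## row accumulator: O(1) appends, bound to data.frame at the end
new_acc <- function() new.env(parent = emptyenv())
acc_add <- function(acc, row) {
  n <- length(acc)
  assign(sprintf("r%09d", n), row, envir = acc)
}
acc_collect <- function(acc, template) {
  nms <- sort(ls(acc))
  if (!length(nms)) return(template)
  do.call(rbind, c(lapply(nms, get, envir = acc), list(make.row.names = FALSE)))
}

#' Run one scenario over one cohort and parameter set
#'
#' Executes the daily cycle for `config$horizon_days` days and returns the
#' complete event ledger.  Bit-identical under identical inputs and seed;
#' the random substreams are keyed by parameter-set index only, so arms of
#' the same parameter set share all policy-untouched randomness.
#'
#' @param cohort a `cohort` (taken by value; the caller's copy is untouched)
#' @param scenario a `policy_scenario`
#' @param parameter_set from [draw_parameter_set()]
#' @param config a `run_config`
#' @return an object of class `ledger`
#' @export
run_simulation <- function(cohort, scenario, parameter_set, config) {
  system <- apply_policy(scenario, config$facilities, config$platforms)
  dt <- parameter_set$disease
  cm <- parameter_set$choice
  horizon <- config$horizon_days

  streams <- rng_streams(
    substream_seed(config$base_seed, paste0("run", parameter_set$index)),
    c("incidence", "choice", "outcome", "progression", "vitals"))

  ## fast lookups from the drawn disease table
  cancers <- unique(dt$cancer)
  levels3 <- PROVIDER_LEVELS
  lk <- function(col) {
    m <- matrix(NA_real_, length(cancers), length(levels3),
                dimnames = list(cancers, levels3))
    m[cbind(match(dt$cancer, cancers), match(dt$level, levels3))] <- dt[[col]]
    m
  }
  cure_m <- lk("cure_probability"); periop_m <- lk("periop_mortality")
  comp_m <- lk("complication_rate"); cost_m <- lk("medical_cost")
  surv_med <- stats::setNames(
    dt$untreated_median_survival[match(cancers, dt$cancer)], cancers)
  tkm <- stats::setNames(
    dt$transport_cost_per_km[match(cancers, dt$cancer)], cancers)
  p_daily_death <- untreated_daily_death_prob(surv_med)
  rates <- unique(dt[, c("cancer", "incidence_rate")])

  fac <- system$facilities
  nf <- nrow(fac)
  plat <- system$platform

  ## episode state (parallel vectors, appended as episodes arise)
  ep <- new.env(parent = emptyenv())
  ep$agent <- integer(0); ep$cancer <- character(0); ep$onset <- integer(0)
  ep$outcome <- character(0); ep$treated <- logical(0)
  ep$pre_income <- numeric(0); ep$quintile <- integer(0)
  ep$oop <- numeric(0); ep$flag_cat <- logical(0); ep$flag_imp <- logical(0)
  ep$censored <- logical(0)

  diagnoses <- new_acc(); choices <- new_acc(); treatments <- new_acc()
  expenditures <- new_acc(); cancer_deaths <- new_acc()
  background_deaths <- new_acc(); catastrophic <- new_acc()
  impoverishment <- new_acc()

  person_days <- numeric(5)
  tick_alive <- integer(horizon); tick_cases <- integer(horizon)
  tick_treat <- integer(horizon); tick_cdeaths <- integer(horizon)

  variant <- scenario$impoverishment_definition

  ## head-death impoverishment: called before households are rebuilt
  head_death <- function(dead_id, day) {
    hh <- cohort$households
    ag <- cohort$agents
    hrow <- match(ag$household_id[match(dead_id, ag$id)], hh$household_id)
    if (is.na(hrow) || hh$head_id[hrow] != dead_id) return(invisible())
    members <- ag$id[ag$alive & ag$household_id == hh$household_id[hrow]]
    survivors <- setdiff(members, dead_id)
    if (!length(survivors)) return(invisible())
    if (variant == "conservative") {
      dec_inc <- ag$income[match(dead_id, ag$id)]
      per_capita <- (hh$pooled_income[hrow] - dec_inc) / length(survivors)
      if (per_capita >= cohort$poverty_line) return(invisible())
    }
    for (sid in survivors) {
      acc_add(impoverishment, data.frame(
        day = day, agent_id = sid,
        quintile = ag$quintile[match(sid, ag$id)],
        cause = "head_death", stringsAsFactors = FALSE))
    }
    invisible()
  }

  kill_agent <- function(id, day, cancer, perioperative) {
    i <- match(id, cohort$agents$id)
    acc_add(cancer_deaths, data.frame(
      day = day, agent_id = id, cancer = cancer,
      quintile = cohort$agents$quintile[i],
      perioperative = perioperative, stringsAsFactors = FALSE))
    head_death(id, day)
    cohort$agents$alive[i] <<- FALSE
    cohort$households <<- rebuild_households(cohort$agents)
    invisible()
  }

  for (day in 0:(horizon - 1L)) {
    cohort$calendar_day <- day
    ag <- cohort$agents

    ## --- incidence ---------------------------------------------------
    active_ids <- ep$agent[!ep$censored & ep$outcome == "ongoing"]
    new_eps <- with_stream(streams, "incidence",
      incident_cases(cohort, rates, day, active_ids))
    if (nrow(new_eps)) {
      for (k in seq_len(nrow(new_eps))) {
        aid <- new_eps$agent_id[k]
        i <- match(aid, ag$id)
        n1 <- length(ep$agent) + 1L
        ep$agent[n1] <- aid; ep$cancer[n1] <- new_eps$cancer[k]
        ep$onset[n1] <- day; ep$outcome[n1] <- "ongoing"
        ep$treated[n1] <- FALSE
        ep$pre_income[n1] <- ag$income[i]
        ep$quintile[n1] <- ag$quintile[i]
        ep$oop[n1] <- 0; ep$flag_cat[n1] <- FALSE; ep$flag_imp[n1] <- FALSE
        ep$censored[n1] <- FALSE
        acc_add(diagnoses, data.frame(
          day = day, agent_id = aid, cancer = new_eps$cancer[k],
          quintile = ag$quintile[i], stringsAsFactors = FALSE))
      }
      tick_cases[day + 1L] <- nrow(new_eps)
    }

    ## --- care-seeking and treatment ----------------------------------
    seekers <- which(!ep$censored & ep$outcome == "ongoing" & !ep$treated &
                     (day - ep$onset) %% config$reeval_days == 0L)
    if (length(seekers)) {
      cap_left <- fac$capacity
      plat_sites <- if (!is.null(plat)) platform_active_sites(plat, day) else NULL
      plat_cap <- if (!is.null(plat)) plat$capacity else 0
      ag <- cohort$agents
      for (e in seekers) {
        aid <- ep$agent[e]
        i <- match(aid, ag$id)
        if (is.na(i) || !ag$alive[i]) next
        cn <- ep$cancer[e]
        ## public alternatives
        dx <- sqrt((fac$x - ag$x[i])^2 + (fac$y - ag$y[i])^2)
        ok <- dx <= cm$radius_km & cap_left > 0
        alts <- NULL
        if (any(ok)) {
          med_base <- fac$price[ok] + cost_m[cn, fac$level[ok]]
          pat_med <- if (scenario$remove_user_fees) rep(0, sum(ok)) else med_base
          tr <- config$transport_round_trip * tkm[[cn]] * dx[ok]
          pat_tr <- if (system$transport_voucher) rep(0, sum(ok)) else tr
          alts <- data.frame(
            alt_id = fac$facility_id[ok],
            type = "public", level = fac$level[ok],
            distance = dx[ok], medical_base = med_base, transport_full = tr,
            price = pat_med, transport = pat_tr,
            quality = cure_m[cn, fac$level[ok]],
            stringsAsFactors = FALSE)
        }
        if (!is.null(plat_sites) && nrow(plat_sites) && plat_cap > 0) {
          pdx <- sqrt((plat_sites$x - ag$x[i])^2 + (plat_sites$y - ag$y[i])^2)
          pok <- pdx <= cm$radius_km
          if (any(pok)) {
            ptr <- config$transport_round_trip * tkm[[cn]] * pdx[pok]
            palts <- data.frame(
              alt_id = paste0("platform_", plat$kind, "_", which(pok)),
              type = "platform", level = plat$clinical_level,
              distance = pdx[pok],
              medical_base = cost_m[cn, plat$clinical_level],
              transport_full = ptr,
              price = rep(plat$patient_price, sum(pok)),
              transport = if (system$transport_voucher) rep(0, sum(pok)) else ptr,
              quality = cure_m[cn, plat$clinical_level],
              stringsAsFactors = FALSE)
            alts <- if (is.null(alts)) palts else rbind(alts, palts)
          }
        }
        situation <- list(agent = list(income = ag$income[i]),
                          alternatives = alts)
        pick <- with_stream(streams, "choice", {
          pr <- choice_probabilities(situation, cm)
          select_provider(pr)
        })
        acc_add(choices, data.frame(
          day = day, agent_id = aid, alternative = pick,
          stringsAsFactors = FALSE))
        if (pick == "no_care") next

        a <- alts[match(pick, alts$alt_id), ]
        lv <- a$level
        quality <- list(periop_mortality = periop_m[cn, lv],
                        cure_probability = cure_m[cn, lv],
                        complication_rate = comp_m[cn, lv])
        res <- with_stream(streams, "outcome",
          treated_outcome(list(outcome = "ongoing"), quality))
        ep$treated[e] <- TRUE
        ep$outcome[e] <- res$outcome

        med_price <- a$medical_base *
          (1 + if (isTRUE(res$complication)) config$complication_cost_factor else 0)
        costs <- episode_costs(med_price, a$transport_full, a$type, system)
        ep$oop[e] <- ep$oop[e] + costs$patient_oop
        acc_add(expenditures, data.frame(
          day = day, agent_id = aid, quintile = ep$quintile[e],
          patient_medical = costs$patient_medical,
          patient_transport = costs$patient_transport,
          program_medical = costs$program_medical,
          program_transport = costs$program_transport,
          stringsAsFactors = FALSE))
        acc_add(treatments, data.frame(
          day = day, agent_id = aid, cancer = cn, quintile = ep$quintile[e],
          provider_id = pick, provider_type = a$type, level = lv,
          outcome = res$outcome, complication = isTRUE(res$complication),
          stringsAsFactors = FALSE))
        tick_treat[day + 1L] <- tick_treat[day + 1L] + 1L

        ## financial flags: once per episode, on cumulative episode OOP
        if (!ep$flag_cat[e] &&
            flag_catastrophic(ep$oop[e], ep$pre_income[e])) {
          ep$flag_cat[e] <- TRUE
          acc_add(catastrophic, data.frame(
            day = day, agent_id = aid, quintile = ep$quintile[e],
            stringsAsFactors = FALSE))
        }
        if (!ep$flag_imp[e] && ep$oop[e] > 0 &&
            ep$pre_income[e] >= cohort$poverty_line &&
            (ep$pre_income[e] - ep$oop[e]) < cohort$poverty_line) {
          ep$flag_imp[e] <- TRUE
          acc_add(impoverishment, data.frame(
            day = day, agent_id = aid, quintile = ep$quintile[e],
            cause = "expense", stringsAsFactors = FALSE))
        }

        if (a$type == "public") {
          fi <- match(pick, fac$facility_id)
          cap_left[fi] <- cap_left[fi] - 1
        } else plat_cap <- plat_cap - 1

        if (res$outcome == "died_perioperative") {
          kill_agent(aid, day, cn, perioperative = TRUE)
          tick_cdeaths[day + 1L] <- tick_cdeaths[day + 1L] + 1L
          ag <- cohort$agents
        }
      }
    }

    ## --- untreated / residual progression ----------------------------
    prog <- which(!ep$censored & ep$outcome == "ongoing")
    if (length(prog)) {
      u <- with_stream(streams, "progression", stats::runif(length(prog)))
      dies <- prog[u < p_daily_death[ep$cancer[prog]]]
      for (e in dies) {
        aid <- ep$agent[e]
        i <- match(aid, cohort$agents$id)
        if (is.na(i) || !cohort$agents$alive[i]) next
        ep$outcome[e] <- "died_of_cancer"
        kill_agent(aid, day, ep$cancer[e], perioperative = FALSE)
        tick_cdeaths[day + 1L] <- tick_cdeaths[day + 1L] + 1L
      }
    }

    ## --- background vital dynamics -----------------------------------
    vit <- with_stream(streams, "vitals", vital_dynamics_step(
      cohort, config$population_spec$background_mortality,
      config$population_spec$fertility_rate))
    cohort <- vit$cohort
    if (length(vit$deaths)) {
      for (id in vit$deaths) {
        qd <- cohort$agents$quintile[match(id, cohort$agents$id)]
        acc_add(background_deaths, data.frame(
          day = day, agent_id = id, quintile = qd, stringsAsFactors = FALSE))
      }
      ## censor any active episode of a background-death agent
      cens <- !ep$censored & ep$outcome == "ongoing" & ep$agent %in% vit$deaths
      ep$censored[cens] <- TRUE
    }

    ## --- person-time -------------------------------------------------
    alive <- cohort$agents$alive
    person_days <- person_days +
      tabulate(cohort$agents$quintile[alive], nbins = 5)
    tick_alive[day + 1L] <- sum(alive)
  }

  empty <- function(...) {
    cols <- list(...)
    as.data.frame(cols, stringsAsFactors = FALSE)
  }
  structure(list(
    scenario = scenario$name,
    parameter_set_index = parameter_set$index,
    horizon_days = horizon,
    diagnoses = acc_collect(diagnoses, empty(
      day = integer(0), agent_id = integer(0), cancer = character(0),
      quintile = integer(0))),
    choices = acc_collect(choices, empty(
      day = integer(0), agent_id = integer(0), alternative = character(0))),
    treatments = acc_collect(treatments, empty(
      day = integer(0), agent_id = integer(0), cancer = character(0),
      quintile = integer(0), provider_id = character(0),
      provider_type = character(0), level = character(0),
      outcome = character(0), complication = logical(0))),
    expenditures = acc_collect(expenditures, empty(
      day = integer(0), agent_id = integer(0), quintile = integer(0),
      patient_medical = numeric(0), patient_transport = numeric(0),
      program_medical = numeric(0), program_transport = numeric(0))),
    cancer_deaths = acc_collect(cancer_deaths, empty(
      day = integer(0), agent_id = integer(0), cancer = character(0),
      quintile = integer(0), perioperative = logical(0))),
    background_deaths = acc_collect(background_deaths, empty(
      day = integer(0), agent_id = integer(0), quintile = integer(0))),
    catastrophic = acc_collect(catastrophic, empty(
      day = integer(0), agent_id = integer(0), quintile = integer(0))),
    impoverishment = acc_collect(impoverishment, empty(
      day = integer(0), agent_id = integer(0), quintile = integer(0),
      cause = character(0))),
    person_days = person_days,
    ticks = data.frame(day = 0:(horizon - 1L), n_alive = tick_alive,
                       new_cases = tick_cases, treatments = tick_treat,
                       cancer_deaths = tick_cdeaths)
  ), class = "ledger")
}

#' @export
print.ledger <- function(x, ...) {
  cat("<ledger> scenario ", x$scenario, ", parameter set ",
      x$parameter_set_index, ": ", nrow(x$diagnoses), " diagnoses, ",
      nrow(x$treatments), " treatments, ", nrow(x$cancer_deaths),
      " cancer deaths over ", x$horizon_days, " days\n", sep = "")
  invisible(x)
}

#' Run the multi-scenario, multi-parameter-set experiment
#'
#' For each parameter-set index, one cohort is built and the status quo
#' plus every requested scenario are run against it under common random
#' numbers.  The default design is 100 parameter sets over the full
#' 50-year horizon.
#'
#' @param scenarios character vector of scenario names (status quo is
#'   always included) or a list of `policy_scenario`s
#' @param n_parameter_sets number of probabilistic parameter draws
#' @param config a `run_config`
#' @return list of class `experiment`: `ledgers[[scenario]][[i]]`,
#'   `scenarios`, `n_parameter_sets`, `config`
#' @export
run_experiment <- function(scenarios, n_parameter_sets = 100L, config = run_config()) {
  if (n_parameter_sets < 1L) stop("n_parameter_sets must be >= 1")
  if (is.character(scenarios))
    scenarios <- lapply(scenarios, policy_scenario)
  nms <- vapply(scenarios, `[[`, "", "name")
  if (!"status_quo" %in% nms) {
    scenarios <- c(list(policy_scenario("status_quo")), scenarios)
    nms <- c("status_quo", nms)
  }
  names(scenarios) <- nms
  ledgers <- stats::setNames(
    replicate(length(scenarios), vector("list", n_parameter_sets), simplify = FALSE),
    nms)
  tables <- list(disease = config$disease_table, choice = config$choice)
  for (i in seq_len(n_parameter_sets)) {
    ps <- draw_parameter_set(tables, i - 1L, config$base_seed)
    cohort <- build_cohort(config$population_spec, config$density_grid,
                           seed = substream_seed(config$base_seed, paste0("cohort", i - 1L)))
    for (s in nms) {
      ledgers[[s]][[i]] <- run_simulation(cohort, scenarios[[s]], ps, config)
    }
  }
  structure(list(ledgers = ledgers, scenarios = scenarios,
                 n_parameter_sets = n_parameter_sets, config = config),
            class = "experiment")
}
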