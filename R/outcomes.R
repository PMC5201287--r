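## Extended cost-effectiveness outcomes.
##
## Ledgers are reduced to the ECEA outcome suite: cancer deaths,
## catastrophic expenditure and impoverishment averted per 100,000 per
## year by wealth quintile, treatment probability, incidence:mortality
## ratios, system cost, Gini-analogue equity indices (positive = pro-poor),
## dominance-based efficiency frontiers with ICERs, cost-standardized
## outcomes and acceptability curves.

QUINTILE_LABELS <- c("poorest", "poor", "middle", "rich", "richest")

#' Catastrophic-expenditure flag
#'
#' True iff out-of-pocket spending is strictly more than 10% of income
#' prior to the cancer-related illness.
#'
#' @param expenditure cumulative out-of-pocket spending (>= 0)
#' @param pre_illness_income annual income before illness (> 0)
#' @param threshold share of income (default 0.10)
#' @return logical
#' @export
flag_catastrophic <- function(expenditure, pre_illness_income, threshold = 0.10) {
  if (any(pre_illness_income <= 0)) stop("pre-illness income must be > 0")
  if (any(expenditure < 0)) stop("expenditure must be >= 0")
  expenditure > threshold * pre_illness_income
}

#' Count persons impoverished by one event
#'
#' Base definition: a health expense impoverishes its payer if it pushes
#' them from at or above the poverty line to below it; the cancer death of
#' a household head counts every surviving member.  Conservative
#' definition: a head/member death counts survivors only if the loss of the
#' deceased's income pushes the survivors' per-capita pooled income below
#' the (familial per-capita) poverty line.
#'
#' @param event list: either `list(type = "expense", income, expense)` or
#'   `list(type = "head_death", deceased_id)`
#' @param household list with `member_incomes` (named by agent id) and
#'   `head_id`; required for death events
#' @param poverty_line money/year (> 0)
#' @param variant "base" or "conservative"
#' @return number of persons impoverished by the event
#' @export
count_impoverishment <- function(event, household = NULL, poverty_line,
                                 variant = c("base", "conservative")) {
  variant <- match.arg(variant)
  if (poverty_line <= 0) stop("poverty line must be > 0")
  if (event$type == "expense") {
    newly_poor <- event$income >= poverty_line &&
      (event$income - event$expense) < poverty_line
    return(as.integer(newly_poor))
  }
  if (event$type != "head_death") stop("unknown event type: ", event$type)
  ids <- names(household$member_incomes)
  survivors <- setdiff(ids, as.character(event$deceased_id))
  if (!length(survivors)) return(0L)
  if (variant == "conservative") {
    pooled_after <- sum(household$member_incomes[survivors])
    if (pooled_after / length(survivors) >= poverty_line) return(0L)
  }
  length(survivors)
}

#' Equal-weight overall value from five quintile values
#'
#' Quintiles are equal-sized by construction, so the population "Overall"
#' row is their arithmetic mean.
#'
#' @param quintile_values numeric vector of exactly 5 values
#'   (poorest to richest)
#' @return numeric scalar
#' @export
aggregate_overall <- function(quintile_values) {
  if (length(quintile_values) != 5L) stop("exactly 5 quintile values required")
  mean(quintile_values)
}

#' Per-scenario outcome levels from one ledger
#'
#' Rates are per 100,000 person-years within each quintile; the overall
#' row is the equal-weight mean of the five quintile rates.
#'
#' @param ledger a `ledger` from [run_simulation()]
#' @param perspective "societal" (patient + program cost) or
#'   "ministry_of_health" (program cost only)
#' @return a list of class `outcome_levels` with per-quintile vectors
#' @export
outcome_levels <- function(ledger, perspective = c("societal", "ministry_of_health")) {
  perspective <- match.arg(perspective)
  py <- ledger$person_days / 365
  if (any(py <= 0)) stop("person-time must be positive in every quintile")
  qcount <- function(df) tabulate(df$quintile, nbins = 5)
  per100k <- function(counts) counts / py * 1e5
  deaths_q <- qcount(ledger$cancer_deaths)
  diag_q <- qcount(ledger$diagnoses)
  treat_q <- qcount(ledger$treatments)
  ex <- ledger$expenditures
  patient_q <- program_q <- numeric(5)
  if (nrow(ex)) {
    patient_q <- vapply(1:5, function(q) {
      sum(ex$patient_medical[ex$quintile == q] + ex$patient_transport[ex$quintile == q])
    }, 0)
    program_q <- vapply(1:5, function(q) {
      sum(ex$program_medical[ex$quintile == q] + ex$program_transport[ex$quintile == q])
    }, 0)
  }
  cost_q <- if (perspective == "societal") patient_q + program_q else program_q
  tp_q <- ifelse(diag_q > 0, treat_q / diag_q, NA_real_)
  structure(list(
    person_years = py,
    deaths = per100k(deaths_q),
    catastrophic = per100k(qcount(ledger$catastrophic)),
    impoverishment = per100k(qcount(ledger$impoverishment)),
    incidence = per100k(diag_q),
    mortality = per100k(deaths_q),
    treatment_probability = tp_q,
    cost = per100k(cost_q),
    patient_cost = per100k(patient_q),
    program_cost = per100k(program_q),
    horizon_days = ledger$horizon_days,
    scenario = ledger$scenario
  ), class = "outcome_levels")
}

#' Incremental outcomes of a scenario over the status quo
#'
#' Averted = status-quo rate minus scenario rate for deaths, catastrophic
#' expenditure and impoverishment (positive = improvement; negative values
#' mean cases created).  Treatment probability is differenced the other way
#' (scenario minus status quo), and the incidence:mortality ratio is the
#' scenario IMR divided by the status-quo IMR (> 1 = improvement).  System
#' cost is the scenario's incremental cost, per 100,000 per year.
#'
#' @param scenario_outcomes,statusquo_outcomes `outcome_levels`
#' @return a list of class `incremental_outcomes`; each element carries the
#'   five quintile values plus the equal-weight `overall`
#' @export
averted <- function(scenario_outcomes, statusquo_outcomes) {
  if (scenario_outcomes$horizon_days != statusquo_outcomes$horizon_days)
    stop("mismatched horizons between scenario and status quo")
  wrap <- function(v) list(by_quintile = v, overall = aggregate_overall(v))
  imr_s <- scenario_outcomes$incidence / scenario_outcomes$mortality
  imr_0 <- statusquo_outcomes$incidence / statusquo_outcomes$mortality
  imr <- ifelse(is.finite(imr_s) & is.finite(imr_0), imr_s / imr_0, NA_real_)
  structure(list(
    scenario = scenario_outcomes$scenario,
    deaths_averted = wrap(statusquo_outcomes$deaths - scenario_outcomes$deaths),
    catastrophic_averted = wrap(statusquo_outcomes$catastrophic - scenario_outcomes$catastrophic),
    impoverishment_averted = wrap(statusquo_outcomes$impoverishment - scenario_outcomes$impoverishment),
    treatment_probability = wrap(scenario_outcomes$treatment_probability -
                                   statusquo_outcomes$treatment_probability),
    imr_ratio = wrap(imr),
    system_cost = aggregate_overall(scenario_outcomes$cost) -
      aggregate_overall(statusquo_outcomes$cost)
  ), class = "incremental_outcomes")
}

#' Incidence:mortality ratio of a scenario relative to the status quo
#'
#' @param scenario_ledger,statusquo_ledger `ledger`s over the same horizon
#' @return list(by_quintile, overall); zero-mortality cells are NA
#'   (flagged undefined, never infinity)
#' @export
imr_ratio <- function(scenario_ledger, statusquo_ledger) {
  s <- outcome_levels(scenario_ledger)
  s0 <- outcome_levels(statusquo_ledger)
  r <- ifelse(s$mortality > 0 & s0$mortality > 0,
              (s$incidence / s$mortality) / (s0$incidence / s0$mortality),
              NA_real_)
  list(by_quintile = r, overall = aggregate_overall(r))
}

#' Treatment probability given a cancer diagnosis
#'
#' @param ledger a `ledger`
#' @return list(by_quintile, overall); quintiles with zero diagnoses are NA
#' @export
treatment_probability <- function(ledger) {
  if (nrow(ledger$diagnoses) == 0L) stop("no diagnoses in ledger")
  d <- tabulate(ledger$diagnoses$quintile, nbins = 5)
  t <- tabulate(ledger$treatments$quintile, nbins = 5)
  p <- ifelse(d > 0, t / d, NA_real_)
  list(by_quintile = p, overall = aggregate_overall(p))
}

#' Gini-analogue equity (concentration) index of a benefit distribution
#'
#' The cumulative benefit-share curve is built over quintiles ordered
#' poorest to richest (population shares 0.2 each) and the index is twice
#' the area between that curve and the diagonal, signed so that positive
#' means benefits concentrated among the poorest.  Uniform benefit gives
#' 0; all benefit to the poorest quintile +0.8; all to the richest -0.8.
#' Negative benefit totals are scored on absolute shares with the sign
#' taken from the direction of concentration (harm concentrated on the
#' poorest is anti-poor, hence negative).
#'
#' @param benefit_by_quintile numeric vector of 5 (may contain negatives)
#' @return index in [-1, 1]; NA if all benefits are zero
#' @export
equity_index <- function(benefit_by_quintile) {
  if (length(benefit_by_quintile) != 5L) stop("exactly 5 quintile benefits required")
  tot <- sum(benefit_by_quintile)
  if (all(benefit_by_quintile == 0)) return(NA_real_)
  if (tot == 0) return(NA_real_)  # undefined concentration of a zero net benefit
  shares <- cumsum(benefit_by_quintile) / tot
  y <- c(0, shares)
  auc <- sum(0.2 * (y[-6] + y[-1]) / 2)
  idx <- 2 * (auc - 0.5)
  if (tot < 0) idx <- -idx
  max(-1, min(1, idx))
}

#' Average of the three per-outcome equity indices
#' @param indices numeric vector of 3 (deaths, catastrophic, impoverishment)
#' @return arithmetic mean
#' @export
average_equity <- function(indices) {
  if (length(indices) != 3L) stop("exactly 3 equity indices required")
  mean(indices)
}

#' Equity summary of one scenario's incremental outcomes
#'
#' @param incremental an `incremental_outcomes`
#' @return list of class `equity_result`: per-outcome indices and their
#'   average
#' @export
equity_result <- function(incremental) {
  idx <- c(
    deaths = equity_index(incremental$deaths_averted$by_quintile),
    catastrophic = equity_index(incremental$catastrophic_averted$by_quintile),
    impoverishment = equity_index(incremental$impoverishment_averted$by_quintile)
  )
  structure(list(index_deaths = idx[["deaths"]],
                 index_catastrophic = idx[["catastrophic"]],
                 index_impoverishment = idx[["impoverishment"]],
                 average = average_equity(unname(idx))),
            class = "equity_result")
}

#' Efficiency frontier with strict and extended dominance
#'
#' The status quo sits at (0, 0).  Strictly dominated points (another
#' option is at least as cheap and at least as beneficial, strictly better
#' in one) are removed first; the survivors are walked in order of
#' increasing benefit and options whose incremental cost-effectiveness
#' ratio is not lower than the next more-effective option's are removed as
#' extended-dominated, leaving strictly increasing ICERs along the
#' frontier.
#'
#' @param points data.frame with columns `scenario`, `cost`, `benefit`
#'   (incremental over the status quo)
#' @return list of class `frontier_result`: `frontier` (scenario, cost,
#'   benefit, icer vs the previous frontier point) and `dominated`
#'   (scenario, type)
#' @export
icer_frontier <- function(points) {
  pts <- points
  if (!"status_quo" %in% pts$scenario)
    pts <- rbind(data.frame(scenario = "status_quo", cost = 0, benefit = 0,
                            stringsAsFactors = FALSE),
                 pts[, c("scenario", "cost", "benefit")])
  n <- nrow(pts)
  strict <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || strict[j]) next
      if (pts$cost[j] <= pts$cost[i] && pts$benefit[j] >= pts$benefit[i] &&
          (pts$cost[j] < pts$cost[i] || pts$benefit[j] > pts$benefit[i])) {
        strict[i] <- TRUE
        break
      }
    }
  }
  cand <- pts[!strict, , drop = FALSE]
  cand <- cand[order(cand$benefit, cand$cost), , drop = FALSE]
  extended <- character(0)
  repeat {
    if (nrow(cand) < 3L) break
    icers <- diff(cand$cost) / diff(cand$benefit)
    bad <- which(diff(icers) <= 0)
    if (!length(bad)) break
    drop_i <- bad[1L] + 1L  # the middle point of the first non-increasing pair
    extended <- c(extended, cand$scenario[drop_i])
    cand <- cand[-drop_i, , drop = FALSE]
  }
  icer <- c(NA_real_, diff(cand$cost) / diff(cand$benefit))
  frontier <- data.frame(scenario = cand$scenario, cost = cand$cost,
                         benefit = cand$benefit, icer = icer,
                         stringsAsFactors = FALSE)
  dominated <- data.frame(
    scenario = c(pts$scenario[strict], extended),
    type = c(rep("strict", sum(strict)), rep("extended", length(extended))),
    stringsAsFactors = FALSE)
  structure(list(frontier = frontier, dominated = dominated),
            class = "frontier_result")
}

#' Benefits per $100,000 of program spending
#'
#' @param benefit numeric benefit(s) (may be negative: cases created)
#' @param cost positive cost on the same accounting basis
#' @return benefit x 100,000 / cost; NA (undefined) at zero cost
#' @export
standardized_outcomes <- function(benefit, cost) {
  ifelse(cost > 0, benefit * 1e5 / cost, NA_real_)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, the fraction of parameter-set runs
#' in which each scenario (status quo included at (0, 0)) maximizes net
#' monetary benefit `wtp * benefit - cost`.  Fractions sum to 1 at every
#' threshold; ties go to the cheaper option.
#'
#' @param per_run data.frame with columns `scenario`, `run`, `cost`,
#'   `benefit` (incremental over status quo, one row per scenario per run)
#' @param wtp_grid numeric vector of willingness-to-pay thresholds
#' @return data.frame: `wtp`, one probability column per scenario
#' @export
acceptability_curves <- function(per_run, wtp_grid) {
  runs <- unique(per_run$run)
  if (length(runs) < 2L) {
    if (length(unique(per_run$scenario)) > 1L)
      stop("at least 2 runs required")
  }
  scens <- c("status_quo", setdiff(unique(per_run$scenario), "status_quo"))
  out <- matrix(0, length(wtp_grid), length(scens),
                dimnames = list(NULL, scens))
  for (wi in seq_along(wtp_grid)) {
    wtp <- wtp_grid[wi]
    wins <- stats::setNames(numeric(length(scens)), scens)
    for (r in runs) {
      sub <- per_run[per_run$run == r, ]
      nmb <- c(status_quo = 0,
               stats::setNames(wtp * sub$benefit - sub$cost, sub$scenario))
      cost <- c(status_quo = 0, stats::setNames(sub$cost, sub$scenario))
      best <- max(nmb)
      tied <- names(nmb)[nmb >= best - 1e-12]
      winner <- tied[which.min(cost[tied])]
      wins[winner] <- wins[winner] + 1
    }
    out[wi, ] <- wins / length(runs)
  }
  data.frame(wtp = wtp_grid, out, check.names = FALSE)
}

#' Discounted aggregate of a yearly stream
#'
#' @param yearly_stream numeric vector, year 0 first
#' @param rate annual discount rate (>= 0)
#' @return sum of `x_t / (1 + rate)^t`
#' @export
discounted_aggregate <- function(yearly_stream, rate) {
  if (rate < 0) stop("rate must be >= 0")
  t <- seq_along(yearly_stream) - 1
  sum(yearly_stream / (1 + rate)^t)
}

#' Full incremental outcome table for an experiment
#'
#' Averages each scenario's incremental outcomes over all parameter sets
#' (arm i differenced against status-quo arm i under common random
#' numbers, then averaged).
#'
#' @param experiment from [run_experiment()]
#' @param perspective cost accounting perspective
#' @return data.frame, one row per scenario x metric x quintile/overall
#' @export
outcome_table <- function(experiment, perspective = c("societal", "ministry_of_health")) {
  perspective <- match.arg(perspective)
  nms <- setdiff(names(experiment$ledgers), "status_quo")
  rows <- list()
  for (s in nms) {
    accum <- NULL
    for (i in seq_len(experiment$n_parameter_sets)) {
      sq <- outcome_levels(experiment$ledgers[["status_quo"]][[i]], perspective)
      sc <- outcome_levels(experiment$ledgers[[s]][[i]], perspective)
      inc <- averted(sc, sq)
      flat <- c(
        deaths_averted = inc$deaths_averted$by_quintile,
        catastrophic_averted = inc$catastrophic_averted$by_quintile,
        impoverishment_averted = inc$impoverishment_averted$by_quintile,
        treatment_probability = inc$treatment_probability$by_quintile,
        imr_ratio = inc$imr_ratio$by_quintile,
        system_cost = inc$system_cost)
      accum <- if (is.null(accum)) flat else accum + flat
    }
    accum <- accum / experiment$n_parameter_sets
    metric <- sub("[0-9]+$", "", names(accum))
    qi <- suppressWarnings(as.integer(sub("^.*?([0-9]+)$", "\\1", names(accum))))
    df <- data.frame(scenario = s, metric = metric,
                     quintile = ifelse(is.na(qi), "overall", QUINTILE_LABELS[qi]),
                     value = unname(accum), stringsAsFactors = FALSE)
    ## add overall rows (equal-weight quintile means)
    for (m in unique(metric[metric != "system_cost"])) {
      v <- df$value[df$metric == m & df$quintile != "overall"]
      df <- rbind(df, data.frame(scenario = s, metric = m, quintile = "overall",
                                 value = aggregate_overall(v),
                                 stringsAsFactors = FALSE))
    }
    rows[[s]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
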