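## The synthetic open cohort.
##
## Agents carry demographics, gamma-distributed annual income, a planar-km
## geoposition sampled from the density raster, household membership and a
## fixed baseline wealth quintile.  The national poverty line is defined
## endogenously as the income quantile below which the target headcount
## (default 19.5%) of the instantiated population lives.

#' Compute the national poverty line from an empirical income distribution
#'
#' Returns the headcount-quantile of the incomes: the line is placed midway
#' between the k-th and (k+1)-th order statistics, k = round(headcount * n),
#' so that the share strictly below the line equals the headcount up to 1/n
#' quantization.
#'
#' @param incomes numeric vector of annual incomes
#' @param headcount target poverty headcount in (0, 1)
#' @return the poverty line (money/year)
#' @export
compute_poverty_line <- function(incomes, headcount) {
  if (length(incomes) == 0L) stop("empty income vector")
  if (headcount <= 0 || headcount >= 1) stop("headcount must be in (0, 1)")
  n <- length(incomes)
  s <- sort(incomes)
  k <- round(headcount * n)
  if (k <= 0L) return(s[1L])
  if (k >= n) k <- n - 1L
  (s[k] + s[k + 1L]) / 2
}

#' Build the synthetic cohort
#'
#' Households are assembled by drawing sizes from the spec's mass function
#' until the agent budget is exhausted (the last household is truncated to
#' fit exactly); each household is placed in a raster cell with probability
#' proportional to density weight and jittered within the cell; ages and
#' sexes follow the age/sex marginals; incomes are i.i.d. gamma; baseline
#' wealth quintiles are assigned by income rank and never re-ranked during
#' a run.
#'
#' @param spec a `population_spec`
#' @param density_grid raster from [generate_density_grid()]
#' @param seed integer seed; identical seeds give identical cohorts
#' @return an object of class `cohort`
#' @export
build_cohort <- function(spec = population_spec(),
                         density_grid = generate_density_grid(),
                         seed = 0L) {
  validate_population_spec(spec)
  if (spec$n_agents < 1L) stop("n_agents must be >= 1")
  if (sum(density_grid$weight) <= 0) stop("density grid has no mass")
  n <- spec$n_agents
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, "cohort"))

  ## households: draw sizes until n agents are allocated
  hs <- spec$household_size_distribution
  sizes <- integer(0)
  total <- 0L
  while (total < n) {
    batch <- sample(seq_along(hs), size = max(16L, ceiling((n - total) / mean(seq_along(hs) * hs))),
                    replace = TRUE, prob = hs)
    sizes <- c(sizes, batch)
    total <- sum(sizes)
  }
  cum <- cumsum(sizes)
  last <- which(cum >= n)[1L]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n)
  sizes <- sizes[sizes > 0L]
  n_hh <- length(sizes)
  household_id <- rep(seq_len(n_hh), times = sizes)

  ## geoposition: one cell per household, members co-located
  cell_km <- if (nrow(density_grid) > 1)
    min(diff(sort(unique(density_grid$x)))) else 1
  cells <- sample.int(nrow(density_grid), n_hh, replace = TRUE,
                      prob = density_grid$weight)
  hx <- density_grid$x[cells] + stats::runif(n_hh, -cell_km / 2, cell_km / 2)
  hy <- density_grid$y[cells] + stats::runif(n_hh, -cell_km / 2, cell_km / 2)

  ## demographics from the age/sex marginals
  m <- spec$age_sex_marginals
  p <- c(m$male, m$female)
  band <- sample.int(length(p), n, replace = TRUE, prob = p)
  is_male <- band <= nrow(m)
  row_i <- ifelse(is_male, band, band - nrow(m))
  age <- stats::runif(n, m$age_lo[row_i], m$age_hi[row_i])

  income <- stats::rgamma(n, shape = spec$income_gamma_shape,
                          scale = spec$income_gamma_scale)
  ## gamma(0+) draws can underflow to 0; incomes must be positive
  income <- pmax(income, .Machine$double.eps)

  quintile <- wealth_quintile(income)

  agents <- data.frame(
    id = seq_len(n),
    sex = ifelse(is_male, "m", "f"),
    age = age,
    household_id = household_id,
    x = hx[household_id],
    y = hy[household_id],
    income = income,
    pre_illness_income = income,
    quintile = quintile,
    alive = TRUE,
    stringsAsFactors = FALSE
  )
  households <- rebuild_households(agents)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  structure(list(
    agents = agents,
    households = households,
    poverty_line = compute_poverty_line(income, spec$target_poverty_headcount),
    calendar_day = 0L,
    next_agent_id = n + 1L
  ), class = "cohort")
}

#' Assign baseline wealth quintiles by income rank
#'
#' Quintile 1 is the poorest fifth.  Ties are broken by position so the
#' partition is always as equal-sized as n allows (exactly n/5 per quintile
#' when 5 divides n).
#'
#' @param income numeric vector
#' @return integer vector in 1..5
#' @export
wealth_quintile <- function(income) {
  n <- length(income)
  r <- rank(income, ties.method = "first")
  as.integer(ceiling(r * 5 / n))
}

## Household table derived from agent state: head = oldest member aged >= 18
## (fallback: oldest member); pooled income = sum of living members' incomes.
#' @keywords internal
rebuild_households <- function(agents) {
  live <- agents[agents$alive, , drop = FALSE]
  ids <- sort(unique(live$household_id))
  head_id <- integer(length(ids))
  pooled <- numeric(length(ids))
  nm <- integer(length(ids))
  sp <- split(seq_len(nrow(live)), live$household_id)
  for (i in seq_along(ids)) {
    rows <- sp[[as.character(ids[i])]]
    adults <- rows[live$age[rows] >= 18]
    cand <- if (length(adults)) adults else rows
    head_id[i] <- live$id[cand[which.max(live$age[cand])]]
    pooled[i] <- sum(live$income[rows])
    nm[i] <- length(rows)
  }
  data.frame(household_id = ids, head_id = head_id,
             pooled_income = pooled, n_members = nm)
}

#' Build the distance-based network
#'
#' Undirected edges between all agent pairs whose Euclidean distance is at
#' most `radius_km` (family edges are implicit through shared household
#' membership).  Spatial binning keeps this well below all-pairs cost for
#' local radii.
#'
#' @param agents agent data.frame with columns `id`, `x`, `y`
#' @param radius_km neighbourhood radius; `Inf` gives the complete graph
#' @return data.frame of edges (`i`, `j`) with i < j
#' @export
build_distance_network <- function(agents, radius_km) {
  if (radius_km < 0) stop("radius_km must be >= 0")
  n <- nrow(agents)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0)))
  if (is.infinite(radius_km)) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(data.frame(i = agents$id[idx[, 1]], j = agents$id[idx[, 2]]))
  }
  cell <- max(radius_km, .Machine$double.eps)
  cx <- floor(agents$x / cell)
  cy <- floor(agents$y / cell)
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  coord <- do.call(rbind, strsplit(names(buckets), " "))
  bx <- as.numeric(coord[, 1]); by <- as.numeric(coord[, 2])
  bmap <- stats::setNames(seq_along(buckets), names(buckets))
  out_i <- integer(0); out_j <- integer(0)
  for (b in seq_along(buckets)) {
    here <- buckets[[b]]
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(bx[b] + dx, by[b] + dy)
      nb <- bmap[k]
      if (is.na(nb) || nb < b) next
      there <- buckets[[nb]]
      if (nb == b) {
        if (length(here) < 2L) next
        pr <- which(upper.tri(matrix(0, length(here), length(here))), arr.ind = TRUE)
        a <- here[pr[, 1]]; bb <- here[pr[, 2]]
      } else {
        g <- expand.grid(a = here, b = there)
        a <- g$a; bb <- g$b
      }
      d2 <- (agents$x[a] - agents$x[bb])^2 + (agents$y[a] - agents$y[bb])^2
      keep <- d2 <= radius_km^2
      out_i <- c(out_i, a[keep]); out_j <- c(out_j, bb[keep])
    }
  }
  ii <- pmin(agents$id[out_i], agents$id[out_j])
  jj <- pmax(agents$id[out_i], agents$id[out_j])
  ord <- order(ii, jj)
  unique(data.frame(i = ii[ord], j = jj[ord]))
}

#' One day of background vital dynamics
#'
#' Each living agent dies with daily probability `mortality_rate / 365`;
#' each living woman aged 15-49 gives birth with daily probability
#' `fertility_rate / 365`.  Newborns inherit household and location, are
#' assigned an equal share of household pooled income and the household
#' head's baseline quintile.  All ages advance by one day.  Draws come from
#' the current RNG state (callers wrap this in a named stream).
#'
#' @param cohort a `cohort`
#' @param mortality_rate background deaths per person-year
#' @param fertility_rate births per woman aged 15-49 per year
#' @return list(cohort, deaths = agent ids, births = agent ids)
#' @export
vital_dynamics_step <- function(cohort, mortality_rate, fertility_rate) {
  if (mortality_rate < 0 || fertility_rate < 0) stop("vital rates must be >= 0")
  ag <- cohort$agents
  live <- which(ag$alive)
  deaths <- integer(0)
  if (mortality_rate > 0 && length(live)) {
    u <- stats::runif(length(live))
    deaths <- ag$id[live[u < mortality_rate / 365]]
    if (length(deaths)) ag$alive[match(deaths, ag$id)] <- FALSE
  }
  births <- integer(0)
  if (fertility_rate > 0) {
    mothers <- which(ag$alive & ag$sex == "f" & ag$age >= 15 & ag$age < 50)
    if (length(mothers)) {
      u <- stats::runif(length(mothers))
      mothers <- mothers[u < fertility_rate / 365]
      if (length(mothers)) {
        hh <- cohort$households
        for (mi in mothers) {
          hrow <- match(ag$household_id[mi], hh$household_id)
          share <- hh$pooled_income[hrow] / (hh$n_members[hrow] + 1L)
          nid <- cohort$next_agent_id
          cohort$next_agent_id <- nid + 1L
          head_row <- match(hh$head_id[hrow], ag$id)
          baby <- data.frame(
            id = nid,
            sex = if (stats::runif(1) < 0.495) "m" else "f",
            age = 0,
            household_id = ag$household_id[mi],
            x = ag$x[mi], y = ag$y[mi],
            income = max(share, .Machine$double.eps),
            pre_illness_income = max(share, .Machine$double.eps),
            quintile = ag$quintile[head_row],
            alive = TRUE,
            stringsAsFactors = FALSE
          )
          ag <- rbind(ag, baby)
          births <- c(births, nid)
        }
      }
    }
  }
  ag$age[ag$alive] <- ag$age[ag$alive] + 1 / 365
  cohort$agents <- ag
  if (length(deaths) || length(births))
    cohort$households <- rebuild_households(ag)
  list(cohort = cohort, deaths = deaths, births = births)
}

#' @export
print.cohort <- function(x, ...) {
  n_live <- sum(x$agents$alive)
  cat("<cohort> ", n_live, " living agents in ",
      nrow(x$households), " households; poverty line ",
      format(x$poverty_line, digits = 4), "/yr; day ",
      x$calendar_day, "\n", sep = "")
  invisible(x)
}
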