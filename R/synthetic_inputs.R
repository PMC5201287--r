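## Synthetic input fixtures.
##
## Everything the pipeline consumes -- a demographic/income specification, a
## population-density raster, a geolocated facility table and a per-cancer
## disease-parameter table -- is generated here with the documented
## statistical structure: DHS-like age/sex marginals, gamma income calibrated
## to a 19.5% poverty headcount, 53 public hospitals on a two-hotspot
## density surface, and seven cancers with 2012-vintage incidence
## magnitudes.  Every value is overridable; the fixtures claim structure,
## not any specific published parameter set.

PROVIDER_LEVELS <- c("district", "regional", "national")

#' Construct a population specification
#'
#' @param n_agents cohort size at instantiation (default 10,000)
#' @param age_sex_marginals data.frame with columns `age_lo`, `age_hi`,
#'   `male`, `female`; the male+female cells sum to 1
#' @param household_size_distribution probability mass over household sizes
#'   1..12
#' @param income_gamma_shape,income_gamma_scale gamma parameters for annual
#'   individual income (money/year)
#' @param target_poverty_headcount fraction of the population below the
#'   national poverty line at instantiation (default 0.195)
#' @param background_mortality crude background death rate, per person-year
#' @param fertility_rate births per woman aged 15-49 per year
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_agents = 10000L,
                            age_sex_marginals = default_age_sex_marginals(),
                            household_size_distribution = default_household_sizes(),
                            income_gamma_shape = 1.5,
                            income_gamma_scale = 550,
                            target_poverty_headcount = 0.195,
                            background_mortality = 0.009,
                            fertility_rate = 0.18) {
  spec <- structure(list(
    n_agents = as.integer(n_agents),
    age_sex_marginals = age_sex_marginals,
    household_size_distribution = household_size_distribution,
    income_gamma_shape = income_gamma_shape,
    income_gamma_scale = income_gamma_scale,
    target_poverty_headcount = target_poverty_headcount,
    background_mortality = background_mortality,
    fertility_rate = fertility_rate
  ), class = "population_spec")
  validate_population_spec(spec)
  spec
}

#' @keywords internal
validate_population_spec <- function(spec) {
  m <- spec$age_sex_marginals
  stopifnot(is.data.frame(m), all(c("age_lo", "age_hi", "male", "female") %in% names(m)))
  if (abs(sum(m$male) + sum(m$female) - 1) > 1e-9)
    stop("age/sex marginals must sum to 1")
  h <- spec$household_size_distribution
  if (abs(sum(h) - 1) > 1e-9) stop("household-size masses must sum to 1")
  if (spec$n_agents < 1L) stop("n_agents must be >= 1")
  if (spec$target_poverty_headcount <= 0 || spec$target_poverty_headcount >= 1)
    stop("target_poverty_headcount must be in (0, 1)")
  if (spec$income_gamma_shape <= 0 || spec$income_gamma_scale <= 0)
    stop("income gamma parameters must be positive")
  if (spec$background_mortality < 0 || spec$fertility_rate < 0)
    stop("vital rates must be non-negative")
  invisible(spec)
}

## A young, high-fertility age pyramid in 5-year-ish bands (male, female
## halves of each band's population share).
default_age_sex_marginals <- function() {
  bands <- data.frame(
    age_lo = c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75),
    age_hi = c(5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 55, 60, 65, 70, 75, 95)
  )
  share <- c(0.180, 0.160, 0.135, 0.105, 0.085, 0.070, 0.060, 0.050,
             0.040, 0.032, 0.025, 0.020, 0.015, 0.011, 0.007, 0.005)
  share <- share / sum(share)
  bands$male <- share * 0.495
  bands$female <- share * 0.505
  bands
}

## Household sizes 1..12, mean about 4.7 persons.
default_household_sizes <- function() {
  p <- stats::dpois(0:11, lambda = 3.7)
  p <- p / sum(p)
  names(p) <- as.character(1:12)
  p
}

#' Generate the default population specification
#'
#' Deterministic: identical seeds give byte-identical specs (the default
#' marginals are fixed constants; the seed is part of the fixture-generation
#' API for forward compatibility with randomized marginals).
#'
#' @param seed non-negative integer
#' @return a `population_spec`
#' @export
generate_population_spec <- function(seed = 0L) {
  stopifnot(length(seed) == 1L, seed >= 0)
  population_spec()
}

#' Generate a synthetic population-density raster
#'
#' A coarse rectangular grid (default 50x50 cells of 10 km) with a uniform
#' rural background and two Gaussian "urban" hotspots, standing in for a
#' WorldPop-style raster.  Real rasters in the same CSV schema (`row`, `col`,
#' `x`, `y`, `weight`) are accepted anywhere a grid is consumed.
#'
#' @param nx,ny grid dimensions (cells)
#' @param cell_km cell edge length in km
#' @param hotspots data.frame with columns `x`, `y`, `sd_km`, `mass`
#' @return data.frame raster with positive total weight
#' @export
generate_density_grid <- function(nx = 50L, ny = 50L, cell_km = 10,
                                  hotspots = data.frame(
                                    x = c(350, 130), y = c(180, 120),
                                    sd_km = c(35, 25), mass = c(6, 3))) {
  cx <- (seq_len(nx) - 0.5) * cell_km
  cy <- (seq_len(ny) - 0.5) * cell_km
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  g$x <- cx[g$col]
  g$y <- cy[g$row]
  w <- rep(1, nrow(g))
  for (i in seq_len(nrow(hotspots))) {
    d2 <- (g$x - hotspots$x[i])^2 + (g$y - hotspots$y[i])^2
    w <- w + hotspots$mass[i] * nx * ny / (2 * pi * hotspots$sd_km[i]^2 / cell_km^2) *
      exp(-d2 / (2 * hotspots$sd_km[i]^2))
  }
  g$weight <- w
  g[, c("row", "col", "x", "y", "weight")]
}

#' Construct a facility-network specification
#'
#' @param n_public_hospitals number of public hospitals (default 53)
#' @param level_mix named proportions over district/regional/national, sum 1
#' @param quality_by_level data.frame(level, periop_mortality,
#'   complication_rate): facility-level quality entering the choice model
#' @param price_by_level patient-facing price per case, by level
#' @param providers_by_level surgical providers per facility, by level
#' @param capacity_by_level surgical cases per day, by level
#' @return an object of class `facility_spec`
#' @export
facility_spec <- function(n_public_hospitals = 53L,
                          level_mix = c(district = 37, regional = 14, national = 2) / 53,
                          quality_by_level = data.frame(
                            level = PROVIDER_LEVELS,
                            periop_mortality = c(0.08, 0.05, 0.03),
                            complication_rate = c(0.15, 0.12, 0.10)),
                          price_by_level = c(district = 150, regional = 250, national = 400),
                          providers_by_level = c(district = 1, regional = 4, national = 20),
                          capacity_by_level = c(district = 1, regional = 2, national = 4)) {
  spec <- structure(list(
    n_public_hospitals = as.integer(n_public_hospitals),
    level_mix = level_mix,
    quality_by_level = quality_by_level,
    price_by_level = price_by_level,
    providers_by_level = providers_by_level,
    capacity_by_level = capacity_by_level
  ), class = "facility_spec")
  if (spec$n_public_hospitals < 1L) stop("n_public_hospitals must be >= 1")
  if (abs(sum(level_mix) - 1) > 1e-9) stop("level_mix proportions must sum to 1")
  if (!all(PROVIDER_LEVELS %in% names(level_mix)))
    stop("level_mix must name district, regional, national")
  spec
}

#' Generate the geolocated facility table
#'
#' One row per public hospital: unique id, planar-km coordinates drawn
#' proportional to the density raster (hospitals sit where people are, the
#' highest-level ones in the densest cells), level, level-specific quality,
#' price, providers and daily capacity.
#'
#' @param spec a `facility_spec`
#' @param density_grid raster from [generate_density_grid()]
#' @param seed integer seed
#' @return data.frame, one row per facility
#' @export
generate_facility_table <- function(spec = facility_spec(),
                                    density_grid = generate_density_grid(),
                                    seed = 0L) {
  if (is.null(density_grid) || nrow(density_grid) == 0L ||
      sum(density_grid$weight) <= 0)
    stop("density grid is empty: unusable geography")
  n <- spec$n_public_hospitals
  ## largest-remainder apportionment of levels
  exact <- spec$level_mix[PROVIDER_LEVELS] * n
  counts <- floor(exact)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, "facilities"))
  cells <- sample.int(nrow(density_grid), n, replace = TRUE,
                      prob = density_grid$weight)
  cell_km <- if (nrow(density_grid) > 1)
    min(diff(sort(unique(density_grid$x)))) else 1
  x <- density_grid$x[cells] + stats::runif(n, -cell_km / 2, cell_km / 2)
  y <- density_grid$y[cells] + stats::runif(n, -cell_km / 2, cell_km / 2)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  ## national facilities to the densest sampled cells, regional next
  ord <- order(density_grid$weight[cells], decreasing = TRUE)
  level <- character(n)
  level[ord] <- rep(c("national", "regional", "district"),
                    times = counts[c("national", "regional", "district")])
  q <- spec$quality_by_level
  idx <- match(level, q$level)
  data.frame(
    facility_id = sprintf("H%02d", seq_len(n)),
    x = x, y = y, level = level,
    periop_mortality = q$periop_mortality[idx],
    complication_rate = q$complication_rate[idx],
    price = unname(spec$price_by_level[level]),
    providers = unname(spec$providers_by_level[level]),
    capacity = unname(spec$capacity_by_level[level]),
    stringsAsFactors = FALSE
  )
}

#' Construct a disease specification: the seven most common cancers
#'
#' Each cancer carries a population-wide incidence rate (cases per 100,000
#' person-years), an untreated median survival (days), cure probability,
#' perioperative mortality and complication rate by provider level, a
#' per-case medical cost and a transport cost per km.  Every numeric field
#' has an uncertainty descriptor for probabilistic parameter draws.
#'
#' @param cancers list of per-cancer parameter lists; see
#'   [default_cancers()] for the required fields
#' @return an object of class `disease_spec`
#' @export
disease_spec <- function(cancers = default_cancers()) {
  spec <- structure(list(cancers = cancers), class = "disease_spec")
  for (cc in cancers) {
    if (any(cc$cure_by_level < 0 | cc$cure_by_level > 1) ||
        any(cc$periop_mortality_by_level < 0 | cc$periop_mortality_by_level > 1) ||
        any(cc$complication_by_level < 0 | cc$complication_by_level > 1))
      stop("probabilities must lie in [0, 1]: ", cc$name)
    if (cc$untreated_median_survival <= 0 || cc$medical_cost <= 0)
      stop("survivals and costs must be positive: ", cc$name)
    if (cc$incidence_rate < 0) stop("incidence must be non-negative: ", cc$name)
  }
  spec
}

#' Default seven-cancer parameter set
#'
#' Population-wide crude incidence magnitudes of 2012 vintage for the seven
#' most common Ugandan cancers; untreated survival medians, surgical cure
#' probabilities by provider level, and per-case costs are plausible
#' order-of-magnitude values, all overridable.
#'
#' @return a list of 7 per-cancer parameter lists
#' @export
default_cancers <- function() {
  mk <- function(name, inc, surv, cure, pm_scale, cost) {
    list(
      name = name,
      incidence_rate = inc,                       # per 100,000 person-years
      untreated_median_survival = surv,           # days
      cure_by_level = stats::setNames(cure, PROVIDER_LEVELS),
      periop_mortality_by_level = stats::setNames(
        c(0.08, 0.05, 0.03) * pm_scale, PROVIDER_LEVELS),
      complication_by_level = stats::setNames(c(0.15, 0.12, 0.10), PROVIDER_LEVELS),
      medical_cost = cost,                        # per-case consumables
      transport_cost_per_km = 0.10
    )
  }
  list(
    mk("kaposi_sarcoma",       14, 540, c(0.30, 0.40, 0.50), 1.0, 120),
    mk("cervical",             20, 720, c(0.55, 0.65, 0.75), 1.0, 180),
    mk("breast",               12, 900, c(0.50, 0.60, 0.70), 1.0, 200),
    mk("prostate",              9, 1400, c(0.50, 0.60, 0.70), 1.0, 220),
    mk("esophageal",            7, 180, c(0.15, 0.25, 0.35), 1.5, 300),
    mk("liver",                 6, 120, c(0.10, 0.15, 0.25), 1.5, 300),
    mk("non_hodgkin_lymphoma",  7, 365, c(0.30, 0.40, 0.50), 1.0, 160)
  )
}

#' Generate the disease-parameter table
#'
#' One row per cancer x provider level, carrying point values plus flattened
#' uncertainty descriptors (`*_family`, `*_par1`, `*_par2`) so the table is
#' CSV-serializable and probabilistic draws need nothing beyond it.
#'
#' Probability fields get beta descriptors with an effective sample size of
#' 50 around their point value; costs get gamma descriptors with CV = 0.2;
#' survival medians are lognormal with sdlog = 0.2; incidence is uniform
#' within +/- 25%.
#'
#' @param spec a `disease_spec`
#' @param seed integer (API symmetry; the default table is deterministic)
#' @return data.frame, 7 cancers x 3 levels = 21 rows by default
#' @export
generate_disease_table <- function(spec = disease_spec(), seed = 0L) {
  ess <- 50  # effective sample size behind beta descriptors
  beta_pars <- function(p) {
    ## guard degenerate 0/1 point values: keep them point masses
    if (p <= 0 || p >= 1) return(c(NA_real_, NA_real_))
    c(p * ess, (1 - p) * ess)
  }
  rows <- lapply(spec$cancers, function(cc) {
    do.call(rbind, lapply(PROVIDER_LEVELS, function(lv) {
      cure <- cc$cure_by_level[[lv]]
      pm <- cc$periop_mortality_by_level[[lv]]
      comp <- cc$complication_by_level[[lv]]
      bc <- beta_pars(cure); bp <- beta_pars(pm); bk <- beta_pars(comp)
      data.frame(
        cancer = cc$name, level = lv,
        incidence_rate = cc$incidence_rate,
        incidence_family = "uniform",
        incidence_par1 = cc$incidence_rate * 0.75,
        incidence_par2 = cc$incidence_rate * 1.25,
        untreated_median_survival = cc$untreated_median_survival,
        survival_family = "lognormal",
        survival_par1 = log(cc$untreated_median_survival),
        survival_par2 = 0.2,
        cure_probability = cure,
        cure_family = if (anyNA(bc)) "point" else "beta",
        cure_par1 = if (anyNA(bc)) cure else bc[1],
        cure_par2 = if (anyNA(bc)) NA_real_ else bc[2],
        periop_mortality = pm,
        periop_family = if (anyNA(bp)) "point" else "beta",
        periop_par1 = if (anyNA(bp)) pm else bp[1],
        periop_par2 = if (anyNA(bp)) NA_real_ else bp[2],
        complication_rate = comp,
        complication_family = if (anyNA(bk)) "point" else "beta",
        complication_par1 = if (anyNA(bk)) comp else bk[1],
        complication_par2 = if (anyNA(bk)) NA_real_ else bk[2],
        medical_cost = cc$medical_cost,
        cost_family = "gamma",
        cost_par1 = 25,
        cost_par2 = cc$medical_cost / 25,
        transport_cost_per_km = cc$transport_cost_per_km,
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$cure_probability < 0 | out$cure_probability > 1) ||
      any(out$periop_mortality < 0 | out$periop_mortality > 1))
    stop("probabilities outside [0,1] in disease table")
  out
}
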