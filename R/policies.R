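## Policy scenarios and delivery platforms.
##
## Six governmental levers and their combinations -- universal public
## financing (UPF: surgery free at the point of care), task shifting (TS:
## more surgical providers, costs untouched) and transport vouchers (V) --
## plus three charitable platforms: semi-annual two-week mission trips (2W),
## a truck-based mobile surgical unit (MS) and a free-standing cancer
## hospital (CH).  Status quo is the identity.

SCENARIO_NAMES <- c("status_quo", "UPF", "TS", "UPFTS",
                    "UPFV", "TSV", "UPFTSV", "2W", "MS", "CH")

#' Construct a policy scenario
#'
#' The nine registered arms (plus status quo) are pre-wired by name;
#' `policy_scenario("custom", ...)` allows arbitrary lever sets.
#'
#' @param name one of "status_quo", "UPF", "TS", "UPFTS", "UPFV", "TSV",
#'   "UPFTSV", "2W", "MS", "CH", or "custom"
#' @param remove_user_fees,task_shifting,vouchers lever flags (custom only)
#' @param platform none | "2W" | "MS" | "CH" (custom only)
#' @param perspective "societal" (default) or "ministry_of_health"
#' @param discount_rate annual rate for discounted aggregate reporting; 0
#'   disables discounting (yearly-average reporting)
#' @param ms_cost_multiplier multiplier on the MS unit cost (default 1; the
#'   high-cost sensitivity uses 12)
#' @param ts_factor capacity/provider scaling under task shifting (default
#'   2x at district facilities)
#' @param impoverishment_definition "base" or "conservative"
#' @return an object of class `policy_scenario`
#' @export
policy_scenario <- function(name,
                            remove_user_fees = FALSE,
                            task_shifting = FALSE,
                            vouchers = FALSE,
                            platform = "none",
                            perspective = c("societal", "ministry_of_health"),
                            discount_rate = 0,
                            ms_cost_multiplier = 1,
                            ts_factor = 2,
                            impoverishment_definition = c("base", "conservative")) {
  perspective <- match.arg(perspective)
  impoverishment_definition <- match.arg(impoverishment_definition)
  if (ms_cost_multiplier <= 0) stop("ms_cost_multiplier must be > 0")
  if (name %in% SCENARIO_NAMES) {
    remove_user_fees <- name %in% c("UPF", "UPFTS", "UPFV", "UPFTSV")
    task_shifting <- name %in% c("TS", "UPFTS", "TSV", "UPFTSV")
    vouchers <- name %in% c("UPFV", "TSV", "UPFTSV")
    platform <- if (name %in% c("2W", "MS", "CH")) name else "none"
  } else if (name != "custom") {
    stop("unknown scenario name: ", name)
  }
  stopifnot(platform %in% c("none", "2W", "MS", "CH"))
  structure(list(
    name = name, remove_user_fees = remove_user_fees,
    task_shifting = task_shifting, vouchers = vouchers,
    platform = platform, perspective = perspective,
    discount_rate = discount_rate,
    ms_cost_multiplier = ms_cost_multiplier, ts_factor = ts_factor,
    impoverishment_definition = impoverishment_definition
  ), class = "policy_scenario")
}

#' Program cost per case from reported NGO totals
#'
#' Reference-NGO unit costs are constructed by dividing reported program
#' cost by reported case volume; scenario multipliers (the 12x MS
#' sensitivity) are applied downstream.
#'
#' @param reported_total_cost reported program cost (money)
#' @param reported_cases reported number of cases (> 0)
#' @return money per case
#' @export
unit_cost_per_case <- function(reported_total_cost, reported_cases) {
  if (reported_cases <= 0) stop("reported_cases must be > 0")
  reported_total_cost / reported_cases
}

#' Construct a platform configuration
#'
#' @param kind "2W", "MS" or "CH"
#' @param sites data.frame of candidate sites (`x`, `y`, optional
#'   `facility_id`); 2W rotates round-robin across trips, MS cycles its
#'   itinerary with a fixed dwell, CH uses its single site
#' @param unit_cost program cost per case (from [unit_cost_per_case()])
#' @param patient_price out-of-pocket price charged by the platform
#'   (default 0: low-to-nil charitable pricing)
#' @param capacity cases per active day
#' @param clinical_level provider level whose cancer-specific outcome
#'   parameters apply ("district"/"regional"/"national")
#' @param trip_length_days,period_days 2W schedule: trip length (14) and
#'   inter-trip period (183 days, semi-annual)
#' @param dwell_days MS itinerary dwell per site (30)
#' @return an object of class `platform_config`
#' @export
platform_config <- function(kind, sites, unit_cost,
                            patient_price = 0, capacity = 4,
                            clinical_level = "regional",
                            trip_length_days = 14L, period_days = 183L,
                            dwell_days = 30L) {
  stopifnot(kind %in% c("2W", "MS", "CH"), nrow(sites) >= 1L)
  if (unit_cost <= 0) stop("unit_cost must be > 0")
  structure(list(
    kind = kind, sites = sites, unit_cost = unit_cost,
    patient_price = patient_price, capacity = capacity,
    clinical_level = clinical_level,
    trip_length_days = as.integer(trip_length_days),
    period_days = as.integer(period_days),
    dwell_days = as.integer(dwell_days)
  ), class = "platform_config")
}

#' Default platform configurations derived from a facility table
#'
#' 2W visits the regional referral hospitals; MS cycles an itinerary over
#' them; CH is a single NGO hospital placed at the second-densest town
#' (standing in for Mbarara).  Unit costs are reference-NGO magnitudes:
#' an expensive mission trip, a lean in-country mobile unit, and a
#' mid-cost standing hospital.
#'
#' @param facilities facility table from [generate_facility_table()]
#' @return named list of `platform_config`s
#' @export
default_platforms <- function(facilities) {
  regional <- facilities[facilities$level == "regional",
                         c("facility_id", "x", "y")]
  if (nrow(regional) == 0L)
    regional <- facilities[, c("facility_id", "x", "y")]
  ch_site <- facilities[facilities$level %in% c("regional", "national"), ]
  ch_site <- ch_site[nrow(ch_site), c("facility_id", "x", "y")]
  list(
    `2W` = platform_config("2W", regional,
                           unit_cost = unit_cost_per_case(6e5, 400),  # 1500/case
                           capacity = 10, clinical_level = "regional"),
    MS = platform_config("MS", regional,
                         unit_cost = unit_cost_per_case(3e5, 2000),   # 150/case
                         capacity = 4, clinical_level = "regional"),
    CH = platform_config("CH", ch_site,
                         unit_cost = unit_cost_per_case(1.8e6, 3000), # 600/case
                         capacity = 10, clinical_level = "national")
  )
}

#' Active platform sites on a given day
#'
#' 2W: one regional site is active for `trip_length_days` consecutive days
#' at the start of every `period_days` window, rotating round-robin across
#' trips.  MS: the itinerary cycles with a fixed dwell; exactly one site is
#' active every day.  CH: its single site is always active.
#'
#' @param platform a `platform_config`
#' @param day simulation day (>= 0)
#' @return data.frame of active sites (zero rows when inactive)
#' @export
platform_active_sites <- function(platform, day) {
  stopifnot(day >= 0)
  s <- platform$sites
  switch(platform$kind,
    "2W" = {
      trip <- day %/% platform$period_days
      if (day %% platform$period_days < platform$trip_length_days) {
        s[(trip %% nrow(s)) + 1L, , drop = FALSE]
      } else s[0L, , drop = FALSE]
    },
    "MS" = s[((day %/% platform$dwell_days) %% nrow(s)) + 1L, , drop = FALSE],
    "CH" = s[1L, , drop = FALSE],
    stop("unknown platform kind: ", platform$kind)
  )
}

#' Apply a policy scenario to the facility network
#'
#' Returns the effective system: the public facility table with
#' patient-facing and program-borne prices after the financing levers,
#' TS-scaled providers and capacity, a transport-voucher flag, and the
#' platform (if any) with its scenario-adjusted unit cost.  Status quo is
#' the identity.  The levers compose: applying UPF, TS and V in any order
#' yields the same effective system.
#'
#' @param scenario a `policy_scenario`
#' @param facilities facility table
#' @param platforms named list of `platform_config`s (defaults derived from
#'   the facility table)
#' @return a list of class `effective_system`
#' @export
apply_policy <- function(scenario, facilities,
                         platforms = default_platforms(facilities)) {
  fac <- facilities
  fac$patient_price <- fac$price
  fac$program_price <- 0
  if (scenario$remove_user_fees) {
    fac$program_price <- fac$patient_price   # program bears the fee
    fac$patient_price <- 0
  }
  if (scenario$task_shifting) {
    dist <- fac$level == "district"
    fac$providers[dist] <- fac$providers[dist] * scenario$ts_factor
    fac$capacity[dist] <- fac$capacity[dist] * scenario$ts_factor
  }
  platform <- NULL
  if (scenario$platform != "none") {
    platform <- platforms[[scenario$platform]]
    if (is.null(platform)) stop("no configuration for platform ", scenario$platform)
    if (scenario$platform == "MS")
      platform$unit_cost <- platform$unit_cost * scenario$ms_cost_multiplier
  }
  structure(list(
    scenario = scenario,
    facilities = fac,
    transport_voucher = scenario$vouchers,
    platform = platform
  ), class = "effective_system")
}

#' Split one treated episode's costs into patient and program shares
#'
#' Patient out-of-pocket = residual medical price + residual transport after
#' the levers; program cost = whatever the government or NGO bears (waived
#' fees under UPF, voucher-paid transport, the NGO unit cost per case).
#' Societal cost is their sum; Ministry-of-Health accounting keeps the
#' program column only.
#'
#' @param medical_price money charged for the case before levers
#' @param transport_cost money to reach the provider (round trip)
#' @param provider_type "public" or "platform"
#' @param system an `effective_system`
#' @return list(patient_oop, program_cost, patient_medical,
#'   patient_transport, program_medical, program_transport)
#' @export
episode_costs <- function(medical_price, transport_cost, provider_type, system) {
  sc <- system$scenario
  if (provider_type == "public") {
    if (sc$remove_user_fees) {
      patient_medical <- 0; program_medical <- medical_price
    } else {
      patient_medical <- medical_price; program_medical <- 0
    }
  } else {  # charitable platform: NGO bears the unit cost, patient the price
    patient_medical <- system$platform$patient_price
    program_medical <- system$platform$unit_cost
  }
  if (system$transport_voucher) {
    patient_transport <- 0; program_transport <- transport_cost
  } else {
    patient_transport <- transport_cost; program_transport <- 0
  }
  list(
    patient_oop = patient_medical + patient_transport,
    program_cost = program_medical + program_transport,
    patient_medical = patient_medical, patient_transport = patient_transport,
    program_medical = program_medical, program_transport = program_transport
  )
}
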