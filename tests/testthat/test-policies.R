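test_that("the nine arms are registered and levers compose", {
  for (nm in c("UPF", "TS", "UPFTS", "UPFV", "TSV", "UPFTSV", "2W", "MS", "CH"))
    expect_s3_class(policy_scenario(nm), "policy_scenario")
  expect_error(policy_scenario("UBI"), "unknown scenario")

  fac <- generate_facility_table(seed = 2L)
  sq <- apply_policy(policy_scenario("status_quo"), fac)
  expect_equal(sq$facilities$patient_price, fac$price)
  expect_equal(sq$facilities$program_price, rep(0, nrow(fac)))
  expect_equal(sq$facilities$capacity, fac$capacity)
  expect_false(sq$transport_voucher)
  expect_null(sq$platform)

  upf <- apply_policy(policy_scenario("UPF"), fac)
  expect_equal(upf$facilities$patient_price, rep(0, nrow(fac)))
  expect_equal(upf$facilities$program_price, fac$price)
  expect_false(upf$transport_voucher)

  ## UPFTS^V = union of the three levers, independent of application order
  combo <- apply_policy(policy_scenario("UPFTSV"), fac)
  expect_equal(combo$facilities$patient_price, rep(0, nrow(fac)))
  expect_true(combo$transport_voucher)
  dist <- fac$level == "district"
  expect_equal(combo$facilities$capacity[dist], fac$capacity[dist] * 2)
  expect_equal(combo$facilities$capacity[!dist], fac$capacity[!dist])
  ## sequential application of the single levers gives the same system
  step <- fac
  step_sys <- apply_policy(policy_scenario("custom", task_shifting = TRUE), step)
  step <- step_sys$facilities
  step$price <- step$patient_price
  two <- apply_policy(policy_scenario("custom", remove_user_fees = TRUE,
                                      vouchers = TRUE), step)
  expect_equal(two$facilities$patient_price, combo$facilities$patient_price)
  expect_equal(two$facilities$capacity, combo$facilities$capacity)
  expect_true(two$transport_voucher)
})

test_that("platform schedules: 2W trips, MS itinerary, CH always on", {
  fac <- generate_facility_table(seed = 2L)
  pf <- default_platforms(fac)

  for (d in 0:13) expect_equal(nrow(platform_active_sites(pf[["2W"]], d)), 1L)
  for (d in c(14, 50, 100, 182)) expect_equal(nrow(platform_active_sites(pf[["2W"]], d)), 0L)
  expect_equal(nrow(platform_active_sites(pf[["2W"]], 183)), 1L)
  ## round-robin across trips
  s1 <- platform_active_sites(pf[["2W"]], 0)$facility_id
  s2 <- platform_active_sites(pf[["2W"]], 183)$facility_id
  expect_false(identical(s1, s2))

  ## MS: dwell 30 over 3 sites, day 65 -> floor(65/30) mod 3 = site index 2
  ms3 <- platform_config("MS", data.frame(x = 1:3, y = 1:3, facility_id = c("A", "B", "C")),
                         unit_cost = 150, dwell_days = 30L)
  expect_equal(platform_active_sites(ms3, 65)$facility_id, "C")
  ## exactly one MS site active on every day
  for (d in sample(0:20000, 200))
    expect_equal(nrow(platform_active_sites(pf$MS, d)), 1L)

  for (d in c(0, 99, 18249)) expect_equal(nrow(platform_active_sites(pf$CH, d)), 1L)
})

test_that("NGO unit costs are reported totals over reported cases, with the 12x MS sensitivity", {
  expect_equal(unit_cost_per_case(120000, 1000), 120)
  expect_equal(unit_cost_per_case(500, 1), 500)
  expect_error(unit_cost_per_case(100, 0), "> 0")

  fac <- generate_facility_table(seed = 2L)
  base <- apply_policy(policy_scenario("MS"), fac)
  hi <- apply_policy(policy_scenario("MS", ms_cost_multiplier = 12), fac)
  expect_equal(hi$platform$unit_cost, base$platform$unit_cost * 12)
})

test_that("episode costs split patient and program shares by lever, conserving the societal total", {
  fac <- generate_facility_table(seed = 2L)

  upf <- apply_policy(policy_scenario("UPF"), fac)
  c1 <- episode_costs(50, 10, "public", upf)
  expect_equal(c1$patient_oop, 10)
  expect_equal(c1$program_cost, 50)

  v <- apply_policy(policy_scenario("custom", vouchers = TRUE), fac)
  c2 <- episode_costs(50, 10, "public", v)
  expect_equal(c2$patient_oop, 50)
  expect_equal(c2$program_cost, 10)

  sq <- apply_policy(policy_scenario("status_quo"), fac)
  c3 <- episode_costs(50, 10, "public", sq)
  expect_equal(c3$patient_oop, 60)
  expect_equal(c3$program_cost, 0)

  ## pure financing levers move cost between columns, never change the total
  set.seed(16)
  for (k in 1:25) {
    med <- runif(1, 0, 500); tr <- runif(1, 0, 100)
    for (sys in list(sq, upf, v,
                     apply_policy(policy_scenario("UPFV"), fac))) {
      cc <- episode_costs(med, tr, "public", sys)
      expect_equal(cc$patient_oop + cc$program_cost, med + tr, tolerance = 1e-12)
    }
  }

  ## platform: NGO bears its unit cost, patient the (nil) platform price
  ms <- apply_policy(policy_scenario("MS"), fac)
  c4 <- episode_costs(200, 30, "platform", ms)
  expect_equal(c4$patient_oop, 30)            # transport only
  expect_equal(c4$program_cost, ms$platform$unit_cost)
})
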