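test_that("catastrophic flag is strict at 10% of pre-illness income", {
  expect_false(flag_catastrophic(10, 100))     # exactly 10%: not "more than"
  expect_true(flag_catastrophic(10.01, 100))
  expect_false(flag_catastrophic(0, 5))
  expect_error(flag_catastrophic(5, 0), "> 0")
})

test_that("impoverishment counting covers expense, head-death and the conservative variant", {
  expect_equal(count_impoverishment(list(type = "expense", income = 110, expense = 15),
                                    poverty_line = 100), 1L)
  expect_equal(count_impoverishment(list(type = "expense", income = 90, expense = 15),
                                    poverty_line = 100), 0L)  # already below
  expect_equal(count_impoverishment(list(type = "expense", income = 200, expense = 15),
                                    poverty_line = 100), 0L)  # stays above

  hh <- list(member_incomes = c("1" = 400, "2" = 50, "3" = 50, "4" = 50),
             head_id = 1)
  ## base: head of a 4-member household dies -> 3 survivors counted
  expect_equal(count_impoverishment(list(type = "head_death", deceased_id = 1),
                                    hh, poverty_line = 100, "base"), 3L)
  ## conservative: survivors' per-capita income (150/3 = 50) below the line
  expect_equal(count_impoverishment(list(type = "head_death", deceased_id = 1),
                                    hh, poverty_line = 100, "conservative"), 3L)
  ## conservative with comfortable survivors: none counted
  rich <- list(member_incomes = c("1" = 100, "2" = 400, "3" = 400, "4" = 400),
               head_id = 1)
  expect_equal(count_impoverishment(list(type = "head_death", deceased_id = 1),
                                    rich, poverty_line = 100, "conservative"), 0L)
  expect_equal(count_impoverishment(list(type = "head_death", deceased_id = 1),
                                    rich, poverty_line = 100, "base"), 3L)
})

test_that("the overall aggregator is the equal-weight quintile mean", {
  expect_equal(round(aggregate_overall(c(68.2, 42.2, 36.9, 35.2, 31.6)), 1), 42.8)
  expect_equal(round(aggregate_overall(c(147.7, 194.9, 226.0, 260.8, 263.8)), 1), 218.6)
  expect_equal(aggregate_overall(rep(3.7, 5)), 3.7)
  expect_error(aggregate_overall(1:4), "5 quintile")
})

test_that("averted outcomes difference ledgers against the status quo", {
  sq <- outcome_levels(fake_ledger(diag_q = rep(1:5, 4), treat_q = rep(1:5, 2),
                                   death_q = c(1, 1, 2, 3, 3, 4, 5, 5),
                                   cat_q = c(1, 2), imp_q = c(1, 1, 2)))
  same <- averted(sq, sq)
  expect_equal(same$deaths_averted$by_quintile, rep(0, 5))
  expect_equal(same$system_cost, 0)
  expect_equal(same$imr_ratio$overall, 1)

  ## 10 deaths vs 6 on 100,000 person-years: 4 averted per 100,000/yr
  sq2 <- outcome_levels(fake_ledger(diag_q = rep(1:5, 4), treat_q = 1:5,
                                    death_q = rep(1:5, 2),
                                    person_days = rep(365 * 20000, 5)))
  sc2 <- outcome_levels(fake_ledger(diag_q = rep(1:5, 4), treat_q = 1:5,
                                    death_q = c(2, 3, 4, 1, 3, 5),
                                    person_days = rep(365 * 20000, 5)))
  inc <- averted(sc2, sq2)
  expect_equal(inc$deaths_averted$overall, 4)

  ## mismatched horizons are refused
  short <- outcome_levels(fake_ledger(diag_q = 1, treat_q = 1, death_q = 1,
                                      horizon_days = 100L))
  expect_error(averted(short, sq), "horizon")

  ## negative entries (cases created) pass through
  worse <- outcome_levels(fake_ledger(diag_q = rep(1:5, 4), treat_q = 1:5,
                                      death_q = rep(1:5, 3),
                                      person_days = rep(365 * 20000, 5)))
  expect_lt(averted(worse, sq2)$deaths_averted$overall, 0)
})

test_that("treatment probability and IMR ratios recount the ledger", {
  l <- fake_ledger(diag_q = c(rep(1, 6), rep(2, 4)), treat_q = c(1, 1, 2),
                   death_q = c(1, 1, 2))
  tp <- treatment_probability(l)
  expect_equal(tp$by_quintile[1], 2 / 6)
  expect_equal(tp$by_quintile[2], 1 / 4)
  expect_true(is.na(tp$by_quintile[3]))

  ## all treated
  l2 <- fake_ledger(diag_q = 1:5, treat_q = 1:5, death_q = integer(0))
  expect_equal(treatment_probability(l2)$by_quintile, rep(1, 5))

  ## scenario halving mortality at equal incidence doubles the IMR ratio
  sq <- fake_ledger(diag_q = rep(1:5, 8), death_q = rep(1:5, 4), treat_q = 1:5)
  sc <- fake_ledger(diag_q = rep(1:5, 8), death_q = rep(1:5, 2), treat_q = 1:5)
  r <- imr_ratio(sc, sq)
  expect_equal(r$by_quintile, rep(2, 5))
  expect_equal(imr_ratio(sq, sq)$overall, 1)
  ## zero mortality flagged undefined, not infinite
  z <- fake_ledger(diag_q = rep(1:5, 2), death_q = integer(0), treat_q = 1:5)
  expect_true(all(is.na(imr_ratio(z, sq)$by_quintile)))
})

test_that("equity index is a signed concentration measure over quintiles", {
  expect_equal(equity_index(c(5, 5, 5, 5, 5)), 0)
  expect_equal(equity_index(c(3, 0, 0, 0, 0)), 0.8)
  expect_equal(equity_index(c(0, 0, 0, 0, 3)), -0.8)
  expect_true(is.na(equity_index(rep(0, 5))))

  ## bounded and antisymmetric under reversing the quintile order
  set.seed(17)
  for (k in 1:200) {
    b <- rnorm(5)
    if (sum(b) == 0) next
    e <- equity_index(b)
    expect_gte(e, -1); expect_lte(e, 1)
    expect_equal(equity_index(rev(b)), -e, tolerance = 1e-12)
  }
  ## harm concentrated on the poorest is anti-poor
  expect_equal(equity_index(c(-3, 0, 0, 0, 0)), -0.8)

  expect_equal(round(average_equity(c(0.150, -0.008, 0.432)), 3), 0.191)
  expect_equal(round(average_equity(c(0.148, -0.109, 0.650)), 3), 0.230)
  expect_equal(average_equity(rep(0.2, 3)), 0.2)
})

test_that("frontier construction removes strict then extended dominance with increasing ICERs", {
  one <- icer_frontier(data.frame(scenario = "A", cost = 100, benefit = 2))
  expect_equal(one$frontier$scenario, c("status_quo", "A"))
  expect_equal(one$frontier$icer, c(NA, 50))

  ## extended dominance: B's ICER to A exceeds C's, B drops off
  pts <- data.frame(scenario = c("A", "B", "C"),
                    cost = c(10, 60, 80), benefit = c(1, 2, 4))
  fr <- icer_frontier(pts)
  expect_equal(fr$frontier$scenario, c("status_quo", "A", "C"))
  expect_true("B" %in% fr$dominated$scenario[fr$dominated$type == "extended"])
  icers <- fr$frontier$icer[-1]
  expect_true(all(diff(icers) > 0))

  ## frontier is invariant to input ordering
  fr2 <- icer_frontier(pts[c(3, 1, 2), ])
  expect_equal(fr2$frontier, fr$frontier)

  ## random point clouds match the brute-force oracle
  set.seed(18)
  for (k in 1:100) {
    n <- sample(3:12, 1)
    cloud <- data.frame(scenario = paste0("s", seq_len(n)),
                        cost = runif(n, -10, 1000),
                        benefit = runif(n, -5, 50))
    expect_equal(icer_frontier(cloud)$frontier$scenario, oracle_frontier(cloud))
  }
})

test_that("standardized outcomes scale by $100,000 of spending", {
  expect_equal(standardized_outcomes(5, 1e5), 5)
  expect_equal(standardized_outcomes(5, 5e4), 10)
  expect_equal(standardized_outcomes(-3, 5e4), -6)  # cases created stay negative
  expect_true(is.na(standardized_outcomes(5, 0)))
})

test_that("acceptability curves report the NMB-optimal fraction across runs", {
  solo <- data.frame(scenario = "A", run = 1:4, cost = c(10, 12, 9, 11),
                     benefit = c(2, 2, 3, 1))
  cv <- acceptability_curves(solo, wtp_grid = c(100, 500))
  expect_equal(cv$A, c(1, 1))

  ## wtp = 0: the cheapest option (status quo at cost 0) wins every run
  expect_equal(acceptability_curves(solo, 0)$status_quo, 1)

  ## two scenarios, four hand-built runs, counted by hand at wtp = 10:
  ## NMB_A = 10*2 - 10 = 10 beats NMB_B in runs 1 and 2; B wins 3 and 4
  hand <- data.frame(scenario = rep(c("A", "B"), each = 4), run = rep(1:4, 2),
                     cost = c(10, 10, 10, 10, 30, 30, 5, 5),
                     benefit = c(2, 2, 1, 0.4, 3, 3, 1.5, 1))
  cc <- acceptability_curves(hand, 10)
  expect_equal(cc$A, 0.5)
  expect_equal(cc$B, 0.5)
  expect_equal(rowSums(cc[, -1]), 1)
})

test_that("discounted aggregates follow the geometric closed form", {
  expect_equal(discounted_aggregate(c(5, 7, 9), 0), 21)
  expect_equal(discounted_aggregate(rep(100, 3), 0.1),
               100 * (1 + 1 / 1.1 + 1 / 1.21), tolerance = 1e-12)
  expect_equal(discounted_aggregate(42, 0.35), 42)
  expect_error(discounted_aggregate(1:3, -0.1), ">= 0")
})
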