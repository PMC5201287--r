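test_that("utility is the stated linear form", {
  agent <- list(income = 400)
  alt <- list(price = 120, transport = 30, distance = 80, quality = 0.6)
  zero <- choice_model(beta_cost = 0, beta_distance = 0, beta_quality = 0,
                       beta_wealth_cost_interaction = 0, asc_no_care = 0)
  expect_equal(utility(agent, alt, zero), 0)

  m <- choice_model(beta_cost = -0.004, beta_distance = -0.015,
                    beta_quality = 3, beta_wealth_cost_interaction = -0.5,
                    asc_no_care = 0.2)
  hand <- -0.004 * 150 - 0.015 * 80 + 3 * 0.6 - 0.5 * 150 / 400
  expect_equal(utility(agent, alt, m), hand, tolerance = 1e-12)
  expect_equal(utility(agent, list(no_care = TRUE), m), 0.2)

  ## beta_cost < 0: raising price strictly lowers V
  alt_hi <- alt; alt_hi$price <- 200
  expect_lt(utility(agent, alt_hi, m), utility(agent, alt, m))

  expect_error(choice_model(nest_dissimilarity = 0), "dissimilarity")
  expect_error(choice_model(beta_cost = Inf), "finite")
})

test_that("nested-logit probabilities are a proper distribution and reduce to MNL at lambda = 1", {
  agent <- list(income = 300)
  sym <- data.frame(price = c(50, 50), transport = c(5, 5),
                    distance = c(10, 10), quality = c(0.5, 0.5))
  m1 <- choice_model(nest_dissimilarity = 1)
  p <- choice_probabilities(list(agent = agent, alternatives = sym), m1)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[[2]], p[[3]], tolerance = 1e-12)

  ## lambda = 1: identical to plain softmax over all three utilities
  alts <- data.frame(price = c(40, 90, 20), transport = c(5, 0, 30),
                     distance = c(12, 60, 100), quality = c(0.4, 0.7, 0.55))
  v <- vapply(1:3, function(i) utility(agent, as.list(alts[i, ]), m1), 0)
  soft <- exp(c(m1$asc_no_care, v)) / sum(exp(c(m1$asc_no_care, v)))
  got <- choice_probabilities(list(agent = agent, alternatives = alts), m1)
  expect_equal(unname(got), unname(soft), tolerance = 1e-12)

  ## property: proper distribution over random configurations
  set.seed(12)
  for (k in 1:50) {
    mm <- choice_model(beta_cost = runif(1, -0.05, 0),
                       beta_distance = runif(1, -0.05, 0),
                       beta_quality = runif(1, 0, 5),
                       beta_wealth_cost_interaction = runif(1, -2, 0),
                       asc_no_care = runif(1, -2, 2),
                       nest_dissimilarity = runif(1, 0.05, 1))
    na <- sample(0:6, 1)
    aa <- data.frame(price = runif(na, 0, 1000), transport = runif(na, 0, 200),
                     distance = runif(na, 0, 500), quality = runif(na, 0, 1))
    pp <- choice_probabilities(list(agent = list(income = runif(1, 50, 5000)),
                                    alternatives = aa), mm)
    expect_equal(sum(pp), 1, tolerance = 1e-9)
    expect_true(all(pp >= 0))
    expect_equal(length(pp), na + 1L)
  }

  ## empty care nest: probability 1 on no-care
  p0 <- choice_probabilities(list(agent = agent,
                                  alternatives = sym[0, ]), m1)
  expect_equal(unname(p0), 1)

  ## limit: as one facility's price explodes its probability vanishes
  exp_alt <- data.frame(price = c(50, 1e8), transport = c(0, 0),
                        distance = c(10, 10), quality = c(0.5, 0.5))
  pl <- choice_probabilities(list(agent = agent, alternatives = exp_alt),
                             choice_model())
  expect_lt(pl[[3]], 1e-10)
})

test_that("cheaper care weakly increases total care-seeking probability", {
  ## the mechanism behind fee-removal and voucher effects
  set.seed(13)
  m <- choice_model()
  for (k in 1:25) {
    na <- sample(1:5, 1)
    aa <- data.frame(price = runif(na, 50, 600), transport = runif(na, 0, 150),
                     distance = runif(na, 0, 400), quality = runif(na, 0, 1))
    agent <- list(income = runif(1, 100, 3000))
    p_before <- choice_probabilities(list(agent = agent, alternatives = aa), m)
    cheaper <- aa; cheaper$price <- 0
    p_after <- choice_probabilities(list(agent = agent, alternatives = cheaper), m)
    expect_gte(1 - p_after[["no_care"]], 1 - p_before[["no_care"]] - 1e-12)
  }
})

test_that("provider selection is a faithful, reproducible categorical draw", {
  expect_equal(select_provider(c(a = 1, b = 0, c = 0)), "a")
  set.seed(14)
  picks <- vapply(1:10000, function(i) select_provider(c(x = 0.5, y = 0.5)), "")
  expect_gt(sum(picks == "x"), 5000 - 150)
  expect_lt(sum(picks == "x"), 5000 + 150)
  set.seed(15); s1 <- vapply(1:50, function(i) select_provider(c(a = .3, b = .7)), "")
  set.seed(15); s2 <- vapply(1:50, function(i) select_provider(c(a = .3, b = .7)), "")
  expect_identical(s1, s2)
  expect_error(select_provider(c(0.5, 0.4)), "malformed")
})
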