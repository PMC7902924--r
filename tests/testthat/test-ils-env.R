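test_that("investment probability falls linearly and hits its bounds", {
  expect_equal(prob_investment(0, 292, 0.9), 1)
  expect_equal(prob_investment(500, 500, 0.9), 1 - 0.9)
  expect_equal(prob_investment(500, 500, 0.37), 1 - 0.37)
  expect_equal(prob_investment(50, 100, 0.8), 0.6)
  # monotone non-increasing in the cumulative investment fraction
  fracs <- seq(0, 1, by = 0.05)
  p <- vapply(fracs, function(f) prob_investment(f * 100, 100, 0.9), 0)
  expect_true(all(diff(p) <= 0))
  expect_true(all(p >= 1 - 0.9 & p <= 1))
  expect_error(prob_investment(1, 0, 0.9), "budget")
  expect_error(prob_investment(2, 1, 0.9), "investment")
})

test_that("total probability is the stated convex combination", {
  expect_equal(total_probability(1, 1, 0.7), 1)
  expect_equal(total_probability(0.5, 0.2, 0.7), 0.41)
  expect_equal(total_probability(0.9, 0.2, 0), 0.2)
  expect_equal(total_probability(0.9, 0.2, 1), 0.9)
  expect_error(total_probability(1.2, 0.2, 0.7), "0, 1")
})

test_that("landslide sampling respects impossible/certain events and benign rule", {
  cfg <- load_condition("high")
  set.seed(1)
  o <- sample_landslide_and_damages(0, cfg)
  expect_false(o$occurred)
  expect_false(o$property_damage || o$injury || o$fatality || o$benign)

  cfg0 <- zero_damage_config()
  set.seed(1)
  o <- sample_landslide_and_damages(1, cfg0)
  expect_true(o$occurred)
  expect_true(o$benign)
})

test_that("sampling consumes exactly one draw without a landslide and four with", {
  cfg <- load_condition("high")
  set.seed(42); invisible(sample_landslide_and_damages(0, cfg))
  after_miss <- stats::runif(1)
  set.seed(42)
  expect_identical(after_miss, stats::runif(2)[2])

  set.seed(42); invisible(sample_landslide_and_damages(1, cfg))
  after_hit <- stats::runif(1)
  set.seed(42)
  expect_identical(after_hit, stats::runif(5)[5])
})

test_that("damage arithmetic matches the condition table exactly", {
  cfg <- load_condition("high")
  st <- new_ils_state(cfg)
  hit <- function(pd, inj, fat) {
    list(occurred = TRUE, property_damage = pd, injury = inj,
         fatality = fat, benign = !(pd || inj || fat))
  }
  r <- apply_damages(st, hit(TRUE, FALSE, FALSE), cfg)
  expect_identical(r$state$property_wealth, 1e7)
  expect_identical(r$pd_amount, 1e7)
  expect_identical(r$income_drop, 0)

  r <- apply_damages(st, hit(FALSE, TRUE, FALSE), cfg)
  expect_equal(r$state$income, 262.8)
  expect_equal(r$income_drop, 292 - 262.8)

  r <- apply_damages(st, hit(FALSE, FALSE, TRUE), cfg)
  expect_equal(r$state$income, 233.6)

  # injury and fatality together compound multiplicatively
  r <- apply_damages(st, hit(FALSE, TRUE, TRUE), cfg)
  expect_equal(r$state$income, 292 * 0.9 * 0.8)

  r <- apply_damages(st, list(occurred = FALSE, property_damage = FALSE,
                              injury = FALSE, fatality = FALSE,
                              benign = FALSE), cfg)
  expect_identical(r$state$income, st$income)
  expect_identical(r$state$property_wealth, st$property_wealth)
  expect_identical(r$income_drop, 0)
  expect_identical(r$pd_amount, 0)
})

test_that("a zero-investment first round composes the probabilities as stated", {
  cfg <- ils_config(p_env = 0, mitigation_return_M = 1,
                    p_property_damage = 0, p_injury = 0, p_fatality = 0)
  st <- new_ils_state(cfg)
  set.seed(7)
  stp <- step_round(st, 0, cfg)
  expect_equal(stp$feedback$p_inv, 1)
  expect_equal(stp$feedback$p_total, cfg$weight_We)
  expect_equal(stp$feedback$win_W, cfg$initial_income)
  expect_equal(stp$feedback$loss_L, 0)
})

test_that("full investment drives the total probability toward zero", {
  cfg <- zero_damage_config(p_env = 0, mitigation_return_M = 1)
  st <- new_ils_state(cfg)
  set.seed(7)
  for (t in 1:30) {
    stp <- step_round(st, 1, cfg)
    st <- stp$state
  }
  expect_equal(stp$feedback$p_inv, 0)
  expect_equal(stp$feedback$p_total, 0)
})

test_that("round stepping is bit-reproducible under a fixed seed", {
  cfg <- load_condition("high")
  run <- function() {
    set.seed(99)
    st <- new_ils_state(cfg)
    out <- list()
    for (t in 1:30) {
      stp <- step_round(st, 0.37, cfg)
      st <- stp$state
      out[[t]] <- stp
    }
    out
  }
  expect_identical(run(), run())
})

test_that("trajectory invariants hold on random trajectories", {
  cfg <- load_condition("high")
  set.seed(123)
  for (rep in 1:60) {
    st <- new_ils_state(cfg)
    ratios <- stats::runif(30)
    incomes <- numeric(30)
    for (t in 1:30) {
      stp <- step_round(st, ratios[t], cfg)
      expect_gte(stp$feedback$p_total, 0)
      expect_lte(stp$feedback$p_total, 1)
      expect_gte(stp$feedback$loss_L, 0)
      expect_equal(stp$feedback$loss_L,
                   stp$feedback$pd_amount + stp$feedback$income_drop)
      expect_lte(stp$state$cum_investment, stp$state$cum_budget)
      incomes[t] <- stp$state$income
      st <- stp$state
    }
    expect_true(all(diff(incomes) <= 0))
  }
})

test_that("without damages, losses vanish and wealth is exact accumulation", {
  cfg <- zero_damage_config()
  set.seed(5)
  st <- new_ils_state(cfg)
  ratios <- stats::runif(30)
  uninvested <- 0
  for (t in 1:30) {
    stp <- step_round(st, ratios[t], cfg)
    expect_identical(stp$feedback$loss_L, 0)
    uninvested <- uninvested + (292 - ratios[t] * 292)
    st <- stp$state
  }
  expect_equal(st$total_wealth, uninvested + cfg$initial_property_wealth)
  expect_identical(st$income, 292)
})

test_that("condition fixtures transcribe the study parameters", {
  low <- load_condition("low")
  high <- load_condition("high")
  med <- load_condition("medium")
  expect_equal(c(low$p_property_damage, low$p_injury, low$p_fatality),
               c(0.03, 0.10, 0.01))
  expect_equal(c(high$p_property_damage, high$p_injury, high$p_fatality),
               c(0.30, 0.90, 0.09))
  expect_equal(c(med$p_property_damage, med$p_injury, med$p_fatality),
               c(0.165, 0.50, 0.05))
  expect_equal(c(low$n_participants, high$n_participants,
                 med$n_participants), c(20L, 23L, 30L))
  for (cfg in list(low, high, med)) {
    expect_equal(cfg$initial_income, 292)
    expect_equal(cfg$initial_property_wealth, 2e7)
    expect_equal(cfg$weight_We, 0.7)
    expect_equal(cfg$n_rounds, 30L)
  }
  # overrides reach the constructor
  expect_equal(load_condition("low", p_env = 0.1)$p_env, 0.1)
  expect_error(ils_config(p_injury = 1.5), "probability")
})
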