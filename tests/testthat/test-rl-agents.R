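test_that("currency feedback scales into utility space", {
  expect_equal(scale_outcome(list(win_W = 292, loss_L = 0), 292),
               list(win = 1, loss = 0, net_x = 1))
  expect_equal(scale_outcome(list(win_W = 0, loss_L = 0), 292),
               list(win = 0, loss = 0, net_x = 0))
  expect_equal(scale_outcome(list(win_W = 146, loss_L = 29.2), 292),
               list(win = 0.5, loss = 0.1, net_x = 0.4))
  expect_error(scale_outcome(list(win_W = 1, loss_L = 0), 0), "positive")
})

test_that("EV valence weights rewards against losses", {
  expect_equal(ev_valence(1, 0, 0), 1)
  expect_equal(ev_valence(0.7, 0.7, 0.5), 0)
  # calibrated-style loss weighting: losses dominate for w > 0.5
  expect_equal(ev_valence(1, 2, 0.728), 0.272 * 1 - 0.728 * 2)
})

test_that("delta-rule update has the stated limits", {
  expect_equal(ev_update(50, -3, 0), 50)
  expect_equal(ev_update(50, -3, 1), -3)
  expect_equal(ev_update(50, 0, 0.5), 25)
})

test_that("sensitivity schedules evaluate as defined", {
  expect_equal(ev_theta(10, 2.7), 1)
  expect_equal(ev_theta(17, 0), 1)
  expect_equal(ev_theta(30, 1), 3)
  expect_equal(pvl_theta(0), 0)
  expect_equal(pvl_theta(1), 2)
  expect_equal(pvl_theta(0.789), 3^0.789 - 1)
})

test_that("softmax probabilities are uniform under symmetry and logistic for two options", {
  expect_equal(softmax_probs(rep(50, 10), 2), rep(0.1, 10))
  expect_equal(softmax_probs(c(5, -1, 3, 0, 2, 7, 1, 4, -2, 6), 0),
               rep(0.1, 10))
  expect_equal(softmax_probs(c(1, 0), 1)[1], exp(1) / (1 + exp(1)))
  # overflow-safe at extreme products
  expect_equal(sum(softmax_probs(c(500, 499, 1), 5)), 1)
  expect_error(softmax_probs(c(NaN, 1), 1), "finite")
})

test_that("softmax probabilities sum to one over random parameter draws", {
  set.seed(2024)
  for (i in 1:1000) {
    ev <- stats::rnorm(10, 0, 50)
    theta <- stats::runif(1, 0, 5)
    expect_lt(abs(sum(softmax_probs(ev, theta)) - 1), 1e-12)
  }
})

test_that("prospect utility has the stated shape and loss handling", {
  expect_equal(prospect_utility(0, 0.5, 2), 0)
  expect_equal(prospect_utility(0.73, 1, 3), 0.73)
  expect_equal(prospect_utility(-1, 0.557, 2.204), -2.204)
  # odd symmetry up to the loss-aversion factor
  for (x in c(0.2, 0.9, 2.5)) {
    expect_equal(prospect_utility(-x, 0.7, 3.1),
                 -3.1 * prospect_utility(x, 0.7, 3.1))
  }
  # higher loss aversion never helps a losing outcome
  expect_lt(prospect_utility(-0.5, 0.6, 4), prospect_utility(-0.5, 0.6, 2))
})

test_that("separable utility cancels symmetric outcomes and reduces to the gain branch", {
  expect_equal(pvl2_utility(0.4, 0.4, 1, 1), 0)
  expect_equal(pvl2_utility(0.9, 0, 1, 3), 0.9)
  expect_equal(pvl2_utility(1, 1, 0.851, 4.797), 1 - 4.797)
  for (w in c(0, 0.3, 1)) {
    expect_equal(pvl2_utility(w, 0, 0.62, 2.5),
                 prospect_utility(w, 0.62, 2.5))
  }
  expect_lt(pvl2_utility(0.2, 0.7, 0.6, 4), pvl2_utility(0.2, 0.7, 0.6, 2))
})

test_that("decay-reinforcement rule has the stated limits", {
  ev <- rep(50, 10)
  out <- decay_update(ev, 3, 7, 0)
  expect_equal(out, c(0, 0, 7, rep(0, 7)))
  out <- decay_update(ev, 3, 7, 1)
  expect_equal(out, c(50, 50, 57, rep(50, 7)))
  out <- decay_update(ev, 4, 10, 0.5)
  expect_equal(out, c(25, 25, 25, 35, rep(25, 6)))
  # zero utility shrinks everything by exactly the decay factor
  ev <- stats::rnorm(10, 20, 5)
  expect_identical(decay_update(ev, 2, 0, 0.37), 0.37 * ev)
})

test_that("EV-family updates leave unchosen options bitwise unchanged", {
  set.seed(31)
  for (model in c("EV", "EV-PU")) {
    par <- as_model_params(model, trace_params(model))
    for (i in 1:50) {
      ev <- stats::rnorm(10, 10, 30)
      k <- sample.int(10, 1)
      out <- update_expectancies(model, par, ev, k, stats::rnorm(1))
      expect_identical(out[-k], ev[-k])
    }
  }
})

test_that("options map to half-open ratio bins", {
  set.seed(8)
  for (i in 1:200) {
    k <- sample.int(10, 1)
    r <- option_to_ratio(k)
    expect_gte(r, (k - 1) / 10)
    expect_lt(r, k / 10)
  }
  expect_equal(option_to_ratio(1, u = 0), 0)
  expect_equal(option_to_ratio(6, u = 0.5), 0.55)
  expect_equal(option_to_ratio(10, u = 0.999), (9 + 0.999) / 10)
  expect_error(option_to_ratio(11), "1..10")
  # exactly one draw consumed
  set.seed(3); invisible(option_to_ratio(5)); nxt <- stats::runif(1)
  set.seed(3); expect_identical(nxt, stats::runif(2)[2])
})

test_that("random model picks the argmax and breaks ties at the lowest index", {
  expect_identical(random_model_choose(u = c(0.2, 0.9, 0.9, 0.1, 0.5,
                                             0.3, 0.9, 0.2, 0.1, 0.4)), 2L)
  expect_identical(random_model_choose(u = rep(0.5, 10)), 1L)
  set.seed(12)
  expect_identical({set.seed(12); random_model_choose()},
                   {set.seed(12); random_model_choose()})
})

test_that("first-round choice is uniform and frozen learning freezes expectancies", {
  for (model in model_ids()) {
    par <- if (model == "RANDOM") numeric(0) else trace_params(model)
    expect_equal(choice_probabilities(model, par, rep(50, 10), 1),
                 rep(0.1, 10))
  }
  # EV with a = 0: feedback never moves expectancies
  par <- ev_params(a = 0, w = 0.5, c = 0.3)
  ev <- rep(50, 10)
  set.seed(77)
  act <- agent_act("EV", par, ev, 2,
                   last_feedback = list(win_W = 100, loss_L = 1e6),
                   last_choice = 4L, scale_divisor = 292)
  expect_identical(act$expectancies, ev)
})

test_that("agent_act skips the update on the first round", {
  set.seed(5)
  act <- agent_act("PVL", trace_params("PVL"), rep(50, 10), 1,
                   last_feedback = NULL, last_choice = NA_integer_)
  expect_identical(act$expectancies, rep(50, 10))
  expect_true(act$option %in% 1:10)
  expect_gte(act$ratio, (act$option - 1) / 10)
  expect_lt(act$ratio, act$option / 10)
})

test_that("parameter validation enforces model-specific bounds", {
  expect_error(as_model_params("EV", c(a = 1.2, w = 0.5, c = 0)), "range")
  expect_error(as_model_params("PVL", c(alpha = 0.5, lambda = 2, A = 0.5,
                                        c = -1)), "range")
  # EV-PU allows negative consistency, PVL does not
  expect_silent(as_model_params("EV-PU", c(alpha = 0.5, lambda = 2,
                                           A = 0.5, c = -1)))
  expect_error(as_model_params("RANDOM", c(a = 1)), "no parameters")
  expect_identical(model_n_params("EV"), 3L)
  expect_identical(model_n_params("PVL-2"), 4L)
  expect_identical(model_n_params("RANDOM"), 0L)
})

test_that("packaged calibrated parameters load and validate", {
  par <- load_calibrated_params()
  expect_named(par, c("low", "high"))
  expect_equal(par$high[["PVL-2"]],
               c(alpha = 0.851, lambda = 4.797, A = 0.099, c = 0.789))
  expect_equal(par$low[["EV"]], c(a = 0.771, w = 0.079, c = 0.282))
  expect_length(par$low[["RANDOM"]], 0)
})

test_that("flat simulator is bit-identical to the compositional agent/environment path", {
  for (model in model_ids()) {
    par <- if (model == "RANDOM") numeric(0) else trace_params(model)
    for (cond in c("low", "high")) {
      cfg <- load_condition(cond)
      expect_identical(simulate_participant(model, par, cfg, seed = 314),
                       compositional_simulate(model, par, cfg, seed = 314),
                       info = paste(model, cond))
    }
  }
})

test_that("trajectories are reproducible and ratios stay in range", {
  cfg <- load_condition("high")
  par <- load_calibrated_params()$high[["PVL-2"]]
  r1 <- simulate_participant("PVL-2", par, cfg, seed = 9)
  r2 <- simulate_participant("PVL-2", par, cfg, seed = 9)
  expect_identical(r1, r2)
  expect_length(r1, 30)
  expect_true(all(r1 >= 0 & r1 < 1))
  log <- simulate_participant("PVL-2", par, cfg, seed = 9, full_log = TRUE)
  expect_identical(log$investment_ratio, r1)
  expect_true(all(diff(log$income) <= 0))
  # property wealth changes only by exact halvings
  pw <- c(cfg$initial_property_wealth, log$property_wealth)
  changed <- diff(pw) != 0
  expect_true(all(pw[-1][changed] == pw[-length(pw)][changed] / 2))
})
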