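#' Reinforcement-learning decision models over investment-ratio bins
#'
#' Five decision models act on ten options, each option an investment-ratio
#' bin of width 10%: the expectancy-valence model (`"EV"`), the
#' prospect-valence learning model (`"PVL"`), the expectancy-valence model
#' with prospect utility (`"EV-PU"`), a prospect-valence variant with a
#' separable gain/loss utility (`"PVL-2"`), and a no-learning baseline
#' (`"RANDOM"`). Every learning model keeps one expectancy per option
#' (initialized to 50 units), evaluates each round's reward/loss feedback
#' through its utility function, updates expectancies with its learning rule,
#' and chooses the next option through a softmax rule whose sensitivity is
#' controlled by a consistency parameter.
#'
#' @name rl_agents
#' @keywords internal
NULL

MODEL_IDS <- c("EV", "EV-PU", "PVL", "PVL-2", "RANDOM")
N_OPTIONS <- 10L
INITIAL_EXPECTANCY <- 50

#' Model identifiers, parameter counts, and calibration bounds
#'
#' `model_ids()` lists the five model identifiers. `model_n_params()` gives
#' the number of free parameters (EV: 3; PVL, PVL-2, EV-PU: 4; RANDOM: 0),
#' which enters the AIC complexity penalty. `model_bounds()` returns the
#' calibration box for each family: EV has recency `a` in `[0,1]`, loss
#' weight `w` in `[0,1]` and consistency `c` in `[-5,5]`; the prospect
#' family has shape `alpha` in `[0,1]`, loss aversion `lambda` in `[0,5]`,
#' recency `A` in `[0,1]`, and consistency `c` in `[0,5]` (PVL, PVL-2) or
#' `[-5,5]` (EV-PU, which uses the EV sensitivity schedule).
#'
#' @param model_id One of `"EV"`, `"EV-PU"`, `"PVL"`, `"PVL-2"`, `"RANDOM"`.
#' @return `model_bounds()`: a list with numeric vectors `lower` and `upper`
#'   named by parameter (zero-length for `"RANDOM"`).
#' @export
model_ids <- function() MODEL_IDS

#' @rdname model_ids
#' @export
model_n_params <- function(model_id) {
  switch(match.arg(model_id, MODEL_IDS),
         "EV" = 3L, "EV-PU" = 4L, "PVL" = 4L, "PVL-2" = 4L, "RANDOM" = 0L)
}

#' @rdname model_ids
#' @export
model_bounds <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id == "EV") {
    list(lower = c(a = 0, w = 0, c = -5), upper = c(a = 1, w = 1, c = 5))
  } else if (model_id == "RANDOM") {
    list(lower = numeric(0), upper = numeric(0))
  } else {
    c_lo <- if (model_id == "EV-PU") -5 else 0
    list(lower = c(alpha = 0, lambda = 0, A = 0, c = c_lo),
         upper = c(alpha = 1, lambda = 5, A = 1, c = 5))
  }
}

#' Construct and validate model parameter vectors
#'
#' `ev_params()` builds the EV parameter vector (recency `a`, loss weight
#' `w`, consistency `c`); `prospect_params()` builds the shared parameter
#' vector of the prospect family (shape `alpha`, loss aversion `lambda`,
#' recency `A`, consistency `c`). `as_model_params()` validates an arbitrary
#' named vector or list against a model's bounds.
#'
#' @param a,w,c,alpha,lambda,A Parameter values, see [model_bounds()] for
#'   ranges.
#' @param model_id Model identifier the parameters belong to.
#' @param params Named numeric vector or list of parameter values.
#' @return A named numeric vector.
#' @export
ev_params <- function(a, w, c) {
  as_model_params("EV", c(a = a, w = w, c = c))
}

#' @rdname ev_params
#' @export
prospect_params <- function(alpha, lambda, A, c, model_id = "PVL") {
  as_model_params(model_id, c(alpha = alpha, lambda = lambda, A = A, c = c))
}

#' @rdname ev_params
#' @export
as_model_params <- function(model_id, params = numeric(0)) {
  model_id <- match.arg(model_id, MODEL_IDS)
  b <- model_bounds(model_id)
  if (model_id == "RANDOM") {
    if (length(params) > 0) {
      stop("the random model has no parameters", call. = FALSE)
    }
    return(numeric(0))
  }
  params <- unlist(params)
  if (!all(names(b$lower) %in% names(params))) {
    stop(sprintf("model %s requires parameters: %s", model_id,
                 paste(names(b$lower), collapse = ", ")), call. = FALSE)
  }
  params <- params[names(b$lower)]
  if (any(is.na(params)) || any(params < b$lower) || any(params > b$upper)) {
    bad <- names(params)[is.na(params) | params < b$lower | params > b$upper]
    stop(sprintf("parameter(s) out of range for model %s: %s", model_id,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  params
}

#' Scale currency feedback into utility space
#'
#' Raw feedback is in EC (income about 3e2, property damage about 1e7);
#' dividing by `scale_divisor` (by default the initial per-round income)
#' brings both onto a scale where the softmax produces non-degenerate choice
#' probabilities, and makes a fully uninvested undamaged round worth
#' exactly 1.
#'
#' @param feedback A feedback list from [step_round()] (fields `win_W`,
#'   `loss_L`), or any list with those fields.
#' @param scale_divisor Positive currency divisor.
#' @return A list with `win`, `loss` (non-negative) and `net_x = win - loss`.
#' @export
scale_outcome <- function(feedback, scale_divisor) {
  if (is.na(scale_divisor) || scale_divisor <= 0) {
    stop("`scale_divisor` must be positive", call. = FALSE)
  }
  win <- feedback$win_W / scale_divisor
  loss <- feedback$loss_L / scale_divisor
  list(win = win, loss = loss, net_x = win - loss)
}

#' Expectancy-valence utility (valence)
#'
#' Weighted combination of the round's reward and loss magnitude. The loss
#' term enters negatively, so `w > 0.5` means losses dominate the valence
#' (loss-averse weighting) and `w < 0.5` means rewards dominate.
#'
#' @param win Scaled reward, `W(t)`.
#' @param loss Scaled loss magnitude, `L(t) >= 0`.
#' @param w Loss-attention weight in `[0,1]`.
#' @return `(1 - w) * win - w * loss`.
#' @export
ev_valence <- function(win, loss, w) {
  (1 - w) * win - w * loss
}

#' Delta-rule expectancy update (EV family)
#'
#' Blends the old expectancy of the chosen option with the new valence;
#' unchosen options are untouched. `a = 0` freezes learning, `a = 1` makes
#' the expectancy track the latest valence exactly.
#'
#' @param ev_k Current expectancy of the chosen option.
#' @param valence Utility of the observed outcome.
#' @param a Recency parameter in `[0,1]`.
#' @return Updated expectancy `(1 - a) * ev_k + a * valence`.
#' @export
ev_update <- function(ev_k, valence, a) {
  (1 - a) * ev_k + a * valence
}

#' Sensitivity schedules for the softmax choice rule
#'
#' The EV family uses a round-dependent sensitivity `(t/10)^c`, rising over
#' rounds for `c > 0` (exploration early, exploitation late) and falling for
#' `c < 0`. The PVL family uses the round-independent `3^c - 1`, which is 0
#' at `c = 0` (uniform choice) and grows with `c`.
#'
#' @param round_t Round index (1-based).
#' @param c Consistency parameter.
#' @return The sensitivity value theta.
#' @export
ev_theta <- function(round_t, c) {
  (round_t / 10)^c
}

#' @rdname ev_theta
#' @export
pvl_theta <- function(c) {
  3^c - 1
}

#' Softmax choice probabilities and sampling
#'
#' `softmax_probs()` maps expectancies to choice probabilities
#' `exp(theta * EV_k) / sum_j exp(theta * EV_j)`, computed after subtracting
#' the maximum of `theta * EV` so large expectancies cannot overflow.
#' `softmax_choose()` samples one option by inverse-CDF using a single
#' uniform draw (supplied explicitly via `u` for scripted traces, otherwise
#' drawn from the current RNG stream).
#'
#' @param expectancies Numeric vector of option expectancies.
#' @param theta Non-negative (PVL family) or any finite sensitivity.
#' @param u Optional uniform draw in `[0,1)` used for inverse-CDF sampling.
#' @return `softmax_probs()`: a probability vector summing to 1;
#'   `softmax_choose()`: an option index in `1..length(expectancies)`.
#' @export
softmax_probs <- function(expectancies, theta) {
  if (!all(is.finite(expectancies)) || !is.finite(theta)) {
    stop("expectancies and theta must be finite", call. = FALSE)
  }
  z <- theta * expectancies
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' @rdname softmax_probs
#' @export
softmax_choose <- function(expectancies, theta, u = stats::runif(1)) {
  p <- softmax_probs(expectancies, theta)
  cs <- cumsum(p)
  cs[length(cs)] <- 1  # guard against cumulative rounding below 1
  which(u <= cs)[1]
}

#' Prospect utility of a net outcome
#'
#' Diminishing sensitivity via the shape parameter and asymmetric treatment
#' of losses via loss aversion: gains map to `x^alpha`, losses to
#' `-lambda * |x|^alpha`.
#'
#' @param net_x Net scaled outcome `win - loss`.
#' @param alpha Shape parameter in `[0,1]`.
#' @param lambda Loss-aversion parameter in `[0,5]`; values above 1 weight
#'   losses more than equal-magnitude gains.
#' @return The utility.
#' @export
prospect_utility <- function(net_x, alpha, lambda) {
  if (net_x >= 0) net_x^alpha else -lambda * abs(net_x)^alpha
}

#' Separable gain/loss prospect utility
#'
#' Evaluates gains and losses separately before combining, so a round with
#' equal reward and loss need not feel neutral: `win^alpha -
#' lambda * loss^alpha`. Reduces to the gain branch of [prospect_utility()]
#' when the loss is zero.
#'
#' @param win Scaled reward, non-negative.
#' @param loss Scaled loss magnitude, non-negative.
#' @inheritParams prospect_utility
#' @return The utility.
#' @export
pvl2_utility <- function(win, loss, alpha, lambda) {
  win^alpha - lambda * loss^alpha
}

#' Decay-reinforcement expectancy update (PVL family)
#'
#' All expectancies decay by the recency factor `A`, then the chosen option
#' absorbs the current outcome utility. `A = 0` wipes history; `A = 1` keeps
#' it intact.
#'
#' @param expectancies Numeric vector of option expectancies.
#' @param chosen_k Index of the option chosen on the round that produced
#'   `utility`.
#' @param utility Outcome utility to credit to the chosen option.
#' @param A Recency (decay) parameter in `[0,1]`.
#' @return The updated expectancy vector.
#' @export
decay_update <- function(expectancies, chosen_k, utility, A) {
  expectancies <- A * expectancies
  expectancies[chosen_k] <- expectancies[chosen_k] + utility
  expectancies
}

#' Map a chosen option to a concrete investment ratio
#'
#' Option `k` covers the half-open investment-ratio bin
#' `[(k-1)/10, k/10)`; the realized ratio is drawn uniformly within the bin
#' (one uniform consumed).
#'
#' @param k Option index in `1..10`.
#' @param u Optional uniform draw in `[0,1)`.
#' @return An investment ratio in `[(k-1)/10, k/10)`.
#' @export
option_to_ratio <- function(k, u = stats::runif(1)) {
  if (is.na(k) || k < 1L || k > N_OPTIONS || k != round(k)) {
    stop("`k` must be an integer option index in 1..10", call. = FALSE)
  }
  (k - 1 + u) / N_OPTIONS
}

#' Baseline random choice
#'
#' Draws ten independent uniform expectancies and picks the option with the
#' largest (ties resolved to the lowest index). No learning, no parameters.
#'
#' @param u Optional vector of ten uniform draws.
#' @return An option index in `1..10`.
#' @export
random_model_choose <- function(u = stats::runif(N_OPTIONS)) {
  which.max(u)
}

#' Model dispatch: utility, learning rule, choice probabilities
#'
#' `model_utility()` evaluates a scaled outcome under a model's utility
#' function: EV uses the weighted valence, PVL and EV-PU the prospect
#' utility of the net outcome, PVL-2 the separable gain/loss utility.
#' `update_expectancies()` applies the model's learning rule: delta-rule on
#' the chosen option for EV and EV-PU (recency `a` resp. `A`),
#' decay-reinforcement over all options for PVL and PVL-2.
#' `choice_probabilities()` applies the model's sensitivity schedule (EV and
#' EV-PU: `(t/10)^c`; PVL and PVL-2: `3^c - 1`; RANDOM has no softmax and
#' returns uniform probabilities, which matches its argmax-of-iid-uniforms
#' choice distribution).
#'
#' @param model_id Model identifier.
#' @param params Parameter vector from [as_model_params()].
#' @param outcome A scaled outcome list from [scale_outcome()].
#' @param expectancies Numeric vector of 10 expectancies.
#' @param chosen_k Option chosen on the round that produced `outcome`.
#' @param utility Utility credited by the learning rule.
#' @param round_t Round index of the choice being made.
#' @return `model_utility()`: a scalar utility; `update_expectancies()`: the
#'   updated expectancy vector; `choice_probabilities()`: a probability
#'   vector of length 10.
#' @export
model_utility <- function(model_id, params, outcome) {
  switch(match.arg(model_id, MODEL_IDS),
    "EV" = ev_valence(outcome$win, outcome$loss, params[["w"]]),
    "PVL" = ,
    "EV-PU" = prospect_utility(outcome$net_x, params[["alpha"]],
                               params[["lambda"]]),
    "PVL-2" = pvl2_utility(outcome$win, outcome$loss, params[["alpha"]],
                           params[["lambda"]]),
    "RANDOM" = 0
  )
}

#' @rdname model_utility
#' @export
update_expectancies <- function(model_id, params, expectancies, chosen_k,
                                utility) {
  switch(match.arg(model_id, MODEL_IDS),
    "EV" = {
      expectancies[chosen_k] <- ev_update(expectancies[chosen_k], utility,
                                          params[["a"]])
      expectancies
    },
    "EV-PU" = {
      expectancies[chosen_k] <- ev_update(expectancies[chosen_k], utility,
                                          params[["A"]])
      expectancies
    },
    "PVL" = ,
    "PVL-2" = decay_update(expectancies, chosen_k, utility, params[["A"]]),
    "RANDOM" = expectancies
  )
}

#' @rdname model_utility
#' @export
choice_probabilities <- function(model_id, params, expectancies, round_t) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id == "RANDOM") {
    return(rep(1 / N_OPTIONS, N_OPTIONS))
  }
  theta <- if (model_id %in% c("EV", "EV-PU")) {
    ev_theta(round_t, params[["c"]])
  } else {
    pvl_theta(params[["c"]])
  }
  softmax_probs(expectancies, theta)
}

#' One decision step of an agent
#'
#' Applies the model's utility to the previous round's feedback (skipped on
#' the first round, when there is none and all expectancies still sit at
#' their initial 50 units, making the first choice uniform), updates
#' expectancies, then samples the new option and its within-bin investment
#' ratio from the current RNG stream. Draw order is choice draw(s) first
#' (one uniform for the softmax models, ten for the random model), then one
#' bin draw.
#'
#' @param model_id Model identifier.
#' @param params Parameter vector matching the model.
#' @param expectancies Current expectancy vector (length 10).
#' @param round_t Round index of the decision being made.
#' @param last_feedback Feedback list from the previous [step_round()], or
#'   `NULL` on the first round.
#' @param last_choice Option chosen on the previous round, or `NA`.
#' @param scale_divisor Currency divisor, see [scale_outcome()].
#' @return A list with `option`, `ratio`, and the updated `expectancies`.
#' @export
agent_act <- function(model_id, params, expectancies, round_t,
                      last_feedback = NULL, last_choice = NA_integer_,
                      scale_divisor = 292) {
  model_id <- match.arg(model_id, MODEL_IDS)
  params <- as_model_params(model_id, params)
  if (!is.null(last_feedback) && !is.na(last_choice) &&
      model_id != "RANDOM") {
    sc <- scale_outcome(last_feedback, scale_divisor)
    u <- model_utility(model_id, params, sc)
    expectancies <- update_expectancies(model_id, params, expectancies,
                                        last_choice, u)
  }
  if (model_id == "RANDOM") {
    k <- random_model_choose()
  } else {
    theta <- if (model_id %in% c("EV", "EV-PU")) {
      ev_theta(round_t, params[["c"]])
    } else {
      pvl_theta(params[["c"]])
    }
    k <- softmax_choose(expectancies, theta)
  }
  ratio <- option_to_ratio(k)
  list(option = k, ratio = ratio, expectancies = expectancies)
}

#' Load packaged calibrated model parameters
#'
#' Returns the calibrated parameter sets shipped with the package for the
#' low and high damage-feedback conditions (a JSON fixture), as named lists
#' `params[[condition]][[model_id]]`.
#'
#' @param path Optional path to an alternative JSON file with the same
#'   layout.
#' @return A nested list of parameter vectors.
#' @export
load_calibrated_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "calibrated_params.json",
                        package = "ilsRL")
    if (!nzchar(path)) stop("packaged parameter fixture not found")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(cond) {
    out <- lapply(names(cond), function(m) {
      as_model_params(m, unlist(cond[[m]]))
    })
    names(out) <- names(cond)
    out
  })
}
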