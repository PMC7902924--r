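#' Interactive landslide-mitigation microworld
#'
#' The microworld puts a decision maker in a region at landslide risk. Each
#' round the player receives an income (in a fictitious Electronic Currency,
#' EC), invests some fraction of it in mitigation (retaining walls, drainage),
#' and then a landslide may or may not occur. The per-round landslide
#' probability blends two terms: an environmental probability `p_env`
#' (subsuming rainfall and spatial susceptibility) and an investment-dependent
#' probability that falls linearly in the cumulative fraction of income
#' invested so far. A landslide, when it occurs, can independently trigger
#' property damage (property wealth halves), injury (income drops by 10%),
#' and fatality (income drops by 20%); a landslide that triggers none of
#' these is benign.
#'
#' @name ils_env
#' @keywords internal
NULL

#' Condition configuration for the landslide microworld
#'
#' Bundles all fixed parameters of one experimental condition. Damage
#' probabilities are per-round point probabilities, applied independently
#' given that a landslide occurred.
#'
#' @param condition_id Label for the condition (e.g. `"low"`, `"high"`,
#'   `"medium"`).
#' @param initial_income Per-round income in EC at the start of play.
#' @param initial_property_wealth Starting property wealth in EC.
#' @param weight_We Weight in `[0,1]` given to the investment-dependent
#'   probability when blending with the environmental probability.
#' @param mitigation_return_M Return-to-mitigation parameter in `[0,1]`; full
#'   cumulative investment drives the investment probability down to `1 - M`.
#' @param p_env Environmental landslide probability; a scalar, or a vector
#'   giving a per-round series (recycled from its last value if shorter than
#'   `n_rounds`).
#' @param p_property_damage,p_injury,p_fatality Per-round damage trigger
#'   probabilities, each in `[0,1]`.
#' @param property_loss_fraction Fraction of property wealth lost on property
#'   damage (0.5: wealth halves).
#' @param injury_income_fraction Fractional income reduction on injury (0.10).
#' @param fatality_income_fraction Fractional income reduction on fatality
#'   (0.20).
#' @param n_rounds Number of rounds of play.
#' @param n_participants Default cohort size for this condition.
#' @param scale_divisor Currency divisor applied to rewards and losses before
#'   they enter a model's utility function; defaults to the initial income so
#'   that a full uninvested income scales to 1.
#'
#' @return An object of class `ils_config` (a validated list).
#' @seealso [load_condition()] for the packaged condition fixtures.
#' @export
ils_config <- function(condition_id = "custom",
                       initial_income = 292,
                       initial_property_wealth = 2e7,
                       weight_We = 0.7,
                       mitigation_return_M = 0.9,
                       p_env = 0.3,
                       p_property_damage = 0.03,
                       p_injury = 0.10,
                       p_fatality = 0.01,
                       property_loss_fraction = 0.5,
                       injury_income_fraction = 0.10,
                       fatality_income_fraction = 0.20,
                       n_rounds = 30L,
                       n_participants = 20L,
                       scale_divisor = initial_income) {
  cfg <- list(
    condition_id = as.character(condition_id),
    initial_income = as.numeric(initial_income),
    initial_property_wealth = as.numeric(initial_property_wealth),
    weight_We = as.numeric(weight_We),
    mitigation_return_M = as.numeric(mitigation_return_M),
    p_env = as.numeric(p_env),
    p_property_damage = as.numeric(p_property_damage),
    p_injury = as.numeric(p_injury),
    p_fatality = as.numeric(p_fatality),
    property_loss_fraction = as.numeric(property_loss_fraction),
    injury_income_fraction = as.numeric(injury_income_fraction),
    fatality_income_fraction = as.numeric(fatality_income_fraction),
    n_rounds = as.integer(n_rounds),
    n_participants = as.integer(n_participants),
    scale_divisor = as.numeric(scale_divisor)
  )
  validate_ils_config(cfg)
  class(cfg) <- "ils_config"
  cfg
}

validate_ils_config <- function(cfg) {
  prob_fields <- c("weight_We", "mitigation_return_M", "p_property_damage",
                   "p_injury", "p_fatality")
  for (f in prob_fields) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single probability in [0, 1]", f),
           call. = FALSE)
    }
  }
  if (any(is.na(cfg$p_env)) || any(cfg$p_env < 0) || any(cfg$p_env > 1)) {
    stop("`p_env` must lie in [0, 1]", call. = FALSE)
  }
  frac_fields <- c("property_loss_fraction", "injury_income_fraction",
                   "fatality_income_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop(sprintf("`%s` must lie strictly between 0 and 1", f), call. = FALSE)
    }
  }
  if (cfg$initial_income < 0 || cfg$initial_property_wealth < 0) {
    stop("income and property wealth must be non-negative", call. = FALSE)
  }
  if (cfg$n_rounds < 1L) stop("`n_rounds` must be at least 1", call. = FALSE)
  if (cfg$n_participants < 1L) {
    stop("`n_participants` must be at least 1", call. = FALSE)
  }
  if (cfg$scale_divisor <= 0) {
    stop("`scale_divisor` must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' Load a packaged condition configuration
#'
#' The package ships YAML fixtures for the three damage-feedback conditions:
#' `low` (property damage 3%, injury 10%, fatality 1%, N = 20), `high` (30%,
#' 90%, 9%, N = 23) and `medium` (16.5%, 50%, 5%, N = 30). All conditions use
#' initial income 292 EC/round, initial property wealth 20 million EC and
#' probability weight 0.7. The return-to-mitigation parameter and the
#' environmental probability carry package defaults (M = 0.9, p_env = 0.3)
#' documented in the methods vignette; any field can be overridden via `...`
#' or by pointing `path` at a user YAML file with the same keys.
#'
#' @param condition One of `"low"`, `"high"`, `"medium"`, ignored when `path`
#'   is given.
#' @param path Optional path to a YAML file with `ils_config` fields.
#' @param ... Named overrides for individual fields.
#' @return An [ils_config()] object.
#' @export
load_condition <- function(condition = c("low", "high", "medium"),
                           path = NULL, ...) {
  if (is.null(path)) {
    condition <- match.arg(condition)
    path <- system.file("extdata", "conditions",
                        paste0(condition, ".yaml"), package = "ilsRL")
    if (!nzchar(path)) stop("packaged condition fixture not found")
  }
  fields <- yaml::read_yaml(path)
  overrides <- list(...)
  fields[names(overrides)] <- overrides
  do.call(ils_config, fields)
}

#' Probability of landslide due to human investments
#'
#' Falls linearly from 1 (nothing invested) to `1 - M` (entire budget to date
#' invested): mitigation never removes the risk entirely because `1 - M > 0`
#' for `M < 1`.
#'
#' @param cum_investment Total EC invested so far.
#' @param cum_budget Total EC that could have been invested so far (sum of
#'   per-round incomes); must be positive.
#' @param M Return-to-mitigation parameter in `[0,1]`.
#' @return `1 - M * cum_investment / cum_budget`, in `[1 - M, 1]`.
#' @export
prob_investment <- function(cum_investment, cum_budget, M) {
  if (cum_budget <= 0) {
    stop("cumulative budget must be positive", call. = FALSE)
  }
  if (cum_investment < 0 || cum_investment > cum_budget) {
    stop("cumulative investment must lie in [0, cumulative budget]",
         call. = FALSE)
  }
  if (M < 0 || M > 1) stop("`M` must lie in [0, 1]", call. = FALSE)
  1 - M * (cum_investment / cum_budget)
}

#' Total landslide probability
#'
#' Convex combination of the investment-dependent probability and the
#' environmental probability.
#'
#' @param p_inv Probability due to human investments.
#' @param p_env Probability due to physical factors (rainfall, susceptibility).
#' @param We Weight in `[0,1]` on the investment term.
#' @return `We * p_inv + (1 - We) * p_env`.
#' @export
total_probability <- function(p_inv, p_env, We) {
  args <- c(p_inv = p_inv, p_env = p_env, We = We)
  if (any(is.na(args)) || any(args < 0) || any(args > 1)) {
    stop("all arguments must lie in [0, 1]", call. = FALSE)
  }
  We * p_inv + (1 - We) * p_env
}

#' Sample a landslide event and its damages
#'
#' Draws one uniform number; a landslide occurs if it is at most `p_total`.
#' Given occurrence, property damage, injury and fatality are sampled as
#' three further independent Bernoulli draws (in that order), so exactly four
#' uniforms are consumed when a landslide occurs and one otherwise. This
#' fixed draw count makes trajectories bit-reproducible from a seed.
#'
#' @param p_total Total landslide probability for the round.
#' @param config An [ils_config()].
#' @return A list of class `landslide_outcome` with logical fields
#'   `occurred`, `property_damage`, `injury`, `fatality`, `benign`.
#' @export
sample_landslide_and_damages <- function(p_total, config) {
  if (is.na(p_total) || p_total < 0 || p_total > 1) {
    stop("`p_total` must lie in [0, 1]", call. = FALSE)
  }
  occurred <- stats::runif(1) <= p_total
  if (occurred) {
    d <- stats::runif(3)
    pd <- d[1] <= config$p_property_damage
    inj <- d[2] <= config$p_injury
    fat <- d[3] <= config$p_fatality
  } else {
    pd <- inj <- fat <- FALSE
  }
  out <- list(
    occurred = occurred,
    property_damage = pd,
    injury = inj,
    fatality = fat,
    benign = occurred && !(pd || inj || fat)
  )
  class(out) <- "landslide_outcome"
  out
}

#' Fresh per-participant state
#'
#' @param config An [ils_config()].
#' @return A list of class `ils_state`: round counter, current income and
#'   property wealth, cumulative investment and budget, accumulated
#'   uninvested income, and total wealth (uninvested income plus property
#'   wealth).
#' @export
new_ils_state <- function(config) {
  st <- list(
    round_t = 1L,
    income = config$initial_income,
    property_wealth = config$initial_property_wealth,
    cum_investment = 0,
    cum_budget = 0,
    cum_uninvested = 0,
    total_wealth = config$initial_property_wealth
  )
  class(st) <- "ils_state"
  st
}

#' Apply sampled damages to the state
#'
#' Property damage halves property wealth; injury multiplies income by 0.90;
#' fatality multiplies income by 0.80. When injury and fatality co-occur the
#' reductions compound multiplicatively (order is immaterial for the
#' product). Damages never increase income or wealth, so income is
#' non-increasing over a trajectory.
#'
#' @param state An `ils_state`.
#' @param outcome A `landslide_outcome`.
#' @param config An [ils_config()].
#' @return A list with the updated `state`, the property-damage amount
#'   `pd_amount` (EC) and the `income_drop` (EC, non-negative).
#' @export
apply_damages <- function(state, outcome, config) {
  pd_amount <- 0
  income_before <- state$income
  if (outcome$occurred) {
    if (outcome$property_damage) {
      pd_amount <- state$property_wealth * config$property_loss_fraction
      state$property_wealth <- state$property_wealth - pd_amount
    }
    if (outcome$injury) {
      state$income <- state$income * (1 - config$injury_income_fraction)
    }
    if (outcome$fatality) {
      state$income <- state$income * (1 - config$fatality_income_fraction)
    }
  }
  list(state = state,
       pd_amount = pd_amount,
       income_drop = income_before - state$income)
}

p_env_at <- function(config, t) {
  pe <- config$p_env
  pe[min(t, length(pe))]
}

#' Advance the microworld by one round
#'
#' One round: the player observes the current income (the round's budget),
#' invests `investment_ratio` of it, the landslide probability is computed
#' from the cumulative investment fraction and the environmental probability,
#' the event is sampled, damages are applied, and reward/loss feedback is
#' emitted. The reward is the uninvested income `W = income - invest`; the
#' loss magnitude is `L = PD + income_drop`, the property damage amount plus
#' the within-round income reduction. Total wealth accumulates the uninvested
#' income and tracks the (possibly halved) property wealth.
#'
#' @param state An `ils_state`.
#' @param investment_ratio Fraction of the round's income invested, in
#'   `[0,1]`.
#' @param config An [ils_config()].
#' @return A list with the updated `state`, the sampled `outcome`, and
#'   `feedback` (fields `win_W`, `loss_L`, `pd_amount`, `income_drop`, plus
#'   the realized probabilities `p_inv` and `p_total`).
#' @export
step_round <- function(state, investment_ratio, config) {
  if (is.na(investment_ratio) || investment_ratio < 0 ||
      investment_ratio > 1) {
    stop("`investment_ratio` must lie in [0, 1]", call. = FALSE)
  }
  income_obs <- state$income
  invest <- investment_ratio * income_obs
  state$cum_budget <- state$cum_budget + income_obs
  state$cum_investment <- state$cum_investment + invest

  p_inv <- prob_investment(state$cum_investment, state$cum_budget,
                           config$mitigation_return_M)
  p_total <- total_probability(p_inv, p_env_at(config, state$round_t),
                               config$weight_We)
  outcome <- sample_landslide_and_damages(p_total, config)
  dmg <- apply_damages(state, outcome, config)
  state <- dmg$state

  win <- income_obs - invest
  state$cum_uninvested <- state$cum_uninvested + win
  state$total_wealth <- state$cum_uninvested + state$property_wealth
  state$round_t <- state$round_t + 1L

  feedback <- list(
    win_W = win,
    loss_L = dmg$pd_amount + dmg$income_drop,
    pd_amount = dmg$pd_amount,
    income_drop = dmg$income_drop,
    p_inv = p_inv,
    p_total = p_total
  )
  list(state = state, outcome = outcome, feedback = feedback)
}
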