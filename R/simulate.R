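#' Simulate one agent through the microworld
#'
#' Runs a single model participant for `config$n_rounds` rounds from a fresh
#' state, drawing all randomness from one seeded stream. The per-round draw
#' order is fixed: choice draw(s) (one uniform for the softmax models, ten
#' for the random model), one within-bin draw, then the environment draws
#' (one uniform, plus three damage draws when a landslide occurs), so a
#' trajectory is bit-reproducible from `(model_id, params, config, seed)`.
#' The loop reproduces the compositional path [agent_act()] +
#' [step_round()] arithmetic exactly; it is written flat because calibration
#' evaluates hundreds of thousands of participant-rounds.
#'
#' @param model_id Model identifier, see [model_ids()].
#' @param params Parameter vector matching the model.
#' @param config An [ils_config()].
#' @param seed Integer seed for the participant's RNG stream.
#' @param full_log If `TRUE`, return a per-round data frame (schema of
#'   [write_cohort()]); otherwise just the investment-ratio vector.
#' @return Numeric vector of investment ratios (length `n_rounds`), or a
#'   data frame when `full_log = TRUE`.
#' @export
simulate_participant <- function(model_id, params, config, seed,
                                 full_log = FALSE) {
  model_id <- match.arg(model_id, MODEL_IDS)
  params <- as_model_params(model_id, params)
  set.seed(seed)

  code <- match(model_id, MODEL_IDS)  # 1 EV, 2 EV-PU, 3 PVL, 4 PVL-2, 5 RANDOM
  if (code == 1L) {
    a <- params[["a"]]; w <- params[["w"]]; cc <- params[["c"]]
  } else if (code < 5L) {
    alpha <- params[["alpha"]]; lambda <- params[["lambda"]]
    A <- params[["A"]]; cc <- params[["c"]]
  }
  theta_pvl <- if (code == 3L || code == 4L) 3^cc - 1

  n <- config$n_rounds
  We <- config$weight_We
  M <- config$mitigation_return_M
  p_pd <- config$p_property_damage
  p_inj <- config$p_injury
  p_fat <- config$p_fatality
  inj_f <- 1 - config$injury_income_fraction
  fat_f <- 1 - config$fatality_income_fraction
  pl_f <- config$property_loss_fraction
  sdiv <- config$scale_divisor
  penv <- config$p_env
  n_pe <- length(penv)

  ev <- rep(INITIAL_EXPECTANCY, N_OPTIONS)
  income <- config$initial_income
  pw <- config$initial_property_wealth
  cum_inv <- 0; cum_bud <- 0; cum_unv <- 0
  last_k <- 0L; last_win <- 0; last_loss <- 0

  ratios <- numeric(n)
  if (full_log) {
    log_income <- log_pw <- log_W <- log_L <- numeric(n)
    log_occ <- log_pd <- log_inj <- log_fat <- logical(n)
  }

  for (t in seq_len(n)) {
    if (t > 1L && code != 5L) {
      if (code == 1L) {
        u_t <- (1 - w) * last_win - w * last_loss
        ev[last_k] <- (1 - a) * ev[last_k] + a * u_t
      } else if (code == 2L) {
        x <- last_win - last_loss
        u_t <- if (x >= 0) x^alpha else -lambda * abs(x)^alpha
        ev[last_k] <- (1 - A) * ev[last_k] + A * u_t
      } else if (code == 3L) {
        x <- last_win - last_loss
        u_t <- if (x >= 0) x^alpha else -lambda * abs(x)^alpha
        ev <- A * ev
        ev[last_k] <- ev[last_k] + u_t
      } else {
        u_t <- last_win^alpha - lambda * last_loss^alpha
        ev <- A * ev
        ev[last_k] <- ev[last_k] + u_t
      }
    }

    if (code == 5L) {
      k <- which.max(stats::runif(N_OPTIONS))
    } else {
      theta <- if (code <= 2L) (t / 10)^cc else theta_pvl
      z <- theta * ev
      z <- z - max(z)
      e <- exp(z)
      p <- e / sum(e)
      cs <- cumsum(p)
      cs[N_OPTIONS] <- 1
      k <- which(stats::runif(1) <= cs)[1]
    }
    ratio <- (k - 1 + stats::runif(1)) / N_OPTIONS

    invest <- ratio * income
    cum_bud <- cum_bud + income
    cum_inv <- cum_inv + invest
    p_inv <- 1 - M * (cum_inv / cum_bud)
    p_tot <- We * p_inv + (1 - We) * penv[if (t < n_pe) t else n_pe]

    occurred <- stats::runif(1) <= p_tot
    pd_amt <- 0
    income_before <- income
    pd <- inj <- fat <- FALSE
    if (occurred) {
      d <- stats::runif(3)
      pd <- d[1] <= p_pd
      inj <- d[2] <= p_inj
      fat <- d[3] <= p_fat
      if (pd) {
        pd_amt <- pw * pl_f
        pw <- pw - pd_amt
      }
      if (inj) income <- income * inj_f
      if (fat) income <- income * fat_f
    }
    W <- income_before - invest
    L <- pd_amt + (income_before - income)
    cum_unv <- cum_unv + W

    last_k <- k
    last_win <- W / sdiv
    last_loss <- L / sdiv
    ratios[t] <- ratio
    if (full_log) {
      log_income[t] <- income; log_pw[t] <- pw
      log_W[t] <- W; log_L[t] <- L
      log_occ[t] <- occurred; log_pd[t] <- pd
      log_inj[t] <- inj; log_fat[t] <- fat
    }
  }

  if (!full_log) return(ratios)
  data.frame(
    round = seq_len(n),
    investment_ratio = ratios,
    income = log_income,
    property_wealth = log_pw,
    occurred = log_occ,
    property_damage = log_pd,
    injury = log_inj,
    fatality = log_fat,
    W = log_W,
    L = log_L
  )
}

#' Derive independent per-participant seeds from a cohort seed
#'
#' @param seed Integer cohort seed.
#' @param n Number of seeds required.
#' @return Integer vector of `n` seeds below 2^31.
#' @keywords internal
participant_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

# Lean cohort run used inside the calibration objective: ratios only.
sim_cohort_ratios <- function(model_id, params, config, seeds) {
  m <- matrix(0, nrow = length(seeds), ncol = config$n_rounds)
  for (i in seq_along(seeds)) {
    m[i, ] <- simulate_participant(model_id, params, config, seeds[i])
  }
  m
}
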