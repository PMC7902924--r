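# Independent oracles used to cross-check the package's statistics and
# learning-rule implementations. These deliberately re-derive everything
# with plain loops / straight-line arithmetic and share no code with R/.

# --- brute-force fit statistics ------------------------------------------

bf_ssd1 <- function(m, h) {
  s <- 0
  for (t in seq_along(m)) s <- s + (m[t] - h[t])^2
  s / length(m)
}

# literal product-moment formula, then squared
bf_r_squared <- function(m, h) {
  n <- length(m)
  sm <- 0; sh <- 0; smh <- 0; sm2 <- 0; sh2 <- 0
  for (t in seq_len(n)) {
    sm <- sm + m[t]; sh <- sh + h[t]
    smh <- smh + m[t] * h[t]
    sm2 <- sm2 + m[t]^2; sh2 <- sh2 + h[t]^2
  }
  r <- (n * smh - sm * sh) /
    sqrt((n * sm2 - sm^2) * (n * sh2 - sh^2))
  r^2
}

bf_aic1 <- function(s1, p, n_rounds = 30) n_rounds * log(s1) + 2 * p

bf_ssd2_aic2 <- function(mg, hg, p) {
  s2 <- (mg - hg)^2
  c(ssd2 = s2, aic2 = log(s2) + 2 * p)
}

bf_block_means <- function(curve, block = 5L) {
  out <- numeric(length(curve) / block)
  for (b in seq_along(out)) {
    s <- 0
    for (j in ((b - 1) * block + 1):(b * block)) s <- s + curve[j]
    out[b] <- s / block
  }
  out
}

# --- hand-trace oracle for the learning models ---------------------------
# Three scripted rounds with fixed choice uniforms and fixed scaled
# feedback; recomputes expectancies and choice probabilities from the model
# equations written out longhand.

trace_protocol <- function() {
  list(u_choice = c(0.12, 0.55, 0.93),
       feedback = list(c(win = 1.0, loss = 0.0),
                       c(win = 0.5, loss = 0.8)))
}

oracle_trace <- function(model) {
  pr <- trace_protocol()
  ev <- rep(50, 10)
  out <- vector("list", 3)
  last_k <- NA
  for (t in 1:3) {
    if (t > 1) {
      w <- pr$feedback[[t - 1]][["win"]]
      l <- pr$feedback[[t - 1]][["loss"]]
      if (model == "EV") {
        v <- (1 - 0.5) * w - 0.5 * l                       # w = 0.5
        ev[last_k] <- (1 - 0.5) * ev[last_k] + 0.5 * v     # a = 0.5
      } else if (model == "EV-PU") {
        x <- w - l
        u <- if (x >= 0) x^0.5 else -2 * abs(x)^0.5        # alpha .5, lambda 2
        ev[last_k] <- (1 - 0.5) * ev[last_k] + 0.5 * u     # A = 0.5
      } else if (model == "PVL") {
        x <- w - l
        u <- if (x >= 0) x^0.5 else -2 * abs(x)^0.5
        ev <- 0.5 * ev
        ev[last_k] <- ev[last_k] + u
      } else if (model == "PVL-2") {
        u <- w^0.5 - 2 * l^0.5
        ev <- 0.5 * ev
        ev[last_k] <- ev[last_k] + u
      }
    }
    theta <- switch(model,
      "EV" = (t / 10)^0,       # c = 0
      "EV-PU" = (t / 10)^1,    # c = 1, round-dependent schedule
      "PVL" = 3^1 - 1,         # c = 1
      "PVL-2" = 3^1 - 1)
    z <- theta * ev
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
    k <- which(pr$u_choice[t] <= cumsum(p))[1]
    out[[t]] <- list(ev = ev, p = p, k = k)
    last_k <- k
  }
  out
}

trace_params <- function(model) {
  if (model == "EV") c(a = 0.5, w = 0.5, c = 0)
  else c(alpha = 0.5, lambda = 2, A = 0.5, c = 1)
}

# Same protocol executed through the package's dispatch surface.
package_trace <- function(model) {
  pr <- trace_protocol()
  ev <- rep(50, 10)
  par <- as_model_params(model, trace_params(model))
  out <- vector("list", 3)
  last_k <- NA
  for (t in 1:3) {
    if (t > 1) {
      fb <- pr$feedback[[t - 1]]
      sc <- list(win = fb[["win"]], loss = fb[["loss"]],
                 net_x = fb[["win"]] - fb[["loss"]])
      u <- model_utility(model, par, sc)
      ev <- update_expectancies(model, par, ev, last_k, u)
    }
    p <- choice_probabilities(model, par, ev, t)
    theta <- if (model %in% c("EV", "EV-PU")) ev_theta(t, par[["c"]])
             else pvl_theta(par[["c"]])
    k <- softmax_choose(ev, theta, u = pr$u_choice[t])
    out[[t]] <- list(ev = ev, p = p, k = k)
    last_k <- k
  }
  out
}

# --- compositional simulator ---------------------------------------------
# Rebuilds a full trajectory through agent_act() + step_round(); used to
# check that the flat simulate_participant() loop is bit-identical to the
# documented per-round composition.

compositional_simulate <- function(model_id, params, config, seed) {
  set.seed(seed)
  ev <- rep(50, 10)
  state <- new_ils_state(config)
  fb <- NULL
  last_k <- NA_integer_
  ratios <- numeric(config$n_rounds)
  for (t in seq_len(config$n_rounds)) {
    act <- agent_act(model_id, params, ev, t, fb, last_k,
                     scale_divisor = config$scale_divisor)
    ev <- act$expectancies
    stp <- step_round(state, act$ratio, config)
    state <- stp$state
    fb <- stp$feedback
    last_k <- act$option
    ratios[t] <- act$ratio
  }
  ratios
}

zero_damage_config <- function(...) {
  ils_config(condition_id = "nodamage", p_property_damage = 0,
             p_injury = 0, p_fatality = 0, ...)
}
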