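#' Genetic-algorithm calibration of model parameters
#'
#' Each model's free parameters are fitted to a cohort's mean
#' investment-ratio trajectory by minimising `SSD1 + (1 - R^2)` with a
#' real-coded genetic algorithm: population 20, crossover rate 0.80,
#' mutation rate 0.01, stopping when the average relative change of the
#' best objective over 50 stall generations falls below 1e-8 (or at the
#' generation cap). Because the objective involves simulation, candidate
#' evaluation uses common random numbers: a fixed bank of per-participant
#' seeds (derived from the calibration seed, shared by every candidate)
#' and averaging over seed replicates, which makes the objective a
#' deterministic function of the parameters and keeps the search
#' well-posed.
#'
#' @name calibration
#' @keywords internal
NULL

#' Genetic-algorithm settings
#'
#' @param population_size Number of individuals per generation (default 20).
#' @param crossover_rate Probability a selected pair is recombined
#'   (default 0.80).
#' @param mutation_rate Per-gene mutation probability (default 0.01).
#' @param stall_generations Window for the stall stopping rule (default 50).
#' @param function_tolerance Threshold on the average relative change of
#'   the best objective over the stall window (default 1e-8).
#' @param max_generations Hard cap on generations (default 500).
#' @param n_sim_participants Simulated participants per objective
#'   evaluation; set to the human cohort size of the condition.
#' @param n_objective_replicates Seed replicates averaged per evaluation
#'   (default 5).
#' @param seed Integer seed controlling both the GA stream and the common
#'   random numbers of the objective.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L,
                      crossover_rate = 0.80,
                      mutation_rate = 0.01,
                      stall_generations = 50L,
                      function_tolerance = 1e-8,
                      max_generations = 500L,
                      n_sim_participants = 23L,
                      n_objective_replicates = 5L,
                      seed = 1L) {
  stopifnot(population_size >= 2L,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            function_tolerance > 0,
            max_generations >= 1L,
            n_sim_participants >= 1L,
            n_objective_replicates >= 1L)
  structure(
    list(population_size = as.integer(population_size),
         crossover_rate = crossover_rate,
         mutation_rate = mutation_rate,
         stall_generations = as.integer(stall_generations),
         function_tolerance = function_tolerance,
         max_generations = as.integer(max_generations),
         n_sim_participants = as.integer(n_sim_participants),
         n_objective_replicates = as.integer(n_objective_replicates),
         seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Cohort mean trajectory
#'
#' @param cohort An `ils_cohort` or a participants-by-rounds ratio matrix.
#' @return Mean investment ratio per round (length `n_rounds`).
#' @export
mean_trajectory <- function(cohort) {
  m <- if (inherits(cohort, "ils_cohort")) cohort$ratios else cohort
  if (is.null(dim(m)) || nrow(m) == 0L) {
    stop("cohort is empty", call. = FALSE)
  }
  colMeans(m)
}

# Seed bank shared by all candidates of one calibration (common random
# numbers): one seed per replicate x participant.
objective_seed_bank <- function(ga_config) {
  set.seed(ga_config$seed)
  matrix(sample.int(2147483646L,
                    ga_config$n_objective_replicates *
                      ga_config$n_sim_participants),
         nrow = ga_config$n_objective_replicates)
}

# Evaluate a candidate and also return its fit statistics.
objective_full <- function(model_id, params, ils_config, target_mean_curve,
                           ga_config, seed_bank = NULL) {
  rng_state <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(rng_state)) {
    assign(".Random.seed", rng_state, globalenv())
  })
  if (is.null(seed_bank)) seed_bank <- objective_seed_bank(ga_config)
  n_rep <- nrow(seed_bank)
  acc <- numeric(ils_config$n_rounds)
  grand <- 0
  for (r in seq_len(n_rep)) {
    m <- sim_cohort_ratios(model_id, params, ils_config, seed_bank[r, ])
    acc <- acc + colMeans(m)
    grand <- grand + mean(m)
  }
  model_curve <- acc / n_rep
  s1 <- ssd1(model_curve, target_mean_curve)
  r2 <- r_squared(model_curve, target_mean_curve)
  list(objective = s1 + (1 - r2), ssd1 = s1, r_squared = r2,
       model_curve = model_curve, model_grand_mean = grand / n_rep)
}

#' Calibration objective for one candidate parameter vector
#'
#' Simulates `n_sim_participants` agents under the candidate parameters,
#' averaged over `n_objective_replicates` seeded replicates, and returns
#' `SSD1 + (1 - R^2)` of the simulated mean curve against the target. The
#' same seed bank is used for every candidate, so the value is
#' deterministic given `(params, ga_config$seed)`; the ambient RNG state
#' is left untouched.
#'
#' @param model_id Model identifier.
#' @param params Candidate parameter vector (within [model_bounds()]).
#' @param ils_config Condition configuration.
#' @param target_mean_curve Target mean curve (length `n_rounds`).
#' @param ga_config A [ga_config()].
#' @return The objective value (non-negative scalar).
#' @export
objective <- function(model_id, params, ils_config, target_mean_curve,
                      ga_config) {
  model_id <- match.arg(model_id, MODEL_IDS)
  params <- as_model_params(model_id, params)
  objective_full(model_id, params, ils_config, target_mean_curve,
                 ga_config)$objective
}

make_fit <- function(model_id, params, ofull, ga_config, ils_config,
                     target_mean_curve, generations_run, history) {
  p <- model_n_params(model_id)
  a2 <- ssd2_aic2(min(1, max(0, ofull$model_grand_mean)),
                  mean(target_mean_curve), p)
  structure(
    list(model_id = model_id,
         condition_id = ils_config$condition_id,
         params = params,
         objective = ofull$objective,
         ssd1 = ofull$ssd1,
         r_squared = ofull$r_squared,
         aic1 = aic1(ofull$ssd1, p, ils_config$n_rounds),
         aic2 = a2$aic2,
         ssd2 = a2$ssd2,
         model_grand_mean = ofull$model_grand_mean,
         model_curve = ofull$model_curve,
         p_free_params = p,
         generations_run = generations_run,
         best_history = history,
         seed = ga_config$seed),
    class = "ils_fit"
  )
}

#' @export
print.ils_fit <- function(x, ...) {
  cat(sprintf("<ils_fit> %s / %s  objective %.6f\n", x$model_id,
              x$condition_id, x$objective))
  if (length(x$params)) {
    cat("  params:", paste(sprintf("%s = %.4f", names(x$params), x$params),
                           collapse = ", "), "\n")
  }
  cat(sprintf("  ssd1 %.5f  R^2 %.4f  AIC1 %.2f  AIC2 %.2f  (%d generations)\n",
              x$ssd1, x$r_squared, x$aic1, x$aic2, x$generations_run))
  invisible(x)
}

#' Calibrate a model to a target mean trajectory
#'
#' Real-coded genetic algorithm over the model's parameter box
#' ([model_bounds()]): tournament selection of size 2, per-gene arithmetic
#' crossover, Gaussian mutation with standard deviation 10% of each
#' parameter's range and reflection at the bounds, and one elite carried
#' over per generation, so the best objective is non-increasing. The random
#' model has no parameters and is evaluated directly.
#'
#' @inheritParams objective
#' @param bounds Optional list with `lower` and `upper` named vectors;
#'   defaults to [model_bounds()] for the model.
#' @return A `ils_fit` object: fitted parameters, objective, SSD1, R^2,
#'   AIC1, AIC2, generations run, and the per-generation best-objective
#'   history.
#' @export
genetic_calibrate <- function(model_id, ils_config, target_mean_curve,
                              ga_config, bounds = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (is.null(bounds)) bounds <- model_bounds(model_id)
  lo <- bounds$lower
  hi <- bounds$upper
  if (length(lo) != length(hi) || any(hi < lo)) {
    stop("invalid bounds: `upper` must dominate `lower`", call. = FALSE)
  }
  seed_bank <- objective_seed_bank(ga_config)
  evalf <- function(par) {
    names(par) <- names(lo)
    objective_full(model_id, par, ils_config, target_mean_curve, ga_config,
                   seed_bank)
  }

  if (length(lo) == 0L) {  # random model: zero-dimensional search
    of <- evalf(numeric(0))
    return(make_fit(model_id, numeric(0), of, ga_config, ils_config,
                    target_mean_curve, 0L, of$objective))
  }

  d <- length(lo)
  rng <- hi - lo
  set.seed(ga_config$seed)
  np <- ga_config$population_size
  pop <- matrix(stats::runif(np * d, rep(lo, each = np),
                             rep(hi, each = np)), nrow = np)
  fit <- apply(pop, 1, function(p) evalf(p)$objective)

  best_hist <- numeric(ga_config$max_generations + 1L)
  best_hist[1L] <- min(fit)
  gen <- 0L
  while (gen < ga_config$max_generations) {
    gen <- gen + 1L
    elite_i <- which.min(fit)
    newpop <- matrix(0, np, d)
    newpop[1L, ] <- pop[elite_i, ]
    for (j in 2:np) {
      # tournament selection, size 2
      i1 <- sample.int(np, 2L)
      p1 <- pop[i1[which.min(fit[i1])], ]
      i2 <- sample.int(np, 2L)
      p2 <- pop[i2[which.min(fit[i2])], ]
      child <- if (stats::runif(1) < ga_config$crossover_rate) {
        b <- stats::runif(d)
        b * p1 + (1 - b) * p2
      } else {
        p1
      }
      mut <- stats::runif(d) < ga_config$mutation_rate
      if (any(mut)) {
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, 0.1 * rng[mut])
        # reflect into the box (twice covers any overshoot at these sds)
        for (rep_i in 1:2) {
          over <- child > hi
          child[over] <- 2 * hi[over] - child[over]
          under <- child < lo
          child[under] <- 2 * lo[under] - child[under]
        }
        child <- pmin(hi, pmax(lo, child))
      }
      newpop[j, ] <- child
    }
    pop <- newpop
    fit[1L] <- fit[elite_i]
    fit[2:np] <- apply(pop[2:np, , drop = FALSE], 1,
                       function(p) evalf(p)$objective)
    best_hist[gen + 1L] <- min(fit)

    if (gen >= ga_config$stall_generations) {
      window <- best_hist[(gen + 1L - ga_config$stall_generations):(gen + 1L)]
      denom <- abs(window[1L])
      rel <- if (denom > 0) {
        mean(abs(diff(window))) / denom
      } else {
        mean(abs(diff(window)))
      }
      if (rel < ga_config$function_tolerance) break
    }
  }

  best_i <- which.min(fit)
  best <- pop[best_i, ]
  names(best) <- names(lo)
  of <- evalf(best)
  make_fit(model_id, best, of, ga_config, ils_config, target_mean_curve,
           gen, best_hist[seq_len(gen + 1L)])
}
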