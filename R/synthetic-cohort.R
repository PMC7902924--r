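#' Synthetic cohorts of investment trajectories
#'
#' The calibration and generalization analyses need cohort trajectory data:
#' per-participant, per-round investment ratios for one condition. This
#' module generates such cohorts in two modes. `model_ground_truth` runs
#' model agents through the microworld, giving data whose generating process
#' is known exactly (used for parameter recovery). `stylized_human` draws
#' noisy trajectories around a target mean curve emulating the qualitative
#' pattern of human cohorts: a flat, low curve in the low damage-feedback
#' condition (overall mean 0.38), a rising, high curve in the high condition
#' (overall mean 0.67), and an intermediate flat curve in the medium
#' condition. Stylized cohorts are synthetic stand-ins; they carry no claim
#' about individual human behavior.
#'
#' @name synthetic_cohort
#' @keywords internal
NULL

#' Specification of one synthetic cohort
#'
#' @param condition_id `"low"`, `"high"` or `"medium"`.
#' @param generator_mode `"model_ground_truth"` or `"stylized_human"`.
#' @param seed Integer seed; every trajectory is reproducible from it.
#' @param n_participants Cohort size; defaults to the condition's study
#'   size (low 20, high 23, medium 30).
#' @param n_rounds Number of rounds (default 30).
#' @param model_id,params Generating model and parameters (ground-truth
#'   mode).
#' @param target_mean_curve Target mean curve of length `n_rounds`
#'   (stylized mode); defaults to [stylized_target_curve()] for the
#'   condition.
#' @param noise_sd Standard deviation of the per-round Gaussian noise
#'   around the target curve (stylized mode), before clipping to `[0,1]`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(condition_id = c("low", "high", "medium"),
                        generator_mode = c("stylized_human",
                                           "model_ground_truth"),
                        seed = 1L,
                        n_participants = NULL,
                        n_rounds = 30L,
                        model_id = NULL,
                        params = NULL,
                        target_mean_curve = NULL,
                        noise_sd = 0.15) {
  condition_id <- match.arg(condition_id)
  generator_mode <- match.arg(generator_mode)
  if (is.null(n_participants)) {
    n_participants <- switch(condition_id, low = 20L, high = 23L,
                             medium = 30L)
  }
  if (generator_mode == "model_ground_truth") {
    if (is.null(model_id)) {
      stop("`model_id` is required for model_ground_truth mode",
           call. = FALSE)
    }
    model_id <- match.arg(model_id, MODEL_IDS)
    params <- as_model_params(model_id, params)
  } else {
    if (is.null(target_mean_curve)) {
      target_mean_curve <- stylized_target_curve(condition_id, n_rounds)
    }
    if (length(target_mean_curve) != n_rounds) {
      stop("`target_mean_curve` must have length `n_rounds`", call. = FALSE)
    }
    if (any(target_mean_curve < 0) || any(target_mean_curve > 1)) {
      stop("`target_mean_curve` values must lie in [0, 1]", call. = FALSE)
    }
    if (is.na(noise_sd) || noise_sd < 0) {
      stop("`noise_sd` must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(condition_id = condition_id, generator_mode = generator_mode,
         seed = as.integer(seed), n_participants = as.integer(n_participants),
         n_rounds = as.integer(n_rounds), model_id = model_id,
         params = params, target_mean_curve = target_mean_curve,
         noise_sd = noise_sd),
    class = "cohort_spec"
  )
}

#' Default stylized target mean curves
#'
#' `low`: constant 0.38. `medium`: constant 0.52 (midway between the low
#' and high overall means). `high`: a logistic rise from 0.30 toward 0.85
#' with slope scale 3 rounds, whose midpoint is solved so the 30-round mean
#' is exactly 0.67 — flat curves match the near-flat low-condition pattern,
#' and the logistic encodes the rapid increase seen under high damage
#' feedback.
#'
#' @param condition_id `"low"`, `"high"` or `"medium"`.
#' @param n_rounds Curve length.
#' @return Numeric vector of length `n_rounds` with values in `[0,1]`.
#' @export
stylized_target_curve <- function(condition_id = c("low", "high", "medium"),
                                  n_rounds = 30L) {
  condition_id <- match.arg(condition_id)
  t <- seq_len(n_rounds)
  switch(condition_id,
    low = rep(0.38, n_rounds),
    medium = rep(0.52, n_rounds),
    high = {
      target_mean <- 0.67
      curve_at <- function(t0) 0.3 + 0.55 / (1 + exp(-(t - t0) / 3))
      t0 <- stats::uniroot(function(t0) mean(curve_at(t0)) - target_mean,
                           c(-n_rounds, 2 * n_rounds), tol = 1e-12)$root
      curve_at(t0)
    }
  )
}

new_cohort <- function(ratios, events, condition_id, generator_mode, seed) {
  structure(
    list(ratios = ratios, events = events, condition_id = condition_id,
         generator_mode = generator_mode, seed = seed),
    class = "ils_cohort"
  )
}

#' @export
print.ils_cohort <- function(x, ...) {
  cat(sprintf("<ils_cohort> %s / %s: %d participants x %d rounds, seed %d\n",
              x$condition_id, x$generator_mode, nrow(x$ratios),
              ncol(x$ratios), x$seed))
  cat(sprintf("  overall mean investment ratio: %.3f\n", mean(x$ratios)))
  invisible(x)
}

#' Generate a cohort from model agents (ground truth known)
#'
#' Runs `spec$n_participants` independent agents of the specified model
#' through the microworld; each participant has its own RNG stream derived
#' from the cohort seed.
#'
#' @param spec A [cohort_spec()] with `generator_mode = "model_ground_truth"`.
#' @param ils_config An [ils_config()]; its `n_rounds` is overridden by the
#'   spec when they disagree.
#' @return An `ils_cohort`: a participants-by-rounds ratio matrix plus a
#'   per-round event log (incomes, wealth, damage flags, rewards, losses).
#' @export
generate_model_cohort <- function(spec, ils_config) {
  if (spec$generator_mode != "model_ground_truth") {
    stop("`spec` must have generator_mode = \"model_ground_truth\"",
         call. = FALSE)
  }
  if (ils_config$n_rounds != spec$n_rounds) {
    ils_config$n_rounds <- spec$n_rounds
  }
  seeds <- participant_seeds(spec$seed, spec$n_participants)
  logs <- vector("list", spec$n_participants)
  ratios <- matrix(0, spec$n_participants, spec$n_rounds)
  for (i in seq_len(spec$n_participants)) {
    log_i <- simulate_participant(spec$model_id, spec$params, ils_config,
                                  seeds[i], full_log = TRUE)
    ratios[i, ] <- log_i$investment_ratio
    logs[[i]] <- cbind(participant_id = i, log_i)
  }
  new_cohort(ratios, do.call(rbind, logs), spec$condition_id,
             spec$generator_mode, spec$seed)
}

#' Generate a stylized human-like cohort
#'
#' Each participant's trajectory is the target mean curve plus independent
#' Gaussian noise per round, clipped to `[0,1]`. With `noise_sd = 0` every
#' participant equals the target exactly.
#'
#' @param spec A [cohort_spec()] with `generator_mode = "stylized_human"`.
#' @return An `ils_cohort` (no environment event log: the generator mimics
#'   only the behavioral ratios).
#' @export
generate_stylized_human_cohort <- function(spec) {
  if (spec$generator_mode != "stylized_human") {
    stop("`spec` must have generator_mode = \"stylized_human\"",
         call. = FALSE)
  }
  seeds <- participant_seeds(spec$seed, spec$n_participants)
  ratios <- matrix(0, spec$n_participants, spec$n_rounds)
  for (i in seq_len(spec$n_participants)) {
    set.seed(seeds[i])
    x <- spec$target_mean_curve + stats::rnorm(spec$n_rounds, 0,
                                               spec$noise_sd)
    ratios[i, ] <- pmin(1, pmax(0, x))
  }
  new_cohort(ratios, NULL, spec$condition_id, spec$generator_mode,
             spec$seed)
}

#' Generate a cohort from its spec
#'
#' Dispatches to [generate_model_cohort()] or
#' [generate_stylized_human_cohort()] according to the spec's mode.
#'
#' @inheritParams generate_model_cohort
#' @return An `ils_cohort`.
#' @export
generate_cohort <- function(spec, ils_config = NULL) {
  if (spec$generator_mode == "model_ground_truth") {
    if (is.null(ils_config)) ils_config <- load_condition(spec$condition_id)
    generate_model_cohort(spec, ils_config)
  } else {
    generate_stylized_human_cohort(spec)
  }
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write and read cohort trajectories as CSV
#'
#' One row per participant-round with columns `participant_id`, `round`,
#' `investment_ratio`, `income`, `property_wealth`, `occurred`,
#' `property_damage`, `injury`, `fatality`, `W`, `L`. Stylized cohorts have
#' no environment log and write `NA` in the environment columns. Ratios are
#' written with 17 significant digits so a write/read round trip reproduces
#' the matrix exactly.
#'
#' @param cohort An `ils_cohort`.
#' @param path File path.
#' @return `write_cohort()`: the path, invisibly. `read_cohort()`: an
#'   `ils_cohort` (generator metadata is not stored in the CSV; the seed is
#'   recorded as `NA`).
#' @export
write_cohort <- function(cohort, path) {
  n_p <- nrow(cohort$ratios)
  n_r <- ncol(cohort$ratios)
  if (is.null(cohort$events)) {
    df <- data.frame(
      participant_id = rep(seq_len(n_p), each = n_r),
      round = rep(seq_len(n_r), n_p),
      investment_ratio = as.vector(t(cohort$ratios)),
      income = NA_real_, property_wealth = NA_real_,
      occurred = NA, property_damage = NA, injury = NA, fatality = NA,
      W = NA_real_, L = NA_real_
    )
  } else {
    df <- cohort$events[c("participant_id", "round", "investment_ratio",
                          "income", "property_wealth", "occurred",
                          "property_damage", "injury", "fatality", "W", "L")]
  }
  num_cols <- c("investment_ratio", "income", "property_wealth", "W", "L")
  out <- df
  for (cl in num_cols) {
    out[[cl]] <- ifelse(is.na(df[[cl]]), "NA", fmt_num(df[[cl]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param condition_id Condition label to attach to the cohort read back.
#' @export
read_cohort <- function(path, condition_id = "unknown") {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse cohort file '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  needed <- c("participant_id", "round", "investment_ratio")
  missing <- setdiff(needed, names(df))
  if (nrow(df) == 0L || length(missing) > 0L) {
    stop(sprintf("malformed cohort file '%s': missing %s", path,
                 if (nrow(df) == 0L) "data rows"
                 else paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(is.na(df$investment_ratio) | df$investment_ratio < 0 |
                 df$investment_ratio > 1)
  if (length(bad) > 0L) {
    b <- bad[1]
    stop(sprintf(
      "invalid investment_ratio %s at row %d (participant %s, round %s)",
      format(df$investment_ratio[b]), b, df$participant_id[b], df$round[b]),
      call. = FALSE)
  }
  ids <- sort(unique(df$participant_id))
  rounds <- sort(unique(df$round))
  ratios <- matrix(NA_real_, length(ids), length(rounds))
  ratios[cbind(match(df$participant_id, ids), match(df$round, rounds))] <-
    df$investment_ratio
  if (anyNA(ratios)) {
    stop(sprintf("cohort file '%s' is not a complete participant x round grid",
                 path), call. = FALSE)
  }
  events <- if (all(is.na(df$income))) NULL else df
  new_cohort(ratios, events, condition_id, "file", NA_integer_)
}
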