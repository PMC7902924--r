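#' Goodness-of-fit and model-comparison statistics
#'
#' Model performance is judged on cohort mean investment-ratio curves. Two
#' error layers are used: per-round (SSD1, the mean over rounds of the
#' squared difference between the model and human mean curves, and R^2, the
#' squared Pearson correlation between the two curves) and grand-mean
#' (SSD2, the squared difference of the means over both participants and
#' rounds). Each layer carries an OLS-style Akaike Information Criterion,
#' `AIC1 = T * ln(SSD1) + 2p` and `AIC2 = ln(SSD2) + 2p`, with `p` the
#' number of free parameters; smaller (more negative) is better.
#'
#' @name evaluation
#' @keywords internal
NULL

#' Per-round mean squared deviation between two mean curves
#'
#' @param model_curve,human_curve Equal-length mean investment-ratio
#'   curves.
#' @return `mean((model_curve - human_curve)^2)`.
#' @export
ssd1 <- function(model_curve, human_curve) {
  if (length(model_curve) != length(human_curve)) {
    stop("curves must have equal length", call. = FALSE)
  }
  mean((model_curve - human_curve)^2)
}

#' Squared Pearson correlation between two mean curves
#'
#' Measures trend agreement; it is invariant under positive affine
#' transforms of either curve (and, being squared, also rewards a perfect
#' anti-trend — a property of the statistic that is kept as defined). When
#' either curve has zero variance the correlation is undefined; the
#' degenerate rule returns 1 if the curves are essentially identical
#' (SSD1 below 1e-12) and 0 otherwise, keeping the calibration objective
#' continuous for constant curves.
#'
#' @inheritParams ssd1
#' @return A value in `[0, 1]`.
#' @export
r_squared <- function(model_curve, human_curve) {
  if (length(model_curve) != length(human_curve)) {
    stop("curves must have equal length", call. = FALSE)
  }
  if (stats::var(model_curve) == 0 || stats::var(human_curve) == 0) {
    return(if (ssd1(model_curve, human_curve) < 1e-12) 1 else 0)
  }
  stats::cor(model_curve, human_curve)^2
}

#' Per-round AIC from SSD1
#'
#' @param ssd1 Per-round mean squared deviation (positive).
#' @param p Number of free parameters.
#' @param n_rounds Round count `T` multiplying the log error term
#'   (default 30).
#' @return `n_rounds * log(ssd1) + 2 * p`; `-Inf` (with a warning) when
#'   `ssd1` is exactly 0.
#' @export
aic1 <- function(ssd1, p, n_rounds = 30L) {
  if (ssd1 < 0) stop("`ssd1` must be non-negative", call. = FALSE)
  if (ssd1 == 0) {
    warning("ssd1 is exactly 0; AIC1 reported as -Inf")
    return(-Inf)
  }
  n_rounds * log(ssd1) + 2 * p
}

#' Grand-mean squared deviation and its AIC
#'
#' Compares the investment ratio averaged over both participants and
#' rounds.
#'
#' @param model_grand_mean,human_grand_mean Grand-mean investment ratios in
#'   `[0, 1]`.
#' @param p Number of free parameters.
#' @return A list with `ssd2 = (model - human)^2` and
#'   `aic2 = log(ssd2) + 2p` (`-Inf` with a warning when `ssd2` is 0).
#' @export
ssd2_aic2 <- function(model_grand_mean, human_grand_mean, p) {
  means <- c(model_grand_mean, human_grand_mean)
  if (any(is.na(means)) || any(means < 0) || any(means > 1)) {
    stop("grand means must lie in [0, 1]", call. = FALSE)
  }
  ssd2 <- (model_grand_mean - human_grand_mean)^2
  if (ssd2 == 0) {
    warning("ssd2 is exactly 0; AIC2 reported as -Inf")
    return(list(ssd2 = 0, aic2 = -Inf))
  }
  list(ssd2 = ssd2, aic2 = log(ssd2) + 2 * p)
}

#' Block means of a round curve
#'
#' Averages consecutive blocks of five rounds (a 30-round curve gives six
#' blocks), the aggregation used when plotting learning curves.
#'
#' @param curve Numeric vector whose length is divisible by 5.
#' @param block_size Rounds per block.
#' @return Numeric vector of block means.
#' @export
block_means <- function(curve, block_size = 5L) {
  n <- length(curve)
  if (n == 0L || n %% block_size != 0L) {
    stop(sprintf("curve length (%d) must be a positive multiple of %d",
                 n, block_size), call. = FALSE)
  }
  as.vector(tapply(curve, rep(seq_len(n / block_size), each = block_size),
                   mean))
}

#' Model-comparison table for one condition
#'
#' Assembles per-model rows of SSD1, R^2, AIC1 and AIC2 against a human
#' (or reference) cohort mean curve, sorted by AIC1 ascending. Each row's
#' AIC values are recomputable from its stored SSD values and parameter
#' count.
#'
#' @param fits List of fit results from [genetic_calibrate()] (or any list
#'   with fields `model_id`, `ssd1`, `r_squared`, `aic1`, `aic2`,
#'   `model_grand_mean`).
#' @param condition_id Condition label attached to every row.
#' @return A `data.frame` with columns `model_id`, `condition_id`, `ssd1`,
#'   `r_squared`, `aic1`, `aic2`, `p_free_params`.
#' @export
comparison_table <- function(fits, condition_id = NULL) {
  rows <- lapply(fits, function(f) {
    data.frame(
      model_id = f$model_id,
      condition_id = if (is.null(condition_id)) f$condition_id
                     else condition_id,
      ssd1 = f$ssd1,
      r_squared = f$r_squared,
      aic1 = f$aic1,
      aic2 = f$aic2,
      p_free_params = model_n_params(f$model_id),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$aic1), , drop = FALSE]
}
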