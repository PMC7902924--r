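#' End-to-end calibration and generalization workflow
#'
#' The full analysis has three stages. (1) Calibration: for the low and
#' high damage-feedback conditions, fit all five decision models to the
#' cohort mean trajectory and tabulate SSD1, R^2, AIC1 and AIC2.
#' (2) Generalization: simulate every model in the medium condition twice,
#' once with its low-calibrated and once with its high-calibrated
#' parameters, with no refitting, and tabulate against the medium cohort.
#' (3) Reporting: a plain-text summary of rankings, fitted parameters and
#' seeds. A run manifest pins every seed, so re-running a manifest
#' reproduces identical numeric outputs.
#'
#' @name pipeline
#' @keywords internal
NULL

#' Create a run manifest
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Master integer seed; condition- and stage-specific seeds are
#'   derived from it deterministically.
#' @param profile `"smoke"` (generation cap 30 — desk-scale runs) or
#'   `"full"` (generation cap 500). Both use population 20, crossover 0.80,
#'   mutation 0.01, stall window 50, tolerance 1e-8 and 5 objective
#'   replicates.
#' @param models Model identifiers to run (default all five).
#' @param conditions Calibration conditions (default `c("low", "high")`).
#' @param generalization_condition Held-out condition (default `"medium"`).
#' @param cohort_mode Generator for the cohorts (`"stylized_human"` by
#'   default; `"model_ground_truth"` requires `cohort_model` and
#'   `cohort_params`).
#' @param cohort_model,cohort_params Generating model for ground-truth
#'   cohorts.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(out_dir,
                         seed = 1L,
                         profile = c("smoke", "full"),
                         models = model_ids(),
                         conditions = c("low", "high"),
                         generalization_condition = "medium",
                         cohort_mode = "stylized_human",
                         cohort_model = NULL,
                         cohort_params = NULL) {
  profile <- match.arg(profile)
  models <- match.arg(models, model_ids(), several.ok = TRUE)
  structure(
    list(out_dir = out_dir,
         seed = as.integer(seed),
         profile = profile,
         models = models,
         conditions = conditions,
         generalization_condition = generalization_condition,
         cohort_mode = cohort_mode,
         cohort_model = cohort_model,
         cohort_params = cohort_params,
         version = as.character(utils::packageVersion("ilsRL")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

profile_ga <- function(manifest, n_sim_participants, seed) {
  ga_config(
    max_generations = if (manifest$profile == "smoke") 30L else 500L,
    n_sim_participants = n_sim_participants,
    n_objective_replicates = 5L,
    seed = seed
  )
}

# Deterministic per-stage seeds derived from the master seed.
stage_seed <- function(master, stage, item) {
  set.seed(master)
  offsets <- sample.int(2147483646L, 64L)
  idx <- (match(stage, c("cohort", "calibrate", "generalize")) - 1L) * 16L +
    (match(item, c("low", "high", "medium", "extra")) %% 16L) + 1L
  offsets[idx]
}

manifest_cohort <- function(manifest, condition) {
  seed <- stage_seed(manifest$seed, "cohort", condition)
  if (manifest$cohort_mode == "stylized_human") {
    generate_stylized_human_cohort(
      cohort_spec(condition, "stylized_human", seed = seed))
  } else {
    generate_model_cohort(
      cohort_spec(condition, "model_ground_truth", seed = seed,
                  model_id = manifest$cohort_model,
                  params = manifest$cohort_params),
      load_condition(condition))
  }
}

write_table <- function(tab, path_stem) {
  utils::write.csv(tab, paste0(path_stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(tab, paste0(path_stem, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
}

fit_to_json <- function(fit, path) {
  jsonlite::write_json(
    list(model_id = fit$model_id, condition_id = fit$condition_id,
         params = as.list(fit$params), objective = fit$objective,
         ssd1 = fit$ssd1, r_squared = fit$r_squared, aic1 = fit$aic1,
         aic2 = fit$aic2, generations_run = fit$generations_run,
         seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
}

#' Run the calibration stage
#'
#' Generates (or accepts) cohorts for each calibration condition, fits
#' every model in the manifest, and writes per-condition comparison tables
#' (CSV and JSON), block-mean curves, cohort CSVs and per-fit JSON files
#' under the manifest's output directory.
#'
#' @param manifest A [run_manifest()].
#' @param cohorts Optional named list of `ils_cohort` objects keyed by
#'   condition; missing entries are generated from the manifest.
#' @return Invisibly, a list with `fits` (nested by condition then model),
#'   `tables`, and `cohorts`.
#' @export
run_calibration_experiment <- function(manifest, cohorts = NULL) {
  dir.create(file.path(manifest$out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(manifest$out_dir, "fits"), showWarnings = FALSE)
  dir.create(file.path(manifest$out_dir, "cohorts"), showWarnings = FALSE)
  dir.create(file.path(manifest$out_dir, "curves"), showWarnings = FALSE)

  fits <- list()
  tables <- list()
  out_cohorts <- list()
  for (cond in manifest$conditions) {
    cohort <- if (!is.null(cohorts) && !is.null(cohorts[[cond]])) {
      cohorts[[cond]]
    } else {
      manifest_cohort(manifest, cond)
    }
    out_cohorts[[cond]] <- cohort
    write_cohort(cohort,
                 file.path(manifest$out_dir, "cohorts",
                           paste0(cond, ".csv")))
    cfg <- load_condition(cond)
    target <- mean_trajectory(cohort)
    ga <- profile_ga(manifest, nrow(cohort$ratios),
                     stage_seed(manifest$seed, "calibrate", cond))
    cond_fits <- list()
    curves <- data.frame(block = seq_len(length(target) %/% 5L),
                         human = block_means(target))
    for (m in manifest$models) {
      message(sprintf("calibrating %s / %s ...", m, cond))
      f <- genetic_calibrate(m, cfg, target, ga)
      cond_fits[[m]] <- f
      curves[[m]] <- block_means(f$model_curve)
      fit_to_json(f, file.path(manifest$out_dir, "fits",
                               paste0(cond, "_", gsub("-", "", m),
                                      ".json")))
    }
    fits[[cond]] <- cond_fits
    tab <- comparison_table(cond_fits, cond)
    tables[[cond]] <- tab
    write_table(tab, file.path(manifest$out_dir, "tables",
                               paste0("calibration_", cond)))
    utils::write.csv(curves,
                     file.path(manifest$out_dir, "curves",
                               paste0("blocks_", cond, ".csv")),
                     row.names = FALSE)
  }
  invisible(list(fits = fits, tables = tables, cohorts = out_cohorts))
}

#' Run the generalization stage
#'
#' Simulates every fitted model in the held-out condition with the
#' parameters frozen from each calibration condition (no refitting) and
#' tabulates performance against the held-out cohort. The random model has
#' no parameters, so its two provenance rows coincide.
#'
#' @param manifest A [run_manifest()].
#' @param fits Nested fit list from [run_calibration_experiment()].
#' @param cohort Optional `ils_cohort` for the held-out condition.
#' @return Invisibly, the generalization table (one row per model and
#'   parameter provenance).
#' @export
run_generalization <- function(manifest, fits, cohort = NULL) {
  cond <- manifest$generalization_condition
  if (is.null(cohort)) cohort <- manifest_cohort(manifest, cond)
  dir.create(file.path(manifest$out_dir, "tables"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(manifest$out_dir, "cohorts"), showWarnings = FALSE)
  write_cohort(cohort, file.path(manifest$out_dir, "cohorts",
                                 paste0(cond, ".csv")))
  cfg <- load_condition(cond)
  target <- mean_trajectory(cohort)
  ga <- profile_ga(manifest, nrow(cohort$ratios),
                   stage_seed(manifest$seed, "generalize", cond))

  rows <- list()
  for (prov in names(fits)) {
    for (m in names(fits[[prov]])) {
      of <- objective_full(m, fits[[prov]][[m]]$params, cfg, target, ga)
      p <- model_n_params(m)
      a2 <- ssd2_aic2(min(1, max(0, of$model_grand_mean)), mean(target), p)
      rows[[paste(m, prov)]] <- data.frame(
        model_id = m,
        condition_id = cond,
        params_from = prov,
        ssd1 = of$ssd1,
        r_squared = of$r_squared,
        aic1 = aic1(of$ssd1, p, cfg$n_rounds),
        aic2 = a2$aic2,
        p_free_params = p,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$params_from, tab$aic1), , drop = FALSE]
  rownames(tab) <- NULL
  write_table(tab, file.path(manifest$out_dir, "tables",
                             paste0("generalization_", cond)))
  invisible(tab)
}

#' Summarise a completed run
#'
#' @param manifest A [run_manifest()].
#' @return A character vector of report lines (also written to
#'   `report.md` in the output directory), or a "no results" message when
#'   the run directory holds no tables.
#' @export
report <- function(manifest) {
  tdir <- file.path(manifest$out_dir, "tables")
  tabs <- if (dir.exists(tdir)) {
    list.files(tdir, pattern = "\\.csv$", full.names = TRUE)
  } else {
    character(0)
  }
  if (length(tabs) == 0L) {
    msg <- "no results found in run directory"
    message(msg)
    return(invisible(msg))
  }
  lines <- c("# Model comparison run",
             sprintf("seed: %d, profile: %s, version: %s", manifest$seed,
                     manifest$profile, manifest$version), "")
  for (tp in tabs) {
    tab <- utils::read.csv(tp)
    lines <- c(lines, sprintf("## %s", sub("\\.csv$", "", basename(tp))), "")
    lines <- c(lines, utils::capture.output(print(tab, row.names = FALSE)),
               "")
  }
  fdir <- file.path(manifest$out_dir, "fits")
  if (dir.exists(fdir)) {
    lines <- c(lines, "## Calibrated parameters", "")
    for (fp in list.files(fdir, pattern = "\\.json$", full.names = TRUE)) {
      f <- jsonlite::read_json(fp, simplifyVector = TRUE)
      lines <- c(lines, sprintf(
        "- %s / %s: %s (objective %.6g, seed %d)", f$model_id,
        f$condition_id,
        if (length(f$params)) {
          paste(sprintf("%s = %s", names(f$params),
                        vapply(f$params, format, "")), collapse = ", ")
        } else "no parameters",
        f$objective, f$seed))
    }
  }
  writeLines(lines, file.path(manifest$out_dir, "report.md"))
  invisible(lines)
}
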