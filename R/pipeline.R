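config_error <- function(msg) {
  stop(errorCondition(msg, class = c("shoalmotion_config_error", "error")))
}
data_error <- function(msg) {
  stop(errorCondition(msg, class = c("shoalmotion_data_error", "error")))
}

default_candidates <- function(response, family = "gaussian",
                               transform = "none") {
  if (family == "beta") {
    # slope models are not fitted for the beta family (1-D random intercept
    # only); the comparison is intercept vs no random effect, both on AICc
    return(list(
      model_spec(response, transform, family, random_intercept = FALSE),
      model_spec(response, transform, family, random_intercept = TRUE)))
  }
  list(
    model_spec(response, transform, family, random_intercept = FALSE),
    model_spec(response, transform, family, random_intercept = TRUE),
    model_spec(response, transform, family, random_intercept = TRUE,
               random_slopes = "interval"),
    model_spec(response, transform, family, random_intercept = TRUE,
               random_slopes = "day"))
}

metric_model_plan <- function() {
  data.frame(
    response = c("polarization", "centroid_speed", "hull_area",
                 "transition_rate", "max_speed_xcorr",
                 "leadership_switch_rate"),
    transform = c("none", "none", "sqrt", "none", "none", "none"),
    family = c("gaussian", "gaussian", "gaussian", "gaussian", "gaussian",
               "beta"),
    stringsAsFactors = FALSE)
}

validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) config_error("config must be a YAML mapping")
  if (is.null(cfg$simulate) && is.null(cfg$input))
    config_error("config needs a `simulate:` or an `input:` section")
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$trajectories))
      config_error("`input:` needs a `trajectories:` CSV path")
    if (is.null(cfg$input$units))
      config_error("`input:` needs `units:` ('px' or 'mm')")
  }
  if (!is.null(cfg$fps) && cfg$fps <= 0) config_error("`fps` must be positive")
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates an end-to-end run: simulate (or read) trajectories,
#' preprocess, compute the six interval metrics, fit and compare the
#' candidate random-effect structures per metric, and — when the
#' best-supported model carries a random slope — evaluate the between-group
#' variance trend and per-group reaction norms. All outputs are CSV/JSON
#' files under `outdir`, and a run manifest records the config, seeds,
#' per-stage row counts and every dropped interval with its reason.
#'
#' @param config path to a YAML config file, or an equivalent list. Keys:
#'   `seed`; `simulate:` (n_groups, days, intervals, n_frames, plus any
#'   [school_sim_config()] field) or `input:` (trajectories CSV, units,
#'   px_per_mm); `fps`; `preprocess:` ([preprocess_config()] fields plus
#'   optional `windows`); `metrics:` ([metric_config()] fields);
#'   `models:` (`responses`, `bootstrap_reps`).
#' @param outdir output directory (created if missing); default from config,
#'   else `"shoalmotion-run"`.
#' @param seed overrides the config seed.
#' @return The run manifest (a list), invisibly; side effect: files
#'   `metrics.csv`, `model_comparison.csv`, `variance_trends.csv`,
#'   `reaction_norms.csv`, `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_pipeline_config(cfg)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  outdir <- outdir %||% cfg$outdir %||% "shoalmotion-run"
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fps <- cfg$fps %||% 25

  pp_args <- cfg$preprocess %||% list()
  windows <- pp_args$windows
  pp_args$windows <- NULL
  pcfg <- do.call(preprocess_config, pp_args)
  mcfg <- do.call(metric_config, cfg$metrics %||% list())

  manifest <- list(config = cfg, seed = seed,
                   package_version = as.character(utils::packageVersion("shoalmotion")),
                   stages = list())

  # ---- stage 1: acquire trajectories ----
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    sim_fields <- intersect(names(sim), names(formals(school_sim_config)))
    scfg <- do.call(school_sim_config,
                    c(sim[sim_fields], list(seed = seed, fps = fps)))
    days <- sim$days %||% seq_len(sim$n_days %||% 12L)
    intervals <- seq_len(sim$n_intervals %||% 5L)
    n_frames <- sim$n_frames %||% 1500L
    study <- simulate_study(scfg, days = days, intervals = intervals,
                            n_frames = n_frames)
    datasets <- study$datasets
    utils::write.csv(study$truth, file.path(outdir, "truth.csv"),
                     row.names = FALSE)
    px_per_mm <- 2.7
  } else {
    units <- cfg$input$units
    px_per_mm <- cfg$input$px_per_mm %||% NA_real_
    datasets <- tryCatch(
      read_trajectories(cfg$input$trajectories,
                        list(fps = fps, units = units, px_per_mm = px_per_mm)),
      error = function(e) data_error(conditionMessage(e)))
  }
  manifest$stages$input <- list(n_datasets = length(datasets))

  # ---- stage 2+3: preprocess and metrics ----
  blocks <- list()
  dropped <- data.frame()
  for (ds in datasets) {
    iv <- attr(ds, "interval_index")
    win <- if (!is.null(windows)) lapply(windows, unlist)
           else list(c(0, ds$n_frames / ds$fps))
    bl <- preprocess_trajectories(ds, pcfg, windows = win,
                                  px_per_mm = px_per_mm)
    dr <- attr(bl, "dropped")
    if (!is.null(iv)) {
      bl <- lapply(bl, function(b) { b$interval_index <- iv; b })
      if (nrow(dr)) dr$interval_index <- iv
    }
    if (nrow(dr)) {
      dr$group <- ds$group_id; dr$day <- ds$day; dr$trial <- ds$trial_id
      dropped <- rbind(dropped, dr)
    }
    blocks <- c(blocks, bl)
  }
  if (!length(blocks)) data_error("no interval passed quality control")
  mt <- metrics_table(blocks, mcfg)
  utils::write.csv(mt, file.path(outdir, "metrics.csv"), row.names = FALSE)
  manifest$stages$preprocess <- list(
    n_blocks = length(blocks),
    n_dropped_intervals = nrow(dropped),
    dropped = dropped)
  manifest$stages$metrics <- list(n_rows = nrow(mt),
                                  n_qc_ok = sum(mt$qc_ok))

  # ---- stage 4: models ----
  plan <- metric_model_plan()
  responses <- (cfg$models %||% list())$responses %||% plan$response
  plan <- plan[plan$response %in% responses, , drop = FALSE]
  nboot <- (cfg$models %||% list())$bootstrap_reps %||% 0
  comp_rows <- list(); var_rows <- list(); norm_rows <- list()
  model_notes <- list()
  for (r in seq_len(nrow(plan))) {
    resp <- plan$response[r]
    dat <- mt[is.finite(mt[[resp]]), , drop = FALSE]
    if (nrow(dat) < 10L || length(unique(dat$group)) < 2L) {
      model_notes[[resp]] <- "skipped: too few usable rows"
      next
    }
    cand <- default_candidates(resp, plan$family[r], plan$transform[r])
    tab <- tryCatch(compare_models(cand, dat),
                    error = function(e) e)
    if (inherits(tab, "error")) {
      model_notes[[resp]] <- paste("model comparison failed:",
                                   conditionMessage(tab))
      next
    }
    tab2 <- as.data.frame(tab)
    tab2 <- cbind(trait = resp, tab2)
    comp_rows[[resp]] <- tab2
    fits <- attr(tab, "fits")
    best_i <- which(!is.na(tab$rank) & tab$rank == 1L)[1L]
    best_fit <- fits[[best_i]]
    slopes <- best_fit$spec$random_slopes
    if (length(slopes)) {
      sl <- slopes[1L]
      centers <- sort(unique(dat[[sl]]))
      vt <- variance_at_covariate(best_fit, sl, centers, nboot = nboot,
                                  seed = seed + r)
      var_rows[[resp]] <- cbind(trait = resp, covariate = sl, vt)
      rn <- predict_reaction_norms(best_fit, sl)
      names(rn)[2L] <- "covariate_value"
      norm_rows[[resp]] <- cbind(trait = resp, covariate = sl, rn)
    } else if (best_fit$spec$random_intercept && !is.null(best_fit$fit)) {
      rn <- predict_reaction_norms(best_fit, "day")
      names(rn)[2L] <- "covariate_value"
      norm_rows[[resp]] <- cbind(trait = resp, covariate = "day", rn)
    }
  }
  write_or_empty <- function(rows, path) {
    df <- if (length(rows)) do.call(rbind, rows) else data.frame()
    utils::write.csv(df, path, row.names = FALSE)
  }
  write_or_empty(comp_rows, file.path(outdir, "model_comparison.csv"))
  write_or_empty(var_rows, file.path(outdir, "variance_trends.csv"))
  write_or_empty(norm_rows, file.path(outdir, "reaction_norms.csv"))
  manifest$stages$models <- list(n_traits = length(comp_rows),
                                 bootstrap_reps = nboot,
                                 notes = model_notes)
  manifest$outputs <- list.files(outdir)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
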