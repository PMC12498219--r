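#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline plus simulation sizes and
#' seeds. Validates positivity and round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param seed master RNG seed.
#' @param n_patients synthetic cohort size.
#' @param n_trials trials simulated per direction in the trial-level demo.
#' @param acceleration_thresholds named per-canal-class minima, deg/s^2.
#' @param blink_cutoff deg/s, see [qc_trial()].
#' @param saccade_threshold deg/s, see [detect_saccades()].
#' @param ms_v_max,ms_c,ms_tolerance main-sequence model parameters.
#' @param rcft_threshold z threshold for RCFT abnormality.
#' @param alpha_remove backward-elimination stay threshold.
#' @param model `"plain_mle"` or `"firth"`.
#' @param min_trials minimum valid impulses per direction.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_patients = 151L, n_trials = 15L,
                            acceleration_thresholds = default_acceleration_thresholds(),
                            blink_cutoff = 350, saccade_threshold = 60,
                            ms_v_max = 500, ms_c = 5, ms_tolerance = 0.25,
                            rcft_threshold = -2.0, alpha_remove = 0.10,
                            model = "plain_mle", min_trials = 10L) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              n_trials = as.integer(n_trials),
              acceleration_thresholds = acceleration_thresholds,
              blink_cutoff = blink_cutoff, saccade_threshold = saccade_threshold,
              ms_v_max = ms_v_max, ms_c = ms_c, ms_tolerance = ms_tolerance,
              rcft_threshold = rcft_threshold, alpha_remove = alpha_remove,
              model = model, min_trials = as.integer(min_trials))
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("blink_cutoff", "saccade_threshold", "ms_v_max", "ms_c",
           "n_patients", "n_trials", "min_trials")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_input(sprintf("config field `%s` must be positive", nm))
    }
  }
  if (any(unlist(cfg$acceleration_thresholds) <= 0)) {
    stop_input("acceleration thresholds must be positive")
  }
  if (!cfg$model %in% c("plain_mle", "firth")) {
    stop_input("model must be 'plain_mle' or 'firth'")
  }
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  # yaml serialises named atomic vectors as plain sequences; keep the names
  out$acceleration_thresholds <- as.list(out$acceleration_thresholds)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$acceleration_thresholds <- unlist(raw$acceleration_thresholds)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

# stable fingerprint of the configuration, stamped into every artifact
config_hash <- function(cfg) rlang::hash(unclass(cfg))

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the inputs, then runs every stage in order: trial QC
#' -> gain table -> saccade table -> classification counts -> association
#' statistics, writing one artifact per stage into `out_dir`. Every JSON
#' artifact carries the config hash and seed; rerunning with the same config
#' yields byte-identical artifacts.
#'
#' Trial-level stages run on one simulated direction (right HC) of
#' `n_trials` impulses; cohort-level stages run on a simulated cohort of
#' `n_patients`. Supply `trials` and/or `cohort` to analyse real data
#' instead.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param trials optional list of [impulse_trial()]; simulated when NULL.
#' @param cohort optional cohort data.frame; simulated when NULL.
#' @return invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         trials = NULL, cohort = NULL) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(config_hash = config_hash(config), seed = config$seed)
  msm <- main_sequence_model(config$ms_v_max, config$ms_c, config$ms_tolerance)
  wj <- function(x, file) {
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (is.null(trials)) {
    trials <- stage("simulate-trials", simulate_trial_set(
      impulse_params(peak_head_velocity = 180, pulse_width = 0.04,
                     true_gain = 1.0, noise_sd = 4),
      n_trials = config$n_trials, rng_seed = config$seed,
      canal = "HC", side = "right"
    ))
  }
  qc <- stage("qc", select_valid_trials(
    trials, thresholds = config$acceleration_thresholds,
    blink_cutoff = config$blink_cutoff, ms_model = msm,
    min_trials = config$min_trials
  ))
  wj(c(stamp, list(
    per_trial = qc$report, n_accepted = qc$n_accepted,
    sufficient = qc$sufficient, canal = qc$canal, side = qc$side
  )), "qc_report.json")

  gains <- stage("gain", lapply(qc$accepted, trial_gain))
  gain_tab <- data.frame(
    trial = seq_along(gains),
    gain_window = vapply(gains, `[[`, numeric(1), "gain_window"),
    gain_auc = vapply(gains, `[[`, numeric(1), "gain_auc")
  )
  utils::write.csv(gain_tab, file.path(out_dir, "gain_table.csv"), row.names = FALSE)

  sac_tab <- stage("saccades", do.call(rbind, lapply(seq_along(qc$accepted), function(i) {
    s <- detect_saccades(qc$accepted[[i]], threshold = config$saccade_threshold,
                         ms_model = msm)
    if (!nrow(s)) return(NULL)
    s$reversed <- is_reversed(s, msm, config$saccade_threshold)
    cbind(trial = i, s)
  })))
  if (is.null(sac_tab)) {
    sac_tab <- data.frame(trial = integer(), onset_s = numeric(),
                          peak_velocity = numeric(), amplitude = numeric(),
                          direction = character(), reversed = logical())
  }
  utils::write.csv(sac_tab, file.path(out_dir, "saccade_table.csv"), row.names = FALSE)

  if (is.null(cohort)) {
    cohort <- stage("simulate-cohort", simulate_cohort(
      cohort_params(n_patients = config$n_patients, seed = config$seed)
    ))
  }
  counts <- stage("classify", cohort_counts(
    cohort, rcft_threshold = config$rcft_threshold
  ))
  wj(c(stamp, unclass(counts)), "classification_counts.json")

  analysis <- stage("analyze", run_primary_analysis(
    cohort, rcft_threshold = config$rcft_threshold,
    alpha_remove = config$alpha_remove, model = config$model
  ))
  wj(c(stamp, list(
    copy_model = analysis$copy_model[c("outcome", "table", "elimination_trace")],
    recall_model = analysis$recall_model[c("outcome", "table", "elimination_trace")],
    correlations = analysis$correlations
  )), "association_results.json")

  write_config(config, file.path(out_dir, "config_used.yaml"))
  invisible(list(qc = qc, gains = gain_tab, saccades = sac_tab,
                 counts = counts, analysis = analysis, out_dir = out_dir))
}
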