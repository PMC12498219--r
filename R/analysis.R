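# Candidate covariate roster for the multivariable models: demographics,
# disease severity, cognition/psychiatric covariates, cadence, and the three
# side-averaged canal gains.
analysis_roster <- function() {
  c("age", "sex_female", "disease_duration", "mds_updrs_iii", "kinetic_tremor",
    "orthostatic_hypotension", "schooling", "mmse", "scopa_pc", "depression",
    "anxiety", "cadence", "gain_hc", "gain_ac", "gain_pc")
}

# Build the design columns from a cohort table; errors list missing columns.
build_design <- function(cohort) {
  need <- c("age", "sex", "disease_duration", "mds_updrs_iii", "kinetic_tremor",
            "orthostatic_hypotension", "schooling", "mmse", "scopa_pc",
            "depression", "anxiety", "cadence", GAIN_COLS)
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop_input("cohort lacks required columns: ", paste(miss, collapse = ", "))
  }
  data.frame(
    age = cohort$age,
    sex_female = as.integer(cohort$sex == "female"),
    disease_duration = cohort$disease_duration,
    mds_updrs_iii = cohort$mds_updrs_iii,
    kinetic_tremor = cohort$kinetic_tremor,
    orthostatic_hypotension = cohort$orthostatic_hypotension,
    schooling = cohort$schooling,
    mmse = cohort$mmse,
    scopa_pc = cohort$scopa_pc,
    depression = cohort$depression,
    anxiety = cohort$anxiety,
    cadence = cohort$cadence,
    gain_hc = (cohort$gain_rhc + cohort$gain_lhc) / 2,
    gain_ac = (cohort$gain_rac + cohort$gain_lac) / 2,
    gain_pc = (cohort$gain_rpc + cohort$gain_lpc) / 2
  )
}

#' Cohort-level association analysis
#'
#' Runs the primary statistical pipeline on a patient cohort:
#' \enumerate{
#'   \item backward-selected multivariable logistic models for abnormal
#'     RCFT-copying and abnormal RCFT-delayed recall on the full candidate
#'     roster (age, sex, disease duration, MDS-UPDRS-III, kinetic tremor,
#'     orthostatic hypotension, schooling, MMSE, SCOPA-PC, depression,
#'     anxiety, cadence, and side-averaged HC/AC/PC gains);
#'   \item Spearman correlations of the RCFT z-scores and MMSE with each
#'     side-averaged canal gain;
#'   \item sensitivity re-analyses: the lenient z < -1.0 abnormality
#'     threshold for RCFT-copying, and decreased-gain indicator variables
#'     (any side below the normative range) replacing the continuous gains.
#' }
#'
#' @param cohort data.frame as produced by [simulate_cohort()] or
#'   [read_cohort()].
#' @param rcft_threshold primary z threshold for abnormality (default -2.0).
#' @param alpha_remove stay threshold for backward elimination.
#' @param model `"plain_mle"` or `"firth"`.
#' @param ranges normative ranges used for the decreased-gain indicators.
#' @param sensitivity run the two sensitivity analyses.
#' @return list of class `vhit_analysis` with `copy_model`, `recall_model`
#'   ([backward_select()] results), `correlations` (data.frame), and
#'   optionally `sensitivity_z1`, `sensitivity_nominal`.
#' @export
run_primary_analysis <- function(cohort, rcft_threshold = -2.0,
                                 alpha_remove = 0.10,
                                 model = c("plain_mle", "firth"),
                                 ranges = default_normative_ranges(),
                                 sensitivity = TRUE) {
  model <- match.arg(model)
  X <- build_design(cohort)
  y_copy <- as.integer(cohort$rcft_copy_z < rcft_threshold)
  y_recall <- as.integer(cohort$rcft_recall_z < rcft_threshold)

  copy_model <- backward_select(y_copy, X, alpha_remove, model,
                                outcome = "abnormal_rcft_copying")
  recall_model <- backward_select(y_recall, X, alpha_remove, model,
                                  outcome = "abnormal_rcft_delayed_recall")

  scores <- list(rcft_copy_z = cohort$rcft_copy_z,
                 rcft_recall_z = cohort$rcft_recall_z, mmse = cohort$mmse)
  gains <- list(gain_hc = X$gain_hc, gain_ac = X$gain_ac, gain_pc = X$gain_pc)
  correlations <- do.call(rbind, lapply(names(scores), function(sn) {
    do.call(rbind, lapply(names(gains), function(gn) {
      ct <- spearman_test(scores[[sn]], gains[[gn]])
      data.frame(score = sn, gain = gn, r = ct$statistic, p_value = ct$p_value)
    }))
  }))

  out <- list(copy_model = copy_model, recall_model = recall_model,
              correlations = correlations, rcft_threshold = rcft_threshold,
              alpha_remove = alpha_remove, model = model)

  if (sensitivity) {
    y1 <- as.integer(cohort$rcft_copy_z < -1.0)
    out$sensitivity_z1 <- backward_select(y1, X, alpha_remove, model,
                                          outcome = "abnormal_rcft_copying_z1")
    Xn <- X
    k <- match(c("HC", "AC", "PC"), ranges$canal_class)
    Xn$gain_hc <- as.integer(cohort$gain_rhc < ranges$low[k[1]] |
                               cohort$gain_lhc < ranges$low[k[1]])
    Xn$gain_ac <- as.integer(cohort$gain_rac < ranges$low[k[2]] |
                               cohort$gain_lac < ranges$low[k[2]])
    Xn$gain_pc <- as.integer(cohort$gain_rpc < ranges$low[k[3]] |
                               cohort$gain_lpc < ranges$low[k[3]])
    names(Xn)[match(c("gain_hc", "gain_ac", "gain_pc"), names(Xn))] <-
      c("decreased_hc", "decreased_ac", "decreased_pc")
    out$sensitivity_nominal <- tryCatch(
      backward_select(y_copy, Xn, alpha_remove, model,
                      outcome = "abnormal_rcft_copying_nominal_gain"),
      error = function(e) e$message  # e.g. no decreased-gain patients drawn
    )
  }
  structure(out, class = "vhit_analysis")
}

#' @export
print.vhit_analysis <- function(x, ...) {
  print(x$copy_model)
  print(x$recall_model)
  cat("Spearman correlations (score vs side-averaged gain):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  invisible(x)
}
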