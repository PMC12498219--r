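#' Write impulse trials to disk
#'
#' One CSV per trial (columns `time_s`, `head_vel_dps`, `eye_vel_dps`) plus a
#' JSON sidecar `<stem>.json` with `canal`, `side` and `sample_rate_hz`.
#'
#' @param trials list of [impulse_trial()] objects.
#' @param dir output directory (created if needed).
#' @param prefix filename stem prefix.
#' @return invisibly, the CSV paths written.
#' @export
write_trials <- function(trials, dir, prefix = "trial") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    stem <- file.path(dir, sprintf("%s_%03d", prefix, i))
    utils::write.csv(
      data.frame(time_s = tr$time, head_vel_dps = tr$head_velocity,
                 eye_vel_dps = tr$eye_velocity),
      paste0(stem, ".csv"), row.names = FALSE
    )
    jsonlite::write_json(
      list(canal = tr$canal, side = tr$side, sample_rate_hz = tr$sample_rate),
      paste0(stem, ".json"), auto_unbox = TRUE, digits = NA
    )
    paste0(stem, ".csv")
  }, character(1))
  invisible(paths)
}

read_one_trial <- function(csv_path) {
  stem <- sub("\\.csv$", "", csv_path)
  sidecar <- paste0(stem, ".json")
  if (!file.exists(sidecar)) stop_input("missing JSON sidecar for ", csv_path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$canal %in% CANALS, TRUE)) {
    stop_input(sprintf("%s: canal '%s' not one of %s", sidecar,
                       as.character(meta$canal), paste(CANALS, collapse = ", ")))
  }
  if (!identical(meta$side %in% SIDES, TRUE)) {
    stop_input(sprintf("%s: side '%s' not one of %s", sidecar,
                       as.character(meta$side), paste(SIDES, collapse = ", ")))
  }
  df <- utils::read.csv(csv_path)
  need <- c("time_s", "head_vel_dps", "eye_vel_dps")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_input(sprintf("%s: missing column(s) %s", csv_path,
                       paste(miss, collapse = ", ")))
  }
  bad <- which(!stats::complete.cases(df[need]))
  if (length(bad)) {
    stop_input(sprintf("%s: malformed row(s) at line(s) %s", csv_path,
                       paste(bad + 1L, collapse = ", ")))  # +1 for the header
  }
  tryCatch(
    impulse_trial(df$time_s, df$head_vel_dps, df$eye_vel_dps,
                  canal = meta$canal, side = meta$side,
                  sample_rate = meta$sample_rate_hz),
    error = function(e) stop_input(sprintf("%s: %s", csv_path, conditionMessage(e)))
  )
}

#' Read impulse trials written by [write_trials()]
#'
#' @param path directory containing `*.csv` + `*.json` pairs, or a character
#'   vector of CSV paths.
#' @return list of [impulse_trial()] objects.
#' @export
read_trials <- function(path) {
  paths <- if (length(path) == 1L && dir.exists(path)) {
    sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  } else path
  if (!length(paths)) stop_input("no trial CSV files found at ", path)
  lapply(paths, read_one_trial)
}

#' Write a cohort table to CSV
#' @param cohort data.frame as from [simulate_cohort()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#' @param path CSV written by [write_cohort()] (or equivalent; at minimum the
#'   six gain columns and the RCFT z-scores).
#' @return data.frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c(GAIN_COLS, "rcft_copy_z", "rcft_recall_z"), names(df))
  if (length(miss)) {
    stop_input("cohort file lacks column(s): ", paste(miss, collapse = ", "))
  }
  df
}
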