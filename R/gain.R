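#' VOR gain over the 40-ms window centred at peak head acceleration
#'
#' The per-trial gain is the ratio of the mean eye velocity to the mean head
#' velocity (in magnitude) over the 40-ms window centred at the peak of the
#' head-acceleration trace. At 120 Hz a 40-ms window is 4.8 sample intervals;
#' the closest symmetric odd window is 5 samples, i.e. indices
#' `peak_index - 2 ... peak_index + 2`, and that is what is used so results
#' are bit-reproducible.
#'
#' @param trial an [impulse_trial()].
#' @param peak_index index of peak head acceleration; computed from the trial
#'   via [head_acceleration()] when omitted.
#' @return dimensionless gain (>= 0).
#' @export
window_gain <- function(trial, peak_index = NULL) {
  peak_index <- peak_index %||% head_acceleration(trial)$peak_index
  half <- 2L
  i0 <- peak_index - half
  i1 <- peak_index + half
  if (i0 < 1L || i1 > length(trial$time)) {
    stop_input("40-ms gain window exceeds trace bounds")
  }
  mh <- mean(trial$head_velocity[i0:i1])
  if (mh == 0) stop_input("undefined gain: mean head velocity is zero in the window")
  abs(mean(trial$eye_velocity[i0:i1])) / abs(mh)
}

#' VOR gain as an area-under-the-curve ratio
#'
#' Ratio of the area under the (absolute) eye-velocity curve to the area under
#' the head-velocity curve, integrated by the trapezoidal rule over the
#' impulse support: the contiguous run of samples around the head-velocity
#' peak where |head velocity| is at least `support_frac` of its maximum.
#' Detected saccade lobes overlapping the support are excised from the eye
#' trace (linear interpolation across the lobe) before integration so that
#' catch-up saccades do not inflate the slow-phase area.
#'
#' @param trial an [impulse_trial()].
#' @param support_frac fraction of the head-velocity peak defining the
#'   impulse support (default 0.10).
#' @param desaccade excise detected saccade lobes from the eye integral.
#' @param ms_model main-sequence model forwarded to [detect_saccades()].
#' @return dimensionless gain (>= 0).
#' @export
auc_gain <- function(trial, support_frac = 0.1, desaccade = TRUE,
                     ms_model = main_sequence_model()) {
  h <- abs(trial$head_velocity)
  pk <- max(h)
  if (pk == 0) stop_input("undefined gain: head trace is identically zero")
  above <- h >= support_frac * pk
  runs <- true_runs(above)
  ipk <- which.max(h)
  row <- which(runs[, "start"] <= ipk & runs[, "end"] >= ipk)
  if (!length(row)) stop_input("empty impulse support")
  idx <- runs[row[1], "start"]:runs[row[1], "end"]

  eye <- trial$eye_velocity
  if (desaccade) {
    sac <- detect_saccades(trial, ms_model = ms_model)
    for (i in seq_len(nrow(sac))) {
      a <- max(sac$onset_index[i] - 1L, 1L)
      b <- min(sac$offset_index[i] + 1L, length(eye))
      span <- a:b
      eye[span] <- seq(eye[a], eye[b], length.out = length(span))
    }
  }
  num <- trapz(trial$time[idx], abs(eye[idx]))
  den <- trapz(trial$time[idx], h[idx])
  if (den == 0) stop_input("undefined gain: zero head-velocity area over support")
  num / den
}

#' Per-trial gain record
#'
#' Convenience wrapper returning both estimators and the window bounds.
#'
#' @param trial an [impulse_trial()].
#' @return list of class `trial_gain` with `gain_window`, `gain_auc`,
#'   `window_start_index`, `window_end_index`, `peak_index`.
#' @export
trial_gain <- function(trial) {
  pk <- head_acceleration(trial)$peak_index
  structure(
    list(gain_window = window_gain(trial, pk),
         gain_auc = auc_gain(trial),
         window_start_index = pk - 2L, window_end_index = pk + 2L,
         peak_index = pk),
    class = "trial_gain"
  )
}

#' Summarise trial gains for a canal
#'
#' The side-level summary is the arithmetic mean of the per-trial window
#' gains and requires at least `min_trials` trials; otherwise the summary is
#' flagged unavailable (`mean_gain = NA`) rather than raising an error. The
#' `"both"`-side summary is the arithmetic mean of the left and right side
#' means.
#'
#' @param gains numeric vector of per-trial gains (window estimator), or a
#'   list of `trial_gain` records.
#' @param canal,side labels for the summary (`side` may be `"both"` only via
#'   [combine_sides()]).
#' @param min_trials minimum trial count for an available summary.
#' @return list of class `canal_gain_summary` with `canal`, `side`,
#'   `mean_gain`, `n_trials`, `available`.
#' @export
summarize_canal <- function(gains, canal, side, min_trials = 10L) {
  if (is.list(gains)) gains <- vapply(gains, `[[`, numeric(1), "gain_window")
  n <- length(gains)
  available <- n >= min_trials
  structure(
    list(canal = canal, side = side,
         mean_gain = if (available) mean(gains) else NA_real_,
         n_trials = n, available = available),
    class = "canal_gain_summary"
  )
}

#' Combine left and right canal summaries into a "both"-side summary
#'
#' @param left,right `canal_gain_summary` objects for the same canal class.
#' @return a `canal_gain_summary` with `side = "both"`; unavailable when
#'   either side is.
#' @export
combine_sides <- function(left, right) {
  stopifnot(left$canal == right$canal)
  available <- left$available && right$available
  structure(
    list(canal = left$canal, side = "both",
         mean_gain = if (available) (left$mean_gain + right$mean_gain) / 2 else NA_real_,
         n_trials = left$n_trials + right$n_trials, available = available),
    class = "canal_gain_summary"
  )
}
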