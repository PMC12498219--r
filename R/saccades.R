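#' Saccadic main-sequence model
#'
#' Exponential amplitude/peak-velocity relation
#' `peak_velocity = v_max * (1 - exp(-amplitude / c))`, the standard
#' saturating main sequence of human saccades. Events whose peak velocity
#' exceeds the model prediction by more than `tolerance` are treated as
#' artifacts rather than saccades. The device cutoff used in clinical
#' recordings is not published; the defaults (`v_max` = 500 deg/s,
#' `c` = 5 deg, 25% tolerance) are standard human values and fully
#' configurable.
#'
#' @param v_max asymptotic peak velocity, deg/s (> 0).
#' @param c amplitude constant, deg (> 0).
#' @param tolerance fractional slack above the prediction still accepted.
#' @return object of class `main_sequence_model`.
#' @export
main_sequence_model <- function(v_max = 500, c = 5, tolerance = 0.25) {
  check_number(v_max, "v_max", lower = 0, strict = TRUE)
  check_number(c, "c", lower = 0, strict = TRUE)
  check_number(tolerance, "tolerance", lower = 0)
  structure(list(v_max = v_max, c = c, tolerance = tolerance),
            class = "main_sequence_model")
}

#' Predicted main-sequence peak velocity at a given amplitude
#' @param model a [main_sequence_model()].
#' @param amplitude saccade amplitude, deg.
#' @return predicted peak velocity, deg/s.
#' @export
ms_peak_velocity <- function(model, amplitude) {
  model$v_max * (1 - exp(-amplitude / model$c))
}

# Least-squares fallback slow-phase gain when the 40-ms window is unusable.
ls_gain <- function(trial) {
  den <- sum(trial$head_velocity^2)
  if (den == 0) return(0)
  abs(sum(trial$eye_velocity * trial$head_velocity)) / den
}

#' Detect catch-up saccades in an eye-velocity trace
#'
#' The slow-phase (compensatory) component is removed by adding
#' `gain * head_velocity` to the eye velocity, using the trial's own 40-ms
#' window gain; what remains are saccadic lobes, artifacts and noise. The
#' residual is reconstructed on a 16x dense grid with a natural cubic spline
#' (at 120 Hz a small saccade spans only 2-4 samples and the sampled peak can
#' fall well below the true one), and candidate lobes are contiguous
#' single-signed dense runs where |residual| exceeds `threshold`. Runs of
#' equal sign separated by less than `merge_gap` samples are merged. Lobe
#' boundaries are extended outwards to where the residual falls below
#' max(5 deg/s, 5% of the lobe peak) before the amplitude integral is taken.
#'
#' @param trial an [impulse_trial()] (or pass `eye`/`head`/`time` explicitly
#'   via a list of the same shape).
#' @param gain slow-phase gain to remove; default: the trial's window gain.
#' @param threshold detection threshold on |residual eye velocity|, deg/s.
#' @param merge_gap maximum gap (in samples) across which equal-signed lobes
#'   are merged.
#' @param ms_model a [main_sequence_model()] (stored with the result and used
#'   by [is_reversed()]).
#' @return data.frame with one row per detected lobe: `onset_index`,
#'   `offset_index` (sample indices), `onset_s`, `peak_velocity` (deg/s),
#'   `amplitude` (deg), `direction` (`"with_head"`/`"against_head"`),
#'   `latency` (s from the head-velocity peak), `sign`.
#' @export
detect_saccades <- function(trial, gain = NULL, threshold = 60, merge_gap = 2L,
                            ms_model = main_sequence_model()) {
  time <- trial$time
  eye <- trial$eye_velocity
  head <- trial$head_velocity
  if (length(eye) != length(head)) stop_input("eye and head traces differ in length")
  if (is.null(gain)) {
    gain <- tryCatch(window_gain(trial), error = function(e) ls_gain(trial))
  }
  head_sign <- sign(head[which.max(abs(head))])
  resid <- eye + gain * head

  f <- stats::splinefun(time, resid, method = "natural")
  nd <- 16L * length(time)
  td <- seq(time[1], time[length(time)], length.out = nd)
  rd <- f(td)

  empty <- data.frame(onset_index = integer(), offset_index = integer(),
                      onset_s = numeric(), peak_velocity = numeric(),
                      amplitude = numeric(), direction = character(),
                      latency = numeric(), sign = numeric())
  hot <- abs(rd) > threshold
  if (!any(hot)) return(empty)

  # single-signed candidate runs on the dense grid
  lab <- ifelse(hot, sign(rd), 0)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, sgn = r$values)[r$values != 0, ]
  if (!nrow(runs)) return(empty)

  # merge equal-signed runs separated by < merge_gap samples
  gap_dense <- merge_gap * 16L
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    if (runs$sgn[i] == merged$sgn[last] &&
        runs$start[i] - merged$end[last] < gap_dense) {
      merged$end[last] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }

  t_hpeak <- time[which.max(abs(head))]
  out <- lapply(seq_len(nrow(merged)), function(i) {
    a <- merged$start[i]; b <- merged$end[i]; s <- merged$sgn[i]
    pk <- max(abs(rd[a:b]))
    floor_v <- max(5, 0.05 * pk)
    while (a > 1L && abs(rd[a - 1L]) >= floor_v && sign(rd[a - 1L]) == s) a <- a - 1L
    while (b < nd && abs(rd[b + 1L]) >= floor_v && sign(rd[b + 1L]) == s) b <- b + 1L
    amp <- abs(trapz(td[a:b], rd[a:b]))
    on_i <- which.min(abs(time - td[a]))
    off_i <- max(which.min(abs(time - td[b])), on_i + 1L)
    data.frame(
      onset_index = on_i, offset_index = off_i, onset_s = td[a],
      peak_velocity = pk, amplitude = amp,
      direction = if (s == head_sign) "with_head" else "against_head",
      latency = td[a] - t_hpeak, sign = s
    )
  })
  res <- do.call(rbind, out)
  attr(res, "ms_model") <- ms_model
  attr(res, "gain_used") <- gain
  res
}

#' Is a detected saccade a reversed catch-up saccade?
#'
#' A reversed catch-up saccade is (1) directed towards the direction of head
#' rotation (`with_head`), (2) has a peak eye velocity above 60 deg/s, and
#' (3) lies on the saccadic main sequence -- its peak velocity does not exceed
#' the model prediction at its amplitude by more than the model tolerance
#' (events above that cap are artifacts, not saccades).
#'
#' @param saccade one row of the [detect_saccades()] table (or a list with
#'   `direction`, `peak_velocity`, `amplitude`).
#' @param ms_model a [main_sequence_model()].
#' @param velocity_threshold minimum peak velocity, deg/s.
#' @return logical.
#' @export
is_reversed <- function(saccade, ms_model = main_sequence_model(),
                        velocity_threshold = 60) {
  saccade$direction == "with_head" &
    saccade$peak_velocity > velocity_threshold &
    saccade$peak_velocity <= ms_peak_velocity(ms_model, saccade$amplitude) *
      (1 + ms_model$tolerance)
}

#' Per-canal reversed-saccade flags for a patient
#'
#' @param trials list of accepted [impulse_trial()] objects across canal
#'   planes (any mixture of canals/sides).
#' @param ms_model a [main_sequence_model()].
#' @param velocity_threshold minimum peak velocity, deg/s.
#' @return named logical vector over `c("HC", "AC", "PC")`: `TRUE` when any
#'   trial in that canal plane contains a reversed catch-up saccade.
#' @export
patient_reversed_flag <- function(trials, ms_model = main_sequence_model(),
                                  velocity_threshold = 60) {
  flags <- stats::setNames(rep(FALSE, length(CANALS)), CANALS)
  for (tr in trials) {
    if (flags[[tr$canal]]) next
    sac <- detect_saccades(tr, ms_model = ms_model)
    if (nrow(sac) &&
        any(is_reversed(sac, ms_model, velocity_threshold))) {
      flags[[tr$canal]] <- TRUE
    }
  }
  flags
}
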