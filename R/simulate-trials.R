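#' Saccade specification for the trial simulator
#'
#' Describes one catch-up saccade to be injected into a simulated eye-velocity
#' trace as a Gaussian velocity lobe. For a Gaussian lobe the amplitude
#' (integral of the velocity profile) and the peak velocity jointly determine
#' the lobe width: `sigma = amplitude / (peak_velocity * sqrt(2 * pi))`.
#'
#' @param onset lobe onset in seconds from trace start (the lobe centre sits
#'   two lobe-sigmas after the onset).
#' @param amplitude saccade amplitude in degrees (> 0).
#' @param direction `"with_head"` (anticompensatory, i.e. towards the head
#'   rotation) or `"against_head"` (the usual compensatory catch-up direction).
#' @param peak_velocity peak eye velocity of the lobe in deg/s (> 0).
#' @param allow_main_sequence_violation set `TRUE` to build an artifact
#'   fixture whose amplitude/peak-velocity pair falls off the saccadic main
#'   sequence; otherwise such pairs are rejected.
#' @param ms_model main-sequence model used for the consistency check, see
#'   [main_sequence_model()].
#' @return an object of class `saccade_spec`.
#' @export
saccade_spec <- function(onset, amplitude, direction = c("against_head", "with_head"),
                         peak_velocity,
                         allow_main_sequence_violation = FALSE,
                         ms_model = main_sequence_model()) {
  direction <- match.arg(direction)
  check_number(onset, "onset", lower = 0)
  check_number(amplitude, "amplitude", lower = 0, strict = TRUE)
  check_number(peak_velocity, "peak_velocity", lower = 0, strict = TRUE)
  if (!allow_main_sequence_violation) {
    cap <- ms_peak_velocity(ms_model, amplitude) * (1 + ms_model$tolerance)
    if (peak_velocity > cap) {
      stop_input(sprintf(
        "peak_velocity %.1f deg/s exceeds the main-sequence cap %.1f deg/s at %.2f deg; set allow_main_sequence_violation = TRUE to build an artifact fixture",
        peak_velocity, cap, amplitude
      ))
    }
  }
  structure(
    list(onset = onset, amplitude = amplitude, direction = direction,
         peak_velocity = peak_velocity),
    class = "saccade_spec"
  )
}

#' Parameters of a simulated head impulse
#'
#' The simulated head impulse is a single-lobed Gaussian velocity pulse
#' `v(t) = V * exp(-(t - t0)^2 / (2 * sigma^2))` so that its peak acceleration
#' has the closed form `V / (sigma * sqrt(e))`, which the test suite uses as
#' an analytic oracle.
#'
#' @param peak_head_velocity pulse peak `V` in deg/s (> 0).
#' @param pulse_width Gaussian half-width `sigma` in seconds (> 0).
#' @param direction rotation sign: `"positive"` is towards the tested side.
#' @param true_gain programmed eye/head velocity ratio (>= 0); the compensatory
#'   eye response is `-true_gain * head`.
#' @param saccades list of [saccade_spec()] objects to inject.
#' @param noise_sd sd in deg/s of additive Gaussian noise on the eye trace.
#' @param blink inject a biphasic +/-400 deg/s, 80 ms blink artifact after the
#'   impulse.
#' @param sample_rate sampling rate in Hz (vHIT devices record at 120 Hz).
#' @return an object of class `impulse_params`.
#' @export
impulse_params <- function(peak_head_velocity = 150, pulse_width = 0.05,
                           direction = c("positive", "negative"),
                           true_gain = 1.0, saccades = list(),
                           noise_sd = 0, blink = FALSE, sample_rate = 120) {
  direction <- match.arg(direction)
  check_number(peak_head_velocity, "peak_head_velocity", lower = 0, strict = TRUE)
  check_number(pulse_width, "pulse_width", lower = 0, strict = TRUE)
  check_number(true_gain, "true_gain", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(sample_rate, "sample_rate", lower = 0, strict = TRUE)
  if (!is.list(saccades) || !all(vapply(saccades, inherits, logical(1), "saccade_spec"))) {
    stop_input("`saccades` must be a list of saccade_spec objects")
  }
  structure(
    list(peak_head_velocity = peak_head_velocity, pulse_width = pulse_width,
         direction = direction, true_gain = true_gain, saccades = saccades,
         noise_sd = noise_sd, blink = isTRUE(blink), sample_rate = sample_rate),
    class = "impulse_params"
  )
}

#' Construct a head-impulse trial
#'
#' Container for one synchronously sampled head/eye angular-velocity recording,
#' labelled by canal plane and rotation side.
#'
#' @param time time grid in seconds, strictly increasing and uniform.
#' @param head_velocity head angular velocity, deg/s.
#' @param eye_velocity eye angular velocity, deg/s.
#' @param canal `"HC"`, `"AC"` or `"PC"`.
#' @param side `"left"` or `"right"`.
#' @param sample_rate sampling rate in Hz; defaults to `1 / median(diff(time))`.
#' @return an object of class `impulse_trial`.
#' @export
impulse_trial <- function(time, head_velocity, eye_velocity, canal = "HC",
                          side = "right", sample_rate = NULL) {
  if (!canal %in% CANALS) {
    stop_input(sprintf("unknown canal '%s'; allowed: %s", canal,
                       paste(CANALS, collapse = ", ")))
  }
  if (!side %in% SIDES) {
    stop_input(sprintf("unknown side '%s'; allowed: %s", side,
                       paste(SIDES, collapse = ", ")))
  }
  n <- length(time)
  if (length(head_velocity) != n || length(eye_velocity) != n) {
    stop_input("time, head_velocity and eye_velocity must have equal length")
  }
  if (n < 24L) {
    stop_input("trial too short: need >= 24 samples (200 ms at 120 Hz)")
  }
  dt <- diff(time)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    stop_input("time grid must be strictly increasing and uniform to 1e-9 s")
  }
  sample_rate <- sample_rate %||% (1 / stats::median(dt))
  structure(
    list(time = as.numeric(time), head_velocity = as.numeric(head_velocity),
         eye_velocity = as.numeric(eye_velocity), canal = canal, side = side,
         sample_rate = sample_rate),
    class = "impulse_trial"
  )
}

#' @export
print.impulse_trial <- function(x, ...) {
  cat(sprintf("<impulse_trial> %s %s, %d samples @ %g Hz, peak |head| %.1f deg/s\n",
              x$side, x$canal, length(x$time), x$sample_rate,
              max(abs(x$head_velocity))))
  invisible(x)
}

#' Simulate a head-velocity impulse
#'
#' Produces the Gaussian velocity pulse described in [impulse_params()],
#' sampled at `sample_rate`. The pulse centre is snapped to the sample grid so
#' the sampled maximum equals `peak_head_velocity` exactly. The trace extends
#' four pulse widths on each side of the centre plus a 150 ms tail.
#'
#' @param params an [impulse_params()] object.
#' @return list with `time` (s) and `velocity` (deg/s).
#' @export
simulate_head_velocity <- function(params) {
  stopifnot(inherits(params, "impulse_params"))
  sr <- params$sample_rate
  sigma <- params$pulse_width
  t0 <- round(4 * sigma * sr) / sr  # snap pulse centre to the grid
  dur <- t0 + 4 * sigma + 0.15
  time <- seq(0, dur, by = 1 / sr)
  v <- params$peak_head_velocity * exp(-(time - t0)^2 / (2 * sigma^2))
  if (params$direction == "negative") v <- -v
  list(time = time, velocity = v, pulse_center = t0)
}

# Gaussian saccade velocity lobe on grid `time`; returns signed velocity.
saccade_lobe <- function(time, spec, sign) {
  sig <- spec$amplitude / (spec$peak_velocity * sqrt(2 * pi))
  centre <- spec$onset + 2 * sig
  sign * spec$peak_velocity * exp(-(time - centre)^2 / (2 * sig^2))
}

#' Simulate an eye-velocity response
#'
#' The compensatory slow phase is `-true_gain * head`; saccade lobes, optional
#' blink artifact and Gaussian noise are added on top. Saccade lobes are signed
#' by their direction relative to the head-rotation sign: a `with_head`
#' (reversed) saccade has the same sign as the head velocity, an
#' `against_head` saccade the opposite sign.
#'
#' @param head trace from [simulate_head_velocity()].
#' @param params an [impulse_params()] object.
#' @param rng_seed integer seed for noise reproducibility (ignored when
#'   `noise_sd = 0` and no randomness is used).
#' @return list with `time` and `velocity`.
#' @export
simulate_eye_velocity <- function(head, params, rng_seed = NULL) {
  stopifnot(inherits(params, "impulse_params"))
  time <- head$time
  head_sign <- if (params$direction == "positive") 1 else -1
  eye <- -params$true_gain * head$velocity
  for (spec in params$saccades) {
    if (spec$onset > max(time)) {
      stop_input(sprintf("saccade onset %.3f s is outside the %.3f s trace",
                         spec$onset, max(time)))
    }
    s <- if (spec$direction == "with_head") head_sign else -head_sign
    eye <- eye + saccade_lobe(time, spec, s)
  }
  if (params$blink) {
    # biphasic +/-400 deg/s transient of ~80 ms placed in the post-impulse tail
    tb <- head$pulse_center + 4 * params$pulse_width + 0.02
    eye <- eye + 400 * exp(-(time - tb)^2 / (2 * 0.01^2)) -
      400 * exp(-(time - (tb + 0.04))^2 / (2 * 0.01^2))
  }
  if (params$noise_sd > 0) {
    eye <- eye + with_seed(rng_seed, stats::rnorm(length(time), 0, params$noise_sd))
  }
  list(time = time, velocity = eye)
}

#' Simulate a set of head-impulse trials
#'
#' Each trial jitters the peak head velocity and pulse width by independent
#' uniform factors on (0.9, 1.1) and may carry an injected blink with
#' probability `blink_prob`. Fully reproducible under `rng_seed`; the draw
#' order is: velocity jitters, width jitters, blink uniforms, per-trial noise
#' sub-seeds.
#'
#' @param params baseline [impulse_params()].
#' @param n_trials number of trials (>= 1).
#' @param rng_seed integer seed.
#' @param canal,side labels attached to every trial.
#' @param blink_prob per-trial probability of an injected blink artifact.
#' @return list of [impulse_trial()] objects; each carries the simulation
#'   truth in attributes `injected_blink` and `true_gain`.
#' @export
simulate_trial_set <- function(params, n_trials, rng_seed = 1L, canal = "HC",
                               side = "right", blink_prob = 0) {
  stopifnot(inherits(params, "impulse_params"))
  if (!is.numeric(n_trials) || n_trials < 1) stop_input("n_trials must be >= 1")
  n_trials <- as.integer(n_trials)
  draws <- with_seed(rng_seed, {
    list(jv = stats::runif(n_trials, 0.9, 1.1),
         jw = stats::runif(n_trials, 0.9, 1.1),
         bu = stats::runif(n_trials),
         sub = sample.int(.Machine$integer.max, n_trials))
  })
  lapply(seq_len(n_trials), function(i) {
    p <- params
    p$peak_head_velocity <- params$peak_head_velocity * draws$jv[i]
    p$pulse_width <- params$pulse_width * draws$jw[i]
    p$blink <- draws$bu[i] < blink_prob
    head <- simulate_head_velocity(p)
    eye <- simulate_eye_velocity(head, p, rng_seed = draws$sub[i])
    tr <- impulse_trial(head$time, head$velocity, eye$velocity,
                        canal = canal, side = side, sample_rate = p$sample_rate)
    attr(tr, "injected_blink") <- p$blink
    attr(tr, "true_gain") <- p$true_gain
    tr
  })
}
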