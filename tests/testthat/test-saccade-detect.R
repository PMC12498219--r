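test_that("compensatory-only trials yield no detections", {
  expect_identical(nrow(detect_saccades(make_trial(gain = 1.0))), 0L)
  expect_identical(nrow(detect_saccades(make_trial(gain = 0.4))), 0L)
})

test_that("an injected overt saccade is detected with direction and peak", {
  sp <- saccade_spec(0.35, amplitude = 3, direction = "against_head",
                     peak_velocity = 150)
  tr <- make_trial(V = 250, sigma = 0.04, gain = 0.9, saccades = list(sp))
  det <- detect_saccades(tr)
  expect_identical(nrow(det), 1L)
  expect_identical(det$direction, "against_head")
  expect_equal(det$peak_velocity, 150, tolerance = 0.05)
  expect_equal(det$amplitude, 3, tolerance = 0.1)
  expect_gt(det$offset_index, det$onset_index)
})

test_that("sub-threshold lobes are not detected", {
  sp <- saccade_spec(0.35, amplitude = 2, direction = "against_head",
                     peak_velocity = 55)
  tr <- make_trial(V = 250, sigma = 0.04, gain = 0.9, saccades = list(sp))
  expect_identical(nrow(detect_saccades(tr)), 0L)
})

test_that("detection and direction are exact across the main-sequence grid", {
  # main-sequence-consistent (amplitude, peak velocity) pairs >= 70 deg/s,
  # at several sub-sample onset phases
  grid <- list(c(1, 70), c(2, 150), c(3, 150), c(5, 250), c(10, 400))
  h <- 1 / 120
  for (g in grid) for (dir in c("with_head", "against_head")) {
    for (phase in c(0, 0.33, 0.5)) {
      sp <- saccade_spec(0.35 + phase * h, amplitude = g[1], direction = dir,
                         peak_velocity = g[2])
      tr <- make_trial(V = 250, sigma = 0.04, gain = 0.8, saccades = list(sp))
      det <- detect_saccades(tr)
      expect_identical(nrow(det), 1L)
      expect_identical(det$direction, dir)
    }
  }
})

test_that("raising the threshold never increases detections", {
  sps <- list(
    saccade_spec(0.30, amplitude = 2, direction = "against_head",
                 peak_velocity = 80),
    saccade_spec(0.42, amplitude = 4, direction = "with_head",
                 peak_velocity = 200)
  )
  tr <- make_trial(V = 250, sigma = 0.04, gain = 0.8, saccades = sps)
  counts <- vapply(c(60, 90, 150, 250), function(th) {
    nrow(detect_saccades(tr, threshold = th))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_identical(counts[1], 2L)
})

test_that("reversed-saccade rule: direction, 60 deg/s, main sequence", {
  ms <- main_sequence_model()  # v_max 500, c 5
  expect_equal(ms_peak_velocity(ms, 3), 500 * (1 - exp(-3 / 5)))
  row <- function(direction, pk, amp) {
    data.frame(direction = direction, peak_velocity = pk, amplitude = amp)
  }
  expect_true(is_reversed(row("with_head", 80, 3), ms))
  expect_false(is_reversed(row("against_head", 200, 3), ms))
  # artifact: far above the main-sequence cap at 0.5 deg (predict ~47.6)
  expect_false(is_reversed(row("with_head", 400, 0.5), ms))
  expect_false(is_reversed(row("with_head", 59, 3), ms))
})

test_that("patient-level reversed flags localise to the canal plane", {
  clean <- unlist(lapply(c("HC", "AC", "PC"), function(cc) {
    simulate_trial_set(impulse_params(250, 0.04, true_gain = 1, noise_sd = 2),
                       3, rng_seed = 17, canal = cc)
  }), recursive = FALSE)
  expect_identical(unname(patient_reversed_flag(clean)), rep(FALSE, 3))

  rev_sp <- saccade_spec(0.35, amplitude = 3, direction = "with_head",
                         peak_velocity = 100)
  one <- make_trial(V = 250, sigma = 0.04, gain = 0.7, saccades = list(rev_sp),
                    canal = "AC")
  flags <- patient_reversed_flag(c(clean, list(one)))
  expect_identical(flags, c(HC = FALSE, AC = TRUE, PC = FALSE))
  # permutation invariance
  perm <- patient_reversed_flag(rev(c(clean, list(one))))
  expect_identical(perm, flags)
})
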