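test_that("acceleration of constant and linear head velocity is exact", {
  tt <- seq(0, 0.5, by = 1 / 120)
  const <- impulse_trial(tt, rep(100, length(tt)), rep(-100, length(tt)))
  expect_lt(head_acceleration(const)$peak, 1e-8)
  ramp <- ramp_trial(120)
  a <- head_acceleration(ramp)
  expect_equal(a$acceleration, rep(120, length(tt)), tolerance = 1e-8)
  expect_equal(a$peak, 120, tolerance = 1e-8)
})

test_that("peak acceleration matches the closed form V/(sigma*sqrt(e))", {
  cases <- list(c(V = 150, s = 0.05), c(V = 250, s = 0.04))
  for (cs in cases) {
    tr <- make_trial(V = cs[["V"]], sigma = cs[["s"]])
    truth <- cs[["V"]] / (cs[["s"]] * sqrt(exp(1)))
    expect_equal(head_acceleration(tr)$peak, truth, tolerance = 0.01)
  }
  expect_error(head_acceleration(list(time = 1:3 / 120, head_velocity = 1:3)),
               "too short")
})

test_that("acceleration thresholds are strict and canal-specific", {
  # exactly at the HC threshold: rejected (strict >)
  at <- qc_trial(ramp_trial(2500))
  expect_false(at$accepted)
  expect_identical(at$rejection_reason, "low_acceleration")
  expect_equal(at$peak_head_acceleration, 2500, tolerance = 1e-6)
  # just above: accepted
  expect_true(qc_trial(ramp_trial(2600))$accepted)
  # same pulse clears the vertical-canal threshold but not the HC one
  tr <- make_trial(V = 150, sigma = 0.05)  # peak ~1820 deg/s^2
  expect_false(qc_trial(tr)$accepted)
  ac <- make_trial(V = 150, sigma = 0.05, canal = "AC")
  expect_true(qc_trial(ac)$accepted)
  expect_error(qc_trial(tr, thresholds = c(AC = 1500)), "threshold")
})

test_that("blink artifacts are rejected; clean saccades are not blinks", {
  blink <- make_trial(V = 140, sigma = 0.05, gain = 1, blink = TRUE, canal = "AC")
  r <- qc_trial(blink)
  expect_false(r$accepted)
  expect_identical(r$rejection_reason, "blink")
  # a legitimate large catch-up saccade (within main sequence) is not a blink
  sp <- saccade_spec(0.4, amplitude = 5, direction = "against_head",
                     peak_velocity = 300)
  sac <- make_trial(V = 250, sigma = 0.04, gain = 0.6, saccades = list(sp))
  expect_true(qc_trial(sac)$accepted)
})

test_that("select_valid_trials counts, outliers and the 10-trial rule", {
  # noiseless fixtures: every trial shares the exact programmed gain, so the
  # set-level MAD outlier rule (which can false-flag at n ~ 10 under noise)
  # stays inert and the counts isolate the acceleration filter
  p_hi <- impulse_params(250, 0.04, true_gain = 1.0)
  p_lo <- impulse_params(150, 0.05, true_gain = 1.0)
  hi <- simulate_trial_set(p_hi, 15, rng_seed = 11)
  sel <- select_valid_trials(hi)
  expect_equal(sel$n_accepted, 15)
  expect_true(sel$sufficient)

  # 12 trials, 3 below the HC threshold -> 9 accepted, insufficient
  mixed <- c(simulate_trial_set(p_hi, 9, rng_seed = 3),
             simulate_trial_set(p_lo, 3, rng_seed = 4))
  sel2 <- select_valid_trials(mixed)
  expect_equal(sel2$n_accepted, 9)
  expect_false(sel2$sufficient)
  expect_equal(sum(sel2$report$reason == "low_acceleration"), 3)

  # sufficiency is inclusive at exactly 10
  ten <- simulate_trial_set(p_hi, 10, rng_seed = 5)
  expect_true(select_valid_trials(ten)$sufficient)

  # mixed canal labels are an input error
  bad <- c(simulate_trial_set(p_hi, 2, rng_seed = 1),
           simulate_trial_set(p_hi, 2, rng_seed = 1, canal = "AC"))
  expect_error(select_valid_trials(bad), "mix")
})

test_that("a gain outlier is rejected at the set level", {
  trials <- simulate_trial_set(impulse_params(250, 0.04, true_gain = 1.0,
                                              noise_sd = 3), 11, rng_seed = 9)
  # graft one trial with a wildly different gain
  odd <- make_trial(V = 250, sigma = 0.04, gain = 0.2)
  sel <- select_valid_trials(c(trials, list(odd)))
  expect_identical(sel$report$reason[12], "outlier")
  # the eleven on-gain trials sit within a fraction of the 0.8 gain deviation
  expect_true(all(abs(sel$report$gain[1:11] - 1) < 0.1))
})

test_that("QC is monotone in the threshold and idempotent", {
  trials <- simulate_trial_set(impulse_params(220, 0.045, true_gain = 1,
                                              noise_sd = 2), 12, rng_seed = 21)
  grid <- seq(1000, 5000, by = 500)
  counts <- vapply(grid, function(th) {
    select_valid_trials(trials, thresholds = c(HC = th))$n_accepted
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))

  sel <- select_valid_trials(trials)
  again <- select_valid_trials(sel$accepted)
  expect_equal(again$n_accepted, sel$n_accepted)
})

test_that("accepted counts match an independent brute-force refilter", {
  p <- impulse_params(205, 0.05, true_gain = 1, noise_sd = 2)
  trials <- simulate_trial_set(p, 20, rng_seed = 13)
  sel <- select_valid_trials(trials, thresholds = c(HC = 2500))
  # oracle: recompute the jittered (V, sigma) from the generator's draw order,
  # apply the closed-form peak acceleration, then the same median +/- 3 MAD
  # rule to the reported per-trial gains
  draws <- local({ set.seed(13L); list(jv = runif(20, 0.9, 1.1),
                                       jw = runif(20, 0.9, 1.1)) })
  peak_cf <- (205 * draws$jv) / ((0.05 * draws$jw) * sqrt(exp(1)))
  ok <- peak_cf > 2500
  g <- sel$report$gain
  md <- mad(g[ok])
  if (md > 0) ok <- ok & abs(g - median(g[ok])) <= 3 * md
  expect_equal(sel$n_accepted, sum(ok))
  expect_identical(which(sel$report$accepted), which(ok))
})
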