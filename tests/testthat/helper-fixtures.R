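# Shared fixtures built in code at test time.

# One simulated trial with the given pulse/gain settings.
make_trial <- function(V = 250, sigma = 0.04, gain = 1.0, saccades = list(),
                       noise_sd = 0, blink = FALSE, canal = "HC",
                       side = "right", direction = "positive", seed = 1L) {
  p <- impulse_params(peak_head_velocity = V, pulse_width = sigma,
                      direction = direction, true_gain = gain,
                      saccades = saccades, noise_sd = noise_sd, blink = blink)
  h <- simulate_head_velocity(p)
  e <- simulate_eye_velocity(h, p, rng_seed = seed)
  tr <- impulse_trial(h$time, h$velocity, e$velocity, canal = canal, side = side)
  attr(tr, "pulse_center") <- h$pulse_center
  tr
}

# Trial whose head velocity is exactly linear, so the spline-derivative
# acceleration equals `slope` exactly everywhere (threshold boundary fixture).
ramp_trial <- function(slope, canal = "HC", eye_scale = -0.5, dur = 0.5, sr = 120) {
  tt <- seq(0, dur, by = 1 / sr)
  v <- slope * (tt - dur / 2)
  impulse_trial(tt, v, eye_scale * v, canal = canal, side = "right")
}

# Cohort of 151 patients whose per-canal statuses reproduce the published
# subgroup breakdown:
#   decreased:     HC 21 (R8/L7/B6), AC 11 (R6/L1/B4), PC 16 (R3/L8/B5)
#   overestimated: HC 23 (R10/L5/B8), AC 48 (R16/L12/B20), PC 13 (R4/L4/B5)
#   34 any-decreased, 69 any-overestimated, 7 in both, 55 all-normal;
#   11 abnormal RCFT-copying, 15 abnormal delayed recall.
pattern_cohort <- function() {
  n <- 151
  normal_mid <- c(HC = 1.03, AC = 0.98, PC = 1.00)
  low_val <- c(HC = 0.70, AC = 0.60, PC = 0.60)    # below each lower bound
  high_val <- c(HC = 1.35, AC = 1.35, PC = 1.40)   # above each upper bound
  g <- matrix(rep(normal_mid[c("HC", "HC", "AC", "AC", "PC", "PC")], each = n),
              nrow = n)
  colnames(g) <- c("gain_rhc", "gain_lhc", "gain_rac", "gain_lac",
                   "gain_rpc", "gain_lpc")
  set_status <- function(ids, canal, sides, value) {
    for (s in sides) g[ids, sprintf("gain_%s%s", s, tolower(canal))] <<- value
  }
  dec <- function(ids, canal, sides) set_status(ids, canal, sides, low_val[canal])
  ove <- function(ids, canal, sides) set_status(ids, canal, sides, high_val[canal])

  # decreased assignments (patients 1..34)
  dec(1:8, "HC", "r"); dec(9:15, "HC", "l"); dec(16:21, "HC", c("r", "l"))
  dec(22:27, "AC", "r"); dec(28, "AC", "l"); dec(29:32, "AC", c("r", "l"))
  dec(c(33, 34, 1), "PC", "r"); dec(2:9, "PC", "l"); dec(10:14, "PC", c("r", "l"))

  # overestimated assignments (patients 1..7 and 35..96); sides chosen so no
  # canal side is both decreased and overestimated
  ove(83:92, "HC", "r"); ove(c(93, 94, 1, 2, 3), "HC", "l")
  ove(c(95, 96, 35:40), "HC", c("r", "l"))
  ove(35:50, "AC", "r"); ove(51:62, "AC", "l"); ove(63:82, "AC", c("r", "l"))
  ove(4:7, "PC", "r"); ove(41:44, "PC", "l"); ove(45:49, "PC", c("r", "l"))

  data.frame(
    patient_id = sprintf("P%03d", 1:n), g,
    rcft_copy_z = c(rep(-2.5, 11), rep(0, n - 11)),
    rcft_recall_z = c(rep(-2.4, 15), rep(-0.3, n - 15))
  )
}

# Brute-force Mann-Whitney U for sample `a`: pairs a > b plus half-ties.
bf_mann_whitney_u <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Independent Fisher two-sided p by explicit hypergeometric enumeration
# (point-probability rule), written from choose() rather than dhyper().
bf_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); mm <- sum(tab[2, ]); k1 <- sum(tab[, 1]); n <- m + mm
  supp <- max(0, k1 - mm):min(m, k1)
  pr <- choose(m, supp) * choose(mm, k1 - supp) / choose(n, k1)
  p_obs <- choose(m, tab[1, 1]) * choose(mm, k1 - tab[1, 1]) / choose(n, k1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# Midrank helper written independently of rank(): average position of equal
# values in the sorted order.
bf_midrank <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}
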