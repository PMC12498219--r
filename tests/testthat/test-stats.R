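test_that("spearman correlation: exact cases and frozen oracle value", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman_test(x, x)$statistic, 1)
  expect_equal(spearman_test(x, -x)$statistic, -1)
  expect_equal(spearman_test(x, x)$p_value, 0)
  # midrank-Pearson oracle: x = 1..5, y = (2,1,4,3,5) -> sum d^2 = 4,
  # r = 1 - 6*4/(5*24) = 0.8
  expect_equal(spearman_test(1:5, c(2, 1, 4, 3, 5))$statistic, 0.8)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 1:2), ">= 3")
})

test_that("spearman matches cor.test and the explicit midrank oracle", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.5 * x
    if (i > 5) { x <- round(x); y <- round(y) }  # force ties
    ours <- spearman_test(x, y)
    # independent midrank-Pearson computation
    rx <- bf_midrank(x); ry <- bf_midrank(y)
    r_bf <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(ours$statistic, r_bf, tolerance = 1e-12)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(ours$statistic, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(ours$p_value, ct$p.value, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney U: exact cases, frozen value, brute-force oracle", {
  expect_equal(mann_whitney_test(1:3, 4:6)$statistic, 0)
  expect_equal(mann_whitney_test(c(2, 4, 6), c(2, 4, 6))$p_value, 1)
  # brute-force pair counting: a = (1,3,5), b = (2,4) -> pairs a > b: (3,2),
  # (5,2), (5,4) -> U = 3
  expect_equal(mann_whitney_test(c(1, 3, 5), c(2, 4))$statistic, 3)
  set.seed(7)
  for (i in 1:20) {
    a <- sample(1:50, sample(2:12, 1), replace = i %% 2 == 0)
    b <- sample(1:50, sample(2:12, 1), replace = i %% 2 == 0)
    expect_equal(mann_whitney_test(a, b)$statistic, bf_mann_whitney_u(a, b))
  }
})

test_that("Mann-Whitney exact p matches wilcox.test on tie-free samples", {
  set.seed(11)
  for (i in 1:10) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1))
    ours <- mann_whitney_test(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("contingency tests: chi-square and Fisher branches", {
  bal <- matrix(c(5, 5, 5, 5), 2)
  r <- contingency_test(bal)
  expect_identical(r$method, "chi_square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # diagonal table: all expected cells = 5 -> chi-square by default,
  # Fisher on request; frozen enumeration value 2 / C(20,10)
  diag20 <- matrix(c(10, 0, 0, 10), 2)
  f <- contingency_test(diag20, force_fisher = TRUE)
  expect_identical(f$method, "fisher_exact")
  expect_equal(f$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  # small expected counts switch to Fisher automatically
  small <- matrix(c(3, 1, 0, 4), 2)
  expect_identical(contingency_test(small)$method, "fisher_exact")
  # doubling both rows leaves the odds-ratio estimate unchanged
  t1 <- matrix(c(8, 3, 2, 9), 2)
  expect_equal(contingency_test(t1)$odds_ratio,
               contingency_test(2 * t1)$odds_ratio)
  expect_error(contingency_test(matrix(0, 2, 2)), "all-zero")
  expect_error(contingency_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("Fisher p agrees with fisher.test on random tables", {
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ours <- contingency_test(tab, force_fisher = TRUE)
    expect_equal(ours$p_value, fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("logistic IRLS matches glm and the 2x2 closed form", {
  set.seed(5)
  n <- 400
  X <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X$x1 - 1.1 * X$x2))
  ours <- logistic_fit(y, X)
  ref <- glm(y ~ x1 + x2, data = X, family = binomial)
  expect_equal(unname(ours$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(ours$se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  # score-equation identity: fitted probabilities sum to the event count
  expect_lt(abs(sum(ours$fitted) - sum(y)), 1e-6)
  # single binary covariate: slope = log odds ratio of the 2x2 table
  f1 <- logistic_fit(y, X["x2"])
  tab <- table(factor(X$x2, c(1, 0)), factor(y, c(1, 0)))
  expect_equal(unname(f1$coefficients[2]),
               log(tab[1, 1] * tab[2, 2] / (tab[1, 2] * tab[2, 1])),
               tolerance = 1e-8)
  expect_error(logistic_fit(rep(1, n), X), "both classes")
})

test_that("null covariates are not significant under a fixed seed", {
  set.seed(123)
  n <- 1000
  x <- rnorm(n)
  y <- rbinom(n, 1, 0.3)
  f <- logistic_fit(y, data.frame(x = x))
  expect_lt(abs(f$coefficients["x"]), 3 * f$se["x"])
})

test_that("separation warns under plain MLE and is finite under Firth", {
  x <- c(rnorm(20, -2), rnorm(20, 2))
  y <- rep(c(0, 1), each = 20)
  expect_warning(logistic_fit(y, data.frame(x = x)), "separation")
  ff <- logistic_fit(y, data.frame(x = x), model = "firth")
  expect_true(ff$converged)
  expect_true(all(is.finite(ff$coefficients)))
  expect_lt(abs(ff$coefficients["x"]), 10)
})

test_that("backward elimination: identity at alpha 1 and signal recovery", {
  set.seed(21)
  n <- 2000
  X <- as.data.frame(matrix(rnorm(n * 6), n,
                            dimnames = list(NULL, c("true", paste0("noise", 1:5)))))
  y <- rbinom(n, 1, plogis(-1 + 1.2 * X$true))
  full <- backward_select(y, X, alpha_remove = 1.0)
  expect_identical(full$table$variable, names(X))
  expect_identical(nrow(full$elimination_trace), 0L)
  sel <- backward_select(y, X, alpha_remove = 0.05)
  expect_true("true" %in% sel$table$variable)
  expect_true(all(sel$table$p_value <= 0.05))
  expect_true(all(sel$table$ci_low <= sel$table$odds_ratio &
                    sel$table$odds_ratio <= sel$table$ci_high))
  # all-noise model may reduce to intercept-only without error
  y0 <- rbinom(n, 1, 0.2)
  null_sel <- backward_select(y0, X[, 2:4], alpha_remove = 0.05)
  expect_true(all(null_sel$table$p_value <= 0.05))
})

test_that("cohort slope recovery and analysis permutation invariance", {
  co <- simulate_cohort(cohort_params(n_patients = 5000, seed = 14,
                                      copy_slope_hc_gain = -6))
  g <- (co$gain_rhc + co$gain_lhc) / 2
  fit <- logistic_fit(as.integer(co$rcft_copy_z < -2), data.frame(gain_hc = g))
  # at n = 5000 the slope SE is ~0.65 (7% events, gain SD 0.085); recovery is
  # asserted at 3 SE, with the SE itself bounded so the check has teeth
  expect_lt(fit$se[["gain_hc"]], 1)
  expect_lt(abs(fit$coefficients[["gain_hc"]] - (-6)), 3 * fit$se[["gain_hc"]])

  small <- simulate_cohort(cohort_params(n_patients = 400, seed = 2))
  a1 <- run_primary_analysis(small, sensitivity = FALSE)
  perm <- small[sample(nrow(small)), ]
  a2 <- run_primary_analysis(perm, sensitivity = FALSE)
  expect_equal(a1$copy_model$table, a2$copy_model$table, tolerance = 1e-9)
  expect_equal(a1$correlations$r, a2$correlations$r, tolerance = 1e-12)
})

test_that("null cohort shows no gain association", {
  co <- simulate_cohort(cohort_params(n_patients = 5000, seed = 6,
                                      copy_slope_hc_gain = 0,
                                      copy_intercept = qlogis(0.073)))
  g <- (co$gain_rhc + co$gain_lhc) / 2
  r <- spearman_test(g, as.numeric(co$true_copy_abnormal))$statistic
  expect_lt(abs(r), 0.1)
})
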