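test_that("full-combinatorial ratios enumerate all pairs", {
  expect_equal(full_combinatorial_ratios(1, 2)$ratios, 0.5)
  rs <- full_combinatorial_ratios(c(1, 2), c(1, 2, 4))
  expect_length(rs$ratios, 6)
  expect_equal(rs$n_pre, 2)
  expect_equal(rs$n_base, 3)
  # double-loop oracle on a random 10 x 10 set
  a <- with_seed(1, rlnorm(10))
  b <- with_seed(2, rlnorm(10))
  oracle <- numeric(0)
  for (i in 1:10) for (j in 1:10) oracle <- c(oracle, a[i] / b[j])
  expect_equal(sort(full_combinatorial_ratios(a, b)$ratios), sort(oracle))
  expect_error(full_combinatorial_ratios(c(1, -1), 1), "positive")
  expect_error(full_combinatorial_ratios(numeric(0), 1), "nonempty")
})

test_that("inhibition statistic is 1 - median with midpoint convention", {
  expect_equal(inhibition_statistic(full_combinatorial_ratios(1:3, 1:3)), 0)
  expect_equal(inhibition_statistic(rep(0.5, 9)), 0.5)
  r <- with_seed(3, rlnorm(101))
  expect_equal(inhibition_statistic(r), 1 - sort(r)[51]) # sort-based oracle
  r2 <- c(0.2, 0.4, 0.6, 0.8)
  expect_equal(inhibition_statistic(r2), 1 - 0.5) # even count: central mean
  # invariance under common amplitude scaling
  a <- with_seed(4, rlnorm(15))
  b <- with_seed(5, rlnorm(15))
  s1 <- inhibition_statistic(full_combinatorial_ratios(a, b))
  s2 <- inhibition_statistic(full_combinatorial_ratios(7.7 * a, 7.7 * b))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("bootstrap SE is seeded, zero for constants, and calibrated", {
  expect_equal(bootstrap_se(rep(2, 5), rep(4, 5), 200, seed = 1)$se, 0)
  b1 <- bootstrap_se(c(1, 2, 3), c(2, 3, 4), 500, seed = 9)
  b2 <- bootstrap_se(c(1, 2, 3), c(2, 3, 4), 500, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_error(bootstrap_se(1, c(1, 2), 10, 1), "at least two")

  # calibration: bootstrap SE within 10 % of the Monte-Carlo sampling SD of
  # the statistic over fresh datasets (15 gap / 15 no-gap, log-normal)
  sim_stat <- function(seed) {
    a <- with_seed(2 * seed, rlnorm(15, 0, 0.4)) * 0.5
    b <- with_seed(2 * seed + 1, rlnorm(15, 0, 0.4))
    inhibition_statistic(full_combinatorial_ratios(a, b))
  }
  mc_sd <- sd(vapply(1:1000, sim_stat, numeric(1)))
  # the SE of a single dataset fluctuates ~ n^-1/2 across datasets, so the
  # calibration check compares the average bootstrap SE over fresh datasets
  bses <- vapply(1:30, function(k) {
    a0 <- with_seed(200000 + 2 * k, rlnorm(15, 0, 0.4)) * 0.5
    b0 <- with_seed(200001 + 2 * k, rlnorm(15, 0, 0.4))
    bootstrap_se(a0, b0, 2000, seed = 77 + k)$se
  }, numeric(1))
  expect_lt(abs(mean(bses) - mc_sd) / mc_sd, 0.10)
})

test_that("log-normal MLE recovers parameters and obeys scaling", {
  # degenerate inputs rejected
  expect_error(fit_lognormal(rep(exp(1), 4)), "variance")
  expect_error(fit_lognormal(c(1, 0)), "positive")
  # parameter recovery at n = 1e5
  A <- with_seed(2024, rlnorm(1e5, meanlog = 0.5, sdlog = 0.2))
  fit <- fit_lognormal(A)
  expect_equal(fit$mu, 0.5, tolerance = 0.003)
  expect_equal(fit$sigma, 0.2, tolerance = 0.002)
  # closed-form ML identities on a small sample
  A2 <- c(0.5, 1.2, 3.1, 0.9)
  f2 <- fit_lognormal(A2)
  expect_equal(f2$mu, mean(log(A2)))
  expect_equal(f2$sigma, sqrt(mean((log(A2) - f2$mu)^2)))
  expect_equal(f2$loglik, sum(dlnorm(A2, f2$mu, f2$sigma, log = TRUE)))
  # scaling A by k shifts mu by log k, sigma unchanged
  f3 <- fit_lognormal(5 * A2)
  expect_equal(f3$mu, f2$mu + log(5))
  expect_equal(f3$sigma, f2$sigma)
})

test_that("lognormality check accepts log-normal ratios, flags uniform ones", {
  expect_error(lognormality_check(rep(1.5, 4)), "at least 8")
  # log-normal simulated ratios: non-rejection at alpha = 0.01 in >= 95 %
  n_reject <- 0
  for (i in 1:200) {
    r <- with_seed(i, rlnorm(225, 0, 0.5))
    if (lognormality_check(r)$p_value < 0.01) n_reject <- n_reject + 1
  }
  expect_lte(n_reject / 200, 0.05)
  # uniform ratios on [10, 11]: strong deviation in the QQ tails
  ru <- with_seed(999, runif(2000, 10, 11))
  rep_u <- lognormality_check(ru)
  tail_dev <- max(abs(rep_u$qq_dev[c(1:20, 1981:2000)]))
  expect_gt(tail_dev, 0.3)
  expect_lt(rep_u$p_value, 0.01)
})

test_that("hard-sigmoid fit recovers parameters and honours the zero floor", {
  lv <- seq(2, 26, 2)
  truth <- c(threshold = 10, slope = 0.05, saturation = 0.8)
  y <- pmin(pmax(truth["slope"] * (lv - truth["threshold"]), 0), truth["saturation"])
  fit <- fit_hard_sigmoid(lv, y)
  expect_equal(fit$threshold_dbspl, 10, tolerance = 1e-6)
  expect_equal(fit$slope, 0.05, tolerance = 1e-6)
  expect_equal(fit$saturation, 0.8, tolerance = 1e-6)
  # the fitted residual never exceeds that of the generating parameters
  expect_lte(fit$rss, sum((y - y)^2) + 1e-12)
  # the fitted curve is exactly zero below threshold
  f_at <- pmin(pmax(fit$slope * (5 - fit$threshold_dbspl), 0), fit$saturation)
  expect_identical(f_at, 0)
  # all-zero PPI: explicit no-threshold flag
  fit0 <- fit_hard_sigmoid(lv, numeric(length(lv)))
  expect_true(fit0$no_threshold)
  expect_true(is.na(fit0$threshold_dbspl))
  # noisy recovery: sigma = 0.05 noise, 100 replicates, median error <= 1 dB
  errs <- vapply(1:100, function(i) {
    yn <- y + with_seed(5000 + i, rnorm(length(y), 0, 0.05))
    abs(fit_hard_sigmoid(lv, yn)$threshold_dbspl - 10)
  }, numeric(1))
  expect_lte(median(errs), 1)
  # non-monotone garbage still yields a finite best fit
  garbage <- with_seed(1, runif(13, -0.2, 0.6))
  fg <- fit_hard_sigmoid(lv, garbage)
  expect_true(is.finite(fg$rss))
  expect_error(fit_hard_sigmoid(c(1, 2, 3), c(0, 0.1, 0.2)), "4 distinct")
})

test_that("rank-sum comparison matches exact enumeration and wilcox.test", {
  # identical groups: exact two-sided p = 1
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # disjoint support, n = 5/5: p = 2 / choose(10, 5)
  p <- compare_groups(1:5, 6:10)$p_value
  expect_equal(p, 2 / choose(10, 5))
  # exhaustive-permutation oracle for n = 4/4 random data
  a <- with_seed(11, rnorm(4))
  b <- with_seed(12, rnorm(4) + 0.5)
  got <- compare_groups(a, b)$p_value
  rk <- rank(c(a, b))
  e_w <- 4 * 9 / 2
  w_obs <- sum(rk[1:4])
  sets <- combn(8, 4)
  ws <- colSums(matrix(rk[sets], nrow = 4))
  expect_equal(got, mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9))
  # large-sample branch agrees with the tie-corrected normal approximation
  x <- with_seed(13, rnorm(20))
  y <- with_seed(14, rnorm(25) + 0.4)
  ours <- compare_groups(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "at least 3")
})

test_that("session-level analysis tables are wired to the statistics", {
  # GPIAS: two frequencies, known inhibition applied to gap amplitudes
  amp <- expand.grid(kind = c("gap", "nogap"), freq = c(4000, 8000),
    rep = 1:15, stringsAsFactors = FALSE)
  base <- with_seed(31, rlnorm(nrow(amp), 0, 0.4))
  amp$amplitude <- ifelse(amp$kind == "gap", 0.5 * base, base)
  amp$habituation <- FALSE
  res <- analyze_gpias(amp, n_bootstrap = 500, seed = 1)
  expect_equal(nrow(res), 2)
  expect_equal(res$n_gap, c(15, 15))
  expect_true(all(abs(res$gpias - 0.5) < 3 * res$se))

  # threshold: PPI rises with level following the generating sigmoid
  lv <- seq(2, 26, 2)
  tone <- expand.grid(level = lv, rep = 1:30)
  tone$kind <- "tone"
  tone$freq <- 2000
  inh <- pmin(pmax(0.05 * (tone$level - 10), 0), 0.8)
  tone$amplitude <- with_seed(32, rlnorm(nrow(tone), 0, 0.4)) * (1 - inh)
  notone <- data.frame(
    level = NA, rep = 1:390, kind = "notone", freq = NA,
    amplitude = with_seed(33, rlnorm(390, 0, 0.4))
  )
  tbl <- rbind(tone, notone)
  tbl$habituation <- FALSE
  res_t <- analyze_threshold(tbl)
  expect_equal(nrow(res_t$ppi), 13)
  fit <- res_t$fits[["2000"]]
  expect_false(fit$no_threshold)
  expect_lt(abs(fit$threshold_dbspl - 10), 2)
})
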