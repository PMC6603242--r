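#' Full-combinatorial set of amplitude ratios
#'
#' All pairwise ratios between pre-stimulus-trial amplitudes and
#' baseline-trial amplitudes, `A_pre[i] / A_base[j]`. Their median defines the
#' inhibition statistic ([inhibition_statistic()]).
#'
#' @param A_pre positive amplitudes of the pre-stimulus trials (gap / tone).
#' @param A_base positive amplitudes of the baseline trials (no gap / no
#'   tone).
#' @return an object of class `ratio_set` with fields `ratios`, `n_pre`,
#'   `n_base`.
#' @export
full_combinatorial_ratios <- function(A_pre, A_base) {
  if (!length(A_pre) || !length(A_base)) stop("both groups must be nonempty")
  if (any(A_pre <= 0) || any(A_base <= 0)) {
    stop("amplitudes must be strictly positive")
  }
  structure(
    list(
      ratios = as.numeric(outer(A_pre, A_base, `/`)),
      n_pre = length(A_pre), n_base = length(A_base)
    ),
    class = "ratio_set"
  )
}

#' Inhibition statistic (PPI / GPIAS)
#'
#' `1 - median(ratios)`: zero when pre-stimulus and baseline amplitudes are
#' interchangeable, approaching 1 for complete suppression of the startle.
#' The median of an even-length set is the mean of the central pair.
#'
#' @param r a [full_combinatorial_ratios()] result or a positive numeric
#'   vector of ratios.
#' @return scalar statistic (<= 1).
#' @export
inhibition_statistic <- function(r) {
  ratios <- if (inherits(r, "ratio_set")) r$ratios else as.numeric(r)
  if (!length(ratios)) stop("ratio set is empty")
  1 - median(ratios)
}

#' Bootstrap standard error of the inhibition statistic
#'
#' Resamples the pre-stimulus and baseline amplitude sets independently with
#' replacement, recomputes the median of the full-combinatorial ratios for
#' each replicate, and reports the standard deviation of the replicate
#' statistics as the standard error of the median-based inhibition statistic.
#'
#' @param A_pre,A_base positive amplitude vectors, each of length >= 2.
#' @param n_bootstrap number of bootstrap replicates (default 100000).
#' @param seed integer seed.
#' @return an object of class `inhibition_result` with fields `statistic`
#'   (the point estimate on the original data), `se`, `n_bootstrap`, and
#'   `replicates` (the bootstrap statistics).
#' @export
bootstrap_se <- function(A_pre, A_base, n_bootstrap = 100000, seed = 1) {
  if (length(A_pre) < 2 || length(A_base) < 2) {
    stop("bootstrap needs at least two trials in each group")
  }
  if (any(A_pre <= 0) || any(A_base <= 0)) {
    stop("amplitudes must be strictly positive")
  }
  stat <- inhibition_statistic(full_combinatorial_ratios(A_pre, A_base))
  np <- length(A_pre)
  nb <- length(A_base)
  reps <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      p <- A_pre[sample.int(np, np, replace = TRUE)]
      b <- A_base[sample.int(nb, nb, replace = TRUE)]
      1 - median(outer(p, b, `/`))
    }, numeric(1))
  })
  structure(
    list(
      statistic = stat, se = sd(reps), n_bootstrap = as.integer(n_bootstrap),
      replicates = reps
    ),
    class = "inhibition_result"
  )
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf(
    "<inhibition: %.4f +/- %.4f (SE of median, %d bootstrap replicates)>\n",
    x$statistic, x$se, x$n_bootstrap
  ))
  invisible(x)
}

#' Maximum-likelihood log-normal fit
#'
#' Closed-form MLE of the log-normal distribution: `mu = mean(log A)`,
#' `sigma = sqrt(mean((log A - mu)^2))` (the biased/ML scale estimate).
#'
#' @param A positive amplitudes, n >= 2, with nonzero variance.
#' @return an object of class `lognormal_fit` with fields `mu`, `sigma`,
#'   `loglik`, `n`.
#' @export
fit_lognormal <- function(A) {
  if (length(A) < 2) stop("need at least two observations")
  if (any(A <= 0)) stop("amplitudes must be strictly positive")
  la <- log(A)
  mu <- mean(la)
  sigma <- sqrt(mean((la - mu)^2))
  if (sigma == 0) stop("zero variance: log-normal scale is degenerate")
  structure(
    list(
      mu = mu, sigma = sigma,
      loglik = sum(dlnorm(A, mu, sigma, log = TRUE)), n = length(A)
    ),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal fit: mu %.4f, sigma %.4f, loglik %.2f, n %d>\n",
    x$mu, x$sigma, x$loglik, x$n
  ))
  invisible(x)
}

#' Check log-normality of a ratio set
#'
#' Descriptive check that the logarithmized ratios are Gaussian: returns the
#' Shapiro-Wilk statistic and p-value of `log(ratios)` together with normal
#' QQ coordinates and their deviations. Shapiro-Wilk is limited to 5000
#' observations; larger sets are thinned deterministically (evenly spaced
#' order statistics).
#'
#' @param ratios positive ratio vector, n >= 8 (or a `ratio_set`).
#' @return list of class `lognormality_report`: `statistic`, `p_value`,
#'   `qq_theoretical`, `qq_sample` (standardized sorted log ratios),
#'   `qq_dev`, `n`.
#' @export
lognormality_check <- function(ratios) {
  if (inherits(ratios, "ratio_set")) ratios <- ratios$ratios
  if (length(ratios) < 8) stop("need at least 8 ratios")
  if (any(ratios <= 0)) stop("ratios must be strictly positive")
  lr <- log(ratios)
  lr_test <- sort(lr)
  if (length(lr_test) > 5000) {
    lr_test <- lr_test[round(seq(1, length(lr_test), length.out = 5000))]
  }
  sw <- shapiro.test(lr_test)
  z <- sort((lr - mean(lr)) / sd(lr))
  n <- length(z)
  theo <- qnorm((seq_len(n) - 0.5) / n)
  structure(
    list(
      statistic = unname(sw$statistic), p_value = sw$p.value,
      qq_theoretical = theo, qq_sample = z, qq_dev = z - theo, n = n
    ),
    class = "lognormality_report"
  )
}

hard_sigmoid <- function(x, threshold, slope, saturation) {
  pmin(pmax(slope * (x - threshold), 0), saturation)
}

#' Fit a hard-sigmoid stimulus-response function
#'
#' Least-squares fit of the piecewise-linear saturating function
#' \eqn{f(x) = \min(\max(m (x - \theta), 0), s)} to PPI values as a function
#' of pre-stimulus level. The lower asymptote is fixed at zero (for
#' sub-threshold pre-stimuli the startle is uninhibited), so the fitted
#' breakpoint \eqn{\theta} — where the function diverges from zero — is the
#' estimated sensory threshold. The fit uses a 0.1 dB threshold grid spanning
#' the level range with a per-gridpoint fit of slope and saturation, followed
#' by continuous joint refinement.
#'
#' @param levels_dbspl pre-stimulus levels in dB SPL (>= 4 distinct values).
#' @param ppi_values PPI statistic per level.
#' @param weights optional fit weights (use `1/se^2` for
#'   inverse-variance weighting).
#' @return an object of class `hard_sigmoid_fit`: `threshold_dbspl`, `slope`
#'   (PPI per dB), `saturation`, `rss`, `no_threshold` (TRUE when the PPI
#'   never rises above zero so no threshold exists).
#' @export
fit_hard_sigmoid <- function(levels_dbspl, ppi_values, weights = NULL) {
  x <- as.numeric(levels_dbspl)
  y <- as.numeric(ppi_values)
  if (length(x) != length(y)) stop("levels and PPI values differ in length")
  if (length(unique(x)) < 4) stop("need at least 4 distinct levels")
  w <- weights %||% rep(1, length(x))
  if (length(w) != length(x) || any(w < 0)) stop("invalid weights")

  if (all(y <= 0)) {
    return(structure(
      list(
        threshold_dbspl = NA_real_, slope = NA_real_, saturation = NA_real_,
        rss = sum(w * y^2), no_threshold = TRUE
      ),
      class = "hard_sigmoid_fit"
    ))
  }

  rss_of <- function(p) {
    sum(w * (y - hard_sigmoid(x, p[1], p[2], p[3]))^2)
  }
  lower <- c(min(x) - 20, 1e-8, 1e-8)
  upper <- c(max(x) + 20, Inf, 1)
  s0 <- min(max(max(y), 0.05), 1)
  fit_given_th <- function(th) {
    m0 <- max((s0 * 0.9) / max(max(x) - th, 1), 1e-4)
    nlminb(c(m0, s0), function(q) rss_of(c(th, q[1], q[2])),
      lower = lower[2:3], upper = upper[2:3],
      control = list(iter.max = 200)
    )
  }
  grid <- seq(min(x), max(x), by = 0.1)
  grid_rss <- vapply(grid, function(th) fit_given_th(th)$objective, numeric(1))
  th_best <- grid[which.min(grid_rss)]
  inner <- fit_given_th(th_best)
  refined <- nlminb(c(th_best, inner$par),
    rss_of,
    lower = lower, upper = upper,
    control = list(
      iter.max = 500, eval.max = 1000, abs.tol = 0,
      rel.tol = 1e-15, x.tol = 1e-12
    )
  )
  p <- refined$par
  structure(
    list(
      threshold_dbspl = p[1], slope = p[2], saturation = p[3],
      rss = refined$objective, no_threshold = FALSE
    ),
    class = "hard_sigmoid_fit"
  )
}

#' @export
print.hard_sigmoid_fit <- function(x, ...) {
  if (x$no_threshold) {
    cat("<hard-sigmoid fit: no threshold (PPI never leaves zero)>\n")
  } else {
    cat(sprintf(
      "<hard-sigmoid fit: threshold %.2f dB SPL, slope %.4f /dB, saturation %.3f, rss %.4g>\n",
      x$threshold_dbspl, x$slope, x$saturation, x$rss
    ))
  }
  invisible(x)
}

#' Two-sided Mann-Whitney U rank-sum comparison of two groups
#'
#' For small samples (combined n <= 12) the exact permutation distribution of
#' the rank sum is enumerated (midranks, so ties are handled); for larger
#' samples the normal approximation with tie correction is used.
#'
#' @param stats_a,stats_b numeric vectors of per-animal statistics, each of
#'   length >= 3.
#' @return list of class `ranksum_result`: `p_value`, `u`, `method`.
#' @export
compare_groups <- function(stats_a, stats_b) {
  na <- length(stats_a)
  nb <- length(stats_b)
  if (na < 3 || nb < 3) stop("both groups must have at least 3 observations")
  pooled <- c(stats_a, stats_b)
  n <- na + nb
  rk <- rank(pooled) # midranks
  w_obs <- sum(rk[seq_len(na)])
  u_obs <- w_obs - na * (na + 1) / 2
  e_w <- na * (n + 1) / 2
  if (n <= 12) {
    sets <- combn(n, na)
    ws <- colSums(matrix(rk[sets], nrow = na))
    p <- mean(abs(ws - e_w) >= abs(w_obs - e_w) - 1e-9)
    method <- "exact permutation"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (w_obs - e_w) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation with tie correction"
  }
  structure(
    list(p_value = p, u = u_obs, method = method),
    class = "ranksum_result"
  )
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf(
    "<rank-sum test: U = %g, two-sided p = %.4g (%s)>\n",
    x$u, x$p_value, x$method
  ))
  invisible(x)
}

#' GPIAS statistics from a per-trial amplitude table
#'
#' For each background-noise center frequency, computes the GPIAS statistic
#' (1 minus the median of the full-combinatorial gap/no-gap amplitude ratios)
#' with its bootstrap standard error. Habituation trials are excluded.
#'
#' @param amplitudes data frame with columns `kind`, `freq`, `amplitude` and
#'   optionally `habituation` (logical).
#' @param n_bootstrap bootstrap replicates per frequency (default 10000).
#' @param seed integer seed.
#' @return data frame with columns `freq`, `n_gap`, `n_nogap`, `gpias`, `se`.
#' @export
analyze_gpias <- function(amplitudes, n_bootstrap = 10000, seed = 1) {
  tbl <- amplitudes
  if ("habituation" %in% names(tbl)) tbl <- tbl[!tbl$habituation, ]
  tbl <- tbl[tbl$kind %in% c("gap", "nogap"), ]
  if (!nrow(tbl)) stop("no gap/nogap trials in the table")
  freqs <- sort(unique(tbl$freq))
  rows <- lapply(seq_along(freqs), function(i) {
    f <- freqs[i]
    a_gap <- tbl$amplitude[tbl$kind == "gap" & tbl$freq == f]
    a_nogap <- tbl$amplitude[tbl$kind == "nogap" & tbl$freq == f]
    res <- bootstrap_se(a_gap, a_nogap, n_bootstrap, trial_seed(seed, i))
    data.frame(
      freq = f, n_gap = length(a_gap), n_nogap = length(a_nogap),
      gpias = res$statistic, se = res$se
    )
  })
  do.call(rbind, rows)
}

#' Threshold-paradigm statistics from a per-trial amplitude table
#'
#' Computes the PPI per (frequency, level) condition against the pooled
#' no-tone baseline of the session, optionally with bootstrap standard
#' errors, and fits a hard-sigmoid stimulus-response function per frequency
#' to estimate the hearing threshold.
#'
#' @param amplitudes data frame with columns `kind`, `freq`, `level`,
#'   `amplitude` and optionally `habituation`.
#' @param n_bootstrap bootstrap replicates per condition; 0 disables SEs
#'   (default 0).
#' @param seed integer seed.
#' @param weighted fit the sigmoid with inverse-variance weights (requires
#'   `n_bootstrap > 0`).
#' @return list with `ppi` (data frame: `freq`, `level`, `n_tone`, `ppi`,
#'   `se`) and `fits` (named list of [fit_hard_sigmoid()] results per
#'   frequency).
#' @export
analyze_threshold <- function(amplitudes, n_bootstrap = 0, seed = 1,
                              weighted = n_bootstrap > 0) {
  tbl <- amplitudes
  if ("habituation" %in% names(tbl)) tbl <- tbl[!tbl$habituation, ]
  base <- tbl$amplitude[tbl$kind == "notone"]
  tone <- tbl[tbl$kind == "tone", ]
  if (!nrow(tone) || length(base) < 2) {
    stop("need tone trials and at least two no-tone baseline trials")
  }
  cond <- unique(tone[, c("freq", "level")])
  cond <- cond[order(cond$freq, cond$level), ]
  rows <- lapply(seq_len(nrow(cond)), function(i) {
    a <- tone$amplitude[tone$freq == cond$freq[i] & tone$level == cond$level[i]]
    if (n_bootstrap > 0) {
      res <- bootstrap_se(a, base, n_bootstrap, trial_seed(seed, i))
      data.frame(
        freq = cond$freq[i], level = cond$level[i], n_tone = length(a),
        ppi = res$statistic, se = res$se
      )
    } else {
      data.frame(
        freq = cond$freq[i], level = cond$level[i], n_tone = length(a),
        ppi = inhibition_statistic(full_combinatorial_ratios(a, base)),
        se = NA_real_
      )
    }
  })
  ppi <- do.call(rbind, rows)
  fits <- lapply(split(ppi, ppi$freq), function(sub) {
    wts <- if (weighted && all(is.finite(sub$se)) && all(sub$se > 0)) {
      1 / sub$se^2
    } else {
      NULL
    }
    fit_hard_sigmoid(sub$level, sub$ppi, wts)
  })
  list(ppi = ppi, fits = fits)
}
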