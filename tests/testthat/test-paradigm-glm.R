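# Localizer paradigm, HRF, design matrix, filtering and GLM.

test_that("paradigm invariants hold across many random seeds", {
  for (seed in seq_len(300)) {
    p <- generate_paradigm(seed)
    expect_equal(nrow(p$trials), 144L)
    expect_equal(as.numeric(table(p$trials$condition)), rep(36, 4))
    expect_equal(sum(p$trials$is_target), 36L)
    expect_equal(as.numeric(table(p$trials$condition[p$trials$is_target])), rep(9, 4))
    expect_length(p$prolonged_iti_after, 11L)
    gaps <- diff(c(0, p$prolonged_iti_after))
    expect_true(all(gaps >= 10 & gaps <= 14))
    expect_equal(p$total_duration, 340)
    # onsets consistent with 2-s trials, 0-ms regular ITI and the schedule
    expect_equal(p$trials$onset[1], 10)
    d_on <- diff(p$trials$onset)
    expect_true(all(d_on %in% c(2, 4)))
    expect_equal(which(d_on == 4), p$prolonged_iti_after)
  }
  # no prolonged ITIs and no lead-in/out: 144 x 2 s
  expect_equal(generate_paradigm(1, n_prolonged = 0, lead_in = 0, lead_out = 0)$total_duration,
               288)
})

test_that("two-gamma kernel has the canonical shape", {
  dt <- 0.01
  h <- two_gamma_hrf(dt)
  expect_equal(h[1], 0)
  expect_equal((which.max(h) - 1) * dt, 5, tolerance = dt)
  # exactly one sign change after the peak (response lobe -> undershoot)
  after <- h[seq(which.max(h), length(h))]
  flips <- sum(diff(sign(after[after != 0])) != 0)
  expect_equal(flips, 1L)
  expect_error(two_gamma_hrf(0), "dt")
  expect_error(two_gamma_hrf(-1), "dt")
})

test_that("design matrix models 166 volumes and matches an oracle convolution", {
  d <- design1()
  expect_equal(nrow(d$matrix), 166L)                   # 170 acquired - 4 discarded
  expect_equal(colnames(d$matrix), c("LL", "LR", "UL", "UR", "constant"))
  expect_true(all(colSums(abs(d$matrix[, 1:4])) > 0))
  # regressors bounded by HRF peak x maximum trial overlap
  hrf <- two_gamma_hrf(0.1)
  bound <- max(hrf) * max(table(paradigm1()$trials$condition)) * 2 # 2 s trials
  expect_true(all(d$matrix[, 1:4] <= bound))
  expect_true(all(d$matrix[, 1:4] >= -1))              # bounded undershoot
  # single-trial regressor peaks near onset + HRF peak (+ trial duration / 2):
  # keep one trial per condition, with the probed trial isolated at 10 s
  p1 <- generate_paradigm(1)
  p1$trials <- p1$trials[match(c("LL", "LR", "UL", "UR"), p1$trials$condition), ]
  p1$trials$onset <- c(10, 150, 200, 250)
  p1$trials$condition <- factor(c("LL", "LR", "UL", "UR"),
                                levels = levels(p1$trials$condition))
  d1 <- build_design(p1, n_discard = 0)
  reg <- d1$matrix[, "LL"]
  # oracle: direct convolution on a fine grid
  dt <- 0.01
  grid <- seq(0, 340, dt)
  box <- as.numeric(grid >= 10 & grid < 12)
  oracle <- stats::convolve(box, rev(two_gamma_hrf(dt)), type = "open")[seq_along(grid)] * dt
  expect_equal(d1$frame_times[which.max(reg)], grid[which.max(oracle)],
               tolerance = d1$TR)
  samp <- oracle[round(d1$frame_times / dt) + 1]
  expect_gt(cor(reg, samp), 0.999)
  # a condition without any event is rejected
  p_bad <- generate_paradigm(2)
  p_bad$trials <- p_bad$trials[p_bad$trials$condition != "UL", ]
  expect_error(build_design(p_bad), "no events")
})

test_that("high-pass filtering removes trend and sub-cutoff components only", {
  TR <- 2; T_len <- 166
  t <- (seq_len(T_len) - 1) * TR
  # linear ramp -> constant
  expect_lt(sd(highpass_and_detrend(3 + 0.5 * t, TR)), 1e-10)
  # bin-aligned slow component (0.006 Hz < 0.00903): its Fourier bins are
  # zeroed exactly; the small remaining power is detrending leakage
  f_lo <- 2 / (T_len * TR)
  s_lo <- sin(2 * pi * f_lo * t)
  out_lo <- highpass_and_detrend(s_lo, TR)
  expect_lt(max(Mod(fft(out_lo)[2:3])), 1e-9)
  expect_lt(sum(out_lo^2) / sum(s_lo^2), 0.05)
  # pass-band component (0.05 Hz) is essentially untouched
  s_hi <- sin(2 * pi * 0.05 * t)
  expect_gt(sum(highpass_and_detrend(s_hi, TR)^2) / sum(s_hi^2), 0.95)
  expect_error(highpass_and_detrend(rnorm(5), TR), "8 samples")
  expect_error(highpass_and_detrend(rnorm(50), TR, cutoff = 0.3), "Nyquist")
})

test_that("GLM is exact least squares with correct t statistics", {
  d <- design1()
  X <- d$matrix
  set.seed(2)
  B_true <- matrix(rnorm(15), 3, 5)
  expect_lt(max(abs(fit_glm(B_true %*% t(X), d)$betas - B_true)), 1e-8)
  # one regressor, bold = 2 x regressor -> beta = 2
  one <- structure(list(matrix = cbind(r = X[, 1])), class = "design_matrix")
  expect_equal(unname(fit_glm(matrix(2 * X[, 1], 1), one)$betas[1, 1]), 2)
  # rank-deficient design names the collinear column
  bad <- cbind(X, dup_LL = X[, "LL"])
  expect_error(fit_glm(matrix(rnorm(2 * 166), 2, 166), bad), "dup_LL|LL")
  # t statistic equals the closed form on noisy data
  set.seed(3)
  Y <- matrix(rnorm(20 * nrow(X)), 20)
  fit <- fit_glm(Y, d)
  cvec <- c(poi_contrast("LR"), constant = 0)
  tt <- contrast_t(fit, poi_contrast("LR"))
  XtXinv <- solve(crossprod(X))
  for (i in c(1, 7, 20)) {
    b <- solve(crossprod(X), crossprod(X, Y[i, ]))
    s2 <- sum((Y[i, ] - X %*% b)^2) / (nrow(X) - ncol(X))
    t_or <- sum(cvec * b) / sqrt(s2 * t(cvec) %*% XtXinv %*% cvec)
    expect_equal(tt[i], as.numeric(t_or), tolerance = 1e-10)
  }
  expect_error(contrast_t(fit, rep(0, 4)), "zero")
  expect_error(contrast_t(fit, c(1, 1)), "4")
})

test_that("contrast t handles degenerate cases as documented", {
  d <- design1()
  X <- d$matrix
  # equal betas cancel under (+3, -1, -1, -1)
  Y <- matrix(rowSums(X[, 1:4]), 1)
  fit <- fit_glm(Y + rnorm(ncol(Y), sd = 0.01), d)
  tt <- contrast_t(fit, poi_contrast("LL"))
  expect_lt(abs(tt[1]), 5)      # numerator ~ 0 against noise-scale denominator
  # noiseless single-condition signal: capped and flagged
  fit0 <- fit_glm(matrix(X[, "LL"], 1), d)
  t0 <- contrast_t(fit0, poi_contrast("LL"))
  expect_true(attr(t0, "capped")[1])
  expect_equal(as.numeric(t0[1]), 1e6)
})

test_that("null data produce the nominal extreme-t rate", {
  d <- design1()
  set.seed(11)
  Y <- matrix(rnorm(20000 * 166), 20000)
  tt <- as.numeric(contrast_t(fit_glm(Y, d), poi_contrast("UL")))
  # P(|t| > 4) at 161 dof is ~ 8e-5; require the observed rate below 0.1%
  expect_lt(mean(abs(tt) > 4), 0.001)
})

test_that("beta recovery is unbiased with noise-proportional RMSE", {
  d <- design1()
  X <- d$matrix
  set.seed(13)
  b_true <- c(LL = 1, LR = 0, UL = 0, UR = 0, constant = 100)
  signal <- as.numeric(X %*% b_true)
  est <- function(sd_n) {
    Y <- matrix(rep(signal, each = 400), 400, byrow = FALSE) +
      matrix(rnorm(400 * length(signal), sd = sd_n), 400)
    fit_glm(Y, d)$betas[, "LL"]
  }
  b1 <- est(1); b4 <- est(4)
  expect_lt(abs(mean(b1) - 1), 0.02)                  # bias < 2%
  expect_lt(sd(b1), sd(b4))                           # RMSE grows with noise
})

test_that("event-related averages separate conditions with 36 epochs each", {
  p <- paradigm1()
  # constant series: flat curves with zero SEM, all 36 epochs complete
  er <- event_related_average(rep(1.5, 170), p)
  expect_true(all(er$mean == 1.5))
  expect_true(all(er$sem == 0))
  expect_true(all(er$n_epochs == 36))
  # with isolated trials an LL-only response dominates the LL curve
  # (the continuous 0-ms-ITI design overlaps responses, so build a sparse
  # probe paradigm: 5 trials per condition, 30 s apart)
  ps <- p
  onsets <- 10 + 30 * (0:19)
  ps$trials <- tibble::tibble(
    trial = 1:20,
    condition = factor(rep(c("LL", "LR", "UL", "UR"), 5),
                       levels = levels(p$trials$condition)),
    onset = onsets, duration = 2, is_target = FALSE
  )
  hrf <- two_gamma_hrf(2)
  series <- numeric(350)
  for (o in onsets[ps$trials$condition == "LL"]) {
    idx <- o / 2 + 1 + seq_along(hrf) - 1
    series[idx] <- series[idx] + 5 * hrf
  }
  er2 <- event_related_average(series[1:330], ps)
  pk <- tapply(er2$mean, er2$condition, max)
  expect_gt(pk[["LL"]], 3 * max(abs(pk[c("LR", "UL", "UR")])))
  # short series: truncation is reported
  expect_warning(event_related_average(rep(1, 100), p), "truncated")
})
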