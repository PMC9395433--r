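# Group evaluation statistics: RFX t maps, thresholds, ROIs, probability
# maps, peak distributions and the position-selectivity comparison.

test_that("RFX group t equals the one-sample formula with zero-variance guards", {
  set.seed(1)
  M <- matrix(rnorm(200 * 6), 200, 6)
  tt <- rfx_group_tmap(M)
  expect_equal(attr(tt, "df"), 5L)
  oracle <- apply(M, 1, function(x) mean(x) / (sd(x) / sqrt(length(x))))
  expect_equal(as.numeric(tt), oracle, tolerance = 1e-10)
  # identical nonzero maps: capped guard everywhere
  C <- matrix(2, 50, 4)
  tc <- rfx_group_tmap(C)
  expect_true(all(attr(tc, "capped")))
  expect_true(all(tc == 1e6))
  # mean-zero (1, -1) pattern gives t = 0
  expect_equal(as.numeric(rfx_group_tmap(cbind(1, -1, 1, -1)))[1], 0)
  expect_error(rfx_group_tmap(M[, 1:2]), "3 subjects")
})

test_that("Bonferroni thresholds reproduce the published analysis-space values", {
  expect_equal(signif(bonferroni_threshold(0.05, 52504), 2), 9.5e-7)
  expect_equal(signif(bonferroni_threshold(0.05, 76132), 2), 6.6e-7)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("group ROI extraction follows the seed rule over the size rule", {
  m <- mesh3()
  tmap <- rep(-1, m$n_vertices)
  # nothing above threshold -> explicit not-found value
  r0 <- extract_group_roi(tmap, m, 0, seed = 1L)
  expect_false(r0$found)
  expect_equal(r0$size, 0L)
  # one suprathreshold disc is returned whole
  disc <- geodesic_disc(m, c(0, 0, 1), 0.3)
  tmap[disc] <- 5
  r1 <- extract_group_roi(tmap, m, 0, seed = which.max(m$vertices[, 3]))
  expect_true(r1$found)
  expect_equal(sort(r1$vertices), sort(disc))
  expect_equal(r1$peak_vertex, disc[which.max(tmap[disc])])
  # two components, seed inside the smaller: seed wins over size
  small <- geodesic_disc(m, c(0, 0, -1), 0.15)
  tmap[small] <- 3
  seed_v <- small[1]
  r2 <- extract_group_roi(tmap, m, 0, seed = seed_v)
  expect_equal(sort(r2$vertices), sort(small))
  expect_lt(r2$size, length(disc))
  # distance cutoff turns a far-away component into not-found
  r3 <- extract_group_roi(tmap, m, 4, seed = seed_v, max_seed_distance = 0.05)
  expect_false(r3$found)     # only the big disc exceeds t = 4, too far away
})

test_that("ROI size change reproduces the published table cells", {
  expect_equal(size_change(47, 295), 528)
  expect_equal(size_change(4, 82), 1950)
  expect_equal(size_change(28, 127), 354)
  expect_equal(size_change(10, 10), 0)
  expect_error(size_change(0, 5), "at least 1")
})

test_that("asymmetry index reproduces the published table cells and is symmetric", {
  expect_equal(asymmetry_index(295, 28), 82.7)
  expect_equal(asymmetry_index(161, 58), 47.0)
  expect_equal(asymmetry_index(4, 3), 14.3)
  expect_equal(asymmetry_index(47, 6), 77.4)
  expect_equal(asymmetry_index(161, 127), 11.8)
  expect_equal(asymmetry_index(7, 7), 0)
  expect_equal(asymmetry_index(10, 30), asymmetry_index(30, 10))
  expect_error(asymmetry_index(0, 0), "undefined")
})

test_that("single-subject thresholding matches the t-quantile oracle", {
  tm <- c(-3, 0, 1.6, 1.66, 5, 10)
  for (dof in c(10L, 100L, 161L)) {
    crit <- qt(0.95, dof)
    expect_equal(single_subject_map(tm, dof), tm > crit)
  }
  expect_true(all(single_subject_map(rep(10, 4), 100)))
  expect_false(any(single_subject_map(rep(0, 4), 100)))
  expect_error(single_subject_map(tm, 0), "dof")
})

test_that("probability maps equal brute-force counting in steps of 100/n", {
  set.seed(7)
  n_v <- 300; n_s <- 50
  maps <- lapply(seq_len(n_s), function(s) runif(n_v) < 0.3)
  pm <- probability_map(maps)
  oracle <- vapply(seq_len(n_v), function(v) {
    sum(vapply(maps, `[`, logical(1), v)) / n_s * 100
  }, numeric(1))
  expect_equal(pm$values, oracle)
  step <- 100 / n_s
  expect_true(all(abs(pm$values - round(pm$values / step) * step) < 1e-9))
  expect_true(all(pm$values >= 0 & pm$values <= 100))
  # 1 of 50 subjects -> 2%
  one <- c(list(rep(TRUE, 4)), replicate(49, rep(FALSE, 4), simplify = FALSE))
  expect_equal(probability_map(one)$values, rep(2, 4))
  # display threshold and cluster filter
  m <- mesh2()
  maps2 <- replicate(10, logical(m$n_vertices), simplify = FALSE)
  disc <- geodesic_disc(m, c(0, 0, 1), 0.4)
  for (s in 1:10) maps2[[s]][disc] <- TRUE
  maps2[[1]][7] <- TRUE          # isolated single-subject vertex (10%)
  pm2 <- probability_map(maps2, m, min_prob = 10, cluster_threshold = 5)
  expect_equal(sum(pm2$values > 0), length(disc))
})

test_that("probability-map extent counts suprathreshold vertices exactly", {
  vals <- c(rep(0, 10), rep(12, 7), rep(9.9, 3))
  pm <- structure(list(values = vals, n_subjects = 50,
                       threshold_info = list()), class = "probability_map")
  expect_equal(pm_extent(pm), 7)
  expect_equal(pm_extent(rep(0, 5)), 0)
  expect_equal(pm_extent(vals, min_prob = 5), 10)
})

test_that("probability difference maps are antisymmetric with correct extrema", {
  a <- c(50, 20, 0, 80, 10)
  b <- c(10, 25, 0, 80, 22)
  pdm <- probability_difference_map(a, b)
  expect_equal(pdm$values, a - b)
  expect_equal(pdm$pd_pos, 40)
  expect_equal(pdm$pd_neg, -12)
  expect_equal(pdm$focus_pos, 1L)
  expect_equal(pdm$n_exceed, 3L)     # +40, -5, -12
  swap <- probability_difference_map(b, a)
  expect_equal(swap$values, -pdm$values)
  zero <- probability_difference_map(a, a)
  expect_true(all(zero$values == 0))
  expect_equal(zero$n_exceed, 0L)
})

test_that("peak vertices use the lowest-index tie rule and match exhaustive argmax", {
  set.seed(9)
  tm <- rnorm(500)
  roi <- sample(500, 60)
  expect_equal(peak_vertex(tm, roi), roi[which.max(tm[roi])][1])
  expect_equal(peak_vertex(tm, 17L), 17L)
  expect_true(is.na(peak_vertex(tm, integer(0))))
  tm2 <- rep(1, 10)
  expect_equal(peak_vertex(tm2, c(9L, 4L, 6L)), 4L)   # tie -> lowest index
})

test_that("peak distributions conserve detected subjects across multiplicities", {
  peaks <- list(
    c(LL = 5L, LR = 9L, UL = 2L, UR = NA),
    c(LL = 5L, LR = 10L, UL = 3L, UR = 7L),
    c(LL = 5L, LR = 11L, UL = NA, UR = 7L)
  )
  pd <- peak_distribution(peaks, 20L)
  expect_equal(pd$detected[["LL"]], 3L)
  expect_equal(pd$detected[["UR"]], 2L)
  expect_equal(max(pd$counts$LL), 3L)       # all three at vertex 5
  expect_equal(max(pd$counts$LR), 1L)       # all distinct
  # conservation: sum(multiplicity x n_vertices) = detected subjects
  for (q in names(pd$detected)) {
    h <- pd$histogram[pd$histogram$quadrant == q, ]
    expect_equal(sum(h$multiplicity * h$n_vertices), as.integer(pd$detected[[q]]))
  }
})

test_that("detection success rates reproduce the published values", {
  expect_equal(detection_success_rate(49, 50), 98)
  expect_equal(detection_success_rate(47, 50), 94)
  expect_equal(detection_success_rate(45, 50), 90)
  expect_equal(detection_success_rate(0, 10), 0)
  expect_equal(mean(detection_success_rate(c(49, 47, 49, 45), 50)), 95)
  expect_error(detection_success_rate(5, 0), "n_total")
  expect_error(detection_success_rate(11, 10), "exceed")
})

test_that("the position-selectivity test matches a sums-of-squares oracle", {
  # 4-subject, 3-arm fixture
  df <- expand.grid(subject = 1:4, arm = c("A", "B", "C"))
  set.seed(21)
  df$score <- rnorm(12) + rep(c(0, 0.5, 1), each = 4) + rep(rnorm(4), 3)
  got <- position_selectivity_test(df)
  # from-scratch two-way sums of squares (arm effect, subject blocks)
  g <- mean(df$score)
  arm_m <- tapply(df$score, df$arm, mean)
  sub_m <- tapply(df$score, df$subject, mean)
  ss_arm <- 4 * sum((arm_m - g)^2)
  ss_sub <- 3 * sum((sub_m - g)^2)
  ss_tot <- sum((df$score - g)^2)
  ss_err <- ss_tot - ss_arm - ss_sub
  f_or <- (ss_arm / 2) / (ss_err / 6)
  expect_equal(got$statistic, f_or, tolerance = 1e-8)
  expect_equal(got$num_df, 2)
  expect_equal(got$den_df, 6)
  expect_equal(got$p_value, pf(f_or, 2, 6, lower.tail = FALSE), tolerance = 1e-10)
  # identical scores in every arm: F = 0, p = 1
  df0 <- df; df0$score <- rep(rnorm(4), 3)
  z <- position_selectivity_test(df0)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # a large constant arm shift is detected at n = 20
  df2 <- expand.grid(subject = 1:20, arm = c("A", "B"))
  set.seed(3)
  df2$score <- rnorm(40) + ifelse(df2$arm == "B", 3, 0)
  expect_lt(position_selectivity_test(df2)$p_value, 0.001)
  expect_error(position_selectivity_test(df2[df2$arm == "A", ]), "2 alignment arms")
})

test_that("the mixed-model route agrees with the ANOVA F on balanced data", {
  df <- expand.grid(subject = factor(1:8), arm = c("A", "B", "C"))
  set.seed(5)
  df$score <- rnorm(24) + rep(c(0, 1, 2), each = 8) + rep(rnorm(8, sd = 2), 3)
  a <- position_selectivity_test(df, method = "anova")
  l <- position_selectivity_test(df, method = "lmm")
  expect_equal(l$statistic, a$statistic, tolerance = 1e-4)
  expect_equal(l$num_df, a$num_df)
})
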