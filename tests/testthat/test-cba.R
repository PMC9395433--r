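# Curvature-driven spherical alignment: rigid search, non-rigid morphing,
# moving-target group alignment and warp application.

test_that("rigid alignment returns the identity for identical maps and a valid rotation", {
  tpl <- template4()
  m <- tpl$sphere
  cs <- smooth_map(tpl$curvature, m, 200)
  R <- rigid_align(cs, cs, m)
  expect_lt(rotation_angle(R) * 180 / pi, 1)
  expect_lt(max(abs(t(unclass(R)) %*% unclass(R) - diag(3))), 1e-9)
  expect_equal(det(unclass(R)), 1, tolerance = 1e-9)
  expect_error(rigid_align(rep(1, m$n_vertices), cs, m), "constant")
})

test_that("rigid alignment recovers a known rotation within 2 degrees", {
  tpl <- template4()
  m <- tpl$sphere
  cv <- as.numeric(tpl$curvature)
  set.seed(3)
  for (rep in 1:2) {
    Q <- cortexalign:::euler_rotation(runif(1, 0, 2 * pi), runif(1, 0, pi),
                                      runif(1, 0, 2 * pi))
    # rotated copy: c_subj(v) = c_template(Q' v), so the expected recovery is Q'
    cs <- resample_map(m, cv, m$vertices %*% Q, "barycentric")
    R <- rigid_align(smooth_map(cs, m, 50), smooth_map(cv, m, 50), m)
    expect_lt(rotation_angle(unclass(R) %*% Q) * 180 / pi, 2)
  }
})

test_that("non-rigid morphing is monotone and inert on already-aligned input", {
  tpl <- template3()
  m <- tpl$sphere
  cs <- smooth_map(tpl$curvature, m, 20)
  res <- nonrigid_align_level(m$vertices, cs, cs, m)
  expect_equal(res$accepted, 0L)                     # nothing to do
  expect_equal(res$warp, m$vertices)
  # huge regulariser pins the warp to the identity
  ct <- smooth_map(make_template(3, seed = 11)$curvature, m, 20)
  res_pin <- nonrigid_align_level(m$vertices, cs, ct, m, lambda = 1e12)
  expect_lt(max(geodesic_distance(res_pin$warp, m$vertices)), 1e-6)
  # morphing toward a different target: objective trace non-increasing
  res2 <- nonrigid_align_level(m$vertices, cs, ct, m, max_iter = 30)
  expect_true(all(diff(res2$trace) <= 0))
  expect_true(all(abs(sqrt(rowSums(res2$warp^2)) - 1) < 1e-9))
  expect_true(all(cortexalign:::face_orientations(res2$warp, m$faces) > 0))
})

test_that("known-warp correspondence recovery reaches under 40% of the initial error", {
  tpl <- template4()
  m <- tpl$sphere
  cv <- as.numeric(tpl$curvature)
  w <- make_warp(m, 0.12, smoothness = 0.4, seed = 21)
  cs <- resample_map(m, cv, w, "barycentric")
  init_err <- mean(correspondence_error(m$vertices, w, m))
  si <- c(200, 80, 20, 2)
  W <- m$vertices
  for (lev in 1:4) {
    cs_l <- smooth_map(cs, m, si[lev])
    ct_l <- smooth_map(cv, m, si[lev])
    for (rep in 1:3) {
      res <- nonrigid_align_level(W, cs_l, ct_l, m, max_iter = 150)
      W <- res$warp
      if (res$accepted < 150) break
    }
  }
  expect_lt(mean(correspondence_error(W, w, m)) / init_err, 0.40)
})

test_that("the moving-average target equals the resample-then-mean oracle", {
  tpl <- template3()
  m <- tpl$sphere
  set.seed(5)
  curvs <- lapply(1:3, function(s) rnorm(m$n_vertices))
  warps <- lapply(1:3, function(s) make_warp(m, 0.1, seed = s))
  avg <- moving_average_target(curvs, warps, m)
  oracle <- Reduce(`+`, lapply(1:3, function(s) {
    resample_map(m, curvs[[s]], warps[[s]], "barycentric")
  })) / 3
  expect_equal(avg, oracle, tolerance = 1e-12)
  # identical subjects under identity warps: average equals any input
  idw <- replicate(2, m$vertices, simplify = FALSE)
  expect_equal(moving_average_target(list(curvs[[1]], curvs[[1]]), idw, m),
               curvs[[1]], tolerance = 1e-12)
  expect_error(moving_average_target(curvs[1], warps[1], m), "2 subjects")
})

test_that("group alignment of identical subjects stays at the identity", {
  tpl <- template3()
  m <- tpl$sphere
  curvs <- replicate(4, as.numeric(tpl$curvature), simplify = FALSE)
  res <- run_group_cba(curvs, m,
                       cba_params(updates_per_level = 1, iters_per_update = 5))
  for (W in res$warps) {
    expect_lt(max(geodesic_distance(W, m$vertices)), 0.02)
  }
  cors <- cor(sapply(seq_along(curvs), function(s) {
    resample_map(m, curvs[[s]], res$warps[[s]], "barycentric")
  }))
  expect_true(all(cors > 0.9999))
  # per-level objective traces never increase
  for (tr in res$objective_trace) expect_true(all(diff(tr) <= 1e-9))
})

test_that("group alignment increases pairwise curvature correlation on a warped cohort", {
  tpl <- template3()
  m <- tpl$sphere
  cv <- as.numeric(tpl$curvature)
  set.seed(10)
  curvs <- lapply(1:5, function(s) {
    resample_map(m, cv, make_warp(m, 0.15, seed = 100 + s), "barycentric") +
      rnorm(m$n_vertices, sd = 0.05)
  })
  pairwise <- function(warps) {
    M <- sapply(seq_along(curvs), function(s) {
      resample_map(m, curvs[[s]], warps[[s]], "barycentric")
    })
    cm <- cor(M)
    mean(cm[upper.tri(cm)])
  }
  before <- pairwise(replicate(5, m$vertices, simplify = FALSE))
  res <- run_group_cba(curvs, m, cba_params(updates_per_level = 2,
                                            iters_per_update = 15))
  expect_gt(pairwise(res$warps), before)
})

test_that("the second pass uses the pass-1 average as its rigid target", {
  tpl <- template3()
  m <- tpl$sphere
  cv <- as.numeric(tpl$curvature)
  set.seed(12)
  curvs <- lapply(1:4, function(s) {
    resample_map(m, cv, make_warp(m, 0.12, seed = 200 + s), "barycentric")
  })
  res <- two_pass_cba(curvs, m, cba_params(updates_per_level = 1,
                                           iters_per_update = 8))
  expect_s3_class(res, "two_pass_cba")
  expect_identical(as.numeric(res$pass1$final_group_curvature),
                   as.numeric(res$pass1_average))
  # structural: pass 2 was seeded by the pass-1 average, not an individual
  expect_false(isTRUE(all.equal(as.numeric(res$pass1_average), curvs[[1]])))
  expect_length(res$warps, 4)
})

test_that("warp application matches resampling oracles and preserves ROI topology", {
  tpl <- template3()
  m <- tpl$sphere
  vals <- as.numeric(tpl$curvature)
  # identity warp leaves a map unchanged
  expect_equal(apply_warp_to_map(vals, m$vertices, m), vals, tolerance = 1e-12)
  # a pure rotation warp equals the rotation-resampled oracle
  R <- cortexalign:::euler_rotation(0.4, 0.3, 0.2)
  W <- m$vertices %*% R
  expect_equal(apply_warp_to_map(vals, W, m, "nearest"),
               vals[nearest_vertex(m, W)])
  # binary ROI transport at a small warp stays connected
  w <- make_warp(m, 0.08, seed = 31)
  mask <- numeric(m$n_vertices)
  mask[tpl$quadrant_rois$LL] <- 1
  moved <- apply_warp_to_map(mask, w, m, "nearest")
  comp <- connected_components(m, which(moved > 0))
  expect_length(comp, 1L)
})

test_that("average folded meshes behave under identity, mirroring and duplication", {
  tpl <- template3()
  m <- tpl$sphere
  f <- tpl$folded
  idw <- list(m$vertices)
  expect_equal(average_folded_mesh(list(f), idw, m)$vertices, f$vertices,
               tolerance = 1e-12)
  # identical subjects: average equals the input
  avg2 <- average_folded_mesh(list(f, f), list(m$vertices, m$vertices), m)
  expect_equal(avg2$vertices, f$vertices, tolerance = 1e-12)
  # a subject and its mirror image about x = 0 average onto the plane
  mir <- f$vertices
  mir[, 1] <- -mir[, 1]
  avg_m <- average_folded_mesh(list(f$vertices, mir),
                               list(m$vertices, m$vertices), m)
  expect_lt(max(abs(avg_m$vertices[, 1])), 1e-9)
})

test_that("correspondence error is zero for perfect recovery and equals displacement at identity", {
  tpl <- template3()
  m <- tpl$sphere
  w <- make_warp(m, 0.1, seed = 17)
  err_id <- correspondence_error(m$vertices, w, m)
  expect_equal(err_id, geodesic_distance(w, m$vertices), tolerance = 1e-6)
  # for a rotation warp the inverse is known in closed form: the exact
  # inverse estimate drives the error to interpolation noise
  R <- cortexalign:::euler_rotation(0.3, 0.2, 0.1)
  true_rot <- m$vertices %*% R
  err_rot_id <- correspondence_error(m$vertices, true_rot, m)
  err_rot_inv <- correspondence_error(m$vertices %*% t(R), true_rot, m)
  expect_gt(mean(err_rot_id), 0.2)
  expect_lt(mean(err_rot_inv), 0.01)
})
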