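# Spherical mesh construction, curvature, smoothing, resampling.

test_that("icosphere construction gives the closed-form vertex counts and a valid manifold", {
  expect_equal(mesh0()$n_vertices, 12L)            # icosahedron
  expect_equal(mesh3()$n_vertices, 642L)           # 10 * 4^3 + 2
  for (m in list(mesh0(), mesh2(), mesh4())) {
    expect_equal(euler_characteristic(m), 2L)
    expect_true(all(abs(sqrt(rowSums(m$vertices^2)) - 1) < 1e-9))
    # neighbor symmetry: u in N(v) <=> v in N(u)
    sym <- vapply(seq_len(m$n_vertices), function(v) {
      all(vapply(m$neighbors[[v]], function(u) v %in% m$neighbors[[u]], logical(1)))
    }, logical(1))
    expect_true(all(sym))
    # outward winding: all spherical face orientations positive
    expect_true(all(cortexalign:::face_orientations(m$vertices, m$faces) > 0))
  }
  # the full-scale standard mesh
  expect_equal(build_icosphere(6)$n_vertices, 40962L)
  expect_error(build_icosphere(-1), "subdivisions")
  expect_error(build_icosphere(8), "subdivisions")
})

test_that("coarser subdivision levels are vertex prefixes of finer ones", {
  expect_equal(mesh4()$vertices[seq_len(642), ], mesh3()$vertices)
})

test_that("curvature of a sphere is constant, positive, and scale invariant", {
  m <- mesh4()
  cv <- mean_curvature(folded_mesh(m, m$vertices * 80))
  expect_lt((max(cv) - min(cv)) / abs(mean(cv)), 1e-6)
  expect_gt(mean(cv), 0)                          # convex => positive
  cv2 <- mean_curvature(folded_mesh(m, m$vertices * 160))
  expect_equal(as.numeric(cv), as.numeric(cv2))   # rescaling convention
})

test_that("curvature of a Gaussian bump matches the analytic sign pattern", {
  m <- mesh4()
  A <- 25; s <- 0.15; R <- 80
  d <- geodesic_distance(m$vertices, c(0, 0, 1))
  folded <- folded_mesh(m, m$vertices * (R + A * exp(-(d / s)^2 / 2)))
  cv <- mean_curvature(folded)
  apex <- which.min(d)
  # analytic mean curvature of the surface of revolution r(theta):
  # meridional curvature from the polar-curve formula, azimuthal from the
  # normal ray; evaluated on a fine grid to find the negative-mean band
  th <- seq(1e-3, 1, length.out = 3000)
  r <- R + A * exp(-(th / s)^2 / 2)
  dr <- -A * th / s^2 * exp(-(th / s)^2 / 2)
  ddr <- A * ((th / s)^2 - 1) / s^2 * exp(-(th / s)^2 / 2)
  k_mer <- (r^2 + 2 * dr^2 - r * ddr) / (r^2 + dr^2)^(3 / 2)
  # azimuthal principal curvature: component of the unit normal toward the axis
  nrm <- cbind(r, -dr) / sqrt(r^2 + dr^2)  # (radial, tangential) in the meridian plane
  k_az <- (nrm[, 1] * sin(th) + nrm[, 2] * cos(th)) / (r * sin(th))
  h_mean <- (k_mer + k_az) / 2
  neg_band <- range(th[h_mean < 0])
  expect_true(any(h_mean < 0))                    # fixture produces a concave ring
  expect_equal(which.max(as.numeric(cv)), apex)   # positive extremum at the apex
  ring <- d > neg_band[1] + 0.02 & d < neg_band[2] - 0.02
  expect_lt(mean(as.numeric(cv)[ring]), 0)        # negative ring at the base
})

test_that("curvature errors on degenerate faces, naming one", {
  m <- mesh0()
  bad <- m$vertices * 10
  bad[m$faces[1, 2], ] <- bad[m$faces[1, 1], ]    # collapse an edge
  expect_error(folded_mesh(m, bad), "degenerate")
})

test_that("1-ring smoothing follows the averaging stencil and contracts", {
  m0 <- mesh0()
  expect_equal(smooth_map(rep(2, 12), m0, 7), rep(2, 12))   # fixed point
  imp <- numeric(12); imp[1] <- 1
  s <- smooth_map(imp, m0, 1)
  deg <- length(m0$neighbors[[1]])
  expect_equal(s[1], 1 / (deg + 1))
  expect_equal(s[m0$neighbors[[1]]], rep(1 / (deg + 1), deg))
  expect_equal(sum(s > 0), deg + 1)
  # convergence to a constant on the connected mesh
  set.seed(1)
  v <- rnorm(mesh2()$n_vertices)
  s2 <- smooth_map(v, mesh2(), 10000)
  expect_lt(max(s2) - min(s2), 1e-6)
  # contraction of the range, monotone in iterations
  rng <- vapply(c(1, 3, 10, 30), function(it) diff(range(smooth_map(v, mesh2(), it))),
                numeric(1))
  expect_true(all(diff(rng) < 0))
  expect_error(smooth_map(v, mesh2(), -1), "iterations")
})

test_that("nearest resampling equals exhaustive search; barycentric interpolates", {
  m <- mesh3()
  set.seed(4)
  vals <- rnorm(m$n_vertices)
  q <- random_directions(200, seed = 5)
  nn <- nearest_vertex(m, q)
  oracle <- apply(q, 1, function(p) which.max(m$vertices %*% p))
  expect_equal(nn, oracle)
  expect_equal(resample_map(m, vals, q, "nearest"), vals[oracle])
  # at a vertex both methods reproduce that vertex's value
  idx <- c(3L, 100L, 642L)
  expect_equal(resample_map(m, vals, m$vertices[idx, ], "nearest"), vals[idx])
  expect_equal(resample_map(m, vals, m$vertices[idx, ], "barycentric"), vals[idx],
               tolerance = 1e-12)
  # face centroid with vertex values (0, 0, 3) -> 1
  m0 <- mesh0()
  f <- m0$faces[4, ]
  cen <- colMeans(m0$vertices[f, ]); cen <- cen / sqrt(sum(cen^2))
  v0 <- numeric(12); v0[f[3]] <- 3
  expect_equal(resample_map(m0, v0, cen, "barycentric"), 1)
  expect_error(resample_map(m, vals, c(1, 1, 0)), "unit")
})

test_that("warm-started nearest search matches the cold start", {
  m <- mesh4()
  q <- cortexalign:::unit_rows(m$vertices + 0.05 * random_directions(m$n_vertices, seed = 8))
  expect_equal(nearest_vertex(m, q, init = seq_len(m$n_vertices)),
               nearest_vertex(m, q))
})

test_that("multiscale curvature has 4 levels with strictly decreasing smoothing", {
  tpl <- template3()
  ms <- multiscale_curvature(tpl$curvature, tpl$sphere)
  expect_length(ms$levels, 4)
  expect_true(all(diff(ms$smoothing_iterations) < 0))
  # heavier smoothing has smaller range
  rngs <- vapply(ms$levels, function(x) diff(range(x)), numeric(1))
  expect_true(all(diff(rngs) > 0))
  expect_error(multiscale_curvature(tpl$curvature, tpl$sphere, iterations = c(5, 5, 2, 1)),
               "decreasing")
})

test_that("surface and map files round-trip through OBJ and CSV", {
  m <- mesh2()
  tf <- tempfile(fileext = ".obj")
  write_surface_obj(m, tf)
  back <- read_surface_obj(tf)
  expect_equal(back$vertices, m$vertices, tolerance = 1e-7)
  expect_equal(back$faces, matrix(as.integer(m$faces), ncol = 3))
  vals <- scalar_map(seq_len(m$n_vertices) / 7, m, label = "demo")
  tc <- tempfile(fileext = ".csv")
  write_map_csv(vals, tc)
  got <- read_map_csv(tc)
  expect_equal(as.numeric(got), as.numeric(vals))
  expect_equal(attr(got, "label"), "demo")
})
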