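## Curvature-driven cortex-based alignment: rigid rotation search plus
## coarse-to-fine non-rigid morphing toward a dynamically updated group
## average curvature target.

## A warp field is an n x 3 matrix of unit positions: row v is the point on
## the *subject* sphere that group-grid vertex v reads its data from. The
## identity warp is the mesh vertex matrix itself; rigid alignment by R gives
## W = V R (i.e. w(v) = R' v).

euler_rotation <- function(a, b, c) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(c)
}

#' Geodesic angle of a rotation matrix (radians)
#' @param R a 3 x 3 rotation matrix
#' @return rotation angle in [0, pi]
#' @export
rotation_angle <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

#' Rigid spherical alignment by global rotation
#'
#' Finds the rotation maximising the Pearson correlation between the target
#' curvature and the subject curvature resampled through the rotation. Both
#' maps should be at the coarsest smoothing level. The search combines a
#' 15-degree Euler-angle grid evaluated on the coarse icosahedral vertex
#' prefix with Nelder-Mead refinement of the best grid candidates at full
#' resolution; near-ties are broken by the smallest rotation angle.
#'
#' @param subject_curv,target_curv per-vertex curvature maps on `mesh`.
#' @param mesh the shared `sphere_mesh`.
#' @param grid_step Euler grid step in degrees (default 15).
#' @param n_refine number of grid candidates refined by Nelder-Mead.
#' @return 3 x 3 rotation matrix of class `rigid_rotation` with attribute
#'   `"correlation"`.
#' @export
rigid_align <- function(subject_curv, target_curv, mesh, grid_step = 15,
                        n_refine = 6) {
  sc <- as.numeric(subject_curv); tc <- as.numeric(target_curv)
  if (stats::sd(sc) == 0 || stats::sd(tc) == 0) {
    stop("constant curvature map: rigid alignment correlation undefined", call. = FALSE)
  }
  ## stage 1: full Euler grid, scored on the 42-vertex icosahedral prefix
  lev <- min(1L, mesh$subdivisions)
  nc <- level_n_vertices(lev)
  cmesh <- if (mesh$subdivisions == lev) mesh else build_icosphere(lev)
  gs <- rigid_grid_scores(cmesh$vertices, sc[seq_len(nc)], tc[seq_len(nc)],
                          grid_step * pi / 180)
  ord <- order(-gs$score, gs$angle)
  cand <- ord[seq_len(min(n_refine, length(ord)))]
  ## stage 2: Nelder-Mead refinement on a mid-resolution prefix
  mid_lev <- min(3L, mesh$subdivisions)
  mmesh <- if (mesh$subdivisions == mid_lev) mesh else build_icosphere(mid_lev)
  nm <- mmesh$n_vertices
  sc_m <- sc[seq_len(nm)]; tc_m <- tc[seq_len(nm)]
  obj_mid <- function(par) {
    R <- euler_rotation(par[1], par[2], par[3])
    -stats::cor(tc_m, resample_map(mmesh, sc_m, mmesh$vertices %*% R, "barycentric"))
  }
  best_par <- NULL; best_val <- Inf; best_angle <- Inf
  for (i in cand) {
    opt <- stats::optim(c(gs$a[i], gs$b[i], gs$c[i]), obj_mid,
                        method = "Nelder-Mead",
                        control = list(maxit = 150, reltol = 1e-7))
    ang <- rotation_angle(euler_rotation(opt$par[1], opt$par[2], opt$par[3]))
    if (opt$value < best_val - 1e-9 ||
        (opt$value < best_val + 1e-9 && ang < best_angle)) {
      best_par <- opt$par; best_val <- opt$value; best_angle <- ang
    }
  }
  ## stage 3: polish the winner at full resolution
  obj_full <- function(par) {
    R <- euler_rotation(par[1], par[2], par[3])
    -stats::cor(tc, resample_map(mesh, sc, mesh$vertices %*% R, "barycentric"))
  }
  opt <- stats::optim(best_par, obj_full, method = "Nelder-Mead",
                      control = list(maxit = 80, reltol = 1e-8))
  best <- euler_rotation(opt$par[1], opt$par[2], opt$par[3])
  structure(best, correlation = -opt$value, class = c("rigid_rotation", "matrix"))
}

#' Vectorised correlation scores for the full Euler grid at low resolution
#' @noRd
rigid_grid_scores <- function(Vc, sc_c, tc_c, step) {
  aa <- seq(0, 2 * pi - step, by = step)
  bb <- seq(0, pi, by = step)
  g <- expand.grid(a = aa, b = bb, c = aa)
  ca <- cos(g$a); sa <- sin(g$a); cb <- cos(g$b); sb <- sin(g$b)
  cc <- cos(g$c); sc2 <- sin(g$c)
  # entries of R = Rz(a) Ry(b) Rz(c), one value per grid rotation
  R11 <- ca * cb * cc - sa * sc2; R12 <- -ca * cb * sc2 - sa * cc; R13 <- ca * sb
  R21 <- sa * cb * cc + ca * sc2; R22 <- -sa * cb * sc2 + ca * cc; R23 <- sa * sb
  R31 <- -sb * cc;                R32 <- sb * sc2;                 R33 <- cb
  nq <- nrow(Vc); nr <- nrow(g)
  # rotated query coordinates, one nq x nr matrix per coordinate: V %*% R
  Px <- outer(Vc[, 1], R11) + outer(Vc[, 2], R21) + outer(Vc[, 3], R31)
  Py <- outer(Vc[, 1], R12) + outer(Vc[, 2], R22) + outer(Vc[, 3], R32)
  Pz <- outer(Vc[, 1], R13) + outer(Vc[, 2], R23) + outer(Vc[, 3], R33)
  bestd <- matrix(-Inf, nq, nr)
  samp <- matrix(0, nq, nr)
  for (j in seq_len(nq)) {
    d <- Px * Vc[j, 1] + Py * Vc[j, 2] + Pz * Vc[j, 3]
    upd <- d > bestd
    bestd[upd] <- d[upd]
    samp[upd] <- sc_c[j]
  }
  # column-wise Pearson correlation with the target values
  tcc <- tc_c - mean(tc_c)
  sm <- colMeans(samp)
  num <- as.numeric(crossprod(samp, tcc))
  den <- sqrt(pmax(colSums(samp^2) - nq * sm^2, 0) * sum(tcc^2))
  score <- ifelse(den > 0, num / den, -Inf)
  ang <- acos(pmin(1, pmax(-1, (R11 + R22 + R33 - 1) / 2)))
  list(a = g$a, b = g$b, c = g$c, score = score, angle = ang)
}

#' @export
print.rigid_rotation <- function(x, ...) {
  cat(sprintf("<rigid_rotation> angle %.2f deg, alignment correlation %.3f\n",
              rotation_angle(x) * 180 / pi, attr(x, "correlation")))
  invisible(x)
}

## ---- gradient field ---------------------------------------------------------

#' Tangential least-squares gradient of a per-vertex map
#' @noRd
gradient_field <- function(mesh, values) {
  V <- mesh$vertices
  n <- mesh$n_vertices
  nb <- mesh$neighbors
  deg <- lengths(nb)
  j <- unlist(nb, use.names = FALSE)
  i <- rep(seq_len(n), deg)
  d <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
  dc <- values[j] - values[i]
  # per-vertex normal equations A g = b with a small ridge along the normal
  axx <- rowsum(d[, 1]^2, i)[, 1]; axy <- rowsum(d[, 1] * d[, 2], i)[, 1]
  axz <- rowsum(d[, 1] * d[, 3], i)[, 1]; ayy <- rowsum(d[, 2]^2, i)[, 1]
  ayz <- rowsum(d[, 2] * d[, 3], i)[, 1]; azz <- rowsum(d[, 3]^2, i)[, 1]
  b <- rowsum(d * dc, i)
  eps <- 1e-3 * mesh$mean_edge^2
  axx <- axx + eps * V[, 1]^2 + 1e-12; ayy <- ayy + eps * V[, 2]^2 + 1e-12
  azz <- azz + eps * V[, 3]^2 + 1e-12
  axy <- axy + eps * V[, 1] * V[, 2]; axz <- axz + eps * V[, 1] * V[, 3]
  ayz <- ayz + eps * V[, 2] * V[, 3]
  # closed-form symmetric 3x3 inverse (cofactors)
  c11 <- ayy * azz - ayz^2; c12 <- axz * ayz - axy * azz; c13 <- axy * ayz - axz * ayy
  c22 <- axx * azz - axz^2; c23 <- axy * axz - axx * ayz; c33 <- axx * ayy - axy^2
  det <- axx * c11 + axy * c12 + axz * c13
  g <- cbind(
    (c11 * b[, 1] + c12 * b[, 2] + c13 * b[, 3]) / det,
    (c12 * b[, 1] + c22 * b[, 2] + c23 * b[, 3]) / det,
    (c13 * b[, 1] + c23 * b[, 2] + c33 * b[, 3]) / det
  )
  g - row_dots(g, V) * V   # tangential part
}

project_tangent <- function(g, P) g - row_dots(g, P) * P

## ---- non-rigid morphing -----------------------------------------------------

warp_energy <- function(W, cw, ct, mesh, lambda, l0) {
  ed <- sum((cw - ct)^2)
  du <- W[mesh$edges[, 1], , drop = FALSE] - W[mesh$edges[, 2], , drop = FALSE]
  l <- row_norms(du)
  list(total = ed + lambda * sum((l / l0 - 1)^2), data = ed)
}

#' One level of non-rigid curvature-driven morphing
#'
#' Gradient descent with backtracking on the objective
#' `sum_v (c_subj(w(v)) - c_target(v))^2 + lambda sum_e (l(e)/l0(e) - 1)^2`,
#' displacing warp positions tangentially and reprojecting to the unit
#' sphere. Steps that invert a spherical face or increase the objective are
#' halved; the level aborts after 10 consecutive rejected trials.
#'
#' @param warp starting warp field (n x 3 unit positions), e.g. the identity
#'   or the rigid-alignment warp.
#' @param subject_curv subject curvature smoothed to this level.
#' @param target_curv target (group) curvature at the same level.
#' @param mesh the `sphere_mesh` the warp lives on.
#' @param lambda edge-length distortion weight (default 0.02).
#' @param max_iter maximum accepted morph iterations (default 25).
#' @param tol relative objective improvement below which the level stops.
#' @param grad_smooth iterations of 1-ring averaging applied to the descent
#'   direction (Sobolev-gradient preconditioning, default 6). Smoothing the
#'   direction propagates matched motion along iso-curvature contours, where
#'   the raw data gradient vanishes; the objective and its monotone line
#'   search are unchanged.
#' @return list with `warp`, `trace` (objective after each accepted step,
#'   non-increasing), `accepted`.
#' @export
nonrigid_align_level <- function(warp, subject_curv, target_curv, mesh,
                                 lambda = 0.02, max_iter = 25, tol = 1e-5,
                                 grad_smooth = 6) {
  sc <- as.numeric(subject_curv); ct <- as.numeric(target_curv)
  W <- warp
  V <- mesh$vertices
  l0 <- row_norms(V[mesh$edges[, 1], , drop = FALSE] - V[mesh$edges[, 2], , drop = FALSE])
  G <- gradient_field(mesh, sc)
  bw <- barycentric_weights(mesh, W)
  interp <- function(bw, field) {
    if (is.null(dim(field))) {
      rowSums(bw$w * matrix(field[bw$idx], nrow(bw$idx), 3))
    } else {
      out <- bw$w[, 1] * field[bw$idx[, 1], , drop = FALSE]
      out + bw$w[, 2] * field[bw$idx[, 2], , drop = FALSE] +
        bw$w[, 3] * field[bw$idx[, 3], , drop = FALSE]
    }
  }
  cw <- interp(bw, sc)
  en <- warp_energy(W, cw, ct, mesh, lambda, l0)
  trace <- en$total
  eta <- NULL
  accepted <- 0L
  fails <- 0L
  e1 <- mesh$edges[, 1]; e2 <- mesh$edges[, 2]
  while (accepted < max_iter) {
    r <- cw - ct
    gd <- 2 * r * interp(bw, G)
    du <- W[e1, , drop = FALSE] - W[e2, , drop = FALSE]
    l <- row_norms(du)
    coef <- 2 * lambda * (l / l0 - 1) / (l0 * pmax(l, 1e-12))
    ge <- coef * du
    gr <- matrix(0, nrow(W), 3)
    ac1 <- rowsum(ge, e1); gr[as.integer(rownames(ac1)), ] <- ac1
    ac2 <- rowsum(-ge, e2); gr[as.integer(rownames(ac2)), ] <-
      gr[as.integer(rownames(ac2)), ] + ac2
    g <- gd + gr
    if (grad_smooth > 0) g <- smooth_matrix(g, mesh, grad_smooth)
    g <- project_tangent(g, W)
    gmax <- max(abs(g))
    if (gmax < 1e-12) break
    if (is.null(eta)) eta <- 0.1 * mesh$mean_edge / gmax
    improved <- FALSE
    while (fails < 10) {
      W_try <- unit_rows(W - eta * g)
      if (!no_face_inversions(W_try, mesh$faces)) {
        eta <- eta / 2; fails <- fails + 1L; next
      }
      bw_try <- barycentric_weights(mesh, W_try, init = bw$nn)
      cw_try <- interp(bw_try, sc)
      en_try <- warp_energy(W_try, cw_try, ct, mesh, lambda, l0)
      if (en_try$total <= en$total) {
        rel <- (en$total - en_try$total) / max(en$total, .Machine$double.eps)
        W <- W_try; bw <- bw_try; cw <- cw_try; en <- en_try
        trace <- c(trace, en$total)
        accepted <- accepted + 1L
        eta <- eta * 1.3
        fails <- 0L
        improved <- TRUE
        if (rel < tol) fails <- 10L   # converged: leave outer loop below
        break
      }
      eta <- eta / 2; fails <- fails + 1L
    }
    if (!improved || fails >= 10) break
  }
  list(warp = W, trace = trace, accepted = accepted, energy = en$total)
}

#' Dynamically updated group-average curvature target
#'
#' @param subject_curvs list of per-subject curvature maps.
#' @param warps list of warp fields (one per subject).
#' @param mesh the shared `sphere_mesh`.
#' @param method resampling method (default barycentric).
#' @return per-vertex mean of all subject curvatures resampled through their
#'   current warps.
#' @export
moving_average_target <- function(subject_curvs, warps, mesh,
                                  method = "barycentric") {
  if (length(subject_curvs) < 2) stop("need at least 2 subjects", call. = FALSE)
  acc <- numeric(mesh$n_vertices)
  for (s in seq_along(subject_curvs)) {
    acc <- acc + resample_map(mesh, subject_curvs[[s]], warps[[s]], method)
  }
  acc / length(subject_curvs)
}

## ---- group alignment --------------------------------------------------------

#' Alignment schedule and optimisation parameters
#'
#' @param updates_per_level number of moving-target updates per smoothing
#'   level (default 4).
#' @param iters_per_update maximum morph iterations per update (default 25).
#' @param lambda edge-distortion regularisation weight (default 0.02).
#' @param smooth_iters 4 strictly decreasing smoothing iteration counts at
#'   the full mesh resolution (defaults to (200, 80, 20, 2) at
#'   subdivisions = 4, scaled with mesh size).
#' @param coarse_levels logical, length 4: run the level on the next-coarser
#'   icosphere prefix (defaults to the two coarsest levels, which at their
#'   smoothing scales carry no information beyond the coarse mesh).
#' @return a `cba_params` list.
#' @export
cba_params <- function(updates_per_level = 4, iters_per_update = 25,
                       lambda = 0.02, smooth_iters = NULL,
                       coarse_levels = c(TRUE, TRUE, FALSE, FALSE)) {
  structure(
    list(updates_per_level = updates_per_level,
         iters_per_update = iters_per_update, lambda = lambda,
         smooth_iters = smooth_iters, coarse_levels = coarse_levels),
    class = "cba_params"
  )
}

upsample_warp <- function(W, fine_mesh) {
  # append midpoints of the last subdivision step's parent pairs
  par <- fine_mesh$parents[[fine_mesh$subdivisions]]
  rbind(W, unit_rows((W[par[, 1], , drop = FALSE] + W[par[, 2], , drop = FALSE]) / 2))
}

subject_energies <- function(warps, curvs, target, mesh, lambda) {
  l0 <- row_norms(mesh$vertices[mesh$edges[, 1], , drop = FALSE] -
                  mesh$vertices[mesh$edges[, 2], , drop = FALSE])
  vapply(seq_along(warps), function(s) {
    cw <- resample_map(mesh, curvs[[s]], warps[[s]], "barycentric")
    warp_energy(warps[[s]], cw, target, mesh, lambda, l0)$total
  }, numeric(1))
}

#' Run group cortex-based alignment (one pass)
#'
#' Rigid rotation of every subject to the rigid target, then four
#' coarse-to-fine levels of non-rigid morphing toward the dynamically updated
#' group-average curvature. Within each level the recorded group objective is
#' non-increasing (morph steps are monotone and each target update minimises
#' the summed data term).
#'
#' @param curvatures list of per-subject curvature maps on `mesh`.
#' @param mesh the shared `sphere_mesh`.
#' @param params a [cba_params()].
#' @param rigid_target curvature map used for the rigid stage (default: the
#'   first subject).
#' @param rigid TRUE to run the rigid stage (default) or FALSE to start from
#'   identity warps.
#' @return object of class `cba_alignment`: `rotations`, `warps` (per
#'   subject, n x 3), `objective_trace` (list per level),
#'   `final_group_curvature`, `params`.
#' @export
run_group_cba <- function(curvatures, mesh, params = cba_params(),
                          rigid_target = NULL, rigid = TRUE) {
  n_sub <- length(curvatures)
  if (n_sub < 2) stop("need at least 2 subjects", call. = FALSE)
  curvatures <- lapply(curvatures, as.numeric)
  if (any(lengths(curvatures) != mesh$n_vertices)) {
    stop("all curvature maps must share the mesh topology", call. = FALSE)
  }
  si <- params$smooth_iters
  if (is.null(si)) si <- default_level_iterations(mesh$subdivisions)
  use_coarse <- params$coarse_levels & mesh$subdivisions >= 3
  cmesh <- if (any(use_coarse)) build_icosphere(mesh$subdivisions - 1L) else NULL

  ## rigid stage on the heaviest smoothing
  rotations <- vector("list", n_sub)
  if (rigid) {
    rt <- as.numeric(if (is.null(rigid_target)) curvatures[[1]] else rigid_target)
    rt_s <- smooth_map(rt, mesh, si[1])
    warps <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      R <- rigid_align(smooth_map(curvatures[[s]], mesh, si[1]), rt_s, mesh)
      rotations[[s]] <- R
      warps[[s]] <- mesh$vertices %*% unclass(R)
    }
  } else {
    warps <- replicate(n_sub, mesh$vertices, simplify = FALSE)
  }

  trace <- vector("list", 4)
  on_coarse <- FALSE
  for (lev in 1:4) {
    lev_coarse <- use_coarse[lev]
    mesh_l <- if (lev_coarse) cmesh else mesh
    if (lev_coarse && !on_coarse) {
      warps <- lapply(warps, function(W) W[seq_len(cmesh$n_vertices), , drop = FALSE])
      on_coarse <- TRUE
    } else if (!lev_coarse && on_coarse) {
      warps <- lapply(warps, upsample_warp, fine_mesh = mesh)
      on_coarse <- FALSE
    }
    it_l <- if (lev_coarse) max(1L, as.integer(round(si[lev] / 4))) else si[lev]
    curvs_l <- lapply(curvatures, function(cv) {
      smooth_map(cv[seq_len(mesh_l$n_vertices)], mesh_l, it_l)
    })
    target <- moving_average_target(curvs_l, warps, mesh_l)
    en <- subject_energies(warps, curvs_l, target, mesh_l, params$lambda)
    tr <- sum(en)
    for (u in seq_len(params$updates_per_level)) {
      for (s in seq_len(n_sub)) {
        res <- nonrigid_align_level(
          warps[[s]], curvs_l[[s]], target, mesh_l,
          lambda = params$lambda, max_iter = params$iters_per_update
        )
        warps[[s]] <- res$warp
        en[s] <- res$energy      # others unchanged under a fixed target
        tr <- c(tr, sum(en))
      }
      target <- moving_average_target(curvs_l, warps, mesh_l)
      en <- subject_energies(warps, curvs_l, target, mesh_l, params$lambda)
      tr <- c(tr, sum(en))
    }
    trace[[lev]] <- tr
  }
  if (on_coarse) warps <- lapply(warps, upsample_warp, fine_mesh = mesh)
  final_avg <- moving_average_target(curvatures, warps, mesh)
  structure(
    list(rotations = rotations, warps = warps, objective_trace = trace,
         final_group_curvature = scalar_map(final_avg, mesh, "group average curvature"),
         params = params, n_subjects = n_sub),
    class = "cba_alignment"
  )
}

#' @export
print.cba_alignment <- function(x, ...) {
  cat(sprintf("<cba_alignment> %d subjects, final objective %.4g\n",
              x$n_subjects, utils::tail(x$objective_trace[[4]], 1)))
  invisible(x)
}

#' Two-pass alignment with an unbiased average rigid target
#'
#' Pass 1 aligns the cohort rigidly to a single subject (the first, i.e. the
#' one drawn under the master seed) and runs the full non-rigid schedule;
#' pass 2 repeats the procedure using the pass-1 aligned average curvature as
#' an unbiased rigid target.
#'
#' @inheritParams run_group_cba
#' @return the pass-2 `cba_alignment` with extra fields `pass1_average`
#'   (curvature map) and `pass1` (the pass-1 alignment).
#' @export
two_pass_cba <- function(curvatures, mesh, params = cba_params()) {
  pass1 <- run_group_cba(curvatures, mesh, params, rigid_target = NULL)
  pass2 <- run_group_cba(curvatures, mesh, params,
                         rigid_target = pass1$final_group_curvature)
  pass2$pass1_average <- pass1$final_group_curvature
  pass2$pass1 <- pass1
  class(pass2) <- c("two_pass_cba", class(pass2))
  pass2
}

## ---- applying warps ---------------------------------------------------------

#' Carry a per-vertex map into the aligned group space
#'
#' The group-space value at vertex v is the subject map resampled at the
#' warp position w(v).
#'
#' @param map per-vertex values on the subject mesh.
#' @param warp warp field (n x 3) from [run_group_cba()] or [two_pass_cba()].
#' @param mesh the shared `sphere_mesh`.
#' @param method `"barycentric"` or `"nearest"`.
#' @return numeric vector on the group grid.
#' @export
apply_warp_to_map <- function(map, warp, mesh, method = "barycentric") {
  resample_map(mesh, map, warp, method)
}

#' Average folded mesh after correspondence
#'
#' @param folded_list list of `folded_mesh` (or n x 3 coordinate matrices).
#' @param warps list of warp fields (identity matrices of vertex positions
#'   for unaligned averaging).
#' @param mesh the shared `sphere_mesh`.
#' @return a `folded_mesh` of the per-vertex mean coordinates.
#' @export
average_folded_mesh <- function(folded_list, warps, mesh) {
  acc <- matrix(0, mesh$n_vertices, 3)
  for (s in seq_along(folded_list)) {
    crd <- if (inherits(folded_list[[s]], "folded_mesh")) {
      folded_list[[s]]$vertices
    } else as.matrix(folded_list[[s]])
    acc <- acc + resample_fields(mesh, crd, warps[[s]])
  }
  folded_mesh(mesh, acc / length(folded_list))
}

#' Correspondence error against a stored ground-truth warp
#'
#' For each group vertex v the estimated subject position w(v) is pushed
#' through the subject's true template correspondence field; the geodesic
#' distance to v's own position is the alignment error (0 for perfect
#' recovery, the raw warp displacement for the identity estimate).
#'
#' @param warp estimated warp field (n x 3).
#' @param true_warp the subject's ground-truth warp field (n x 3, template
#'   positions per subject vertex).
#' @param mesh the shared `sphere_mesh`.
#' @return per-vertex geodesic error in radians.
#' @export
correspondence_error <- function(warp, true_warp, mesh) {
  pred <- unit_rows(resample_fields(mesh, true_warp, warp))
  geodesic_distance(pred, mesh$vertices)
}

## ---- broom-style methods ----------------------------------------------------

#' Tidy per-level objective traces of an alignment
#' @param x a `cba_alignment`
#' @param ... unused
#' @method tidy cba_alignment
#' @export
tidy.cba_alignment <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$objective_trace), function(lv) {
    tr <- x$objective_trace[[lv]]
    tibble::tibble(level = lv, step = seq_along(tr) - 1, objective = tr)
  }))
}

#' One-row alignment summary
#' @param x a `cba_alignment`
#' @param ... unused
#' @method glance cba_alignment
#' @export
glance.cba_alignment <- function(x, ...) {
  tr <- tidy(x)
  tibble::tibble(
    n_subjects = x$n_subjects,
    initial_objective = tr$objective[1],
    final_objective = utils::tail(tr$objective, 1),
    mean_rigid_angle_deg = if (length(x$rotations) && !is.null(x$rotations[[1]])) {
      mean(vapply(x$rotations, rotation_angle, numeric(1))) * 180 / pi
    } else NA_real_
  )
}
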