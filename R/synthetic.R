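## Synthetic cohort generator: template anatomy, per-subject warps with known
## ground truth, and quadrant-selective BOLD time series.

#' Build the synthetic template brain
#'
#' Curvature is a smoothed, zero-mean sum of oriented ridge functions
#' (synthetic gyri and sulci with alternating sign); the folded mesh displaces
#' the sphere radially in proportion to curvature; the four quadrant ROIs are
#' geodesic discs at mirror-symmetric positions inside the occipital cap
#' (60 degree half-angle around the +z pole). The disc centers sit on mirror
#' planes of the icosahedral symmetry group, so opposing ROIs contain exactly
#' the same number of vertices by construction.
#'
#' @param subdivisions icosphere subdivision level (default 4: 2,562 vertices).
#' @param n_ridges number of curvature ridges (>= 1, default 60: dense enough
#'   that folds tile the sphere as cortical gyri and sulci do).
#' @param seed RNG seed.
#' @param roi_radius geodesic ROI disc radius in radians (default 0.25).
#' @param roi_colatitude angular distance of ROI centers from the occipital
#'   pole (default 25 degrees).
#' @param radius_mm folded-mesh base radius (default 80 mm).
#' @param fold_amplitude_mm radial displacement per unit curvature (default 6).
#' @param true_amplitude named response amplitude per condition (signal units).
#' @return object of class `template_brain` with fields `sphere`, `folded`,
#'   `curvature`, `quadrant_rois` (named list of vertex index sets),
#'   `roi_centers` (4 x 3), `occipital_pole`, `occipital_cap` (vertex set),
#'   `true_amplitude`.
#' @export
make_template <- function(subdivisions = 4, n_ridges = 60, seed = 1,
                          roi_radius = 0.25, roi_colatitude = 25 * pi / 180,
                          radius_mm = 80, fold_amplitude_mm = 6,
                          true_amplitude = c(LL = 1, LR = 1, UL = 1, UR = 1)) {
  if (n_ridges < 1) stop("`n_ridges` must be at least 1", call. = FALSE)
  mesh <- build_icosphere(subdivisions)
  V <- mesh$vertices
  curv <- with_seed(seed, {
    acc <- numeric(mesh$n_vertices)
    for (k in seq_len(n_ridges)) {
      ctr <- as.numeric(unit_rows(matrix(stats::rnorm(3), 1)))
      tang <- stats::rnorm(3)
      tang <- tang - sum(tang * ctr) * ctr
      tang <- tang / sqrt(sum(tang^2))
      sgn <- if (k %% 2 == 1) 1 else -1
      width <- stats::runif(1, 0.06, 0.10)
      len <- stats::runif(1, 0.3, 0.6)
      d <- geodesic_distance(V, ctr)
      tcomp <- V - as.numeric(V %*% ctr) * matrix(ctr, mesh$n_vertices, 3, byrow = TRUE)
      tn <- row_norms(tcomp)
      tn[tn == 0] <- 1
      phi <- tcomp / tn
      along <- d * (phi %*% tang)[, 1]
      perp2 <- pmax(d^2 - along^2, 0)
      acc <- acc + sgn * exp(-perp2 / (2 * width^2) - along^2 / (2 * len^2))
    }
    acc
  })
  curv <- smooth_map(curv, mesh, 2)
  curv <- curv - mean(curv)
  curv <- curv / max(abs(curv)) * 0.85
  curv <- scalar_map(curv, mesh, label = "template curvature")
  folded <- folded_mesh(mesh, V * (radius_mm + fold_amplitude_mm * as.numeric(curv)))
  pole <- c(0, 0, 1)
  # mirror-symmetric ROI centers: x -> -x maps LL<->LR and UL<->UR,
  # y -> -y maps lower <-> upper (both are icosahedral symmetries)
  st <- sin(roi_colatitude); ct <- cos(roi_colatitude)
  a <- st / sqrt(2)
  centers <- rbind(
    LL = c( a,  a, ct),
    LR = c(-a,  a, ct),
    UL = c( a, -a, ct),
    UR = c(-a, -a, ct)
  )
  rois <- lapply(seq_len(4), function(i) geodesic_disc(mesh, centers[i, ], roi_radius))
  names(rois) <- rownames(centers)
  for (i in 1:3) for (j in (i + 1):4) {
    if (length(intersect(rois[[i]], rois[[j]]))) {
      stop("quadrant ROI discs overlap; use a smaller `roi_radius`", call. = FALSE)
    }
  }
  cap <- geodesic_disc(mesh, pole, 60 * pi / 180)
  structure(
    list(
      sphere = mesh, folded = folded, curvature = curv,
      quadrant_rois = rois, roi_centers = centers,
      occipital_pole = pole, occipital_cap = cap,
      true_amplitude = true_amplitude,
      radius_mm = radius_mm, fold_amplitude_mm = fold_amplitude_mm,
      seed = seed, n_ridges = n_ridges
    ),
    class = "template_brain"
  )
}

#' @export
print.template_brain <- function(x, ...) {
  cat(sprintf("<template_brain> %d vertices, ROI sizes: %s\n",
              x$sphere$n_vertices,
              paste(names(x$quadrant_rois), lengths(x$quadrant_rois),
                    sep = "=", collapse = " ")))
  invisible(x)
}

#' Per-subject generation parameters
#'
#' @param seed subject RNG seed.
#' @param warp_magnitude maximum localized rotation angle in radians
#'   (default 0.15, at most 0.5).
#' @param warp_smoothness angular falloff (sd, radians) of the localized
#'   rotations (default 0.8: warps are globally coherent and near-isometric,
#'   emulating residual misalignment after volumetric normalisation plus
#'   smooth local variability).
#' @param curvature_noise_sd additive Gaussian noise on the warped curvature.
#' @param signal_amplitude BOLD response amplitude inside a condition's ROI.
#' @param noise_sd marginal standard deviation of the AR(1) BOLD noise
#'   (default 6, chosen so single-subject ROI t values fall in the 4-8 range
#'   typical of attention-enhanced checkerboard localizers).
#' @param ar1_coefficient temporal autocorrelation in [0, 1).
#' @return a `subject_spec` list.
#' @export
subject_spec <- function(seed, warp_magnitude = 0.15, warp_smoothness = 0.8,
                         curvature_noise_sd = 0.05, signal_amplitude = 1,
                         noise_sd = 6, ar1_coefficient = 0.3) {
  if (warp_magnitude < 0) stop("`warp_magnitude` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    stop("`ar1_coefficient` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(seed = seed, warp_magnitude = warp_magnitude,
         warp_smoothness = warp_smoothness,
         curvature_noise_sd = curvature_noise_sd,
         signal_amplitude = signal_amplitude, noise_sd = noise_sd,
         ar1_coefficient = ar1_coefficient),
    class = "subject_spec"
  )
}

rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

apply_local_rotation <- function(P, center, axis, max_angle, sigma) {
  ang <- max_angle * exp(-geodesic_distance(P, center)^2 / (2 * sigma^2))
  # Rodrigues rotation with per-point angle around a shared axis
  a <- matrix(axis / sqrt(sum(axis^2)), nrow(P), 3, byrow = TRUE)
  cosv <- cos(ang); sinv <- sin(ang)
  adp <- row_dots(a, P)
  P * cosv + row_cross(a, P) * sinv + a * adp * (1 - cosv)
}

#' Generate a smooth random warp of the sphere
#'
#' Composition of `k_rotations` localized rotations (random axis, random
#' center, Gaussian angular falloff); the maximum local rotation angle is
#' `magnitude`. If the warp inverts any spherical face it is damped and
#' redrawn, up to 5 times.
#'
#' @param mesh a `sphere_mesh`.
#' @param magnitude maximum rotation angle in radians (<= 0.5).
#' @param smoothness Gaussian falloff sd in radians (default 0.8).
#' @param seed RNG seed.
#' @param k_rotations number of composed localized rotations (default 24:
#'   enough that the displacement field covers the sphere evenly and the
#'   anatomical variability it generates is statistically stable across
#'   cohorts).
#' @return n x 3 matrix of unit target positions (vertex i of `mesh` moves to
#'   row i).
#' @export
make_warp <- function(mesh, magnitude, smoothness = 0.8, seed = 1,
                      k_rotations = 24) {
  if (magnitude > 0.5) stop("`magnitude` must be at most 0.5 rad", call. = FALSE)
  if (magnitude < 0) stop("`magnitude` must be non-negative", call. = FALSE)
  V <- mesh$vertices
  if (magnitude == 0) return(V)
  with_seed(seed, {
    params <- lapply(seq_len(k_rotations), function(k) {
      list(
        center = unit_rows(matrix(stats::rnorm(3), 1)),
        axis = stats::rnorm(3),
        angle = stats::runif(1, 0.7, 1) * magnitude * sample(c(-1, 1), 1)
      )
    })
    damp <- 1
    for (attempt in 1:5) {
      P <- V
      for (pr in params) {
        P <- apply_local_rotation(P, pr$center, pr$axis, pr$angle * damp, smoothness)
      }
      P <- unit_rows(P)
      if (no_face_inversions(P, mesh$faces)) return(P)
      damp <- damp * 0.7
    }
    stop("warp still inverts faces after 5 damped retries", call. = FALSE)
  })
}

ar1_noise <- function(n_units, n_time, sd_marginal, phi) {
  if (sd_marginal == 0) return(matrix(0, n_units, n_time))
  innov_sd <- sd_marginal * sqrt(1 - phi^2)
  E <- matrix(stats::rnorm(n_units * n_time, sd = innov_sd), n_units, n_time)
  E[, 1] <- stats::rnorm(n_units, sd = sd_marginal)
  if (phi > 0) {
    for (t in 2:n_time) E[, t] <- phi * E[, t - 1] + E[, t]
  }
  E
}

#' Generate one synthetic subject
#'
#' The subject's curvature is the template curvature pulled back through a
#' random smooth warp (plus optional Gaussian noise); its quadrant ROIs are
#' the template ROIs transported through the same warp by nearest-vertex
#' lookup; its BOLD grid is `X beta + AR(1) noise` with `beta = amplitude`
#' inside the condition's warped ROI and 0 elsewhere, over the full
#' acquisition (170 volumes at TR 2 s by default).
#'
#' @param template a [make_template()] object.
#' @param spec a [subject_spec()].
#' @param paradigm a [generate_paradigm()] object.
#' @param TR,n_volumes acquisition timing (defaults 2 s, 170).
#' @param baseline additive BOLD baseline (default 100 signal units).
#' @return object of class `synthetic_subject` with `curvature`,
#'   `true_warp` (n x 3), `roi_sets`, `bold` (vertices x volumes), `spec`.
#' @export
make_subject <- function(template, spec, paradigm, TR = 2, n_volumes = 170,
                         baseline = 100) {
  stopifnot(inherits(template, "template_brain"), inherits(spec, "subject_spec"),
            inherits(paradigm, "paradigm"))
  mesh <- template$sphere
  warp <- make_warp(mesh, spec$warp_magnitude, spec$warp_smoothness,
                    seed = spec$seed)
  identity_warp <- spec$warp_magnitude == 0
  tcurv <- as.numeric(template$curvature)
  curv <- if (identity_warp) tcurv else resample_map(mesh, tcurv, warp, "barycentric")
  with_seed(spec$seed + 1L, {
    if (spec$curvature_noise_sd > 0) {
      curv <- curv + stats::rnorm(mesh$n_vertices, sd = spec$curvature_noise_sd)
    }
    # ROI transport: subject vertex v carries condition c iff its template
    # position (the warp target) falls in the template ROI of c
    roi_sets <- if (identity_warp) {
      template$quadrant_rois
    } else {
      nn <- nearest_vertex(mesh, warp)
      lapply(template$quadrant_rois, function(r) which(nn %in% r))
    }
    design <- build_design(paradigm, TR = TR, n_volumes = n_volumes, n_discard = 0)
    X <- design$matrix[, QUADRANTS, drop = FALSE]
    B <- matrix(0, mesh$n_vertices, 4)
    colnames(B) <- QUADRANTS
    for (q in QUADRANTS) {
      B[roi_sets[[q]], q] <- spec$signal_amplitude * template$true_amplitude[[q]]
    }
    bold <- B %*% t(X) + baseline +
      ar1_noise(mesh$n_vertices, n_volumes, spec$noise_sd, spec$ar1_coefficient)
    structure(
      list(
        sphere = mesh, curvature = scalar_map(curv, mesh, "subject curvature"),
        true_warp = warp, roi_sets = roi_sets, bold = bold,
        spec = spec, TR = TR, n_volumes = n_volumes,
        paradigm_ref = paradigm
      ),
      class = "synthetic_subject"
    )
  })
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> seed %d, %d vertices x %d volumes, warp %.2g rad\n",
              x$spec$seed, nrow(x$bold), ncol(x$bold), x$spec$warp_magnitude))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' @param template a [make_template()].
#' @param n_subjects number of subjects (>= 2).
#' @param paradigm a [generate_paradigm()]; shared by all subjects.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param ... default-overriding arguments passed to [subject_spec()]
#'   (e.g. `warp_magnitude`, `noise_sd`).
#' @return list of `synthetic_subject` (class `synthetic_cohort`).
#' @export
make_cohort <- function(template, n_subjects, paradigm, seed = 1, ...) {
  if (n_subjects < 2) stop("`n_subjects` must be at least 2", call. = FALSE)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 2L, n_subjects))
  cohort <- lapply(seq_len(n_subjects), function(i) {
    make_subject(template, subject_spec(seed = sub_seeds[i], ...), paradigm)
  })
  structure(cohort, class = "synthetic_cohort", template_seed = template$seed,
            master_seed = seed)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects on %d vertices\n",
              length(x), x[[1]]$sphere$n_vertices))
  invisible(x)
}
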