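## Experiment orchestration: simulate a cohort, run the per-subject localizer
## GLM, produce the three alignment arms (volume, unaligned surface, CBA),
## and compute every group evaluation table.

ARM_LEVELS <- c("volume", "surface_unaligned", "surface_cba")
ARM_LABELS <- c(volume = "VBA-analog", surface_unaligned = "SBAV-analog",
                surface_cba = "CBA")

#' Experiment configuration
#'
#' @param master_seed seed from which every stage's randomness is derived.
#' @param n_subjects cohort size (>= 3 for the random-effects analyses).
#' @param mesh_subdivisions icosphere level (default 4; 6 gives the
#'   40,962-vertex standard mesh).
#' @param arms analysis arms to run, a subset of
#'   `c("volume", "surface_unaligned", "surface_cba")` (at least 2).
#' @param alpha family-wise error rate for Bonferroni-corrected group maps.
#' @param single_subject_p one-sided uncorrected threshold for single-subject
#'   maps (default 0.05).
#' @param pm_display_threshold probability-map display threshold in percent.
#' @param pdm_threshold probability-difference reporting threshold in percent.
#' @param cluster_threshold cluster extent threshold in vertices for
#'   displayed probability maps.
#' @param warp_magnitude,warp_smoothness,curvature_noise_sd,signal_amplitude,noise_sd,ar1_coefficient
#'   cohort generation parameters, see [subject_spec()].
#' @param n_ridges template folding density, see [make_template()].
#' @param roi_radius geodesic radius (radians) of the template quadrant ROI
#'   discs, see [make_template()].
#' @param fold_amplitude_mm radial folding amplitude of the synthetic
#'   anatomy (0 gives a perfectly spherical, mirror-symmetric cortex).
#' @param voxel_size_mm voxel size of the volume arm (default 3).
#' @param seed_max_distance maximum geodesic distance (radians) between an
#'   ROI candidate cluster and its expected seed (default 0.35).
#' @param cba a [cba_params()] object.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(master_seed = 1, n_subjects = 20,
                              mesh_subdivisions = 4,
                              arms = ARM_LEVELS,
                              alpha = 0.05, single_subject_p = 0.05,
                              pm_display_threshold = 10, pdm_threshold = 5,
                              cluster_threshold = 100,
                              warp_magnitude = 0.15, warp_smoothness = 0.8,
                              curvature_noise_sd = 0.05,
                              signal_amplitude = 1, noise_sd = 6,
                              ar1_coefficient = 0.3, n_ridges = 60,
                              roi_radius = 0.18, fold_amplitude_mm = 6,
                              voxel_size_mm = 3, seed_max_distance = 0.35,
                              cba = cba_params()) {
  arms <- match.arg(arms, ARM_LEVELS, several.ok = TRUE)
  if (length(arms) < 2) stop("need at least 2 analysis arms", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, single_subject_p > 0, single_subject_p < 1,
            pm_display_threshold > 0, pm_display_threshold < 100,
            pdm_threshold > 0, pdm_threshold < 100, cluster_threshold >= 1)
  structure(
    list(master_seed = master_seed, n_subjects = n_subjects,
         mesh_subdivisions = mesh_subdivisions, arms = arms,
         alpha = alpha, single_subject_p = single_subject_p,
         pm_display_threshold = pm_display_threshold,
         pdm_threshold = pdm_threshold, cluster_threshold = cluster_threshold,
         warp_magnitude = warp_magnitude, warp_smoothness = warp_smoothness,
         curvature_noise_sd = curvature_noise_sd,
         signal_amplitude = signal_amplitude, noise_sd = noise_sd,
         ar1_coefficient = ar1_coefficient, n_ridges = n_ridges,
         roi_radius = roi_radius, fold_amplitude_mm = fold_amplitude_mm,
         voxel_size_mm = voxel_size_mm, seed_max_distance = seed_max_distance,
         cba = cba),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from a YAML or JSON file
#' @param path configuration file; keys are [experiment_config()] arguments.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  cba_args <- vals$cba
  vals$cba <- NULL
  cfg <- do.call(experiment_config, vals)
  if (!is.null(cba_args)) cfg$cba <- do.call(cba_params, cba_args)
  cfg
}

## ---- stage: simulate --------------------------------------------------------

#' Simulate the template, paradigm and cohort of an experiment
#' @param config an [experiment_config()].
#' @return list with `template`, `paradigm`, `cohort`.
#' @export
simulate_experiment <- function(config) {
  template <- make_template(config$mesh_subdivisions, n_ridges = config$n_ridges,
                            seed = config$master_seed,
                            roi_radius = config$roi_radius,
                            fold_amplitude_mm = config$fold_amplitude_mm)
  paradigm <- generate_paradigm(config$master_seed + 1L)
  cohort <- make_cohort(
    template, config$n_subjects, paradigm, seed = config$master_seed + 2L,
    warp_magnitude = config$warp_magnitude,
    warp_smoothness = config$warp_smoothness,
    curvature_noise_sd = config$curvature_noise_sd,
    signal_amplitude = config$signal_amplitude,
    noise_sd = config$noise_sd, ar1_coefficient = config$ar1_coefficient
  )
  list(template = template, paradigm = paradigm, cohort = cohort)
}

## ---- stage: per-subject surface GLM -----------------------------------------

#' Per-subject surface analysis: smoothing, filtering, GLM, contrasts
#' @param subject a `synthetic_subject`.
#' @param design the shared [build_design()] object.
#' @param mesh the `sphere_mesh`.
#' @param n_discard acquisition volumes dropped before modelling.
#' @return list with `con` (vertices x 4 contrast estimates), `t`
#'   (vertices x 4 contrast t), `cond_t` (vertices x 4 per-condition t),
#'   `dof`.
#' @export
subject_surface_glm <- function(subject, design, mesh, n_discard = 4) {
  keep <- (n_discard + 1):ncol(subject$bold)
  Y <- smooth_matrix(subject$bold, mesh, 1)[, keep, drop = FALSE]
  Y <- highpass_and_detrend(Y, subject$TR)
  fit <- fit_glm(Y, design)
  con <- sapply(QUADRANTS, function(q) {
    as.numeric(fit$betas[, QUADRANTS] %*% poi_contrast(q)[QUADRANTS])
  })
  tmaps <- sapply(QUADRANTS, function(q) as.numeric(contrast_t(fit, poi_contrast(q))))
  list(con = con, t = tmaps, cond_t = condition_t(fit), dof = fit$dof)
}

## ---- stage: volume arm ------------------------------------------------------

subject_volume_glm <- function(subject, template, design, n_discard = 4,
                               voxel_size = 3, ref_grid = NULL) {
  mesh <- subject$sphere
  # folded anatomy: radial displacement by the subject's own curvature
  folded_s <- folded_mesh(
    mesh, mesh$vertices * (template$radius_mm + template$fold_amplitude_mm *
                             as.numeric(subject$curvature))
  )
  vg <- rasterize_surface_timeseries(folded_s, subject$bold, voxel_size,
                                     grid = ref_grid)
  vg <- gaussian_smooth_3d(vg, fwhm = voxel_size)
  keep <- (n_discard + 1):ncol(vg$data)
  Y <- highpass_and_detrend(vg$data[, keep, drop = FALSE], subject$TR)
  fit <- fit_glm(Y, design)
  con <- sapply(QUADRANTS, function(q) {
    as.numeric(fit$betas[, QUADRANTS] %*% poi_contrast(q)[QUADRANTS])
  })
  tmaps <- sapply(QUADRANTS, function(q) as.numeric(contrast_t(fit, poi_contrast(q))))
  dims <- vg$dim
  lin <- vg$voxel_ijk[, 1] + dims[1] * (vg$voxel_ijk[, 2] - 1) +
    dims[1] * dims[2] * (vg$voxel_ijk[, 3] - 1)
  list(grid = vg, lin = lin, con = con, t = tmaps, cond_t = condition_t(fit),
       dof = fit$dof, folded = folded_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_reference_grid <- function(template, voxel_size) {
  # grid centred on the origin and mirror-symmetric in every axis, padded for
  # warped anatomies; symmetry keeps voxelisation from breaking the
  # template's mirror symmetries
  V <- template$folded$vertices
  half <- ceiling((max(abs(V)) + 4 * voxel_size) / voxel_size)
  list(origin = rep(-half * voxel_size, 3), dim = rep(2 * half, 3),
       voxel_size = voxel_size)
}

project_values_to_surface <- function(values, lin, ref, folded, fill = NA_real_) {
  dims <- ref$dim
  k <- lin - 1
  vox_ijk <- cbind(k %% dims[1] + 1, (k %/% dims[1]) %% dims[2] + 1,
                   k %/% (dims[1] * dims[2]) + 1)
  grid <- structure(
    list(data = matrix(values, ncol = 1), voxel_ijk = vox_ijk, dim = dims,
         origin = ref$origin, voxel_size = ref$voxel_size),
    class = "volume_grid"
  )
  out <- project_volume_map_to_surface(grid, folded)
  if (!is.na(fill)) out[is.na(out)] <- fill
  out
}

## ---- full experiment --------------------------------------------------------

#' Run the full three-arm alignment comparison
#'
#' Simulates the cohort, fits the localizer GLM per subject, produces
#' per-subject statistical maps in each arm's analysis space (volumetric,
#' unaligned surface, cortex-based aligned surface) and computes the group
#' evaluation tables: group ROIs and their size changes, position
#' selectivity, asymmetry indices, probability maps, probability difference
#' maps and peak vertex distributions.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress (default TRUE).
#' @return an `experiment_result` (see package vignette); `$tables` holds
#'   the report tibbles.
#' @export
run_experiment <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  if (config$n_subjects < 3) stop("random-effects analyses need >= 3 subjects", call. = FALSE)
  t_start <- Sys.time()
  timing <- list()
  say <- function(...) if (verbose) message(sprintf(...))
  tick <- function(stage, t0) {
    timing[[stage]] <<- as.numeric(Sys.time() - t0, units = "secs")
  }

  ## simulate ------------------------------------------------------------
  t0 <- Sys.time()
  say("simulate: n = %d subjects at subdivisions = %d",
      config$n_subjects, config$mesh_subdivisions)
  sim <- simulate_experiment(config)
  template <- sim$template; paradigm <- sim$paradigm; cohort <- sim$cohort
  mesh <- template$sphere
  n_sub <- length(cohort)
  design <- build_design(paradigm)
  tick("simulate", t0)

  ## per-subject surface GLM ---------------------------------------------
  t0 <- Sys.time()
  say("glm: per-subject surface analysis")
  surf <- lapply(cohort, subject_surface_glm, design = design, mesh = mesh)
  dof <- surf[[1]]$dof
  t_crit_ss <- stats::qt(1 - config$single_subject_p, df = dof)
  tick("glm", t0)

  arms <- list()

  ## surface arms ---------------------------------------------------------
  if ("surface_unaligned" %in% config$arms) {
    arms$surface_unaligned <- list(
      con = lapply(surf, `[[`, "con"),
      t = lapply(surf, `[[`, "t"),
      cond_t = lapply(surf, `[[`, "cond_t"),
      binary = lapply(surf, function(s) s$t > t_crit_ss),
      n_tests = mesh$n_vertices,
      space = "surface"
    )
  }

  alignment <- NULL
  if ("surface_cba" %in% config$arms) {
    t0 <- Sys.time()
    say("align: two-pass cortex-based alignment")
    alignment <- two_pass_cba(lapply(cohort, function(s) s$curvature), mesh,
                              config$cba)
    transport <- function(M, s) {
      apply(M, 2, function(col) {
        resample_map(mesh, col, alignment$warps[[s]], "barycentric")
      })
    }
    con_g <- lapply(seq_len(n_sub), function(s) transport(surf[[s]]$con, s))
    t_g <- lapply(seq_len(n_sub), function(s) transport(surf[[s]]$t, s))
    ct_g <- lapply(seq_len(n_sub), function(s) transport(surf[[s]]$cond_t, s))
    arms$surface_cba <- list(
      con = con_g, t = t_g, cond_t = ct_g,
      binary = lapply(t_g, function(tm) tm > t_crit_ss),
      n_tests = mesh$n_vertices,
      space = "surface"
    )
    tick("align", t0)
  }

  ## volume arm ------------------------------------------------------------
  if ("volume" %in% config$arms) {
    t0 <- Sys.time()
    say("volume: rasterise, smooth 3D, per-voxel GLM")
    ref <- make_reference_grid(template, config$voxel_size_mm)
    vol <- lapply(cohort, subject_volume_glm, template = template,
                  design = design, voxel_size = config$voxel_size_mm,
                  ref_grid = ref)
    common <- Reduce(intersect, lapply(vol, `[[`, "lin"))
    pick <- function(v, M) M[match(common, v$lin), , drop = FALSE]
    avg_folded <- average_folded_mesh(
      lapply(vol, `[[`, "folded"),
      replicate(n_sub, mesh$vertices, simplify = FALSE), mesh
    )
    arms$volume <- list(
      con = lapply(vol, function(v) pick(v, v$con)),
      t = lapply(vol, function(v) pick(v, v$t)),
      cond_t = lapply(vol, function(v) pick(v, v$cond_t)),
      binary = lapply(vol, function(v) pick(v, v$t) > t_crit_ss),
      n_tests = length(common),
      space = "volume", lin = common, ref = ref, avg_folded = avg_folded
    )
    tick("volume", t0)
  }

  ## evaluation -------------------------------------------------------------
  t0 <- Sys.time()
  say("evaluate: group maps, ROIs, probability maps")
  result <- evaluate_arms(arms, config, template, cohort, alignment, dof)
  tick("evaluate", t0)

  structure(
    c(result,
      list(config = config, template = template, paradigm = paradigm,
           alignment = alignment, dof = dof,
           timing = c(timing, total = as.numeric(Sys.time() - t_start, units = "secs")))),
    class = "experiment_result"
  )
}

## expected ROI seed vertices per arm from the ground-truth ROI overlap
truth_seeds <- function(arm, template, cohort, alignment) {
  mesh <- template$sphere
  n_sub <- length(cohort)
  sapply(QUADRANTS, function(q) {
    overlap <- numeric(mesh$n_vertices)
    for (s in seq_len(n_sub)) {
      mask <- numeric(mesh$n_vertices)
      mask[cohort[[s]]$roi_sets[[q]]] <- 1
      if (identical(arm, "surface_cba")) {
        mask <- as.numeric(resample_map(mesh, mask, alignment$warps[[s]], "nearest"))
      }
      overlap <- overlap + mask
    }
    which.max(overlap)
  })
}

evaluate_arms <- function(arms, config, template, cohort, alignment, dof) {
  mesh <- template$sphere
  n_sub <- length(cohort)
  arm_names <- names(arms)
  seeds <- lapply(stats::setNames(arm_names, arm_names), function(a) {
    truth_seeds(if (a == "surface_cba") "surface_cba" else "surface", template,
                cohort, alignment)
  })

  per_arm <- list()
  for (a in arm_names) {
    arm <- arms[[a]]
    is_vol <- arm$space == "volume"
    t_crit_grp <- stats::qt(1 - bonferroni_threshold(config$alpha, arm$n_tests),
                            df = n_sub - 1)
    rois <- list(); rfx_surface <- list(); pm_surface <- list()
    for (qi in seq_along(QUADRANTS)) {
      q <- QUADRANTS[qi]
      con_q <- sapply(arm$con, function(M) M[, q])
      rfx <- rfx_group_tmap(con_q)
      bin_q <- lapply(arm$binary, function(M) M[, q])
      pm <- probability_map(do.call(cbind, bin_q))
      if (is_vol) {
        # threshold in volume, project the thresholded map, then the raw PM
        masked <- ifelse(as.numeric(rfx) > t_crit_grp, as.numeric(rfx), 0)
        rfx_s <- project_values_to_surface(masked, arm$lin, arm$ref,
                                           arm$avg_folded, fill = 0)
        pm_s <- project_values_to_surface(pm$values, arm$lin, arm$ref,
                                          arm$avg_folded, fill = 0)
        roi <- extract_group_roi(rfx_s, mesh, 0, seeds[[a]][[q]],
                                 config$seed_max_distance)
        pm_surface[[q]] <- pm_s
        rfx_surface[[q]] <- rfx_s
      } else {
        roi <- extract_group_roi(as.numeric(rfx), mesh, t_crit_grp,
                                 seeds[[a]][[q]], config$seed_max_distance)
        pm_surface[[q]] <- pm$values
        rfx_surface[[q]] <- as.numeric(rfx)
      }
      rois[[q]] <- roi
    }
    per_arm[[a]] <- list(rois = rois, rfx = rfx_surface, pm = pm_surface,
                         t_crit_group = t_crit_grp, n_tests = arm$n_tests,
                         seeds = seeds[[a]])
  }

  ## Table 1 analog: group ROIs
  group_rois <- dplyr::bind_rows(lapply(arm_names, function(a) {
    dplyr::bind_rows(lapply(QUADRANTS, function(q) {
      r <- per_arm[[a]]$rois[[q]]
      tibble::tibble(
        quadrant = q, arm = ARM_LABELS[[a]], found = r$found,
        n_vertices = r$size,
        peak_vertex = r$peak_vertex, peak_t = r$peak_t,
        center_x = if (r$found) r$center[1] else NA_real_,
        center_y = if (r$found) r$center[2] else NA_real_,
        center_z = if (r$found) r$center[3] else NA_real_
      )
    }))
  }))

  ## Table 2 analog: pairwise ROI size changes
  pair_defs <- list(
    c("volume", "surface_unaligned"),
    c("volume", "surface_cba"),
    c("surface_unaligned", "surface_cba")
  )
  size_changes <- dplyr::bind_rows(lapply(pair_defs, function(p) {
    if (!all(p %in% arm_names)) return(NULL)
    dplyr::bind_rows(lapply(QUADRANTS, function(q) {
      r1 <- per_arm[[p[1]]]$rois[[q]]; r2 <- per_arm[[p[2]]]$rois[[q]]
      tibble::tibble(
        quadrant = q,
        comparison = paste(ARM_LABELS[[p[1]]], "->", ARM_LABELS[[p[2]]]),
        size_before = r1$size, size_after = r2$size,
        change_pct = if (r1$size >= 1) size_change(r1$size, r2$size) else NA_real_
      )
    }))
  }))

  ## Table 3 analog: position selectivity across arms.
  ## Per-condition t maps in surface space (volume arm: projected once).
  cond_t_surface <- lapply(stats::setNames(arm_names, arm_names), function(a) {
    if (arms[[a]]$space == "volume") {
      lapply(arms[[a]]$cond_t, function(ct) {
        sapply(QUADRANTS, function(cc) {
          project_values_to_surface(ct[, cc], arms[[a]]$lin, arms[[a]]$ref,
                                    arms[[a]]$avg_folded, fill = 0)
        })
      })
    } else arms[[a]]$cond_t
  })
  selectivity <- dplyr::bind_rows(lapply(QUADRANTS, function(q) {
    rows <- dplyr::bind_rows(lapply(arm_names, function(a) {
      r <- per_arm[[a]]$rois[[q]]
      if (!r$found) return(NULL)
      sc <- vapply(seq_len(n_sub), function(s) {
        m <- colMeans(cond_t_surface[[a]][[s]][r$vertices, , drop = FALSE])
        3 * m[[q]] - sum(m[setdiff(QUADRANTS, q)])
      }, numeric(1))
      tibble::tibble(subject = seq_len(n_sub), arm = ARM_LABELS[[a]], score = sc)
    }))
    if (is.null(rows) || nrow(rows) == 0 || length(unique(rows$arm)) < 2) {
      return(tibble::tibble(quadrant = q, statistic = NA_real_, num_df = NA_real_,
                            den_df = NA_real_, p_value = NA_real_,
                            p_adjusted = NA_real_))
    }
    ts <- position_selectivity_test(rows)
    tibble::tibble(quadrant = q, statistic = ts$statistic, num_df = ts$num_df,
                   den_df = ts$den_df, p_value = ts$p_value,
                   p_adjusted = pmin(1, ts$p_value * length(QUADRANTS)))
  }))

  ## Table 4 analog: asymmetry indices
  ai_pairs <- list(
    c("vertical", "LR", "LL"), c("vertical", "UL", "UR"),
    c("horizontal", "LR", "UR"), c("horizontal", "LL", "UL")
  )
  asymmetry <- dplyr::bind_rows(lapply(ai_pairs, function(p) {
    dplyr::bind_rows(lapply(arm_names, function(a) {
      s1 <- per_arm[[a]]$rois[[p[2]]]$size; s2 <- per_arm[[a]]$rois[[p[3]]]$size
      tibble::tibble(
        symmetry = p[1], roi_comparison = paste(p[2], "and", p[3]),
        arm = ARM_LABELS[[a]],
        ai = if (s1 + s2 >= 1) asymmetry_index(s1, s2) else NA_real_
      )
    }))
  }))

  ## Table 5 analog: probability map extent and maxima
  pm_summary <- dplyr::bind_rows(lapply(arm_names, function(a) {
    dplyr::bind_rows(lapply(QUADRANTS, function(q) {
      pmv <- per_arm[[a]]$pm[[q]]
      tibble::tibble(
        quadrant = q, arm = ARM_LABELS[[a]],
        n_vertices = pm_extent(pmv, config$pm_display_threshold),
        mpo = max(pmv),
        mpo_vertex = which.max(pmv)
      )
    }))
  }))

  ## Table 6 analog: probability difference maps
  pdm_summary <- dplyr::bind_rows(lapply(pair_defs, function(p) {
    if (!all(p %in% arm_names)) return(NULL)
    dplyr::bind_rows(lapply(QUADRANTS, function(q) {
      pdm <- probability_difference_map(
        per_arm[[p[2]]]$pm[[q]], per_arm[[p[1]]]$pm[[q]],
        threshold = config$pdm_threshold,
        pair_label = paste(ARM_LABELS[[p[2]]], "minus", ARM_LABELS[[p[1]]])
      )
      tibble::tibble(
        quadrant = q, comparison = pdm$pair_label,
        n_vertices = pdm$n_exceed, pd_pos = pdm$pd_pos, pd_neg = pdm$pd_neg,
        focus_pos = pdm$focus_pos, focus_neg = pdm$focus_neg
      )
    }))
  }))

  ## Table 7 analog: single-subject peak vertex distributions (surface arms)
  peak_arms <- intersect(c("surface_unaligned", "surface_cba"), arm_names)
  peaks <- list(); detection <- NULL; peak_summary <- NULL
  if (length(peak_arms)) {
    t_crit_ss <- stats::qt(1 - config$single_subject_p, df = dof)
    for (a in peak_arms) {
      pk <- lapply(seq_len(n_sub), function(s) {
        out <- stats::setNames(rep(NA_integer_, 4), QUADRANTS)
        for (q in QUADRANTS) {
          roi <- extract_group_roi(arms[[a]]$t[[s]][, q], mesh, t_crit_ss,
                                   per_arm[[a]]$seeds[[q]],
                                   config$seed_max_distance)
          if (roi$found) out[q] <- peak_vertex(arms[[a]]$t[[s]][, q], roi$vertices)
        }
        out
      })
      peaks[[a]] <- peak_distribution(pk, mesh$n_vertices)
    }
    detection <- dplyr::bind_rows(lapply(peak_arms, function(a) {
      tibble::tibble(
        quadrant = QUADRANTS, arm = ARM_LABELS[[a]],
        n_detected = as.integer(peaks[[a]]$detected[QUADRANTS]),
        n_total = n_sub,
        rate_pct = detection_success_rate(peaks[[a]]$detected[QUADRANTS], n_sub)
      )
    }))
    peak_summary <- dplyr::bind_rows(lapply(peak_arms, function(a) {
      dplyr::mutate(peaks[[a]]$histogram, arm = ARM_LABELS[[a]], .before = 1)
    }))
  }

  list(
    arms = per_arm,
    subject_maps = arms,
    tables = list(
      group_rois = group_rois, size_changes = size_changes,
      selectivity = selectivity, asymmetry = asymmetry,
      pm_summary = pm_summary, pdm_summary = pdm_summary,
      peak_summary = peak_summary, detection = detection
    ),
    peaks = peaks
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d subjects, arms: %s (%.0f s)\n",
              x$config$n_subjects, paste(x$config$arms, collapse = ", "),
              x$timing[["total"]]))
  mpo <- x$tables$pm_summary
  if (!is.null(mpo)) {
    agg <- stats::aggregate(mpo$mpo, list(arm = mpo$arm), max)
    cat("  max probability of activation overlap: ",
        paste(sprintf("%s %.0f%%", agg$arm, agg$x), collapse = ", "), "\n")
  }
  invisible(x)
}

#' One-row summary of an experiment
#' @param x an `experiment_result`
#' @param ... unused
#' @method glance experiment_result
#' @export
glance.experiment_result <- function(x, ...) {
  mpo <- x$tables$pm_summary
  out <- tibble::tibble(
    n_subjects = x$config$n_subjects,
    n_vertices = x$template$sphere$n_vertices,
    n_arms = length(x$config$arms),
    runtime_s = x$timing[["total"]]
  )
  for (a in unique(mpo$arm)) {
    out[[paste0("mpo_", gsub("-analog", "", a))]] <- max(mpo$mpo[mpo$arm == a])
  }
  out
}

#' Write the report tables and run manifest of an experiment
#'
#' Writes one CSV per evaluation table (deterministic content) plus a JSON
#' manifest with the configuration, seeds, analysis-space sizes and stage
#' wall-clock times.
#'
#' @param result an `experiment_result`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(result$tables)) {
    tb <- result$tables[[nm]]
    if (is.null(tb)) next
    utils::write.csv(as.data.frame(tb), file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cortexalign")),
    config = result$config[setdiff(names(result$config), "cba")],
    cba = unclass(result$config$cba),
    n_tests = lapply(result$arms, `[[`, "n_tests"),
    timing_s = result$timing,
    note = paste("volume arm is a simplified analog: 3D smoothing and",
                 "voxel-level analysis without macroanatomical alignment;",
                 "no scanner-side corrections are simulated")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
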