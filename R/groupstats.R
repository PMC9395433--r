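## Group-level and single-subject evaluation statistics: RFX t maps,
## Bonferroni thresholds, group ROIs, size-change and asymmetry indices,
## probability (difference) maps, peak vertex distributions, and the
## position-selectivity comparison across alignment arms.

#' Random-effects group t map (one-sample t across subjects)
#'
#' @param subject_maps list (or units x subjects matrix) of per-subject
#'   contrast maps sharing one topology.
#' @return numeric vector of t values with df = n - 1 (attribute `"df"`);
#'   zero-variance units are capped at +/- 1e6 and flagged via attribute
#'   `"capped"`.
#' @export
rfx_group_tmap <- function(subject_maps) {
  M <- if (is.list(subject_maps)) {
    do.call(cbind, lapply(subject_maps, as.numeric))
  } else as.matrix(subject_maps)
  n <- ncol(M)
  if (n < 3) stop("random-effects analysis needs at least 3 subjects", call. = FALSE)
  mu <- rowMeans(M)
  s2 <- rowSums((M - mu)^2) / (n - 1)
  se <- sqrt(s2 / n)
  capped <- se <= .Machine$double.eps * pmax(abs(mu), 1)
  t_val <- numeric(length(mu))
  t_val[!capped] <- mu[!capped] / se[!capped]
  # zero-variance guard: cap, but numerically-zero means stay zero
  t_val[capped] <- sign(mu[capped]) * T_CAP
  t_val[capped & abs(mu) <= 1e-8 * max(abs(mu))] <- 0
  over <- abs(t_val) > T_CAP
  t_val[over] <- sign(t_val[over]) * T_CAP
  structure(t_val, df = n - 1L, capped = capped | over)
}

#' Bonferroni-corrected per-test alpha
#'
#' @param alpha family-wise error rate (e.g. 0.05).
#' @param n_tests number of vertices or voxels in the analysis space (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    stop("`n_tests` must be a positive count", call. = FALSE)
  }
  alpha / n_tests
}

#' Extract a group ROI from a thresholded t map
#'
#' Suprathreshold vertices are split into edge-connected components; the
#' component containing the expected seed vertex is returned, or failing
#' that the component geodesically nearest to the seed (within
#' `max_seed_distance`). An empty result is a value, not an error.
#'
#' @param tmap per-vertex t values.
#' @param mesh the `sphere_mesh`.
#' @param t_threshold critical t value; vertices with `t > t_threshold` enter.
#' @param seed expected ROI seed: a vertex index or unit 3-vector.
#' @param max_seed_distance maximum geodesic distance (radians) between seed
#'   and the nearest component vertex (default Inf).
#' @return object of class `group_roi`: `found`, `vertices`, `size`,
#'   `peak_vertex`, `peak_t`, `center` (unit 3-vector).
#' @export
extract_group_roi <- function(tmap, mesh, t_threshold, seed,
                              max_seed_distance = Inf) {
  tmap <- as.numeric(tmap)
  sup <- which(tmap > t_threshold)
  not_found <- structure(
    list(found = FALSE, vertices = integer(0), size = 0L,
         peak_vertex = NA_integer_, peak_t = NA_real_, center = NULL),
    class = "group_roi"
  )
  if (!length(sup)) return(not_found)
  seed_pos <- if (length(seed) == 1) mesh$vertices[seed, ] else seed / sqrt(sum(seed^2))
  comps <- connected_components(mesh, sup)
  dists <- vapply(comps, function(cp) {
    min(geodesic_distance(mesh$vertices[cp, , drop = FALSE], matrix(seed_pos, 1)))
  }, numeric(1))
  best <- which.min(dists)
  if (dists[best] > max_seed_distance) return(not_found)
  verts <- comps[[best]]
  pk <- verts[which.max(tmap[verts])]
  ctr <- colMeans(mesh$vertices[verts, , drop = FALSE])
  ctr <- ctr / sqrt(sum(ctr^2))
  structure(
    list(found = TRUE, vertices = verts, size = length(verts),
         peak_vertex = pk, peak_t = tmap[pk], center = ctr),
    class = "group_roi"
  )
}

#' @export
print.group_roi <- function(x, ...) {
  if (!x$found) cat("<group_roi> not found\n")
  else cat(sprintf("<group_roi> %d vertices, peak t = %.2f at vertex %d\n",
                   x$size, x$peak_t, x$peak_vertex))
  invisible(x)
}

#' Percentage change of ROI size between alignment methods
#'
#' `(after - before) / before x 100`, rounded to the nearest integer for
#' reports.
#'
#' @param size_before,size_after vertex counts (before >= 1).
#' @param round_result round to the printed integer precision (default TRUE).
#' @return percentage (scalar).
#' @export
size_change <- function(size_before, size_after, round_result = TRUE) {
  if (any(size_before < 1)) stop("reference ROI size must be at least 1", call. = FALSE)
  out <- (size_after - size_before) / size_before * 100
  if (round_result) round(out) else out
}

#' Asymmetry index of two ROI sizes
#'
#' `|a - b| / (a + b) x 100`, one-decimal rounding for reports; symmetric in
#' its arguments and 0 for equal sizes.
#'
#' @param size_a,size_b vertex counts with `size_a + size_b >= 1`.
#' @param round_result round to one decimal (default TRUE).
#' @return percentage (scalar).
#' @export
asymmetry_index <- function(size_a, size_b, round_result = TRUE) {
  if (any(size_a + size_b < 1)) {
    stop("asymmetry index undefined for two empty ROIs", call. = FALSE)
  }
  out <- abs(size_a - size_b) / (size_a + size_b) * 100
  if (round_result) round(out, 1) else out
}

#' Threshold a single-subject t map at an uncorrected one-sided p
#'
#' @param tmap per-vertex t values.
#' @param dof degrees of freedom of the t map.
#' @param p one-sided uncorrected threshold (default 0.05).
#' @return logical per-vertex indicator of `t > t_crit`.
#' @export
single_subject_map <- function(tmap, dof, p = 0.05) {
  if (dof < 1) stop("`dof` must be at least 1", call. = FALSE)
  as.numeric(tmap) > stats::qt(1 - p, df = dof)
}

#' Probability map of activation overlap
#'
#' Per-vertex percentage of subjects whose single-subject binary map is
#' active, optionally display-thresholded at a minimum probability and
#' cluster-filtered.
#'
#' @param binary_maps list (or units x subjects matrix) of logical maps.
#' @param mesh `sphere_mesh`, required only when `cluster_threshold` is used.
#' @param min_prob display threshold in percent (values below are zeroed);
#'   `NULL` (default) keeps the raw map.
#' @param cluster_threshold minimum cluster size in vertices applied after
#'   the probability threshold; `NULL` to skip.
#' @return object of class `probability_map`: `values` (percent),
#'   `n_subjects`, `threshold_info`.
#' @export
probability_map <- function(binary_maps, mesh = NULL, min_prob = NULL,
                            cluster_threshold = NULL) {
  M <- if (is.list(binary_maps)) {
    do.call(cbind, lapply(binary_maps, as.logical))
  } else as.matrix(binary_maps)
  n <- ncol(M)
  vals <- rowSums(M) / n * 100
  if (!is.null(min_prob)) vals[vals < min_prob] <- 0
  if (!is.null(cluster_threshold)) {
    if (is.null(mesh)) stop("`mesh` needed for cluster thresholding", call. = FALSE)
    comps <- connected_components(mesh, which(vals > 0))
    for (cp in comps) if (length(cp) < cluster_threshold) vals[cp] <- 0
  }
  structure(
    list(values = vals, n_subjects = n,
         threshold_info = list(min_prob = min_prob,
                               cluster_threshold = cluster_threshold)),
    class = "probability_map"
  )
}

#' @export
print.probability_map <- function(x, ...) {
  cat(sprintf("<probability_map> n = %d, max overlap %.0f%%\n",
              x$n_subjects, max(x$values)))
  invisible(x)
}

#' Number of vertices exceeding a probability-map threshold
#'
#' @param pm a [probability_map()] (or plain percentage vector).
#' @param min_prob threshold in percent (default 10).
#' @return vertex count.
#' @export
pm_extent <- function(pm, min_prob = 10) {
  vals <- if (inherits(pm, "probability_map")) pm$values else as.numeric(pm)
  sum(vals >= min_prob)
}

#' Probability difference map between two alignment arms
#'
#' Vertex-wise `pm_a - pm_b` from the unthresholded probability maps, with
#' the positive and negative foci and the vertex counts beyond +/-
#' `threshold` percent.
#'
#' @param pm_a,pm_b [probability_map()] objects (the "more advanced" arm
#'   first).
#' @param threshold reporting threshold in percent (default 5).
#' @param pair_label free-text label such as "CBA minus SBAV".
#' @return object of class `probability_difference_map`: `values`,
#'   `pair_label`, `pd_pos`, `pd_neg`, `focus_pos`, `focus_neg` (vertex
#'   indices), `n_exceed` (count beyond the +/- threshold).
#' @export
probability_difference_map <- function(pm_a, pm_b, threshold = 5,
                                       pair_label = "") {
  a <- if (inherits(pm_a, "probability_map")) pm_a$values else as.numeric(pm_a)
  b <- if (inherits(pm_b, "probability_map")) pm_b$values else as.numeric(pm_b)
  if (length(a) != length(b)) stop("probability maps differ in topology", call. = FALSE)
  v <- a - b
  structure(
    list(values = v, pair_label = pair_label,
         pd_pos = max(v), pd_neg = min(v),
         focus_pos = which.max(v), focus_neg = which.min(v),
         n_exceed = sum(v >= threshold | v <= -threshold),
         threshold = threshold),
    class = "probability_difference_map"
  )
}

#' @export
print.probability_difference_map <- function(x, ...) {
  cat(sprintf("<probability_difference_map> %s: PD+ %.0f%%, PD- %.0f%%, %d vertices beyond +/-%g%%\n",
              x$pair_label, x$pd_pos, x$pd_neg, x$n_exceed, x$threshold))
  invisible(x)
}

#' Peak vertex of a t map within an ROI
#'
#' @param tmap per-vertex t values.
#' @param roi integer vertex set (may be empty).
#' @return the argmax vertex index (ties broken by lowest index), or
#'   `NA_integer_` for an empty ROI.
#' @export
peak_vertex <- function(tmap, roi) {
  roi <- as.integer(roi)
  if (!length(roi)) return(NA_integer_)
  roi <- sort(roi)
  roi[which.max(as.numeric(tmap)[roi])]
}

#' Distribution of single-subject peak vertices
#'
#' @param peaks_by_subject list over subjects of named per-quadrant peak
#'   vertex indices (NA = quadrant not detected for that subject).
#' @param n_vertices mesh vertex count.
#' @return object of class `peak_distribution`: `counts` (per quadrant, a
#'   vertex-count vector), `detected` (per-quadrant subject counts),
#'   `histogram` (tibble: quadrant, multiplicity, n_vertices).
#' @export
peak_distribution <- function(peaks_by_subject, n_vertices) {
  quads <- names(peaks_by_subject[[1]])
  counts <- lapply(quads, function(q) {
    pk <- vapply(peaks_by_subject, function(p) as.integer(p[[q]]), integer(1))
    pk <- pk[!is.na(pk)]
    tabulate(pk, n_vertices)
  })
  names(counts) <- quads
  detected <- vapply(quads, function(q) {
    sum(!is.na(vapply(peaks_by_subject, function(p) as.integer(p[[q]]), integer(1))))
  }, integer(1))
  hist <- dplyr::bind_rows(lapply(quads, function(q) {
    ct <- counts[[q]]
    mx <- max(ct, 1)
    tibble::tibble(quadrant = q, multiplicity = seq_len(mx),
                   n_vertices = vapply(seq_len(mx), function(k) sum(ct == k), integer(1)))
  }))
  structure(list(counts = counts, detected = detected, histogram = hist),
            class = "peak_distribution")
}

#' @export
print.peak_distribution <- function(x, ...) {
  cat(sprintf("<peak_distribution> detected: %s\n",
              paste(names(x$detected), x$detected, sep = "=", collapse = " ")))
  invisible(x)
}

#' Detection success rate in percent
#'
#' @param n_detected,n_total subject counts (`n_detected <= n_total`,
#'   `n_total >= 1`).
#' @param round_result round to the printed integer precision (default TRUE).
#' @return percentage.
#' @export
detection_success_rate <- function(n_detected, n_total, round_result = TRUE) {
  if (any(n_total < 1)) stop("`n_total` must be at least 1", call. = FALSE)
  if (any(n_detected > n_total)) stop("`n_detected` cannot exceed `n_total`", call. = FALSE)
  out <- n_detected / n_total * 100
  if (round_result) round(out) else out
}

#' Test whether position selectivity differs across alignment arms
#'
#' Per-subject selectivity scores (`3 t_target - sum of the other three`)
#' are compared across alignment arms with a repeated-measures one-way
#' analysis (arm effect with subject as blocking factor); optionally a
#' random-intercept linear mixed model via lmerTest.
#'
#' @param scores data frame (or tibble) with columns `subject`, `arm`,
#'   `score` (one row per subject x arm, complete cases).
#' @param method `"anova"` (default) or `"lmm"` (needs lmerTest installed).
#' @return tibble with columns statistic (F), num_df, den_df, p_value.
#' @export
position_selectivity_test <- function(scores, method = c("anova", "lmm")) {
  method <- match.arg(method)
  scores <- as.data.frame(scores)
  arms <- unique(scores$arm)
  if (length(arms) < 2) stop("need at least 2 alignment arms", call. = FALSE)
  if (length(unique(scores$subject)) < 3) stop("need at least 3 subjects", call. = FALSE)
  if (anyNA(scores$score)) stop("scores must be complete cases", call. = FALSE)
  if (method == "lmm") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("method = 'lmm' requires the lmerTest package", call. = FALSE)
    }
    fit <- lmerTest::lmer(score ~ arm + (1 | subject), data = scores)
    an <- stats::anova(fit)
    return(tibble::tibble(statistic = an[["F value"]][1],
                          num_df = an[["NumDF"]][1], den_df = an[["DenDF"]][1],
                          p_value = an[["Pr(>F)"]][1]))
  }
  fit <- stats::aov(score ~ factor(arm) + factor(subject), data = scores)
  an <- summary(fit)[[1]]
  f_val <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]
  ss <- an[["Sum Sq"]]
  # no arm effect at all (e.g. identical scores in every arm): F = 0, p = 1
  if (!is.finite(f_val) || ss[1] <= 1e-12 * sum(ss)) { f_val <- 0; p_val <- 1 }
  tibble::tibble(statistic = f_val, num_df = an[["Df"]][1],
                 den_df = an[["Df"]][3], p_value = p_val)
}
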