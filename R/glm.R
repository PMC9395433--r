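## Per-vertex least-squares GLM, weighted contrasts, event-related averages.

#' Guard value used when a t statistic has (numerically) zero residual variance
#' @noRd
T_CAP <- 1e6

#' Fit the localizer GLM at every vertex (or voxel)
#'
#' Ordinary least squares of each row of `bold` on the design matrix.
#'
#' @param bold numeric matrix, units (vertices or voxels) x time.
#' @param design a [build_design()] object (or plain matrix with named
#'   columns).
#' @return object of class `glm_result`: `betas` (units x predictors),
#'   `residual_variance`, `dof` (= volumes - rank), `XtXinv`,
#'   `condition_names`.
#' @export
fit_glm <- function(bold, design) {
  X <- if (inherits(design, "design_matrix")) design$matrix else as.matrix(design)
  bold <- as.matrix(bold)
  if (ncol(bold) != nrow(X)) {
    stop("`bold` must be units x time with time matching the design", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  B <- t(qr.coef(qx, t(bold)))                     # units x predictors
  fitted <- B %*% t(X)
  dof <- nrow(X) - qx$rank
  rss <- rowSums((bold - fitted)^2)
  structure(
    list(
      betas = B,
      residual_variance = rss / dof,
      dof = dof,
      XtXinv = chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE],
      condition_names = intersect(colnames(X), QUADRANTS),
      predictor_names = colnames(X)
    ),
    class = "glm_result"
  )
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> %d units, %d predictors, dof = %d\n",
              nrow(x$betas), ncol(x$betas), x$dof))
  invisible(x)
}

#' Position-of-interest contrast weights (+3 on the target quadrant)
#'
#' @param quadrant one of "LL", "LR", "UL", "UR".
#' @return numeric vector of 4 weights named by condition.
#' @export
poi_contrast <- function(quadrant) {
  quadrant <- match.arg(quadrant, QUADRANTS)
  w <- rep(-1, 4)
  names(w) <- QUADRANTS
  w[quadrant] <- 3
  w
}

#' t map of a weighted condition contrast
#'
#' Computes `t = c'beta / sqrt(sigma^2 c'(X'X)^-1 c)` per unit. Units with
#' numerically zero residual variance are capped at +/- 1e6 and flagged via
#' the `"capped"` attribute.
#'
#' @param result a [fit_glm()] object.
#' @param weights 4 condition weights (named or in condition order); nuisance
#'   predictors receive weight 0.
#' @return numeric vector of t values (attribute `"capped"`: logical vector).
#' @export
contrast_t <- function(result, weights) {
  stopifnot(inherits(result, "glm_result"))
  if (length(weights) != 4) stop("`weights` must have exactly 4 entries", call. = FALSE)
  if (all(weights == 0)) stop("`weights` must not be all zero", call. = FALSE)
  cn <- result$condition_names
  if (!is.null(names(weights))) weights <- weights[cn]
  cvec <- stats::setNames(rep(0, length(result$predictor_names)), result$predictor_names)
  cvec[cn] <- weights
  num <- as.numeric(result$betas %*% cvec)
  quad <- as.numeric(t(cvec) %*% result$XtXinv %*% cvec)
  se2 <- result$residual_variance * quad
  tiny <- se2 <= (.Machine$double.eps * max(num^2, 1))
  t_val <- numeric(length(num))
  t_val[!tiny] <- num[!tiny] / sqrt(se2[!tiny])
  # zero-residual guard: cap, but treat numerically-zero effects as zero
  num_zero <- abs(num) <= 1e-8 * max(abs(num))
  t_val[tiny] <- sign(num[tiny]) * T_CAP
  t_val[tiny & num_zero] <- 0
  over <- abs(t_val) > T_CAP
  t_val[over] <- sign(t_val[over]) * T_CAP
  structure(t_val, capped = tiny | over)
}

#' Per-condition t values (each condition beta against zero)
#' @noRd
condition_t <- function(result) {
  cn <- result$condition_names
  p <- result$predictor_names
  out <- sapply(cn, function(q) {
    cvec <- stats::setNames(rep(0, length(p)), p)
    cvec[q] <- 1
    as.numeric(contrast_t_raw(result, cvec))
  })
  colnames(out) <- cn
  out
}

#' @noRd
contrast_t_raw <- function(result, cvec) {
  num <- as.numeric(result$betas %*% cvec)
  quad <- as.numeric(t(cvec) %*% result$XtXinv %*% cvec)
  se2 <- result$residual_variance * quad
  tiny <- se2 <= (.Machine$double.eps * max(num^2, 1))
  t_val <- numeric(length(num))
  t_val[!tiny] <- num[!tiny] / sqrt(se2[!tiny])
  t_val[tiny] <- sign(num[tiny]) * T_CAP
  t_val[tiny & abs(num) <= 1e-8 * max(abs(num))] <- 0
  t_val
}

#' Event-related average time courses per condition
#'
#' Extracts epochs locked to trial onsets, averages them per condition and
#' reports the standard error of the mean over epochs.
#'
#' @param series numeric vector: a single (e.g. ROI-averaged) BOLD time
#'   series sampled every `TR` seconds, first sample at time `t0`.
#' @param paradigm a [generate_paradigm()] object.
#' @param TR sampling interval (default 2 s).
#' @param window epoch length in seconds (default 20, must be <= 20).
#' @param t0 acquisition time of the first sample (default 0; use
#'   `n_discard * TR` for series whose initial volumes were discarded).
#' @return tibble with columns condition, time, mean, sem, n_epochs.
#' @export
event_related_average <- function(series, paradigm, TR = 2, window = 20, t0 = 0) {
  stopifnot(inherits(paradigm, "paradigm"))
  if (window > 20) stop("`window` must be at most 20 s", call. = FALSE)
  n <- length(series)
  offsets <- seq(0, window - TR, by = TR)
  truncated <- character(0)
  rows <- lapply(QUADRANTS, function(q) {
    onsets <- paradigm$trials$onset[paradigm$trials$condition == q]
    idx <- outer(onsets, offsets, function(o, d) round((o + d - t0) / TR) + 1)
    if (any(idx > n)) truncated <<- c(truncated, q)
    vals <- matrix(ifelse(idx >= 1 & idx <= n, series[pmin(pmax(idx, 1), n)], NA_real_),
                   nrow(idx), ncol(idx))
    tibble::tibble(
      condition = q,
      time = offsets,
      mean = colMeans(vals, na.rm = TRUE),
      sem = apply(vals, 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
      }),
      n_epochs = colSums(!is.na(vals))
    )
  })
  if (length(truncated)) {
    warning(sprintf("epoch window truncated at series end for condition(s) %s",
                    paste(truncated, collapse = ", ")))
  }
  dplyr::bind_rows(rows)
}

## ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-unit GLM estimates into a long tibble
#' @param x a `glm_result`
#' @param ... unused
#' @method tidy glm_result
#' @export
tidy.glm_result <- function(x, ...) {
  B <- x$betas[, x$condition_names, drop = FALSE]
  tibble::tibble(
    unit = rep(seq_len(nrow(B)), times = ncol(B)),
    condition = rep(colnames(B), each = nrow(B)),
    estimate = as.numeric(B)
  )
}

#' One-row GLM fit summary
#' @param x a `glm_result`
#' @param ... unused
#' @method glance glm_result
#' @export
glance.glm_result <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$betas),
    n_predictors = ncol(x$betas),
    dof = x$dof,
    median_residual_variance = stats::median(x$residual_variance)
  )
}
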