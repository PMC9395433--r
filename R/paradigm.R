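## Attention-enhanced visual field localizer paradigm and design matrix.

QUADRANTS <- c("LL", "LR", "UL", "UR")

#' Evaluate an expression with a temporary RNG seed
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Generate the visual field localizer paradigm
#'
#' 144 trials of 2000 ms (36 per quadrant condition, in randomised order),
#' 36 target trials (9 per condition), regular inter-trial interval 0 ms with
#' a prolonged 2000-ms ITI once every 10-14 trials (11 times overall), a 10-s
#' fixation lead-in and a 20-s lead-out: 340 s in total.
#'
#' @param seed integer RNG seed for the randomised condition order, target
#'   placement and prolonged-ITI schedule.
#' @param n_prolonged number of prolonged ITIs (default 11).
#' @param lead_in,lead_out fixation periods in seconds (defaults 10 and 20).
#' @return an object of class `paradigm`: list with `trials` (tibble with
#'   columns trial, condition, onset, duration, is_target), element
#'   `prolonged_iti_after` (trial indices), `lead_in`, `lead_out`,
#'   `total_duration` (seconds).
#' @export
generate_paradigm <- function(seed, n_prolonged = 11, lead_in = 10, lead_out = 20) {
  n_trials <- 144L
  per_cond <- 36L
  targets_per_cond <- 9L
  trial_dur <- 2
  iti_prolonged <- 2
  with_seed(seed, {
    condition <- sample(rep(QUADRANTS, per_cond))
    is_target <- logical(n_trials)
    for (q in QUADRANTS) {
      idx <- which(condition == q)
      is_target[sample(idx, targets_per_cond)] <- TRUE
    }
    prolonged_after <- integer(0)
    if (n_prolonged > 0) {
      repeat {
        gaps <- sample(10:14, n_prolonged, replace = TRUE)
        pos <- cumsum(gaps)
        if (max(pos) <= n_trials - 1L) { prolonged_after <- pos; break }
      }
    }
    n_prolonged_before <- vapply(
      seq_len(n_trials), function(i) sum(prolonged_after < i), integer(1)
    )
    onset <- lead_in + trial_dur * (seq_len(n_trials) - 1) +
      iti_prolonged * n_prolonged_before
    trials <- tibble::tibble(
      trial = seq_len(n_trials),
      condition = factor(condition, levels = QUADRANTS),
      onset = onset,
      duration = trial_dur,
      is_target = is_target
    )
    structure(
      list(
        trials = trials,
        prolonged_iti_after = prolonged_after,
        lead_in = lead_in, lead_out = lead_out,
        total_duration = lead_in + n_trials * trial_dur +
          length(prolonged_after) * iti_prolonged + lead_out
      ),
      class = "paradigm"
    )
  })
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf(
    "<paradigm> %d trials (%d targets), %d prolonged ITIs, %g s total\n",
    nrow(x$trials), sum(x$trials$is_target), length(x$prolonged_iti_after),
    x$total_duration
  ))
  invisible(x)
}

#' Canonical two-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities: a response lobe peaking at
#' `time_to_peak` s and an undershoot peaking at `undershoot_peak` s with
#' amplitude ratio `ratio`, truncated at `duration` s and scaled to unit peak.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param time_to_peak response peak time (default 5 s).
#' @param undershoot_peak undershoot peak time (default 15 s).
#' @param ratio response-to-undershoot amplitude ratio (default 6).
#' @param duration kernel support in seconds (default 32).
#' @return numeric vector of kernel values sampled at `0, dt, 2 dt, ...`.
#' @export
two_gamma_hrf <- function(dt, time_to_peak = 5, undershoot_peak = 15,
                          ratio = 6, duration = 32) {
  if (length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  t <- seq(0, duration, by = dt)
  # gamma density with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = time_to_peak + 1, rate = 1) -
    stats::dgamma(t, shape = undershoot_peak + 1, rate = 1) / ratio
  h / max(h)
}

#' Build the HRF-convolved design matrix for a paradigm
#'
#' Each condition is modelled as an ideal box-car covering its trials at
#' stimulus resolution `dt`, convolved with the two-gamma kernel and sampled
#' at the volume acquisition times; the first `n_discard` volumes are
#' discarded before modelling. A constant column is appended.
#'
#' @param paradigm a [generate_paradigm()] object.
#' @param TR repetition time in seconds (default 2).
#' @param n_volumes acquired volumes (default 170).
#' @param n_discard initial volumes dropped for T1 equilibration (default 4).
#' @param dt stimulus-resolution grid step for the convolution (default 0.1 s).
#' @param hrf optional kernel values sampled at `dt` (default [two_gamma_hrf()]).
#' @return object of class `design_matrix`: list with `matrix`
#'   ((n_volumes - n_discard) x 5), `predictor_names`, `TR`, `n_volumes`
#'   (modelled volumes), `frame_times` (seconds), `n_discard`.
#' @export
build_design <- function(paradigm, TR = 2, n_volumes = 170, n_discard = 4,
                         dt = 0.1, hrf = NULL) {
  stopifnot(inherits(paradigm, "paradigm"))
  scan_dur <- n_volumes * TR
  if (scan_dur < paradigm$total_duration - n_discard * TR) {
    stop(sprintf(
      "paradigm (%g s) overshoots the modelled scan by %g s",
      paradigm$total_duration, paradigm$total_duration - n_discard * TR - scan_dur
    ), call. = FALSE)
  }
  counts <- table(paradigm$trials$condition)
  if (any(counts == 0)) {
    stop(sprintf("condition(s) with no events: %s",
                 paste(names(counts)[counts == 0], collapse = ", ")), call. = FALSE)
  }
  if (is.null(hrf)) hrf <- two_gamma_hrf(dt)
  grid_n <- ceiling(max(scan_dur, paradigm$total_duration) / dt) + 1
  grid_t <- (seq_len(grid_n) - 1) * dt
  frame_times <- (seq_len(n_volumes) - 1) * TR
  X <- matrix(0, n_volumes, length(QUADRANTS))
  colnames(X) <- QUADRANTS
  for (q in QUADRANTS) {
    tr <- paradigm$trials[paradigm$trials$condition == q, ]
    box <- numeric(grid_n)
    for (i in seq_len(nrow(tr))) {
      box[grid_t >= tr$onset[i] & grid_t < tr$onset[i] + tr$duration[i]] <- 1
    }
    reg <- stats::convolve(box, rev(hrf), type = "open")[seq_len(grid_n)] * dt
    # sample at acquisition times (grid is exact for TR multiples of dt)
    X[, q] <- reg[round(frame_times / dt) + 1]
  }
  keep <- (n_discard + 1):n_volumes
  X <- cbind(X[keep, , drop = FALSE], constant = 1)
  structure(
    list(
      matrix = X, predictor_names = colnames(X), TR = TR,
      n_volumes = length(keep), frame_times = frame_times[keep],
      n_discard = n_discard
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %d volumes x %d predictors (TR = %g s)\n",
              x$n_volumes, ncol(x$matrix), x$TR))
  invisible(x)
}

#' Linear trend removal and FFT high-pass filtering of time series
#'
#' Removes the per-series linear trend (the mean is retained), then zeroes
#' all Fourier components with frequency strictly below `cutoff`, excluding
#' the DC component.
#'
#' @param series numeric vector, or matrix with one series per row.
#' @param TR sampling interval in seconds.
#' @param cutoff high-pass cutoff in Hz (default 0.00903, must be below
#'   Nyquist).
#' @return filtered series with the same shape as the input.
#' @export
highpass_and_detrend <- function(series, TR, cutoff = 0.00903) {
  vec <- is.null(dim(series))
  Y <- if (vec) matrix(series, nrow = 1) else as.matrix(series)
  T_len <- ncol(Y)
  if (T_len < 8) stop("time series must have at least 8 samples", call. = FALSE)
  if (cutoff >= 1 / (2 * TR)) stop("`cutoff` must be below the Nyquist frequency", call. = FALSE)
  t <- seq_len(T_len) - mean(seq_len(T_len))
  slope <- (Y %*% t) / sum(t^2)
  Y <- Y - slope %*% t
  f <- (seq_len(T_len) - 1) / (T_len * TR)
  f <- pmin(f, 1 / TR - f)            # two-sided frequency axis
  kill <- f > 0 & f < cutoff
  if (any(kill)) {
    Yf <- t(stats::mvfft(t(Y)))
    Yf[, kill] <- 0
    Y <- Re(t(stats::mvfft(t(Yf), inverse = TRUE))) / T_len
  }
  if (vec) as.numeric(Y) else Y
}
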