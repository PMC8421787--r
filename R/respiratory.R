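#' Respiratory response function constants
#'
#' Constants of the canonical two-gamma-like respiratory response function
#' `a1 * t^p1 * exp(-t/tau1) - a2 * t^p2 * exp(-t/tau2)` describing the BOLD
#' impulse response to a brief respiratory event: an early positive lobe
#' peaking near 3 s followed by a slow negative lobe.
#'
#' @param a1,p1,tau1 Amplitude, power and decay (s) of the positive term.
#' @param a2,p2,tau2 Amplitude, power and decay (s) of the negative term.
#' @return An object of class `rrf_params`.
#' @export
rrf_params <- function(a1 = 0.6, p1 = 2.1, tau1 = 1.5,
                       a2 = 0.0023, p2 = 3.54, tau2 = 4.25) {
  pars <- list(a1 = a1, p1 = p1, tau1 = tau1, a2 = a2, p2 = p2, tau2 = tau2)
  assert_that(all(unlist(pars) > 0), "all RRF constants must be positive")
  structure(pars, class = "rrf_params")
}

#' Evaluate the respiratory response function
#'
#' @param t Time in seconds (vectorized, must be non-negative).
#' @param params An [rrf_params()] object.
#' @return The RRF values at `t`.
#' @examples
#' rrf(0)   # 0
#' rrf(1)   # ~0.306
#' @export
rrf <- function(t, params = rrf_params()) {
  stopifnot(inherits(params, "rrf_params"))
  assert_that(all(is.finite(t)) && all(t >= 0), "t must be non-negative")
  params$a1 * t^params$p1 * exp(-t / params$tau1) -
    params$a2 * t^params$p2 * exp(-t / params$tau2)
}

#' Initial breath-hold regressor
#'
#' Discrete convolution of the breath-hold-phase indicator with the
#' respiratory response function sampled at `t = 0, TR, 2 TR, ...` over a
#' 60 s support (covering both RRF lobes), truncated to the run length.
#'
#' @param timing A [build_breathhold_timing()] result.
#' @param params [rrf_params()] to use.
#' @param tr Repetition time in seconds (taken from `timing` by default).
#' @param support RRF sampling support in seconds.
#' @return Numeric regressor, one value per volume.
#' @export
initial_regressor <- function(timing, params = rrf_params(),
                              tr = attr(timing, "tr"), support = 60) {
  assert_that(!is.null(tr) && tr > 0, "tr must be available and positive")
  stim <- hold_indicator(timing)
  kern <- rrf(seq(0, support, by = tr), params)
  full <- stats::convolve(stim, rev(kern), type = "open")
  full[seq_along(stim)]
}

#' Order-statistic smoother weights
#'
#' Weights of the three-point order-statistic filter
#' `y_t = w_med * median + w_max * max + w_min * min` over the window
#' `(x_{t-1}, x_t, x_{t+1})`. The default weights (0.70, 0.15, 0.15) sum to
#' one, so a constant signal passes through unchanged. `printed = TRUE`
#' selects the (0.7, 1.15, 0.15) variant found in some published
#' descriptions of this filter; those weights sum to 2 and double a constant
#' signal, so the unit-sum set is the default.
#'
#' @param w_med,w_max,w_min Weights of the window median, maximum, minimum.
#' @param printed Use the non-unit-sum published variant.
#' @return An object of class `osfilt_weights`.
#' @export
osfilt_weights <- function(w_med = 0.70, w_max = 0.15, w_min = 0.15,
                           printed = FALSE) {
  if (printed) { w_med <- 0.7; w_max <- 1.15; w_min <- 0.15 }
  structure(list(w_med = w_med, w_max = w_max, w_min = w_min),
            class = "osfilt_weights")
}

#' Three-point order-statistic smoothing
#'
#' @param x Numeric series of length >= 3.
#' @param weights An [osfilt_weights()] object.
#' @return The smoothed series (endpoints handled by edge replication).
#' @examples
#' osfilt_smooth(c(1, 2, 3))  # interior value 0.7*2 + 0.15*3 + 0.15*1 = 2
#' @export
osfilt_smooth <- function(x, weights = osfilt_weights()) {
  stopifnot(inherits(weights, "osfilt_weights"))
  n <- length(x)
  if (n < 3) stopf("order-statistic smoothing needs at least 3 samples (got %d)", n)
  xl <- c(x[1], x[-n])      # edge replication
  xr <- c(x[-1], x[n])
  hi <- pmax(xl, x, xr)
  lo <- pmin(xl, x, xr)
  md <- xl + x + xr - hi - lo
  weights$w_med * md + weights$w_max * hi + weights$w_min * lo
}

# Correlation of every VOI voxel with the regressor at integer delays
# 0..max_lag TR (regressor delayed, overlapping samples only). Returns the
# per-voxel best score and best lag plus eligibility.
lagged_correlation <- function(run, regressor, voi, max_lag_tr = 4L) {
  voi <- as_mask(voi, "voi")
  assert_that(any(voi), "VOI is empty")
  tlen <- n_volumes(run)
  assert_that(length(regressor) == tlen, "regressor length must match the run")
  idx <- which(voi)
  y <- t(run_matrix(run)[idx, , drop = FALSE])   # T x n
  eligible <- apply(y, 2, stats::sd) > 0
  score <- matrix(-Inf, ncol(y), max_lag_tr + 1L)
  for (l in 0:max_lag_tr) {
    cc <- suppressWarnings(
      stats::cor(y[(l + 1):tlen, , drop = FALSE], regressor[seq_len(tlen - l)]))
    cc[!is.finite(cc)] <- -Inf
    score[, l + 1L] <- cc
  }
  best_lag <- max.col(score, ties.method = "first") - 1L
  best <- score[cbind(seq_len(nrow(score)), best_lag + 1L)]
  list(index = idx, score = best, lag = best_lag, eligible = eligible)
}

#' Select the most task-correlated voxels
#'
#' Scores every non-constant VOI voxel by its maximum Pearson correlation
#' with the regressor over integer delays of 0 to `max_lag_tr` TR, and
#' returns the top `pct` fraction (at least one voxel; deterministic
#' tie-breaking by voxel index).
#'
#' @param run A [bold_run()].
#' @param regressor Numeric regressor matching the run length.
#' @param voi 3D logical volume of interest.
#' @param pct Fraction of eligible voxels to keep (default 0.01, the top 1%).
#' @param max_lag_tr Maximum delay scanned, in TR units.
#' @return Integer vector of linear voxel indices (into the 3D grid), with
#'   the matching delays in `attr(, "lag")`.
#' @export
select_top_correlated <- function(run, regressor, voi, pct = 0.01, max_lag_tr = 4L) {
  assert_that(pct > 0 && pct <= 1, "pct must be in (0, 1]")
  sc <- lagged_correlation(run, regressor, voi, max_lag_tr)
  keep <- which(sc$eligible)
  if (!length(keep)) stopf("no eligible (non-constant) voxels in the VOI")
  k <- ceiling(pct * length(keep))
  ord <- keep[order(-sc$score[keep], keep)][seq_len(k)]
  structure(sc$index[ord], lag = sc$lag[ord])
}

# Shift a series by `s` samples (positive = later), edge-replicating the
# exposed end.
shift_series <- function(w, s) {
  n <- length(w)
  if (s == 0) w
  else if (s > 0) c(rep(w[1], s), w[seq_len(n - s)])
  else c(w[(-s + 1):n], rep(w[n], -s))
}

# Signed delay (positive = waveform later) at which the waveform best matches
# each voxel of the T x n matrix y, with the best correlation attained.
relative_delays <- function(y, w, max_lag) {
  shifts <- -max_lag:max_lag
  cc <- vapply(shifts, function(e)
    suppressWarnings(drop(stats::cor(y, shift_series(w, e)))),
    numeric(ncol(y)))
  cc <- matrix(cc, ncol = length(shifts))
  cc[!is.finite(cc)] <- -Inf
  pick <- max.col(cc, ties.method = "first")
  list(delay = shifts[pick], cor = cc[cbind(seq_len(nrow(cc)), pick)])
}

# Anchor a waveform template so that delay 0 corresponds to the earliest
# delay class supported by a non-trivial share of well-correlated voxels.
# The per-voxel delays from the one-sided 0..max_lag selection scan carry a
# common offset whenever the subject's response latency differs from the
# generic regressor's; this removes it.
anchor_waveform <- function(w, y_voi, max_lag, min_cor = 0.4) {
  rel <- relative_delays(y_voi, w, max_lag)
  ok <- rel$cor >= min_cor
  if (!any(ok)) return(w)
  d <- rel$delay[ok]
  support <- max(3L, ceiling(0.005 * length(d)))
  classes <- sort(unique(d))
  counts <- vapply(classes, function(k) sum(d == k), integer(1))
  keep <- classes[counts >= support]
  if (!length(keep)) keep <- classes
  shift_series(w, min(keep))
}

#' Estimate a subject's personal respiratory waveform
#'
#' Averages the time series of the top `pct` most task-correlated voxels and
#' smooths the average with the three-point order-statistic filter. Before
#' averaging, each selected series is re-aligned by its own best
#' cross-correlation delay so that voxels responding at different lags
#' reinforce rather than smear the waveform; the average is then anchored so
#' that the earliest-responding selected voxel sits at delay 0, making the
#' result a lag-0 response template even when the subject's true response
#' latency differs from the generic regressor's.
#'
#' @inheritParams select_top_correlated
#' @param weights Smoother weights, see [osfilt_weights()].
#' @param align_lags Re-align selected voxels by their best delay before
#'   averaging.
#' @return An object of class `personal_waveform` with elements `values`
#'   (length = run length), `tr` and `n_source_voxels`.
#' @export
estimate_personal_waveform <- function(run, regressor, voi, pct = 0.01,
                                       max_lag_tr = 4L,
                                       weights = osfilt_weights(),
                                       align_lags = TRUE) {
  sel <- select_top_correlated(run, regressor, voi, pct, max_lag_tr)
  lags <- attr(sel, "lag")
  tlen <- n_volumes(run)
  y <- t(run_matrix(run)[sel, , drop = FALSE])   # T x k
  if (align_lags && any(lags > 0)) {
    for (j in which(lags > 0)) {
      l <- lags[j]
      y[, j] <- c(y[(l + 1):tlen, j], rep(y[tlen, j], l))   # edge-pad tail
    }
  }
  w <- osfilt_smooth(rowMeans(y), weights)
  if (align_lags) {
    idx <- which(as_mask(voi, "voi"))
    y_voi <- t(run_matrix(run)[idx, , drop = FALSE])
    w <- anchor_waveform(w, y_voi, max_lag_tr)
  }
  structure(list(values = w, tr = run$tr, n_source_voxels = length(sel)),
            class = "personal_waveform")
}

#' @export
print.personal_waveform <- function(x, ...) {
  cat(sprintf("<personal_waveform> %d samples at TR = %g s, from %d voxels\n",
              length(x$values), x$tr, x$n_source_voxels))
  invisible(x)
}

#' @export
plot.personal_waveform <- function(x, ...) {
  graphics::plot((seq_along(x$values) - 1) * x$tr, x$values, type = "l",
                 xlab = "time (s)", ylab = "signal",
                 main = "Personal respiratory waveform", ...)
  invisible(x)
}

#' Breath-hold CVR beta map by lagged regression
#'
#' For every VOI voxel, regresses the voxel time series on the personal
#' respiratory waveform delayed by 0 to `max_lag_tr` TR (intercept + slope,
#' ordinary least squares on the overlapping samples). The delay with the
#' highest coefficient of determination wins (ties broken toward the
#' smallest delay); that delay's slope is the voxel's breath-hold CVR
#' metric.
#'
#' @param run A [bold_run()] (typically truncated and mean-100 scaled).
#' @param waveform A [personal_waveform()] or numeric series matching the
#'   run length.
#' @param voi 3D logical volume of interest.
#' @param max_lag_tr Maximum delay scanned, in TR units.
#' @return A [cvr_map()] with `metric_kind = "breathhold_beta"` and the
#'   winning delays in `best_lag`.
#' @export
breathhold_cvr_map <- function(run, waveform, voi, max_lag_tr = 4L) {
  w <- if (inherits(waveform, "personal_waveform")) waveform$values else waveform
  tlen <- n_volumes(run)
  assert_that(length(w) == tlen, "waveform length must equal the run length")
  if (stats::sd(w) == 0) stopf("waveform has zero variance")
  voi <- as_mask(voi, "voi")
  idx <- which(voi)
  assert_that(length(idx) > 0, "VOI is empty")
  y <- run_matrix(run)[idx, , drop = FALSE]      # n x T
  nl <- max_lag_tr + 1L
  betas <- r2 <- matrix(0, length(idx), nl)
  for (l in 0:max_lag_tr) {
    xs <- w[seq_len(tlen - l)]
    xc <- xs - mean(xs)
    sxx <- sum(xc^2)
    yl <- y[, (l + 1):tlen, drop = FALSE]
    sxy <- drop(yl %*% xc)
    syy <- rowSums(yl^2) - rowSums(yl)^2 / length(xs)
    b <- sxy / sxx
    rr <- ifelse(syy > 0, (sxy^2) / (sxx * syy), 0)
    betas[, l + 1L] <- b
    r2[, l + 1L] <- rr
  }
  pick <- max.col(r2, ties.method = "first")
  d <- dim(run$data)[1:3]
  vals <- array(NA_real_, d)
  vals[idx] <- betas[cbind(seq_along(idx), pick)]
  lag <- array(0L, d)
  lag[idx] <- pick - 1L
  cvr_map(vals, voi, "breathhold_beta", best_lag = lag)
}
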