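#' Truncate a breath-hold run to its analysis window
#'
#' Removes the 4 s equilibration period (2 volumes at TR = 2 s) plus the
#' next 10 volumes from the start, and the last 20 volumes (whose final
#' breath-hold response is not fully captured) from the end. A standard
#' 132-volume run yields exactly 100 volumes (200 s).
#'
#' @param x A [bold_run()] (TR must be 2 s) or a numeric series/regressor.
#' @param ... Unused.
#' @return Object of the same type, truncated.
#' @export
truncate_breathhold <- function(x, ...) UseMethod("truncate_breathhold")

bh_keep_index <- function(n) {
  drop_head <- 2L + 10L
  drop_tail <- 20L
  if (n < drop_head + drop_tail + 1L)
    stopf(paste("breath-hold truncation needs at least %d volumes",
                "(remove %d leading equilibration+transition and %d trailing volumes);",
                "got %d"), drop_head + drop_tail + 1L, drop_head, drop_tail, n)
  (drop_head + 1L):(n - drop_tail)
}

#' @rdname truncate_breathhold
#' @export
truncate_breathhold.bold_run <- function(x, ...) {
  assert_that(abs(x$tr - 2) < 1e-9,
              "breath-hold truncation rule is defined for TR = 2 s (got %g s)", x$tr)
  keep <- bh_keep_index(n_volumes(x))
  bold_run(x$data[, , , keep, drop = FALSE], x$tr, excluded = x$excluded)
}

#' @rdname truncate_breathhold
#' @export
truncate_breathhold.numeric <- function(x, ...) x[bh_keep_index(length(x))]

#' Truncate a resting-state run
#'
#' Removes the 4 s equilibration period (2 volumes) and keeps the first
#' `keep` of the remaining volumes (default 210, i.e. 420 s), roughly
#' matching the breath-hold analysis window length.
#'
#' @param run A [bold_run()].
#' @param keep Number of volumes to retain after equilibration removal.
#' @return A [bold_run()] with `keep` volumes.
#' @export
truncate_resting <- function(run, keep = 210L) {
  stopifnot(inherits(run, "bold_run"))
  n <- n_volumes(run)
  if (n < keep + 2L)
    stopf("resting truncation needs at least %d volumes (2 equilibration + %d kept); got %d",
          keep + 2L, keep, n)
  bold_run(run$data[, , , 2L + seq_len(keep), drop = FALSE], run$tr,
           excluded = run$excluded)
}

#' Scale each voxel's time series to a mean of 100
#'
#' Per voxel: `x -> 100 * x / mean(x)`, then clipped to `[0, 200]`. Voxels
#' with a non-positive or non-finite mean cannot be scaled; they are set to
#' `NA` and flagged in the run's `excluded` mask so downstream VOIs can drop
#' them.
#'
#' @param run A [bold_run()].
#' @return A [bold_run()] in mean-100 units.
#' @export
scale_to_mean_100 <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  m <- run_matrix(run)
  mu <- rowMeans(m)
  bad <- !is.finite(mu) | mu <= 0
  scl <- 100 / mu
  scl[bad] <- NA_real_
  m <- pmin(pmax(m * scl, 0), 200)
  d <- dim(run$data)
  excluded <- array(bad, d[1:3])
  if (!is.null(run$excluded)) excluded <- excluded | run$excluded
  bold_run(array(m, d), run$tr, excluded = excluded)
}

#' ALFF band parameters
#'
#' @param f_low,f_high Band edges in Hz (inclusive; defaults 0.01 and 0.08).
#' @param detrend Remove a linear trend before the Fourier transform
#'   (default `TRUE`; protects the lowest band bin from scanner drift).
#' @return An object of class `alff_params`.
#' @export
alff_params <- function(f_low = 0.01, f_high = 0.08, detrend = TRUE) {
  assert_that(f_low > 0 && f_high > f_low, "need 0 < f_low < f_high")
  structure(list(f_low = f_low, f_high = f_high, detrend = isTRUE(detrend)),
            class = "alff_params")
}

# Linear detrend of the columns of a T x n matrix (mean always removed).
detrend_cols <- function(m, linear = TRUE) {
  tlen <- nrow(m)
  if (!linear) return(sweep(m, 2, colMeans(m)))
  x <- cbind(1, seq_len(tlen))
  m - x %*% qr.solve(x, m)
}

# Single-sided amplitude spectrum sums over the band; m is T x n.
alff_cols <- function(m, tr, params) {
  tlen <- nrow(m)
  assert_that(params$f_high < 1 / (2 * tr) + 1e-12,
              "f_high must lie below the Nyquist frequency 1/(2 TR) = %g Hz", 1 / (2 * tr))
  k <- seq_len(floor(tlen / 2))
  f <- k / (tlen * tr)
  band <- f >= params$f_low - 1e-12 & f <= params$f_high + 1e-12
  if (!any(band))
    stopf("no Fourier bins fall inside [%g, %g] Hz at N = %d, TR = %g s",
          params$f_low, params$f_high, tlen, tr)
  ft <- stats::mvfft(detrend_cols(m, params$detrend))
  amp <- 2 * Mod(ft[k + 1L, , drop = FALSE]) / tlen
  colSums(amp[band, , drop = FALSE])
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Removes the mean (and, by default, a linear trend), Fourier-transforms the
#' series, and sums the single-sided amplitude spectrum `2 |X_k| / N` over
#' bins with `f_low <= f_k <= f_high`. A pure in-band sinusoid of amplitude
#' `A` landing on a Fourier bin returns `A`.
#'
#' @param series Numeric time series.
#' @param tr Sampling interval (TR) in seconds.
#' @param params An [alff_params()] object.
#' @return Non-negative scalar ALFF.
#' @export
alff <- function(series, tr, params = alff_params()) {
  stopifnot(inherits(params, "alff_params"))
  assert_that(tr > 0, "tr must be positive")
  assert_that(all(is.finite(series)), "series must be finite")
  drop(alff_cols(matrix(series, ncol = 1), tr, params))
}

#' Resting-state CVR-estimate (ALFF) map
#'
#' Computes per-voxel ALFF over the VOI for one or two (truncated, scaled)
#' resting runs; with two runs the per-voxel mean of the two ALFF maps is
#' returned.
#'
#' @param runs A [bold_run()] or a list of one or two runs on the same grid.
#' @param voi 3D logical volume of interest.
#' @param params An [alff_params()] object.
#' @return A [cvr_map()] with `metric_kind = "resting_alff"`.
#' @export
resting_cvre_map <- function(runs, voi, params = alff_params()) {
  if (inherits(runs, "bold_run")) runs <- list(runs)
  assert_that(length(runs) %in% 1:2 && all(vapply(runs, inherits, TRUE, "bold_run")),
              "runs must be one or two bold_run objects")
  dims <- lapply(runs, function(r) dim(r$data)[1:3])
  assert_that(all(vapply(dims, identical, TRUE, dims[[1]])), "run grids do not match")
  voi <- as_mask(voi, "voi")
  assert_that(identical(dim(voi), dims[[1]]), "VOI grid mismatch")
  idx <- which(voi)
  maps <- lapply(runs, function(r)
    alff_cols(t(run_matrix(r)[idx, , drop = FALSE]), r$tr, params))
  vals <- array(NA_real_, dims[[1]])
  vals[idx] <- Reduce(`+`, maps) / length(maps)
  cvr_map(vals, voi, "resting_alff")
}

#' Average two breath-hold CVR maps
#'
#' Voxel-wise mean of the per-run beta maps. Where the two runs disagree on
#' the best-fit delay, the smaller delay is kept (consistent with the
#' smallest-delay tie rule of the per-run fit).
#'
#' @param map1,map2 [cvr_map()] objects on the same grid and VOI.
#' @return A [cvr_map()].
#' @export
average_breathhold_runs <- function(map1, map2) {
  stopifnot(inherits(map1, "cvr_map"), inherits(map2, "cvr_map"))
  assert_that(identical(dim(map1$values), dim(map2$values)), "map grids do not match")
  assert_that(identical(map1$voi, map2$voi), "map VOIs do not match")
  assert_that(identical(map1$metric_kind, map2$metric_kind), "metric kinds differ")
  vals <- (map1$values + map2$values) / 2
  lag <- if (!is.null(map1$best_lag) && !is.null(map2$best_lag))
    pmin(map1$best_lag, map2$best_lag) else map1$best_lag %||% map2$best_lag
  cvr_map(vals, map1$voi, map1$metric_kind, best_lag = lag)
}
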