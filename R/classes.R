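#' BOLD run container
#'
#' A 4D BOLD time series (`x`, `y`, `z`, `t`) with its repetition time.
#'
#' @param data 4D numeric array, time along the fourth dimension.
#' @param tr Repetition time in seconds.
#' @param excluded Optional 3D logical array flagging voxels excluded from
#'   analysis (e.g. non-positive means found during intensity scaling).
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, excluded = NULL) {
  assert_that(is.numeric(data) && length(dim(data)) == 4L,
              "a BOLD run must be a 4D numeric array")
  assert_that(is.numeric(tr) && length(tr) == 1L && tr > 0, "tr must be a positive scalar")
  if (!is.null(excluded)) {
    excluded <- as_mask(excluded, "excluded")
    assert_that(identical(dim(excluded), dim(data)[1:3]), "excluded mask must match the grid")
  }
  structure(list(data = data, tr = tr, excluded = excluded), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %d x %d x %d grid, %d volumes, TR = %g s (%.0f s)\n",
              d[1], d[2], d[3], d[4], x$tr, d[4] * x$tr))
  invisible(x)
}

n_volumes <- function(run) dim(run$data)[4]

# V x T matrix view of a run (rows = voxels in array order).
run_matrix <- function(run) matrix(run$data, ncol = dim(run$data)[4])

#' Tissue label volume
#'
#' Per-voxel tissue labels: 0 = excluded, 1 = gray matter, 2 = white matter.
#' The gray+white volume of interest (GWM-VOI) is `labels %in% 1:2`; the
#' gray-only VOI (GM-VOI) is `labels == 1`.
#'
#' @param labels 3D integer array with values in `{0, 1, 2}`.
#' @param voxel_dims Voxel dimensions in mm.
#' @return An object of class `tissue_volume`.
#' @export
tissue_volume <- function(labels, voxel_dims = c(1.875, 1.875, 5)) {
  assert_that(is.numeric(labels) && length(dim(labels)) == 3L,
              "labels must be a 3D array")
  assert_that(all(labels %in% 0:2), "tissue labels must be 0 (excluded), 1 (gray) or 2 (white)")
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 voxel_dims = voxel_dims),
            class = "tissue_volume")
}

#' @export
print.tissue_volume <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf("<tissue_volume> %s grid; %d gray, %d white, %d excluded voxels\n",
              paste(dim(x$labels), collapse = " x "), tab[2], tab[3], tab[1]))
  invisible(x)
}

#' Gray+white and gray-only volumes of interest
#'
#' @param tissue A [tissue_volume()].
#' @return 3D logical array.
#' @export
gwm_voi <- function(tissue) array(tissue$labels %in% 1:2, dim(tissue$labels))

#' @rdname gwm_voi
#' @export
gm_voi <- function(tissue) array(tissue$labels == 1L, dim(tissue$labels))

#' CVR map container
#'
#' A per-voxel scalar CVR metric over a volume of interest: the lagged
#' regression beta for breath-hold runs, or the resting-state ALFF.
#'
#' @param values 3D numeric array; finite exactly on `voi`, `NA` elsewhere.
#' @param voi 3D logical volume of interest.
#' @param metric_kind `"breathhold_beta"` or `"resting_alff"`.
#' @param best_lag Optional 3D integer array of best-fit lags (TR units,
#'   breath-hold only).
#' @return An object of class `cvr_map`.
#' @export
cvr_map <- function(values, voi, metric_kind = c("breathhold_beta", "resting_alff"),
                    best_lag = NULL) {
  metric_kind <- match.arg(metric_kind)
  voi <- as_mask(voi, "voi")
  assert_that(is.numeric(values) && identical(dim(values), dim(voi)),
              "values must be a 3D array matching the VOI grid")
  assert_that(all(is.finite(values[voi])), "map values must be finite on the VOI")
  values[!voi] <- NA_real_
  if (!is.null(best_lag)) {
    assert_that(identical(dim(best_lag), dim(voi)), "best_lag grid mismatch")
    assert_that(all(best_lag[voi] %in% 0:4), "best_lag must lie in 0..4 TR")
  }
  structure(list(values = values, voi = voi, metric_kind = metric_kind,
                 best_lag = best_lag),
            class = "cvr_map")
}

#' @export
print.cvr_map <- function(x, ...) {
  v <- x$values[x$voi]
  cat(sprintf("<cvr_map> %s, %d VOI voxels; range [%.4g, %.4g], median %.4g\n",
              x$metric_kind, length(v), min(v), max(v), stats::median(v)))
  invisible(x)
}

#' @export
summary.cvr_map <- function(object, ...) {
  v <- object$values[object$voi]
  out <- list(metric_kind = object$metric_kind, n_voxels = length(v),
              quantiles = stats::quantile(v, c(0, .25, .5, .75, 1)),
              mean = mean(v), sd = stats::sd(v))
  class(out) <- "summary.cvr_map"
  out
}

#' @export
print.summary.cvr_map <- function(x, ...) {
  cat(sprintf("CVR map (%s), %d voxels\n  mean %.4g, sd %.4g\n",
              x$metric_kind, x$n_voxels, x$mean, x$sd))
  print(x$quantiles)
  invisible(x)
}

map_values <- function(map, voi = NULL) {
  voi <- voi %||% map$voi
  v <- map$values[voi]
  assert_that(all(is.finite(v)), "metric is not defined on all requested VOI voxels")
  v
}
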