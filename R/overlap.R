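#' Contingency table of a voxel classification
#'
#' Counts (or percentages) of true positive, true negative, false positive
#' and false negative voxels for one threshold setting (or threshold pair).
#'
#' @param tp,tn,fp,fn Non-negative cell values.
#' @return An object of class `contingency_table` with the four cells and
#'   their `total`.
#' @export
contingency_table <- function(tp, tn, fp, fn) {
  cells <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  assert_that(all(is.finite(cells)) && all(cells >= 0),
              "contingency cells must be finite and non-negative")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn, total = sum(cells)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> TP %g, TN %g, FP %g, FN %g (total %g)\n",
              x$tp, x$tn, x$fp, x$fn, x$total))
  if (x$total > 0) {
    p <- as_percent(x)
    cat(sprintf("  %%: TP %.1f, TN %.1f, FP %.1f, FN %.1f; Acc %.1f, Dice %s\n",
                p["tp"], p["tn"], p["fp"], p["fn"], 100 * accuracy(x),
                if (2 * x$tp + x$fp + x$fn > 0) sprintf("%.1f", 100 * dice(x)) else "NA"))
  }
  invisible(x)
}

#' @rdname contingency_table
#' @param x A `contingency_table`.
#' @export
as_percent <- function(x) {
  stopifnot(inherits(x, "contingency_table"))
  assert_that(x$total > 0, "empty contingency table")
  100 * c(tp = x$tp, tn = x$tn, fp = x$fp, fn = x$fn) / x$total
}

#' Classification accuracy
#'
#' `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param t A [contingency_table()].
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
accuracy <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$total <= 0) stopf("accuracy undefined: empty contingency table")
  (t$tp + t$tn) / t$total
}

#' Dice overlap coefficient
#'
#' `2 TP / (2 TP + FP + FN)`.
#'
#' @param t A [contingency_table()].
#' @return Dice coefficient as a fraction in `[0, 1]`.
#' @export
dice <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  den <- 2 * t$tp + t$fp + t$fn
  if (den <= 0) stopf("Dice undefined: no positive voxels in either labeling")
  2 * t$tp / den
}

metric_values_3d <- function(metric) {
  if (inherits(metric, "cvr_map")) metric$values
  else {
    assert_that(is.numeric(metric) && length(dim(metric)) == 3L,
                "metric must be a cvr_map or 3D numeric array")
    metric
  }
}

#' Classify a CVR map against a reference mask
#'
#' A voxel is responsive iff `metric >= threshold`. Within the VOI:
#' TP = responsive and reference, TN = neither, FP = responsive only,
#' FN = reference only.
#'
#' @param metric A [cvr_map()] or 3D numeric array.
#' @param threshold Responsiveness threshold (boundary counts as responsive).
#' @param reference 3D logical reference mask (e.g. gray matter).
#' @param voi 3D logical volume over which to count.
#' @return A [contingency_table()].
#' @export
classify_vs_mask <- function(metric, threshold, reference, voi) {
  voi <- as_mask(voi, "voi")
  assert_that(any(voi), "VOI is empty")
  reference <- as_mask(reference, "reference")
  vals <- metric_values_3d(metric)[voi]
  assert_that(all(is.finite(vals)), "metric must be defined (finite) on the whole VOI")
  resp <- vals >= threshold
  ref <- reference[voi]
  contingency_table(tp = sum(resp & ref), tn = sum(!resp & !ref),
                    fp = sum(resp & !ref), fn = sum(!resp & ref))
}

#' Threshold grid over a metric's VOI values
#'
#' @param values Numeric metric values.
#' @param n Number of grid points.
#' @param type `"percentile"` (0th--100th percentiles, deduplicated; adapts
#'   to the per-subject metric scale) or `"raw"` (uniform between min and
#'   max).
#' @return Strictly increasing numeric grid.
#' @export
threshold_grid <- function(values, n = 101L, type = c("percentile", "raw")) {
  type <- match.arg(type)
  assert_that(n >= 2, "grid needs at least 2 points")
  values <- values[is.finite(values)]
  assert_that(length(values) > 0, "no finite values for the grid")
  g <- switch(type,
              percentile = unique(stats::quantile(values, seq(0, 1, length.out = n),
                                                  names = FALSE)),
              raw = seq(min(values), max(values), length.out = n))
  unique(g)
}

#' One-dimensional threshold sweep against gray matter
#'
#' Classifies the map against gray matter (reference = gray labels, VOI =
#' gray+white) at every grid threshold, recording accuracy and Dice; the
#' threshold maximizing accuracy is returned (ties broken toward the
#' smallest, most inclusive threshold).
#'
#' @param metric A [cvr_map()] defined on the GWM-VOI.
#' @param tissue A [tissue_volume()].
#' @param grid Optional explicit threshold grid; by default a percentile
#'   grid over the VOI metric values.
#' @param n_grid Grid size when `grid` is `NULL`.
#' @param grid_type Passed to [threshold_grid()].
#' @return An object of class `cvr_sweep` with `thresholds`, `accuracy`,
#'   `dice`, per-threshold `tables`, `argmax_threshold`, `max_accuracy` and
#'   `best_table`.
#' @export
sweep_vs_gray <- function(metric, tissue, grid = NULL, n_grid = 101L,
                          grid_type = "percentile") {
  stopifnot(inherits(tissue, "tissue_volume"))
  voi <- gwm_voi(tissue)
  if (inherits(metric, "cvr_map")) voi <- voi & metric$voi
  reference <- gm_voi(tissue)
  assert_that(sum(reference & voi) > 0 && sum(voi & !reference) > 0,
              "sweep needs both gray and white voxels in the VOI")
  vals <- metric_values_3d(metric)[voi]
  if (is.null(grid)) grid <- threshold_grid(vals, n_grid, grid_type)
  tabs <- lapply(grid, function(th) classify_vs_mask(metric, th, reference, voi))
  acc <- vapply(tabs, accuracy, numeric(1))
  dce <- vapply(tabs, function(t)
    if (2 * t$tp + t$fp + t$fn > 0) dice(t) else NA_real_, numeric(1))
  best <- which.max(acc)   # first max = smallest threshold on ties
  structure(list(thresholds = grid, accuracy = acc, dice = dce, tables = tabs,
                 argmax_threshold = grid[best], max_accuracy = acc[best],
                 best_table = tabs[[best]],
                 metric_kind = if (inherits(metric, "cvr_map")) metric$metric_kind else NA),
            class = "cvr_sweep")
}

#' @export
print.cvr_sweep <- function(x, ...) {
  cat(sprintf("<cvr_sweep> %d thresholds (%s); max accuracy %.3f at threshold %.4g\n",
              length(x$thresholds), x$metric_kind, x$max_accuracy, x$argmax_threshold))
  print(x$best_table)
  invisible(x)
}

#' @export
plot.cvr_sweep <- function(x, ...) {
  graphics::plot(x$thresholds, x$accuracy, type = "l", ylim = c(0, 1),
                 xlab = "threshold", ylab = "fraction",
                 main = sprintf("Threshold sweep (%s)", x$metric_kind), ...)
  graphics::lines(x$thresholds, x$dice, lty = 2)
  graphics::abline(v = x$argmax_threshold, col = "gray")
  graphics::legend("bottomleft", c("accuracy", "Dice"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Cross-metric accuracy surface
#'
#' For every pair of (breath-hold, resting-state) thresholds, classifies
#' resting-responsive voxels as predictors of breath-hold-responsive voxels
#' within the gray-matter VOI, filling accuracy and Dice matrices. Corner
#' summaries A1--A4 are computed at forced thresholds (`+Inf`/`-Inf`) where
#' all voxels become TN, FP, FN or TP and accuracy is exactly 1, 0, 0, 1.
#' If `saddle_thresholds` (the independently 1D-optimized pair) is given,
#' the surface value at that pair is reported as the saddle point.
#'
#' @param bh Breath-hold [cvr_map()].
#' @param rs Resting-state [cvr_map()].
#' @param gm_voi 3D logical gray-matter VOI.
#' @param bh_grid,rs_grid Optional threshold grids (percentile grids over the
#'   VOI by default).
#' @param n_grid Grid size when grids are `NULL`.
#' @param saddle_thresholds Optional `c(bh =, rs =)` threshold pair.
#' @return An object of class `accuracy_surface`: `bh_thresholds`,
#'   `rs_thresholds`, matrices `accuracy` and `dice` (rows = breath-hold
#'   thresholds), `corners` (A1--A4) and `saddle`.
#' @export
cross_metric_surface <- function(bh, rs, gm_voi, bh_grid = NULL, rs_grid = NULL,
                                 n_grid = 101L, saddle_thresholds = NULL) {
  voi <- as_mask(gm_voi, "gm_voi")
  vb <- map_values(bh, voi)
  vr <- map_values(rs, voi)
  nv <- length(vb)
  if (is.null(bh_grid)) bh_grid <- threshold_grid(vb, n_grid)
  if (is.null(rs_grid)) rs_grid <- threshold_grid(vr, n_grid)
  assert_that(length(bh_grid) >= 2 && length(rs_grid) >= 2, "degenerate threshold grid")
  BH <- outer(vb, bh_grid, ">=") * 1
  RS <- outer(vr, rs_grid, ">=") * 1
  tp <- crossprod(BH, RS)                  # nb x nr
  npos_bh <- colSums(BH)
  npos_rs <- colSums(RS)
  fn <- npos_bh - tp                       # breath-hold positive, resting negative
  fp <- matrix(npos_rs, nrow(tp), ncol(tp), byrow = TRUE) - tp
  tn <- nv - tp - fn - fp
  acc <- (tp + tn) / nv
  den <- 2 * tp + fp + fn
  dce <- ifelse(den > 0, 2 * tp / den, NA_real_)
  corner <- function(th_bh, th_rs) {
    resp_b <- vb >= th_bh
    resp_r <- vr >= th_rs
    t <- contingency_table(tp = sum(resp_r & resp_b), tn = sum(!resp_r & !resp_b),
                           fp = sum(resp_r & !resp_b), fn = sum(!resp_r & resp_b))
    list(table = t, accuracy = accuracy(t))
  }
  corners <- list(A1 = corner(Inf, Inf),     # all TN
                  A2 = corner(Inf, -Inf),    # all FP
                  A3 = corner(-Inf, Inf),    # all FN
                  A4 = corner(-Inf, -Inf))   # all TP
  saddle <- NULL
  if (!is.null(saddle_thresholds)) {
    st <- corner(saddle_thresholds[["bh"]], saddle_thresholds[["rs"]])
    saddle <- list(bh_threshold = saddle_thresholds[["bh"]],
                   rs_threshold = saddle_thresholds[["rs"]],
                   table = st$table, accuracy = st$accuracy,
                   dice = if (2 * st$table$tp + st$table$fp + st$table$fn > 0)
                     dice(st$table) else NA_real_)
  }
  structure(list(bh_thresholds = bh_grid, rs_thresholds = rs_grid,
                 accuracy = acc, dice = dce, corners = corners,
                 saddle = saddle, n_voxels = nv),
            class = "accuracy_surface")
}

#' @export
print.accuracy_surface <- function(x, ...) {
  cat(sprintf("<accuracy_surface> %d x %d threshold pairs over %d voxels\n",
              length(x$bh_thresholds), length(x$rs_thresholds), x$n_voxels))
  ca <- vapply(x$corners, `[[`, numeric(1), "accuracy")
  cat(sprintf("  corners (A1 all-TN, A2 all-FP, A3 all-FN, A4 all-TP): %s\n",
              paste(sprintf("%s=%.1f", names(ca), ca), collapse = ", ")))
  if (!is.null(x$saddle))
    cat(sprintf("  saddle at (bh %.4g, rs %.4g): accuracy %.3f, Dice %.3f\n",
                x$saddle$bh_threshold, x$saddle$rs_threshold,
                x$saddle$accuracy, x$saddle$dice))
  invisible(x)
}

#' @export
plot.accuracy_surface <- function(x, ...) {
  graphics::image(x$bh_thresholds, x$rs_thresholds, x$accuracy,
                  xlab = "breath-hold threshold", ylab = "resting-state threshold",
                  main = "Cross-metric accuracy surface",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(x$bh_thresholds, x$rs_thresholds, x$accuracy, add = TRUE)
  if (!is.null(x$saddle))
    graphics::points(x$saddle$bh_threshold, x$saddle$rs_threshold, pch = 8, col = "white")
  invisible(x)
}

#' Split-run self-concordance of a CVR metric
#'
#' Thresholds each run's map at its own 1D-optimal (vs. gray matter)
#' threshold, then cross-classifies run 1 (reference) against run 2
#' (predictor) within the VOI. This estimates the maximum attainable
#' concordance given the metric's own run-to-run noise.
#'
#' @param map_run1,map_run2 [cvr_map()] objects of the same metric kind.
#' @param tissue A [tissue_volume()] (used to find each run's optimal
#'   threshold).
#' @param voi VOI for the cross-classification (defaults to the GM-VOI).
#' @param n_grid Sweep grid size.
#' @return An object of class `self_concordance` with the two thresholds,
#'   the contingency table, accuracy and Dice.
#' @export
self_concordance <- function(map_run1, map_run2, tissue, voi = NULL, n_grid = 101L) {
  stopifnot(inherits(map_run1, "cvr_map"), inherits(map_run2, "cvr_map"))
  assert_that(identical(map_run1$metric_kind, map_run2$metric_kind),
              "maps must share a metric kind")
  voi <- as_mask(voi %||% gm_voi(tissue), "voi")
  th1 <- sweep_vs_gray(map_run1, tissue, n_grid = n_grid)$argmax_threshold
  th2 <- sweep_vs_gray(map_run2, tissue, n_grid = n_grid)$argmax_threshold
  r1 <- map_values(map_run1, voi) >= th1
  r2 <- map_values(map_run2, voi) >= th2
  tab <- contingency_table(tp = sum(r2 & r1), tn = sum(!r2 & !r1),
                           fp = sum(r2 & !r1), fn = sum(!r2 & r1))
  structure(list(thresholds = c(run1 = th1, run2 = th2), table = tab,
                 accuracy = accuracy(tab),
                 dice = if (2 * tab$tp + tab$fp + tab$fn > 0) dice(tab) else NA_real_,
                 metric_kind = map_run1$metric_kind),
            class = "self_concordance")
}

#' @export
print.self_concordance <- function(x, ...) {
  cat(sprintf("<self_concordance> %s: accuracy %.3f, Dice %.3f (thresholds %.4g / %.4g)\n",
              x$metric_kind, x$accuracy, x$dice, x$thresholds[1], x$thresholds[2]))
  invisible(x)
}

robust_norm <- function(v, probs = c(0.01, 0.99)) {
  q <- stats::quantile(v, probs, names = FALSE)
  if (q[2] <= q[1]) stopf("map is (near-)constant; normalization undefined")
  pmin(pmax((v - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Unthresholded comparison of the two CVR metrics
#'
#' Robustly min--max normalizes each map over the VOI (1st--99th percentile
#' mapped to `[0, 1]`, clipped outside), computes the voxel-wise Pearson
#' correlation, the per-voxel difference (normalized resting minus
#' normalized breath-hold), and scatter data clipped to the central 95% of
#' voxels of each metric.
#'
#' @param bh,rs [cvr_map()] objects defined on `gm_voi`.
#' @param gm_voi 3D logical VOI.
#' @param norm_probs Normalization percentiles.
#' @return An object of class `map_comparison`: `pearson_r`, `difference`
#'   (3D array, `NA` outside the VOI) and `scatter` (data frame).
#' @export
unthresholded_compare <- function(bh, rs, gm_voi, norm_probs = c(0.01, 0.99)) {
  voi <- as_mask(gm_voi, "gm_voi")
  vb <- map_values(bh, voi)
  vr <- map_values(rs, voi)
  if (stats::sd(vb) == 0 || stats::sd(vr) == 0)
    stopf("correlation undefined for a constant map")
  nb <- robust_norm(vb, norm_probs)
  nr <- robust_norm(vr, norm_probs)
  r <- stats::cor(nb, nr)
  diffmap <- array(NA_real_, dim(voi))
  diffmap[voi] <- nr - nb
  inb <- vb >= stats::quantile(vb, 0.025) & vb <= stats::quantile(vb, 0.975)
  inr <- vr >= stats::quantile(vr, 0.025) & vr <= stats::quantile(vr, 0.975)
  structure(list(pearson_r = r, difference = diffmap,
                 scatter = data.frame(bh = nb, rs = nr)[inb & inr, ]),
            class = "map_comparison")
}

#' @export
print.map_comparison <- function(x, ...) {
  d <- x$difference[is.finite(x$difference)]
  cat(sprintf("<map_comparison> Pearson r = %.3f; difference mean %.3f (sd %.3f); %d scatter voxels\n",
              x$pearson_r, mean(d), stats::sd(d), nrow(x$scatter)))
  invisible(x)
}

#' @export
plot.map_comparison <- function(x, ...) {
  graphics::plot(x$scatter$bh, x$scatter$rs, pch = ".",
                 xlab = "breath-hold CVR (normalized)",
                 ylab = "resting-state CVRe (normalized)",
                 main = sprintf("Unthresholded comparison (r = %.2f)", x$pearson_r), ...)
  invisible(x)
}
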