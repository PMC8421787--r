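#' Pipeline configuration
#'
#' One knob per analysis choice, with the defaults used throughout the
#' package.
#'
#' @param pct_top Fraction of top-correlated voxels averaged into the
#'   personal respiratory waveform.
#' @param max_lag_tr Maximum regression delay in TR units.
#' @param smoother [osfilt_weights()] for the waveform smoother.
#' @param alff [alff_params()] for the resting metric.
#' @param n_grid Threshold-grid size for sweeps and surfaces.
#' @param grid_type `"percentile"` or `"raw"` threshold grids.
#' @param bh_average `"maps"` (fit each run, average the beta maps) or
#'   `"timeseries"` (average the two runs, then fit once).
#' @param rs_runs `"both"` (mean of the two per-run ALFF maps) or `"first"`.
#' @param keep_resting Resting volumes kept after equilibration removal.
#' @param norm_probs Robust normalization percentiles for the unthresholded
#'   comparison.
#' @return An object of class `cvr_config`.
#' @export
cvr_config <- function(pct_top = 0.01, max_lag_tr = 4L,
                       smoother = osfilt_weights(), alff = alff_params(),
                       n_grid = 101L, grid_type = "percentile",
                       bh_average = c("maps", "timeseries"),
                       rs_runs = c("both", "first"),
                       keep_resting = 210L, norm_probs = c(0.01, 0.99)) {
  structure(list(pct_top = pct_top, max_lag_tr = as.integer(max_lag_tr),
                 smoother = smoother, alff = alff, n_grid = as.integer(n_grid),
                 grid_type = grid_type, bh_average = match.arg(bh_average),
                 rs_runs = match.arg(rs_runs), keep_resting = as.integer(keep_resting),
                 norm_probs = norm_probs),
            class = "cvr_config")
}

#' MD5 hash of a configuration
#'
#' @param config A [cvr_config()].
#' @return Hex digest string, recorded in every output bundle.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  declass <- function(x) if (is.list(x)) lapply(unclass(x), declass) else x
  jsonlite::write_json(declass(config), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

pipeline_inputs <- function(subject) {
  if (inherits(subject, "cvr_phantom")) {
    list(id = sprintf("phantom_seed%d", subject$spec$seed),
         bh = subject$bh_runs, rs = subject$rs_runs,
         tissue = subject$tissue, tr = subject$spec$tr, seed = subject$spec$seed)
  } else if (inherits(subject, "run_manifest")) {
    list(id = subject$subject,
         bh = lapply(subject$bh_paths, read_bold, tr = subject$tr),
         rs = lapply(subject$rs_paths, read_bold, tr = subject$tr),
         tissue = read_tissue(subject$tissue_path),
         tr = subject$tr, seed = subject$seed)
  } else stopf("subject must be a cvr_phantom or run_manifest")
}

report_row <- function(comparison, table, acc, dce) {
  p <- as_percent(table)
  data.frame(comparison = comparison, tp = p[["tp"]], tn = p[["tn"]],
             fp = p[["fp"]], fn = p[["fn"]], acc = 100 * acc, dice = 100 * dce)
}

#' Run the full concordance pipeline for one subject
#'
#' Executes, in order: breath-hold and resting truncation; mean-100 scaling;
#' personal-waveform estimation and lagged-regression beta mapping per
#' breath-hold run; run averaging; per-voxel ALFF for the resting runs;
#' 1D threshold optimization of each metric against gray matter; the 2D
#' cross-metric accuracy surface (saddle evaluated at the 1D-optimal pair);
#' split-run self-concordance for both metrics; and the unthresholded
#' correlation/difference comparison.
#'
#' @param subject A `cvr_phantom` (from [simulate_subject()]) or a
#'   [run_manifest()].
#' @param config A [cvr_config()].
#' @param out_dir Optional directory; when given, [write_report()] is called.
#' @param verbose Log each stage via `message()`.
#' @return An object of class `cvr_report`.
#' @export
run_pipeline <- function(subject, config = cvr_config(), out_dir = NULL,
                         verbose = FALSE) {
  inp <- pipeline_inputs(subject)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    say("stage %-22s %6.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  timing <- build_breathhold_timing(inp$tr)
  bh <- stage("truncate+scale bh", lapply(inp$bh, function(r)
    scale_to_mean_100(truncate_breathhold(r))))
  rs <- stage("truncate+scale rs", lapply(inp$rs, function(r)
    scale_to_mean_100(truncate_resting(r, config$keep_resting))))

  excluded <- Reduce(`|`, lapply(c(bh, rs), function(r) r$excluded))
  gwm <- gwm_voi(inp$tissue) & !excluded
  gm <- gm_voi(inp$tissue) & !excluded

  regressor <- truncate_breathhold(initial_regressor(timing, rrf_params(), inp$tr))

  waveforms <- stage("personal waveforms", lapply(bh, function(r)
    estimate_personal_waveform(r, regressor, gwm, pct = config$pct_top,
                               max_lag_tr = config$max_lag_tr,
                               weights = config$smoother)))
  bh_map <- stage("breath-hold betas", {
    if (config$bh_average == "maps") {
      maps <- Map(function(r, w) breathhold_cvr_map(r, w, gwm, config$max_lag_tr),
                  bh, waveforms)
      list(per_run = maps, combined = average_breathhold_runs(maps[[1]], maps[[2]]))
    } else {
      avg <- bold_run((bh[[1]]$data + bh[[2]]$data) / 2, inp$tr)
      wf <- estimate_personal_waveform(avg, regressor, gwm, pct = config$pct_top,
                                       max_lag_tr = config$max_lag_tr,
                                       weights = config$smoother)
      one <- breathhold_cvr_map(avg, wf, gwm, config$max_lag_tr)
      maps <- Map(function(r, w) breathhold_cvr_map(r, w, gwm, config$max_lag_tr),
                  bh, waveforms)
      list(per_run = maps, combined = one)
    }
  })
  rs_map <- stage("resting ALFF", {
    per_run <- lapply(rs, resting_cvre_map, voi = gwm, params = config$alff)
    combined <- if (config$rs_runs == "both")
      resting_cvre_map(rs, gwm, config$alff) else per_run[[1]]
    list(per_run = per_run, combined = combined)
  })

  sweep_bh <- stage("sweep bh vs gray",
                    sweep_vs_gray(bh_map$combined, inp$tissue,
                                  n_grid = config$n_grid, grid_type = config$grid_type))
  sweep_rs <- stage("sweep rs vs gray",
                    sweep_vs_gray(rs_map$combined, inp$tissue,
                                  n_grid = config$n_grid, grid_type = config$grid_type))
  surface <- stage("cross-metric surface",
                   cross_metric_surface(bh_map$combined, rs_map$combined, gm,
                                        n_grid = config$n_grid,
                                        saddle_thresholds = c(
                                          bh = sweep_bh$argmax_threshold,
                                          rs = sweep_rs$argmax_threshold)))
  concordance <- stage("self-concordance", list(
    bh = self_concordance(bh_map$per_run[[1]], bh_map$per_run[[2]], inp$tissue,
                          voi = gm, n_grid = config$n_grid),
    rs = self_concordance(rs_map$per_run[[1]], rs_map$per_run[[2]], inp$tissue,
                          voi = gm, n_grid = config$n_grid)))
  unthresh <- stage("unthresholded compare",
                    unthresholded_compare(bh_map$combined, rs_map$combined, gm,
                                          config$norm_probs))

  rows <- rbind(
    report_row("rs_vs_gm", sweep_rs$best_table, accuracy(sweep_rs$best_table),
               dice(sweep_rs$best_table)),
    report_row("bh_vs_gm", sweep_bh$best_table, accuracy(sweep_bh$best_table),
               dice(sweep_bh$best_table)),
    report_row("rs_vs_bh", surface$saddle$table, surface$saddle$accuracy,
               surface$saddle$dice))
  rownames(rows) <- NULL

  report <- structure(list(
    subject = inp$id, seed = inp$seed, rows = rows,
    sweeps = list(bh = sweep_bh, rs = sweep_rs), surface = surface,
    concordance = concordance, unthresholded = unthresh,
    waveforms = waveforms, bh_map = bh_map$combined, rs_map = rs_map$combined,
    config = config, config_hash = config_hash(config)),
    class = "cvr_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.cvr_report <- function(x, ...) {
  cat(sprintf("<cvr_report> subject %s (seed %s), config %s\n",
              x$subject, x$seed, substr(x$config_hash, 1, 8)))
  print(format_report_table(x$rows), row.names = FALSE)
  cat(sprintf("  self-concordance: bh %.3f, rs %.3f; unthresholded r = %.3f\n",
              x$concordance$bh$accuracy, x$concordance$rs$accuracy,
              x$unthresholded$pearson_r))
  invisible(x)
}

# Percentages at table precision: integers for TP/TN/FP/FN/Acc, one decimal
# for Dice.
format_report_table <- function(rows) {
  out <- rows
  for (col in c("tp", "tn", "fp", "fn", "acc")) out[[col]] <- sprintf("%.0f", rows[[col]])
  out$dice <- sprintf("%.1f", rows$dice)
  names(out) <- c("comparison", "TP%", "TN%", "FP%", "FN%", "Acc%", "Dice%")
  out
}

#' Write a report bundle
#'
#' Writes the per-comparison contingency rows as CSV (table precision), the
#' sweep grids as CSV, and a full-precision JSON summary including the
#' config hash. Identical inputs and seed produce byte-identical bundles.
#'
#' @param report A `cvr_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cvr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_report_table(report$rows),
                   file.path(dir, "contingency_tables.csv"), row.names = FALSE)
  sw <- do.call(rbind, lapply(names(report$sweeps), function(nm) {
    s <- report$sweeps[[nm]]
    data.frame(metric = nm, threshold = s$thresholds,
               accuracy = s$accuracy, dice = s$dice)
  }))
  utils::write.csv(sw, file.path(dir, "threshold_sweeps.csv"), row.names = FALSE)
  summary <- list(
    subject = report$subject, seed = report$seed,
    config_hash = report$config_hash,
    rows = report$rows,
    optimal_thresholds = list(bh = report$sweeps$bh$argmax_threshold,
                              rs = report$sweeps$rs$argmax_threshold),
    max_accuracy = list(bh = report$sweeps$bh$max_accuracy,
                        rs = report$sweeps$rs$max_accuracy),
    saddle = report$surface$saddle[c("bh_threshold", "rs_threshold", "accuracy", "dice")],
    corners = lapply(report$surface$corners, `[[`, "accuracy"),
    self_concordance = list(bh = report$concordance$bh$accuracy,
                            rs = report$concordance$rs$accuracy),
    unthresholded_r = report$unthresholded$pearson_r)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  surf <- list(bh_thresholds = report$surface$bh_thresholds,
               rs_thresholds = report$surface$rs_thresholds,
               accuracy = report$surface$accuracy,
               dice = report$surface$dice)
  jsonlite::write_json(surf, file.path(dir, "accuracy_surface.json"), digits = NA)
  invisible(dir)
}

#' Run a multi-subject phantom study
#'
#' Runs [run_pipeline()] for each subject and appends an `Ave +/- SD` row
#' per comparison (mean and sample SD of the per-subject columns, the usual
#' summary convention for such tables).
#'
#' @param subjects List of `phantom_spec`s, `cvr_phantom`s or
#'   `run_manifest`s; integers are interpreted as phantom seeds.
#' @param config A [cvr_config()].
#' @param out_dir Optional directory for per-subject bundles and the study
#'   table (`study_table.csv`, `study_summary.json`).
#' @param verbose Log stages.
#' @return An object of class `cvr_study`: per-subject reports plus the
#'   combined `table` (with mean and sd rows) in full precision.
#' @export
run_study <- function(subjects, config = cvr_config(), out_dir = NULL,
                      verbose = FALSE) {
  subjects <- lapply(subjects, function(s) {
    if (is.numeric(s)) s <- phantom_spec(seed = s)
    if (inherits(s, "phantom_spec")) s <- simulate_subject(s)
    s
  })
  reports <- lapply(seq_along(subjects), function(i) {
    run_pipeline(subjects[[i]], config,
                 out_dir = if (is.null(out_dir)) NULL
                           else file.path(out_dir, sprintf("subject%02d", i)),
                 verbose = verbose)
  })
  rows <- do.call(rbind, lapply(seq_along(reports), function(i)
    cbind(subject = reports[[i]]$subject, reports[[i]]$rows)))
  num <- c("tp", "tn", "fp", "fn", "acc", "dice")
  agg <- do.call(rbind, lapply(split(rows, rows$comparison), function(d) {
    rbind(data.frame(subject = "Ave", comparison = d$comparison[1],
                     t(colMeans(d[num]))),
          data.frame(subject = "SD", comparison = d$comparison[1],
                     t(apply(d[num], 2, stats::sd))))
  }))
  rownames(agg) <- NULL
  table <- rbind(rows, agg)
  study <- structure(list(reports = reports, table = table,
                          config = config, config_hash = config_hash(config)),
                     class = "cvr_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- table
    for (col in num) out[[col]] <- sprintf("%.1f", table[[col]])
    utils::write.csv(out, file.path(out_dir, "study_table.csv"), row.names = FALSE)
    jsonlite::write_json(list(config_hash = study$config_hash, table = table),
                         file.path(out_dir, "study_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  study
}

#' @export
print.cvr_study <- function(x, ...) {
  cat(sprintf("<cvr_study> %d subjects, config %s\n",
              length(x$reports), substr(x$config_hash, 1, 8)))
  print(x$table[x$table$subject %in% c("Ave", "SD"), ], row.names = FALSE)
  invisible(x)
}
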