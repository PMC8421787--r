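#' Breath-hold task timing
#'
#' Builds the per-volume phase labels of the standard breath-hold paradigm:
#' a 4 s equilibration period, four epochs of 40 s normal breathing + 4 s
#' inhalation + 16 s breath-hold, and a final 20 s block of normal breathing
#' (264 s in total; 132 volumes at TR = 2 s).
#'
#' @param tr Repetition time in seconds; must evenly tile every block
#'   duration (4, 16, 20 and 40 s).
#' @return A data frame of class `bh_timing` with one row per volume and
#'   columns `onset` (s), `phase` (`"rest"`, `"inhale"` or `"hold"`) and
#'   `equilibration`. The TR is stored in `attr(, "tr")`.
#' @examples
#' timing <- build_breathhold_timing(tr = 2)
#' nrow(timing)          # 132 volumes
#' sum(timing$phase == "hold")  # 4 blocks x 8 volumes
#' @export
build_breathhold_timing <- function(tr = 2) {
  assert_that(is.numeric(tr) && length(tr) == 1L && tr > 0, "tr must be a positive scalar")
  blocks <- c(4, 16, 20, 40)
  bad <- blocks[abs(blocks / tr - round(blocks / tr)) > 1e-9]
  if (length(bad))
    stopf("tr = %g s does not evenly divide the task block durations (%s s)",
          tr, paste(bad, collapse = ", "))
  seg <- function(dur, phase, equil = FALSE) {
    n <- as.integer(round(dur / tr))
    data.frame(phase = rep(phase, n), equilibration = rep(equil, n))
  }
  epoch <- rbind(seg(40, "rest"), seg(4, "inhale"), seg(16, "hold"))
  out <- rbind(seg(4, "rest", equil = TRUE),
               epoch, epoch, epoch, epoch,
               seg(20, "rest"))
  out <- cbind(onset = (seq_len(nrow(out)) - 1) * tr, out)
  attr(out, "tr") <- tr
  class(out) <- c("bh_timing", "data.frame")
  out
}

hold_indicator <- function(timing) as.numeric(timing$phase == "hold")

#' Synthetic subject specification
#'
#' Collects every free parameter of the phantom generator. The defaults
#' describe a healthy-subject acquisition: baseline intensity 100 (so
#' generated data are already in mean-100 scaled units), a ~2% breath-hold
#' BOLD response in gray matter, a gray:white amplitude contrast of 2.5 for
#' both metrics, per-voxel response lags of 0--4 TR, and white Gaussian
#' noise with SD 0.4 (20% of the gray-matter response amplitude).
#'
#' @param shape Grid dimensions (>= 8 in each direction).
#' @param tr Repetition time in seconds.
#' @param gm_fraction Target gray fraction of the gray+white VOI.
#' @param cvr_amplitude Mean breath-hold response amplitude in gray matter
#'   (signal units on the 100 baseline).
#' @param cvr_contrast Gray:white amplitude ratio for the breath-hold metric.
#' @param alff_amplitude Mean low-frequency fluctuation amplitude in gray
#'   matter (SD units of the band-limited component).
#' @param alff_contrast Gray:white ratio for the resting fluctuation amplitude.
#' @param amp_jitter Per-voxel uniform amplitude jitter (fraction, +/-).
#' @param rrf_jitter Per-subject uniform jitter applied to each respiratory
#'   response function constant (fraction, +/-).
#' @param noise_sd SD of additive white Gaussian noise in both run types.
#' @param wm_responsive If `FALSE`, white matter has zero true CVR amplitude,
#'   making the ground-truth responsive mask coincide with gray matter.
#' @param lesion Optional `list(center =, radius =)` (voxel units) zeroing
#'   true CVR inside a sphere, emulating a focal neurovascular-uncoupling
#'   region.
#' @param baseline Baseline signal level.
#' @param voxel_dims Voxel dimensions in mm (metadata only).
#' @param seed Integer seed fixing all randomness of the subject.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(24, 24, 16), tr = 2, gm_fraction = 0.55,
                         cvr_amplitude = 2.0, cvr_contrast = 2.5,
                         alff_amplitude = 1.5, alff_contrast = 2.5,
                         amp_jitter = 0.2, rrf_jitter = 0.2,
                         noise_sd = 0.4, wm_responsive = TRUE,
                         lesion = NULL, baseline = 100,
                         voxel_dims = c(1.875, 1.875, 5), seed = 1L) {
  assert_that(length(shape) == 3L && all(shape >= 8), "grid shape must be >= 8 in each dimension")
  assert_that(gm_fraction > 0 && gm_fraction <= 1, "gm_fraction must be in (0, 1]")
  assert_that(cvr_amplitude >= 0 && alff_amplitude >= 0 && noise_sd >= 0,
              "amplitudes and noise_sd must be non-negative")
  assert_that(cvr_contrast > 0 && alff_contrast > 0, "contrasts must be positive")
  structure(list(shape = as.integer(shape), tr = tr, gm_fraction = gm_fraction,
                 cvr_amplitude = cvr_amplitude, cvr_contrast = cvr_contrast,
                 alff_amplitude = alff_amplitude, alff_contrast = alff_contrast,
                 amp_jitter = amp_jitter, rrf_jitter = rrf_jitter,
                 noise_sd = noise_sd, wm_responsive = isTRUE(wm_responsive),
                 lesion = lesion, baseline = baseline,
                 voxel_dims = voxel_dims, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate the tissue label volume of a phantom subject
#'
#' Deterministic concentric geometry: an ellipsoidal white-matter core inside
#' a gray-matter shell, surrounded by excluded background. The inner radius
#' is chosen so that the gray fraction of the gray+white VOI matches
#' `spec$gm_fraction` up to discretization.
#'
#' @param spec A [phantom_spec()].
#' @return A [tissue_volume()].
#' @export
generate_tissue_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ax <- lapply(d, function(n) ((seq_len(n) - (n + 1) / 2) / (0.45 * n))^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  s2 <- (1 - spec$gm_fraction)^(2 / 3)   # inner/outer radius ratio squared
  labels <- array(0L, d)
  labels[r2 <= 1] <- 1L
  labels[r2 < s2] <- 2L
  tissue_volume(labels, spec$voxel_dims)
}

#' Ground-truth fields of a phantom subject
#'
#' Draws the seeded per-voxel true CVR amplitudes, response lags (0--4 TR),
#' resting fluctuation amplitudes, the responsive mask and the subject's
#' jittered respiratory-response-function constants.
#'
#' @param spec A [phantom_spec()].
#' @param tissue The subject's [tissue_volume()]; generated from `spec` if
#'   missing.
#' @return An object of class `phantom_truth` with elements `cvr_amplitude`,
#'   `lag_map`, `alff_amplitude`, `responsive_mask` and `rrf_params`.
#' @export
phantom_truth <- function(spec, tissue = generate_tissue_volume(spec)) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  assert_that(identical(dim(tissue$labels), d), "tissue grid does not match spec")
  with_seed(sub_seed(spec$seed, 1L), {
    jit <- function(n, frac) 1 + frac * stats::runif(n, -1, 1)
    gm <- tissue$labels == 1L
    wm <- tissue$labels == 2L
    cvr <- array(0, d)
    cvr[gm] <- spec$cvr_amplitude * jit(sum(gm), spec$amp_jitter)
    if (spec$wm_responsive)
      cvr[wm] <- spec$cvr_amplitude / spec$cvr_contrast * jit(sum(wm), spec$amp_jitter)
    alff <- array(0, d)
    alff[gm] <- spec$alff_amplitude * jit(sum(gm), spec$amp_jitter)
    alff[wm] <- spec$alff_amplitude / spec$alff_contrast * jit(sum(wm), spec$amp_jitter)
    lag <- array(0L, d)
    voi <- gm | wm
    lag[voi] <- sample(0:4, sum(voi), replace = TRUE)
    if (!is.null(spec$lesion)) {
      ctr <- spec$lesion$center
      dist2 <- outer(outer((seq_len(d[1]) - ctr[1])^2, (seq_len(d[2]) - ctr[2])^2, "+"),
                     (seq_len(d[3]) - ctr[3])^2, "+")
      cvr[dist2 <= spec$lesion$radius^2] <- 0
    }
    pars <- rrf_params()
    pars[] <- lapply(pars, function(p) p * (1 + spec$rrf_jitter * stats::runif(1, -1, 1)))
    structure(list(cvr_amplitude = cvr, lag_map = lag, alff_amplitude = alff,
                   responsive_mask = cvr > 0, rrf_params = pars),
              class = "phantom_truth")
  })
}

# Regressor delayed by `lag` samples; start padded with zeros (pre-task
# baseline), matching the analysis-side shifting convention.
delay_series <- function(x, lag) {
  n <- length(x)
  if (lag == 0) x else c(rep(0, lag), x[seq_len(n - lag)])
}

#' Generate a synthetic breath-hold BOLD run
#'
#' Each voxel's series is `baseline + amplitude * regressor(lagged) + noise`,
#' where the regressor is the breath-hold timing convolved with the subject's
#' jittered respiratory response function, normalized to unit peak.
#'
#' @param spec A [phantom_spec()].
#' @param truth A [phantom_truth()] aligned to the spec's grid.
#' @param timing A [build_breathhold_timing()] result (built from `spec$tr`
#'   by default).
#' @param run Run index (1 or 2); runs differ only by independent noise.
#' @return A [bold_run()] with 132 volumes at TR = 2 s.
#' @export
generate_breathhold_run <- function(spec, truth,
                                    timing = build_breathhold_timing(spec$tr),
                                    run = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  assert_that(identical(dim(truth$cvr_amplitude), spec$shape),
              "truth fields are not aligned to the spec grid")
  reg <- initial_regressor(timing, truth$rrf_params, spec$tr)
  assert_that(max(reg) > 0, "degenerate regressor")
  reg <- reg / max(reg)
  tlen <- length(reg)
  nvox <- prod(spec$shape)
  mat <- with_seed(sub_seed(spec$seed, 2L, run),
                   matrix(stats::rnorm(tlen * nvox, 0, spec$noise_sd), tlen, nvox))
  mat <- mat + spec$baseline
  resp <- which(truth$responsive_mask)
  if (length(resp)) {
    shifts <- vapply(0:4, function(l) delay_series(reg, l), numeric(tlen))
    sig <- shifts[, truth$lag_map[resp] + 1L, drop = FALSE]
    mat[, resp] <- mat[, resp] + t(t(sig) * truth$cvr_amplitude[resp])
  }
  bold_run(array(t(mat), c(spec$shape, tlen)), spec$tr)
}

# Band-limited (0.01-0.08 Hz) unit-SD random fluctuations, one column per
# voxel, generated by zeroing out-of-band Fourier bins of white noise.
bandlimited_noise <- function(tlen, nvox, tr, f_low = 0.01, f_high = 0.08) {
  w <- matrix(stats::rnorm(tlen * nvox), tlen, nvox)
  f <- (seq_len(tlen) - 1) / (tlen * tr)
  f <- pmin(f, 1 / tr - f)            # two-sided frequency axis
  keep <- f >= f_low & f <= f_high
  ft <- stats::mvfft(w)
  ft[!keep, ] <- 0
  x <- Re(stats::mvfft(ft, inverse = TRUE)) / tlen
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

#' Generate a synthetic resting-state BOLD run
#'
#' Each voxel's series is `baseline + alff_amplitude * band-limited
#' (0.01--0.08 Hz) unit-SD fluctuation + broadband noise`; 302 volumes at
#' TR = 2 s (604 s).
#'
#' @inheritParams generate_breathhold_run
#' @param n_volumes Number of volumes.
#' @return A [bold_run()].
#' @export
generate_resting_run <- function(spec, truth, run = 1L, n_volumes = 302L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  assert_that(identical(dim(truth$alff_amplitude), spec$shape),
              "truth fields are not aligned to the spec grid")
  nvox <- prod(spec$shape)
  mat <- with_seed(sub_seed(spec$seed, 3L, run), {
    m <- matrix(stats::rnorm(n_volumes * nvox, 0, spec$noise_sd), n_volumes, nvox)
    act <- which(truth$alff_amplitude > 0)
    if (length(act)) {
      fluct <- bandlimited_noise(n_volumes, length(act), spec$tr)
      m[, act] <- m[, act] + t(t(fluct) * truth$alff_amplitude[act])
    }
    m
  })
  mat <- mat + spec$baseline
  bold_run(array(t(mat), c(spec$shape, n_volumes)), spec$tr)
}

#' Simulate a complete phantom subject
#'
#' Generates the tissue volume, ground-truth fields, two breath-hold runs and
#' two resting-state runs (independent noise per run). With `dir` set, writes
#' NIfTI volumes (`bh_run1/2`, `rs_run1/2`, `tissue`, `truth_*`) plus a JSON
#' sidecar holding the spec.
#'
#' @param spec A [phantom_spec()].
#' @param dir Optional output directory.
#' @return An object of class `cvr_phantom` bundling spec, tissue, truth,
#'   timing and the four runs.
#' @export
simulate_subject <- function(spec = phantom_spec(), dir = NULL) {
  tissue <- generate_tissue_volume(spec)
  truth <- phantom_truth(spec, tissue)
  timing <- build_breathhold_timing(spec$tr)
  subj <- structure(list(
    spec = spec, tissue = tissue, truth = truth, timing = timing,
    bh_runs = list(generate_breathhold_run(spec, truth, timing, run = 1L),
                   generate_breathhold_run(spec, truth, timing, run = 2L)),
    rs_runs = list(generate_resting_run(spec, truth, run = 1L),
                   generate_resting_run(spec, truth, run = 2L))),
    class = "cvr_phantom")
  if (!is.null(dir)) write_phantom(subj, dir)
  subj
}

#' @export
print.cvr_phantom <- function(x, ...) {
  cat(sprintf("<cvr_phantom> seed %d, %s grid\n", x$spec$seed,
              paste(x$spec$shape, collapse = " x ")))
  cat(sprintf("  breath-hold: 2 runs x %d volumes; resting: 2 runs x %d volumes\n",
              n_volumes(x$bh_runs[[1]]), n_volumes(x$rs_runs[[1]])))
  print(x$tissue)
  invisible(x)
}
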