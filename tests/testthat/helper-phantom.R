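# Small phantom used throughout the tests: ~1200 gray+white voxels keeps the
# full pipeline under a second per subject.
small_spec <- function(seed = 1L, ...) {
  phantom_spec(shape = c(16L, 16L, 12L), seed = seed, ...)
}

# Phantom matching the stated recovery condition exactly: every responsive
# voxel has noise_sd = 0.2 x amplitude and the ground-truth responsive mask
# coincides with gray matter.
recovery_spec <- function(seed = 1L, noise_sd = 0.4) {
  small_spec(seed = seed, wm_responsive = FALSE, amp_jitter = 0,
             cvr_amplitude = 2.0, noise_sd = noise_sd)
}

# Truncated, scaled breath-hold run plus matching regressor and VOI.
prepared_bh <- function(subj) {
  run <- scale_to_mean_100(truncate_breathhold(subj$bh_runs[[1]]))
  reg <- truncate_breathhold(initial_regressor(subj$timing, rrf_params(), subj$spec$tr))
  list(run = run, regressor = reg, gwm = gwm_voi(subj$tissue))
}

# Exhaustive 1D threshold oracle: best accuracy over every distinct metric
# value (plus one value above the maximum), by direct counting.
oracle_best_threshold <- function(values, is_gray) {
  cand <- sort(unique(values))
  cand <- c(cand, max(cand) + 1)
  accs <- vapply(cand, function(th) {
    resp <- values >= th
    (sum(resp & is_gray) + sum(!resp & !is_gray)) / length(values)
  }, numeric(1))
  list(threshold = cand[which.max(accs)], accuracy = max(accs),
       thresholds = cand, accuracies = accs)
}
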