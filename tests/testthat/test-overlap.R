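test_that("classification, accuracy and Dice match hand enumeration", {
  d <- c(2, 2, 1)
  metric <- array(c(1, 1, 0, 0), d)
  ref <- array(c(TRUE, FALSE, TRUE, FALSE), d)
  voi <- array(TRUE, d)
  tab <- classify_vs_mask(metric, 0.5, ref, voi)
  expect_equal(c(tab$tp, tab$fp, tab$fn, tab$tn), c(1, 1, 1, 1))
  expect_equal(accuracy(tab), 0.5)
  expect_equal(dice(tab), 0.5)

  # forcing: threshold below all values -> no negatives; above all -> no positives
  low <- classify_vs_mask(metric, -1, ref, voi)
  expect_equal(c(low$fn, low$tn), c(0, 0))
  high <- classify_vs_mask(metric, 2, ref, voi)
  expect_equal(c(high$tp, high$fp), c(0, 0))
  # boundary counts as responsive
  expect_equal(classify_vs_mask(metric, 1, ref, voi)$tp, 1)
  expect_error(classify_vs_mask(metric, 0.5, ref, array(FALSE, d)), "empty")

  # published percentages: TP 45, TN 32, FP 15, FN 8 -> Acc 77%, Dice 90/113
  t1 <- contingency_table(45, 32, 15, 8)
  expect_equal(accuracy(t1), 0.77)
  expect_equal(dice(t1), 90 / 113)
  expect_equal(100 * dice(t1), 79.6, tolerance = 0.1)
  t2 <- contingency_table(72, 9, 13, 6)
  expect_equal(100 * dice(t2), 88.3, tolerance = 0.05)
  expect_equal(dice(contingency_table(10, 5, 0, 0)), 1)
  expect_error(dice(contingency_table(0, 5, 0, 0)), "Dice undefined")
  expect_error(accuracy(contingency_table(0, 0, 0, 0)), "empty|undefined")
})

test_that("counts are conserved and responsiveness is monotone in threshold", {
  set.seed(3)
  d <- c(6, 6, 4)
  metric <- array(rnorm(prod(d)), d)
  ref <- array(runif(prod(d)) > 0.5, d)
  voi <- array(runif(prod(d)) > 0.2, d)
  ths <- sort(rnorm(15))
  npos_prev <- Inf
  for (th in ths) {
    tab <- classify_vs_mask(metric, th, ref, voi)
    expect_equal(tab$total, sum(voi))
    expect_equal(sum(as_percent(tab)), 100)
    npos <- tab$tp + tab$fp
    expect_lte(npos, npos_prev)
    npos_prev <- npos
  }
})

test_that("the 1D sweep finds the separating threshold and matches the oracle", {
  subj <- simulate_subject(recovery_spec(seed = 12))
  p <- prepared_bh(subj)
  wf <- estimate_personal_waveform(p$run, p$regressor, p$gwm)
  map <- breathhold_cvr_map(p$run, wf, p$gwm)
  sw <- sweep_vs_gray(map, subj$tissue)

  expect_gt(sw$max_accuracy, 0.95)
  # argmax lies between the white and gray modes
  gm_vals <- map$values[subj$tissue$labels == 1]
  wm_vals <- map$values[subj$tissue$labels == 2]
  expect_gt(sw$argmax_threshold, median(wm_vals))
  expect_lt(sw$argmax_threshold, median(gm_vals))

  # oracle equivalence: within one grid step of the exhaustive optimum
  vals <- map$values[p$gwm]
  oracle <- oracle_best_threshold(vals, subj$tissue$labels[p$gwm] == 1)
  step <- max(diff(sw$thresholds))
  expect_lte(abs(sw$argmax_threshold - oracle$threshold), step + 1e-12)
  # the percentile grid may straddle the exact optimum but must come close
  expect_gte(sw$max_accuracy, oracle$accuracy - 0.01)

  # grid entirely below the minimum: everything responsive, accuracy = gray fraction
  below <- sweep_vs_gray(map, subj$tissue, grid = min(vals) - c(2, 1))
  gray_frac <- mean(subj$tissue$labels[p$gwm] == 1)
  expect_equal(below$accuracy, rep(gray_frac, 2))

  # separable phantom: accuracy rises to a single interior maximum then falls
  acc <- sw$accuracy
  peak <- which.max(acc)
  expect_gt(peak, 1)
  expect_lt(peak, length(acc))
  expect_gt(min(acc[peak] - acc[c(1, length(acc))]), 0)
})

test_that("the accuracy surface has forced corners and is symmetric in role swap", {
  subj <- simulate_subject(small_spec(seed = 13))
  rep <- run_pipeline(subj)
  surf <- rep$surface
  ca <- vapply(surf$corners, `[[`, numeric(1), "accuracy")
  expect_identical(unname(ca), c(1, 0, 0, 1))   # A1 all-TN, A2 all-FP, A3 all-FN, A4 all-TP
  expect_equal(unname(vapply(surf$corners, function(x) x$table$total, numeric(1))),
               rep(surf$n_voxels, 4))

  # swapping predictor and reference transposes the accuracy matrix
  gm <- gm_voi(subj$tissue) & rep$bh_map$voi
  s1 <- cross_metric_surface(rep$bh_map, rep$rs_map, gm, n_grid = 21)
  s2 <- cross_metric_surface(rep$rs_map, rep$bh_map, gm, n_grid = 21)
  expect_equal(s1$accuracy, t(s2$accuracy), tolerance = 1e-12)
  expect_equal(s1$dice, t(s2$dice), tolerance = 1e-12)

  # the saddle value equals direct classification at the 1D-optimal pair
  ref <- array(FALSE, dim(gm))
  ref[gm] <- rep$bh_map$values[gm] >= rep$sweeps$bh$argmax_threshold
  tab <- classify_vs_mask(rep$rs_map, rep$sweeps$rs$argmax_threshold, ref, gm)
  expect_equal(rep$surface$saddle$accuracy, accuracy(tab))
})

test_that("threshold recovery classifies like the ground truth on separable phantoms", {
  subj <- simulate_subject(recovery_spec(seed = 14))
  p <- prepared_bh(subj)
  wf <- estimate_personal_waveform(p$run, p$regressor, p$gwm)
  map <- breathhold_cvr_map(p$run, wf, p$gwm)
  sw <- sweep_vs_gray(map, subj$tissue)
  pred <- map$values[p$gwm] >= sw$argmax_threshold
  truth <- subj$truth$responsive_mask[p$gwm]
  expect_gte(mean(pred == truth), 0.95)
})

test_that("self-concordance is 1 for identical maps and ~0.5 for independent noise", {
  subj <- simulate_subject(small_spec(seed = 15))
  rep <- run_pipeline(subj)
  sc <- self_concordance(rep$bh_map, rep$bh_map, subj$tissue)
  expect_equal(sc$accuracy, 1)
  expect_equal(sc$dice, 1)

  # independent pure-noise maps thresholded at their medians agree ~50%
  set.seed(21)
  d <- c(12, 12, 8)
  a <- array(rnorm(prod(d)), d)
  b <- array(rnorm(prod(d)), d)
  voi <- array(TRUE, d)
  ra <- a >= median(a)
  tab <- classify_vs_mask(b, median(b), ra, voi)
  expect_equal(accuracy(tab), 0.5, tolerance = 0.06)

  # resting self-concordance beats breath-hold when breath-hold noise is higher
  spec_lo <- small_spec(seed = 16, noise_sd = 0.3)
  spec_hi <- small_spec(seed = 16, noise_sd = 8)
  tis <- generate_tissue_volume(spec_lo)
  tru <- phantom_truth(spec_lo, tis)
  timing <- build_breathhold_timing(2)
  reg <- truncate_breathhold(initial_regressor(timing, rrf_params(), 2))
  gwm <- gwm_voi(tis)
  bh_maps <- lapply(1:2, function(i) {
    r <- scale_to_mean_100(truncate_breathhold(
      generate_breathhold_run(spec_hi, tru, timing, run = i)))
    breathhold_cvr_map(r, estimate_personal_waveform(r, reg, gwm), gwm)
  })
  rs_maps <- lapply(1:2, function(i)
    resting_cvre_map(scale_to_mean_100(truncate_resting(
      generate_resting_run(spec_lo, tru, run = i))), gwm))
  sc_bh <- self_concordance(bh_maps[[1]], bh_maps[[2]], tissue_volume(tis$labels))
  sc_rs <- self_concordance(rs_maps[[1]], rs_maps[[2]], tissue_volume(tis$labels))
  expect_gt(sc_rs$accuracy, sc_bh$accuracy)
})

test_that("unthresholded comparison detects affine identity and independence", {
  subj <- simulate_subject(small_spec(seed = 17))
  rep <- run_pipeline(subj)
  gm <- gm_voi(subj$tissue) & rep$bh_map$voi

  affine <- cvr_map(3 * rep$bh_map$values + 7, rep$bh_map$voi, "resting_alff")
  cmpA <- unthresholded_compare(rep$bh_map, affine, gm)
  expect_equal(cmpA$pearson_r, 1, tolerance = 1e-9)
  dvals <- cmpA$difference[is.finite(cmpA$difference)]
  expect_lt(sd(dvals), 0.02)   # spatially ~constant difference

  set.seed(5)
  noiseA <- cvr_map(array(rnorm(prod(dim(gm))), dim(gm)), gm, "breathhold_beta")
  noiseB <- cvr_map(array(rnorm(prod(dim(gm))), dim(gm)), gm, "resting_alff")
  cmpN <- unthresholded_compare(noiseA, noiseB, gm)
  expect_lt(abs(cmpN$pearson_r), 0.15)
  # central-95% clipping on each metric keeps ~90-95% of voxels jointly
  frac <- nrow(cmpN$scatter) / sum(gm)
  expect_gt(frac, 0.89)
  expect_lte(frac, 0.96)

  const <- cvr_map(array(1, dim(gm)), gm, "resting_alff")
  expect_error(unthresholded_compare(rep$bh_map, const, gm), "constant")
})
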