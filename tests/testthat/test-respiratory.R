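test_that("the respiratory response function has the stated values and shape", {
  expect_equal(rrf(0), 0)
  expect_equal(rrf(1), 0.306, tolerance = 2e-3)
  expect_error(rrf(-1), "non-negative")
  expect_error(rrf_params(a1 = -1), "positive")

  # dense-grid oracle: one positive lobe then one negative lobe on (0, 60]
  tg <- seq(0.01, 60, by = 0.01)
  v <- rrf(tg)
  sign_changes <- sum(diff(sign(v)) != 0)
  expect_equal(sign_changes, 1L)
  expect_gt(v[1], 0)
  expect_lt(v[length(v)], 0)
  # the negative lobe decays back toward zero by 60 s
  expect_lt(abs(rrf(60)), 0.05 * max(v))
})

test_that("the initial regressor is the hold-timing convolved with the RRF", {
  timing <- build_breathhold_timing(2)
  reg <- initial_regressor(timing)
  expect_length(reg, 132L)

  # all-zero timing gives an all-zero regressor
  quiet <- timing
  quiet$phase <- "rest"
  expect_equal(initial_regressor(quiet, tr = 2), rep(0, 132))

  # convolution identity: a single hold volume at k places the sampled RRF at k
  imp <- timing
  imp$phase <- "rest"
  imp$phase[20] <- "hold"
  r <- initial_regressor(imp, tr = 2)
  kern <- rrf(seq(0, 60, by = 2))
  expect_equal(r[20:(20 + length(kern) - 1)], kern, tolerance = 1e-10)
  expect_equal(r[1:19], rep(0, 19), tolerance = 1e-10)

  # four epochs produce four response lobes above half peak
  above <- reg > max(reg) / 2
  lobes <- sum(diff(c(FALSE, above)) == 1)
  expect_equal(lobes, 4L)
})

test_that("order-statistic smoothing matches window arithmetic and is scale-equivariant", {
  w <- osfilt_weights()
  expect_equal(osfilt_smooth(rep(5, 10), w), rep(5, 10))
  # linear ramp: interior value 0.7*2 + 0.15*3 + 0.15*1 = 2
  expect_equal(osfilt_smooth(c(1, 2, 3), w)[2], 2.0)
  expect_error(osfilt_smooth(c(1, 2), w), "at least 3")

  # the printed non-unit-sum variant doubles a constant
  expect_equal(osfilt_smooth(rep(5, 10), osfilt_weights(printed = TRUE)), rep(10, 10))

  # a lone spike is attenuated (brute-force window arithmetic oracle)
  x <- c(0, 0, 0, 10, 0, 0, 0)
  y <- osfilt_smooth(x, w)
  oracle <- vapply(2:6, function(t) {
    win <- x[(t - 1):(t + 1)]
    0.7 * median(win) + 0.15 * max(win) + 0.15 * min(win)
  }, numeric(1))
  expect_equal(y[2:6], oracle)
  expect_lt(max(abs(y)), max(abs(x)))

  # unit-sum weights: osfilt(aX) = a osfilt(X)
  set.seed(42)
  for (i in 1:5) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10)
    expect_equal(osfilt_smooth(a * x, w), a * osfilt_smooth(x, w), tolerance = 1e-12)
  }
})

test_that("top-correlated voxel selection counts and ranks correctly", {
  # synthetic run: 1000 eligible voxels, two amplitude tiers, small noise
  timing <- build_breathhold_timing(2)
  reg <- initial_regressor(timing)
  reg <- reg / max(reg)
  n <- 1000
  amps <- rep(c(0.2, 3), c(950, 50))
  set.seed(7)
  m <- 100 + outer(amps, reg) + matrix(rnorm(n * 132, 0, 0.3), n, 132)
  run <- bold_run(array(m, c(10, 10, 10, 132)), tr = 2)
  voi <- array(TRUE, c(10, 10, 10))

  sel <- select_top_correlated(run, reg, voi, pct = 0.01)
  expect_length(sel, 10L)
  expect_true(all(amps[sel] == 3))   # top tier only
  expect_length(select_top_correlated(run, reg, voi, pct = 1), 1000L)
  expect_error(select_top_correlated(run, reg, voi, pct = 0), "pct")

  # constant voxels are ineligible
  m2 <- m; m2[1:990, ] <- 100
  run2 <- bold_run(array(m2, c(10, 10, 10, 132)), tr = 2)
  expect_length(select_top_correlated(run2, reg, voi, pct = 1), 10L)
})

test_that("personal waveform recovers the subject's response shape", {
  # all lags 0, no noise: waveform is proportional to the regressor
  spec <- small_spec(seed = 3, noise_sd = 0, rrf_jitter = 0)
  tis <- generate_tissue_volume(spec)
  tru <- phantom_truth(spec, tis)
  tru$lag_map[] <- 0L
  timing <- build_breathhold_timing(2)
  run <- scale_to_mean_100(truncate_breathhold(
    generate_breathhold_run(spec, tru, timing)))
  reg <- truncate_breathhold(initial_regressor(timing, rrf_params(), 2))
  wf <- estimate_personal_waveform(run, reg, gwm_voi(tis))
  expect_gt(cor(wf$values, reg), 0.99)
  expect_equal(wf$n_source_voxels, ceiling(0.01 * sum(gwm_voi(tis))))

  # determinism: identical runs give identical waveforms
  wf2 <- estimate_personal_waveform(run, reg, gwm_voi(tis))
  expect_identical(wf, wf2)

  # jittered subject RRF: the recovered waveform matches the subject's own
  # regressor better than the generic one
  specj <- small_spec(seed = 5)
  subj <- simulate_subject(specj)
  p <- prepared_bh(subj)
  wfj <- estimate_personal_waveform(p$run, p$regressor, p$gwm)
  reg_subj <- truncate_breathhold(
    initial_regressor(subj$timing, subj$truth$rrf_params, 2))
  expect_gt(cor(wfj$values, reg_subj), cor(wfj$values, p$regressor))
})

test_that("lagged regression recovers beta, lag and amplitude", {
  timing <- build_breathhold_timing(2)
  reg <- truncate_breathhold(initial_regressor(timing))
  reg <- reg / max(reg)
  tlen <- length(reg)
  d <- c(4, 4, 4)
  voi <- array(TRUE, d)

  # voxel = 3 x waveform: beta 3 at lag 0
  m <- matrix(100, prod(d), tlen)
  m[1, ] <- 100 + 3 * reg
  m[2, ] <- 100 + c(rep(0, 2), reg[seq_len(tlen - 2)])  # delayed 2 TR
  run <- bold_run(array(m, c(d, tlen)), tr = 2)
  map <- breathhold_cvr_map(run, reg, voi)
  expect_equal(map$values[1], 3, tolerance = 1e-10)
  expect_equal(map$best_lag[1], 0L)
  expect_equal(map$best_lag[2], 2L)
  expect_error(breathhold_cvr_map(run, rep(1, tlen), voi), "zero variance")

  # beta is linear in amplitude with unit slope against the true regressor
  amps <- seq(0.5, 4, length.out = 8)
  m2 <- matrix(100, prod(d), tlen)
  m2[seq_along(amps), ] <- 100 + outer(amps, reg)
  run2 <- bold_run(array(m2, c(d, tlen)), tr = 2)
  map2 <- breathhold_cvr_map(run2, reg, voi)
  expect_equal(map2$values[seq_along(amps)], amps, tolerance = 1e-10)

  # pure-noise voxels: mean beta ~ 0 over many voxels
  set.seed(99)
  nn <- 500
  mn <- 100 + matrix(rnorm(nn * tlen, 0, 1), nn, tlen)
  runn <- bold_run(array(mn, c(10, 10, 5, tlen)), tr = 2)
  mapn <- breathhold_cvr_map(runn, reg, array(TRUE, c(10, 10, 5)))
  expect_lt(abs(mean(mapn$values)), 0.1)
})

test_that("best-fit lags match the ground truth under the stated noise condition", {
  # noiseless: exact agreement for every responsive voxel
  subj0 <- simulate_subject(recovery_spec(seed = 8, noise_sd = 0))
  p0 <- prepared_bh(subj0)
  wf0 <- estimate_personal_waveform(p0$run, p0$regressor, p0$gwm)
  map0 <- breathhold_cvr_map(p0$run, wf0, p0$gwm)
  resp0 <- subj0$truth$responsive_mask
  expect_equal(mean(map0$best_lag[resp0] == subj0$truth$lag_map[resp0]), 1)

  # noise_sd = 0.2 x amplitude: at least 95% agreement
  subj <- simulate_subject(recovery_spec(seed = 8))
  p <- prepared_bh(subj)
  wf <- estimate_personal_waveform(p$run, p$regressor, p$gwm)
  map <- breathhold_cvr_map(p$run, wf, p$gwm)
  resp <- subj$truth$responsive_mask
  expect_gte(mean(map$best_lag[resp] == subj$truth$lag_map[resp]), 0.95)
})
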