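test_that("mesh_rois averages pixel blocks per frame", {
  # uniform image: every ROI trace equals the global intensity
  mv <- list(movie = array(7, dim = c(3, 1, 6, 6)), pixel_area = 1, fs = 5,
             pre_frames = 1:2, post_frames = 3:3)
  rois <- mesh_rois(mv, roi_area = 9)
  expect_true(all(rois$traces == 7))
  expect_equal(rois$grid, c(2, 2))

  # 2x2 block over {1,2,3,4} -> 2.5
  mv2 <- list(movie = array(c(1, 2, 3, 4), dim = c(1, 1, 2, 2)),
              pixel_area = 1, fs = 5, pre_frames = 1, post_frames = 1)
  expect_equal(as.numeric(mesh_rois(mv2, roi_area = 4)$traces), 2.5)

  # non-integer block: error names the nearest valid area
  expect_error(mesh_rois(mv, roi_area = 5), "nearest valid roi_area")
})

test_that("highpass removes slow components and passes fast ones", {
  fs <- 5
  n <- 3000
  t_s <- (seq_len(n) - 1) / fs
  # constant trace -> ~0
  out <- highpass(rep(100, n), 0.2, fs)
  expect_lt(max(abs(out)), 1e-6 * 100)
  # 0.05 Hz attenuated >= 10x; 1 Hz attenuated <= 1.2x (mid-trace amplitude)
  mid <- seq(n %/% 4, 3 * n %/% 4)
  slow <- highpass(sin(2 * pi * 0.05 * t_s), 0.2, fs)
  expect_lt(max(abs(slow[mid])), 0.1)
  fast <- highpass(sin(2 * pi * 1 * t_s), 0.2, fs)
  expect_gt(max(abs(fast[mid])), 1 / 1.2)
  # guard rails
  expect_error(highpass(rep(1, 10), 0.2, fs), "warm-up")
  expect_error(highpass(rep(1, n), 3, fs), "fs/2")
})

test_that("count_transients detects planted events and rejects bad baselines", {
  expect_equal(count_transients(rep(0, 100), f0 = 1, fs = 5), 0)

  # 7 well-separated transients at 5x the noise SD (over several seeds)
  events <- seq(10, 100, by = 15)
  for (s in c(7, 42, 99)) {
    dff <- planted_trace(600, 5, events, amp = 0.1, noise_sd = 0.02, seed = s)
    expect_equal(count_transients(dff, f0 = 1, fs = 5), 7)
  }

  expect_error(count_transients(rep(1, 5), f0 = 1, fs = 5), "10 samples")
  expect_error(count_transients(rnorm(100), f0 = -2, fs = 5), "positive")
})

test_that("count_transients agrees with an independent reference and the
           expected crossing rate on white noise", {
  set.seed(11)
  counts_pkg <- counts_ref <- numeric(100)
  for (i in 1:100) {
    x <- rnorm(500)
    counts_pkg[i] <- count_transients(x, f0 = 1, fs = 1)
    counts_ref[i] <- ref_count_transients(x, fs = 1)
  }
  expect_equal(counts_pkg, counts_ref)
  # iid-Gaussian upward-crossing rate at a mean + 2 SD threshold
  expected <- 499 * pnorm(2) * pnorm(2, lower.tail = FALSE)
  se <- sd(counts_pkg) / sqrt(100)
  expect_lt(abs(mean(counts_pkg) - expected), 3 * se)
})

test_that("registration recovers identity and known rotations", {
  tpl <- brain_template(60, 40)
  img <- matrix(0, 60, 40)
  img[tpl$mask] <- 1
  img[15:25, ] <- img[15:25, ] * 2
  img[40:50, 10:31] <- img[40:50, 10:31] * 1.5

  tf0 <- register_to_template(img, tpl)
  expect_lte(abs(tf0$rotation_deg), 0.5)
  expect_lte(max(abs(c(tf0$dy, tf0$dx))), 1)

  # independent oracle: rotate +10 degrees with EBImage, expect -10 +/- 1
  e <- EBImage::Image(t(img))
  rot <- EBImage::rotate(e, 10, output.dim = c(40, 60), bg.col = 0)
  img_rot <- t(EBImage::imageData(rot))
  tf <- register_to_template(img_rot, tpl)
  expect_lt(abs(tf$rotation_deg - (-10)), 1)

  expect_error(register_to_template(matrix(0, 60, 40), tpl), "foreground")
})

test_that("apply_transform drops eye-region ROIs from the map", {
  tpl <- brain_template(20, 16)
  tf <- structure(list(rotation_deg = 0, dy = 0, dx = 0, scale = 1),
                  class = "bam_transform")
  out <- apply_transform(matrix(1, 20, 16), tf, tpl)
  expect_true(all(is.na(out[tpl$eye_mask])))
  expect_true(all(!is.na(out[tpl$retained])))
})

test_that("compute_bam differences counts with rate normalization", {
  # two layers, c1 = (3, 4), c0 = (1, 2), equal durations -> 4
  c0 <- array(c(1, 2), dim = c(1, 1, 2))
  c1 <- array(c(3, 4), dim = c(1, 1, 2))
  expect_equal(as.numeric(compute_bam(c0, c1)), 4)
  # identical counts -> zero map
  x <- array(sample(0:5, 24, TRUE), dim = c(3, 4, 2))
  expect_true(all(compute_bam(x, x) == 0))
  # 15 counts / 15 min vs 10 counts / 10 min -> 0 after normalization
  expect_equal(as.numeric(compute_bam(matrix(10, 1, 1), matrix(15, 1, 1),
                                      dur0_s = 600, dur1_s = 900)), 0)
  # ... but 5 without it
  expect_equal(as.numeric(compute_bam(matrix(10, 1, 1), matrix(15, 1, 1),
                                      dur0_s = 600, dur1_s = 900,
                                      normalize = FALSE)), 5)
  expect_error(compute_bam(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("layer additivity: per-layer BAMs sum to the pooled BAM", {
  set.seed(8)
  c0 <- array(rpois(60, 5), dim = c(3, 5, 4))
  c1 <- array(rpois(60, 6), dim = c(3, 5, 4))
  per_layer <- Reduce(`+`, lapply(1:4, function(k) {
    compute_bam(c0[, , k], c1[, , k])
  }))
  expect_equal(per_layer, compute_bam(c0, c1))
})

test_that("T-score BAM follows the replicate T statistic and its policies", {
  reps <- lapply(c(1, 2, 3, 4, 5), function(v) matrix(v, 1, 1))
  expect_equal(as.numeric(compute_tscore_bam(reps)),
               3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-10)
  # all-zero replicates -> t = 0
  zeros <- lapply(1:5, function(i) matrix(0, 2, 2))
  expect_true(all(compute_tscore_bam(zeros) == 0))
  # sd = 0, mean != 0 -> finite, floored
  same <- lapply(1:5, function(i) matrix(3, 1, 1))
  expect_equal(as.numeric(compute_tscore_bam(same, eps = 1)), 3 * sqrt(5))
  expect_error(compute_tscore_bam(list(matrix(0, 2, 2))), "2 replicates")
  expect_error(compute_tscore_bam(list(matrix(0, 2, 2), matrix(0, 3, 3))),
               "mismatch")
})

test_that("T-score BAM is scale-invariant and sign-antisymmetric", {
  set.seed(13)
  reps <- lapply(1:5, function(i) matrix(rnorm(12, 2, 10), 3, 4))
  t1 <- compute_tscore_bam(reps)
  t_scaled <- compute_tscore_bam(lapply(reps, function(m) 7 * m))
  expect_equal(t1, t_scaled, tolerance = 1e-12)
  t_neg <- compute_tscore_bam(lapply(reps, function(m) -m))
  expect_equal(t_neg, -t1, tolerance = 1e-12)
})

test_that("movie-to-BAM recovers the planted sign pattern without noise", {
  tpl <- make_cluster_templates(1, 12, 10, seed = 5)[[1]]
  mv <- suppressMessages(
    simulate_movie(tpl, duration_pre_s = 900, duration_post_s = 900, fs = 4,
                   n_layers = 1, baseline_rate_hz = 0.05,
                   rate_per_unit = 0.05, drift_amp = 0, noise_sd = 0,
                   seed = 11))
  rois <- mesh_rois(mv)
  counts <- count_epoch_transients(rois)
  bam <- compute_bam(counts$c0, counts$c1, counts$dur0_s, counts$dur1_s)
  affected <- abs(tpl) > 0.5
  expect_true(all(sign(bam[affected]) == sign(tpl[affected])))
})
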