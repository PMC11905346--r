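test_that("tone-aligned responses isolate tone-evoked activity", {
  set.seed(2)
  n <- 8; n_fr <- 4000; fr <- 30
  freqs <- c(4, 8, 12, 16, 24, 32)
  tt <- data.frame(frequency_khz = rep(freqs, 6),
                   onset_frame = seq(100, by = 70, length.out = 36))
  # activity independent of tones: responses near zero
  act <- matrix(rnorm(n * n_fr, 5, 1), n, n_fr)
  ta <- tone_aligned_response(act, tt, fr, seed = 3)
  expect_lt(max(abs(ta$responses)), 0.5)
  expect_true(mean(ta$responsive) < 0.4)

  # a neuron driven only during 8 kHz tones peaks at 8 kHz
  act2 <- act
  for (e in which(tt$frequency_khz == 8)) {
    o <- tt$onset_frame[e]
    act2[3, o:(o + fr - 1)] <- act2[3, o:(o + fr - 1)] + 4
  }
  ta2 <- tone_aligned_response(act2, tt, fr, seed = 3)
  expect_equal(ta2$frequencies_khz[which.max(ta2$responses[3, ])], 8)
  expect_true(ta2$responsive[3])

  # loop-based recomputation of one neuron's per-frequency response
  z <- (act2[3, ] - mean(act2[3, ])) / sd(act2[3, ])
  for (f in freqs) {
    vals <- c()
    for (e in which(tt$frequency_khz == f)) {
      o <- tt$onset_frame[e]
      vals <- c(vals, mean(z[o:(o + fr - 1)]) - mean(z[(o - 10):(o - 1)]))
    }
    expect_equal(ta2$responses[3, as.character(f)], c(mean(vals)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Gaussian fits recover the best frequency", {
  freqs <- c(4, 8, 12, 16, 24, 32)
  x <- log2(freqs)
  y <- 2 * exp(-(x - log2(8))^2 / (2 * 0.8^2))
  rec <- fit_best_frequency(y, freqs)
  expect_true(rec$selective)
  expect_equal(rec$bf_khz, 8, tolerance = 1e-3)
  expect_gt(rec$fit_r2, 0.999)

  # flat responses are non-selective
  rec_flat <- fit_best_frequency(rep(0.3, 6), freqs)
  expect_false(rec_flat$selective)
  expect_true(is.na(rec_flat$bf_khz))

  # non-responsive neurons get no fit
  rec_nr <- fit_best_frequency(y, freqs, responsive = FALSE)
  expect_true(is.na(rec_nr$bf_khz))

  # center bound: a peak outside the tested range clamps to the edge
  y_edge <- 2 * exp(-(x - 6)^2 / (2 * 1^2))
  rec_e <- fit_best_frequency(y_edge, freqs)
  if (rec_e$selective) expect_lte(rec_e$bf_log2, 5)
})

test_that("best-frequency differences are symmetric octave distances", {
  expect_equal(delta_bf(8, 16), 1)
  expect_equal(delta_bf(12, 12), 0)
  expect_equal(delta_bf(4, 32), 3)
  expect_equal(delta_bf(6, 17), delta_bf(17, 6))
})

test_that("the BF shuffle test obeys its counting and floor rules", {
  set.seed(14)
  n_neu <- 40
  tun <- data.frame(neuron_id = 1:n_neu,
                    bf_log2 = runif(n_neu, 2, 5))
  rec <- expand.grid(target_id = 1:5, neuron_id = 6:n_neu)
  dbf <- abs(tun$bf_log2[rec$target_id] - tun$bf_log2[rec$neuron_id])
  rec$neuron_type <- "NonSOM"
  rec$sig_class <- "none"
  rec$excluded <- FALSE
  rec$distance_um <- 100

  # influence perfectly anti-ordered with tuning difference: observed r = -1,
  # more negative than every shuffle, so p hits the 1/n floor
  rec$influence <- -dbf
  ts <- tuning_shuffle_test(rec, tun, n_shuffles = 500, seed = 3)
  expect_equal(ts$observed_r, -1)
  expect_equal(ts$p, 1 / 500)
  expect_equal(length(ts$null_r), 500)

  # identical seed reproduces the identical null distribution
  ts2 <- tuning_shuffle_test(rec, tun, n_shuffles = 500, seed = 3)
  expect_identical(ts$null_r, ts2$null_r)

  # influence independent of tuning: p is not extreme
  set.seed(15)
  rec$influence <- rnorm(nrow(rec))
  ts3 <- tuning_shuffle_test(rec, tun, n_shuffles = 200, seed = 4)
  expect_gt(ts3$p, 0.005)

  # all BFs identical: test undefined
  tun_flat <- tun; tun_flat$bf_log2 <- 3
  expect_error(tuning_shuffle_test(rec, tun_flat, 100, 1), "undefined")
})

test_that("generator tuning is recovered end to end on a small session", {
  p <- gt_params(n_neurons = 50, som_fraction = 0.1, n_targets = 4,
                 n_control_targets = 1, n_repeats = 6, with_tones = TRUE,
                 n_tone_repeats = 8, seed = 21)
  s <- generate_session(p)
  act <- preprocess_session(s)
  tt <- tuning_table(act$events, s$tone_table, p$frame_rate, seed = 7)
  ok <- !is.na(tt$bf_log2)
  expect_gt(sum(ok), 25)
  err <- abs(tt$bf_log2[ok] - s$ground_truth$true_bf[ok])
  # interior true BFs should be recovered well; edge BFs clamp
  interior <- ok & s$ground_truth$true_bf > 2.3 & s$ground_truth$true_bf < 4.7
  expect_gt(mean(abs(tt$bf_log2[interior] -
                       s$ground_truth$true_bf[interior]) < 0.5), 0.8)
})
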