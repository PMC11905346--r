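# synthetic influence records with a known difference-of-Gaussians shape,
# used to unit-test the aggregation functions without a full session
dog_records <- function(seed = 1, n_targets = 6, n_neurons = 150,
                        ac = 0.6, sc = 45, as_ = 0.12, ss = 180,
                        noise = 0) {
  set.seed(seed)
  pos <- matrix(runif(2 * n_neurons, 0, 500), n_neurons, 2)
  tids <- seq_len(n_targets)
  rec <- expand.grid(target_id = tids,
                     neuron_id = seq_len(n_neurons))
  rec <- rec[rec$target_id != rec$neuron_id, ]
  d <- sqrt(rowSums((pos[rec$target_id, ] - pos[rec$neuron_id, ])^2))
  rec$neuron_type <- "NonSOM"
  rec$influence <- ac * exp(-d^2 / (2 * sc^2)) - as_ * exp(-d^2 / (2 * ss^2)) +
    noise * rnorm(nrow(rec))
  rec$distance_um <- d
  rec$excluded <- d < 25
  rec$sig_class <- ifelse(rec$excluded, NA_character_,
                          ifelse(rec$influence > 0.2, "positive",
                                 ifelse(rec$influence < -0.08, "negative",
                                        "none")))
  list(records = rec, positions = pos)
}

test_that("centered maps are normalized per targeted neuron", {
  # 2 targets, each with one influenced neuron at the identical offset
  pos <- rbind(c(100, 100), c(300, 300), c(150, 100), c(350, 300))
  rec <- data.frame(target_id = c(1, 2), neuron_id = c(3, 4),
                    neuron_type = "NonSOM", influence = c(1, 1),
                    sig_class = "positive", excluded = FALSE,
                    distance_um = c(50, 50))
  m <- centered_influence_map(rec, pos, "positive", "NonSOM", bin_size = 20)
  expect_equal(sum(m$grid), 1)           # 2 neurons / 2 targets
  expect_equal(max(m$grid), 1)           # identical offset -> one bin

  # no influenced neurons -> all-zero map
  rec0 <- rec; rec0$sig_class <- "none"
  m0 <- centered_influence_map(rec0, pos, "positive", "NonSOM")
  expect_true(all(m0$grid == 0))

  expect_error(centered_influence_map(rec[0, ], pos, "positive"), "empty")
})

test_that("map totals equal influenced count over target count exactly", {
  dr <- dog_records(seed = 8)
  m <- centered_influence_map(dr$records, dr$positions, "positive", "NonSOM",
                              bin_size = 20)
  n_pos <- sum(dr$records$sig_class == "positive" &
                 !dr$records$excluded, na.rm = TRUE)
  expect_equal(sum(m$grid), n_pos / m$n_targets, tolerance = 1e-12)
})

test_that("maps from mirrored positions are mirror images", {
  dr <- dog_records(seed = 3)
  m1 <- centered_influence_map(dr$records, dr$positions, "positive", "NonSOM",
                               bin_size = 50, extent = 500)
  pos_m <- dr$positions
  pos_m[, 1] <- -pos_m[, 1]
  m2 <- centered_influence_map(dr$records, pos_m, "positive", "NonSOM",
                               bin_size = 50, extent = 500)
  expect_equal(m2$grid, m1$grid[rev(seq_len(nrow(m1$grid))), ],
               tolerance = 1e-12)
})

test_that("distance distributions summarize each significance group", {
  # all influenced neurons at one distance -> step CDF
  rec <- data.frame(target_id = 1, neuron_id = 2:6, neuron_type = "NonSOM",
                    influence = 1, sig_class = "positive", excluded = FALSE,
                    distance_um = 80)
  dd <- distance_distributions(rec)
  expect_equal(unique(dd$cdfs[["NonSOM.positive"]]), 80)

  # group means equal a direct mean over the record subset
  dr <- dog_records(seed = 4)
  dd2 <- distance_distributions(dr$records)
  r <- dr$records[!dr$records$excluded, ]
  for (g in c("positive", "negative", "none")) {
    sub <- r$distance_um[r$sig_class == g]
    row <- dd2$summary[dd2$summary$group == g &
                         dd2$summary$cell_type == "NonSOM", ]
    expect_equal(row$mean_distance, mean(sub), tolerance = 1e-12)
    expect_equal(row$sd_distance, sd(sub), tolerance = 1e-12)
    expect_equal(row$n, length(sub))
  }
  allrow <- dd2$summary[dd2$summary$group == "all" &
                          dd2$summary$cell_type == "NonSOM", ]
  expect_equal(allrow$n, nrow(r))
})

test_that("distance-binned influence matches a brute-force recomputation", {
  # all influences zero -> flat zero profile
  rec0 <- data.frame(target_id = 1, neuron_id = 2:50, neuron_type = "NonSOM",
                     influence = 0, sig_class = "none", excluded = FALSE,
                     distance_um = runif(49, 30, 400))
  pr0 <- distance_binned_influence(rec0)
  expect_true(all(pr0$mean_influence[pr0$n > 0] == 0))

  dr <- dog_records(seed = 6, noise = 0.05)
  pr <- distance_binned_influence(dr$records)
  r <- dr$records[!dr$records$excluded, ]
  edges <- seq(25, 425, by = 50)
  or <- bf_bin_means(r$influence, r$distance_um, edges)
  got <- pr[pr$cell_type == "NonSOM", ]
  expect_equal(got$mean_influence[or$n > 0], or$mean[or$n > 0],
               tolerance = 1e-12)
  expect_equal(got$n, or$n)

  # DoG-shaped records: positive near the target, negative far away
  expect_gt(got$mean_influence[1], 0)
  expect_lt(got$mean_influence[got$bin_center == 400], 0)
})

test_that("center/surround fit recovers noiseless DoG parameters", {
  d <- seq(35, 415, by = 20)
  truth <- c(0.5, 40, 0.1, 200)
  prof <- data.frame(bin_center = d,
                     mean_influence = truth[1] * exp(-d^2 / (2 * truth[2]^2)) -
                       truth[3] * exp(-d^2 / (2 * truth[4]^2)),
                     n = rep(50, length(d)))
  fit <- fit_center_surround(prof, cell_type = NULL)
  expect_true(fit$converged)
  expect_lt(abs(fit$amp_center - truth[1]) / truth[1], 0.01)
  expect_lt(abs(fit$sigma_center - truth[2]) / truth[2], 0.01)
  expect_lt(abs(fit$sigma_surround - truth[4]) / truth[4], 0.05)
  expect_gt(fit$sigma_surround, fit$sigma_center)

  # flat zero profile -> near-zero amplitudes
  prof0 <- data.frame(bin_center = d, mean_influence = 0, n = 50)
  fit0 <- fit_center_surround(prof0, cell_type = NULL)
  expect_lt(abs(fit0$amp_center), 1e-3)
  expect_lt(abs(fit0$amp_surround), 1e-3)

  expect_error(fit_center_surround(prof[1:4, ], cell_type = NULL), "6 bins")
})
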