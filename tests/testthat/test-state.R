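# minimal hand-built pm_influence carrier for the quartile functions
fake_infl <- function(pre, post, stim_table, records) {
  structure(list(records = records,
                 aligned = list(pre = pre, post = post,
                                stim_table = stim_table),
                 exclude_radius = 25),
            class = "pm_influence")
}

test_that("prestimulus speed is the mean over the 20 preceding frames", {
  expect_equal(as.numeric(prestim_speed(rep(4, 100), c(30, 60, 90))),
               rep(4, 3))
  # ramp 0, 1, ..., N-1 (frame f carries speed f-1): onset frame 31
  # averages speeds 10..29
  sp <- prestim_speed(0:199, 31)
  expect_equal(as.numeric(sp), 19.5)
  expect_equal(as.numeric(prestim_speed(rep(0, 100), c(40, 80))), c(0, 0))
  sp2 <- prestim_speed(rep(1, 100), c(5, 50))
  expect_equal(attr(sp2, "kept"), c(FALSE, TRUE))
  expect_error(prestim_speed(rep(1, 100), c(3, 8)), "dropped")
})

test_that("quartile assignment is a within-session partition with ties down", {
  qa <- assign_quartiles(c(0, 0, 0, 0, 1, 2, 3, 4))
  expect_equal(qa$trial_quartile[1:4], rep(1L, 4))
  expect_true(all(qa$trial_quartile %in% 1:4))
  # oracle: boundaries are the type-7 percentiles
  sp <- c(0, 0, 0, 0, 1, 2, 3, 4)
  expect_equal(qa$boundaries,
               as.numeric(quantile(sp, c(.25, .5, .75), type = 7)))

  expect_warning(qa2 <- assign_quartiles(rep(2, 8)), "equal")
  expect_true(qa2$degenerate)
  expect_true(all(qa2$trial_quartile == 1L))

  # every usable trial lands in exactly one quartile
  set.seed(1)
  sp3 <- c(rep(0, 30), rlnorm(30, 2, 0.4))
  qa3 <- assign_quartiles(sp3)
  expect_equal(length(qa3$trial_quartile), 60)
  expect_equal(sum(table(qa3$trial_quartile)), 60)
  # boundary ties go to the lower quartile
  b <- qa3$boundaries
  at_b <- which(sp3 == b[2])
  if (length(at_b) > 0) expect_true(all(qa3$trial_quartile[at_b] <= 2))

  expect_error(assign_quartiles(c(1, 2, 3)), "at least 4")
})

test_that("per-quartile influence equals a brute-force trial-subset oracle", {
  set.seed(12)
  n <- 6; n_ev <- 40
  pre <- matrix(rnorm(n * n_ev), n, n_ev)
  post <- matrix(rnorm(n * n_ev), n, n_ev)
  stim <- data.frame(target_id = rep(c(1, 2), each = 20),
                     onset_frame = seq(100, by = 50, length.out = n_ev))
  records <- data.frame(target_id = rep(c(1, 2), each = 2),
                        neuron_id = c(3, 4, 5, 6),
                        neuron_type = c("NonSOM", "SOM", "NonSOM", "NonSOM"),
                        influence = 1, sig_class = "positive",
                        excluded = FALSE, distance_um = 100)
  infl <- fake_infl(pre, post, stim, records)
  qa <- assign_quartiles(c(rep(0, 10), rlnorm(30, 1.5, 0.3)))
  out <- influence_by_quartile(infl, qa)
  for (i in seq_len(nrow(out$pairs))) {
    row <- out$pairs[i, ]
    cols <- which(stim$target_id == row$target_id &
                    qa$trial_quartile == row$quartile)
    or <- bf_influence(pre[row$neuron_id, cols], post[row$neuron_id, cols])
    expect_equal(row$influence, or, tolerance = 1e-12)
  }
  # summary means agree with a direct aggregation
  agg <- out$summary
  for (i in seq_len(nrow(agg))) {
    sub <- out$pairs[out$pairs$quartile == agg$quartile[i] &
                       out$pairs$neuron_type == agg$cell_type[i], ]
    expect_equal(agg$mean_influence[i], mean(sub$influence, na.rm = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("zero-influence pairs yield near-zero quartile means", {
  set.seed(5)
  n <- 4; n_ev <- 80
  base <- matrix(rnorm(n * n_ev), n, n_ev)
  stim <- data.frame(target_id = rep(1:2, each = 40),
                     onset_frame = seq_len(n_ev) * 40)
  records <- data.frame(target_id = c(1, 2), neuron_id = c(3, 4),
                        neuron_type = "NonSOM", influence = 0,
                        sig_class = "positive", excluded = FALSE,
                        distance_um = 100)
  infl <- fake_infl(base, matrix(rnorm(n * n_ev), n, n_ev), stim, records)
  qa <- assign_quartiles(runif(n_ev))
  out <- influence_by_quartile(infl, qa)
  expect_true(all(abs(out$summary$mean_influence) < 0.5))
})

test_that("per-quartile activity means match a direct recomputation", {
  set.seed(6)
  n <- 5; n_ev <- 32
  pre <- matrix(rnorm(n * n_ev, 1), n, n_ev)
  stim <- data.frame(target_id = rep(1, n_ev), onset_frame = seq_len(n_ev) * 40)
  infl <- fake_infl(pre, pre + 0.1, stim, data.frame())
  qa <- assign_quartiles(runif(n_ev))
  ct <- c("SOM", "NonSOM", "NonSOM", "SOM", "NonSOM")
  out <- activity_by_quartile(infl, qa, ct)
  for (q in 1:4) {
    cols <- which(qa$trial_quartile == q)
    for (cty in c("SOM", "NonSOM")) {
      got <- out$summary$mean_activity[out$summary$quartile == q &
                                         out$summary$cell_type == cty]
      expect_equal(got, mean(pre[ct == cty, cols]), tolerance = 1e-12)
    }
  }
  # constant activity: equal means across quartiles
  infl_c <- fake_infl(matrix(2, n, n_ev), matrix(2, n, n_ev), stim,
                      data.frame())
  out_c <- activity_by_quartile(infl_c, qa, ct)
  expect_true(all(out_c$summary$mean_activity == 2))
})
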