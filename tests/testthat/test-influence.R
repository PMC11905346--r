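test_that("trial alignment produces the stated pre/post window means", {
  # constant trace: pre = post = constant
  tw <- align_trials(rep(3, 200), c(50, 100, 150))
  expect_equal(tw$pre, rep(3, 3))
  expect_equal(tw$post, rep(3, 3))

  # +1 step exactly at each onset: post - pre = 1 per trial
  on <- c(60, 140, 220)
  x <- numeric(300)
  for (o in on) x[o:(o + 15)] <- 1
  tw <- align_trials(x, on)
  expect_equal(tw$post - tw$pre, rep(1, 3))

  # brute-force windowing oracle on a random trace
  set.seed(2)
  y <- rnorm(500)
  on2 <- c(30, 101, 250, 333, 480)
  tw2 <- align_trials(y, on2)
  or <- bf_window_means(y, on2)
  expect_equal(tw2$pre, or$pre, tolerance = 1e-12)
  expect_equal(tw2$post, or$post, tolerance = 1e-12)

  # onsets too close to the edge are dropped, none usable is an error
  expect_message(tw3 <- align_trials(y, c(5, 250)), "dropped")
  expect_equal(length(tw3$pre), 1)
  expect_error(suppressMessages(align_trials(y, c(3, 498))), "zero usable")
})

test_that("influence is mean over sd of the per-trial difference", {
  expect_equal(as.numeric(compute_influence(
    list(pre = rep(0, 4), post = c(0, 0, 0, 0)))), 0)

  # hand computation: d = (2,0,1,1), mean 1, sd sqrt(2/3)
  v <- compute_influence(list(pre = rep(0, 4), post = c(2, 0, 1, 1)))
  expect_equal(as.numeric(v), 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_false(attr(v, "degenerate"))

  # degenerate: zero sd, nonzero mean
  vd <- compute_influence(list(pre = rep(0, 3), post = rep(2, 3)))
  expect_true(is.na(vd))
  expect_true(attr(vd, "degenerate"))

  expect_error(compute_influence(list(pre = 1, post = 2)), "insufficient")
})

test_that("influence is shift-invariant and sign-equivariant", {
  set.seed(7)
  pre <- rnorm(30); post <- rnorm(30)
  v0 <- as.numeric(compute_influence(list(pre = pre, post = post)))
  v_shift <- as.numeric(compute_influence(list(pre = pre + 5, post = post + 5)))
  expect_equal(v0, v_shift, tolerance = 1e-12)
  v_flip <- as.numeric(compute_influence(list(pre = post, post = pre)))
  expect_equal(v_flip, -v0, tolerance = 1e-12)
})

test_that("classification against the null uses strict 1%/99% tails", {
  th <- c(-0.5, 0.5)
  expect_equal(classify_influence(0.5, th), "none")    # tie -> none
  expect_equal(classify_influence(10, th), "positive")
  expect_equal(classify_influence(-10, th), "negative")
  expect_equal(classify_influence(0, th), "none")
  expect_true(is.na(classify_influence(NA_real_, th)))
  expect_error(classify_influence(1, c(NA, 1)), "finite")
})

test_that("shuffle nulls are deterministic under a fixed seed", {
  s <- tiny_session(seed = 5)
  act <- preprocess_session(s)
  tid <- s$targets$target_id[1]
  th1 <- shuffle_null(act$dff, s$stim_table, tid, n_shuffles = 100, seed = 9)
  th2 <- shuffle_null(act$dff, s$stim_table, tid, n_shuffles = 100, seed = 9)
  expect_identical(th1, th2)
  expect_true(all(th1[, "upper"] >= th1[, "lower"]))
  # pool smaller than the trial count is an error
  one_target <- s$stim_table[s$stim_table$target_id == tid, ]
  expect_error(shuffle_null(act$dff, one_target, tid, n_shuffles = 10),
               "shuffle-pool")
})

test_that("proximity exclusion applies the 25 um rule on Euclidean distance", {
  pos <- rbind(c(0, 0), c(3, 4), c(30, 40))
  rec <- data.frame(target_id = c(1, 1), neuron_id = c(2, 3))
  out <- proximity_exclusion(rec, pos)
  expect_equal(out$distance_um, c(5, 50))
  expect_equal(out$excluded, c(TRUE, FALSE))

  # brute-force distance filter on random geometry
  set.seed(3)
  pos2 <- matrix(runif(100, 0, 300), 50, 2)
  rec2 <- expand.grid(target_id = 1:5, neuron_id = 6:50)
  out2 <- proximity_exclusion(rec2, pos2, radius = 60)
  kept_bf <- 0
  for (i in seq_len(nrow(rec2))) {
    d <- sqrt(sum((pos2[rec2$target_id[i], ] - pos2[rec2$neuron_id[i], ])^2))
    if (d >= 60) kept_bf <- kept_bf + 1
  }
  expect_equal(sum(!out2$excluded), kept_bf)

  expect_error(proximity_exclusion(data.frame(target_id = 1, neuron_id = 99),
                                   pos), "position")
})

test_that("target success requires a positive self-response; controls fail", {
  expect_true(target_success(5, c(-0.4, 0.4)))
  expect_false(target_success(0.1, c(-0.4, 0.4)))
  expect_false(target_success(-3, c(-0.4, 0.4)))

  # on a null session (direct drive only) the shuffle null is exactly
  # exchangeable: opsin targets succeed, controls fail at the 1% rate
  s <- generate_null_session(gt_params(n_neurons = 60, som_fraction = 0.12,
                                       n_targets = 6, n_control_targets = 4,
                                       n_repeats = 25, seed = 5))
  act <- preprocess_session(s)
  infl <- influence_map(s, act, n_shuffles = 300, seed = 2)
  tg <- infl$targets
  # strong direct drive: all opsin targets successfully stimulated
  expect_true(all(tg$successful[!tg$control]))
  # non-opsin control targets have no direct effect
  expect_true(all(!tg$successful[tg$control]))
  # records come only from successful non-control targets
  expect_true(all(infl$records$target_id %in% tg$target_id[!tg$control]))
  # a target with zero direct effect is (almost surely) not successful:
  # its self influence sits inside the null band
  expect_true(all(abs(tg$self_influence[tg$control]) < 1))
})

test_that("excluded records carry no significance class", {
  s <- tiny_session(seed = 5)
  act <- preprocess_session(s)
  infl <- influence_map(s, act, n_shuffles = 200, seed = 2)
  rec <- infl$records
  expect_true(all(is.na(rec$sig_class[rec$excluded])))
  expect_true(all(!is.na(rec$influence[!rec$excluded])))
  expect_true(all(rec$distance_um >= 0))
})

test_that("dF/F and event traces give concordant influence estimates", {
  s <- tiny_session(seed = 15, n_repeats = 40)
  act <- preprocess_session(s)
  i_dff <- influence_map(s, act, trace = "dff", n_shuffles = 200, seed = 2)
  i_ev <- influence_map(s, act, trace = "events", n_shuffles = 200, seed = 2)
  key <- function(r) paste(r$target_id, r$neuron_id)
  m <- match(key(i_dff$records), key(i_ev$records))
  ok <- !is.na(m) & !i_dff$records$excluded
  a <- i_dff$records$influence[ok]
  b <- i_ev$records$influence[m[ok]]
  expect_gt(cor(a, b, use = "complete.obs"), 0.3)
  # strong dF/F effects keep their sign in the event trace
  strong <- ok & abs(i_dff$records$influence) > 0.5
  if (sum(strong, na.rm = TRUE) > 5) {
    sa <- sign(i_dff$records$influence[strong])
    sb <- sign(i_ev$records$influence[match(key(i_dff$records), key(i_ev$records))[strong]])
    expect_gt(mean(sa == sb, na.rm = TRUE), 0.7)
  }
})
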