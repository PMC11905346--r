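# Brute-force reference implementations used as independent oracles.
# These are deliberately simple loops, kept free of any code path shared
# with the package internals.

bf_window_means <- function(trace, onsets, pre_len = 10, post_len = 10) {
  pre <- numeric(0); post <- numeric(0)
  for (o in onsets) {
    if (o <= pre_len || o + post_len > length(trace)) next
    s1 <- 0
    for (f in (o - pre_len):(o - 1)) s1 <- s1 + trace[f]
    s2 <- 0
    for (f in (o + 1):(o + post_len)) s2 <- s2 + trace[f]
    pre <- c(pre, s1 / pre_len)
    post <- c(post, s2 / post_len)
  }
  list(pre = pre, post = post)
}

bf_influence <- function(pre, post) {
  d <- post - pre
  m <- sum(d) / length(d)
  v <- sum((d - m)^2) / (length(d) - 1)
  m / sqrt(v)
}

bf_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

bf_bin_means <- function(values, distances, edges) {
  out <- numeric(length(edges) - 1)
  cnt <- integer(length(edges) - 1)
  for (i in seq_along(values)) {
    for (b in seq_len(length(edges) - 1)) {
      if (distances[i] >= edges[b] && distances[i] < edges[b + 1]) {
        out[b] <- out[b] + values[i]
        cnt[b] <- cnt[b] + 1
      }
    }
  }
  list(mean = ifelse(cnt > 0, out / pmax(cnt, 1), NA_real_), n = cnt)
}

# small fast session shared across unit-test files
tiny_session <- function(seed = 5, n_repeats = 25, ...) {
  generate_session(gt_params(n_neurons = 60, som_fraction = 0.12,
                             n_targets = 6, n_control_targets = 2,
                             n_repeats = n_repeats, seed = seed, ...))
}

# compact full-pipeline summary for one area regime; large objects are
# dropped so several regimes fit in memory side by side
area_summary <- function(params, shuffle_seed = 1, n_shuffles = 1000,
                         tuning = FALSE) {
  s <- generate_session(params)
  act <- preprocess_session(s)
  infl <- influence_map(s, act, n_shuffles = n_shuffles, seed = shuffle_seed)
  ret <- infl$records[!infl$records$excluded, , drop = FALSE]
  fit <- fit_center_surround(distance_binned_influence(infl$records,
                                                       bin_width = 20))
  prof <- distance_binned_influence(infl$records)
  far <- prof$mean_influence[prof$cell_type == "NonSOM" &
                               prof$bin_center >= 200]
  posd <- ret$distance_um[!is.na(ret$sig_class) &
                            ret$sig_class == "positive" &
                            ret$neuron_type == "NonSOM"]
  ax <- stimulus_axes(s, infl)
  wbd <- weights_by_distance(ax$weights)
  sp <- prestim_speed(s$run_speed, infl$aligned$stim_table$onset_frame)
  qa <- assign_quartiles(sp)
  ibq <- influence_by_quartile(infl, qa)
  abq <- activity_by_quartile(infl, qa, s$labels$cell_type)$summary
  nt <- noise_correlation_table(s, infl)
  rel <- correlation_influence_relation(nt, infl$records)
  tun <- NULL
  if (tuning && nrow(s$tone_table) > 0) {
    tt <- tuning_table(act$events, s$tone_table, params$frame_rate, seed = 5)
    tun <- list(table = tt,
                true_bf = s$ground_truth$true_bf,
                test = tuning_shuffle_test(infl$records, tt, seed = 5))
  }
  idx <- cbind(match(as.character(ret$target_id), rownames(s$true_effect)),
               ret$neuron_id)
  list(frac_pos = mean(ret$sig_class == "positive"),
       frac_neg = mean(ret$sig_class == "negative"),
       sigma_center = fit$sigma_center, amp_surround = fit$amp_surround,
       fit_converged = fit$converged,
       mean_far_influence = mean(far),
       median_pos_dist = if (length(posd) > 0) median(posd) else NA_real_,
       pos_w_50 = wbd$mean_abs_weight[wbd$subset == "positive" &
                                        wbd$bin_center == 50],
       neg_w_far = mean(wbd$mean_abs_weight[wbd$subset == "negative" &
                                              wbd$bin_center >= 150],
                        na.rm = TRUE),
       quartile_pairs = ibq$pairs,
       quartile_summary = ibq$summary,
       activity_quartiles = abq,
       noisecorr = rel,
       tuning = tun,
       spearman_truth = cor(s$true_effect[idx], ret$influence,
                            method = "spearman"),
       n_successful = sum(infl$targets$successful & !infl$targets$control),
       n_control_successful = sum(infl$targets$successful &
                                    infl$targets$control))
}
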