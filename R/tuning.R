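#' Tone-aligned responses per neuron and frequency
#'
#' Each neuron's trace is z-scored over the whole recording; the response to
#' one tone presentation is the mean z-scored activity over the 1 s tone
#' window minus the mean over the 10-frame prestimulus baseline. Responses
#' are averaged per frequency. A per-neuron responsiveness flag is computed
#' with a sign-flip permutation test of the per-trial (tone - baseline)
#' differences pooled across frequencies (two-sided, alpha = 0.05).
#'
#' @param activity (neurons x frames) matrix; the deconvolved event traces
#'   are the conventional choice for tone responses.
#' @param tone_table data frame with `frequency_khz` and `onset_frame`.
#' @param frame_rate imaging rate (Hz); the tone window is `frame_rate`
#'   frames (1 s).
#' @param baseline_len baseline window (frames).
#' @param n_iterations iterations for the responsiveness permutation test.
#' @param alpha responsiveness significance level.
#' @param seed RNG seed for the responsiveness test.
#' @return list: `responses` (neurons x frequencies matrix, columns named by
#'   kHz), `trial_responses` (neurons x tone events), `responsive` (logical
#'   per neuron), `frequencies_khz`.
#' @export
tone_aligned_response <- function(activity, tone_table, frame_rate,
                                  baseline_len = 10, n_iterations = 500,
                                  alpha = 0.05, seed = 1) {
  if (nrow(tone_table) == 0) stop("empty tone table")
  z <- activity
  mu <- rowMeans(z)
  s <- apply(z, 1, sd)
  s[s == 0] <- 1
  z <- (z - mu) / s
  tone_len <- round(frame_rate)
  n_fr <- ncol(z)
  ok <- tone_table$onset_frame > baseline_len &
    (tone_table$onset_frame + tone_len - 1) <= n_fr
  tt <- tone_table[ok, , drop = FALSE]
  tr <- matrix(0, nrow(z), nrow(tt))
  for (e in seq_len(nrow(tt))) {
    o <- tt$onset_frame[e]
    tr[, e] <- rowMeans(z[, o:(o + tone_len - 1), drop = FALSE]) -
      rowMeans(z[, (o - baseline_len):(o - 1), drop = FALSE])
  }
  freqs <- sort(unique(tt$frequency_khz))
  resp <- sapply(freqs, function(f)
    rowMeans(tr[, tt$frequency_khz == f, drop = FALSE]))
  colnames(resp) <- as.character(freqs)

  ## responsiveness: sign-flip null on the pooled per-trial differences
  set.seed(seed)
  n_ev <- ncol(tr)
  signs <- matrix(sample(c(-1, 1), n_ev * n_iterations, replace = TRUE),
                  n_ev, n_iterations)
  null_means <- abs(tr %*% signs) / n_ev
  obs <- abs(rowMeans(tr))
  pvals <- (rowSums(null_means >= obs) + 1) / (n_iterations + 1)
  list(responses = resp, trial_responses = tr,
       responsive = pvals < alpha, frequencies_khz = freqs)
}

#' Fit a Gaussian tuning curve and extract the best frequency
#'
#' Least-squares fit, in log2 frequency, of
#' `a * exp(-(x - c)^2 / (2 w^2)) + b` to a neuron's per-frequency
#' responses, with bounded center `c` in `[2, 5]` log2-kHz (the tested 4-32
#' kHz range) and width `w` in `[0.1, 4]` octaves; the bounds keep 6-point
#' fits well behaved. The best frequency is `2^c` kHz. Flat response
#' profiles are flagged non-selective and get no BF.
#'
#' @param responses numeric vector of per-frequency responses.
#' @param frequencies_khz the tested frequencies (default 4, 8, 12, 16, 24,
#'   32 kHz).
#' @param responsive responsiveness flag carried into the record.
#' @param min_r2 minimum fit R^2 for a BF to be reported.
#' @return a one-row data frame (`TuningRecord`): `responsive`, `selective`,
#'   `bf_khz`, `bf_log2`, `fit_amplitude`, `fit_center`, `fit_width`,
#'   `fit_r2`.
#' @export
fit_best_frequency <- function(responses,
                               frequencies_khz = c(4, 8, 12, 16, 24, 32),
                               responsive = TRUE, min_r2 = 0.5) {
  x <- log2(frequencies_khz)
  y <- as.numeric(responses)
  rec <- data.frame(responsive = responsive, selective = FALSE,
                    bf_khz = NA_real_, bf_log2 = NA_real_,
                    fit_amplitude = NA_real_, fit_center = NA_real_,
                    fit_width = NA_real_, fit_r2 = NA_real_)
  if (!responsive || sd(y) == 0) return(rec)
  sse <- function(par) sum((y - (par[1] *
    exp(-(x - par[2])^2 / (2 * par[3]^2)) + par[4]))^2)
  amp0 <- max(y) - min(y)
  best <- NULL
  for (c0 in c(2.5, 3, 3.5, 4, 4.5)) for (w0 in c(0.5, 1.5)) {
    fit <- tryCatch(
      optim(c(amp0, c0, w0, min(y)), sse, method = "L-BFGS-B",
            lower = c(0, 2, 0.1, min(y) - 2 * abs(amp0) - 1e-6),
            upper = c(10 * amp0 + 1, 5, 4, max(y) + 1e-6)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) return(rec)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - best$value / tss else 0
  rec$fit_amplitude <- best$par[1]
  rec$fit_center <- best$par[2]
  rec$fit_width <- best$par[3]
  rec$fit_r2 <- r2
  if (r2 >= min_r2 && best$par[1] > 0) {
    rec$selective <- TRUE
    rec$bf_log2 <- min(max(best$par[2], 2), 5)
    rec$bf_khz <- 2^rec$bf_log2
  }
  rec
}

#' Best-frequency records for every neuron of a session
#'
#' Convenience driver: [tone_aligned_response()] followed by
#' [fit_best_frequency()] per neuron.
#'
#' @param activity (neurons x frames) activity matrix.
#' @param tone_table the session's tone table.
#' @param frame_rate imaging rate (Hz).
#' @param ... passed to [tone_aligned_response()].
#' @return data frame with one `TuningRecord` row per neuron (`neuron_id`
#'   first column).
#' @export
tuning_table <- function(activity, tone_table, frame_rate, ...) {
  ta <- tone_aligned_response(activity, tone_table, frame_rate, ...)
  recs <- lapply(seq_len(nrow(activity)), function(i)
    fit_best_frequency(ta$responses[i, ], ta$frequencies_khz,
                       responsive = ta$responsive[i]))
  cbind(data.frame(neuron_id = seq_len(nrow(activity))), do.call(rbind, recs))
}

#' Best-frequency difference in octaves
#'
#' `|log2(BF_a) - log2(BF_b)|`; symmetric by construction.
#'
#' @param bf_a,bf_b best frequencies in kHz.
#' @return octaves (`NA` when either BF is missing).
#' @examples
#' delta_bf(8, 16)   # 1 octave
#' @export
delta_bf <- function(bf_a, bf_b) abs(log2(bf_a) - log2(bf_b))

#' Frequency-preference shuffle test of the influence--tuning relationship
#'
#' Observed statistic: the Pearson correlation between influence and the
#' target-neuron best-frequency difference (octaves) over all pairs with
#' both BFs defined. The null shuffles the BF labels across all neurons in
#' the field of view (`n_shuffles` times, default 500) and recomputes the
#' correlation; `p` is the fraction of shuffles with a correlation at least
#' as negative as observed (a negative correlation means like-to-like:
#' stronger influence between similarly tuned neurons), floored at
#' `1 / n_shuffles`.
#'
#' @param records influence records (retained pairs are used).
#' @param tuning a `tuning_table()` data frame (needs `neuron_id`,
#'   `bf_log2`).
#' @param n_shuffles number of BF-label shuffles.
#' @param seed RNG seed.
#' @return list: `observed_r`, `p`, `n_pairs`, `n_shuffles`, `null_r`
#'   (shuffle distribution), `seed`.
#' @export
tuning_shuffle_test <- function(records, tuning, n_shuffles = 500, seed = 1) {
  bf <- tuning$bf_log2[order(tuning$neuron_id)]
  rec <- records[!records$excluded & !is.na(records$influence), , drop = FALSE]
  ok <- !is.na(bf[rec$target_id]) & !is.na(bf[rec$neuron_id])
  rec <- rec[ok, , drop = FALSE]
  if (nrow(rec) < 3) stop("too few pairs with defined best frequencies")
  if (length(unique(bf[!is.na(bf)])) < 2)
    stop("test undefined: all best frequencies identical")
  dbf <- abs(bf[rec$target_id] - bf[rec$neuron_id])
  obs <- cor(rec$influence, dbf)
  ## BF labels are permuted among the neurons that have a defined BF, so
  ## the multiset of BFs and the pair set are preserved in every shuffle
  set.seed(seed)
  has_bf <- which(!is.na(bf))
  null_r <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    perm <- bf
    perm[has_bf] <- bf[sample(has_bf)]
    dbf_s <- abs(perm[rec$target_id] - perm[rec$neuron_id])
    null_r[b] <- if (sd(dbf_s) == 0) NA_real_ else cor(rec$influence, dbf_s)
  }
  p <- max(sum(null_r <= obs, na.rm = TRUE), 1) / n_shuffles
  list(observed_r = obs, p = p, n_pairs = nrow(rec),
       n_shuffles = n_shuffles, null_r = null_r, seed = seed)
}
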