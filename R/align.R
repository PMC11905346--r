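#' Align an activity trace on stimulation onsets
#'
#' For each onset, computes the mean activity over the `pre_len` frames
#' before the onset (frames `onset - pre_len` to `onset - 1`) and the
#' `post_len` frames after it (frames `onset + 1` to `onset + post_len`).
#' The onset frame itself, which contains the stimulation artifact, is part
#' of neither window. With 30 Hz imaging the default 10-frame windows span
#' 333 ms. Onsets too close to a trace edge are dropped (and reported).
#'
#' @param activity single-neuron activity trace.
#' @param onsets stimulation onset frames (1-based).
#' @param pre_len,post_len window lengths in frames.
#' @return a `pm_trialwindows` list: `pre`, `post` (per-trial window means),
#'   `onsets_used`, `n_dropped`.
#' @export
align_trials <- function(activity, onsets, pre_len = 10, post_len = 10) {
  n <- length(activity)
  ok <- onsets > pre_len & (onsets + post_len) <= n
  if (sum(!ok) > 0)
    message(sum(!ok), " trial(s) dropped: too close to trace edge")
  onsets <- onsets[ok]
  if (length(onsets) == 0) stop("zero usable trials")
  pre <- vapply(onsets,
                function(o) mean(activity[(o - pre_len):(o - 1)]), 0)
  post <- vapply(onsets,
                 function(o) mean(activity[(o + 1):(o + post_len)]), 0)
  structure(list(pre = pre, post = post, onsets_used = onsets,
                 n_dropped = sum(!ok)),
            class = "pm_trialwindows")
}

## matrix version: window means for all neurons at once.
## Returns pre / post as (neurons x events) matrices.
window_means <- function(act, onsets, pre_len = 10, post_len = 10) {
  n_frames <- ncol(act)
  ok <- onsets > pre_len & (onsets + post_len) <= n_frames
  onsets <- onsets[ok]
  if (length(onsets) == 0) stop("zero usable trials")
  pre <- matrix(0, nrow(act), length(onsets))
  post <- matrix(0, nrow(act), length(onsets))
  for (e in seq_along(onsets)) {
    o <- onsets[e]
    pre[, e] <- rowMeans(act[, (o - pre_len):(o - 1), drop = FALSE])
    post[, e] <- rowMeans(act[, (o + 1):(o + post_len), drop = FALSE])
  }
  list(pre = pre, post = post, kept = ok)
}
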