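#' Trial-normalized influence statistic
#'
#' The influence of a target on a neuron is the mean over trials of the
#' per-trial difference `d = post - pre` (window means from
#' [align_trials()]), divided by the sample standard deviation (n - 1) of
#' that difference across trials. If the SD is zero the statistic is 0 when
#' the mean is also zero, and the pair is flagged degenerate otherwise
#' (never a division by zero).
#'
#' @param tw a `pm_trialwindows` object (or any list with numeric `pre` and
#'   `post` of equal length >= 2).
#' @return a numeric scalar; `NA` with attribute `degenerate = TRUE` for the
#'   degenerate sd-zero, nonzero-mean case.
#' @examples
#' compute_influence(list(pre = c(0, 0, 0, 0), post = c(2, 0, 1, 1)))
#' @export
compute_influence <- function(tw) {
  d <- tw$post - tw$pre
  if (length(d) < 2) stop("insufficient trials (< 2)")
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(structure(0, degenerate = FALSE))
    return(structure(NA_real_, degenerate = TRUE))
  }
  structure(m / s, degenerate = FALSE)
}

## row-wise influence for all neurons over a set of event columns of the
## per-event difference matrix D (neurons x events). Two-pass SD.
.influence_rows <- function(D, cols) {
  k <- length(cols)
  if (k < 2) stop("insufficient trials (< 2)")
  sub <- D[, cols, drop = FALSE]
  m <- rowMeans(sub)
  s <- sqrt(rowSums((sub - m)^2) / (k - 1))
  val <- m / s
  zero <- s == 0
  deg <- zero & m != 0
  val[zero & m == 0] <- 0
  val[deg] <- NA_real_
  list(value = val, degenerate = deg)
}

#' Trial-shuffle null distribution for one target
#'
#' Builds the per-pair null used to classify influence: for each shuffle the
#' target's onset set is replaced with an equal-size draw (without
#' replacement) from the pooled onsets of all *other* targets, and the
#' influence statistic is recomputed for every neuron. Resampling real
#' stimulation onsets (rather than arbitrary time points) preserves slow
#' drift and the temporal density of stimulation. Returns the per-neuron
#' 1st and 99th percentiles of the null.
#'
#' @param activity (neurons x frames) activity matrix (dF/F or events).
#' @param stim_table data frame with `target_id` and `onset_frame`.
#' @param target_id the target whose null is being built.
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed RNG seed.
#' @param pre_len,post_len window lengths in frames.
#' @param probs the two null percentiles (lower, upper).
#' @return matrix (neurons x 2) of null thresholds, columns `lower`, `upper`.
#' @export
shuffle_null <- function(activity, stim_table, target_id, n_shuffles = 1000,
                         seed = 1, pre_len = 10, post_len = 10,
                         probs = c(0.01, 0.99)) {
  wm <- window_means(activity, stim_table$onset_frame, pre_len, post_len)
  D <- wm$post - wm$pre
  tid <- stim_table$target_id[wm$kept]
  own <- which(tid == target_id)
  pool <- which(tid != target_id)
  set.seed(seed)
  .shuffle_thresholds(D, pool, length(own), n_shuffles, probs)
}

## fast core: thresholds from BLAS-computed null influences.
## D: (neurons x events) differences; pool: candidate event columns;
## k: trials per draw. Uses the one-pass variance (adequate for thresholds).
.shuffle_thresholds <- function(D, pool, k, n_shuffles, probs = c(0.01, 0.99)) {
  npool <- length(pool)
  if (npool < k)
    stop("shuffle-pool error: pool (", npool, ") smaller than trial count (",
         k, ")")
  Dp <- D[, pool, drop = FALSE]
  idx <- vapply(seq_len(n_shuffles), function(b) sample.int(npool, k),
                integer(k))
  S <- matrix(0, npool, n_shuffles)
  S[cbind(as.vector(idx), rep(seq_len(n_shuffles), each = k))] <- 1
  M1 <- (Dp %*% S) / k
  M2 <- (Dp * Dp) %*% S
  V <- (M2 - k * M1^2) / (k - 1)
  V[V < 0] <- 0
  null <- M1 / sqrt(V)
  null[!is.finite(null)] <- 0
  th <- t(apply(null, 1, quantile, probs = probs, names = FALSE, type = 7))
  colnames(th) <- c("lower", "upper")
  th
}

#' Classify an observed influence against its shuffle null
#'
#' `positive` if the observed value is strictly greater than the upper
#' (99th-percentile) null threshold, `negative` if strictly less than the
#' lower (1st-percentile) threshold, `none` otherwise. Ties are `none`.
#'
#' @param observed numeric vector of observed influence values.
#' @param null_thresholds matrix with columns `lower`, `upper` (one row per
#'   observation, or a single row recycled), or a length-2 vector.
#' @return character vector in `{"positive", "negative", "none"}` (`NA` for
#'   `NA` observations).
#' @export
classify_influence <- function(observed, null_thresholds) {
  if (is.null(dim(null_thresholds)))
    null_thresholds <- matrix(null_thresholds, 1, 2)
  if (nrow(null_thresholds) == 1 && length(observed) > 1)
    null_thresholds <- null_thresholds[rep(1, length(observed)), , drop = FALSE]
  if (any(!is.finite(null_thresholds))) stop("thresholds must be finite")
  out <- rep(NA_character_, length(observed))
  ok <- !is.na(observed)
  out[ok] <- "none"
  out[ok & observed > null_thresholds[, 2]] <- "positive"
  out[ok & observed < null_thresholds[, 1]] <- "negative"
  out
}

#' Flag pairs within the direct-stimulation exclusion radius
#'
#' Stores the 2-D Euclidean intersomatic distance for every record and flags
#' as excluded any neuron closer than `radius` (default 25 um) to its
#' target, since such neurons can be directly driven by the stimulation
#' spiral rather than through the network.
#'
#' @param records data frame with `target_id` and `neuron_id` columns.
#' @param positions (neurons x 2) centroid positions in um, rows indexed by
#'   neuron id.
#' @param radius exclusion radius in um.
#' @return `records` with `distance_um` and `excluded` columns (an existing
#'   `excluded` flag is OR-ed with the proximity rule).
#' @export
proximity_exclusion <- function(records, positions, radius = 25) {
  if (any(records$target_id > nrow(positions)) ||
      any(records$neuron_id > nrow(positions)))
    stop("missing position for some neuron id")
  pt <- positions[records$target_id, , drop = FALSE]
  pn <- positions[records$neuron_id, , drop = FALSE]
  if (any(!is.finite(pt)) || any(!is.finite(pn)))
    stop("missing position for some neuron id")
  d <- sqrt(rowSums((pt - pn)^2))
  records$distance_um <- d
  prox <- d < radius
  records$excluded <- if ("excluded" %in% names(records))
    records$excluded | prox else prox
  records
}

#' Was a target successfully stimulated?
#'
#' A target counts as successfully stimulated when its own influence
#' statistic (pre/post windows on its own trace) is classified positive
#' against its trial-shuffle null. Only successful, non-control targets
#' contribute influence records.
#'
#' @param self_influence the target's own observed influence value.
#' @param self_thresholds length-2 vector (or 1 x 2 matrix) of the target's
#'   own null thresholds.
#' @return logical.
#' @export
target_success <- function(self_influence, self_thresholds) {
  !is.na(self_influence) &&
    classify_influence(self_influence, self_thresholds) == "positive"
}

#' Compute the full influence map of a session
#'
#' Runs the influence analysis end to end for one session: aligns every
#' neuron on every stimulation, computes the observed influence of each
#' target on each other neuron, builds the per-target trial-shuffle null,
#' classifies each pair, determines target success from the target's own
#' response, and applies the proximity exclusion. Only successful non-control
#' targets contribute records.
#'
#' @param session a `pm_session`.
#' @param activity a `pm_activity` from [preprocess_session()].
#' @param trace which trace to analyze: `"dff"` (default) or `"events"`.
#' @param pre_len,post_len influence windows in frames (default 10 = 333 ms
#'   at 30 Hz).
#' @param n_shuffles shuffles per target for the null.
#' @param seed RNG seed for the shuffles.
#' @param exclude_radius proximity exclusion radius (um).
#' @return an object of class `pm_influence`: list with
#'   \describe{
#'     \item{records}{data frame of (target, neuron) pairs: `target_id`,
#'       `neuron_id`, `neuron_type`, `distance_um`, `influence`,
#'       `sig_class`, `excluded`.}
#'     \item{targets}{per-target data frame: `target_id`, `control`,
#'       `self_influence`, `successful`.}
#'     \item{aligned}{list with the (neurons x events) `pre` and `post`
#'       window-mean matrices and the kept `stim_table`, reused by the
#'       state, noise-correlation and population-axis analyses.}
#'     \item{pre_len, post_len, trace}{analysis settings.}
#'   }
#' @export
influence_map <- function(session, activity, trace = c("dff", "events"),
                          pre_len = 10, post_len = 10, n_shuffles = 1000,
                          seed = 1, exclude_radius = 25) {
  stopifnot(inherits(session, "pm_session"), inherits(activity, "pm_activity"))
  trace <- match.arg(trace)
  act <- activity[[trace]]
  wm <- window_means(act, session$stim_table$onset_frame, pre_len, post_len)
  stim <- session$stim_table[wm$kept, , drop = FALSE]
  D <- wm$post - wm$pre

  tg <- session$targets
  n_t <- nrow(tg)
  n <- nrow(act)
  set.seed(seed)
  obs <- matrix(NA_real_, n_t, n)
  deg <- matrix(FALSE, n_t, n)
  self_inf <- numeric(n_t)
  successful <- logical(n_t)
  sig <- matrix(NA_character_, n_t, n)
  for (k in seq_len(n_t)) {
    tid <- tg$target_id[k]
    own <- which(stim$target_id == tid)
    pool <- which(stim$target_id != tid)
    ir <- .influence_rows(D, own)
    obs[k, ] <- ir$value
    deg[k, ] <- ir$degenerate
    th <- .shuffle_thresholds(D, pool, length(own), n_shuffles)
    sig[k, ] <- classify_influence(ir$value, th)
    self_inf[k] <- ir$value[tid]
    successful[k] <- !is.na(ir$value[tid]) && sig[k, tid] == "positive"
  }
  tg$self_influence <- self_inf
  tg$successful <- successful

  keep <- which(successful & !tg$control)
  rec_list <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    tid <- tg$target_id[k]
    js <- setdiff(seq_len(n), tid)
    rec_list[[i]] <- data.frame(
      target_id = tid,
      neuron_id = js,
      neuron_type = session$labels$cell_type[js],
      influence = obs[k, js],
      sig_class = sig[k, js],
      excluded = deg[k, js],
      stringsAsFactors = FALSE)
  }
  records <- if (length(rec_list) > 0) do.call(rbind, rec_list) else
    data.frame(target_id = integer(0), neuron_id = integer(0),
               neuron_type = character(0), influence = numeric(0),
               sig_class = character(0), excluded = logical(0))
  if (nrow(records) > 0) {
    records <- proximity_exclusion(records, session$positions, exclude_radius)
    records$sig_class[records$excluded] <- NA_character_
  } else {
    records$distance_um <- numeric(0)
  }
  rownames(records) <- NULL
  structure(list(records = records, targets = tg,
                 aligned = list(pre = wm$pre, post = wm$post,
                                stim_table = stim),
                 pre_len = pre_len, post_len = post_len, trace = trace,
                 n_shuffles = n_shuffles, seed = seed,
                 exclude_radius = exclude_radius),
            class = "pm_influence")
}

#' @export
print.pm_influence <- function(x, ...) {
  r <- x$records[!x$records$excluded, , drop = FALSE]
  cat("<pm_influence> ", sum(x$targets$successful & !x$targets$control),
      "/", sum(!x$targets$control), " successful targets, ",
      nrow(r), " retained pairs (",
      round(100 * mean(r$sig_class == "positive"), 2), "% positive, ",
      round(100 * mean(r$sig_class == "negative"), 2), "% negative)\n",
      sep = "")
  invisible(x)
}
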