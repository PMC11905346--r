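#' Population stimulus axis for one target
#'
#' The stimulus axis is the unit vector in population-activity space that
#' points from the population's mean prestimulus activity to its mean
#' response to the target's stimulation:
#' `w = (post_mean - pre_mean) / ||post_mean - pre_mean||`.
#' Unit normalization makes weights comparable across targets; the sign of
#' each weight equals the sign of that neuron's mean post - pre response.
#'
#' @param pre_mean,post_mean per-neuron trial-averaged window means over the
#'   included neurons.
#' @return unit-norm numeric weight vector.
#' @examples
#' stimulus_axis(c(0, 0), c(3, 4))   # (0.6, 0.8)
#' @export
stimulus_axis <- function(pre_mean, post_mean) {
  if (length(pre_mean) != length(post_mean)) stop("dimension mismatch")
  d <- post_mean - pre_mean
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("undefined axis: post_mean equals pre_mean")
  d / nrm
}

#' Project population activity onto a stimulus axis
#'
#' Dot product of the prestimulus-mean-subtracted population activity with
#' the axis weights. Activity equal to `pre_mean` projects to 0; the
#' defining `post_mean` projects to `||post_mean - pre_mean||`.
#'
#' @param activity per-neuron activity vector (one frame or one trial mean)
#'   over the included neurons.
#' @param weights stimulus-axis weights.
#' @param pre_mean the prestimulus mean used to define the axis.
#' @return scalar projection.
#' @export
project_axis <- function(activity, weights, pre_mean) {
  if (length(activity) != length(weights) ||
      length(pre_mean) != length(weights)) stop("dimension mismatch")
  sum((activity - pre_mean) * weights)
}

#' Stimulus axes for every successful target of a session
#'
#' For each successful non-control target, the axis is defined on the
#' trial-averaged pre/post window means (same windows as the influence
#' statistic) over all SOM and Non-SOM neurons at least `exclude_radius` um
#' from the target (the target itself is excluded). Also returns per-trial
#' projections of the post-window population activity onto each axis.
#'
#' @param session a `pm_session`.
#' @param infl a `pm_influence` from [influence_map()] (its cached aligned
#'   window means are reused).
#' @return list with `weights` (long data frame: `target_id`, `neuron_id`,
#'   `neuron_type`, `weight`, `distance_um`) and `projections` (data frame:
#'   `target_id`, `trial`, `projection`).
#' @export
stimulus_axes <- function(session, infl) {
  stopifnot(inherits(infl, "pm_influence"))
  pre <- infl$aligned$pre
  post <- infl$aligned$post
  stim <- infl$aligned$stim_table
  pos <- session$positions
  keep_t <- infl$targets$target_id[infl$targets$successful &
                                     !infl$targets$control]
  wrows <- list(); prows <- list()
  for (tid in keep_t) {
    d <- sqrt((pos[, 1] - pos[tid, 1])^2 + (pos[, 2] - pos[tid, 2])^2)
    incl <- which(d >= infl$exclude_radius & seq_len(nrow(pos)) != tid)
    own <- which(stim$target_id == tid)
    pre_mean <- rowMeans(pre[incl, own, drop = FALSE])
    post_mean <- rowMeans(post[incl, own, drop = FALSE])
    if (all(post_mean == pre_mean)) next
    w <- stimulus_axis(pre_mean, post_mean)
    wrows[[length(wrows) + 1]] <- data.frame(
      target_id = tid, neuron_id = incl,
      neuron_type = session$labels$cell_type[incl],
      weight = w, distance_um = d[incl], stringsAsFactors = FALSE)
    proj <- as.numeric(crossprod(post[incl, own, drop = FALSE] - pre_mean, w))
    prows[[length(prows) + 1]] <- data.frame(
      target_id = tid, trial = seq_along(own), projection = proj)
  }
  list(weights = do.call(rbind, wrows), projections = do.call(rbind, prows))
}

#' Mean stimulus-axis weight magnitude by distance
#'
#' Splits the axis weights into positively and negatively weighted subsets
#' and returns the mean weight magnitude per distance bin for each subset.
#'
#' @param weights numeric weight vector, or the `weights` data frame from
#'   [stimulus_axes()] (column `weight`).
#' @param distances distances to the target (um); ignored when `weights` is
#'   a data frame with a `distance_um` column.
#' @param bin_width bin width in um.
#' @param min_dist,max_dist bin range in um.
#' @return data frame: `subset` ("positive"/"negative"), `bin_center`,
#'   `mean_abs_weight`, `n` (empty bins reported with `n = 0`).
#' @export
weights_by_distance <- function(weights, distances = NULL, bin_width = 50,
                                min_dist = 25, max_dist = 425) {
  if (is.data.frame(weights)) {
    distances <- weights$distance_um
    weights <- weights$weight
  }
  if (length(weights) != length(distances)) stop("weights/distances mismatch")
  edges <- seq(min_dist, max_dist, by = bin_width)
  centers <- head(edges, -1) + bin_width / 2
  bin <- findInterval(distances, edges, rightmost.closed = FALSE)
  rows <- list()
  for (sgn in c("positive", "negative")) {
    sel <- if (sgn == "positive") weights > 0 else weights < 0
    for (b in seq_along(centers)) {
      v <- abs(weights[sel & bin == b & distances < max_dist])
      rows[[length(rows) + 1]] <- data.frame(
        subset = sgn, bin_center = centers[b],
        mean_abs_weight = if (length(v) > 0) mean(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
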