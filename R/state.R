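#' Prestimulus running speed per trial
#'
#' Mean running speed over the `window` frames (default 20, i.e. 660 ms at
#' 30 Hz) preceding each stimulation onset. Onsets with fewer than `window`
#' preceding frames are dropped (and counted).
#'
#' @param run_speed per-frame running speed (cm/s).
#' @param onsets stimulation onset frames (1-based).
#' @param window window length in frames.
#' @return numeric vector of per-trial speeds with attribute `kept`
#'   (logical, which onsets were usable).
#' @export
prestim_speed <- function(run_speed, onsets, window = 20) {
  ok <- onsets > window
  if (all(!ok)) stop("all trials dropped: onsets too early for speed window")
  sp <- vapply(onsets[ok],
               function(o) mean(run_speed[(o - window):(o - 1)]), 0)
  attr(sp, "kept") <- ok
  sp
}

#' Assign trials to within-session running-speed quartiles
#'
#' Cut points are the 25/50/75 percentiles of the within-session prestimulus
#' speed distribution; a trial whose speed ties a boundary goes to the lower
#' quartile. In sessions where the animal is frequently stationary, quartile
#' 1 is the stationary (zero-speed) set. Quartiles are always computed per
#' session, never across sessions.
#'
#' @param speeds per-trial prestimulus speeds of one session.
#' @return a `pm_quartiles` list: `boundaries` (3 cut points),
#'   `trial_quartile` (integer in 1..4 per trial), `degenerate` (TRUE when
#'   all speeds are equal, in which case every trial is quartile 1).
#' @export
assign_quartiles <- function(speeds) {
  if (length(speeds) < 4) stop("need at least 4 usable trials")
  b <- quantile(speeds, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q <- 1L + (speeds > b[1]) + (speeds > b[2]) + (speeds > b[3])
  degenerate <- length(unique(speeds)) == 1
  if (degenerate) warning("all prestimulus speeds equal; all trials in quartile 1")
  structure(list(boundaries = b, trial_quartile = as.integer(q),
                 degenerate = degenerate),
            class = "pm_quartiles")
}

#' Influence by running-speed quartile
#'
#' Recomputes the influence statistic per (target, neuron) pair using only
#' the trials in each running quartile, restricted to pairs that were
#' significantly positively influenced when all trials were considered, and
#' averages within (quartile, cell type). Pairs with fewer than 2 usable
#' trials in a quartile are skipped for that quartile. Significance is not
#' re-assessed per quartile; quartile means are meant to be compared to each
#' other (e.g. with permutation tests).
#'
#' @param infl a `pm_influence` (its aligned window means are reused).
#' @param quartiles a `pm_quartiles` whose `trial_quartile` aligns with the
#'   rows of `infl$aligned$stim_table`.
#' @return list with `summary` (data frame: `quartile`, `cell_type`,
#'   `mean_influence`, `n_pairs`) and `pairs` (long data frame with the
#'   per-pair per-quartile influence).
#' @export
influence_by_quartile <- function(infl, quartiles) {
  stopifnot(inherits(infl, "pm_influence"), inherits(quartiles, "pm_quartiles"))
  stim <- infl$aligned$stim_table
  if (length(quartiles$trial_quartile) != nrow(stim))
    stop("quartile labels do not align with the stimulation table")
  D <- infl$aligned$post - infl$aligned$pre
  rec <- infl$records
  rec <- rec[!rec$excluded & !is.na(rec$sig_class) &
               rec$sig_class == "positive", , drop = FALSE]
  rows <- list()
  for (tid in unique(rec$target_id)) {
    js <- rec$neuron_id[rec$target_id == tid]
    types <- rec$neuron_type[rec$target_id == tid]
    own <- which(stim$target_id == tid)
    for (q in 1:4) {
      cols <- own[quartiles$trial_quartile[own] == q]
      if (length(cols) < 2) next
      ir <- .influence_rows(D, cols)
      rows[[length(rows) + 1]] <- data.frame(
        target_id = tid, neuron_id = js, neuron_type = types, quartile = q,
        influence = ir$value[js], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(target_id = integer(0), neuron_id = integer(0),
               neuron_type = character(0), quartile = integer(0),
               influence = numeric(0))
  agg <- if (nrow(pairs) > 0)
    do.call(rbind, lapply(split(pairs, list(pairs$quartile, pairs$neuron_type),
                                drop = TRUE), function(g) data.frame(
      quartile = g$quartile[1], cell_type = g$neuron_type[1],
      mean_influence = mean(g$influence, na.rm = TRUE),
      n_pairs = sum(!is.na(g$influence)), stringsAsFactors = FALSE)))
  else data.frame(quartile = integer(0), cell_type = character(0),
                  mean_influence = numeric(0), n_pairs = integer(0))
  rownames(agg) <- NULL
  list(summary = agg, pairs = pairs)
}

#' Mean prestimulus activity by running-speed quartile
#'
#' Mean of the prestimulus window means over the trials of each quartile,
#' per cell type (and per neuron).
#'
#' @param infl a `pm_influence`.
#' @param quartiles a `pm_quartiles` aligned with `infl$aligned$stim_table`.
#' @param cell_types per-neuron cell-type labels (e.g.
#'   `session$labels$cell_type`).
#' @return list with `summary` (data frame: `quartile`, `cell_type`,
#'   `mean_activity`, `n_neurons`) and `per_neuron` (neurons x 4 matrix).
#' @export
activity_by_quartile <- function(infl, quartiles, cell_types) {
  stopifnot(inherits(infl, "pm_influence"))
  pre <- infl$aligned$pre
  if (length(quartiles$trial_quartile) != ncol(pre))
    stop("quartile labels do not align with the stimulation table")
  per <- sapply(1:4, function(q) {
    cols <- which(quartiles$trial_quartile == q)
    if (length(cols) == 0) return(rep(NA_real_, nrow(pre)))
    rowMeans(pre[, cols, drop = FALSE])
  })
  colnames(per) <- paste0("Q", 1:4)
  rows <- list()
  for (ct in unique(cell_types)) {
    sel <- cell_types == ct
    for (q in 1:4) {
      rows[[length(rows) + 1]] <- data.frame(
        quartile = q, cell_type = ct,
        mean_activity = mean(per[sel, q], na.rm = TRUE),
        n_neurons = sum(sel), stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, rows), per_neuron = per)
}
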