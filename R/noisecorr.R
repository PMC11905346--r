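#' Trial residual responses around every stimulation event
#'
#' For every stimulation event, a neuron's "response" is its mean activity
#' in the post-onset window (default 10 frames, 333 ms); the residual is
#' that response minus the neuron's trial-averaged response to that event's
#' target. Mean subtraction removes every deterministic, target-locked
#' response component, so residuals capture trial-to-trial co-fluctuations.
#' Residuals are zero-mean within each target's event set by construction.
#' Targets with a single trial are dropped (residual undefined).
#'
#' @param post (neurons x events) post-window mean matrix (e.g.
#'   `infl$aligned$post`).
#' @param stim_table the aligned stimulation table (`target_id` per event).
#' @return list with `residuals` (neurons x kept events) and `stim_table`
#'   (the kept events).
#' @export
stim_aligned_residuals <- function(post, stim_table) {
  if (ncol(post) != nrow(stim_table))
    stop("post matrix and stim_table do not align")
  keep <- rep(TRUE, nrow(stim_table))
  R <- post
  for (tid in unique(stim_table$target_id)) {
    idx <- which(stim_table$target_id == tid)
    if (length(idx) < 2) { keep[idx] <- FALSE; next }
    R[, idx] <- post[, idx, drop = FALSE] -
      rowMeans(post[, idx, drop = FALSE])
  }
  list(residuals = R[, keep, drop = FALSE],
       stim_table = stim_table[keep, , drop = FALSE])
}

#' Pairwise noise correlation excluding the target's own trials
#'
#' Pearson correlation between the residual responses of a target neuron and
#' another neuron, computed only over events on which that target was *not*
#' stimulated, so neither the direct stimulation response nor its variance
#' enters the correlation.
#'
#' @param resid the list from [stim_aligned_residuals()].
#' @param target_id,neuron_id the pair (neuron indices).
#' @return list: `r` (Pearson correlation, `NA` with `flagged = TRUE` when
#'   either series has zero variance), `n_trials_used`, `flagged`.
#' @export
pairwise_noise_correlation <- function(resid, target_id, neuron_id) {
  keep <- resid$stim_table$target_id != target_id
  if (sum(keep) < 3) stop("fewer than 3 usable trials after exclusion")
  x <- resid$residuals[target_id, keep]
  y <- resid$residuals[neuron_id, keep]
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, n_trials_used = sum(keep), flagged = TRUE))
  list(r = cor(x, y), n_trials_used = sum(keep), flagged = FALSE)
}

#' Noise-correlation records for all target-neuron pairs of a session
#'
#' @param session a `pm_session`.
#' @param infl a `pm_influence`; residuals are computed from its aligned
#'   post-window means and pairs follow its retained records.
#' @param split distance (um) separating the near and far classes.
#' @return data frame: `target_id`, `neuron_id`, `neuron_type`, `r`,
#'   `n_trials_used`, `distance_um`, `distance_class` ("near"/"far").
#' @export
noise_correlation_table <- function(session, infl, split = 125) {
  resid <- stim_aligned_residuals(infl$aligned$post, infl$aligned$stim_table)
  rec <- infl$records[!infl$records$excluded, , drop = FALSE]
  out <- vector("list", length(unique(rec$target_id)))
  i <- 0
  for (tid in unique(rec$target_id)) {
    js <- rec$neuron_id[rec$target_id == tid]
    keep <- resid$stim_table$target_id != tid
    x <- resid$residuals[tid, keep]
    Y <- resid$residuals[js, keep, drop = FALSE]
    sx <- sd(x)
    sy <- apply(Y, 1, sd)
    r <- rep(NA_real_, length(js))
    ok <- sx > 0 & sy > 0
    if (sx > 0 && any(ok))
      r[ok] <- as.numeric(cor(x, t(Y[ok, , drop = FALSE])))
    i <- i + 1
    out[[i]] <- data.frame(
      target_id = tid, neuron_id = js,
      neuron_type = rec$neuron_type[rec$target_id == tid],
      r = r, n_trials_used = sum(keep),
      distance_um = rec$distance_um[rec$target_id == tid],
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, out)
  tab$distance_class <- ifelse(tab$distance_um < split, "near", "far")
  tab
}

#' Relationship between noise correlation and influence by distance class
#'
#' Joins the noise-correlation and influence records on (target, neuron) and
#' computes the Pearson correlation (with p-value) between noise correlation
#' and influence within each (cell type, distance class) cell, in the layout
#' near (< `split` um) vs far (>= `split` um).
#'
#' @param noise_tab output of [noise_correlation_table()].
#' @param records influence records.
#' @param split distance split in um (default 125).
#' @return data frame: `cell_type`, `distance_class`, `r`, `p`, `n_pairs`
#'   (`NA` entries for classes with fewer than 3 pairs).
#' @export
correlation_influence_relation <- function(noise_tab, records, split = 125) {
  rec <- records[!records$excluded & !is.na(records$influence), , drop = FALSE]
  key_n <- paste(noise_tab$target_id, noise_tab$neuron_id)
  key_r <- paste(rec$target_id, rec$neuron_id)
  m <- match(key_n, key_r)
  joined <- noise_tab[!is.na(m), , drop = FALSE]
  joined$influence <- rec$influence[m[!is.na(m)]]
  joined <- joined[!is.na(joined$r), , drop = FALSE]
  joined$distance_class <- ifelse(joined$distance_um < split, "near", "far")
  rows <- list()
  for (ct in unique(joined$neuron_type)) {
    for (cl in c("near", "far")) {
      g <- joined[joined$neuron_type == ct & joined$distance_class == cl, ]
      if (nrow(g) < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = ct, distance_class = cl, r = NA_real_, p = NA_real_,
          n_pairs = nrow(g), stringsAsFactors = FALSE)
        next
      }
      ct_res <- cor.test(g$r, g$influence)
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, distance_class = cl,
        r = unname(ct_res$estimate), p = ct_res$p.value, n_pairs = nrow(g),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
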