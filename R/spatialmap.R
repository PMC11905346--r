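#' Target-centered map of significantly influenced neurons
#'
#' Every target is translated to the origin and the relative positions
#' (neuron minus target) of its significantly influenced neurons of the
#' requested sign and cell type are accumulated into square spatial bins;
#' the summed counts are divided by the number of contributing targets, so
#' each bin reads "influenced neurons per targeted neuron at this relative
#' location". By construction the map total equals
#' (number of influenced neurons) / (number of targets).
#'
#' @param records influence records (from [influence_map()]); excluded pairs
#'   are ignored.
#' @param positions (neurons x 2) centroids in um.
#' @param sign `"positive"` or `"negative"`.
#' @param cell_type `"NonSOM"` or `"SOM"` (or `NULL` for both).
#' @param bin_size bin side in um.
#' @param extent half-width of the map in um; `NULL` auto-expands to cover
#'   all offsets (so the normalization identity holds exactly).
#' @return a `pm_map`: list with `grid` (bins x bins), `bin_edges`,
#'   `bin_size`, `extent`, `sign`, `cell_type`, `n_targets`.
#' @export
centered_influence_map <- function(records, positions,
                                   sign = c("positive", "negative"),
                                   cell_type = "NonSOM", bin_size = 20,
                                   extent = NULL) {
  sign <- match.arg(sign)
  n_targets <- length(unique(records$target_id))
  if (n_targets == 0) stop("empty input: no targets in records")
  r <- records[!records$excluded & !is.na(records$sig_class) &
                 records$sig_class == sign, , drop = FALSE]
  if (!is.null(cell_type))
    r <- r[r$neuron_type %in% cell_type, , drop = FALSE]
  dx <- positions[r$neuron_id, 1] - positions[r$target_id, 1]
  dy <- positions[r$neuron_id, 2] - positions[r$target_id, 2]
  if (is.null(extent)) {
    m <- if (nrow(r) > 0) max(abs(c(dx, dy))) else bin_size
    extent <- bin_size * ceiling((m + 1e-9) / bin_size)
  }
  edges <- seq(-extent, extent, by = bin_size)
  nb <- length(edges) - 1
  grid <- matrix(0, nb, nb)
  inside <- dx >= -extent & dx < extent & dy >= -extent & dy < extent
  if (any(inside)) {
    ix <- findInterval(dx[inside], edges, rightmost.closed = FALSE)
    iy <- findInterval(dy[inside], edges, rightmost.closed = FALSE)
    for (i in seq_along(ix)) grid[ix[i], iy[i]] <- grid[ix[i], iy[i]] + 1
  }
  structure(list(grid = grid / n_targets, bin_edges = edges,
                 bin_size = bin_size, extent = extent, sign = sign,
                 cell_type = cell_type, n_targets = n_targets,
                 n_influenced = nrow(r)),
            class = "pm_map")
}

#' Distance distributions of influenced neurons
#'
#' For each (cell type, significance class) group of retained records,
#' returns the empirical cumulative distribution of target--neuron
#' intersomatic distances together with the group mean, SD, and n, plus the
#' all-neuron reference distribution per cell type.
#'
#' @param records influence records; excluded pairs are dropped first.
#' @return list with `summary` (data frame: `cell_type`, `group`,
#'   `mean_distance`, `sd_distance`, `n`) and `cdfs` (named list of sorted
#'   distance vectors; empty groups are reported with `n = 0` and no CDF).
#' @export
distance_distributions <- function(records) {
  r <- records[!records$excluded, , drop = FALSE]
  groups <- c("all", "positive", "negative", "none")
  out <- list()
  rows <- list()
  for (ct in unique(r$neuron_type)) {
    rc <- r[r$neuron_type == ct, , drop = FALSE]
    for (g in groups) {
      d <- if (g == "all") rc$distance_um else
        rc$distance_um[!is.na(rc$sig_class) & rc$sig_class == g]
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, group = g,
        mean_distance = if (length(d) > 0) mean(d) else NA_real_,
        sd_distance = if (length(d) > 1) sd(d) else NA_real_,
        n = length(d), stringsAsFactors = FALSE)
      if (length(d) > 0) out[[paste(ct, g, sep = ".")]] <- sort(d)
    }
  }
  list(summary = do.call(rbind, rows), cdfs = out)
}

#' Mean influence binned by distance to the target
#'
#' Mean influence over *all* retained pairs (not only significant ones) in
#' contiguous distance bins, per cell type. Default bins are 50 um wide
#' starting at the 25 um exclusion radius: \[25, 75), \[75, 125), ...
#'
#' @param records influence records.
#' @param bin_width bin width in um.
#' @param max_dist upper limit of the last bin in um.
#' @param min_dist lower edge of the first bin in um.
#' @return a `pm_distance_profile` data frame: `cell_type`, `bin_center`,
#'   `mean_influence`, `n`.
#' @export
distance_binned_influence <- function(records, bin_width = 50,
                                      max_dist = 425, min_dist = 25) {
  r <- records[!records$excluded & !is.na(records$influence), , drop = FALSE]
  edges <- seq(min_dist, max_dist, by = bin_width)
  centers <- head(edges, -1) + bin_width / 2
  rows <- list()
  for (ct in unique(r$neuron_type)) {
    rc <- r[r$neuron_type == ct, , drop = FALSE]
    bin <- findInterval(rc$distance_um, edges, rightmost.closed = FALSE)
    for (b in seq_along(centers)) {
      v <- rc$influence[bin == b]
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct, bin_center = centers[b],
        mean_influence = if (length(v) > 0) mean(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pm_distance_profile", "data.frame")
  out
}

#' Fit a difference-of-Gaussians center/surround model to a distance profile
#'
#' Weighted least squares fit of
#' `A_c * exp(-d^2 / 2 sigma_c^2) - A_s * exp(-d^2 / 2 sigma_s^2)`
#' to a binned mean-influence profile, with bin counts as weights. A grid of
#' starting values is tried with box-constrained L-BFGS-B and the best
#' converged fit is returned; the two Gaussians are ordered so that
#' `sigma_s > sigma_c`.
#'
#' @param profile a `pm_distance_profile` (optionally filtered to one cell
#'   type) or any data frame with `bin_center`, `mean_influence`, and
#'   optionally `n`.
#' @param cell_type restrict the profile to one cell type first (default
#'   `"NonSOM"`; `NULL` uses all rows).
#' @return list with `amp_center`, `sigma_center`, `amp_surround`,
#'   `sigma_surround`, `residual` (weighted RSS), `converged`, `fitted`.
#' @export
fit_center_surround <- function(profile, cell_type = "NonSOM") {
  pr <- as.data.frame(profile)
  if (!is.null(cell_type) && "cell_type" %in% names(pr))
    pr <- pr[pr$cell_type %in% cell_type, , drop = FALSE]
  pr <- pr[!is.na(pr$mean_influence), , drop = FALSE]
  if (nrow(pr) < 6) stop("need at least 6 bins to fit a center/surround model")
  d <- pr$bin_center
  y <- pr$mean_influence
  w <- if ("n" %in% names(pr)) pr$n else rep(1, length(y))
  w <- w / sum(w)
  dog <- function(par) par[1] * exp(-d^2 / (2 * par[2]^2)) -
    par[3] * exp(-d^2 / (2 * par[4]^2))
  sse <- function(par) sum(w * (y - dog(par))^2)
  a0 <- max(abs(y)); if (a0 == 0) a0 <- 1e-6
  starts <- expand.grid(ac = c(a0, 2 * a0), sc = c(25, 50, 90),
                        as = c(a0 / 10, a0 / 2), ss = c(120, 220, 350))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
            lower = c(0, 5, 0, 10), upper = c(Inf, 500, Inf, 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(amp_center = NA_real_, sigma_center = NA_real_,
                amp_surround = NA_real_, sigma_surround = NA_real_,
                residual = NA_real_, converged = FALSE, fitted = NULL))
  par <- best$par
  if (par[2] > par[4]) par <- par[c(3, 4, 1, 2)] * c(-1, 1, -1, 1)
  list(amp_center = par[1], sigma_center = par[2],
       amp_surround = par[3], sigma_surround = par[4],
       residual = best$value, converged = best$convergence == 0,
       fitted = par[1] * exp(-d^2 / (2 * par[2]^2)) -
         par[3] * exp(-d^2 / (2 * par[4]^2)))
}
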