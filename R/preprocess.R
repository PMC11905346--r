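#' Neuropil correction
#'
#' Subtracts a scaled copy of the neuropil fluorescence from the raw somatic
#' trace: `f_raw - r * f_neu`, elementwise. The default scale factor is 0.7.
#'
#' @param f_raw raw fluorescence trace or (neurons x frames) matrix.
#' @param f_neu neuropil fluorescence, same shape as `f_raw`.
#' @param r neuropil scale factor in `[0, 1]`.
#' @return corrected fluorescence, same shape as the input.
#' @examples
#' neuropil_correct(10, 5)        # 6.5
#' @export
neuropil_correct <- function(f_raw, f_neu, r = 0.7) {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]")
  if (length(f_raw) != length(f_neu) ||
      !identical(dim(f_raw), dim(f_neu)))
    stop("f_raw and f_neu must have identical shapes")
  f_raw - r * f_neu
}

#' Percentile-baseline dF/F
#'
#' Per frame, the baseline is the `pct`-th percentile (linear interpolation
#' between order statistics) of the trace over a window of `half_window`
#' frames before and after that frame, truncated at the trace edges; dF/F is
#' `(F - F_baseline) / F_baseline`. With 30 Hz imaging, the default
#' `half_window = 450` spans about 15 s each way. dF/F is invariant to a
#' positive rescaling of the fluorescence trace.
#'
#' @param f fluorescence trace (vector) or (neurons x frames) matrix.
#' @param half_window window half-width in frames.
#' @param pct baseline percentile (default 8).
#' @return dF/F, same shape as input.
#' @examples
#' delta_f_over_f(c(10, 10, 20), half_window = 2)
#' @export
delta_f_over_f <- function(f, half_window = 450, pct = 8) {
  if (is.matrix(f)) {
    out <- f
    for (i in seq_len(nrow(f)))
      out[i, ] <- delta_f_over_f(f[i, ], half_window, pct)
    return(out)
  }
  if (length(f) < 1) stop("empty trace")
  if (any(!is.finite(f))) stop("non-finite fluorescence")
  base <- rolling_percentile_cpp(as.numeric(f), as.integer(half_window),
                                 as.numeric(pct))
  if (any(base <= 0))
    stop("degenerate baseline: percentile baseline <= 0; flag this neuron")
  (f - base) / base
}

#' AR1 deconvolution of dF/F into event magnitudes
#'
#' Inverts the first-order autoregressive calcium impulse response with
#' coefficient `g = exp(-1 / (frame_rate * tau))`: the event at frame t is
#' `max(y[t] - g * y[t-1], 0)`. Events smaller than `event_floor` (default
#' 0.05 a.u.) are set to zero to remove low-magnitude noise events. This is a
#' direct sparse AR1 inversion with a magnitude threshold; per-neuron kernel
#' optimization is out of scope (downstream analyses default to dF/F).
#'
#' @param dff dF/F trace (vector) or (neurons x frames) matrix.
#' @param frame_rate imaging rate (Hz).
#' @param tau indicator decay constant (s), > 0.
#' @param event_floor minimum retained event magnitude (a.u.).
#' @return non-negative event magnitudes, same shape as input.
#' @export
deconvolve_ar1 <- function(dff, frame_rate, tau, event_floor = 0.05) {
  if (tau <= 0) stop("tau must be positive")
  if (any(!is.finite(dff))) stop("non-finite dF/F input")
  g <- exp(-1 / (frame_rate * tau))
  if (is.matrix(dff)) {
    prev <- cbind(0, dff[, -ncol(dff), drop = FALSE])
    ev <- dff - g * prev
  } else {
    ev <- dff - g * c(0, dff[-length(dff)])
  }
  ev[ev < 0] <- 0
  ev[ev < event_floor] <- 0
  ev
}

#' Preprocess a session into dF/F and deconvolved events
#'
#' Applies [neuropil_correct()], [delta_f_over_f()], and [deconvolve_ar1()]
#' to every neuron of a session. Both the dF/F and the event traces are
#' carried through the pipeline; downstream analyses default to dF/F.
#'
#' @param session a `pm_session`.
#' @param r neuropil scale factor.
#' @param half_window,pct dF/F baseline window and percentile.
#' @param tau,event_floor deconvolution decay constant (s; defaults to the
#'   session's generator value when available) and event threshold.
#' @return an object of class `pm_activity`: list with `dff`, `events`
#'   (neurons x frames) and `frame_rate`.
#' @export
preprocess_session <- function(session, r = 0.7, half_window = 450, pct = 8,
                               tau = NULL, event_floor = 0.05) {
  stopifnot(inherits(session, "pm_session"))
  if (is.null(tau)) tau <- session$params$calcium_tau
  fc <- neuropil_correct(session$f_raw, session$f_neu, r)
  dff <- delta_f_over_f(fc, half_window, pct)
  events <- deconvolve_ar1(dff, session$params$frame_rate, tau, event_floor)
  structure(list(dff = dff, events = events,
                 frame_rate = session$params$frame_rate),
            class = "pm_activity")
}

#' @export
print.pm_activity <- function(x, ...) {
  cat("<pm_activity> ", nrow(x$dff), " neurons x ", ncol(x$dff),
      " frames at ", x$frame_rate, " Hz\n", sep = "")
  invisible(x)
}
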