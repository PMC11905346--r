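#' Generate a synthetic photostimulation session
#'
#' Simulates one field-of-view recording with known ground truth. Neurons are
#' placed uniformly in a square field of view and labeled SOM/Non-SOM;
#' opsin-expressing targets and non-opsin control targets are drawn from the
#' Non-SOM pool. Every target is stimulated once per repeat block in
#' pseudorandom order at the configured interstimulus interval. Spiking is an
#' inhomogeneous Poisson process whose rate is the product of the baseline
#' rate, a running-state gain, and a slow shared latent (one per cell type);
#' stimulation adds, for `stim_frames` frames after each onset, a direct
#' drive to the target (and to any neuron within `direct_radius`) and a
#' network rate change to every other neuron given by the
#' difference-of-Gaussians [influence_kernel()], optionally scaled by tuning
#' similarity (like-to-like) and by a latent-loading coupling. Calcium is the
#' AR1 convolution of the spikes; raw fluorescence adds a per-neuron gain,
#' Gaussian imaging noise, and a `neuropil_mix` fraction of a simulated
#' neuropil trace. Auditory-like sessions append a pure-tone block
#' (4--32 kHz, 1 s tones) after the stimulation block.
#'
#' `generate_null_session()` produces the matched calibration session in
#' which all network (off-target) stimulation effects are zero; by default
#' the direct effect on the target itself is retained so that targets still
#' register as successfully stimulated.
#'
#' @param params a [gt_params()] object.
#' @param direct_on_target keep the direct photostimulation effect on the
#'   target itself in the null session.
#' @return an object of class `pm_session`: a list with `params`, `positions`
#'   (neurons x 2, um), `labels` (per-neuron data frame), `f_raw`, `f_neu`
#'   (neurons x frames), `stim_table`, `run_speed`, `tone_table`,
#'   `area_tag`, `targets`, `true_effect` (targets x neurons ground-truth
#'   rate change), and a `ground_truth` list (true best frequencies, running
#'   state, latent loadings).
#' @examples
#' s <- generate_session(gt_params(n_neurons = 30, n_targets = 3,
#'                                 n_control_targets = 1, n_repeats = 5))
#' dim(s$f_raw)
#' @export
generate_session <- function(params) {
  .simulate_session(params, network_effects = TRUE, direct_effects = TRUE)
}

#' @rdname generate_session
#' @export
generate_null_session <- function(params, direct_on_target = TRUE) {
  .simulate_session(params, network_effects = FALSE,
                    direct_effects = direct_on_target)
}

.simulate_session <- function(p, network_effects = TRUE,
                              direct_effects = TRUE) {
  validate_params(p)
  set.seed(p$seed)
  n <- p$n_neurons
  fr <- p$frame_rate

  positions <- cbind(x = runif(n, 0, p$fov_size), y = runif(n, 0, p$fov_size))
  is_som <- runif(n) < p$som_fraction
  nonsom_idx <- which(!is_som)
  n_t <- p$n_targets + p$n_control_targets
  if (length(nonsom_idx) < n_t)
    stop("not enough Non-SOM neurons to place all targets")
  opsin <- sample(nonsom_idx, p$n_targets)
  ctrl <- if (p$n_control_targets > 0)
    sample(setdiff(nonsom_idx, opsin), p$n_control_targets) else integer(0)
  targets <- c(opsin, ctrl)
  is_control <- c(rep(FALSE, p$n_targets), rep(TRUE, p$n_control_targets))

  ## stimulation schedule: each repeat block is one pseudorandom permutation
  ## of all targets, onsets spaced exactly isi apart
  isi_frames <- round(p$isi * fr)
  ord <- as.vector(vapply(seq_len(p$n_repeats),
                          function(i) sample.int(n_t), integer(n_t)))
  n_events <- length(ord)
  warm <- 10L * fr
  onsets <- warm + (seq_len(n_events) - 1L) * isi_frames
  stim_table <- data.frame(
    target_id = targets[ord],
    onset_frame = as.integer(onsets),
    trial_index = rep(seq_len(p$n_repeats), each = n_t))
  stim_end <- max(onsets) + isi_frames

  ## tone block (auditory-like sessions): 1 s tones, 1 s gaps
  freqs_khz <- c(4, 8, 12, 16, 24, 32)
  tone_table <- data.frame(frequency_khz = numeric(0),
                           onset_frame = integer(0))
  tone_end <- stim_end
  if (p$with_tones) {
    tone_seq <- sample(rep(freqs_khz, p$n_tone_repeats))
    tone_onsets <- stim_end + warm + (seq_along(tone_seq) - 1L) * (2L * fr)
    tone_table <- data.frame(frequency_khz = tone_seq,
                             onset_frame = as.integer(tone_onsets))
    tone_end <- max(tone_onsets) + 2L * fr
  }
  req_frames <- tone_end + warm
  if (is.null(p$n_frames)) {
    n_frames <- req_frames
  } else {
    if (p$n_frames < req_frames)
      stop("protocol error: n_frames too short for the requested trials (need ",
           req_frames, ")")
    n_frames <- p$n_frames
  }

  run <- .sim_running(n_frames, fr)
  z_som <- .ar1_latent(n_frames, sd = p$shared_latent_sd)
  z_non <- .ar1_latent(n_frames, sd = p$shared_latent_sd)
  load_u <- runif(n, 0.5, 1.5)
  true_bf <- runif(n, 2, 5)                       # log2 kHz
  tune_amp <- p$tone_amp * runif(n, 0.5, 1.5)

  ## firing rate (events/s): baseline x running gain x (1 + shared latent)
  gain <- ifelse(is_som, p$run_gain_som, p$run_gain_nonsom)
  lambda <- p$baseline_rate * (1 + tcrossprod(gain - 1, run$state))
  if (any(is_som))
    lambda[is_som, ] <- lambda[is_som, ] *
      (1 + outer(load_u[is_som], z_som))
  lambda[!is_som, ] <- lambda[!is_som, ] *
    (1 + outer(load_u[!is_som], z_non))

  if (p$with_tones && nrow(tone_table) > 0) {
    tone_len <- fr                                # 1 s tone window
    for (k in seq_len(nrow(tone_table))) {
      resp <- tune_amp *
        exp(-(log2(tone_table$frequency_khz[k]) - true_bf)^2 /
              (2 * p$tuning_sigma^2))
      cols <- tone_table$onset_frame[k]:(tone_table$onset_frame[k] + tone_len - 1L)
      lambda[, cols] <- lambda[, cols] + resp      # additive rate, events/s
    }
  }

  ## ground-truth stimulation effects (events/s during stim_frames)
  true_effect <- matrix(0, n_t, n,
                        dimnames = list(as.character(targets), NULL))
  direct_mat <- matrix(0, n_t, n)
  for (k in seq_len(n_t)) {
    tn <- targets[k]
    if (is_control[k]) next
    d <- sqrt((positions[, 1] - positions[tn, 1])^2 +
                (positions[, 2] - positions[tn, 2])^2)
    if (direct_effects) {
      direct_mat[k, d < p$direct_radius] <- p$direct_amp
      direct_mat[k, tn] <- p$direct_amp
    }
    if (network_effects) {
      ## like-to-like and latent coupling modulate the excitatory center
      ## only; the suppressive surround is untuned and uncoupled
      cen <- p$center_amp * exp(-d^2 / (2 * p$center_sigma^2))
      sur <- p$surround_amp * exp(-d^2 / (2 * p$surround_sigma^2))
      if (p$like_to_like_strength > 0) {
        dbf <- abs(true_bf - true_bf[tn])
        cen <- cen * ((1 - p$like_to_like_strength) +
                        p$like_to_like_strength * exp(-dbf^2 / 2))
      }
      if (p$corr_coupling != 0) {
        cen <- cen * pmax(0, 1 + p$corr_coupling *
                            (load_u * load_u[tn] - 1))
      }
      eff <- cen - sur
      eff[tn] <- 0
      eff[direct_mat[k, ] > 0] <- 0
      true_effect[k, ] <- eff
    }
  }

  target_row <- match(stim_table$target_id, targets)
  for (e in seq_len(n_events)) {
    k <- target_row[e]
    o <- stim_table$onset_frame[e]
    cols <- o:(o + p$stim_frames - 1L)
    scale_net <- if (run$state[o] > 0) p$run_effect_scale else 1
    add <- direct_mat[k, ] + scale_net * true_effect[k, ]
    if (any(add != 0))
      lambda[, cols] <- lambda[, cols] + add
  }
  lambda[lambda < 0] <- 0

  spikes <- matrix(rpois(n * n_frames, lambda / fr), n, n_frames)
  rm(lambda)

  g <- exp(-1 / (fr * p$calcium_tau))
  calcium <- matrix(0, n, n_frames)
  for (i in seq_len(n)) {
    calcium[i, ] <- stats::filter(spikes[i, ], g, method = "recursive")
  }
  rm(spikes)

  f0 <- runif(n, 80, 120)
  f_cell <- f0 * (1 + p$ca_gain * calcium) +
    f0 * p$noise_sd * matrix(rnorm(n * n_frames), n, n_frames)
  rm(calcium)
  neu_base <- runif(n, 40, 60)
  z_neu <- .ar1_latent(n_frames, sd = 0.05)
  f_neu <- outer(neu_base, 1 + z_neu) +
    neu_base * 0.02 * matrix(rnorm(n * n_frames), n, n_frames)
  f_raw <- f_cell + p$neuropil_mix * f_neu
  rm(f_cell)

  structure(list(
    params = p,
    positions = positions,
    labels = data.frame(
      neuron_id = seq_len(n),
      cell_type = ifelse(is_som, "SOM", "NonSOM"),
      opsin_target = seq_len(n) %in% opsin,
      control_target = seq_len(n) %in% ctrl),
    f_raw = f_raw, f_neu = f_neu,
    stim_table = stim_table,
    run_speed = run$speed,
    tone_table = tone_table,
    area_tag = p$area_tag,
    targets = data.frame(target_id = targets, control = is_control),
    true_effect = true_effect,
    ground_truth = list(true_bf = true_bf, run_state = run$state,
                        latent_loading = load_u)),
    class = "pm_session")
}

## two-state (stationary/running) Markov process; speed is constant within a
## running bout (log-normal across bouts), zero while stationary
.sim_running <- function(n_frames, frame_rate,
                         mean_stat_s = 15, mean_run_s = 12) {
  p_sr <- 1 / (mean_stat_s * frame_rate)
  p_rs <- 1 / (mean_run_s * frame_rate)
  state <- integer(n_frames)
  u <- runif(n_frames)
  s <- 0L
  for (t in seq_len(n_frames)) {
    if (s == 0L) {
      if (u[t] < p_sr) s <- 1L
    } else {
      if (u[t] < p_rs) s <- 0L
    }
    state[t] <- s
  }
  speed <- numeric(n_frames)
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (b in seq_along(r$values)) {
    if (r$values[b] == 1L)
      speed[starts[b]:ends[b]] <- exp(rnorm(1, log(8), 0.4))
  }
  list(state = state, speed = speed)
}

.ar1_latent <- function(n_frames, phi = 0.98, sd = 0.1) {
  if (sd <= 0) return(numeric(n_frames))
  e <- rnorm(n_frames, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' @export
print.pm_session <- function(x, ...) {
  cat("<pm_session> ", x$area_tag, ": ", nrow(x$f_raw), " neurons x ",
      ncol(x$f_raw), " frames, ", nrow(x$stim_table), " stimulations of ",
      nrow(x$targets), " targets\n", sep = "")
  invisible(x)
}
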