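#' Ground-truth parameters for synthetic photostimulation sessions
#'
#' Builds the parameter set that fully determines one simulated field of view:
#' population geometry, imaging protocol, the difference-of-Gaussians (DoG)
#' influence kernel, behavioral-state dynamics, and nuisance processes
#' (shared latents, neuropil contamination, measurement noise). Identical
#' parameters and seed produce a bit-identical session.
#'
#' Protocol defaults mirror the emulated experiment: 30 Hz imaging, ~200
#' Non-SOM plus ~15 SOM neurons per field of view, ~30 single-neuron targets
#' plus a handful of non-opsin control targets, at least 100 pseudorandom
#' repeats per target at a 1 s interstimulus interval, and 100 ms (3-frame)
#' stimulations. Effect magnitudes (center/surround amplitudes, direct
#' activation) are free simulator parameters; the defaults are calibrated so
#' that the fraction of significantly influenced neighbors falls in the
#' few-percent range typical of single-cell perturbation experiments.
#'
#' @param n_neurons total neurons in the field of view.
#' @param som_fraction fraction of neurons labeled SOM.
#' @param fov_size side of the square field of view (um).
#' @param frame_rate imaging frame rate (Hz).
#' @param n_frames total frames; `NULL` auto-sizes to fit the protocol.
#' @param n_targets number of opsin-expressing stimulation targets.
#' @param n_control_targets number of non-opsin control targets.
#' @param n_repeats stimulation repeats per target.
#' @param isi interstimulus interval (s).
#' @param center_amp amplitude of the positive influence center (events/s
#'   added to neighbors' firing rate during the stimulation frames).
#' @param center_sigma Gaussian width of the positive center (um).
#' @param surround_amp amplitude (>= 0) of the suppressive surround, applied
#'   negatively (events/s).
#' @param surround_sigma Gaussian width of the surround (um); must exceed
#'   `center_sigma` (the surround is the spatially diffuse component).
#' @param direct_amp direct photostimulation drive to the target itself
#'   (events/s during the stimulation frames).
#' @param direct_radius radius (um) within which the spiral directly excites
#'   a neuron other than the intended target.
#' @param stim_frames duration of the stimulation effect in frames.
#' @param baseline_rate spontaneous firing rate (events/s).
#' @param calcium_tau calcium indicator decay constant (s).
#' @param ca_gain dF/F amplitude per deconvolved event (a.u.).
#' @param noise_sd imaging noise SD in dF/F units.
#' @param neuropil_mix fraction of neuropil fluorescence mixed into the raw
#'   somatic trace.
#' @param run_gain_som,run_gain_nonsom multiplicative rate gain while the
#'   animal is running, per cell type.
#' @param run_effect_scale multiplier applied to network (off-target)
#'   stimulation effects on trials where the animal is running; 1 means
#'   influence is state-independent.
#' @param shared_latent_sd SD of the slow shared latent that induces
#'   within-cell-type noise correlations.
#' @param corr_coupling couples pairwise influence strength to the product of
#'   the two neurons' latent loadings, so that influence and noise
#'   correlation become related for nearby pairs; 0 disables.
#' @param tuning_sigma Gaussian tuning width in octaves (tone sessions).
#' @param tone_amp peak tone-evoked rate increase (events/s).
#' @param n_tone_repeats tone repeats per frequency.
#' @param like_to_like_strength in `[0, 1]`; scales the positive influence
#'   center by tuning similarity, so similarly tuned pairs influence each
#'   other more strongly. 0 disables.
#' @param with_tones include a pure-tone presentation block (auditory-like
#'   sessions).
#' @param area_tag free-text label for the simulated area regime.
#' @param seed integer RNG seed.
#' @return an object of class `pm_params` (a validated named list).
#' @seealso [ac_like_params()], [ppc_like_params()], [generate_session()]
#' @export
gt_params <- function(n_neurons = 215, som_fraction = 0.07, fov_size = 500,
                      frame_rate = 30, n_frames = NULL,
                      n_targets = 30, n_control_targets = 5, n_repeats = 100,
                      isi = 1,
                      center_amp = 15, center_sigma = 50,
                      surround_amp = 1, surround_sigma = 250,
                      direct_amp = 25, direct_radius = 12.5, stim_frames = 3,
                      baseline_rate = 1, calcium_tau = 0.6, ca_gain = 0.15,
                      noise_sd = 0.05, neuropil_mix = 0.7,
                      run_gain_som = 1, run_gain_nonsom = 1,
                      run_effect_scale = 1,
                      shared_latent_sd = 0.15, corr_coupling = 0,
                      tuning_sigma = 1, tone_amp = 8, n_tone_repeats = 12,
                      like_to_like_strength = 0,
                      with_tones = FALSE, area_tag = "generic", seed = 1L) {
  p <- list(
    n_neurons = as.integer(n_neurons), som_fraction = som_fraction,
    fov_size = fov_size, frame_rate = frame_rate, n_frames = n_frames,
    n_targets = as.integer(n_targets),
    n_control_targets = as.integer(n_control_targets),
    n_repeats = as.integer(n_repeats), isi = isi,
    center_amp = center_amp, center_sigma = center_sigma,
    surround_amp = surround_amp, surround_sigma = surround_sigma,
    direct_amp = direct_amp, direct_radius = direct_radius,
    stim_frames = as.integer(stim_frames),
    baseline_rate = baseline_rate, calcium_tau = calcium_tau,
    ca_gain = ca_gain, noise_sd = noise_sd, neuropil_mix = neuropil_mix,
    run_gain_som = run_gain_som, run_gain_nonsom = run_gain_nonsom,
    run_effect_scale = run_effect_scale,
    shared_latent_sd = shared_latent_sd, corr_coupling = corr_coupling,
    tuning_sigma = tuning_sigma, tone_amp = tone_amp,
    n_tone_repeats = as.integer(n_tone_repeats),
    like_to_like_strength = like_to_like_strength,
    with_tones = isTRUE(with_tones), area_tag = as.character(area_tag),
    seed = as.integer(seed))
  validate_params(p)
  class(p) <- "pm_params"
  p
}

validate_params <- function(p) {
  stopifnot(p$n_neurons >= 2, p$n_targets >= 1, p$n_repeats >= 1,
            p$n_control_targets >= 0)
  if (p$som_fraction < 0 || p$som_fraction > 1)
    stop("som_fraction must lie in [0, 1]")
  if (p$center_sigma <= 0 || p$surround_sigma <= 0)
    stop("kernel sigmas must be positive")
  if (p$surround_sigma <= p$center_sigma)
    stop("surround_sigma must exceed center_sigma (surround is the diffuse component)")
  if (p$surround_amp < 0) stop("surround_amp must be >= 0 (applied negatively)")
  if (p$frame_rate <= 0 || p$isi <= 0) stop("frame_rate and isi must be positive")
  if (p$calcium_tau <= 0) stop("calcium_tau must be positive")
  if (p$neuropil_mix < 0 || p$neuropil_mix > 1)
    stop("neuropil_mix must lie in [0, 1]")
  if (p$like_to_like_strength < 0 || p$like_to_like_strength > 1)
    stop("like_to_like_strength must lie in [0, 1]")
  if (!is.null(p$n_frames) && p$n_frames < p$frame_rate)
    stop("n_frames too small")
  invisible(TRUE)
}

#' Preset parameter regimes for the two simulated area types
#'
#' `ac_like_params()` emulates a sensory-cortex-like regime: a narrow zone of
#' positive influence with a wide, relatively strong suppressive surround,
#' weak locomotion modulation, and a pure-tone block with like-to-like
#' (tuning-similarity-dependent) positive coupling. `ppc_like_params()`
#' emulates an association-cortex-like regime: a wider positive center with a
#' narrower and weaker surround, strong positive running modulation of
#' activity (especially SOM), and network influence that weakens while the
#' animal runs.
#'
#' @param ... overrides passed on to [gt_params()].
#' @return a `pm_params` object.
#' @export
ac_like_params <- function(...) {
  defaults <- list(center_sigma = 35, surround_sigma = 220,
                   center_amp = 20, surround_amp = 1.2,
                   run_gain_som = 1, run_gain_nonsom = 1,
                   run_effect_scale = 1, corr_coupling = 1,
                   with_tones = TRUE, like_to_like_strength = 0.9,
                   area_tag = "AC-like")
  do.call(gt_params, utils::modifyList(defaults, list(...)))
}

#' @rdname ac_like_params
#' @export
ppc_like_params <- function(...) {
  defaults <- list(center_sigma = 70, surround_sigma = 140,
                   center_amp = 15, surround_amp = 0.5,
                   run_gain_som = 1.8, run_gain_nonsom = 1.3,
                   run_effect_scale = 0.35, corr_coupling = 1,
                   with_tones = FALSE, like_to_like_strength = 0,
                   area_tag = "PPC-like")
  do.call(gt_params, utils::modifyList(defaults, list(...)))
}

#' @export
print.pm_params <- function(x, ...) {
  cat("<pm_params> ", x$area_tag, ": ", x$n_neurons, " neurons, ",
      x$n_targets, "+", x$n_control_targets, " targets x ", x$n_repeats,
      " repeats, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
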