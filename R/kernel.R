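#' Ground-truth difference-of-Gaussians influence kernel
#'
#' Rate change (events/s) imposed on a neuron at distance `d` from the
#' stimulated target: a narrow excitatory Gaussian center minus a broader
#' suppressive Gaussian surround,
#' \deqn{K(d) = A_c e^{-d^2 / 2\sigma_c^2} - A_s e^{-d^2 / 2\sigma_s^2}.}
#' The DoG is the minimal two-scale family that reproduces a center/surround
#' influence structure and keeps parameter recovery well posed.
#'
#' @param distance intersomatic distance(s) in um; must be non-negative.
#' @param params a [gt_params()] object (uses `center_amp`, `center_sigma`,
#'   `surround_amp`, `surround_sigma`).
#' @return numeric vector of rate changes (events/s), same length as
#'   `distance`.
#' @examples
#' p <- gt_params()
#' influence_kernel(c(0, 50, 200), p)
#' @export
influence_kernel <- function(distance, params) {
  if (any(!is.finite(distance)) || any(distance < 0))
    stop("distance must be finite and >= 0")
  params$center_amp * exp(-distance^2 / (2 * params$center_sigma^2)) -
    params$surround_amp * exp(-distance^2 / (2 * params$surround_sigma^2))
}
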