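# Voxel tuning model: rectified cosine channels in doubled-angle space, and
# per-participant random weight matrices mapping channel activations to voxels.

#' Create a cosine tuning basis over the orientation space
#'
#' Builds `n_channels` tuning channels whose centers sit at the discrete
#' stimulus orientations (equally spaced across 0-180 degrees). The response
#' of a channel centered at `c` to an orientation `theta` is
#' `max(0, cos(2 * d * pi / 180))^power` with `d = theta - c`: the cosine is
#' evaluated in doubled-angle space (so tuning is 180-degree periodic), then
#' half-wave rectified before exponentiation (so an odd power cannot go
#' negative). Each channel peaks at 1 at its center and is exactly 0 at the
#' orthogonal orientation 90 degrees away.
#'
#' @param n_channels Number of channels (>= 2).
#' @param power Exponent applied after rectification (>= 1).
#' @return An object of class `orientation_basis`.
#' @export
#' @examples
#' b <- make_basis(12, 11)
#' basis_response(b, 7.5)[1, 1]  # 1: channel 1 is centered at 7.5 degrees
make_basis <- function(n_channels = 12, power = 11) {
  if (!is.finite(n_channels) || n_channels < 2 || n_channels != round(n_channels)) {
    stop("n_channels must be an integer >= 2")
  }
  if (!is.finite(power) || power < 1) stop("power must be >= 1")
  structure(list(
    centers = stimulus_orientations(n_channels),
    power = power,
    n_channels = as.integer(n_channels)
  ), class = "orientation_basis")
}

#' Evaluate basis channel responses at orientations
#'
#' @param basis An [make_basis()] object.
#' @param theta_deg Orientations in degrees (wrapped into the 180-degree
#'   space).
#' @return A `length(theta_deg) x n_channels` matrix of responses in `[0, 1]`.
#' @export
basis_response <- function(basis, theta_deg) {
  stopifnot(inherits(basis, "orientation_basis"), is.numeric(theta_deg),
            all(is.finite(theta_deg)))
  d <- outer(theta_deg, basis$centers, "-")
  r <- cos(2 * d * pi / 180)
  r[r < 0] <- 0
  r^basis$power
}

#' @export
print.orientation_basis <- function(x, ...) {
  cat(sprintf("Orientation tuning basis: %d channels, power %g\n",
              x$n_channels, x$power))
  cat("  centers (deg):", paste(format(x$centers), collapse = ", "), "\n")
  invisible(x)
}

#' Draw a participant's voxel-by-channel weight matrix
#'
#' Entries are i.i.d. standard normal, drawn from a substream keyed by the
#' master seed and the participant id only, so the matrix stays constant for a
#' participant across iterations, conditions and noise levels.
#'
#' @param params A [sim_params()] object.
#' @param participant Participant id (integer >= 1).
#' @return An `n_voxels x n_channels` matrix with attribute `participant`.
#' @export
sample_weights <- function(params, participant) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.finite(participant) || participant < 1 ||
      participant != round(participant)) {
    stop("participant must be an integer >= 1")
  }
  W <- with_seed(
    substream_seed(params$seed, 101L, participant),
    matrix(rnorm(params$n_voxels * params$n_channels),
           params$n_voxels, params$n_channels)
  )
  attr(W, "participant") <- as.integer(participant)
  W
}

#' Noise-free voxel activity pattern(s) for orientation label(s)
#'
#' Implements the linear generative model: channel activations of the labels
#' are mixed through the weight matrix and scaled by the signal factor,
#' `activity = (W x basis(label)) x signal_factor`.
#'
#' @param W Weight matrix from [sample_weights()] (`n_voxels x n_channels`).
#' @param basis Basis from [make_basis()].
#' @param labels Orientation label(s) in degrees; values outside `[0, 180)`
#'   are wrapped, not rejected.
#' @param signal_factor Scalar weight on the signal.
#' @return A voxel vector for a single label, or a
#'   `length(labels) x n_voxels` matrix for several.
#' @export
orientation_activity <- function(W, basis, labels, signal_factor = 1) {
  stopifnot(is.matrix(W), inherits(basis, "orientation_basis"),
            ncol(W) == basis$n_channels, is.finite(signal_factor))
  act <- basis_response(basis, labels %% 180) %*% t(W) * signal_factor
  if (length(labels) == 1L) drop(act) else act
}
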