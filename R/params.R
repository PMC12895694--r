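#' Simulation parameters for multivoxel orientation patterns
#'
#' Bundles the generative settings of the pattern simulator. Defaults mirror
#' the reference experiment: 81 participants, 4 runs, 12 discrete orientations
#' (15 degrees apart, from 7.5 to 172.5), 1000 voxels, voxel tuning built from
#' 12 cosine basis channels raised to the 11th power, a signal factor of 1 and
#' standard-normal noise scaled by `noise_factor`. The effective signal
#' strength is `signal_factor / noise_factor` and is reported alongside
#' results.
#'
#' @param n_participants Number of simulated participants.
#' @param n_runs Number of scanner runs per participant.
#' @param n_orientations Number of discrete stimulus orientations.
#' @param n_voxels Number of voxels per pattern.
#' @param n_channels Number of cosine tuning channels.
#' @param basis_power Exponent applied to the rectified cosine tuning curves.
#' @param signal_factor Dimensionless weight on the signal.
#' @param noise_factor Dimensionless weight on the noise (>= 0).
#' @param noise_mean Mean of the voxel noise, activity units.
#' @param noise_sd Standard deviation of the voxel noise (> 0).
#' @param trials_per_run_per_condition Trials per run and condition; must be a
#'   multiple of `n_orientations` so the first item can be counterbalanced
#'   within each run. The default 48 mirrors the reference experiment's 192
#'   trials over 4 runs.
#' @param seed Master seed; all randomness derives from it via
#'   [substream_seed()].
#' @return An object of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_participants = 2, n_voxels = 50, noise_factor = 10)
#' signal_strength(p)
sim_params <- function(n_participants = 81,
                       n_runs = 4,
                       n_orientations = 12,
                       n_voxels = 1000,
                       n_channels = 12,
                       basis_power = 11,
                       signal_factor = 1,
                       noise_factor = 1,
                       noise_mean = 0,
                       noise_sd = 1,
                       trials_per_run_per_condition = 48,
                       seed = 1L) {
  counts <- c(n_participants = n_participants, n_runs = n_runs,
              n_orientations = n_orientations, n_voxels = n_voxels,
              n_channels = n_channels,
              trials_per_run_per_condition = trials_per_run_per_condition)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("all counts must be integers >= 1")
  }
  if (!is.finite(basis_power) || basis_power < 1) stop("basis_power must be >= 1")
  if (!is.finite(noise_factor) || noise_factor < 0) stop("noise_factor must be >= 0")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.finite(signal_factor)) stop("signal_factor must be finite")
  if (trials_per_run_per_condition %% n_orientations != 0) {
    stop("trials_per_run_per_condition must be a multiple of n_orientations ",
         "so orientations can be counterbalanced within each run")
  }
  structure(list(
    n_participants = as.integer(n_participants),
    n_runs = as.integer(n_runs),
    n_orientations = as.integer(n_orientations),
    n_voxels = as.integer(n_voxels),
    n_channels = as.integer(n_channels),
    basis_power = basis_power,
    signal_factor = signal_factor,
    noise_factor = noise_factor,
    noise_mean = noise_mean,
    noise_sd = noise_sd,
    trials_per_run_per_condition = as.integer(trials_per_run_per_condition),
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' Effective signal strength of a parameter set
#'
#' Defined as `signal_factor / noise_factor`; e.g. signal strengths 0.1, 0.08
#' and 0.05 correspond to noise factors 10, 12.5 and 20 at a signal factor
#' of 1.
#'
#' @param params A [sim_params()] object.
#' @return Scalar signal strength (Inf when `noise_factor` is 0).
#' @export
signal_strength <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$noise_factor == 0) return(Inf)
  params$signal_factor / params$noise_factor
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters\n")
  cat(sprintf("  participants: %d, runs: %d, orientations: %d, voxels: %d\n",
              x$n_participants, x$n_runs, x$n_orientations, x$n_voxels))
  cat(sprintf("  basis: %d channels, power %g\n", x$n_channels, x$basis_power))
  cat(sprintf("  signal factor %g, noise factor %g (signal strength %g)\n",
              x$signal_factor, x$noise_factor, signal_strength(x)))
  cat(sprintf("  noise ~ N(%g, %g^2), %d trials/run/condition, seed %d\n",
              x$noise_mean, x$noise_sd, x$trials_per_run_per_condition, x$seed))
  invisible(x)
}

#' Discrete stimulus orientations for an n-orientation design
#'
#' Equally spaced across the 0-180 degree space and offset by half a step, so
#' 12 orientations run from 7.5 to 172.5 degrees in 15-degree steps.
#'
#' @param n_orientations Number of discrete orientations.
#' @return Numeric vector of orientations in degrees.
#' @export
stimulus_orientations <- function(n_orientations = 12) {
  stopifnot(n_orientations >= 1)
  step <- 180 / n_orientations
  step * (seq_len(n_orientations) - 1) + step / 2
}
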