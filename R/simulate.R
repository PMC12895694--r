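# Generative simulator for multivoxel orientation patterns under load and
# capacity manipulations, plus behavioral and time-resolved fixtures.
#
# Conditions:
#   "load1"       one orientation per trial; data = activity + noise * nf
#   "load2-cap2"  two orientations, additively superposed (capacity two)
#   "load2-cap1"  two orientations, but only one (picked uniformly at random
#                 per trial) is represented in the pattern (capacity one)

.conditions_all <- c("load1", "load2-cap2", "load2-cap1")

.cond_code <- function(condition) match(condition, .conditions_all)

.check_conditions <- function(conditions) {
  if (!length(conditions)) stop("at least one condition is required")
  bad <- setdiff(conditions, .conditions_all)
  if (length(bad)) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(.conditions_all, collapse = ", "))
  }
  conditions
}

#' Simulate one trial's voxel data vector
#'
#' A single application of the generative rule: the noise-free activity of the
#' label(s) plus one draw of i.i.d. Gaussian voxel noise scaled by the noise
#' factor. With two labels, capacity mode `"cap2"` superposes both activity
#' patterns; `"cap1"` represents one of the two, chosen uniformly at random.
#'
#' @param W Weight matrix ([sample_weights()]).
#' @param basis Tuning basis ([make_basis()]).
#' @param labels One (load 1) or two (load 2) orientation labels in degrees.
#' @param capacity_mode `"na"` for a single label, else `"cap2"` or `"cap1"`.
#' @param params A [sim_params()] object (noise settings, signal factor).
#' @return A voxel data vector, with attribute `represented_item` (1, 2 or NA)
#'   recording which item a `"cap1"` trial carried.
#' @export
simulate_trial <- function(W, basis, labels, capacity_mode = c("na", "cap2", "cap1"),
                           params) {
  capacity_mode <- match.arg(capacity_mode)
  stopifnot(inherits(params, "sim_params"))
  if (length(labels) == 1L) {
    if (capacity_mode != "na") {
      stop("capacity_mode applies to load-2 trials only; got a single label")
    }
  } else if (length(labels) == 2L) {
    if (capacity_mode == "na") stop("two labels require capacity_mode cap2 or cap1")
  } else {
    stop("labels must contain one or two orientations")
  }
  item <- NA_integer_
  if (length(labels) == 1L) {
    act <- orientation_activity(W, basis, labels, params$signal_factor)
  } else if (capacity_mode == "cap2") {
    act <- orientation_activity(W, basis, labels[1], params$signal_factor) +
      orientation_activity(W, basis, labels[2], params$signal_factor)
  } else {
    item <- sample.int(2L, 1L)
    act <- orientation_activity(W, basis, labels[item], params$signal_factor)
  }
  noise <- rnorm(params$n_voxels, params$noise_mean, params$noise_sd)
  out <- act + noise * params$noise_factor
  attr(out, "represented_item") <- item
  out
}

# Design + data for one (participant, condition) block; assumes the caller
# has positioned the RNG (one substream per block).
.simulate_condition_block <- function(W, basis, labs, params, condition,
                                      exclude_duplicate_labels = FALSE) {
  tprc <- params$trials_per_run_per_condition
  reps <- tprc / params$n_orientations
  load2 <- condition != "load1"
  run <- rep(seq_len(params$n_runs), each = tprc)
  l1 <- l2 <- numeric(0)
  for (r in seq_len(params$n_runs)) {
    l1 <- c(l1, sample(rep(labs, reps)))  # counterbalanced within run
    if (load2) {
      s2 <- sample(labs, tprc, replace = TRUE)
      if (exclude_duplicate_labels) {
        tail1 <- l1[(length(l1) - tprc + 1):length(l1)]
        while (any(dup <- s2 == tail1)) {
          s2[dup] <- sample(labs, sum(dup), replace = TRUE)
        }
      }
      l2 <- c(l2, s2)
    }
  }
  n <- length(l1)
  if (!load2) l2 <- rep(NA_real_, n)
  item <- rep(NA_integer_, n)

  A <- orientation_activity(W, basis, l1, params$signal_factor)
  if (condition == "load2-cap2") {
    A <- A + orientation_activity(W, basis, l2, params$signal_factor)
  } else if (condition == "load2-cap1") {
    item <- sample.int(2L, n, replace = TRUE)
    A2 <- orientation_activity(W, basis, l2, params$signal_factor)
    pick2 <- item == 2L
    A[pick2, ] <- A2[pick2, ]
  }
  noise <- matrix(rnorm(n * params$n_voxels, params$noise_mean, params$noise_sd),
                  n, params$n_voxels)
  list(
    design = data.frame(
      run = run,
      trial = seq_len(n),
      condition = condition,
      capacity_mode = if (condition == "load1") "na"
                      else sub("load2-", "", condition),
      label_1 = l1,
      label_2 = l2,
      represented_item = item,
      stringsAsFactors = FALSE
    ),
    data = A + noise * params$noise_factor
  )
}

#' Simulate a full multivoxel pattern dataset
#'
#' Generates a trial design (first item counterbalanced within each run;
#' load-2 second items drawn independently and uniformly, duplicates allowed
#' unless excluded) and the corresponding voxel patterns for every participant
#' and requested condition. Each participant's weight matrix is drawn once
#' from a substream keyed only by `(seed, participant)` and therefore shared
#' across conditions and iterations; trial noise and label orderings use a
#' substream keyed by `(seed, iteration, participant, condition)`.
#'
#' @param params A [sim_params()] object.
#' @param conditions Subset of `"load1"`, `"load2-cap2"`, `"load2-cap1"`.
#' @param iteration Integer tag decorrelating noise across repeated
#'   simulations that share weight matrices.
#' @param participants Participant ids to generate (default all); subsetting
#'   does not change any participant's data.
#' @param exclude_duplicate_labels If `TRUE`, resample load-2 second items
#'   that coincide with the first item.
#' @return An object of class `pattern_dataset`: a list with `design`
#'   (data.frame: participant, run, trial, condition, capacity_mode, label_1,
#'   label_2, represented_item), `data` (trials x voxels matrix) and `params`.
#' @export
#' @examples
#' p <- sim_params(n_participants = 2, n_voxels = 30, noise_factor = 5)
#' ds <- simulate_dataset(p, "load1")
#' nrow(ds$design)  # 2 participants x 4 runs x 12 trials
simulate_dataset <- function(params, conditions = .conditions_all,
                             iteration = 0L,
                             participants = seq_len(params$n_participants),
                             exclude_duplicate_labels = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  .check_conditions(conditions)
  stopifnot(all(participants >= 1), all(participants <= params$n_participants))
  basis <- make_basis(params$n_channels, params$basis_power)
  labs <- stimulus_orientations(params$n_orientations)
  designs <- list()
  datas <- list()
  k <- 0L
  for (pid in participants) {
    W <- sample_weights(params, pid)
    for (cond in conditions) {
      blk <- with_seed(
        substream_seed(params$seed, 202L, iteration, pid, .cond_code(cond)),
        .simulate_condition_block(W, basis, labs, params, cond,
                                  exclude_duplicate_labels)
      )
      blk$design <- cbind(participant = pid, blk$design)
      k <- k + 1L
      designs[[k]] <- blk$design
      datas[[k]] <- blk$data
    }
  }
  data <- do.call(rbind, datas)
  colnames(data) <- sprintf("v%04d", seq_len(params$n_voxels))
  structure(list(
    design = do.call(rbind, designs),
    data = data,
    params = params,
    conditions = conditions
  ), class = "pattern_dataset")
}

#' @export
print.pattern_dataset <- function(x, ...) {
  cat("Pattern dataset:", nrow(x$design), "trial rows x",
      ncol(x$data), "voxels\n")
  cat("  participants:", length(unique(x$design$participant)),
      " conditions:", paste(unique(x$design$condition), collapse = ", "), "\n")
  if (!is.null(x$design$time)) {
    cat("  time-resolved:", length(unique(x$design$time)), "time points\n")
  }
  invisible(x)
}

#' Simulate behavioral orientation recall
#'
#' A fixture for the circular precision statistics: targets are drawn
#' uniformly from the discrete stimulus orientations, and responses add
#' wrapped-normal noise of the requested circular SD in doubled-angle space.
#'
#' @param n_participants Number of participants.
#' @param sd_per_condition Named numeric vector of circular SDs (radians,
#'   doubled-angle space), one per condition; all must be > 0.
#' @param trials_per_condition Trials per participant and condition.
#' @param n_orientations Number of discrete target orientations.
#' @param seed Master seed.
#' @return A `behavioral_dataset` data.frame with columns participant,
#'   condition, target_deg, response_deg.
#' @export
#' @examples
#' b <- simulate_behavior(3, c(load1 = 1 / 4.8, load2 = 1 / 4.24),
#'                        trials_per_condition = 20)
simulate_behavior <- function(n_participants,
                              sd_per_condition,
                              trials_per_condition = 48,
                              n_orientations = 12,
                              seed = 1L) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1)
  if (is.null(names(sd_per_condition)) || any(names(sd_per_condition) == "")) {
    stop("sd_per_condition must be a named vector (one circular SD per condition)")
  }
  if (any(!is.finite(sd_per_condition)) || any(sd_per_condition <= 0)) {
    stop("all circular SDs must be > 0")
  }
  labs <- stimulus_orientations(n_orientations)
  rows <- list()
  k <- 0L
  for (pid in seq_len(n_participants)) {
    for (ci in seq_along(sd_per_condition)) {
      blk <- with_seed(substream_seed(seed, 303L, pid, ci), {
        target <- sample(labs, trials_per_condition, replace = TRUE)
        # doubled-angle wrapped-normal response noise
        psi <- target * pi / 90 + rnorm(trials_per_condition, 0,
                                        sd_per_condition[ci])
        data.frame(
          participant = pid,
          condition = names(sd_per_condition)[ci],
          target_deg = target,
          response_deg = (psi * 90 / pi) %% 180,
          stringsAsFactors = FALSE
        )
      })
      k <- k + 1L
      rows[[k]] <- blk
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("behavioral_dataset", "data.frame")
  out
}

#' Simulate a time-resolved dataset with a controllable code drift
#'
#' A fixture for temporal-generalization analyses: at time point `t` the
#' effective channel mapping is rotated by `(t - 1) * code_rotation` degrees,
#' i.e. activity at time `t` for label `theta` equals the time-1 activity of
#' `theta + (t - 1) * code_rotation`. A rotation of 0 yields a perfectly
#' stable code; with 12 channels a rotation of 15 degrees returns to the
#' original code after 12 steps. Noise is drawn independently per trial and
#' time point.
#'
#' @param params A [sim_params()] object.
#' @param n_timepoints Number of time points (>= 2).
#' @param code_rotation Degrees of code rotation per time step.
#' @param conditions Conditions to simulate (default `"load1"`).
#' @param iteration Integer substream tag, as in [simulate_dataset()].
#' @param participants Participant ids to generate.
#' @return A time-resolved `pattern_dataset`; `design` gains a `time` column
#'   and contains one row per (trial, time point).
#' @export
simulate_timecourse <- function(params, n_timepoints, code_rotation = 0,
                                conditions = "load1", iteration = 0L,
                                participants = seq_len(params$n_participants)) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.finite(n_timepoints) || n_timepoints < 2) {
    stop("n_timepoints must be >= 2")
  }
  .check_conditions(conditions)
  basis <- make_basis(params$n_channels, params$basis_power)
  labs <- stimulus_orientations(params$n_orientations)
  designs <- list()
  datas <- list()
  k <- 0L
  for (pid in participants) {
    W <- sample_weights(params, pid)
    for (cond in conditions) {
      # the trial design (labels, cap1 item picks) is fixed across time:
      # draw it noise-free once, from the same substream as simulate_dataset
      base <- with_seed(
        substream_seed(params$seed, 202L, iteration, pid, .cond_code(cond)),
        .simulate_condition_block(W, basis, labs,
                                  .zero_noise(params), cond, FALSE)
      )
      des <- base$design
      for (t in seq_len(n_timepoints)) {
        rot <- (t - 1) * code_rotation
        A <- orientation_activity(W, basis, des$label_1 + rot,
                                  params$signal_factor)
        if (cond == "load2-cap2") {
          A <- A + orientation_activity(W, basis, des$label_2 + rot,
                                        params$signal_factor)
        } else if (cond == "load2-cap1") {
          A2 <- orientation_activity(W, basis, des$label_2 + rot,
                                     params$signal_factor)
          pick2 <- des$represented_item == 2L
          A[pick2, ] <- A2[pick2, ]
        }
        noise <- with_seed(
          substream_seed(params$seed, 404L, iteration, pid, .cond_code(cond), t),
          matrix(rnorm(nrow(A) * params$n_voxels, params$noise_mean,
                       params$noise_sd), nrow(A), params$n_voxels)
        )
        k <- k + 1L
        designs[[k]] <- cbind(participant = pid, time = t, des)
        datas[[k]] <- A + noise * params$noise_factor
      }
    }
  }
  data <- do.call(rbind, datas)
  colnames(data) <- sprintf("v%04d", seq_len(params$n_voxels))
  design <- do.call(rbind, designs)
  design <- design[, c("participant", "run", "trial", "time", "condition",
                       "capacity_mode", "label_1", "label_2",
                       "represented_item")]
  structure(list(design = design, data = data, params = params,
                 conditions = conditions),
            class = "pattern_dataset")
}

# copy of params with the noise switched off (used to draw designs only)
.zero_noise <- function(params) {
  params$noise_factor <- 0
  params
}
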