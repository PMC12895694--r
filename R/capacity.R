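# Capacity experiment: sweep signal strengths, simulate Load 1 and the two
# Load 2 regimes (capacity two = additive superposition, capacity one = one
# random item), decode everything with the periodic SVR and tabulate
# Load1/Load2 accuracy ratios.

#' Specification of a capacity simulation experiment
#'
#' @param signal_strengths Signal strengths `signal_factor / noise_factor` to
#'   sweep (all > 0); 0.1, 0.08 and 0.05 correspond to noise factors 10, 12.5
#'   and 20 at signal factor 1.
#' @param n_iterations Simulation repetitions per signal strength (>= 1). The
#'   reference analysis uses 1000; 100 is the package's reduced default with
#'   correspondingly wider Monte-Carlo error.
#' @param params Template [sim_params()]; its `noise_factor` is overridden
#'   per signal strength and its `seed` is the experiment's master seed.
#' @param scheme Training scheme for the load-2 conditions (default
#'   `"joint"`).
#' @return Object of class `capacity_spec`.
#' @export
capacity_spec <- function(signal_strengths = c(0.1, 0.08, 0.05),
                          n_iterations = 100,
                          params = sim_params(),
                          scheme = "joint") {
  stopifnot(inherits(params, "sim_params"))
  if (!length(signal_strengths) || any(signal_strengths <= 0)) {
    stop("signal strengths must be > 0")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  scheme <- match.arg(scheme, .schemes)
  structure(list(signal_strengths = signal_strengths,
                 n_iterations = as.integer(n_iterations),
                 params = params, scheme = scheme),
            class = "capacity_spec")
}

# decode one participant's freshly simulated conditions for one iteration
.capacity_iteration <- function(params, conditions, scheme, iter_tag,
                                cost, epsilon) {
  fca <- matrix(NA_real_, params$n_participants, length(conditions),
                dimnames = list(NULL, conditions))
  for (pid in seq_len(params$n_participants)) {
    ds <- simulate_dataset(params, conditions, iteration = iter_tag,
                           participants = pid)
    for (cond in conditions) {
      sc <- cross_validated_decode(ds, condition = cond,
                                   scheme = if (cond == "load1") "joint" else scheme,
                                   cost = cost, epsilon = epsilon)
      fca[pid, cond] <- sc$fca_above_chance
    }
  }
  colMeans(fca)
}

#' Run the capacity simulation experiment
#'
#' For every signal strength and iteration, simulates a fresh dataset (weight
#' matrices fixed per participant across iterations and strengths), decodes
#' Load 1 and the requested Load 2 conditions with leave-one-run-out periodic
#' SVR, and averages the group-mean FCA over iterations. Ratios are reported
#' both as the ratio of iteration-averaged means (primary, matching how
#' average accuracies are compared) and as the mean of per-iteration ratios.
#'
#' @param spec A [capacity_spec()].
#' @param conditions Conditions to simulate; must include `"load1"` and at
#'   least one load-2 condition for ratios.
#' @param cost,epsilon SVR hyperparameters.
#' @param verbose Print progress per signal strength.
#' @return Object of class `capacity_result` with data.frames
#'   `per_condition` (signal_strength, noise_factor, condition, scheme,
#'   mean_fca, se_fca, n_iterations), `ratios` (signal_strength, capacity,
#'   ratio_of_means, mean_of_ratios, se_ratio, n_valid, undefined) and
#'   `per_iteration` (group-mean FCA per iteration and condition).
#' @export
run_capacity_experiment <- function(spec,
                                    conditions = c("load1", "load2-cap2",
                                                   "load2-cap1"),
                                    cost = 1, epsilon = 0.1,
                                    verbose = FALSE) {
  stopifnot(inherits(spec, "capacity_spec"))
  .check_conditions(conditions)
  if (!"load1" %in% conditions) stop("conditions must include 'load1'")
  params <- spec$params
  per_iter <- list()
  k <- 0L
  for (si in seq_along(spec$signal_strengths)) {
    s <- spec$signal_strengths[si]
    p_s <- params
    p_s$noise_factor <- params$signal_factor / s
    t0 <- Sys.time()
    for (it in seq_len(spec$n_iterations)) {
      # iteration tag unique across (strength, iteration) so noise draws
      # never repeat, while weights (keyed by participant only) are shared
      tag <- (si - 1L) * spec$n_iterations + it
      gm <- .capacity_iteration(p_s, conditions, spec$scheme, tag,
                                cost, epsilon)
      k <- k + 1L
      per_iter[[k]] <- data.frame(signal_strength = s,
                                  noise_factor = p_s$noise_factor,
                                  iteration = it,
                                  condition = names(gm),
                                  mean_fca = unname(gm),
                                  stringsAsFactors = FALSE)
    }
    if (verbose) {
      message(sprintf("signal strength %g: %d iterations in %.1f s", s,
                      spec$n_iterations,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  per_iter <- do.call(rbind, per_iter)

  agg <- function(f, ...) aggregate(mean_fca ~ signal_strength + condition,
                                    data = per_iter, FUN = f, ...)
  per_condition <- agg(mean)
  names(per_condition)[names(per_condition) == "mean_fca"] <- "mean_fca"
  ses <- agg(function(v) sd(v) / sqrt(length(v)))
  per_condition$se_fca <- ses$mean_fca
  per_condition$noise_factor <- params$signal_factor / per_condition$signal_strength
  per_condition$scheme <- ifelse(per_condition$condition == "load1",
                                 "single", spec$scheme)
  per_condition$n_iterations <- spec$n_iterations
  per_condition <- per_condition[order(-per_condition$signal_strength,
                                       per_condition$condition),
                                 c("signal_strength", "noise_factor",
                                   "condition", "scheme", "mean_fca",
                                   "se_fca", "n_iterations")]

  load2_conds <- setdiff(conditions, "load1")
  ratios <- list()
  k <- 0L
  for (s in spec$signal_strengths) {
    sub <- per_iter[per_iter$signal_strength == s, ]
    l1 <- sub$mean_fca[sub$condition == "load1"]
    for (cond in load2_conds) {
      l2 <- sub$mean_fca[sub$condition == cond]
      valid <- l2 > 0
      per_it_ratio <- ifelse(valid, l1 / l2, NA_real_)
      undefined <- mean(l2) <= 0
      k <- k + 1L
      ratios[[k]] <- data.frame(
        signal_strength = s,
        capacity = sub("load2-", "", cond),
        load1_mean_fca = mean(l1),
        load2_mean_fca = mean(l2),
        ratio_of_means = if (undefined) NA_real_ else mean(l1) / mean(l2),
        mean_of_ratios = mean(per_it_ratio, na.rm = TRUE),
        se_ratio = sd(per_it_ratio, na.rm = TRUE) / sqrt(sum(valid)),
        n_valid = sum(valid),
        undefined = undefined,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(list(per_condition = per_condition,
                 ratios = do.call(rbind, ratios),
                 per_iteration = per_iter,
                 spec = spec),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("Capacity simulation experiment\n")
  cat(sprintf("  %d iterations, %d participants, scheme '%s'\n",
              x$spec$n_iterations, x$spec$params$n_participants,
              x$spec$scheme))
  cat("\nGroup-mean FCA above chance (%):\n")
  print(x$per_condition, row.names = FALSE, digits = 4)
  cat("\nLoad1/Load2 ratios (on iteration-averaged means):\n")
  print(x$ratios[, c("signal_strength", "capacity", "ratio_of_means",
                     "mean_of_ratios", "se_ratio")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Sweep decoding accuracy across signal strengths and training schemes
#'
#' Runs Load 1 plus joint and separate Load 2 (capacity two) decoding at each
#' signal strength and returns the per-condition curves with Monte-Carlo
#' standard errors. Separate training averages the item-1 and item-2 models.
#'
#' @param spec A [capacity_spec()] (>= 3 signal strengths recommended; a
#'   single point warns).
#' @param schemes Which load-2 training schemes to include.
#' @param cost,epsilon SVR hyperparameters.
#' @return data.frame: signal_strength, condition, scheme, mean_fca, se_fca.
#' @export
signal_strength_sweep <- function(spec, schemes = c("joint", "separate"),
                                  cost = 1, epsilon = 0.1) {
  stopifnot(inherits(spec, "capacity_spec"))
  if (length(spec$signal_strengths) < 2) {
    warning("sweeping fewer than 2 signal strengths")
  }
  schemes <- match.arg(schemes, c("joint", "separate"), several.ok = TRUE)
  params <- spec$params
  rows <- list()
  k <- 0L
  for (si in seq_along(spec$signal_strengths)) {
    s <- spec$signal_strengths[si]
    p_s <- params
    p_s$noise_factor <- params$signal_factor / s
    acc <- list()
    for (it in seq_len(spec$n_iterations)) {
      tag <- (si - 1L) * spec$n_iterations + it
      fca <- matrix(NA_real_, p_s$n_participants, 1 + length(schemes))
      for (pid in seq_len(p_s$n_participants)) {
        ds <- simulate_dataset(p_s, c("load1", "load2-cap2"),
                               iteration = tag, participants = pid)
        fca[pid, 1] <- cross_validated_decode(ds, "load1", cost = cost,
                                              epsilon = epsilon)$fca_above_chance
        col <- 1L
        if ("joint" %in% schemes) {
          col <- col + 1L
          fca[pid, col] <- cross_validated_decode(ds, "load2-cap2", "joint",
                                                  cost = cost,
                                                  epsilon = epsilon)$fca_above_chance
        }
        if ("separate" %in% schemes) {
          col <- col + 1L
          f1 <- cross_validated_decode(ds, "load2-cap2", "separate-item1",
                                       cost = cost, epsilon = epsilon)
          f2 <- cross_validated_decode(ds, "load2-cap2", "separate-item2",
                                       cost = cost, epsilon = epsilon)
          fca[pid, col] <- (f1$fca_above_chance + f2$fca_above_chance) / 2
        }
      }
      acc[[it]] <- colMeans(fca)
    }
    acc <- do.call(rbind, acc)
    labels <- c("load1", paste0("load2-cap2:", schemes))
    for (j in seq_along(labels)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        signal_strength = s,
        condition = sub(":.*", "", labels[j]),
        scheme = if (j == 1) "single" else sub(".*:", "", labels[j]),
        mean_fca = mean(acc[, j]),
        se_fca = sd(acc[, j]) / sqrt(nrow(acc)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Project an empirical Load-1 accuracy through a simulated ratio
#'
#' @param empirical_load1_fca Empirical Load-1 FCA above chance (percent).
#' @param simulated_ratio Simulated Load1/Load2 ratio (> 0).
#' @return Predicted Load-2 FCA, `empirical_load1_fca / simulated_ratio`.
#' @export
#' @examples
#' predict_empirical_load2(10, 2)  # 5
predict_empirical_load2 <- function(empirical_load1_fca, simulated_ratio) {
  stopifnot(is.finite(empirical_load1_fca), is.finite(simulated_ratio))
  if (simulated_ratio <= 0) stop("simulated_ratio must be > 0")
  empirical_load1_fca / simulated_ratio
}

#' Empirical Load1/Load2 ratio with a bootstrap confidence interval
#'
#' Ratio of group means of participant-aligned decoding scores, with a
#' percentile bootstrap over participants.
#'
#' @param fca_load1,fca_load2 Participant-aligned FCA scores.
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional seed for the resampling.
#' @return List with `ratio`, `ci` (length 2), `n_boot`, `flagged`
#'   (`TRUE` when the group-mean Load 2 accuracy is not positive).
#' @export
empirical_ratio <- function(fca_load1, fca_load2, n_boot = 2000,
                            conf = 0.95, seed = NULL) {
  stopifnot(length(fca_load1) == length(fca_load2))
  n <- length(fca_load1)
  flagged <- mean(fca_load2) <= 0
  if (flagged) {
    warning("group-mean Load 2 accuracy is not positive; ratio undefined")
    return(list(ratio = NA_real_, ci = c(NA_real_, NA_real_),
                n_boot = n_boot, flagged = TRUE))
  }
  ratio <- mean(fca_load1) / mean(fca_load2)
  boots <- function() {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      m2 <- mean(fca_load2[idx])
      if (m2 <= 0) NA_real_ else mean(fca_load1[idx]) / m2
    }, numeric(1))
  }
  bs <- if (is.null(seed)) boots() else with_seed(seed, boots())
  alpha <- (1 - conf) / 2
  list(ratio = ratio,
       ci = unname(quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE)),
       n_boot = n_boot, flagged = FALSE)
}
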