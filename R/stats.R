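# Group-level inference: circular recall precision, paired comparisons,
# Pearson / partial correlations, cluster-based sign-permutation tests on
# decoding matrices, and the dynamic-cluster criterion.

#' Circular precision of orientation recall
#'
#' Recall errors are computed as circular differences in doubled-angle space
#' (so 2 vs 178 degrees is a small error, not a large one). The circular SD
#' is `sqrt(-2 * log(Rbar))` with `Rbar` the mean resultant length of the
#' doubled error angles, and precision is its reciprocal (1/rad).
#'
#' @param targets_deg Target orientations, degrees.
#' @param responses_deg Response orientations, degrees.
#' @return List with `precision` (1/rad), `circular_sd` (rad), `n`, and
#'   `degenerate` (`TRUE` with infinite precision when all errors coincide).
#' @export
#' @examples
#' circular_precision(c(2, 100), c(178, 96))$circular_sd
circular_precision <- function(targets_deg, responses_deg) {
  stopifnot(length(targets_deg) == length(responses_deg))
  if (length(targets_deg) < 2) stop("need at least 2 target/response pairs")
  stopifnot(all(is.finite(targets_deg)), all(is.finite(responses_deg)))
  psi <- (responses_deg - targets_deg) * pi / 90  # doubled-angle errors
  rbar <- sqrt(mean(cos(psi))^2 + mean(sin(psi))^2)
  rbar <- min(rbar, 1)
  circ_sd <- sqrt(-2 * log(rbar))
  degenerate <- circ_sd == 0
  if (degenerate) {
    warning("all recall errors identical: circular SD 0, precision infinite")
  }
  list(precision = if (degenerate) Inf else 1 / circ_sd,
       circular_sd = circ_sd, n = length(psi), degenerate = degenerate)
}

#' Per-participant, per-condition recall precision table
#'
#' @param behavior A `behavioral_dataset` (see [simulate_behavior()]) or any
#'   data.frame with participant, condition, target_deg, response_deg.
#' @return data.frame with participant, condition, n, circular_sd, precision.
#' @export
precision_by_participant <- function(behavior) {
  need <- c("participant", "condition", "target_deg", "response_deg")
  stopifnot(all(need %in% names(behavior)))
  out <- list()
  k <- 0L
  for (pid in sort(unique(behavior$participant))) {
    for (cond in unique(behavior$condition)) {
      sub <- behavior[behavior$participant == pid & behavior$condition == cond, ]
      if (!nrow(sub)) next
      pr <- circular_precision(sub$target_deg, sub$response_deg)
      k <- k + 1L
      out[[k]] <- data.frame(participant = pid, condition = cond, n = pr$n,
                             circular_sd = pr$circular_sd,
                             precision = pr$precision,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Paired (or two-sample) comparison of participant scores
#'
#' Two-sided t-test; the paired version aligns scores by position (one row
#' per participant). Zero-variance differences are flagged as degenerate
#' rather than erroring, with `t = 0, p = 1` when the scores are identical.
#'
#' @param scores_a,scores_b Numeric vectors of equal length.
#' @param paired Paired test (default) or Welch two-sample.
#' @return List with `statistic`, `df`, `p_value`, `mean_diff`, `method`,
#'   `degenerate`.
#' @export
group_compare <- function(scores_a, scores_b, paired = TRUE) {
  if (length(scores_a) != length(scores_b) && paired) {
    stop("paired comparison needs equally long, participant-aligned vectors")
  }
  stopifnot(all(is.finite(scores_a)), all(is.finite(scores_b)))
  if (paired) {
    d <- scores_a - scores_b
    if (sd(d) == 0) {
      zero <- mean(d) == 0
      return(list(statistic = if (zero) 0 else NA_real_,
                  df = length(d) - 1,
                  p_value = if (zero) 1 else NA_real_,
                  mean_diff = mean(d), method = "paired t-test",
                  degenerate = TRUE))
    }
    tt <- t.test(scores_a, scores_b, paired = TRUE)
    method <- "paired t-test"
  } else {
    tt <- t.test(scores_a, scores_b)
    method <- "Welch two-sample t-test"
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(scores_a) - mean(scores_b),
       method = method, degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p P-values.
#' @param m Family size (default `length(p)`).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Pearson or partial correlation
#'
#' Without controls, the ordinary Pearson correlation; with controls, the
#' partial correlation computed by residualizing both variables on the
#' controls, with the test degrees of freedom reduced accordingly
#' (`df = n - 2 - n_controls`).
#'
#' @param x,y Aligned numeric vectors (>= 3 points).
#' @param controls Optional numeric vector, matrix or data.frame of control
#'   variables.
#' @return List with `r`, `statistic` (t), `df`, `p_value`, `n`, `method`.
#' @export
association <- function(x, y, controls = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  if (is.null(controls)) {
    r <- cor(x, y)
    df <- n - 2
    method <- "pearson"
  } else {
    cm <- as.matrix(controls)
    stopifnot(nrow(cm) == n)
    rx <- resid(lm(x ~ cm))
    ry <- resid(lm(y ~ cm))
    if (sd(rx) < 1e-10 || sd(ry) < 1e-10) {
      stop("a control explains one variable exactly; partial correlation undefined")
    }
    r <- cor(rx, ry)
    df <- n - 2 - ncol(cm)
    if (df < 1) stop("too many controls for the sample size")
    method <- "partial pearson"
  }
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df), n = n, method = method)
}

# coerce a list of matrices / 3D array into subjects x elements + dims
.stack_matrices <- function(matrices) {
  if (is.list(matrices)) {
    dm <- dim(matrices[[1]])
    stopifnot(all(vapply(matrices, function(m) identical(dim(m), dm), TRUE)))
    M <- t(vapply(matrices, as.vector, numeric(prod(dm))))
  } else if (is.array(matrices) && length(dim(matrices)) == 3) {
    dm <- dim(matrices)[2:3]
    M <- matrix(aperm(matrices, c(1, 2, 3)), nrow = dim(matrices)[1])
  } else {
    stop("matrices must be a list of matrices or a 3D array (subject x r x c)")
  }
  list(M = M, nr = dm[1], nc = dm[2])
}

.tail_code <- function(tail) switch(tail, two = 2L, pos = 1L, neg = -1L)

#' Cluster-based sign-permutation test on per-participant matrices
#'
#' Element-wise one-sample t-tests against zero form clusters of contiguous
#' (4-connected) supra-threshold cells; the observed summed-t cluster masses
#' are compared against a null distribution of the maximal cluster mass
#' obtained by randomly flipping the sign of each participant's whole matrix
#' (the one-sample sign-flip null; a chance-level decoding matrix is
#' symmetric around 0).
#'
#' @param matrices List of per-participant matrices, or a 3D array
#'   `subjects x rows x cols` (>= 5 participants).
#' @param n_perm Number of sign permutations (default 1000; < 100 warns).
#' @param cluster_forming_alpha Two-sided element-wise alpha forming clusters
#'   (default 0.05).
#' @param cluster_alpha Family-wise alpha for declaring a cluster significant
#'   (default 0.05).
#' @param tail Which clusters to consider: `"two"` (default), `"pos"`, or
#'   `"neg"` (e.g. testing for significantly lower accuracy).
#' @param seed Optional seed for the permutation draws.
#' @return Object of class `cluster_test`: `t` (t-map), `labels` (cluster id
#'   per cell, 0 = sub-threshold), `masses`, `p_values` (per cluster),
#'   `sig_mask` (logical matrix), `null_max` (permutation distribution), and
#'   the settings.
#' @export
cluster_sign_permutation <- function(matrices, n_perm = 1000,
                                     cluster_forming_alpha = 0.05,
                                     cluster_alpha = 0.05,
                                     tail = c("two", "pos", "neg"),
                                     seed = NULL) {
  tail <- match.arg(tail)
  st <- .stack_matrices(matrices)
  M <- st$M
  n <- nrow(M)
  if (n < 5) stop("need at least 5 participants")
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse null")

  mu <- colMeans(M)
  s <- apply(M, 2, sd)
  tvals <- ifelse(s > 0, mu / (s / sqrt(n)), ifelse(mu == 0, 0, sign(mu) * Inf))
  tmat <- matrix(tvals, st$nr, st$nc)
  thresh <- qt(1 - cluster_forming_alpha / 2, df = n - 1)
  tc <- .tail_code(tail)
  cl <- label_clusters_cpp(tmat, thresh, tc)
  masses <- as.numeric(cl$masses)

  draw <- function() matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                            n_perm, n)
  S <- if (is.null(seed)) draw() else with_seed(seed, draw())
  mu_p <- S %*% M / n
  ssq <- matrix(colSums(M^2), n_perm, ncol(M), byrow = TRUE)
  var_p <- (ssq - n * mu_p^2) / (n - 1)
  t_p <- mu_p / sqrt(var_p / n)
  t_p[!is.finite(t_p)] <- 0
  null_max <- perm_max_masses_cpp(t_p, st$nr, st$nc, thresh, tc)

  p_values <- vapply(masses, function(m) {
    (1 + sum(null_max >= abs(m))) / (n_perm + 1)
  }, numeric(1))
  sig_ids <- which(p_values < cluster_alpha)
  sig_mask <- matrix(cl$labels %in% sig_ids, st$nr, st$nc)

  structure(list(t = tmat, labels = cl$labels, masses = masses,
                 p_values = p_values, sig_mask = sig_mask,
                 null_max = null_max, n_perm = n_perm, tail = tail,
                 cluster_forming_alpha = cluster_forming_alpha,
                 cluster_alpha = cluster_alpha, n = n,
                 t_threshold = thresh),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("Cluster sign-permutation test (%d participants, %d permutations, %s-tailed)\n",
              x$n, x$n_perm, x$tail))
  if (length(x$masses)) {
    for (i in seq_along(x$masses)) {
      cat(sprintf("  cluster %d: mass %.2f, p = %.4g%s\n", i, x$masses[i],
                  x$p_values[i],
                  if (x$p_values[i] < x$cluster_alpha) " *" else ""))
    }
  } else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' Dynamic elements of a temporal generalization matrix
#'
#' An off-diagonal element (i, j) is dynamic when its decoding accuracy is
#' significantly lower than both of its corresponding diagonal elements --
#' `a_ij < a_ii` and `a_ij < a_jj`, each difference tested with the same
#' cluster-based sign-permutation procedure (negative tail) -- and the
#' element lies inside the above-chance mask. Diagonal elements are never
#' dynamic.
#'
#' @param gen_matrices Per-participant generalization matrices (list or 3D
#'   array `subjects x T x T`, e.g. from [generalization_array()]).
#' @param above_chance_mask Logical `T x T` mask of above-chance elements,
#'   typically `cluster_sign_permutation(gen_matrices)$sig_mask`.
#' @param n_perm,cluster_forming_alpha,cluster_alpha,seed Passed to the two
#'   difference tests.
#' @return Object of class `dynamic_mask`: `dynamic` (logical matrix), plus
#'   the two underlying `cluster_test` results (`test_row_diag`,
#'   `test_col_diag`).
#' @export
dynamic_clusters <- function(gen_matrices, above_chance_mask, n_perm = 1000,
                             cluster_forming_alpha = 0.05,
                             cluster_alpha = 0.05, seed = NULL) {
  st <- .stack_matrices(gen_matrices)
  if (st$nr != st$nc) stop("generalization matrices must be square over time")
  Tn <- st$nr
  stopifnot(is.logical(above_chance_mask),
            all(dim(above_chance_mask) == c(Tn, Tn)))
  nsub <- nrow(st$M)
  A <- array(st$M, c(nsub, Tn, Tn))
  D_row <- D_col <- A
  for (s in seq_len(nsub)) {
    d <- diag(A[s, , ])
    D_row[s, , ] <- A[s, , ] - matrix(d, Tn, Tn, byrow = FALSE)  # a_ij - a_ii
    D_col[s, , ] <- A[s, , ] - matrix(d, Tn, Tn, byrow = TRUE)   # a_ij - a_jj
  }
  t1 <- cluster_sign_permutation(D_row, n_perm, cluster_forming_alpha,
                                 cluster_alpha, tail = "neg",
                                 seed = if (is.null(seed)) NULL else seed)
  t2 <- cluster_sign_permutation(D_col, n_perm, cluster_forming_alpha,
                                 cluster_alpha, tail = "neg",
                                 seed = if (is.null(seed)) NULL else seed + 1L)
  dynamic <- above_chance_mask & t1$sig_mask & t2$sig_mask
  diag(dynamic) <- FALSE
  structure(list(dynamic = dynamic, test_row_diag = t1, test_col_diag = t2),
            class = "dynamic_mask")
}

#' @export
print.dynamic_mask <- function(x, ...) {
  cat(sprintf("Dynamic-cluster mask: %d of %d elements dynamic\n",
              sum(x$dynamic), length(x$dynamic)))
  invisible(x)
}
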