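# Cross-validated decoding of pattern datasets: leave-one-run-out periodic
# SVR, trial scoring as feature-continuous accuracy above chance, and the
# temporal / cross-condition generalization matrices.

.schemes <- c("joint", "separate-item1", "separate-item2")

.scheme_code <- function(scheme, load2) {
  if (!load2) return(0L)  # single-label decoding
  switch(scheme, "joint" = 1L, "separate-item1" = 2L, "separate-item2" = 3L)
}

#' Leave-one-run-out fold plan
#'
#' @param runs Vector of run ids, one per trial.
#' @return List of folds, each with `train` and `test` trial indices; train
#'   and test never share a run.
#' @export
make_folds <- function(runs) {
  ids <- sort(unique(runs))
  if (length(ids) < 2) stop("need at least 2 runs for cross-validation")
  lapply(ids, function(r) {
    list(run = r, train = which(runs != r), test = which(runs == r))
  })
}

.check_scheme <- function(scheme, condition) {
  scheme <- match.arg(scheme, .schemes)
  if (condition == "load1" && scheme != "joint") {
    stop("scheme '", scheme, "' needs two item labels; condition 'load1' ",
         "has one (use the default scheme)")
  }
  scheme
}

# rows of a dataset for one participant/condition (and optional time point)
.block_rows <- function(design, pid, condition, timepoint = NULL) {
  sel <- design$participant == pid & design$condition == condition
  if (!is.null(timepoint)) {
    if (is.null(design$time)) stop("dataset is not time-resolved")
    sel <- sel & design$time == timepoint
  } else if (!is.null(design$time)) {
    stop("time-resolved dataset: pick a timepoint or decode all with ",
         "timepoint = NULL handled by the caller")
  }
  which(sel)
}

#' Cross-validated periodic SVR decoding of a pattern dataset
#'
#' For every participant, trains on the trials of all but one run and tests
#' on the left-out run, with per-fold min-max scaling fitted on the training
#' trials. For two-item (load 2) conditions the default `"joint"` scheme uses
#' each trial twice -- once per item label -- in both training and testing;
#' the `"separate-item1"` / `"separate-item2"` schemes fit one model per item
#' position and score it against that item only. Angular errors are averaged
#' within fold, then across folds.
#'
#' @param dataset A `pattern_dataset` (see [simulate_dataset()]).
#' @param condition Condition to decode; may be omitted when the dataset
#'   holds a single condition.
#' @param scheme Training scheme, see Details.
#' @param timepoint For time-resolved datasets: the time point(s) to decode
#'   (default: all, one score row per time point).
#' @param cost,epsilon,gamma,tol,max_iter SVR hyperparameters; see
#'   [fit_psvr()].
#' @return A data.frame of class `decoding_scores` with one row per
#'   participant (and time point): participant, condition, scheme, timepoint,
#'   n_trials, mean_error_rad, fca_above_chance.
#' @export
cross_validated_decode <- function(dataset, condition = NULL,
                                   scheme = "joint", timepoint = NULL,
                                   cost = 1, epsilon = 0.1, gamma = NULL,
                                   tol = 1e-3, max_iter = 50000L) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  des <- dataset$design
  if (is.null(condition)) {
    conds <- unique(des$condition)
    if (length(conds) != 1) {
      stop("dataset holds several conditions (",
           paste(conds, collapse = ", "), "); pick one")
    }
    condition <- conds
  }
  if (!condition %in% des$condition) {
    stop("condition '", condition, "' not present in the dataset")
  }
  scheme <- .check_scheme(scheme, condition)
  timepoints <- if (is.null(des$time)) list(NULL) else {
    as.list(if (is.null(timepoint)) sort(unique(des$time)) else timepoint)
  }
  gamma_arg <- if (is.null(gamma)) -1 else gamma
  load2 <- condition != "load1"
  code <- .scheme_code(scheme, load2)

  out <- list()
  k <- 0L
  for (pid in sort(unique(des$participant))) {
    for (tp in timepoints) {
      rows <- .block_rows(des, pid, condition, tp)
      if (!length(rows)) next
      run <- des$run[rows]
      if (length(unique(run)) < 2) stop("need at least 2 runs per participant")
      th1 <- degrees_to_theta(des$label_1[rows])
      th2 <- if (load2) degrees_to_theta(des$label_2[rows]) else th1
      res <- psvr_decode_cpp(dataset$data[rows, , drop = FALSE], th1, th2,
                             as.integer(run), code, cost, epsilon, gamma_arg,
                             tol, max_iter)
      k <- k + 1L
      out[[k]] <- data.frame(
        participant = pid, condition = condition, scheme = scheme,
        timepoint = if (is.null(tp)) NA_integer_ else tp,
        n_trials = length(rows),
        mean_error_rad = res$mean_error,
        fca_above_chance = res$fca_above_chance,
        stringsAsFactors = FALSE
      )
    }
  }
  scores <- do.call(rbind, out)
  class(scores) <- c("decoding_scores", "data.frame")
  scores
}

# fit + predict for one (train rows -> test rows) pair at the R level;
# used by the generalization matrix where train and test may differ in time
# and condition, so the duplication rule is resolved per side
.decode_cell <- function(data, des, train_rows, test_rows, train_code,
                         test_code, cost, epsilon, gamma, tol, max_iter) {
  sc <- scale_train_apply_test(data[train_rows, , drop = FALSE],
                               data[test_rows, , drop = FALSE])
  th1 <- degrees_to_theta(des$label_1[train_rows])
  xtr <- sc$train
  if (train_code == 1L) {
    th <- c(th1, degrees_to_theta(des$label_2[train_rows]))
    xtr <- rbind(xtr, xtr)
  } else if (train_code == 3L) {
    th <- degrees_to_theta(des$label_2[train_rows])
  } else {
    th <- th1
  }
  fit <- fit_psvr(xtr, th, cost = cost, epsilon = epsilon, gamma = gamma,
                  tol = tol, max_iter = max_iter)
  pr <- predict(fit, sc$test)
  t1 <- degrees_to_theta(des$label_1[test_rows])
  if (test_code == 1L) {
    t2 <- degrees_to_theta(des$label_2[test_rows])
    errs <- c(angular_error(t1, pr$theta_hat), angular_error(t2, pr$theta_hat))
  } else if (test_code == 3L) {
    errs <- angular_error(degrees_to_theta(des$label_2[test_rows]), pr$theta_hat)
  } else {
    errs <- angular_error(t1, pr$theta_hat)
  }
  mean(errs)
}

#' Temporal (and cross-condition) generalization of the decoder
#'
#' Trains the periodic SVR at each time point of `condition_train` and tests
#' it at every time point of `condition_test`, keeping leave-one-run-out
#' cross-validation in every cell so train and test trials never share a run.
#' The within-condition diagonal equals time-resolved
#' [cross_validated_decode()].
#'
#' @param dataset A time-resolved `pattern_dataset`
#'   ([simulate_timecourse()]).
#' @param condition_train,condition_test Conditions to train and test on
#'   (default: the single condition in the dataset).
#' @param scheme Training scheme, as in [cross_validated_decode()]; the test
#'   condition is scored with the matching rule.
#' @param cost,epsilon,gamma,tol,max_iter SVR hyperparameters.
#' @return A long-format data.frame of class `generalization_result`:
#'   participant, train_condition, test_condition, train_time, test_time,
#'   fca_above_chance.
#' @export
temporal_generalization <- function(dataset, condition_train = NULL,
                                    condition_test = NULL, scheme = "joint",
                                    cost = 1, epsilon = 0.1, gamma = NULL,
                                    tol = 1e-3, max_iter = 50000L) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  des <- dataset$design
  if (is.null(des$time)) stop("dataset is not time-resolved")
  if (is.null(condition_train)) {
    conds <- unique(des$condition)
    if (length(conds) != 1) stop("several conditions present; pick one to train on")
    condition_train <- conds
  }
  if (is.null(condition_test)) condition_test <- condition_train
  stopifnot(condition_train %in% des$condition,
            condition_test %in% des$condition)
  scheme <- .check_scheme(scheme, condition_train)
  code_tr <- .scheme_code(scheme, condition_train != "load1")
  code_te <- .scheme_code(scheme, condition_test != "load1")
  tps <- sort(unique(des$time))
  if (length(tps) < 2) stop("need at least 2 time points")

  out <- list()
  k <- 0L
  for (pid in sort(unique(des$participant))) {
    acc <- matrix(0, length(tps), length(tps))
    runs <- sort(unique(des$run[des$participant == pid]))
    for (r in runs) {
      for (ti in seq_along(tps)) {
        tr_rows <- which(des$participant == pid &
                           des$condition == condition_train &
                           des$time == tps[ti] & des$run != r)
        for (tj in seq_along(tps)) {
          te_rows <- which(des$participant == pid &
                             des$condition == condition_test &
                             des$time == tps[tj] & des$run == r)
          err <- .decode_cell(dataset$data, des, tr_rows, te_rows,
                              code_tr, code_te,
                              cost, epsilon, gamma, tol, max_iter)
          acc[ti, tj] <- acc[ti, tj] + err
        }
      }
    }
    acc <- acc / length(runs)
    k <- k + 1L
    out[[k]] <- data.frame(
      participant = pid,
      train_condition = condition_train,
      test_condition = condition_test,
      train_time = rep(tps, times = length(tps)),
      test_time = rep(tps, each = length(tps)),
      mean_error_rad = as.vector(acc),
      fca_above_chance = 50 - as.vector(acc) / pi * 100,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  class(res) <- c("generalization_result", "data.frame")
  res
}

#' Stack a generalization result into a participants x time x time array
#'
#' @param result A `generalization_result` from [temporal_generalization()].
#' @param value Column to extract (default `fca_above_chance`).
#' @return Numeric array `n_participants x n_train_times x n_test_times`.
#' @export
generalization_array <- function(result, value = "fca_above_chance") {
  stopifnot(inherits(result, "generalization_result"), value %in% names(result))
  pids <- sort(unique(result$participant))
  tr <- sort(unique(result$train_time))
  te <- sort(unique(result$test_time))
  arr <- array(NA_real_, c(length(pids), length(tr), length(te)),
               dimnames = list(pids, tr, te))
  for (i in seq_along(pids)) {
    sub <- result[result$participant == pids[i], ]
    arr[i, , ] <- matrix(sub[[value]][order(sub$test_time, sub$train_time)],
                         length(tr), length(te))
  }
  arr
}
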