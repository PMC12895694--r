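# Voxel time-series utilities used ahead of decoding: slow-drift removal via
# a node-based cubic spline, and temporal smoothing with a centered moving
# average.

#' Remove slow drift from a voxel time series with a cubic spline
#'
#' The series is split into `n_nodes` contiguous, (near-)equal segments; each
#' node sits at the segment center with ordinate equal to the segment mean. A
#' natural cubic spline through the nodes is evaluated at every time point and
#' subtracted, removing drifts slow relative to the node spacing while leaving
#' faster structure largely intact.
#'
#' @param series Numeric vector, or a matrix with one column per voxel.
#' @param n_nodes Number of spline nodes (default 24); the series must be
#'   longer than the node count.
#' @return Detrended series of the same shape.
#' @export
#' @examples
#' detrend_spline(rep(3, 100), n_nodes = 5)  # all zeros
detrend_spline <- function(series, n_nodes = 24) {
  if (is.matrix(series)) {
    return(apply(series, 2, detrend_spline, n_nodes = n_nodes))
  }
  n <- length(series)
  if (!is.finite(n_nodes) || n_nodes < 2) stop("n_nodes must be >= 2")
  if (n <= n_nodes) stop("series must be longer than the node count")
  bounds <- round(seq(0, n, length.out = n_nodes + 1))
  node_x <- node_y <- numeric(n_nodes)
  for (k in seq_len(n_nodes)) {
    idx <- (bounds[k] + 1):bounds[k + 1]
    node_x[k] <- mean(idx)
    node_y[k] <- mean(series[idx])
  }
  trend <- spline(node_x, node_y, xout = seq_len(n), method = "natural")$y
  series - trend
}

#' Centered moving average with shrinking edge windows
#'
#' @param series Numeric vector, or a matrix with one column per voxel.
#' @param window Odd window length (default 5). At the series edges the
#'   window shrinks symmetrically rather than padding, so no signal is
#'   fabricated beyond the run borders.
#' @return Smoothed series of the same shape.
#' @export
#' @examples
#' moving_average(c(0, 0, 1, 0, 0), 5)
moving_average <- function(series, window = 5) {
  if (!is.finite(window) || window < 1 || window %% 2 != 1) {
    stop("window must be an odd integer >= 1")
  }
  if (is.matrix(series)) {
    return(apply(series, 2, moving_average, window = window))
  }
  n <- length(series)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, series))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
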