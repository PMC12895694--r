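# Behavioral and group-level statistics.

test_that("circular precision handles wrap-around and degenerate input", {
  # wrap-around pairs give small errors, not ~176 degrees
  pr <- circular_precision(c(2, 100, 45), c(178, 96, 47))
  expect_lt(pr$circular_sd, 0.2)
  expect_warning(pd <- circular_precision(c(10, 20), c(10, 20)), "identical")
  expect_true(pd$degenerate)
  expect_equal(pd$precision, Inf)
  expect_error(circular_precision(1, 2), "at least 2")
})

test_that("paired comparisons match a hand-computed t and flag degeneracy", {
  # brute-force reference: d = (2, 1, 0, 2, -2), t = mean/ (sd/sqrt(5))
  cmp <- group_compare(c(10, 12, 9, 14, 11), c(8, 11, 9, 12, 13))
  expect_equal(cmp$statistic, 0.801783725737, tolerance = 1e-9)
  expect_equal(cmp$p_value, 0.467604754609, tolerance = 1e-9)
  expect_equal(cmp$df, 4)

  same <- group_compare(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  const <- group_compare(2:6, 1:5)
  expect_true(const$degenerate)
  expect_true(is.na(const$p_value))
  expect_error(group_compare(1:4, 1:5), "aligned")
})

test_that("Bonferroni adjustment is min(1, m * p)", {
  expect_equal(bonferroni_adjust(c(0.01, 0.4), m = 3), c(0.03, 1))
  expect_equal(bonferroni_adjust(0.02), 0.02)
  expect_error(bonferroni_adjust(1.2), ">= 0")
})

test_that("associations match closed-form Pearson and partial correlations", {
  expect_equal(association(1:10, 2 * (1:10) + 1)$r, 1)
  # 4-point brute-force reference
  expect_equal(association(c(1, 2, 3, 5), c(2, 1, 4, 6))$r,
               0.902243638678, tolerance = 1e-9)
  # 6-point partial correlation, verified against the recursion formula and
  # an independent implementation (pingouin) during development
  pa <- association(c(1, 2, 3, 4, 6, 8), c(2, 1, 5, 4, 8, 9),
                    controls = c(1, 1, 2, 3, 5, 7))
  expect_equal(pa$r, 0.0603747621522, tolerance = 1e-9)
  expect_equal(pa$df, 3)                 # n - 2 - one control
  expect_equal(pa$p_value, 0.923175, tolerance = 1e-5)  # pingouin-verified

  x <- c(1, 2, 3, 4, 6, 8)
  expect_error(association(x, rnorm(6), controls = x), "exactly")
  expect_error(association(rep(1, 5), 1:5), "zero-variance")
  expect_error(association(1:2, 1:2), "at least 3")
})

test_that("cluster sign permutation recovers a planted block and honors nulls", {
  set.seed(11)
  n <- 20
  mats <- array(rnorm(n * 8 * 8), c(n, 8, 8))
  mats[, 2:4, 2:4] <- mats[, 2:4, 2:4] + 1.5       # planted positive block
  ct <- cluster_sign_permutation(mats, n_perm = 500, seed = 3)
  expect_true(any(ct$sig_mask))
  expect_true(all(ct$sig_mask[2:4, 2:4]))
  expect_false(any(ct$sig_mask[6:8, 6:8]))
  # significant cells belong to labeled contiguous clusters
  expect_true(all(ct$labels[ct$sig_mask] > 0))
  expect_true(all(ct$p_values >= 0 & ct$p_values <= 1))

  # a zero matrix: degenerate null at 0, no clusters at all
  zct <- cluster_sign_permutation(array(0, c(6, 4, 4)), n_perm = 200, seed = 1)
  expect_length(zct$masses, 0)
  expect_false(any(zct$sig_mask))
  expect_true(all(zct$null_max == 0))

  expect_error(cluster_sign_permutation(array(0, c(3, 4, 4))), "at least 5")
  expect_warning(cluster_sign_permutation(array(rnorm(5 * 16), c(5, 4, 4)),
                                          n_perm = 50, seed = 1), "coarse")
  expect_error(cluster_sign_permutation(list(matrix(0, 2, 2),
                                             matrix(0, 3, 3))))
})

test_that("dynamic-cluster criterion gates on the above-chance mask", {
  set.seed(12)
  n <- 16; Tn <- 5
  # strong diagonal, weak off-diagonal: a dynamic code's signature
  base <- matrix(5, Tn, Tn); diag(base) <- 25
  mats <- array(rnorm(n * Tn * Tn, sd = 2), c(n, Tn, Tn)) +
    aperm(array(base, c(Tn, Tn, n)), c(3, 1, 2))
  above <- cluster_sign_permutation(mats, n_perm = 300, seed = 5)$sig_mask
  dc <- dynamic_clusters(mats, above, n_perm = 300, seed = 6)
  expect_true(any(dc$dynamic))
  expect_false(any(diag(dc$dynamic)))              # diagonal never dynamic
  expect_true(all(dc$dynamic[dc$dynamic] & above[dc$dynamic]))

  # an all-false gate forces an all-false mask regardless of differences
  none <- dynamic_clusters(mats, matrix(FALSE, Tn, Tn), n_perm = 300, seed = 6)
  expect_false(any(none$dynamic))

  # monotone in evidence: moving off-diagonals toward the diagonals can only
  # shrink the mask on the same noise realization
  closer <- mats
  for (s in seq_len(n)) {
    off <- matrix(TRUE, Tn, Tn); diag(off) <- FALSE
    closer[s, , ][off] <- closer[s, , ][off] + 10
  }
  dc2 <- dynamic_clusters(closer, above, n_perm = 300, seed = 6)
  expect_true(all(dc$dynamic | !dc2$dynamic))      # dc2 subset of dc
})
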