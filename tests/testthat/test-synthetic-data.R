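# Generative simulator: parameters, tuning basis, weights, trials, datasets.

test_that("sim_params validates its inputs and reports signal strength", {
  p <- sim_params(n_participants = 2, n_voxels = 50, noise_factor = 10)
  expect_s3_class(p, "sim_params")
  expect_equal(signal_strength(p), 0.1)
  expect_equal(signal_strength(sim_params(noise_factor = 0)), Inf)

  expect_error(sim_params(n_participants = 0), "counts")
  expect_error(sim_params(noise_sd = 0), "noise_sd")
  expect_error(sim_params(noise_factor = -1), "noise_factor")
  expect_error(sim_params(basis_power = 0.5), "basis_power")
  expect_error(sim_params(trials_per_run_per_condition = 10), "multiple")
})

test_that("basis channels are rectified, periodic, and circulant at the labels", {
  b <- make_basis(12, 11)
  labs <- stimulus_orientations(12)
  expect_equal(labs[1], 7.5)
  expect_equal(diff(labs), rep(15, 11))

  r <- basis_response(b, 7.5)
  expect_equal(r[1, 1], 1)                      # peak at the center
  expect_equal(basis_response(b, 97.5)[1, 1], 0) # zero at the orthogonal
  # independently evaluated scalar reference: max(0, cos(2*15*pi/180))^11
  expect_equal(basis_response(b, 22.5)[1, 1], 0.205511887812, tolerance = 1e-10)
  expect_equal(basis_response(b, 37.5)[1, 1], 0.00048828125, tolerance = 1e-12)

  R <- basis_response(b, labs)                  # 12 x 12 channel matrix
  expect_true(all(R >= 0))
  for (k in 1:11) {                             # circulant: each row a shift
    expect_equal(R[k + 1, ], R[k, c(12, 1:11)], tolerance = 1e-12)
  }
  # 180-degree periodicity and wrapping
  theta <- c(3, 91.2, 140)
  expect_equal(basis_response(b, theta), basis_response(b, theta + 180),
               tolerance = 1e-12)

  expect_error(make_basis(1, 11), "n_channels")
  expect_error(make_basis(12, 0), "power")
})

test_that("weight matrices are reproducible, participant-specific, standard normal", {
  p <- tiny_params()
  W1 <- sample_weights(p, 1)
  expect_identical(W1, sample_weights(p, 1))     # same seed + participant
  expect_false(isTRUE(all.equal(W1, sample_weights(p, 2))))
  expect_equal(dim(W1), c(p$n_voxels, p$n_channels))

  # law of large numbers on a 10^6-entry draw: mean within 4 standard errors
  big <- sim_params(n_participants = 1, n_voxels = 50000, n_channels = 20,
                    seed = 1)
  Wb <- sample_weights(big, 1)
  expect_lt(abs(mean(Wb)), 4 / sqrt(length(Wb)))
  expect_equal(sd(Wb), 1, tolerance = 0.01)
})

test_that("orientation activity is linear in the signal factor", {
  p <- tiny_params()
  b <- make_basis(p$n_channels, p$basis_power)
  W <- sample_weights(p, 1)
  expect_equal(orientation_activity(W, b, 33, 0), rep(0, p$n_voxels))
  a1 <- orientation_activity(W, b, 33, 1)
  expect_equal(orientation_activity(W, b, 33, 2), 2 * a1)
  # one-hot weights: voxel picks out a single channel's response
  W1 <- matrix(0, 4, p$n_channels); W1[2, 1] <- 1
  expect_equal(orientation_activity(W1, b, 7.5, 3)[2], 3)
  expect_equal(orientation_activity(W1, b, 7.5, 3)[1], 0)
})

test_that("simulate_trial follows the load/capacity generative rules", {
  p <- tiny_params(noise_factor = 0)
  b <- make_basis(p$n_channels, p$basis_power)
  W <- sample_weights(p, 1)
  a1 <- orientation_activity(W, b, 7.5, p$signal_factor)
  a2 <- orientation_activity(W, b, 97.5, p$signal_factor)

  expect_error(simulate_trial(W, b, 7.5, "cap2", p), "load-2")
  expect_error(simulate_trial(W, b, c(7.5, 97.5), "na", p), "capacity_mode")
  expect_error(simulate_trial(W, b, c(1, 2, 3), "cap2", p), "one or two")

  expect_equal(as.vector(simulate_trial(W, b, 7.5, "na", p)), a1)
  expect_equal(as.vector(simulate_trial(W, b, c(7.5, 97.5), "cap2", p)),
               a1 + a2)
  set.seed(1)
  one <- simulate_trial(W, b, c(7.5, 97.5), "cap1", p)
  expect_true(isTRUE(all.equal(as.vector(one), a1)) ||
                isTRUE(all.equal(as.vector(one), a2)))
  expect_equal(as.vector(one),
               list(a1, a2)[[attr(one, "represented_item")]])
})

test_that("injected noise has the calibrated scale", {
  p <- sim_params(n_participants = 1, n_voxels = 100000, noise_factor = 5,
                  seed = 3)
  b <- make_basis(p$n_channels, p$basis_power)
  W <- sample_weights(p, 1)
  act <- orientation_activity(W, b, 52.5, p$signal_factor)
  set.seed(9)
  resid <- as.vector(simulate_trial(W, b, 52.5, "na", p)) - act
  # var = (noise_factor * sd)^2 = 25, within 3 Monte-Carlo SEs at 10^5 draws
  se <- 25 * sqrt(2 / length(resid))
  expect_lt(abs(var(resid) - 25), 3 * se)
  expect_lt(abs(mean(resid)), 3 * 5 / sqrt(length(resid)))
})

test_that("simulated datasets have the right design and are deterministic", {
  p <- sim_params(n_participants = 2, n_runs = 4, n_voxels = 30,
                  trials_per_run_per_condition = 12, noise_factor = 5,
                  seed = 5)
  ds <- simulate_dataset(p, "load1")
  expect_equal(nrow(ds$design), 2 * 4 * 12)     # participants x runs x trials
  expect_equal(nrow(ds$data), nrow(ds$design))
  expect_true(all(is.na(ds$design$label_2)))

  # counterbalancing: every orientation once per run (12 trials, 12 labels)
  labs <- stimulus_orientations(12)
  for (r in 1:4) {
    run_labels <- ds$design$label_1[ds$design$participant == 1 &
                                      ds$design$run == r]
    expect_equal(sort(run_labels), labs)
  }

  expect_identical(ds, simulate_dataset(p, "load1"))  # bit-identical rerun
  expect_false(identical(ds$data,
                         simulate_dataset(p, "load1", iteration = 1)$data))

  # load-2 labels drawn from the discrete set, independently of item 1
  ds2 <- simulate_dataset(p, "load2-cap2")
  expect_true(all(ds2$design$label_2 %in% labs))
  dsx <- simulate_dataset(p, "load2-cap2", exclude_duplicate_labels = TRUE)
  expect_true(all(dsx$design$label_1 != dsx$design$label_2))

  # subsetting participants must not change anyone's data
  both <- simulate_dataset(p, "load1")
  solo <- simulate_dataset(p, "load1", participants = 2)
  expect_equal(solo$data,
               both$data[both$design$participant == 2, , drop = FALSE])

  expect_error(simulate_dataset(p, character(0)), "at least one")
  expect_error(simulate_dataset(p, "load3"), "unknown condition")
})

test_that("noise-free capacity-2 patterns are the exact sum of the item patterns", {
  p <- sim_params(n_participants = 1, n_voxels = 40, noise_factor = 0,
                  trials_per_run_per_condition = 12, seed = 8)
  b <- make_basis(p$n_channels, p$basis_power)
  W <- sample_weights(p, 1)
  ds <- simulate_dataset(p, "load2-cap2")
  A1 <- orientation_activity(W, b, ds$design$label_1, p$signal_factor)
  A2 <- orientation_activity(W, b, ds$design$label_2, p$signal_factor)
  expect_equal(unname(ds$data), unname(A1 + A2), tolerance = 1e-12)

  dsc1 <- simulate_dataset(p, "load2-cap1")
  picked <- ifelse(dsc1$design$represented_item == 1,
                   dsc1$design$label_1, dsc1$design$label_2)
  expect_equal(unname(dsc1$data),
               unname(orientation_activity(W, b, picked, p$signal_factor)),
               tolerance = 1e-12)
})

test_that("behavioral responses recover the generating circular SD", {
  expect_error(simulate_behavior(2, c(a = 0)), "SD")
  expect_error(simulate_behavior(2, 0.1), "named")

  # tiny SD: responses essentially equal targets (wrap-aware)
  b0 <- simulate_behavior(2, c(load1 = 1e-6), trials_per_condition = 50)
  d <- (b0$response_deg - b0$target_deg + 90) %% 180 - 90
  expect_lt(max(abs(d)), 0.01)

  # recovery at n = 1e5 for the two reported precision levels
  big <- simulate_behavior(1, c(load1 = 1 / 4.80, load2 = 1 / 4.24),
                           trials_per_condition = 100000, seed = 2)
  for (cond in c("load1", "load2")) {
    sub <- big[big$condition == cond, ]
    pr <- circular_precision(sub$target_deg, sub$response_deg)
    expect_equal(pr$precision, c(load1 = 4.80, load2 = 4.24)[[cond]],
                 tolerance = 0.02)
  }
})

test_that("timecourse fixture rotates the code as requested", {
  p <- sim_params(n_participants = 1, n_voxels = 40, noise_factor = 0,
                  trials_per_run_per_condition = 12, n_runs = 2, seed = 4)
  stable <- simulate_timecourse(p, n_timepoints = 3, code_rotation = 0)
  d1 <- stable$data[stable$design$time == 1, ]
  for (t in 2:3) {
    expect_equal(unname(stable$data[stable$design$time == t, ]), unname(d1))
  }
  # full cycle: 15-degree steps with 12 channels return to the start
  cyc <- simulate_timecourse(p, n_timepoints = 13, code_rotation = 15)
  expect_equal(unname(cyc$data[cyc$design$time == 13, ]),
               unname(cyc$data[cyc$design$time == 1, ]), tolerance = 1e-10)
  expect_false(isTRUE(all.equal(unname(cyc$data[cyc$design$time == 2, ]),
                                unname(cyc$data[cyc$design$time == 1, ]))))
  expect_error(simulate_timecourse(p, 1, 0), "n_timepoints")
})
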