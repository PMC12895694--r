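# Shared fixtures, built in code and cached for the duration of the test run.

.fix <- new.env(parent = emptyenv())

# small, fast parameter set for unit tests (not the experiment's scale)
tiny_params <- function(...) {
  args <- list(n_participants = 3, n_runs = 3, n_voxels = 60,
               trials_per_run_per_condition = 12, noise_factor = 2,
               seed = 42)
  args[names(list(...))] <- list(...)
  do.call(sim_params, args)
}

# strong-signal two-condition dataset used by several decoding tests
strong_signal_dataset <- function() {
  if (is.null(.fix$strong)) {
    p <- sim_params(n_participants = 2, n_runs = 4, n_voxels = 80,
                    trials_per_run_per_condition = 12, noise_factor = 0.1,
                    seed = 7)
    .fix$strong <- simulate_dataset(p, c("load1", "load2-cap2"))
  }
  .fix$strong
}

# capacity experiment at the reference scale (81 participants, 1000 voxels,
# 48 trials/run/condition) but with few iterations; shared by the acceptance
# tests for criteria 1 and 4. Scale-down from the nominal 100 iterations is
# deliberate (runtime budget); tolerances below use the criterion's guideline
# bands plus the measured Monte-Carlo SE.
acceptance_capacity_result <- function() {
  if (is.null(.fix$capacity)) {
    spec <- capacity_spec(signal_strengths = c(0.1, 0.08, 0.05),
                          n_iterations = 6,
                          params = sim_params(seed = 20260911L))
    .fix$capacity <- run_capacity_experiment(spec)
  }
  .fix$capacity
}
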