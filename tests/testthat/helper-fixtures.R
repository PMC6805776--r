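# Shared fixtures, computed lazily and cached for the whole test file.

.fixture_cache <- new.env(parent = emptyenv())

# steady-state-consistent published parameterization + its equilibrium
consistent_fixture <- function() {
  if (is.null(.fixture_cache$eq))
    .fixture_cache$eq <- solve_consistent_equilibrium()
  .fixture_cache$eq
}

# small noisy calibration suite (fixed seed)
suite_fixture <- function() {
  if (is.null(.fixture_cache$suite))
    .fixture_cache$suite <-
      generate_calibration_suite(synth_design(seed = 1234))
  .fixture_cache$suite
}

# a parameter set with every value zero (null system)
zero_parameters <- function() {
  p <- hif_parameters()
  p$values[] <- 0
  p
}

# random non-negative state, reproducible given an RNG state
random_state <- function() {
  stats::setNames(stats::runif(10, 0, 5), paste0("y", 1:10))
}
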