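# Shared fixtures: the default workflow operating point and random
# parameter draws for property-style tests.

# defaults for a hypothetical 12k x 12k px serial-section EM workflow
default_workflow <- function(...) acquisition_params(...)

# the hand-traced pipeline toy: compute idles at the section boundary then
# backlogs, so the parallel closed form (510 s) underestimates the
# simulated makespan (530 s)
toy_params <- function() {
  acquisition_params(n_sections = 2, n_tiles = 2, t_section_s = 100,
                     t_tile_s = 0, t_fast_s = 10, t_compute_s = 50,
                     t_slow_s = 0, t_trad_s = 1)
}

# random workflow draw; small tile counts keep simulated logs cheap
random_params <- function() {
  acquisition_params(
    quality_standard = stats::runif(1, 0.52, 1),
    n_tiles = sample(1:6, 1),
    n_sections = sample(1:5, 1),
    t_trad_s = stats::runif(1, 0, 200),
    t_fast_s = stats::runif(1, 0, 50),
    t_slow_s = stats::runif(1, 0, 200),
    t_compute_s = stats::runif(1, 0, 100),
    t_tile_s = stats::runif(1, 0, 10),
    t_section_s = stats::runif(1, 0, 50)
  )
}

expect_close <- function(object, expected, tol = 1e-9) {
  expect_equal(object, expected, tolerance = tol)
}
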