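test_that("specimens are deterministic, seed-sensitive and membrane-like", {
  s1 <- generate_specimen(256, 256, seed = 1)
  s1b <- generate_specimen(256, 256, seed = 1)
  expect_identical(s1$labels, s1b$labels)
  frac <- mean(s1$labels)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.40)
  s2 <- generate_specimen(256, 256, seed = 2)
  expect_gt(mean(s1$labels != s2$labels), 0.01)
  expect_error(generate_specimen(8, 8, seed = 1))
  # both classes present even at the minimum size
  tiny <- generate_specimen(16, 16, seed = 3)
  expect_setequal(unique(as.vector(tiny$labels)), c(0L, 1L))
})

test_that("scans are deterministic per seed and noise-free in the limit", {
  s <- generate_specimen(64, 64, seed = 5)
  a <- simulate_scan(s, 100, seed = 9)
  b <- simulate_scan(s, 100, seed = 9)
  expect_identical(a$intensities, b$intensities)
  clean <- simulate_scan(s, 1200, seed = 1, noise = FALSE)
  # normalized expected-count map: 1.0 on membrane, 0.3 on background
  expect_equal(sort(unique(as.vector(clean$intensities))), c(0.3, 1))
  expect_error(simulate_scan(s, -5, seed = 1))
})

test_that("higher dwell gives higher class separation (Poisson SNR)", {
  set.seed(99)
  sep <- function(scan, truth) {
    x <- scan$intensities
    mem <- x[truth$labels == 1L]
    bg <- x[truth$labels == 0L]
    (mean(mem) - mean(bg)) / sqrt((stats::var(mem) + stats::var(bg)) / 2)
  }
  wins <- 0L
  for (seed in 1:20) {
    s <- generate_specimen(128, 128, seed = seed)
    slow <- simulate_scan(s, 1200, seed = 1000 + seed)
    fast <- simulate_scan(s, 25, seed = 2000 + seed)
    if (sep(slow, s) > sep(fast, s)) wins <- wins + 1L
  }
  expect_equal(wins, 20L)
})

test_that("rescan masks hit their target fraction within quantization", {
  m <- rescan_mask(256, 256, 0.37, seed = 1, strategy = "uniform_random")
  expect_lte(abs(mean(m$mask) - 0.37), 1 / sqrt(256 * 256))
  mb <- rescan_mask(256, 256, 0.37, seed = 1, strategy = "random_blocks",
                    block_px = 32)
  expect_lte(abs(mean(mb$mask) - 0.37), (32 * 32) / (256 * 256))
  expect_equal(mean(rescan_mask(64, 64, 0, seed = 1)$mask), 0)
  expect_equal(mean(rescan_mask(64, 64, 1, seed = 1)$mask), 1)
})

test_that("compose_mixed conserves pixels from exactly one source", {
  s <- generate_specimen(64, 64, seed = 2)
  fast <- simulate_scan(s, 25, seed = 3)
  slow <- simulate_scan(s, 1200, seed = 4)
  zero <- rescan_mask(64, 64, 0, seed = 1)
  one <- rescan_mask(64, 64, 1, seed = 1)
  expect_identical(compose_mixed(fast, slow, zero)$intensities,
                   fast$intensities)
  expect_identical(compose_mixed(fast, slow, one)$intensities,
                   slow$intensities)
  # checkerboard: verify against an explicit pixel loop
  cb <- outer(1:64, 1:64, function(i, j) as.integer((i + j) %% 2 == 0))
  mixed <- compose_mixed(fast, slow, cb)$intensities
  brute <- fast$intensities
  for (i in 1:64) for (j in 1:64) {
    if (cb[i, j] == 1L) brute[i, j] <- slow$intensities[i, j]
  }
  expect_identical(mixed, brute)
  # every pixel comes from one of the two inputs
  expect_true(all(mixed == fast$intensities | mixed == slow$intensities))
  small <- simulate_scan(generate_specimen(32, 32, seed = 1), 25, seed = 1)
  expect_error(compose_mixed(fast, small, zero), "shapes must match")
})

test_that("segmentation scores perfectly separable input at 1.0", {
  s <- generate_specimen(128, 128, seed = 7)
  clean <- simulate_scan(s, 1200, seed = 1, noise = FALSE)
  # two exact intensity levels: thresholding alone separates them
  expect_equal(segment_and_score(clean, s, sigma = 0), 1.0)
  # polarity is arbitrary: an inverted perfect map still scores 1.0
  inverted <- 1 - clean$intensities
  expect_equal(segment_and_score(inverted, s, sigma = 0), 1.0)
})

test_that("pure noise degenerates to majority-class accuracy", {
  # near-zero dwell: almost every pixel counts zero electrons, so the
  # thresholded prediction degenerates to (close to) the majority class
  accs <- prior <- numeric(20)
  for (k in 1:20) {
    s <- generate_specimen(128, 128, seed = 300 + k)
    starved <- simulate_scan(s, 0.1, seed = 500 + k)
    accs[k] <- segment_and_score(starved, s)
    prior[k] <- max(mean(s$labels), 1 - mean(s$labels))
  }
  expect_lt(abs(mean(accs) - mean(prior)), 0.03)
  # constant images don't error
  s <- generate_specimen(64, 64, seed = 1)
  flat <- structure(list(intensities = matrix(0.5, 64, 64), dwell_ns = 1,
                         seed = 1), class = "scan_image")
  expect_true(segment_and_score(flat, s) >= 0.5)
})

test_that("estimate_quality_curve reports replicates, CIs and a monotone fit", {
  est <- estimate_quality_curve(seeds = 1:5, fractions = c(0, 0.5, 1),
                                width = 96, height = 96)
  expect_equal(est$samples$n_replicates, rep(5L, 3))
  expect_true(all(est$samples$ci_low <= est$samples$quality &
                    est$samples$quality <= est$samples$ci_high))
  expect_true(validate_quality_curve(est$curve, 101)$pass)
  expect_gt(est$samples$quality[3], est$samples$quality[1])
  expect_equal(dim(est$raw), c(3L, 5L))
  # deterministic given the same seeds
  est2 <- estimate_quality_curve(seeds = 1:5, fractions = c(0, 0.5, 1),
                                 width = 96, height = 96)
  expect_identical(est$raw, est2$raw)
})

test_that("an estimated curve closes the loop with the planner", {
  est <- estimate_quality_curve(seeds = 1:6, fractions = seq(0, 1, 0.25),
                                width = 96, height = 96)
  q_target <- mean(range(est$samples$quality))
  a <- invert_for_alpha(est$curve, q_target)
  expect_gte(est$curve$fun(a), q_target - 1e-6)
  # re-running the pipeline near alpha achieves the target up to
  # interpolation and replication error
  s <- generate_specimen(96, 96, seed = 123)
  fast <- simulate_scan(s, 25, seed = 124)
  slow <- simulate_scan(s, 1200, seed = 125)
  accs <- vapply(1:6, function(k) {
    m <- rescan_mask(96, 96, a, seed = 400 + k)
    segment_and_score(compose_mixed(fast, slow, m), s)
  }, numeric(1))
  expect_gt(mean(accs), q_target - 0.05)
})

test_that("images round-trip through plain-text PGM", {
  s <- generate_specimen(32, 32, seed = 9)
  scan <- simulate_scan(s, 400, seed = 10)
  path <- withr::local_tempfile(fileext = ".pgm")
  write_pgm(pmin(scan$intensities, 1), path)
  back <- read_pgm(path)
  expect_equal(dim(back), dim(scan$intensities))
  expect_lt(max(abs(back - pmin(scan$intensities, 1))), 1 / 65535)
  write_pgm(s$labels, path, maxval = 1L)
  expect_identical(read_pgm(path), s$labels + 0)
})
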