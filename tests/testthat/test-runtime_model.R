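test_that("per-tile imaging time follows pixels x dwell", {
  expect_identical(derive_tile_time(12000, 12000, 100), 14.4)
  expect_identical(derive_tile_time(12000, 12000, 1000), 144)
  expect_identical(derive_tile_time(1, 1, 1e9), 1)
  expect_error(derive_tile_time(0, 12000, 100), "positive")
  expect_error(derive_tile_time(100, 100, -1), "positive")
  p <- params_from_tiles(12000, 12000, 100, 1000)
  expect_equal(p$t_fast_s, 14.4)
  expect_equal(p$t_slow_s, 144)
  expect_equal(p$t_trad_s, 144)
})

test_that("analytic runtimes match hand-evaluated values at the defaults", {
  p <- default_workflow()
  expect_equal(traditional_runtime(p), 107160)
  expect_equal(serial_smart_runtime(p, 0), 34584)
  expect_equal(serial_smart_runtime(p, 1), 138264)
  # alpha from inverting the logistic curve at Q = 0.8
  a <- invert_for_alpha(logistic_quality_curve(), 0.8)
  expect_close(parallel_smart_runtime(p, a), 57365.6596, tol = 1e-4)
})

test_that("degenerate workflows evaluate as written", {
  zero <- acquisition_params(t_trad_s = 0, t_fast_s = 0, t_slow_s = 0,
                             t_compute_s = 0, t_tile_s = 0, t_section_s = 0)
  expect_equal(traditional_runtime(zero), 0)
  expect_equal(serial_smart_runtime(zero, 0.5), 0)
  one <- acquisition_params(n_sections = 1, n_tiles = 1, t_section_s = 0,
                            t_tile_s = 0, t_trad_s = 10)
  expect_equal(traditional_runtime(one), 10)
  # single tile: both max operands vanish, no overlap possible
  one2 <- acquisition_params(n_sections = 1, n_tiles = 1, t_section_s = 0,
                             t_tile_s = 0, t_fast_s = 7, t_compute_s = 3)
  expect_equal(parallel_smart_runtime(one2, 0), 10)
  # hand-traced toy value of the parallel closed form
  expect_equal(parallel_smart_runtime(toy_params(), 0), 510)
})

test_that("parameter validation rejects invalid workflows and plans", {
  expect_error(acquisition_params(n_tiles = 0), "positive integer")
  expect_error(acquisition_params(n_sections = 2.5), "positive integer")
  expect_error(acquisition_params(t_fast_s = -1), "non-negative")
  expect_error(acquisition_params(quality_standard = 1.2), "\\[0, 1\\]")
  expect_error(rescan_plan(-0.1), "\\[0, 1\\]")
  expect_error(rescan_plan(1.1), "\\[0, 1\\]")
  expect_error(serial_smart_runtime(default_workflow(), 2), "\\[0, 1\\]")
})

test_that("runtimes are affine in alpha and monotone in every parameter", {
  set.seed(42)
  for (i in 1:25) {
    p <- random_params()
    a <- stats::runif(2)
    for (fn in c(serial_smart_runtime, parallel_smart_runtime)) {
      r0 <- fn(p, 0)
      r1 <- fn(p, 1)
      # affine: value at alpha equals linear interpolation of the endpoints
      expect_close(fn(p, a[1]), r0 + a[1] * (r1 - r0), tol = 1e-12)
      expect_true(fn(p, max(a)) >= fn(p, min(a)))
    }
    # non-decreasing in each time parameter
    for (f in c("t_trad_s", "t_fast_s", "t_slow_s", "t_compute_s",
                "t_tile_s", "t_section_s")) {
      q <- p
      q[[f]] <- q[[f]] + 1
      expect_true(traditional_runtime(q) >= traditional_runtime(p))
      expect_true(serial_smart_runtime(q, a[1]) >=
                    serial_smart_runtime(p, a[1]))
      expect_true(parallel_smart_runtime(q, a[1]) >=
                    parallel_smart_runtime(p, a[1]))
    }
    # linear in the number of sections
    q <- p
    q$n_sections <- 2 * p$n_sections
    expect_close(traditional_runtime(q), 2 * traditional_runtime(p))
    expect_close(serial_smart_runtime(q, a[1]),
                 2 * serial_smart_runtime(p, a[1]))
  }
})

test_that("serial runtime at alpha = 0 is traditional with T_trad -> T_f + T_c", {
  set.seed(7)
  for (i in 1:10) {
    p <- random_params()
    q <- p
    q$t_trad_s <- p$t_fast_s + p$t_compute_s
    expect_close(serial_smart_runtime(p, 0), traditional_runtime(q))
  }
})

test_that("parallel runtime with T_c = 0, alpha = 0 is a fast pass plus a transition pass", {
  set.seed(8)
  for (i in 1:10) {
    p <- random_params()
    p$t_compute_s <- 0
    ns <- p$n_sections
    nt <- p$n_tiles
    expected <- ns * (p$t_section_s + nt * (p$t_tile_s + p$t_fast_s)) +
      ns * (p$t_section_s + nt * p$t_tile_s)
    expect_close(parallel_smart_runtime(p, 0), expected)
  }
})

test_that("parallel closed form matches its two-stage pipeline identity", {
  # Eq: total = max{A_n + T_c, a_1 + n T_c} + rescan pass, where
  # a_1 = T_t' + T_t + T_f (first arrival) and A_n = full fast-pass span
  set.seed(9)
  for (i in 1:50) {
    p <- random_params()
    a <- stats::runif(1)
    n <- p$n_sections * p$n_tiles
    a1 <- p$t_section_s + p$t_tile_s + p$t_fast_s
    An <- p$n_sections * (p$t_section_s +
                            p$n_tiles * (p$t_tile_s + p$t_fast_s))
    rescan <- p$n_sections * (p$t_section_s +
                                p$n_tiles * (p$t_tile_s + a * p$t_slow_s))
    expect_close(parallel_smart_runtime(p, a),
                 max(An + p$t_compute_s, a1 + n * p$t_compute_s) + rescan)
  }
})

test_that("compare_modes returns the minimizer with a deterministic tie-break", {
  p <- default_workflow()
  a <- invert_for_alpha(logistic_quality_curve(), 0.8)
  v <- compare_modes(p, a)
  expect_s3_class(v, "mode_verdict")
  expect_identical(v$fastest_mode, "smart_parallel_global")
  expect_equal(unname(v$per_mode_totals["traditional"]), 107160)
  expect_true(v$margin_s >= 0)
  expect_equal(min(v$per_mode_totals),
               v$per_mode_totals[[v$fastest_mode]])

  # huge compute time makes traditional fastest
  slow_c <- acquisition_params(t_compute_s = 1e6)
  expect_identical(compare_modes(slow_c, a)$fastest_mode, "traditional")

  # exact tie between traditional and serial smart: traditional reported
  tie <- acquisition_params(t_fast_s = 144, t_compute_s = 0, t_slow_s = 0)
  vt <- compare_modes(tie, 1)
  expect_identical(vt$fastest_mode, "traditional")
  expect_equal(vt$margin_s, 0)
})

test_that("breakeven_alpha solves the linear crossing or flags none", {
  p <- default_workflow()
  be <- breakeven_alpha(p, "smart_serial")
  expect_identical(be$status, "crossing")
  expect_close(be$alpha, (144 - 14.4 - 28.8) / 144)
  # fast + compute alone slower than traditional: smart never wins
  never <- acquisition_params(t_fast_s = 100, t_compute_s = 100)
  expect_identical(breakeven_alpha(never, "smart_serial")$status,
                   "never_faster")
  # free rescans and cheap fast pass: smart always wins
  always <- acquisition_params(t_slow_s = 0)
  ba <- breakeven_alpha(always, "smart_serial")
  expect_identical(ba$status, "always_faster")
  expect_true(is.na(ba$alpha))
  # crossing value actually equates the runtimes
  set.seed(11)
  for (i in 1:20) {
    q <- random_params()
    b <- breakeven_alpha(q, "smart_parallel_global")
    if (b$status == "crossing") {
      expect_close(parallel_smart_runtime(q, b$alpha),
                   traditional_runtime(q), tol = 1e-8)
    }
  }
})

test_that("runtime breakdowns account for the totals", {
  p <- default_workflow()
  a <- 0.3
  for (m in c("traditional", "smart_serial")) {
    b <- runtime_breakdown(p, a, mode = m)
    expect_close(sum(b$components), b$total_s)
  }
  bp <- runtime_breakdown(p, a, mode = "smart_parallel_global")
  expect_true(sum(bp$components) >= bp$total_s) # overlap hides compute
})
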