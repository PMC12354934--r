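#' Traditional acquisition runtime
#'
#' Total imaging time for the traditional workflow, in which every tile is
#' imaged once at the traditional rate:
#' \deqn{T_{single} = N_s (T_t' + N_t (T_t + T_{trad}))}
#'
#' @param p An `acq_params` object, see [acquisition_params()].
#' @return Runtime in seconds.
#' @examples
#' traditional_runtime(acquisition_params())  # 107160
#' @export
traditional_runtime <- function(p) {
  validate_acquisition_params(p)
  p$n_sections * (p$t_section_s + p$n_tiles * (p$t_tile_s + p$t_trad_s))
}

#' Serial smart acquisition runtime
#'
#' End-to-end runtime when each tile is, in turn, fast-scanned, its rescan
#' mask computed, and a fraction \eqn{\alpha} of it rescanned at the slow
#' rate, all on a single serial timeline:
#' \deqn{T_{smart} = N_s (T_t' + N_t (T_t + T_f + T_c + \alpha T_s))}
#'
#' @inheritParams traditional_runtime
#' @param plan A [rescan_plan()] or a bare rescan fraction in \[0, 1\].
#' @return Runtime in seconds.
#' @examples
#' serial_smart_runtime(acquisition_params(), 0)  # 34584
#' @export
serial_smart_runtime <- function(p, plan) {
  validate_acquisition_params(p)
  alpha <- as_alpha(plan)
  p$n_sections * (p$t_section_s +
    p$n_tiles * (p$t_tile_s + p$t_fast_s + p$t_compute_s + alpha * p$t_slow_s))
}

#' Parallel smart acquisition runtime (global pipelining)
#'
#' End-to-end runtime when the fast-scan pass over all sections overlaps
#' with rescan-mask computation on a second thread, followed by a full
#' rescan pass:
#' \deqn{T_{smart,par} = \big(T_t' + T_t + T_f +
#'   \max\{(N_s-1)T_t' + (N_sN_t-1)(T_t+T_f),\ (N_sN_t-1)T_c\} + T_c\big)
#'   + N_s (T_t' + N_t (T_t + \alpha T_s))}
#'
#' The max term selects the pipeline bottleneck: the imaging thread (left
#' operand) or the computation thread (right operand). The rescan pass
#' charges a full tile transition per tile and section transition per
#' section even when the rescanned area is zero.
#'
#' This closed form is a lower bound on the schedule produced by a FIFO
#' producer/consumer simulation: it is exact whenever the computation
#' thread either never backlogs (\eqn{T_c \le T_t + T_f}) or never idles
#' after the first tile (\eqn{T_c \ge T_t' + T_t + T_f}); between those
#' regimes compute can idle at a section boundary and then backlog, and the
#' simulated makespan can exceed this value. See
#' [validate_against_analytic()].
#'
#' @inheritParams serial_smart_runtime
#' @return Runtime in seconds.
#' @examples
#' parallel_smart_runtime(acquisition_params(), 0.32)
#' @export
parallel_smart_runtime <- function(p, plan) {
  validate_acquisition_params(p)
  alpha <- as_alpha(plan)
  n <- p$n_sections * p$n_tiles
  first_pass <- p$t_section_s + p$t_tile_s + p$t_fast_s +
    max((p$n_sections - 1) * p$t_section_s +
          (n - 1) * (p$t_tile_s + p$t_fast_s),
        (n - 1) * p$t_compute_s) +
    p$t_compute_s
  rescan_pass <- p$n_sections *
    (p$t_section_s + p$n_tiles * (p$t_tile_s + alpha * p$t_slow_s))
  first_pass + rescan_pass
}

mode_labels <- c("traditional", "smart_serial", "smart_parallel_global")

#' Runtime breakdown by pipeline step
#'
#' Decomposes the analytic runtime of one acquisition mode into section
#' transitions, tile transitions, initial scan, compute and rescan
#' components. For serial modes the components sum to the total; for the
#' parallel mode the components sum to at least the total because compute
#' overlaps imaging.
#'
#' @inheritParams serial_smart_runtime
#' @param mode One of `"traditional"`, `"smart_serial"`,
#'   `"smart_parallel_global"`.
#' @return A list of class `runtime_breakdown` with elements `mode`,
#'   `total_s` and `components` (named numeric vector over
#'   `section_transitions`, `tile_transitions`, `initial_scan`, `compute`,
#'   `rescan`).
#' @export
runtime_breakdown <- function(p, plan = rescan_plan(0),
                              mode = c("traditional", "smart_serial",
                                       "smart_parallel_global")) {
  mode <- match.arg(mode)
  validate_acquisition_params(p)
  alpha <- as_alpha(plan)
  n <- p$n_sections * p$n_tiles
  comp <- switch(mode,
    traditional = c(
      section_transitions = p$n_sections * p$t_section_s,
      tile_transitions = n * p$t_tile_s,
      initial_scan = n * p$t_trad_s,
      compute = 0,
      rescan = 0
    ),
    smart_serial = c(
      section_transitions = p$n_sections * p$t_section_s,
      tile_transitions = n * p$t_tile_s,
      initial_scan = n * p$t_fast_s,
      compute = n * p$t_compute_s,
      rescan = n * alpha * p$t_slow_s
    ),
    smart_parallel_global = c(
      section_transitions = 2 * p$n_sections * p$t_section_s,
      tile_transitions = 2 * n * p$t_tile_s,
      initial_scan = n * p$t_fast_s,
      compute = n * p$t_compute_s,
      rescan = n * alpha * p$t_slow_s
    )
  )
  total <- switch(mode,
    traditional = traditional_runtime(p),
    smart_serial = serial_smart_runtime(p, alpha),
    smart_parallel_global = parallel_smart_runtime(p, alpha)
  )
  structure(list(mode = mode, total_s = total, components = comp),
            class = "runtime_breakdown")
}

#' @export
print.runtime_breakdown <- function(x, ...) {
  cat(sprintf("Runtime breakdown [%s]: total %.1f s\n", x$mode, x$total_s))
  for (nm in names(x$components)) {
    cat(sprintf("  %-20s %.1f s\n", nm, x$components[[nm]]))
  }
  invisible(x)
}

#' Compare acquisition modes
#'
#' Evaluates the traditional, serial-smart and parallel-smart analytic
#' runtimes at a common operating point and reports which mode is fastest
#' and by how much. Ties are broken deterministically in the fixed order
#' traditional < smart_serial < smart_parallel_global.
#'
#' @inheritParams serial_smart_runtime
#' @return A list of class `mode_verdict` with `fastest_mode`, `margin_s`
#'   (seconds saved relative to the second-fastest mode) and
#'   `per_mode_totals` (named numeric vector).
#' @examples
#' p <- acquisition_params()
#' a <- invert_for_alpha(logistic_quality_curve(), p$quality_standard)
#' compare_modes(p, a)
#' @export
compare_modes <- function(p, plan) {
  validate_acquisition_params(p)
  alpha <- as_alpha(plan)
  totals <- c(
    traditional = traditional_runtime(p),
    smart_serial = serial_smart_runtime(p, alpha),
    smart_parallel_global = parallel_smart_runtime(p, alpha)
  )
  best <- which.min(totals) # first minimum wins: fixed order tie-break
  margin <- sort(totals)[2] - totals[[best]]
  structure(list(
    fastest_mode = names(totals)[best],
    margin_s = unname(margin),
    per_mode_totals = totals,
    alpha = alpha
  ), class = "mode_verdict")
}

#' @export
print.mode_verdict <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' @export
format.mode_verdict <- function(x, ...) {
  c(sprintf("Fastest mode: %s (alpha = %g)", x$fastest_mode, x$alpha),
    sprintf("  saves %.1f s over the second-fastest mode", x$margin_s),
    sprintf("  %-22s %.1f s", names(x$per_mode_totals), x$per_mode_totals))
}

#' Break-even rescan fraction against traditional imaging
#'
#' The smart runtimes are affine and non-decreasing in the rescan fraction
#' \eqn{\alpha}, so the \eqn{\alpha} at which a smart mode's runtime equals
#' the traditional runtime has a closed form. For the serial mode it is
#' \eqn{\alpha^* = (T_{trad} - T_f - T_c)/T_s}.
#'
#' @inheritParams traditional_runtime
#' @param mode `"smart_serial"` or `"smart_parallel_global"`.
#' @return A list of class `breakeven` with `alpha` (the crossing point, or
#'   `NA` if none exists in \[0, 1\]) and `status`, one of `"crossing"`,
#'   `"always_faster"` (smart beats traditional on all of \[0, 1\]) or
#'   `"never_faster"`.
#' @examples
#' breakeven_alpha(acquisition_params(), "smart_serial")$alpha  # 0.7
#' @export
breakeven_alpha <- function(p, mode = c("smart_serial",
                                        "smart_parallel_global")) {
  mode <- match.arg(mode)
  validate_acquisition_params(p)
  fn <- switch(mode,
    smart_serial = serial_smart_runtime,
    smart_parallel_global = parallel_smart_runtime
  )
  t_trad <- traditional_runtime(p)
  r0 <- fn(p, 0)
  r1 <- fn(p, 1)
  # runtime is affine in alpha with slope r1 - r0 >= 0
  if (r0 > t_trad) {
    res <- list(alpha = NA_real_, status = "never_faster")
  } else if (r1 <= t_trad) {
    status <- if (r1 == t_trad) "crossing" else "always_faster"
    res <- list(alpha = if (r1 == t_trad) 1 else NA_real_, status = status)
  } else if (r1 == r0) { # t_slow_s == 0 with unequal endpoints
    res <- list(alpha = NA_real_,
                status = if (r0 <= t_trad) "always_faster" else "never_faster")
  } else {
    res <- list(alpha = (t_trad - r0) / (r1 - r0), status = "crossing")
  }
  structure(res, class = "breakeven")
}

#' @export
print.breakeven <- function(x, ...) {
  if (x$status == "crossing") {
    cat(sprintf("Break-even rescan fraction: alpha* = %g\n", x$alpha))
  } else {
    cat(sprintf("No break-even point in [0, 1]: smart mode is %s\n",
                sub("_", " ", x$status)))
  }
  invisible(x)
}
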