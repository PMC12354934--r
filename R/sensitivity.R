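sweepable_params <- c("quality_standard", "n_tiles", "n_sections",
                      "t_fast_s", "t_slow_s", "t_compute_s",
                      "t_tile_s", "t_section_s")

#' Default one-at-a-time sweep grid for a parameter
#'
#' 25 evenly spaced points spanning 0.1x to 10x the base value (counts are
#' rounded to integers >= 1 and de-duplicated; the quality standard is
#' clamped to \[0, 1\]).
#'
#' @param base An `acq_params` object supplying the default value.
#' @param parameter One of the eight sweepable parameter names (all of the
#'   model's parameters except `t_trad_s`).
#' @param n Number of grid points.
#' @return A numeric vector of parameter values.
#' @export
default_sweep_grid <- function(base, parameter, n = 25) {
  parameter <- match.arg(parameter, sweepable_params)
  v0 <- base[[parameter]]
  if (parameter == "quality_standard") {
    return(seq(0, 1, length.out = n))
  }
  lo <- 0.1 * v0
  hi <- 10 * v0
  if (v0 == 0) {
    lo <- 0
    hi <- 1
  }
  vals <- seq(lo, hi, length.out = n)
  if (parameter %in% c("n_tiles", "n_sections")) {
    vals <- unique(pmax(1, round(vals)))
  }
  vals
}

#' Specify a one-at-a-time parameter sweep
#'
#' @inheritParams default_sweep_grid
#' @param values Ordered values to substitute for `parameter`; defaults to
#'   [default_sweep_grid()].
#' @param curve The quality curve used to recompute the rescan fraction at
#'   each grid point; defaults to the logistic curve.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(base, parameter, values = NULL,
                       curve = logistic_quality_curve()) {
  if (identical(parameter, "t_trad_s")) {
    stop("'t_trad_s' is not swept in the model's sensitivity analysis",
         call. = FALSE)
  }
  parameter <- match.arg(parameter, sweepable_params)
  validate_acquisition_params(base)
  stopifnot(inherits(curve, "quality_curve"))
  if (is.null(values)) values <- default_sweep_grid(base, parameter)
  if (!is.numeric(values) || length(values) == 0) {
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  }
  structure(list(base = base, parameter = parameter,
                 values = as.numeric(values), curve = curve),
            class = "sweep_spec")
}

#' Run a one-at-a-time sensitivity sweep
#'
#' Varies one model parameter over a grid while holding the others at their
#' base values, and evaluates the traditional, serial-smart and
#' parallel-smart runtimes at each point. The rescan fraction is re-derived
#' from the quality standard through the quality curve at every row; it
#' therefore only actually varies when `quality_standard` is the swept
#' parameter. Rows whose quality standard exceeds the curve's reachable
#' range get `NA` runtimes for the smart modes and `unreachable = TRUE`.
#'
#' @param spec A [sweep_spec()].
#' @return An object of class `sweep_result`: list with `spec` and `rows`,
#'   a data frame with columns `value`, `alpha`, `t_traditional_s`,
#'   `t_smart_serial_s`, `t_smart_parallel_s`, `unreachable`.
#' @examples
#' sw <- sweep_parameter(sweep_spec(acquisition_params(), "n_sections",
#'                                  values = c(1, 10, 30)))
#' sw$rows
#' @export
sweep_parameter <- function(spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- lapply(spec$values, function(v) {
    p <- spec$base
    p[[spec$parameter]] <- v
    bad <- tryCatch({
      validate_acquisition_params(p)
      FALSE
    }, error = function(e) TRUE)
    if (bad) {
      return(data.frame(value = v, alpha = NA_real_,
                        t_traditional_s = NA_real_,
                        t_smart_serial_s = NA_real_,
                        t_smart_parallel_s = NA_real_, unreachable = NA))
    }
    t_trad <- traditional_runtime(p)
    alpha <- tryCatch(invert_for_alpha(spec$curve, p$quality_standard),
                      error = function(e) NA_real_)
    if (is.na(alpha)) {
      data.frame(value = v, alpha = NA_real_, t_traditional_s = t_trad,
                 t_smart_serial_s = NA_real_,
                 t_smart_parallel_s = NA_real_, unreachable = TRUE)
    } else {
      data.frame(value = v, alpha = alpha, t_traditional_s = t_trad,
                 t_smart_serial_s = serial_smart_runtime(p, alpha),
                 t_smart_parallel_s = parallel_smart_runtime(p, alpha),
                 unreachable = FALSE)
    }
  })
  structure(list(spec = spec, rows = do.call(rbind, rows)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep of '%s' over %d values:\n",
              x$spec$parameter, length(x$spec$values)))
  print(utils::head(x$rows, 10))
  if (nrow(x$rows) > 10) cat(sprintf("  ... %d more rows\n", nrow(x$rows) - 10))
  invisible(x)
}

#' Time savings of smart modes over traditional imaging
#'
#' @param result A `sweep_result`.
#' @return A data frame with columns `value`, `savings_serial_s` and
#'   `savings_parallel_s` (traditional minus smart runtime per row; negative
#'   when the smart mode is slower).
#' @export
savings_table <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  r <- result$rows
  data.frame(value = r$value,
             savings_serial_s = r$t_traditional_s - r$t_smart_serial_s,
             savings_parallel_s = r$t_traditional_s - r$t_smart_parallel_s)
}

#' Export a sweep result to CSV
#'
#' @param result A `sweep_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  df <- result$rows
  names(df)[names(df) == "value"] <- result$spec$parameter
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot runtimes of all three modes across a sweep
#'
#' @param x A `sweep_result`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sweep_result <- function(x, ...) {
  r <- x$rows
  graphics::matplot(r$value,
                    cbind(r$t_traditional_s, r$t_smart_serial_s,
                          r$t_smart_parallel_s),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "#d95f02", "#1b9e77"),
                    xlab = x$spec$parameter, ylab = "runtime (s)", ...)
  graphics::legend("topleft",
                   legend = c("traditional", "smart serial", "smart parallel"),
                   col = c("black", "#d95f02", "#1b9e77"), lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}
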