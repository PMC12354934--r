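# Config parsing and report emission: the programmatic replacement for the
# interactive runtime-comparison app.

param_keys <- c("quality_standard", "n_tiles", "n_sections", "t_trad_s",
                "t_fast_s", "t_slow_s", "t_compute_s", "t_tile_s",
                "t_section_s")
tile_keys <- c("tile_width_px", "tile_height_px", "fast_dwell_ns",
               "slow_dwell_ns", "trad_dwell_ns")

#' Read a run configuration from JSON or YAML
#'
#' The config supplies the workflow parameters either directly (keys
#' `quality_standard`, `n_tiles`, `n_sections`, `t_trad_s`, `t_fast_s`,
#' `t_slow_s`, `t_compute_s`, `t_tile_s`, `t_section_s`) or through tile
#' geometry (`tile_width_px`, `tile_height_px`, `fast_dwell_ns`,
#' `slow_dwell_ns`, optional `trad_dwell_ns`) from which the per-tile times
#' are derived. Optional keys: `steepness_k` (logistic quality curve
#' steepness, default 4), `quality_samples_csv` (path to a two-column
#' quality-sample CSV; when present the curve is fitted from it instead),
#' `seed` (integer, default 1), and `sweep` (list with `parameter` and
#' optional `values`).
#'
#' YAML configs require the optional `yaml` package.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list of class `run_config` with `params` (an `acq_params`),
#'   `curve` (a `quality_curve`), `seed` and optional `sweep`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  build_run_config(raw)
}

build_run_config <- function(raw) {
  known <- c(param_keys, tile_keys, "steepness_k", "quality_samples_csv",
             "seed", "sweep")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  has_tiles <- any(tile_keys %in% names(raw))
  if (has_tiles) {
    need <- setdiff(tile_keys[1:4], names(raw))
    if (length(need)) {
      stop("tile-based config missing key(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    conflicting <- intersect(c("t_trad_s", "t_fast_s", "t_slow_s"),
                             names(raw))
    if (length(conflicting)) {
      stop("config mixes tile geometry with explicit imaging time(s): ",
           paste(conflicting, collapse = ", "), call. = FALSE)
    }
    extra <- raw[intersect(setdiff(param_keys, c("t_trad_s", "t_fast_s",
                                                 "t_slow_s")), names(raw))]
    p <- do.call(params_from_tiles, c(
      raw[intersect(tile_keys, names(raw))], extra))
  } else {
    p <- do.call(acquisition_params, raw[intersect(param_keys, names(raw))])
  }
  if (!is.null(raw$quality_samples_csv) && !is.null(raw$steepness_k)) {
    stop(paste("config must name exactly one quality source:",
               "'steepness_k' or 'quality_samples_csv'"), call. = FALSE)
  }
  curve <- if (!is.null(raw$quality_samples_csv)) {
    fit_monotone_curve(read_quality_samples(raw$quality_samples_csv))
  } else {
    logistic_quality_curve(k = if (is.null(raw$steepness_k)) 4
                           else raw$steepness_k)
  }
  cfg <- list(params = p, curve = curve,
              seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
              sweep = raw$sweep)
  class(cfg) <- "run_config"
  cfg
}

#' Plan an acquisition and write the report files
#'
#' Computes the minimal rescan fraction meeting the quality standard,
#' evaluates the analytic runtimes of all three modes, validates the serial
#' and parallel formulas against the discrete-event simulation, and writes
#' the report: `runtimes.csv` (one row per mode with component columns),
#' `verdict.txt` (a plain-text statement of the fastest mode and margin)
#' and `des_validation.csv`. Outputs are deterministic functions of the
#' config.
#'
#' @param config A `run_config` from [read_run_config()], or a path to a
#'   config file.
#' @param output_dir Directory for report files (created if needed).
#' @param plots If `TRUE`, additionally write `runtime_vs_alpha.png` and a
#'   Gantt chart of a down-scaled schedule.
#' @return Invisibly, a list with `alpha`, `verdict` (a `mode_verdict`),
#'   `validation` and the output file paths.
#' @export
run_plan <- function(config, output_dir = ".", plots = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  alpha <- invert_for_alpha(config$curve, p$quality_standard)
  verdict <- compare_modes(p, alpha)
  validation <- validate_against_analytic(p, alpha)

  modes <- c("traditional", "smart_serial", "smart_parallel_global")
  rows <- lapply(modes, function(m) {
    b <- runtime_breakdown(p, alpha, mode = m)
    cbind(data.frame(mode = m, alpha = alpha, total_s = b$total_s),
          as.data.frame(as.list(b$components)))
  })
  runtimes_csv <- file.path(output_dir, "runtimes.csv")
  utils::write.csv(do.call(rbind, rows), runtimes_csv, row.names = FALSE)

  verdict_txt <- file.path(output_dir, "verdict.txt")
  writeLines(c(
    format(verdict),
    sprintf("  rescan fraction alpha = %.6f meets Q = %g on curve: %s",
            alpha, p$quality_standard, config$curve$label),
    sprintf("  DES check: serial %.3f s (formula %.3f), parallel %.3f s (formula %.3f, gap %.3f)",
            validation$des_serial, validation$eq_serial,
            validation$des_parallel_global, validation$eq_parallel,
            validation$gap)
  ), verdict_txt)

  des_csv <- file.path(output_dir, "des_validation.csv")
  utils::write.csv(as.data.frame(validation), des_csv, row.names = FALSE)

  paths <- c(runtimes = runtimes_csv, verdict = verdict_txt, des = des_csv)
  if (plots) {
    png_path <- file.path(output_dir, "runtime_vs_alpha.png")
    grDevices::png(png_path, width = 800, height = 500)
    alphas <- seq(0, 1, length.out = 101)
    graphics::matplot(alphas, cbind(
      rep(traditional_runtime(p), length(alphas)),
      vapply(alphas, function(a) serial_smart_runtime(p, a), numeric(1)),
      vapply(alphas, function(a) parallel_smart_runtime(p, a), numeric(1))),
      type = "l", lty = 1, lwd = 2, col = c("black", "#d95f02", "#1b9e77"),
      xlab = "rescan fraction alpha", ylab = "runtime (s)")
    graphics::abline(v = alpha, lty = 2)
    graphics::legend("topleft", c("traditional", "smart serial",
                                  "smart parallel"), lwd = 2,
                     col = c("black", "#d95f02", "#1b9e77"), bty = "n")
    grDevices::dev.off()
    paths <- c(paths, plot = png_path)
  }
  invisible(list(alpha = alpha, verdict = verdict, validation = validation,
                 paths = paths))
}

#' Run configured sensitivity sweeps and write CSVs
#'
#' Sweeps the parameter named in the config's `sweep` entry (or, when
#' `parameter` is `"all"`, every sweepable parameter) and writes one CSV
#' per sweep, named `sweep_<parameter>.csv`.
#'
#' @inheritParams run_plan
#' @return Invisibly, a named list of `sweep_result` objects.
#' @export
run_sweep <- function(config, output_dir = ".", plots = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$sweep) || is.null(config$sweep$parameter)) {
    stop("config has no 'sweep' entry with a 'parameter'", call. = FALSE)
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  pars <- config$sweep$parameter
  if (identical(pars, "all")) pars <- sweepable_params
  values <- config$sweep$values
  results <- list()
  for (par in pars) {
    spec <- sweep_spec(config$params, par,
                       values = if (length(pars) == 1L) values else NULL,
                       curve = config$curve)
    res <- sweep_parameter(spec)
    write_sweep_csv(res, file.path(output_dir,
                                   sprintf("sweep_%s.csv", par)))
    if (plots) {
      grDevices::png(file.path(output_dir, sprintf("sweep_%s.png", par)),
                     width = 700, height = 450)
      plot(res)
      grDevices::dev.off()
    }
    results[[par]] <- res
  }
  invisible(results)
}
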