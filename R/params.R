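#' Acquisition workflow parameters
#'
#' Bundle the nine parameters describing a serial-section imaging workflow:
#' the quality standard, the tiling geometry, and the per-tile / transition
#' times for the traditional and smart acquisition modes. All times are in
#' seconds.
#'
#' @param quality_standard Minimum acceptable quality \eqn{Q \in [0,1]}.
#' @param n_tiles Number of tiles (fields of view) per section, integer >= 1.
#' @param n_sections Number of sections, integer >= 1.
#' @param t_trad_s Traditional imaging time per tile (s).
#' @param t_fast_s Fast (overview) imaging time per tile (s).
#' @param t_slow_s Slow (high-quality) imaging time per full tile (s); a
#'   rescan of a fraction \eqn{\alpha} of a tile takes \eqn{\alpha} times this.
#' @param t_compute_s Rescan-mask compute time per tile (s).
#' @param t_tile_s Stage transition time between tiles within a section (s),
#'   including per-tile auto-functions.
#' @param t_section_s Stage transition time between sections (s).
#'
#' @details The defaults describe a hypothetical scanning-EM connectomics
#' workflow with 12,000 x 12,000 px tiles imaged at 100 ns/px (fast),
#' 1000 ns/px (slow and traditional), two serial U-Net inferences per tile
#' for the rescan mask, and stage moves of order 10-100 um. Use
#' [params_from_tiles()] to derive the imaging times from pixel geometry and
#' dwell times instead of entering them directly.
#'
#' @return An object of class `acq_params` (a named list of the nine fields).
#' @seealso [traditional_runtime()], [serial_smart_runtime()],
#'   [parallel_smart_runtime()], [params_from_tiles()]
#' @examples
#' p <- acquisition_params()
#' traditional_runtime(p)
#' @export
acquisition_params <- function(quality_standard = 0.8,
                               n_tiles = 24,
                               n_sections = 30,
                               t_trad_s = 144,
                               t_fast_s = 14.4,
                               t_slow_s = 144,
                               t_compute_s = 28.8,
                               t_tile_s = 4,
                               t_section_s = 20) {
  p <- list(
    quality_standard = as.numeric(quality_standard),
    n_tiles = as.numeric(n_tiles),
    n_sections = as.numeric(n_sections),
    t_trad_s = as.numeric(t_trad_s),
    t_fast_s = as.numeric(t_fast_s),
    t_slow_s = as.numeric(t_slow_s),
    t_compute_s = as.numeric(t_compute_s),
    t_tile_s = as.numeric(t_tile_s),
    t_section_s = as.numeric(t_section_s)
  )
  class(p) <- "acq_params"
  validate_acquisition_params(p)
  p
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Acquisition workflow parameters\n")
  cat(sprintf("  quality standard Q : %g\n", x$quality_standard))
  cat(sprintf("  sections x tiles   : %g x %g\n", x$n_sections, x$n_tiles))
  cat(sprintf("  per-tile times (s) : trad %g | fast %g | slow %g | compute %g\n",
              x$t_trad_s, x$t_fast_s, x$t_slow_s, x$t_compute_s))
  cat(sprintf("  transitions (s)    : tile %g | section %g\n",
              x$t_tile_s, x$t_section_s))
  invisible(x)
}

validate_acquisition_params <- function(p) {
  stopifnot(inherits(p, "acq_params"))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in c("t_trad_s", "t_fast_s", "t_slow_s", "t_compute_s",
              "t_tile_s", "t_section_s")) {
    if (!num1(p[[f]]) || p[[f]] < 0) {
      stop(sprintf("'%s' must be a single finite non-negative number", f),
           call. = FALSE)
    }
  }
  for (f in c("n_tiles", "n_sections")) {
    v <- p[[f]]
    if (!num1(v) || v < 1 || v != round(v)) {
      stop(sprintf("'%s' must be a positive integer", f), call. = FALSE)
    }
  }
  q <- p$quality_standard
  if (!num1(q) || q < 0 || q > 1) {
    stop("'quality_standard' must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Per-tile imaging time from pixel geometry and dwell time
#'
#' The idealized imaging time of one tile is the number of pixels times the
#' per-pixel dwell time: `width_px * height_px * dwell_ns * 1e-9` seconds.
#' This is a lower bound on real scan time (it ignores line flyback, beam
#' settling and pattern overheads).
#'
#' @param width_px,height_px Tile dimensions in pixels (positive integers).
#' @param dwell_ns Dwell time in nanoseconds per pixel (positive).
#' @return Imaging time in seconds.
#' @examples
#' derive_tile_time(12000, 12000, 100)   # 14.4 s
#' derive_tile_time(12000, 12000, 1000)  # 144 s
#' @export
derive_tile_time <- function(width_px, height_px, dwell_ns) {
  for (nm in c("width_px", "height_px", "dwell_ns")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
    }
  }
  if (width_px != round(width_px) || height_px != round(height_px)) {
    stop("tile dimensions must be whole numbers of pixels", call. = FALSE)
  }
  as.numeric(width_px) * as.numeric(height_px) * as.numeric(dwell_ns) * 1e-9
}

#' Build acquisition parameters from tile geometry and dwell times
#'
#' Derives `t_fast_s`, `t_slow_s` and `t_trad_s` from tile pixel dimensions
#' and dwell times via [derive_tile_time()]; all other fields are passed
#' through to [acquisition_params()].
#'
#' @param tile_width_px,tile_height_px Tile dimensions in pixels.
#' @param fast_dwell_ns,slow_dwell_ns,trad_dwell_ns Dwell times (ns/px) for
#'   the fast, slow and traditional scans.
#' @param ... Remaining fields for [acquisition_params()]
#'   (`quality_standard`, `n_tiles`, `n_sections`, `t_compute_s`,
#'   `t_tile_s`, `t_section_s`).
#' @return An `acq_params` object.
#' @examples
#' p <- params_from_tiles(12000, 12000, 100, 1000, 1000)
#' p$t_fast_s  # 14.4
#' @export
params_from_tiles <- function(tile_width_px, tile_height_px,
                              fast_dwell_ns, slow_dwell_ns,
                              trad_dwell_ns = slow_dwell_ns, ...) {
  acquisition_params(
    t_fast_s = derive_tile_time(tile_width_px, tile_height_px, fast_dwell_ns),
    t_slow_s = derive_tile_time(tile_width_px, tile_height_px, slow_dwell_ns),
    t_trad_s = derive_tile_time(tile_width_px, tile_height_px, trad_dwell_ns),
    ...
  )
}

#' Rescan plan
#'
#' A rescan plan is the single global rescan fraction `alpha`: the fraction
#' of each tile re-imaged at the slow rate. Rescan time per tile is assumed
#' proportional to the rescanned area, `alpha * t_slow_s`.
#'
#' @param alpha Rescan fraction in \[0, 1\].
#' @return An object of class `rescan_plan`.
#' @export
rescan_plan <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("'alpha' must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha)), class = "rescan_plan")
}

#' @export
print.rescan_plan <- function(x, ...) {
  cat(sprintf("Rescan plan: alpha = %g\n", x$alpha))
  invisible(x)
}

# accept either a rescan_plan or a bare numeric alpha
as_alpha <- function(plan) {
  if (inherits(plan, "rescan_plan")) return(plan$alpha)
  rescan_plan(plan)$alpha
}
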