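#' Logistic quality function
#'
#' The reference quality model mapping a rescan fraction \eqn{x \in [0,1]}
#' to a quality value in \eqn{[q(0), 1]}:
#' \deqn{q(x) = \frac{1}{1+e^{-kx}} + \frac{e^{-k}}{1+e^{-k}}}
#' The second term normalizes the curve so that \eqn{q(1) = 1} exactly for
#' every steepness \eqn{k > 0}. With the default \eqn{k = 4},
#' \eqn{q(0) = 1/2 + e^{-4}/(1+e^{-4}) \approx 0.518}: the quality obtained
#' from fast imaging alone.
#'
#' @param x Rescan fraction(s) in \[0, 1\] (vectorized).
#' @param k Steepness, a single positive number. Default 4.
#' @return Quality value(s) in \[0, 1\].
#' @examples
#' logistic_quality(1)       # exactly 1
#' logistic_quality(0)       # ~0.518
#' @export
logistic_quality <- function(x, k = 4) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("'k' must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop("rescan fraction 'x' must lie in [0, 1]", call. = FALSE)
  }
  # e^{-k}/(1+e^{-k}) == 1 - plogis(k); written this way the x = 1 endpoint
  # evaluates to exactly 1.0 in floating point (Sterbenz: 1 - plogis(k) is
  # exact, and adding plogis(k*1) back reconstitutes 1)
  stats::plogis(k * x) + (1 - stats::plogis(k))
}

#' Construct a quality curve
#'
#' A quality curve wraps a continuous non-decreasing function
#' \eqn{q: [0,1] \to [0,1]} together with its endpoint values
#' \eqn{q_0 = q(0)} and \eqn{q_1 = q(1)}. The curve is the object that
#' [invert_for_alpha()] inverts to find the minimal rescan fraction meeting
#' a quality standard.
#'
#' @param fun A vectorized function of one argument on \[0, 1\].
#' @param label Short description used in printing.
#' @param check If `TRUE` (default), run [validate_quality_curve()] on a
#'   201-point grid and fail on violations.
#' @return An object of class `quality_curve` with fields `fun`, `q0`, `q1`,
#'   `label`.
#' @seealso [logistic_quality_curve()], [fit_monotone_curve()]
#' @export
quality_curve <- function(fun, label = "user quality curve", check = TRUE) {
  stopifnot(is.function(fun))
  q0 <- fun(0)
  q1 <- fun(1)
  curve <- structure(list(fun = fun, q0 = q0, q1 = q1, label = label),
                     class = "quality_curve")
  if (check) {
    v <- validate_quality_curve(curve, grid_size = 201)
    if (!v$pass) {
      stop(sprintf("invalid quality curve: %s at x = %g", v$reason, v$x),
           call. = FALSE)
    }
  }
  curve
}

#' @export
print.quality_curve <- function(x, ...) {
  cat(sprintf("Quality curve (%s): q(0) = %.5f, q(1) = %.5f\n",
              x$label, x$q0, x$q1))
  invisible(x)
}

#' The packaged logistic quality curve
#'
#' @param k Steepness of [logistic_quality()]; default 4.
#' @return A `quality_curve` object.
#' @export
logistic_quality_curve <- function(k = 4) {
  force(k)
  quality_curve(function(x) logistic_quality(x, k = k),
                label = sprintf("logistic, k = %g", k), check = FALSE)
}

#' Validate a quality curve on a grid
#'
#' Checks, on a uniform grid over \[0, 1\], that the curve stays in
#' \[0, 1\] and never decreases by more than a numerical tolerance.
#'
#' @param curve A `quality_curve`.
#' @param grid_size Number of grid points, >= 2.
#' @param tol Largest tolerated decrease between consecutive grid points.
#' @return A list with `pass` (logical) and, on failure, `x` (first
#'   offending grid point) and `reason`.
#' @export
validate_quality_curve <- function(curve, grid_size = 101, tol = 1e-9) {
  stopifnot(inherits(curve, "quality_curve"), grid_size >= 2)
  xs <- seq(0, 1, length.out = grid_size)
  qs <- curve$fun(xs)
  out_of_range <- which(qs < -tol | qs > 1 + tol)
  if (length(out_of_range)) {
    return(list(pass = FALSE, x = xs[out_of_range[1]],
                reason = "value outside [0, 1]"))
  }
  drops <- which(diff(qs) < -tol)
  if (length(drops)) {
    return(list(pass = FALSE, x = xs[drops[1] + 1L],
                reason = "quality decreases"))
  }
  list(pass = TRUE, x = NA_real_, reason = NA_character_)
}

#' Minimal rescan fraction achieving a quality standard
#'
#' Finds the smallest \eqn{\alpha \in [0,1]} with \eqn{q(\alpha) \ge Q} by
#' bisection on the monotone curve. Requires \eqn{q(0) \le Q \le q(1)};
#' returns exactly 0 when \eqn{Q \le q(0)}. On a plateau the left edge is
#' returned (the infimum of the satisfying set).
#'
#' @param curve A `quality_curve`.
#' @param Q Quality standard in \[0, 1\].
#' @param tol Bisection interval width at termination (default 1e-9;
#'   iteration is capped at 200 halvings).
#' @return The minimal rescan fraction, a single number in \[0, 1\].
#' @examples
#' invert_for_alpha(logistic_quality_curve(), 0.8)  # ~0.31936
#' @export
invert_for_alpha <- function(curve, Q, tol = 1e-9) {
  stopifnot(inherits(curve, "quality_curve"))
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q < 0 || Q > 1) {
    stop("quality standard 'Q' must be a single number in [0, 1]",
         call. = FALSE)
  }
  if (Q > curve$q1) {
    stop(sprintf(paste0("unreachable quality standard: Q = %g exceeds q(1) ",
                        "= %g (curve spans [%g, %g])"),
                 Q, curve$q1, curve$q0, curve$q1), call. = FALSE)
  }
  if (Q <= curve$q0) return(0)
  lo <- 0
  hi <- 1
  # invariant: q(lo) < Q <= q(hi)
  for (i in seq_len(200)) {
    if (hi - lo <= tol) break
    mid <- (lo + hi) / 2
    if (curve$fun(mid) >= Q) hi <- mid else lo <- mid
  }
  hi
}

#' Fit a monotone quality curve to empirical samples
#'
#' Isotonic (pool-adjacent-violators) regression of measured quality on
#' rescan fraction, linearly interpolated between the fitted knots and
#' clamped to \[0, 1\]. This is the estimator used to turn empirical
#' (rescan fraction, accuracy) pairs — e.g. from
#' [estimate_quality_curve()] — into an invertible curve.
#'
#' @param samples A data frame with columns `rescan_fraction` (in \[0, 1\])
#'   and `quality` (or `accuracy`), at least two distinct fractions.
#' @return A `quality_curve`; outside the sampled range the fit is extended
#'   flat.
#' @examples
#' s <- data.frame(rescan_fraction = c(0, 0.5, 1), quality = c(0.6, 0.5, 0.9))
#' curve <- fit_monotone_curve(s)
#' curve$fun(0)    # 0.55: first two samples pooled
#' @export
fit_monotone_curve <- function(samples) {
  samples <- as.data.frame(samples)
  if (!"quality" %in% names(samples) && "accuracy" %in% names(samples)) {
    samples$quality <- samples$accuracy
  }
  stopifnot(all(c("rescan_fraction", "quality") %in% names(samples)))
  x <- as.numeric(samples$rescan_fraction)
  y <- as.numeric(samples$quality)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) stop("need at least two samples", call. = FALSE)
  if (any(x < 0 | x > 1)) {
    stop("rescan fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("degenerate design: all samples at a single rescan fraction",
         call. = FALSE)
  }
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  fit <- stats::isoreg(x, y)
  yf <- pmin(pmax(fit$yf, 0), 1)
  # collapse duplicate x to their common fitted value (isoreg gives ties
  # within a duplicated x a single pooled level)
  ux <- unique(x)
  uy <- vapply(ux, function(v) mean(yf[x == v]), numeric(1))
  interp <- stats::approxfun(ux, uy, method = "linear", rule = 2)
  quality_curve(interp,
                label = sprintf("isotonic fit (%d samples)", length(x)),
                check = FALSE)
}

#' Read and write quality samples
#'
#' Quality samples are exchanged as a two-column CSV with header
#' `rescan_fraction,quality`.
#'
#' @param path File path.
#' @return `read_quality_samples()` returns a data frame;
#'   `write_quality_samples()` returns `path` invisibly.
#' @export
read_quality_samples <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("rescan_fraction", "quality") %in% names(df))) {
    stop("quality sample CSV must have columns 'rescan_fraction','quality'",
         call. = FALSE)
  }
  df
}

#' @rdname read_quality_samples
#' @param samples Data frame with columns `rescan_fraction` and `quality`.
#' @export
write_quality_samples <- function(samples, path) {
  utils::write.csv(samples[, intersect(
    c("rescan_fraction", "quality", "n_replicates", "ci_low", "ci_high"),
    names(samples)), drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
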