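# Synthetic specimens, dwell-dependent scans and empirical quality curves.
#
# This module emulates, end to end and without any external data, the
# procedure of estimating a quality function from mixed-dwell-time images:
# a membrane-like binary specimen is generated, noisy fast and slow scans
# of it are simulated under Poisson shot noise, composed through a rescan
# mask, segmented with a classical segmenter, and scored against the
# ground truth.

# deterministic sub-seed derivation so each randomized step has its own
# stream; keeps results independent of evaluation order
sub_seed <- function(seed, i) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, i)[i]
}

#' Generate a synthetic membrane specimen
#'
#' Produces a binary ground-truth image resembling a cell-membrane
#' segmentation: cell interiors are the cells of a seeded random Voronoi
#' partition and the membrane is the band around cell boundaries where the
#' distances to the nearest and second-nearest Voronoi site differ by less
#' than `membrane_px` (a dilated boundary roughly `membrane_px` pixels
#' thick). This is a synthetic stand-in for real electron micrograph
#' annotations; it reproduces their geometry (thin closed contours
#' enclosing convex-ish regions) but none of their texture.
#'
#' @param width,height Image dimensions in pixels, at least 16.
#' @param seed Integer seed; the image is a deterministic function of
#'   `(width, height, seed)`.
#' @param cell_density Expected Voronoi sites per pixel; the default gives
#'   about 40 cells on a 256 x 256 image.
#' @param membrane_px Approximate membrane thickness in pixels (2-4).
#' @return An object of class `specimen_image`: list with `labels` (an
#'   integer matrix, membrane = 1, background = 0), `width`, `height`,
#'   `seed`. The membrane fraction always lies in (0, 1); with default
#'   settings it falls between 5% and 40%.
#' @export
generate_specimen <- function(width, height, seed,
                              cell_density = 40 / 256^2,
                              membrane_px = 3) {
  stopifnot(width >= 16, height >= 16, membrane_px > 0)
  n_sites <- max(2L, round(cell_density * width * height))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  sx <- stats::runif(n_sites, 0.5, width + 0.5)
  sy <- stats::runif(n_sites, 0.5, height + 0.5)
  px <- rep(seq_len(width), times = height)   # column-major over (x, y)
  py <- rep(seq_len(height), each = width)
  best1 <- rep(Inf, width * height)
  best2 <- rep(Inf, width * height)
  for (i in seq_len(n_sites)) {
    d2 <- (px - sx[i])^2 + (py - sy[i])^2
    closer <- d2 < best1
    best2 <- ifelse(closer, best1, pmin(best2, d2))
    best1 <- ifelse(closer, d2, best1)
  }
  band <- sqrt(best2) - sqrt(best1) < membrane_px
  labels <- matrix(as.integer(band), nrow = height, ncol = width,
                   byrow = TRUE)
  frac <- mean(labels)
  if (frac <= 0 || frac >= 1) {
    stop("degenerate specimen geometry: single-class image", call. = FALSE)
  }
  structure(list(labels = labels, width = width, height = height,
                 seed = seed),
            class = "specimen_image")
}

#' @export
print.specimen_image <- function(x, ...) {
  cat(sprintf("Synthetic specimen %dx%d px, membrane fraction %.3f, seed %d\n",
              x$width, x$height, mean(x$labels), x$seed))
  invisible(x)
}

#' Simulate a scan of a specimen at a given dwell time
#'
#' Electron-counting shot-noise model: the expected count at a pixel is
#' `base_rate * dwell_ns * contrast`, with a low contrast for background
#' and a high contrast for membrane; observed counts are Poisson with that
#' mean and the image is normalized by the maximum expected count, so
#' intensities concentrate in \[0, 1\] (individual pixels can exceed 1 by
#' shot noise). Per-pixel signal-to-noise grows as the square root of the
#' dwell time, which is the property the smart-microscopy fast/slow
#' tradeoff exploits.
#'
#' @param spec A `specimen_image`.
#' @param dwell_ns Dwell time in ns/pixel, positive.
#' @param seed Integer seed for the Poisson draw.
#' @param base_rate Expected counts per ns at unit contrast (default 0.01).
#' @param contrast Length-2 vector: expected-signal multipliers for
#'   (background, membrane). Default `c(0.3, 1)`.
#' @param noise If `FALSE`, return the normalized expected-count map
#'   exactly (the infinite-dwell limit).
#' @return An object of class `scan_image`: list with `intensities` (a
#'   numeric matrix), `dwell_ns`, `seed`.
#' @export
simulate_scan <- function(spec, dwell_ns, seed, base_rate = 0.01,
                          contrast = c(0.3, 1), noise = TRUE) {
  stopifnot(inherits(spec, "specimen_image"),
            is.numeric(dwell_ns), length(dwell_ns) == 1L, dwell_ns > 0,
            length(contrast) == 2L, all(contrast > 0))
  lambda <- base_rate * dwell_ns * ifelse(spec$labels == 1L,
                                          contrast[2], contrast[1])
  scale <- base_rate * dwell_ns * max(contrast)
  if (noise) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed %% .Machine$integer.max)
    counts <- matrix(stats::rpois(length(lambda), lambda),
                     nrow = nrow(lambda))
  } else {
    counts <- lambda
  }
  structure(list(intensities = counts / scale, dwell_ns = dwell_ns,
                 seed = seed),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("Scan %dx%d px at %g ns/px dwell\n",
              ncol(x$intensities), nrow(x$intensities), x$dwell_ns))
  invisible(x)
}

#' Construct a rescan mask
#'
#' Marks the pixels to be taken from the slow (high-dwell) scan when
#' composing a mixed-dwell image. Two placement strategies are provided,
#' both content-blind stand-ins for a learned rescan-mask predictor:
#' `random_blocks` selects whole square blocks at random (spatially
#' coherent, like real rescan regions), `uniform_random` selects individual
#' pixels. Both select exactly the number of units closest to
#' `target_fraction`, so the achieved fraction differs from the target by
#' at most one unit's area fraction.
#'
#' @param width,height Mask dimensions in pixels.
#' @param target_fraction Desired rescanned area fraction in \[0, 1\].
#' @param seed Integer seed.
#' @param strategy `"random_blocks"` or `"uniform_random"`.
#' @param block_px Block side length for `random_blocks` (default 32).
#' @return An object of class `rescan_mask`: list with `mask` (integer
#'   matrix, 1 = rescan), `target_fraction`, `strategy`.
#' @export
rescan_mask <- function(width, height, target_fraction, seed,
                        strategy = c("random_blocks", "uniform_random"),
                        block_px = 32) {
  strategy <- match.arg(strategy)
  stopifnot(width >= 1, height >= 1,
            target_fraction >= 0, target_fraction <= 1)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  m <- matrix(0L, nrow = height, ncol = width)
  if (strategy == "uniform_random") {
    k <- round(target_fraction * length(m))
    if (k > 0) m[sample.int(length(m), k)] <- 1L
  } else {
    bx <- ceiling(width / block_px)
    by <- ceiling(height / block_px)
    k <- round(target_fraction * bx * by)
    if (k > 0) {
      chosen <- sample.int(bx * by, k)
      for (b in chosen) {
        i0 <- ((b - 1) %% by) * block_px
        j0 <- ((b - 1) %/% by) * block_px
        rows <- (i0 + 1):min(i0 + block_px, height)
        cols <- (j0 + 1):min(j0 + block_px, width)
        m[rows, cols] <- 1L
      }
    }
  }
  structure(list(mask = m, target_fraction = target_fraction,
                 strategy = strategy),
            class = "rescan_mask")
}

#' Compose a mixed-dwell image from fast and slow scans
#'
#' Each output pixel is taken from the slow scan where the rescan mask is
#' 1 and from the fast scan elsewhere — the synthetic equivalent of saving
#' a fast overview scan with selectively rescanned regions patched in.
#'
#' @param fast,slow `scan_image` objects of the same shape.
#' @param mask A `rescan_mask` (or bare 0/1 matrix) of the same shape.
#' @return A `scan_image` whose `dwell_ns` is `NA` (mixed); attribute
#'   `dwell_pair_ns` records the two source dwells.
#' @export
compose_mixed <- function(fast, slow, mask) {
  stopifnot(inherits(fast, "scan_image"), inherits(slow, "scan_image"))
  m <- if (inherits(mask, "rescan_mask")) mask$mask else mask
  if (!identical(dim(fast$intensities), dim(slow$intensities)) ||
      !identical(dim(fast$intensities), dim(m))) {
    stop("fast scan, slow scan and mask shapes must match", call. = FALSE)
  }
  mixed <- ifelse(m == 1L, slow$intensities, fast$intensities)
  out <- structure(list(intensities = mixed, dwell_ns = NA_real_,
                        seed = fast$seed),
                   class = "scan_image")
  attr(out, "dwell_pair_ns") <- c(fast = fast$dwell_ns, slow = slow$dwell_ns)
  out
}

# separable Gaussian convolution with edge replication
gaussian_smooth <- function(mat, sigma = 2) {
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  conv_rows <- function(m) {
    nr <- nrow(m)
    pad <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
    acc <- matrix(0, nr, ncol(m))
    for (i in seq_along(w)) {
      acc <- acc + w[i] * pad[(i - 1L) + seq_len(nr), , drop = FALSE]
    }
    acc
  }
  t(conv_rows(t(conv_rows(mat))))
}

# Otsu's histogram threshold: maximizes between-class variance
otsu_threshold <- function(x, n_bins = 256) {
  x <- as.numeric(x)
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sb <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  breaks[which.max(sb) + 1L]
}

#' Segment a scan and score it against the ground truth
#'
#' The classical stand-in for a learned segmenter: Gaussian smoothing
#' (default sigma 2 px) followed by Otsu's threshold. The reported score is
#' pixelwise accuracy, orientation-corrected: because class polarity is
#' arbitrary, the class assignment (above-threshold = membrane or
#' above-threshold = background) that maximizes accuracy is used.
#'
#' @param img A `scan_image` (or bare numeric matrix).
#' @param truth The `specimen_image` ground truth of the same shape.
#' @param sigma Gaussian smoothing bandwidth in pixels; 0 disables
#'   smoothing.
#' @return Pixelwise accuracy in \[0.5, 1\].
#' @export
segment_and_score <- function(img, truth, sigma = 2) {
  x <- if (inherits(img, "scan_image")) img$intensities else img
  stopifnot(inherits(truth, "specimen_image"))
  if (!identical(dim(x), dim(truth$labels))) {
    stop("image and ground-truth shapes must match", call. = FALSE)
  }
  if (sigma > 0) x <- gaussian_smooth(x, sigma)
  thr <- otsu_threshold(x)
  pred <- x >= thr
  acc <- mean(pred == (truth$labels == 1L))
  max(acc, 1 - acc)
}

#' Estimate an empirical quality curve from synthetic mixed-dwell images
#'
#' For every rescan fraction on the grid and every seed, generates a
#' specimen, simulates fast and slow scans at the given dwell pair,
#' composes them through a fresh rescan mask, segments the mixed image and
#' scores it against the ground truth. Per fraction it reports the mean
#' accuracy across seeds with a normal-approximation 95% confidence
#' interval, and fits a monotone curve to the means with
#' [fit_monotone_curve()].
#'
#' @param seeds Integer vector of replicate seeds (>= 2).
#' @param fractions Rescan-fraction grid in \[0, 1\] (>= 2 values).
#' @param width,height Image dimensions (default 256 x 256).
#' @param dwell_fast_ns,dwell_slow_ns The dwell pair (default 25 and
#'   1200 ns/px, a realistic fast/slow EM pairing).
#' @param strategy Mask strategy, see [rescan_mask()].
#' @return A list of class `quality_estimate` with `samples` (data frame:
#'   `rescan_fraction`, `quality`, `n_replicates`, `ci_low`, `ci_high`),
#'   `curve` (the fitted `quality_curve`) and `raw` (accuracy matrix,
#'   fractions x seeds).
#' @examples
#' \donttest{
#' est <- estimate_quality_curve(seeds = 1:5, fractions = c(0, 0.5, 1),
#'                               width = 64, height = 64)
#' est$samples
#' }
#' @export
estimate_quality_curve <- function(seeds, fractions,
                                   width = 256, height = 256,
                                   dwell_fast_ns = 25, dwell_slow_ns = 1200,
                                   strategy = "random_blocks") {
  stopifnot(length(seeds) >= 2, length(fractions) >= 2,
            all(fractions >= 0 & fractions <= 1))
  fractions <- sort(fractions)
  raw <- matrix(NA_real_, nrow = length(fractions), ncol = length(seeds),
                dimnames = list(fraction = fractions, seed = seeds))
  for (j in seq_along(seeds)) {
    s <- seeds[j]
    spec <- generate_specimen(width, height, seed = sub_seed(s, 1))
    fast <- simulate_scan(spec, dwell_fast_ns, seed = sub_seed(s, 2))
    slow <- simulate_scan(spec, dwell_slow_ns, seed = sub_seed(s, 3))
    for (i in seq_along(fractions)) {
      mask <- rescan_mask(width, height, fractions[i],
                          seed = sub_seed(s, 4L + i), strategy = strategy)
      mixed <- compose_mixed(fast, slow, mask)
      raw[i, j] <- segment_and_score(mixed, spec)
    }
  }
  mean_acc <- rowMeans(raw)
  se <- apply(raw, 1, stats::sd) / sqrt(length(seeds))
  samples <- data.frame(
    rescan_fraction = fractions,
    quality = mean_acc,
    n_replicates = length(seeds),
    ci_low = mean_acc - 1.96 * se,
    ci_high = mean_acc + 1.96 * se
  )
  rownames(samples) <- NULL
  structure(list(samples = samples, curve = fit_monotone_curve(samples),
                 raw = raw),
            class = "quality_estimate")
}

#' @export
print.quality_estimate <- function(x, ...) {
  cat(sprintf("Empirical quality curve from %d replicates:\n",
              x$samples$n_replicates[1]))
  print(x$samples, digits = 4)
  invisible(x)
}

#' Read and write images as plain-text PGM
#'
#' Images are exchanged as ASCII PGM (portable graymap, magic `P2`), a
#' plain-text format readable by standard image tools. Intensities in
#' \[0, 1\] are quantized to 16-bit; binary masks use maxval 1.
#'
#' @param mat Numeric matrix (intensities in \[0, 1\]) or integer 0/1 mask.
#' @param path Output file path.
#' @param maxval Maximum gray value (65535 for scans, 1 for masks).
#' @return `write_pgm()` returns `path` invisibly; `read_pgm()` returns a
#'   numeric matrix scaled back to \[0, 1\].
#' @export
write_pgm <- function(mat, path, maxval = 65535L) {
  v <- round(pmin(pmax(mat, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mat), nrow(mat)), as.character(maxval)), con)
  utils::write.table(matrix(as.integer(v), nrow = nrow(mat)), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_pgm
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (toks[1] != "P2") stop("only ASCII PGM (P2) is supported", call. = FALSE)
  w <- as.integer(toks[2])
  h <- as.integer(toks[3])
  maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload", call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}
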