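# Smoothing, depth normalization, and the windowed shape-difference (RMSD)
# profile between a test and a control sample.

#' Truncated discrete Gaussian kernel
#'
#' Kernel weights at integer offsets, truncated to the central `mass`
#' fraction of a Gaussian with standard deviation `sigma` and renormalized
#' to unit sum. The half-width is `ceiling(qnorm((1 + mass)/2) * sigma)`
#' (141 nt for sigma = 50, mass = 0.995).
#'
#' @param sigma standard deviation in nt (> 0).
#' @param mass central two-sided mass fraction retained, in (0, 1).
#' @return numeric vector of weights with attribute `halfwidth`.
#' @export
gaussian_kernel <- function(sigma = 50, mass = 0.995) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(mass) || mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  h <- as.integer(ceiling(stats::qnorm((1 + mass) / 2) * sigma))
  w <- stats::dnorm(seq.int(-h, h), sd = sigma)
  w <- w / sum(w)
  attr(w, "halfwidth") <- h
  w
}

#' Gaussian-smooth a coverage track
#'
#' Spreads each position's signal by the truncated, renormalized Gaussian
#' kernel. At sequence ends the kernel is truncated and renormalized per
#' source position (no wraparound), so the total signal of each sequence is
#' preserved exactly. Masked positions carry value 0 into the smoothing and
#' stay flagged.
#'
#' @param track a [coverage_track()].
#' @param sigma kernel standard deviation in nt (default 50).
#' @param mass kernel mass fraction retained (default 0.995).
#' @return a `smoothed_track` (a `coverage_track` subclass with `sigma`,
#'   `mass` fields).
#' @export
smooth_coverage <- function(track, sigma = 50, mass = 0.995) {
  w <- gaussian_kernel(sigma, mass)
  h <- attr(w, "halfwidth")
  cw <- cumsum(w)
  out <- track$values
  for (sq in names(out)) {
    v <- out[[sq]]
    n <- length(v)
    if (n == 0L) next
    p <- seq_len(n)
    hi <- pmin(n, p + h)
    lower_idx <- pmax(h + 1L - p, 0L)
    edge_mass <- cw[hi - p + h + 1L] - c(0, cw)[lower_idx + 1L]
    z <- v / edge_mass
    zp <- c(numeric(h), z, numeric(h))
    f <- stats::filter(zp, w, method = "convolution", sides = 2)
    out[[sq]] <- as.numeric(f[(h + 1L):(h + n)])
  }
  res <- track
  res$values <- out
  res$sigma <- sigma
  res$mass <- mass
  res$depth_normalized <- FALSE
  class(res) <- c("smoothed_track", "coverage_track")
  res
}

#' Depth-normalize a smoothed track
#'
#' Divides every value by the sample's total signal (the genome-wide sum of
#' unmasked raw coverage), making samples of different sequencing depth
#' comparable.
#'
#' @param track a `smoothed_track` (or `coverage_track`).
#' @param total positive total signal; by default the track's own
#'   [total_signal()].
#' @return the normalized track.
#' @export
normalize_depth <- function(track, total = total_signal(track)) {
  if (!is.finite(total) || total <= 0) {
    stop("total signal must be finite and > 0")
  }
  track$values <- lapply(track$values, function(v) v / total)
  track$depth_normalized <- TRUE
  track$depth_total <- total
  track
}

#' Windowed shape difference (RMSD) between two tracks
#'
#' Slides a window of `window` nt in steps of `step` nt along every
#' sequence. In each window both samples' values are rescaled to unit sum
#' (area normalization) and the root mean squared deviation between the two
#' rescaled curves is computed. Windows where either sample sums to zero
#' get RMSD 0 and are flagged (`zero`); windows overlapping masked
#' positions are flagged (`masked`). Each window is anchored at its central
#' base (position `start + floor(window/2)`), so per-position quantities
#' evaluated "at" a peak refer to the middle of the peak window; a 5'-end
#' anchor would shift them half a window upstream, asymmetrically between
#' strands.
#'
#' @param ctrl,test tracks sharing one layout (normally smoothed,
#'   depth-normalized; the RMSD itself is invariant to depth scaling).
#' @param window window size in nt (default 150).
#' @param step step size in nt (default 5).
#' @return a `shape_diff_track`: per sequence, anchors, `rmsd`, `zero` and
#'   `masked` flags.
#' @export
shape_difference <- function(ctrl, test, window = 150L, step = 5L) {
  if (!layout_identical(ctrl$layout, test$layout)) {
    stop("control and test tracks have different layouts")
  }
  if (window <= 0 || step <= 0) stop("window and step must be > 0")
  window <- as.integer(window)
  step <- as.integer(step)
  data <- list()
  for (sq in seq_names(ctrl$layout)) {
    a <- ctrl$values[[sq]]
    b <- test$values[[sq]]
    n <- length(a)
    if (n < window) {
      data[[sq]] <- list(
        anchors = integer(0), rmsd = numeric(0),
        zero = logical(0), masked = logical(0)
      )
      next
    }
    half <- window %/% 2L
    wstart <- seq.int(1L, n - window + 1L, by = step)
    anchors <- wstart + half
    sa <- numeric(length(anchors))
    sb <- numeric(length(anchors))
    for (j in seq_len(window)) {
      idx <- wstart + (j - 1L)
      sa <- sa + a[idx]
      sb <- sb + b[idx]
    }
    zero <- (sa == 0) | (sb == 0)
    sa1 <- ifelse(sa == 0, 1, sa)
    sb1 <- ifelse(sb == 0, 1, sb)
    ss <- numeric(length(anchors))
    for (j in seq_len(window)) {
      idx <- wstart + (j - 1L)
      d <- a[idx] / sa1 - b[idx] / sb1
      ss <- ss + d * d
    }
    rmsd <- sqrt(ss / window)
    rmsd[zero] <- 0
    mk <- NULL
    if (!is.null(ctrl$mask)) mk <- ctrl$mask[[sq]]
    if (!is.null(test$mask)) {
      mk <- if (is.null(mk)) test$mask[[sq]] else (mk | test$mask[[sq]])
    }
    if (is.null(mk)) {
      masked <- rep(FALSE, length(anchors))
    } else {
      cm <- cumsum(mk)
      masked <- (cm[wstart + window - 1L] - c(0, cm)[wstart]) > 0
    }
    data[[sq]] <- list(anchors = anchors, rmsd = rmsd, zero = zero,
                       masked = masked)
  }
  structure(
    list(
      layout = ctrl$layout, window = window, step = step, data = data,
      samples = c(ctrl = ctrl$sample, test = test$sample)
    ),
    class = "shape_diff_track"
  )
}

#' @export
print.shape_diff_track <- function(x, ...) {
  nw <- sum(vapply(x$data, function(d) length(d$anchors), numeric(1)))
  cat(
    "<shape_diff_track> ", x$samples[["test"]], " vs ", x$samples[["ctrl"]],
    ": ", nw, " windows (", x$window, " nt / step ", x$step, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Export a shape-difference profile as bedGraph
#'
#' Writes each window's RMSD at its anchor (one `step`-wide interval per
#' window) for genome-browser inspection.
#'
#' @param diff a `shape_diff_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_shape_diff_bedgraph <- function(diff, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (sq in names(diff$data)) {
    d <- diff$data[[sq]]
    keep <- d$rmsd != 0
    if (any(keep)) {
      writeLines(sprintf(
        "%s\t%d\t%d\t%s",
        sq, d$anchors[keep] - 1L, d$anchors[keep] - 1L + diff$step,
        sprintf("%.17g", d$rmsd[keep])
      ), con)
    }
  }
  invisible(path)
}
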