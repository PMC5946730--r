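#' Sample skewness (population convention)
#'
#' Third standardized moment m3 / m2^(3/2) with no small-sample bias
#' correction.  Used both for the putative-Pyr classification and for
#' selecting sparse cells during neuropil correction.
#'
#' @param x numeric vector.
#' @return skewness, or `NA_real_` for traces with zero variance.
#' @export
trace_skewness <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  mean((x - m)^3) / m2^1.5
}

# Centered boxcar moving average over k points; ends use the partial window.
boxcar_smooth <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, ceiling(seq_len(n) - half))
  hi <- pmin(n, floor(seq_len(n) + half))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Boxcar moving average on an irregular axis: mean of all samples whose
# axis value is within +/- span/2 of each point.  Used for the signal-curve
# smoothing where the span is given in degrees of stimulus diameter.
boxcar_smooth_span <- function(x, axis, span, subset = rep(TRUE, length(x))) {
  out <- x
  for (i in which(subset)) {
    sel <- abs(axis - axis[i]) <= span / 2
    out[i] <- mean(x[sel])
  }
  out
}

# Hamming-window moving average of given width (in samples), normalized to
# unit sum.  Edges are handled with renormalized partial windows.
hamming_smooth <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  k <- seq_len(width) - 1L
  w <- 0.54 - 0.46 * cos(2 * pi * k / (width - 1L))
  n <- length(x)
  num <- stats::filter(x, w / sum(w), sides = 2)
  den <- stats::filter(rep(1, n), w / sum(w), sides = 2)
  out <- as.numeric(num / den)
  # partial windows at the edges
  half_lo <- which(is.na(out))
  for (i in half_lo) {
    lo <- max(1L, i - (width %/% 2)); hi <- min(n, lo + width - 1L)
    ww <- w[seq_len(hi - lo + 1L)]
    out[i] <- sum(x[lo:hi] * ww) / sum(ww)
  }
  out
}

# Linear interpolation of a series onto a new timebase (rule = 2 keeps the
# end values rather than introducing NAs).
interp_to <- function(t, x, t_out) {
  stats::approx(t, x, xout = t_out, rule = 2)$y
}

# Shape-preserving piecewise-cubic (pchip) interpolation.
pchip_interp <- function(x, y, xout) {
  if (length(x) < 3L) return(stats::approx(x, y, xout = xout, rule = 2)$y)
  signal::pchip(x, y, xout)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nf <- function(...) stop(sprintf(...), call. = FALSE)

# Deterministic child seeds below 2^31, derived from a user seed.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + 7 * as.numeric(k) + 13
  as.integer(s %% 2147483629)
}
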