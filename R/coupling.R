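# Pyr-interneuron population coupling ----------------------------------------

#' Spontaneous population coupling between two cell classes
#'
#' Each cell's activity is normalized by its maximum, averaged within class,
#' boxcar-smoothed over 1 s and decimated to one sample per second; the
#' class trace is then shifted by its 1st percentile and divided by its
#' standard deviation: K_c = (R_c - prctile1(R_c)) / sd(R_c).  The coupling
#' is the Pearson correlation of the two K traces, computed separately for
#' stationary and locomotion samples.
#'
#' @param act1,act2 activity matrices (cells x time) of the two classes
#'   (corrected fluorescence by default; deconvolved traces can be passed
#'   through the same interface).
#' @param speed running-speed trace on the same timebase.
#' @param fs sampling rate, Hz.
#' @param speed_threshold cm/s locomotion threshold.
#' @return list with `K1`, `K2`, `t`, and `rho0` (named vector: stationary,
#'   locomotion, all); constant class traces flag `valid = FALSE`.
#' @export
spontaneous_coupling <- function(act1, act2, speed, fs, speed_threshold = 1) {
  pop_trace <- function(act) {
    act <- rbind(act)
    norm <- apply(act, 1, function(x) {
      m <- max(x)
      if (m <= 0) return(rep(0, length(x)))
      x / m
    })
    rowMeans(norm)                      # time x cells -> population mean
  }
  r1 <- pop_trace(act1); r2 <- pop_trace(act2)
  win <- max(1L, round(fs))
  sm1 <- boxcar_smooth(r1, win); sm2 <- boxcar_smooth(r2, win)
  dec <- seq(1L, length(sm1), by = win)
  z <- function(x) {
    if (stats::sd(x) == 0) return(NULL)
    (x - stats::quantile(x, 0.01, names = FALSE)) / stats::sd(x)
  }
  K1 <- z(sm1[dec]); K2 <- z(sm2[dec])
  if (is.null(K1) || is.null(K2))
    return(list(K1 = NULL, K2 = NULL, rho0 = NULL, valid = FALSE))
  run <- boxcar_smooth(speed, win)[dec] > speed_threshold
  rho <- c(stationary = if (sum(!run) >= 3) stats::cor(K1[!run], K2[!run]) else NA_real_,
           locomotion = if (sum(run) >= 3) stats::cor(K1[run], K2[run]) else NA_real_,
           all = stats::cor(K1, K2))
  list(K1 = K1, K2 = K2, t = (dec - 1L) / fs, run = run, rho0 = rho, valid = TRUE)
}

#' Signal and noise coupling between two cell classes
#'
#' Signal: class-mean responses per (size, condition), divided by their
#' standard deviation over all (size, condition) pairs, minus the
#' stationary-blank value, giving dK with dK(s = 0, v = 0) = 0.  Noise:
#' per-trial class means minus their (size, condition) mean, z-scored over
#' all trials.  The smoothed signal curve applies a 25-degree boxcar to
#' sizes > 20 degrees, then a 20-degree boxcar to all sizes, then
#' shape-preserving piecewise-cubic interpolation between measured sizes.
#'
#' @param responses1,responses2 trial-response data.frames of the two
#'   classes (columns `cell_id`, `stim_id`, `diameter`, `dF`, `condition`).
#' @param interp_sizes sizes at which to evaluate the smoothed curves
#'   (default: 1-degree steps over the measured range).
#' @return list with `signal` (data.frame size, condition, dK1, dK2),
#'   `noise` (per-trial dZ pairs), `rho_s`, `rho_n`, and `smooth` (smoothed,
#'   interpolated signal curves per condition).
#' @export
stimulus_coupling <- function(responses1, responses2, interp_sizes = NULL) {
  class_signal <- function(responses) {
    # population mean per trial, then mean per (size, condition)
    tr <- stats::aggregate(dF ~ stim_id + diameter + condition,
                           data = responses, FUN = mean)
    sig <- stats::aggregate(dF ~ diameter + condition, data = tr, FUN = mean)
    sd_sv <- stats::sd(sig$dF)
    if (sd_sv == 0) stop_nf("stimulus_coupling: degenerate signal (constant responses)")
    sig$dR <- sig$dF / sd_sv
    blank <- sig$dR[sig$diameter == 0 & sig$condition == 0L]
    if (length(blank) != 1L)
      stop_nf("stimulus_coupling: stationary blank response missing")
    sig$dK <- sig$dR - blank
    list(sig = sig, trials = tr, sd = sd_sv)
  }
  s1 <- class_signal(responses1); s2 <- class_signal(responses2)
  m <- merge(s1$sig[, c("diameter", "condition", "dK")],
             s2$sig[, c("diameter", "condition", "dK")],
             by = c("diameter", "condition"), suffixes = c("1", "2"))
  rho_s <- stats::cor(m$dK1, m$dK2)

  # noise: per-trial residuals, z-scored over all trials
  noise_resid <- function(trials) {
    mu <- stats::aggregate(dF ~ diameter + condition, data = trials, FUN = mean)
    key <- paste(trials$diameter, trials$condition)
    dN <- trials$dF - mu$dF[match(key, paste(mu$diameter, mu$condition))]
    (dN - mean(dN)) / stats::sd(dN)
  }
  nm <- merge(transform(s1$trials, dZ1 = noise_resid(s1$trials))[
                , c("stim_id", "diameter", "condition", "dZ1")],
              transform(s2$trials, dZ2 = noise_resid(s2$trials))[
                , c("stim_id", "dZ2")], by = "stim_id")
  rho_n <- stats::cor(nm$dZ1, nm$dZ2)

  smooth_curve <- function(sig, v) {
    sv <- sig[sig$condition == v, ]
    sv <- sv[order(sv$diameter), ]
    y <- boxcar_smooth_span(sv$dK, sv$diameter, 25, subset = sv$diameter > 20)
    y <- boxcar_smooth_span(y, sv$diameter, 20)
    xs <- interp_sizes %||% seq(min(sv$diameter), max(sv$diameter), by = 1)
    xs <- xs[xs >= min(sv$diameter) & xs <= max(sv$diameter)]  # no extrapolation
    list(sizes = xs, values = pchip_interp(sv$diameter, y, xs),
         measured_sizes = sv$diameter, measured = y)
  }
  smooth <- lapply(0:1, function(v)
    list(c1 = smooth_curve(s1$sig, v), c2 = smooth_curve(s2$sig, v)))
  names(smooth) <- c("stationary", "locomotion")
  list(signal = m, noise = nm, rho_s = rho_s, rho_n = rho_n, smooth = smooth)
}

#' Coupling angles of the interneuron-vs-Pyr signal relationship
#'
#' With Pyr response on the x axis and interneuron response on the y axis,
#' theta1 is the angle (degrees, from the horizontal) of the segment from
#' the smallest-size (5 degree) point to the point at the Pyr-preferred
#' size, and theta2 the signed angle between that segment and the segment
#' from the Pyr-preferred point to the largest-size (60 degree) point
#' (positive counterclockwise; collinear continuation gives 0).
#'
#' @param p5,p_pref,p60 two-element vectors (Pyr, interneuron) at 5 degrees,
#'   the Pyr-preferred size, and 60 degrees.
#' @return list with `theta1`, `theta2` (degrees); zero-length segments give
#'   `valid = FALSE`.
#' @export
coupling_angles <- function(p5, p_pref, p60) {
  v1 <- p_pref - p5
  v2 <- p60 - p_pref
  if (sqrt(sum(v1^2)) < 1e-12 || sqrt(sum(v2^2)) < 1e-12)
    return(list(theta1 = NA_real_, theta2 = NA_real_, valid = FALSE))
  theta1 <- atan2(v1[2], v1[1]) * 180 / pi
  theta2 <- atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)) * 180 / pi
  list(theta1 = theta1, theta2 = theta2, valid = TRUE)
}

#' Coupling angles from smoothed signal curves
#'
#' Convenience wrapper: takes the output of [stimulus_coupling()] for one
#' condition, finds the Pyr-preferred size as the argmax of the smoothed
#' Pyr curve (ties toward the smaller size), and evaluates
#' [coupling_angles()] at 5 degrees, the preferred size, and 60 degrees.
#' `c1` is treated as the Pyr (x) axis.
#'
#' @param smooth one condition entry of `stimulus_coupling()$smooth`.
#' @return as [coupling_angles()], plus `preferred_size`.
#' @export
coupling_angles_from_curves <- function(smooth) {
  x <- smooth$c1; y <- smooth$c2
  at <- function(s) {
    i <- which.min(abs(x$sizes - s))
    c(x$values[i], y$values[i])
  }
  pref <- x$sizes[which.max(x$values)]   # which.max takes the first maximum
  res <- coupling_angles(at(5), at(pref), at(60))
  res$preferred_size <- pref
  res
}

#' Watson's two-sample U-squared statistic for circular data
#'
#' @param a1,a2 numeric vectors of angles, degrees.
#' @return the U-squared statistic.
#' @export
watson_u2 <- function(a1, a2) {
  x <- (a1 %% 360) / 360
  y <- (a2 %% 360) / 360
  n <- length(x); m <- length(y); N <- n + m
  pooled <- sort(unique(c(x, y)))
  cx <- vapply(pooled, function(v) sum(x <= v), numeric(1)) / n
  cy <- vapply(pooled, function(v) sum(y <= v), numeric(1)) / m
  # weights: number of pooled observations at each jump point
  cnt <- vapply(pooled, function(v) sum(x == v) + sum(y == v), numeric(1))
  d <- cx - cy
  dbar <- sum(d * cnt) / N
  n * m / N^2 * sum(cnt * (d - dbar)^2)
}

#' Permutation test on Watson's U-squared
#'
#' Compares two samples of angles by Watson's U-squared with a label
#' permutation null: p = (1 + #\{U2_perm >= U2_obs\}) / (n_perm + 1).
#'
#' @param a1,a2 angle samples, degrees (>= 3 each).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return list with `p`, `u2`, `n_perm`.
#' @export
watson_u2_permutation <- function(a1, a2, n_perm = 1000, seed = 1L) {
  if (n_perm < 1) stop_nf("watson_u2_permutation: n_perm must be >= 1")
  if (length(a1) < 3L || length(a2) < 3L)
    stop_nf("watson_u2_permutation: need >= 3 angles per group")
  u2_obs <- watson_u2(a1, a2)
  pooled <- c(a1, a2)
  n1 <- length(a1); N <- length(pooled)
  set.seed(derive_seed(seed, 505L))
  u2_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(N, n1)
    watson_u2(pooled[idx], pooled[-idx])
  }, numeric(1))
  list(p = (1 + sum(u2_perm >= u2_obs)) / (n_perm + 1), u2 = u2_obs,
       n_perm = n_perm)
}
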