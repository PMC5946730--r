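# Locomotion and activity statistics -----------------------------------------

# Shared preprocessing of a (trace, speed) pair: interpolate both onto a
# common 10 Hz timebase, boxcar-smooth over 5 points, decimate to 1 Hz.
prepare_speed_pair <- function(trace, speed, t_trace = NULL, t_speed = NULL,
                               fs = 10) {
  n <- length(trace)
  t_trace <- t_trace %||% ((seq_len(n) - 1) / fs)
  t_speed <- t_speed %||% ((seq_along(speed) - 1) / fs)
  t0 <- max(min(t_trace), min(t_speed))
  t1 <- min(max(t_trace), max(t_speed))
  if (t1 <= t0) stop_nf("speed_correlation: timebases do not overlap")
  tb <- seq(t0, t1, by = 1 / 10)
  x <- boxcar_smooth(interp_to(t_trace, trace, tb), 5L)
  y <- boxcar_smooth(interp_to(t_speed, speed, tb), 5L)
  dec <- seq(1L, length(tb), by = 10L)
  list(x = x[dec], y = y[dec], t = tb[dec],
       y10 = y, t10 = tb)
}

#' Correlation of activity with running speed
#'
#' Pearson correlation between a fluorescence trace and the running-speed
#' trace, both interpolated to 10 Hz, boxcar-smoothed over 5 points and
#' decimated to 1 Hz.  Optionally drops samples within
#' `exclude_transitions` seconds of any rest/run transition (running defined
#' as speed > 1 cm/s) before correlating, to control for locomotion-phase
#' effects.
#'
#' @param trace fluorescence trace.
#' @param speed running speed (cm/s).
#' @param t_trace,t_speed optional time axes (seconds); default assumes both
#'   sampled at `fs`.
#' @param fs sampling rate assumed when no time axes are given.
#' @param exclude_transitions window half-width in seconds, or `NULL`.
#' @return list with `rho`, `n` (samples used) and `valid` (FALSE when
#'   either decimated series is constant).
#' @export
speed_correlation <- function(trace, speed, t_trace = NULL, t_speed = NULL,
                              fs = 10, exclude_transitions = NULL) {
  pp <- prepare_speed_pair(trace, speed, t_trace, t_speed, fs)
  keep <- rep(TRUE, length(pp$x))
  if (!is.null(exclude_transitions)) {
    run10 <- pp$y10 > 1
    trans_t <- pp$t10[which(diff(run10) != 0L)]
    if (length(trans_t))
      keep <- vapply(pp$t, function(tt) all(abs(tt - trans_t) > exclude_transitions),
                     logical(1))
  }
  x <- pp$x[keep]; y <- pp$y[keep]
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, n = length(x), valid = FALSE))
  list(rho = stats::cor(x, y), n = length(x), valid = TRUE)
}

#' Circular-shift shuffle test for the speed correlation
#'
#' Serial correlation makes successive samples dependent, so the usual
#' correlation test is invalid; instead the speed series is circularly
#' shifted by `n_shuffles` uniform random offsets and the two-sided p-value
#' is (1 + #\{|rho_shuffle| >= |rho_obs|\}) / (n_shuffles + 1).
#'
#' @inheritParams speed_correlation
#' @param n_shuffles number of random circular shifts (>= 1).
#' @param seed integer seed.
#' @return list with `p`, `rho`, `n_shuffles`, `valid`.
#' @export
shuffle_test <- function(trace, speed, n_shuffles = 1000, seed = 1L,
                         t_trace = NULL, t_speed = NULL, fs = 10) {
  if (n_shuffles < 1) stop_nf("shuffle_test: n_shuffles must be >= 1")
  pp <- prepare_speed_pair(trace, speed, t_trace, t_speed, fs)
  x <- pp$x; y <- pp$y
  if (length(x) < 3L || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(p = NA_real_, rho = NA_real_, n_shuffles = n_shuffles, valid = FALSE))
  rho_obs <- stats::cor(x, y)
  n <- length(x)
  set.seed(derive_seed(seed, 404L))
  shifts <- sample.int(n - 1L, n_shuffles, replace = TRUE)
  # center once; circular shifts preserve mean and sd
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  rho_sh <- vapply(shifts, function(s) {
    ys <- c(yc[(s + 1L):n], yc[seq_len(s)])
    sum(xc * ys) / denom
  }, numeric(1))
  p <- (1 + sum(abs(rho_sh) >= abs(rho_obs))) / (n_shuffles + 1)
  list(p = p, rho = rho_obs, n_shuffles = n_shuffles, valid = TRUE)
}

#' Robust regression of a per-cell statistic on cortical depth
#'
#' Bisquare-weighted robust linear regression (M-estimation) of `values` on
#' `depths`; the slope's significance is a t-test on the robust standard
#' error.
#'
#' @param values per-cell statistic (e.g. the gray-screen speed correlation).
#' @param depths cortical depths, micrometres.
#' @return list with `slope`, `intercept`, `p`, `se`.
#' @export
depth_regression <- function(values, depths) {
  keep <- is.finite(values) & is.finite(depths)
  values <- values[keep]; depths <- depths[keep]
  if (length(values) < 3L || length(unique(depths)) < 2L)
    stop_nf("depth_regression: need >= 3 cells with distinct depths")
  if (stats::sd(values) == 0)
    return(list(slope = 0, intercept = values[1], p = 1, se = 0))
  fit <- MASS::rlm(values ~ depths, psi = MASS::psi.bisquare, maxit = 100)
  cf <- summary(fit)$coefficients
  tval <- cf["depths", "t value"]
  # a zero slope with zero robust scale (constant input) carries no evidence
  p <- if (!is.finite(tval)) 1 else 2 * stats::pt(-abs(tval), df = length(values) - 2L)
  list(slope = unname(cf["depths", "Value"]),
       intercept = unname(cf["(Intercept)", "Value"]),
       p = unname(p), se = unname(cf["depths", "Std. Error"]))
}

#' Locomotion modulation index
#'
#' M = (mean(x1) - mean(x0)) / sqrt(var(x1) + var(x0)) with population
#' variances; x are either 1 s virtual-trial means of gray-screen activity
#' (baseline mode, M_B) or per-trial residual responses d_t = dF_t - mean
#' response to that trial's size (response mode, M_R).
#'
#' @param x0 values in the stationary condition (>= 2).
#' @param x1 values in the locomotion condition (>= 2).
#' @return list with `M`, `n0`, `n1`, `valid` (FALSE when the pooled
#'   variance is zero).
#' @export
modulation_index <- function(x0, x1) {
  if (length(x0) < 2L || length(x1) < 2L)
    stop_nf("modulation_index: need >= 2 values per condition")
  pvar <- function(x) mean((x - mean(x))^2)
  den <- sqrt(pvar(x0) + pvar(x1))
  if (den == 0)
    return(list(M = NA_real_, n0 = length(x0), n1 = length(x1), valid = FALSE))
  list(M = (mean(x1) - mean(x0)) / den,
       n0 = length(x0), n1 = length(x1), valid = TRUE)
}

#' Residual responses for the response modulation index
#'
#' d_t = dF_t - mean dF over trials of the same stimulus size; the residuals
#' are split by locomotion condition and fed to [modulation_index()] to give
#' M_R.  Baseline (gray screen) virtual-trial means split the same way give
#' M_B.
#'
#' @param responses data.frame with columns `dF`, `diameter`, `condition`
#'   (0/1) for one cell.
#' @return list with `M` (the M_R index) plus residual sets `d0`, `d1`.
#' @export
response_modulation <- function(responses) {
  mean_by_size <- tapply(responses$dF, responses$diameter, mean)
  d <- as.numeric(responses$dF - mean_by_size[as.character(responses$diameter)])
  d0 <- d[responses$condition == 0L]
  d1 <- d[responses$condition == 1L]
  if (length(d0) < 2L || length(d1) < 2L)
    return(list(M = NA_real_, d0 = d0, d1 = d1, valid = FALSE))
  mi <- modulation_index(d0, d1)
  list(M = mi$M, d0 = d0, d1 = d1, valid = mi$valid)
}

#' Size-by-locomotion interaction test
#'
#' Assembles the smallest (5 degree) and largest (60 degree) stimulus
#' trials in both locomotion conditions and delegates to a standard two-way
#' ANOVA, reporting the main effects and the size-by-locomotion interaction
#' p-values.
#'
#' @param responses trial-response data.frame (columns `dF`, `diameter`,
#'   `condition`) for one cell or one population.
#' @param small,large the two diameters contrasted (degrees).
#' @return list with `p_size`, `p_locomotion`, `p_interaction`, `n_trials`.
#' @export
size_locomotion_interaction <- function(responses, small = 5, large = 60) {
  rr <- responses[responses$diameter %in% c(small, large), ]
  if (length(unique(rr$diameter)) < 2L || length(unique(rr$condition)) < 2L)
    stop_nf("size_locomotion_interaction: need both sizes in both conditions")
  fit <- stats::aov(dF ~ factor(diameter) * factor(condition), data = rr)
  tab <- summary(fit)[[1]]
  p <- tab[["Pr(>F)"]]
  list(p_size = p[1], p_locomotion = p[2], p_interaction = p[3],
       n_trials = nrow(rr))
}

#' Baseline (gray screen) modulation index from virtual trials
#'
#' Splits the inter-stimulus gray-screen activity into contiguous 1 s
#' virtual trials, labels each by the > 1 cm/s locomotion rule, and computes
#' the modulation index of the virtual-trial means.
#'
#' @param trace dF/F0 trace.
#' @param speed running speed trace, same sampling.
#' @param fs sampling rate (Hz).
#' @param gray_mask optional logical mask of gray-screen samples (default
#'   all).
#' @param speed_threshold cm/s locomotion threshold.
#' @return as [modulation_index()].
#' @export
baseline_modulation <- function(trace, speed, fs, gray_mask = NULL,
                                speed_threshold = 1) {
  n <- length(trace)
  gray_mask <- gray_mask %||% rep(TRUE, n)
  win <- max(1L, round(fs))
  starts <- seq(1L, n - win + 1L, by = win)
  keep <- vapply(starts, function(s) all(gray_mask[s:(s + win - 1L)]), logical(1))
  starts <- starts[keep]
  if (length(starts) < 4L) stop_nf("baseline_modulation: too few virtual trials")
  f_bar <- vapply(starts, function(s) mean(trace[s:(s + win - 1L)]), numeric(1))
  v <- vapply(starts, function(s) mean(speed[s:(s + win - 1L)]) > speed_threshold,
              logical(1))
  if (sum(v) < 2L || sum(!v) < 2L)
    return(list(M = NA_real_, n0 = sum(!v), n1 = sum(v), valid = FALSE))
  modulation_index(f_bar[!v], f_bar[v])
}
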