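# Trace-level preprocessing --------------------------------------------------

#' Estimate the neuropil contamination slope of one cell
#'
#' Bins the neuropil trace into 20 equal-count intervals, takes the 5th
#' percentile of the raw somatic fluorescence within each bin, and returns
#' the linear-regression slope of those percentiles against the bin centers
#' (mean neuropil value per bin).  The slope estimates the contamination
#' factor alpha because the lower envelope of the soma-vs-neuropil scatter
#' is set by contamination alone.  An intercept is included.
#'
#' @param F somatic fluorescence trace.
#' @param N neuropil trace (same length, >= 200 samples).
#' @param n_bins number of equal-count bins.
#' @return estimated slope (dimensionless).
#' @export
estimate_neuropil_alpha <- function(F, N, n_bins = 20L, refine = 2L) {
  if (length(F) != length(N)) stop_nf("estimate_neuropil_alpha: traces differ in length")
  if (length(F) < 200L) stop_nf("estimate_neuropil_alpha: need >= 200 samples")
  if (stats::sd(N) == 0) stop_nf("estimate_neuropil_alpha: degenerate neuropil trace")
  br <- stats::quantile(N, probs = seq(0, 1, length.out = n_bins + 1L))
  br <- unique(br)
  if (length(br) < 3L) stop_nf("estimate_neuropil_alpha: degenerate neuropil trace")
  bin <- cut(N, br, include.lowest = TRUE)
  centers <- tapply(N, bin, mean)
  env_slope <- function(x) {
    p5 <- tapply(x, bin, stats::quantile, probs = 0.05, names = FALSE)
    keep <- !is.na(centers) & !is.na(p5)
    unname(stats::coef(stats::lm(p5[keep] ~ centers[keep]))[2])
  }
  alpha <- env_slope(F)
  # refinement: within a wide bin the 5th percentile co-selects low N, which
  # attenuates the raw slope; re-estimating the envelope on the residual
  # F - alpha N makes the within-bin floor independent of N and removes the
  # bias (the update converges in one or two passes)
  for (k in seq_len(refine)) alpha <- alpha + env_slope(F - alpha * N)
  alpha
}

#' Neuropil-correct a whole session
#'
#' Estimates alpha_i for every cell, averages over cells whose raw-trace
#' skewness exceeds `skew_threshold` (sparsely firing cells, for which the
#' lower-envelope regression is reliable), and subtracts
#' `alpha_exp * N` from every cell's trace.  When no cell passes the
#' skewness cut the canonical cross-experiment average `fallback_alpha`
#' (0.82) is used.  Refuses to run twice on the same session.
#'
#' @param session an `nf_session`.
#' @param skew_threshold skewness cut for cells entering the average.
#' @param fallback_alpha correction factor used when no cell qualifies.
#' @return the corrected session; the fit is recorded in
#'   `session$neuropil_fit`.
#' @export
correct_session_neuropil <- function(session, skew_threshold = 4,
                                     fallback_alpha = 0.82) {
  stopifnot(inherits(session, "nf_session"))
  if (isTRUE(session$meta$corrected))
    stop_nf("correct_session_neuropil: session is already neuropil-corrected")
  n_cells <- nrow(session$cells)
  alpha_i <- rep(NA_real_, n_cells)
  skew <- rep(NA_real_, n_cells)
  for (i in seq_len(n_cells)) {
    skew[i] <- trace_skewness(session$F[i, ])
    alpha_i[i] <- tryCatch(estimate_neuropil_alpha(session$F[i, ], session$N[i, ]),
                           error = function(e) NA_real_)
  }
  high <- !is.na(alpha_i) & !is.na(skew) & skew > skew_threshold
  alpha_exp <- if (any(high)) mean(alpha_i[high]) else fallback_alpha
  session$F <- session$F - alpha_exp * session$N
  session$meta$corrected <- TRUE
  session$meta$alpha_exp <- alpha_exp
  session$neuropil_fit <- list(alpha_i = alpha_i, skewness = skew,
                               alpha_exp = alpha_exp,
                               n_high_skew = sum(high),
                               skew_threshold = skew_threshold,
                               fallback_alpha = fallback_alpha,
                               used_fallback = !any(high))
  session
}

#' Fractional fluorescence change dF/F0
#'
#' F0 is the global minimum of the trace smoothed with a 0.5 s Hamming
#' window; the returned trace is (F - F0) / F0.
#'
#' @param F fluorescence trace (positive baseline required).
#' @param fs sampling rate, Hz.
#' @return dF/F0 trace.
#' @export
compute_dff <- function(F, fs) {
  if (fs <= 0) stop_nf("compute_dff: fs must be positive")
  width <- max(1L, round(0.5 * fs))
  if (length(F) <= width) stop_nf("compute_dff: trace shorter than the filter width")
  F0 <- min(hamming_smooth(F, width))
  if (F0 <= 0) stop_nf("compute_dff: non-positive baseline (F0 = %.3g)", F0)
  (F - F0) / F0
}

#' Classify an unlabeled cell as putative pyramidal by trace skewness
#'
#' Sparse, low-rate Pyr activity yields strongly right-skewed fluorescence
#' distributions; densely firing interneurons do not.  A cell is putative
#' Pyr iff skewness exceeds `threshold` (default 2.7, a conservative value;
#' below-threshold cells could be of any type and are excluded).
#'
#' @param trace fluorescence trace (length >= 100).
#' @param threshold skewness threshold.
#' @return list with `label` (`"putative_pyr"` or `"excluded"`), `skewness`,
#'   and `reason` for exclusions.
#' @export
classify_putative_pyr <- function(trace, threshold = 2.7) {
  if (length(trace) < 100L) stop_nf("classify_putative_pyr: need >= 100 samples")
  sk <- trace_skewness(trace)
  if (is.na(sk))
    return(list(label = "excluded", skewness = NA_real_, reason = "degenerate"))
  if (sk > threshold)
    list(label = "putative_pyr", skewness = sk, reason = NA_character_)
  else
    list(label = "excluded", skewness = sk, reason = "low skewness")
}

#' Per-trial responses and cell selection
#'
#' For every stimulus the response is the mean dF/F0 over the first 1 s of
#' the stimulus minus the mean over the preceding 1 s of baseline.  A trial
#' is a locomotion trial when mean running speed over the response window
#' exceeds `speed_threshold` (1 cm/s).  Trials whose pupil position deviates
#' more than `pupil_radius` (5 degrees) from the session average are dropped
#' when the pupil filter is on.  Cells are selected when their RF center is
#' within `rf_radius` of the stimulus center and a one-way ANOVA of response
#' across stimulus sizes is significant (p < `anova_alpha`) in at least one
#' locomotion condition.
#'
#' @param session a neuropil-corrected `nf_session`.
#' @param rf_radius RF-distance criterion, degrees (10 default; 15 for
#'   interaction analyses, 20 for population tuning pools).
#' @param pupil_filter drop trials with deviated pupil position?
#' @param pupil_radius pupil deviation criterion, degrees.
#' @param speed_threshold locomotion threshold, cm/s.
#' @param anova_alpha selection significance level.
#' @param subtract_blank subtract the mean stationary blank response from
#'   every response?
#' @return list with `responses` (data.frame: cell_id, stim_id, diameter,
#'   dF, condition, pupil_offset, rf_offset), `selected` (cell ids),
#'   `anova_p` (matrix cells x conditions), and `dropped_trials`.
#' @export
trial_responses_and_selection <- function(session, rf_radius = 10,
                                          pupil_filter = TRUE,
                                          pupil_radius = 5,
                                          speed_threshold = 1,
                                          anova_alpha = 0.05,
                                          subtract_blank = FALSE) {
  stopifnot(inherits(session, "nf_session"))
  fs <- session$fs
  n <- length(session$time)
  n_cells <- nrow(session$cells)
  dff <- t(apply(session$F, 1, compute_dff, fs = fs))

  px0 <- mean(session$pupil$x); py0 <- mean(session$pupil$y)
  rf_off <- sqrt(session$cells$rf_x^2 + session$cells$rf_y^2)

  rows <- list(); dropped <- integer(0)
  for (k in seq_len(nrow(session$stimuli))) {
    onset <- session$stimuli$onset[k]
    i0 <- round(onset * fs) + 1L
    post <- i0:(i0 + fs - 1L)
    pre <- (i0 - fs):(i0 - 1L)
    if (min(pre) < 1L || max(post) > n) { dropped <- c(dropped, k); next }
    v <- as.integer(mean(session$speed[post]) > speed_threshold)
    p_off <- sqrt((mean(session$pupil$x[post]) - px0)^2 +
                  (mean(session$pupil$y[post]) - py0)^2)
    dF <- rowMeans(dff[, post, drop = FALSE]) - rowMeans(dff[, pre, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = session$cells$cell_id, stim_id = session$stimuli$stim_id[k],
      diameter = session$stimuli$diameter[k], dF = dF, condition = v,
      pupil_offset = p_off, rf_offset = rf_off)
  }
  responses <- do.call(rbind, rows)
  if (pupil_filter)
    responses <- responses[responses$pupil_offset <= pupil_radius, ]
  if (subtract_blank) {
    blank <- responses[responses$diameter == 0 & responses$condition == 0L, ]
    b_mean <- tapply(blank$dF, blank$cell_id, mean)
    adj <- b_mean[as.character(responses$cell_id)]
    adj[is.na(adj)] <- 0
    responses$dF <- responses$dF - adj
  }

  anova_p <- matrix(NA_real_, n_cells, 2,
                    dimnames = list(session$cells$cell_id, c("v0", "v1")))
  for (i in seq_len(n_cells)) {
    ri <- responses[responses$cell_id == session$cells$cell_id[i] &
                      responses$diameter > 0, ]
    for (v in 0:1) {
      rv <- ri[ri$condition == v, ]
      if (nrow(rv) >= 4L && length(unique(rv$diameter)) >= 2L &&
          stats::sd(rv$dF) > 0) {
        fit <- stats::aov(dF ~ factor(diameter), data = rv)
        anova_p[i, v + 1L] <- summary(fit)[[1]][["Pr(>F)"]][1]
      }
    }
  }
  sig <- apply(anova_p, 1, function(p) any(!is.na(p) & p < anova_alpha))
  selected <- session$cells$cell_id[rf_off <= rf_radius & sig]
  list(responses = responses, selected = selected, anova_p = anova_p,
       dropped_trials = dropped)
}
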