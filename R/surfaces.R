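# Continuous tuning surfaces from replicate measurements ---------------------

#' Build continuous tuning surfaces from replicate fields
#'
#' Extends sampled population responses to the continuous surfaces the
#' clamped-rate fit needs.  Per class and condition: replicate fields are
#' averaged across experiments; for every offset r < `r_L` (33 degrees) the
#' size tuning is fitted with the erf-difference family; for r > `r_L` the
#' surface is extrapolated as f(s, r_L) exp(-(r - r_L)/b), where b is the
#' mean of per-size exponential decay lengths c(s), fitted on
#' r in [r_m, r_L] (r_m = response-maximizing offset) and averaged over
#' sizes 0-30 degrees.  The across-experiment variance per (s, r, v) is
#' returned as the weighting surface of the fitting objective; when it is
#' identically zero (noiseless replicates) the normalizer falls back to the
#' mean squared field value and is flagged.
#'
#' @param sim output of [simulate_population_tuning()], or any list with
#'   `replicates` (list over experiments of per-condition [field_set()]s)
#'   and `grid`.
#' @param r_L outer edge of the fitting domain and of the erf-difference
#'   smoothing.
#' @param tail_fallback decay length used when no decay is detected
#'   (`Inf` = flat, with a warning).
#' @param use_samples_beyond_rL keep sampled means at offsets beyond `r_L`
#'   (default); set `FALSE` to force the exponential extrapolation from
#'   `r_L`, as used when off-center samples are missing.
#' @return object of class `tuning_surfaces`: per class and condition the
#'   smoothed surface values on the grid, the decay length `b`, the
#'   per-offset fit parameters; plus `variance`, per-class normalizers
#'   `norm`, `grid`, `r_L`.
#' @export
build_tuning_surfaces <- function(sim, r_L = 33, tail_fallback = Inf,
                                  use_samples_beyond_rL = TRUE) {
  grid <- sim$grid
  reps <- sim$replicates
  if (max(grid$offsets) < r_L || max(grid$sizes) < 60)
    stop_nf("build_tuning_surfaces: samples must cover r to >= %g and s to 60", r_L)
  n_exp <- length(reps)
  fit_dom_r <- grid$offsets <= r_L
  out <- list()
  variance <- list()
  norm <- c()
  fallback <- c()
  for (cl in CLASSES) {
    out[[cl]] <- list()
    for (v in CONDITIONS) {
      arr <- vapply(reps, function(rp) rp[[v]][[cl]], reps[[1]][[v]][[cl]])
      mean_f <- apply(arr, c(1, 2), mean)
      var_f <- if (n_exp > 1) apply(arr, c(1, 2), stats::var) else mean_f * 0
      # per-offset erf-difference fits for r < r_L (continuous description;
      # the grid values themselves stay empirical -- the across-experiment
      # mean is the unbiased estimate, and the family's small systematic
      # lack-of-fit would otherwise leak into the clamped regression)
      fits <- list()
      vals <- mean_f
      fitted_vals <- matrix(NA_real_, length(grid$sizes), length(grid$offsets))
      for (j in which(fit_dom_r)) {
        if (all(abs(mean_f[, j]) < 1e-12)) {
          fitted_vals[, j] <- 0
          fits[[j]] <- NULL
          next
        }
        ft <- fit_size_tuning(grid$sizes, mean_f[, j])
        fits[[j]] <- ft
        fitted_vals[, j] <- ft$fitted
      }
      # exponential decay lengths per size on [r_m, r_L]
      peak_per_r <- apply(mean_f[, fit_dom_r, drop = FALSE], 2, max)
      r_m_idx <- which.max(peak_per_r)
      decay_r <- which(fit_dom_r)
      decay_r <- decay_r[decay_r >= r_m_idx]
      cs <- rep(NA_real_, length(grid$sizes))
      if (length(decay_r) >= 2L) {
        for (i in which(grid$sizes > 0 & grid$sizes <= 30)) {
          yy <- mean_f[i, decay_r]
          if (all(yy > 0) && yy[length(yy)] < yy[1]) {
            sl <- stats::lm.fit(cbind(1, grid$offsets[decay_r]), log(yy))$coefficients[2]
            if (is.finite(sl) && sl < 0) cs[i] <- -1 / sl
          }
        }
      }
      b <- if (any(is.finite(cs))) mean(cs[is.finite(cs)]) else tail_fallback
      flat <- !is.finite(b)
      if (flat && length(decay_r) < 2L)
        warning("build_tuning_surfaces: fewer than 2 offsets beyond r_m; flat extrapolation",
                call. = FALSE)
      # beyond r_L: keep the sampled means where samples exist (the decaying
      # exponential with rate b is only needed past the sampled range, and is
      # applied per size by the convolution tail rule); when asked to mimic
      # sparse data (use_samples_beyond_rL = FALSE), extrapolate from r_L
      j_L <- max(which(fit_dom_r))
      for (j in which(!fit_dom_r)) {
        if (use_samples_beyond_rL) {
          vals[, j] <- mean_f[, j]
        } else {
          fac <- if (flat) 1 else exp(-(grid$offsets[j] - grid$offsets[j_L]) / b)
          vals[, j] <- vals[, j_L] * fac
        }
      }
      out[[cl]][[v]] <- list(values = vals, fitted_values = fitted_vals,
                             b = b, flat = flat,
                             fits = fits, mean_raw = mean_f,
                             decay_cs = cs, r_m = grid$offsets[r_m_idx])
      variance[[v]][[cl]] <- var_f
    }
    # per-class objective normalizer over the fitting domain, both conditions
    vv <- c(variance$stationary[[cl]][, fit_dom_r],
            variance$locomotion[[cl]][, fit_dom_r])
    if (mean(vv) > 0) {
      norm[cl] <- mean(vv)
      fallback[cl] <- FALSE
    } else {
      ff <- c(out[[cl]]$stationary$values[, fit_dom_r],
              out[[cl]]$locomotion$values[, fit_dom_r])
      norm[cl] <- mean(ff^2)
      if (norm[cl] <= 0) norm[cl] <- 1   # identically zero class
      fallback[cl] <- TRUE
    }
  }
  attr(norm, "fallback") <- fallback
  structure(list(surfaces = out, variance = variance, norm = norm,
                 grid = grid, r_L = r_L, n_experiments = n_exp),
            class = "tuning_surfaces")
}

#' @export
print.tuning_surfaces <- function(x, ...) {
  cat(sprintf("tuning_surfaces: %d experiments, r_L = %g deg\n",
              x$n_experiments, x$r_L))
  for (cl in CLASSES)
    cat(sprintf("  %s: b = %.3g (stationary) / %.3g (locomotion) deg, norm %.3g%s\n",
                cl, x$surfaces[[cl]]$stationary$b, x$surfaces[[cl]]$locomotion$b,
                x$norm[cl],
                if (any(attr(x$norm, "fallback"))) " [fallback]" else ""))
  invisible(x)
}

#' Pvalb/Pyr tracking ratio
#'
#' Least-squares through-origin ratio mu = sum(f_P f_E) / sum(f_E^2) over
#' the fitting domain, quantifying how closely Pvalb activity tracks Pyr
#' activity.
#'
#' @param f_E,f_P Pyr and Pvalb surfaces (matrices or vectors, same shape).
#' @return mu (scalar).
#' @export
estimate_mu <- function(f_E, f_P) {
  if (all(f_E == 0)) stop_nf("estimate_mu: Pyr field is identically zero")
  sum(f_P * f_E) / sum(f_E^2)
}
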