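# Size-tuning curve fits, population curves, and offset maps -----------------

#' Evaluate the erf-difference size-tuning family
#'
#' f(s) = R * (erf(s / sigma1) - k * erf(s / sigma2)); f(0) = 0 for every
#' parameter set.
#'
#' @param s stimulus diameters (degrees).
#' @param R,k,sigma1,sigma2 family parameters.
#' @export
size_tuning_curve <- function(s, R, k, sigma1, sigma2) {
  R * (pracma::erf(s / sigma1) - k * pracma::erf(s / sigma2))
}

#' Least-squares fit of the erf-difference size-tuning family
#'
#' Multi-start Levenberg-Marquardt over a documented grid of initial values
#' (sigma1 in \{5, 15, 40\}, sigma2 in \{15, 50\}, k in \{0, 0.5, 1\},
#' R from the response range).  Ties are broken by lower
#' loss, then smaller sigma1 + sigma2, then start order, so reruns are
#' deterministic.
#'
#' @param sizes stimulus diameters (>= 5 distinct).
#' @param responses measured responses, same length.
#' @return list with `R`, `k`, `sigma1`, `sigma2`, `loss` (sum of squared
#'   residuals), and `fitted`.
#' @export
fit_size_tuning <- function(sizes, responses) {
  if (any(!is.finite(responses))) stop_nf("fit_size_tuning: non-finite responses")
  if (length(unique(sizes)) < 5L) stop_nf("fit_size_tuning: need >= 5 distinct sizes")
  scale0 <- max(abs(responses))
  if (scale0 == 0) scale0 <- 1
  starts <- expand.grid(R = scale0, k = c(0, 0.5, 1),
                        sigma1 = c(5, 15, 40), sigma2 = c(15, 50))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- as.numeric(starts[i, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st,
        lower = c(-Inf, -Inf, 0.5, 0.5), upper = c(Inf, Inf, 500, 500),
        fn = function(p) size_tuning_curve(sizes, p[1], p[2], p[3], p[4]) - responses,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    width <- fit$par[3] + fit$par[4]
    if (is.null(best) || loss < best$loss - 1e-12 ||
        (abs(loss - best$loss) <= 1e-12 && width < best$width - 1e-9)) {
      best <- list(par = fit$par, loss = loss, width = width)
    }
  }
  if (is.null(best)) stop_nf("fit_size_tuning: all starts failed")
  p <- best$par
  list(R = p[1], k = p[2], sigma1 = p[3], sigma2 = p[4], loss = best$loss,
       fitted = size_tuning_curve(sizes, p[1], p[2], p[3], p[4]))
}

#' Normalized population size-tuning curves
#'
#' Per cell, the mean stationary blank response is subtracted from every
#' response; cells with RF offset < 20 degrees are pooled; the centered pool
#' (offset < 10) and off-centered pool (10 <= offset < 20) averages are each
#' divided by the maximum of the all-cell average curve.
#'
#' @param responses trial-response data.frame (columns `cell_id`,
#'   `diameter`, `dF`, `condition`, `rf_offset`), e.g. from
#'   [trial_responses_and_selection()].
#' @param condition 0 (stationary) or 1 (locomotion) curve to extract.
#' @return list with `sizes`, `centered`, `off_centered`, `all`, and pool
#'   sizes; empty pools give `NULL` curves.
#' @export
population_size_tuning <- function(responses, condition = 0L) {
  blank <- responses[responses$diameter == 0 & responses$condition == 0L, ]
  if (nrow(blank) == 0L)
    stop_nf("population_size_tuning: no stationary blank trials")
  b_mean <- tapply(blank$dF, blank$cell_id, mean)
  rr <- responses[responses$condition == condition & responses$diameter > 0, ]
  rr <- rr[rr$rf_offset < 20, ]
  if (nrow(rr) == 0L)
    return(list(sizes = numeric(0), centered = NULL, off_centered = NULL,
                all = NULL, n_centered = 0L, n_off = 0L))
  adj <- b_mean[as.character(rr$cell_id)]
  adj[is.na(adj)] <- 0
  rr$dF <- rr$dF - adj
  # per-cell mean tuning, then pool averages
  cell_curve <- tapply(rr$dF, list(rr$cell_id, rr$diameter), mean)
  sizes <- as.numeric(colnames(cell_curve))
  offs <- tapply(rr$rf_offset, rr$cell_id, mean)[rownames(cell_curve)]
  all_curve <- colMeans(cell_curve, na.rm = TRUE)
  norm <- max(all_curve, na.rm = TRUE)
  pool <- function(sel) {
    if (!any(sel)) return(NULL)
    colMeans(cell_curve[sel, , drop = FALSE], na.rm = TRUE) / norm
  }
  list(sizes = sizes,
       centered = pool(offs < 10),
       off_centered = pool(offs >= 10 & offs < 20),
       all = all_curve / norm,
       n_centered = sum(offs < 10), n_off = sum(offs >= 10 & offs < 20))
}

#' Size-tuning-by-offset map
#'
#' Each cell contributes the outer product of its normalized tuning curve
#' n_i(s) with a Gaussian of width `sigma_y` centered at its RF offset r_i;
#' the session map is the Gaussian-weighted average
#' m(s, r) = sum_i n_i(s) g_i(r) / sum_i g_i(r), which avoids edge effects
#' by normalizing by the local cell density.  Offsets where the density
#' falls below `density_floor` are masked (NA).
#'
#' @param tuning matrix cells x sizes of tuning values n_i(s).
#' @param offsets per-cell RF offsets r_i (degrees).
#' @param r_out radial offsets at which to evaluate the map.
#' @param sigma_y Gaussian smoothing width, degrees (default 5, matching
#'   the 5-degree RF-mapping pixels).
#' @param density_floor minimum summed Gaussian weight.
#' @return matrix sizes x length(r_out); masked entries are NA.
#' @export
size_tuning_offset_map <- function(tuning, offsets, r_out = seq(0, 40, by = 1),
                                   sigma_y = 5, density_floor = 1e-6) {
  tuning <- rbind(tuning)
  if (nrow(tuning) != length(offsets))
    stop_nf("size_tuning_offset_map: one offset per cell required")
  g <- outer(offsets, r_out, function(ri, r) exp(-(r - ri)^2 / (2 * sigma_y^2)))
  den <- colSums(g)
  num <- t(tuning) %*% g            # sizes x r_out
  map <- sweep(num, 2, den, "/")
  map[, den < density_floor] <- NA_real_
  map
}

#' Normalize a stationary/locomotion map pair
#'
#' Both maps are divided by the stationary map value at (s = 10, r = 0),
#' the reference point used for cross-session averaging.
#'
#' @param map_stat,map_loco maps from [size_tuning_offset_map()] (rows are
#'   `sizes`; the first column must be r = 0).
#' @param sizes row sizes (degrees).
#' @param ref_size normalization reference size (degrees).
#' @return list of the two normalized maps.
#' @export
normalize_offset_maps <- function(map_stat, map_loco, sizes, ref_size = 10) {
  i <- which.min(abs(sizes - ref_size))
  ref <- map_stat[i, 1]
  if (!is.finite(ref) || ref == 0)
    stop_nf("normalize_offset_maps: undefined normalization reference")
  list(stationary = map_stat / ref, locomotion = map_loco / ref)
}
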