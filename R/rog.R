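#' Ratio-of-Gaussians parameters for the thalamic drive
#'
#' The external (thalamic) input to the cortical circuit is modelled by a
#' ratio-of-Gaussians size-tuning surface h(s, r).  One parameter set is used
#' per locomotion condition.  The default values are the published estimates
#' from fits to dLGN recordings: stationary a1 = 1.2, a2 = 1.9,
#' sigma1 = 36.7, sigma2 = 33.9; locomotion a1 = 0.5, a2 = 0.4,
#' sigma1 = 24.7, sigma2 = 10.0.
#'
#' @param a1,a2 dimensionless gains of the excitatory and suppressive
#'   integrals (both >= 0).
#' @param sigma1,sigma2 spatial extents in degrees (both > 0).
#' @return an object of class `rog_params`.
#' @export
rog_params <- function(a1 = 1.2, a2 = 1.9, sigma1 = 36.7, sigma2 = 33.9) {
  if (a1 < 0 || a2 < 0) stop_nf("rog_params: a1 and a2 must be nonnegative")
  if (sigma1 <= 0 || sigma2 <= 0) stop_nf("rog_params: sigmas must be positive")
  structure(list(a1 = a1, a2 = a2, sigma1 = sigma1, sigma2 = sigma2),
            class = "rog_params")
}

#' Published thalamic drive parameters per locomotion condition
#'
#' @return list with elements `stationary` and `locomotion`, each a
#'   [rog_params()] object.
#' @export
rog_params_default <- function() {
  list(stationary = rog_params(1.2, 1.9, 36.7, 33.9),
       locomotion = rog_params(0.5, 0.4, 24.7, 10.0))
}

# u(s, r, sigma) = erf((s + r)/sigma) + sign(s - r) erf(|s - r|/sigma),
# with sign(0) = 0 so the surface is continuous at s = r.
rog_u <- function(s, r, sigma) {
  pracma::erf((s + r) / sigma) + sign(s - r) * pracma::erf(abs(s - r) / sigma)
}

#' Thalamic drive from the ratio-of-Gaussians model
#'
#' h(s, r) = a1 u(s, r, sigma1) / (1 + a2 u(s, r, sigma2)), where u is an
#' erf-based aperture integral of a Gaussian receptive field over a stimulus
#' of diameter s centered at radial offset r.  h(0, r) = 0 for every r.
#'
#' @param s stimulus diameter(s), degrees (>= 0).
#' @param r retinotopic offset(s), degrees (>= 0); recycled against `s`.
#' @param params a [rog_params()] object.
#' @return numeric drive values (dimensionless).
#' @export
rog_input <- function(s, r, params) {
  stopifnot(inherits(params, "rog_params"))
  if (any(s < 0) || any(r < 0)) stop_nf("rog_input: s and r must be >= 0")
  u1 <- rog_u(s, r, params$sigma1)
  u2 <- rog_u(s, r, params$sigma2)
  params$a1 * u1 / (1 + params$a2 * u2)
}

#' Evaluate the thalamic drive surface on a grid
#'
#' @param grid a [space_grid()].
#' @param params a [rog_params()] object.
#' @return matrix of drive values (rows = sizes, columns = offsets).
#' @export
rog_surface <- function(grid, params) {
  outer(grid$sizes, grid$offsets, function(s, r) rog_input(s, r, params))
}
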