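# Retinotopic convolution of circularly symmetric fields ---------------------
#
# The model convolves each presynaptic rate surface with an isotropic 2D
# Gaussian G(z) = exp(-|z|^2 / 2 sigma^2) / (2 pi sigma^2) over retinotopic
# space.  For a circularly symmetric field f(rho) the angular integral is
# analytic and the convolution reduces to a 1D integral with a Bessel
# kernel:
#
#   (G * f)(r) = int_0^inf f(rho) (rho / sigma^2)
#                exp(-(r^2 + rho^2) / 2 sigma^2) I0(r rho / sigma^2) drho
#
# evaluated here with the exponentially scaled Bessel function for
# numerical stability and a trapezoid rule on a kernel-resolving node grid.
# The discrete kernel rows are renormalized to unit mass, which makes the
# operator exact on constant fields and compensates domain truncation.

# Exponential-tail description of a radial profile beyond the sampled range.
# b is the decay length scale in degrees; b = Inf extends the profile flat.
fit_tail_decay <- function(r, y, npts = 4L) {
  n <- length(r)
  idx <- seq(max(1L, n - npts + 1L), n)
  yy <- y[idx]
  if (any(yy <= 0) || yy[length(yy)] >= yy[1]) return(Inf)
  fit <- stats::lm.fit(cbind(1, r[idx]), log(yy))
  slope <- fit$coefficients[2]
  if (!is.finite(slope) || slope >= 0) return(Inf)
  -1 / slope
}

# Build a vectorized radial profile function from samples on [0, r_max],
# natural-spline inside the sampled range and exponential (length b) or flat
# beyond it.
radial_profile_fun <- function(r, y, tail_b = NULL) {
  r_max <- r[length(r)]
  y_end <- y[length(y)]
  b <- tail_b %||% fit_tail_decay(r, y)
  sf <- if (length(r) >= 4L) stats::splinefun(r, y, method = "natural")
        else stats::approxfun(r, y, rule = 2)
  function(rr) {
    out <- numeric(length(rr))
    inside <- rr <= r_max
    if (any(inside)) out[inside] <- sf(rr[inside])
    if (any(!inside)) {
      out[!inside] <- if (is.finite(b) && y_end > 0)
        y_end * exp(-(rr[!inside] - r_max) / b) else y_end
    }
    out
  }
}

# Quadrature nodes and row-normalized kernel matrix for one sigma.
# Returns list(nodes, K) with K[i, j] the weight of f(nodes[j]) in the
# convolved value at r_out[i].  Composite Simpson weights.
radial_kernel_matrix <- function(sigma, r_out, step, rho_max) {
  n_nodes <- ceiling(rho_max / step) + 1L
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L   # Simpson needs odd count
  nodes <- seq(0, rho_max, length.out = n_nodes)
  hh <- nodes[2] - nodes[1]
  wq <- rep(2, n_nodes)
  wq[seq(2L, n_nodes - 1L, by = 2L)] <- 4
  wq[c(1L, n_nodes)] <- 1
  wq <- wq * hh / 3
  K <- matrix(0, length(r_out), length(nodes))
  s2 <- sigma^2
  for (i in seq_along(r_out)) {
    r <- r_out[i]
    z <- r * nodes / s2
    # exp(-(r-rho)^2/2s2) * I0e(z) since I0(z) = I0e(z) e^z and
    # -(r^2+rho^2)/2s2 + z = -(r-rho)^2/2s2
    K[i, ] <- (nodes / s2) * exp(-(r - nodes)^2 / (2 * s2)) *
      besselI(z, 0, expon.scaled = TRUE) * wq
  }
  list(K = K / rowSums(K), nodes = nodes)
}

# Reusable convolution operator for one (sigma, grid) pair; building the
# Bessel kernel matrix once and reusing it across fixed-point iterations and
# weight fits is the main cost saver of the fitting pipeline.
make_convolver <- function(sigma, grid, r_out = grid$offsets, step = NULL) {
  if (sigma <= 0) stop_nf("field_convolve: sigma must be positive")
  if (sigma < grid$step / 2)
    stop_nf("field_convolve: under-resolved kernel (sigma = %.3g < step/2 = %.3g)",
            sigma, grid$step / 2)
  qstep <- step %||% min(sigma / 4, grid$step)
  rho_max <- max(r_out) + 6 * sigma
  kk <- radial_kernel_matrix(sigma, r_out, qstep, rho_max)
  km <- kk$K
  nodes <- kk$nodes
  offs <- grid$offsets
  function(field, tail_b = NULL) {
    if (is.function(field)) return(drop(km %*% field(nodes)))
    if (is.matrix(field)) {
      vals <- t(apply(field, 1, function(y)
        radial_profile_fun(offs, y, tail_b)(nodes)))
      return(vals %*% t(km))
    }
    drop(km %*% radial_profile_fun(offs, as.numeric(field), tail_b)(nodes))
  }
}

#' Convolve a circularly symmetric field with an isotropic Gaussian kernel
#'
#' Computes the two-dimensional retinotopic convolution of a radial profile
#' (or a size-by-offset surface, row-wise) with a unit-mass Gaussian of
#' width `sigma`, returning values on the requested radial offsets.  Sampled
#' fields are continued beyond their last offset by an exponential tail
#' (decay length `tail_b`, estimated from the outermost samples when not
#' supplied) before convolving.
#'
#' @param field either a numeric vector of field values on `grid$offsets`, a
#'   matrix (rows = `grid$sizes`, columns = `grid$offsets`), or a vectorized
#'   function of radial offset.
#' @param sigma Gaussian kernel width, degrees (> 0).
#' @param grid a [space_grid()]; its `step` sets the quadrature resolution
#'   for sampled fields.
#' @param r_out output offsets (degrees); defaults to `grid$offsets`.
#' @param tail_b optional exponential decay length (degrees) used beyond the
#'   sampled range; `Inf` extends the field flat.
#' @param step optional quadrature step override (degrees).
#' @return convolved values, same shape as the input (vector or matrix).
#' @export
field_convolve <- function(field, sigma, grid, r_out = grid$offsets,
                           tail_b = NULL, step = NULL) {
  conv <- make_convolver(sigma, grid, r_out, step)
  conv(field, tail_b)
}
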