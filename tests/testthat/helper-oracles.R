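# Independent brute-force implementations used as oracles.  These share no
# code with the package's computational path: the convolution is done on a
# 2D Cartesian grid, and the model right-hand side is reassembled from
# scratch.

# 2D Cartesian brute-force convolution of a circularly symmetric field
# (given as a function of radius) with an isotropic Gaussian, evaluated at
# radial offsets r_out.
cartesian_convolve <- function(f, sigma, r_out, step = sigma / 12,
                               extent = 9 * sigma) {
  ax <- seq(-extent, extent, by = step)
  gx <- outer(ax, ax, function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)))
  gx <- gx / (2 * pi * sigma^2) * step^2
  vapply(r_out, function(r) {
    # field evaluated at distance from the point (r, 0)
    rr <- sqrt(outer((r - ax)^2, ax^2, `+`))
    sum(f(rr) * gx)
  }, numeric(1))
}

# Brute-force clamped RHS for analytic radial fields, one condition.
# fields: list of functions of radius per class (E, P, S, V); h_fun likewise;
# weights: named effective weights; sigmas, modes as in the package.
bruteforce_rhs <- function(fields, h_fun, weights, sigmas, modes,
                           r_out, step_frac = 8) {
  conv <- function(cl_fun, sigma)
    cartesian_convolve(cl_fun, sigma, r_out, step = sigma / step_frac)
  rect <- function(x, y, mode) if (mode == "subtractive") pmax(x - y, 0) else pmax(x / (1 + y), 0)
  h <- h_fun(r_out)
  list(
    E = rect(weights["EH"] * h, weights["ES"] * conv(fields$S, sigmas["ES"]),
             modes[["ES"]]),
    P = rect(weights["PH"] * h + weights["PE"] * conv(fields$E, sigmas["PE"]),
             weights["PS"] * conv(fields$S, sigmas["PS"]), modes[["PS"]]),
    S = rect(weights["SH"] * conv(h_fun, sigmas["SH"]) +
               weights["SE"] * conv(fields$E, sigmas["SE"]),
             weights["SV"] * conv(fields$V, sigmas["SV"]), modes[["SV"]]),
    V = rect(weights["VE"] * conv(fields$E, sigmas["VE"]),
             weights["VS"] * conv(fields$S, sigmas["VS"]), modes[["VS"]]))
}

# population skewness oracle (plain formula, independent of the package)
skew_oracle <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}
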