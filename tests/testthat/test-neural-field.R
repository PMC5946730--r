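# Forward circuit model: drive, rectification, convolution, effective
# weights, clamped prediction, fixed point.

test_that("ratio-of-Gaussians drive obeys its closed forms", {
  p <- rog_params(1.2, 1.9, 36.7, 33.9)
  # zero-size stimulus gives zero drive at any offset
  expect_equal(rog_input(0, c(0, 10, 33, 50), p), rep(0, 4))
  # centered closed form: h = 2 a1 erf(s/s1) / (1 + 2 a2 erf(s/s2))
  s <- c(5, 20, 60)
  expected <- 2 * 1.2 * pracma::erf(s / 36.7) /
    (1 + 2 * 1.9 * pracma::erf(s / 33.9))
  expect_equal(rog_input(s, 0, p), expected, tolerance = 1e-12)
  # continuity across the s = r line (sign(0) = 0 convention)
  eps <- 1e-8
  expect_lt(abs(rog_input(20 + eps, 20, p) - rog_input(20 - eps, 20, p)), 1e-6)
})

test_that("frozen oracle value of the stationary drive at (60, 0) is reproduced", {
  # value computed from the closed form with an independent erf
  # implementation (erf(x) = 2 pnorm(x sqrt(2)) - 1) and frozen
  erf0 <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  frozen <- 2 * 1.2 * erf0(60 / 36.7) / (1 + 2 * 1.9 * erf0(60 / 33.9))
  expect_equal(frozen, 0.494432758945, tolerance = 1e-9)
  expect_equal(rog_input(60, 0, rog_params(1.2, 1.9, 36.7, 33.9)), frozen,
               tolerance = 1e-10)
})

test_that("rectified response implements subtractive and divisive modes", {
  expect_equal(rectified_response(2, 3, "subtractive"), 0)
  expect_equal(rectified_response(3, 2, "divisive"), 1)
  # modes coincide at zero inhibition
  x <- c(-1, 0, 2.5)
  expect_equal(rectified_response(x, 0, "subtractive"),
               rectified_response(x, 0, "divisive"))
  expect_equal(rectified_response(x, 0, "subtractive"), pmax(x, 0))
  # monotone nonincreasing in the inhibition argument
  y <- seq(0, 5, by = 0.5)
  for (mode in c("subtractive", "divisive")) {
    out <- rectified_response(rep(2, length(y)), y, mode)
    expect_true(all(diff(out) <= 1e-12))
  }
})

test_that("Gaussian field convolution matches the variance-addition closed form", {
  g <- space_grid()
  sf <- 10; sk <- 15
  bump <- function(r) exp(-r^2 / (2 * sf^2))
  out <- field_convolve(bump, sk, g)
  truth <- sf^2 / (sf^2 + sk^2) * exp(-g$offsets^2 / (2 * (sf^2 + sk^2)))
  expect_lt(max(abs(out - truth)) / max(truth), 1e-4)
  # constant fields are preserved (unit kernel mass)
  expect_equal(field_convolve(rep(2, length(g$offsets)), 40, g, tail_b = Inf),
               rep(2, length(g$offsets)), tolerance = 1e-10)
  # under-resolved kernel is refused
  expect_error(field_convolve(bump, 0.2, g), "under-resolved")
})

test_that("radial convolution agrees with the 2D Cartesian brute force", {
  g <- space_grid()
  set.seed(42)
  for (i in 1:3) {
    a <- runif(1, 0.5, 2); w <- runif(1, 8, 20); c0 <- runif(1, 0, 0.3)
    f <- function(r) a * exp(-r^2 / (2 * w^2)) + c0 * exp(-r^2 / (2 * (2.5 * w)^2))
    sigma <- sample(c(5, 15, 30), 1)
    r_out <- c(0, 12, 27)
    mine <- field_convolve(f, sigma, g, r_out = r_out, step = 0.25)
    oracle <- cartesian_convolve(f, sigma, r_out)
    expect_lt(max(abs(mine - oracle)) / max(abs(oracle)), 1e-6)
  }
})

test_that("effective weights implement the loop reduction and its identities", {
  w <- c(EH = 1, EE = 0.5, EP = 0.5, ES = 0.4, PH = 1, PE = 2, PP = 1,
         PS = 0.5, SH = 0.3, SE = 1, SV = 0.5, VE = 0.7, VS = 0.9)
  sig <- c(ES = 30, PE = 5, PS = 30, SH = 25, SE = 5, SV = 15, VE = 5, VS = 15)
  np <- network_params(w, sig, c(VS = "divisive"), mu = 1)
  tw <- effective_weights(np)
  expect_equal(unname(tw["EH", 1]), 1 / (1 - 0.5 + 0.5))   # = 1.0
  expect_equal(unname(tw["PE", 1]), 2 / (1 + 1))           # = 1.0
  # shared denominator: ratio of E weights preserved
  expect_equal(tw["EH", 1] / tw["ES", 1], w[["EH"]] / w[["ES"]])
  # no recurrence: effective equals raw
  w0 <- w; w0[c("EE", "EP", "PP")] <- 0
  tw0 <- effective_weights(network_params(w0, sig, c(), mu = 1))
  expect_equal(unname(tw0[c("EH", "ES", "PH", "PE", "PS"), 1]),
               unname(w0[c("EH", "ES", "PH", "PE", "PS")]))
  # unstable reduction rejected
  wbad <- w; wbad["EE"] <- 1.6; wbad["EP"] <- 0
  expect_error(effective_weights(network_params(wbad, sig, c(), mu = 1)),
               "unstable")
})

test_that("clamped prediction matches the brute-force quadrature oracle", {
  g <- space_grid(sizes = c(0, 10, 30, 60), offsets = c(0, 8, 16, 24, 33, 45, 60),
                  step = 1)
  net <- sample_network(1, "paper-like", jitter = 0)
  tw <- effective_weights(net)[, "stationary"]
  set.seed(7)
  r_out <- c(0, 16, 33)
  sizes <- c(10, 30, 60)
  # analytic random radial fields per class and size
  mkf <- function() {
    a <- runif(1, 0.3, 1.5); w <- runif(1, 10, 25)
    function(r) a * exp(-r^2 / (2 * w^2)) + 0.2 * a * exp(-r^2 / (2 * (2.5 * w)^2))
  }
  flds <- lapply(1:3, function(i) list(E = mkf(), P = mkf(), S = mkf(), V = mkf()))
  h_fun <- function(r) rog_input(60, r, rog_params())
  h_funs <- lapply(sizes, function(s) function(r) rog_input(s, r, rog_params()))
  for (i in seq_along(sizes)) {
    oracle <- bruteforce_rhs(flds[[i]], h_funs[[i]], tw, net$sigmas, net$modes,
                             r_out)
    # package path: per-size radial functions through the convolver
    conv <- function(fun, sigma) field_convolve(fun, sigma, g, r_out = r_out,
                                                step = 0.25)
    h <- h_funs[[i]](r_out)
    mine <- list(
      E = rectified_response(tw["EH"] * h, tw["ES"] * conv(flds[[i]]$S, net$sigmas[["ES"]]),
                             net$modes[["ES"]]),
      P = rectified_response(tw["PH"] * h + tw["PE"] * conv(flds[[i]]$E, net$sigmas[["PE"]]),
                             tw["PS"] * conv(flds[[i]]$S, net$sigmas[["PS"]]), net$modes[["PS"]]),
      S = rectified_response(tw["SH"] * conv(h_funs[[i]], net$sigmas[["SH"]]) +
                               tw["SE"] * conv(flds[[i]]$E, net$sigmas[["SE"]]),
                             tw["SV"] * conv(flds[[i]]$V, net$sigmas[["SV"]]), net$modes[["SV"]]),
      V = rectified_response(tw["VE"] * conv(flds[[i]]$E, net$sigmas[["VE"]]),
                             tw["VS"] * conv(flds[[i]]$S, net$sigmas[["VS"]]), net$modes[["VS"]]))
    for (cl in c("E", "P", "S", "V")) {
      scale <- max(abs(oracle[[cl]]), 1e-6)
      expect_lt(max(abs(mine[[cl]] - oracle[[cl]])) / scale, 1e-6)
    }
  }
})

test_that("effective-weight degeneracy: different raw loops, identical predictions", {
  g <- space_grid()
  th <- rog_params_default()
  base <- sample_network(1, "paper-like", jitter = 0)
  sol <- solve_fixed_point(base, th, g, conditions = "stationary")
  # two parameterizations with identical effective weights
  w1 <- base$weights[, 1]
  w2 <- w1
  den1 <- 1 - w1[["EE"]] + base$mu * w1[["EP"]]
  w2["EE"] <- 0.1; w2["EP"] <- 0.4
  den2 <- 1 - w2[["EE"]] + base$mu * w2[["EP"]]
  w2["EH"] <- w1[["EH"]] * den2 / den1
  w2["ES"] <- w1[["ES"]] * den2 / den1
  n1 <- network_params(cbind(stationary = w1, locomotion = w1), base$sigmas,
                       base$modes, base$mu)
  n2 <- network_params(cbind(stationary = w2, locomotion = w2), base$sigmas,
                       base$modes, base$mu)
  p1 <- predict_rates_clamped(n1, sol$stationary, th$stationary, "stationary")
  p2 <- predict_rates_clamped(n2, sol$stationary, th$stationary, "stationary")
  expect_lt(max(abs(p1$E - p2$E)) / max(p1$E), 1e-12)
})

test_that("fixed-point solver honors closed forms and self-consistency", {
  g <- space_grid()
  th <- rog_params_default()
  # zero drive -> zero fields
  z <- matrix(0, length(g$sizes), length(g$offsets))
  net <- sample_network(1, "paper-like", jitter = 0)
  sol0 <- solve_fixed_point(net, list(stationary = z, locomotion = z), g)
  expect_equal(max(abs(unlist(sol0$stationary[c("E", "P", "S", "V")]))), 0)
  # single-class linear case: f_E = w_EH h / (1 - w_EE)
  w <- c(EH = 0.8, EE = 0.4)
  lin <- network_params(w, c(), c(), mu = 1)
  sol1 <- solve_fixed_point(lin, th, g, conditions = "stationary")
  h <- rog_surface(g, th$stationary)
  expect_equal(sol1$stationary$E, 0.8 * h / (1 - 0.4), tolerance = 1e-6)
  # paper-like preset: converged, nonnegative, self-consistent
  sol <- solve_fixed_point(net, th, g, conditions = "stationary")
  f <- sol$stationary
  expect_true(all(unlist(f[c("E", "P", "S", "V")]) >= 0))
  pred <- predict_rates_clamped(net, f, th$stationary, "stationary")
  resid <- max(abs(pred$E - f$E), abs(pred$P - f$P),
               abs(pred$S - f$S), abs(pred$V - f$V))
  expect_lt(resid / max(f$E), 1e-7)
  # Pyr tuning at r = 0 rises then falls (surround suppression)
  e0 <- f$E[, 1]
  expect_gt(which.max(e0), 2)
  expect_lt(which.max(e0), length(e0))
  expect_lt(e0[length(e0)], max(e0))
})
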