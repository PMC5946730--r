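# Tuning-surface construction and the clamped-rate estimation pipeline.

# small shared fixtures built once per file
net0 <- sample_network(1, "paper-like", jitter = 0)
spec0 <- ground_truth_spec(network = net0, noise_cv = 0, n_experiments = 1)
sim0 <- simulate_population_tuning(spec0)
surf0 <- build_tuning_surfaces(sim0)

test_that("surface building recovers a known separable DoG-erf x exponential truth", {
  g <- sim0$grid
  truth_b <- 15
  truth_curve <- size_tuning_curve(g$sizes, R = 1.2, k = 0.55, sigma1 = 9, sigma2 = 38)
  vals <- outer(truth_curve, exp(-g$offsets / truth_b))
  fake_fs <- field_set(vals, vals, vals, vals, g)
  sim <- list(replicates = list(list(stationary = fake_fs, locomotion = fake_fs)),
              grid = g)
  surf <- build_tuning_surfaces(sim)
  est <- surf$surfaces$E$stationary
  expect_lt(abs(est$b - truth_b) / truth_b, 0.1)
  dom <- g$offsets <= 33
  expect_lt(max(abs(est$fitted_values[, dom] - vals[, dom])) / max(vals), 0.02)
  # a surface constant in r is flagged flat
  vflat <- outer(truth_curve, rep(1, length(g$offsets)))
  fs_flat <- field_set(vflat, vflat, vflat, vflat, g)
  surf_flat <- build_tuning_surfaces(list(replicates = list(list(
    stationary = fs_flat, locomotion = fs_flat)), grid = g))
  expect_true(surf_flat$surfaces$E$stationary$flat)
})

test_that("noiseless replicates trigger the mean-square fallback normalizer", {
  expect_true(all(attr(surf0$norm, "fallback")))
  expect_true(all(surf0$norm > 0))
  # noisy replicates use the across-experiment variance instead
  spec_n <- ground_truth_spec(network = net0, noise_cv = 0.1, n_experiments = 6)
  sim_n <- simulate_population_tuning(spec_n, seed = 4)
  surf_n <- build_tuning_surfaces(sim_n)
  expect_false(any(attr(surf_n$norm, "fallback")))
})

test_that("the penalized objective decomposes as documented", {
  cfg <- err_config()
  # truth on its own surfaces: tiny mse, no L0 term, known penalties
  obj <- objective_err(net0, surf0, spec0$thalamic, cfg)
  expect_lt(obj$mse, 1e-4)
  expect_equal(obj$n_dw, 3)   # paper-like modulates EH, PH, SH
  expect_equal(obj$l0, 0.3)
  expect_equal(obj$kernel,
               0.01 * sum((net0$sigmas[!is.na(net0$sigmas)] / 40)^2))
  # unfreezing exactly one weight adds exactly lambda1
  tw <- effective_weights(net0)
  p0 <- list(tw = tw, sigmas = net0$sigmas, modes = net0$modes)
  tw1 <- tw; tw1["VE", "locomotion"] <- tw1["VE", "locomotion"] + 1e-6
  p1 <- list(tw = tw1, sigmas = net0$sigmas, modes = net0$modes)
  e0 <- objective_err(p0, surf0, spec0$thalamic, cfg)
  e1 <- objective_err(p1, surf0, spec0$thalamic, cfg)
  expect_equal(e1$l0 - e0$l0, cfg$lambda1)
  expect_equal(e1$n_dw, e0$n_dw + 1)
  # hand-built instance: all-zero weights predict 0, so the fallback-
  # normalized mse of the nonzero E equation is exactly 1
  g2 <- sim0$grid
  z2 <- matrix(0, length(g2$sizes), length(g2$offsets))
  f2 <- outer(size_tuning_curve(g2$sizes, 1, 0.4, 10, 40),
              exp(-g2$offsets / 20))
  fs2 <- field_set(f2, z2, z2, z2, g2)
  sim2 <- list(replicates = list(list(stationary = fs2, locomotion = fs2)),
               grid = g2)
  surf2 <- suppressWarnings(build_tuning_surfaces(sim2))
  tw2 <- tw * 0
  p2 <- list(tw = tw2, sigmas = stats::setNames(rep(NA_real_, 8), names(net0$sigmas)),
             modes = net0$modes)
  o2 <- objective_err(p2, surf2, spec0$thalamic, err_config(0.1, 0, 0, 40))
  expect_equal(o2$mse, 1, tolerance = 1e-12)
  expect_equal(o2$err, 1, tolerance = 1e-12)
})

test_that("weight fitting honors degenerate and deterministic cases", {
  cfg0 <- err_config(0, 0, 0, 40)
  # zero target fields with positive drive force feedforward weights to zero
  g <- sim0$grid
  z <- matrix(0, length(g$sizes), length(g$offsets))
  fsz <- field_set(z, z, z, z, g)
  simz <- list(replicates = list(list(stationary = fsz, locomotion = fsz)),
               grid = g)
  surfz <- build_tuning_surfaces(simz)
  fitz <- fit_weights_given_sigmas(as.list(net0$sigmas), net0$modes, surfz,
                                   spec0$thalamic, cfg0, n_starts = 4, seed = 1)
  expect_lt(max(fitz$tw[c("EH", "PH", "SH"), ]), 1e-4)
  # same seed, same answer
  f1 <- fit_weights_given_sigmas(as.list(net0$sigmas), net0$modes, surf0,
                                 spec0$thalamic, cfg0, n_starts = 4, seed = 7)
  f2 <- fit_weights_given_sigmas(as.list(net0$sigmas), net0$modes, surf0,
                                 spec0$thalamic, cfg0, n_starts = 4, seed = 7)
  expect_identical(f1$tw, f2$tw)
})

test_that("noiseless weights are recovered at the true kernel widths", {
  cfg0 <- err_config(0, 0, 0, 40)
  tw_true <- effective_weights(net0)
  fit <- fit_weights_given_sigmas(as.list(net0$sigmas), net0$modes, surf0,
                                  spec0$thalamic, cfg0,
                                  free_weights = rownames(tw_true),
                                  n_starts = 6, seed = 2)
  expect_lt(max(abs(fit$tw - tw_true) / tw_true), 0.05)
})

test_that("the kernel grid search returns the true combination when the grid contains it", {
  cfg0 <- err_config(0, 0, 0, 40)
  # grid restricted to the single true sigma combination
  single <- lapply(as.list(net0$sigmas), function(s) s)
  gs1 <- sigma_grid_search(surf0, spec0$thalamic, config = cfg0, grids = single,
                           free_weights = rownames(effective_weights(net0)), n_starts = 4, seed = 1)
  expect_equal(gs1$sigmas[names(net0$sigmas)], net0$sigmas)
  # coarse 3-point grid containing the truth selects the exact grid point
  gs3 <- sigma_grid_search(surf0, spec0$thalamic, config = cfg0, grids = "reduced",
                           free_weights = rownames(effective_weights(net0)), n_starts = 6, seed = 1)
  expect_equal(gs3$sigmas[names(net0$sigmas)], net0$sigmas)
  tw_true <- effective_weights(net0)
  expect_lt(max(abs(gs3$tw - tw_true) / tw_true), 0.05)
})

test_that("locomotion model selection finds the modulated synapse", {
  netm <- sample_network(2, "single-modulation", jitter = 0)
  specm <- ground_truth_spec(network = netm, noise_cv = 0, n_experiments = 1)
  simm <- simulate_population_tuning(specm)
  surfm <- build_tuning_surfaces(simm)
  sel <- locomotion_model_selection(surfm, specm$thalamic, sigmas = netm$sigmas,
                                    config = err_config(), n_max = 2,
                                    n_starts = 6, seed = 5)
  expect_equal(sel$selected, 1)
  expect_equal(sel$free_weights, "EH")
  # identical weights across conditions -> nothing modulated
  net_id <- sample_network(3, "no-modulation", jitter = 0)
  spec_id <- ground_truth_spec(network = net_id, noise_cv = 0, n_experiments = 1)
  surf_id <- build_tuning_surfaces(simulate_population_tuning(spec_id))
  sel_id <- locomotion_model_selection(surf_id, spec_id$thalamic,
                                       sigmas = net_id$sigmas,
                                       config = err_config(), n_max = 2,
                                       n_starts = 6, seed = 5)
  expect_equal(sel_id$selected, 0)
  # with lambda1 = 0 the best achievable error is nonincreasing in n_dw
  sel_free <- locomotion_model_selection(surfm, specm$thalamic,
                                         sigmas = netm$sigmas,
                                         config = err_config(lambda1 = 0),
                                         n_max = 2, n_starts = 6, seed = 5)
  errs <- vapply(sel_free$path, `[[`, numeric(1), "err")
  expect_true(all(diff(errs) <= 1e-6))
})

test_that("mu estimation is the through-origin regression ratio", {
  f_E <- sim0$noiseless$stationary$E
  expect_equal(estimate_mu(f_E, 2 * f_E), 2)
  expect_equal(estimate_mu(f_E, f_E), 1)
  set.seed(9)
  mus <- vapply(1:20, function(i)
    estimate_mu(f_E, f_E + matrix(rnorm(length(f_E), 0, 0.01), nrow(f_E))),
    numeric(1))
  expect_lt(abs(mean(mus) - 1), 0.02)
  expect_error(estimate_mu(f_E * 0, f_E), "zero")
})

test_that("experiment relabeling leaves the objective unchanged", {
  spec_n <- ground_truth_spec(network = net0, noise_cv = 0.15, n_experiments = 5)
  sim_n <- simulate_population_tuning(spec_n, seed = 6)
  surf_a <- build_tuning_surfaces(sim_n)
  sim_perm <- sim_n
  sim_perm$replicates <- sim_n$replicates[c(3, 1, 5, 2, 4)]
  surf_b <- build_tuning_surfaces(sim_perm)
  oa <- objective_err(net0, surf_a, spec_n$thalamic, err_config())
  ob <- objective_err(net0, surf_b, spec_n$thalamic, err_config())
  expect_equal(oa$err, ob$err, tolerance = 1e-12)
})

test_that("the inhibition-mode search identifies the generating combination", {
  ms <- inhibition_mode_search(surf0, spec0$thalamic, as.list(net0$sigmas),
                               config = err_config(0, 0, 0, 40),
                               free_weights = rownames(effective_weights(net0)),
                               n_starts = 4, seed = 4)
  expect_equal(unname(ms$modes[c("ES", "PS", "SV", "VS")]),
               c("subtractive", "subtractive", "subtractive", "divisive"))
})
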