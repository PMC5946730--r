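# Neuropil correction, dF/F0, skewness classification, trial selection.

make_alpha_fixture <- function(alpha, n = 3000, seed = 1) {
  set.seed(seed)
  N <- 20 + 5 * sin(seq_len(n) / 120) + as.numeric(stats::filter(rnorm(n, 0, 1.5),
                                                                 rep(0.2, 5), sides = 2))
  N[is.na(N)] <- 20
  events <- rbinom(n, 1, 0.004) * rexp(n, 1 / 40)
  soma <- 15 + as.numeric(stats::filter(events, 0.85^(0:49) , method = "convolution",
                                        sides = 1))
  soma[is.na(soma)] <- 15
  list(F = soma + alpha * N + rnorm(n, 0, 0.2), N = N)
}

test_that("percentile regression recovers the contamination slope", {
  for (alpha in c(0.5, 0.8)) {
    fx <- make_alpha_fixture(alpha, seed = round(100 * alpha))
    expect_lt(abs(estimate_neuropil_alpha(fx$F, fx$N) - alpha), 0.05)
  }
  # uncorrelated soma and neuropil -> slope near 0
  fx <- make_alpha_fixture(0, seed = 3)
  expect_lt(abs(estimate_neuropil_alpha(fx$F, fx$N)), 0.05)
  expect_error(estimate_neuropil_alpha(rep(1, 300), rep(2, 300)), "degenerate")
  expect_error(estimate_neuropil_alpha(1:100, 1:100), ">= 200")
})

test_that("session-level correction averages high-skewness cells and falls back to 0.82", {
  net <- sample_network(1, "paper-like", jitter = 0)
  spec <- ground_truth_spec(network = net, duration = 500, neuropil_alpha = 0.7)
  ses <- simulate_session(spec, seed = 2)
  cor1 <- correct_session_neuropil(ses)
  expect_lt(abs(cor1$neuropil_fit$alpha_exp - 0.7), 0.05)
  expect_gt(cor1$neuropil_fit$n_high_skew, 0)
  # corrected flag prevents double correction
  expect_error(correct_session_neuropil(cor1), "already")
  # a session with only low-skewness cells uses the canonical 0.82
  spec_inh <- ground_truth_spec(network = net, duration = 200, neuropil_alpha = 0.6,
                                cells_per_class = c(Pyr = 1, Pvalb = 6, Sst = 5, Vip = 5))
  ses_inh <- simulate_session(spec_inh, seed = 4)
  ses_inh$F <- ses_inh$F[-1, , drop = FALSE]   # drop the lone sparse cell
  ses_inh$N <- ses_inh$N[-1, , drop = FALSE]
  ses_inh$cells <- ses_inh$cells[-1, ]
  corr <- correct_session_neuropil(ses_inh)
  expect_true(corr$neuropil_fit$used_fallback)
  expect_equal(corr$neuropil_fit$alpha_exp, 0.82)
})

test_that("dF/F0 has the documented baseline and invariances", {
  fs <- 10
  expect_equal(compute_dff(rep(3, 100), fs), rep(0, 100))
  # single sharp spike: baseline near floor, positive peak
  tr <- rep(10, 200); tr[100:102] <- c(40, 30, 20)
  d <- compute_dff(tr, fs)
  expect_gt(max(d), 0)
  expect_lt(abs(d[1]), 0.05)
  # a 1 s flat floor pins F0 (within smoothing error)
  tr2 <- 30 + 10 * abs(sin(seq_len(300) / 20)); tr2[150:159] <- 12
  d2 <- compute_dff(tr2, fs)
  f0_implied <- tr2[1] / (d2[1] + 1)
  expect_lt(abs(f0_implied - 12), 1.5)
  # invariance to positive rescaling of the trace
  expect_equal(compute_dff(5 * tr2, fs), compute_dff(tr2, fs), tolerance = 1e-12)
  expect_error(compute_dff(c(rep(-1, 20), rep(1, 80)), fs), "non-positive")
})

test_that("skewness classifier separates sparse from dense traces", {
  set.seed(1)
  gauss <- rnorm(2000)
  expect_equal(classify_putative_pyr(gauss)$label, "excluded")
  # affine invariance of skewness
  expect_equal(trace_skewness(3 * gauss + 7), trace_skewness(gauss), tolerance = 1e-12)
  expect_equal(trace_skewness(gauss), skew_oracle(gauss), tolerance = 1e-12)
  const <- rep(2, 500)
  out <- classify_putative_pyr(const)
  expect_equal(out$label, "excluded")
  expect_equal(out$reason, "degenerate")
  # synthetic labeled traces: error rate below 5 percent at threshold 2.7
  net <- sample_network(1, "paper-like", jitter = 0)
  spec <- ground_truth_spec(network = net, duration = 500)
  ses <- correct_session_neuropil(simulate_session(spec, seed = 11))
  lab <- apply(ses$F, 1, function(x) classify_putative_pyr(x)$label)
  truth <- ifelse(ses$truth$class == "Pyr", "putative_pyr", "excluded")
  expect_lt(mean(lab != truth), 0.05)
})

test_that("trial responses and selection implement the stated criteria", {
  net <- sample_network(1, "paper-like", jitter = 0)
  spec <- ground_truth_spec(network = net, duration = 400)
  ses <- correct_session_neuropil(simulate_session(spec, seed = 3))
  sel <- trial_responses_and_selection(ses, rf_radius = 10)
  expect_true(all(c("cell_id", "diameter", "dF", "condition") %in% names(sel$responses)))
  expect_true(all(sel$responses$condition %in% 0:1))
  # selected cells are within the RF radius
  offs <- sqrt(ses$cells$rf_x^2 + ses$cells$rf_y^2)
  expect_true(all(offs[match(sel$selected, ses$cells$cell_id)] <= 10))
  # all pupil offsets small -> pupil filter removes nothing
  ses2 <- ses; ses2$pupil$x[] <- 0; ses2$pupil$y[] <- 0
  n_off <- nrow(trial_responses_and_selection(ses2, pupil_filter = FALSE)$responses)
  n_on <- nrow(trial_responses_and_selection(ses2, pupil_filter = TRUE)$responses)
  expect_equal(n_on, n_off)
  # a cell with identical responses at all sizes is never selected
  ses3 <- ses
  ses3$F[1, ] <- 30   # flat trace -> no size tuning
  sel3 <- trial_responses_and_selection(ses3)
  expect_false(ses3$cells$cell_id[1] %in% sel3$selected)
})
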