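# Synthetic-data generator ---------------------------------------------------
#
# The generator produces (a) ground-truth population tuning surfaces by
# solving the circuit model self-consistently, with multiplicative lognormal
# across-experiment noise, and (b) full imaging sessions whose traces have
# the statistical structure the analysis pipeline assumes: sparse highly
# skewed Pyr traces vs dense interneuron traces, additive neuropil
# contamination, locomotion-coupled baselines, and class-specific size
# tuning inherited from the circuit.

#' Ground-truth specification for the synthetic-data generator
#'
#' @param network a [network_params()] circuit (default: `paper-like`).
#' @param thalamic list of [rog_params()] per condition (default: the
#'   published dLGN fits).
#' @param n_experiments number of simulated experiments (fields of view).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   across-experiment response noise.
#' @param cells_per_class named counts of simulated cells; Pyr cells are
#'   written out as `unlabeled` (their identity is ground truth, recovered
#'   by the skewness classifier), interneurons carry their genetic label.
#' @param trace_params per-class calcium-trace parameters: `event_rate`
#'   (Hz), `decay` (s, single-exponential kernel), `amplitude` (a.u.),
#'   `loc_gain` (multiplicative locomotion gain on the event rate).
#' @param neuropil_alpha true contamination factor in `[0, 1]`.
#' @param speed_model two-state locomotion model: mean dwell times (s) and
#'   running-speed distribution (cm/s; running is defined as > 1 cm/s).
#' @param fs sampling rate, Hz.
#' @param duration session length, seconds.
#' @param stim_sizes stimulus diameters (degrees); 0 is the blank.
#' @param stim_period seconds between stimulus onsets (1 s stimulus + gap).
#' @param rng_seed default seed.
#' @return object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(network = sample_network(1L, "paper-like"),
                              thalamic = rog_params_default(),
                              n_experiments = 24L,
                              noise_cv = 0.1,
                              cells_per_class = c(Pyr = 30L, Pvalb = 10L,
                                                  Sst = 8L, Vip = 8L),
                              trace_params = default_trace_params(),
                              neuropil_alpha = 0.7,
                              speed_model = list(dwell_run = 20, dwell_rest = 25,
                                                 speed_mean = 8, speed_sd = 3),
                              fs = 10, duration = 600,
                              stim_sizes = c(0, 5, 10, 20, 30, 40, 60),
                              stim_period = 4,
                              rng_seed = 1L) {
  if (noise_cv < 0) stop_nf("ground_truth_spec: noise_cv must be >= 0")
  if (neuropil_alpha < 0 || neuropil_alpha > 1)
    stop_nf("ground_truth_spec: neuropil_alpha must be in [0, 1]")
  if (n_experiments < 1 || any(cells_per_class < 1))
    stop_nf("ground_truth_spec: counts must be >= 1")
  stopifnot(inherits(network, "network_params"))
  if (!all(c("Pyr", "Pvalb", "Sst", "Vip") %in% names(cells_per_class)))
    stop_nf("ground_truth_spec: cells_per_class must name Pyr, Pvalb, Sst, Vip")
  if (!all(c(5, 60) %in% stim_sizes) || !0 %in% stim_sizes)
    stop_nf("ground_truth_spec: stimulus set must include the blank, 5 and 60 degrees")
  structure(list(network = network, thalamic = thalamic,
                 n_experiments = as.integer(n_experiments),
                 noise_cv = noise_cv,
                 cells_per_class = cells_per_class,
                 trace_params = trace_params,
                 neuropil_alpha = neuropil_alpha,
                 speed_model = speed_model,
                 fs = fs, duration = duration,
                 stim_sizes = sort(stim_sizes), stim_period = stim_period,
                 rng_seed = as.integer(rng_seed)),
            class = "ground_truth_spec")
}

#' Default per-class calcium-trace parameters
#'
#' Event rates differ strongly between sparse Pyr cells and densely active
#' interneurons so that the skewness classifier has something to classify;
#' kernel decay is a generic GCaMP-like 0.7 s.
#' @export
default_trace_params <- function() {
  list(Pyr   = list(event_rate = 0.03, decay = 0.7, amplitude = 60, loc_gain = 0.4),
       Pvalb = list(event_rate = 2.6,  decay = 0.7, amplitude = 4,  loc_gain = 0.8),
       Sst   = list(event_rate = 1.2,  decay = 0.7, amplitude = 4,  loc_gain = 0.3),
       Vip   = list(event_rate = 1.8,  decay = 0.7, amplitude = 4,  loc_gain = 0.7))
}

class_letter <- c(Pyr = "E", Pvalb = "P", Sst = "S", Vip = "V")

#' Ground-truth tuning surfaces with across-experiment replicates
#'
#' Solves the circuit self-consistently on `grid` (both conditions) and
#' produces `n_experiments` noisy replicates: noiseless field times
#' iid lognormal noise with unit mean and CV `noise_cv` per (class, s, r,
#' condition, experiment).  The across-experiment variance of the
#' replicates is returned for use as the weighting surface of the fitting
#' objective.
#'
#' @param spec a [ground_truth_spec()].
#' @param grid a [space_grid()].
#' @param seed seed (defaults to `spec$rng_seed`).
#' @return list with `noiseless` (list of [field_set()] per condition),
#'   `replicates` (list over experiments, same shape), `variance`
#'   (list per condition of per-class variance matrices), and `grid`.
#' @export
simulate_population_tuning <- function(spec, grid = space_grid(),
                                       seed = spec$rng_seed) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (max(grid$sizes) < 60 || max(grid$offsets) < 33)
    stop_nf("simulate_population_tuning: grid must cover s in [0, 60], r to >= 33")
  noiseless <- solve_fixed_point(spec$network, spec$thalamic, grid)
  cv <- spec$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2        # unit-mean lognormal
  set.seed(derive_seed(seed, 202L))
  replicates <- lapply(seq_len(spec$n_experiments), function(e) {
    out <- lapply(CONDITIONS, function(v) {
      f <- noiseless[[v]]
      noisy <- lapply(CLASSES, function(cl) {
        m <- f[[cl]]
        if (cv == 0) return(m)
        m * matrix(stats::rlnorm(length(m), meanlog, sdlog), nrow(m))
      })
      names(noisy) <- CLASSES
      field_set(noisy$E, noisy$P, noisy$S, noisy$V, grid)
    })
    names(out) <- CONDITIONS
    out
  })
  variance <- lapply(CONDITIONS, function(v) {
    out <- lapply(CLASSES, function(cl) {
      arr <- vapply(replicates, function(rep) rep[[v]][[cl]],
                    noiseless[[v]][[cl]])
      apply(arr, c(1, 2), stats::var)
    })
    names(out) <- CLASSES
    out
  })
  names(variance) <- CONDITIONS
  list(noiseless = noiseless, replicates = replicates,
       variance = variance, grid = grid)
}

# two-state semi-Markov locomotion: exponential dwell times, lognormal bout
# speeds (> 1 cm/s while running, ~0 at rest)
simulate_speed <- function(n, fs, sm) {
  state <- numeric(0); speed <- numeric(0)
  running <- FALSE
  while (length(state) < n) {
    dwell <- max(2, stats::rexp(1, 1 / (if (running) sm$dwell_run else sm$dwell_rest)))
    len <- min(round(dwell * fs), n - length(state))
    if (running) {
      lvl <- max(1.5, stats::rlnorm(1, log(sm$speed_mean), sm$speed_sd / sm$speed_mean))
      sp <- pmax(1.05, lvl + stats::rnorm(len, 0, 0.5))
    } else {
      sp <- abs(stats::rnorm(len, 0, 0.08))
    }
    state <- c(state, rep(as.integer(running), len))
    speed <- c(speed, sp)
    running <- !running
  }
  list(state = state[seq_len(n)], speed = boxcar_smooth(speed[seq_len(n)], 5))
}

#' Simulate a full imaging session from a ground-truth circuit
#'
#' Builds per-cell somatic traces (baseline + Poisson event train convolved
#' with an exponential kernel, with event rates modulated by the stimulus
#' response of the cell's class at its receptive-field offset and by a
#' per-cell locomotion gain), a shared locomotion-coupled neuropil trace,
#' recorded fluorescence F = soma + alpha * neuropil, a stimulus log with a
#' blank and diameters including 5 and 60 degrees, running speed from the
#' two-state model, and pupil positions.  Ground truth (true class, true
#' alpha, event trains) is kept in `$truth`.
#'
#' @param spec a [ground_truth_spec()].
#' @param seed integer seed (defaults to `spec$rng_seed`).
#' @param fields optional precomputed output of [simulate_population_tuning()]
#'   (reused across sessions to avoid re-solving the circuit).
#' @return object of class `nf_session`.
#' @export
simulate_session <- function(spec, seed = spec$rng_seed, fields = NULL) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (is.null(fields)) {
    grid <- space_grid()
    noiseless <- solve_fixed_point(spec$network, spec$thalamic, grid)
  } else {
    grid <- fields$grid
    noiseless <- fields$noiseless
  }
  set.seed(derive_seed(seed, 303L))
  fs <- spec$fs
  n <- round(spec$duration * fs)
  t_axis <- (seq_len(n) - 1) / fs

  loco <- simulate_speed(n, fs, spec$speed_model)

  # stimulus log: randomized diameters, fixed period, 1 s presentations
  onsets <- seq(5, spec$duration - spec$stim_period, by = spec$stim_period)
  diameters <- sample(rep(spec$stim_sizes, length.out = length(onsets)))
  stimuli <- data.frame(stim_id = seq_along(onsets), onset = onsets,
                        duration = 1, diameter = diameters)

  # cells
  classes <- rep(names(spec$cells_per_class), spec$cells_per_class)
  n_cells <- length(classes)
  rf_r <- sqrt(stats::runif(n_cells)) * 25      # uniform in a 25 deg disc
  rf_th <- stats::runif(n_cells, 0, 2 * pi)
  cells <- data.frame(
    cell_id = seq_len(n_cells),
    class_label = ifelse(classes == "Pyr", "unlabeled", classes),
    depth = round(stats::runif(n_cells, 150, 350), 1),
    rf_x = round(rf_r * cos(rf_th), 2),
    rf_y = round(rf_r * sin(rf_th), 2))

  # shared neuropil trace: baseline + locomotion coupling + slow noise
  np_slow <- boxcar_smooth(stats::rnorm(n, 0, 12), 101L)
  neuropil <- 20 + 0.8 * boxcar_smooth(loco$speed, 11L) + np_slow
  neuropil <- pmax(neuropil, 1)

  # per-trial condition and response gain per class, from the circuit fields;
  # each class is normalized by its own field maximum so the peak
  # multiplicative stimulus gain is comparable across classes
  max_field <- vapply(CLASSES, function(cl)
    max(noiseless$stationary[[cl]], noiseless$locomotion[[cl]], 1e-9),
    numeric(1))
  stim_frame <- round(stimuli$onset * fs) + 1L
  kernel_len <- round(5 * fs)

  F_soma <- matrix(0, n_cells, n)
  events <- matrix(0, n_cells, n)
  for (i in seq_len(n_cells)) {
    cl <- classes[i]
    tp <- spec$trace_params[[cl]]
    letter <- class_letter[[cl]]
    r_i <- sqrt(cells$rf_x[i]^2 + cells$rf_y[i]^2)
    # baseline event rate with locomotion gain
    rate <- tp$event_rate * (1 + tp$loc_gain * loco$state)
    # stimulus-evoked multiplicative gain during the 1 s stimulus window
    for (k in seq_len(nrow(stimuli))) {
      idx <- stim_frame[k]:min(n, stim_frame[k] + fs - 1L)
      v <- if (mean(loco$speed[idx]) > 1) "locomotion" else "stationary"
      fval <- interp_field(noiseless[[v]][[letter]], grid, stimuli$diameter[k], r_i)
      rate[idx] <- rate[idx] * (1 + 8 * fval / max_field[[letter]])
    }
    ev <- stats::rpois(n, rate / fs)
    events[i, ] <- ev
    amp <- tp$amplitude * stats::rlnorm(n, -0.02, 0.2)
    kern <- exp(-(seq_len(kernel_len) - 1) / (tp$decay * fs))
    resp <- stats::convolve(ev * amp, rev(kern), type = "open")[seq_len(n)]
    F_soma[i, ] <- 20 + resp + stats::rnorm(n, 0, 1)
  }
  F_rec <- F_soma + spec$neuropil_alpha * matrix(neuropil, n_cells, n, byrow = TRUE)
  N_rec <- matrix(neuropil, n_cells, n, byrow = TRUE)

  # pupil: tight jitter around a fixed gaze plus occasional deviated epochs
  pupil_x <- stats::rnorm(n, 0, 0.6)
  pupil_y <- stats::rnorm(n, 0, 0.6)
  n_dev <- max(1L, round(n / 2000))
  for (d in seq_len(n_dev)) {
    at <- sample.int(n - 50L, 1L)
    pupil_x[at:(at + 49L)] <- pupil_x[at:(at + 49L)] + 8
  }

  structure(list(
    cells = cells,
    F = F_rec, N = N_rec,
    fs = fs, time = t_axis,
    speed = loco$speed,
    pupil = data.frame(x = pupil_x, y = pupil_y),
    stimuli = stimuli,
    meta = list(corrected = FALSE, alpha_exp = NA_real_, fs = fs,
                stim_center = c(0, 0)),
    truth = list(class = classes, neuropil_alpha = spec$neuropil_alpha,
                 events = events, run_state = loco$state,
                 seed = seed)),
    class = "nf_session")
}

# bilinear interpolation of a field surface at (s, r)
interp_field <- function(mat, grid, s, r) {
  s <- min(max(s, min(grid$sizes)), max(grid$sizes))
  r <- min(max(r, min(grid$offsets)), max(grid$offsets))
  is_ <- findInterval(s, grid$sizes, rightmost.closed = TRUE)
  ir <- findInterval(r, grid$offsets, rightmost.closed = TRUE)
  is2 <- min(is_ + 1L, length(grid$sizes)); ir2 <- min(ir + 1L, length(grid$offsets))
  ws <- if (is2 > is_) (s - grid$sizes[is_]) / (grid$sizes[is2] - grid$sizes[is_]) else 0
  wr <- if (ir2 > ir) (r - grid$offsets[ir]) / (grid$offsets[ir2] - grid$offsets[ir]) else 0
  (1 - ws) * ((1 - wr) * mat[is_, ir] + wr * mat[is_, ir2]) +
    ws * ((1 - wr) * mat[is2, ir] + wr * mat[is2, ir2])
}

#' @export
print.nf_session <- function(x, ...) {
  cat(sprintf("nf_session: %d cells, %.0f s at %g Hz, %d stimuli, %s\n",
              nrow(x$cells), length(x$time) / x$fs, x$fs, nrow(x$stimuli),
              if (isTRUE(x$meta$corrected)) "neuropil-corrected" else "raw"))
  print(table(x$cells$class_label))
  invisible(x)
}
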