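# Clamped-rate parameter estimation ------------------------------------------
#
# With the presynaptic surfaces clamped to measurements, the four class
# equations decouple: each class's weights (effective weights for E and P)
# enter only its own prediction and its own constraint penalty.  The fit
# therefore proceeds per postsynaptic class, and the exhaustive kernel
# search and the L0 model selection factorize over classes, which is what
# makes the exhaustive protocol tractable.

# term structure of each class equation
CLASS_TERMS <- list(
  E = list(weights = c("EH", "ES"),
           exc = list(EH = list(input = "h", sigma = NA)),
           inh = list(ES = list(input = "S", sigma = "ES")), mode = "ES"),
  P = list(weights = c("PH", "PE", "PS"),
           exc = list(PH = list(input = "h", sigma = NA),
                      PE = list(input = "E", sigma = "PE")),
           inh = list(PS = list(input = "S", sigma = "PS")), mode = "PS"),
  S = list(weights = c("SH", "SE", "SV"),
           exc = list(SH = list(input = "h", sigma = "SH"),
                      SE = list(input = "E", sigma = "SE")),
           inh = list(SV = list(input = "V", sigma = "SV")), mode = "SV"),
  V = list(weights = c("VE", "VS"),
           exc = list(VE = list(input = "E", sigma = "VE")),
           inh = list(VS = list(input = "S", sigma = "VS")), mode = "VS"))

CLASS_SIGMA_SETS <- list(E = "ES", P = c("PE", "PS"),
                         S = c("SH", "SE", "SV"), V = c("VE", "VS"))

# kernel-width search grids: one range for kernels whose presynaptic source
# is the visual input or excitatory cells, a broader one for Sst/Vip sources
EXC_KERNELS <- c("PE", "SE", "VE", "SH")
INH_KERNELS <- c("ES", "PS", "SV", "VS")

#' Kernel-width search grids
#'
#' `"paper"`: visual-input/excitatory kernels 1-40 degrees in 15 equal
#' steps, Sst/Vip kernels 1-100 degrees in 12 equal steps.  `"reduced"`: a
#' coarse 3-point grid per group for desk-scale runs.  A named list of
#' per-synapse values can be given directly.
#'
#' @param which `"paper"` or `"reduced"`.
#' @return named list of candidate sigma vectors per kernel synapse.
#' @export
sigma_grids <- function(which = c("paper", "reduced")) {
  which <- match.arg(which)
  if (which == "paper") {
    exc <- seq(1, 40, length.out = 15)
    inh <- seq(1, 100, length.out = 12)
  } else {
    exc <- c(5, 20, 35)
    inh <- c(15, 30, 60)
  }
  c(stats::setNames(rep(list(exc), length(EXC_KERNELS)), EXC_KERNELS),
    stats::setNames(rep(list(inh), length(INH_KERNELS)), INH_KERNELS))
}

#' Objective configuration
#'
#' Weights of the penalized objective: `lambda1` (L0 penalty per
#' locomotion-modulated weight, 0.1), `lambda2` (kernel-extent penalty,
#' 0.01, scale `sigma_L` = 40 degrees), `lambda3` (biological constraint
#' penalty on the Sst and Pvalb equations, 0.2).
#'
#' @param lambda1,lambda2,lambda3,sigma_L nonnegative penalty parameters.
#' @return object of class `err_config`.
#' @export
err_config <- function(lambda1 = 0.1, lambda2 = 0.01, lambda3 = 0.2,
                       sigma_L = 40) {
  if (any(c(lambda1, lambda2, lambda3, sigma_L) < 0))
    stop_nf("err_config: penalties must be nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 sigma_L = sigma_L), class = "err_config")
}

# Constraint ratios; degenerate denominators map to a fixed large penalty
# (1e6 on the squared term) to keep optimizers stable.
constraint_ratio <- function(class, tw) {
  ratio_or_big <- function(num, den) if (den < 1e-9) 1e3 else num / den
  if (class == "S") {
    sum(vapply(CONDITIONS, function(v)
      ratio_or_big(tw["SH", v], tw["SE", v] + tw["SV", v]), numeric(1)))
  } else if (class == "P") {
    sum(vapply(CONDITIONS, function(v)
      ratio_or_big(tw["PE", v], tw["PH", v] + tw["PS", v]), numeric(1)))
  } else 0
}

# Precompute, for one class and one sigma assignment, the basis surfaces
# (restricted to the fitting domain) that multiply each weight, per
# condition.  `cache` is an environment keyed by input/sigma/condition.
class_bases <- function(class, sigmas, surfaces, thalamic, cache = NULL) {
  grid <- surfaces$grid
  fit_r <- grid$offsets[grid$offsets <= surfaces$r_L]
  terms <- CLASS_TERMS[[class]]
  get_input <- function(input, v) {
    if (input == "h") {
      hv <- thalamic[[v]]
      if (inherits(hv, "rog_params")) rog_surface(grid, hv) else hv
    } else surfaces$surfaces[[input]][[v]]$values
  }
  # per-size tails are estimated from the outermost surface samples by the
  # convolution itself; the class-level decay length b describes the mean
  # decay and is reported, not imposed per size
  get_tail <- function(input, v) NULL
  conv_basis <- function(input, sigma, v, direct = FALSE) {
    if (direct) {                 # direct (unconvolved) drive
      m <- get_input(input, v)
      return(m[, grid$offsets <= surfaces$r_L, drop = FALSE])
    }
    if (is.na(sigma)) {           # inactive synapse: no basis
      m <- get_input(input, v)
      return(0 * m[, grid$offsets <= surfaces$r_L, drop = FALSE])
    }
    key <- sprintf("%s|%.6g|%s", input, sigma, v)
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    conv <- make_convolver(sigma, grid, r_out = fit_r)
    out <- conv(get_input(input, v), tail_b = get_tail(input, v))
    if (!is.null(cache)) cache[[key]] <- out
    out
  }
  lapply(stats::setNames(CONDITIONS, CONDITIONS), function(v) {
    list(exc = lapply(terms$exc, function(tm)
           conv_basis(tm$input, if (is.na(tm$sigma)) NA else sigmas[[tm$sigma]], v,
                      direct = is.na(tm$sigma))),
         inh = lapply(terms$inh, function(tm)
           conv_basis(tm$input, sigmas[[tm$sigma]], v)),
         target = surfaces$surfaces[[class]][[v]]$values[
           , grid$offsets <= surfaces$r_L, drop = FALSE])
  })
}

# Predicted surface of one class from its bases and weights (one condition).
class_predict <- function(bases_v, w, mode) {
  exc <- Reduce(`+`, Map(function(nm, B) w[[nm]] * B,
                         names(bases_v$exc), bases_v$exc))
  inh <- Reduce(`+`, Map(function(nm, B) w[[nm]] * B,
                         names(bases_v$inh), bases_v$inh))
  rectified_response(exc, inh, mode)
}

# Fit one class's weights given bases.  free_weights lists the class weights
# allowed to differ between conditions.  Multi-start bounded
# Levenberg-Marquardt; deterministic for fixed seed.  Returns the best fit
# by sum of squares (ties: first start).
fit_class_weights <- function(class, bases, surfaces, config,
                              free_weights = character(0),
                              n_starts = 50, seed = 1L,
                              weighting = c("points", "mean")) {
  weighting <- match.arg(weighting)
  terms <- CLASS_TERMS[[class]]
  wn <- terms$weights
  free <- intersect(free_weights, wn)
  shared <- setdiff(wn, free)
  par_names <- c(shared, if (length(free)) paste0(free, ".0"),
                 if (length(free)) paste0(free, ".1"))
  npar <- length(par_names)
  norm_a <- surfaces$norm[[class]]
  n_pts <- sum(vapply(bases, function(b) length(b$target), numeric(1)))
  # per-point inverse-variance weights (heteroscedastic noise): floored at a
  # tenth of the mean variance so exact-zero-variance points stay finite;
  # falls back to the scalar normalizer for noiseless surfaces
  if (weighting == "points" && !isTRUE(attr(surfaces$norm, "fallback")[[class]])) {
    grid <- surfaces$grid
    dom <- grid$offsets <= surfaces$r_L
    wt <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(v) {
      va <- surfaces$variance[[v]][[class]][, dom, drop = FALSE]
      w <- 1 / (va + 0.1 * mean(va))
      # keep the overall scale of the mean-normalized objective
      w / mean(w) * (1 / norm_a)
    })
  } else {
    wt <- lapply(stats::setNames(CONDITIONS, CONDITIONS), function(v) 1 / norm_a)
  }
  weights_from_par <- function(p) {
    names(p) <- par_names
    tw <- matrix(NA_real_, length(wn), 2, dimnames = list(wn, CONDITIONS))
    for (w in shared) tw[w, ] <- p[[w]]
    for (w in free) tw[w, ] <- c(p[[paste0(w, ".0")]], p[[paste0(w, ".1")]])
    tw
  }
  resid_fn <- function(p) {
    tw <- weights_from_par(p)
    res <- unlist(lapply(CONDITIONS, function(v) {
      pred <- class_predict(bases[[v]],
                            as.list(stats::setNames(tw[, v], wn)),
                            surfaces_mode(surfaces, class))
      (pred - bases[[v]]$target) * sqrt(wt[[v]] / n_pts)
    }))
    c(res, sqrt(config$lambda3) * constraint_ratio(class, tw))
  }
  set.seed(derive_seed(seed, sum(utf8ToInt(class))))
  starts <- matrix(exp(stats::runif(n_starts * npar, log(1e-3), log(10))),
                   n_starts, npar)
  starts[1, ] <- 1   # one deterministic unit start
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = rep(0, npar),
                         upper = rep(50, npar), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(fit$fvec^2)
    if (is.null(best) || ss < best$ss - 1e-14) best <- list(par = fit$par, ss = ss)
  }
  if (is.null(best)) stop_nf("fit_class_weights: all %d starts failed (class %s)",
                             n_starts, class)
  tw <- weights_from_par(best$par)
  list(class = class, tw = tw, ss = best$ss, n_free = length(free),
       free = free)
}

# inhibition mode of a class: stored on the surfaces object when fitting
# searched modes, else the default subtractive/divisive assignment
surfaces_mode <- function(surfaces, class) {
  md <- attr(surfaces, "modes")
  syn <- CLASS_TERMS[[class]]$mode
  if (!is.null(md)) md[[syn]] else
    c(ES = "subtractive", PS = "subtractive",
      SV = "subtractive", VS = "divisive")[[syn]]
}

set_surface_modes <- function(surfaces, modes) {
  attr(surfaces, "modes") <- modes
  surfaces
}

#' Penalized objective of the clamped-rate fit
#'
#' Err = <(fhat - f)^2> / <var> + lambda1 n_dw + lambda2 ||sigma/sigma_L||^2
#' + lambda3 (R_S^2 + R_P^2).  The first term is the variance-normalized
#' mean squared error, averaged over the fitting domain (s in [0, 60],
#' r in [0, 33], both conditions) and summed over the four class equations;
#' n_dw counts the weights that differ between conditions (the L0 term);
#' the kernel penalty sums over all active kernel widths; R_S keeps the Sst
#' drive mostly local, R_P keeps the Pyr input from dominating the Pvalb
#' equation.
#'
#' @param params either a [network_params()] object or a list with elements
#'   `tw` (matrix of fitted weights x condition), `sigmas`, `modes`.
#' @param surfaces a [build_tuning_surfaces()] object.
#' @param thalamic per-condition drive ([rog_params()] or matrices).
#' @param config an [err_config()].
#' @return list with `err` and components `mse`, `l0` (with `n_dw`),
#'   `kernel`, `constraint`.
#' @export
objective_err <- function(params, surfaces, thalamic, config = err_config()) {
  if (inherits(params, "network_params")) {
    tw <- effective_weights(params)
    sigmas <- params$sigmas
    modes <- params$modes
  } else {
    tw <- params$tw; sigmas <- params$sigmas; modes <- params$modes
  }
  sigmas <- unlist(sigmas)
  surfaces <- set_surface_modes(surfaces, modes)
  mse <- 0
  constraint <- 0
  for (cl in CLASSES) {
    bases <- class_bases(cl, sigmas, surfaces, thalamic)
    sse <- 0; npt <- 0
    for (v in CONDITIONS) {
      pred <- class_predict(bases[[v]],
                            as.list(stats::setNames(tw[CLASS_TERMS[[cl]]$weights, v],
                                                    CLASS_TERMS[[cl]]$weights)),
                            surfaces_mode(surfaces, cl))
      sse <- sse + sum((pred - bases[[v]]$target)^2)
      npt <- npt + length(bases[[v]]$target)
    }
    mse <- mse + (sse / npt) / surfaces$norm[[cl]]
    constraint <- constraint + config$lambda3 * constraint_ratio(cl, tw)^2
  }
  n_dw <- sum(abs(tw[, 1] - tw[, 2]) > 1e-9)
  active <- names(sigmas)[!is.na(sigmas)]
  kernel <- config$lambda2 * sum((sigmas[active] / config$sigma_L)^2)
  l0 <- config$lambda1 * n_dw
  list(err = mse + l0 + kernel + constraint,
       mse = mse, l0 = l0, n_dw = n_dw, kernel = kernel,
       constraint = constraint)
}

#' Fit synaptic weights for fixed kernel widths
#'
#' Minimizes the penalized objective over nonnegative weights (effective
#' weights for the E and P equations) with the kernel widths held at
#' `sigmas`, using bounded Levenberg-Marquardt from `n_starts` random
#' initializations (weights log-uniform in [1e-3, 10]).
#'
#' @param sigmas named kernel widths (degrees) for all active synapses.
#' @param modes inhibition modes per inhibitory synapse.
#' @param surfaces a [build_tuning_surfaces()] object.
#' @param thalamic per-condition drive.
#' @param config an [err_config()].
#' @param free_weights weights allowed to differ between conditions.
#' @param n_starts random restarts per class.
#' @param seed integer seed.
#' @param classes classes to fit (default all).
#' @return list with `tw` (weight matrix), per-class fits, and `err`
#'   (the [objective_err()] decomposition) when all classes were fitted.
#' @export
fit_weights_given_sigmas <- function(sigmas, modes, surfaces, thalamic,
                                     config = err_config(),
                                     free_weights = character(0),
                                     n_starts = 50, seed = 1L,
                                     classes = CLASSES) {
  surfaces <- set_surface_modes(surfaces, modes)
  cache <- new.env(parent = emptyenv())
  fits <- lapply(stats::setNames(classes, classes), function(cl) {
    bases <- class_bases(cl, sigmas, surfaces, thalamic, cache)
    fit_class_weights(cl, bases, surfaces, config, free_weights,
                      n_starts, seed)
  })
  tw <- matrix(NA_real_, length(FITTED_WEIGHTS), 2,
               dimnames = list(FITTED_WEIGHTS, CONDITIONS))
  for (f in fits) tw[rownames(f$tw), ] <- f$tw
  err <- if (identical(sort(classes), sort(CLASSES)))
    objective_err(list(tw = tw, sigmas = sigmas, modes = modes),
                  surfaces, thalamic, config) else NULL
  list(tw = tw, fits = fits, err = err, sigmas = sigmas, modes = modes)
}

#' Exhaustive kernel-width search
#'
#' Enumerates kernel-width combinations per postsynaptic class equation
#' (the equations decouple under clamping), fitting the weights for each
#' combination and keeping the per-class best by sum of squares plus the
#' class's kernel penalty; ties break toward the smaller width sum, then
#' enumeration order.
#'
#' @inheritParams fit_weights_given_sigmas
#' @param grids `"paper"`, `"reduced"`, or a named list of candidate values
#'   per kernel synapse (see [sigma_grids()]).
#' @return list with the winning `sigmas`, `tw`, per-class search traces,
#'   and the total `err`.
#' @export
sigma_grid_search <- function(surfaces, thalamic, modes = NULL,
                              config = err_config(), grids = "reduced",
                              free_weights = character(0),
                              n_starts = 50, seed = 1L, classes = CLASSES) {
  if (is.character(grids)) grids <- sigma_grids(grids)
  modes <- modes %||% c(ES = "subtractive", PS = "subtractive",
                        SV = "subtractive", VS = "divisive")
  surfaces <- set_surface_modes(surfaces, modes)
  cache <- new.env(parent = emptyenv())
  results <- list()
  for (cl in classes) {
    syns <- CLASS_SIGMA_SETS[[cl]]
    combos <- expand.grid(lapply(stats::setNames(syns, syns),
                                 function(s) grids[[s]]))
    best <- NULL; trace <- vector("list", nrow(combos))
    for (i in seq_len(nrow(combos))) {
      sg <- stats::setNames(as.numeric(combos[i, ]), syns)
      bases <- class_bases(cl, as.list(sg), surfaces, thalamic, cache)
      fit <- fit_class_weights(cl, bases, surfaces, config, free_weights,
                               n_starts, seed)
      obj <- fit$ss + config$lambda2 * sum((sg / config$sigma_L)^2)
      trace[[i]] <- list(sigmas = sg, ss = fit$ss, obj = obj)
      if (is.null(best) || obj < best$obj - 1e-14 ||
          (abs(obj - best$obj) <= 1e-14 && sum(sg) < sum(best$sigmas) - 1e-9)) {
        best <- list(sigmas = sg, fit = fit, obj = obj)
      }
    }
    results[[cl]] <- list(best = best, trace = trace)
  }
  sigmas <- stats::setNames(rep(NA_real_, length(KERNEL_SYNAPSES)), KERNEL_SYNAPSES)
  tw <- matrix(NA_real_, length(FITTED_WEIGHTS), 2,
               dimnames = list(FITTED_WEIGHTS, CONDITIONS))
  for (cl in classes) {
    b <- results[[cl]]$best
    sigmas[names(b$sigmas)] <- b$sigmas
    tw[rownames(b$fit$tw), ] <- b$fit$tw
  }
  err <- if (identical(sort(classes), sort(CLASSES)))
    objective_err(list(tw = tw, sigmas = sigmas, modes = modes),
                  surfaces, thalamic, config) else NULL
  list(sigmas = sigmas, tw = tw, per_class = results, err = err,
       modes = modes)
}

#' Exhaustive search over inhibition-mode combinations
#'
#' Each inhibitory synapse (Sst to Pyr, Sst to Pvalb, Vip to Sst, Sst to
#' Vip) can act subtractively or divisively; all 16 combinations are fitted
#' at fixed kernel widths and the best total objective wins.
#'
#' @inheritParams fit_weights_given_sigmas
#' @param sigmas kernel widths to use during the search.
#' @return list with `modes` (winning combination), `err`, `tw`, and the
#'   per-combination `trace`.
#' @export
inhibition_mode_search <- function(surfaces, thalamic, sigmas,
                                   config = err_config(),
                                   free_weights = character(0),
                                   n_starts = 20, seed = 1L) {
  combos <- expand.grid(ES = c("subtractive", "divisive"),
                        PS = c("subtractive", "divisive"),
                        SV = c("subtractive", "divisive"),
                        VS = c("subtractive", "divisive"),
                        stringsAsFactors = FALSE)
  best <- NULL
  trace <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    md <- unlist(combos[i, ])
    fit <- fit_weights_given_sigmas(sigmas, md, surfaces, thalamic, config,
                                    free_weights, n_starts, seed)
    trace[[i]] <- list(modes = md, err = fit$err$err)
    if (is.null(best) || fit$err$err < best$err$err)
      best <- list(modes = md, err = fit$err, tw = fit$tw)
  }
  list(modes = best$modes, err = best$err, tw = best$tw, trace = trace)
}

#' L0-penalized selection of locomotion-modulated weights
#'
#' Evaluates models of increasing complexity: n_dw = 0 (all weights shared
#' between conditions), every single-weight modulation (n_dw = 1), and so
#' on up to `n_max`.  Because the class equations decouple, the best model
#' at each complexity level is found exactly by combining per-class fits of
#' every within-class free-weight subset.  The level minimizing the total
#' penalized Err is selected.
#'
#' @inheritParams fit_weights_given_sigmas
#' @param sigmas kernel widths to use (e.g. the [sigma_grid_search()]
#'   winner).
#' @param n_max largest number of modulated weights considered.
#' @return list with `selected` (n_dw), `free_weights` of the winning
#'   model, `tw`, `err`, and the full `path` (best model per level).
#' @export
locomotion_model_selection <- function(surfaces, thalamic, sigmas,
                                       modes = NULL, config = err_config(),
                                       n_max = 3, n_starts = 50, seed = 1L) {
  modes <- modes %||% c(ES = "subtractive", PS = "subtractive",
                        SV = "subtractive", VS = "divisive")
  surfaces <- set_surface_modes(surfaces, modes)
  cache <- new.env(parent = emptyenv())
  # per-class: fit every subset of its weights as free, sizes 0..min(n_max, |w|)
  class_fits <- list()
  for (cl in CLASSES) {
    bases <- class_bases(cl, as.list(sigmas), surfaces, thalamic, cache)
    wn <- CLASS_TERMS[[cl]]$weights
    subsets <- list(character(0))
    for (k in seq_len(min(n_max, length(wn))))
      subsets <- c(subsets, utils::combn(wn, k, simplify = FALSE))
    class_fits[[cl]] <- lapply(subsets, function(fw) {
      fit <- fit_class_weights(cl, bases, surfaces, config, fw, n_starts, seed)
      list(free = fw, ss = fit$ss, tw = fit$tw, n_free = length(fw))
    })
  }
  # combine classes: best total SS per total number of free weights
  best_per_level <- vector("list", n_max + 1L)
  combine <- function(acc, cl_fits) {
    out <- list()
    for (a in acc) for (f in cl_fits) {
      n <- a$n + f$n_free
      if (n > n_max) next
      cand <- list(n = n, ss = a$ss + f$ss, parts = c(a$parts, list(f)))
      if (is.null(out[[as.character(n)]]) || cand$ss < out[[as.character(n)]]$ss)
        out[[as.character(n)]] <- cand
    }
    out
  }
  acc <- list(list(n = 0L, ss = 0, parts = list()))
  for (cl in CLASSES) acc <- combine(acc, class_fits[[cl]])
  active <- names(sigmas)[!is.na(sigmas)]
  kernel_pen <- config$lambda2 * sum((sigmas[active] / config$sigma_L)^2)
  path <- lapply(acc, function(a) {
    tw <- matrix(NA_real_, length(FITTED_WEIGHTS), 2,
                 dimnames = list(FITTED_WEIGHTS, CONDITIONS))
    fw <- character(0)
    for (p in a$parts) { tw[rownames(p$tw), ] <- p$tw; fw <- c(fw, p$free) }
    err <- a$ss + config$lambda1 * a$n + kernel_pen
    list(n_dw = a$n, free_weights = fw, tw = tw, ss = a$ss, err = err)
  })
  path <- path[order(vapply(path, `[[`, numeric(1), "n_dw"))]
  errs <- vapply(path, `[[`, numeric(1), "err")
  sel <- path[[which.min(errs)]]
  list(selected = sel$n_dw, free_weights = sel$free_weights, tw = sel$tw,
       err = sel$err, path = path, sigmas = sigmas, modes = modes)
}
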