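CLASSES <- c("E", "P", "S", "V")

#' Threshold-linear response with subtractive or divisive inhibition
#'
#' Subtractive: max(x - y, 0).  Divisive: max(x / (1 + y), 0).  `x` is the
#' summed excitatory drive, `y` the (nonnegative) inhibitory drive.
#'
#' @param x excitatory drive (any shape).
#' @param y inhibitory drive, same shape; must be nonnegative.
#' @param mode `"subtractive"` or `"divisive"`.
#' @return rectified rate, same shape as `x`.
#' @export
rectified_response <- function(x, y, mode = c("subtractive", "divisive")) {
  mode <- match.arg(mode)
  if (any(y < -1e-12)) stop_nf("rectified_response: inhibition must be nonnegative")
  out <- if (mode == "subtractive") x - y else x / (1 + y)
  pmax(out, 0)
}

#' Container for the four class rate surfaces of one condition
#'
#' @param E,P,S,V matrices of population rates (rows = `grid$sizes`,
#'   columns = `grid$offsets`).
#' @param grid the [space_grid()] the surfaces live on.
#' @return object of class `field_set`.
#' @export
field_set <- function(E, P, S, V, grid) {
  flds <- list(E = E, P = P, S = S, V = V)
  dims <- c(length(grid$sizes), length(grid$offsets))
  for (cl in CLASSES) {
    if (!all(dim(flds[[cl]]) == dims))
      stop_nf("field_set: class %s surface is not sizes x offsets", cl)
  }
  structure(c(flds, list(grid = grid)), class = "field_set")
}

# Per-class drive assembly.  `tw` is a named weight vector for one condition
# (effective weights for E/P), `cv` a list of convolved presynaptic surfaces
# and the drive surface h.
class_rhs <- function(class, tw, cv, modes) {
  switch(class,
    E = rectified_response(tw["EH"] * cv$h,
                           tw["ES"] * cv$ES_S, modes[["ES"]]),
    P = rectified_response(tw["PH"] * cv$h + tw["PE"] * cv$PE_E,
                           tw["PS"] * cv$PS_S, modes[["PS"]]),
    S = rectified_response(tw["SH"] * cv$SH_h + tw["SE"] * cv$SE_E,
                           tw["SV"] * cv$SV_V, modes[["SV"]]),
    V = rectified_response(tw["VE"] * cv$VE_E,
                           tw["VS"] * cv$VS_S, modes[["VS"]]))
}

# Convolved inputs needed by every class equation, for one condition.
# fields: list(E=, P=, S=, V= matrices); h: drive matrix.
convolved_inputs <- function(params, fields, h, grid, convs = NULL, step = NULL) {
  zero <- matrix(0, length(grid$sizes), length(grid$offsets))
  get_conv <- function(syn) {
    if (!is.null(convs) && !is.null(convs[[syn]])) return(convs[[syn]])
    if (is.na(params$sigmas[[syn]])) return(function(m, ...) zero)
    make_convolver(params$sigmas[[syn]], grid, step = step)
  }
  list(h = h,
       ES_S = get_conv("ES")(fields$S),
       PE_E = get_conv("PE")(fields$E),
       PS_S = get_conv("PS")(fields$S),
       SH_h = get_conv("SH")(h),
       SE_E = get_conv("SE")(fields$E),
       SV_V = get_conv("SV")(fields$V),
       VE_E = get_conv("VE")(fields$E),
       VS_S = get_conv("VS")(fields$S))
}

#' Predict class rates with presynaptic rates clamped to measurements
#'
#' Evaluates the right-hand side of the reduced four-class system with every
#' presynaptic surface held at its supplied (measured) value; this is the
#' prediction the clamped-rate fit matches to the data.  The E and P
#' equations use the effective weights of [effective_weights()].
#'
#' @param params a [network_params()] object.
#' @param fields a [field_set()] of measured surfaces for one condition.
#' @param h external-drive surface on the same grid (matrix), or a
#'   [rog_params()] object from which it is evaluated.
#' @param condition `"stationary"` or `"locomotion"` (selects the weights).
#' @param step optional convolution quadrature step override (degrees).
#' @return a `field_set` of predicted surfaces.
#' @export
predict_rates_clamped <- function(params, fields, h,
                                  condition = "stationary", step = NULL) {
  stopifnot(inherits(params, "network_params"), inherits(fields, "field_set"))
  grid <- fields$grid
  if (inherits(h, "rog_params")) h <- rog_surface(grid, h)
  if (!all(dim(h) == dim(fields$E)))
    stop_nf("predict_rates_clamped: drive surface does not match the field grid")
  tw <- effective_weights(params)[, condition]
  cv <- convolved_inputs(params, fields, h, grid, step = step)
  out <- lapply(CLASSES, function(cl) class_rhs(cl, tw, cv, params$modes))
  names(out) <- CLASSES
  field_set(out$E, out$P, out$S, out$V, grid)
}

#' Self-consistent solution of the neural-field equations
#'
#' Damped fixed-point iteration f <- (1 - damping) f + damping RHS(f) from
#' zero initial fields, run separately per locomotion condition.  Used by
#' the synthetic-data generator to produce ground-truth tuning surfaces.
#'
#' @param params a [network_params()] object.
#' @param thalamic list with `stationary` and `locomotion` [rog_params()]
#'   (or drive matrices).
#' @param grid a [space_grid()].
#' @param damping damping factor in (0, 1].
#' @param tol convergence tolerance on the maximum relative update.
#' @param max_iter iteration cap.
#' @param conditions which conditions to solve.
#' @return named list of `field_set` objects, one per condition.
#' @export
solve_fixed_point <- function(params, thalamic, grid,
                              damping = 0.25, tol = 1e-9, max_iter = 5000,
                              conditions = CONDITIONS) {
  stopifnot(inherits(params, "network_params"))
  if (damping <= 0 || damping > 1) stop_nf("solve_fixed_point: damping must be in (0, 1]")
  if (tol <= 0) stop_nf("solve_fixed_point: tol must be positive")
  dims <- c(length(grid$sizes), length(grid$offsets))
  zero <- matrix(0, dims[1], dims[2])
  convs <- lapply(stats::setNames(KERNEL_SYNAPSES, KERNEL_SYNAPSES),
                  function(syn) {
                    # inactive synapses (zero weight, no width) contribute 0
                    if (is.na(params$sigmas[[syn]])) return(function(m, ...) zero)
                    make_convolver(params$sigmas[[syn]], grid)
                  })
  out <- list()
  for (v in conditions) {
    hv <- thalamic[[v]]
    if (inherits(hv, "rog_params")) hv <- rog_surface(grid, hv)
    tw <- effective_weights(params)[, v]
    f <- lapply(CLASSES, function(cl) matrix(0, dims[1], dims[2]))
    names(f) <- CLASSES
    sh_h <- convs$SH(hv)   # drive convolution is constant across iterations
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      cv <- list(h = hv,
                 ES_S = convs$ES(f$S), PE_E = convs$PE(f$E),
                 PS_S = convs$PS(f$S), SH_h = sh_h,
                 SE_E = convs$SE(f$E), SV_V = convs$SV(f$V),
                 VE_E = convs$VE(f$E), VS_S = convs$VS(f$S))
      f_new <- lapply(CLASSES, function(cl) class_rhs(cl, tw, cv, params$modes))
      names(f_new) <- CLASSES
      scale <- max(unlist(lapply(f_new, function(m) max(abs(m)))), 1e-12)
      resid <- max(unlist(Map(function(a, b) max(abs(a - b)), f_new, f))) / scale
      f <- Map(function(a, b) (1 - damping) * a + damping * b, f, f_new)
      if (!all(is.finite(unlist(f))) || scale > 1e6)
        stop_nf("solve_fixed_point: divergence in condition '%s' (unstable parameter set)", v)
      if (resid < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop_nf("solve_fixed_point: no convergence in %d iterations (condition '%s', residual %.3g)",
              max_iter, v, resid)
    out[[v]] <- field_set(f$E, f$P, f$S, f$V, grid)
  }
  out
}
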