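#' @name network_params
#' @title Circuit parameters of the four-class neural-field model
#'
#' @description
#' The model describes the population rates of Pyr (E), Pvalb (P), Sst (S)
#' and Vip (V) cells.  Only synapse classes with in-vitro support enter the
#' equations:
#' E<-H, E<-E, E<-P, E<-S; P<-H, P<-E, P<-P, P<-S; S<-H, S<-E, S<-V;
#' V<-E, V<-S (H is the external visual drive).  Each synapse carries a
#' nonnegative peak weight per locomotion condition; non-local synapses
#' carry a Gaussian retinotopic kernel width sigma; the within-class and
#' P-to-E connections (EE, EP, PP) are local (Dirac delta, no sigma).
#' Inhibitory synapses (ES, PS, SV, VS) act either subtractively or
#' divisively.  The ratio mu captures how closely Pvalb activity tracks Pyr
#' activity (fP ~ mu fE), which is used to reduce the E equation.
NULL

# synapse bookkeeping -------------------------------------------------------

SYNAPSES <- c("EH", "EE", "EP", "ES",
              "PH", "PE", "PP", "PS",
              "SH", "SE", "SV",
              "VE", "VS")
DELTA_SYNAPSES <- c("EE", "EP", "PP")   # local; no kernel width
KERNEL_SYNAPSES <- setdiff(SYNAPSES, c(DELTA_SYNAPSES, "EH", "PH"))
INHIBITORY_SYNAPSES <- c("ES", "PS", "SV", "VS")
# weights actually estimated by the clamped-rate fit (E and P equations are
# fitted through their effective weights)
FITTED_WEIGHTS <- c("EH", "ES", "PH", "PE", "PS", "SH", "SE", "SV", "VE", "VS")
CONDITIONS <- c("stationary", "locomotion")

#' Construct and validate network parameters
#'
#' @param weights matrix with rownames from the allowed synapse set and two
#'   columns (`stationary`, `locomotion`) of nonnegative peak weights.  A
#'   named vector is accepted for condition-independent weights.
#' @param sigmas named vector of kernel widths (degrees, > 0) for the
#'   non-local synapses `r paste(KERNEL_SYNAPSES, collapse = ", ")`.
#' @param modes named character vector over the inhibitory synapses, each
#'   `"subtractive"` or `"divisive"`.
#' @param mu Pvalb/Pyr tracking ratio (> 0).
#' @return an object of class `network_params`.
#' @export
network_params <- function(weights, sigmas, modes, mu = 1) {
  if (is.null(dim(weights))) {
    weights <- cbind(stationary = weights, locomotion = weights)
  }
  weights <- as.matrix(weights)
  colnames(weights) <- CONDITIONS
  bad <- setdiff(rownames(weights), SYNAPSES)
  if (length(bad))
    stop_nf("network_params: synapse(s) %s not in the allowed set [%s]",
            paste(bad, collapse = ", "), paste(SYNAPSES, collapse = ", "))
  full <- matrix(0, length(SYNAPSES), 2,
                 dimnames = list(SYNAPSES, CONDITIONS))
  full[rownames(weights), ] <- weights
  if (any(full < 0)) stop_nf("network_params: weights must be nonnegative")
  sig <- stats::setNames(rep(NA_real_, length(KERNEL_SYNAPSES)), KERNEL_SYNAPSES)
  sig[intersect(names(sigmas), KERNEL_SYNAPSES)] <-
    sigmas[intersect(names(sigmas), KERNEL_SYNAPSES)]
  if (any(!is.na(sig) & sig <= 0))
    stop_nf("network_params: kernel widths must be positive")
  active <- rownames(full)[rowSums(full) > 0]
  need <- intersect(active, KERNEL_SYNAPSES)
  if (any(is.na(sig[need])))
    stop_nf("network_params: missing sigma for active synapse(s) %s",
            paste(need[is.na(sig[need])], collapse = ", "))
  md <- stats::setNames(rep("subtractive", length(INHIBITORY_SYNAPSES)),
                        INHIBITORY_SYNAPSES)
  md[intersect(names(modes), INHIBITORY_SYNAPSES)] <-
    modes[intersect(names(modes), INHIBITORY_SYNAPSES)]
  if (!all(md %in% c("subtractive", "divisive")))
    stop_nf("network_params: modes must be 'subtractive' or 'divisive'")
  if (mu <= 0) stop_nf("network_params: mu must be positive")
  structure(list(weights = full, sigmas = sig, modes = md, mu = mu),
            class = "network_params")
}

#' @export
print.network_params <- function(x, ...) {
  cat("network_params (four-class neural-field circuit)\n")
  cat(sprintf("  mu (Pvalb/Pyr tracking): %.3g\n", x$mu))
  act <- rownames(x$weights)[rowSums(x$weights) > 0]
  for (s in act) {
    cat(sprintf("  w_%s: %.3g / %.3g%s%s\n", s,
                x$weights[s, 1], x$weights[s, 2],
                if (s %in% KERNEL_SYNAPSES)
                  sprintf("  sigma %.3g deg", x$sigmas[s]) else "  (local)",
                if (s %in% INHIBITORY_SYNAPSES)
                  paste0("  ", x$modes[s]) else ""))
  }
  invisible(x)
}

#' Effective weights of the reduced model
#'
#' Under the simplifying assumptions (E and P rates positive over the
#' stimulus domain; EE, EP and PP connections local; fP ~ mu fE) the
#' recurrent E and P loops can be eliminated algebraically:
#' wt_EH = w_EH / (1 - w_EE + mu w_EP), wt_ES = w_ES / (1 - w_EE + mu w_EP),
#' wt_PH = w_PH / (1 + w_PP), wt_PE = w_PE / (1 + w_PP),
#' wt_PS = w_PS / (1 + w_PP).  All remaining weights pass through unchanged.
#'
#' @param params a [network_params()] object.
#' @return matrix of effective weights (rows `r paste(FITTED_WEIGHTS, collapse=", ")`,
#'   columns per condition).
#' @export
effective_weights <- function(params) {
  stopifnot(inherits(params, "network_params"))
  w <- params$weights
  out <- matrix(NA_real_, length(FITTED_WEIGHTS), 2,
                dimnames = list(FITTED_WEIGHTS, CONDITIONS))
  for (v in CONDITIONS) {
    den_e <- 1 - w["EE", v] + params$mu * w["EP", v]
    if (den_e <= 0)
      stop_nf("effective_weights: unstable effective reduction (1 - w_EE + mu w_EP = %.3g <= 0)",
              den_e)
    den_p <- 1 + w["PP", v]
    out["EH", v] <- w["EH", v] / den_e
    out["ES", v] <- w["ES", v] / den_e
    out["PH", v] <- w["PH", v] / den_p
    out["PE", v] <- w["PE", v] / den_p
    out["PS", v] <- w["PS", v] / den_p
    for (s in c("SH", "SE", "SV", "VE", "VS")) out[s, v] <- w[s, v]
  }
  out
}

# presets -------------------------------------------------------------------

network_presets <- function() c("paper-like", "single-modulation",
                                "no-modulation", "no-recurrence")

base_circuit <- function() {
  w0 <- c(EH = 1.0, EE = 0.3, EP = 0.25, ES = 1.0,
          PH = 1.8, PE = 0.9, PP = 0.5, PS = 0.75,
          SH = 0.35, SE = 1.2, SV = 0.8,
          VE = 0.8, VS = 1.0)
  sig <- c(ES = 30, PE = 20, PS = 30, SH = 35, SE = 5, SV = 15, VE = 5, VS = 15)
  modes <- c(ES = "subtractive", PS = "subtractive",
             SV = "subtractive", VS = "divisive")
  list(w0 = w0, sig = sig, modes = modes, mu = 0.8)
}

#' Sample a ground-truth circuit from a documented preset
#'
#' Presets:
#' \describe{
#'   \item{paper-like}{broad Sst kernels onto Pyr/Pvalb, broad feedforward
#'     drive to Sst, divisive Sst-to-Vip inhibition, no Vip-to-Pyr synapse;
#'     locomotion boosts the feedforward weights (EH, PH, SH).}
#'   \item{single-modulation}{as paper-like but locomotion modulates only
#'     the external drive to Pyr (w_EH, factor 1.6).}
#'   \item{no-modulation}{as paper-like with identical weights in both
#'     conditions.}
#'   \item{no-recurrence}{all local recurrent weights (EE, EP, PP) zero, so
#'     effective weights equal the raw feedforward weights.}
#' }
#' The seed jitters the synaptic weights (log-uniform within +/- 10 percent,
#' the same factor in both conditions) so different seeds give different but
#' structurally identical circuits; kernel widths and inhibition modes are
#' fixed by the preset.
#'
#' @param seed integer random seed.
#' @param preset one of `network_presets()`.
#' @param jitter relative weight jitter half-width (0 disables).
#' @return a [network_params()] object.
#' @export
sample_network <- function(seed = 1L, preset = "paper-like", jitter = 0.1) {
  if (!preset %in% network_presets())
    stop_nf("sample_network: unknown preset '%s'; valid presets: %s",
            preset, paste(network_presets(), collapse = ", "))
  bc <- base_circuit()
  w0 <- bc$w0
  if (preset == "no-recurrence") w0[c("EE", "EP", "PP")] <- 0
  if (jitter > 0) {
    set.seed(derive_seed(seed, 101L))
    w0 <- w0 * exp(stats::runif(length(w0), log(1 - jitter), log(1 + jitter)))
  }
  boost <- stats::setNames(rep(1, length(w0)), names(w0))
  if (preset %in% c("paper-like", "no-recurrence")) {
    boost[c("EH", "PH", "SH")] <- c(1.5, 1.4, 1.4)
  } else if (preset == "single-modulation") {
    boost["EH"] <- 3
  }
  weights <- cbind(stationary = w0, locomotion = w0 * boost)
  network_params(weights, bc$sig, bc$modes, mu = bc$mu)
}
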