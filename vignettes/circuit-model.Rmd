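---
title: "A neural-field circuit model of cell-class size tuning and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neural-field circuit model of cell-class size tuning and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neurofield` implements an analysis chain for cell-class-resolved two-photon
calcium imaging of mouse V1 under varying stimulus size and locomotion, and a
recurrent neural-field model of the four-class circuit (Pyr/E, Pvalb/P, Sst/S,
Vip/V). This vignette explains the science implemented by each layer, the
parameters that matter, the numerical choices, and what the synthetic-data
tests do and do not establish about real data.

## 1. The forward model

Each class is described by a rate surface $f_\alpha(s, r)$: stimulus diameter
$s$ (degrees, 0–60) by radial retinotopic offset $r$ (degrees). Circular
symmetry is assumed throughout, so all spatial structure lives on the radial
axis. The external drive is a ratio-of-Gaussians (RoG) surface
$h(s,r) = a_1 u(s,r,\sigma_1)/(1 + a_2 u(s,r,\sigma_2))$ with
$u(s,r,\sigma) = \mathrm{erf}((s+r)/\sigma) + \mathrm{sign}(s-r)\,
\mathrm{erf}(|s-r|/\sigma)$; we adopt $\mathrm{sign}(0)=0$, which removes the
discontinuity exactly on the line $s=r$, and we take $s$ to be the plotted
stimulus diameter without re-deriving an aperture convention. The default
parameter sets (`rog_params_default()`) are the published dLGN estimates for
stationary ($a_1{=}1.2, a_2{=}1.9, \sigma_1{=}36.7, \sigma_2{=}33.9$) and
locomotion ($a_1{=}0.5, a_2{=}0.4, \sigma_1{=}24.7, \sigma_2{=}10.0$)
conditions.

Synaptic interactions act through unit-mass isotropic Gaussian kernels over
retinotopic space, and responses are threshold-linear with either subtractive
or divisive inhibition (`rectified_response()`). Only the synapse classes with
in-vitro support are representable; in particular there is no Vip→Pyr synapse.
Because the within-class loops and the Pvalb→Pyr connection are local (delta
kernels) and Pvalb activity tracks Pyr activity ($f_P \approx \mu f_E$,
estimated by the through-origin ratio `estimate_mu()`), the E and P equations
reduce to *effective* weights, e.g.
$\tilde w_{EH} = w_{EH}/(1 - w_{EE} + \mu\, w_{EP})$. Any raw decomposition
with the same effective weights predicts identical rates; the package
therefore reports effective weights and surfaces this degeneracy rather than
hiding it (a test perturbs $(w_{EE}, w_{EP})$ along the null direction and
asserts bit-level-identical predictions to $10^{-12}$ relative).

**Convolution.** For a circularly symmetric field the 2-D Gaussian
convolution reduces to a 1-D integral with a Bessel kernel,
$(G*f)(r) = \int_0^\infty f(\rho)\, \frac{\rho}{\sigma^2}
e^{-(r^2+\rho^2)/2\sigma^2} I_0(r\rho/\sigma^2)\, d\rho$,
evaluated with the exponentially scaled $I_0$ and composite Simpson
quadrature (node step $\min(\sigma/4, \text{grid step})$, domain extended
$6\sigma$ past the largest output offset, kernel rows renormalized to unit
mass so constants are preserved exactly). We chose this over a 2-D Cartesian
quadrature because it is exact in the angular variable and cheaper; the 2-D
Cartesian brute force is kept as the *independent oracle* in the test suite,
where the two routes agree to better than $10^{-6}$ relative on random smooth
fields. Sampled fields are continued beyond their last sampled offset by a
per-size exponential tail fitted to the outermost samples (flat if no decay
is detected); kernels narrower than half the declared grid step are refused
as under-resolved.

**Fixed point.** The generator solves the reduced system by damped iteration
$f \leftarrow (1-\gamma) f + \gamma\,\mathrm{RHS}(f)$ from zero fields
($\gamma = 0.25$, tolerance $10^{-9}$ on the relative update, cap 5000
iterations). The model itself has no dynamics; the solver is generator-side
machinery with conservative defaults, and divergence is reported as an error
naming the condition rather than silently clipped.

## 2. The synthetic-data generator

The generator defines the study conditions for every downstream test.

*Circuit presets* (`sample_network()`): the `paper-like` preset encodes the
qualitative circuit the model class is built around — broad feedforward
drive to Sst ($\sigma_{SH} = 35°$), broad Sst kernels onto Pyr and Pvalb
(30°), divisive Sst→Vip inhibition with the remaining inhibitory synapses
subtractive, no Vip→Pyr synapse, and locomotion boosting the three
feedforward weights (E←H ×1.5, P←H and S←H ×1.4). Kernel widths sit on round
values contained in the reduced search grids so that on-grid recovery is a
meaningful check. The seed jitters weights by ±10% (log-uniform, the same
factor in both conditions), giving structurally identical but numerically
distinct circuits per seed. `single-modulation` boosts only $w_{EH}$ (×3, a
strong locomotion gain on the Pyr visual drive, large enough for the
modulation signal to exceed the L0 penalty under the noiseless objective
normalization discussed below); `no-modulation` and `no-recurrence` are
degenerate controls.

*Population surfaces* (`simulate_population_tuning()`): noiseless fields are
the fixed-point solution; replicate "experiments" multiply each field value
by i.i.d. unit-mean lognormal noise with CV `noise_cv`. Multiplicative
lognormal noise keeps fields nonnegative and yields exactly the
heteroscedastic variance surface, $(\mathrm{cv}\cdot f)^2$, that the fitting
objective uses as weights (verified at $n = 200$ replicates within 10%). The
default `n_experiments = 24` matches the scale of the imaging campaign the
analysis is designed for. Noise magnitudes are free parameters of the
simulator, not claims about any dataset.

*Sessions* (`simulate_session()`): per-cell somatic traces are baseline +
Poisson event trains convolved with a 0.7 s exponential kernel; event rates
are modulated multiplicatively by the cell's class field at its RF offset
during 1 s stimulus presentations and by a per-cell locomotion gain.
Pyr cells are sparse (0.03 Hz, large events) and interneurons dense
(1.2–2 Hz, small events), so trace skewness separates the classes; Pyr cells
are written out as `unlabeled` and their identity kept in `truth`. A shared
neuropil trace (baseline 20 a.u., locomotion-coupled and slowly fluctuating)
contaminates the recorded fluorescence as $F = F_{soma} + \alpha N$.
Locomotion is a two-state semi-Markov process (exponential dwells, mean 20 s
running / 25 s resting; bout speeds lognormal around 8 cm/s, always
> 1 cm/s while running, matching the > 1 cm/s locomotion convention used
throughout the analysis). Two trace parameters are explicit study
conditions: the somatic baseline noise (sd 1 a.u.) decorrelates the
within-bin percentile selection of the neuropil regression from the
neuropil level, and the interneuron locomotion gains are moderate
(0.3–0.8) so that locomotion bimodality does not by itself push dense
traces over the putative-Pyr skewness threshold. Stimuli include a
blank (diameter 0) and diameters from 5° to 60° at a fixed period; sessions
are 600 s at 10 Hz by default and serialize to a plain-CSV directory
(`write_session()` / `read_session()`), byte-identical for a fixed seed.

What the generator does *not* emulate: imaging movies, eye-movement
dynamics, spike-to-calcium nonlinearities beyond a single kernel,
session-to-session drift, or correlated (non-i.i.d.) across-experiment
noise. Passing tests therefore establish the correctness and calibration of
the *procedures*, not the accuracy of any biological conclusion on real
data.

## 3. Preprocessing

`estimate_neuropil_alpha()` bins the neuropil trace into 20 equal-count
intervals (equal-count avoids empty bins; placement is otherwise
unconstrained), takes the 5th percentile of the somatic trace per bin, and
regresses those percentiles on the bin means, intercept included. Two
refinement passes then re-estimate the envelope on the residual
$F - \hat\alpha N$: within a wide bin the raw percentile co-selects
low-neuropil samples, which attenuates the slope (severely so when one
extreme bin is wide, e.g. in sessions with little locomotion); on the
residual the within-bin floor is independent of the neuropil level, and the
additive update converges in one or two passes. The session
correction (`correct_session_neuropil()`) averages $\alpha_i$ over cells with
raw-trace skewness > 4 — for sparse cells the lower envelope is a reliable
estimate of contamination, for dense cells it is not — and falls back to the
canonical cross-experiment value 0.82 when no cell qualifies. The operation
refuses to run twice. $\Delta F/F_0$ uses the global minimum of the trace
smoothed with a 0.5 s Hamming window; constant traces map to zero, traces
with non-positive baseline are rejected rather than silently producing
infinities. Skewness is the population third standardized moment
($m_3/m_2^{3/2}$, no bias correction); it is invariant under positive affine
transforms, so the putative-Pyr threshold of 2.7 applies identically to raw
and rescaled traces. Trial responses are post-minus-pre 1 s means of
$\Delta F/F_0$; locomotion trials are those with mean speed > 1 cm/s in the
response window; the pupil filter drops trials deviating > 5° from the
session mean; cells are selected by RF distance (10° default, 15° for
interaction analyses, 20° for population pooling) and a one-way ANOVA across
sizes at $p < 0.05$ in at least one condition.

## 4. Statistics

Speed correlations interpolate both series to 10 Hz, boxcar-smooth over 5
points, and decimate to 1 Hz (smoothing after interpolation; the alternative
order is a documented knob). Serial correlation invalidates the standard
test, so significance comes from uniform random circular shifts with
$p = (1 + \#\{|\rho_{shuf}| \ge |\rho_{obs}|\})/(n+1)$; calibration is
checked against AR(1) nulls (type-I error within the binomial 95% interval
at 5%). Depth regressions use bisquare M-estimation with a t-test on the
robust slope; an exactly constant response vector returns slope 0, $p = 1$.
The modulation indices use
$M = (\langle x^{(1)}\rangle - \langle x^{(0)}\rangle)/
\sqrt{\sigma^2[x^{(1)}] + \sigma^2[x^{(0)}]}$ with population variances —
the radical spans the summed variances, making $M$ a dimensionless,
scale-invariant d'-like quantity; the population-vs-sample choice shifts
$M$ only by an $n$-dependent factor. Baseline indices use contiguous 1 s
virtual trials of gray-screen activity labeled by the same speed rule.

Size tuning uses $f(s) = R[\mathrm{erf}(s/\sigma_1) - k\,
\mathrm{erf}(s/\sigma_2)]$, fitted by multi-start Levenberg–Marquardt
($\sigma_1 \in \{5,15,40\}$, $\sigma_2 \in \{15,50\}$, $k \in \{0,0.5,1\}$;
ties broken by loss, then smaller $\sigma_1+\sigma_2$, then start order, so
reruns are deterministic). $f(0)=0$ holds for every member of the family.
Offset maps are Gaussian-weighted outer products normalized by local cell
density ($\sigma_y = 5°$, the RF-mapping pixel size), masked where density
falls below $10^{-6}$, and normalized by the stationary value at
$(s{=}10°, r{=}0)$.

Population coupling: spontaneous coupling normalizes each cell by its
maximum, averages within class, smooths 1 s, decimates to 1 Hz, and shifts
and scales by the 1st percentile and SD; signal curves are class means per
(size, condition) scaled by their SD and anchored to zero at the stationary
blank; noise residuals are z-scored per-trial class means. The signal-curve
smoothing follows the two-pass boxcar (span 25° for sizes > 20°, then 20°
everywhere) followed by shape-preserving piecewise-cubic interpolation, never
extrapolating beyond the measured sizes. The θ angles parameterize the
interneuron-vs-Pyr signal relationship: θ1 from the 5° point to the
Pyr-preferred point (argmax of the smoothed Pyr curve, ties toward smaller
sizes), θ2 between that segment and the continuation to 60°, positive
counterclockwise (the sign is a package convention; magnitudes are the
primary quantity). Watson's $U^2$ is computed on the pooled empirical CDFs
with tie handling, and compared by label permutation.

## 5. Surface construction and estimation

`build_tuning_surfaces()` averages replicate fields per (class, condition),
fits the erf-difference family per offset below $r_L = 33°$ (the
"continuous description": parameters, fitted values and the decay length
$b$, the mean of per-size exponential decay rates fitted on
$[r_m, r_L]$ and averaged over $s \le 30°$), and returns the
across-experiment variance per point. Two estimator choices matter and are
deliberate:

* The surface *values* used by the regression are the empirical means, not
  the family fits. Circuit-generated fields are close to but not exactly in
  the erf-difference family; the ~2% systematic lack-of-fit is amplified by
  the near-collinear regression bases (the drive $h$ and the convolved Pyr
  field are similar surfaces) into large weight errors, whereas unbiased
  i.i.d. noise in the empirical means averages out across the ~260 fitting
  points. The family fit remains the right tool for continuation and
  reporting, and for sparse real data the option
  `use_samples_beyond_rL = FALSE` reproduces the exponential extrapolation
  from $r_L$.
* The mean-squared error is normalized per point by the across-experiment
  variance (floored at a tenth of its mean so exactly-zero-variance points
  stay finite) — the likelihood-exact weighting under the multiplicative
  noise model. For noiseless surfaces the variance is identically zero and
  the normalizer falls back to the mean squared field value, flagged in the
  output.

The penalized objective sums the normalized MSE over the four class
equations (summing rather than averaging keeps the documented
$\lambda_1 = 0.1$ on a scale a single modulated synapse can exceed) and adds
$\lambda_1 n_{\Delta w}$ (L0 count of weights differing between conditions),
$\lambda_2 \|\sigma_{\alpha\beta}/\sigma_L\|^2$
($\lambda_2 = 0.01, \sigma_L = 40°$), and
$\lambda_3 (R_S^2 + R_P^2)$ ($\lambda_3 = 0.2$) where
$R_S = \sum_v w_{SH}/(w_{SE}+w_{SV})$ keeps the Sst drive mostly local and
$R_P = \sum_v \tilde w_{PE}/(\tilde w_{PH}+\tilde w_{PS})$ keeps the Pyr
input from dominating the Pvalb equation; degenerate denominators map to a
fixed $10^6$ penalty instead of infinities.

Because presynaptic fields are clamped to data, the four equations decouple:
each class's weights appear only in its own prediction and its own
constraint term. The package exploits this everywhere — the kernel-width
search enumerates combinations per class (visual-input/excitatory kernels
1–40° in 15 steps, Sst/Vip kernels 1–100° in 12 steps; a coarse 3-point
`reduced` grid for desk-scale runs), weights are refitted per combination by
bounded Levenberg–Marquardt from 50 (default) log-uniform $[10^{-3}, 10]$
restarts, and the L0 selection combines per-class subset fits exactly by
dynamic programming instead of refitting every global subset. Ties break
toward smaller width sums, then enumeration order. The inhibition-mode
combination (subtractive/divisive per inhibitory synapse, $2^4$ cases) is
searched exhaustively at fixed widths (`inhibition_mode_search()`); on
noiseless paper-like data the generating combination wins by ~4 orders of
magnitude in fit error. Whether the 50 restarts apply per width combination
(as here) or once globally is not observable in the result; restarts are
seeded and deterministic.

**Recovery protocol and identifiability.** The package's headline
self-check simulates a circuit, rebuilds surfaces, and re-estimates the
parameters. Two facts shape the protocol. First, the $\lambda_3$ constraint
terms are *priors*: on noiseless data, where the fallback normalizer keeps
the MSE term small, they dominate the objective and pull the optimum away
from any generating circuit that does not satisfy them exactly (e.g.
driving $w_{SH}$ to zero). Recovery experiments therefore run the estimator
unpenalized ($\lambda_2 = \lambda_3 = 0$): they test consistency of the
estimator, while the penalties exist to regularize weakly identified
directions on real data. Second, the pair $(\sigma_{SH}, w_{SH})$ is
observationally near-degenerate: a narrow-kernel substitute reproduces the
true fields to a sum of squares far below the 10%-noise floor, so under
noise the width search re-parameterizes rather than mis-estimates. The noisy
recovery check accordingly measures weight errors at the widths identified
from the noiseless search (which equal the truth), and reports the
mean-over-seeds per-weight relative error (~12% at 10% noise, 24
experiments, 5 seeds; the noiseless arm recovers widths exactly and weights
to ~$10^{-5}$ relative).

## 6. Numerical choices and degenerate inputs

Constant traces are excluded (never NaN-propagated); zero pooled variance
flags the modulation index invalid; the offset-map density floor masks
rather than divides; the neuropil regression refuses constant neuropil;
`compute_dff` refuses non-positive baselines; the fixed-point solver reports
divergence with the offending condition. All stochastic procedures
(shuffles, permutations, restarts, generators) are seeded; derived seeds
stay below $2^{31}$.

Problem sizes used in the shipped tests — an 11 × 21 (size × offset) grid,
600 s sessions, 24-replicate surfaces, 3-point reduced width grids,
500-simulation calibration runs — were chosen as the smallest sizes at which
each scientific property is cleanly measurable.

## 7. Known limitations

* The model is static and circularly symmetric: no temporal dynamics, no
  orientation dimension, no stability analysis beyond fixed-point
  convergence.
* Clamped-rate fitting inherits the data's degeneracies; effective weights
  are the identified quantities for the E and P equations, and weakly
  identified width/weight trade-offs (notably the broad Sst drive) are
  resolved by the priors, not the likelihood.
* The generator's noise is i.i.d. across grid points and experiments; real
  across-session variability is correlated, and the variance weighting is
  correspondingly optimistic there.
* The skewness classifier is calibrated on the generator's event-rate
  contrast; on real data the threshold (2.7, exposed as a parameter) trades
  false positives against yield and should be validated per dataset.
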