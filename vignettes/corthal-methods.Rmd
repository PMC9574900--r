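---
title: "Modelling cortical synaptic loss in a corticothalamic network"
author: "corthal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cortical synaptic loss in a corticothalamic network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(corthal)
```

## The scientific question

Post-mortem histology in multiple sclerosis (MS) shows that both excitatory
and inhibitory synapses are lost in the deep cortical layers of
normal-appearing gray matter, with inhibitory loss slightly exceeding
excitatory loss (about -12.5% excitatory and -14.9% inhibitory in layer VI
relative to non-neurological controls).  What does such a shift of the
excitation-inhibition balance do to large-scale brain dynamics?  `corthal`
addresses this with a whole-brain computational experiment: a network of
corticothalamic neural-mass units, coupled through a structural connectome,
in which the cortical excitatory and/or inhibitory synaptic strengths are
reduced step-wise toward the histologically measured end-points while
alpha-band (8-13 Hz) power and phase-locking connectivity are tracked.

The package implements both stages end to end: the nested mixed-effects
analysis that turns ROI-level density tables into covariate-adjusted percent
losses, and the network simulation that consumes those percentages as
reduction end-points.

## The corticothalamic unit

Each of the `n` regions contains four interacting neural populations:
cortical excitatory (e), cortical inhibitory (i), thalamic reticular (r,
inhibitory) and thalamic relay (s, excitatory).  Three standard ingredients
define the dynamics:

1. **Dendritic filtering.**  The mean membrane potential `V_a` of
   population `a` responds to synaptic input through a second-order
   low-pass operator with rise rate `beta_d` and decay rate `alpha_d`:

   `(1/(alpha beta)) V_a'' + (1/alpha + 1/beta) V_a' + V_a = sum_b nu_ab phi_b(t - tau_ab)`

   The couplings `nu_ab` (V s) are the product of the mean number of
   synapses from population b to a and the typical post-synaptic potential
   size; they are the quantities the synaptic-loss experiment scales.

2. **Firing-rate conversion.**  `Q_a = Q_max / (1 + exp(-(V_a - theta)/sigma'))`,
   a saturating sigmoid with maximum rate `Q_max`, threshold `theta` and
   slope `sigma'`.

3. **Axonal propagation.**  The cortical excitatory field `phi_e` obeys
   damped second-order dynamics with rate `gamma_e`
   (`(1/gamma^2) phi'' + (2/gamma) phi' + phi = Q_e`); the other
   populations project without axonal dispersion (`phi_b = Q_b`).

The corticothalamic loop introduces a conduction delay `t0/2` on each leg
(cortex to thalamus on `e -> r` and `e -> s`, thalamus to cortex on
`s -> e` and `s -> i`), so the full loop takes `t0`.  This delayed loop is
what generates the alpha rhythm: a resonance appears near `1/t0` corrected
by the dendritic and axonal phase lags.  The thalamic relay population
receives the external drive `nu_sn * phi_n(t)`, modelled as a constant mean
plus white noise; this is the stochastic input that the linearized transfer
function predicts the response to.

Intracortical connectivity is assumed random (`nu_ie = nu_ee`,
`nu_ii = nu_ei`, `nu_is = nu_es`), the standard reduction that makes both
cortical populations see identical afferents.

Long-range coupling enters the excitatory population only: region j
receives `global_coupling * sum_k W[j,k] phi_e_k` with row-normalized
connectome weights, so `global_coupling` is the total long-range synaptic
strength per region (V s) regardless of the weight scale or degree
distribution.

## Default operating point

The equations above are standard; published variants differ in the
numerical constants.  The defaults here use a canonical alpha-regime set
for this model family: `Q_max` 340 1/s, `theta` 12.92 mV, `sigma'`
3.93 mV, `alpha_d` 83 1/s, `beta_d` 769 1/s, `gamma_e` 116 1/s, `t0`
85 ms.  The coupling strengths were constructed in gain space: operating
firing rates for the four populations were chosen first (cortex near
7 1/s, reticular near 32 1/s, relay near 25 1/s), the fixed point was made
exact by deriving the remaining couplings and the relay drive from the
time-independent equations, and the corticothalamic loop strength was then
placed, using the linearized oracle only, so that

* the baseline is stable with its dominant spectral peak inside 8-13 Hz
  for both an isolated unit and the coupled network;
* the entire excitatory-reduction path (to -12.5%) stays linearly stable,
  so excitatory loss weakens the rhythm smoothly;
* the inhibitory-reduction path approaches the alpha-frequency Hopf
  boundary closely: the linearization crosses it at about -23% inhibitory
  reduction, just beyond the normal-appearing gray-matter end-point
  (-14.9%) but inside the demyelinated-cortex end-point (-29.3%).
  NAGM-level disinhibition therefore produces strong but bounded
  near-critical amplification of the alpha rhythm, and the demyelinated
  preset crosses into self-sustained oscillation.

The relay noise amplitude (`noise_std` 0.8) was chosen so that baseline
phase locking sits mid-range (mean PLV near 0.4-0.5), leaving
synchronization headroom in both directions; noise amplitude does not
enter the linear stability calibration.  This calibration is a design
choice of the package, made entirely against the linearized spectrum and
the qualitative constraints above; the simulated experiments are not
fitted to any target values.  Under these defaults the inhibitory outcome
curves rise steeply through the middle iterations and their growth slows
toward the end-point, the qualitative plateau pattern the acceptance
suite checks.

## The reduction experiment

A [reduction_schedule()] fixes the condition (`excitatory`, `inhibitory`
or `combined`), the number of iterations (50), and the end-point fractions
(defaults -12.5% / -14.9%, the layer-VI normal-appearing gray-matter
values; `preset = "demyelinated"` swaps in -18.5% / -29.3%).  Scales
interpolate linearly: `s_X(i) = 1 - endpoint_X * i/n`.  Both reduction
policies scale the intracortical couplings (`nu_ee`, `nu_ie` by `s_E`;
`nu_ei`, `nu_ii` by `s_I`); under the default
`"intracortical_longrange"` policy the long-range cortico-cortical
input -- anatomically also excitatory synapses onto cortical neurons --
is scaled by `s_E` as well.  The design was genuinely open (the histology
measured local cortical synapses, and whether long-range projections were
scaled in the source experiment is unstated); the long-range-inclusive
default was chosen because purely intracortical scaling leaves
phase-locking connectivity almost untouched under excitatory loss
(the change is within estimation noise, about -1%), which contradicts the
robust connectivity decrease that the excitatory condition is expected to
produce.  `policy = "intracortical"` restores the purely local variant.
Thalamic and noise couplings are never scaled.

Each iteration simulates the full network (stochastic Heun scheme, step
`dt = 1e-4` s, ring-buffer delay history, independent per-region noise
streams drawn deterministically from one master seed) and computes two
outcomes:

* **alpha power** -- Welch PSD (2 s Hann windows, 50% overlap: about 9
  averaged segments on a 10 s record), band integral over 8-13 Hz by the
  trapezoidal rule, averaged over regions;
* **mean PLV** -- phase-locking value on the 8-13 Hz zero-phase band-passed
  (4th-order Butterworth, forward-backward) analytic signal, 1 s trimmed at
  each edge, averaged over the strict upper triangle of the region-pair
  matrix.

Percent changes are reported relative to iteration 0.  Per-iteration noise
realizations are fresh by default (`seed_i = h(master, i)`); a frozen-noise
mode reuses the iteration-0 realization to isolate pure coupling effects.

The integrator records `phi_e` block-averaged from the 10 kHz integration
grid down to 250 Hz; the 40-sample block average is the anti-alias stage.
Residual aliasing is negligible because the model spectrum falls off
steeply above the axonal cut-off (`gamma_e/2pi` is about 18 Hz).

## The linearized oracle

`linear_spectrum()` is the package's independent verification route: the
model is linearized about its fixed point, and the transfer function from
the relay noise drive to `phi_e` is evaluated per frequency by solving the
4x4 complex population system, with `exp(-i w t0/2)` delay factors.
Stability is decided by the argument principle (winding number of the
characteristic determinant along the imaginary axis, with adaptive grid
refinement near resonances).  At low noise the Welch spectrum of a
simulated unit must match this prediction up to a global scale factor; the
test suite enforces shape agreement over 2-30 Hz.  The fixed point itself
is found by nested monotone 1-D reductions (the inhibitory-source
couplings make the inner maps strictly decreasing, so inner roots are
unique and bracketable), targeting the low-firing branch.

## Synthetic inputs

Neither the empirical tractography connectome nor the post-mortem density
data are redistributable, so both are emulated by generators that are
first-class, tested package code:

* `generate_connectome()` draws random 3-D positions in the unit cube,
  keeps the `edge_density` fraction of pairs with the strongest
  exponential-distance scores, assigns log-normal weights attenuated by
  the same distance rule, bridges any disconnected components
  deterministically, and normalizes to maximum weight 1.  This reproduces
  the gross statistics of tractography matrices (symmetry, sparseness,
  heavy-tailed distance-decaying weights, connectedness) without claiming
  anatomical detail -- network-topology-specific effects (e.g. hub
  vulnerability) are outside what passing tests can show.
* `generate_histology()` reproduces the nested post-mortem design: 9
  control subjects and 33 MS subjects, of whom 13 carry demyelinated
  cortex (4 with both ROIs demyelinated, 9 mixed), aggregating to 9 NC,
  29 NAGM and 13 demyelinated measurement units.  Densities are log-normal
  around `baseline x multiplier` with a subject-level random effect
  (between-subject SD 0.10 log units) and ROI noise (0.08); these
  variance magnitudes are unpublished, so the defaults are chosen to give
  realistic ~10% between-subject coefficients of variation.  Covariates
  emulate the demographic structure (comparable age and sex, post-mortem
  delay markedly shorter in MS).  The default effect multipliers inject
  the published layer-VI percentages (0.875 / 0.851 NAGM, 0.815 / 0.707
  demyelinated); the transient layer-I excitatory increase is available as
  an opt-in preset but is off by default because it did not survive
  NeuN-density covariate correction in the source data.

## The histology stage

`fit_density_model()` mirrors the nested analysis: linear mixed-effects
models (REML) with a random intercept per subject; fixed effects tissue
type, and for synapses cortical layer plus the tissue-type x layer
interaction; covariates age, sex and post-mortem delay (optionally an
extra covariate such as NeuN density).  The interaction is tested first
(type-III F test, Satterthwaite degrees of freedom); per-layer follow-up
models with pairwise tissue contrasts are fitted when it is significant
(or always, via `follow_up = "always"`).  Percent differences are computed
from covariate-adjusted marginal means at covariate averages, with NC as
the reference.  Degenerate inputs (zero variance, singular random-effect
estimates) are reported as diagnostics in the fit metadata rather than as
errors.

Because post-mortem delay differs systematically between the groups, the
group contrast and the delay covariate are partially collinear; this
inflates contrast standard errors (it does in the source design too) but
leaves the estimates unbiased, which is what the round-trip calibration
tests check at the ensemble level.

## Numerical choices and limitations

* Integration step `dt = 1e-4` s resolves the delay (`t0/dt = 850`) and
  the fastest dendritic rate (`beta_d * dt = 0.077`); the stochastic Heun
  scheme is strong order 1.0 for this additive-noise system.
* Divergence guard: any `|V| > 1` V or `|phi_e| > 10 Q_max` aborts with an
  instability signal naming the step and region -- orders of magnitude
  beyond physiological range, so limit cycles are not mistaken for
  divergence.
* Default run length is 12 s per iteration with a 2 s transient discarded;
  the experiment functions accept any `iterations` subset (the worked
  examples retain iterations 0, 5, ..., 50).  These sizes give stable
  Welch estimates (about 4 windows) while keeping a three-condition,
  multi-seed experiment desk-sized.
* The spatial `graded` reduction mode exists because the source design
  caps the reduction at the level where "one region" reaches the measured
  loss; no regional profile is published, so `uniform` is the default and
  the graded profile is user-supplied.
* Heterogeneous per-region parameters, spatially continuous field models,
  MEG forward modelling and parameter fitting to empirical recordings are
  out of scope.
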