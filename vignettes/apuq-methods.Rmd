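---
title: "Methods: the cell model, its uncertainty analysis, and the numerical choices behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cell model, its uncertainty analysis, and the numerical choices behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The cell model

`apuq` implements a deliberately compact Hodgkin–Huxley-style model of the
canine epicardial action potential: six ionic currents, seven state
variables, 36 parameters. The transmembrane voltage obeys

$$C_m \frac{dV}{dt} + I_{Na} + I_{K1} + I_{to} + I_{CaL} + I_{Kr} + I_{Ks}
  = I_{stim},$$

with $C_m = 1\,\mu F/cm^2$ and the currents

$$I_{Na} = g_{Na} m^3 h^2 (V - E_{Na}), \quad
  I_{K1} = g_{K1} z_\infty (V - E_K), \quad
  I_{to} = g_{to} r_\infty s (V - E_K),$$
$$I_{CaL} = g_{CaL} d_\infty f (V - E_{Ca}), \quad
  I_{Kr} = g_{Kr} x_r y_\infty (V - E_K), \quad
  I_{Ks} = g_{Ks} x_s (V - E_K).$$

Every gating variable has a sigmoid steady state
$Y_\infty(V) = \left(1 + e^{\mp (V - E_Y)/k_Y}\right)^{-1}$
(− for activation gates $m, r, d, x_r, x_s$; + for inactivation gates
$h, z, s, f, y$) and relaxes as $\tau_Y \, dY/dt = Y_\infty(V) - Y$. The
model does not resolve the full voltage dependence of the time constants:
$\tau_m, \tau_s, \tau_f, \tau_{xr}, \tau_{xs}$ are constants, gates
$z, r, d, y$ are instantaneous (evaluated at the current voltage inside
the current equations, never integrated), and only the sodium
inactivation gate keeps a voltage-dependent time constant,

$$\tau_h(V) = \frac{2\,\tau_{h0}\, e^{\delta_h (V - E_h)/k_h}}
                   {1 + e^{(V - E_h)/k_h}},$$

which equals $\tau_{h0}$ at $V = E_h$ and is skewed by $\delta_h$. The
state vector is therefore $(V, m, h, s, f, x_r, x_s)$ — seven ODEs.

Two editorial notes on the parameter table. The nominal half-activation
voltage of $I_{CaL}$ is taken as $E_d = +0.7$ mV (the tabulated value;
a sign-flipped $-0.7$ mV circulates elsewhere and can be set with
`nominal_parameters(Ed = -0.7)`). $\tau_{h0}$ is a time constant and is
treated in ms. The parameter vector counts 36 entries including the three
Nernst potentials $E_{Na}, E_K, E_{Ca}$; those three (and $C_m$) are
environmental quantities and are never perturbed, so 33 parameters
actually vary under uncertainty.

Initial conditions are the resting state: $V = E_K = -85$ mV and every
state gate at its steady state there, so all gate derivatives start at
exactly zero.

The model omits intracellular ion concentration dynamics, Markov channel
schemes, temperature effects, and drug block — it is built for studying
parametric uncertainty, not for mechanisms that need those components.

## Simulation protocols

* **Threshold** (`find_threshold`): the minimum amplitude of a 0.5 ms
  square pulse that drives $V$ above 0 mV within 50 ms of onset, found by
  bisection on $[0, 200]\,\mu A/cm^2$ to 0.5% relative tolerance. The
  0 mV criterion cleanly separates sub- from supra-threshold responses;
  the returned value depolarizes while `value / 1.005` does not.
* **Single AP** (`simulate_ap`): one pulse at $1.1\times$ the parameter
  set's own threshold (recomputed per parameter set), 1000 ms horizon.
* **Pacing** (`pace`): repeated pulses at a fixed cycle length with the
  state carried continuously between beats; the post-pacing AP is the
  beat following ten beats at 1 Hz.
* **Dynamic restitution** (`dynamic_restitution`): consecutive pacing at
  a decreasing list of cycle lengths (default
  1000, 800, 600, 500, 400, 300 ms, 20 beats each — the protocol's beat
  count and schedule are a package choice; the qualitative restitution
  shape is insensitive to them), reporting the final beat's APD95 and
  diastolic interval; loss of 1:1 capture flags the row rather than
  failing.

## Quantities of interest

From each AP: **threshold**; **maximum upstroke velocity** and its
**time** (from stimulus onset); **APA**, the first post-upstroke voltage
peak minus the resting potential at stimulus onset; **APD**, the time
from activation (first upward crossing of −70 mV, linearly interpolated)
to the subsequent downward crossing — a fixed −70 mV threshold rather
than APD90, so APD sensitivities are not contaminated by APA
sensitivities; and the **notch minimum / maximum** voltages when the
spike–notch–dome morphology is present. Every potentially undefined
quantity carries an explicit flag and is excluded from summaries rather
than silently zeroed.

`dVdt` on the output grid is the model right-hand side evaluated at the
grid states, not a finite difference; the upstroke argmax is refined by
local parabolic interpolation. This removes output-grid artifacts from
the upstroke metrics (with plain grid argmax the 0.05 ms grid is visible
in the time-of-max distribution).

## Behavior taxonomy

Classification uses the interior local extrema of the post-stimulus
trace over 1000 ms:

1. dome without spike — one local maximum, later than 10 ms, no minimum;
2. spike without dome — one local maximum within 10 ms, no minimum;
3. oscillatory — more than one local minimum, or exactly two maxima and
   one minimum with the *first* maximum later than 10 ms (the voltage
   keeps rising after the upstroke before oscillating; shapes with an
   early first peak and the same extremum counts are the normal
   morphology);
4. normal — everything else.

Oscillatory APs are split by the voltage 1000 ms after onset: below
−75 mV the AP got back to rest (early afterdepolarizations, 3A), above
−25 mV it failed to repolarize (3B), in between it shows low-voltage
oscillations (3C). The −75 mV cut operationalizes "at resting potential"
as the complement of the 3C band, so 3A/3B/3C partition class 3.

Extremum detection is the one genuinely tunable step: raw extrema come
from sign changes of the sampled trace's differences, and adjacent
extremum pairs closer than **0.5 mV** in voltage are merged away (the
trace endpoints act as barriers, so a lone shallow wiggle at the resting
tail is also removed). 0.5 mV is large enough to swallow solver and
interpolation wiggle (sub-0.1 mV) and small enough to keep genuine
notches; it is the main knob behind the behavior probabilities, and the
noise-injection regression test pins its effect.

## Uncertainty model

A single hyper-parameter $\hat\sigma$ scales all input uncertainty.
Half-(in)activation voltages are normal,
$p \sim N(p_{nom}, (\hat\sigma R)^2)$ with reference range $R = 100$ mV —
using a common reference range instead of proportional scaling keeps
voltages near 0 mV (such as $E_d$) from being artificially certain.
Positive parameters (conductances, slopes, time constants, $\delta_h$)
are lognormal with underlying mean $\log p_{nom} - \hat\sigma^2/2$ and
sd $\hat\sigma$, so their analytic mean is exactly $p_{nom}$ and their
relative sd is $\approx \hat\sigma$. All parameters are sampled
independently; $\hat\sigma = 0$ collapses everything to the nominal
point.

This sampler is the package's synthetic-data generator: it emulates
population variability / measurement uncertainty in the *prescribed*
form above, not empirically measured distributions, and it assumes
independence — real channel parameters are known to co-vary. Passing
tests therefore demonstrate correctness of the machinery and
reproducibility of the model's published behavior under these prescribed
conditions, not fidelity of the input distributions themselves.

Monte Carlo propagation (`propagate`) records per-sample QOIs, behavior
labels and failure status (threshold bracket failure, solver failure);
failures never abort a batch. Summaries report the N-vs-N/2 rule: the
mean must be stable to three significant figures and the sd to two when
re-estimated from half the sample. The random stream is consumed one
parameter at a time in a fixed canonical order, so draws for a given
(n, seed) never depend on which QOIs are analyzed afterwards.

## Sensitivity analysis

Sobol first-order and total indices are estimated on the standard
Saltelli A/B/AB design ($N(k+2)$ model runs). The first-order estimator
is the mixed-matrix form $\langle f_B (f_{AB_i} - f_A)\rangle / V$ and
the total index uses Jansen's $\langle (f_A - f_{AB_i})^2 \rangle /2V$;
outputs are centered before estimation, which leaves both estimators
unbiased but removes the mean-level noise amplification that otherwise
swamps $S_1$ for outputs with large means. Errors are half-widths of
central 95% bootstrap intervals over base-sample indices (100
resamples). Designs with undefined outputs fail loudly beyond 1%
undefined rows — a variance decomposition over a censored sample is not
meaningful — which in practice restricts Sobol runs to
$\hat\sigma = 1\%$, where no failures occur. Morris elementary-effects
screening (trajectory design, 4 levels, step $p/(2(p-1))$, 50
trajectories by default, 1% tail truncation of the quantile transform)
ranks parameters by $\mu^*$ to pre-exclude non-influential ones before
expensive Sobol runs; the exclusion cutoff is
$\mu^* < 1\%\ \text{of}\ \max \mu^*$.

## Monte Carlo filtering

For each behavior class the sampled points are split into
"behavior occurred" vs "all others" and each parameter's two conditional
CDFs are compared with the two-sample Kolmogorov–Smirnov test
(asymptotic p-values; with $M = 10{,}000$ continuous samples the
asymptotics are accurate and ties do not arise). Parameters with
$D > 0.2$ are highly influential; $p < 0.01$ otherwise marks influential
(no multiple-testing correction, by design — the rule is applied per
parameter). Sub-behaviors can be conditioned either within the full
sample (default) or within class 3 only; both modes are exposed because
the choice is genuinely ambiguous. Behavior-conditioned Pearson
correlations take $\delta_h$ on the log scale, matching its lognormal
sampling law.

## Tissue strand

The 1D monodomain equation
$\chi (C_m \partial_t V + \Sigma I_{ion}) = \partial_x(\sigma \partial_x V)$
with $\chi = 1400\,cm^{-1}$, $\sigma = 1.4$ mS/cm is solved on a 1 cm
strand by operator splitting: a Rush–Larsen / forward-Euler reaction
step and a backward-Euler diffusion step (second-order centered stencil,
Thomas tridiagonal solve, no-flux ends). Defaults $dx = 0.005$ cm and
$dt = 0.01$ ms; the acceptance-level conduction
velocity is computed at $dx = 0.0025$ cm, $dt = 0.005$ ms, where
refinement changes CV by well under 2% (the convergence test is the
contract — CV is scheme-agnostic at convergence, so a finite-difference
scheme is as good as any). The stimulus is applied to the first 0.05 cm
at twice the single-cell threshold for 1 ms (tissue stimulus geometry is
not pinned by the calibration; CV at convergence is insensitive to it,
which the tests assert rather than assume). Conduction velocity is the
inverse slope of activation times between 0.25 and 0.75 cm; activation
is the −70 mV upward crossing, matching the single-cell convention.

## Numerics

The cell ODEs are integrated in C++ with an adaptive Dormand–Prince
5(4) pair, relative tolerance $10^{-6}$, absolute $10^{-8}$, maximum
step 1 ms, and forced step boundaries at stimulus on/off times (the
square pulse never straddles a step, so the integrator only ever sees a
smooth right-hand side). Output is cubic-Hermite interpolated onto a
uniform 0.05 ms grid. Gates are clamped to $[0,1]$ after each accepted
step (the interval is attracting; clamping only shaves numerical
overshoot at the $10^{-8}$ level). Tightening tolerances tenfold moves
APD by less than 0.1 ms and every other QOI by well under 0.5%.
Integration is deterministic: identical inputs give bit-identical
traces. Non-finite states or step-size underflow raise an error carrying
the parameter set — never a silent NaN trace.

## Study sizes and reproduced values

The package's own acceptance checks (see `scripts/acceptance.R` and
`tests/testthat/test-acceptance.R`) re-run the full study at desk scale:
2000 samples for the $\hat\sigma = 1\%$ CoVs, 1000–2000 per
behavior-probability level, $M = 10{,}000$ for filtering-level
correlations, Saltelli base 128–1024 for index checks. With those sizes
the package reproduces: CoVs of threshold / max upstroke velocity / APD
of about 5.2% / 8.3% / 1.8% at $\hat\sigma = 1\%$ with zero non-normal
APs; non-normal fractions of ~3.4% at $\hat\sigma = 3\%$ and ~23.3% at
5%; 998/1000 normal APs when $E_h, \delta_h, E_r, E_d, E_f$ are held at
nominal with everything else at 5%; a conduction velocity of ~59.2 cm/s
at nominal parameters; and $E_h$ carrying the dominant total Sobol index
for the maximum upstroke velocity while $E_m, k_m, E_z$ dominate its
timing.

Two quantities deserve an explicit caveat. The post-pacing peak
$|I_{Kr}|$ computes to 0.56 $\mu A/cm^2$ (peak $|I_{Ks}|$ 0.134): the
model's delayed-rectifier calibration constrains the *ratio* of these
peaks (4.18, which this implementation matches to three figures), not
their absolute values, so the absolute peak should be read together with
that ratio. And the normal-AP-conditioned correlation between $E_h$ and
$\log \delta_h$ converges to about $-0.08$; at $M = 10{,}000$ its
sampling sd is ~0.012, so single-seed estimates scatter noticeably
(−0.07 to −0.12 across the seeds exercised here).

## Limitations

Prescribed, independent input distributions (see above); no S1–S2
restitution, alternans metrics or arrhythmia protocols; 1D tissue only;
the behavior taxonomy depends on the 0.5 mV prominence choice, and the
probabilities it yields should be compared across settings of that knob
before being taken quantitatively; sensitivity results are conditional
on the prescribed distributions and should not be extrapolated to other
uncertainty models.
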