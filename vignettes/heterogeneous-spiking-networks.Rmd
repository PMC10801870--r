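---
title: "Models and methods: spike-threshold heterogeneity in spiking networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: spike-threshold heterogeneity in spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetspike)
```

# The model

`hetspike` studies networks of Izhikevich neurons in which the spike
threshold carries *quenched disorder*: each neuron draws its threshold
$v_{\theta,i}$ once from a distribution and keeps it forever. The membrane
equation of neuron $i$ is

$$C \dot v_i = k (v_i - v_r)(v_i - v_{\theta,i}) - u + I(t) + g\,s\,(E - v_i),$$

with a spike recorded when $v_i$ reaches a cutoff $v_p$ (reset to $v_0$). Two
slow variables are shared across the population: a recovery variable $u$ with

$$\tau_u \dot u = -u + b\,(\bar v - v_r) + \tau_u \kappa r,$$

driven by the population-mean voltage $\bar v$ and the population rate $r$
(each spike kicks $u$ by $\kappa / N$), and a synaptic activation $s$ with

$$\tau_s \dot s = -s + \tau_s J r,$$

so each neuron receives the rate-filtered recurrent drive $g s (E - v_i)$.
Three cell-type presets are shipped (`izh_params()`): excitatory
regular-spiking (RS), inhibitory fast-spiking (FS), and inhibitory
low-threshold-spiking (LTS) neurons, with the RS adaptation strength
$\kappa$ switchable between a weakly (10 pA) and strongly (100 pA) adapting
variant.

## Threshold disorder

Thresholds are Lorentzian (Cauchy) distributed with center $\bar v_\theta$
and half-width-at-half-maximum $\Delta_v$; $\Delta_v$ is the package's
heterogeneity dial. For network simulations the distribution is truncated
symmetrically about the center with the lower bound at the resting
potential, so no neuron's threshold falls below $v_r$
(`default_truncation()`), and sampling uses the inverse CDF restricted to
the quantile interval of the truncation bounds — deterministic cost, exact
distribution, all samples strictly inside the open interval
(`sample_thresholds()`). A Gaussian family is provided for robustness
checks; its width is matched to the Lorentzian by equating interquartile
ranges, $\sigma = \Delta_v / \Phi^{-1}(0.75) \approx 1.483\,\Delta_v$
(`gaussian_equivalent_width()`), since moment matching is impossible for a
Cauchy distribution.

## The mean-field reduction

For all-to-all coupling and untruncated Lorentzian thresholds the
population dynamics close exactly in four variables
$(r, v, u, s)$ — rate (spikes/ms), mean voltage, recovery, synaptic
activation:

$$C \dot r = \frac{\Delta_v k^2 \sigma_v (v - v_r)}{\pi C}
  + r\left[k (2 v - v_r - \bar v_\theta) - g s\right],$$
$$C \dot v = k v (v - v_r - \bar v_\theta)
  - \pi C r \left(\Delta_v \sigma_v + \frac{\pi C r}{k}\right)
  + k v_r \bar v_\theta - u + I + g s (E - v),$$

with $\sigma_v = \operatorname{sign}(v - v_r)$, plus the $u$ and $s$
equations above. The placement of the $1/(\pi C)$ and $\pi C r / k$ factors
is the unique dimensionally consistent reading of the compact typeset form
of these equations (every term of $C\dot r$ is pA/ms per mV, every term of
$C\dot v$ is pA); `mf_derivative()` documents and implements exactly this
form. Note that $\sigma_v (v - v_r) = |v - v_r| \ge 0$: heterogeneity always
feeds the rate, but only when the mean voltage leaves rest.

### Coupled populations

Multi-population models (`population_graph()`) attach one synaptic
activation per synapse group, each low-pass filtering its presynaptic rate
with its own $(J, g, E, \tau_s)$; conductance parameters default to the
*presynaptic* cell type's values, treating reversal potential and kinetics
as properties of the source population's transmitter. Every afferent
conductance enters both the voltage equation (as $g_m s_m (E_m - v)$) and
the bracket of the rate equation (as $-g_m s_m$): the latter term
originates from the population average of the $-g_m s_m v$ part of the
current, so it must be present for each synapse type, not only for the
recurrent one. The default two-population excitatory–inhibitory model uses
couplings $J_{rr} = J_{rf} = 16$ and $J_{fr} = J_{ff} = 4$ (indices
post, pre), reflecting the excess of excitatory neurons and balanced
excitatory/inhibitory drive onto excitatory cells.

# Numerical integration

Both simulators use the explicit Euler method at $\Delta t = 0.01$ ms. Two
engineering details matter:

* **Spike cutoff and reset.** The mean-field reduction assumes
  $v_p \to \infty$, $v_0 \to -\infty$ symmetrically about the vertex of the
  membrane quadratic. Defaults are $v_p = \bar v_\theta + 240$ mV and
  $v_0 = (v_r + \bar v_\theta) - v_p$ (for RS: $+200$ / $-300$ mV), large
  enough that the traversal time is negligible; both are configurable
  (`integrator_config()`).
* **Stiffness safeguard (mean-field only).** At near-zero heterogeneity
  strongly adapting populations produce relaxation-oscillation spikes whose
  rising phase moves the state by more than the Euler step can resolve;
  plain Euler at 0.01 ms then overshoots and diverges for a few extreme
  grid cells (e.g. FS at $\Delta_v = 0.01$ mV, $I \ge 80$ pA). When a step
  would move $v$ by more than 2 mV or $r$ by more than 0.02 spikes/ms — an
  order of magnitude above any smooth trajectory's per-step motion — that
  step is subdivided locally. Everywhere else the trajectory is the plain
  Euler one, and halving $\Delta t$ changes a 1-s RS trajectory's rate by
  well under 0.5%.

# Connectivity

Sparse networks give every neuron exactly $\lfloor pN \rfloor$ synaptic
inputs of equal weight $J / (pN)$, preserving the mean-field total drive
$J$. Ring networks draw each input's source with probability proportional
to (circular distance)$^{-d}$. These draws are made **with** replacement:
drawing a fifth of the ring without replacement exhausts the local pool and
flattens the realized distance kernel by an order of magnitude (measured:
tail mass beyond distance 250 on a 2000-ring at $d = 1.5$ rises from the
intended 2.5% to 29%), which lets localized activity invade the whole ring
and destroys the bump phenomenology. Repeated draws simply stack as
multi-edges of equal strength, so the realized kernel matches the intended
density exactly while keeping the in-degree fixed.

# Regime classification and ramp-based bifurcation detection

`classify_mf_regime()` integrates the mean-field equations from two initial
conditions — quiescent $(0, v_r, 0, 0)$ and an excited state consistent
with a high-rate attractor — discards a settling period (default 1 s) and
inspects a measurement window (default 2 s, long enough to hold five cycles
of the slowest ~250 ms relaxation oscillations). The rules use fixed
thresholds: a condition is *oscillatory* when at least 5 consecutive cycles
have trough-to-peak amplitude ≥ 10 Hz; *bistable* when the two initial
conditions settle on non-oscillatory states more than 10 Hz apart; and
otherwise monostable active/quiescent by the 10 Hz rate threshold $r_T$.
`map_regimes()` classifies a grid and refines boundaries by three bisection
steps.

The same thresholds drive the ramp detectors used on spiking networks:
`detect_fold_by_ramp()` interpolates the input at the first $r_T$ crossing
of a slowly ramped trace; `detect_hopf_by_ramp()` returns the input
interval spanned by the longest run of ≥ 5 consecutive ≥ 10 Hz cycles. Ramp
estimates lag the true bifurcation by a slow-passage delay that shrinks
with the ramp rate (defaults 0.01 pA/ms for folds, 0.005 pA/ms for Hopf
points); finite-$N$ rate traces are Gaussian-smoothed before detection
(20 ms for fold detection, 10 ms for the ~5 Hz adaptation-driven
oscillation). Cross-family comparisons on $N = 1000$ networks reproduce the
mean-field fold and Hopf locations to a few pA; a systematic ~5 pA
Lorentzian/Gaussian difference remains at $\Delta_v \gtrsim 0.8$ mV, where
the truncated Lorentzian's tail neurons desynchronize the network earlier
than the IQR-matched Gaussian does.

# Ring-bump protocol

`run_bump_trial()` holds a power-law ring ($d = 1.5$, $p = 0.2$) at a
30 pA baseline inside the bistable regime and raises a contiguous arc of
$\lceil p_{in} N\rceil$ neurons to 60 pA during the stimulation window
(default 500–1000 ms of a 3 s recording; any window ending well before the
final test window preserves the asymptotic character of the analysis).
Single-neuron rates are smoothed with a Gaussian kernel of 200 samples at
10 samples/ms (20 ms), averaged over the final 200 ms, and normalized by
the maximum. Retention is the RMSE between this profile and the binary
input mask, plus the mean normalized activity outside the arc. The window
average is computed in closed form from per-spike kernel masses
(`pnorm` differences), which equals the average of the convolved signal
without materializing the $N \times T$ matrix. A silent test window is
flagged and scored as the all-zero profile (RMSE $= \sqrt{p_{in}}$).

# Reservoir-computing protocol

`collect_responses()` burns a ring network ($d = 0.75$) in for 2 s at a
regime-selecting current; if the burned-in rate trace oscillates (≥ 10 Hz
cycles), the burn-in is extended to the next rate trough and the onset
times are spread over one measured intrinsic period, otherwise over 250 ms.
Each trial restarts from the shared stored state, applies a 30 pA, 20 ms
pulse to a quarter of the ring (the pulse is not printed in the protocol
this emulates; the arc width matches the bump protocol's default input
width and was fixed once so the pulse evokes a measurable response at
reduced sizes), and records Gaussian-smoothed (10 ms) single-neuron rates
over the following 250 ms as the $N \times T$ feature matrix.

The readout is the analytic ridge solution
$w = y X^\top (X X^\top + \gamma I)^{-1}$ over the concatenated training
trials. No penalty value is inherited from the emulated protocol; the
default chooses $\gamma$ by leave-one-trial-out cross-validation on the
training trials over a log-spaced grid relative to
$\mathrm{tr}(X X^\top)/N$ (`cv_gamma()`). Dimensionality is the
participation ratio $(\sum\lambda)^2 / \sum\lambda^2$ of the row-centered
covariance spectrum. The trial kernel is the ridge hat map
$K = X_{trial}^\top (X X^\top + \gamma I)^{-1} X_{trial}$ — for any target,
the trained readout reproduces $yK$ on that trial — and the kernel
variance takes $Q_{ij}$ as the mean absolute pairwise difference of
$K_{ij}$ across training trials, $q = \sum_{ij} Q_{ij}^2$, reported
alongside $q/T^2$.

**Scale caveat.** The heterogeneity benefits for function generation are
resolution-limited. At the desk-scale used in the test suite ($N = 300$,
10 onsets, 8 train / 2 test) the cross-validated test error sits within
~10% of the null-predictor level in every regime and its ordering across
$\Delta_v$ is seed noise, while the dimensionality increase with
$\Delta_v$ is robust even there. At $N = 1000$ with 25 onsets the
decreasing-MSE trend appears in all three regimes. Conclusions about the
error and kernel-variance trends should be drawn at or above that scale.

# Entrainment

`entrainment_map()` drives the single-population mean-field model with
$I(t) = I_0 + \alpha \sin(2\pi\omega t)$ and quantifies locking by the
phase-locking value $|\langle e^{i(\varphi_r - \varphi_f)}\rangle|$, with
instantaneous phases from FFT band-passed analytic signals (band
$\pm 30\%$ of $\omega$). A constant rate trace is flagged and scored 0. The
default baseline $I_0 = 55$ pA places the strongly adapting RS population
inside its oscillatory regime (intrinsic frequency ≈ 4–5 Hz), so the map
probes how heterogeneity widens the range of forcing frequencies the
population locks to. Band width is reported as the number of locked grid
frequencies, since locking regions need not be contiguous (subharmonic
tongues).

# What the synthetic conditions do and do not show

All experiments are simulations of the package's own generative model:
quenched thresholds are the *only* disorder, connectivity is random with
fixed in-degree, inputs are noiseless, and the recovery variable is shared
population-wide. Real cortical populations add synaptic noise, conduction
delays, per-neuron adaptation, and correlated parameter heterogeneity, none
of which are modeled. Passing tests therefore certify the internal
consistency of theory and simulation (mean-field ↔ network agreement,
regime topology, protocol metrics), not quantitative predictions for
biological tissue. Two known systematic effects are documented by the
tests themselves: sparse, truncated networks settle ~10% away from the
untruncated all-to-all mean-field rate (independent of $N$ between 200 and
1000), and truncated-Lorentzian vs IQR-matched-Gaussian networks differ by
up to ~5 pA in ramp-detected bifurcation locations at moderate
heterogeneity.

# Problem sizes used by the shipped checks

The test suite runs entirely on one CPU: regime maps on 6 × 26–31 grids
(about 20 s for all four cell-type variants), ramp cross-validation on
$N = 1000$ networks (three realizations per disorder family), the bump
protocol at $N = 400$ for 1.5 s with five realizations, the
function-generation protocol at $N = 300$ with 10 onsets and three to five
realizations, and the entrainment map on a 15-frequency grid. The
full-scale defaults ($N = 2000$, 3 s recordings, 50 onsets) are what
`bump_protocol()` and `onset_protocol()` construct when called without
arguments.
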