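---
title: "Methods: attractor dynamics and the speed-accuracy trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attractor dynamics and the speed-accuracy trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(satdyn)
```

## The model

`satdyn` simulates a reduced two-variable mean-field model of two-choice
decision making. Two populations selective for the decision alternatives
compete through effective cross-inhibition while exciting themselves
recurrently; the slow NMDA gating variables $S_1, S_2 \in [0,1]$ are the
only dynamical state:

$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_S} + (1 - S_i)\,\gamma\, H(x_i),$$

with the simplified frequency–current relation

$$H(x) = \frac{a x - b}{1 - e^{-d (a x - b)}},$$

a continuous, strictly increasing function whose removable singularity at
$a x = b$ is filled by its limit $1/d$. Each population's total input
current is

$$x_1 = J_{11} S_1 - J_{12} S_2 + I_0 + I_{\mathrm{stim},1} + I_{\mathrm{noise},1},$$

symmetrically for $x_2$. During the stimulus epoch the evidence currents
are $I_{\mathrm{stim},1} = J_{\mathrm{ext}}\,\mu_0 (1 + c/100)$ and
$I_{\mathrm{stim},2} = J_{\mathrm{ext}}\,\mu_0 (1 - c/100)$, where $c$ is
the motion coherence in percent and population 1 is, by convention, the
target. The noise currents are independent Ornstein–Uhlenbeck processes
with correlation time $\tau_{\mathrm{noise}}$ and stationary standard
deviation $\sigma_{\mathrm{noise}}$.

Internally, time is in ms, rates in Hz and currents in nA; $H$ (in Hz) is
scaled by $10^{-3}$ where it enters the per-ms gating dynamics. Config
files accept $I_0$ in pA, the unit in which background currents are
usually quoted.

### Parameters

| parameter | default | unit | role |
|---|---|---|---|
| $a$ | 270 | Hz/nA | f–I gain |
| $b$ | 108 | Hz | f–I offset |
| $d$ | 0.154 | s | f–I curvature |
| $\gamma$ | 0.641 | – | gating increment per spike |
| $\tau_S$ | 100 | ms | NMDA gating decay |
| $\tau_{\mathrm{noise}}$ | 2 | ms | noise correlation time |
| $J_{11}=J_{22}$ | 0.2609 | nA | recurrent self-coupling |
| $J_{12}=J_{21}$ | 0.0497 | nA | cross-inhibition |
| $J_{\mathrm{ext}}$ | $5.2\times 10^{-4}$ | nA/Hz | stimulus scaling |
| $\mu_0$ | 30 | Hz | stimulus reference rate |
| $\sigma_{\mathrm{noise}}$ | 0.02 | nA | noise amplitude |

These are the canonical published values of the reduced model; the package
treats them as a fixed reference point and varies only the nonselective
background current $I_0$ across task conditions: 325 pA (speed), 321 pA
(neutral), 316 pA (accuracy). The couplings are hard-wired symmetric;
asymmetric networks are out of scope. The per-condition noise amplitude is
configurable but defaults to a common $\sigma_{\mathrm{noise}} = 0.02$ nA,
since no per-condition values are established; the conclusions tested here
are orderings across $I_0$ and are insensitive to small common changes of
$\sigma$.

## What the simulator generates

A trial is a 2.5 s pre-stimulus epoch followed by a 5 s stimulus epoch,
integrated by the Euler–Maruyama scheme at $dt = 0.1$ ms. Gating variables
are clipped to $[0,1]$ after each step because the explicit scheme can
overshoot the invariant interval by $O(dt)$. Noise currents are initialised
from their stationary law, so there is no burn-in transient. Each trial has
a private seed derived deterministically from (master seed, condition,
coherence, trial index), making any single trial reproducible in isolation.

The generator emulates the statistical structure the analyses assume:
coherence-scaled evidence currents, exponentially correlated input noise,
and baseline activity whose mean tracks $I_0$. It does *not* emulate
spiking variability, receptor kinetics, firing-rate adaptation, non-decision
(motor) time, or trial-history effects — passing tests therefore speak to
the dynamics of the reduced rate model, not to quantitative fits of
behavioural or neural data.

### Choice detection

A choice is registered when either population's firing rate
$r_i = H(x_i)$ reaches the choice threshold $\theta = 15$ Hz during the
stimulus epoch; the first population to cross determines the choice and the
crossing time is the decision time. Because $x_i$ contains the
fast noise current and $H$ is convex, the *instantaneous* rate makes
millisecond excursions an order of magnitude above baseline; with a purely
instantaneous rule those spikes register as choices, and under the speed
condition about 15% of trials would "cross" 15 Hz before any evidence
arrives — the breakdown regime that should only appear at much lower
thresholds. Detection therefore requires the rate to stay at or above
$\theta$ for a sustained window, `sustain_ms` (default 2 ms, one noise
correlation time). The window suppresses one-step spikes while leaving
attractor excursions, which evolve on the ~100 ms gating timescale,
untouched. With it, pre-stimulus crossings at $\theta = 15$ Hz drop below
0.5% in every condition. The same windowed-minimum rate is stored in the
re-detection envelopes (below), so every threshold uses the identical rule.

Undecided trials (no crossing within the 5 s stimulus) are excluded from
accuracy and decision-time summaries and reported as counts. At $c = 0$
"correct" is defined as choosing population 1 — an arbitrary labelling that
yields the expected 50% accuracy point.

## Behavioural analyses

Per-condition accuracies are fitted with a Weibull psychometric function
$P(c) = 0.5 + 0.5\,(1 - e^{-(c/\alpha)^\beta})$ by binomial maximum
likelihood (Nelder–Mead on $(\log\alpha, \log\beta)$); the 75%-accuracy
coherence follows in closed form, $c_{75} = \alpha (\ln 2)^{1/\beta}$. All
coherences contribute, including the ~50% cell at $c = 0$. Fits are refused
(with diagnostics) when the data are degenerate — all cells at chance or
all saturated — since $\alpha$ is then unidentifiable.

Chronometric summaries report mean decision time ± SE per (condition,
coherence), separately for correct and error trials.

### The threshold-compensation experiment

The package's central experiment asks whether reinstating the neutral
condition's threshold–baseline difference recovers neutral behaviour. The
baseline differences $\Delta_{ns}$ (speed − neutral) and $\Delta_{na}$
(neutral − accuracy) are computed from mean rates over the last 1000 ms of
the pre-stimulus epoch. For every threshold in a grid (default 9–21 Hz in
1 Hz steps, bracketing the 15 Hz default and extending low enough to show
the moderate-effect regime), choices are re-detected with the speed
threshold raised by $\Delta_{ns}$ and the accuracy threshold lowered by
$\Delta_{na}$, the neutral condition never adjusted.

Re-detection uses per-trial *envelopes* — the within-bin maximum of the
windowed-minimum rate, at 5 ms bins over the whole trial — rather than
re-simulation. The first bin whose envelope reaches $\theta$ is the first
sustained crossing of $\theta$, exact up to the 5 ms quantisation, so every
threshold is evaluated on the *same* trials (a paired design in which
between-threshold comparisons carry no fresh Monte-Carlo noise) at a
memory cost of about 0.5 GB for 21,000 trials. Cells where more than 5% of
trials cross the applied threshold before stimulus onset are flagged as
breakdown rather than silently included; cells with no decided trials are
flagged degenerate.

## Phase-plane analysis

All dynamical analysis is noise-free. Fixed points are found by damped
Newton iteration (analytic Jacobian) from a 21 × 21 grid of seeds over
$[0,1]^2$, accepted at drift norm $< 10^{-9}$ ms$^{-1}$, deduplicated at
$10^{-6}$, and classified by their eigenvalues. In the bistable decision
regime the system has two choice attractors separated by a saddle; among
saddle points the decision saddle is the one nearest the symmetric
diagonal. The effective time constant of integration is
$\tau_{\mathrm{eff}} = 1/\lambda_+$, the reciprocal of the saddle's
repelling eigenvalue: it sets how long the network lingers near the saddle
integrating evidence before committing.

Manifolds are traced by integrating the flow from the saddle displaced by
$\varepsilon = 10^{-4}$ along the eigenvectors — forward along the unstable
eigenvector (each branch ends at a choice attractor), backward along the
stable one. Integration is performed in *arclength* parameterisation
($dS/ds = \pm F/|F|$, `deSolve::lsodar`, output every $10^{-3}$ gating
units) with root-triggered termination at attractors, at a vanishing vector
field, or at the domain boundary. The arclength form was chosen over
fixed-time-step tracing because the stimulus extinguishes the spontaneous
state in a saddle-node bifurcation whose slow "ghost" stalls a time-domain
integrator exactly where the stable manifold matters most (near the
initial state); unit-speed integration passes through at uniform
resolution.

The initial state of a trial is the network state at the end of the
pre-stimulus epoch — by default the spontaneous fixed point of the
stimulus-off system, or the across-trial mean simulated gating state when a
batch is supplied. Because the figures of interest plot the stimulus-on
decision landscape while the initial state is defined immediately *before*
evidence onset, the initial state is mapped to rate space with
pre-stimulus currents (the activity actually observed at that moment) and
the manifolds with stimulus-on currents; the stimulus-on mapping of the
initial state is also exported so either convention can be reproduced. The
distance from the initial state to the stable manifold — the basin
boundary whose crossing by noise produces errors — is the minimal
point-to-segment distance in rate space (Hz), the coordinate system of the
decision-space figures.

## Ideal-observer analysis

For each (condition, coherence) cell the across-trial distribution of
target-population rates is compared with the distractor-population
distribution in 10 ms bins; the per-bin area under the ROC curve (ties
counted half, computed from the rank-sum statistic) gives a discriminability
time course. The discrimination time is the first bin where the AUC reaches
0.75 and stays there for 3 consecutive bins; criterion and sustain are
config keys since no canonical values exist. The rate at discrimination is
the mean target rate at that bin, and subtracting the condition's baseline
rate gives the discrimination–baseline difference. The pooled ("across all
positive coherences") variant is the unweighted mean over coherences of the
per-coherence rate at that coherence's discrimination time.

By default the AUC uses all trials of a cell. At low coherences the
across-trial distributions then never separate — the AUC asymptotes near
the cell's accuracy level, below the criterion — so those cells report an
absent discrimination time and drop out of the pooled mean (the count is
reported). The alternative `trials = "correct"` restricts the ROC to
correct trials, as in target-selection analyses of choice-sorted neural
data; it reaches criterion at every positive coherence but discriminates
within a bin or two of stimulus onset, while rates are still at baseline,
which makes the baseline-difference comparison uninformative. The default
keeps the variant that reflects separation driven by the attractor
dynamics.

A second read-out determines decision time per trial as the *last
intersection* of target and distractor traces, smoothed with a 50 ms
centred moving average (instantaneous rates carry 2 ms-correlated noise
that produces spurious micro-crossings); the implied choice is the
population on top after the final crossing, and the rate at separation is
the common value of the two smoothed traces at that crossing. Agreement of
the implied choice with the threshold choice exceeds 90% on decided trials
at $c \ge 8$%.

## Numerical choices and test scale

* Integration step $dt = 0.1$ ms (noise stability requires
  $dt \le \tau_{\mathrm{noise}}/2$); a fast mode at $dt = 0.5$ ms is used
  in contract tests, where decision-time accuracy is not at stake.
* Newton tolerance $10^{-12}$ on the drift norm; manifold seeds
  $\varepsilon = 10^{-4}$; attractor capture radius $10^{-3}$.
* Envelope bins 5 ms (decision-time quantisation for re-detection), trace
  bins 10 ms (AUC and averaging).
* The package's full-scale property checks run 1000 trials per cell over
  the 7-coherence grid — the study's trial count — which takes a few
  minutes of CPU; the example acceptance script uses 400 trials per cell,
  enough to resolve every ordering it reports several-fold beyond its
  Monte-Carlo error.

## Known limitations

* The model is a two-variable reduction: no spiking statistics, no
  separate inhibitory population, no receptor-level kinetics.
* Decision time is threshold-crossing time; non-decision components of
  reaction time are not modelled.
* Errors are produced by noise crossing the stable manifold, which makes
  error trials *slower* than correct trials — a property of single-circuit
  attractor models that does not hold in all task paradigms.
* No bifurcation tracking across continuous $I_0$ sweeps is provided, only
  the named conditions (plus any user-specified $I_0$).
* The threshold sweep's decision times are quantised at the 5 ms envelope
  bin; means over hundreds of trials are insensitive to this.
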