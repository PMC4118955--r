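---
title: "Two models of sleep-wake regulation and the machinery that connects them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two models of sleep-wake regulation and the machinery that connects them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepdyn)
```

## The two models

**Two-process model.** A scalar homeostatic sleep pressure $H$ relaxes
exponentially towards an upper asymptote $\mu$ during wake (time constant
$\chi_w$) and towards a lower asymptote (zero by default) during sleep
(time constant $\chi_s$). Switching happens at circadian-modulated
thresholds $H^{\pm}(t) = H_0^{\pm} + C(t)$: wake ends when $H$ reaches the
upper threshold from below, sleep ends when $H$ reaches the lower threshold
from above. A pressure exactly on a threshold keeps its current state; only
a strict crossing switches. The circadian waveform $C$ is a sinusoid by
default, with optional higher harmonics.

**Mutual-inhibition (flip-flop) model.** The sleep-active ventro-lateral
pre-optic population (VLPO) and the wake-active mono-aminergic (MA)
population of the ascending arousal system inhibit each other:

$$\tau \dot V_v = -V_v - \nu_{vm} Q(V_m) + D_v(t), \qquad
  \tau \dot V_m = -V_m - \nu_{mv} Q(V_v) + A,$$

with the sigmoidal firing function
$Q(V) = Q_{max}/(1 + e^{-(V-\theta)/\sigma})$ and the VLPO drive
$D_v = \nu_{vh} H + D_{0v} + C(t)$. The homeostat obeys
$\chi \dot H = P(Q(V_m)) - H$ with linear production $P(Q) = \mu_h Q$ by
default. All weights are positive with explicit signs; the mean circadian
drive component is folded into $D_{0v}$. The canonical human values
(`pr_human()`) are the standard set of Phillips & Robinson (2007):
$Q_{max} = 100\,/\mathrm{s}$, $\theta = 10$ mV, $\sigma = 3$ mV,
$\nu_{vm} = 2.1$, $\nu_{mv} = 1.8$ mV s, $\nu_{vh} = 1$ mV/nM,
$\mu_h = 4.4$ nM s, $\chi = 45$ h, $\tau = 10$ s, $A = 1.3$ mV,
$D_{0v} = -13.05$ mV, circadian amplitude $2.9$ mV. We verified before
adopting them that they reproduce a monophasic 24-hour cycle with roughly
8.5 h of daily sleep. The sigmoid width follows the $\sigma'$ convention,
i.e. $Q(\theta) = Q_{max}/2$ and the quoted width is the exponential scale.

Time is in hours throughout; $\tau$ is entered in seconds and converted
internally. $H$ is dimensionless "pressure" in the two-process model and
concentration-like (nM, e.g. adenosine) in the flip-flop model; the two are
identified through $\nu_{vh}$.

## Simulation engines and numerical choices

The two-process model is simulated *event-driven*: within an episode $H(t)$
is the exact exponential, and switching times are found by scanning
$H(t) - H^{\pm}(t)$ at 0.005 h resolution and polishing each sign change
with root-finding to $10^{-12}$ h. The scan step is small enough to catch
the double crossings that appear near grazing tangencies. Runs that never
cross a threshold within a 40-day horizon (permanent wake or sleep) are
returned as truncated patterns, not errors.

The flip-flop model is integrated with a stiff solver (`deSolve::lsoda`,
absolute and relative tolerances $10^{-8}$) at a dense output step of
0.005 h; the wake/sleep label is defined by the MA rate crossing
$1\,/\mathrm{s}$, and crossing times are refined by root-finding on an
interpolant of the dense output, in both directions. The hard-switch
variant has a discontinuous vector field, so it is integrated mode by mode
with exact event location at the switch voltage. Episodes shorter than one
minute are merged before any pattern statistics, which suppresses numerical
chatter at grazing parameters.

## The hard-switch reduction and its calibration

With the firing sigmoid replaced by a switch ($\bar Q$ above $V_{th}$, 0
below), the slow dynamics are *exactly* a two-process model:
$\mu = \mu_h \bar Q$, $\chi_w = \chi_s = \chi$,
$H_0^+ = (V_{th} + \nu_{vm}\bar Q - D_{0v})/\nu_{vh}$,
$H_0^- = (V_{th} - D_{0v})/\nu_{vh}$, threshold modulation
$-C(t)/\nu_{vh}$. The threshold gap $\nu_{vm}\bar Q/\nu_{vh}$ *is* the
VLPO's loss of MA inhibition between wake and sleep -- the hysteresis of the
flip-flop -- and shifting the mean VLPO drive moves both thresholds together
without changing the gap.

Calibrating $(\bar Q, V_{th})$ from the full sigmoid model
(`calibrate_switch_from_pr()`) proceeds in three steps, valid for
monophasic cycles away from bifurcation points: (i) identify the thresholds
with the saddle-node drives $D_v^{\pm}$ of the frozen-drive slow manifold
(for the human set, $D_v^- = 1.4503$ and $D_v^+ = 2.4635$ mV), so
$V_{th} = D_v^-$; (ii) integrate one converged cycle, extract the homeostat
extrema by quadratic interpolation of the dense output, and choose $\mu$ so
that the wake exponential passes through both extrema, giving
$\bar Q = \mu/\mu_h \approx 4.85\,/\mathrm{s}$ -- close to the mean wake
firing rate and far below $Q_{max}$, because only the foot of the sigmoid
is ever used; (iii) take the lower asymptote as zero and set the switch
model's $\nu_{vm}$ to $(D_v^+ - D_v^-)/\bar Q$ so the mapped gap matches
the fold separation. Since the calibrated $V_{th}$ exceeds the nominal MA
drive $A$, the switch model's $A$ is raised to $V_{th} + 0.5$ mV; $A$
enters the switch dynamics only through the sign of $V_m - V_{th}$, so the
equivalence is unaffected. The calibrated $\mu$ retains a residual
dependence on $\chi$ (a different $\chi$ visits a different part of the
firing curve); we expose it rather than bound it, and hold the asymptotes
fixed at their default-point values during parameter scans (the
`recalibrate` flag of `scan_parameter()` re-runs the calibration per grid
point as a sensitivity study).

Three levels of agreement result, each measured by our tests: the switch
model and its mapped two-process model match transition-for-transition to
within about a minute (the residual is the $\tau$-scale relaxation through
the switch); the full sigmoid model matches both to within about 12
minutes, the systematic lag with which a trajectory leaves a vanished state
through the saddle-node *ghost* before the MA rate actually crosses
$1\,/\mathrm{s}$; and the mapped wake exponential passes through the source
model's homeostat extrema to numerical precision.

## Return maps, discontinuities, grazing

`next_onset()` propagates a state on the upper threshold through one sleep
and one wake episode to the next sleep onset; `build_return_map()`
tabulates this map on $[0, 24)$ (half-open modular arithmetic, day counts
kept separately). Jumps above 0.5 h between neighbouring grid values --
well above interpolation error, well below genuine jumps of hours -- are
refined by bisection; fixed points are sign changes of $map(t) - t$ (mod
24) polished on the exact map, with central-difference slopes. At the human
defaults the map has a single stable fixed point with slope $\approx 0.12$
(hence perturbed sleep times recover within a few days) and one
discontinuity, whose flanking trajectories pass within $10^{-6}$ pressure
units of a threshold: every discontinuity is a threshold tangency. The map
steepens like a square root on the approach to the tangency, which is why
interpolated map values are only accurate away from a buffer around the
discontinuity.

Grazing (border-collision) bifurcations are located by bisection on the
classified episode count (`locate_grazing()`), with a certificate at the
critical value: the converged trajectory's minimum interior distance to the
grazed threshold (below $10^{-4}$ pressure units), the vanishing time
derivative of trajectory minus threshold at the near-touch, and the
coincidence of the map discontinuity with the diagonal. Decreasing the
homeostatic time constant from the human value adds sleep episodes one
grazing at a time (monophasic below $\chi \approx 19.4$ h in the mapped
two-process model), with period-two windows between consecutive integer
episode counts -- we scan only this first level of the adding scheme and cap
period detection at 16 days. Moving both thresholds together (equivalently,
the mean VLPO drive) ends in no-wake and no-sleep regimes through grazings
whose nearby cycles contain episodes longer than 24 h. The convergence
protocol for scans discards a 30-day transient, tests repetition over up to
16 days (events matched modulo 24 h within 0.02 h), and warm-starts each
grid point from the previous one.

## Sleep deprivation and wake effort

Enforced wakefulness in the two-process model means the homeostat continues
along the wake exponential past the upper threshold -- equivalently the
threshold is moved continuously to keep the model awake; the homeostat can
never exceed $\mu$ by construction. In the flip-flop model the wake state
disappears at the fold $D_v^+(D_m)$, and keeping the model awake means
following that saddle-node boundary in the $(D_v, D_m)$ plane: the *wake
effort* is the extra MA drive
$\Delta D_m(t) = D_m^{fold}(D_v(t)) - A$, zero below the fold. The fold
curve ends at a corner near $D_v \approx 225$ mV (far outside the
physiological range for these parameters) beyond which no MA drive
maintains wake and the effort is reported unavailable; the symmetric
sleep-side construction shows a much smaller extension span, so holding
sleep is harder than holding wake. We ship it as an exploratory quantity
(`effort_spans()`) without quantitative claims.

Fitting $\Delta D_m$ against the pressure excess $x = H - H^+(t)$ over a
window spanning a four-day total deprivation ($x \le 7$ nM) gives the
closed-form two-process effort $W = c_1 x + c_2 x^2$, with
$c_1 \approx 0.39$ mV/nM and a small quadratic coefficient
($|c_2|/c_1 \approx 0.04$ per nM, fit RMS below 1% of the effort range).
The coefficients depend only on the fold geometry, not on any protocol.

During enforced wake the deprived flip-flop model is simulated on the slow
manifold, and the MA rate feeding the homeostatic production is held at the
fully-awake reference rate $Q_{ref}$ -- the maximum wake-branch rate of the
converged undeprived cycle ($\approx 5.05\,/\mathrm{s}$ at the defaults) --
reflecting that the effort restores normal waking function. This choice
matters: the fold-point firing rate itself *rises* along the boundary as
the effort deepens, and feeding it into the linear production form creates
a runaway asymptote, which contradicts the observed saturation of
sleepiness measures over multi-day deprivation. With $Q_{ref}$, the linear
form $P = \mu_h Q$ gives a deprived asymptote $\mu_h Q_{ref} \approx 22.2$
nM, a few percent above the calibrated (episode-averaged) two-process
$\mu \approx 21.4$ nM, because the calibration cycle includes the
transition dips of the firing rate that sustained wakefulness lacks. The
compounding of that gap over four days is exactly the effect the asymptote
treatment is meant to expose: the two effort formulations diverge by
$\approx 8.5\%$ at day 4 (`wake_effort_compare()`), while the saturating
production form $P(Q) = \mu_{sat} Q/(Q + Q_{half})$ -- our operational
Michaelis-Menten choice, normalised so that $P$ matches the linear form at
the unopposed waking rate $Q(A)$, with $Q_{half} = 1\,/\mathrm{s}$ --
is insensitive to the firing-rate difference and agrees with the
two-process effort to within a few percent throughout.

## What the self-generated experiments do and do not show

Everything in this package is deterministic model dynamics; there is no
noise, no data fitting, and no claim about recorded human or animal sleep.
The default parameter sets define "the human condition" only in the sense
the underlying models do. Passing tests demonstrate internal consistency
(closed forms against simulations, brute-force oracles against refined
root-finding, cross-model equivalences) and reproduce the models' known
phenomenology -- monophasic/polyphasic transitions as grazings, near-linear
effort-pressure relations -- but say nothing about EEG markers, inter-subject
variability, or light-driven entrainment, all of which are outside the
models as implemented. Problem sizes used by the test-suite and the
reproduction script (10-12 day equivalence runs, 30-day scan transients,
four-day deprivation protocols) were chosen as the smallest at which the
reported quantities are stable to well within their stated tolerances.
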