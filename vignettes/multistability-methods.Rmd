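---
title: "Models and methods: competitive networks for perceptual multistability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: competitive networks for perceptual multistability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multistable)
```

## The models

When the visual system is shown an ambiguous stimulus — two orthogonal
gratings, one to each eye, or a single bistable figure — perception
alternates between the competing interpretations. This package
implements three related rate models of that competition and the
statistical machinery to analyze the alternations they produce.

**Ring model.** A neural field $u(x,t)$ on the orientation domain
$x \in [-\pi/2, \pi/2)$ with cosine connectivity $w(x-y) = \cos 2(x-y)$
(similar orientations excite, orthogonal ones inhibit disynaptically),
short-term synaptic depression, and a bimodal stimulus:

$$\tau_m \dot u = -u + w * (q\,f(u)) + I(x) + \xi(x,t), \qquad
  \tau \dot q = 1 - q - \beta\, q f(u),$$

with $I(x) = -I_0\cos 4x + I_a \sin 2x$, which peaks at $\pm\pi/4$ with
heights $I_R = I_0 + I_a$ and $I_L = I_0 - I_a$. The gain $f$ is the
Heaviside step $H(u - \kappa)$ by default ($H(0) = 1$), with a logistic
sigmoid available. The noise $\xi$ is white in time with spatial
correlation $\epsilon\, s\, \cos(x-y)$, realized exactly by the rank-2
expansion $\xi = \sqrt{\epsilon s}(\eta_1 \cos x + \eta_2 \sin x)$.
The resource field $q \in (0,1]$ depletes inside active bumps at rate
$(1+\beta)/\tau$ (exact solution of $\tau\dot q = 1-(1+\beta)q$) and
recovers at rate $1/\tau$.

**Space-free networks.** The two-population reduction replaces the
bumps by rates $u_R, u_L$ coupled by mutual inhibition through
depressing synapses ($\dot u_R = -u_R + H(I_R - q_L u_L) + \xi_1$,
etc.); the tristable version has three populations, each inhibited by
the other two. These are the models in which noise-driven switching
and switch-ordering statistics are analyzed.

Time is measured in units of the synaptic timescale, 10 ms per model
unit, so $\tau = 50$ corresponds to a 0.5 s depression recovery time
(physiological range 200–800 ms) and a dominance time of 70 model
units is 0.70 s.

## Numerical integration

All three simulators use the Euler–Maruyama scheme in compiled code.
The ring convolution exploits the separability
$\cos 2(x-y) = \cos 2x \cos 2y + \sin 2x \sin 2y$, so each step costs
two inner products over the grid ($O(n)$, checked against direct
$O(n^2)$ quadrature to $10^{-12}$ in the test-suite). Grids are
rectangle-rule uniform on the half-open domain.

Default problem sizes were chosen so a laptop reproduces every
statistic in minutes: ring `n_grid = 512`, `dt = 1e-3`, a few thousand
model units per replicate with statistics pooled over replicates;
space-free networks `dt = 1e-4`. The full-resolution settings
(`n_grid = 2000`, `dt = 1e-4` for the ring; `dt = 1e-6` reduced) are
available via `scale = "full_res"` in `run_experiment()`. Noise-free
dominance times change by well under 0.5% when `dt` is halved, and the
bump half-width error scales like the grid spacing; `n_grid = 512`
keeps the noise-free oscillation period within about 0.3% of the
`n_grid = 1024` value, whereas 128-point grids distort it by several
percent (the bump edge is then resolved too coarsely).

## Dominance detection

A percept is dominant while its bump peak (ring: peak of $u$ over
$x>0$ vs. $x<0$) or its population rate is strictly the largest; exact
ties retain the incumbent. Raw label series are debounced: a
candidate switch must persist at least `min_dwell = 0.5` model units
(5 ms), otherwise it is absorbed into the incumbent epoch. Without
debouncing, the threshold crossing at each genuine switch — where both
activities briefly straddle — generates a cloud of near-zero epochs
that contaminate every downstream statistic; 5 ms is well below any
perceptual dwell and well above the crossing jitter. The first 50
model units plus the epoch inherited from the initial condition are
discarded (simulations start from the deterministic winner-take-all
state); a run with no post-burn-in switch reports its single epoch,
flagged `censored`, and censored epochs are excluded from all fits and
means. The mean dominance time is sensitive to the dwell parameter in
the strongly noise-driven regime (the cloud of crossing flickers is
dense), which is worth keeping in mind when comparing against numbers
obtained with unknown debouncing conventions.

In that regime the detected durations are in fact bimodal at the
default dwell: genuine inter-escape epochs (hundreds of model units at
the default noise convention) coexist with few-unit bounces from
*failed* escape attempts, in which the suppressed bump briefly
overtops the dominant one without completing the switch. Transitions
last a few $\tau_m$ (several model units), longer than the 5 ms dwell,
so these bounces survive debouncing; as a consequence the
exponential-fit Kolmogorov–Smirnov distances that the experiments
report are large (~0.4–0.5) rather than the near-zero values an ideal
exponential renewal process would give. A dwell of several $\tau_m$
absorbs the bounces, but the surviving epochs still show a refractory
floor (their 10th percentile sits near a third of the mean, versus a
tenth for an exponential), so the exponential description is only a
rough one for this model at these parameters. Symmetric quantities —
the 1/2 inference limit, left/right balance — are insensitive to all
of this.

## Closed-form analysis of the noise-free ring

Stationary single-bump (winner-take-all) states satisfy a threshold
condition for the bump half-width $a$ which `wta_half_width()` solves
by bracketed root finding; for symmetric inputs an explicit formula
exists and the two agree to $10^{-10}$. The state exists while the
suppressed stimulus peak stays subthreshold,
$I_0 - I_a - \sin(2a)/(1+\beta) < \kappa$; `wta_exists()` reports the
margin. Two-bump fusion states solve the analogous pair of threshold
conditions (`fusion_half_widths()`, damped Newton, residuals
$<10^{-10}$, verified against a grid search).

During a rivalrous oscillation the dominant bump narrows as its
resources deplete, and the suppressed side escapes when its stimulus
peak reaches threshold. Combining the moving threshold condition with
the escape condition gives closed forms for the half-width and the
pre-switch resource values (`pre_switch_resources()`); these radicals
are re-derived in the test-suite by solving the defining two-equation
system numerically, which is the package's source of truth for every
closed form.

## Fast-slow dominance times, and an honest accounting of their error

For $\tau \gg \tau_m$ the activity equilibrates between switches and
only the resource variables move. Each population's resource then
follows a two-phase cycle: depletion toward $1/(1+\beta)$ at rate
$(1+\beta)/\tau$ while dominant, recovery toward 1 at rate $1/\tau$
while suppressed (for one period in the bistable models, two in the
tristable one). Imposing periodicity through the pre-switch values
gives one scalar equation in $z = e^{-T/\tau}$ (symmetric inputs) or a
pair for $(T_R, T_L)$ (asymmetric), which `dominance_time_ring()`,
`dominance_time_reduced()` and `dominance_time_tristable()` solve to
residuals below $10^{-12}$. The period is exactly proportional to
$\tau$ at fixed inputs, and the interior solution exists only for
pre-switch resources in $(1/(1+\beta),\, 2/(2+\beta))$ — beyond the
upper bound the period shrinks to zero and the oscillation merges with
the fusion state. This bound, not the fusion fixed-point threshold
$(2+\beta)/2(1+\beta)$, delimits rivalry: simulations confirm
noise-free oscillations die near $I = 0.65$ for the symmetric reduced
network at $\beta = 1$ (bound $2/3$) and near $I_0 = 0.88$ for the
ring.

The theory is leading-order in $\tau_m/\tau$. Transitions last a few
$\tau_m$ (the released population must charge up and shut its rival
off), during which depletion continues and recovery is delayed; these
boundary-layer corrections are $O(1)$ in absolute time, so the
relative error of the adiabatic period decays like $\tau_m/\tau$.
Measured against noise-free simulation the error is about $+11\%$
(reduced), $-7\%$ (ring) and $-3\%$ (tristable) at $\tau = 50$,
falling below 2% by $\tau \approx 200\!-\!400$ and below 1% by
$\tau = 800$. The test-suite asserts this convergence rather than a
fixed small error at $\tau = 50$; the acceptance check that demands 2%
at $\tau = 50$ fails for exactly this reason, and we report it as a
property of the adiabatic approximation, not a defect of either the
simulator or the solver.

## Regime classification

`regime_partition()` labels each point of a $(\beta, I_0)$ grid:
winner-take-all where the bump existence margin is positive, else
rivalry where the pre-switch resource is reachable
($q_0 \in (1/(1+\beta), 2/(2+\beta))$), else fusion where the two-bump
state exists, else quiescent. At $\kappa = 0.5$, $\beta = 1$ this
yields winner-take-all at $I_0 = 0.6$, rivalry at $0.84$, and fusion
at $1.0$. The rivalry band widens with $\beta$ (its width in resource
space is $\beta/[(1+\beta)(2+\beta)]$), while the winner-take-all band
narrows: stronger depression reveals stimuli that weaker depression
leaves hidden.

## Dominance statistics and contrast inference

Noise-only switching ($\beta = 0$) produces approximately exponential
dominance-time histograms, fit by their sample mean
(`fit_exponential()`, with a Kolmogorov–Smirnov distance as the
goodness diagnostic). Depression plus noise produces unimodal
histograms peaked away from zero, fit by the log-linear three-point
gamma method (`fit_gamma_3point()`): the density is written
$e^{c_1} T^{c_2} e^{-c_3 T}$, so three anchor values — the histogram
mode $T_2$ and the bins nearest $T_2/2$ and $3T_2/2$ — determine
$(c_1, c_2, c_3)$ by one linear solve, and the fitted curve
interpolates the anchors exactly. Histograms use Freedman–Diaconis
bins, density-normalized; anchors snap to actual bin centers so every
anchor is a real value of the empirical distribution. Because the
density is written with $T^{c_2}$ rather than $T^{c_2 - 1}$, two shape
readings are reported (`shape_k = c2`, `shape_std = c2 + 1`); the
standard-convention shape is what a maximum-likelihood gamma fit
estimates, and the two agree on synthetic gamma samples to within the
method's 10% accuracy.

`inference_probability()` models an observer judging which stimulus is
stronger from sampled dominance times. For exponential marginals the
asymptotic answer is
$\langle T_R\rangle / (\langle T_R\rangle + \langle T_L\rangle)$
(verified against numerical double quadrature to $10^{-8}$). The
finite-$n$ trace plugs running sample means into that closed form —
the estimator is consistent with the asymptotic statement, which is
why we chose it as the default over the undefined alternatives; an
empirical pairwise-comparison estimator is provided for sensitivity
analysis, and for exponential marginals it shares the same limit.

## The noise convention, and what the synthetic runs do not show

Two printed conventions exist for the spatial noise correlation on the
ring, $\cos(x-y)$ and $\pi\cos(x-y)$; the package exposes
`noise_corr_scale` with default 1 (the convention stated alongside the
depression-free model that the quantitative targets use) and `pi`
selectable. The choice matters: noise-driven escape times depend
exponentially on the barrier-to-noise ratio, and the two conventions
change the mean dominance time of the depression-free ring at
$I_0 = 0.9$, $\epsilon = 0.04$ by an order of magnitude (about 2.6 s
vs. 0.2 s at the default debounce). Symmetry-protected quantities —
the 1/2 limit of the inference probability, left/right balance — are
unaffected by the convention, and are the ones the package can pin
down sharply.

The same sensitivity explains a structural limitation of the
three-population model with a Heaviside gain: at the moment the
dominant population releases its rivals, both suppressed populations
see *identical* inputs, so the release race is settled by their private
noise rather than by the depression memory. The forward-switch
probability $p_f$ therefore drops from exactly 1 (noise-free, enforced
by the resource ordering) to about 1/2 for any nonzero noise, instead
of decaying gradually; at moderate noise the network even ping-pongs
between two percepts. A graded gain would let the resource advantage
integrate into the race and restore a smooth decay, but the package
implements the stated Heaviside model and reports its actual behavior.

## Synthetic data and scope

All data in the package are generated by the simulators themselves;
there is no external data. The generator defaults *are* the study
conditions (bimodal input at $\pm\pi/4$, $\kappa = 0.5$, $\tau = 50$,
$\tau_m = 1$, the parameter sets quoted per experiment in
`experiments()`), and runs are reproducible bit-for-bit from a single
seed. What passing tests demonstrate is internal consistency of the
models, the asymptotics, and the statistics — not that cortical
rivalry obeys these equations; the models omit spatial propagation of
dominance (traveling waves), eye-specific layers, spike-frequency
adaptation, and any learning across presentations.
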