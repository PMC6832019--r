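---
title: "Regime shifts in a phage–bacterium ecosystem: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regime shifts in a phage–bacterium ecosystem: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phageshift)
```

## The model and its assumptions

`phageshift` studies the smallest phage–bacterium community that can hold
alternative stable states: two bacterial species ($B_1$, $B_2$) competing
for one limiting nutrient ($C$) under infection by one shared virulent
phage ($P$), in a well-mixed chemostat-like environment supplied with
nutrient at rate $\phi$:

$$\frac{dC}{dt} = \phi - \delta_C C - C\!\left(\frac{\lambda_1 B_1}{Y_1}
  + \frac{\lambda_2 B_2}{Y_2}\right), \qquad
\frac{dB_i}{dt} = B_i(\lambda_i C - \eta_i P - \delta_B),$$
$$\frac{dP}{dt} = P(\beta_1\eta_1 B_1 + \beta_2\eta_2 B_2 - \delta_P).$$

All quantities are dimensionless model units; no unit-conversion layer is
provided. The assumptions worth keeping in mind:

* **Mass action, no spatial structure.** Growth is linear in $C$,
  infection bilinear in $B_iP$; there is no latency, lysogeny, saturation
  (Monod) kinetics or spatial refuge.
* **Nutrient bookkeeping.** The consumption term is
  $\lambda_i C B_i / Y_i$: growth $\lambda_i C B_i$ divided by the yield.
  This is the only reading under which, with the reference parameters at
  $\phi = 0.25$, the $B_1$-dominated state has
  $C = 0.25/(0.2 + 0.5) = 0.357$, which the analytic and numerical
  modules both reproduce. With $Y_1 = Y_2 = 1$ (the defaults) the
  distinction is invisible anyway. A useful sanity check (tested): with
  $Y_i = 1$, no phage and no losses, $d(C+B_1+B_2)/dt = \phi$.
* **One phage, shared.** Resistance is partial and continuous through
  $\eta_i$; the special case $\beta_1 = 0,\ \eta_1 > 0$ describes a host
  that phage enter and kill without progeny (perfect abortive infection).
* **No evolution.** Parameter values are fixed; resistant mutants and
  arms-race dynamics are out of scope.

State vectors are ordered $(C, B_1, B_2, P)$ everywhere, including file
output.

## Parameters

`model_params()` bundles the eleven rate constants plus $\phi$. The
defaults (also shipped as the `fig1_defaults` YAML fixture so code and
file cannot drift apart) are the package's reference bistable set:
$\lambda_1 = 1$, $\lambda_2 = 0.8$, $Y_1 = Y_2 = 1$, $\eta_1 = 0.2$,
$\eta_2 = 0.15$, $\beta_1 = 2$, $\beta_2 = 40$,
$\delta_C = \delta_B = \delta_P = 0.2$, $\phi = 0.66$. The slow grower
pays an 20 % growth penalty and enjoys a 25 % lower adsorption rate but
carries a 20-fold larger burst size — the stoichiometric asymmetry
($Y_2\beta_2 \gg Y_1\beta_1$) that makes mutual exclusion possible.

Three inequalities classify the regime (`bistability_class()`):
$\lambda_1 > \lambda_2$ (species 1 wins pure nutrient competition),
$\lambda_1/\eta_1 < \lambda_2/\eta_2$ (species 1 is more susceptible per
unit growth), and $\lambda_1/(Y_1\beta_1\eta_1) >
\lambda_2/(Y_2\beta_2\eta_2)$ (species 2 produces more phage per unit
nutrient). All three give bistability; reversing the third turns the
coexistence point into a stable node (regime `stable_coexistence`). Zero
denominators ($\beta = 0$ or $\eta = 0$) are handled as infinite-ratio
comparisons, never division faults — with $\beta_1 = 0$ the third
inequality holds trivially and the upper window edge
$\phi^{(1)}$ is $+\infty$: the $B_1$-dominated state persists at every
supply rate.

## Closed-form analytics

Every species has a zero net growth isocline (ZNGI)
$\lambda C - \eta P = \delta_B$ in the $(C, P)$ environment plane.
`coexistence_point()` solves the $2\times 2$ linear system directly
(never a transcribed formula), giving $(C^*, P^*) = (1, 4)$ for the
defaults. From it, `phi_thresholds()` derives the four regime
boundaries

$$\phi_{B1} = \frac{\delta_C\delta_B}{\lambda_1}, \quad
\phi_{P1} = \phi_{B1}\left(1 + \frac{\delta_P}{\delta_C}
  \frac{\lambda_1}{Y_1\beta_1\eta_1}\right), \quad
\phi^{(i)} = C^*\delta_P\left(\frac{\lambda_i}{Y_i\beta_i\eta_i}
  + \frac{\delta_C}{\delta_P}\right),$$

equal to $0.04$, $0.14$, $\phi^{(1)} = 0.7$ and
$\phi^{(2)} = 17/75 \approx 0.2267$ for the defaults.
`steady_states()` enumerates, at any $\phi$, the uninvadable fixed
points — abiotic, $B_1$-only, $B_1$+phage (`F`), $B_2$+phage (`S`), the
saddle `U` at $(C^*, P^*)$ whose bacterial abundances interpolate
linearly between the window edges, and the stable coexistence state
where the regime admits one — each carrying the Jacobian eigenvalues and
a strict stability verdict (margin $10^{-9}$; marginal spectra are
flagged `NA`, never silently classified). Invadable single-species
states can be included with `include_invadable = TRUE` but are excluded
by default. In the `S`-state formulas the $B_2$ abundance is
$\delta_P/(\beta_2\eta_2)$ — phage balance pins the *resident host*, so
each species' abundance in "its" state involves its own $\beta\eta$
product ($B_2(S) = 0.2/6 = 0.0333$ for the defaults).

`jump_states()` gives the environment points landed on just past the two
ends of the hysteresis loop, e.g.
$C_{2x} = \phi^{(1)}/(\delta_C + \delta_P\lambda_2/(Y_2\beta_2\eta_2))
= 3.09$ and $P_{2x} = 15.14$ for the defaults.

## Deterministic integration and the influx floor

`integrate_model()` wraps `deSolve::ode` (lsoda) with the right-hand
side, analytic Jacobian and floor event compiled in C. Tolerances are
`rtol = 1e-8`, `atol = 1e-10` regardless of problem size, overridable
per call.

Real communities are never at exact zero: a weak influx keeps every
species present at trace level, ready to invade the moment its net
growth rate turns positive. The package emulates this with a **floor**:
at unit time intervals (`clamp_dt = 1`) an event clamps $B_1$, $B_2$,
$P$ up to $4\times10^{-4}$ ($C$ is only kept non-negative, never lifted).
Clamping at the reporting timescale, rather than adding a source term to
the equations, keeps the analytic steady states exact solutions of the
unmodified vector field; reported trajectories show the maintained
levels. The floor is ON by default everywhere (sweeps, pulse runs),
OFF only on explicit request (`floor = 0`).

Two consequences of the floor are worth knowing:

* The resident equilibria shift by $O(\text{floor} \times
  \text{amplification})$: with $B_2$ held at $4\times10^{-4}$, its phage
  production moves $B_1$ in the `F` state from $0.500$ to $\approx
  0.494$ (1.2 %). Classification (below) tolerates this.
* Near a regime boundary, a floor-held species invades at a per-capita
  rate proportional to the distance from the boundary — *critical
  slowing down*. A fixed relaxation time would drag every detected
  transition past its true location. `relax_state()` (used by sweeps and
  pulse runs) therefore extends integration in `t_relax` chunks, up to
  `extend` $\times$ `t_relax`, while a floor-held species has positive
  per-capita growth or the off-floor residual exceeds $10^{-6}$. With
  the default `extend = 10` the upward regime shift is detected at
  $\phi = 0.705 \pm 0.005$ and the downward one at $0.225$, both within
  one grid step of the analytic $\phi^{(1)} = 0.7$ and
  $\phi^{(2)} = 0.2267$.

## Classifying a final state

`classify_state()` compares a relaxed state against every analytic
steady state at that $\phi$. A species at or below twice the floor
counts as absent; a candidate disagreeing about which species are
present is rejected; otherwise the distance is the largest relative
deviation over present components, and the best candidate wins if it is
within `tol = 0.05` — far below the contrast between the alternative
states ($B_1$: 0.5 vs $B_2$: 0.033) yet roomy enough for the
floor-induced 1–2 % equilibrium shifts. Anything else is `OTHER`, which
legitimately occurs for states still in slow transit near thresholds
(e.g. within $\pm 0.02$ of the phage-onset boundary, where the
influx-maintained phage population is amplified and sits between
"absent" and its small equilibrium value).

## The stochastic simulator

`simulate_gillespie()` runs an exact stochastic simulation algorithm on
populations quantized in units of $\Delta$ (`quantum`, default
$2\times10^{-4}$). Nine elementary processes — nutrient supply and
dilution, two replications, two infections, three deaths — each fire
with propensity equal to the corresponding deterministic flux divided by
$\Delta$, and move the state by $\pm\Delta$ (an infection of species $i$
removes $\Delta$ of host and releases $\beta_i\Delta$ of phage; a
replication consumes $\Delta/Y$ of nutrient). Two identities pin the
construction down (both tested):

* **drift**: $\sum_k a_k(x)\,\Delta x_k = f(x)$ exactly, for every state
  $x$ — the mean dynamics are the ODE;
* **noise scale**: fluctuations shrink as $\sqrt{\Delta}$, so halving
  the quantum collapses the ensemble onto the deterministic flow.

The large burst size $\beta_2 = 40$ is the reason the quantum must be
small: one infection event moves $P$ by $40\Delta$. After every event,
species are clamped up to the floor ($4\times10^{-4} \ge \Delta$, so a
single death cannot cross zero). Waiting times and event choices draw
from R's global RNG (`unif_rand`/`exp_rand` in C), so `set.seed()` — or
the `seed` argument, recorded in the trajectory's attributes along with
per-process event counts — makes runs bitwise reproducible. At the
reference $\phi = 0.66$ the simulator exhibits spontaneous shifts
between the two alternative states within a few thousand time units
(the saddle sits close to the `F` state there, so demographic noise of
order $\sqrt{B_1/\Delta}$ quanta can carry the system across).

## Sweeps and pulse control

`sweep_phi()`/`hysteresis_loop()` implement the quasi-static protocol:
change $\phi$ in steps of $\Delta\phi = 0.01$, relax 1000 time units per
step (with the extension rule above) warm-starting from the previous
endpoint, classify, and record label changes as jumps at grid-interval
midpoints — never interpolated below the grid resolution. The loop also
reports the phage-onset supply rate as the point where the standing
phage population first exceeds $10\times$ the floor, which is sharper
than label changes in the slowly-developing onset region.

`apply_pulse()`/`pulse_scan()` implement impulsive control: start at an
exact stable state (absent species at the floor), add a one-time amount
of one variable, relax 1000 time units with the floor on, classify.
Magnitudes are expressed as multiples of the perturbed variable's value
in the *target* state at the same $\phi$ (`normalize = "target"`;
`"raw"` is available). Default scan grids are 200 log-spaced magnitudes
and $\Delta\phi = 0.01$ across the bistable window;
`switching_boundary()` then reports the extreme $\phi$ whose column
contains a switching cell, resolved to one grid step. Findings with the
reference set:

* $B_1$ pulses into `S` switch only for $\phi \le 0.46$ when magnitudes
  are capped at $2\times$ the target abundance; with larger pulses the
  region stretches slightly (to $\sim 0.50$ at $4\times$) and the
  success region is *reentrant* — at $\phi = 0.40$, pulses of
  $0.9$–$5.2\times$ succeed but larger ones fail again, because an
  oversized $B_1$ addition crashes the nutrient and feeds a phage
  rebound that restores `S`. The reentrance only becomes visible above
  $\approx 3.9\times$, so the dedicated check scans magnitudes up to
  $10\times$.
* $P$ pulses into `F` switch for $\phi \gtrsim 0.31$–$0.32$ up to the
  window edge at $0.70$. This lower boundary is sensitive to the floor
  protocol (clamping at $4\times10^{-3}$ instead of $4\times10^{-4}$
  moves it to $0.28$): the decisive factor is how deep $B_1$ may crash,
  relative to $B_2$'s refuge level, during the transient high-phage
  phase. It is the one quantity in the package whose value depends
  materially on the floor implementation; the clamp level itself is
  part of the study conditions and is not tuned.
* At $\phi = 0.25$, just above the window's lower edge, no single pulse
  of $C$, $P$ or $B_2$ (up to $3\times$ target values) switches `F` to
  `S`: the saddle's $B_1$ coordinate ($0.0246$) is far below $B_1$'s
  starting value ($0.5$), and no single-variable displacement crosses
  the basin boundary.

`combined_pulse()` applies several pulses at once. Its motivating use is
the therapy scenario under perfect abortive infection
($\beta_1 = 0$): phage cannot persist on the defended resident alone
($\phi_{P1} = \phi^{(1)} = \infty$), $B_2$-only pulses collapse after a
transient phage flare, and moderate $P$-only pulses fail — but phage
*plus* the susceptible competitor together establish `S` for
$\phi > \phi^{(2)}$ at doses where either alone fails.
`place_state()` supports the full-state control variant: set all four
variables just saddle-ward of the target and the system completes the
shift on its own.

## Numerical choices, degenerate inputs, tie-breaks

* Parallel ZNGIs ($\lambda_1\eta_2 = \lambda_2\eta_1$) raise a
  degenerate-geometry error; an intersection outside the positive
  quadrant reports "no positive coexistence point" and leaves
  $\phi^{(1,2)}$ undefined (`NA` with a note, never silent `NaN`).
* Stability is decided strictly: $\max\mathrm{Re}\,\lambda < -10^{-9}$
  stable, $> 10^{-9}$ unstable, otherwise marginal (`NA`).
* Saddle states are returned only strictly inside the bistable window;
  at the edges they merge with a resident state.
* Event times for the floor are output times, so seeded runs write
  byte-identical tables (`write_table()` fixes 12 significant digits).

## What the tests do and do not show

The test suite (and `scripts/acceptance.R`) works entirely at the
reference parameter set and at randomized parameter sets drawn inside
the bistable cone (`random_bistable_params()`), with problem sizes
chosen for a desktop run: hysteresis at $\Delta\phi = 0.01$ with 1000
time units per step, pulse grids of $46 \times 120$–$200$ cells,
stochastic ensembles of 60–100 runs of 1–3000 time units. These verify
internal consistency (closed forms vs. simulation vs. stochastic drift)
and the package's quantitative claims under the model's own
assumptions. They do not validate the model against data: real
phage–bacterium communities have saturating uptake, latent periods,
spatial refuges, evolving resistance and more than one nutrient, any of
which can move — or remove — the bistable window.

## Known limitations

* Exactly two bacterial species and one phage; no general $n$-species
  ZNGI machinery.
* No event detection of shift times within a trajectory and no
  continuation-style bifurcation tracking (closed forms exist for every
  boundary).
* No tau-leaping: stochastic runs resolve every event, which is
  comfortable at the reference parameters (about $10^4$ events per time
  unit) but slow for much smaller quanta.
* The floor's clamp implementation is a modeling choice; quantities that
  hinge on sub-floor excursions (notably the lower $P$-pulse switching
  boundary) inherit an uncertainty of a few grid steps, as discussed
  above.
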