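---
title: "Methods: continuous logic modelling of chondrocyte mechano-inflammation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: continuous logic modelling of chondrocyte mechano-inflammation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondronet)
```

## The model and its assumptions

`chondronet` treats a signed directed interactome as a continuous
semi-quantitative logic model. Each node $n$ carries a normalized
activation $x_n \in [0,1]$, read as a relative protein concentration or
pathway activity. The incoming activating edges (weights $\alpha$) and
inhibiting edges (weights $\beta$) of a node are folded into one
normalized regulatory input $\omega_n \in [0,1]$:

$$
\omega_n \;=\;
\underbrace{\frac{1+\sum\alpha}{\sum\alpha}\,
\frac{\sum\alpha x^a}{1+\sum\alpha x^a}}_{\text{activator term}}
\cdot
\underbrace{\left(1-\frac{1+\sum\beta}{\sum\beta}\,
\frac{\sum\beta x^i}{1+\sum\beta x^i}\right)}_{\text{inhibitor term}}
$$

with the convention that a missing activator (or inhibitor) set replaces
its term by 1, and a node with no inputs at all gets $\omega = 0$. The node
then evolves as

$$
\frac{dx_n}{dt} = S(\omega_n) - \gamma_n x_n, \qquad
S(\omega) = \frac{e^{-h(\omega-\frac12)} - e^{h/2}}
{\left(1-e^{h/2}\right)\left(1+e^{-h(\omega-\frac12)}\right)},
$$

a sigmoid normalized so that $S(0)=0$, $S(0.5)=0.5$ and $S(1)=1$ for every
gain $h>0$ (the published rendering of this response function is
typographically corrupted; we adopt the normalization that matches its
three anchor properties, and assert them to machine precision in the test
suite). Modelling assumptions worth making explicit:

* **Saturating, not mass-action kinetics.** The $x/(1+x)$ terms impose
  Michaelis–Menten-like saturation without requiring rate constants; only
  network topology, signs and (optional) weights enter.
* **Multiplicative inhibition.** With both input types present, the
  inhibitor term multiplies the activator term, so a saturated inhibitor
  silences a node regardless of its activators. This is what makes the
  catabolic NF-κB state of the packaged network absorbing until its
  upstream drivers are removed.
* **Constitutive activity of inhibitor-only nodes.** A node whose only
  inputs are inhibitors has $\omega = 1$ when they are silent, i.e. it
  rests ON. The packaged network uses this deliberately for matrix
  components under protease control (fibronectin; growth factors under
  NF-κB control), which gives the unstimulated network a realistic
  anabolic resting tone.
* **Sustained stimuli are clamps.** An external condition is a node held
  at a fixed value for the whole integration; it is the only way to
  sustain activity against the decay term.

## Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| $h$ | sigmoid gain (dimensionless) | 10 | switch-like but smooth response; per-node configurable |
| $\gamma$ | decay rate (per time unit) | 1 | sets the time scale; with $\gamma \ge 1$, $[0,1]$ is invariant |
| $\alpha,\beta$ | edge weights (> 0) | 1 | the packaged curations are unweighted |
| `dt` | RK4 step (time units) | 0.01 | stable and cheap at $h=10$; halved once automatically if a step overshoots |
| `t_max` | horizon | 50 | an order of magnitude above the slowest observed relaxations |
| `convergence_tol` | max per-node $|dx/dt|$ | 1e-6 | declared steady only when sustained for 1 full time unit |
| `epsilon` | direction-call threshold | 0.05 | a 5-point change on a [0,1] scale is the smallest difference we treat as biology rather than numerics |

## The RGD conformational switch

Edges in this formalism normally cannot change sign. The integrins α5β1
and αVβ3, however, act as chondroprotective fibronectin receptors when RGD
peptide (a matrix degradation fragment) is scarce, and as catabolic
receptors when RGD binds them. `chondronet` models this with *switch
rules*: whenever the watch node (RGD) is strictly above its threshold
(0.5), the rule's modifications are applied to the base topology — the
integrin→actin edges flip from activating to inhibiting, the
fibronectin→integrin edges are removed, RGD becomes the integrins' driver,
and the RGD-bound integrins activate NF-κB. At or below the threshold the
base topology is restored exactly; the switch is memoryless (no
hysteresis), and `x = 0.5` itself is assigned to the unswitched branch.
The RGD→integrin and integrin→NF-κB additions go beyond the narrowest
reading of the switch (flip + removal only), but without them the flipped
inhibiting edges would originate from undriven integrins and high RGD
could never lower actin — the opposite of the documented biology.

During integration the switch state is re-evaluated once per step from the
step-start state and held fixed across the four Runge-Kutta sub-stages, so
no step ever mixes two topologies.

## Numerical choices

* **Integrator.** Classic fixed-step RK4 in compiled code; one sparse
  effective topology per switch-flag combination is prebuilt and selected
  by bitmask each step.
* **Boundedness.** With $\gamma \ge 1$ the field points inward at both
  boundaries, so trajectories stay in $[0,1]$ up to floating-point dust;
  excursions below $10^{-12}$ are clipped, anything larger triggers one
  retry at `dt/2` and then a hard numerical error.
* **Convergence vs. proximity.** Convergence is declared on the
  *derivative*, not on distance to the true fixed point; near a slow mode
  a `1e-6` derivative can still mean a `1e-5` distance. Where the test
  suite compares the integrator against the independent fixed-point oracle
  at `1e-6` per node, it therefore tightens `convergence_tol` to `1e-9`.
* **Oscillations.** If the horizon is reached without convergence and the
  trailing 10% of the run has per-node amplitude above `oscillation_tol`
  (`1e-3`), the run is flagged oscillating and reported as the
  time-average over that window — a deliberate fallback, since sustained
  oscillations (e.g. a three-node repressilator) have no steady state to
  report.
* **Initial state.** Unstated in the source material; the package default
  is all-zero, making the baseline the relaxation of the unstimulated
  network. For the packaged network this baseline is *not* trivial: its
  inhibitor-only nodes switch on and pull the anabolic module up.
* **Ties and degeneracies.** A constant node in the ANOVA (TSS = 0) is
  flagged degenerate with all importances 0 rather than dividing by zero;
  a saturated design (two categories with the full second-order model)
  reports exact importances with `NA` F statistics.

## Scenarios

Six built-in scenarios clamp their stimulus nodes at 1: PO (TRPV4 +
α5β1), INF (IL-1β, TNF-α, IL-6, IL-8, IL-17, IL-18), antiINF (TGF-β,
IGF1, IL-4, IL-13, IL-1Ra), HSC (PTCH), HC (PIEZO) and TS (αVβ5). Two
documented inconsistencies in the source literature are exposed as
variants rather than resolved: `TS_aVb3` (results prose names αVβ3 where
the scenario table names αVβ5) and `antiINF_prose` (IL-10 in place of
IL-13). The package follows the scenario table for the defaults.

## Sensitivity analysis

The built-in design crosses the six scenario categories at clamp levels
0, 0.5 and 1 ($3^6 = 729$ runs). Design decisions:

* **A level is a clamp**, held for the whole integration, for all levels
  including 0 — symmetric treatment keeps the design balanced and matches
  the clamp semantics of a sustained condition. The alternative reading
  (level as a free initial value) is available via
  `run_design(level_mode = "initial")`.
* **Baseline.** Every run starts from the catabolic steady state (the INF
  scenario's attractor), i.e. an osteoarthritic chondrocyte; the baseline
  supplies only the initial state, not persisting clamps.
* **Variance decomposition.** The printed partial-sum-of-squares formula
  in the source is not computable as written; the package implements the
  standard balanced-factorial decomposition from cell means (orthogonal,
  order-free), with main effects and two-way interactions, everything else
  pooled into error. The identity $\sum \mathrm{PSS} + \mathrm{error} =
  \mathrm{TSS}$ is asserted on every node of a real 729-run batch, and the
  per-effect sums of squares are cross-checked against `stats::aov` as an
  independent oracle on small designs.
* **Excluded pairs.** The physiologically meaningless mechanical pairs
  HSC:TS, HC:HSC and TS:HC are pooled into the error term (not dropped
  from the run set), keeping the decomposition identity intact.
* **Inference.** Per-effect F tests at α = 0.05 against the pooled error,
  no multiple-testing correction; importance $I = \mathrm{PSS}/\mathrm{TSS}
  \times 100$ with a sign from the extreme-level contrast.

## Validation harness

The harness clamps one mechanosensor at a time at 1, compares each
annotated target against the unclamped baseline with the `epsilon = 0.05`
direction threshold (recorded in the report), and scores the fraction of
replicated responses. Checks whose nodes do not resolve are reported
*unevaluable* and excluded from the denominator — never silently passed.
A "down" expectation is only observable if the target is active at
baseline; the `validation_demo` motif therefore gives its down-target an
inhibitor-only input (constitutively ON), providing a 100%-accuracy ground
truth by construction, and the packaged reduced network's report must be
read with its resting state in mind (below).

## What the packaged synthetic data emulates — and what it does not

**Reduced network** (`load_reduced_network()`, 52 nodes / 85 edges / 2
switch rules). A stand-in for the full curated 118-node / 358-edge
interactome, which exists only in supplementary material that is not
shipped; `load_curated_network()` fails with an explicit pointer here. The
reduced wiring is assembled strictly from pathway statements: the
α5β1→SP→IL-4 homeostatic axis; TRPV4/PIEZO calcium signalling;
PIEZO-driven ROS and actin depolymerization; the
fibronectin–integrin–actin module with the RGD switch; the NF-κB core with
cytokine feedback; Wnt/β-catenin and TLR inputs; hedgehog and PTHrP
routes; and proteases that degrade Agg/COL2-α/fibronectin and release RGD.
It reproduces the headline behaviours: an anabolic attractor under PO, a
catabolic attractor under INF/HC/TS in which the RGD switch ignites and
locks the system, and inflammation as the dominant factorial driver of the
degrading enzymes.

It does **not** reproduce the curated network's validation profile. Its
resting state is saturated (anabolic side at ceiling, catabolic side at
floor), so of the 17 packaged literature checks only the seven structural
ones replicate (41.18% with default settings); responses that need an
intermediate baseline (e.g. TRPV4 lowering basal NO or IL-1β) read as
"unchanged". The published 94.12% figure belongs to the curated network
and stays untestable until that asset can be transcribed; the
corresponding acceptance tests are deliberately left red rather than
tuned. A green test on the reduced network therefore establishes engine
and harness correctness, not biological completeness of the stand-in.

**Random networks** (`make_random_network()`) are simple signed digraphs,
uniform over ordered pairs with a fixed inhibitor fraction, generated as a
pure function of their seed. They are property-test substrates
(boundedness, monotonicity, oracle agreement, serialization round-trips),
not null models: no degree heterogeneity, no motif enrichment.

## Verification strategy

Every steady-state claim is dual-routed: the RK4 integrator against an
independent damped fixed-point iteration (`fixed_point_oracle()`, residual
`1e-9`), plus an explicit-Euler consistency check at `dt/100` on the
analytic motifs, whose fixed points are also known in closed form
($x^\* = S(2c/(1+c))$ for a clamped single activator, etc.). ANOVA partial
sums of squares are cross-checked against `stats::aov`. The acceptance
tests additionally sweep 25 random 20-node networks and 1000 randomized
property draws.

## Known limitations

* No dose–response mapping from physical load magnitude/frequency to
  partial receptor activation; a load regime is all-or-none via its
  mechanoreceptor clamp.
* No stochasticity, delays, or spatial/tissue-level coupling.
* Weights, gains and decay rates are uniform in the packaged assets; the
  engine supports per-node/per-edge values but no fitting procedure is
  provided.
* The reduced network is a pedagogical stand-in: directional conclusions
  transfer, absolute steady-state values and the validation accuracy do
  not.
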