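---
title: "Simulating object recognition with the SOP opponent-process model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating object recognition with the SOP opponent-process model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soprec)
```

## The model

`soprec` simulates recognition-memory procedures with Wagner's Standard
Operating Procedures (SOP) theory of stimulus processing.  Every stimulus —
an object, or an arena location treated as a context — is a pool of
representational elements distributed over three states: inactive (I),
primary activity (A1), and secondary, refractory activity (A2).  Primary
activity drives vigorous responding (exploration); secondary activity
encodes recency and expectancy and blocks re-entry into A1.  The state
proportions of node $i$ obey

$$ I_i(t) + A1_i(t) + A2_i(t) = 1, \qquad I_i(0) = 1, $$

$$
\frac{dI_i}{dt} = pd2_i\,A2_i - (p1_i + p2_i)\,I_i,\quad
\frac{dA1_i}{dt} = p1_i\,I_i - pd1_i\,A1_i,\quad
\frac{dA2_i}{dt} = pd1_i\,A1_i + p2_i\,I_i - pd2_i\,A2_i,
$$

where $p1_i$ is nonzero only while the stimulus is presented, and $pd1$ and
$pd2$ are stimulus-independent decay rates.  Context-to-object links carry
separate excitatory and inhibitory accumulators,

$$ \frac{dV^+_{x\text{-}P}}{dt} = L^+ A1_x A1_P, \qquad
   \frac{dV^-_{x\text{-}P}}{dt} = L^- A1_x A2_P, \qquad
   V_{x\text{-}P} = V^+_{x\text{-}P} - V^-_{x\text{-}P}, $$

and an object's associative promotion probability aggregates over its
linked contexts with truncation to the unit interval,

$$ p2_P = \min\!\Big(1, \max\big(0, \textstyle\sum_{c} A1_c V_{c\text{-}P}\big)\Big). $$

Contexts never receive associative input ($p2 \equiv 0$ for context nodes),
links are unidirectional (context to object only), and object-to-object
links are deliberately excluded.  Two priming routes fall out of these
dynamics: *self-generated priming* (residual A2 from the object's own
recent presentation) and *associatively generated priming* (promotion of
object elements from I to A2 by an active, associated context).  Both
reduce the object's peak A1 at test, the model's proxy for exploration
time.

## Parameters and their defaults

| parameter | meaning | default | unit |
|---|---|---|---|
| `p1_object` | salience of objects | 0.75 | per step |
| `p1_context` | salience of contexts | 0.25 | per step |
| `pd1` | A1 → A2 decay | 0.1 | per step |
| `pd2` | A2 → I decay | 0.02 | per step |
| `l_plus` | excitatory learning rate $L^+$ | 0.25 | per step |
| `l_minus` | inhibitory learning rate $L^-$ | 0.025 | per step |
| `dt_seconds` | wall-clock seconds per step | 3 | s |

The defaults embody three ordered assumptions: objects are more salient
than contexts; secondary activity outlasts primary activity
(`pd2 < pd1`), which is what makes priming possible at all; and excitatory
learning dominates inhibitory learning 10:1, so net context-object
associations are excitatory under ordinary schedules.  `l_plus` is large
because recognition procedures demand single-trial learning.

**Time units.** All rates are expressed per internal time unit, one
integration step, with 3 s of wall-clock time per step (so 1 min = 20
steps).  Durations in the schedule builders are given in minutes and
converted by `min_to_steps()`.  Under this convention self-priming has a
half-life of roughly 1.7 min (`pd2 = 0.02`) and has dissipated completely
within a couple of hours, which is the regime the simulated delay
manipulations (5 min vs. 120 min) probe.  The conversion constant is a
single parameter, so a different calibration is one line away.

## Schedules

A schedule (`sop_schedule()`) is a set of timed on/off events over a fixed
node table, plus per-object test windows and contrast definitions.  Two
families of presets are provided.

**Empirical presets** (`empirical_preset()`) emulate four published
procedures.  Contexts tile each sample/test phase in equal shares, and each
object occupies the final half of its context window — locations are
encountered before the objects they contain.  Habituation is a context-only
block presented once, in fixed ascending order, before the first sample;
inter-phase intervals (ISI, RI) have all stimuli off (the animal is out of
the arena).  Counterbalancing enumerates the full Cartesian product of
context orders over the permuted phases — e.g. 4! × 4! × 4! = 13,824
variants for the combined recency/displacement battery — and reports means
plus the max–min spread across variants.  Timings that fall between grid
steps (0.625-min object windows are 12.5 steps) are snapped to the nearest
step, rounding half up.

**Conceptual presets** (`conceptual_preset()`) isolate the mechanisms on a
single timeline — sample, ISI, sample, RI, test (5-min phases, 2-min
intervals by default) — with four canonical conditions: *novel* (test
only), *recent in-place* (sample 2, tested in the sampling context),
*remote in-place* (sample 1, same context), and *recent displaced*
(sample 2, tested in a different context).  Each task contrasts two
conditions: novel vs. recent in-place (SOR), remote vs. recent in-place
(RR), displaced vs. in-place (OIP).

Three design choices in the conceptual scheme were genuinely open and
deserve justification:

* **Per-condition runs.** Each condition is simulated independently over
  two shared context nodes.  A joint simulation in which several
  context+object pairs are concurrently active would let every active
  context associate with every active object symmetrically, which provably
  nulls the displacement contrast; independent condition runs keep context
  identity meaningful while sharing the timeline.
* **Half-window objects.** As in the empirical presets, the object occupies
  the final half of its phase, with the context alone in the first half.
  Under the alternative (object coextensive with the whole phase) the
  excitatory accumulators saturate — $p2$ clamps at 1 for any in-place
  object — and the recency and displacement contrasts collapse to a few
  percent, at odds with the robust contrasts the canonical parameter set is
  known to produce.  The half-window convention keeps the associative drive
  in its sensitive range.
* **Extinction in the remote condition.** Because both samples present the
  same context x, the remote object's context–object link accrues
  inhibitory strength during sample 2 (context A1 paired with the absent
  object's decaying A2), an extinction-like weakening that adds to the
  self-priming recency mechanism.

The y context appears only as the displaced condition's test context, so
in-place and displaced timelines are *identical* except for context
identity; with learning switched off their readouts are equal to the last
bit, and the displacement contrast is a pure measure of associative
priming.

## Numerical integration

The coupled node/link system is advanced by classic fixed-step fourth-order
Runge–Kutta with the on/off flags held constant within a step, in compiled
code, with a plain-R reference implementation (`engine = "r"`) that
reproduces the same arithmetic bit for bit.  For a node with no associative
input the system is linear within each constant-input segment, and
`closed_form_isolated_node()` provides the exact matrix-exponential
solution; the test suite sweeps random rates and random on/off profiles
against this oracle.

Accuracy at the 3-s step deserves honesty.  RK4's local truncation error is
of order $(\lambda h)^5/120$ per step: immediately after a stimulus switch
the state error is about $2\times10^{-3}$ at the canonical object salience,
and it decays along the contraction to below $10^{-6}$ within roughly two
minutes of constant input and to $10^{-10}$ over a phase.  Peak-A1 readouts
therefore carry errors of order $10^{-3}$ — negligible against the
contrasts of interest (order $10^{-1}$) and against every classification
threshold used downstream, but far from machine precision.  The oracle
tests assert the $10^{-6}$ bound at phase-scale segment boundaries, where
it genuinely holds.  After every step the integrator checks conservation
($|I+A1+A2-1| \le 10^{-9}$ per node); repairs are counted and warned about,
so the clamp doubles as an error detector.  In routine use it never fires.

## The observation model

Model activation is mapped to observed exploration seconds by a single
global scaling, $\hat y_i = k\,\widehat{A1}_i$, fit by weighted least
squares through the origin,
$k = \sum_i w_i \widehat{A1}_i y_i \big/ \sum_i w_i \widehat{A1}_i^2$.
Raw weights are inverse variances of the reported means ($1/se_i^2$),
rescaled in two stages so that every (study, task) cell carries equal
weight within its study and every study carries equal weight overall; at
the contrast level a battery's combined procedure splits its weight equally
across its three component contrasts.  Uncertainty in $k$ comes from an
*exact* study-level bootstrap: all $S^S$ ordered with-replacement resamples
of the $S$ studies are enumerated (256 for four studies), $k$ is refit on
each with weights re-normalized, and the 2.5/97.5 percentiles are reported.
Enumeration removes resampling noise, but with only four resampled units
the percentile interval still undercovers its nominal 95% level — replicated
synthetic experiments measure roughly 80% coverage — which is a property of
any bootstrap at $S = 4$, not of the enumeration.  Leave-one-study-out
refits quantify the influence of each study.

The studies behind the published comparisons report their means only in
figure-adapted form, so the package does not ship them as ground truth.
`generate_synthetic_studies()` instead emits study tables with *known*
scaling: it runs the conceptual presets at study-specific delays, scales
the resulting activations by a true $k$, adds Gaussian noise, and reports
standard errors commensurate with that noise.  Passing tests on these
fixtures demonstrate estimator correctness (exact recovery at zero noise,
agreement with a grid-search minimizer, CI behaviour under noise); they do
not validate the behavioural realism of any particular dataset, and
real studies add between-study heterogeneity — apparatus, scoring,
mutually exclusive choice tests — that a single linear scaling cannot
absorb.

## Sensitivity machinery

All three suites operate on the conceptual contrasts with
(pd1, pd2, $L^+$, $L^-$) free and the saliences fixed at canonical values.

**Parameter space partitioning** (`run_psp()`) samples the four parameters
log-uniformly over $[0.001, 1]$, classifies each task at each point as
*robust* ($\widehat{A1}_Q > (1+\varepsilon)\widehat{A1}_P$), *weak* (ordinal
relation only), or *fail* (relation violated, or both peaks at or below the
0.005 activity floor), with $\varepsilon \in \{0.05, 0.10, 0.15\}$, and
reports volume proportions with across-run standard deviations, geometric
summaries of the all-robust and selective-failure regions, and the
probabilities of the canonical constraints (pd1 > pd2, $L^+ > L^-$) within
them.  Volumes are plain Monte Carlo proportions in log-space measure.
Ties classify as fail — strict inequalities — which matters: whenever the
net association is non-positive, truncation makes the displaced and
in-place conditions *exactly* equal, and this tie mass is what builds the
large OIP failure volume.

**Sobol' decomposition** (`run_sobol()`) uses a Saltelli cross-sampling
design with $n_{base}(2k+2)$ evaluations over the log-transformed parameter
box, the Saltelli-2010 first-order estimator, the Jansen total-effect
estimator, and the closed-pair second-order estimator, with outputs centred
before the cross-products.  Bootstrap resampling of design rows gives CI
half-widths, and independent designs are averaged across runs.  The
estimators are validated against an additive function and the Ishigami
function, whose indices are known in closed form.  Defaults:
$n_{base} = 1024$, 3 runs, 500 bootstrap replicates.

**Local factorial** (`run_local_factorial()`) evaluates the contrast at the
16 corners of a $2^4$ design with log-symmetric ±10% perturbations
($\theta\,1.1^{\pm1}$), decomposes it by orthogonal ±1 coding (an effect is
the regression coefficient, i.e. half the high-minus-low difference — the
convention is stated because the alternative full-difference definition
doubles every effect; the variance shares are invariant to the choice),
scales effects by the canonical contrast, and reports terms with at least
1% of the local sum of squares, plus the minimum corner ratio
$\widehat{A1}_Q/\widehat{A1}_P$.

Problem sizes used by the shipped tests and the acceptance script — 20,000
PSP points × 5 runs, $n_{base} = 1024$ × 3 runs — were chosen so that the
Monte Carlo standard errors (a few tenths of a percentage point for PSP
volumes, a few hundredths for Sobol' indices) are small against the
tolerances of the quantities being checked.

## Known limitations

* The simulator is deterministic: no trial-level stochasticity, subject
  variability, or coupling of exposure duration to ongoing activation.
  Outputs are expected values.
* Capacity-limited processing under distractor load (decay inflation by
  total A1+A2), arousal modulation, and object-to-object associations are
  out of scope.
* Order variability across counterbalanced permutations is reported as a
  spread but can be substantial for individual objects (an object tested
  2.5 min later in the test phase benefits from extra self-priming decay);
  only the averaged readouts are order-free.
* The activation-to-seconds map is linear and task-general by design;
  systematic residuals against any particular study are informative about
  that study's measurement model, not fittable here.
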