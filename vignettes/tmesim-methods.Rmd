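---
title: "Methods: cell-fate and 3D tumor-microenvironment simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-fate and 3D tumor-microenvironment simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmesim)
```

# Overview

`tmesim` models a cancer cell population at single-cell resolution through
three layers:

1. a **lineage layer**: trees of cells with timed fate events — bipolar
   division (BD), multipolar division (MD, three or more daughters), cell
   death (CD), cell fusion (CF) — plus an explicit `ALIVE_END` fate for
   cells censored by the end of observation;
2. an **expression layer**: α2-6-linked sialic acid abundance per cell,
   measured by SNA1 lectin fluorescence on the terminal cells and
   back-propagated up the tree;
3. a **spatial layer**: the deduced population placed in a 3D sphere among
   suppressive, permissive and lethal microenvironment agents that modify
   doubling times or kill cells.

This vignette documents the model assumptions, the tunable parameters and
their defaults, the numerical choices, and what the synthetic-data
generators do and do not emulate.

# The lineage data model

A `lineage_db` is a flat table, one row per cell, keyed by
`(lineage_id, cell_id)`. Parentage uses one id for division products and two
for fusion products. The validator enforces the event grammar: a BD cell has
exactly two daughter records, an MD cell exactly `md_poles >= 3`, CD and
`ALIVE_END` none; a CF cell is referenced by exactly one two-parent fusion
product and both fusion partners share the fusion time; every child is born
at its parent's fate time, progenitors at time 0. Because birth times
strictly increase along parent edges, these local checks already imply
acyclicity.

Times are minutes. Empirical databases are expected on a 10-min frame grid
(the `frame_interval` attribute); simulated databases carry continuous
times on the same scale. `ALIVE_END` is an explicit fate rather than a
missing value so that population curves can count censored cells through
the end of the window — a cell alive at the final frame is alive *at* it,
not gone.

# Lineage analytics

* **Population curves** count cells with `birth <= t < fate_time`
  (censored cells counted through the window end) and can be rescaled so
  the first time point equals a reference count such as 100.
* **Fate patterns** classify each MD/CF product by its own terminal fate
  ("CF > BD", "MD > CD", ...). Products still alive at the end count
  nothing: their fate is unknown, and putting them in denominators would
  understate every pattern share for long-lived products. This was a
  genuinely open choice; the package excludes them.
* **Doubling times** are intervals of cells both born from a BD and ending
  in a BD — the only unambiguous cycle measurement in this event grammar.
* **Per-lineage SNA1 summaries** use half-open bins: low < 2000,
  mid [2000, 4000), high ≥ 4000 total SNA1 units, matching the customary
  "<2000, 2000–3999, >4000" labels with both boundaries resolved upward.
* **MD-progeny**: a cell counts as reproductive MD-progeny when it is an MD
  product or descends from one and undergoes at least one BD.
  "Reproductive" has no standard operational definition; at least one
  bipolar division during observation is the weakest defensible reading.
  The fraction is taken over cells alive at the observation end.

# Expression back-propagation

Only terminal cells are stained, so internal values are reconstructed:
every dividing ancestor receives the arithmetic mean of its daughters'
(post-propagation) values. Two silent corners had to be decided:

* **Dead branches** contribute nothing — there is no terminal stain for a
  dead cell, and treating death as "expression 0" would conflate death with
  non-expression. Ancestors average over measured branches only.
* **Fusion products** propagate their value to *both* parents equally; the
  symmetric choice is the only one that does not invent an asymmetry the
  data cannot support.

The operation is idempotent, and on a fully measured balanced binary tree
the root equals the leaf mean — both are tested. The **expression list**
then pools the value of every cell of every generation, zeros included:
non-expressing cells are real members of the sampling pool, and dropping
them would bias assigned expression upward.

# The event-transition model

For each prior event (progenitor start, BD, MD, CF) the model stores the
multiset of observed `(next event, waiting time)` pairs. Generation
resamples these *jointly* rather than fitting a parametric law: joint
resampling preserves whatever association between event type and waiting
time the data contain, with zero extra assumptions.

Censoring is handled asymmetrically and deliberately. Roughly half the
cells of any observation-truncated tree are censored leaves, so `ALIVE_END`
observations are kept in the model (as a censored multiset) but excluded
from the transition probabilities; simulation reproduces censoring
naturally when a sampled event falls beyond the horizon. Folding
`ALIVE_END` into the probabilities would make a population that mostly
stalls after one generation.

Two fusion-specific corrections keep the fit → simulate → refit loop
self-consistent, both discovered by closing that loop on synthetic data:

* a fusion writes CF on **both** partners' records, so the per-cell CF
  frequency counts each event twice; the simulator therefore draws
  fusion *initiations* at half the cell-level rate and lets the recruited
  partner supply the other half;
* a recruited partner's recorded waiting time is truncated at the fusion
  clock, so recorded CF durations are contractions; the initiator's
  intrinsic wait is drawn from the prior's pooled duration multiset
  instead.

Without these, refitted CF probabilities land ~50 % above the generating
value; with them the loop recovers all transition probabilities within
binomial sampling error (tested at ≥ 2000 events).

# Deduced populations

`simulate_population()` starts `n_progenitors` (default 500) independent
lineages. Each progenitor draws its first `(event, duration)` pair and then
subtracts a uniform phase in `[0, duration)`, so the population starts
spread across the cell cycle rather than synchronized. MD arities are
resampled from the observed arities; a cell whose sampled fate is CF
recruits a co-resident cell of its own lineage as partner (the partner's
scheduled event is cancelled), and resamples its fate if no partner exists.
Everything is reproducible bit-for-bit from the seed.

**Expression assignment** happens at bipolar divisions. Each daughter is
gated on its own sampled waiting time: it may receive expression only if at
least one expressing source cell (sna1 > 0 after back-propagation) has a
BD-to-BD doubling time within ±10 % (`doubling_window`) of that waiting
time. The first passing daughter draws uniformly from the expression list;
a second passing daughter draws uniformly within ±15 % (`sibling_window`)
of its sibling's value. The gate encodes the empirical association between
expression and reproduction speed: if no expressing cell divides at that
tempo, the daughters stay unassigned. Two readings of the gate exist —
against *each* expressing cell (default, `gate_mode = "any"`) or against
their *average* doubling time (`gate_mode = "average"`); both are exposed.
Daughters of MD and fusion products are not assigned: the measured
association is defined on bipolar divisions only. `scale_expression()`
multiplies values by a chosen factor (1.5, 0.5, 0.25, ...) and caps at the
source maximum `v_max` — the cap keeps scaled populations inside the
empirically observed dynamic range.

# Landscape categorization

Per-case composition tables (one row per cancer case, one percentage column
per cell type, in the style of ConsensusTME deconvolution exports) reduce
to three fractions. The default map assigns CD4+/CD8+/γδ T cells, B cells,
plasma cells and monocytes to *suppressive*; M2 macrophages, regulatory
T cells, mast cells, endothelial cells and cancer-associated fibroblasts to
*permissive*; cytotoxic cells and NK cells to *lethal*. M1 macrophages and
neutrophils are recognized but excluded — their role is context-dependent
in both directions. Because deconvolution exports label types
inconsistently, the map is an editable data.frame and matching is performed
on normalized names; columns resolving to no entry are reported, never
silently dropped. Fractions are independent ratios to the cancer
population (they may sum above 1) and convert to agent counts by
`round(n_cancer × fraction)` — R's round-half-to-even; the reference
examples (45 % of 500 → 225; ratio 1:0.5 → 250) are exact under any
convention.

# The 3D TME engine

Defaults: sphere radius 50 px, search radius 6 px, daughter placement
radius 6 px, motility cap 2 px, timestep 10 min, horizon 6000 min.
Placement is i.i.d. uniform over the solid sphere (direction from a
normalized Gaussian triple, radius `R·U^(1/3)`), so radial distances follow
the CDF `(r/R)^3` — verified by a goodness-of-fit test at n = 10,000.

Anchors never move: the motility cap bounds *display* jitter only and does
not enter effect geometry. A cancer cell's two nearest agents within the
search radius are therefore constant for its whole lifetime, which has a
strong consequence: each cell's effect casework can be resolved **once**,
at the first timestep at which it is alive. For lethal effects this is the
stated once-per-(cell, agent) semantics — re-drawing a 100 % lethal setting
every 10 min would make any setting value effectively 100 %. For
suppressive/permissive effects the same argument applies to the resistance
draw, so a failed draw is not retried. Daughters get fresh positions within
6 px of the parent anchor (rejection-sampled into the sphere, 100 tries,
then projected radially inward) and are again eligible.

Resolution casework, given nearest agent 1 and second-nearest agent 2:

* 1 lethal: resistance draw, then `s_lethal`/100 draw; on success the cell
  dies at the current timestep and its entire subtree is removed.
* 1 suppressive, 2 not permissive: resistance draw; on success the cell's
  remaining wait and every descendant wait are multiplied by
  `1 + s_sup/100`.
* 1 permissive, 2 not suppressive: waits multiplied by `1 − s_perm/100`,
  floored at the shortest doubling time observed in the deduced population;
  no resistance draw — resistance protects against suppressive and lethal
  effects only.
* mixed pair: the nearer effect applies at the distance-weighted strength
  `max(0, s_near − s_second · d_near/d_second)` (50/50 at 3 px vs 6 px
  gives 25); the suppressive-nearest branch keeps its resistance draw.

A cell that received a suppressive or permissive modification receives no
second one in its lifetime; the inherited rescaling of its progeny does not
consume *their* eligibility. Resistance maps expression linearly to a fold
`1 + (R_max − 1)·e/e_max` and the effect succeeds with the reciprocal
probability; the linear map is anchored by the single fixed point available
(maximum expression at 5-fold resistance → 20 % hit chance) and is the
simplest interpolation through it.

Numerical details worth recording: rescaling recomputes the subtree
timeline top-down in original birth order, visiting fusion products once
even though they hang under two parents; if only one fusion partner lies in
a rescaled subtree the other partner's clock is re-synchronized so the pair
still fuses simultaneously. The permissive floor never *extends* a wait
that was already below it. If a lethal removal orphans a fusion partner
(its partner or product removed), the partner survives unfused to the
horizon. Waits pushed past the horizon leave the cell `ALIVE_END`; all
waits (not only division times) are rescaled, since a lineage timeline with
mixed scaled/unscaled intervals would be incoherent.

Sweeps enumerate the Cartesian grid of per-category ratios (1:0 … 1:1 at
0.1 gives 11³ = 1331 runs); each grid point derives its seed from the base
seed and its grid index, so results are independent of execution order.

# Synthetic data

The generators provide every input with known ground truth. Lineages are
generated by an event-driven branching process (independent of the deduced
population engine, so recovery tests have an external data source) with
log-normal waiting times — positive and right-skewed, the standard
phenomenology for cell-cycle durations. Defaults emulate an adherent cancer
line under long-term tracking: BD dominant (~94 %), MD/CD/CF rare, ~25 h
median cycle, about half the terminal cells expressing SNA1 with log-normal
values, and expressing cells' parental division intervals concentrated
within ±10 % of the mean interval (association strength 1 by default).
Landscape tables draw case compositions from Dirichlet-like gamma draws
over all mapped cell types plus the excluded M1/neutrophil columns.

What the generators do *not* emulate: measurement noise in fluorescence,
spatial correlation of fates within a colony, cell-type-specific MD arity
beyond a 3/4 mixture, or any real cell line's actual event rates. Passing
tests therefore demonstrate that the algorithms are correct and internally
consistent under realistic statistical structure — not that any particular
biological claim about a real line is reproduced.

# Problem sizes and verification

The test suite runs the oracle-equivalence checks on ≥ 100 fuzzed instances
per operation, parameter recovery at ≥ 2000 completed events, and the
stochastic simulation properties (population monotone decreasing in lethal
load, monotone increasing in the expression scale factor under lethal
pressure at 5-fold resistance) as means over 20 seeds with 200-progenitor
populations and a 2800-min horizon — sizes chosen to make the Monte-Carlo
contrasts decisive at desk scale. Determinism is enforced end to end:
identical configuration and seed reproduce byte-identical databases,
traces, logs and CLI outputs.

# Known limitations

* No cell–cell mechanics, diffusion or cytokine fields; microenvironment
  influence is purely nearest-neighbor geometry on static anchors.
* The three-category abstraction ignores cell-type-specific effect sizes;
  strengths are user-set scalars.
* Fusion mechanics in simulation (partner recruitment among co-resident
  cells) are a modeling choice; tracked data do not constrain them.
* Expression assignment treats the gate per daughter; a per-division-pair
  reading is equally defensible and would couple siblings more tightly.
* Back-propagation assumes expression is conserved through division in the
  mean; there is no model of expression drift over time.
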