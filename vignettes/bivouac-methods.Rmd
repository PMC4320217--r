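---
title: "Model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(bivouac)
```

`bivouac` is an agent-based lattice model of army-ant foraging: a colony of
Major and Minor ants searches a bounded grid for feeding spots, lays and
follows a two-layer pheromone field, and self-assembles *living bridges*
(chains of agents in an "Altruism" state) across ditches that no single ant
can cross.  This vignette documents the model equations, the geometric
conventions, and the interpretation decisions baked into the defaults, so
that every number the simulator produces can be traced to a definition.

## Lattice geometry and the Distance metric

Cells are 0-based `(x, y)` integer pairs on a bounded `width x height`
grid; the edges are impassable walls (no torus).  The lattice metric is the
Chebyshev distance, called *Distance* throughout: orthogonal **and**
diagonal neighbours are both 1 Distance away.

```{r}
chebyshev_distance(c(0, 0), c(1, 1))
```

Perception radii are fixed model constants: food and ditches are noticed
within 1 Distance, pheromone and other agents within 2 Distances
(`behavior_params()`).

## The default world

The standard arena is a 100 x 100 grid.  A rectangular nest sits at the
centre, fenced on the left, right and bottom by three ditches (*leftbar*,
*rightbar*, *centerbar*), each exactly 3 cells wide.  Bar corner
coordinates follow a half-open convention on the max edge: leftbar blocks
x in {30, 31, 32} and rightbar x in {70, 71, 72} over y in [30, 69], and
centerbar blocks y in {70, 71, 72} over x in [30, 72].

```{r}
env <- build_default_environment()
env
cell_class_counts(env)
```

The strip above the bars (y < 30) stays open.  This is deliberate: a lone
ant can reach any feeding area by a long detour around a ditch end, so a
living bridge is the *short cut* rather than the only route.  Restricted
to the side-barred rows (y in 30..69) the direct line is fully blocked —
those rows fall into exactly three parts — and restricted to the centre-bar
rows (y in 70..72) into exactly two.  `reachable_cells()` verifies both
facts by flood fill.

Three feeding spots surround the nest: A below the centre ditch, B beyond
the left ditch, C beyond the right ditch.  A spot is a rectangle holding an
integer stock of food units; any footprint cell yields food while stock
remains.

### Occupancy areas

Per-tick metrics count agents by *area*.  Area A is the bottom region
beyond the centre ditch, B the region left of the left ditch, C the region
right of the right ditch — and each area **includes the ditch band between
it and the nest**, so chain members assembled into a bridge count as
occupying the area they bridge toward (`default_areas()`).  The open strip
above the bars and the nest side itself belong to no area.

## Pheromone: a two-layer field

Pheromone lives in two layers (`pheromone_field()`).  Agents deposit on the
**ground** layer; each tick a fixed fraction evaporates into the **space**
layer, which diffuses, decays, and is the only layer agents perceive.

The space layer updates synchronously from the time-*t* snapshot, with
out-of-grid neighbours contributing zero:

$$s'(x, y) = r_A\, s + r_B \left(\textstyle\sum_{orth} s - 4 s\right)
           + r_C \left(\textstyle\sum_{diag} s - 4 s\right)$$

with defaults $r_A = 0.788$, $r_B = 0.043$, $r_C = 0.010$.  On a uniform
interior field the neighbour sums cancel and one step contracts the level
by exactly $r_A$.  The literal ("laplacian") form can drive edge cells
slightly negative; those are clipped to zero and counted.  A
"conservative" kernel variant drops the $-4s$ terms, which is exactly
mass-conserving in the interior because the defaults satisfy
$r_A + 4 r_B + 4 r_C = 1$.

The ground-to-space exchange is applied cellwise after diffusion:

$$s(t+1) = s'(t) + r_e\, g(t), \qquad g(t+1) = (1 - r_e)\, g(t)$$

with $r_e = 0.05$, so an untouched ground cell decays geometrically as
$(1-r_e)^t$.  After the exchange both layers are flushed: values below
`floor` (default $10^{-12}$) become exact zeros.  Exponential decay
otherwise leaves physically meaningless residues — eventually subnormal
doubles — on every cell ever touched, which both poisons floating-point
performance and lets agents "perceive" pheromone forever.  A unit deposit
falls below the default floor in about 115 ticks.

A deposit adds `deposit_ground` (default 1) to the ground layer at the
agent's cell, halved (`diagonal_deposit_factor = 0.5`) when the agent moved
diagonally, reflecting that scattered pheromone diminishes on diagonal
steps.  Major ants deposit every tick; Minor ants deposit while carrying
food home.

```{r}
f <- point_mass_field(9, 9, c(4, 4), 1, layer = "ground")
f <- ground_space_exchange(f, pheromone_params())
total_pheromone(f)
```

## The agent state machine

Each ant is Major or Minor and occupies one of three states; one action is
taken per ant per tick, in a freshly shuffled order.

**Search.**  A Minor with food within 1 Distance takes one unit and
switches to Return.  Otherwise, if the chain-entry condition holds and an
unbridged ditch cell lies within 1 Distance, the ant steps onto it and
switches to Altruism; cells adjacent to an existing chain are preferred,
so chains grow contiguously.  Otherwise the ant moves: a Minor perceiving
any space pheromone within 2 Distances picks among free neighbour cells
with probability proportional to their space level
(`pheromone_guided_move()`); otherwise — and always for Majors — a random
direction is drawn in which the straight-ahead heading keeps weight 1 and
every other free direction weight `alpha` (default 0.5).  A fully
surrounded ant waits.

The default entry condition ("model 1") holds when another *walking* agent
is within 2 Distances.  Chain members do not count: bridges form under
traffic congestion, rather than every passer-by being absorbed by an
existing chain.  An alternative ("model 2") triggers on a space-pheromone
threshold instead.

**Return.**  A carrier standing on a nest cell delivers its unit and
returns to Search.  With a ditch within 1 Distance (or underfoot, on a
bridge) it takes the weighted random step so it can find and cross a
bridge; on open ground it takes the free neighbour cell that strictly
reduces the Chebyshev distance to the nest, ties broken uniformly.

**Altruism.**  Chains are the connected components (1-Distance adjacency)
of Altruism-state agents; the size $X_i$ of the chain containing agent $i$
drives its decisions (`rebuild_chains()`).  A member leaves when fewer
than `n` (default 2) other agents remain within 2 Distances, or with the
pheromone-coupled probability

$$P_1(X_i) = \frac{a}{1 + b X_i^2}, \qquad
  b = \min(\eta \log(s + 1) + \epsilon,\ 1)$$

evaluated at the member's own cell ($a = 0.4$, $\eta = \epsilon = 0.1$), so
chains on strong trails persist.  At $X_i = 0$ the probability is exactly
$a$.  A member with a walker standing on its back never leaves — otherwise
crossing ants would be stranded mid-ditch on a cell they cannot legally
occupy.  A leaver steps to a free non-ditch cell within 1 Distance; if
every such cell is taken it stays embedded.

Two reference aggregation models are provided for analysis alongside the
default rule: a saturating entry curve
$P_e(X) = C_{e0} + C_{e1} X / (C_{e2} + X)$ (`prob_enter_chain()`), and a
size-only exit curve $P_l(X) = C_{s0} + C_{s1} / (C_{s2} + X^{\nu})$
(`prob_leave_chain_lioni()`), selectable via
`behavior_params(leave_rule = "lioni")`.

```{r}
prob_leave_chain_pheromone(leave_model(), Xi = 0, space_level = 0)
prob_enter_chain(chain_entry_model(), Xi = 4)
prob_leave_chain_lioni(chain_exit_model(), Xi = 3)
```

A ditch cell is traversable by a walker only while a chain member bridges
it; a single walker may stand on top of a member (`is_traversable()`).

## Tick order and determinism

One `sim_step()` advances the clock, lets every agent act once in shuffled
order (deposits applied immediately), rebuilds chains, applies diffusion
and the ground-space exchange, and records a metrics row.

Scenario construction seeds R's RNG, and stepping consumes the global
stream, so a preset plus seed fully determines a run.  Two steppers are
provided: a compiled one (`engine = "cpp"`, the default) and a pure-R
reference (`engine = "r"`).  They share the same elementary draw
primitives and consume the random stream draw for draw, so both engines
produce **bit-identical trajectories** for the same seed — the R stepper
is the readable specification, the compiled one the fast implementation,
and the test suite holds them to exact agreement.

```{r}
st <- corridor_world(16, n_minor = 6, seed = 7)
for (i in 1:50) sim_step(st)
st
```

## Scenarios and metrics

`scenario_presets()` lists the eight standard scenarios: series 1 uses
3 Major + 100 Minor ants, series 2 uses 3 Major + 50 Minor, with A:B:C
food ratios 2:1:1, 1:2:1, 1:1:2 and 4:2:1.  `make_scenario()` sizes each
spot as `base_food_units` times its ratio component and places all ants on
random nest cells.

```{r}
scenario_presets()
```

Each tick records agents per area, per-spot food, units carried and
delivered, chain statistics, and whether each ditch is actively bridged —
`bridge_active()` requires a connected chain whose endpoints let a walker
enter and leave on opposite sides of the ditch.  `depletion_order()`
summarises a run by the order in which spots were exhausted;
`detect_groups()` reports spatial clusters of agents outside the nest
(connected components at radius 2, clusters of 10 or more by default),
and `sweep_agents()` aggregates those statistics over colony sizes and
trials.

```{r}
st <- make_scenario("Env 2-1", seed = 1, base_food_units = 2)
run <- sim_run(st, max_ticks = 400, stop_when_done = FALSE)
tail(run$metrics[, c("tick", "n_A", "n_B", "n_C", "n_nest", "n_other",
                     "delivered", "ants_in_chains")], 3)
```

## Qualitative behaviours and scaled test problems

Three qualitative signatures characterise the model, and the package's
test suite checks them on deliberately scaled-down problems whose sizes
were chosen by pilot runs *before* the tests were frozen:

* **Collective crossing.**  In a 5-cell-wide corridor bisected by a
  3-cell ditch (`corridor_world()`), a single ant can never reach the far
  side — the ditch spans the full width and a lone ant that hangs into it
  merely becomes a stranded chain of one — while a colony of 30 bridges
  it within a few dozen ticks.
* **Sequential depletion.**  With 50 Minor ants the colony cannot split:
  pheromone recruitment concentrates the search on one spot at a time, so
  spots deplete one after another rather than concurrently.  Scaled runs
  use `base_food_units = 3`.
* **Concurrent group search.**  With 100 Minor ants the colony divides:
  at some tick at least two areas simultaneously hold 10 or more agents
  (including bridge members fronting each area).  Scaled runs use
  `base_food_units = 5`.

## Files and reproduction

`sim_run()` returns per-tick metrics, the full event log of state
transitions, and a summary; `write_outputs()` writes them as
`metrics.csv`, `events.ndjson` and `summary.json`.  `make_config()` /
`read_config()` round-trip a complete scenario through an editable YAML
file, and `inst/cli/bivouac.R` exposes `run`, `sweep` and `make-config`
subcommands for the command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "bivouac.R", package = "bivouac"))')" \
  run --preset "Env 2-1" --seed 1 --ticks 2000 --out out/
```
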