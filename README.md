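# bivouac

An agent-based lattice simulator of army-ant foraging and living-bridge
self-assembly.  A colony of Major and Minor ants searches a bounded
100 × 100 grid for feeding spots, lays and follows a two-layer pheromone
field, and — when a 3-cell-wide ditch blocks the way — assembles *living
bridges*: chains of agents in an "Altruism" state that other ants walk
across.  A ditch no single ant can cross becomes passable to the colony.

The package provides:

* a deterministic simulation core with two interchangeable engines — a
  pure-R reference stepper and a compiled stepper that reproduces it
  **bit-for-bit** for the same seed;
* the standard arena (central nest fenced by three ditches, three feeding
  spots) plus eight preset scenarios over two colony sizes and four food
  ratios;
* a two-layer pheromone field (ground deposit, space diffusion with
  decay rates `r_A = 0.788`, `r_B = 0.043`, `r_C = 0.010`, ground→space
  exchange `r_e = 0.05`);
* chain entry/exit models, including the pheromone-coupled leave
  probability `P1(Xi) = a / (1 + b Xi^2)`;
* per-tick metrics (occupancy by area, food ledger, chain statistics,
  bridge detection), group detection, depletion-order analysis, colony-size
  sweeps, YAML scenario configs, CSV/NDJSON/JSON outputs and a small CLI.

See `vignette("bivouac-methods")` for the full model description.

## Quick start

A single ant can never cross a full-width ditch, but a small colony
bridges it in minutes of simulated time:

```r
library(bivouac)

st  <- corridor_world(16, n_minor = 20, seed = 7)   # 5x16 strip, 3-cell ditch
run <- sim_run(st, max_ticks = 400, stop_when_done = TRUE)
run$summary$stopped
#> [1] "all_food_delivered"
run$summary$ticks
#> [1] 109
```

The 20 ants formed a bridge and delivered all food across the ditch by
tick 109; with `n_minor = 1` the same run times out with nothing
delivered.

Preset scenarios reproduce the characteristic colony-level behaviours.
With a 50-Minor colony (series 2), pheromone recruitment focuses the
whole colony on one feeding spot at a time, so spots deplete
*sequentially*:

```r
st  <- make_scenario("Env 2-1", seed = 1, base_food_units = 1)
run <- sim_run(st, max_ticks = 8000, stop_when_done = TRUE)
run
#> <sim_run 'Env 2-1' seed 1: 7945 ticks (all_food_delivered), delivered 4/4 units>

depletion_order(run$metrics)
#> [1] "C" "A" "B"
#> attr(,"tick")
#> [1] 2782 5153 6034

tail(run$metrics[, c("tick", "n_A", "n_B", "n_C", "n_nest",
                     "delivered", "ants_in_chains")], 2)
#>      tick n_A n_B n_C n_nest delivered ants_in_chains
#> 7945 7944  10  11  27      3         3             42
#> 7946 7945  10  11  27      3         4             42
```

Spot C depleted first (tick 2782), then A, then B — one at a time.  The
100-Minor colonies of series 1 instead split into concurrent groups; see
the vignette.  Runs are fully reproducible: the preset name and seed
determine every trajectory, on either engine
(`make_scenario(..., engine = "r")` selects the reference stepper).

The eight presets:

```r
scenario_presets()
#>      name n_major n_minor ratio
#> 1 Env 1-1       3     100 2:1:1
#> 2 Env 1-2       3     100 1:2:1
#> ...
#> 8 Env 2-4       3      50 4:2:1
```

## Command line

```sh
BIVOUAC_CLI=$(Rscript -e 'cat(system.file("cli", "bivouac.R", package = "bivouac"))')
Rscript "$BIVOUAC_CLI" run --preset "Env 2-1" --seed 1 --ticks 2000 --out out/
Rscript "$BIVOUAC_CLI" sweep --agents 10,20,40 --trials 3 --out sweep/
Rscript "$BIVOUAC_CLI" make-config --preset "Env 1-3" --out scenario.yaml
```

`run` writes `metrics.csv` (per-tick metrics), `events.ndjson` (state
transitions) and `summary.json`.

## Testing

```r
testthat::test_dir("tests/testthat", package = "bivouac",
                   load_package = "installed")
```

The suite covers closed-form model values, diffusion against a per-cell
oracle, conservation laws over long runs, exact R/C++ engine agreement,
state-machine edge soundness, and stochastic acceptance checks of the
colony-level behaviours.
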