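# socfix

Exact fixation probabilities for producers of social goods in
graph-structured populations, at **arbitrary selection intensity**.

Most analytical results on the evolution of cooperation assume weak
selection, where payoffs barely perturb neutral drift. `socfix` is built for
the regime in between weak and strong selection, where the interplay of
drift and selection produces qualitatively new behavior — including a
"sweet spot" of intermediate selection intensities at which prosocial
traits spread even under global competition for reproduction (Birth-death
updating), a setting long considered hostile to altruism.

## The model

A population of `N` individuals occupies the nodes of a symmetric weighted
graph `(w_ij)`. Each individual is a producer `C` or a non-producer `D`.
Producers generate benefits at a personal cost under one of three goods
schemes (with `p_ij = w_ij / Σ_k w_ik` the one-step random-walk
probabilities):

| scheme | benefit | cost | payoffs |
|--------|---------|------|---------|
| `pp` | `b` to each neighbor | `c` per neighbor | deterministic |
| `ff` | `b` split as `b·p_ij` over neighbors | `c` total | deterministic |
| `cf` | all of `b` to one random neighbor (`~ p_ij`) | `c` total | stochastic |

`ff` is the mean field of `cf`: the expected cf payoff vector equals the ff
payoff vector in every configuration, yet outside weak selection the two
schemes evolve differently, because transition probabilities are
expectations of fecundity *ratios*, not ratios of expectations.

Payoff `u` maps to fecundity through `F(u) = exp(δu)` — the unique map
satisfying positivity, monotonicity, continuity, payoff scaling by the
selection intensity `δ`, and invariance of competition under a shared
payoff shift. Competition within any group `I` is the softmax
`F_i / Σ_{j∈I} F_j`, always computed in log space.

Two update rules are supported:

* **death-Birth (dB)** — a uniformly random individual dies; its neighbors
  compete for the vacancy proportionally to fecundity;
* **Birth-death (Bd)** — an individual reproduces proportionally to
  fecundity (global competition); its offspring replaces a random neighbor.

A rare mutant appears either uniformly (`1/N` per node) or by
**temperature initialization**, proportionally to each node's replacement
rate `d_i = Σ_j (F_j/Σ_k F_k) p_ji` in the resident monomorphic state. The
package computes the mean fixation probabilities `ρ_C`, `ρ_D` of either
mutant type exactly:

* reduced chains for the cycle under dB (cluster-size space `{0..N}`) and
  the star under Bd (hub-trait × leaf-count space `{0,1}×{0..N−1}`),
* a brute-force chain over all `2^N` configurations of any small graph
  (the lumping oracle),
* closed-form expressions for ff-goods on the star under Bd, evaluated in
  log space and `O(N)` per intensity — practical for `N` in the thousands,
* a Monte Carlo trajectory sampler as an independent stochastic check.

Selection verdicts at each `δ` come as four strict conditions: `A0`
(`ρ_C(δ) > ρ_C(0)`), `A'` (`ρ_C'(δ) > 0`), `R0` (`ρ_C(δ) > ρ_D(δ)`), and
`R'` (`ρ_C' ρ_D > ρ_C ρ_D'`, i.e. the fraction of time spent in the
all-producer state is locally increasing).

## Worked example

Producers of ff-goods on a star of `N = 10` under Bd updating with
temperature initialization (`b = 5`, `c = 1`):

```r
library(socfix)
mod <- social_model("star", "Bd", goods_scheme("ff", b = 5, c = 1), N = 10,
                    init = "temperature")
delta_sweep(mod, deltas = c(0.05, 0.5, 1, 2, 5), refine = FALSE)
#> sweep_result: 5 deltas on [0.05, 5], neutral rho_C = 0.0219512
#>   1 local maximum(a) of rho_C; global peak 0.0315945 at delta = 0.5
#>   delta        rho_C        rho_D ratio_to_neutral time_in_C
#> 1  0.05 1.658350e-02 1.123926e-01      0.755470690 0.1285781
#> 2  0.50 3.159447e-02 3.557479e-08      1.439303520 0.9999989
#> 3  1.00 1.776858e-02 4.445305e-16      0.809457329 1.0000000
#> 4  2.00 4.398388e-03 4.440892e-16      0.200371011 1.0000000
#> 5  5.00 4.189225e-05 4.440892e-16      0.001908425 1.0000000
```

Weak selection (`δ = 0.05`) *disfavors* producers — `ρ_C` is below its
neutral value `≈ 0.0220` and far below `ρ_D`. At
`δ ≈ 0.5` the sweet spot opens: `ρ_C` rises 44% above neutral while `ρ_D`
collapses, so the population spends essentially all its time in the
all-producer state (`time_in_C ≈ 1`). Very strong selection closes the
window again (`δ = 5`). (`ρ_D` values of order `1e-16` are at the
round-off floor of the linear solve: "zero for all practical purposes".)

The effect grows dramatically with population size. For `N = 2000` the
closed-form engine sweeps 400 intensities and refines the peaks in
seconds:

```r
big <- social_model("star", "Bd", goods_scheme("ff", 5, 1), N = 2000,
                    init = "temperature")
sweep <- delta_sweep(big)       # default dense grid, closed-form engine
attr(sweep, "maxima")
#>       delta        value refined
#> 1 0.9613475 6.948579e-05    TRUE
#> 2 2.0831976 4.435884e-05    TRUE
max(attr(sweep, "maxima")$value) / attr(sweep, "neutral_rho_C")
#> [1] 138.9021
```

Two distinct local maxima appear — the first attributable to mutants
arising at leaf nodes, the second to mutants arising at the hub — and at
its peak the fixation probability of a single producer is ~139-fold its
neutral value.

## Command line

A thin Rscript front end lives at `inst/cli/socfix` (installed under
`system.file("cli", "socfix", package = "socfix")`):

```sh
socfix star-bd --N 10 --scheme ff --b 5 --c 1 --init temperature \
       --delta-grid 1e-3,10,200 --out results/star --seed 1
socfix mc-check --structure cycle --rule dB --N 6 --scheme cf --b 4 --c 1 \
       --delta 1 --nrep 10000 --seed 1
```

Each run writes `<prefix>_sweep.csv`, `<prefix>_conditions.csv` and
`<prefix>_meta.json`. A YAML `--config` file may mirror any flag; explicit
flags win.

## Package layout

* `R/structures.R` — population graphs (cycle, star, file-backed general)
  and random-walk matrices
* `R/payoffs.R` — goods schemes, payoff distributions, exponential
  fecundity map, log-domain competition
* `R/kernels.R` — reduced and brute-force transition kernels
* `R/simulate.R` — Monte Carlo trajectory sampler
* `R/fixation.R` — linear solves, initialization, closed-form star
  expressions
* `R/metrics.R` — selection conditions, sweeps, peak detection, exports
* `R/cli.R`, `inst/cli/socfix` — command-line interface
* `vignettes/selection-intensity.Rmd` — the methods vignette
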