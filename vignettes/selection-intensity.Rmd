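---
title: "Fixation of social-goods producers at arbitrary selection intensity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation of social-goods producers at arbitrary selection intensity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socfix)
```

## The question

Does natural selection help or hinder the spread of a costly, prosocial
trait in a spatially structured population — and how does the answer
depend on *how strong* selection is? Weak-selection theory answers with
first-order expansions around neutral drift; `socfix` instead computes
fixation probabilities exactly at any selection intensity $\delta$, which
is where the interesting phenomena live: stochastic payoff schemes that
diverge from their mean-field twins, and intermediate-$\delta$ "sweet
spots" where producers thrive under update rules that disfavor them both
for weak and for strong selection.

## Model and assumptions

**Population structure.** Individuals occupy the nodes of a connected,
symmetric, non-negatively weighted graph with zero diagonal. Edges carry
both interactions (who benefits from whom) and dispersal (where offspring
go). Disconnected graphs are rejected outright: fixation of a single
lineage is not a well-posed event across components. The step matrix
$p_{ij} = w_{ij} / \sum_k w_{ik}$ is the package's single source of
"random neighbor" semantics.

**Traits and goods.** Each node is a producer (C) or non-producer (D).
Producers act; non-producers do nothing. The three accounting schemes —
`pp` (benefit and cost proportional to degree), `ff` (fixed total benefit
diffusely split), `cf` (fixed total benefit concentrated on one random
neighbor) — share the same benefit parameter $b \ge 0$ and cost
$c \ge 0$. cf payoffs are random; the package represents them as an
explicit finite distribution of payoff vectors (one scenario per joint
recipient assignment, merged when assignments yield identical payoffs).
The expected cf payoff vector equals the ff payoff vector exactly, on
every graph and configuration; this identity is enforced in the test
suite rather than assumed.

The original formulation of all three schemes is for unweighted graphs.
On weighted graphs this package *defines* ff-splitting as $b\,p_{ij}$ and
cf-recipient choice as a $p_{ij}$-draw, which reduces to "evenly" and
"uniformly" in the unweighted case. That generalization is a design
choice, not an established convention; results on weighted graphs should
be read with it in mind.

**From payoff to fecundity.** Fecundity is $F(u) = e^{\delta u}$. Under
the axioms of non-negativity, monotonicity, continuity, intensity-scaling
of payoffs, and invariance of competition under a common payoff shift,
the exponential map is the only choice (up to rescaling $\delta$, which is
why no extra slope parameter is exposed). Alternatives such as
$1 + \delta u$ coincide with it under weak selection but can go negative
— precisely the regime this package targets is where the choice matters.
Competition within any group is the softmax of $\delta u$, evaluated in
shifted-exponent form; the implementation contract is finite output for
$\delta\,|u|$ up to $10^4$, and shift invariance to $10^{-12}$.

If selection acts on survival instead of reproduction, the mirrored
axioms give the death weight $e^{-\delta u}$. This is exposed through
`fecundity_map(mode = "survival")` and honored by
`competition_probabilities()`, but the update-rule kernels are defined
for selection on reproduction only — a survival-mode Bd or dB chain would
require semantics (who dies, who then reproduces) that the reproduction
formulation does not determine, so the kernel constructors refuse rather
than guess. For the same reason, survival mode is not wired into
temperature initialization.

**Update rules and their chains.**

* *dB*: the dying node is uniform; its neighbors compete by fecundity.
  On the cycle, a mutant lineage started from one node stays a contiguous
  arc (a simulation-verified invariant in the tests), so the chain lumps
  to cluster sizes $\{0, \dots, N\}$. Transition probabilities follow
  from boundary competitions; at cluster sizes $1$ and $N-1$ the two
  boundaries share an individual, which the builder handles by treating
  each dying node individually rather than by a two-boundary formula.
  Payoffs are evaluated *before* the death: the dying individual still
  produces, and for cf goods its recipient choice is part of the
  per-step expectation.
* *Bd*: the reproducing node is chosen by fecundity over the whole
  population; its offspring replaces a $p_{ij}$-drawn neighbor. On the
  star the chain lumps to (hub trait, number of producer leaves).

For stochastic payoffs every transition probability is the expectation of
the competition *ratio* over cf scenarios — never the ratio of expected
fecundities. The expectation is taken per update step, matching
recipient choices that are redrawn each step. Exact cf enumeration is
kept tractable by a relevance filter: only producers adjacent to the
competing group can affect the competitors' payoffs, so only their
choices are enumerated (everyone else contributes diffuse expected
benefit, which is immaterial to the coordinates the competition reads).
Enumeration refuses beyond 20 multi-neighbor producers and points to the
Monte Carlo sampler.

`kernel_full()` builds the chain on all $2^N$ trait configurations of any
graph (capped at $N = 12$) directly from the update-rule definitions. It
is deliberately naive: its role is to be the oracle that the reduced
chains must lump onto exactly, which the acceptance suite verifies
entrywise to $10^{-10}$ for $N \in \{4,\dots,8\}$, all schemes,
$\delta \in \{0, 0.5, 2, 10\}$.

**Initialization.** Uniform initialization places the invading mutant at
each node with probability $1/N$. Temperature initialization ties mutant
appearance to reproduction: the mutant arises at node $i$ proportionally
to $i$'s replacement rate $d_i = \sum_j (F_j / \sum_k F_k)\, p_{ji}$ in
the resident monomorphic state. Under dB updating replacement is uniform
and the two modes coincide. On lumped state spaces, node masses aggregate
onto orbits (all leaf starts of a star onto the single leaf-start state).

**Quantifying selection.** At each $\delta$, four strict conditions
compare $\rho_C$ against its neutral value (`A0`), its local trend
(`A'`), against $\rho_D$ (`R0`), and against the trend of the
time-in-all-C share $\rho_C/(\rho_C+\rho_D)$ (`R'`). Derivatives are
central finite differences with step $\max(10^{-4}, 10^{-3}\delta)$
(one-sided at $\delta = 0$), with the step recorded in the report and an
error if it would cross zero. The conditions use zero tolerance, but raw
margins are reported so users can apply their own. At $\delta = 0$ the
two traits follow identical processes, so `A0` and `R0` are equalities
*by symmetry*; the implementation reports them as false directly instead
of comparing two round-off-sized numbers. `A'` and `R'` are genuine
one-sided derivative statements at $\delta = 0$ and may well be true
there (on the cycle under dB with $b/c$ above the degree, weak selection
does favor producers).

## Numerical choices

* **Linear solves.** Fixation probabilities solve
  $(I - P_{TT})\,\rho_T = P_{T,\mathrm{allC}}$ by direct factorization
  (sparse for the large star ladders, dense otherwise), with a hard
  residual gate $\|\rho - P\rho\|_\infty < 10^{-10}$ and a conditioning
  diagnostic on failure. Values are clipped to $[0,1]$ only after the
  residual check. At extreme intensities some fixation probabilities sit
  below the round-off floor ($\sim 10^{-16}$); they are exact zeros for
  every practical purpose, and the closed form below is the tool of
  choice when such tiny values matter.
* **Kernel hygiene.** Rows must sum to 1 within $10^{-10}$; entries may
  be clipped into $[0,1]$ only within $10^{-14}$ — anything larger is
  treated as a logic bug and raised, never silently repaired.
* **Closed form for the large star.** For ff-goods on the star under Bd,
  the fixation probabilities from the two single-producer states are
  explicit products and sums of conditioned transition probabilities.
  All terms are positive, so the $i$-sum of $j$-products is accumulated
  entirely in log space; the expressions stay finite for $N$ at least
  $5000$ and $\delta$ at least $50$. This engine is the default for star
  ff sweeps at $N > 200$ ($O(N)$ per intensity versus the solve's worst
  case $O(N^3)$), and it is verified against the linear solve to
  $10^{-9}$ at accessible sizes. The printed transcription of the
  conditioned-ratio term is validated by that oracle equivalence rather
  than trusted.
* **Grids and peaks.** Default sweep grids are log-spaced: 200 points on
  $[10^{-3}, 10]$ for $N \le 200$, 400 points on $[10^{-4}, 5]$ above
  (chosen to resolve the two peaks of large-star curves; user-overridable
  everywhere). Local maxima are interior points strictly above both
  neighbors, with ties within $10^{-14}$ merged as one plateau and
  endpoints never reported. Refinement runs golden-section search
  (`stats::optimize`) between the bracketing grid neighbors on the
  engine's value function, so refined peaks from the closed form are
  grid-independent.
* **Monte Carlo.** The sampler realizes the same update rules with
  concrete cf recipients drawn each step; it is seeded explicitly,
  reports censoring rather than dropping it, and is compared against the
  exact solver within three binomial standard errors at $10^4$ replicates
  in the acceptance suite. It is an independent check, never a fallback
  for the exact machinery.

## Problem sizes

The test and acceptance suites run exact kernels at $N \le 25$, the full
$2^N$ oracle at $N \le 8$, Monte Carlo at $N = 6$ with $10^4$ replicates
per case, and closed-form sweeps at $N = 2000$ (400 grid points). These
sizes make every exactness claim checkable in minutes while covering the
full qualitative repertoire: the cycle's stochastic/deterministic
divergence, the star's sweet spot, and the two-peak structure of large
stars.

## What the exact small-population results do and do not show

The cycle and the star are the two extremes of payoff accrual — perfectly
homogeneous versus maximally heterogeneous — and every quantitative claim
in the package is exact for them. They are reference points, not samples
of real networks: nothing here demonstrates how intermediate-intensity
effects scale on graphs with broad degree distributions, and the $2^N$
oracle caps general graphs at a dozen nodes. Metastable coexistence
(transient dynamics before absorption, which can be very long under
strong global competition), fixation times, mutation-selection balance
beyond the rare-mutation time-share ratio, directed or time-varying
graphs, and non-exponential (thresholded or concave) fecundity maps are
all out of scope.

## A known sharp edge

On the cycle, pp payoffs are exactly twice ff payoffs (every node has two
neighbors), so the pp model at intensity $\delta$ *is* the ff model at
$2\delta$ — the package's kernels reproduce this identity to machine
precision, and the test suite uses it. One consequence worth knowing: a
lone ff/pp non-producer among producers earns $b$ while its producing
rivals earn $b - c$, so at sufficiently strong selection non-producers
are again favored relative to producers ($\rho_D > \rho_C$ crosses over
near $\delta \approx 16$ for ff with $N = 10$, $b = 4$, $c = 1$, hence
$\delta \approx 8$ for pp). Statements like "producers are always favored
relative to non-producers" for these schemes are statements about
moderate intensity ranges, and the qualitative tests pin them to such
ranges explicitly.

## Session info

```{r}
sessionInfo()
```
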