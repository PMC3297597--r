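---
title: "Methods: the fearfulness-boldness simulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the fearfulness-boldness simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearbold)
```

## The model

`fearbold` simulates the evolutionary contest between two heritable pure
anti-predator strategies in a bird-like population: **fearfulness** (F) —
flee immediately at any threat, real predator attack or harmless
disturbance — and **boldness** (B) — stay alert and flee only once a
threat proves to be a real attack.  Fearful individuals survive attacks
more often but spend energy on every escape; bold individuals keep more
energy for reproduction but are easier to capture when a predator targets
them.  The population is asexual, of constant size $N$ at each
breeding-season start, with overlapping generations: individuals live at
most $A$ seasons, mature at age 1, and offspring inherit the mother's
phenotype exactly.

One breeding season consists of:

1. **$a$ sequential predator attacks.**  Each attack selects a phenotype
   group, then a victim uniformly within the group (the risk model is
   age-blind), then captures it with probability $p_F$ or $p_B$.  At most
   one individual dies per attack, and the selection probabilities of
   attack $k+1$ use the counts left after attack $k$.
2. **$d$ non-lethal disturbances.**  These kill nobody and are not
   simulated event-by-event; they enter only the energy accounting, because
   fearful individuals flee at them too.
3. **Reproduction, senescence, ageing.**  All deaths are replaced, so the
   season-to-season population size is exactly $N$.

### Risk sharing

The parameter $\beta \in [0,1]$ is the relative probability that a fearful
individual is selected, compared with a bold one.  Two selection modes are
implemented:

* **Frequency-dependent** (the main model): the F group is selected with
  probability $\beta n_F / (\beta n_F + n_B)$, giving per-capita kill
  probabilities $\beta p_F / (\beta n_F + n_B)$ for F and
  $p_B / (\beta n_F + n_B)$ for B.  The commoner phenotype absorbs risk —
  the dilution effect emerges from the denominator.
* **Frequency-independent**: the split is fixed at $\beta : 1$ regardless
  of the counts, so per-capita risks are
  $\frac{\beta}{1+\beta} p_F / n_F$ and $\frac{1}{1+\beta} p_B / n_B$.

These forms are pinned down by the risk-sharing consistency property that
defines the comparison between the two modes: under frequency dependence
the per-capita risk of the rarer phenotype is shared onto the commoner
one, and the two modes coincide exactly when $n_F = n_B$.  Both statements
hold for these forms (and would fail for obvious alternatives such as
unweighted group selection) and are verified exhaustively in the test
suite over all counts with $n_F + n_B \le 40$.

In frequency-independent mode the predator may select an empty group; the
attack then simply fails.  We keep that literal reading (selection truly
independent of population structure) as the default and expose
`empty_group_renormalize = TRUE` to redirect such attacks to the non-empty
group instead.

### Energy and reproduction

A surviving fearful individual ends the season with reserves
$x_F = \max(0,\, e_0 - (a + d)\,c)$ and a bold one with
$x_B = \max(0,\, e_0 - a\,c)$, where $e_0$ is the seasonal energy gain and
$c$ the cost of one escape flight.  Bold individuals are assumed to pay no
vigilance cost during disturbances.  Reproductive success is proportional
to reserves, $f(x) = \lambda x$; the constant $\lambda$ cancels in every
offspring share, and a power-law alternative $f(x) = \lambda x^\theta$
(`repro_exponent`) is exposed as a sensitivity switch for users who want
diminishing or accelerating returns on reserves.  The clip at zero
reserves only guards pathological configurations.

At season end, $D$ = (predation kills) + (post-attack individuals at age
$A$, removed even if never captured).  All post-attack survivors,
including the age-$A$ ones, reproduce.  The expected fearful share of the
$D$ replacement offspring is

$$W_F = D\,\frac{n_F'\, f(x_F)\,\Phi_F}{n_F'\, f(x_F)\,\Phi_F + n_B'\, f(x_B)\,\Phi_B},$$

with post-attack counts $n_F', n_B'$.  The realized count is drawn as
$k_F \sim \mathrm{Binomial}(D,\, W_F / D)$ and $k_B = D - k_F$: the
simplest stochastic allocation whose mean reproduces the expectation
exactly and whose total is exactly $D$.  If both
phenotypes have zero reproductive output while survivors exist, offspring
are allocated proportionally to survivor counts so the population never
silently vanishes under exotic configurations.  Newborns enter at age 1 at
the next season start.

### Background fitness and coexistence

Optionally, reproductive output is weighted by a background fitness defined
by analogy to Lotka-Volterra interspecific competition:

$$\Phi_F = \max(0,\, r_F - a_{FF} n_F - a_{FB} n_B), \qquad
  \Phi_B = \max(0,\, r_B - a_{BF} n_F - a_{BB} n_B),$$

evaluated on the post-attack counts (the same counts that enter the
offspring expectations).  Subscript convention: first index = affected
phenotype, second = source.  Without competition, $\Phi \equiv 1$ and the
states $n_F = 0$ and $n_F = N$ are absorbing; with it, coexistence becomes
possible.

## Experiment protocols

* **Run-to-fixation replicate** (`run_replicate`): iterate seasons until
  the population is pure F or pure B, a season cap is reached (reported as
  a timeout, never as a fixation), or the population empties (extinct —
  possible only when $a \ge N$).
* **Fixation frequency** (`estimate_fixation_frequency`): $\rho_F$ = the
  fraction of replicates fixing to fearfulness, default 1000 replicates,
  with a 95% Wilson score interval.  Timeouts and extinctions are counted
  separately.
* **Coexistence trajectory** (`run_coexistence_experiment`): run a fixed
  number of seasons with competition enabled, no fixation stop, and report
  the mean and standard deviation of the fearful frequency over a trailing
  window (default 100 seasons — the fluctuation strength) plus a
  persistence flag.  The reference run length (2000 seasons) and the
  choice of the trailing-window standard deviation as the fluctuation
  statistic are this package's conventions.
* **Sweeps** (`run_fixation_sweep`, `run_coexistence_sweep`): cross
  products of parameter axes.  By default all cells share the base seed,
  so replicate $i$ sees common random numbers in every cell; paired
  comparisons along an axis (monotonicity in initial proportion or escape
  cost) are then far sharper than with independent cells.

## Randomness and reproducibility

Replicate $i$ runs on its own stream seeded by
`replicate_seed(base_seed, i)`, a counter-based multiplicative-hash spawn
(mod $2^{31}-1$): O(1), order-invariant, so experiments could be
parallelized without correlation and any single replicate can be re-run in
isolation.  The replicate loop exists twice: a readable R reference path
through the per-operation API and a compiled fast path.  Both consume the
random stream through an identical draw protocol — one uniform per initial
age; selection, capture, victim uniforms per attack; one binomial per
season with deaths — so the two engines produce **bit-identical**
trajectories from the same seed (tested).  For this reason uniform
integers are drawn as $\lfloor u \cdot k \rfloor + 1$ rather than through
`sample.int()`, whose algorithm a C++ loop cannot cheaply mirror.

Initial fearful counts use round-half-up on $\text{init\_freq}_F \times N$
(exact on the 10%-step grids of the sweep experiments and independent of
parity).  The initial age composition is a free choice of the
experimenter: the default assigns each individual an independent uniform
age on $1..A$, which avoids an artificial synchronized die-off $A$
seasons in, and `all_youngest` is offered for deterministic tests.

## The exact oracle

For $A = 1$ every survivor is senior at season end, so all $N$ individuals
are replaced each season and the state reduces to the fearful count.
`attack_outcome_distribution` enumerates the sequential attack process by
dynamic programming; `season_transition_kernel` composes it with the
binomial offspring draw into an exact $(N{+}1)\times(N{+}1)$ kernel; and
`exact_fixation_probability` solves the absorbing-chain linear system by a
direct dense solve (small $N$ keeps this trivial).  This oracle shares no
code with the replicate engine beyond the per-attack probability formulas,
and is the package's primary verification instrument: simulated fixation
frequencies (20,000 replicates per initial state) must fall inside 99%
binomial bands around the exact probabilities across configurations
spanning both risk modes, $N \in \{2,4,6\}$ and $a \in \{1,2,4\}$.  With
overlapping ages the exact state space explodes; $A = 1$ exercises the
full predation-energy-allocation-absorption pipeline end to end.  Any
probability of mid-season extinction (only possible when $a \ge N$) is
reported as a `p_extinct` attribute and treated as absorbing failure in
the fixation solve; the verification configurations all use $a < N$, where
that mass is exactly zero.

## Reference study conditions

`reference_params()` ships the package's reference study conditions —
chosen once so that each experiment family sits squarely in the regime it
is meant to probe, then frozen:

* **Predation scenario** (population-size / attack-intensity / escape-cost
  experiments): $A=5$, $a=20$, $d=20$, $\beta=0.1$, $p_F=0.5$, $p_B=0.8$,
  $e_0=8$, $c=0.1$, 50% initial fearful proportion, 1000 replicates.
  Population-size levels 50 / 200 / 350.  In this regime fearfulness fixes
  almost surely at $N=50$, boldness at $N=350$, the transition sits near
  $N=200$; at $N=150$ the attack sweep $a \in \{2,\dots,60\}$ has an
  interior optimum (few attacks: bold reproduction wins; many attacks: the
  fearful energy budget collapses, since $x_F = e_0 - (a+d)c$ shrinks by
  $c$ per attack); and $\rho_F$ falls monotonically in $c$ with its
  transition inside the reference escape-cost level grid
  0.08 / 0.10 / 0.12.
* **Coexistence scenario**: sharper survival contrast ($p_F=0.2$,
  $p_B=0.9$), milder energy gap ($c=0.05$), and coefficients $r_F=r_B=2$,
  $a_{FF}=0.005$, $a_{FB}=0.006$, $a_{BF}=0.0005$, $a_{BB}=0.008$ — the
  bold phenotype's competitive effects exceed the fearful one's
  (individuals that risk more against predators compete more
  aggressively).  Population-size band 240-320, default 285.

The coexistence design choice deserves its own note.  A mean-field parity
argument shows that with linear background fitness, *stability* of an
interior equilibrium requires the bold phenotype's self-limitation
($a_{BB}$) to dominate — but then the background equilibrium alone would
push the mean fearful frequency *up* with $N$.  The observed decline of
the mean fearful frequency with population size therefore has to come from
the predation game, whose per-capita survival advantage for fearfulness
scales like $a/N$ and decays as the population grows.  That is why this
scenario uses a strong capture contrast and a small escape cost: the game
term then dominates the competition's own size trend, and across the band
both the mean fearful frequency and its fluctuation strength (the
windowed standard deviation, which scales like demographic noise,
$\sim N^{-1/2}$) decrease with $N$, while both phenotypes persist for
thousands of seasons.

## What the tests do and do not show

The test suite verifies the simulator against hand enumeration, closed
forms, Monte-Carlo/oracle agreement at 4-sigma and 99%-band tolerances,
exhaustive small-count identities, and 500-configuration conservation
sweeps (population size restored every season, ages bounded by $A$, kills
bounded by $a$, offspring exactly equal to deaths).  Problem sizes were
chosen to keep the default run at a few minutes: oracle bands use 20,000
replicates per initial state, neutrality 2,000 replicates, sweep checks
300 replicates per point, coexistence 10-50 runs of 2,000 seasons.

These are all *internal* validations plus regime reproductions.  The model
itself idealizes aggressively: phenotype-level (not individual) energy
budgets, a constant attack count, age-blind predation, asexual inheritance
with no mutation, no spatial structure, and a rigidly constant population
size.  Passing tests show the implementation is faithful to that model —
not that the model describes any particular field population.

## Known limitations

* The exact oracle covers only $A = 1$; overlapping-generation dynamics
  are verified by invariants and cross-engine agreement, not exactly.
* With competition enabled there are no absorbing states and no exact
  long-run distribution is computed; coexistence statements are
  simulation-based.
* `rho_f` is reported as the fraction of *all* replicates that fixed to
  fearfulness; in configurations where timeouts or extinctions occur these
  are visible in the estimate object and should be inspected before
  interpreting `rho_f`.
* Extremely asymmetric configurations (for example $\beta = 0$ with an
  all-fearful population) are handled by explicit conventions (no
  selectable group, attack fails) documented at the operation level.
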