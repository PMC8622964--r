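---
title: "Asynchronously tuned ECA: model, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asynchronously tuned ECA: model, measures, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ateca)
```

## The model

An elementary cellular automaton is a one-dimensional array of binary
cells evolving by a radius-1 rule $f_r:\{0,1\}^3\to\{0,1\}$, with the
rule number $r=\sum_s 2^s d_s$, $s=4x+2y+z$. The package implements
three update regimes over this shared rule space.

**Synchronous.** Every cell simultaneously applies $f_r$ to its time-$t$
neighbourhood. This is the textbook regime and the baseline for all
comparisons.

**Probabilistically asynchronous.** Each cell independently keeps its
state with probability $p$ and otherwise applies $f_r$ to its time-$t$
neighbourhood. All rule inputs are read from time $t$; $p=0$ recovers
the synchronous regime exactly and $p=1$ freezes the configuration.

**Asynchronously tuned.** Each step draws a uniformly random bijection
$\mathrm{Ord}_t$ ranking the cells, and cells update one at a time in
ascending rank. The relative ranks of a cell and its two neighbours put
it in exactly one of four cases (the four strict-order patterns are
exhaustive and mutually exclusive because ranks never tie):

| case | local order | state update | active-rule tuning |
|---|---|---|---|
| active minimum | both neighbours later | own active rule on time-$t$ inputs | none |
| left first | left earlier, right later | passive rule, left input already updated | entry $m$ re-initialised |
| right first | left later, right earlier | passive rule, right input already updated | entry $m$ re-initialised |
| passive maximum | both neighbours earlier | passive rule, both inputs updated | entry $m := c_i(t+1)$ |

Here $m = 4c_{i-1}(t)+2c_i(t)+c_{i+1}(t)$ indexes the cell's time-$t$
neighbourhood. The *passive* rule is a single table fixed for the whole
run and shared by all cells; each cell's *active* rule is its own
8-entry table, initialised to the passive rule and modified in at most
one entry per step. Processing cells in ascending rank with one evolving
state array plus a frozen time-$t$ snapshot realises the
"already-updated neighbour" semantics without bookkeeping flags: a
neighbour's new state is read exactly when its rank is smaller. The test
suite checks this against an instrumented reference implementation that
stores both time layers explicitly.

Two structural consequences are useful as sanity anchors and are
asserted as properties: with the identity rule (204) as passive rule,
every case returns $c_i(t)$ and tuning rewrites an entry with its
existing value, so nothing ever changes; with the zero rule, the
all-zero state is reached at $t=1$ and is invariant.

### The re-initialisation variant

For the two one-sided cases the tuning step "re-initialises" the active
rule at entry $m$. The package's default restores entry $m$ to the
passive rule's output $a_m$ for that same neighbourhood — the only
reading under which the operation actually returns the entry to its
initial value. An alternative formulation of the scheme fixes the
replacement value at $a_0$ (the output for neighbourhood 000)
regardless of $m$; the switch `eq12_literal_a0 = TRUE` selects that
variant. The two readings coincide at $m=0$, and in practice the
measures below are insensitive to the choice; the default is the
self-consistent one.

## Boundary conventions

Pattern simulation uses a periodic ring by default (the least arbitrary
closed topology; clamped pairs are also supported). The computability
measure always clamps one random boundary pair $(c_0, c_{n+1})$, fixed
for all time steps of a replicate, as part of the measure's definition.
For tuned dynamics under clamping, boundary cells never update and are
treated as ranking *later* than every interior cell, which keeps the
four-case classification total without extending the permutation; their
value is time-invariant either way. (Including the boundary cells in
the permutation instead changes the n = 8 break fractions by under one
percentage point.) A ring needs at least two cells for the local order
to be defined.

## The computability measures

For interior width $n$, horizon $T_{\max}$ and penalty $T_\theta$:

* every one of the $2^n$ interior initial states is run to $T_{\max}$
  with the boundary clamped;
* the **reachable set** is the set of configurations occupied at
  $T_{\max}$, and the **universality** $U(r)$ its cardinality,
  normalised as $UN(r)=U(r)/2^n$;
* the first-hitting time of goal $X$ from initial state $Y$ is the
  smallest $t\ge 1$ with the trajectory at $X$ (the initial state at
  $t=0$ does not count — this convention is forced by the identity
  rule's closed form $\tau = 1 + T_\theta(2^n-1)$, where the self-hit
  contributes 1), or $T_\theta$ if $X$ is never visited;
* $\tau_r(X)$ sums hitting times over all initial states, and the
  **efficiency** $E(r)$ is the mean of $\tau_r$ over the reachable set.

Defaults $T_{\max}=T_\theta=2^n$: within $2^n$ steps every
deterministic synchronous trajectory has entered a cycle (pigeonhole on
the state space), so the configuration at the horizon is a well-defined
representative of the trajectory's attractor, and $2^n$ is the smallest
penalty consistent with "not reached within the horizon". Both are
configurable; $E$ scales with $T_\theta$, so sweeps are only comparable
at equal settings and `tradeoff_breaks()` enforces that.

**Stochastic regimes** (asynchronously tuned, probabilistically
asynchronous) are replicated: each replicate redraws the boundary pair
and the update randomness, the per-replicate $U$ and $E$ are averaged,
and the reachable set is reported as the union. Ten replicates per rule
is the default. The aggregation is a genuine protocol choice —
averaging $U$ answers "how many goals does one realisation reach",
while the union answers "how many goals are reachable at all"; the mean
keeps $U$ and $E$ mutually consistent (both describe a typical
realisation) and is what the sweeps use.

**EMIN and tradeoff breaks.** The normalized-universality range is
divided into $m$ half-open semi-intervals $((k-1)/m,\,k/m]$ (so
$UN = k/m$ belongs to interval $k$; $UN$ is never 0 because the
reachable set is nonempty). Each interval is assigned the minimum
synchronous $E$ over the rules whose $UN$ falls in it; an empty
interval inherits the minimum over all larger-index intervals, making
EMIN a step function over the whole range. Default $m=20$. The broad
increase of EMIN with universality is the universality–efficiency
tradeoff; at small widths the increase is not strictly monotone (the
top interval's occupants can undercut a slightly lower interval), so
the property suite asserts the trend — top $\gg$ bottom, at least 80%
of adjacent steps non-decreasing — rather than strict monotonicity.
A rule **breaks** the tradeoff when its alternative-regime efficiency
is strictly below the synchronous EMIN at its own universality
interval; the break fraction divides by the number of rules swept.

## Randomness and reproducibility

All stochastic ingredients — initial configurations, boundary pairs,
per-step order permutations, per-cell skip coins — draw from R's RNG.
Every run-level function takes a seed, and sweeps derive per-rule,
per-replicate, per-component sub-seeds deterministically (a fixed
integer hash into $[0, 2^{31})$), so that: results are independent of
the order in which rules are evaluated; a single rule re-evaluated
alone reproduces its row in a sweep; and the synchronous and
probabilistically asynchronous regimes share boundary sub-streams,
which makes the $p=0$ sweep equal the synchronous sweep
record-for-record (asserted in the tests).

## What the generated data emulate — and what they do not

There is no external data: the study conditions are fully synthetic.
Initial configurations are i.i.d. Bernoulli(0.5) — maximum-entropy
starts that give every rule the same footing; order permutations are
uniform per step (no spatial or temporal correlation in who fires
first); boundary pairs are uniform over $\{0,1\}^2$. These conditions
probe intrinsic rule behaviour. They do **not** emulate structured
inputs (gliders, engineered seeds), correlated update schedules
(refractory periods, clocks), or open boundaries driven by signals —
so passing tests say nothing about computation on structured problems,
and the universality measured here is reachable-state cardinality, not
Turing universality of any single rule.

## Problem sizes

The shipped experiments use widths chosen to keep exhaustive
enumeration honest: the measure enumerates all $2^n$ initial states, so
the full-sweep experiments run at $n=8$ ($T_{\max}=T_\theta=256$, 10
replicates per rule, $m=20$), the oracle-equivalence checks at $n=3$
where a brute-force trajectory-table implementation is feasible for all
256 rules, and the property suites at widths 2–64. The break fraction
is width-dependent; the $n=8$ values reported by
`scripts/acceptance.R` are a scaled-down reproduction of the regime
comparison, not width-asymptotic estimates. The probabilistically
asynchronous grid runs $p = 0.05, 0.10, \dots, 1.0$, twenty settings.

## Criticality diagnostics

`density_series()` and `decimal_series()` reduce a space-time diagram
to scalar series (the decimal expression is normalised to $[0,1)$ with
bit weights $2^{-(i+1)}$ so it is width-independent; a raw-integer
switch exists for widths up to 62). `powerlaw_exponent()` fits the
log-log least-squares slope of density against time over a window of
strictly positive values — a descriptive estimate in the style used
for absorbing-state decay analyses, deliberately not a
maximum-likelihood power-law model, and invariant to positive
rescaling. `spectrum_slope()` fits the log-log slope of the raw
periodogram (mean removed, no taper) over a frequency window; slopes
near $0$, $-1$ and $-2$ correspond to white, flicker and Brownian
spectra. Finite series bias the high-frequency end of a random walk's
periodogram towards shallower slopes, so reference checks fit the
low-frequency window. A fit is flagged when one ordinate carries more
than half the total power (a dominant oscillation makes a slope
meaningless). No reference exponents are hard-coded: the package ships
estimators, not claims about specific rules.

## Known limitations

* The measure's exhaustive enumeration caps the interior width (guard
  at $n \le 12$); everything reported at $n=8$ inherits finite-size
  effects, and regime comparisons at larger widths may differ
  quantitatively.
* Efficiency depends on the penalty $T_\theta$; cross-study comparisons
  require identical $T_\theta$ conventions.
* The four-case local order needs strict rank comparisons; a
  single-cell ring has no distinct neighbours and is rejected for the
  tuned regime.
* The criticality module estimates slopes; it performs no bootstrap or
  goodness-of-fit testing, and window choice is the user's
  responsibility.
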