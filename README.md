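# ateca

Elementary cellular automata under asynchronous tuning, with quantitative
measures of computational universality and efficiency.

## What this package is for

An elementary cellular automaton (ECA) is a ring or line of binary cells
c_i ∈ {0, 1} updated by one of the 256 radius-1 rules
f_r : {0,1}³ → {0,1}, encoded by the Wolfram number
r = Σ_s 2^s d_s with s = 4x + 2y + z. Classical ECA update every cell
simultaneously. Biological multicellular systems do not: whether a cell's
update counts as *active* (it fires before its neighbours) or *passive*
(it reacts to neighbours that already fired) depends on the order in
which updates happen.

The **asynchronously tuned** regime (AT-ECA) implemented here makes that
order explicit. At every step a uniformly random bijective ranking
Ord_t(i) of the cells is drawn, and each cell falls into exactly one of
four local-order cases:

* both neighbours rank later — the cell applies **its own active rule**
  g_i^t to the time-t neighbourhood;
* the left (resp. right) neighbour ranks earlier — the cell applies the
  shared **passive rule** f with that neighbour's already-updated state
  substituted;
* both neighbours rank earlier — the passive rule sees both updated
  states.

After the state update the cell's active rule is re-tuned at the single
entry m = 4c_{i−1}(t) + 2c_i(t) + c_{i+1}(t): left unchanged in the
first case, re-initialised from the passive rule in the middle two, and
overwritten with the freshly computed state c_i(t+1) in the last. The
passive rule is fixed and universal; the active rules start equal to it
and drift by at most one entry per cell per step. This perpetual
adjustment drives almost any passive rule — ordered, periodic or chaotic
under synchronous updating — towards sustained cluster-like dynamics.

For comparison the package also provides plain synchronous updating and
probabilistically asynchronous updating (each cell keeps its state with
probability p, else applies the rule to time-t inputs).

**Computability measures.** For interior width n with a clamped random
boundary pair, all 2^n initial states are run to the horizon T = 2^n:

* universality U(r) = number of distinct configurations occupied at T
  (the *reachable states*), UN(r) = U(r)/2^n;
* efficiency E(r) = mean over reachable X of
  τ_r(X) = Σ_Y T_hit(Y → X), where T_hit is the first t ≥ 1 at which the
  trajectory from Y occupies X, or a penalty T_θ if it never does
  (smaller E = faster, more efficient computation);
* the EMIN step function: the minimum synchronous E per
  normalized-universality semi-interval ((k−1)/m, k/m], whose increase
  expresses the universality–efficiency tradeoff;
* tradeoff *breaks*: rules whose alternative-regime E falls strictly
  below the synchronous EMIN at their own universality interval.

A descriptive criticality toolkit (density-decay power-law exponent,
periodogram spectral slope of the decimal-expression series) supports
edge-of-chaos diagnostics of the generated patterns.

## Worked example

```r
library(ateca)

eca_rule(110)
#> ECA rule 110 (d7..d0 = 01101110)

cfg <- measure_config(n = 3, t_theta = 8, runs = 1, seed = 1)
evaluate_rule(0, "sync", cfg)
#> Rule 0 [sync] n = 3: U = 1, UN = 0.125, E = 8 (1 replicate)
rec <- evaluate_rule(204, "sync", cfg)
rec
#> Rule 204 [sync] n = 3: U = 8, UN = 1, E = 57 (1 replicate)
rec$tau
#> 000 001 010 011 100 101 110 111
#>  57  57  57  57  57  57  57  57
```

Rule 0 erases everything: only `000` is reachable, so U = 1 and every
initial state reaches it in one step (E = 8 sums one hit per initial
state). Rule 204 is the identity: all 8 width-3 states are reachable
(U = 8, UN = 1), but each goal is only ever hit by itself at t = 1, so
τ = 1 + T_θ(2^n − 1) = 1 + 8·7 = 57 for every goal — maximally
universal, minimally efficient, the two ends of the tradeoff.

```r
res <- run_at_eca(110, n = 80, steps = 80, seed = 1)
res$diagram
#> Space-time diagram: 80 steps x 80 cells (rule 110, at, periodic boundary)
res$state
#> AT-ECA state: 80 cells at t = 80, passive rule 110, 74 cell(s) with tuned active rules
plot(res$diagram)   # space-time pattern, time running downward
```

Sweeps and comparisons:

```r
cfg8  <- measure_config(n = 8, runs = 10, seed = 1)
sync  <- sweep_all_rules("sync", cfg8)
at    <- sweep_all_rules("at", cfg8)
tb    <- tradeoff_breaks(sync, at, m = 20)
tb$break_fraction   # fraction of the 256 rules beating the sync EMIN
plot(tb)            # E vs UN scatter with the EMIN step function
```

A thin command-line front end over the same functions ships in
`inst/cli/ateca.R` (`simulate`, `measure`, `tradeoff`, `diagnose`,
`fixtures` subcommands; `--seed`, `--config`, `--out` flags; YAML/JSON
config files mirroring `run_config()`).

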