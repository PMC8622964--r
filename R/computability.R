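# Computational universality and efficiency measures, the per-interval
# minimum-efficiency (EMIN) step function, and tradeoff-break statistics.

#' Measure configuration
#'
#' Settings for the universality/efficiency measure. All `2^n` interior
#' initial states of width `n` are enumerated; each trajectory runs for
#' `t_max` steps with a clamped random boundary pair; a goal state not
#' reached within the horizon contributes the penalty time `t_theta` to
#' the hitting-time sum. Stochastic regimes are replicated `runs` times
#' (each replicate redraws the boundary pair and the update randomness)
#' and the measures averaged.
#'
#' @param n Interior width (`1 <= n <= 12`); the state space has `2^n`
#'   configurations.
#' @param t_max Observation/hitting horizon; defaults to `2^n`, within
#'   which every deterministic synchronous trajectory has entered a cycle.
#' @param t_theta Penalty time for unreached goals; defaults to `2^n`.
#' @param runs Number of stochastic replicates.
#' @param seed Base seed; per-rule, per-replicate sub-seeds are derived
#'   deterministically from it, so sweep results do not depend on the
#'   order in which rules are evaluated.
#' @return A `measure_config` list.
#' @export
measure_config <- function(n, t_max = 2^n, t_theta = 2^n, runs = 10L,
                           seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L || n > 12L)
    stop("n must be an integer in [1, 12] (exhaustive enumeration guard)")
  t_max <- as.integer(t_max); t_theta <- as.integer(t_theta)
  runs <- as.integer(runs); seed <- as.integer(seed)
  if (t_max < 1L) stop("t_max must be >= 1")
  if (t_theta < 1L) stop("t_theta must be >= 1")
  if (runs < 1L) stop("runs must be >= 1")
  structure(list(n = n, t_max = t_max, t_theta = t_theta, runs = runs,
                 seed = seed),
            class = "measure_config")
}

# Deterministic sub-seed in [0, 2^31): decorrelates the boundary draw,
# the dynamics randomness, each replicate, and each rule, so that any
# component can be re-run independently of evaluation order.
derive_seed <- function(seed, rule, rep, stream) {
  (abs(seed) %% 2147483647 * 69069 + rule * 7919 +
     rep * 104729 + stream * 15485863) %% 2147483647
}

state_code_to_string <- function(code, n) {
  vapply(code, function(x)
    paste(as.integer(bitwAnd(bitwShiftR(x, (n - 1):0), 1L)), collapse = ""),
    "")
}

#' Evaluate computational universality and efficiency of one rule
#'
#' Runs the reachable-set measure for one rule under one update regime.
#' Per replicate: one random boundary pair is drawn and clamped for all
#' time steps; all `2^n` interior initial states are enumerated and run
#' to the horizon `t_max`; the reachable set is the set of configurations
#' occupied at `t_max`; the hitting time of goal `X` from initial state
#' `Y` is the smallest `t >= 1` at which the trajectory occupies `X`
#' (the initial state at `t = 0` does not count), or `t_theta` if `X` is
#' never visited. `tau(X)` sums hitting times over all initial states,
#' and the efficiency `E` is the mean of `tau` over the reachable set
#' (smaller is more efficient). For stochastic regimes the measures are
#' averaged over `cfg$runs` replicates, with `U` reported as the mean and
#' the reachable set as the union.
#'
#' @param rule Rule number or [eca_rule()].
#' @param regime `"sync"`, `"async"`, or `"at"` (asynchronously tuned).
#' @param cfg A [measure_config()].
#' @param p Skip probability for the `"async"` regime.
#' @param boundary Optional fixed binary pair `c(left, right)`; by default
#'   each replicate draws its own random pair.
#' @param eq12_literal_a0 Active-rule re-initialisation variant, see
#'   [at_step()].
#' @return A `computability_record`: rule and regime identifiers, the
#'   averaged `U`, `UN = U / 2^n` and `E`, the union `reachable` set (as
#'   state codes and as binary strings), the map `tau` of mean hitting
#'   times, and the per-replicate values.
#' @examples
#' cfg <- measure_config(n = 3, runs = 1)
#' evaluate_rule(204, "sync", cfg)$U  # the identity rule reaches all 8 states
#' @export
evaluate_rule <- function(rule, regime = c("sync", "async", "at"), cfg,
                          p = 0.25, boundary = NULL,
                          eq12_literal_a0 = FALSE) {
  regime <- match.arg(regime)
  if (!inherits(cfg, "measure_config")) stop("cfg must be a measure_config")
  rule <- eca_rule(rule)
  regime_code <- match(regime, c("sync", "async", "at")) - 1L
  if (!is.null(boundary)) {
    boundary <- as.integer(boundary)
    if (length(boundary) != 2L || !all(boundary %in% c(0L, 1L)))
      stop("boundary must be a binary pair c(left, right)")
  }
  total <- 2L^cfg$n
  reps <- vector("list", cfg$runs)
  for (j in seq_len(cfg$runs)) {
    if (is.null(boundary)) {
      set.seed(derive_seed(cfg$seed, rule$number, j, 1L))
      bpair <- sample(0:1, 2L, replace = TRUE)
    } else {
      bpair <- boundary
    }
    set.seed(derive_seed(cfg$seed, rule$number, j, 2L))
    res <- cpp_measure_replicate(rule$outputs, regime_code, cfg$n,
                                 cfg$t_max, cfg$t_theta, p,
                                 isTRUE(eq12_literal_a0),
                                 bpair[1L], bpair[2L])
    res$boundary <- bpair
    reps[[j]] <- res
  }
  reach_union <- sort(unique(unlist(lapply(reps, `[[`, "reachable"))))
  # mean hitting-time map over the replicates in which each goal was reachable
  tau <- vapply(reach_union, function(x) {
    vals <- unlist(lapply(reps, function(r) r$tau[match(x, r$reachable)]))
    mean(vals, na.rm = TRUE)
  }, 0)
  names(tau) <- state_code_to_string(reach_union, cfg$n)
  structure(list(
    rule = rule$number, regime = regime,
    p = if (regime == "async") p else NA_real_,
    n = cfg$n, t_max = cfg$t_max, t_theta = cfg$t_theta,
    runs = cfg$runs, seed = cfg$seed,
    U = mean(vapply(reps, `[[`, 0L, "U")),
    UN = mean(vapply(reps, `[[`, 0L, "U")) / total,
    E = mean(vapply(reps, `[[`, 0, "E")),
    reachable = reach_union,
    reachable_states = state_code_to_string(reach_union, cfg$n),
    tau = tau,
    per_replicate = data.frame(
      rep = seq_len(cfg$runs),
      U = vapply(reps, `[[`, 0L, "U"),
      E = vapply(reps, `[[`, 0, "E"),
      boundary = vapply(reps, function(r) paste(r$boundary, collapse = ""), ""))
  ), class = "computability_record")
}

#' @export
print.computability_record <- function(x, ...) {
  cat(sprintf("Rule %d [%s%s] n = %d: U = %.4g, UN = %.4g, E = %.6g (%d replicate%s)\n",
              x$rule, x$regime,
              if (!is.na(x$p)) sprintf(", p = %g", x$p) else "",
              x$n, x$U, x$UN, x$E, x$runs, if (x$runs > 1L) "s" else ""))
  invisible(x)
}

#' Normalized computational universality
#'
#' The reachable-state count as a fraction of the `2^n` possible goals.
#'
#' @param record A `computability_record` from [evaluate_rule()].
#' @return `U / 2^n`, in `(0, 1]`.
#' @export
normalized_universality <- function(record) {
  if (!inherits(record, "computability_record"))
    stop("record must be a computability_record")
  record$U / 2^record$n
}

#' Sweep the measure over rules
#'
#' Evaluates [evaluate_rule()] for every requested rule under one regime.
#' Per-rule sub-seeds are derived from `cfg$seed`, so the resulting table
#' is identical whatever the evaluation order.
#'
#' @inheritParams evaluate_rule
#' @param rules Integer vector of rule numbers (default all 256).
#' @return A data frame of class `ca_sweep` with one row per rule and
#'   columns `rule`, `regime`, `p`, `U`, `UN`, `E`, `seed`, `n`,
#'   `t_theta`, `runs`.
#' @export
sweep_all_rules <- function(regime = c("sync", "async", "at"), cfg,
                            p = 0.25, rules = 0:255,
                            eq12_literal_a0 = FALSE) {
  regime <- match.arg(regime)
  if (anyDuplicated(rules)) stop("duplicate rule numbers in sweep")
  recs <- lapply(rules, function(r)
    evaluate_rule(r, regime, cfg, p = p, eq12_literal_a0 = eq12_literal_a0))
  out <- data.frame(
    rule = vapply(recs, `[[`, 0L, "rule"),
    regime = regime,
    p = if (regime == "async") p else NA_real_,
    U = vapply(recs, `[[`, 0, "U"),
    UN = vapply(recs, `[[`, 0, "UN"),
    E = vapply(recs, `[[`, 0, "E"),
    seed = cfg$seed, n = cfg$n, t_theta = cfg$t_theta, runs = cfg$runs)
  class(out) <- c("ca_sweep", "data.frame")
  out
}

# Interval index k with UN in Int_k = ((k-1)/m, k/m]; UN in (0, 1].
universality_interval <- function(un, m) {
  pmin(pmax(ceiling(un * m), 1L), m)
}

#' Per-interval minimum-efficiency step function
#'
#' Divides the normalized-universality range `(0, 1]` into `m` half-open
#' semi-intervals `Int_k = ((k-1)/m, k/m]` and assigns each interval the
#' minimum efficiency `E` over the rules whose `UN` falls in it. An empty
#' interval inherits the minimum `E` over all rules in larger-index
#' intervals, which makes the curve a step function over the whole range.
#' Its monotone increase expresses the universality-efficiency tradeoff.
#'
#' @param sweep A `ca_sweep` from [sweep_all_rules()] (normally the
#'   synchronous sweep over all 256 rules).
#' @param m Number of semi-intervals.
#' @return A data frame of class `emin_curve` with columns `k`, `lower`,
#'   `upper`, `n_rules`, `emin`. Intervals above the last occupied one
#'   have no fallback and carry `NA` (cannot occur in a full 256-rule
#'   sweep, where the identity rule occupies the top interval).
#' @export
emin_curve <- function(sweep, m = 20L) {
  if (!is.data.frame(sweep) || !all(c("UN", "E") %in% names(sweep)))
    stop("sweep must contain UN and E columns")
  if (nrow(sweep) < 1L) stop("empty sweep: no rules to build EMIN from")
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  k_of <- universality_interval(sweep$UN, m)
  emin <- rep(NA_real_, m)
  for (k in seq_len(m)) {
    inside <- sweep$E[k_of == k]
    if (length(inside)) emin[k] <- min(inside)
    else {
      later <- sweep$E[k_of > k]
      if (length(later)) emin[k] <- min(later)
    }
  }
  out <- data.frame(k = seq_len(m), lower = (seq_len(m) - 1) / m,
                    upper = seq_len(m) / m,
                    n_rules = tabulate(k_of, nbins = m),
                    emin = emin)
  class(out) <- c("emin_curve", "data.frame")
  attr(out, "m") <- m
  out
}

#' Tradeoff-break statistics between two regimes
#'
#' Compares an alternative-regime sweep (asynchronously tuned or
#' probabilistically asynchronous) against the synchronous EMIN step
#' function. A rule "breaks the tradeoff" when its alternative-regime
#' efficiency is strictly smaller (better) than the synchronous minimum
#' efficiency at its own universality interval, i.e. when the deviation
#' `EMIN(k) - E(r)` with `UN(r)` in `Int_k` is positive.
#'
#' @param sync_sweep Synchronous `ca_sweep` (defines the EMIN curve).
#' @param alt_sweep Alternative-regime `ca_sweep` over the same rules and
#'   measure configuration.
#' @param m Number of universality semi-intervals.
#' @return A `tradeoff_summary` list: the `emin` curve, a per-rule table
#'   (`rule`, `UN`, `E`, `k`, `emin`, `deviation`, `breaks`), the
#'   `break_fraction`, and per-interval mean deviations.
#' @export
tradeoff_breaks <- function(sync_sweep, alt_sweep, m = 20L) {
  for (s in list(sync_sweep, alt_sweep))
    if (!is.data.frame(s) || !all(c("rule", "UN", "E") %in% names(s)))
      stop("sweeps must contain rule, UN and E columns")
  if (!setequal(sync_sweep$rule, alt_sweep$rule) ||
      anyDuplicated(alt_sweep$rule))
    stop("the two sweeps must cover the same set of rules")
  if (!identical(unique(sync_sweep$n), unique(alt_sweep$n)) ||
      !identical(unique(sync_sweep$t_theta), unique(alt_sweep$t_theta)))
    stop("the two sweeps must use the same measure configuration")
  curve <- emin_curve(sync_sweep, m)
  k <- universality_interval(alt_sweep$UN, m)
  emin_at <- curve$emin[k]
  deviation <- emin_at - alt_sweep$E
  rules <- data.frame(rule = alt_sweep$rule, UN = alt_sweep$UN,
                      E = alt_sweep$E, k = k, emin = emin_at,
                      deviation = deviation, breaks = deviation > 0)
  per_interval <- data.frame(
    k = seq_len(m),
    mean_deviation = vapply(seq_len(m), function(kk) {
      d <- deviation[k == kk]
      if (length(d)) mean(d) else NA_real_
    }, 0))
  structure(list(emin = curve, rules = rules,
                 break_fraction = mean(rules$breaks),
                 per_interval = per_interval, m = m,
                 alt_regime = if ("regime" %in% names(alt_sweep))
                   alt_sweep$regime[1L] else NA_character_),
            class = "tradeoff_summary")
}

#' @export
print.tradeoff_summary <- function(x, ...) {
  cat(sprintf("Tradeoff breaks vs synchronous EMIN (m = %d intervals)\n", x$m))
  cat(sprintf("  alternative regime: %s\n", x$alt_regime))
  cat(sprintf("  rules breaking the tradeoff: %d / %d (fraction %.3f)\n",
              sum(x$rules$breaks), nrow(x$rules), x$break_fraction))
  invisible(x)
}

#' Plot efficiency against universality with the EMIN step function
#'
#' Scatter of `E(r)` against `UN(r)` for an alternative-regime sweep,
#' overlaid with the synchronous EMIN step function; rules falling below
#' the step break the tradeoff.
#'
#' @param x A `tradeoff_summary`.
#' @param log_e Plot the efficiency axis on a log scale.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tradeoff_summary <- function(x, log_e = TRUE, ...) {
  r <- x$rules
  graphics::plot(r$UN, r$E, log = if (log_e) "y" else "",
                 xlab = "normalized universality UN",
                 ylab = "efficiency E (mean hitting time)",
                 col = ifelse(r$breaks, "firebrick", "grey40"),
                 pch = 19, cex = 0.6, ...)
  e <- x$emin
  graphics::segments(e$lower, e$emin, e$upper, e$emin, lwd = 2,
                     col = "steelblue")
  graphics::legend("topleft", bty = "n",
                   legend = c("breaks tradeoff", "does not", "sync EMIN"),
                   col = c("firebrick", "grey40", "steelblue"),
                   pch = c(19, 19, NA), lty = c(NA, NA, 1))
  invisible(x)
}

#' Break fractions over a grid of asynchrony probabilities
#'
#' Runs a probabilistically asynchronous sweep for each `p` in `p_grid`
#' and records the fraction of rules breaking the synchronous tradeoff,
#' for comparison with the asynchronously tuned regime.
#'
#' @param sync_sweep Synchronous `ca_sweep` defining the EMIN curve.
#' @param cfg The same [measure_config()] the synchronous sweep used.
#' @param p_grid Probabilities to evaluate.
#' @param m Number of universality semi-intervals.
#' @param rules Rule numbers (must match `sync_sweep`).
#' @return Data frame with columns `p` and `break_fraction`.
#' @export
break_fraction_grid <- function(sync_sweep, cfg,
                                p_grid = seq(0.05, 1, by = 0.05),
                                m = 20L, rules = 0:255) {
  fr <- vapply(p_grid, function(p) {
    sw <- sweep_all_rules("async", cfg, p = p, rules = rules)
    tradeoff_breaks(sync_sweep, sw, m)$break_fraction
  }, 0)
  data.frame(p = p_grid, break_fraction = fr)
}
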