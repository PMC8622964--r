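# Independent reference implementations used as oracles. These are
# deliberately naive: per-cell table lookups and explicit two-layer state
# storage, written straight from the definitions, sharing no code with
# the package internals beyond the rule-table encoding.

rule_table_oracle <- function(rule_number) {
  # bit s of the rule number is the output for neighbourhood index s
  vapply(0:7, function(s) (rule_number %/% 2^s) %% 2, 0)
}

neighbour_vals <- function(config, i, boundary) {
  n <- length(config)
  if (identical(boundary, "periodic")) {
    l <- config[if (i == 1) n else i - 1]
    r <- config[if (i == n) 1 else i + 1]
  } else {
    l <- if (i == 1) boundary[1] else config[i - 1]
    r <- if (i == n) boundary[2] else config[i + 1]
  }
  c(l, r)
}

sync_step_oracle <- function(config, rule_number, boundary = "periodic") {
  tab <- rule_table_oracle(rule_number)
  n <- length(config)
  out <- integer(n)
  for (i in seq_len(n)) {
    lr <- neighbour_vals(config, i, boundary)
    out[i] <- tab[4 * lr[1] + 2 * config[i] + lr[2] + 1]
  }
  out
}

# Instrumented asynchronously tuned step keeping both time layers
# explicitly: old` is frozen at time t, `new` is filled cell by cell in
# ascending rank. Also records, per cell, the case and the neighbour
# values actually fed to the rule, so the substitution semantics can be
# asserted directly.
at_step_oracle <- function(config, active, passive_number, order,
                           topology = "ring", boundary = c(0, 0),
                           eq12_literal_a0 = FALSE) {
  a <- rule_table_oracle(passive_number)
  n <- length(config)
  old <- config
  new <- rep(NA_integer_, n)
  act <- active
  cases <- character(n)
  used <- matrix(NA_real_, n, 3) # (left, self, right) inputs actually used
  rank_of <- function(j) {
    if (topology == "ring") order[(j - 1) %% n + 1]
    else if (j < 1 || j > n) Inf else order[j]
  }
  val_at <- function(j, updated) {
    # updated = TRUE reads the t+1 layer (defined because ranks ascend)
    if (topology == "ring") {
      jj <- (j - 1) %% n + 1
      if (updated) new[jj] else old[jj]
    } else if (j < 1) boundary[1]
    else if (j > n) boundary[2]
    else if (updated) new[j] else old[j]
  }
  for (i in order(order)) { # ascending rank
    lr <- rank_of(i - 1); rr <- rank_of(i + 1); my <- order[i]
    m <- 4 * val_at(i - 1, FALSE) + 2 * old[i] + val_at(i + 1, FALSE)
    if (lr > my && rr > my) {
      cases[i] <- "active_min"
      l <- val_at(i - 1, FALSE); r <- val_at(i + 1, FALSE)
      new[i] <- act[i, 4 * l + 2 * old[i] + r + 1]
    } else if (lr < my && rr > my) {
      cases[i] <- "left_first"
      l <- val_at(i - 1, TRUE); r <- val_at(i + 1, FALSE)
      new[i] <- a[4 * l + 2 * old[i] + r + 1]
      act[i, m + 1] <- if (eq12_literal_a0) a[1] else a[m + 1]
    } else if (lr > my && rr < my) {
      cases[i] <- "right_first"
      l <- val_at(i - 1, FALSE); r <- val_at(i + 1, TRUE)
      new[i] <- a[4 * l + 2 * old[i] + r + 1]
      act[i, m + 1] <- if (eq12_literal_a0) a[1] else a[m + 1]
    } else {
      cases[i] <- "passive_max"
      l <- val_at(i - 1, TRUE); r <- val_at(i + 1, TRUE)
      new[i] <- a[4 * l + 2 * old[i] + r + 1]
      act[i, m + 1] <- new[i]
    }
    used[i, ] <- c(l, old[i], r)
  }
  list(config = new, active = act, cases = cases, used = used, old = old)
}

# Brute-force universality/efficiency measure from the definitions:
# explicit trajectory tables for all 2^n interior initial states under
# synchronous dynamics with a clamped boundary pair.
measure_oracle_sync <- function(rule_number, n, t_max, t_theta, boundary) {
  states <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  total <- 2^n
  key <- function(v) paste(v, collapse = "")
  trajs <- vector("list", total)
  for (y in seq_len(total)) {
    cur <- states[y, ]
    tab <- character(t_max)
    for (t in seq_len(t_max)) {
      cur <- sync_step_oracle(cur, rule_number, boundary)
      tab[t] <- key(cur)
    }
    trajs[[y]] <- tab
  }
  finals <- vapply(trajs, function(tr) tr[t_max], "")
  reachable <- sort(unique(finals))
  tau <- vapply(reachable, function(x) {
    sum(vapply(trajs, function(tr) {
      hit <- which(tr == x)
      if (length(hit)) hit[1] else t_theta
    }, 0))
  }, 0)
  list(reachable = reachable, U = length(reachable), tau = tau,
       E = mean(tau))
}
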