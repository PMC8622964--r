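test_that("worked universality examples hold at n = 3", {
  cfg <- measure_config(n = 3, runs = 1, seed = 1)
  r0 <- evaluate_rule(0, "sync", cfg)
  expect_identical(r0$U, 1)
  expect_identical(r0$reachable_states, "000")
  r204 <- evaluate_rule(204, "sync", cfg)
  expect_identical(r204$U, 8)
  expect_setequal(r204$reachable_states,
                  apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = ""))
})

test_that("the identity rule reproduces the hitting-time closed form", {
  # every initial state only ever occupies itself: tau(X) = 1 + Tθ(2^n − 1)
  cfg <- measure_config(n = 3, t_theta = 8, runs = 1, seed = 1)
  rec <- evaluate_rule(204, "sync", cfg)
  expect_true(all(rec$tau == 1 + 8 * (8 - 1)))
  expect_identical(rec$E, 57)
})

test_that("evaluate_rule matches the brute-force oracle for all 256 rules", {
  cfg <- measure_config(n = 3, runs = 1, seed = 1)
  for (r in 0:255) {
    rec <- evaluate_rule(r, "sync", cfg, boundary = c(0L, 1L))
    orc <- measure_oracle_sync(r, n = 3, t_max = 8, t_theta = 8,
                               boundary = c(0, 1))
    expect_identical(rec$U, as.double(orc$U))
    expect_identical(rec$reachable_states, orc$reachable)
    expect_equal(unname(rec$tau), unname(orc$tau))
    expect_equal(rec$E, orc$E)
  }
})

test_that("normalized universality is U / 2^n", {
  cfg <- measure_config(n = 3, runs = 1, seed = 1)
  expect_identical(normalized_universality(evaluate_rule(204, "sync", cfg)), 1)
  expect_identical(normalized_universality(evaluate_rule(0, "sync", cfg)), 0.125)
  # upper bound attained means UN = 1 whatever n
  cfg4 <- measure_config(n = 4, runs = 1, seed = 1)
  expect_identical(normalized_universality(evaluate_rule(204, "sync", cfg4)), 1)
})

test_that("async p = 0 reproduces the sync record and p = 1 freezes everything", {
  cfg <- measure_config(n = 4, runs = 3, seed = 7)
  for (r in c(3, 30, 90, 110, 204)) {
    s <- evaluate_rule(r, "sync", cfg)
    a0 <- evaluate_rule(r, "async", cfg, p = 0)
    expect_identical(a0$U, s$U)
    expect_identical(a0$E, s$E)
    expect_identical(a0$reachable, s$reachable)
    # p = 1: each initial state is stuck at itself, as for the identity rule
    a1 <- evaluate_rule(r, "async", cfg, p = 1)
    expect_identical(a1$U, 16)
    expect_true(all(a1$tau == 1 + cfg$t_theta * (16 - 1)))
  }
})

test_that("deterministic sync trajectories cycle within the 2^n horizon", {
  set.seed(8)
  for (r in 0:255) {
    n <- 6
    bd <- sample(0:1, 2, replace = TRUE)
    init <- random_configuration(n)
    d <- run_trajectory(init, r, "sync", steps = 2^n, boundary = bd)
    keys <- apply(unclass(d), 1L, paste, collapse = "")
    expect_true(anyDuplicated(keys) > 0)   # pigeonhole: a state repeats
  }
})

test_that("tau and E respect their structural bounds", {
  cfg <- measure_config(n = 4, runs = 2, seed = 3)
  for (r in c(0, 18, 45, 110, 150, 204)) {
    for (regime in c("sync", "async", "at")) {
      rec <- evaluate_rule(r, regime, cfg)
      expect_true(all(rec$tau >= 1))
      expect_true(all(rec$tau <= cfg$t_theta * 2^cfg$n))
      expect_gte(rec$E, 1)
      expect_lte(rec$E, cfg$t_theta * 2^cfg$n)
      expect_gte(rec$U, 1); expect_lte(rec$U, 2^cfg$n)
    }
  }
})

test_that("sweeps are reproducible and order-independent", {
  cfg <- measure_config(n = 3, runs = 2, seed = 11)
  a <- sweep_all_rules("at", cfg, rules = 0:15)
  b <- sweep_all_rules("at", cfg, rules = 0:15)
  expect_identical(a, b)
  # evaluating a rule on its own gives the same row as inside the sweep
  solo <- evaluate_rule(9, "at", cfg)
  expect_identical(solo$U, a$U[a$rule == 9])
  expect_identical(solo$E, a$E[a$rule == 9])
  # async p = 0 sweep equals the sync sweep record-for-record
  s <- sweep_all_rules("sync", cfg, rules = 0:31)
  z <- sweep_all_rules("async", cfg, p = 0, rules = 0:31)
  expect_identical(s$U, z$U)
  expect_identical(s$E, z$E)
})

test_that("emin_curve implements the per-interval minimum with fallback", {
  # degenerate single record: every interval inherits the one efficiency
  one <- data.frame(rule = 204, UN = 1.0, E = 57)
  e1 <- emin_curve(one, m = 4)
  expect_identical(e1$emin, rep(57, 4))
  # the fallback takes the min over ALL larger intervals, not the next one;
  # intervals above the last occupied one have no fallback and stay NA
  two <- data.frame(rule = c(1, 2), UN = c(0.3, 0.6), E = c(10, 5))
  e2 <- emin_curve(two, m = 4)   # E=10 sits in Int_2, E=5 in Int_3
  expect_identical(e2$emin, c(5, 10, 5, NA_real_))
  # interval bounds are half-open: UN = k/m belongs to interval k, not k+1
  edge <- data.frame(rule = 1, UN = 0.25, E = 3)
  expect_identical(emin_curve(edge, m = 4)$n_rules, c(1L, 0L, 0L, 0L))
  expect_error(emin_curve(data.frame(UN = numeric(0), E = numeric(0))),
               "empty")
})

test_that("the sync sweep shows the universality-efficiency tradeoff trend", {
  cfg <- measure_config(n = 3, runs = 1, seed = 1)
  sw <- sweep_all_rules("sync", cfg)
  e <- emin_curve(sw, m = 20)
  expect_true(all(is.finite(e$emin)))
  # EMIN rises strongly from the low- to the high-universality end; small
  # local inversions at the top intervals occur at this width, so the
  # assertion is on the trend, not strict monotonicity
  expect_gt(e$emin[20], 4 * e$emin[1])
  expect_gte(mean(diff(e$emin) >= 0), 0.8)
})

test_that("self-comparison never breaks the tradeoff", {
  cfg <- measure_config(n = 3, runs = 1, seed = 2)
  sw <- sweep_all_rules("sync", cfg)
  tb <- tradeoff_breaks(sw, sw, m = 20)
  expect_identical(tb$break_fraction, 0)
  expect_true(all(tb$rules$deviation <= 0))
})

test_that("mismatched sweeps are rejected", {
  cfg <- measure_config(n = 3, runs = 1, seed = 1)
  a <- sweep_all_rules("sync", cfg, rules = 0:7)
  b <- sweep_all_rules("sync", cfg, rules = 8:15)
  expect_error(tradeoff_breaks(a, b), "same set of rules")
  cfg2 <- measure_config(n = 4, runs = 1, seed = 1)
  d <- sweep_all_rules("sync", cfg2, rules = 0:7)
  expect_error(tradeoff_breaks(a, d), "same measure configuration")
  expect_error(measure_config(n = 0), "\\[1, 12\\]")
  expect_error(measure_config(n = 13), "\\[1, 12\\]")
  expect_error(evaluate_rule(3, "sync", list(n = 3)), "measure_config")
})
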