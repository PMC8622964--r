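test_that("draw_order yields a uniform-looking bijection", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    ord <- draw_order(n)
    expect_identical(sort(ord), seq_len(n))   # bijectivity
  }
  expect_identical(draw_order(1), 1L)
  expect_error(draw_order(0), ">= 1")
})

test_that("classify_case reproduces the worked permutation examples", {
  ord <- c(3L, 5L, 4L, 1L, 2L)  # the five-cell example assignment
  # cell 4: own rank 1, neighbour ranks 4 and 2 -> both later
  expect_identical(classify_case(ord, 4), "active_min")
  # cell 2: ranks (3, 5, 4) -> both neighbours earlier
  expect_identical(classify_case(ord, 2), "passive_max")
  # cell 5: ranks (1, 2, 3) with the right neighbour wrapping to cell 1
  expect_identical(classify_case(ord, 5), "left_first")
  # clamped topology: boundary counts as later on that side
  expect_identical(classify_case(c(1L, 2L), 1, topology = "clamped"),
                   "active_min")
  expect_identical(classify_case(c(2L, 1L), 2, topology = "clamped"),
                   "active_min")
  expect_identical(classify_case(c(2L, 1L), 1, topology = "clamped"),
                   "right_first")
})

test_that("the four update cases partition the cells for every permutation", {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1L, function(p) all(sort(p) == 1:5)), ]
  expect_equal(nrow(perms), 120L)  # all orders at N = 5
  for (pi in seq_len(nrow(perms))) {
    ord <- as.integer(perms[pi, ])
    for (i in 1:5) {
      lr <- ord[(i - 2) %% 5 + 1]; rr <- ord[i %% 5 + 1]; my <- ord[i]
      # evaluate the four strict-order predicates directly: exactly one holds
      preds <- c(active_min  = lr > my && rr > my,
                 left_first  = lr < my && rr > my,
                 right_first = lr > my && rr < my,
                 passive_max = lr < my && rr < my)
      expect_identical(sum(preds), 1L)
      expect_identical(classify_case(ord, i), names(which(preds)))
    }
    # the earliest cell is an active minimum, the latest a passive maximum
    expect_identical(classify_case(ord, which.min(ord)), "active_min")
    expect_identical(classify_case(ord, which.max(ord)), "passive_max")
  }
})

test_that("at_step agrees with the instrumented two-layer oracle", {
  set.seed(6)
  for (trial in 1:150) {
    n <- sample(2:10, 1)
    topo <- sample(c("ring", "clamped"), 1)
    bd <- sample(0:1, 2, replace = TRUE)
    rule <- sample(0:255, 1)
    config <- sample(0:1, n, replace = TRUE)
    active <- matrix(sample(0:1, n * 8, replace = TRUE), n, 8)
    ord <- sample(n)
    lit <- sample(c(TRUE, FALSE), 1)
    st <- at_state(config, rule, active = active)
    res <- at_step(st, ord, topology = topo, boundary = bd,
                   eq12_literal_a0 = lit)
    orc <- at_step_oracle(config, active, rule, ord, topo, bd, lit)
    expect_equal(res$config, orc$config, ignore_attr = TRUE)
    expect_equal(unname(res$active), unname(orc$active), ignore_attr = TRUE)
    expect_identical(res$time, st$time + 1L)
    # substitution semantics: the neighbour value actually used is the
    # updated one exactly when the neighbour's rank is smaller
    for (i in seq_len(n)) {
      li <- if (topo == "ring") (i - 2) %% n + 1 else i - 1
      if (li >= 1 && li <= n) {
        expected <- if (ord[li] < ord[i]) orc$config[li] else orc$old[li]
        expect_equal(orc$used[i, 1], expected)
      }
      ri <- if (topo == "ring") i %% n + 1 else i + 1
      if (ri >= 1 && ri <= n) {
        expected <- if (ord[ri] < ord[i]) orc$config[ri] else orc$old[ri]
        expect_equal(orc$used[i, 3], expected)
      }
    }
  }
})

test_that("a passive-maximum cell writes its new state into the active rule", {
  # passive rule 22, ring of 5, order chosen so that cell 3 updates last
  # with old neighbourhood (0,0,0) while its left neighbour has become 1:
  # the active-rule entry for neighbourhood index 0 becomes c(t+1) = 1.
  st <- at_state(c(1L, 0L, 0L, 0L, 0L), 22)
  res <- at_step(st, order = c(3L, 1L, 5L, 2L, 4L))
  expect_identical(res$config, c(0L, 1L, 1L, 0L, 0L))
  expect_identical(classify_case(c(3L, 1L, 5L, 2L, 4L), 3), "passive_max")
  expect_identical(res$active[3L, 1L], 1L)          # entry for 000 tuned to 1
  expect_identical(res$active[3L, -1L], rule_outputs(22)[-1L])
  # an active-minimum cell's row is untouched
  expect_identical(classify_case(c(3L, 1L, 5L, 2L, 4L), 2), "active_min")
  expect_identical(res$active[2L, ], rule_outputs(22))
})

test_that("active-rule tuning changes at most one entry per cell per step", {
  set.seed(7)
  for (trial in 1:20) {
    st <- at_state(random_configuration(32), sample(0:255, 1))
    for (s in 1:40) {
      nxt <- at_step(st)
      drift <- rowSums(nxt$active != st$active)
      expect_true(all(drift <= 1L))
      st <- nxt
    }
  }
})

test_that("passive rule 204 keeps any configuration fixed forever", {
  for (seed in 1:20) {
    set.seed(seed)
    init <- random_configuration(sample(2:64, 1))
    res <- run_at_eca(204, steps = 100, seed = seed, initial = init)
    expect_true(all(apply(unclass(res$diagram), 1L, identical, init)))
    # the active field never drifts from the passive rule
    expect_true(all(res$state$active ==
                      matrix(rule_outputs(204), length(init), 8,
                             byrow = TRUE)))
  }
})

test_that("passive rule 0 absorbs to all-zero at t = 1 and stays there", {
  for (seed in 1:20) {
    set.seed(seed)
    res <- run_at_eca(0, n = sample(2:64, 1), steps = 30, seed = seed)
    expect_true(all(unclass(res$diagram)[-1L, ] == 0L))
  }
})

test_that("run_at_eca is deterministic given the seed", {
  a <- run_at_eca(110, n = 40, steps = 60, seed = 123)
  b <- run_at_eca(110, n = 40, steps = 60, seed = 123)
  expect_identical(unclass(a$diagram), unclass(b$diagram))
  expect_identical(a$state$active, b$state$active)
})

test_that("invalid AT inputs are rejected", {
  st <- at_state(c(0L, 1L, 0L), 22)
  expect_error(at_step(st, order = c(1L, 2L)), "permutation")
  expect_error(at_step(st, order = c(1L, 1L, 2L)), "permutation")
  expect_error(at_state(c(0L, 1L), 22, active = matrix(0L, 2, 7)), "N x 8")
  expect_error(run_at_eca(22, initial = 1L, steps = 5), "at least 2")
})
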