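# Asynchronously tuned dynamics: update-order permutations, the four
# local-order update cases, and active-rule tuning.

#' Draw a random update-order permutation
#'
#' At each time step of the asynchronously tuned regime every cell is
#' assigned a distinct rank in `1..N`; cells update one at a time in
#' ascending rank. A cell that updates before both neighbours acts with
#' its own (active) rule; a cell that updates after a neighbour sees that
#' neighbour's already-updated state through the shared passive rule.
#'
#' @param n Number of cells (`>= 1`).
#' @return An integer permutation of `1:n`; element `i` is the rank of
#'   cell `i`.
#' @export
draw_order <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be >= 1")
  sample.int(as.integer(n))
}

#' Classify a cell's local update case
#'
#' The relative ranks of a cell and its two neighbours put it in exactly
#' one of four cases: `"active_min"` (both neighbours update later; the
#' cell applies its own active rule to time-t states), `"left_first"` /
#' `"right_first"` (one neighbour has already updated; the passive rule is
#' applied with that neighbour's new state), or `"passive_max"` (both
#' neighbours already updated; the passive rule sees both new states).
#'
#' @param order Integer permutation as from [draw_order()].
#' @param i Cell index in `1..N`.
#' @param topology `"ring"` (ranks wrap) or `"clamped"` (boundary cells
#'   never update, so they always count as updating later).
#' @return One of `"active_min"`, `"left_first"`, `"right_first"`,
#'   `"passive_max"`.
#' @examples
#' classify_case(c(3, 5, 4, 1, 2), 4)  # both neighbours later: "active_min"
#' @export
classify_case <- function(order, i, topology = c("ring", "clamped")) {
  topology <- match.arg(topology)
  n <- length(order)
  if (n < 1L || !setequal(order, seq_len(n)))
    stop("order must be a permutation of 1..N")
  if (i < 1 || i > n) stop("cell index i out of range")
  if (topology == "ring") {
    if (n < 2L) stop("ring topology needs at least 2 cells")
    lr <- order[if (i == 1L) n else i - 1L]
    rr <- order[if (i == n) 1L else i + 1L]
  } else {
    lr <- if (i == 1L) Inf else order[i - 1L]
    rr <- if (i == n) Inf else order[i + 1L]
  }
  my <- order[i]
  if (lr > my && rr > my) "active_min"
  else if (lr < my && rr > my) "left_first"
  else if (lr > my && rr < my) "right_first"
  else "passive_max"
}

#' Asynchronously tuned cell state
#'
#' Bundles a configuration with its per-cell active rules and the shared
#' passive rule. Every cell starts with its active rule equal to the
#' passive rule; tuning then modifies at most one active-rule entry per
#' cell per step, while the passive rule stays fixed for the whole run.
#'
#' @param config Binary vector of cell states.
#' @param passive The passive [eca_rule()] shared by all cells.
#' @param active Optional `N x 8` binary matrix of active-rule outputs;
#'   defaults to every row equal to the passive rule's outputs.
#' @param time Step counter (default 0).
#' @return An object of class `at_state` with elements `config`, `active`,
#'   `passive`, `time`.
#' @export
at_state <- function(config, passive, active = NULL, time = 0L) {
  config <- check_configuration(config)
  passive <- eca_rule(passive)
  n <- length(config)
  if (is.null(active)) {
    active <- matrix(rep(passive$outputs, each = n), nrow = n)
  } else {
    active <- matrix(as.integer(active), nrow = n)
    if (ncol(active) != 8L || anyNA(active) || !all(active %in% c(0L, 1L)))
      stop("active must be a binary N x 8 matrix")
  }
  structure(list(config = config, active = active, passive = passive,
                 time = as.integer(time)),
            class = "at_state")
}

#' @export
print.at_state <- function(x, ...) {
  cat(sprintf("AT-ECA state: %d cells at t = %d, passive rule %d, %d cell(s) with tuned active rules\n",
              length(x$config), x$time, x$passive$number,
              sum(apply(x$active, 1L, function(r)
                any(r != x$passive$outputs)))))
  invisible(x)
}

#' One asynchronously tuned step
#'
#' Cells update one at a time in ascending rank of `order`. A cell in the
#' `active_min` case applies its own active rule to the time-t states of
#' its neighbours; in the other three cases the passive rule is applied
#' with already-updated neighbour states substituted where the neighbour's
#' rank is smaller. After the state update the active rule is tuned at the
#' single entry `m = 4*c[i-1](t) + 2*c[i](t) + c[i+1](t)`: unchanged for
#' `active_min`; re-initialised from the passive rule for `left_first` /
#' `right_first`; set to the just-computed new state for `passive_max`.
#'
#' @param state An [at_state()].
#' @param order Update-order permutation from [draw_order()]; drawn
#'   internally when `NULL`.
#' @param topology `"ring"` or `"clamped"`; a clamped run reads the
#'   constant `boundary` pair at the edges.
#' @param boundary Binary pair `c(left, right)` for the clamped topology.
#' @param eq12_literal_a0 If `TRUE`, the re-initialisation entry for
#'   `left_first`/`right_first` cells is set to the passive rule's output
#'   for neighbourhood 000 instead of its output for neighbourhood `m`
#'   (a variant reading of the tuning scheme; the two coincide at `m = 0`).
#' @return The updated `at_state` (time advanced by 1).
#' @export
at_step <- function(state, order = NULL, topology = c("ring", "clamped"),
                    boundary = c(0L, 0L), eq12_literal_a0 = FALSE) {
  topology <- match.arg(topology)
  if (!inherits(state, "at_state")) stop("state must be an at_state")
  n <- length(state$config)
  if (topology == "ring" && n < 2L)
    stop("ring topology needs at least 2 cells")
  if (is.null(order)) order <- draw_order(n)
  order <- as.integer(order)
  if (length(order) != n || !setequal(order, seq_len(n)))
    stop("order must be a permutation of 1..N matching the configuration length")
  boundary <- as.integer(boundary)
  res <- cpp_at_step(state$config, state$active, state$passive$outputs,
                     order, topology == "ring", boundary[1L], boundary[2L],
                     isTRUE(eq12_literal_a0))
  at_state(res$cells, state$passive, active = res$active,
           time = state$time + 1L)
}

#' Run an asynchronously tuned ECA
#'
#' Initialises every cell's active rule to the passive rule, then iterates
#' [at_step()] with a fresh uniformly random update order at every step.
#' Fully reproducible given `seed`.
#'
#' @param passive Passive [eca_rule()] or rule number.
#' @param n Number of cells (used when `initial` is `NULL`).
#' @param steps Number of steps `T >= 0`.
#' @param seed Optional integer seed.
#' @param initial Binary initial configuration; a Bernoulli(0.5) random
#'   configuration of length `n` when `NULL`.
#' @param topology,boundary,eq12_literal_a0 See [at_step()].
#' @return A list with `diagram` (a `ca_diagram`, `steps + 1` rows) and
#'   `state` (the final [at_state()], including the tuned active rules).
#' @examples
#' res <- run_at_eca(22, n = 32, steps = 32, seed = 1)
#' res$diagram
#' @export
run_at_eca <- function(passive, n = NULL, steps, seed = NULL, initial = NULL,
                       topology = c("ring", "clamped"), boundary = c(0L, 0L),
                       eq12_literal_a0 = FALSE) {
  topology <- match.arg(topology)
  passive <- eca_rule(passive)
  if (steps < 0) stop("steps must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(initial)) {
    if (is.null(n)) stop("supply either n or an initial configuration")
    initial <- random_configuration(n)
  }
  initial <- check_configuration(initial)
  if (topology == "ring" && length(initial) < 2L)
    stop("ring topology needs at least 2 cells")
  boundary <- as.integer(boundary)
  res <- cpp_at_trajectory(initial, passive$outputs, as.integer(steps),
                           topology == "ring", boundary[1L], boundary[2L],
                           isTRUE(eq12_literal_a0))
  diagram <- new_ca_diagram(res$diagram, passive, "at",
                            if (is.null(seed)) NA_integer_ else seed,
                            if (topology == "ring") "periodic" else boundary)
  final <- at_state(res$diagram[nrow(res$diagram), ], passive,
                    active = res$active, time = as.integer(steps))
  list(diagram = diagram, state = final)
}

#' Export an active-rule field as a plain-text matrix
#'
#' Writes the `N x 8` active-rule field of an [at_state()] as
#' space-separated 0/1 rows for inspection or regression comparison.
#'
#' @param state An [at_state()].
#' @param path Output file path.
#' @export
write_active_field <- function(state, path) {
  if (!inherits(state, "at_state")) stop("state must be an at_state")
  utils::write.table(state$active, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
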