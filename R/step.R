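# Configuration and boundary validation shared by the step functions.

check_configuration <- function(config) {
  config <- as.integer(config)
  if (length(config) < 1L) stop("configuration must have at least one cell")
  if (anyNA(config) || !all(config %in% c(0L, 1L)))
    stop("configuration cells must all be 0 or 1")
  config
}

# boundary: "periodic" or a length-2 binary vector c(left, right).
# Returns list(periodic, left, right) with dummy clamp values on a ring.
check_boundary <- function(boundary) {
  if (identical(boundary, "periodic"))
    return(list(periodic = TRUE, left = 0L, right = 0L))
  if (is.character(boundary))
    stop("boundary must be \"periodic\" or a binary pair c(left, right)")
  boundary <- as.integer(boundary)
  if (length(boundary) != 2L || anyNA(boundary) ||
      !all(boundary %in% c(0L, 1L)))
    stop("boundary must be \"periodic\" or a binary pair c(left, right)")
  list(periodic = FALSE, left = boundary[1L], right = boundary[2L])
}

#' One synchronous ECA step
#'
#' Simultaneously replaces every cell by the rule applied to its
#' `(left, self, right)` neighbourhood. Edge cells read either their
#' periodic (ring) neighbours or the constant clamped boundary pair.
#'
#' @param config Binary vector of cell states.
#' @param rule An [eca_rule()] or rule number.
#' @param boundary `"periodic"` (default) or a binary pair `c(left, right)`
#'   clamped for all time steps.
#' @return The successor configuration (same length).
#' @examples
#' sync_step(c(0, 0, 1, 0, 0), 110)
#' @export
sync_step <- function(config, rule, boundary = "periodic") {
  config <- check_configuration(config)
  b <- check_boundary(boundary)
  cpp_sync_step(config, rule_outputs(rule), b$periodic, b$left, b$right)
}

#' One probabilistically asynchronous ECA step
#'
#' Each cell independently keeps its time-t state with probability `p` and
#' otherwise applies the rule to its time-t neighbourhood (all rule inputs
#' are read from time t, never from already-updated cells). `p = 0`
#' reduces to [sync_step()]; `p = 1` is the identity. Uses R's random
#' number generator; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams sync_step
#' @param p Probability in `[0, 1]` that a cell skips its update.
#' @return The successor configuration.
#' @export
async_step <- function(config, rule, p, boundary = "periodic") {
  config <- check_configuration(config)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a probability in [0, 1]")
  b <- check_boundary(boundary)
  cpp_async_step(config, rule_outputs(rule), p, b$periodic, b$left, b$right)
}

#' Random initial configuration
#'
#' i.i.d. Bernoulli(density) cell states, the standard initial condition
#' for pattern-generation runs.
#'
#' @param n Number of cells.
#' @param density Probability that a cell starts in state 1.
#' @return Binary vector of length `n`.
#' @export
random_configuration <- function(n, density = 0.5) {
  if (n < 1) stop("n must be >= 1")
  as.integer(stats::runif(n) < density)
}

new_ca_diagram <- function(rows, rule, regime, seed, boundary, p = NA_real_) {
  seed <- if (is.null(seed) || is.na(seed)) NA_integer_ else as.integer(seed)
  structure(rows,
            class = c("ca_diagram", "matrix"),
            rule = rule_number(rule), regime = regime, seed = seed,
            boundary = if (identical(boundary, "periodic")) "periodic"
                       else paste(boundary, collapse = ""),
            p = p)
}

#' Run a space-time trajectory
#'
#' Iterates a synchronous or probabilistically asynchronous ECA for
#' `steps` steps and records every configuration. Row `t + 1` of the
#' result is the configuration at time `t` (row 1 is the initial state).
#'
#' @inheritParams sync_step
#' @param initial Binary vector: the initial configuration.
#' @param regime `"sync"` or `"async"`.
#' @param steps Number of steps `T >= 0`; the diagram has `T + 1` rows.
#' @param p Skip probability for the `"async"` regime.
#' @param seed Optional integer seed; when supplied the run is fully
#'   reproducible (identical seed and inputs give a bit-identical diagram).
#' @return A `ca_diagram`: an integer matrix of 0/1 with one row per time
#'   step and metadata attributes (`rule`, `regime`, `seed`, `boundary`).
#' @examples
#' d <- run_trajectory(c(0, 0, 0, 1, 0, 0, 0), 110, steps = 5)
#' density_series(d)
#' @export
run_trajectory <- function(initial, rule, regime = c("sync", "async"),
                           steps, p = 0.25, seed = NULL,
                           boundary = "periodic") {
  regime <- match.arg(regime)
  initial <- check_configuration(initial)
  if (steps < 0) stop("steps must be >= 0")
  b <- check_boundary(boundary)
  if (!is.null(seed)) set.seed(seed)
  rows <- cpp_trajectory(initial, rule_outputs(rule),
                         if (regime == "sync") 0L else 1L,
                         p, as.integer(steps), b$periodic, b$left, b$right)
  new_ca_diagram(rows, rule, regime, if (is.null(seed)) NA_integer_ else seed,
                 boundary, p = if (regime == "async") p else NA_real_)
}

#' @export
print.ca_diagram <- function(x, ...) {
  cat(sprintf("Space-time diagram: %d steps x %d cells (rule %d, %s, %s boundary)\n",
              nrow(x) - 1L, ncol(x), attr(x, "rule"), attr(x, "regime"),
              attr(x, "boundary")))
  invisible(x)
}

#' Plot a space-time diagram
#'
#' Renders the diagram as an image with time running downward, one pixel
#' per cell (state 1 black, state 0 white).
#'
#' @param x A `ca_diagram`.
#' @param ... Further arguments passed to [graphics::image()].
#' @export
plot.ca_diagram <- function(x, ...) {
  m <- unclass(x)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)),
                  z = t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = c("white", "black"), axes = FALSE,
                  xlab = "cell", ylab = "time",
                  main = sprintf("rule %d (%s)", attr(x, "rule"),
                                 attr(x, "regime")), ...)
  invisible(x)
}
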