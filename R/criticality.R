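# Descriptive criticality diagnostics: density-of-ones decay exponent and
# periodogram spectral slope of the decimal-expression time series. These
# are estimator tools only; no reference exponents are hard-coded.

#' Density-of-ones time series of a diagram
#'
#' @param diagram A `ca_diagram` (or 0/1 matrix with one row per step).
#' @return Numeric vector; element `t + 1` is the fraction of cells in
#'   state 1 at time `t`.
#' @export
density_series <- function(diagram) {
  m <- unclass(diagram)
  if (!is.matrix(m) || nrow(m) < 1L) stop("diagram must be a nonempty matrix")
  rowMeans(m)
}

#' Decimal-expression time series of a diagram
#'
#' Maps each configuration row to a single number by reading the cells as
#' binary digits, leftmost cell most significant. By default the value is
#' normalized to `[0, 1)` with bit weights `2^-(i+1)` so that the series
#' is width-independent and never overflows; `raw = TRUE` returns the
#' plain integer reading (exact only for widths up to 62 bits).
#'
#' @param diagram A `ca_diagram` or 0/1 matrix.
#' @param raw Return raw integers instead of the normalized fraction.
#' @return Numeric vector, one value per diagram row.
#' @export
decimal_series <- function(diagram, raw = FALSE) {
  m <- unclass(diagram)
  if (!is.matrix(m) || nrow(m) < 1L) stop("diagram must be a nonempty matrix")
  n <- ncol(m)
  if (raw) {
    if (n > 62L) stop("raw decimal expression overflows beyond 62 cells")
    drop(m %*% 2^((n - 1):0))
  } else {
    drop(m %*% 2^-(1:n))
  }
}

#' Power-law decay exponent of a density series
#'
#' Least-squares slope of `log(density)` against `log(time)` over a
#' window, the standard descriptive estimate for a power-law decay
#' `rho(t) ~ t^alpha` (at an absorbing-state critical point the density
#' of occupied sites decays with a characteristic negative exponent).
#' The estimate is invariant to rescaling the series by a positive
#' constant. This is a plain regression fit, not a maximum-likelihood
#' power-law model.
#'
#' @param values Density series (e.g. from [density_series()]).
#' @param times Time of each value; defaults to `0, 1, ...` as produced
#'   from a diagram's rows.
#' @param fit_window Length-2 numeric `c(t_min, t_max)` restricting the
#'   fit to times in that closed range; defaults to all times `>= 1`.
#' @return A `powerlaw_fit` list: `slope`, `se`, `intercept`, `window`,
#'   `n_points`.
#' @examples
#' f <- powerlaw_exponent((1:200)^-0.5, times = 1:200)
#' f$slope  # -0.5
#' @export
powerlaw_exponent <- function(values, times = seq_along(values) - 1,
                              fit_window = NULL) {
  if (length(values) != length(times)) stop("values and times must align")
  if (is.null(fit_window)) fit_window <- c(1, max(times))
  keep <- times >= fit_window[1] & times <= fit_window[2]
  if (sum(keep) < 2L) stop("fit window contains fewer than 2 points")
  v <- values[keep]; tt <- times[keep]
  if (any(tt <= 0)) stop("fit window must only contain times > 0")
  if (any(v <= 0))
    stop("nonpositive densities in the fit window; shrink the window to the ",
         "decay segment before the series hits zero")
  fit <- stats::lm(log(v) ~ log(tt))
  # exact power laws fit perfectly; the zero-residual warning is expected
  est <- suppressWarnings(stats::coef(summary(fit)))
  structure(list(slope = unname(est["log(tt)", "Estimate"]),
                 se = unname(est["log(tt)", "Std. Error"]),
                 intercept = unname(est["(Intercept)", "Estimate"]),
                 window = fit_window, n_points = sum(keep)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("Power-law fit over t in [%g, %g] (%d points): slope %.4f (se %.2g)\n",
              x$window[1], x$window[2], x$n_points, x$slope, x$se))
  invisible(x)
}

#' Log-log spectral slope of a time series
#'
#' Raw periodogram of the mean-removed series (no taper, no padding)
#' followed by a least-squares fit of `log(power)` against
#' `log(frequency)` over a frequency window. A slope near 0 indicates
#' white noise, near -1 so-called 1/f noise, and near -2 a random-walk
#' (Brownian) spectrum. If a single periodogram ordinate carries more
#' than half of the total power the series is dominated by one frequency
#' and the fit is flagged as `concentrated`.
#'
#' @param series Numeric series of length `>= 64` (e.g. from
#'   [decimal_series()]).
#' @param fit_window Length-2 numeric frequency range (cycles per step,
#'   within `(0, 0.5]`); defaults to the full available range.
#' @return A `spectral_fit` list: `freq`, `power`, `slope`, `se`,
#'   `window`, `concentrated`.
#' @export
spectrum_slope <- function(series, fit_window = NULL) {
  series <- as.numeric(series)
  if (length(series) < 64L) stop("series must have at least 64 points")
  pg <- stats::spec.pgram(stats::ts(series), taper = 0, detrend = FALSE,
                          demean = TRUE, fast = FALSE, plot = FALSE)
  freq <- pg$freq
  power <- pg$spec
  if (is.null(fit_window)) fit_window <- range(freq)
  if (fit_window[1] < min(freq) - 1e-12 || fit_window[2] > max(freq) + 1e-12)
    stop(sprintf("fit window must lie within the frequency support [%g, %g]",
                 min(freq), max(freq)))
  keep <- freq >= fit_window[1] & freq <= fit_window[2] & power > 0
  if (sum(keep) < 2L) stop("fit window contains fewer than 2 usable frequencies")
  concentrated <- max(power) / sum(power) > 0.5
  fit <- stats::lm(log(power[keep]) ~ log(freq[keep]))
  est <- stats::coef(summary(fit))
  structure(list(freq = freq, power = power,
                 slope = unname(est[2, "Estimate"]),
                 se = unname(est[2, "Std. Error"]),
                 window = fit_window, concentrated = concentrated),
            class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf("Spectral fit over f in [%g, %g]: slope %.4f (se %.2g)%s\n",
              x$window[1], x$window[2], x$slope, x$se,
              if (x$concentrated)
                " [power concentrated at one frequency; slope unreliable]"
              else ""))
  invisible(x)
}

#' Plot a spectral fit on log-log axes
#'
#' @param x A `spectral_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spectral_fit <- function(x, ...) {
  graphics::plot(x$freq, x$power, log = "xy", type = "l", col = "grey50",
                 xlab = "frequency (cycles/step)", ylab = "power", ...)
  graphics::abline(stats::lm(log10(x$power[x$power > 0]) ~
                               log10(x$freq[x$power > 0])),
                   col = "firebrick", lwd = 2, untf = FALSE)
  invisible(x)
}
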