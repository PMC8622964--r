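#' Elementary cellular automaton rule table
#'
#' Builds the 8-entry transition table of an elementary cellular automaton
#' (ECA) from its Wolfram rule number. The table entry for the binary
#' neighbourhood `(x, y, z)` sits at index `s = 4x + 2y + z`, and the rule
#' number is the sum of `2^s * d_s` over s, so encoding and decoding are exact
#' inverses for all 256 rules.
#'
#' @param rule Either an integer rule number in `[0, 255]`, an existing
#'   `eca_rule`, or a length-8 binary vector of outputs `d_0 ... d_7`.
#' @return An object of class `eca_rule`: a list with elements `number`
#'   (the rule number) and `outputs` (integer vector of length 8, entry
#'   `k + 1` giving the output for neighbourhood index `k`).
#' @examples
#' eca_rule(110)
#' rule_outputs(eca_rule(204))  # f(x, y, z) = y: the identity rule
#' @export
eca_rule <- function(rule) {
  if (inherits(rule, "eca_rule")) return(rule)
  if (length(rule) == 8L) {
    outputs <- as.integer(rule)
    if (anyNA(outputs) || !all(outputs %in% c(0L, 1L)))
      stop("rule outputs must all be 0 or 1")
    number <- as.integer(sum(outputs * 2^(0:7)))
  } else if (length(rule) == 1L) {
    number <- rule
    if (is.na(number) || number != trunc(number) || number < 0 || number > 255)
      stop("rule number must be an integer in [0, 255], got ", format(rule))
    number <- as.integer(number)
    outputs <- as.integer(bitwAnd(bitwShiftR(number, 0:7), 1L))
  } else {
    stop("supply a rule number in [0, 255] or a length-8 output vector")
  }
  structure(list(number = number, outputs = outputs), class = "eca_rule")
}

#' @rdname eca_rule
#' @export
rule_number <- function(rule) eca_rule(rule)$number

#' @rdname eca_rule
#' @export
rule_outputs <- function(rule) eca_rule(rule)$outputs

#' Apply a rule table to a single neighbourhood
#'
#' @param rule An [eca_rule()] (or rule number).
#' @param x,y,z Binary states of the left neighbour, the cell itself, and
#'   the right neighbour.
#' @return The binary successor state.
#' @export
apply_rule <- function(rule, x, y, z) {
  rule_outputs(rule)[4L * x + 2L * y + z + 1L]
}

#' @export
format.eca_rule <- function(x, ...) {
  bits <- paste(rev(x$outputs), collapse = "")
  sprintf("ECA rule %d (d7..d0 = %s)", x$number, bits)
}

#' @export
print.eca_rule <- function(x, ...) {
  cat(format(x), "\n")
  tab <- data.frame(
    neighbourhood = vapply(0:7, function(s)
      paste(as.integer(bitwAnd(bitwShiftR(s, 2:0), 1L)), collapse = ""), ""),
    output = x$outputs
  )
  print(tab, row.names = FALSE)
  invisible(x)
}
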