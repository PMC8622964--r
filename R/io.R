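# Diagram and table writers/readers.

#' Write a space-time diagram to disk
#'
#' Formats: `"txt"` — plain-text 0/1 matrix, one row per time step,
#' cells space-separated, with metadata in `#`-comment header lines
#' (round-trips exactly through [read_diagram()]); `"pgm"` — ASCII PGM
#' image, one pixel per cell, time running downward, state 1 black;
#' `"png"` — PNG via the `png` package.
#'
#' @param diagram A `ca_diagram`.
#' @param path Output file path.
#' @param format `"txt"`, `"pgm"`, or `"png"`; guessed from the file
#'   extension when missing.
#' @return `path`, invisibly.
#' @export
write_diagram <- function(diagram, path, format = c("auto", "txt", "pgm", "png")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("txt", "pgm", "png")) ext else "txt"
  }
  m <- unclass(diagram)
  if (format == "txt") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# rule %s regime %s seed %s boundary %s",
                       attr(diagram, "rule"), attr(diagram, "regime"),
                       attr(diagram, "seed"), attr(diagram, "boundary")), con)
    writeLines(apply(m, 1L, paste, collapse = " "), con)
  } else if (format == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("# rule %s regime %s", attr(diagram, "rule"),
                               attr(diagram, "regime")),
                 sprintf("%d %d", ncol(m), nrow(m)), "1"), con)
    writeLines(apply(1L - m, 1L, paste, collapse = " "), con)
  } else {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required for PNG output")
    png::writePNG(1 - m, path)
  }
  invisible(path)
}

#' Read a plain-text space-time diagram
#'
#' Inverse of [write_diagram()] for the `"txt"` format.
#'
#' @param path File written by [write_diagram()].
#' @return A `ca_diagram` with the stored metadata re-attached.
#' @export
read_diagram <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  m <- do.call(rbind, lapply(strsplit(body, " +"), as.integer))
  meta <- list(rule = NA_integer_, regime = NA_character_,
               seed = NA_integer_, boundary = "periodic")
  if (length(header)) {
    tok <- strsplit(sub("^#\\s*", "", header[1L]), " +")[[1L]]
    val <- function(key) if (key %in% tok) tok[match(key, tok) + 1L] else NA
    meta$rule <- suppressWarnings(as.integer(val("rule")))
    meta$regime <- as.character(val("regime"))
    meta$seed <- suppressWarnings(as.integer(val("seed")))
    meta$boundary <- as.character(val("boundary"))
  }
  structure(m, class = c("ca_diagram", "matrix"),
            rule = meta$rule, regime = meta$regime, seed = meta$seed,
            boundary = meta$boundary, p = NA_real_)
}

#' Write a measure sweep as CSV
#'
#' @param sweep A `ca_sweep` from [sweep_all_rules()].
#' @param path Output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(as.data.frame(sweep), path, row.names = FALSE)
  invisible(path)
}

#' Read a measure sweep from CSV
#'
#' @param path CSV written by [write_sweep_csv()].
#' @return A `ca_sweep` data frame.
#' @export
read_sweep_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("ca_sweep", "data.frame")
  out
}

#' Serialize a tradeoff summary as JSON
#'
#' @param summary A `tradeoff_summary` from [tradeoff_breaks()].
#' @param path Output JSON path.
#' @export
write_tradeoff_json <- function(summary, path) {
  jsonlite::write_json(
    list(m = summary$m, alt_regime = summary$alt_regime,
         break_fraction = summary$break_fraction,
         emin = summary$emin, rules = summary$rules,
         per_interval = summary$per_interval),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
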