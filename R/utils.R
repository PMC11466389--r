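# Classed conditions so callers (and the CLI) can distinguish validation
# problems (bad inputs/config, exit code 1) from I/O problems (exit code 2).

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sewershedpop_validation_error",
                                "sewershedpop_error")))
}

abort_geometry <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sewershedpop_geometry_error",
                                "sewershedpop_validation_error",
                                "sewershedpop_error")))
}

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("sewershedpop_io_error", "sewershedpop_error")))
}

#' Round half away from zero
#'
#' Commercial rounding used for the integer percent-monitored column of the
#' coverage table (base R `round()` rounds half to even, which does not
#' reproduce published coverage tables).
#'
#' @param x numeric vector.
#' @return integer vector, halves rounded away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 44.59))
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Atomic write: run `writer(tmp)` then rename onto `path`, so an error never
# leaves a truncated file behind.
write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_io("output directory does not exist: %s", dir)
  }
  tmp <- tempfile(tmpdir = dir, fileext = paste0(".", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!suppressWarnings(file.rename(tmp, path))) {
    abort_io("could not write %s", path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
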