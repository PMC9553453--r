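# Internal helpers: typed conditions and leveled logging.

lrx_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lrx_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

lrx_format_error <- function(msg, ...) lrx_error("lrx_format_error", msg, ...)
lrx_config_error <- function(msg, ...) lrx_error("lrx_config_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

.log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set the package log level
#'
#' Messages below the chosen level are suppressed. Used by the command-line
#' interface (`--log-level`) and available interactively.
#'
#' @param level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return the previous level, invisibly.
#' @export
lrx_log_level <- function(level = c("info", "debug", "warn", "error")) {
  level <- match.arg(level)
  old <- getOption("lrxtalk.log_level", "info")
  options(lrxtalk.log_level = level)
  invisible(old)
}

lrx_log <- function(level, fmt, ...) {
  threshold <- .log_levels[[getOption("lrxtalk.log_level", "info")]]
  if (.log_levels[[level]] >= threshold) {
    message(sprintf("[lrxtalk %s] %s", level, sprintf(fmt, ...)))
  }
}

# Uppercase + trim gene symbols; the pipeline's single gene identity rule.
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    lrx_config_error(sprintf("'%s' must be a finite numeric scalar", name))
  }
  ok_lower <- if (strict_lower) x > lower else x >= lower
  if (!ok_lower || x > upper) {
    lrx_config_error(sprintf("'%s' = %s out of allowed range", name, format(x)))
  }
  invisible(x)
}
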