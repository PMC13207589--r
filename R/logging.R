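#' Package logging
#'
#' All automatic corrections (coordinate-column swap, positive-semi-definite
#' projection, tie-breaks, clipped variances, clamped classes) are reported on
#' standard error through this logger.  Verbosity is controlled by
#' `options(isokrig.log_level = "info"|"warn"|"off")`; default `"info"`.
#'
#' @param level One of `"info"`, `"warn"`.
#' @param fmt `sprintf` format string.
#' @param ... Values for `fmt`.
#' @return Invisibly, the formatted message.
#' @keywords internal
iso_log <- function(level = c("info", "warn"), fmt, ...) {
  level <- match.arg(level)
  opt <- getOption("isokrig.log_level", "info")
  show <- switch(opt,
    off = FALSE,
    warn = level == "warn",
    TRUE)
  msg <- sprintf("[isokrig %s] %s", toupper(level), sprintf(fmt, ...))
  if (show) message(msg)
  invisible(msg)
}
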