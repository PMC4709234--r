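#' Configure emulation logging
#'
#' Routes per-LPU log messages to a shared plain-text log file and/or the
#' console. Messages are prefixed with the emitting LPU's id.
#'
#' @param fileName path of the log file, or NULL to disable file logging.
#' @param screen also print messages to the console.
#' @return invisibly, the previous settings.
#' @export
setupLogger <- function(fileName = NULL, screen = FALSE) {
  old <- options(lpuSim.logFile = fileName, lpuSim.logScreen = screen)
  if (!is.null(fileName) && !file.exists(fileName))
    file.create(fileName)
  invisible(old)
}

#' Emit a tagged log message from inside a hook
#'
#' @param state the hook's state environment (carries the LPU id).
#' @param ... message parts, pasted together.
#' @return invisibly, the formatted line.
#' @export
lpuLog <- function(state, ...) {
  line <- sprintf("[%s] %s", if (!is.null(state$lpuId)) state$lpuId else "?",
                  paste0(..., collapse = ""))
  f <- getOption("lpuSim.logFile")
  if (!is.null(f)) cat(line, "\n", file = f, append = TRUE, sep = "")
  if (isTRUE(getOption("lpuSim.logScreen"))) message(line)
  invisible(line)
}
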