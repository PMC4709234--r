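setValidity("PortMapper", function(object) {
  msgs <- character(0)
  if (!object@kind %in% c("gpot", "spike"))
    msgs <- c(msgs, "kind must be 'gpot' or 'spike'")
  if (length(object@buffer) != length(object@ids))
    msgs <- c(msgs, "buffer length must equal number of ports")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "duplicate identifiers")
  if (object@kind == "spike" && length(object@buffer) &&
      !all(object@buffer %in% c(0, 1)))
    msgs <- c(msgs, "spike buffer values must be 0 or 1")
  if (object@kind == "gpot" && length(object@buffer) &&
      !all(is.finite(object@buffer)))
    msgs <- c(msgs, "gpot buffer values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Build a port mapper over a zeroed value buffer
#'
#' Maps the ports denoted by a wildcard-free selector to the contiguous
#' 0-based indices of a value buffer, in the selector's expansion order.
#' Graded-potential buffers hold doubles; spike buffers hold 0/1 integers.
#' The buffer is zero-initialized.
#'
#' @param sel wildcard-free selector (or identifier vector).
#' @param kind `"gpot"` or `"spike"`.
#' @return a [PortMapper].
#' @examples
#' m <- portMapper("/lam[0:3]", "gpot")
#' portIndex(m)  # /lam[0] -> 0, /lam[1] -> 1, /lam[2] -> 2
#' @export
portMapper <- function(sel, kind = c("gpot", "spike")) {
  kind <- match.arg(kind)
  ids <- .ids(sel)
  new("PortMapper", ids = ids, kind = kind,
      buffer = numeric(length(ids)))
}

#' 0-based array index of each port in a mapper
#'
#' @param x a [PortMapper].
#' @return named integer vector of 0-based indices, in port order.
#' @export
portIndex <- function(x) {
  stats::setNames(seq_along(x@ids) - 1L, x@ids)
}

.mapperIdx <- function(x, sel) {
  ids <- .ids(sel)
  idx <- match(ids, x@ids)
  if (anyNA(idx))
    .selStop(sprintf("unknown port(s): %s",
                     paste(utils::head(ids[is.na(idx)], 3), collapse = ", ")),
             "unknownPortError")
  idx
}

#' Read port values by selector
#'
#' @param x a [PortMapper].
#' @param sel selector for the ports to read; all must exist in the mapper.
#' @param ... unused.
#' @return numeric vector of values in the selector's expansion order.
#' @export
#' @rdname getValues
setMethod("getValues", "PortMapper", function(x, sel, ...) {
  unname(x@buffer[.mapperIdx(x, sel)])
})

#' Write port values by selector
#'
#' Sets the selected ports to `values` (matched positionally against the
#' selector's expansion order); all other entries are untouched. Spike
#' mappers only accept values in \{0, 1\}.
#'
#' @param x a [PortMapper].
#' @param sel selector for the ports to write.
#' @param values numeric vector, one value per selected port.
#' @param ... unused.
#' @return the updated [PortMapper].
#' @export
#' @rdname setValues
setMethod("setValues", "PortMapper", function(x, sel, values, ...) {
  idx <- .mapperIdx(x, sel)
  if (length(values) != length(idx))
    .selStop(sprintf("expected %d value(s), got %d",
                     length(idx), length(values)), "lengthMismatchError")
  if (x@kind == "spike" && !all(values %in% c(0, 1)))
    .selStop("spike values must be 0 or 1", "domainError")
  if (x@kind == "gpot" && !all(is.finite(values)))
    .selStop("gpot values must be finite", "domainError")
  x@buffer[idx] <- values
  x
})

#' @export
setMethod("length", "PortMapper", function(x) length(x@ids))

#' @export
setMethod("show", "PortMapper", function(object) {
  cat(formatMapper(object), sep = "\n")
  invisible(object)
})

#' Format a mapper as a port/index/data table
#'
#' Renders the identifier-to-index layout and current buffer contents of a
#' mapper, one line per port, suitable for logs and documentation.
#'
#' @param x a [PortMapper].
#' @param digits digits for graded-potential values.
#' @return character vector of table lines (header + one row per port).
#' @examples
#' m <- setValues(portMapper("/lam[0:3]", "gpot"), "/lam[0:3]",
#'                c(0.71, 0.83, 0.52))
#' cat(formatMapper(m), sep = "\n")
#' @export
formatMapper <- function(x, digits = 2) {
  vals <- if (x@kind == "spike") format(as.integer(x@buffer))
          else format(round(x@buffer, digits), nsmall = 0)
  rows <- c("Port\tArray Index\tArray Data",
            if (length(x@ids))
              paste(x@ids, seq_along(x@ids) - 1L, trimws(vals), sep = "\t"))
  rows
}

#' Dump a mapper to a delimited text file
#'
#' Debugging helper: writes the port/index/data table of [formatMapper()]
#' as tab-separated text.
#'
#' @param x a [PortMapper].
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
dumpMapper <- function(x, file) {
  writeLines(formatMapper(x), file)
  invisible(file)
}
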