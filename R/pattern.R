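.emptyPorts <- function() {
  data.frame(identifier = character(0), interface = integer(0),
              io = character(0), transmission = character(0),
              stringsAsFactors = FALSE)
}

.emptyConnections <- function() {
  data.frame(source = character(0), destination = character(0),
              stringsAsFactors = FALSE)
}

setValidity("Pattern", function(object) {
  p <- object@ports
  k <- object@connections
  msgs <- character(0)
  if (!all(c("identifier", "interface", "io", "transmission") %in% names(p)))
    return("ports must have columns identifier, interface, io, transmission")
  if (anyDuplicated(p$identifier))
    msgs <- c(msgs, "duplicate port identifiers")
  if (!all(p$interface %in% c(0L, 1L)))
    msgs <- c(msgs, "interface labels must be 0 or 1")
  if (!all(is.na(p$io) | p$io %in% c("in", "out")))
    msgs <- c(msgs, "io must be 'in', 'out', or NA")
  if (!all(is.na(p$transmission) | p$transmission %in% c("gpot", "spike")))
    msgs <- c(msgs, "transmission must be 'gpot', 'spike', or NA")
  if (nrow(k) > 0) {
    si <- match(k$source, p$identifier)
    di <- match(k$destination, p$identifier)
    if (anyNA(si) || anyNA(di))
      msgs <- c(msgs, "connection endpoint not registered as a port")
    else {
      if (any(p$interface[si] == p$interface[di]))
        msgs <- c(msgs, "connection endpoints must lie on opposite interfaces")
      if (!all(p$io[si] == "in" & p$io[di] == "out"))
        msgs <- c(msgs,
          "connections must run from an 'in' port to an 'out' port")
      if (!all(p$transmission[si] == p$transmission[di]) ||
          anyNA(p$transmission[si]))
        msgs <- c(msgs, "connection endpoints must share a transmission kind")
      if (anyDuplicated(k$destination))
        msgs <- c(msgs, "a destination port may have at most one source")
      if (anyDuplicated(paste(k$source, k$destination)))
        msgs <- c(msgs, "duplicate connection")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Create an inter-LPU connectivity pattern
#'
#' Registers the ports of the two interfaces (labels 0 and 1). The two
#' identifier sets must be disjoint. Port io/transmission attributes are
#' unset until [setPortAttributes()] is called; connections are added with
#' [addConnections()].
#'
#' @param sel0,sel1 selectors (or identifier vectors) naming the ports of
#'   interface 0 and interface 1.
#' @return a [Pattern] with no connections.
#' @examples
#' p <- makePattern("/lam[0:6]", "/med[0:5]")
#' nrow(ports(p))  # 11
#' @export
makePattern <- function(sel0, sel1) {
  ids0 <- .ids(sel0)
  ids1 <- .ids(sel1)
  both <- intersect(ids0, ids1)
  if (length(both) > 0)
    .selStop(sprintf("identifier(s) present in both interfaces: %s",
                     paste(utils::head(both, 3), collapse = ", ")),
             "overlapError")
  n <- length(ids0) + length(ids1)
  ports <- data.frame(
    identifier = c(ids0, ids1),
    interface = rep(c(0L, 1L), c(length(ids0), length(ids1))),
    io = rep(NA_character_, n), transmission = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  new("Pattern", ports = ports, connections = .emptyConnections())
}

#' Pattern port and connection tables
#'
#' @param x a [Pattern].
#' @return `ports()`: the port attribute table; `connections()`: the
#'   source/destination connection table; `connectionCount()`: the number of
#'   stored connections.
#' @export
ports <- function(x) x@ports

#' @rdname ports
#' @export
connections <- function(x) x@connections

#' @rdname ports
#' @export
connectionCount <- function(x) nrow(x@connections)

#' Set the io/transmission attributes of pattern ports
#'
#' Directions are pattern-relative: mark an LPU's *output* ports as `"in"`
#' (they feed data into the pattern) and its *input* ports as `"out"` (the
#' pattern delivers data to them).
#'
#' Re-setting attributes is idempotent; a change that would violate the
#' invariants of existing connections is rejected.
#'
#' @param x a [Pattern].
#' @param sel selector for the ports to set (must all belong to `interface`).
#' @param interface interface label, 0 or 1.
#' @param io `"in"` or `"out"` (pattern-relative).
#' @param transmission `"gpot"` or `"spike"`.
#' @param ... unused.
#' @return the updated [Pattern].
#' @export
#' @rdname setPortAttributes
setMethod("setPortAttributes", "Pattern",
          function(x, sel, interface, io, transmission, ...) {
  ids <- .ids(sel)
  io <- match.arg(io, c("in", "out"))
  transmission <- match.arg(transmission, c("gpot", "spike"))
  interface <- as.integer(interface)
  idx <- match(ids, x@ports$identifier)
  if (anyNA(idx))
    .selStop(sprintf("unknown port(s): %s",
                     paste(utils::head(ids[is.na(idx)], 3), collapse = ", ")),
             "unknownPortError")
  wrongIface <- x@ports$interface[idx] != interface
  if (any(wrongIface))
    .selStop(sprintf("port(s) not on interface %d: %s", interface,
                     paste(utils::head(ids[wrongIface], 3), collapse = ", ")),
             "interfaceMismatchError")
  x@ports$io[idx] <- io
  x@ports$transmission[idx] <- transmission
  v <- validObject(x, test = TRUE)
  if (!isTRUE(v))
    .selStop(paste("attribute change violates pattern invariants:",
                   paste(v, collapse = "; ")), "invariantViolationError")
  x
})

#' Add connections between pattern ports
#'
#' Adds directed connections from `src` (pattern `"in"`) ports to `dst`
#' (pattern `"out"`) ports. `src` and `dst` are paired elementwise and must
#' expand to equal length. All endpoints must already carry attributes.
#' Violations raise classed errors: `fanInError` (destination already has a
#' source), `typeMismatchError` (transmission kinds differ),
#' `directionError`, `sameInterfaceError`, `unknownPortError`.
#'
#' @param x a [Pattern].
#' @param src,dst selectors or identifier vectors of equal expanded length.
#' @param ... unused.
#' @return the updated [Pattern].
#' @export
#' @rdname addConnections
setMethod("addConnections", "Pattern", function(x, src, dst, ...) {
  # character vectors keep their duplicates (fan-out pairs the same source
  # with several destinations); selectors expand duplicate-free as usual
  asPairs <- function(s)
    if (is.character(s)) .canonicalizeIds(s) else expandSelector(s)
  srcIds <- asPairs(src)
  dstIds <- asPairs(dst)
  if (length(srcIds) == 1L && length(dstIds) > 1L)  # fan-out convenience
    srcIds <- rep(srcIds, length(dstIds))
  if (length(srcIds) != length(dstIds))
    .selStop(sprintf("source/destination cardinality mismatch (%d vs %d)",
                     length(srcIds), length(dstIds)), "cardinalityError")
  p <- x@ports
  si <- match(srcIds, p$identifier)
  di <- match(dstIds, p$identifier)
  if (anyNA(si) || anyNA(di))
    .selStop(sprintf("unknown port(s): %s",
      paste(utils::head(c(srcIds[is.na(si)], dstIds[is.na(di)]), 3),
            collapse = ", ")), "unknownPortError")
  if (anyNA(p$io[si]) || anyNA(p$io[di]))
    .selStop("ports must have attributes set before connecting",
             "unsetAttributesError")
  bad <- p$interface[si] == p$interface[di]
  if (any(bad))
    .selStop(sprintf("endpoints on the same interface: %s -> %s",
                     srcIds[bad][1], dstIds[bad][1]), "sameInterfaceError")
  bad <- p$io[si] != "in" | p$io[di] != "out"
  if (any(bad))
    .selStop(sprintf(
      "connection must run from a pattern 'in' port to an 'out' port: %s -> %s",
      srcIds[bad][1], dstIds[bad][1]), "directionError")
  bad <- p$transmission[si] != p$transmission[di]
  if (any(bad))
    .selStop(sprintf("transmission kinds differ: %s (%s) -> %s (%s)",
                     srcIds[bad][1], p$transmission[si][bad][1],
                     dstIds[bad][1], p$transmission[di][bad][1]),
             "typeMismatchError")
  allDst <- c(x@connections$destination, dstIds)
  dup <- duplicated(allDst)[-seq_len(nrow(x@connections))]
  if (any(dup))
    .selStop(sprintf(
      "destination port %s already has a source (fan-in is prohibited)",
      dstIds[dup][1]), "fanInError")
  newRows <- data.frame(source = srcIds, destination = dstIds,
                        stringsAsFactors = FALSE)
  x@connections <- rbind(x@connections, newRows)
  x
})

#' @describeIn addConnections single-connection convenience wrapper.
#' @param pattern a [Pattern].
#' @export
addConnection <- function(pattern, src, dst) addConnections(pattern, src, dst)

#' Check compatibility between a pattern interface and an LPU interface
#'
#' An LPU is compatible with a pattern interface when every *connected*
#' pattern port on that interface matches an LPU port by identifier and
#' transmission kind, and directions correspond: a pattern `"in"` port must
#' be an LPU output port, a pattern `"out"` port an LPU input port.
#' Unconnected pattern ports are ignored. A pattern with no connections is
#' vacuously compatible with any LPU.
#'
#' @param x a [Pattern].
#' @param interface interface label, 0 or 1.
#' @param lpuInterface an [LPUSpec], or a data.frame with columns
#'   `identifier`, `io` (LPU-relative `"in"`/`"out"`), `transmission`.
#' @param ... unused.
#' @return a list of class `"compatibilityReport"` with elements
#'   `compatible` (logical) and `mismatches` (data.frame `identifier`,
#'   `problem`, one row per mismatch).
#' @export
#' @rdname checkCompatibility
setMethod("checkCompatibility", "Pattern",
          function(x, interface, lpuInterface, ...) {
  if (is(lpuInterface, "LPUSpec")) lpuInterface <- lpuInterface@interface
  interface <- as.integer(interface)
  p <- x@ports
  used <- unique(c(x@connections$source, x@connections$destination))
  sel <- p$identifier %in% used & p$interface == interface
  mism <- data.frame(identifier = character(0), problem = character(0),
                     stringsAsFactors = FALSE)
  if (any(sel)) {
    pp <- p[sel, , drop = FALSE]
    li <- match(pp$identifier, lpuInterface$identifier)
    missing <- is.na(li)
    if (any(missing))
      mism <- rbind(mism, data.frame(identifier = pp$identifier[missing],
                                     problem = "not exposed by LPU"))
    ok <- !missing
    if (any(ok)) {
      tmis <- pp$transmission[ok] != lpuInterface$transmission[li[ok]]
      if (any(tmis))
        mism <- rbind(mism, data.frame(
          identifier = pp$identifier[ok][tmis],
          problem = "transmission kind mismatch"))
      # pattern 'in' <-> LPU 'out'; pattern 'out' <-> LPU 'in'
      want <- ifelse(pp$io[ok] == "in", "out", "in")
      dmis <- want != lpuInterface$io[li[ok]]
      if (any(dmis))
        mism <- rbind(mism, data.frame(
          identifier = pp$identifier[ok][dmis],
          problem = "direction mismatch"))
    }
  }
  structure(list(compatible = nrow(mism) == 0L, mismatches = mism),
            class = "compatibilityReport")
})

#' @export
print.compatibilityReport <- function(x, ...) {
  cat("Compatibility:", if (x$compatible) "compatible" else "INCOMPATIBLE",
      "\n")
  if (nrow(x$mismatches)) print(x$mismatches)
  invisible(x)
}

#' Selector of connected ports on one pattern interface
#'
#' Returns a selector denoting exactly the ports on the given interface with
#' the given pattern-relative direction that participate in at least one
#' connection.
#'
#' @param x a [Pattern].
#' @param interface interface label, 0 or 1.
#' @param direction pattern-relative `"in"` or `"out"`.
#' @param ... unused.
#' @return a [PortSelector] (possibly empty).
#' @export
#' @rdname connectedPorts
setMethod("connectedPorts", "Pattern", function(x, interface, direction, ...) {
  direction <- match.arg(direction, c("in", "out"))
  interface <- as.integer(interface)
  p <- x@ports
  used <- if (direction == "in") unique(x@connections$source)
          else unique(x@connections$destination)
  ids <- p$identifier[p$identifier %in% used &
                        p$interface == interface & p$io == direction]
  portSelector(ids)
})

#' @export
setMethod("show", "Pattern", function(object) {
  p <- object@ports
  cat("Pattern with ", nrow(p), " port(s) (",
      sum(p$interface == 0L), " on interface 0, ",
      sum(p$interface == 1L), " on interface 1) and ",
      nrow(object@connections), " connection(s)\n", sep = "")
  invisible(object)
})
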