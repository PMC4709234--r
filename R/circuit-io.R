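# Readers/writers for declarative circuit documents.
#
# LPU GEXF schema (GEXF 1.2, self-defined attribute vocabulary, version
# "lpuSim-1"): every <node> is either a component (attribute `model` naming
# a registry entry, optional `params` serialized as "name=value;...") or a
# port (attribute `port` holding the identifier, plus `io` and
# `transmission`). Edges are directed: port -> component binds an input
# port, component -> port binds an output port, component -> component is
# an internal connection. Identifiers in files use canonical bracket form.
#
# Pattern CSV dialect: a two-column connection table with header
# "source,destination" and a four-column attribute table with header
# "identifier,interface,io,transmission"; io in {in, out} (pattern-
# relative), transmission in {gpot, spike}.

.gexfNs <- "http://www.gexf.net/1.2draft"

.ioStop <- function(msg, locator, class = "documentError") {
  stop(errorCondition(sprintf("%s (%s)", msg, locator),
                      class = c(class, "lpuSimError")))
}

.serializeParams <- function(p) {
  if (length(p) == 0) return("")
  paste(names(p), format(unname(p), digits = 17, scientific = TRUE,
                         trim = TRUE), sep = "=", collapse = ";")
}

.deserializeParams <- function(s, locator) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    .ioStop(sprintf("malformed params entry '%s'", parts[bad][1]), locator)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, character(1), 2L)))
  if (anyNA(vals))
    .ioStop("non-numeric parameter value", locator)
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1L))
}

#' Write an LPU specification as GEXF
#'
#' Stores the component graph, port nodes, and bindings of an [LPUSpec] as
#' a GEXF 1.2 property graph (see the schema notes in the vignette).
#' [readLpuGexf()] of the result reconstructs an equivalent spec.
#'
#' @param spec an [LPUSpec].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeLpuGexf <- function(spec, file) {
  doc <- xml2::xml_new_root("gexf", xmlns = .gexfNs, version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed",
                               label = spec@id)
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  titles <- c("model", "params", "port", "io", "transmission")
  for (k in seq_along(titles))
    xml2::xml_add_child(attrs, "attribute", id = as.character(k - 1L),
                        title = titles[k], type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  addNode <- function(id, vals) {
    nd <- xml2::xml_add_child(nodes, "node", id = id, label = id)
    av <- xml2::xml_add_child(nd, "attvalues")
    for (k in seq_along(titles))
      if (!is.na(vals[k]) && nzchar(vals[k]))
        xml2::xml_add_child(av, "attvalue", "for" = as.character(k - 1L),
                            value = vals[k])
  }
  comps <- spec@components
  for (i in seq_len(nrow(comps)))
    addNode(comps$component[i],
            c(comps$model[i], .serializeParams(comps$params[[i]]),
              NA, NA, NA))
  iface <- spec@interface
  for (i in seq_len(nrow(iface)))
    addNode(iface$identifier[i],
            c(NA, NA, iface$identifier[i], iface$io[i],
              iface$transmission[i]))
  edges <- xml2::xml_add_child(graph, "edges")
  eid <- 0L
  addEdge <- function(from, to) {
    xml2::xml_add_child(edges, "edge", id = as.character(eid),
                        source = from, target = to)
    eid <<- eid + 1L
  }
  for (i in seq_len(nrow(spec@edges)))
    addEdge(spec@edges$from[i], spec@edges$to[i])
  b <- spec@bindings
  bio <- iface$io[match(b$port, iface$identifier)]
  for (i in seq_len(nrow(b))) {
    if (identical(bio[i], "in")) addEdge(b$port[i], b$component[i])
    else addEdge(b$component[i], b$port[i])
  }
  xml2::write_xml(doc, file)
  invisible(file)
}

.attvalMap <- function(node, titleById) {
  avs <- xml2::xml_find_all(node, "./attvalues/attvalue")
  vals <- xml2::xml_attr(avs, "value")
  stats::setNames(vals, titleById[xml2::xml_attr(avs, "for")])
}

#' Read an LPU specification from GEXF
#'
#' Parses a GEXF property graph into an [LPUSpec] and checks it against the
#' model registry; schema violations (missing model attribute, unknown
#' model name, malformed port identifier) are raised with the offending
#' node id.
#'
#' @param file path to a GEXF file written by [writeLpuGexf()] or
#'   conforming to the documented schema.
#' @param registry model registry used to resolve model names.
#' @param id optional LPU id override; defaults to the graph label.
#' @return an [LPUSpec] passing [validateSpec()].
#' @export
readLpuGexf <- function(file, registry = defaultRegistry(), id = NULL) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  graph <- xml2::xml_find_first(doc, "./graph")
  if (inherits(graph, "xml_missing"))
    .ioStop("no <graph> element", file)
  if (is.null(id)) {
    id <- xml2::xml_attr(graph, "label")
    if (is.na(id)) id <- tools::file_path_sans_ext(basename(file))
  }
  attrNodes <- xml2::xml_find_all(graph, "./attributes[@class='node']/attribute")
  titleById <- stats::setNames(xml2::xml_attr(attrNodes, "title"),
                               xml2::xml_attr(attrNodes, "id"))
  nodes <- xml2::xml_find_all(graph, "./nodes/node")
  comp <- list(); iface <- list()
  nodeKind <- character(0)
  for (nd in nodes) {
    nid <- xml2::xml_attr(nd, "id")
    vals <- .attvalMap(nd, titleById)
    if (!is.na(vals["model"]) && nzchar(vals["model"])) {
      modelInfo(registry, vals[["model"]])  # unknown model -> error
      comp[[length(comp) + 1L]] <- data.frame(
        component = nid, model = vals[["model"]],
        params = I(list(.deserializeParams(
          if ("params" %in% names(vals)) vals[["params"]] else "",
          paste0("node ", nid)))),
        stringsAsFactors = FALSE)
      nodeKind[nid] <- "component"
    } else if (!is.na(vals["port"]) && nzchar(vals["port"])) {
      pid <- tryCatch(.canonicalizeIds(vals[["port"]]),
        error = function(e) .ioStop(
          sprintf("malformed port identifier '%s'", vals[["port"]]),
          paste0("node ", nid)))
      io <- vals["io"]; tr <- vals["transmission"]
      if (is.na(io) || !io %in% c("in", "out"))
        .ioStop("port node lacks a valid io attribute", paste0("node ", nid))
      if (is.na(tr) || !tr %in% c("gpot", "spike"))
        .ioStop("port node lacks a valid transmission attribute",
                paste0("node ", nid))
      iface[[length(iface) + 1L]] <- data.frame(
        identifier = pid, io = unname(io), transmission = unname(tr),
        stringsAsFactors = FALSE)
      names(iface)[length(iface)] <- nid
      nodeKind[nid] <- "port"
    } else {
      .ioStop("node is neither a component (model) nor a port",
              paste0("node ", nid))
    }
  }
  comps <- if (length(comp)) do.call(rbind, comp) else .emptyComponents()
  ifaceDf <- if (length(iface)) do.call(rbind, c(iface, make.row.names = FALSE))
             else interfaceTable()
  portOf <- stats::setNames(ifaceDf$identifier, names(iface))
  edges <- xml2::xml_find_all(graph, "./edges/edge")
  intEdges <- list(); bindings <- list()
  for (ed in edges) {
    s <- xml2::xml_attr(ed, "source"); t <- xml2::xml_attr(ed, "target")
    ks <- nodeKind[s]; kt <- nodeKind[t]
    if (is.na(ks) || is.na(kt))
      .ioStop("edge references unknown node",
              paste0("edge ", xml2::xml_attr(ed, "id")))
    if (ks == "component" && kt == "component") {
      intEdges[[length(intEdges) + 1L]] <- data.frame(
        from = s, to = t, stringsAsFactors = FALSE)
    } else if (ks == "port" && kt == "component") {
      bindings[[length(bindings) + 1L]] <- data.frame(
        port = unname(portOf[s]), component = t, stringsAsFactors = FALSE)
    } else if (ks == "component" && kt == "port") {
      bindings[[length(bindings) + 1L]] <- data.frame(
        port = unname(portOf[t]), component = s, stringsAsFactors = FALSE)
    } else {
      .ioStop("edge connects two ports",
              paste0("edge ", xml2::xml_attr(ed, "id")))
    }
  }
  spec <- lpuSpec(id, ifaceDf,
                  components = comps,
                  edges = if (length(intEdges)) do.call(rbind, intEdges)
                          else .emptyEdges(),
                  bindings = if (length(bindings)) do.call(rbind, bindings)
                             else .emptyBindings())
  rep <- validateSpec(spec)
  if (nrow(rep) > 0)
    .ioStop(paste("invalid LPU document:",
                  paste(rep$message, collapse = "; ")), file)
  spec
}

#' Write a connectivity pattern as CSV tables
#'
#' Writes the connection table (`source,destination`) and the port
#' attribute table (`identifier,interface,io,transmission`) of a [Pattern]
#' as two CSV files; [readPatternCsv()] of the result reconstructs the
#' pattern exactly.
#'
#' @param pattern a [Pattern].
#' @param connectionsFile,portsFile output paths.
#' @return invisibly, `c(connectionsFile, portsFile)`.
#' @export
writePatternCsv <- function(pattern, connectionsFile, portsFile) {
  utils::write.csv(pattern@connections, connectionsFile, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(pattern@ports, portsFile, row.names = FALSE,
                   quote = FALSE)
  invisible(c(connectionsFile, portsFile))
}

#' Read a connectivity pattern from CSV tables
#'
#' Reconstructs a [Pattern] from the two-table CSV dialect of
#' [writePatternCsv()]. File-level violations of the pattern invariants are
#' reported with the offending row number: fan-in (`fanInError`),
#' transmission mismatch (`typeMismatchError`), malformed identifiers, and
#' connections referencing unlisted ports.
#'
#' @param connectionsFile CSV with header `source,destination`.
#' @param portsFile CSV with header `identifier,interface,io,transmission`.
#' @return a [Pattern] satisfying all pattern invariants.
#' @export
readPatternCsv <- function(connectionsFile, portsFile) {
  pts <- utils::read.csv(portsFile, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("identifier", "interface", "io", "transmission")
  if (!identical(names(pts), need))
    .ioStop(sprintf("expected header '%s'", paste(need, collapse = ",")),
            portsFile)
  kon <- utils::read.csv(connectionsFile, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!identical(names(kon), c("source", "destination")))
    .ioStop("expected header 'source,destination'", connectionsFile)
  pts$interface <- suppressWarnings(as.integer(pts$interface))
  for (i in seq_len(nrow(pts))) {
    loc <- paste0(portsFile, " row ", i)
    if (is.na(pts$interface[i]) || !pts$interface[i] %in% c(0L, 1L))
      .ioStop("interface label must be 0 or 1", loc)
    if (!pts$io[i] %in% c("in", "out"))
      .ioStop("io must be 'in' or 'out'", loc)
    if (!pts$transmission[i] %in% c("gpot", "spike"))
      .ioStop("transmission must be 'gpot' or 'spike'", loc)
    pts$identifier[i] <- tryCatch(.canonicalizeIds(pts$identifier[i]),
      error = function(e) .ioStop(sprintf("malformed identifier '%s'",
                                          pts$identifier[i]), loc))
  }
  p <- makePattern(pts$identifier[pts$interface == 0L],
                   pts$identifier[pts$interface == 1L])
  for (grp in split(seq_len(nrow(pts)),
                    paste(pts$interface, pts$io, pts$transmission)))
    p <- setPortAttributes(p, pts$identifier[grp], pts$interface[grp[1]],
                           pts$io[grp[1]], pts$transmission[grp[1]])
  if (nrow(kon)) {
    for (i in seq_len(nrow(kon))) {
      loc <- paste0(connectionsFile, " row ", i)
      kon$source[i] <- tryCatch(.canonicalizeIds(kon$source[i]),
        error = function(e) .ioStop(sprintf("malformed identifier '%s'",
                                            kon$source[i]), loc))
      kon$destination[i] <- tryCatch(.canonicalizeIds(kon$destination[i]),
        error = function(e) .ioStop(sprintf("malformed identifier '%s'",
                                            kon$destination[i]), loc))
    }
    # locate invariant violations by row before building
    dup <- duplicated(kon$destination)
    if (any(dup))
      .ioStop(sprintf("destination %s already has a source (fan-in)",
                      kon$destination[dup][1]),
              paste0(connectionsFile, " row ", which(dup)[1]), "fanInError")
    ti <- match(kon$source, pts$identifier)
    tj <- match(kon$destination, pts$identifier)
    if (anyNA(ti) || anyNA(tj))
      .ioStop("connection references a port missing from the attribute table",
              paste0(connectionsFile, " row ",
                     which(is.na(ti) | is.na(tj))[1]), "unknownPortError")
    mism <- pts$transmission[ti] != pts$transmission[tj]
    if (any(mism))
      .ioStop("transmission kinds differ between endpoints",
              paste0(connectionsFile, " row ", which(mism)[1]),
              "typeMismatchError")
    p <- addConnections(p, kon$source, kon$destination)
  }
  p
}

#' Write / read a pattern as GEXF
#'
#' GEXF alternative to the CSV dialect: port nodes carry `interface`, `io`
#' and `transmission` attributes; directed edges are the connections.
#'
#' @param pattern a [Pattern].
#' @param file path.
#' @return `writePatternGexf()`: `file` invisibly; `readPatternGexf()`: a
#'   [Pattern].
#' @export
writePatternGexf <- function(pattern, file) {
  doc <- xml2::xml_new_root("gexf", xmlns = .gexfNs, version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  titles <- c("interface", "io", "transmission")
  for (k in seq_along(titles))
    xml2::xml_add_child(attrs, "attribute", id = as.character(k - 1L),
                        title = titles[k], type = "string")
  nodes <- xml2::xml_add_child(graph, "nodes")
  pp <- pattern@ports
  for (i in seq_len(nrow(pp))) {
    nd <- xml2::xml_add_child(nodes, "node", id = pp$identifier[i],
                              label = pp$identifier[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    vals <- c(as.character(pp$interface[i]), pp$io[i], pp$transmission[i])
    for (k in seq_along(titles))
      if (!is.na(vals[k]))
        xml2::xml_add_child(av, "attvalue", "for" = as.character(k - 1L),
                            value = vals[k])
  }
  edges <- xml2::xml_add_child(graph, "edges")
  kk <- pattern@connections
  for (i in seq_len(nrow(kk)))
    xml2::xml_add_child(edges, "edge", id = as.character(i - 1L),
                        source = kk$source[i], target = kk$destination[i])
  xml2::write_xml(doc, file)
  invisible(file)
}

#' @rdname writePatternGexf
#' @export
readPatternGexf <- function(file) {
  doc <- xml2::read_xml(file)
  xml2::xml_ns_strip(doc)
  graph <- xml2::xml_find_first(doc, "./graph")
  attrNodes <- xml2::xml_find_all(graph,
                                  "./attributes[@class='node']/attribute")
  titleById <- stats::setNames(xml2::xml_attr(attrNodes, "title"),
                               xml2::xml_attr(attrNodes, "id"))
  nodes <- xml2::xml_find_all(graph, "./nodes/node")
  rows <- lapply(nodes, function(nd) {
    vals <- .attvalMap(nd, titleById)
    nid <- xml2::xml_attr(nd, "id")
    data.frame(identifier = nid,
               interface = suppressWarnings(as.integer(vals["interface"])),
               io = if ("io" %in% names(vals)) unname(vals["io"])
                    else NA_character_,
               transmission = if ("transmission" %in% names(vals))
                 unname(vals["transmission"]) else NA_character_,
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, rows)
  if (anyNA(pts$interface))
    .ioStop("port node lacks an interface attribute", file)
  p <- makePattern(pts$identifier[pts$interface == 0L],
                   pts$identifier[pts$interface == 1L])
  attributed <- !is.na(pts$io)
  for (grp in split(which(attributed),
                    paste(pts$interface[attributed], pts$io[attributed],
                          pts$transmission[attributed])))
    p <- setPortAttributes(p, pts$identifier[grp], pts$interface[grp[1]],
                           pts$io[grp[1]], pts$transmission[grp[1]])
  edges <- xml2::xml_find_all(graph, "./edges/edge")
  if (length(edges))
    p <- addConnections(p, xml2::xml_attr(edges, "source"),
                        xml2::xml_attr(edges, "target"))
  p
}
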