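.emptyComponents <- function() {
  data.frame(component = character(0), model = character(0),
             params = I(list()), stringsAsFactors = FALSE)
}

.emptyEdges <- function() {
  data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
}

.emptyBindings <- function() {
  data.frame(port = character(0), component = character(0),
             stringsAsFactors = FALSE)
}

#' Build an LPU interface table from typed selectors
#'
#' Convenience constructor for the `interface` slot of an [LPUSpec]: each
#' argument is a selector naming the ports of one (direction, kind)
#' combination. Directions are LPU-relative.
#'
#' @param inGpot,outGpot,inSpike,outSpike selectors (or identifier vectors),
#'   or NULL.
#' @return data.frame with columns `identifier`, `io`, `transmission`.
#' @examples
#' interfaceTable(inGpot = "/a/in/gpot[0:2]", outSpike = "/a/out/spike[0:2]")
#' @export
interfaceTable <- function(inGpot = NULL, outGpot = NULL,
                           inSpike = NULL, outSpike = NULL) {
  block <- function(sel, io, tr) {
    if (is.null(sel)) return(NULL)
    ids <- .ids(sel)
    if (length(ids) == 0L) return(NULL)
    data.frame(identifier = ids, io = io, transmission = tr,
               stringsAsFactors = FALSE)
  }
  out <- rbind(block(inGpot, "in", "gpot"), block(outGpot, "out", "gpot"),
               block(inSpike, "in", "spike"), block(outSpike, "out", "spike"))
  if (is.null(out)) out <- data.frame(identifier = character(0),
                                      io = character(0),
                                      transmission = character(0),
                                      stringsAsFactors = FALSE)
  out
}

#' Construct an LPU specification
#'
#' @param id unique LPU name.
#' @param interface data.frame (`identifier`, `io`, `transmission`), e.g.
#'   from [interfaceTable()]. An empty interface is valid: components that
#'   do not communicate with other LPUs are simply not exposed.
#' @param components optional data.frame (`component`, `model`, `params`
#'   list column) describing an internal circuit executable by the built-in
#'   engine (see [circuitHook()]).
#' @param edges optional data.frame (`from`, `to`) of directed internal
#'   connections between components.
#' @param bindings optional data.frame (`port`, `component`) connecting
#'   interface ports to internal components.
#' @return an [LPUSpec]. Use [validateSpec()] for a full report.
#' @export
lpuSpec <- function(id, interface = interfaceTable(), components = NULL,
                    edges = NULL, bindings = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.null(components)) components <- .emptyComponents()
  if (is.null(edges)) edges <- .emptyEdges()
  if (is.null(bindings)) bindings <- .emptyBindings()
  if (nrow(interface) > 0)
    interface$identifier <- .canonicalizeIds(interface$identifier)
  if (nrow(bindings) > 0)
    bindings$port <- .canonicalizeIds(bindings$port)
  new("LPUSpec", id = id, interface = interface,
      components = components, edges = edges, bindings = bindings)
}

# canonicalize identifier strings elementwise (no dedup, preserves length)
.canonicalizeIds <- function(x) {
  ok <- grepl(.canonicalIdRegex, x)
  if (all(ok)) return(x)
  x[!ok] <- vapply(x[!ok], function(s) {
    ids <- expandSelector(parseSelector(s))
    if (length(ids) != 1L)
      .selStop(sprintf("'%s' does not denote a single port", s),
               "identifierError")
    ids
  }, character(1))
  x
}

#' Validate an LPU specification
#'
#' Pure, report-based validation: returns a data.frame listing every
#' violation (zero rows means the spec is valid). Checked: duplicate port
#' identifiers (including a port declared both `in` and `out`), missing
#' io/transmission values, bindings referencing unknown ports or components,
#' edges referencing unknown components, duplicate component ids, and --
#' when the spec has components -- interface ports with no binding.
#'
#' @param x an [LPUSpec].
#' @param ... unused.
#' @return data.frame with columns `code` and `message`.
#' @export
#' @rdname validateSpec
setMethod("validateSpec", "LPUSpec", function(x, ...) {
  bad <- function(code, message) data.frame(code = code, message = message,
                                            stringsAsFactors = FALSE)
  rep <- bad(character(0), character(0))
  iface <- x@interface
  dup <- unique(iface$identifier[duplicated(iface$identifier)])
  for (d in dup)
    rep <- rbind(rep, bad("duplicate_port",
      sprintf("port %s declared more than once", d)))
  miss <- is.na(iface$io) | !iface$io %in% c("in", "out")
  for (d in iface$identifier[miss])
    rep <- rbind(rep, bad("missing_io",
      sprintf("port %s lacks a valid io setting", d)))
  miss <- is.na(iface$transmission) |
    !iface$transmission %in% c("gpot", "spike")
  for (d in iface$identifier[miss])
    rep <- rbind(rep, bad("missing_transmission",
      sprintf("port %s lacks a valid transmission setting", d)))
  comps <- x@components
  dup <- unique(comps$component[duplicated(comps$component)])
  for (d in dup)
    rep <- rbind(rep, bad("duplicate_component",
      sprintf("component %s declared more than once", d)))
  for (col in c("from", "to")) {
    unknown <- setdiff(x@edges[[col]], comps$component)
    for (d in unknown)
      rep <- rbind(rep, bad("dangling_edge",
        sprintf("edge endpoint %s is not a component", d)))
  }
  b <- x@bindings
  unknown <- setdiff(b$port, iface$identifier)
  for (d in unknown)
    rep <- rbind(rep, bad("unknown_port",
      sprintf("binding references unknown port %s", d)))
  unknown <- setdiff(b$component, comps$component)
  for (d in unknown)
    rep <- rbind(rep, bad("dangling_component_reference",
      sprintf("binding references unknown component %s", d)))
  if (nrow(comps) > 0) {
    unbound <- setdiff(iface$identifier, b$port)
    for (d in unbound)
      rep <- rbind(rep, bad("unbound_port",
        sprintf("port %s is not bound to a component", d)))
  }
  rep
})

setValidity("LPUSpec", function(object) {
  TRUE  # construction is permissive; validateSpec() gives the full report
})

#' Interface accessor
#'
#' @param x an [LPUSpec] or [LPURuntime].
#' @return the interface data.frame.
#' @export
lpuInterface <- function(x) {
  if (is(x, "LPURuntime")) x <- x@spec
  x@interface
}

#' @rdname lpuInterface
#' @export
lpuId <- function(x) {
  if (is(x, "LPURuntime")) x <- x@spec
  x@id
}

.kindPorts <- function(iface, kind, io = NULL) {
  sel <- iface$transmission == kind
  if (!is.null(io)) sel <- sel & iface$io == io
  iface$identifier[sel]
}

#' Instantiate an LPU runtime with attached port mappers
#'
#' Validates the spec (raising an `invalidSpecError` carrying the report if
#' it fails), then creates the runtime with one graded-potential and one
#' spike buffer over the interface ports, both zero-initialized, indices in
#' interface order. If `hook` is NULL and the spec has components, the
#' built-in circuit engine ([circuitHook()]) is used; with no components
#' the hook defaults to a no-op (outputs stay at 0).
#'
#' @param x an [LPUSpec].
#' @param hook optional step function `(gpot, spike, state, t, dt)`.
#' @param registry model registry for the circuit engine.
#' @param ... unused.
#' @return an [LPURuntime].
#' @export
#' @rdname attachMappers
setMethod("attachMappers", "LPUSpec",
          function(x, hook = NULL, registry = defaultRegistry(), ...) {
  rep <- validateSpec(x)
  if (nrow(rep) > 0)
    stop(errorCondition(
      paste0("invalid LPU spec '", x@id, "': ",
             paste(rep$message, collapse = "; ")),
      class = c("invalidSpecError", "lpuSimError"), report = rep))
  state <- new.env(parent = emptyenv())
  gpotIds <- .kindPorts(x@interface, "gpot")
  spikeIds <- .kindPorts(x@interface, "spike")
  state$gpot <- stats::setNames(numeric(length(gpotIds)), gpotIds)
  state$spike <- stats::setNames(numeric(length(spikeIds)), spikeIds)
  state$.outGpot <- .kindPorts(x@interface, "gpot", "out")
  state$.outSpike <- .kindPorts(x@interface, "spike", "out")
  state$.inGpot <- .kindPorts(x@interface, "gpot", "in")
  state$.inSpike <- .kindPorts(x@interface, "spike", "in")
  state$lpuId <- x@id
  if (is.null(hook)) {
    hook <- if (nrow(x@components) > 0) {
      state$.circuit <- .initCircuit(x, registry)
      circuitHook(x, registry)
    } else {
      function(gpot, spike, state, t, dt) NULL
    }
  } else if (nrow(x@components) > 0 && is.null(state$.circuit)) {
    # custom hooks may still consult the circuit if they wish
    state$.circuit <- .initCircuit(x, registry)
  }
  new("LPURuntime", spec = x, hook = hook, state = state)
})

#' Port mappers of a runtime
#'
#' Returns the graded-potential and spike [PortMapper] views over the
#' runtime's current buffers. Index layout is stable: interface order of the
#' defining spec, one independent index space per transmission kind.
#'
#' @param x an [LPURuntime].
#' @return `list(gpot = PortMapper, spike = PortMapper)`.
#' @export
portMappers <- function(x) {
  list(gpot = new("PortMapper", ids = names(x@state$gpot), kind = "gpot",
                  buffer = unname(x@state$gpot)),
       spike = new("PortMapper", ids = names(x@state$spike), kind = "spike",
                   buffer = unname(x@state$spike)))
}

#' Advance an LPU runtime by one step
#'
#' Invokes the runtime's hook with the current port buffers; the hook's
#' returned `gpot`/`spike` named vectors are written to the corresponding
#' output ports (other output ports retain their previous values). Hook
#' errors are re-raised wrapped with the LPU id and step index. If the state
#' carries an RNG stream (`.rng`), it is installed before and captured after
#' the hook so stochastic hooks are reproducible regardless of execution
#' order or placement.
#'
#' @param x an [LPURuntime].
#' @param t 0-based step index.
#' @param dt step size in seconds.
#' @param ... unused.
#' @return the runtime, invisibly (state is updated in place).
#' @export
#' @rdname stepLPU
setMethod("stepLPU", "LPURuntime", function(x, t, dt, ...) {
  state <- x@state
  if (!is.null(state$.rng))
    assign(".Random.seed", state$.rng, envir = globalenv())
  res <- tryCatch(x@hook(state$gpot, state$spike, state, t, dt),
    error = function(e) stop(errorCondition(
      sprintf("LPU '%s' failed at step %d: %s", x@spec@id, t,
              conditionMessage(e)),
      class = c("hookError", "lpuSimError"), parent = e)))
  if (!is.null(state$.rng))
    state$.rng <- get(".Random.seed", envir = globalenv())
  if (!is.null(res$gpot) && length(res$gpot)) {
    nm <- names(res$gpot)
    if (is.null(nm) || !all(nm %in% state$.outGpot))
      .selStop(sprintf(
        "LPU '%s': hook wrote non-output gpot port(s)", x@spec@id),
        "unknownPortError")
    state$gpot[nm] <- res$gpot
  }
  if (!is.null(res$spike) && length(res$spike)) {
    nm <- names(res$spike)
    if (is.null(nm) || !all(nm %in% state$.outSpike))
      .selStop(sprintf(
        "LPU '%s': hook wrote non-output spike port(s)", x@spec@id),
        "unknownPortError")
    if (!all(res$spike %in% c(0, 1)))
      .selStop(sprintf("LPU '%s': spike outputs must be 0/1", x@spec@id),
               "domainError")
    state$spike[nm] <- res$spike
  }
  invisible(x)
})

# deep copy of a runtime so repeated runs start from identical state
.cloneRuntime <- function(rt) {
  st <- new.env(parent = emptyenv())
  for (nm in ls(rt@state, all.names = TRUE))
    assign(nm, get(nm, envir = rt@state), envir = st)
  new("LPURuntime", spec = rt@spec, hook = rt@hook, state = st)
}

#' @export
setMethod("show", "LPURuntime", function(object) {
  iface <- object@spec@interface
  cat("LPURuntime '", object@spec@id, "': ", nrow(iface), " port(s) (",
      sum(iface$transmission == "gpot"), " gpot, ",
      sum(iface$transmission == "spike"), " spike), ",
      nrow(object@spec@components), " component(s)\n", sep = "")
  invisible(object)
})

#' @export
setMethod("show", "LPUSpec", function(object) {
  cat("LPUSpec '", object@id, "': ", nrow(object@interface), " port(s), ",
      nrow(object@components), " component(s), ",
      nrow(object@edges), " internal edge(s)\n", sep = "")
  invisible(object)
})

# --- stock hooks ------------------------------------------------------------

#' Stock step hooks
#'
#' * `constantHook(gpot, spike)`: writes fixed named values every step.
#' * `echoHook(gpotMap, spikeMap)`: copies input ports to output ports;
#'   each map is a named character vector `c(outputPort = inputPort)`.
#' * `zeroHook()`: writes 0 to every output port every step.
#' * `emptyHook()`: does nothing (outputs retain previous values); used by
#'   the communication benchmarks.
#' * `randomHook()`: uniform values on gpot outputs, Bernoulli(1/2) on spike
#'   outputs, drawn from the LPU's seeded RNG stream.
#'
#' @param gpot,spike named numeric vectors of output-port values.
#' @param gpotMap,spikeMap named character vectors mapping output ports to
#'   input ports.
#' @return a hook function for [attachMappers()]/[addLPU()].
#' @export
constantHook <- function(gpot = NULL, spike = NULL) {
  force(gpot); force(spike)
  function(g, s, state, t, dt) list(gpot = gpot, spike = spike)
}

#' @rdname constantHook
#' @export
echoHook <- function(gpotMap = NULL, spikeMap = NULL) {
  force(gpotMap); force(spikeMap)
  function(g, s, state, t, dt) {
    out <- list()
    if (!is.null(gpotMap))
      out$gpot <- stats::setNames(unname(g[unname(gpotMap)]), names(gpotMap))
    if (!is.null(spikeMap))
      out$spike <- stats::setNames(unname(s[unname(spikeMap)]),
                                   names(spikeMap))
    out
  }
}

#' @rdname constantHook
#' @export
zeroHook <- function() {
  function(g, s, state, t, dt)
    list(gpot = stats::setNames(numeric(length(state$.outGpot)),
                                state$.outGpot),
         spike = stats::setNames(numeric(length(state$.outSpike)),
                                 state$.outSpike))
}

#' @rdname constantHook
#' @export
emptyHook <- function() {
  function(g, s, state, t, dt) NULL
}

#' @rdname constantHook
#' @export
randomHook <- function() {
  function(g, s, state, t, dt) {
    out <- list()
    if (length(state$.outGpot))
      out$gpot <- stats::setNames(stats::runif(length(state$.outGpot)),
                                  state$.outGpot)
    if (length(state$.outSpike))
      out$spike <- stats::setNames(
        as.numeric(stats::runif(length(state$.outSpike)) < 0.5),
        state$.outSpike)
    out
  }
}

# --- built-in circuit engine ------------------------------------------------

# Precompute the execution structures for a component-graph spec. Stored as
# a plain list in state$.circuit so runtime cloning copies it by value.
.initCircuit <- function(spec, registry) {
  comps <- spec@components
  n <- nrow(comps)
  infos <- lapply(comps$model, function(m) modelInfo(registry, m))
  params <- lapply(seq_len(n), function(i) {
    p <- infos[[i]]$defaults
    user <- comps$params[[i]]
    if (length(user)) p[names(user)] <- user
    p
  })
  states <- lapply(seq_len(n), function(i) infos[[i]]$factory(params[[i]]))
  cindex <- stats::setNames(seq_len(n), comps$component)
  incoming <- rep(list(integer(0)), n)
  target <- rep(NA_integer_, n)
  if (nrow(spec@edges) > 0) {
    fi <- cindex[spec@edges$from]
    ti <- cindex[spec@edges$to]
    for (k in seq_along(fi)) {
      incoming[[ti[k]]] <- c(incoming[[ti[k]]], fi[k])
      if (is.na(target[fi[k]])) target[fi[k]] <- ti[k]
    }
  }
  iface <- spec@interface
  b <- spec@bindings
  bi <- match(b$port, iface$identifier)
  inBind <- b[iface$io[bi] == "in", , drop = FALSE]
  outBind <- b[iface$io[bi] == "out", , drop = FALSE]
  inKind <- iface$transmission[match(inBind$port, iface$identifier)]
  outKind <- iface$transmission[match(outBind$port, iface$identifier)]
  v0 <- vapply(seq_len(n), function(i) {
    v <- states[[i]]$v
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
  list(n = n, infos = infos, params = params, states = states,
       out = numeric(n), v = v0, spike = numeric(n),
       incoming = incoming, target = target,
       inComp = stats::setNames(unname(cindex[inBind$component]),
                                inBind$port),
       inKind = stats::setNames(inKind, inBind$port),
       outComp = stats::setNames(unname(cindex[outBind$component]),
                                 outBind$port),
       outKind = stats::setNames(outKind, outBind$port))
}

#' Step hook interpreting a declarative component graph
#'
#' Executes the internal component graph of an [LPUSpec] one emulation step
#' at a time using the models of a registry. Update scheme: every component
#' reads the *previous-step* outputs of its upstream components (Jacobi
#' style, one-step internal latency per edge), neurons sum incoming synapse
#' currents plus any bound input-port value, synapses read their
#' presynaptic source (an upstream component or a bound input port) and the
#' previous potential of their target neuron. The emulation `dt` (seconds)
#' is converted to milliseconds for the model equations.
#'
#' Normally not called directly: [attachMappers()] and [addLPU()] install it
#' automatically for specs with components.
#'
#' @param spec an [LPUSpec] with components.
#' @param registry model registry.
#' @return a hook function.
#' @export
circuitHook <- function(spec, registry = defaultRegistry()) {
  force(spec); force(registry)
  function(gpot, spike, state, t, dt) {
    cc <- state$.circuit
    dtMs <- dt * 1000
    prevOut <- cc$out
    prevV <- cc$v
    newOut <- numeric(cc$n)
    newV <- prevV
    newSpike <- numeric(cc$n)
    portIn <- c(gpot, spike)
    extFor <- stats::setNames(rep(NA_real_, cc$n), NULL)
    if (length(cc$inComp)) {
      vals <- portIn[names(cc$inComp)]
      for (k in seq_along(cc$inComp)) {
        i <- cc$inComp[[k]]
        extFor[i] <- if (is.na(extFor[i])) vals[[k]] else extFor[i] + vals[[k]]
      }
    }
    for (i in seq_len(cc$n)) {
      info <- cc$infos[[i]]
      if (info$role == "neuron") {
        drive <- sum(prevOut[cc$incoming[[i]]])
        if (!is.na(extFor[i])) drive <- drive + extFor[i]
        res <- info$step(cc$states[[i]], drive, cc$params[[i]], dtMs)
      } else {
        pre <- if (!is.na(extFor[i])) extFor[i]
               else if (length(cc$incoming[[i]])) prevOut[cc$incoming[[i]][1]]
               else 0
        vp <- if (!is.na(cc$target[i]) && !is.na(prevV[cc$target[i]]))
                prevV[cc$target[i]] else 0
        res <- info$step(cc$states[[i]], c(pre = pre, vpost = vp),
                         cc$params[[i]], dtMs)
      }
      cc$states[[i]] <- res$state
      newOut[i] <- res$output
      if (!is.null(res$v)) newV[i] <- res$v
      if (!is.null(res$spike)) newSpike[i] <- res$spike
    }
    cc$out <- newOut
    cc$v <- newV
    cc$spike <- newSpike
    state$.circuit <- cc
    out <- list()
    if (length(cc$outComp)) {
      isG <- cc$outKind == "gpot"
      if (any(isG)) {
        ci <- cc$outComp[isG]
        vals <- ifelse(is.na(newV[ci]), newOut[ci], newV[ci])
        out$gpot <- stats::setNames(vals, names(cc$outComp)[isG])
      }
      if (any(!isG)) {
        ci <- cc$outComp[!isG]
        out$spike <- stats::setNames(newSpike[ci], names(cc$outComp)[!isG])
      }
    }
    out
  }
}
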