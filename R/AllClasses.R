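#' @import methods
NULL

#' PortSelector: an ordered set of hierarchical port identifiers
#'
#' A `PortSelector` holds the parse tree of a path-like selector expression
#' such as `"/med/L1[0:10]"`. A selector without a wildcard denotes a finite,
#' duplicate-free, ordered set of port identifiers; a selector whose final
#' level is `*` can only be resolved against a concrete universe of ports
#' (see [expandAgainst()]).
#'
#' Identifiers are rendered in a canonical bracketed form in which integer
#' levels appear as `[i]` and name levels as `/name`, so `"/med/L1/0"` and
#' `"/med/L1[0]"` denote the same port.
#'
#' @slot ast parsed expression tree (internal representation).
#' @slot source the original selector string.
#' @slot cache environment memoizing the expansion.
#' @seealso [parseSelector()], [expandSelector()], [countPorts()],
#'   [combineSelectors()]
#' @export
setClass("PortSelector",
         representation(ast = "list", source = "character",
                        cache = "environment"))

#' Pattern: a validated inter-LPU connectivity pattern
#'
#' A `Pattern` describes how the ports of two LPU interfaces (labelled 0 and
#' 1) are wired to each other. It stores (1) the attributes of every port in
#' the two interfaces and (2) a sparse set of directed connections between
#' them; only existing connections are stored, so memory grows with the
#' number of connections rather than with the product of the interface sizes.
#'
#' Port directions are *pattern-relative*: a pattern `"in"` port receives an
#' LPU's **output**, and a pattern `"out"` port delivers data to an LPU's
#' **input**. This inverts the naive reading of the attribute table and is
#' asserted by [checkCompatibility()].
#'
#' Invariants (enforced by the validity method and all mutators):
#' * connection endpoints exist and lie on opposite interfaces;
#' * a connection runs from an `"in"` port to an `"out"` port;
#' * the two endpoints carry the same transmission kind (`"gpot"`/`"spike"`);
#' * every destination port has in-degree at most one (fan-in prohibited;
#'   fan-out is unlimited).
#'
#' @slot ports data.frame with columns `identifier`, `interface` (0/1),
#'   `io` (`"in"`/`"out"`/`NA`), `transmission` (`"gpot"`/`"spike"`/`NA`).
#' @slot connections data.frame with columns `source`, `destination`
#'   (canonical identifier strings).
#' @seealso [makePattern()], [setPortAttributes()], [addConnections()],
#'   [checkCompatibility()]
#' @export
setClass("Pattern",
         representation(ports = "data.frame", connections = "data.frame"))

#' PortMapper: identifier-to-buffer-index mapping over a value array
#'
#' Maps an ordered set of port identifiers to the contiguous 0-based indices
#' of a value buffer of one transmission kind. Graded-potential (`"gpot"`)
#' buffers hold finite doubles; spike buffers hold 0/1.
#'
#' @slot ids ordered identifiers; position `k` maps to array index `k - 1`.
#' @slot kind `"gpot"` or `"spike"`.
#' @slot buffer numeric value buffer, one element per port.
#' @seealso [portMapper()], [getValues()], [setValues()]
#' @export
setClass("PortMapper",
         representation(ids = "character", kind = "character",
                        buffer = "numeric"))

#' LPUSpec: declarative specification of a local processing unit
#'
#' An LPU (local processing unit) is a neural circuit module with a unique
#' id, a typed port interface, and (optionally) an internal component graph
#' of model-typed nodes that the built-in circuit engine can execute.
#'
#' @slot id unique module name.
#' @slot interface data.frame: `identifier`, `io` (`"in"`/`"out"`),
#'   `transmission` (`"gpot"`/`"spike"`). Directions here are LPU-relative.
#' @slot components data.frame: `component` (id), `model` (registry name),
#'   `params` (list column of named numeric vectors).
#' @slot edges data.frame of directed internal connections: `from`, `to`.
#' @slot bindings data.frame mapping interface ports to components:
#'   `port`, `component`.
#' @seealso [lpuSpec()], [validateSpec()], [attachMappers()]
#' @export
setClass("LPUSpec",
         representation(id = "character", interface = "data.frame",
                        components = "data.frame", edges = "data.frame",
                        bindings = "data.frame"))

#' LPURuntime: an instantiated LPU ready to execute
#'
#' Couples a validated [LPUSpec] with a per-step hook and mutable state,
#' including the two port buffers (one per transmission kind) that the
#' executor reads and writes. Buffers are zero-initialized.
#'
#' @slot spec the [LPUSpec].
#' @slot hook function `(gpot, spike, state, t, dt)` returning a list with
#'   optional named elements `gpot` and `spike` holding values for output
#'   ports. Output ports not written retain their previous value.
#' @slot state environment holding `gpot` and `spike` named buffers plus any
#'   model state the hook maintains.
#' @seealso [attachMappers()], [stepLPU()], [circuitHook()]
#' @export
setClass("LPURuntime",
         representation(spec = "LPUSpec", hook = "function",
                        state = "environment"))

#' EmulationPlan: LPUs, pattern bindings, routing table and clock
#'
#' The control-plane object: a set of registered LPUs, the connectivity
#' patterns binding their interfaces, the routing table compiled from them,
#' and the emulation clock. Build with [emulationPlan()], populate with
#' [addLPU()] and [connectLPUs()], compile with [compileRoutes()], and
#' execute with [runEmulation()].
#'
#' @slot lpus named list of [LPURuntime] objects.
#' @slot bindings list of bindings, each
#'   `list(id0, id1, pattern, label0, label1)`.
#' @slot routes compiled routing table (data.frame), or NULL-like empty
#'   data.frame before [compileRoutes()].
#' @slot compiled logical flag.
#' @slot dt emulation step size in seconds.
#' @export
setClass("EmulationPlan",
         representation(lpus = "list", bindings = "list",
                        routes = "data.frame", compiled = "logical",
                        dt = "numeric"))

#' ExecutionRecord: result of running an emulation
#'
#' @slot steps number of steps executed.
#' @slot dt step size in seconds.
#' @slot final named list per LPU: `list(gpot = , spike = )` final buffers.
#' @slot trace named list per LPU of per-step snapshot matrices (steps x
#'   ports, taken after each step's hook, before propagation), present for
#'   recorded LPUs only.
#' @export
setClass("ExecutionRecord",
         representation(steps = "numeric", dt = "numeric",
                        final = "list", trace = "list"))
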