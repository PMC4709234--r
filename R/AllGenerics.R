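#' @rdname expandSelector
#' @export
setGeneric("expandSelector", function(x, ...) standardGeneric("expandSelector"))

#' @rdname countPorts
#' @export
setGeneric("countPorts", function(x, ...) standardGeneric("countPorts"))

#' @rdname renderSelector
#' @export
setGeneric("renderSelector", function(x, ...) standardGeneric("renderSelector"))

#' @rdname expandAgainst
#' @export
setGeneric("expandAgainst",
           function(x, universe, ...) standardGeneric("expandAgainst"))

#' @rdname getValues
#' @export
setGeneric("getValues", function(x, sel, ...) standardGeneric("getValues"))

#' @rdname setValues
#' @export
setGeneric("setValues",
           function(x, sel, values, ...) standardGeneric("setValues"))

#' @rdname setPortAttributes
#' @export
setGeneric("setPortAttributes",
           function(x, sel, interface, io, transmission, ...)
             standardGeneric("setPortAttributes"))

#' @rdname addConnections
#' @export
setGeneric("addConnections",
           function(x, src, dst, ...) standardGeneric("addConnections"))

#' @rdname checkCompatibility
#' @export
setGeneric("checkCompatibility",
           function(x, interface, lpuInterface, ...)
             standardGeneric("checkCompatibility"))

#' @rdname connectedPorts
#' @export
setGeneric("connectedPorts",
           function(x, interface, direction, ...)
             standardGeneric("connectedPorts"))

#' @rdname validateSpec
#' @export
setGeneric("validateSpec", function(x, ...) standardGeneric("validateSpec"))

#' @rdname attachMappers
#' @export
setGeneric("attachMappers", function(x, ...) standardGeneric("attachMappers"))

#' @rdname stepLPU
#' @export
setGeneric("stepLPU", function(x, t, dt, ...) standardGeneric("stepLPU"))

#' @rdname addLPU
#' @export
setGeneric("addLPU", function(x, spec, ...) standardGeneric("addLPU"))

#' @rdname connectLPUs
#' @export
setGeneric("connectLPUs",
           function(x, id0, id1, pattern, label0 = 0L, label1 = 1L, ...)
             standardGeneric("connectLPUs"))

#' @rdname compileRoutes
#' @export
setGeneric("compileRoutes", function(x, ...) standardGeneric("compileRoutes"))

#' @rdname runEmulation
#' @export
setGeneric("runEmulation", function(x, ...) standardGeneric("runEmulation"))

#' @rdname partitionLPUs
#' @export
setGeneric("partitionLPUs",
           function(x, workers, ...) standardGeneric("partitionLPUs"))
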