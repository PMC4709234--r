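# Control plane: register LPUs, bind patterns, compile a routing table, run
# the bulk-synchronous loop over a pluggable transport. One step =
# (1) every LPU's hook runs on its current input buffers, (2) all output
# port data crosses the patterns to destination input buffers; no LPU sees
# step-t outputs before step t+1 (one-step transport latency). Step-0 inputs
# are zeros; unconnected input ports read 0 forever.

.emptyRoutes <- function() {
  data.frame(srcLpu = character(0), dstLpu = character(0),
             kind = character(0), srcPort = character(0),
             dstPort = character(0), srcIndex = integer(0),
             dstIndex = integer(0), stringsAsFactors = FALSE)
}

#' Create an empty emulation plan
#'
#' @param dt emulation step size in seconds.
#' @return an [EmulationPlan].
#' @examples
#' plan <- emulationPlan(dt = 1e-2)
#' @export
emulationPlan <- function(dt = 1e-4) {
  stopifnot(is.numeric(dt), dt > 0)
  new("EmulationPlan", lpus = list(), bindings = list(),
      routes = .emptyRoutes(), compiled = FALSE, dt = dt)
}

#' Register an LPU with a plan
#'
#' Validates the spec (surfacing the validation report on failure) and
#' instantiates an [LPURuntime] with zeroed mappers.
#'
#' @param x an [EmulationPlan].
#' @param spec an [LPUSpec] with an id not already present.
#' @param hook optional custom step function (see [attachMappers()]).
#' @param registry model registry for spec-interpreted LPUs.
#' @param ... unused.
#' @return the updated plan.
#' @export
#' @rdname addLPU
setMethod("addLPU", "EmulationPlan",
          function(x, spec, hook = NULL, registry = defaultRegistry(), ...) {
  if (spec@id %in% names(x@lpus))
    .selStop(sprintf("an LPU with id '%s' is already registered", spec@id),
             "duplicateIdError")
  rt <- attachMappers(spec, hook = hook, registry = registry)
  x@lpus[[spec@id]] <- rt
  x@compiled <- FALSE
  x
})

#' Bind a connectivity pattern between two registered LPUs
#'
#' Records the binding only if [checkCompatibility()] succeeds on both
#' sides; otherwise raises an `incompatibilityError` whose condition carries
#' both reports (`report0`, `report1`). Self-connection (`id0 == id1` with a
#' pattern over disjoint port subsets) is allowed; its data crosses the
#' pattern with the usual one-step latency. At most one pattern may bind a
#' given ordered LPU pair with a given label assignment.
#'
#' @param x an [EmulationPlan].
#' @param id0,id1 registered LPU ids.
#' @param pattern a [Pattern].
#' @param label0,label1 which pattern interface faces which LPU.
#' @param ... unused.
#' @return the updated plan.
#' @export
#' @rdname connectLPUs
setMethod("connectLPUs", "EmulationPlan",
          function(x, id0, id1, pattern, label0 = 0L, label1 = 1L, ...) {
  for (id in unique(c(id0, id1)))
    if (!id %in% names(x@lpus))
      .selStop(sprintf("LPU '%s' is not registered", id), "unknownIdError")
  label0 <- as.integer(label0); label1 <- as.integer(label1)
  for (b in x@bindings)
    if (b$id0 == id0 && b$id1 == id1 && b$label0 == label0 &&
        b$label1 == label1)
      .selStop(sprintf(
        "a pattern already binds ('%s', '%s') with labels (%d, %d)",
        id0, id1, label0, label1), "duplicateBindingError")
  rep0 <- checkCompatibility(pattern, label0, x@lpus[[id0]]@spec)
  rep1 <- checkCompatibility(pattern, label1, x@lpus[[id1]]@spec)
  if (!rep0$compatible || !rep1$compatible)
    stop(errorCondition(
      sprintf("pattern is incompatible with %s",
              paste(c(if (!rep0$compatible) sprintf("'%s' (label %d)", id0,
                                                    label0),
                      if (!rep1$compatible) sprintf("'%s' (label %d)", id1,
                                                    label1)),
                    collapse = " and ")),
      class = c("incompatibilityError", "lpuSimError"),
      report0 = rep0, report1 = rep1))
  x@bindings[[length(x@bindings) + 1L]] <-
    list(id0 = id0, id1 = id1, pattern = pattern,
         label0 = label0, label1 = label1)
  x@compiled <- FALSE
  x
})

#' Compile the routing table of a plan
#'
#' Derives, for every pattern connection, exactly one route
#' (source LPU, source port/buffer index) -> (destination LPU, destination
#' port/buffer index) of the connection's transmission kind. The table is
#' complete and minimal: its row count equals the total connection count
#' over all bound patterns. A destination buffer element may be fed by at
#' most one source across *all* patterns (global fan-in prohibition);
#' violations raise a `globalFanInError`.
#'
#' @param x an [EmulationPlan].
#' @param ... unused.
#' @return the plan with its `routes` slot filled (see [routingTable()]).
#' @export
#' @rdname compileRoutes
setMethod("compileRoutes", "EmulationPlan", function(x, ...) {
  rts <- list()
  for (b in x@bindings) {
    pat <- b$pattern
    conn <- pat@ports
    k <- pat@connections
    if (nrow(k) == 0) next
    si <- match(k$source, conn$identifier)
    di <- match(k$destination, conn$identifier)
    lpuOf <- function(lbl) if (lbl == b$label0) b$id0 else b$id1
    srcLpu <- vapply(conn$interface[si], lpuOf, character(1))
    dstLpu <- vapply(conn$interface[di], lpuOf, character(1))
    rts[[length(rts) + 1L]] <- data.frame(
      srcLpu = srcLpu, dstLpu = dstLpu, kind = conn$transmission[si],
      srcPort = k$source, dstPort = k$destination,
      stringsAsFactors = FALSE)
  }
  routes <- if (length(rts)) do.call(rbind, rts) else .emptyRoutes()
  if (nrow(routes)) {
    # buffer indices per destination/source LPU mapper (0-based)
    idxIn <- function(lpu, port, kind) {
      buf <- if (kind == "gpot") x@lpus[[lpu]]@state$gpot
             else x@lpus[[lpu]]@state$spike
      match(port, names(buf)) - 1L
    }
    routes$srcIndex <- mapply(idxIn, routes$srcLpu, routes$srcPort,
                              routes$kind)
    routes$dstIndex <- mapply(idxIn, routes$dstLpu, routes$dstPort,
                              routes$kind)
    dstKey <- paste(routes$dstLpu, routes$kind, routes$dstPort)
    if (anyDuplicated(dstKey))
      .selStop(sprintf(
        "destination %s is fed by more than one pattern (global fan-in)",
        dstKey[duplicated(dstKey)][1]), "globalFanInError")
  }
  x@routes <- routes
  x@compiled <- TRUE
  x
})

#' @rdname compileRoutes
#' @param plan a compiled [EmulationPlan].
#' @return `routingTable()`: the routes data.frame (`srcLpu`, `dstLpu`,
#'   `kind`, `srcPort`, `dstPort`, `srcIndex`, `dstIndex`).
#' @export
routingTable <- function(plan) {
  if (!plan@compiled) plan <- compileRoutes(plan)
  plan@routes
}

#' @export
setMethod("show", "EmulationPlan", function(object) {
  cat("EmulationPlan: ", length(object@lpus), " LPU(s), ",
      length(object@bindings), " pattern binding(s), dt = ",
      object@dt, " s",
      if (object@compiled)
        sprintf(", %d compiled route(s)", nrow(object@routes)) else
        " (routes not compiled)",
      "\n", sep = "")
  invisible(object)
})

# --- propagation ------------------------------------------------------------

# Pre-split routes by (destination, kind, source) so the sync phase is a
# handful of vectorized buffer gathers per step.
.routePlan <- function(routes) {
  if (nrow(routes) == 0) return(list())
  grps <- split(routes, paste(routes$dstLpu, routes$kind, routes$srcLpu))
  lapply(grps, function(g)
    list(dst = g$dstLpu[1L], kind = g$kind[1L], src = g$srcLpu[1L],
         srcIdx = g$srcIndex + 1L, dstPort = g$dstPort))
}

# outputs: named list lpu -> list(gpot =, spike =) full named buffers.
# Returns named list lpu -> list(gpot = named values, spike = named values)
# holding only routed input-port updates.
.routeOutputs <- function(routeGroups, outputs) {
  inputs <- list()
  for (grp in routeGroups) {
    vals <- stats::setNames(
      unname(outputs[[grp$src]][[grp$kind]][grp$srcIdx]), grp$dstPort)
    cur <- inputs[[grp$dst]][[grp$kind]]
    inputs[[grp$dst]][[grp$kind]] <- if (is.null(cur)) vals else c(cur, vals)
  }
  inputs
}

# apply input updates + stimulus to a runtime's buffers, then step it
.applyAndStep <- function(rt, upd, t, dt) {
  if (!is.null(upd)) {
    if (!is.null(upd$gpot) && length(upd$gpot))
      rt@state$gpot[names(upd$gpot)] <- upd$gpot
    if (!is.null(upd$spike) && length(upd$spike))
      rt@state$spike[names(upd$spike)] <- upd$spike
  }
  stepLPU(rt, t, dt)
  list(gpot = rt@state$gpot, spike = rt@state$spike)
}

.mergeInputs <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (kind in c("gpot", "spike"))
    if (!is.null(b[[kind]])) {
      if (is.null(a[[kind]])) a[[kind]] <- b[[kind]]
      else a[[kind]][names(b[[kind]])] <- b[[kind]]
    }
  a
}

# --- transports -------------------------------------------------------------

# A transport hides where LPU runtimes live. It exposes
#   $step(inputs, t, dt) -> outputs (named list per lpu)
#   $teardown()
.serialTransport <- function(rts) {
  list(
    step = function(inputs, t, dt) {
      outs <- list()
      for (id in names(rts))  # registration order; barrier makes it unobservable
        outs[[id]] <- .applyAndStep(rts[[id]], inputs[[id]], t, dt)
      outs
    },
    teardown = function() invisible(NULL))
}

#' Create a worker cluster for the multiprocess backend
#'
#' Starts a PSOCK cluster whose workers inherit the current library paths
#' and load this package, ready to be passed to [runEmulation()] as
#' `cluster` (and reused across runs).
#'
#' @param workers number of worker processes.
#' @return a cluster object; stop it with [parallel::stopCluster()].
#' @export
makeWorkerCluster <- function(workers = 2L) {
  cl <- parallel::makePSOCKcluster(workers)
  lp <- .libPaths()
  parallel::clusterCall(cl, function(paths) {
    .libPaths(paths)
    library(lpuSim)
    invisible(NULL)
  }, lp)
  cl
}

# worker-side helpers; package-level so clusterApply serializes them by
# namespace reference rather than shipping captured environments each step
.workerInit <- function(ids, all) {
  assign(".lpuSimWorkerRts", all[ids], envir = globalenv())
  invisible(NULL)
}

.workerStep <- function(p) {
  rts <- get(".lpuSimWorkerRts", envir = globalenv())
  outs <- list()
  for (id in names(rts))
    outs[[id]] <- .applyAndStep(rts[[id]], p$inputs[[id]], p$t, p$dt)
  outs
}

.mpTransport <- function(rts, assignment, cluster) {
  workers <- sort(unique(assignment))
  byWorker <- lapply(workers, function(w) names(assignment)[assignment == w])
  names(byWorker) <- as.character(workers)
  # ship each worker its runtimes once; they persist in the worker session
  parallel::clusterApply(cluster, byWorker, .workerInit, all = rts)
  force(cluster)
  list(
    step = function(inputs, t, dt) {
      payloads <- lapply(byWorker, function(ids)
        list(inputs = inputs[intersect(names(inputs), ids)], t = t, dt = dt))
      res <- parallel::clusterApply(cluster, payloads, .workerStep)
      do.call(c, res)
    },
    teardown = function() invisible(NULL))
}

# --- run loop ---------------------------------------------------------------

#' Execute an emulation bulk-synchronously
#'
#' Runs the plan for `steps` steps (or `floor(duration/dt)`). Each step,
#' every LPU's hook is invoked exactly once on its current input buffers;
#' all output-port data is then propagated across the patterns before any
#' LPU begins the next step. The serial backend and the multiprocess
#' backend implement identical semantics: routing only copies values, so
#' port buffers agree bitwise between the two at every step.
#'
#' The plan itself is not mutated: runtimes are deep-copied before the run,
#' so repeated calls with equal arguments produce identical records.
#'
#' @param x a compiled (or compilable) [EmulationPlan].
#' @param steps number of steps; alternatively give `duration` (seconds).
#' @param duration emulation duration in seconds (`steps = floor(duration /
#'   dt)`).
#' @param backend `"serial"` (in-process reference) or `"multiprocess"`
#'   (PSOCK workers exchanging port data by message passing).
#' @param workers worker count for the multiprocess backend.
#' @param cluster optional pre-built cluster from [makeWorkerCluster()]
#'   (reused, not stopped); if NULL one is created and stopped internally.
#' @param seed optional integer; gives every LPU an independent,
#'   reproducible RNG stream (stream `i` seeded with `seed + i`), so
#'   stochastic plans are bitwise reproducible on both backends.
#' @param record which LPUs to record: `"all"`, a character vector of ids,
#'   or NULL. Recorded traces snapshot the full port buffers after each
#'   step's hook, before propagation.
#' @param stimulus optional function `(step)` returning a named list
#'   `lpu -> list(gpot =, spike =)` of named input-port values injected
#'   before that step runs (external input, e.g. light).
#' @param ... unused.
#' @return an [ExecutionRecord].
#' @export
#' @rdname runEmulation
setMethod("runEmulation", "EmulationPlan",
          function(x, steps = NULL, duration = NULL,
                   backend = c("serial", "multiprocess"), workers = 2L,
                   cluster = NULL, seed = NULL, record = NULL,
                   stimulus = NULL, ...) {
  backend <- match.arg(backend)
  if (is.null(steps)) {
    if (is.null(duration))
      .selStop("give either steps or duration", "argumentError")
    steps <- floor(duration / x@dt)
  }
  steps <- as.integer(steps)
  if (!x@compiled) x <- compileRoutes(x)
  rts <- lapply(x@lpus, .cloneRuntime)
  if (!is.null(seed)) {
    for (i in seq_along(rts)) {
      set.seed(as.integer(seed) + i)
      rts[[i]]@state$.rng <- get(".Random.seed", envir = globalenv())
    }
  }
  if (identical(record, "all")) record <- names(rts)
  routeGroups <- .routePlan(x@routes)

  ownCluster <- FALSE
  transport <- if (backend == "serial") {
    .serialTransport(rts)
  } else {
    if (is.null(cluster)) {
      cluster <- makeWorkerCluster(workers)
      ownCluster <- TRUE
    }
    assignment <- partitionLPUs(x, length(cluster))
    .mpTransport(rts, assignment, cluster)
  }
  on.exit({
    transport$teardown()
    if (ownCluster) parallel::stopCluster(cluster)
  })

  trace <- list()
  if (!is.null(record))
    for (id in record)
      trace[[id]] <- list(gpot = matrix(NA_real_, steps,
                            length(rts[[id]]@state$gpot),
                            dimnames = list(NULL, names(rts[[id]]@state$gpot))),
                          spike = matrix(NA_real_, steps,
                            length(rts[[id]]@state$spike),
                            dimnames = list(NULL,
                                            names(rts[[id]]@state$spike))))
  inputs <- list()  # step-0 inputs are zeros (buffers start zeroed)
  outputs <- NULL
  for (t in seq_len(steps) - 1L) {
    if (!is.null(stimulus)) {
      stim <- stimulus(t)
      for (id in names(stim))
        inputs[[id]] <- .mergeInputs(inputs[[id]], stim[[id]])
    }
    outputs <- transport$step(inputs, t, x@dt)
    outputs <- outputs[names(rts)]
    if (!is.null(record))
      for (id in record) {
        trace[[id]]$gpot[t + 1L, ] <- outputs[[id]]$gpot
        trace[[id]]$spike[t + 1L, ] <- outputs[[id]]$spike
      }
    inputs <- .routeOutputs(routeGroups, outputs)
  }
  final <- if (is.null(outputs))
    lapply(rts, function(r) list(gpot = r@state$gpot, spike = r@state$spike))
  else outputs
  new("ExecutionRecord", steps = as.numeric(steps), dt = x@dt,
      final = final, trace = trace)
})

#' @export
setMethod("show", "ExecutionRecord", function(object) {
  cat("ExecutionRecord: ", object@steps, " step(s) at dt = ", object@dt,
      " s; ", length(object@final), " LPU(s)",
      if (length(object@trace))
        paste0("; traces for ", paste(names(object@trace), collapse = ", ")),
      "\n", sep = "")
  invisible(object)
})

#' Write a recorded trace as delimited text
#'
#' Long-format TSV with columns `step`, `lpu`, `kind`, `port`, `value`.
#'
#' @param rec an [ExecutionRecord] with traces.
#' @param file path or connection.
#' @return `file`, invisibly.
#' @export
writeRecording <- function(rec, file) {
  rows <- list()
  for (id in names(rec@trace))
    for (kind in c("gpot", "spike")) {
      m <- rec@trace[[id]][[kind]]
      if (length(m) == 0 || ncol(m) == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        step = rep(seq_len(nrow(m)) - 1L, ncol(m)),
        lpu = id, kind = kind,
        port = rep(colnames(m), each = nrow(m)),
        value = as.vector(m), stringsAsFactors = FALSE)
    }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(step = integer(0), lpu = character(0), kind = character(0),
               port = character(0), value = numeric(0))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

# --- partitioning -----------------------------------------------------------

# symmetric inter-LPU connection-count matrix
.lpuWeights <- function(plan) {
  ids <- names(plan@lpus)
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  routes <- routingTable(plan)
  if (nrow(routes))
    for (r in seq_len(nrow(routes))) {
      a <- routes$srcLpu[r]; b <- routes$dstLpu[r]
      if (a != b) {
        w[a, b] <- w[a, b] + 1
        w[b, a] <- w[b, a] + 1
      }
    }
  w
}

#' Edge cut of a worker assignment
#'
#' Number of inter-LPU connections whose endpoints are assigned to
#' different workers.
#'
#' @param plan an [EmulationPlan].
#' @param assignment named integer vector (LPU id -> worker).
#' @return nonnegative count.
#' @export
edgeCut <- function(plan, assignment) {
  routes <- routingTable(plan)
  if (nrow(routes) == 0) return(0L)
  sum(assignment[routes$srcLpu] != assignment[routes$dstLpu])
}

#' Assign LPUs to workers, reducing the edge cut
#'
#' Greedy Kernighan-Lin-style heuristic: LPUs are placed in decreasing
#' order of total connectivity onto the worker that minimizes the cut
#' increase (subject to a balance capacity of `ceiling(n/workers)`),
#' followed by single-move local search until no move improves the cut.
#' `method = "roundrobin"` gives the naive baseline for comparison.
#'
#' @param x an [EmulationPlan].
#' @param workers number of workers (>= 1).
#' @param method `"greedy"` or `"roundrobin"`.
#' @param ... unused.
#' @return named integer vector mapping every LPU id to a worker in
#'   `1:workers`.
#' @export
#' @rdname partitionLPUs
setMethod("partitionLPUs", "EmulationPlan",
          function(x, workers, method = c("greedy", "roundrobin"), ...) {
  method <- match.arg(method)
  ids <- names(x@lpus)
  n <- length(ids)
  workers <- as.integer(workers)
  stopifnot(workers >= 1L)
  if (method == "roundrobin" || workers == 1L || n == 0L)
    return(stats::setNames(rep(seq_len(workers), length.out = n), ids))
  w <- .lpuWeights(x)
  cap <- ceiling(n / workers)
  assignment <- stats::setNames(rep(NA_integer_, n), ids)
  for (id in ids[order(-rowSums(w))]) {
    load <- tabulate(assignment[!is.na(assignment)], workers)
    # external weight added if id joins worker k = edges to other workers
    cost <- vapply(seq_len(workers), function(k) {
      if (load[k] >= cap) return(Inf)
      placed <- names(assignment)[!is.na(assignment)]
      sum(w[id, placed][assignment[placed] != k])
    }, numeric(1))
    assignment[id] <- which.min(cost)
  }
  repeat {
    improved <- FALSE
    for (id in ids) {
      cur <- assignment[id]
      load <- tabulate(assignment, workers)
      others <- names(assignment)[names(assignment) != id]
      ext <- function(k) sum(w[id, others][assignment[others] != k])
      base <- ext(cur)
      for (k in seq_len(workers)) {
        if (k == cur || load[k] >= cap) next
        if (ext(k) < base) {
          assignment[id] <- k
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) break
  }
  assignment
})
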