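# Synthetic fixtures: the toy retina/lamina composition of the fly early
# visual system, equation-count bookkeeping, and the communication
# benchmark topologies/sweeps. These are first-class generators, not test
# scaffolding: the demo and benchmark CLIs run on them.

#' Centered hexagonal array
#'
#' Axial coordinates of a hexagonal lattice consisting of a central element
#' plus `rings` concentric rings, walked ring by ring in a fixed direction
#' order. The element count obeys the centered-hexagonal closed form
#' `1 + 3 rings (rings + 1)`; 15 rings give the 721 ommatidia of the fly
#' retina model.
#'
#' @param rings nonnegative ring count.
#' @return data.frame with columns `index` (0-based), `q`, `r` (axial
#'   coordinates), `ring`.
#' @examples
#' nrow(hexArray(15))  # 721
#' @export
hexArray <- function(rings) {
  if (!is.numeric(rings) || length(rings) != 1L || is.na(rings) || rings < 0)
    .selStop("rings must be a nonnegative count", "argumentError")
  rings <- as.integer(rings)
  dirs <- matrix(c(1, 0, 1, -1, 0, -1, -1, 0, -1, 1, 0, 1),
                 ncol = 2, byrow = TRUE)
  coords <- matrix(0, 1 + 3 * rings * (rings + 1), 2)
  ringOf <- integer(nrow(coords))
  row <- 2L
  for (k in seq_len(rings)) {
    cur <- c(-k, k)  # k steps along direction 5 from the center
    for (d in seq_len(6L)) for (s in seq_len(k)) {
      coords[row, ] <- cur
      ringOf[row] <- k
      cur <- cur + dirs[d, ]
      row <- row + 1L
    }
  }
  data.frame(index = seq_len(nrow(coords)) - 1L,
             q = coords[, 1], r = coords[, 2], ring = ringOf)
}

#' @rdname hexArray
#' @return `hexCount()`: the closed-form element count.
#' @export
hexCount <- function(rings) 1 + 3 * rings * (rings + 1)

#' Equation-count bookkeeping for the stochastic photoreceptor model
#'
#' Total equation count of a retina in which each ommatidium holds
#' `photoreceptors` photoreceptors, each photoreceptor `microvilli`
#' microvilli, and each microvillus is modeled by `eqsPerMicrovillus`
#' differential equations: the product of the four factors. With the full
#' fly-retina numbers (721, 6, 30000, 15) this is 1,946,700,000 -- about
#' 1.95 billion equations.
#'
#' @param ommatidia,photoreceptors,microvilli,eqsPerMicrovillus nonnegative
#'   counts.
#' @return total equation count (numeric, exact for these magnitudes).
#' @export
equationCount <- function(ommatidia, photoreceptors, microvilli,
                          eqsPerMicrovillus) {
  args <- c(ommatidia, photoreceptors, microvilli, eqsPerMicrovillus)
  if (any(!is.finite(args)) || any(args < 0))
    .selStop("all factors must be nonnegative", "argumentError")
  ommatidia * photoreceptors * microvilli * eqsPerMicrovillus
}

# port naming helpers
.retOut <- function(p, i) sprintf("/ret/R%d[%d]", p, i)
.retStim <- function(p, i) sprintf("/ret/stim/R%d[%d]", p, i)
.lamIn <- function(p, j) sprintf("/lam/R%d[%d]", p, j)
.lamOut <- function(k, j) sprintf("/lam/L%d[%d]", k, j)

#' Build the toy retina/lamina fixture
#'
#' Generates the two LPU specs and the feed-forward connectivity pattern of
#' the toy early-visual-system composition:
#'
#' * **retina**: one surrogate photoreceptor per (ommatidium, position
#'   R1..R6) over a [hexArray()] of `rings` rings, each exposing a graded
#'   potential output port `/ret/Rp[i]` and a light input port
#'   `/ret/stim/Rp[i]`;
#' * **lamina**: one cartridge per ommatidium with `neuronsPerCartridge`
#'   Morris-Lecar neurons (graded output) and one inhibitory conductance
#'   synapse per photoreceptor input `/lam/Rp[j]`; neurons L1 (and L2 when
#'   present) are exposed as outputs;
#' * **pattern**: one connection per photoreceptor output,
#'   `/ret/Rp[i] -> /lam/Rp[(i + p - 1) mod N]`. The cyclic index shift per
#'   position is a deterministic synthetic stand-in for the anatomical
#'   neural superposition wiring; being a bijection for every position it
#'   preserves the fan-in invariant, and the connection count is exactly
#'   `6 N` (4,326 at the default 15 rings).
#'
#' @param rings hex-array ring count (default 15, the 721-ommatidium scale).
#' @param neuronsPerCartridge lamina neurons per cartridge (default 6,
#'   giving 4,326 lamina neurons at full scale).
#' @return list with elements `retina`, `lamina` ([LPUSpec]s), `pattern`
#'   ([Pattern]), `hex` (the array), and `bookkeeping` (named list of
#'   equation-count factors; see [equationCount()]).
#' @examples
#' fx <- buildRetinaLamina(rings = 1)
#' connectionCount(fx$pattern)  # 42
#' @export
buildRetinaLamina <- function(rings = 15, neuronsPerCartridge = 6) {
  stopifnot(neuronsPerCartridge >= 1)
  hex <- hexArray(rings)
  n <- nrow(hex)
  pos <- rep(1:6, each = n)
  omm <- rep(hex$index, 6)

  retOut <- .retOut(pos, omm)
  retStim <- .retStim(pos, omm)
  photComp <- sprintf("phot_R%d_%d", pos, omm)
  retina <- lpuSpec(
    "retina",
    interface = rbind(
      data.frame(identifier = retStim, io = "in", transmission = "gpot",
                 stringsAsFactors = FALSE),
      data.frame(identifier = retOut, io = "out", transmission = "gpot",
                 stringsAsFactors = FALSE)),
    components = data.frame(component = photComp,
                            model = "PhotoreceptorSurrogate",
                            params = I(rep(list(numeric(0)), length(photComp))),
                            stringsAsFactors = FALSE),
    bindings = data.frame(port = c(retStim, retOut),
                          component = c(photComp, photComp),
                          stringsAsFactors = FALSE))

  cart <- rep(hex$index, 6)
  lamIn <- .lamIn(pos, cart)
  synComp <- sprintf("syn_R%d_%d", pos, cart)
  targetNeuron <- ((pos - 1L) %% neuronsPerCartridge) + 1L
  neurK <- rep(seq_len(neuronsPerCartridge), each = n)
  neurJ <- rep(hex$index, neuronsPerCartridge)
  neurComp <- sprintf("n%d_%d", neurK, neurJ)
  outK <- seq_len(min(2L, neuronsPerCartridge))
  lamOutPorts <- unlist(lapply(outK, function(k) .lamOut(k, hex$index)))
  lamOutComp <- unlist(lapply(outK, function(k) sprintf("n%d_%d", k,
                                                        hex$index)))
  lamina <- lpuSpec(
    "lamina",
    interface = rbind(
      data.frame(identifier = lamIn, io = "in", transmission = "gpot",
                 stringsAsFactors = FALSE),
      data.frame(identifier = lamOutPorts, io = "out",
                 transmission = "gpot", stringsAsFactors = FALSE)),
    components = rbind(
      data.frame(component = synComp, model = "ConductanceSynapse",
                 params = I(rep(list(numeric(0)), length(synComp))),
                 stringsAsFactors = FALSE),
      data.frame(component = neurComp, model = "MorrisLecar",
                 params = I(rep(list(numeric(0)), length(neurComp))),
                 stringsAsFactors = FALSE)),
    edges = data.frame(from = synComp,
                       to = sprintf("n%d_%d", targetNeuron, cart),
                       stringsAsFactors = FALSE),
    bindings = data.frame(port = c(lamIn, lamOutPorts),
                          component = c(synComp, lamOutComp),
                          stringsAsFactors = FALSE))

  pattern <- makePattern(retOut, lamIn)
  pattern <- setPortAttributes(pattern, retOut, 0L, "in", "gpot")
  pattern <- setPortAttributes(pattern, lamIn, 1L, "out", "gpot")
  destCart <- (omm + pos - 1L) %% n  # cyclic superposition stand-in
  pattern <- addConnections(pattern, retOut, .lamIn(pos, destCart))

  list(retina = retina, lamina = lamina, pattern = pattern, hex = hex,
       bookkeeping = list(ommatidia = n, photoreceptorsPerOmmatidium = 6,
                          microvilliPerPhotoreceptor = 30000,
                          equationsPerMicrovillus = 15))
}

#' Count lamina neuron components of a fixture
#'
#' @param fixture result of [buildRetinaLamina()].
#' @return number of neuron (non-synapse) components in the lamina spec.
#' @export
laminaNeuronCount <- function(fixture) {
  comps <- fixture$lamina@components
  sum(comps$model %in% c("MorrisLecar", "LeakyIAF", "HodgkinHuxley"))
}

# --- communication benchmark harness ---------------------------------------
#
# Reproduces the *experimental design* of the module-communication
# benchmarks (topologies and parameter grids). Timing results are
# hardware-dependent and are not acceptance quantities.

#' Benchmark emulation topologies
#'
#' Builds a ready-to-run [EmulationPlan] of LPUs with empty step hooks,
#' wired in one of three topologies:
#' * `"pair"`: 2 LPUs, each exposing `portsPerLpu` graded-potential output
#'   ports wired one-to-one to the peer's inputs (so `2 * portsPerLpu`
#'   directed routes);
#' * `"all_to_all"`: every LPU connected to every other, the fixed
#'   `portsPerLpu` output ports of each LPU split evenly across its
#'   `numLpus - 1` peers;
#' * `"connectome_counts"`: a synthetic stand-in for a connectome-derived
#'   sequence: LPU k joins the emulation connected to LPU k-1 with a
#'   geometrically decaying connection count
#'   `max(1, round(portsPerLpu * decay^(k-2)))`.
#'
#' @param numLpus number of LPUs (>= 2).
#' @param portsPerLpu output ports exposed per LPU (>= 1; for
#'   `"all_to_all"`, at least `numLpus - 1`).
#' @param topology one of `"pair"`, `"all_to_all"`, `"connectome_counts"`.
#' @param dt step size in seconds.
#' @param decay geometric decay rate for `"connectome_counts"`.
#' @return a compiled [EmulationPlan].
#' @export
benchmarkTopology <- function(numLpus, portsPerLpu,
                              topology = c("pair", "all_to_all",
                                           "connectome_counts"),
                              dt = 1e-4, decay = 0.7) {
  topology <- match.arg(topology)
  stopifnot(numLpus >= 2, portsPerLpu >= 1)
  ids <- sprintf("lpu%d", seq_len(numLpus))
  plan <- emulationPlan(dt = dt)

  mkPorts <- function(id, peers, counts) {
    # counts: named by peer, ports this LPU sends to each peer (same
    # counts are received back from each peer)
    outSel <- unlist(lapply(seq_along(peers), function(k)
      sprintf("/%s/out/to_%s[%d]", id, peers[k], seq_len(counts[k]) - 1L)))
    inSel <- unlist(lapply(seq_along(peers), function(k)
      sprintf("/%s/in/from_%s[%d]", id, peers[k], seq_len(counts[k]) - 1L)))
    interfaceTable(inGpot = inSel, outGpot = outSel)
  }
  linkPair <- function(plan, a, b, nAB, nBA) {
    aOut <- sprintf("/%s/out/to_%s[%d]", a, b, seq_len(nAB) - 1L)
    bIn <- sprintf("/%s/in/from_%s[%d]", b, a, seq_len(nAB) - 1L)
    bOut <- sprintf("/%s/out/to_%s[%d]", b, a, seq_len(nBA) - 1L)
    aIn <- sprintf("/%s/in/from_%s[%d]", a, b, seq_len(nBA) - 1L)
    p <- makePattern(c(aOut, aIn), c(bIn, bOut))
    if (nAB > 0) {
      p <- setPortAttributes(p, aOut, 0L, "in", "gpot")
      p <- setPortAttributes(p, bIn, 1L, "out", "gpot")
      p <- addConnections(p, aOut, bIn)
    }
    if (nBA > 0) {
      p <- setPortAttributes(p, bOut, 1L, "in", "gpot")
      p <- setPortAttributes(p, aIn, 0L, "out", "gpot")
      p <- addConnections(p, bOut, aIn)
    }
    connectLPUs(plan, a, b, p, 0L, 1L)
  }

  if (topology == "pair") {
    peers <- list(ids[2], ids[1])
    for (k in 1:2)
      plan <- addLPU(plan, lpuSpec(ids[k],
        mkPorts(ids[k], peers[[k]],
                stats::setNames(portsPerLpu, peers[[k]]))),
        hook = emptyHook())
    plan <- linkPair(plan, ids[1], ids[2], portsPerLpu, portsPerLpu)
  } else if (topology == "all_to_all") {
    if (portsPerLpu < numLpus - 1)
      .selStop("all_to_all needs portsPerLpu >= numLpus - 1",
               "argumentError")
    base <- portsPerLpu %/% (numLpus - 1L)
    extra <- portsPerLpu %% (numLpus - 1L)
    for (i in seq_len(numLpus)) {
      peers <- ids[-i]
      counts <- stats::setNames(base + (seq_along(peers) <= extra), peers)
      plan <- addLPU(plan, lpuSpec(ids[i], mkPorts(ids[i], peers, counts)),
                     hook = emptyHook())
    }
    for (i in seq_len(numLpus - 1L)) for (j in (i + 1L):numLpus) {
      peersI <- ids[-i]; peersJ <- ids[-j]
      cI <- base + (match(ids[j], peersI) <= extra)
      cJ <- base + (match(ids[i], peersJ) <= extra)
      plan <- linkPair(plan, ids[i], ids[j], cI, cJ)
    }
  } else {  # connectome_counts
    counts <- pmax(1, round(portsPerLpu * decay^(seq_len(numLpus - 1L) - 1L)))
    peersOf <- lapply(seq_len(numLpus), function(i) {
      p <- character(0)
      if (i > 1) p <- c(p, ids[i - 1])
      if (i < numLpus) p <- c(p, ids[i + 1])
      p
    })
    countsOf <- lapply(seq_len(numLpus), function(i) {
      cc <- integer(0)
      if (i > 1) cc <- c(cc, counts[i - 1])
      if (i < numLpus) cc <- c(cc, counts[i])
      stats::setNames(cc, peersOf[[i]])
    })
    for (i in seq_len(numLpus))
      plan <- addLPU(plan, lpuSpec(ids[i],
        mkPorts(ids[i], peersOf[[i]], countsOf[[i]])), hook = emptyHook())
    for (i in seq_len(numLpus - 1L))
      plan <- linkPair(plan, ids[i], ids[i + 1L], counts[i], counts[i])
  }
  compileRoutes(plan)
}

#' Benchmark parameter grids
#'
#' `benchmarkPortSweep()` returns the 25 equally spaced output-port counts
#' between 50 and 15,000 of the 2-LPU sweep; `benchmarkLpuSweep()` the LPU
#' counts (2 to 19) of the all-to-all/connectome sweeps.
#'
#' @return integer vector of grid values.
#' @export
benchmarkPortSweep <- function() round(seq(50, 15000, length.out = 25))

#' @rdname benchmarkPortSweep
#' @export
benchmarkLpuSweep <- function() 2:19

#' Ordered connected LPU pairs of a plan
#'
#' @param plan a compiled [EmulationPlan].
#' @return number of ordered (source, destination) LPU pairs with at least
#'   one route.
#' @export
connectedPairCount <- function(plan) {
  r <- routingTable(plan)
  if (nrow(r) == 0) return(0L)
  nrow(unique(r[, c("srcLpu", "dstLpu")]))
}

#' Time the synchronization loop of a plan
#'
#' Runs the plan and reports mean wall-clock time per step and port
#' throughput. These numbers are hardware-dependent: they characterize the
#' machine as much as the code and are reported for design exploration
#' only.
#'
#' @param plan a compiled [EmulationPlan].
#' @param steps steps to execute.
#' @param backend,workers,cluster see [runEmulation()].
#' @return data.frame with `steps`, `totalSeconds`, `meanStepSeconds`,
#'   `routedPortsPerSecond`.
#' @export
benchmarkRun <- function(plan, steps = 100L, backend = "serial",
                         workers = 2L, cluster = NULL) {
  nRoutes <- nrow(routingTable(plan))
  el <- system.time(runEmulation(plan, steps = steps, backend = backend,
                                 workers = workers, cluster = cluster))
  total <- unname(el["elapsed"])
  data.frame(steps = steps, totalSeconds = total,
             meanStepSeconds = total / steps,
             routedPortsPerSecond = nRoutes * steps / total)
}

# --- demo -------------------------------------------------------------------

# map hex centers onto pixel coordinates of a frame (nearest pixel)
.hexPixels <- function(hex, ny, nx) {
  x <- hex$q + hex$r / 2
  y <- hex$r * sqrt(3) / 2
  toIdx <- function(v, n) {
    if (max(v) == min(v)) return(rep(ceiling(n / 2), length(v)))
    1L + as.integer(round((v - min(v)) / (max(v) - min(v)) * (n - 1L)))
  }
  cbind(row = toIdx(y, ny), col = toIdx(x, nx))
}

#' Run the retina/lamina demo emulation
#'
#' Builds the fixture at the requested scale, drives the photoreceptors
#' with a 2-D intensity frame sequence (each ommatidium samples the nearest
#' pixel to its hex center; all 6 photoreceptors of an ommatidium see the
#' same intensity), runs the bulk-synchronous loop, and records the R1
#' photoreceptor outputs and the lamina outputs.
#'
#' @param frames intensity input: a matrix (static image), a 3-D array
#'   `[ny, nx, nframes]` (frames spread evenly over the duration), or NULL
#'   for spatially uniform intensity 1.
#' @param rings hex-array scale (small values run in seconds on a laptop).
#' @param duration emulation duration in seconds.
#' @param dt step size in seconds.
#' @param out optional TSV path for the recordings (see [writeRecording()]).
#' @param seed optional RNG seed (only relevant with photoreceptor shot
#'   noise).
#' @return an [ExecutionRecord] with traces for both LPUs.
#' @export
runDemo <- function(frames = NULL, rings = 2, duration = 0.05, dt = 1e-3,
                    out = NULL, seed = NULL) {
  fx <- buildRetinaLamina(rings = rings)
  n <- nrow(fx$hex)
  if (is.null(frames)) frames <- matrix(1, 3, 3)
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  nf <- dim(frames)[3]
  px <- .hexPixels(fx$hex, dim(frames)[1], dim(frames)[2])
  steps <- floor(duration / dt)
  stimPorts <- unlist(lapply(1:6, function(p) .retStim(p, fx$hex$index)))
  frameOf <- function(t) min(nf, 1L + (t * nf) %/% max(1L, steps))
  stimulus <- function(t) {
    f <- frames[, , frameOf(t)]
    vals <- f[px]  # one intensity per ommatidium
    list(retina = list(gpot = stats::setNames(rep(vals, 6), stimPorts)))
  }
  plan <- emulationPlan(dt = dt)
  plan <- addLPU(plan, fx$retina)
  plan <- addLPU(plan, fx$lamina)
  plan <- connectLPUs(plan, "retina", "lamina", fx$pattern, 0L, 1L)
  rec <- runEmulation(plan, steps = steps, record = c("retina", "lamina"),
                      stimulus = stimulus, seed = seed)
  if (!is.null(out)) writeRecording(rec, out)
  rec
}
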