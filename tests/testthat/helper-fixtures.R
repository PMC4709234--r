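# Shared builders used across the suite. Everything is generated in code;
# no fixture files.

# The worked-example pattern between LPUs lam and med: 11 attributed ports,
# 6 connections (two fan-outs), both directions crossing one pattern.
workedPattern <- function() {
  p <- makePattern("/lam[0:6]", "/med[0:5]")
  p <- setPortAttributes(p, "/lam[0:2]", 0, "in", "gpot")
  p <- setPortAttributes(p, "/lam[2]", 0, "out", "gpot")
  p <- setPortAttributes(p, "/lam[3:6]", 0, "out", "spike")
  p <- setPortAttributes(p, "/med[0:3]", 1, "out", "gpot")
  p <- setPortAttributes(p, "/med[3:5]", 1, "in", "spike")
  addConnections(p,
    c("/lam[0]", "/lam[0]", "/lam[1]", "/med[3]", "/med[4]", "/med[4]"),
    c("/med[0]", "/med[1]", "/med[2]", "/lam[3]", "/lam[4]", "/lam[5]"))
}

# LPU interfaces matching the two sides of workedPattern()
workedLamInterface <- function() {
  data.frame(
    identifier = sprintf("/lam[%d]", 0:5),
    io = c("out", "out", "in", "in", "in", "in"),
    transmission = c("gpot", "gpot", "gpot", "spike", "spike", "spike"),
    stringsAsFactors = FALSE)
}

workedMedInterface <- function() {
  data.frame(
    identifier = sprintf("/med[%d]", 0:4),
    io = c("in", "in", "in", "out", "out"),
    transmission = c("gpot", "gpot", "gpot", "spike", "spike"),
    stringsAsFactors = FALSE)
}

# --- random selector generator with a brute-force oracle --------------------

# Builds a random wildcard-free selector string together with its expected
# expansion computed independently (nested loops over token sets, not the
# parser's machinery).
randomSelectorCase <- function() {
  names <- c("med", "lam", "a", "b_2", "x")
  randLevel <- function() {
    kind <- sample(3, 1)
    if (kind == 1) {
      nm <- sample(names, 1)
      list(text = paste0("/", nm), tokens = nm)
    } else if (kind == 2) {
      k <- sample(3, 1)
      toks <- as.character(sample(0:9, k))
      list(text = paste0("[", paste(toks, collapse = ","), "]"),
           tokens = toks)
    } else {
      lo <- sample(0:5, 1); hi <- lo + sample(1:4, 1)
      list(text = sprintf("[%d:%d]", lo, hi),
           tokens = as.character(lo:(hi - 1)))
    }
  }
  randPath <- function() {
    nm <- sample(names, 1)
    levels <- c(list(list(text = paste0("/", nm), tokens = nm)),
                replicate(sample(1:2, 1), randLevel(), simplify = FALSE))
    # brute-force cross product, left-major
    seqs <- list(character(0))
    for (lev in levels)
      seqs <- unlist(lapply(seqs, function(s)
        lapply(lev$tokens, function(tk) c(s, tk))), recursive = FALSE)
    ids <- vapply(seqs, function(s) {
      isInt <- grepl("^[0-9]+$", s)
      paste0(ifelse(isInt, paste0("[", s, "]"), paste0("/", s)),
             collapse = "")
    }, character(1))
    list(text = paste(vapply(levels, `[[`, character(1), "text"),
                      collapse = ""),
         ids = ids)
  }
  nBranch <- sample(1:3, 1)
  branches <- replicate(nBranch, randPath(), simplify = FALSE)
  list(text = paste(vapply(branches, `[[`, character(1), "text"),
                    collapse = ","),
       ids = unique(unlist(lapply(branches, `[[`, "ids"))))
}

# --- random emulation plans -------------------------------------------------

# A random chain/branch plan with deterministic-or-seeded hooks; wiring,
# sizes and hook choice vary with the ambient RNG state.
randomPlan <- function(maxLpus = 4, maxPorts = 4, dt = 1e-3) {
  nlpu <- sample(2:maxLpus, 1)
  nports <- sample(1:maxPorts, 1)
  ids <- sprintf("m%d", seq_len(nlpu))
  plan <- emulationPlan(dt = dt)
  for (id in ids) {
    spec <- lpuSpec(id, interfaceTable(
      inGpot = sprintf("/%s/in/g[0:%d]", id, nports),
      outGpot = sprintf("/%s/out/g[0:%d]", id, nports),
      inSpike = sprintf("/%s/in/s[0:%d]", id, nports),
      outSpike = sprintf("/%s/out/s[0:%d]", id, nports)))
    plan <- addLPU(plan, spec, hook = randomHook())
  }
  # wire consecutive LPUs (both kinds), plus a random back edge
  link <- function(plan, a, b) {
    aOutG <- sprintf("/%s/out/g[0:%d]", a, nports)
    bInG <- sprintf("/%s/in/g[0:%d]", b, nports)
    aOutS <- sprintf("/%s/out/s[0:%d]", a, nports)
    bInS <- sprintf("/%s/in/s[0:%d]", b, nports)
    p <- makePattern(paste(aOutG, aOutS, sep = ","),
                     paste(bInG, bInS, sep = ","))
    p <- setPortAttributes(p, aOutG, 0, "in", "gpot")
    p <- setPortAttributes(p, bInG, 1, "out", "gpot")
    p <- setPortAttributes(p, aOutS, 0, "in", "spike")
    p <- setPortAttributes(p, bInS, 1, "out", "spike")
    keep <- which(stats::runif(nports) < 0.8)
    if (length(keep)) {
      p <- addConnections(p, expandSelector(aOutG)[keep],
                          expandSelector(bInG)[keep])
      p <- addConnections(p, expandSelector(aOutS)[keep],
                          expandSelector(bInS)[keep])
    }
    connectLPUs(plan, a, b, p)
  }
  for (i in seq_len(nlpu - 1)) plan <- link(plan, ids[i], ids[i + 1])
  compileRoutes(plan)
}

# Chain of echo LPUs: head emits a constant, every other LPU copies its
# input to its output; used for latency tests.
echoChainPlan <- function(L, value = 0.7) {
  plan <- emulationPlan(dt = 1e-3)
  ids <- sprintf("c%d", seq_len(L))
  for (k in seq_len(L)) {
    id <- ids[k]
    spec <- lpuSpec(id, interfaceTable(
      inGpot = if (k > 1) sprintf("/%s/in[0]", id),
      outGpot = sprintf("/%s/out[0]", id)))
    hook <- if (k == 1) constantHook(
      gpot = stats::setNames(value, sprintf("/%s/out[0]", id)))
    else echoHook(gpotMap = stats::setNames(sprintf("/%s/in[0]", id),
                                            sprintf("/%s/out[0]", id)))
    plan <- addLPU(plan, spec, hook = hook)
  }
  for (k in seq_len(L - 1)) {
    a <- ids[k]; b <- ids[k + 1]
    p <- makePattern(sprintf("/%s/out[0]", a), sprintf("/%s/in[0]", b))
    p <- setPortAttributes(p, sprintf("/%s/out[0]", a), 0, "in", "gpot")
    p <- setPortAttributes(p, sprintf("/%s/in[0]", b), 1, "out", "gpot")
    p <- addConnections(p, sprintf("/%s/out[0]", a), sprintf("/%s/in[0]", b))
    plan <- connectLPUs(plan, a, b, p)
  }
  compileRoutes(plan)
}

# verify that every routed destination input at step t+1 equals its source
# output at step t, and that unrouted inputs stay 0 (value conservation)
checkConservation <- function(plan, rec) {
  routes <- routingTable(plan)
  steps <- rec@steps
  ok <- TRUE
  for (r in seq_len(nrow(routes))) {
    src <- rec@trace[[routes$srcLpu[r]]][[routes$kind[r]]][, routes$srcPort[r]]
    dst <- rec@trace[[routes$dstLpu[r]]][[routes$kind[r]]][, routes$dstPort[r]]
    # trace snapshots are post-hook: dst column shows the input visible at
    # that step, i.e. the source output of the previous step
    ok <- ok && identical(unname(dst[-1]), unname(src[-steps]))
    ok <- ok && dst[1] == 0
  }
  ok
}
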