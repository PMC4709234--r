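# Control plane: registration, binding, route compilation, the
# bulk-synchronous loop, and partitioning.

test_that("LPU registration enforces unique ids and valid specs", {
  plan <- emulationPlan(1e-3)
  plan <- addLPU(plan, lpuSpec("m1", interfaceTable(outGpot = "/m1/o[0]")))
  plan <- addLPU(plan, lpuSpec("m2", interfaceTable(inGpot = "/m2/i[0]")))
  expect_identical(names(plan@lpus), c("m1", "m2"))
  expect_error(addLPU(plan, lpuSpec("m1", interfaceTable())),
               class = "duplicateIdError")
  bad <- lpuSpec("m3", data.frame(identifier = c("/x[0]", "/x[0]"),
                                  io = c("in", "out"),
                                  transmission = "gpot",
                                  stringsAsFactors = FALSE))
  err <- expect_error(addLPU(plan, bad), class = "invalidSpecError")
  expect_true(is.data.frame(err$report) && nrow(err$report) > 0)
})

simplePair <- function(dt = 1e-2, value = 0.7) {
  a <- lpuSpec("A", interfaceTable(outGpot = "/A/out[0]"))
  b <- lpuSpec("B", interfaceTable(inGpot = "/B/in[0:3]"))
  pat <- makePattern("/A/out[0]", "/B/in[0:3]")
  pat <- setPortAttributes(pat, "/A/out[0]", 0, "in", "gpot")
  pat <- setPortAttributes(pat, "/B/in[0:3]", 1, "out", "gpot")
  pat <- addConnections(pat, "/A/out[0]", c("/B/in[0]", "/B/in[1]"))
  plan <- emulationPlan(dt)
  plan <- addLPU(plan, a, hook = constantHook(gpot = c("/A/out[0]" = value)))
  plan <- addLPU(plan, b, hook = emptyHook())
  connectLPUs(plan, "A", "B", pat)
}

test_that("binding requires registered, compatible LPUs", {
  plan <- simplePair()
  expect_identical(length(plan@bindings), 1L)
  # swapped labels invert the direction expectations -> incompatible
  pat <- plan@bindings[[1]]$pattern
  err <- expect_error(connectLPUs(plan, "A", "B", pat, 1L, 0L),
                      class = "incompatibilityError")
  expect_false(err$report0$compatible)
  expect_error(connectLPUs(emulationPlan(1e-3), "A", "B",
                           makePattern("", "")), class = "unknownIdError")
  # one pattern per ordered pair + label assignment
  expect_error(connectLPUs(plan, "A", "B", pat, 0L, 1L),
               class = "duplicateBindingError")
})

test_that("route compilation is complete, minimal, and indexed", {
  plan <- compileRoutes(simplePair())
  r <- routingTable(plan)
  expect_identical(nrow(r), 2L)
  expect_identical(r$srcIndex, c(0L, 0L))
  expect_identical(sort(r$dstIndex), c(0L, 1L))
  expect_identical(unique(r$kind), "gpot")
  # empty bindings -> empty table
  p0 <- compileRoutes(addLPU(emulationPlan(1e-3),
                             lpuSpec("solo", interfaceTable())))
  expect_identical(nrow(routingTable(p0)), 0L)
})

test_that("worked-example routes map onto the documented mapper indices", {
  pat <- workedPattern()
  lam <- lpuSpec("lam", workedLamInterface())
  med <- lpuSpec("med", workedMedInterface())
  plan <- emulationPlan(1e-3)
  plan <- addLPU(plan, lam, hook = emptyHook())
  plan <- addLPU(plan, med, hook = emptyHook())
  plan <- compileRoutes(connectLPUs(plan, "lam", "med", pat))
  r <- routingTable(plan)
  expect_identical(nrow(r), connectionCount(pat))
  g <- r[r$kind == "gpot" & r$srcLpu == "lam", ]
  g <- g[order(g$dstPort), ]
  # /lam[0] (gpot index 0) fans out to /med[0], /med[1] (indices 0, 1);
  # /lam[1] (index 1) feeds /med[2] (index 2)
  expect_identical(g$srcIndex, c(0L, 0L, 1L))
  expect_identical(g$dstIndex, 0:2)
})

test_that("route count equals total connection count over patterns", {
  set.seed(17)
  for (rep in 1:5) {
    plan <- randomPlan()
    total <- sum(vapply(plan@bindings,
                        function(b) connectionCount(b$pattern), integer(1)))
    expect_identical(nrow(routingTable(plan)), total)
  }
})

test_that("outputs cross one pattern per step (zero-init, then latency 1)", {
  rec <- runEmulation(simplePair(), steps = 4, record = "all")
  bIn <- rec@trace$B$gpot
  expect_identical(unname(bIn[, "/B/in[0]"]), c(0, 0.7, 0.7, 0.7))
  # fan-out delivers identical values to both destinations every step
  expect_identical(bIn[, "/B/in[0]"], bIn[, "/B/in[1]"])
  # unconnected input port reads zero forever
  expect_true(all(bIn[, "/B/in[2]"] == 0))
})

test_that("duration is converted to whole steps", {
  plan <- compileRoutes(addLPU(emulationPlan(dt = 1e-2),
                               lpuSpec("solo", interfaceTable()),
                               hook = emptyHook()))
  rec <- runEmulation(plan, duration = 10.0)
  expect_identical(rec@steps, 1000)
})

test_that("an LPU may be wired to itself; data returns after one step", {
  spec <- lpuSpec("loop", interfaceTable(inGpot = "/loop/in[0]",
                                         outGpot = "/loop/out[0]"))
  pat <- makePattern("/loop/out[0]", "/loop/in[0]")
  pat <- setPortAttributes(pat, "/loop/out[0]", 0, "in", "gpot")
  pat <- setPortAttributes(pat, "/loop/in[0]", 1, "out", "gpot")
  pat <- addConnection(pat, "/loop/out[0]", "/loop/in[0]")
  plan <- emulationPlan(1e-3)
  # count steps in which the input is already nonzero
  plan <- addLPU(plan, spec, hook = function(g, s, state, t, dt)
    list(gpot = stats::setNames(g[["/loop/in[0]"]] + 1, "/loop/out[0]")))
  plan <- connectLPUs(plan, "loop", "loop", pat)
  rec <- runEmulation(plan, steps = 4, record = "all")
  # out(t) = in(t) + 1 and in(t+1) = out(t): counts steps
  expect_identical(unname(rec@trace$loop$gpot[, "/loop/out[0]"]),
                   c(1, 2, 3, 4))
})

test_that("a change at the head of an echo chain reaches the tail after L steps", {
  for (L in c(2L, 4L, 6L)) {
    plan <- echoChainPlan(L)
    rec <- runEmulation(plan, steps = L + 2, record = "all")
    tail <- rec@trace[[sprintf("c%d", L)]]$gpot[, sprintf("/c%d/out[0]", L)]
    firstSeen <- which(tail != 0)[1] - 1L  # 0-based step index
    expect_identical(firstSeen, L - 1L)
  }
})

test_that("values are conserved across the sync barrier", {
  set.seed(41)
  for (rep in 1:5) {
    plan <- randomPlan()
    rec <- runEmulation(plan, steps = 20, seed = rep, record = "all")
    expect_true(checkConservation(plan, rec))
  }
})

test_that("serial and multiprocess transports agree bitwise", {
  cl <- makeWorkerCluster(2)
  on.exit(parallel::stopCluster(cl))
  set.seed(53)
  for (rep in 1:3) {
    plan <- randomPlan()
    r1 <- runEmulation(plan, steps = 20, seed = rep, record = "all")
    r2 <- runEmulation(plan, steps = 20, seed = rep, record = "all",
                       backend = "multiprocess", cluster = cl)
    expect_identical(r1@trace, r2@trace)
    expect_identical(r1@final, r2@final)
  }
})

test_that("reruns of a stochastic plan with equal seeds are identical", {
  set.seed(61)
  plan <- randomPlan()
  r1 <- runEmulation(plan, steps = 15, seed = 5, record = "all")
  r2 <- runEmulation(plan, steps = 15, seed = 5, record = "all")
  r3 <- runEmulation(plan, steps = 15, seed = 6, record = "all")
  expect_identical(r1@trace, r2@trace)
  expect_false(identical(r1@trace, r3@trace))
})

test_that("partitioning balances load and reduces the edge cut", {
  # two disconnected pairs: greedy reaches cut 0, round-robin does not
  plan <- emulationPlan(1e-3)
  link <- function(plan, a, b) {
    p <- makePattern(sprintf("/%s/o[0]", a), sprintf("/%s/i[0]", b))
    p <- setPortAttributes(p, sprintf("/%s/o[0]", a), 0, "in", "gpot")
    p <- setPortAttributes(p, sprintf("/%s/i[0]", b), 1, "out", "gpot")
    p <- addConnection(p, sprintf("/%s/o[0]", a), sprintf("/%s/i[0]", b))
    connectLPUs(plan, a, b, p)
  }
  for (id in c("w", "x", "y", "z"))
    plan <- addLPU(plan, lpuSpec(id, interfaceTable(
      inGpot = sprintf("/%s/i[0]", id), outGpot = sprintf("/%s/o[0]", id))),
      hook = emptyHook())
  plan <- link(plan, "w", "x")
  plan <- link(plan, "y", "z")
  plan <- compileRoutes(plan)
  greedy <- partitionLPUs(plan, 2)
  expect_identical(edgeCut(plan, greedy), 0L)
  expect_identical(sort(as.vector(table(greedy))), c(2L, 2L))
  rr <- partitionLPUs(plan, 2, method = "roundrobin")
  expect_gt(edgeCut(plan, rr), edgeCut(plan, greedy))
  # brute force over all balanced assignments confirms 0 is optimal
  best <- min(apply(expand.grid(rep(list(1:2), 4)), 1, function(a)
    edgeCut(plan, stats::setNames(a, names(plan@lpus)))))
  expect_identical(edgeCut(plan, greedy), as.integer(best))
  # one worker: everything local
  expect_identical(edgeCut(plan, partitionLPUs(plan, 1)), 0L)
  # heavily mutually connected pair across 2 workers: cut is unavoidable
  p2 <- compileRoutes(simplePair())
  expect_identical(edgeCut(p2, partitionLPUs(p2, 2)),
                   nrow(routingTable(p2)))
})

test_that("recordings serialize to delimited text", {
  rec <- runEmulation(simplePair(), steps = 3, record = "all")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeRecording(rec, f)
  df <- utils::read.delim(f)
  expect_setequal(names(df), c("step", "lpu", "kind", "port", "value"))
  expect_identical(sort(unique(df$lpu)), c("A", "B"))
  expect_equal(df$value[df$port == "/B/in[0]" & df$step == 1], 0.7)
})
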