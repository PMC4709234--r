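# LPU contract: spec validation, mapper attachment, step semantics.

eightPortSpec <- function(id = "a") {
  lpuSpec(id, interfaceTable(
    inGpot = sprintf("/%s/in/gpot[0:2]", id),
    outGpot = sprintf("/%s/out/gpot[0:2]", id),
    inSpike = sprintf("/%s/in/spike[0:2]", id),
    outSpike = sprintf("/%s/out/spike[0:2]", id)))
}

test_that("a fully typed interface validates cleanly", {
  rep <- validateSpec(eightPortSpec())
  expect_identical(nrow(rep), 0L)
  # validation is pure
  expect_identical(validateSpec(eightPortSpec()), rep)
})

test_that("conflicting, incomplete, or dangling specs are reported", {
  s <- lpuSpec("a", data.frame(
    identifier = c("/a/p[0]", "/a/p[0]"),
    io = c("in", "out"), transmission = c("gpot", "gpot"),
    stringsAsFactors = FALSE))
  expect_true("duplicate_port" %in% validateSpec(s)$code)
  s2 <- lpuSpec("a", data.frame(identifier = "/a/p[0]", io = NA_character_,
                                transmission = "gpot",
                                stringsAsFactors = FALSE))
  expect_true("missing_io" %in% validateSpec(s2)$code)
  # an empty interface is valid: internal components need not be exposed
  expect_identical(nrow(validateSpec(lpuSpec("quiet"))), 0L)
  s3 <- lpuSpec("a", interfaceTable(outGpot = "/a/o[0]"),
                components = data.frame(component = "n1", model = "LeakyIAF",
                                        params = I(list(numeric(0)))),
                bindings = data.frame(port = "/a/o[0]", component = "nope"))
  expect_true("dangling_component_reference" %in% validateSpec(s3)$code)
  s4 <- lpuSpec("a", interfaceTable(outGpot = "/a/o[0]"),
                components = data.frame(component = "n1", model = "LeakyIAF",
                                        params = I(list(numeric(0)))))
  expect_true("unbound_port" %in% validateSpec(s4)$code)
})

test_that("mappers cover exactly the ports of each kind, zeroed", {
  rt <- attachMappers(eightPortSpec())
  pm <- portMappers(rt)
  expect_identical(length(pm$gpot), 4L)
  expect_identical(length(pm$spike), 4L)
  expect_true(all(pm$gpot@buffer == 0))
  rtG <- attachMappers(lpuSpec("g", interfaceTable(inGpot = "/g/i[0:3]")))
  expect_identical(length(portMappers(rtG)$spike), 0L)
  # index layout matches the interface-0 worked example
  lam <- attachMappers(lpuSpec("lam", data.frame(
    identifier = sprintf("/lam[%d]", 0:5),
    io = c("out", "out", "in", "in", "in", "in"),
    transmission = rep(c("gpot", "spike"), each = 3),
    stringsAsFactors = FALSE)))
  expect_identical(portIndex(portMappers(lam)$gpot),
                   c("/lam[0]" = 0L, "/lam[1]" = 1L, "/lam[2]" = 2L))
  expect_identical(portIndex(portMappers(lam)$spike),
                   c("/lam[3]" = 0L, "/lam[4]" = 1L, "/lam[5]" = 2L))
  expect_error(attachMappers(lpuSpec("bad", data.frame(
    identifier = c("/b[0]", "/b[0]"), io = c("in", "out"),
    transmission = c("gpot", "gpot"), stringsAsFactors = FALSE))),
    class = "invalidSpecError")
})

test_that("hooks see inputs and write outputs; unwritten ports persist", {
  spec <- lpuSpec("e", interfaceTable(inGpot = "/e/in[0:2]",
                                      outGpot = "/e/out[0:2]"))
  rt <- attachMappers(spec, hook = echoHook(
    gpotMap = c("/e/out[0]" = "/e/in[0]", "/e/out[1]" = "/e/in[1]")))
  rt@state$gpot[c("/e/in[0]", "/e/in[1]")] <- c(0.5, 0.25)
  stepLPU(rt, 0L, 1e-3)
  expect_identical(unname(rt@state$gpot[c("/e/out[0]", "/e/out[1]")]),
                   c(0.5, 0.25))
  # constant-zero hook zeroes outputs every step
  rt0 <- attachMappers(spec, hook = zeroHook())
  rt0@state$gpot["/e/out[0]"] <- 9
  stepLPU(rt0, 0L, 1e-3)
  expect_true(all(rt0@state$gpot[c("/e/out[0]", "/e/out[1]")] == 0))
  # a hook that writes only some outputs leaves the others untouched
  rt2 <- attachMappers(spec, hook = constantHook(gpot = c("/e/out[0]" = 1)))
  stepLPU(rt2, 0L, 1e-3)
  stepLPU(rt2, 1L, 1e-3)
  expect_identical(unname(rt2@state$gpot["/e/out[1]"]), 0)
})

test_that("hook failures are wrapped with LPU id and step index", {
  spec <- lpuSpec("frail", interfaceTable(outGpot = "/f/o[0]"))
  rt <- attachMappers(spec, hook = function(g, s, state, t, dt)
    stop("boom"))
  err <- expect_error(stepLPU(rt, 3L, 1e-3), class = "hookError")
  expect_match(conditionMessage(err), "frail")
  expect_match(conditionMessage(err), "step 3")
  # writing a non-output port is rejected
  rt2 <- attachMappers(spec, hook = function(g, s, state, t, dt)
    list(gpot = c("/f/nope[0]" = 1)))
  expect_error(stepLPU(rt2, 0L, 1e-3), class = "unknownPortError")
})

test_that("a circuit-interpreted LIF matches a standalone integrator", {
  spec <- lpuSpec(
    "one",
    interfaceTable(inGpot = "/one/i[0]", outSpike = "/one/o[0]"),
    components = data.frame(component = "n1", model = "LeakyIAF",
                            params = I(list(numeric(0))),
                            stringsAsFactors = FALSE),
    bindings = data.frame(port = c("/one/i[0]", "/one/o[0]"),
                          component = c("n1", "n1"),
                          stringsAsFactors = FALSE))
  rt <- attachMappers(spec)
  dt <- 1e-4  # seconds -> 0.1 ms per model step
  current <- 3
  spikes <- numeric(200)
  for (t in 0:199) {
    rt@state$gpot["/one/i[0]"] <- current
    stepLPU(rt, t, dt)
    spikes[t + 1] <- rt@state$spike["/one/o[0]"]
  }
  # independent reference: direct model stepping
  p <- modelDefaults("LeakyIAF")
  st <- lifInit(p)
  ref <- numeric(200)
  for (t in 1:200) {
    r <- lifStep(st, current, p, dt * 1000)
    st <- r$state
    ref[t] <- r$spike
  }
  expect_identical(spikes, ref)
  expect_gt(sum(spikes), 0)
})

test_that("stepping is deterministic given state, inputs, and seed", {
  run <- function() {
    spec <- lpuSpec("r", interfaceTable(outGpot = "/r/o[0:3]"))
    rt <- attachMappers(spec, hook = randomHook())
    set.seed(99)
    rt@state$.rng <- get(".Random.seed", envir = globalenv())
    for (t in 0:4) stepLPU(rt, t, 1e-3)
    rt@state$gpot
  }
  expect_identical(run(), run())
})
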