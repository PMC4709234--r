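# Compute-plane models: analytic anchors, reference integrations, registry.

test_that("LIF rests at its fixed point and converges to rest + RI", {
  p <- modelDefaults("LeakyIAF")
  st <- lifInit(p)
  for (k in 1:1000) {
    r <- lifStep(st, 0, p, 0.05)
    st <- r$state
    expect_identical(r$spike, 0)
  }
  expect_equal(st$v, p[["vrest"]])
  # subthreshold drive: monotone approach to vrest + R I
  I <- 1  # R I = 10 < vth - vrest = 15
  st <- lifInit(p)
  vs <- numeric(4000)
  for (k in 1:4000) {
    r <- lifStep(st, I, p, 0.05)
    st <- r$state
    vs[k] <- r$v
  }
  expect_true(all(diff(vs) >= -1e-12))
  expect_equal(st$v, p[["vrest"]] + p[["r"]] * I, tolerance = 1e-3)
})

test_that("LIF interspike interval matches the closed form within 1%", {
  p <- modelDefaults("LeakyIAF")
  dt <- 0.01  # ms (1e-5 s)
  I <- 2      # R I = 20 above threshold distance 15
  theory <- p[["tau"]] * log(p[["r"]] * I /
                               (p[["r"]] * I - (p[["vth"]] - p[["vrest"]])))
  st <- lifInit(p)
  spikeTimes <- numeric(0)
  for (k in seq_len(15000)) {
    r <- lifStep(st, I, p, dt)
    st <- r$state
    if (r$spike == 1) spikeTimes <- c(spikeTimes, k * dt)
  }
  expect_gt(length(spikeTimes), 3)
  isi <- mean(diff(spikeTimes))
  expect_lt(abs(isi - theory) / theory, 0.01)
})

mlParams <- function() modelDefaults("MorrisLecar")

mlEquilibrium <- function(p, I = 0) {
  f <- function(v) {
    minf <- 0.5 * (1 + tanh((v - p[["v1"]]) / p[["v2"]]))
    winf <- 0.5 * (1 + tanh((v - p[["v3"]]) / p[["v4"]]))
    I - p[["gl"]] * (v - p[["vl"]]) - p[["gca"]] * minf * (v - p[["vca"]]) -
      p[["gk"]] * winf * (v - p[["vk"]])
  }
  v <- stats::uniroot(f, c(-80, 0))$root
  list(v = v, w = 0.5 * (1 + tanh((v - p[["v3"]]) / p[["v4"]])))
}

test_that("Morris-Lecar is stationary at its nullcline intersection", {
  p <- mlParams()
  eq <- mlEquilibrium(p)
  st <- list(v = eq$v, w = eq$w)
  for (k in 1:2000) st <- morrisLecarStep(st, 0, p, 0.01)$state
  expect_equal(st$v, eq$v, tolerance = 1e-6)
  expect_equal(st$w, eq$w, tolerance = 1e-6)
})

test_that("Morris-Lecar recovery variable stays in [0, 1] under noise", {
  set.seed(31)
  p <- mlParams()
  st <- morrisLecarInit(p)
  for (k in 1:20000) {
    st <- morrisLecarStep(st, stats::runif(1, -50, 120), p, 0.05)$state
    if (st$w < 0 || st$w > 1) break
  }
  expect_gte(st$w, 0)
  expect_lte(st$w, 1)
  expect_true(is.finite(st$v))
})

test_that("nearby Morris-Lecar trajectories converge to the same rest", {
  p <- mlParams()
  run <- function(v0) {
    st <- list(v = v0, w = 0.5 * (1 + tanh((v0 - p[["v3"]]) / p[["v4"]])))
    for (k in 1:40000) st <- morrisLecarStep(st, 0, p, 0.02)$state
    st$v
  }
  eq <- mlEquilibrium(p)
  v1 <- run(eq$v - 2)
  v2 <- run(eq$v + 2)
  expect_equal(v1, v2, tolerance = 1e-4)
  # reference integration (adaptive lsoda) lands at the same rest state
  skip_if_not_installed("deSolve")
  deriv <- function(t, y, parms) {
    minf <- 0.5 * (1 + tanh((y[1] - p[["v1"]]) / p[["v2"]]))
    winf <- 0.5 * (1 + tanh((y[1] - p[["v3"]]) / p[["v4"]]))
    tauw <- 1 / cosh((y[1] - p[["v3"]]) / (2 * p[["v4"]]))
    dv <- (-p[["gl"]] * (y[1] - p[["vl"]]) -
             p[["gca"]] * minf * (y[1] - p[["vca"]]) -
             p[["gk"]] * y[2] * (y[1] - p[["vk"]])) / p[["c"]]
    list(c(dv, p[["phi"]] * (winf - y[2]) / tauw))
  }
  out <- deSolve::lsoda(c(v = eq$v - 2, w = eq$w), c(0, 800), deriv, NULL)
  expect_equal(unname(out[2, "v"]), v1, tolerance = 1e-3)
})

hhReferenceSpikes <- function(I, tmax, p = modelDefaults("HodgkinHuxley")) {
  # independent oracle: adaptive lsoda integration of the same equations
  vtrap <- function(a, b) ifelse(abs(a / b) < 1e-6, b * (1 - a / (2 * b)),
                                 a / (exp(a / b) - 1))
  deriv <- function(t, y, parms) {
    v <- y[1]; m <- y[2]; h <- y[3]; n <- y[4]
    am <- 0.1 * vtrap(-(v + 40), 10); bm <- 4 * exp(-(v + 65) / 18)
    ah <- 0.07 * exp(-(v + 65) / 20); bh <- 1 / (1 + exp(-(v + 35) / 10))
    an <- 0.01 * vtrap(-(v + 55), 10); bn <- 0.125 * exp(-(v + 65) / 80)
    dv <- (I - p[["gna"]] * m^3 * h * (v - p[["vna"]]) -
             p[["gk"]] * n^4 * (v - p[["vk"]]) -
             p[["gl"]] * (v - p[["vl"]])) / p[["c"]]
    list(c(dv, am * (1 - m) - bm * m, ah * (1 - h) - bh * h,
           an * (1 - n) - bn * n))
  }
  y0 <- unlist(hodgkinHuxleyInit(p))
  out <- deSolve::lsoda(y0, seq(0, tmax, by = 0.05), deriv, NULL,
                        rtol = 1e-8, atol = 1e-8)
  v <- out[, "v"]
  sum(v[-1] >= 0 & v[-length(v)] < 0)
}

test_that("Hodgkin-Huxley stays quiet at rest and fires under drive", {
  skip_if_not_installed("deSolve")
  p <- modelDefaults("HodgkinHuxley")
  st <- hodgkinHuxleyInit(p)
  nsp <- 0
  for (k in 1:10000) {  # 100 ms at 0.01 ms
    r <- hodgkinHuxleyStep(st, 0, p, 0.01)
    st <- r$state
    nsp <- nsp + r$spike
    expect_true(all(c(st$m, st$h, st$n) >= 0 & c(st$m, st$h, st$n) <= 1))
  }
  expect_identical(nsp, 0)
  expect_identical(hhReferenceSpikes(0, 100), 0L)
  # strong constant current: repetitive firing, count within +-1 of the
  # adaptive reference
  st <- hodgkinHuxleyInit(p)
  nsp <- 0
  for (k in 1:10000) {
    r <- hodgkinHuxleyStep(st, 10, p, 0.01)
    st <- r$state
    nsp <- nsp + r$spike
  }
  expect_gt(nsp, 3)
  expect_lte(abs(nsp - hhReferenceSpikes(10, 100)), 1)
})

test_that("alpha synapse peaks at t = tau and is silent without input", {
  p <- modelDefaults("AlphaSynapse")
  dt <- 0.01
  st <- alphaSynapseInit(p)
  g <- numeric(2000)
  for (k in 1:2000) {
    r <- alphaSynapseStep(st, if (k == 1) 1 else 0, p, dt)
    st <- r$state
    g[k] <- r$g
  }
  expect_lte(abs(which.max(g) * dt - p[["tau"]]), dt)
  expect_equal(max(g), p[["gmax"]], tolerance = 0.01)
  # zero input, zero state -> zero output forever
  st <- alphaSynapseInit(p)
  for (k in 1:100) {
    r <- alphaSynapseStep(st, 0, p, dt)
    st <- r$state
    expect_identical(r$g, 0)
  }
})

test_that("conductance synapse current vanishes at the reversal potential", {
  p <- modelDefaults("ConductanceSynapse")
  st <- conductanceSynapseInit(p)
  for (k in 1:200) {
    r <- conductanceSynapseStep(st, -40, p, 0.01, vpost = p[["erev"]])
    st <- r$state
    expect_identical(r$current, 0)
  }
  expect_gt(st$g, 0)
  # below-rest reversal makes it inhibitory at a typical Vpost
  r <- conductanceSynapseStep(st, -40, p, 0.01, vpost = -60)
  expect_lt(r$current, 0)
})

test_that("halving dt shows first-order convergence on a fixed drive", {
  skip_if_not_installed("deSolve")
  p <- mlParams()
  eq <- mlEquilibrium(p)
  drive <- function(t) 30 * sin(t / 5)  # smooth deterministic input, ms
  runAt <- function(dt) {
    st <- list(v = eq$v, w = eq$w)
    for (k in seq_len(round(40 / dt)))
      st <- morrisLecarStep(st, drive((k - 1) * dt), p, dt)$state
    st$v
  }
  deriv <- function(t, y, parms) {
    minf <- 0.5 * (1 + tanh((y[1] - p[["v1"]]) / p[["v2"]]))
    winf <- 0.5 * (1 + tanh((y[1] - p[["v3"]]) / p[["v4"]]))
    tauw <- 1 / cosh((y[1] - p[["v3"]]) / (2 * p[["v4"]]))
    dv <- (drive(t) - p[["gl"]] * (y[1] - p[["vl"]]) -
             p[["gca"]] * minf * (y[1] - p[["vca"]]) -
             p[["gk"]] * y[2] * (y[1] - p[["vk"]])) / p[["c"]]
    list(c(dv, p[["phi"]] * (winf - y[2]) / tauw))
  }
  ref <- deSolve::lsoda(c(v = eq$v, w = eq$w), c(0, 40), deriv, NULL,
                        rtol = 1e-10, atol = 1e-10)[2, "v"]
  errs <- abs(vapply(c(0.2, 0.1, 0.05), runAt, numeric(1)) - ref)
  ratios <- errs[-length(errs)] / errs[-1]
  # explicit Euler: error halves (up to constants) when dt halves
  expect_true(all(ratios > 1.5 & ratios < 3))
})

test_that("the registry holds the built-in models and accepts plugins", {
  reg <- defaultRegistry()
  expect_setequal(modelNames(reg),
                  c("LeakyIAF", "MorrisLecar", "HodgkinHuxley",
                    "AlphaSynapse", "ConductanceSynapse",
                    "PhotoreceptorSurrogate"))
  registerModel(reg, "Echo",
                factory = function(p) list(last = 0),
                step = function(state, input, params, dt)
                  list(state = list(last = input), output = input,
                       v = input),
                defaults = c(gain = 1))
  expect_true("Echo" %in% modelNames(reg))
  expect_error(registerModel(reg, "Echo", function(p) list(),
                             function(state, input, params, dt)
                               list(state = state, output = 0),
                             c()), class = "duplicateModelError")
  # a registered plugin is instantiable from a spec and runs in a plan
  spec <- lpuSpec("p", interfaceTable(inGpot = "/p/i[0]",
                                      outGpot = "/p/o[0]"),
                  components = data.frame(component = "e1", model = "Echo",
                                          params = I(list(numeric(0))),
                                          stringsAsFactors = FALSE),
                  bindings = data.frame(port = c("/p/i[0]", "/p/o[0]"),
                                        component = "e1",
                                        stringsAsFactors = FALSE))
  plan <- addLPU(emulationPlan(1e-3), spec, registry = reg)
  rec <- runEmulation(plan, steps = 2,
                      stimulus = function(t)
                        list(p = list(gpot = c("/p/i[0]" = 0.4))),
                      record = "p")
  expect_equal(unname(rec@trace$p$gpot[2, "/p/o[0]"]), 0.4)
})

test_that("model steps reject nonpositive dt", {
  p <- modelDefaults("LeakyIAF")
  expect_error(lifStep(lifInit(p), 0, p, 0), class = "dtError")
  expect_error(morrisLecarStep(morrisLecarInit(mlParams()), 0, mlParams(),
                               -1), class = "dtError")
})
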