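# Point-neuron and synapse models. All step functions are pure:
# (state, input, params, dt) -> updated state + output, with dt in
# milliseconds and voltages in mV. The emulation clock runs in seconds;
# the circuit engine converts (see circuitHook). Integration is explicit
# Euler at the given dt; callers may sub-step internally.

.checkDt <- function(dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .selStop("dt must be a positive number (milliseconds)", "dtError")
}

# --- leaky integrate-and-fire ----------------------------------------------

#' Leaky integrate-and-fire neuron step
#'
#' Canonical leaky integrator `tau dV/dt = -(V - Vrest) + R I`; on crossing
#' `Vth` the neuron emits a spike and resets to `Vreset`. With
#' `Vreset = Vrest`, the interspike interval under constant suprathreshold
#' current is `tau log(RI / (RI - (Vth - Vrest)))`.
#'
#' @param state list with element `v` (membrane potential, mV); create with
#'   `lifInit(params)`.
#' @param current injected current.
#' @param params named numeric: `tau` (ms), `r` (resistance), `vrest`,
#'   `vth`, `vreset` (mV). See `modelDefaults("LeakyIAF")`.
#' @param dt step size in milliseconds.
#' @return list with `state` (updated), `spike` (0/1), `v`.
#' @export
lifStep <- function(state, current, params, dt) {
  .checkDt(dt)
  v <- state$v + dt / params[["tau"]] *
    (-(state$v - params[["vrest"]]) + params[["r"]] * current)
  spike <- 0
  if (v >= params[["vth"]]) {
    spike <- 1
    v <- params[["vreset"]]
  }
  list(state = list(v = v), spike = spike, v = v)
}

#' @rdname lifStep
#' @export
lifInit <- function(params) list(v = params[["vrest"]])

# --- Morris-Lecar (graded-potential configuration) --------------------------

.mlMinf <- function(v, p) 0.5 * (1 + tanh((v - p[["v1"]]) / p[["v2"]]))
.mlWinf <- function(v, p) 0.5 * (1 + tanh((v - p[["v3"]]) / p[["v4"]]))
.mlTauW <- function(v, p) 1 / cosh((v - p[["v3"]]) / (2 * p[["v4"]]))

#' Morris-Lecar neuron step
#'
#' Two-variable Morris-Lecar model
#' `C dV/dt = I - gL (V-VL) - gCa m_inf(V) (V-VCa) - gK w (V-VK)`,
#' `dw/dt = phi (w_inf(V) - w) / tau_w(V)`, with
#' `m_inf, w_inf` sigmoidal in V and `tau_w(V) = 1/cosh((V-v3)/(2 v4))`.
#' Used here in a graded-potential configuration: the output is the membrane
#' potential itself, without thresholding. The recovery variable is clamped
#' to `[0, 1]` (explicit Euler can overshoot by O(dt)).
#'
#' @param state list with `v` (mV) and `w` (recovery, dimensionless).
#' @param current injected current.
#' @param params see `modelDefaults("MorrisLecar")` (Rinzel-Ermentrout
#'   parameterization).
#' @param dt step size in milliseconds.
#' @return list with `state`, `v` (graded output).
#' @export
morrisLecarStep <- function(state, current, params, dt) {
  .checkDt(dt)
  v <- state$v; w <- state$w
  dv <- (current - params[["gl"]] * (v - params[["vl"]]) -
           params[["gca"]] * .mlMinf(v, params) * (v - params[["vca"]]) -
           params[["gk"]] * w * (v - params[["vk"]])) / params[["c"]]
  dw <- params[["phi"]] * (.mlWinf(v, params) - w) / .mlTauW(v, params)
  v <- v + dt * dv
  w <- min(1, max(0, w + dt * dw))
  list(state = list(v = v, w = w), v = v)
}

#' @rdname morrisLecarStep
#' @export
morrisLecarInit <- function(params) {
  v <- params[["vinit"]]
  list(v = v, w = .mlWinf(v, params))
}

# --- Hodgkin-Huxley ---------------------------------------------------------

# a/(1-exp(-a/b)) with the removable singularity at a = 0 handled
.vtrap <- function(a, b) ifelse(abs(a / b) < 1e-6, b * (1 - a / (2 * b)),
                                a / (exp(a / b) - 1))

.hhRates <- function(v) {
  list(
    am = 0.1 * .vtrap(-(v + 40), 10),
    bm = 4 * exp(-(v + 65) / 18),
    ah = 0.07 * exp(-(v + 65) / 20),
    bh = 1 / (1 + exp(-(v + 35) / 10)),
    an = 0.01 * .vtrap(-(v + 55), 10),
    bn = 0.125 * exp(-(v + 65) / 80))
}

#' Hodgkin-Huxley neuron step
#'
#' Four-variable Hodgkin-Huxley squid-axon model with the standard rate
#' functions (1952 parameterization, resting potential about -65 mV). The
#' spike flag marks an upward crossing of 0 mV, at most one per step.
#'
#' Explicit Euler is conditionally stable for this system; keep
#' `dt <= 0.05` ms (the fastest gating time constant is ~0.1 ms near spike
#' threshold), or sub-step internally.
#'
#' @param state list with `v` (mV) and gating variables `m`, `h`, `n`.
#' @param current injected current (uA/cm^2).
#' @param params see `modelDefaults("HodgkinHuxley")`.
#' @param dt step size in milliseconds.
#' @return list with `state`, `spike` (0/1), `v`.
#' @export
hodgkinHuxleyStep <- function(state, current, params, dt) {
  .checkDt(dt)
  v <- state$v; m <- state$m; h <- state$h; n <- state$n
  r <- .hhRates(v)
  ina <- params[["gna"]] * m^3 * h * (v - params[["vna"]])
  ik <- params[["gk"]] * n^4 * (v - params[["vk"]])
  il <- params[["gl"]] * (v - params[["vl"]])
  vNew <- v + dt * (current - ina - ik - il) / params[["c"]]
  m <- min(1, max(0, m + dt * (r$am * (1 - m) - r$bm * m)))
  h <- min(1, max(0, h + dt * (r$ah * (1 - h) - r$bh * h)))
  n <- min(1, max(0, n + dt * (r$an * (1 - n) - r$bn * n)))
  spike <- as.numeric(v < 0 && vNew >= 0)
  list(state = list(v = vNew, m = m, h = h, n = n), spike = spike, v = vNew)
}

#' @rdname hodgkinHuxleyStep
#' @export
hodgkinHuxleyInit <- function(params) {
  v <- params[["vinit"]]
  r <- .hhRates(v)
  list(v = v, m = r$am / (r$am + r$bm), h = r$ah / (r$ah + r$bh),
       n = r$an / (r$an + r$bn))
}

# --- synapses ---------------------------------------------------------------

#' Alpha-function synapse step
#'
#' Conductance with alpha-kernel impulse response: a single presynaptic
#' spike at t = 0 produces `g(t) = gmax (t/tau) exp(1 - t/tau)`, which peaks
#' at exactly `g = gmax` when `t = tau`. Implemented as the two-state linear
#' system `z' = -z/tau` (jumping by `gmax` per spike),
#' `g' = (e z - g)/tau`. The postsynaptic current contribution is
#' `g (Erev - Vpost)`.
#'
#' @param state list with `z`, `g`; create with `alphaSynapseInit()`.
#' @param pre presynaptic spike indicator (0/1) for this step.
#' @param params named numeric: `gmax`, `tau` (ms), `erev` (mV).
#' @param dt step size in milliseconds.
#' @param vpost postsynaptic membrane potential (mV).
#' @return list with `state`, `g`, `current`.
#' @export
alphaSynapseStep <- function(state, pre, params, dt, vpost = 0) {
  .checkDt(dt)
  tau <- params[["tau"]]
  z <- state$z + dt * (-state$z / tau) + params[["gmax"]] * pre
  g <- state$g + dt * (exp(1) * state$z - state$g) / tau
  g <- max(0, g)
  list(state = list(z = z, g = g), g = g,
       current = g * (params[["erev"]] - vpost))
}

#' @rdname alphaSynapseStep
#' @export
alphaSynapseInit <- function(params) list(z = 0, g = 0)

#' Graded conductance synapse step
#'
#' Conductance driven by the presynaptic membrane potential through a
#' sigmoidal activation `s(Vpre) = 1/(1 + exp(-(Vpre - vmid)/vslope))`
#' low-pass filtered with time constant `tau`; the current contribution is
#' `g (Erev - Vpost)`. With `Erev` below the postsynaptic resting potential
#' the synapse is inhibitory (e.g. histaminergic photoreceptor output in the
#' fly lamina).
#'
#' @param state list with `g`; create with `conductanceSynapseInit()`.
#' @param pre presynaptic membrane potential (mV).
#' @param params named numeric: `gmax`, `tau` (ms), `vmid`, `vslope`,
#'   `erev` (mV).
#' @param dt step size in milliseconds.
#' @param vpost postsynaptic membrane potential (mV).
#' @return list with `state`, `g`, `current`.
#' @export
conductanceSynapseStep <- function(state, pre, params, dt, vpost = 0) {
  .checkDt(dt)
  sinf <- 1 / (1 + exp(-(pre - params[["vmid"]]) / params[["vslope"]]))
  g <- state$g + dt * (params[["gmax"]] * sinf - state$g) / params[["tau"]]
  g <- max(0, g)
  list(state = list(g = g), g = g,
       current = g * (params[["erev"]] - vpost))
}

#' @rdname conductanceSynapseStep
#' @export
conductanceSynapseInit <- function(params) list(g = 0)

# --- surrogate photoreceptor ------------------------------------------------

#' Surrogate photoreceptor step
#'
#' A deliberately simple stand-in for a biophysical phototransduction
#' cascade: log-intensity transduction
#' `Vtarget = vrest + k log(1 + I)` followed by a first-order low-pass with
#' time constant `tau`. With `shot > 0`, the light input is replaced by a
#' Poisson photon count `Pois(I shot dt) / (shot dt)` (shot noise), drawn
#' from the calling LPU's RNG stream. This is a synthetic surrogate and
#' makes no claim of biophysical fidelity.
#'
#' @param state list with `v`; create with `photoreceptorInit()`.
#' @param light nonnegative light intensity (arbitrary units).
#' @param params named numeric: `k` (mV per log unit), `tau` (ms),
#'   `vrest` (mV), `shot` (photon rate scale; 0 disables noise).
#' @param dt step size in milliseconds.
#' @return list with `state`, `v`.
#' @export
photoreceptorStep <- function(state, light, params, dt) {
  .checkDt(dt)
  light <- max(0, light)
  if (params[["shot"]] > 0) {
    lam <- light * params[["shot"]] * dt
    light <- stats::rpois(1L, lam) / (params[["shot"]] * dt)
  }
  target <- params[["vrest"]] + params[["k"]] * log1p(light)
  v <- state$v + dt * (target - state$v) / params[["tau"]]
  list(state = list(v = v), v = v)
}

#' @rdname photoreceptorStep
#' @export
photoreceptorInit <- function(params) list(v = params[["vrest"]])

# --- model registry ---------------------------------------------------------

# adapter giving every registered model the uniform plugin signature
# step(state, input, params, dt) -> list(state, output, v?, spike?)
.builtinModels <- function() {
  list(
    LeakyIAF = list(
      role = "neuron", output = "spike",
      defaults = c(tau = 20, r = 10, vrest = -65, vth = -50, vreset = -65),
      factory = lifInit,
      step = function(state, input, params, dt) {
        r <- lifStep(state, input, params, dt)
        list(state = r$state, output = r$spike, v = r$v, spike = r$spike)
      }),
    MorrisLecar = list(
      role = "neuron", output = "v",
      defaults = c(c = 20, gca = 4.4, gk = 8, gl = 2, vca = 120, vk = -84,
                   vl = -60, v1 = -1.2, v2 = 18, v3 = 2, v4 = 30,
                   phi = 0.04, vinit = -60),
      factory = morrisLecarInit,
      step = function(state, input, params, dt) {
        r <- morrisLecarStep(state, input, params, dt)
        list(state = r$state, output = r$v, v = r$v, spike = 0)
      }),
    HodgkinHuxley = list(
      role = "neuron", output = "spike",
      defaults = c(c = 1, gna = 120, gk = 36, gl = 0.3, vna = 50, vk = -77,
                   vl = -54.387, vinit = -65),
      factory = hodgkinHuxleyInit,
      step = function(state, input, params, dt) {
        r <- hodgkinHuxleyStep(state, input, params, dt)
        list(state = r$state, output = r$spike, v = r$v, spike = r$spike)
      }),
    AlphaSynapse = list(
      role = "synapse", output = "current",
      defaults = c(gmax = 1, tau = 5, erev = 0),
      factory = alphaSynapseInit,
      step = function(state, input, params, dt) {
        r <- alphaSynapseStep(state, input[["pre"]], params, dt,
                              vpost = input[["vpost"]])
        list(state = r$state, output = r$current, g = r$g)
      }),
    ConductanceSynapse = list(
      role = "synapse", output = "current",
      defaults = c(gmax = 0.5, tau = 10, vmid = -55, vslope = 5, erev = -80),
      factory = conductanceSynapseInit,
      step = function(state, input, params, dt) {
        r <- conductanceSynapseStep(state, input[["pre"]], params, dt,
                                    vpost = input[["vpost"]])
        list(state = r$state, output = r$current, g = r$g)
      }),
    PhotoreceptorSurrogate = list(
      role = "neuron", output = "v",
      defaults = c(k = 10, tau = 20, vrest = -70, shot = 0),
      factory = photoreceptorInit,
      step = function(state, input, params, dt) {
        r <- photoreceptorStep(state, input, params, dt)
        list(state = r$state, output = r$v, v = r$v, spike = 0)
      })
  )
}

#' The compute-plane model registry
#'
#' A registry maps model type names (the strings used in circuit documents)
#' to a state factory, a step function, a role (`"neuron"` or `"synapse"`),
#' and default parameters. The default registry contains the built-in models
#' `LeakyIAF`, `MorrisLecar`, `HodgkinHuxley`, `AlphaSynapse`,
#' `ConductanceSynapse`, and `PhotoreceptorSurrogate`. Additional models can
#' be plugged in with [registerModel()].
#'
#' @return an environment mapping model names to model definitions.
#' @examples
#' modelNames(defaultRegistry())
#' @export
defaultRegistry <- function() {
  reg <- new.env(parent = emptyenv())
  for (nm in names(.builtinModels()))
    assign(nm, .builtinModels()[[nm]], envir = reg)
  reg
}

#' @rdname defaultRegistry
#' @param registry a model registry environment.
#' @export
modelNames <- function(registry = defaultRegistry()) {
  sort(ls(registry))
}

#' @rdname defaultRegistry
#' @param name model type name.
#' @export
modelInfo <- function(registry, name) {
  if (!exists(name, envir = registry, inherits = FALSE))
    .selStop(sprintf("unknown model '%s'", name), "unknownModelError")
  get(name, envir = registry, inherits = FALSE)
}

#' @rdname defaultRegistry
#' @export
modelDefaults <- function(name, registry = defaultRegistry()) {
  modelInfo(registry, name)$defaults
}

#' Register a plugin model
#'
#' Adds a model to a registry so circuit documents can instantiate it by
#' name. The default parameters are validated by constructing a state with
#' the factory and running one step.
#'
#' @param registry a registry environment (from [defaultRegistry()]).
#' @param name unused model type name.
#' @param factory function `(params) -> state list`.
#' @param step function `(state, input, params, dt) -> list(state, output,
#'   ...)`.
#' @param defaults named numeric vector of default parameters.
#' @param role `"neuron"` (input is summed current / external drive) or
#'   `"synapse"` (input is `c(pre = , vpost = )`).
#' @param output label of the routed output: `"v"`, `"spike"`, or
#'   `"current"`.
#' @return the registry, invisibly.
#' @export
registerModel <- function(registry, name, factory, step, defaults,
                          role = c("neuron", "synapse"),
                          output = c("v", "spike", "current")) {
  role <- match.arg(role)
  output <- match.arg(output)
  if (exists(name, envir = registry, inherits = FALSE))
    .selStop(sprintf("model '%s' is already registered", name),
             "duplicateModelError")
  if (is.null(names(defaults)) && length(defaults) > 0)
    .selStop("defaults must be a named numeric vector", "schemaError")
  st <- factory(defaults)
  probe <- if (role == "synapse") c(pre = 0, vpost = 0) else 0
  res <- step(st, probe, defaults, 0.01)
  if (!is.list(res) || is.null(res$state) || is.null(res$output))
    .selStop("step function must return list(state =, output =, ...)",
             "schemaError")
  assign(name, list(role = role, output = output, defaults = defaults,
                    factory = factory, step = step), envir = registry)
  invisible(registry)
}
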