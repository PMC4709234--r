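---
title: "Modular circuit emulation: model, interfaces, and numerical choices"
author: "lpuSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular circuit emulation: model, interfaces, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpuSim)
```

## The programming model

Insect brains decompose into a modest number of functional modules --
neuropils such as the lamina, medulla, or antennal lobe -- each
characterized by its own population of local neurons. lpuSim models such a
module as a *local processing unit* (LPU): a black box with

* a unique id,
* a typed **port interface**: every port either receives input or emits
  output, and carries either *spike* data (0/1 per step) or
  *graded-potential* data (a double per step); the two settings are
  mutually exclusive per port,
* a **step hook** that implements one emulation step of the module's
  internal dynamics, reading input-port values and writing output-port
  values.

What happens inside the hook is entirely the module author's business --
synapse models, sub-stepping at a finer internal time resolution, custom
state. The framework only guarantees how modules *communicate*: after
every step, output-port data crosses the inter-LPU connectivity patterns
to destination input ports, and no LPU starts step `t + 1` until all data
from step `t` has been delivered (bulk-synchronous execution). One
consequence is deliberate and documented: information crosses exactly one
pattern per step, so a chain of `L` modules has a head-to-tail latency of
`L` steps, and every emulation starts from zeroed buffers at step 0.
Unconnected input ports read 0 forever. Self-connections (an LPU wired to
itself through a pattern) are allowed and see the same one-step latency.

## Port selectors

Interfaces routinely hold thousands of ports, so ports are named by
hierarchical path-like identifiers and addressed in bulk by *selectors*:

```{r selectors}
expandSelector("/med/[L1,L2][0]")
countPorts("/med/L1[0:10]")
expandAgainst("/med/L1/*", c("/med/L1[0]", "/med/L1[1]", "/med/L2[0]"))
```

Grammar decisions that the selector notation itself does not pin down were
fixed once and are normative for this package:

* ranges `[i:j]` are **half-open** (`[0:10]` is ten ports) -- forced by the
  convention that a range of ten indices selects ten ports;
* expansion order is deterministic: list and range elements in source
  order, products left-major, union duplicates removed keeping the first
  occurrence;
* name levels match `[A-Za-z_][A-Za-z0-9_]*`; an all-digit level is an
  integer index, which makes `/med/L1/0` and `/med/L1[0]` the same
  identifier; renderers emit the canonical bracketed form;
* the wildcard `*` may appear only as the final level, and wildcard
  selectors are second-class: they cannot be counted or expanded standalone,
  only resolved against a universe (`expandAgainst()`), where they match
  identifiers extending the prefix by at least one level;
* between selector *strings*, `+` is concatenation (a left-major product)
  and `.+` an equal-cardinality elementwise join; between selector
  *objects*, `+` is set union, which is the operation one wants when
  assembling an interface from its typed subsets. Whether a product of two
  multi-element selectors is meaningful is not something the notation
  dictates; we define it as the full left-major product and note that this
  is our extrapolation.

## Connectivity patterns

A `Pattern` links two interfaces (labels 0 and 1) with a sparse set of
directed connections; storage grows with the number of connections, never
with the product of interface sizes. Two conventions deserve emphasis:

* **Directions are pattern-relative.** An LPU's *output* port is a pattern
  `"in"` port (it feeds the pattern) and an LPU's *input* port is a pattern
  `"out"` port. `checkCompatibility()` enforces exactly this
  correspondence, so the inversion cannot silently go wrong.
* **Fan-in is prohibited; fan-out is free.** Each destination port has at
  most one source, across *all* patterns of an emulation (the routing
  compiler re-checks globally). Multiplexing of several sources belongs
  inside the receiving LPU, where the module author controls it. Connections
  are presence-only: they carry no weights or delays, because synapses are
  models inside LPUs, not properties of the wiring.

A pattern is bidirectional: connections may run 0 to 1 and 1 to 0 in the
same object. Ports may carry attributes yet remain unconnected; routing
and compatibility checks simply ignore them. Attributes may be revised
after connections exist only if every invariant still holds -- failing
early here is cheaper than failing at route compilation.

## Port mappers and routing

A `PortMapper` assigns the ports of one transmission kind contiguous
0-based buffer indices in the defining selector's expansion order (the
interface declaration order for an LPU's two mappers). Index layout is
stable across a run. Graded-potential buffers are doubles; spike buffers
are 0/1 integers; both start zeroed. Where the buffers physically live is
a backend concern: the reference backend is plain host arrays, and nothing
in the contract would change for an accelerator-resident implementation.

`compileRoutes()` turns patterns plus mappers into a flat routing table --
one `(source LPU, source index) -> (destination LPU, destination index)`
row per connection and kind. The sync phase is then a set of vectorized
gathers; it copies values and does nothing else, which is what makes the
serial and multiprocess backends bitwise interchangeable.

## Execution backends

The transport abstraction hides where LPUs run:

* the **serial** backend steps all LPUs in registration order in-process;
  the barrier makes the order unobservable;
* the **multiprocess** backend places LPUs on PSOCK worker processes
  (`makeWorkerCluster()`), ships each worker its runtimes once, and per
  step exchanges only input updates and output buffers by message passing.

Both satisfy the same barrier contract, and the suite asserts bitwise
identical port buffers between them on randomized plans. Stochastic hooks
stay reproducible across placements because each LPU owns a private RNG
stream (seeded `seed + i` from the run seed, restored around every hook
invocation), so placement and scheduling cannot perturb draws.

Worker placement uses a greedy Kernighan--Lin-style partitioner
(`partitionLPUs()`): highest-connectivity LPUs are placed first on the
worker minimizing the cut increase under a `ceiling(n/workers)` balance
cap, followed by single-move local search. It plays the same role a
general graph partitioner would at cluster scale, at desk scale and with
no external dependency; `edgeCut()` lets users compare it against round-robin.

## The compute plane

Models plug into a registry keyed by the type names used in circuit
documents. The built-ins are canonical textbook formulations -- the
framework names the models it supports but their equations are standard:

| model | state | parameters (defaults) |
|---|---|---|
| `LeakyIAF` | `v` | `tau` 20 ms, `r` 10, `vrest` -65, `vth` -50, `vreset` -65 mV |
| `MorrisLecar` | `v`, `w` | Rinzel--Ermentrout set: `c` 20, `gca` 4.4, `gk` 8, `gl` 2, `vca` 120, `vk` -84, `vl` -60, `v1` -1.2, `v2` 18, `v3` 2, `v4` 30 mV, `phi` 0.04 |
| `HodgkinHuxley` | `v`, `m`, `h`, `n` | 1952 squid-axon set: `c` 1, `gna` 120, `gk` 36, `gl` 0.3, `vna` 50, `vk` -77, `vl` -54.387 mV |
| `AlphaSynapse` | `z`, `g` | `gmax` 1, `tau` 5 ms, `erev` 0 mV |
| `ConductanceSynapse` | `g` | `gmax` 0.5, `tau` 10 ms, `vmid` -55, `vslope` 5, `erev` -80 mV |
| `PhotoreceptorSurrogate` | `v` | `k` 10 mV/log-unit, `tau` 20 ms, `vrest` -70 mV, `shot` 0 |

Numerical choices:

* **Integration** is explicit Euler at the emulation step. Model equations
  use the field's conventional units (mV, ms); the emulation clock is in
  seconds and the circuit engine converts. Euler is first-order: halving
  `dt` halves the endpoint error, which the suite verifies against
  adaptive `deSolve::lsoda` references. Hooks may sub-step internally.
* **Stability**: explicit Euler on Hodgkin--Huxley needs `dt` at or below
  about 0.05 ms (the fastest gating time constant near threshold); the
  Morris--Lecar graded configuration is forgiving up to ~0.1 ms.
* **Clamps**: gating/recovery variables are clamped to [0, 1] and synaptic
  conductances to nonnegative values, bounding the O(dt) Euler overshoot
  that could otherwise leave the physical domain.
* **Spikes** are at most one per neuron per emulation step (a flag, not a
  timestamp); Hodgkin--Huxley spikes are upward crossings of 0 mV.
* The analytic anchor of the module is the LIF interspike interval: with
  `vreset = vrest`, constant suprathreshold current `I` gives
  `ISI = tau * log(RI / (RI - (vth - vrest)))`, which the Euler
  integration reproduces within 1% at `dt` = 0.01 ms.
* The **alpha synapse** is the linear system `z' = -z/tau`,
  `g' = (e z - g)/tau` with `z` jumping by `gmax` per spike, whose impulse
  response `gmax (t/tau) exp(1 - t/tau)` peaks at exactly `t = tau`.

The **circuit engine** (`circuitHook()`) executes declarative component
graphs with a Jacobi-style update: every component reads the
previous-step outputs of its upstream components, so each internal edge
carries one step of latency. This keeps the scheme order-independent and
deterministic at the cost of an O(dt) skew relative to a Gauss--Seidel
sweep -- consistent with the first-order integrator, and convergent under
the same refinement. Conductance synapses read their target neuron's
previous-step potential for the driving force.

The `PhotoreceptorSurrogate` deserves a caveat: real fly phototransduction
is a stochastic cascade of tens of thousands of microvilli with many
equations each. That model lives outside this package's scope; the
surrogate (log-intensity transduction, first-order low-pass, optional
Poisson shot noise) reproduces only the qualitative light-to-depolarization
map so the composition can be exercised end-to-end, and
`equationCount()` keeps the bookkeeping of what the full model would cost:
`721 * 6 * 30000 * 15` is about 1.95 billion equations.

## The retina/lamina fixture

`buildRetinaLamina()` generates the package's flagship composition: a
retina LPU of surrogate photoreceptors over a centered hexagonal array
(`hexArray()`, count `1 + 3 r (r + 1)`; 15 rings give 721 ommatidia with 6
photoreceptors each), a lamina LPU of Morris--Lecar cartridge neurons fed
through inhibitory (histamine-like, `erev` below rest) conductance
synapses, and a feed-forward pattern with exactly one connection per
photoreceptor -- 4,326 at full scale.

In the real eye, photoreceptors from six neighboring ommatidia that view
the same point of space converge on one lamina cartridge (neural
superposition). The anatomical mapping is not reproduced here; the fixture
substitutes a deterministic cyclic shift (position `p` maps ommatidium
`i` to cartridge `(i + p - 1) mod N`). The substitute is chosen for its
properties, not its anatomy: it is a bijection for every position, so the
fan-in invariant holds and the connection count is exactly `6 N`, and
position R1 maps retinotopically, which is what the demo records.

What passing fixture tests do and do not show: they validate the
*framework* -- interface typing, pattern validation, routing, the
bulk-synchronous contract, sign-correct inhibition through the chain --
on a composition of realistic scale and shape. They do not validate
biophysics: the surrogate photoreceptor and the stand-in wiring make no
quantitative claim about real retinal responses, and real inputs (videos,
receptor noise, optics) have structure the uniform/step test frames do
not.

## The benchmark harness

`benchmarkTopology()` reproduces the *experimental designs* used to probe
inter-module communication: a 2-LPU pair with the output-port count swept
over 25 equally spaced values in [50, 15000]; all-to-all emulations of up
to 19 LPUs with the per-LPU port total fixed; and a synthetic
`connectome_counts` sequence in which successive LPUs join with
geometrically decaying connection counts, standing in for per-LPU counts
that come from connectome reconstructions and are not re-derived here. All
benchmark LPUs have empty step hooks, isolating communication cost.
Timing numbers from `benchmarkRun()` are hardware-dependent and are
deliberately excluded from any correctness claim; the harness asserts only
the design (grids, route counts, topology shape).

## Problem sizes used by the test suite

The suite exercises the full-scale fixture only where the quantity *is*
the scale (counting 721 ommatidia, 4,326 connections and neurons, which
takes well under a second). Dynamics are tested at small scale: random
plans of 2--4 LPUs with up to 4 ports per kind, 50-step runs for the
transport-equivalence sweep (100 random plans), echo chains up to length
6, demo runs at 0--2 rings for 20--200 steps, and single-neuron
integrations of 10--40 ms at `dt` 0.01--0.08 ms. These sizes were chosen
so the whole suite runs in about a minute while still crossing every
contract boundary; nothing in the semantics depends on scale.

## Known limitations

* Connections are static for the lifetime of an emulation; there is no
  dynamic rewiring.
* Spike transport is dense per step (one 0/1 per spiking port); there is
  no event/timestamp representation, so very sparse activity pays the
  full sync cost.
* All ports are sampled every step; per-port sampling rates are out of
  scope.
* The circuit engine is an interpreter in R: adequate for hundreds of
  components per LPU at millisecond steps, not for 10^5-neuron modules.
  The LPU contract was designed so such modules can implement their hook
  however they like (including compiled code) without touching the
  framework.
* `runDemo()` maps video pixels to ommatidia by nearest pixel to the hex
  center -- no optics, no per-photoreceptor lines of sight.
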