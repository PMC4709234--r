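# lpuSim

Modular emulation of interconnected neural circuits in R.

Insect brains -- the fruit fly's in particular -- decompose into a few
dozen functional modules (neuropils such as the retina, lamina, and
medulla), each defined by its own local neuron population. lpuSim is for
computational neuroscientists who want to build models of such modules
*independently* and then compose them: it enforces a programming model in
which every module (a *local processing unit*, LPU) is a black box behind
a typed port interface, inter-module wiring is a validated first-class
object, and execution is bulk-synchronous, so independently developed
modules interoperate regardless of their internal design.

The core abstractions:

* **Port selectors** — hierarchical path-like names for ports with an
  algebra of lists, half-open ranges, unions (`,`), products (`+`),
  elementwise joins (`.+`), and a terminal wildcard:
  `/med/L1[0:10]` is ten ports; `/med/[L1,L2][0]` equals
  `(/med/L1,/med/L2)+[0]`.
* **Patterns** — two attributed interfaces plus a sparse directed
  connection set. Typing is enforced (spike ports never feed
  graded-potential ports), every destination has at most one source
  (fan-in is prohibited; multiplexing belongs inside the receiving LPU),
  and fan-out is unlimited. Directions are pattern-relative: an LPU's
  output port is a pattern `in` port.
* **Port mappers** — ordered identifier-to-index maps over contiguous
  value buffers (one per transmission kind), the data surface a module's
  step hook reads and writes.
* **Executor** — registers LPUs, checks pattern/interface compatibility,
  compiles a routing table, and runs the loop: every LPU steps, then all
  output data crosses the patterns before any LPU proceeds. A serial
  reference backend and a multiprocess (PSOCK message-passing) backend
  produce bitwise-identical buffers; a greedy Kernighan–Lin-style
  partitioner assigns LPUs to workers to reduce the edge cut.
* **Compute plane** — pluggable point-neuron and synapse models
  (leaky integrate-and-fire, Morris–Lecar, Hodgkin–Huxley, alpha and
  conductance synapses, a surrogate photoreceptor), explicit Euler at the
  emulation step, with circuits specifiable declaratively as GEXF property
  graphs and patterns as CSV/GEXF documents.

See `vignettes/modular-circuit-emulation.Rmd` for the model, parameter
tables, and numerical choices.

## Worked example

Wire two LPUs and run three bulk-synchronous steps:

```r
library(lpuSim)

m1_out <- parseSelector("/a/out/gpot[0:2]")   # 2 ports
m2_in  <- parseSelector("/b/in/gpot[0:2]")

pat <- makePattern(m1_out, m2_in)
pat <- setPortAttributes(pat, m1_out, 0, "in", "gpot")   # LPU output = pattern "in"
pat <- setPortAttributes(pat, m2_in, 1, "out", "gpot")
pat <- addConnections(pat, expandSelector(m1_out), expandSelector(m2_in))
pat
#> Pattern with 4 port(s) (2 on interface 0, 2 on interface 1) and 2 connection(s)

plan <- emulationPlan(dt = 1e-2)
plan <- addLPU(plan, lpuSpec("a", interfaceTable(outGpot = m1_out)),
               hook = constantHook(gpot = c("/a/out/gpot[0]" = 0.71,
                                            "/a/out/gpot[1]" = 0.83)))
plan <- addLPU(plan, lpuSpec("b", interfaceTable(inGpot = m2_in)))
plan <- connectLPUs(plan, "a", "b", pat)

rec <- runEmulation(plan, steps = 3, record = "b")
rec@trace$b$gpot
#>      /b/in/gpot[0] /b/in/gpot[1]
#> [1,]          0.00          0.00
#> [2,]          0.71          0.83
#> [3,]          0.71          0.83
```

The first row is zero: buffers start zeroed and data crosses one pattern
per step, so LPU `b` sees `a`'s step-0 outputs at step 1.

The package's flagship fixture composes a surrogate-photoreceptor retina
with a Morris–Lecar lamina over a 721-ommatidium hexagonal array:

```r
fx <- buildRetinaLamina(rings = 15)
fx$pattern
#> Pattern with 8652 port(s) (4326 on interface 0, 4326 on interface 1) and 4326 connection(s)
c(ommatidia = nrow(fx$hex), connections = connectionCount(fx$pattern),
  laminaNeurons = laminaNeuronCount(fx))
#>     ommatidia   connections laminaNeurons
#>           721          4326          4326
equationCount(721, 6, 30000, 15)   # cost of the full stochastic retina
#> [1] 1946700000
```

721 ommatidia × 6 photoreceptors give 4,326 feed-forward connections into
4,326 lamina neurons; the full (out-of-scope) stochastic photoreceptor
cascade would amount to about 1.95 billion equations, which is the
bookkeeping `equationCount()` reproduces. `runDemo()` drives the
composition with an intensity frame sequence and records R1 photoreceptor
and lamina L1 outputs.

A thin CLI over the same functions lives at `inst/cli/lpusim`
(`run <config.yaml>`, `demo retina-lamina`, `benchmark ports|lpus`).

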