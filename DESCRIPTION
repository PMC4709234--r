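Package: lpuSim
Title: Modular Emulation of Interconnected Neural Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: A programming model and execution engine for modular neural
    circuit emulation. Circuit modules (local processing units, LPUs) expose
    typed communication interfaces made of hierarchically named ports carrying
    either spike (boolean) or graded-potential (real) data. Inter-module
    wiring is expressed as validated connectivity patterns between pairs of
    interfaces, and emulations are executed bulk-synchronously: every module
    steps, then all output-port data is routed to destination input ports
    before any module advances. Includes a path-like port selector algebra,
    port-to-buffer mappers, a compute plane of point-neuron and synapse
    models (leaky integrate-and-fire, Morris-Lecar, Hodgkin-Huxley, alpha
    and conductance synapses), GEXF/CSV circuit readers and writers, and a
    toy retina/lamina composition of the fly early visual system.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    parallel,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
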