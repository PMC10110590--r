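Package: willisim
Title: Lumped-Parameter Simulation of Cerebral Circulation Through the
    Circle of Willis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Zero-dimensional (lumped-parameter) modelling of blood flow
    through the Circle of Willis. Arterial segments are nonlinear hydraulic
    resistances combining Hagen-Poiseuille baselines with semi-empirical
    corrections for vessel tortuosity and entrance (developing-flow)
    effects; the network is solved by nodal analysis with fixed-point
    iteration on the flow-dependent resistances. Terminal territories may
    be closed by fixed peripheral resistances or by an ideal cerebral
    autoregulation controller, from which the autoregulation pressure
    reserve and critical stenosis severities are derived. Includes a
    scenario engine for occlusion and progressive-stenosis experiments,
    deterministic fixture generation, YAML/JSON network serialization and
    a validation harness against bundled computational-fluid-dynamics
    benchmark flows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
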