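# willisim

Lumped-parameter (0D) simulation of cerebral circulation through the
Circle of Willis — for hemodynamics researchers and modellers who need
fast, reproducible answers to collateral-flow questions (occlusions,
progressive carotid stenosis, communicating-artery variants) without
running a full CFD model.

## The model in brief

The Circle of Willis is represented as a resistive circuit of 18
arterial segments between pressure nodes: four inlets (both ICAs and
both VAs at 93 mmHg), the basilar and cerebral segments, the
communicating anastomoses, and six terminal perfusion beds. Each
segment's resistance is the Hagen-Poiseuille baseline
R<sub>HP</sub> = 128 μL/(π d⁴) multiplied by a flow-dependent
correction:

* tortuous (long/curved) vessels:
  R<sub>t</sub>/R<sub>HP</sub> = 0.526 + √(0.225 + 0.022 √(d/a_k) · Re)
* short (entrance-dominated) vessels:
  R<sub>l</sub>/R<sub>HP</sub> = 1 + 0.044 (d/l) · Re

The nodal-analysis equations are solved by under-relaxed fixed-point
iteration on the resistances. Terminal beds are either fixed
peripheral resistances (the CFD-matching validation configuration) or
an ideal autoregulation controller,
R = clip((P − P<sub>drain</sub>)/q<sub>target</sub>, r<sub>min</sub>, r<sub>max</sub>),
that holds each territory at its target flow between the 50 and
150 mmHg autoregulation limits. From a regulated solution the package
computes the autoregulation pressure reserve
APR = {P* − 50, 150 − P*} per territory and locates critical stenosis
severities where a territory exits regulation. See the vignette
(`vignettes/circle-of-willis-model.Rmd`) for the full account.

## Worked example

```r
library(willisim)

net <- reference_network()
sol <- solve_nonlinear(net)
round(sol$segment_flows[c("ICAL", "M1L", "A2L", "P2L", "PCoAL", "ACoA")], 2)
#>   ICAL    M1L    A2L    P2L  PCoAL   ACoA
#> 235.30 160.54  78.82 124.43  -4.06   0.00
```

Flows are in ml/min, signed by each segment's stated convention: left
and right are equal and the ACoA carries nothing because the anatomy is
symmetric, while the small negative PCoA flow means the vertebrobasilar
system contributes a trickle to the anterior circulation at rest. The
linear (pure Hagen-Poiseuille) model overestimates the same M1 flow:

```r
solve_linear(net)$segment_flows[["M1L"]]
#> [1] 174.3416
```

Under autoregulation, each middle territory is held at its
162 ml/min target, and a hypoplastic anterior communicating artery
makes a left-ICA stenosis critical much earlier than a generous one:

```r
reg <- regulate(net)
reg$solution$bed_flows[["middle_L"]]
#> [1] 162

find_autoregulation_exit(set_diameter(net, "ACoA", 0.4),
                         stenosed_segment = "ICAL", territory = "middle_L")
#> [1] 0.3527344          # exit at ~35% diameter stenosis
find_autoregulation_exit(set_diameter(net, "ACoA", 1.6),
                         stenosed_segment = "ICAL", territory = "middle_L")
#> [1] 0.5847656          # a thick ACoA defers it to ~58%
```

A negative APR component marks the exit: the territory's
cerebral-artery pressure has crossed an autoregulation limit and flow
is no longer preserved. `validate_model()` reruns the bundled CFD
benchmark comparison:

```r
validate_model()[, c("case", "model_value", "reference_value", "relative_error", "pass")]
#>                    case model_value reference_value relative_error pass
#>     nonlinear_reference    160.5443          161.99     0.00892472 TRUE
#>  nonlinear_ICAL_blocked    101.0746           92.52     0.09246180 TRUE
#>        linear_reference    174.3416          161.99     0.07624934 TRUE
```

Scenario files (YAML/JSON, schema in `inst/schema/`) and a thin CLI
(`inst/cli/willisim.R`, subcommands `export-config`, `solve`, `sweep`,
`validate`, `fixtures`) wrap the same functions for shell use, e.g.

```sh
Rscript inst/cli/willisim.R sweep --segments ICAL,ICAR --simultaneous \
        --regulation on --to 0.9 --out sweep.csv
```

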