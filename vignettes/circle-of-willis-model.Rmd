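---
title: "A lumped-parameter model of cerebral circulation with hydrodynamic nonlinearities and ideal autoregulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of cerebral circulation with hydrodynamic nonlinearities and ideal autoregulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(willisim)
```

## The model

The Circle of Willis (CoW) is the anastomotic ring at the base of the
brain that joins the two internal carotid arteries (ICA) and the
vertebrobasilar system (VA + BA) and redistributes their supply to six
perfusion territories: the paired anterior, middle and posterior
cerebral beds. `willisim` represents this circulation as a
zero-dimensional resistive circuit: 18 arterial segments connect a
small set of pressure nodes, four inlets impose systemic arterial
pressure (93 mmHg by default), and each territory drains through a
lumped peripheral resistance to venous pressure. Flow is steady and
laminar (segment Reynolds numbers sit in the 100–500 range), blood is
treated as a Newtonian fluid, and vessel walls are rigid.

Each segment's baseline resistance is the Hagen-Poiseuille value

$$R_{HP} = \frac{128\,\mu L}{\pi d^4},$$

with $\mu = 0.0035$ Pa·s and $\rho = 1050$ kg/m³ by default. The
constant viscosity is the high-shear plateau of blood rheology: at
arterial shear rates the shear-thinning Carreau–Yasuda law (available
as `carreau_yasuda_viscosity()`) is already within a fraction of a
percent of its infinite-shear asymptote, so a Newtonian closure changes
computed flows negligibly while removing a nonlinearity that the
lumped model cannot resolve spatially anyway.

Two hydrodynamic corrections make the segment resistances
flow-dependent:

* **Tortuosity.** Curved vessels develop secondary (transverse-vortex)
  flows that dissipate extra energy. For a segment of diameter $d$ and
  bend curvature radius $a_k$,
  $$\frac{R_t}{R_{HP}} = 0.526 + \sqrt{0.225 + 0.022\sqrt{d/a_k}\,Re},$$
  which tends to the Hagen-Poiseuille value as $Re \to 0$ or
  $a_k \to \infty$. It is applied to the long or markedly curved
  vessels (ICA, VA, BA, M1, A2, P2).
* **Entrance effect.** In short vessels the parabolic profile never
  fully develops and the wall shear is higher than Poiseuille's:
  $$\frac{R_l}{R_{HP}} = 1 + 0.044\,(d/l)\,Re,$$
  applied to the short proximal and communicating segments (A1, P1,
  PCoA, ACoA).

Both corrections are $\ge 1$, monotone in $Re$, and symmetric in the
flow direction ($Re$ uses $|Q|$): resistance is dissipative regardless
of which way blood runs through a collateral.

### The Reynolds-number convention of the corrections

The package reports the conventional diameter-based Reynolds number,
$Re = 4\rho|Q|/(\pi\mu d)$, through `reynolds_number()`. The
semi-empirical corrections above, however, are calibrated against the
radius-based convention $\rho \bar v r/\mu$ — half the diameter-based
value — which is common in the hydraulics literature these correction
laws descend from. This is a genuine ambiguity of the source
formulas, and the package resolves it empirically: only the
radius-based reading reproduces the bundled CFD benchmark (`validate_model()`
errors of 0.9% and 9.2%, against accepted bounds of 2.6% and 9.9%;
the diameter-based reading misses both bounds) and the critical-stenosis
behaviour discussed below. `segment_resistance()` and
`solver_settings()` therefore default to `re_convention = "radius"`
and keep `"diameter"` available for sensitivity studies.

## Solving the circuit

Pressures at the free nodes are the unknowns of nodal analysis: flow
balance at every node, with terminal beds entering the conductance
matrix as ordinary conductances toward their fixed drain pressures.
Because the corrections make resistances depend on the flows, the
nonlinear solution is the fixed point of

1. nodal solve at frozen resistances,
2. resistance update from the formulas at the new Reynolds numbers,

iterated with under-relaxation 0.5 on the resistance updates. The
system is tiny (about 14 unknown pressures), so the default tolerance
is tight (relative flow change $\le 10^{-8}$) and the default budget
generous (200 iterations); the reference network converges in ~30
iterations and the iteration is initialized at the Hagen-Poiseuille
(linear) solution, which sits comfortably inside the attraction basin.
An absolute flow floor of $10^{-15}$ m³/s in the convergence test keeps
rounding noise from stalling zero-flow configurations. Occluded
segments are removed from assembly entirely rather than being given a
huge resistance, which keeps the matrix well conditioned; a node left
without any path to a pressure boundary raises a structured error
naming it. Everything is assembled in SI units; mmHg, ml/min and
mmHg·min/ml appear only at the interface.

`solve_linear()` keeps the Hagen-Poiseuille resistances and solves the
system exactly in one step. Because the nonlinear corrections only ever
increase resistance, the linear model systematically overestimates
cerebral flows — on the reference anatomy its left-M1 flow is ~8% above
the CFD benchmark where the nonlinear model is within 1% — which is
the quantitative argument for not using linear network models of the
intracranial circulation.

## Ideal autoregulation and the pressure reserve

Each territory's arteriolar bed actively holds its flow at a target
$q_{target}$ across a band of perfusion pressures by adjusting its
resistance. The ideal characteristic implemented in `regulate()` is

$$R_{bed} = \mathrm{clip}\!\left(\frac{P_{attach}-P_{drain}}{q_{target}},\;
r_{min},\; r_{max}\right),$$

per territory and per side: anterior 111 ml/min within
[0.46, 1.31] mmHg·min/ml, middle 162 within [0.32, 0.90], posterior
120 within [0.44, 1.20], with autoregulation limits of 50 and
150 mmHg for every territory. The resistance bounds are, up to
rounding, the characteristic evaluated at the limits
($50/162 \approx 0.32$), which is also why autoregulated beds drain to
0 mmHg by default: the bounds reproduce the 50/150 mmHg limits only
against a venous reference near zero. The fixed-resistance beds of the
validation configuration (which mimic the CFD outlet boundary) instead
drain to 10 mmHg; both are configurable per bed.

The controller update is interleaved with the segment-resistance update
in one under-relaxed loop with a shared convergence test — an outer
loop nested around an inner fixed point would converge to the same
answer but stalls more easily and costs more solves.

The **autoregulation pressure reserve** (APR) of a territory is the
pair of signed margins between the pressure at the level of its major
cerebral artery and the two limits:

$$APR = \{\,P^{*} - P_{lower},\; P_{upper} - P^{*}\,\}.$$

Both components positive means flow is preserved; a negative component
marks the exit from autoregulation at that end. The probe pressure
$P^{*}$ is taken on the cerebral artery itself — M1, A2 or P2 for the
middle, anterior and posterior territories — as the lumped segment's
mean pressure, i.e. the average of its end-node pressures. Three probe
readings were considered when the design was open: the bed attach node
(the artery's distal end), the artery's origin on the circle, and the
segment mean. The attach node systematically understates $P^{*}$ by the
artery's full pressure drop (~4 mmHg on M1 at target flow) and the
origin overstates it by the same amount; the segment mean is the
natural lumped-element reading of "pressure in the artery", and it is
the choice under which the model's critical-stenosis predictions match
the CFD-validated behaviour of the anatomy (see below). The regulated
solution also reports the attach-node pressure, and
`find_autoregulation_exit(criterion = "saturation")` provides the
alternative clipping-based exit test, which nearly coincides with the
pressure test but differs by the rounding of $r_{min}$ and the probe
offset.

## Critical stenosis experiments

A stenosis of severity $s$ scales a segment's diameter by $1-s$
uniformly along its length — the lumped model has no sub-segment
localization, so severity is exactly the fractional diameter change;
$s = 1$ removes the vessel. `find_autoregulation_exit()` sweeps the
severity of a named stenosis (coarse scan at step 0.05, then bisection
to a default resolution of $10^{-3}$) and reports the smallest severity
at which a watched territory's APR turns negative, returning `NA` as
the explicit no-exit sentinel when regulation survives complete
occlusion.

The canonical experiment narrows the left ICA and watches the left
middle territory. With a hypoplastic anterior communicating artery
(ACoA at 0.4 mm) the collateral route from the right carotid is
nearly useless and autoregulation fails at ~35% stenosis; with a
generous ACoA (1.6 mm) the exit is deferred to ~58%. These are the
package's computed values under the default conventions and match the
CFD-anchored benchmark behaviour of this anatomy (34.1% and 58.5%)
within the tolerance such semi-empirical models support. Under
*bilateral* symmetric stenosis the ACoA carries no flow and its calibre
ceases to matter — the exit severity is the same for both diameters, a
symmetry property the test suite asserts — while the posterior
communicating arteries become the decisive collaterals.

## Tunable parameters

| Parameter | Default | Units | Where |
|---|---|---|---|
| inlet pressure | 93 | mmHg | `reference_network()`, `set_inlet_pressure()` |
| blood viscosity $\mu$ | 0.0035 | Pa·s | `fluid_properties()` |
| blood density $\rho$ | 1050 | kg/m³ | `fluid_properties()` (enters only via $Re$) |
| terminal resistances (validation beds) | 3.52/7.04/4.22 ×10⁹ | Pa·s/m³ | `reference_network()` |
| validation drain pressure | 10 | mmHg | bed `drain` column |
| autoregulation targets | 162/111/120 per side | ml/min | `default_autoregulation_params()` |
| autoregulation limits | 50 / 150 | mmHg | idem |
| regulated drain pressure | 0 | mmHg | idem |
| flow tolerance | 1e-8 (relative) | — | `solver_settings()` |
| under-relaxation | 0.5 | — | `solver_settings()` |
| sweep resolution | 1e-3 | severity | `find_autoregulation_exit()` |

## Synthetic test anatomies

`generate_fixture_networks()` produces deterministic-by-seed variants
of the reference anatomy for property testing: independent uniform
diameter factors in $[1-p, 1+p]$ per segment and, optionally, removal
of one communicating vessel (ACoA or a PCoA), emulating the common
incomplete-circle variants. These fixtures probe solver robustness
(convergence, conservation, topology validity) across plausible
anatomical spread. They do **not** emulate real anatomical
covariance — real vessel calibres co-vary within a subject, lengths and
curvatures vary too, and patient geometries include fetal-type and
string-like variants beyond diameter scaling — so passing the fixture
harness demonstrates numerical robustness, not anatomical realism.

## Problem sizes and runtime

All computations in the examples, tests and acceptance harness run on
the bundled 18-segment anatomy: a nonlinear solve is ~30 iterations of
a 14×14 dense system (milliseconds), a regulated solve ~60
interleaved iterations, and a full critical-stenosis localization ~30
regulated solves (well under a second). The test suite's property
harness uses 12 perturbed fixtures at 20% diameter spread; the whole
suite completes in a few seconds.

## Known limitations

* Steady flow only: no pulsatility, no wall compliance or inertance,
  no Windkessel outlets. Stationary network models of this circulation
  reproduce flow *distribution* well but can err on the order of 10% in
  absolute flow under strongly unsteady conditions.
* No junction losses: energy dissipation in the recirculation zones and
  impinging jets that develop at the circle's junctions under heavy
  collateral recruitment is not modelled, which is the dominant error
  source in near-complete-occlusion configurations (the ~9% validation
  case).
* The ideal autoregulation characteristic is static — no CO₂
  reactivity, metabolic feedback or dynamic (time-resolved) response —
  and its parameters are population-level, not patient-specific.
* Stenoses are whole-segment diameter reductions; a focal plaque of
  equal diameter loss produces less resistance than the model's
  uniform narrowing at the same nominal severity.
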