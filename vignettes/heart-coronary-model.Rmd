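---
title: "A closed-loop heart-coronary model with demand-driven flow regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop heart-coronary model with demand-driven flow regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`coroflow` simulates the coupling between regional cardiac mechanics and
regional coronary perfusion in a closed-loop lumped-parameter circulation,
with a metabolic feedback that regulates coronary flow to regional oxygen
demand. Its purpose is mechanistic: to ask how asynchronous ventricular
activation (left bundle branch block, LBBB) redistributes myocardial work,
oxygen demand, resting and maximal (hyperemic) perfusion, and the
myocardial flow reserve, and how chronic demand-driven redistribution of
wall mass (asymmetric hypertrophy) reshapes these distributions.

This vignette is the package's account of the model: the equations, the
parameters that matter, the numerical choices, and the limits of what the
simulations can show.

## Ventricular mechanics

The two ventricles are built from three thick walls — LV lateral free
wall, septum, RV free wall — joined at a circular junction. Each wall is a
spherical cap; mechanical equilibrium of the in-plane tensile forces at
the junction (the axial and radial components of the three wall tensions
must cancel) determines the septal cap volume and junction radius at every
instant, and with them each wall's midwall area, curvature, and the two
cavity pressures (transmural pressure of a cap is `2 Tm Cm`).

The LV free wall is divided into 12 and the septum into 5 wall segments
following the standard 17-segment bullseye convention, each with its own
mechanical activation time and its own coronary territory (LAD, LCx, RCA,
with the posterior descending branch serving the inferoseptal/inferior
column). Segments of one wall share the wall's curvature and carry a
common membrane tension; each segment's midwall area is free to
redistribute within the wall under that equal-tension constraint. This is
what lets a late-activated segment be pre-stretched by its early-activated
neighbours — the mechanism underlying work redistribution in LBBB — and it
is why the segment areas are carried as unknowns of the model rather than
as a fixed partition (the reference areas are partitioned proportional to
segment wall volume).

Segment fiber mechanics use the one-fiber closure: natural fiber strain
`eps = 0.5 log(Am/Am_ref)`, tension `Tm = sigma Vw/(2 Am)`. The fiber
stress is a three-element Hill-type model:

* a prescribed smooth twitch `C(t)` (cosine rise over `TR = 90` ms to a
  peak, cosine decay over `TD = 260` ms, plus a 0.6% resting tone), fast
  in the rise and slow in the decay as in physiological activation;
* length-dependent activation, linear in contractile-element length above
  `Lsc0 = 1.38` µm (the Frank–Starling mechanism: pre-stretched segments
  contract more forcefully);
* a series-elastic element of isometric stretch `Lse_iso` whose state
  `Lsc` follows `dLsc/dt = ((Ls − Lsc)/Lse_iso − 1) v_max`, giving
  force–velocity behaviour;
* passive stress: exponential strain stiffening above the zero-stress
  sarcomere length (`Ls0 = 1.8` µm, i.e. the strain at zero transmural
  pressure), with a slope-matched exponential compression branch below it
  so that a severely shortened or compressed wall pushes back rather than
  crumpling to zero volume.

The twitch shape and its constants are this package's own formulation of
the sarcomere (the published framework this model family descends from
does not restate them); they are calibrated so the reference simulation
gives physiological LV pressures (~110 mmHg peak at 92 mmHg mean arterial
pressure) and a peak stress-proportional intramyocardial pressure
component of about 20% of peak LV pressure (below).

Atria are single-segment elastance chambers; valves are Bernoulli orifices
with blood inertia and leaflet opening dynamics (the opening state relaxes
toward a pressure/flow-determined target with a 5 ms time constant, which
removes the numerically hostile algebraic flow-area feedback of
instantaneous valve models); systemic and pulmonary beds are windkessels.
A pericardial sac with an exponential pressure-volume relation surrounds
the heart and the epicardial coronary vessels.

## Coronary circulation

The left main and right coronary arteries branch from the aorta; LAD, LCx
and RCA proximal vessels are short elastic two-node segments, from which
one sub-branch per perfused segment (7 LAD, 5 LCx, 6 RCA including the
posterior descending column and the RV branch) feeds the intramural
network. Sub-branch resistances grow with vascular path length toward the
apex (and further for the PDA), which is what produces the base-to-apex
fall of flow reserve. Venous blood collects per territory and drains
through the coronary sinus into the right atrium.

Within each perfused segment the intramural bed is resolved into three
transmural layers (subendo, mid, subepi at radial positions 5/6, 3/6, 1/6)
of five serial compartment classes: small artery, arteriole, capillary,
venule, small vein.

**Intramyocardial pressure.** Each layer is squeezed by

`IMP = (r P1 + (1−r) P2) + gamma * sigma_f`

the sum of linearly transmitted cavity pressure (cavity-induced
extracellular pressure: LV cavity to pericardium for the LV free wall, LV
to RV cavity for the septum, RV cavity to pericardium for the RV wall) and
a varying-elastance component proportional to the segment's fiber stress
with `gamma = 0.06` for all walls, chosen so its peak is ~20% of peak LV
pressure. Intravascular pressure is transmural pressure plus IMP.

**Tube law.** Compartment transmural pressure follows the nonlinear
pressure–area relation

`p_trans = p0 [ ((A + Aw/2)/(fDil A0 + Aw/2))^(k/3) − 1 − max(0, (A/(fDil A0))^0.7 (Aw/(fDil A0))^(−0.4) − 1)^2 ]`

in which the vasodilation factor `fDil` shifts the relation to the right
(a dilated vessel holds a larger lumen at the same pressure). The second
bracket term is implemented exactly as formulated; note that it does not
vanish at `A = A0` unless `Aw = A0`, and a monotonicity check over the
operating range runs at model construction. Because the law's suction
branch is bounded near `−p0`, strong systolic compression would otherwise
drive volumes to zero; a steep residual-lumen barrier below 8% of the
reference volume represents the finite lumen of a collapsed vessel.

**Resistance.** A compartment's hydraulic resistance follows Poiseuille's
law referenced to its volume: conductance `(q0_ref/dp0) (V/V0)^2`.
Vasodilation therefore lowers resistance through the tube law — a dilated
compartment holds more volume at the same pressure — and systolic
compression raises it, which produces the diastole-dominant flow of the
left coronaries (the intramyocardial pump). Writing the flow law with a
separate `1/fDil^2` factor against a fixed reference conductance would
make dilation raise resistance and the metabolic feedback unstable; the
package therefore keeps the reference conductance attached to the dilated
reference state, which is equivalent to the pure volume law used here.

## Oxygen demand and flow regulation

Regional oxygen demand is estimated from the fiber stress–strain area
(SSA), the regional analogue of the ventricular pressure–volume area:

* external work `EW` is the signed (counterclockwise-positive) area of the
  beat's stress–strain loop — early-activated segments in LBBB show
  clockwise portions, i.e. negative work;
* potential energy `PE` is the area bounded by the end-systolic
  stress–strain relation, the diastolic limb of the loop, the
  end-diastolic stress–strain relation and the strain axis, with the
  zero-stress strain as anchor. The bounding relations are straight lines
  from the anchor to the end-systolic and end-diastolic samples. End
  systole is the instant of minimal LV cavity volume, shared by all
  segments; end diastole is the segment's own activation onset. (A
  per-segment maximal-elastance definition of end systole was evaluated
  and rejected: under dyssynchrony it dates end systole during the early
  unloaded shortening of septal segments.)

Demand follows the linear relation `VO2 = c1 SSA/t_cycle + c2` with
`c1 = 4.94 mmol/kJ`, `c2 = 24.2 mmol m^-3 s^-1` (paced-dog calibration);
evaluated on the SSA density (kJ/m^3) it yields demand per tissue volume,
and times the segment wall volume the absolute demand.

Regulation closes the loop once per beat:

1. target flows follow demand multiplicatively, `q0 <- q0 * VO2/VO2_old`,
   anchored once in the converged reference so that total resting coronary
   flow is 4% of cardiac output, distributed across segments proportional
   to absolute demand and across layers as 1.11 : 1.055 : 1 (endo : mid :
   epi);
2. every arteriolar compartment updates its vasodilation factor
   `fDil <- clamp(fDil exp(alpha (1 − qbar/q0)), 0.5, fDilMax)` with
   damping `alpha = 0.2`;
3. small arteries follow the maximal arteriolar factor of their segment's
   three layers, capped at 1.4.

The arteriolar caps are 3.00 (subendo) falling linearly to 1.70 (subepi)
for the left coronaries and 2.40/2.30 for the right — identical midwall
caps of 2.35 — so that maximal vasodilation yields an average LV flow
reserve above 4 while the endo-to-epi flow ratio stays near 1.11.

Hyperemia sets every regulated compartment to its cap (scaled by the
segment's wall-mass factor), freezes circulating volume, peripheral
resistance and the demand feedback, and runs to a periodic state. Flow
reserve is the ratio of hyperemic to resting mean segmental flow.

## Homeostatic control and steady state

Resting simulations hold heart rate 70/min, cardiac output 5.1 L/min and
mean arterial pressure 92 mmHg by adjusting systemic peripheral resistance
and total blood volume. The exported `homeostaticControl()` is the plain
multiplicative rule with the target pair as fixed point. Internally the
driver uses the same family of multiplicative corrections but routes them
through the inverse of the measured steady-state log-gain matrix of this
circulation (volume has a log-gain near 6 on both cardiac output and
pressure, with strong cross-coupling to the resistance loop), acting every
fourth beat on short averages: independent per-beat proportional loops on
this plant lock into a limit cycle rather than converging. The fixed point
is unchanged.

A run is converged when, simultaneously: beat-to-beat changes of all
stroke volumes and regulated flows are below 0.1% for three consecutive
beats; cardiac output and pressure are within 1% of target; and every
unsaturated regulated compartment is within 0.5% of its target flow.

## Chronic remodeling

Chronic LBBB is modeled as demand-driven redistribution of LV wall mass:
after each converged resting simulation, every LV and septal segment's
mass factor moves toward the LV-wide mean demand per tissue weight,
`m <- clamp(m (d/dbar)^0.5, 0.75, 1.25)`, with wall volume, intramural
vascular volume and the hyperemic dilation caps scaling linearly with the
mass factor (so hyperemic, but not resting, flow follows mass). Reference
midwall areas are held, so mass change manifests as wall thickness change.
The outer loop alternates adaptation with re-convergence until mass
factors change by less than 0.5% or sit at the ±25% cap; the RV does not
remodel.

## Numerics

The full system — cavity, vascular and coronary compartment volumes, valve
flows and opening states, contractile-element lengths, plus the algebraic
TriSeg geometry (septal cap volume, junction radius, and the 18 segment
areas under the equal-tension constraints) — is integrated as a DAE with
BDF2 at a fixed 1 ms step (implicit Euler on the first step), solved by a
modified Newton iteration on a finite-difference Jacobian with row/column
equilibration, per-component trust regions, adaptive refactorization, and
bisection fallback. Newton tolerance is 1e-8 on the scaled update norm.

Two regularizations deserve mention. Near the end of relaxation all three
wall tensions can pass through zero together, at which point the junction
force balance degenerates (any geometry satisfies 0 = 0) and the plain
Newton iteration jumps between solution branches; a weak temporal damping
term on the junction and tension-equality rows — scaled to fade
quadratically with the tension magnitude, so equilibrium is exact whenever
forces meaningfully constrain the geometry — pins the geometry to its
previous-step value exactly in that window. Second, the small resting
activation tone (0.6%) keeps the ventricular walls from losing tension
entirely. Blood volume is conserved to machine precision by construction;
the suite checks < 0.01% per beat.

Problem sizes: the full model integrates ~350 states; a converged
three-condition pipeline (reference, acute, chronic, each with hyperemia)
runs in roughly 8–12 minutes. The test suite uses a reduced 3-segment
fixture (two LV segments and one septal segment, each with its own
sub-branch and three layers) for the integration-level properties.

## Calibration

Parameters the source framework defines elsewhere (per-class tube-law
constants, reference pressure drops, layer tone, sub-branch lengths) are
exposed in `defaultConfig()` and set by the shipped calibration procedure
(`inst/scripts/calibrate.R`) to the model's stated operating points:
total resting coronary flow 4% of cardiac output; mean LV flow reserve
above 4 with basal-to-apical values near 4.6/4.1 (LAD+LCx) and 4.4/3.7
(PDA); resting and hyperemic endo-to-epi ratio near 1.11; peak
varying-elastance component near 20% of peak LV pressure. Two structural
lessons from that calibration: the flow-reserve ceiling is set by how far
resting arteriolar tone sits below its dilation cap (resting flow being
pinned at 4% of cardiac output by regulation), and the hyperemic
endo-to-epi ratio is controlled by the ratio of subendo to subepi baseline
arteriolar tone.

## What the simulations do and do not show

The model reproduces, and the test-suite asserts, the qualitative
physiology: diastole-dominant LAD/LCx versus more uniform RCA flow
waveforms; transmural IMP ordering; negative-work loops in the early
septum and supranormal work in the late lateral wall under LBBB with
near-invariant hyperemic flow; vasodilation of the LCx territory and
constriction of most LAD/RCA sub-branches; homogenization of demand per
tissue weight with asymmetric hypertrophy under chronic LBBB.

Quantitatively, the redistribution of demand under acute LBBB in this
implementation is stronger than in the framework it re-implements (the
early septum is unloaded further), which propagates into the extreme
per-segment demand ratios and the LCx-territory average. This traces to
the simplified sarcomere (prescribed twitch, linear length dependence) and
to the degree of septal rebound stretch, to which the stress-strain area
of early-activated segments is very sensitive. The affected quantities
are reported as computed.

Real-data features deliberately outside the model: transmural activation
propagation (the endo-to-epi ratio is a calibrated constant, not a
prediction); oxygen content and extraction; myogenic/neural control
pathways (collapsed into the single vasodilator signal); ventricular
dilatation or stiffness change with remodeling; and any imaging physics —
the bullseye tables are model quantities, not synthetic perfusion images.
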