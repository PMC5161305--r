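---
title: "A virtual hepatic lobule for acetaminophen toxicity experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual hepatic lobule for acetaminophen toxicity experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`vlobule` is a stochastic, discrete-time, agent-based analog of a hepatic
lobule connected to a simple extrahepatic compartment ("the body"). It is
built for *virtual experiments*: seeded, measurable simulations that can
discriminate competing mechanistic hypotheses of acetaminophen
(APAP)-induced centrilobular necrosis.

Space is a directed graph of 68 **sinusoid segments** in three zones (45
periportal, 20 midzonal, 3 pericentral), wired by 99 edges: 55 from zone 1
to zone 2, 10 within zone 1, 24 from zone 2 to zone 3, 10 within zone 2,
none within zone 3. Zone-3 segments drain to the central vein (CV), which
returns flow to the body. Segment lengths and circumferences are drawn
uniformly per zone at each Monte Carlo build, and edges are rewired, so no
two lobule variants are identical; within-zone edges always follow a random
topological order, keeping the graph acyclic.

The **hepatocyte census is fixed** at 9,310 / 3,948 / 742 cells in zones
1-3 (14,000 per lobule) for every variant; only dimensions and wiring vary.
This makes multi-variant totals exact (12 variants hold 168,000 cells, 332
hold 4,648,000) and keeps census-dependent calibrations stable. Cells are
apportioned to segments proportionally to length with round-robin
remainders, and spread round-robin over a segment's axial grid columns.

Every hepatocyte has a path-length coordinate
`dPP = x + offset(zone)`, where `x` is its distance from the segment inlet
and the zone offset is the sum of the *mean* segment lengths of upstream
zones. With the default zone means of 25/15/10 grid spaces the mean total
path length is `d_max = 50`. Zonated features are **gradients** over this
coordinate: constant, linear, or reverse-sigmoid (a logistic decrease from
the periportal value to the CV value).

## The intra-hepatocyte cascade

Each simulated second, every hepatocyte executes five sub-steps in a
pseudo-randomly shuffled order. All events are per-object Bernoulli trials,
implemented as binomial draws on integer counts (distributionally
identical, and verified against brute-force per-object simulation by
chi-squared tests in the suite):

1. **Metabolism.** Each cell-resident APAP object is metabolized with
   probability `p_metabolize(dPP)` (linear 0.35 to 0.95, periportal to CV).
   A metabolite is the reactive species NAPQI with probability
   `p_napqi(dPP)` (linear 0.33 to 0.90); otherwise it is an inactive
   G&S metabolite, exported immediately to the body. Cells that have
   experienced a death trigger stop metabolizing. Unmetabolized APAP may
   leave the cell again (`p_cell_exit`).
2. **NAPQI fate.** While a cell's cumulative glutathione (GSH) depletion
   events are below its `gsh_threshold(dPP)`, each NAPQI is destroyed with
   probability 0.5, counting one depletion event. At or above the
   threshold, each NAPQI reacts (probability 0.5) into a damage product:
   mitochondrial (mitoD) or non-mitochondrial (nonMD) with equal chance.
3. **Amplification.** Each new mitoD undergoes exactly one amplification,
   adding `n ~ DiscreteUniform{1..6}` further mitoD, so one reacted NAPQI
   yields at most 7. "Uniform (1, 6)" is read as discrete, consistent
   with "at most 6 additional".
4. **Mitigation.** Each mitoD (amplified or not) is destroyed with
   probability `p_mitod_mitigation(dPP)`; each nonMD with constant
   probability 0.67.
5. **Death trigger.** When total mitoD reaches the death-trigger
   threshold (6, i.e. more than 5), death is triggered irreversibly. The
   observable death occurs after a per-cell delay drawn from
   uniform [1.2, 12] hours (a normal(7.2 h, 4.1 h) alternative is
   configurable). At death the cell releases unmetabolized APAP to its
   sinusoid column, its damage pools are cleared, and it becomes inert.

Non-integer thresholds (e.g. 3.5) are compared with `>=` against the
integer depletion counter; nonMD never contributes to the trigger.

### Mechanism presets

Four hypotheses about which features are zonated:

| preset | GSH threshold | mitoD mitigation |
|--------|----------------------------|-----------------------------------|
| NZ | constant 3.5 | constant 0.67 |
| GNZ | linear 5 at PP, CV value calibrated | constant 0.67 |
| MNZ | constant 3.5 | reverse sigmoid 0.9 to 0, steepness calibrated |
| MGNZ | as GNZ | as MNZ |

All four share the metabolism and NAPQI gradients. The zonated variants
are calibrated by monotone root finding so their mean over the canonical
census equals the constant value (3.5 and 0.67 within 1e-6), making the
presets comparable at the whole-lobule level. The sigmoid inflection sits
at the zone-2 mean `dPP` with steepness as the free parameter; the
calibrated steepness is necessarily shallow, because a steeper transition
at that inflection cannot reach a census mean of 0.67.

Variants for strain-diversity sweeps override one to seven of ten knobs
(the five zonation-capable gradients plus reaction probability, damage
split, nonMD mitigation, trigger threshold, death delay) via
`make_variant()`.

## Transport and pharmacokinetics

Dosing places APAP objects in a depot (intragastric/intraperitoneal) or
directly in the body (intravenous). Absorption is first order
(`k_abs = 0.001` per second; over 97% absorbed within an hour). Each
second a fraction `hepatic_fraction = 6e-4` of body APAP is metered to the
periportal entrance segments, apportioned by circumference; this maps to
hepatic blood flow relative to the whole-body distribution volume and
yields a plasma-like half-life of roughly half an hour at sub-toxic doses.

Inside the lobule, objects percolate column by column: per free object per
second, hepatocyte uptake (`p_uptake = 0.0175`), else endothelial binding
(`p_bind = 0.05`, released with `p_release = 0.5`), else a forward-biased
move (`p_fwd = 0.9`); at a segment's end the object routes uniformly over
outlet edges, and from zone 3 to the CV, returning to the body. An
**extracellular marker** behaves identically except that it never binds,
never enters cells, and is never eliminated — an internal flow standard.
Integer mass balance of APAP-derived objects and of the marker is audited
at every polling step and is exact by construction.

`p_uptake` is the one transport constant calibrated against a validation
attribute: the single-pass perfusion protocol (constant input at the
entrances, toxicity disabled) must stabilize at a hepatic extraction ratio
of 0.6, and 0.0175 places the default configuration at ER 0.60 with
seed-to-seed spread of about 0.01. The remaining transport defaults were
fixed first and are ordinary, unremarkable choices documented above.

The **dose scale** maps 1 mg/kg to 1,200 objects, so the 300 mg/kg toxic
reference dose is 360,000 objects (about 26 per hepatocyte). It was chosen
by calibrating the dose-response attribute: halving the reference dose
must reduce 24-hour hepatocyte death by about half (the default lands near
a 56% reduction, with roughly half of all hepatocytes dead at the full
reference dose). Much larger scales push every cell past its thresholds
(uniform death, no zonation signal); much smaller ones leave periportal
cells unable to trigger at all.

## Experiments, observation, and derived measures

All protocols are seeded: a master seed spawns one child seed per Monte
Carlo trial, each trial builds its own lobule variant, and results are
bit-reproducible. Death events are recorded mechanism-side; the *observer*
(`poll_death_observer()`, default 60 s polling) is a pure function of the
logs, so changing the polling frequency cannot perturb a trajectory — the
suite asserts bit-identity.

* `run_single_pass_perfusion()` — extraction ratio, with stabilization
  detected as a windowed outflow mean (300 s) varying less than 2%.
* `run_bolus_experiment()` — 24-h time course; regional means of NAPQI,
  G&S, depletion events, mitoD and mitigation events in three
  5-grid-space bands (periportal, midzonal centered at `d_max/2`,
  pericentral); death log with trigger/death times and positions.
* `run_dose_response()`, `run_variant_sweep()` — paired trial seeds
  across doses/variants; the sweep flags variants within 20% of the
  reference mean as experimentally indistinguishable.

The **trigger-distance series** is the per-second mean distance from the
CV of that second's trigger events, pooled over trials and smoothed with a
100-second centered moving average. `target_phenomenon_check()` declares
pericentral settlement achieved when, after a 1,200 s settling period, the
smoothed series stays within the zone-3 band (distance no more than the
mean zone-3 segment length) for at least 95% of the event-bearing time
points. The zone-3 band and the 95% occupancy rule are declared
conventions of this package; the underlying phenomenon is qualitative.

The death-curve checker compares cumulative deaths (fraction of final)
against an editable envelope shipped as
`extdata/death_curve_band_synthetic.csv` — a synthetic stand-in encoding
two anchors: no detectable necrosis in the first hour, and no appreciable
further necrosis after 12 hours (tolerance 10% of final deaths).

## What the default study conditions show — and what they do not

At the default dose the four presets separate as the mechanism logic
predicts in three of four directions: NZ, GNZ and MNZ all fail pericentral
settlement, and the NZ series shows its characteristic signature — an
early drift toward the CV with a reversal toward the periportal side near
ten minutes, driven by the much larger periportal cell population. MGNZ
produces the strongest and longest pericentral settlement of the four, but
does not hold the 95% occupancy criterion to the end of the horizon: zone
3 contains only 742 of 14,000 cells, so once most have triggered, the
trigger front necessarily moves outward and the tail of event-bearing
seconds sits outside the band. Under this implementation's exposure
landscape that saturation is unavoidable at any dose strong enough to make
periportal cells vulnerable, so the binary verdict for MGNZ is sensitive
to the occupancy convention; the *ordering* of the mechanisms is not.

Two other known properties deserve emphasis:

* **NAPQI dose fraction.** With no extrahepatic elimination, a recirculated
  bolus is eventually metabolized almost completely, so cumulative
  NAPQI/dose converges to the exposure-weighted mean of the NAPQI
  probability gradient — about 0.5 under the default configuration, and
  bounded below by roughly 0.45 for any exposure weighting that is not
  concentrated in the first few periportal grid spaces. Lower in-vivo-like
  fractions would require an extrahepatic sink, which this model
  deliberately omits.
* **Late necrosis tail.** At the reference dose about 15% of deaths fall
  after 12 h, because marginal zone-1 cells keep triggering while the
  half-cleared dose recirculates; the plateau check reports this.

## Numerical and design choices

* Per-object Bernoulli semantics are realized as binomial draws on counts;
  counts below 48 use looped uniform draws inside the compiled kernel.
* The five sub-steps are shuffled **once per step for the whole
  population** rather than per hepatocyte. Cells do not interact within a
  step, so each cell's marginal trajectory distribution is unchanged, and
  the shared order enables a single-pass compiled kernel (Rcpp); the
  whole-census 24-h experiment runs in seconds instead of hours.
* Single-cell reference implementations of every sub-step are exported and
  tested against the same oracles as the kernel.
* Positions past `d_max` (deep in an unusually long zone-3 segment) are
  clamped to `d_max` for gradient evaluation and distance, keeping values
  within their endpoint bounds.
* Amplification happens on the first pass through the amplification
  sub-step after damage creation (same or next second, depending on the
  shuffle), and each mitoD is amplified at most once.
* Calibration root finding uses `stats::uniroot` to 1e-12 with an explicit
  achievable-range error when a target mean cannot be reached.
* Problem sizes in the test suite: full-scale experiments use 3-12 Monte
  Carlo trials of the complete 14,000-cell lobule over 24 simulated hours;
  engine-level invariant tests use a deterministic 6-segment, 60-cell
  fixture lobule whose coordinates are hand-checkable.

## Limitations

The lobule is a flow-path sample, not a 3-D reconstruction: no bile
network, no inter-lobule connectivity, no endothelial metabolism, no GSH
resynthesis, no explicit oxidant-stress pathway — each deliberately
subsumed into the lumped events above. The synthetic lobule generator
reproduces structural variability (dimensions, wiring, flow heterogeneity)
but not biological covariates such as strain-specific enzyme expression;
passing tests therefore demonstrate internal consistency and the intended
mechanism logic, not fidelity to any particular animal's histology.
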