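---
title: "Modeling the endothelial VEGF / Ang-Tie signaling network with endonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the endothelial VEGF / Ang-Tie signaling network with endonet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`endonet` is a mechanistic ordinary-differential-equation model of the
signaling network formed by the two master regulators of vascular growth and
stability in endothelial cells: the VEGF/VEGFR2 axis (pro-angiogenic and
pro-permeability) and the angiopoietin/Tie2 axis (pro-stability).  The
package couples a coarse-grained, rule-derived reaction network to a stiff
simulator, a pattern-search calibrator, variance-based global sensitivity
analysis, and a set of reproducible in-silico experiments: the VEGF
crosstalk dose sweeps, the chronic-versus-acute Ang1 protection protocols,
and the inhibitor-by-Ang1 combination grids.

# The model

## State space and rate laws

The network is expressed as ~80 species and ~115 expanded reactions.  A
species is a molecular configuration (for instance, a ligand-induced Tie2
cluster `A1c` has composition Tie2 x 4 + Ang1 x 1) living in one of seven
compartments (extracellular, surface, junctional, cytosol, ER, internalized,
Weibel-Palade body).  Rules use three rate-law families:

* mass action for binding and first-order conversion steps, with an
  optional catalytic modifier (a species or a weighted-sum observable);
* Michaelis-Menten kinetics `kcat * E * S/(Km + S)` for enzymatic
  (de)phosphorylation, e.g. VE-PTP acting on junctional phospho-Tie2;
* a Vmax form `V * S/(Km + S)` for carrier-like fluxes (SERCA reuptake).

Any rule can carry saturating co-factor terms `X/(K + X)`; these implement,
for example, the calcium requirement of eNOS activation and the
VEGFR2-dependence of Tie2 shedding enhancement.  Every species carries a
monomer composition, so the assembler verifies elemental balance of every
rule that is not explicitly flagged as synthesis/degradation/shedding, and
conserved pools (one per monomer) are derived automatically and audited by
`conservation_report()`.

## Units

All species are expressed in nM as bath-equivalent concentrations, including
surface receptors; time is in minutes.  A single unit system keeps
bimolecular rate constants in 1/nM/min everywhere, makes the monomer
conservation checks exact, and matches how the experimental literature
reports doses: ligand doses in ng/mL are converted with configurable
molecular masses (VEGF-A dimer 45 kDa, Ang1 tetramer 280 kDa, Ang2 monomer
66 kDa), so 50 ng/mL VEGF is 1.11 nM and 50 ng/mL Ang1 is 0.18 nM of
tetramer.  An Ang2 dose is split into dimer/trimer/tetramer species with
default mole fractions 0.4/0.3/0.3 of multimers.

## Mechanisms

**VEGF axis.** VEGF binds VEGFR2 (`konvegfr2`/`koffvegfr2`); the liganded
receptor recruits a second VEGFR2 into a dimer that autophosphorylates
(`kphosvegfr2`).  VEGFR1 acts as a decoy both by sequestering ligand and by
forming signaling-dead VEGFR1-VEGFR2 heterodimers; NRP1 binds VEGF and
VEGFR1; TSP1 bound to CD47 associates with VEGFR2 and blocks its
dimerization.  Receptors cycle constitutively
(`kintvegfr2`/`krecvegfr2`/`ksynvegfr2`/`kdegvegfr2`), and ligand-bound
dimers (phosphorylated or not) internalize at the faster ligand-induced
rate `kintpvegfr2` and are degraded (`kdegvegfr2dpe2_nrp`).  Internalizing
unphosphorylated dimers as well is deliberate: a receptor-kinase inhibitor
must not strand ligated receptors at the surface, otherwise its downstream
effect at 15 min inverts sign.

**Tie axis.** Ang1 is a tetramer; Ang2 exists as dimer, trimer and
tetramer.  Tetrameric ligand on Tie2 seeds a lumped clustering step that
recruits three further Tie2 (cluster size capped at four receptors); only
clusters autophosphorylate.  Ang2 dimer/trimer occupy Tie2 without
clustering (competitive antagonism) and the Ang2 tetramer clusters at an
`ang2_agonist_factor` of the Ang1 rate (weak agonism).  Phospho-clusters
translocate to the junctional compartment (`ktransloctie2`) where VE-PTP
dephosphorylates them; Tie1 blocks ligand access at the surface
(Tie1-Tie2 heterodimers) but stabilizes junctional clusters, modeled as a
`tie1_shield_factor` on the VE-PTP rate for Tie1-bound clusters.  Tie1 and
Tie2 shed their ectodomains constitutively; soluble Tie2 is a ligand trap
for Ang1 and all Ang2 forms.  Surface Tie2 and Tie1 are maintained by
zeroth-order synthesis balancing constitutive shedding, so the ligand-free
model is at flux balance after `pre_equilibrate()`.

**Crosstalk.** Active VEGFR2 multiplies the Tie2 shedding rate constant by
a saturating enhancement calibrated to double constitutive shedding at
saturating VEGF.  VEGFR2 also drives (PKC/DAG- and VEGFR2-gated)
sphingosine-kinase activity; the resulting S1P releases a finite
Weibel-Palade-body Ang2 store into the extracellular multimer mixture.
Junctional phospho-Tie2 activates PI3K independently of Src and loads
RhoA-GTP, which binds mDia; the RhoA-GTP/mDia complex sequesters Src.

**Downstream.** VEGFR2 activates Src (`kactivesrc`), Axl (transactivation)
and PLC-gamma.  PLC-gamma produces IP3 (minimal three-flux calcium cycle:
IP3-gated ER release, leak, SERCA reuptake) and DAG.  DAG is the main
driver of PI3K activation (a coarse-grained PKC arm), with smaller
contributions from pSrc, pAxl and junctional pTie2; PI3K activates Akt
(`kcatPI3KAkt` against `kinactPI3K` deactivation), Akt plus calcium
activate eNOS.  Raf activation requires DAG with S1P and calcium co-factors
and feeds a linear Raf-MEK-Erk cascade.  pSrc phosphorylates VE-cadherin,
the permeability readout.

Two wiring choices deserve emphasis because the upstream literature leaves
them open.  *Axl* is placed downstream of VEGFR2 feeding PI3K in parallel
with Src; this is consistent with the observation that Axl inhibition fails
to block Src activation, and it is a package decision, not an established
mechanism.  *The PLC-gamma/DAG arm into PI3K* realizes the canonical
PKC-dependent coupling of receptor activity to sphingosine kinase and
PI3K/Akt; it is what makes Akt signaling sensitive to PLC-gamma abundance
and activity, and at the same time lets Ang1 rescue Akt through the
Tie2-PI3K arm when the VEGFR2 axis is inhibited.  `ppAkt` names the single
"active Akt" state; no claim about dual-site phosphorylation is intended.

## Inhibitors

Inhibitors are instantaneous activity scalings: from their application time
every rate constant tagged with the target node (Src, Axl, Akt, VEGFR2) is
multiplied by `1 - fraction`.  They are not binding species, so dose units
and pharmacokinetics are out of scope.

# Simulation

`simulate_protocol()` integrates piecewise between protocol events with
`deSolve::lsoda` (rtol 1e-8, atol 1e-10 by default); ligand additions are
instantaneous concentration jumps against an infinite bath (no volume
change), but binding depletion of the added ligand *is* modeled.
`pre_equilibrate()` iterates the ligand-free system in 250-min chunks until
`|dx/dt|/(|x| + 1e-4) < 1e-8` for every species.  The packaged initial
values are the ligand-free flux-balance state itself, so equilibration from
the defaults converges in a fraction of a second; perturbed parameter sets
converge within the 5000-min cap or raise an error naming the worst
species.  Peaks reported by `peak_refined()` re-simulate a +-1 min window
around the coarse-grid maximum at 0.1-min resolution.

# Calibration

`objective_sse()` is the weighted sum of squared errors between normalized
predictions and dataset values; weights default to 1/n per dataset so every
calibration surface counts equally.  Normalization follows the data:
percent-of-maximum (scale-invariant, as for western-blot time courses),
fold-over-baseline, or absolute.  Time-course datasets that share a
stimulation protocol are simulated once per candidate on the union of their
grids.  Integration tolerances are relaxed to rtol 1e-6 inside the
objective because it is evaluated thousands of times; a failed candidate
(integration failure, non-convergent equilibration) contributes a large
finite penalty (1e9) instead of an error.

`pattern_search()` is a generalized pattern search: 2n coordinate polls in
lexicographic parameter order (+ before -), first improving poll accepted,
mesh doubled on success and halved on failure, stopping below a mesh of
1e-6 or at 5000 evaluations.  Two poll schemes are available: the strict
scheme restarts the round at the first improving poll (the default, and
the one benchmarked on the classical curved-valley problem), while the
`"cyclic"` scheme continues the lexicographic scan past an accepted poll.
`fit()` defaults to cyclic polling because on 6-8-parameter calibration
problems the strict scheme repeatedly improves the lexicographically first
coordinates and starves the rest of the evaluation budget.  `fit()` runs
the search in log10 parameter space with
bounds defaulting to [0.01x, 100x] of the initial estimate and an initial
mesh of 0.5 log10 units.  The generic default initial mesh is 0.25, small
enough that curved-valley objectives (the classical two-dimensional banana
benchmark) keep progressing within typical budgets.  The packaged baseline
parameter set was obtained the same way the original two-stage procedure
works: manual tuning to the documented protocol outcomes first, pattern
search against the synthetic fixture suite for refinement.

# Global sensitivity analysis

`sobol_first_order()` and `sobol_second_order()` implement variance-based
indices on the Saltelli (A, B, AB_i / BA_i) design.  Reported main effects
use the Jansen difference estimator `S_i = 1 - mean((f_B - f_AB_i)^2)/2V`,
which in our benchmarks is substantially more accurate at small sample
sizes than the correlation form; inside the second-order synergy estimator
the product-moment first-order form is used instead so that its
quasi-random bias cancels against the product-moment `V_ij` term.  Raw
estimates may be slightly negative; values are reported unclipped with
percentile bootstrap confidence intervals (B = 1000, 95% by default) over
sample rows.  Run counts are exactly `N (d + 2)` for first order and
`N (2d + 2)` for second order.

Two samplers are available: seeded Latin hypercube sampling (the default,
used for the model analysis) and an unscrambled Sobol' sequence with
skip 1000 and leap 100 by default.  `leap` counts the points omitted
between draws (stride `leap + 1`, the convention of the common quasi-random
toolboxes); this matters because an even stride pins low-order bits of the
base-2 sequence and destroys its uniformity, while the odd stride 101
preserves it — the packaged discrepancy test verifies the leaped sequence
still beats i.i.d. sampling.  Estimator-verification tests (the
three-factor benchmark with analytic indices, additive and pure-product
cases) use the contiguous sequence, since leaping trades accuracy for
reproducing the study configuration.

The model evaluator perturbs all non-structural parameters (kinetic
constants and initial abundances; molecular masses, multimer fractions and
baseline complex occupancies are tagged `fixed`) uniformly on 0.2-fold to
5-fold of baseline, re-equilibrates the ligand-free model on a fixed
800-min horizon, applies the simultaneous stimulus (VEGF 10, Ang1 200,
Ang2 500 ng/mL) at t = 0 and reads the outputs at 5 min.  The fixed
equilibration horizon, the BDF integrator and the relaxed tolerances
(rtol 1e-4, atol 1e-6) are deliberate: the analysis integrates tens of
thousands of runs, and ranking of variance contributions is insensitive to
these choices at the packaged problem sizes (n_base 256 over the full
parameter set, roughly 35,000 runs).  At this design size the Monte-Carlo
resolution of a main-effect index is about +-0.02; indices below that level
are reported but their mutual order is not meaningful.

# Synthetic data

`make_fixture_suite()` generates twenty calibration datasets emulating the
statistical structure of the calibration surfaces the model family is
fitted to: normalized phospho-protein time courses under 50 ng/mL VEGF
(receptor totals, surface receptor, pVEGFR2, pSrc, pAxl, ppAkt, peNOS,
pPLC-gamma, cytosolic calcium, pErk), Tie-axis time courses and Ang1/Ang2
dose responses of pTie2, a VEGF dose response of S1P, VEGF-induced Ang2
release, and constitutive and VEGF-enhanced soluble-Tie2 accumulation.
Sparse sampling (6-9 points over 0-60 or 0-120 min; 8-9 doses over 0-800
or 0-20 ng/mL) mirrors typical blot/ELISA designs.  Noise is multiplicative
lognormal with CV 5% by default, a typical densitometry variability; noise
is applied to the raw signal before normalization so that declared
normalizations hold exactly (a percent-of-max dataset always has maximum
100).  The generator does not emulate blot saturation, batch effects or
correlated replicate structure, so passing recovery tests demonstrates
identifiability under idealized noise, not robustness to real-data
artifacts.

The designated identifiable subset for recovery experiments
(`identifiable_subset()`) holds eight kinetic constants with direct leverage
on fixture curve shapes: `kintpvegfr2`, `kdephossrc`, `ktransloctie2`,
`kactrhoa`, `konang1tie2`, `koffang2tie2`, `krelang2`, `kcatveptp`.
Scale-type parameters are deliberately excluded: percent-of-max
normalization removes amplitude information, so only shape-determining
constants are recoverable from the suite.

# In-silico experiments

`run_crosstalk_sweep()` sweeps VEGF 0-20 ng/mL (41 doses) and reports
cumulative Ang2 release over 60 min, the peak Tie2-shedding rate-constant
fold over constitutive, and percent inhibition of Ang1-induced steady
pTie2 (60 min) under 200 ng/mL Ang1 co-stimulation; each curve carries its
plateau (value at the top dose) and the smallest dose covering 95% of the
baseline-to-plateau span.  `run_ang1_protection()` compares VEGF-only
stimulation against Ang1 pre-stimulation (default 25 min at 50 ng/mL),
simultaneous co-stimulation, or Ang1 alone; transient readouts (pSrc,
pVE-cadherin) are compared at their post-VEGF peaks, and Src sequestration
is `1 - (free Src + pSrc)/total Src`, the fraction held in RhoA-GTP/mDia
complexes.  `run_combination_grid()` applies one inhibitor at t = 0
together with simultaneous Ang1 against a 50 ng/mL VEGF background (the
background dose is a package default, flagged in the output, because the
combination protocol leaves it open) and reads pTie2, pSrc, ppAkt and pErk
at 15 min.  VE-cadherin activation is reported as percent of the VEGF-only
maximum.  The Fig-4G-style inhibition curve co-stimulates with 200 ng/mL
Ang1 by default; both defaults are configurable arguments.

# Numerical and design choices

* Integrator tolerances: simulator rtol 1e-8/atol 1e-10; calibration
  objective rtol 1e-6; sensitivity evaluator rtol 1e-4 with BDF.  The
  tolerance-stability test verifies observables move < 0.1% under a 10x
  tighter simulator tolerance.
* Negative states are tolerated by the right-hand side (saturating terms
  clamp at zero) and flagged by `validate_state()`.
* Ties in sensitivity rankings break lexicographically by parameter key;
  pattern-search polls are ordered lexicographically with + before -.
* The packaged initial values are the exact ligand-free flux-balance state
  (complex occupancies included, tagged `fixed`), which keeps
  pre-equilibration fast and exact at the defaults.
* Problem sizes used by the packaged tests: recovery fits run a few hundred
  objective evaluations on the fixture suite; the full-model sensitivity
  analysis uses n_base 256 over all non-structural parameters; the
  estimator benchmarks use n_base 2048-4096 on analytic functions.

# Known limitations

* Cluster size is capped at four Tie2 per cluster; higher-oligomer
  combinatorics are not represented.
* The state space is a coarse-grained lumping, not a full rule-expansion;
  site-level combinatorial species (e.g. mixed Ang1/Ang2 clusters) do not
  exist in the model.
* Inhibitors are activity scalings without pharmacokinetics.
* Tie2 abundance at baseline is set by the synthesis/shedding balance, so
  sensitivity of baseline-dependent outputs to `Tie2_0` alone is limited;
  the synthesis flux carries that role.
* The in-vitro bath assumption (constant extracellular volume, no
  paracrine re-uptake) means absolute soluble-species accumulations should
  be read as relative trends.
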