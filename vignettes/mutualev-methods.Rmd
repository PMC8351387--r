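---
title: "Models and methods behind mutualev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mutualev}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutualev)
```

`mutualev` studies a question from microbial community engineering: when a
yeast that cannot make a vitamin is co-cultured with a bacterium that cannot
make amino acids, the two survive only by cross-feeding — and serial-transfer
co-evolution of such communities selects bacteria that secrete *more* vitamin
even though secretion costs them energy. Why do costly over-secretors persist
instead of being displaced by cheaters? The package provides the three
computational pieces used to study this: a spatial agent-based model of the
community with a serial-transfer protocol and a mutant-invasion experiment; a
relative-expression-constrained flux-balance fit that connects proteomic
fold-changes to metabolic flux predictions; and the phenotype-quantification
formulas (growth rates, generation counts, screening fold-changes,
aggregation and biofilm readouts) used throughout such studies.

## The agent-based model

### World and agents

The world is a torus of 32 x 32 patches. Each patch holds two continuous
pools: amino acids and vitamin. Agents are individual cells — yeast, wild
bacteria, or mutant bacteria — with a position and an energy store. Several
agents may share one patch; agents do not exclude each other spatially.

Each tick applies six sub-steps in a fixed order:

1. **Movement.** With probability `mixing` an agent teleports to a uniformly
   random patch (culture shaking); otherwise, with probability `wander_prob`
   it steps to a uniformly chosen patch of its 3 x 3 neighbourhood (cell
   motility at the patch scale).
2. **Secretion.** Every yeast deposits `yeast_secretion_rate` amino-acid
   units on its patch; every bacterium deposits `bact_secretion_rate` vitamin
   units, multiplied by `mutant_secretion_fold` for mutants. Each secreted
   unit costs `secretion_cost` energy, paid unconditionally — secretion is a
   constitutive burden, which is exactly the fitness cost under study.
3. **Diffusion.** Each pool spreads: a patch keeps `1 - diffusion_rate` of
   its content and passes `diffusion_rate / 8` to each of its eight
   neighbours. Mass is conserved exactly.
4. **Consumption.** In a freshly shuffled order, each agent removes up to
   `uptake_max` units of its required metabolite (yeast: vitamin; bacteria:
   amino acids) from its own patch and gains `conversion_efficiency` energy
   per unit. The shuffle avoids positional bias when a patch cannot serve
   all its occupants.
5. **Death.** Agents at energy <= 0 are removed. Because secretion is paid
   before consumption, an agent whose energy cannot cover its secretion cost
   dies of it ("pay then die").
6. **Division.** Agents at or above `division_threshold` are replaced by two
   same-patch daughters, each holding half the parent's energy. Death is
   checked before division so a cell can never do both in one tick.

This order makes the secretion cost unconditional and lets consumption see
the diffused field; it is fixed and documented rather than configurable.

### Serial transfers

A growth cycle runs until the census reaches the initial count times
2^`doublings_per_transfer` (default 5 doublings — the transfer trigger used
in the wet-lab protocol the model mirrors), the population dies out, or a
tick cap is hit. A transfer then samples exactly the initial number of
agents uniformly without replacement — label-blind, energies preserved —
and places them at random positions in a fresh world with both pools at
zero. An invasion experiment runs 25 such transfers and asks whether the
descendants of a single seeded mutant are still present at the end.

### Calibration

Two constraints anchor the energy economy: wild-type agents of both species
net exactly +1 energy per tick under saturated uptake (which equalizes yeast
and bacterial doubling times), and one yeast feeds about eight bacteria
(yeast secretion = 8 x bacterial uptake). Within those constraints the
absolute parameter levels are free, and we fixed them by a viability-driven
calibration before running any invasion statistics:

* **Bacteria**: `uptake_max = 1`, `secretion_rate = 1`,
  `conversion_efficiency = 1.1`, `secretion_cost = 0.1`. A fold-2 mutant
  therefore nets 0.9 per tick at optimum — costly but viable.
* **Yeast**: `uptake_max = 16`, `secretion_rate = 8`,
  `conversion_efficiency = 0.075`, `secretion_cost = 0.025`. The uptake
  capacity is set to twice the vitamin supply a yeast receives in a balanced
  wild-type neighbourhood (eight bacteria secreting one unit each), so
  wild-type yeast operate below saturation and *extra* vitamin translates
  into faster local yeast growth. This is the mechanistic heart of the
  model: where spatial structure keeps that faster-growing yeast next to the
  over-secreting mutant lineage, the mutant recoups its cost through the
  amino acids those yeast return.
* **World**: `diffusion_rate = 0.1` keeps secreted metabolites close to
  their source, so cross-feeding is a patch-neighbourhood interaction;
  `wander_prob = 0` — agents are immobile unless mixing moves them, so
  daughters pile on their natal patch and lineages stay spatially
  assorted (calibration runs showed that even slow motility lets wild-type
  bacteria free-ride on over-secretors' neighbourhoods and erases the
  structured-culture advantage; the flag remains available for studying
  exactly that erosion); `energy_init = 10`, `division_threshold = 20`.
* **Inoculum**: 100 yeast, 799 wild bacteria and 1 mutant — the observed
  roughly 1:8 yeast:bacteria ratio, at a density (about 0.9 agents per
  patch) where founding yeast-bacterium encounters are common enough for the
  community to re-establish after every transfer.

During calibration we found two regimes that *fail* to reproduce the known
biology, which is informative about the mechanism: with immobile agents and
strong diffusion the benefit of extra secretion spreads mean-field-like over
the grid and cheaper secretors always win; with immobile agents and weak
diffusion, cross-feeding requires exact patch co-location and founding
lotteries drown selection entirely. The chosen defaults sit between these
regimes. All parameters remain user-configurable; the defaults define the
reference conditions used by the acceptance analyses.

A practical note on problem sizes: the bundled analyses run 200 replicates
of 25 transfers per condition, the full scale of the reference experiment,
which takes a few minutes per condition on one core with the compiled tick
kernel.

### What the invasion experiment shows

At `mixing = 0` the community is spatially structured and a single fold-2
over-secretor invades (persists through 25 transfers) several-fold more
often than the neutral fold-1 control; at `mixing = 1` every agent is
shuffled every tick, the secreted vitamin becomes a global common good, and
over-secretors of any fold are eliminated. Fisher's exact test on invasion
counts compares conditions. Mutant-fraction summaries over invaded
replicates report mean, min, max and (when more than two invasions) SD;
a mean of zero denotes no invasion. Replicates that collapse before the
last transfer count as not invaded — a conservative choice the experiment
driver records explicitly.

## The expression-constrained flux fit

The second component connects proteomics to metabolism. Given a
stoichiometric model, the growth rates of a reference (parental) and an
evolved condition, and enzyme log2 fold-changes between them, it predicts
paired flux states by linear programming:

* Each condition minimizes total nutrient uptake (the sum of
  uptake-direction exchange fluxes, excluding oxygen) subject to steady
  state, flux bounds, the measured growth rate as a biomass lower bound,
  and — for the parental condition — the measured product secretion rate as
  a product lower bound. This defines the per-condition optimum U*.
* The joint fit then solves one LP over both flux vectors (split into
  non-negative forward/reverse parts so magnitudes stay linear): each
  condition's uptake may exceed its U* by at most a relaxation `epsilon`
  (default 3%); the summed flux magnitude over enzymatic reactions is held
  equal between conditions, a linear proxy for a conserved total metabolic
  proteome; and the objective minimizes the absolute deviations
  `| |v_evo| - 2^log2fc x |v_ref| |` over the reactions with a significant
  fold-change (|log2fc| >= 0.5, i.e. at least 50% change).

Enzyme-level fold-changes map onto reactions as the mean over a reaction's
associated enzymes; complex/isozyme logic is out of scope and reaction-level
entries override the aggregation. A tie-break term (weight 1e-6) pulls
unconstrained enzymatic reactions toward mirrored magnitudes so that an
empty expression table reproduces the reference state exactly — without it
the joint LP would be degenerate. Reversible reactions can in principle
inflate forward and reverse parts simultaneously; the bundled toy network
avoids this by making all enzymatic reactions irreversible, and users of
reversible models should treat per-reaction magnitudes with care.

The bundled 14-reaction toy network stands in for a genome-scale lactic
acid bacterium model: glucose/amino-acid/oxygen uptake, lumped glycolysis
and respiration, a GTP branch, the six riboflavin-pathway steps from GTP
cyclohydrolase II to riboflavin synthase, riboflavin export, and biomass.
SBML import (Level 3 with FBC bounds) is provided for users with a real
model. The solver is the two-phase simplex from the `boot` package; at the
bundled problem sizes (tens of variables) it is exact to the reported
1e-6 tolerance on ratios.

The specific production rate that anchors the parental product bound is
estimated from an end-point titer:
`rate = (titer * 1e-6 / molar_mass) * 1e3 / duration / (biomass_fraction * od600 * cdw_per_od)`.
The OD600-to-cell-dry-weight factor `cdw_per_od` is a strain- and
instrument-specific calibration with no universal value, so it is a
required argument; 0.2528 g/L per OD unit is the value consistent with the
reference inputs (42 ng/ml riboflavin over 72 h at OD600 2 with the
producer as half the biomass, molar mass 376.36 g/mol) and a specific rate
of 6.13e-6 mmol/(gCDW h).

## Phenotype quantification

The formulas are deliberately literal implementations of the conventions
used in the wet-lab work they mirror:

* **Growth rate**: the maximum least-squares slope of log2(OD600) over
  sliding windows of exactly `min_points` consecutive samples (5 for
  monocultures; 6-8 conventionally for conditioned-media curves). Fixing
  the window length keeps the estimator well defined; longer windows do not
  compete. The unit is doublings per hour.
* **Generations**: `log10(Af/Ai) / 0.3` with the literal 0.3 of the field
  formula (a rounding of log10(2), so the count slightly overestimates true
  doublings by a factor log10(2)/0.3 = 0.3010/0.3).
* **Screening fold-change**: isolate mean over parental mean, with the
  parental replicate mean as the sole denominator and no blank subtraction
  unless a blank is supplied.
* **Aggregation**: `(1 - At/A0) x 100`, reported as-is (negative when the
  suspension OD rises).
* **Biofilm**: blank-mean-subtracted A570 with sample mean and SD.
* **Two-group comparison**: classical unpaired two-tailed Student t-test;
  Welch's form behind a flag. Two identical zero-variance groups return
  t = 0, p = 1 by convention.

## Synthetic data

Every stage has a seeded generator so the pipeline is testable with no
downloads, and each generator returns its ground truth for closed-loop
parameter-recovery tests:

* `gen_growth_curve()` samples a logistic curve in base-2 parametrization
  with Gaussian noise on log2(OD) (multiplicative on OD, the simplest model
  consistent with positivity).
* `gen_fluorescence_plate()` draws parental and isolate intensities under
  lognormal noise; the default coefficient of variation of 0.39 matches a
  parental readout spread of about 16.4 on a mean of 42.
* `gen_toy_model_case()` wires a chosen pathway log2 fold-change into the
  toy network's first riboflavin enzyme together with reference/evolved
  conditions.

Randomness uses R's Mersenne-Twister stream via `set.seed()`, which is
platform-independent; all generators and the simulator are pure functions
of their seed.

What the generators deliberately do not emulate: instrument drift and edge
effects on plates, lag phases and death phases in growth curves, correlated
proteomic noise, or any sequence-level realism. Passing recovery tests
therefore show estimator correctness under the stated noise models, not
robustness to every artefact of real instruments.

## Numerical and design notes

* Grid topology is a torus, the convention of patch-grid modelling
  environments; death uses strictly `energy <= 0`; daughters inherit the
  parent's patch.
* A transfer from a world smaller than the inoculum keeps all agents (no
  resampling); an empty world cannot be transferred.
* Fisher's exact test is the two-sided hypergeometric tail sum with a 1e-7
  relative slack on probability ties, matching `stats::fisher.test` to
  numerical precision.
* LP tolerances: 1e-10 simplex pivot tolerance, 1e-9 on feasibility checks
  in tests, 1e-6 on reported flux ratios.
* The invasion experiment assigns replicate i the seed `base_seed + i - 1`
  and grid cells disjoint seed blocks, so extending a sweep never perturbs
  completed cells.

## Known limitations

* The agent-based model is a minimal caricature: no explicit carbon
  sources, no within-run mutation, no off-lattice physics, no agent
  crowding. It is built to study the qualitative interplay of spatial
  structure, secretion cost and cross-feeding, not to fit measured
  population dynamics.
* The absolute calibration of the energy economy is this package's own
  (constraint-respecting) choice; invasion percentages shift quantitatively
  within the constraint family, and conclusions should be drawn from
  contrasts (mutant versus neutral, mixed versus structured), not absolute
  frequencies.
* The expression fit is a linear surrogate: no thermodynamics, no enzyme
  kinetics, no quadratic objectives, and the proteome proxy weighs all
  enzymatic reactions equally.
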