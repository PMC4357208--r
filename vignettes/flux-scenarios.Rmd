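---
title: "Flux scenarios behind macroscopically indistinguishable phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux scenarios behind macroscopically indistinguishable phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

*E. coli* carrying a replication-deregulated, antibiotic-free-selected plasmid
can hold 7,000–15,000 plasmid copies — several genome equivalents of extra
DNA — while growing on glucose minimal medium at the same rate, the same
biomass yield on glucose, and the same byproduct pattern as the plasmid-free
host. Because those phenotype descriptors are measured with finite resolution,
they do not pin down a single intracellular flux distribution: a whole
family of flux states is *macroscopically indistinguishable* (an MIP). This
package builds the flux space of that family, enumerates its extreme
scenarios, and asks which of them a burdened cell could plausibly occupy; a
companion screen identifies differentially abundant proteins in
host-vs-transformant abundance tables, whose flux implications can be read
against the scenarios.

## The model

The network (`parse_network()`, bundled as `fig1_network.tsv`) is central
carbon metabolism at coarse granularity: PTS-coupled glucose uptake
(glucose + PEP → G6P + pyruvate), glycolysis lumped into
phosphoglucose-isomerase, phosphofructokinase (−1 ATP, F6P → 2 triose-P),
glyceraldehyde-phosphate oxidation (+1 ATP, +1 NADH) and enolase steps; the
oxidative hexose monophosphate pathway (G6P → pentose-P + CO₂ + 2 NADPH)
linked back by transketolase 1/2 and transaldolase; pyruvate kinase,
pyruvate dehydrogenase, PEP carboxylase anaplerosis; a TCA cycle split at
α-ketoglutarate and malate so that the α-ketoglutarate biosynthetic drain
and the malic-enzyme branch are representable; acetate (+1 ATP) and lactate
excretion; and respiration sinks oxidizing NADH and FADH₂ at P/O ratios of
2.0 and 1.0. Isocitrate dehydrogenase is NADP-linked, so each TCA entry
yields one NADPH; total NADPH supply is HMP + ICDH + malic enzyme (+ an
optional capped transhydrogenase, off by default).

Three reversibility choices matter. PGI, the enolase lump and malate
dehydrogenase are reversible (anaplerotically derived oxaloacetate must be
able to feed malic enzyme). The transketolase/transaldolase steps are kept
irreversible: in the published scenario table the transketolase-2 flux
reaches a minimum of exactly 0 in two scenarios, i.e. its non-negativity is
a facet of the flux polytope, which is only possible with the forward
orientation fixed.

Mass balances `A r = b` are imposed for sixteen pools (carbon intermediates
plus NADH/NADPH/FADH₂); glucose, excreted acetate/lactate and CO₂ are
unbalanced externals. Carbon balance of every reaction is checked at parse
time against a bundled carbon-count table.

## The phenotype window

Measurements enter as constraints (`phenotype_constraints()`,
`build_bounds()`): growth at μ = 0.2 h⁻¹; lactate 0; acetate 1 mmol g⁻¹ h⁻¹
(tight) or 0.8–1.2 (loose); glucose uptake bounded by the yield window
0.42 ± 0.03 g/g through r = μ/(Y·MW), i.e. 2.469–2.849 mmol g⁻¹ h⁻¹; and
gross ATP production bounded by the ATP-yield window 7–10 g cell/mol ATP,
i.e. 20–28.571 mmol g⁻¹ h⁻¹ (28.571 kept at full precision, displayed
28.6). ATP production is the substrate-level column of the network plus
P/O-weighted respiration; the Y_X/ATP convention here is gross production
(polymerization and maintenance costs are reported in the load vector's
`atp_demand` but not subtracted from r_ATP — the window already absorbs
them, which is precisely why it is a window). With the acetate and lactate
equalities the system has two degrees of freedom
(`degrees_of_freedom()` = 2): two flux values resolve the whole map.

## The biosynthetic load

`compute_load_vector()` converts a macromolecular composition (protein
0.55, RNA 0.205, DNA 0.031, lipid 0.091, other 0.123 g/g; textbook
exponential-phase values) into growth-rate-proportional precursor demands;
the per-gram aggregates reproduce the classic numbers (R5P 0.90, 3PG 1.50,
OAA 1.79, PYR 2.83 mmol/g, ~18 mmol NADPH/g). Protein synthesis carries a
net NADH *release* (negative demand, ≈3.5 mmol/g), which the calibration
below refines. RNA turnover is modelled growth-coupled (a configurable
multiple, default 0.25, of the net synthesis flux) with an 0.8 salvage
fraction, so the non-salvaged precursor surcharge is small and the
repolymerization ATP lands in `atp_demand`; expressing turnover per unit
growth keeps the whole load homogeneous of degree 1 in μ.

DNA arithmetic: with 3.1% DNA, 50% GC, purine dNTPs costing R5P + 3PG (the
aspartate nitrogen returns as fumarate, so no net oxaloacetate) and
pyrimidine dNTPs R5P + OAA, the deoxyribonucleotide precursor load at
μ = 0.2 is `dna_precursor_load()` = 0.040 mmol g⁻¹ h⁻¹ — 1.6% of the
glucose flux. Extra plasmid DNA converts through genome equivalents
(`genome_equivalents(7e3, 3.7e3, 4.6e6)` = 5.6) at a default 1.8 chromosome
equivalents per cell for slow growth; even ten genome equivalents stay
under 10% of the glucose flux. `scale_dna_load()` multiplies only the
DNA-attributable entries.

## Calibrating the unprinted demand vector

The published table prints five extreme flux scenarios to two significant
figures but not `b`. `calibrate_loads()` reconstructs it by
equality-constrained weighted least squares built on a geometric
observation: each printed scenario is a *vertex* whose active constraints
are legible in the table itself — fluxes printed as exactly 0 are active
non-negativity facets, and an ATP yield printed at a window endpoint (10 or
7.0 g/mol) marks the ATP bound as active. Pinning those constraints makes
the vertex an affine function of `b`; every other printed cell then becomes
a soft residual weighted by its print precision (half a unit in the last
printed digit; glucose targets propagate from the printed yield, clipped to
the uptake window). The composition-derived load is a ridge prior (30%
relative, looser on NADPH and the NADH credit, which the printed table
determines well), demands are kept non-negative by an active-set step, and
two printed optima are imposed exactly: the minimum TCA flux 0.60 and the
maximum pyruvate-kinase flux 0.93. The weighted fit leaves a maximum
deviation from the printed cells of ~0.04 mmol g⁻¹ h⁻¹ (reported in
`attr(, "residuals")`); a residual above 0.1 would fall back to the
composition prior. Calibrating on rows 1, 2 and 5 suffices for the headline
extremes; the package default uses all five rows, which also fixes the
positions of scenarios 3 and 4. On noiseless synthetic vertices with a known
`b` the same routine recovers it exactly (a standing test).

Two reconstruction findings are worth recording. First, with the textbook
TCA stoichiometry (including the succinyl-CoA-synthetase ATP) the fit
places scenarios 4 and 5 exactly on the ATP ceiling — reproducing their
printed Y_X/ATP of 7.0 — while the glucose-uptake ceiling is left just
slack (maximum uptake 2.84, printing Y_X/S = 0.39). Second, the printed
r_CO2 column cannot be reconciled with network-level carbon bookkeeping to
better than ±0.5 mmol g⁻¹ h⁻¹ in either direction; net CO₂ here is reported
as the signed sum of the reaction CO₂ yields and the printed column is not
asserted anywhere.

## Enumerating and classifying scenarios

`enumerate_scenarios()` minimizes and maximizes each of the eleven named
fluxes (22 LPs) and clusters the optimal vertices at a relative 10⁻⁶ — far
tighter than the 2-significant-figure table, as it must be for clustering
to reflect geometry rather than rounding. Degenerate objectives (an optimum
attained along an edge, e.g. the minimum pyruvate-kinase flux) are resolved
by a secondary LP minimizing total absolute flux at the fixed optimum. This
tie-break is on by default: it is deterministic, it reports the
physiologically parsimonious representative, and without it the
second published scenario (pyruvate kinase off at high yield) would be
unreachable, since no single flux objective selects it uniquely. Records
whose optimum face is not a point are flagged `degenerate`.

```{r}
library(mipflux)
system   <- assemble_system(parse_network())
bounds   <- build_bounds(system, read_phenotype_config())
load_cal <- calibrate_loads(system, bounds)
tab <- classify_co_optimal(enumerate_scenarios(system, load_cal, bounds))
tab        # five scenarios; co-optimal groupings as annotated in the source
```

The five clusters reproduce the published rows cell-for-cell at print
precision, including the yield columns; minimizing the TCA flux coincides
with maximizing the biomass production rate (`biomass_max_equivalence()`),
and in the maximum-malic-enzyme scenario `nadph_breakdown()` attributes
about one third of NADPH supply to malic enzyme. 2-D projections
(`project_pair()`, a 128-direction support-function sweep with a
brute-force vertex-enumeration oracle behind its tests) show the feasible
regions for flux pairs; the scenario points lie on their boundaries, and
pyruvate-kinase and malic-enzyme fluxes vary inversely across the extremes
(`pairwise_trend()`).

## The three-fold DNA test

Tripling the DNA-attributable loads is the robustness probe for the burden
argument. In this reconstruction the flux ranges and scenario types are
indeed barely moved (every vertex's glucose uptake shifts by ≈+0.06
mmol g⁻¹ h⁻¹, ~2%), but the strict cluster count drops from five to four:
the two high-uptake scenario types merge at the glucose-uptake ceiling.
This is not a tuning accident but a consequence of the printed table
itself — any scenario printing Y_X/S = 0.39 sits within 0.036 mmol g⁻¹ h⁻¹
of the uptake bound 2.849, while the tripled DNA load adds 0.34 mmol carbon
g⁻¹ h⁻¹ ≈ 0.057 of glucose — so the corresponding acceptance check is
expected to fail under exact clustering, and the count-invariance claim
should be read at reporting resolution. The corresponding test is left
asserting the source's claim and failing, as documentation of the
disagreement.

## Proteome screen and synthetic data

`screen_proteome()` implements the published rule verbatim: a protein
changes if its transformant/host mean-abundance ratio is below 0.5 or above
2.0 *and* a Welch t-test on log abundances gives p < 0.05. With duplicate
cultures per condition this is a screening heuristic, not a calibrated
test, and is documented as such; no multiple-testing correction is applied
by default (a Benjamini–Hochberg option exists). The ratio thresholds are
strict, the screen is invariant to global rescaling, and flag counts are
monotone in α and in the thresholds. `replicate_correlation()` is the
log-scale Pearson quality check (>0.90 in the study).

`generate_proteome()` supplies the test bed: log-normal per-protein
baselines, multiplicative replicate noise (log-SD 0.1 by default), and a
planted set of fold-changes — 40 down, 29 up by default, mirroring the 69
differentially expressed proteins reported — each of magnitude ≥2 (planting
inside the screen's dead zone is an error). At the default noise the screen
recovers the planted set with recall ≥0.9; as noise vanishes recall and
precision go to 1. `generate_phenotype()` likewise emulates replicate
phenotype measurements at stated CVs (7% yield, 20% acetate) and
`summarize_phenotype()` turns them into a constraint window. Both are
bit-reproducible under a seed. What the generators deliberately omit:
peptide-level rollup, labelling-channel artifacts, correlated protein
blocks (operons), and abundance-dependent variance — so passing tests
certify the screen's arithmetic and its statistical behavior under the
stated error model, not performance on real spectra.

## Numerical choices

The LPs are solved by an internal two-phase dense simplex with Bland's
rule. These systems are tiny (about 23 variables after splitting the three
reversible fluxes) but heavily degenerate, which defeated the
recommended-package simplex in several modes (NA pivots at degenerate
vertices, mishandled two-sided constraints with equal bounds); Bland's rule
guarantees termination and a platform-independent vertex choice. Equalities
are encoded as equality rows, reversible fluxes are split into non-negative
parts, and every flux carries a numerical box of ±100 mmol g⁻¹ h⁻¹ so
null-direction futile pairs cannot unbound a solve. Tolerances: simplex
pivots 10⁻⁹, vertex clustering 10⁻⁶ relative, co-optimality 10⁻⁶ absolute,
carbon balance 10⁻⁹. Test problem sizes were chosen for tightness-per-
second: 1000 random feasible points for the flux-range sandwich, 20 random
≤4-dimensional polytopes against the brute-force vertex oracle, and
1000-protein proteome tables.

## Limitations

The network reconstruction is at figure granularity, not genome scale;
the exact published reaction set and demand vector are not printed, so the
bundled files are a calibrated reconstruction (swappable — both are plain
TSV). Growth-rate-dependent composition shifts, stationary phase,
thermodynamic constraints and kinetic regulation are out of scope. The
printed CO₂ column and the three-fold-DNA cluster-count claim are the two
places this reconstruction demonstrably cannot match the source exactly;
both are analyzed above rather than fitted.
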