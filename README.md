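# mipflux

Flux scenarios for **m**acroscopically **i**ndistinguishable **p**henotypes:
constraint-based analysis of *E. coli* central carbon metabolism when the
measured phenotype — growth rate, biomass yield on glucose, byproduct
secretion, ATP yield — is fixed only within experimental resolution. The
motivating system is a host carrying a replication-deregulated, high-copy
(7,000+) plasmid selected without antibiotics: several genome equivalents of
extra DNA, yet growth on minimal medium is macroscopically unchanged. Which
intracellular flux rearrangements are compatible with that, and which could
cover the extra ATP drain of plasmid DNA synthesis and RNA turnover?

## The model

For flux vector $r$ (mmol g⁻¹ h⁻¹) over a lumped map of glycolysis, the
hexose monophosphate (HMP) pathway, and the TCA cycle, each phenotype window
defines a polytope:

$$\min Z \quad \text{s.t.}\quad A\,r = b,\quad r_{lac}=0,\quad r_{ac}=1,\quad
2.469 \le r_{glu} \le 2.849,\quad 20 \le r_{ATP} \le 28.6,$$

where $A$ holds the mass balances of 16 internal pools (including
NADH/NADPH/FADH₂; NADP-linked isocitrate dehydrogenase), $b$ is the
growth-rate-scaled biosynthetic precursor demand derived from cell
composition, the glucose window encodes $Y_{X/S} = 0.42 \pm 0.03$ g/g at
$\mu = 0.2\ \mathrm{h^{-1}}$, and the ATP window encodes
$Y_{X/ATP} \in [7, 10]$ g/mol at P/O ratios 2.0 (NADH) and 1.0 (FADH₂).
Minimizing and maximizing each named flux ("FVA-style" enumeration)
harvests the extreme flux scenarios; the system has two degrees of freedom,
so the feasible set projects to polygons in any flux-pair plane. The demand
vector $b$ is not printed in the source study; `calibrate_loads()`
reconstructs it by constrained weighted least squares against the published
scenario table (see the methods vignette `vignettes/flux-scenarios.Rmd`).

A second component implements the study's proteome screen — a protein is
differential if its transformant/host ratio is `< 0.5` or `> 2.0` with
t-test `p < 0.05` — plus synthetic phenotype/proteome generators with
planted effects for testing every stage without external data.

## Worked example

```r
library(mipflux)
system <- assemble_system(parse_network())          # bundled Fig-1-style network
bounds <- build_bounds(system, read_phenotype_config())
cal    <- calibrate_loads(system, bounds)           # b from the printed table
tab    <- enumerate_scenarios(system, cal, bounds)
tab
#> scenario_table: 22 objectives in 5 distinct flux scenarios
#>  1. [MIN r_GLU, MAX r_HMP, MAX r_TA, MAX r_TK1, MAX r_TK2, MIN r_TCA, MIN r_ME, ...]
#>     r_GLU=2.487 r_TCA=0.6 r_PYK=0.475 r_HMP=1.391 r_ME=0 r_TA=0.428 r_TK1=0.428 r_TK2=0.356 r_ANA=0.57
#>  2. [MAX r_GLU, MAX r_TCA] r_GLU=2.844 r_TCA=1.67 r_PYK=0.123 r_HMP=0.323 r_ME=1.066 ...
#>  3. [MIN r_HMP, MIN r_TA, MIN r_TK1, MIN r_TK2, MAX r_ME, MAX r_ANA] r_GLU=2.803 r_TCA=1.588 r_PYK=0 ...
#>  4. [MIN r_PYK] r_GLU=2.506 r_TCA=0.771 r_PYK=0 r_HMP=0.992 r_ME=0.628 ...
#>  5. [MAX r_PYK] r_GLU=2.811 r_TCA=1.379 r_PYK=0.93 r_HMP=1.001 r_ME=0 ...
```

Five distinct scenarios span the phenotype window: a high-yield,
TCA-minimal state (scenario 1 — also the biomass-rate-maximal solution,
with `Y_X/S = 0.45` and `Y_X/ATP = 10`), and low-yield states with high TCA
flux, pyruvate kinase ranging from knocked-out (0) to 0.93 mmol g⁻¹ h⁻¹,
and transketolase/transaldolase nearly silenced. In the maximum-malic-enzyme
scenario:

```r
s3 <- solve_flux_lp(system, cal, bounds, "r_ME", "max")
round(nadph_breakdown(s3, system), 3)
#>          HMP         ICDH malic_enzyme
#>        0.191        0.470        0.339
```

malic enzyme supplies about one third of NADPH, relieving the HMP pathway.
The plasmid burden itself is small: `dna_precursor_load(mu = 0.2)` gives
0.040 mmol g⁻¹ h⁻¹ of combined R5P+3PG+OAA demand against a glucose flux of
~2.5, and `genome_equivalents(7e3, 3.7e3, 4.6e6)` = 5.6 genome equivalents
of plasmid DNA. Flux-pair feasibility regions come from
`project_pair(system, cal, bounds, c("r_TCA", "r_PYK"))`; the proteome
screen from `screen_proteome(generate_proteome(seed = 7))`.

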