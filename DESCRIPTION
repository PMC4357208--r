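Package: mipflux
Title: Flux Scenarios for Macroscopically Indistinguishable Phenotypes in E. coli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of Escherichia coli central carbon
    metabolism for cells whose measured phenotype (growth rate, biomass yield
    on glucose, byproduct secretion, ATP yield window) is fixed within
    experimental resolution, as arises when comparing plasmid-free hosts with
    cells carrying replication-deregulated high-copy plasmids. Builds a
    lumped stoichiometric model of glycolysis, the hexose monophosphate
    pathway and the TCA cycle with growth-rate-scaled biosynthetic precursor
    demands; enumerates the extreme flux scenarios compatible with the
    phenotype window by per-flux minimization and maximization; classifies
    co-optimal objectives; projects the feasible flux polytope onto flux
    pairs; quantifies the plasmid DNA precursor burden; and provides a simple
    fold-change plus t-test differential screen for iTRAQ-style proteome
    abundance tables together with synthetic data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
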