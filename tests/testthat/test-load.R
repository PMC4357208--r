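test_that("load vector scales linearly in growth rate and vanishes at mu = 0", {
  cm <- read_composition()
  l0 <- compute_load_vector(cm, mu = 0)
  expect_true(all(l0$b == 0))
  expect_equal(l0$atp_demand, 0)
  l1 <- compute_load_vector(cm, mu = 0.2)
  l2 <- compute_load_vector(cm, mu = 0.4)
  expect_equal(l2$b, 2 * l1$b)
  expect_equal(l2$atp_demand, 2 * l1$atp_demand)
  ## carbon content per unit growth is growth-rate independent and plausible
  sys <- assemble_system(parse_network())
  carbon <- function(l) sum(l$b[names(l$b) %in% names(sys$carbon_counts)] *
                              sys$carbon_counts[names(l$b)[names(l$b) %in% names(sys$carbon_counts)]])
  expect_equal(carbon(l2) / 0.4, carbon(l1) / 0.2)
  expect_gt(carbon(l1) / 0.2, 35)   # mmol C per g cell
  expect_lt(carbon(l1) / 0.2, 50)
})

test_that("single-macromolecule composition reproduces the one-line arithmetic", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "comp.tsv")
  writeLines(c("macromolecule\tmass_fraction\tresidue_mass\tprecursors\tatp_per_bond\tatp_per_denovo",
               "protein\t1.0\t0.110\tPYR:2\t4\t0"), f)
  cm <- read_composition(f)
  l <- compute_load_vector(cm, polymerization_costs(), mu = 0.3)
  expect_equal(unname(l$b["PYR"]), 0.3 * 1.0 / 0.110 * 2)
  expect_equal(l$atp_demand, 0.3 * 1.0 / 0.110 * 4)
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("macromolecule\tmass_fraction\tresidue_mass\tprecursors\tatp_per_bond\tatp_per_denovo",
               "protein\t-0.2\t0.110\tPYR:2\t4\t0"), bad)
  expect_error(read_composition(bad), "negative mass fraction")
})

test_that("DNA precursor load: printed value, linearity, burden bound", {
  cm <- read_composition()
  v <- dna_precursor_load(cm, mu = 0.2)
  expect_equal(signif(v, 1), 0.04)
  ## doubling the DNA fraction exactly doubles the load
  cm2 <- cm
  cm2$mass_fraction[cm2$macromolecule == "dna"] <- 2 * cm2$mass_fraction[cm2$macromolecule == "dna"]
  expect_equal(dna_precursor_load(cm2, mu = 0.2), 2 * v)
  ## ten genome equivalents of extra DNA stay below 10% of the glucose flux
  v10 <- dna_precursor_load(cm, mu = 0.2, genome_equivalents_extra = 10)
  expect_lt(v10 - v, 0.1 * 2.5)
  cm0 <- cm[cm$macromolecule != "dna", ]
  expect_error(dna_precursor_load(cm0, mu = 0.2), "no DNA fraction")
})

test_that("genome equivalents arithmetic", {
  expect_equal(round(genome_equivalents(7e3, 3.7e3, 4.6e6), 1), 5.6)
  expect_equal(genome_equivalents(0, 3.7e3, 4.6e6), 0)
  expect_equal(round(genome_equivalents(15e3, 3.74e3, 4.6e6), 1), 12.2)
  expect_error(genome_equivalents(7e3, 0, 4.6e6), "positive")
})

test_that("DNA-load scaling touches only DNA-attributable entries and composes", {
  l <- compute_load_vector(mu = 0.2)
  expect_equal(scale_dna_load(l, 1)$b, l$b)
  l3 <- scale_dna_load(l, 3)
  expect_equal(sum(l3$dna_b[c("R5P", "PG3", "OAA")]),
               3 * sum(l$dna_b[c("R5P", "PG3", "OAA")]))
  expect_equal(signif(sum(l3$dna_b[c("R5P", "PG3", "OAA")]), 2), 0.12)
  ## non-DNA entries untouched (e.g. PEP is purely protein-derived)
  expect_equal(l3$b["PEP"], l$b["PEP"])
  ## composition of factors
  l6 <- scale_dna_load(scale_dna_load(l, 2), 3)
  expect_equal(l6$b, scale_dna_load(l, 6)$b)
  expect_error(scale_dna_load(l, -1), ">= 0")
})
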