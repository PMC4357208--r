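test_that("bundled network parses with the named fluxes and carbon balance", {
  net <- parse_network()
  reg <- c("r_GLU", "r_HMP", "r_TA", "r_TK1", "r_TK2", "r_TCA", "r_PYK",
           "r_ME", "r_ANA", "r_LAC", "r_ACE")
  expect_true(all(reg %in% net$reactions$id))
  expect_gt(nrow(net$reactions), length(reg))  # plus uptake-chain/PDH/respiration
  ## carbon balance is validated at parse time; corrupting a reaction fails
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  lines <- readLines(mipflux_file("fig1_network.tsv"))
  lines <- sub("r_PDH\tPYR -> ACCOA\tFALSE\t0\t1\t0\t0\t1",
               "r_PDH\tPYR -> ACCOA\tFALSE\t0\t1\t0\t0\t0", lines, fixed = TRUE)
  writeLines(lines, bad)
  expect_error(parse_network(bad), "carbon imbalance.*r_PDH")
})

test_that("parse errors name the offending input", {
  dir <- withr::local_tempdir()
  met <- file.path(dir, "met.tsv")
  writeLines(c("id\tname\tbalanced\tcarbons", "A\ta\tTRUE\t1"), met)
  empty <- file.path(dir, "empty.tsv")
  writeLines("id\tequation\treversible\tATP\tNADH\tNADPH\tFADH2\tCO2", empty)
  expect_error(parse_network(empty, met), "no reactions")
  unk <- file.path(dir, "unk.tsv")
  writeLines(c("id\tequation\treversible\tATP\tNADH\tNADPH\tFADH2\tCO2",
               "v1\tA -> Z\tFALSE\t0\t0\t0\t0\t0"), unk)
  expect_error(parse_network(unk, met), "unknown metabolite Z")
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("id\tequation\treversible\tATP\tNADH\tNADPH\tFADH2\tCO2",
               "v1\tA -> A\tFALSE\t1\t0\t0\t0\t0",
               "v1\tA -> A\tFALSE\t1\t0\t0\t0\t0"), dup)
  expect_error(parse_network(dup, met), "duplicate reaction ids")
})

test_that("toy chain assembles to a 1 x 2 balance matrix", {
  net <- toy_chain_network()
  sys <- assemble_system(net)
  expect_equal(dim(sys$A), c(1L, 2L))
  expect_equal(unname(sys$A["B", ]), c(1, -1))
  ## fully determined chain: zero degrees of freedom given one equality
  expect_equal(degrees_of_freedom(sys, "v1"), 0L)
})

test_that("assembly is invariant to reaction declaration order", {
  dir <- withr::local_tempdir()
  lines <- readLines(mipflux_file("fig1_network.tsv"))
  hdr <- grep("^id\t", lines)
  body <- lines[(hdr + 1):length(lines)]
  perm <- file.path(dir, "perm.tsv")
  set.seed(11)
  writeLines(c(lines[seq_len(hdr)], sample(body)), perm)
  s1 <- assemble_system(parse_network())
  s2 <- assemble_system(parse_network(perm))
  expect_setequal(colnames(s1$A), colnames(s2$A))
  expect_equal(s1$A[, colnames(s1$A)], s2$A[rownames(s1$A), colnames(s1$A)])
})

test_that("degrees of freedom match the row-reduction oracle", {
  st <- study_setup()
  sys <- st$system
  ## phenotype equalities (lactate = 0, acetate = 1) leave two free fluxes
  expect_equal(degrees_of_freedom(sys, st$bounds), 2L)
  oracle <- function(ids) {
    eq <- t(sapply(ids, function(f) as.numeric(sys$flux_order == f)))
    length(sys$flux_order) - rref_rank(rbind(sys$A, eq))
  }
  expect_equal(degrees_of_freedom(sys, c("r_LAC", "r_ACE")), oracle(c("r_LAC", "r_ACE")))
  ## dropping the acetate equality frees one more dimension
  expect_equal(degrees_of_freedom(sys, "r_LAC"), 3L)
  expect_equal(degrees_of_freedom(sys, "r_LAC"), oracle("r_LAC"))
  ## transhydrogenase adds a degree of freedom
  sys_thd <- assemble_system(add_transhydrogenase(parse_network()))
  expect_equal(degrees_of_freedom(sys_thd, c("r_LAC", "r_ACE")), 3L)
})

test_that("derived fluxes: zeros, TCA-turn bookkeeping, missing ids", {
  sys <- assemble_system(parse_network())
  z <- stats::setNames(rep(0, length(sys$flux_order)), sys$flux_order)
  expect_equal(unname(derived_fluxes(z, sys)), rep(0, 5))
  ## one TCA turn (entry + lower lump + MDH), NADH/FADH2 routed to respiration:
  ## 1 substrate-level ATP, 2 NADH (P/O 2.0) and 1 FADH2 (P/O 1.0) oxidized
  v <- z
  v[c("r_TCA", "r_OGDH", "r_MDH")] <- 1
  v["r_RESPN"] <- 2; v["r_RESPF"] <- 1
  d <- derived_fluxes(v, sys)
  expect_equal(unname(d["r_ATP"]), 1 + 2 * 2 + 1 * 1)
  expect_equal(unname(d["NADH"]), 2)    # alpha-KG dehydrogenase lump + MDH
  expect_equal(unname(d["NADPH"]), 1)   # NADP-linked isocitrate dehydrogenase
  expect_equal(unname(d["FADH2"]), 1)
  expect_equal(unname(d["r_CO2"]), 2)
  ## P/O ratios scale the oxidative share linearly
  expect_equal(unname(derived_fluxes(v, sys, po_nadh = 1, po_fadh = 0)["r_ATP"]), 3)
  expect_error(derived_fluxes(v[-1], sys), "missing flux id")
})
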