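#' Read a macromolecular composition table
#'
#' Columns: `macromolecule`, `mass_fraction` (g/g cell), `residue_mass`
#' (g/mmol residue), `precursors` (semicolon-separated `id:coeff`, mol
#' precursor per mol residue; negative NADH coefficients denote net NADH
#' release by biosynthesis), `atp_per_bond` and `atp_per_denovo` (ATP per
#' polymerized bond / per de novo monomer).
#'
#' @param path Composition file; defaults to the bundled E. coli table.
#' @return An object of class `"composition"`.
#' @export
read_composition <- function(path = mipflux_file("ecoli_composition.tsv")) {
  cm <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(cm$mass_fraction < 0)) stop("negative mass fraction", call. = FALSE)
  if (sum(cm$mass_fraction) > 1 + 1e-9) stop("mass fractions sum to > 1", call. = FALSE)
  if (any(cm$residue_mass <= 0)) stop("residue masses must be positive", call. = FALSE)
  cm$precursors <- lapply(cm$precursors, function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    stats::setNames(vapply(kv, function(x) as.numeric(x[2]), 0),
                    vapply(kv, `[`, "", 1))
  })
  for (i in seq_len(nrow(cm))) {
    p <- cm$precursors[[i]]
    bad <- p[names(p) != "NADH" & p < 0]
    if (length(bad)) stop("negative precursor coefficient in ",
                          cm$macromolecule[i], call. = FALSE)
  }
  structure(cm, class = c("composition", "data.frame"))
}

#' Polymerization cost parameters
#'
#' ATP accounting knobs for the load vector: per-bond polymerization costs are
#' taken from the composition table (DNA about one third of protein per bond);
#' `denovo_dntp_atp` is the de novo cost per dNTP; `rna_recycle` is the
#' fraction of RNA-turnover monomers that are salvaged (reducing the net
#' precursor demand of turnover while still paying repolymerization ATP), and
#' `rna_turnover` the first-order turnover rate of the RNA pool.
#'
#' @param denovo_dntp_atp ATP per de novo dNTP (about 10).
#' @param rna_recycle Salvage fraction in `[0, 1]`.
#' @param rna_turnover RNA-pool turnover expressed per unit net synthesis
#'   (dimensionless: the turnover flux is this multiple of the growth-coupled
#'   RNA synthesis flux, so the load stays homogeneous in the growth rate).
#' @return A list of class `"polymerization_costs"`.
#' @export
polymerization_costs <- function(denovo_dntp_atp = 10, rna_recycle = 0.8,
                                 rna_turnover = 0.25) {
  stopifnot(denovo_dntp_atp >= 0, rna_recycle >= 0, rna_recycle <= 1,
            rna_turnover >= 0)
  structure(list(denovo_dntp_atp = denovo_dntp_atp, rna_recycle = rna_recycle,
                 rna_turnover = rna_turnover), class = "polymerization_costs")
}

#' Biosynthetic load vector at a given growth rate
#'
#' Converts the cell composition into the right-hand side `b` of the balance
#' equations: for every precursor `p`,
#' `b[p] = mu * sum_m fraction_m / residue_mass_m * stoich_m[p]`
#' (mmol per g cell per h), plus the non-salvaged share of RNA turnover
#' (itself growth-coupled).
#' Every entry is linear in `mu`. The aggregate ATP cost of polymerization,
#' de novo dNTP synthesis and RNA repolymerization is carried separately in
#' `atp_demand` (it does not enter the balance matrix; the phenotype ATP
#' window constrains gross production).
#'
#' @param composition A `"composition"`.
#' @param costs A `"polymerization_costs"`.
#' @param mu Specific growth rate, 1/h (>= 0).
#' @return An object of class `"load_vector"`: list with `b` (named demand
#'   vector, mmol/g cell/h), `atp_demand`, `mu`, and the DNA-attributable
#'   share `dna_b` used by [scale_dna_load()].
#' @export
compute_load_vector <- function(composition = read_composition(),
                                costs = polymerization_costs(), mu) {
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  b <- numeric(0); atp <- 0; dna_b <- numeric(0); dna_atp <- 0
  for (i in seq_len(nrow(composition))) {
    mmol <- composition$mass_fraction[i] / composition$residue_mass[i]  # mmol residues / g cell
    p <- composition$precursors[[i]]
    contrib <- mu * mmol * p
    for (id in names(contrib)) b[id] <- (if (id %in% names(b)) b[id] else 0) + contrib[[id]]
    bond_atp <- mu * mmol * composition$atp_per_bond[i]
    denovo <- mu * mmol * composition$atp_per_denovo[i]
    atp <- atp + bond_atp + denovo
    if (composition$macromolecule[i] == "dna") { dna_b <- contrib; dna_atp <- bond_atp + denovo }
    if (composition$macromolecule[i] == "rna" && costs$rna_turnover > 0) {
      turn <- costs$rna_turnover * mu * mmol        # mmol monomers turned over / g h
      extra <- (1 - costs$rna_recycle) * turn * p   # non-salvaged de novo share
      for (id in names(extra)) b[id] <- (if (id %in% names(b)) b[id] else 0) + extra[[id]]
      atp <- atp + costs$rna_recycle * turn * composition$atp_per_bond[i]  # repolymerization
    }
  }
  structure(list(b = b, atp_demand = atp, mu = mu, dna_b = dna_b,
                 dna_atp = dna_atp, dna_factor = 1),
            class = "load_vector")
}

#' @export
print.load_vector <- function(x, ...) {
  cat("load_vector at mu =", x$mu, "1/h;",
      length(x$b), "precursor demands; atp_demand =",
      round(x$atp_demand, 3), "mmol/g h\n")
  invisible(x)
}

#' Expand a load vector over the balanced metabolites of a system
#'
#' @param load A `"load_vector"` (or a bare named numeric vector).
#' @param system A `"stoich_system"`.
#' @return Named vector `b` over `rownames(system$A)` (zeros where no demand).
#' @export
load_as_b <- function(load, system) {
  b <- stats::setNames(rep(0, nrow(system$A)), rownames(system$A))
  src <- if (inherits(load, "load_vector")) load$b else load
  keep <- intersect(names(src), names(b))
  b[keep] <- src[keep]
  b
}

#' DNA precursor load
#'
#' Combined R5P + 3PG + OAA demand attributable to deoxyribonucleotide
#' synthesis at growth rate `mu` (mmol/g cell/h). With the default
#' composition (3.1% DNA, 50% GC, purine dNTP = R5P + 3PG, pyrimidine dNTP =
#' R5P + OAA) this is 0.04 at one significant figure for `mu = 0.2`, small
#' against the glucose flux of about 2.5.
#'
#' @inheritParams compute_load_vector
#' @param genome_equivalents_extra Extra DNA expressed in genome equivalents
#'   (0 for the plasmid-free chromosome complement).
#' @param genomes_per_cell Chromosome equivalents per cell at this growth
#'   rate (converts genome equivalents to mass fraction); default 1.8.
#' @return Demand flux in mmol/g cell/h.
#' @export
dna_precursor_load <- function(composition = read_composition(), mu,
                               genome_equivalents_extra = 0,
                               genomes_per_cell = 1.8) {
  i <- match("dna", composition$macromolecule)
  if (is.na(i) || composition$mass_fraction[i] <= 0)
    stop("composition has no DNA fraction", call. = FALSE)
  mmol <- composition$mass_fraction[i] / composition$residue_mass[i]
  p <- composition$precursors[[i]]
  per_unit <- mu * mmol * sum(p[intersect(names(p), c("R5P", "PG3", "OAA"))])
  scale <- 1 + genome_equivalents_extra / genomes_per_cell
  unname(per_unit * scale)
}

#' Genome equivalents of plasmid DNA
#'
#' `pcn * plasmid_bp / genome_bp`: how many chromosome-lengths of extra DNA a
#' plasmid population represents (7000 copies of a 3.7 kb plasmid in a 4.6 Mb
#' genome are 5.6 genome equivalents).
#'
#' @param pcn Plasmid copy number per cell (> 0 unless 0).
#' @param plasmid_bp Plasmid length, bp.
#' @param genome_bp Genome length, bp.
#' @return Dimensionless genome equivalents.
#' @export
genome_equivalents <- function(pcn, plasmid_bp, genome_bp) {
  if (plasmid_bp <= 0 || genome_bp <= 0) stop("lengths must be positive", call. = FALSE)
  if (pcn < 0) stop("pcn must be >= 0", call. = FALSE)
  pcn * plasmid_bp / genome_bp
}

#' Scale the DNA-attributable share of a load vector
#'
#' Multiplies only the DNA-attributable precursor demands (and the dNTP ATP
#' share of `atp_demand`) by `factor`, leaving all other entries untouched.
#' Factors compose multiplicatively.
#'
#' @param load A `"load_vector"`.
#' @param factor Non-negative multiplier (3 for the three-fold DNA burden
#'   robustness test).
#' @return The scaled `"load_vector"`.
#' @export
scale_dna_load <- function(load, factor) {
  if (factor < 0) stop("factor must be >= 0", call. = FALSE)
  delta <- (factor - 1) * load$dna_b
  for (id in names(delta)) load$b[id] <- load$b[id] + delta[[id]]
  load$atp_demand <- load$atp_demand + (factor - 1) * load$dna_atp
  load$dna_b <- factor * load$dna_b
  load$dna_atp <- factor * load$dna_atp
  load$dna_factor <- load$dna_factor * factor
  load
}
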