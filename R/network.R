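#' Path to a bundled data file
#'
#' Convenience accessor for the data files shipped with the package: the
#' central-metabolism reaction table (`"fig1_network.tsv"`), its metabolite
#' and carbon-count registry (`"fig1_metabolites.tsv"`), the E. coli
#' macromolecular composition (`"ecoli_composition.tsv"`), the transcribed
#' published scenario table (`"table1_scenarios.tsv"`) and the phenotype
#' configuration (`"paper_phenotype.yaml"`).
#'
#' @param file File name within the package's `extdata` directory.
#' @return Absolute path to the file.
#' @export
mipflux_file <- function(file) {
  p <- system.file("extdata", file, package = "mipflux", mustWork = FALSE)
  if (!nzchar(p)) stop("no bundled file '", file, "'", call. = FALSE)
  p
}

parse_equation <- function(eq) {
  ## "GLC + PEP -> G6P + PYR" or "-" for cofactor-only reactions
  eq <- trimws(eq)
  if (eq == "-" || eq == "") return(numeric(0))
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("malformed equation: '", eq, "'", call. = FALSE)
  out <- numeric(0)
  for (k in 1:2) {
    terms <- strsplit(sides[k], "+", fixed = TRUE)[[1]]
    for (tm in terms) {
      tm <- trimws(tm)
      if (!nzchar(tm)) next
      mm <- regmatches(tm, regexec("^([0-9.]+[ ]+)?([A-Za-z][A-Za-z0-9_]*)$", tm))[[1]]
      if (length(mm) == 0L) stop("malformed term '", tm, "' in equation '", eq, "'", call. = FALSE)
      coef <- if (nzchar(trimws(mm[2]))) as.numeric(mm[2]) else 1
      id <- mm[3]
      out[id] <- (if (id %in% names(out)) out[id] else 0) + (if (k == 1L) -coef else coef)
    }
  }
  out[out != 0]
}

COFACTORS <- c("ATP", "NADH", "NADPH", "FADH2", "CO2")

#' Parse a reaction-table file and its metabolite registry
#'
#' Reads a delimited reaction table (columns `id`, `equation`, `reversible`,
#' and the cofactor yields `ATP`, `NADH`, `NADPH`, `FADH2`, `CO2`) together
#' with a metabolite table (columns `id`, `name`, `balanced`, `carbons`),
#' validates identifiers and checks the carbon balance of every reaction
#' (carbon in substrates equals carbon in products plus the signed CO2 yield).
#'
#' @param path Reaction-table file; defaults to the bundled central-metabolism
#'   network.
#' @param metabolite_path Metabolite/carbon-count table; defaults to the
#'   bundled registry.
#' @return An object of class `"flux_network"`: a list with `reactions`
#'   (data frame with list-column `stoichiometry`) and `metabolites`.
#' @export
parse_network <- function(path = mipflux_file("fig1_network.tsv"),
                          metabolite_path = mipflux_file("fig1_metabolites.tsv")) {
  if (!file.exists(path)) stop("network file not found: ", path, call. = FALSE)
  rx <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  mets <- utils::read.delim(metabolite_path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(rx) == 0L) stop("no reactions", call. = FALSE)
  if (anyDuplicated(rx$id)) stop("duplicate reaction ids: ",
                                 paste(rx$id[duplicated(rx$id)], collapse = ", "), call. = FALSE)
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids", call. = FALSE)
  carbons <- stats::setNames(mets$carbons, mets$id)
  stoich <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    s <- parse_equation(rx$equation[i])
    unknown <- setdiff(names(s), mets$id)
    if (length(unknown))
      stop("line ", i, " (", rx$id[i], "): unknown metabolite ",
           paste(unknown, collapse = ", "), call. = FALSE)
    if (length(s) == 0L && all(rx[i, COFACTORS] == 0))
      stop("reaction ", rx$id[i], " has no nonzero coefficient", call. = FALSE)
    cbal <- sum(s * carbons[names(s)]) + rx$CO2[i]
    if (abs(cbal) > 1e-9)
      stop("carbon imbalance in reaction ", rx$id[i], " (", cbal, " C)", call. = FALSE)
    stoich[[i]] <- s
  }
  rx$stoichiometry <- stoich
  structure(list(reactions = rx, metabolites = mets),
            class = "flux_network")
}

#' @export
print.flux_network <- function(x, ...) {
  cat("flux_network: ", nrow(x$reactions), " reactions, ",
      sum(x$metabolites$balanced), " balanced of ", nrow(x$metabolites),
      " metabolites\n", sep = "")
  invisible(x)
}

#' Assemble a stoichiometric system from a parsed network
#'
#' Builds the matrix `A` of the balance equations `A r = b`, with one row per
#' balanced metabolite (redox cofactors NADH/NADPH/FADH2 are balanced pools
#' whose coefficients come from the cofactor-yield columns) and one column per
#' reaction in declaration order. Respiration sinks (reactions whose only
#' action is consuming one NADH or one FADH2) are identified so ATP production
#' can be credited at the configured P/O ratios.
#'
#' @param network A `"flux_network"` from [parse_network()], or arguments to it.
#' @return An object of class `"stoich_system"`: list with `A`, `flux_order`,
#'   `carbon_counts`, cofactor-yield matrix `cofactors`, `respiration`
#'   (named flux ids for NADH/FADH2 oxidation) and `reversible`.
#' @export
assemble_system <- function(network = parse_network()) {
  rx <- network$reactions; mets <- network$metabolites
  bal <- mets$id[as.logical(mets$balanced)]
  flux_order <- rx$id
  A <- matrix(0, length(bal), length(flux_order), dimnames = list(bal, flux_order))
  cof <- as.matrix(rx[, COFACTORS]); rownames(cof) <- rx$id
  for (i in seq_len(nrow(rx))) {
    s <- rx$stoichiometry[[i]]
    keep <- intersect(names(s), bal)
    A[keep, i] <- s[keep]
    for (cf in c("NADH", "NADPH", "FADH2"))
      if (cf %in% bal) A[cf, i] <- A[cf, i] + cof[i, cf]
  }
  resp <- c(NADH = NA_character_, FADH2 = NA_character_)
  for (i in seq_len(nrow(rx))) {
    if (length(rx$stoichiometry[[i]]) == 0L) {
      if (cof[i, "NADH"] == -1 && all(cof[i, setdiff(COFACTORS, "NADH")] == 0))
        resp["NADH"] <- rx$id[i]
      if (cof[i, "FADH2"] == -1 && all(cof[i, setdiff(COFACTORS, "FADH2")] == 0))
        resp["FADH2"] <- rx$id[i]
    }
  }
  structure(list(A = A, flux_order = flux_order,
                 carbon_counts = stats::setNames(mets$carbons, mets$id),
                 cofactors = cof, respiration = resp,
                 reversible = stats::setNames(as.logical(rx$reversible), rx$id)),
            class = "stoich_system")
}

#' @export
print.stoich_system <- function(x, ...) {
  cat("stoich_system: ", nrow(x$A), " balanced metabolites x ",
      ncol(x$A), " fluxes; ", sum(x$reversible), " reversible\n", sep = "")
  invisible(x)
}

#' Degrees of freedom of the constrained flux system
#'
#' Number of fluxes minus the rank of the stoichiometric matrix stacked with
#' the equality-constraint rows. With the bundled network and the phenotype
#' equalities (lactate = 0, acetate fixed) this is 2: two flux values resolve
#' the whole distribution.
#'
#' @param system A `"stoich_system"`.
#' @param equalities Either a matrix of equality rows over
#'   `system$flux_order`, a character vector of flux ids fixed to a value, or
#'   a `"bound_set"` (rows are taken where lower == upper).
#' @return Integer degrees of freedom.
#' @export
degrees_of_freedom <- function(system, equalities = NULL) {
  rows <- system$A
  n <- length(system$flux_order)
  eq <- NULL
  if (inherits(equalities, "bound_set")) {
    fixed <- names(which(equalities$lower == equalities$upper))
    fixed <- intersect(fixed, system$flux_order)
    equalities <- fixed
  }
  if (is.character(equalities)) {
    eq <- matrix(0, length(equalities), n)
    for (i in seq_along(equalities)) eq[i, match(equalities[i], system$flux_order)] <- 1
  } else if (is.matrix(equalities)) eq <- equalities
  if (!is.null(eq)) rows <- rbind(rows, eq)
  n - qr(rows)$rank
}

#' Derived fluxes: net CO2, total ATP production and redox totals
#'
#' `r_CO2` is the signed sum of the per-reaction CO2 yields (anaplerotic
#' fixation counts negatively). `r_ATP` is total (gross) ATP production:
#' net substrate-level phosphorylation from the ATP yield column plus
#' oxidative phosphorylation credited at `po_nadh` per NADH and `po_fadh`
#' per FADH2 routed through the respiration sinks. Redox totals are the
#' production by non-respiratory reactions (equal, at steady state, to the
#' respiratory consumption plus any biosynthetic credit in the load vector).
#'
#' @param flux_vector Named numeric vector over `system$flux_order` (a full
#'   flux distribution).
#' @param system A `"stoich_system"`.
#' @param po_nadh,po_fadh P/O ratios (ATP per NADH, per FADH2); defaults 2.0
#'   and 1.0.
#' @return Named vector with `r_CO2`, `r_ATP`, `NADH`, `NADPH`, `FADH2`.
#' @export
derived_fluxes <- function(flux_vector, system, po_nadh = 2, po_fadh = 1) {
  miss <- setdiff(system$flux_order, names(flux_vector))
  if (length(miss)) stop("missing flux id(s): ", paste(miss, collapse = ", "), call. = FALSE)
  v <- flux_vector[system$flux_order]
  cof <- system$cofactors[system$flux_order, , drop = FALSE]
  resp <- system$respiration
  r_co2 <- sum(cof[, "CO2"] * v)
  r_atp <- sum(cof[, "ATP"] * v)
  if (!is.na(resp["NADH"])) r_atp <- r_atp + po_nadh * v[resp["NADH"]]
  if (!is.na(resp["FADH2"])) r_atp <- r_atp + po_fadh * v[resp["FADH2"]]
  nonresp <- setdiff(system$flux_order, stats::na.omit(resp))
  tot <- function(cf) sum(pmax(cof[nonresp, cf], 0) * pmax(v[nonresp], 0)) -
    sum(pmax(-cof[nonresp, cf], 0) * pmax(v[nonresp], 0))
  c(r_CO2 = unname(r_co2), r_ATP = unname(r_atp),
    NADH = tot("NADH"), NADPH = tot("NADPH"), FADH2 = tot("FADH2"))
}

#' Linear ATP-production coefficients over the flux order
#'
#' The gross ATP production `r_ATP` is linear in the fluxes; this returns its
#' coefficient vector (ATP yield column plus P/O-weighted respiration).
#'
#' @inheritParams derived_fluxes
#' @return Named numeric vector over `system$flux_order`.
#' @export
atp_coefficients <- function(system, po_nadh = 2, po_fadh = 1) {
  a <- stats::setNames(system$cofactors[system$flux_order, "ATP"], system$flux_order)
  resp <- system$respiration
  if (!is.na(resp["NADH"])) a[resp["NADH"]] <- a[resp["NADH"]] + po_nadh
  if (!is.na(resp["FADH2"])) a[resp["FADH2"]] <- a[resp["FADH2"]] + po_fadh
  a
}

#' Add a bounded transhydrogenase flux to a parsed network
#'
#' Appends an NADH -> NADPH conversion (`r_THD`). The default model omits it
#' (cap 0), which keeps the system at two degrees of freedom under the
#' phenotype equalities; a positive cap adds one degree of freedom and lets
#' transhydrogenase substitute for HMP/isocitrate dehydrogenase/malic enzyme
#' NADPH supply. The cap itself is enforced through the bound set.
#'
#' @param network A `"flux_network"`.
#' @return The network with the `r_THD` reaction appended.
#' @export
add_transhydrogenase <- function(network) {
  rx <- network$reactions
  if ("r_THD" %in% rx$id) return(network)
  row <- rx[1, ]
  row$id <- "r_THD"; row$equation <- "-"; row$reversible <- FALSE
  row[COFACTORS] <- 0; row$NADH <- -1; row$NADPH <- 1
  row$stoichiometry <- list(numeric(0))
  network$reactions <- rbind(rx, row)
  network
}
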