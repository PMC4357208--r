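#' Phenotype measurements with resolution bounds
#'
#' Collects the measured phenotype that defines a macroscopically
#' indistinguishable phenotype (MIP): growth rate, biomass yield on glucose
#' with its resolution window, the ATP-yield window, byproduct fluxes and the
#' P/O ratios. Defaults are the study conditions: `mu = 0.2` 1/h, `Y_X/S`
#' 0.42 +/- 0.03 g/g, `Y_X/ATP` in [7, 10] g/mol, acetate about 1 mmol/g h
#' (fixed in `"tight"` mode, in [0.8, 1.2] in `"loose"` mode), no lactate.
#'
#' @param mu Growth rate, 1/h (> 0).
#' @param yxs_range Biomass yield on glucose, g cell/g glucose, `c(low, high)`.
#' @param yxatp_range Biomass yield on ATP, g cell/mol ATP, `c(low, high)`.
#' @param acetate_mode `"tight"` (equality) or `"loose"` (range).
#' @param acetate Acetate flux, mmol/g h (tight mode).
#' @param acetate_range Acetate range (loose mode).
#' @param lactate Lactate flux, mmol/g h (an equality; 0 as measured).
#' @param po_nadh,po_fadh P/O ratios for NADH and FADH2.
#' @param glucose_mw Glucose molar mass, g/mol.
#' @return Object of class `"phenotype_constraints"`.
#' @export
phenotype_constraints <- function(mu = 0.2, yxs_range = c(0.39, 0.45),
                                  yxatp_range = c(7, 10),
                                  acetate_mode = c("tight", "loose"),
                                  acetate = 1, acetate_range = c(0.8, 1.2),
                                  lactate = 0, po_nadh = 2, po_fadh = 1,
                                  glucose_mw = 180) {
  acetate_mode <- match.arg(acetate_mode)
  stopifnot(mu > 0, po_nadh > 0, po_fadh > 0,
            yxs_range[1] <= yxs_range[2], yxatp_range[1] <= yxatp_range[2],
            acetate_range[1] <= acetate_range[2])
  structure(list(mu = mu, yxs_range = yxs_range, yxatp_range = yxatp_range,
                 acetate_mode = acetate_mode, acetate = acetate,
                 acetate_range = acetate_range, lactate = lactate,
                 po_nadh = po_nadh, po_fadh = po_fadh,
                 glucose_mw = glucose_mw),
            class = "phenotype_constraints")
}

#' Read phenotype constraints from a YAML config
#'
#' Keys mirror the arguments of [phenotype_constraints()] (flat keys
#' `yxs_low`/`yxs_high`, `yxatp_low`/`yxatp_high`, `acetate_low`/`acetate_high`).
#'
#' @param path YAML file; defaults to the bundled study configuration.
#' @return A `"phenotype_constraints"`.
#' @export
read_phenotype_config <- function(path = mipflux_file("paper_phenotype.yaml")) {
  y <- yaml::read_yaml(path)
  phenotype_constraints(mu = y$mu, yxs_range = c(y$yxs_low, y$yxs_high),
                        yxatp_range = c(y$yxatp_low, y$yxatp_high),
                        acetate_mode = y$acetate_mode, acetate = y$acetate,
                        acetate_range = c(y$acetate_low, y$acetate_high),
                        lactate = y$lactate, po_nadh = y$po_nadh,
                        po_fadh = y$po_fadh, glucose_mw = y$glucose_mw)
}

#' Glucose-uptake bounds from the yield window
#'
#' `r_GLU = mu / (Y_X/S * MW_glc)` with the molar mass in g/mmol, so the
#' upper yield maps to the lower flux bound and vice versa: the window
#' 0.39-0.45 g/g at `mu = 0.2` gives uptake in [2.469, 2.849] mmol/g h.
#'
#' @param yxs_range Yield window, g cell/g glucose.
#' @param mu Growth rate, 1/h.
#' @param glucose_mw Glucose molar mass, g/mol.
#' @return `c(lower, upper)` in mmol/g cell/h.
#' @export
glucose_bounds <- function(yxs_range, mu, glucose_mw = 180) {
  if (any(yxs_range <= 0)) stop("yields must be positive", call. = FALSE)
  sort(mu / (yxs_range * glucose_mw / 1000))
}

#' ATP-production bounds from the ATP-yield window
#'
#' `r_ATP = 1000 * mu / Y_X/ATP`: the window [7, 10] g cell/mol ATP at
#' `mu = 0.2` gives production in [20, 28.57] (printed 28.6) mmol/g h.
#'
#' @param yxatp_range Yield window, g cell/mol ATP.
#' @param mu Growth rate, 1/h.
#' @return `c(lower, upper)` in mmol/g cell/h (full precision; display may
#'   round).
#' @export
atp_bounds <- function(yxatp_range, mu) {
  if (any(yxatp_range <= 0)) stop("yields must be positive", call. = FALSE)
  sort(1000 * mu / yxatp_range)
}

#' Build the per-flux bound set for a system under a measured phenotype
#'
#' Encodes the phenotype window as flux bounds: lactate fixed, acetate fixed
#' (tight) or ranged (loose), glucose uptake bounded by the yield window,
#' total ATP production bounded by the ATP-yield window (as a linear
#' expression over fluxes, kept separately in `atp`), irreversible fluxes
#' non-negative, reversible fluxes free, and a numerical box cap on all
#' fluxes to keep LPs bounded. Equalities are encoded as `lower == upper`.
#'
#' @param system A `"stoich_system"`.
#' @param constraints A `"phenotype_constraints"`.
#' @param thd_cap Upper bound for the transhydrogenase flux if the system
#'   includes one (default 0: off).
#' @param box Numerical cap on every flux magnitude (mmol/g h).
#' @return Object of class `"bound_set"`: `lower`/`upper` per flux plus the
#'   `atp` element (`coef`, `lower`, `upper`).
#' @export
build_bounds <- function(system, constraints, thd_cap = 0, box = 100) {
  fl <- system$flux_order
  lower <- stats::setNames(ifelse(system$reversible[fl], -box, 0), fl)
  upper <- stats::setNames(rep(box, length(fl)), fl)
  gb <- glucose_bounds(constraints$yxs_range, constraints$mu, constraints$glucose_mw)
  if ("r_GLU" %in% fl) { lower["r_GLU"] <- gb[1]; upper["r_GLU"] <- gb[2] }
  if ("r_LAC" %in% fl) { lower["r_LAC"] <- constraints$lactate; upper["r_LAC"] <- constraints$lactate }
  if ("r_ACE" %in% fl) {
    if (constraints$acetate_mode == "tight") {
      lower["r_ACE"] <- constraints$acetate; upper["r_ACE"] <- constraints$acetate
    } else {
      lower["r_ACE"] <- constraints$acetate_range[1]
      upper["r_ACE"] <- constraints$acetate_range[2]
    }
  }
  if ("r_THD" %in% fl) { lower["r_THD"] <- 0; upper["r_THD"] <- thd_cap }
  if (any(lower > upper)) stop("inconsistent bounds (lower > upper)", call. = FALSE)
  ab <- atp_bounds(constraints$yxatp_range, constraints$mu)
  structure(list(lower = lower, upper = upper,
                 atp = list(coef = atp_coefficients(system, constraints$po_nadh,
                                                    constraints$po_fadh),
                            lower = ab[1], upper = ab[2]),
                 mu = constraints$mu, glucose_mw = constraints$glucose_mw),
            class = "bound_set")
}

#' @export
print.bound_set <- function(x, ...) {
  fixed <- sum(x$lower == x$upper)
  cat("bound_set over", length(x$lower), "fluxes;", fixed, "equalities; ATP in [",
      round(x$atp$lower, 3), ",", round(x$atp$upper, 3), "]\n")
  invisible(x)
}
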