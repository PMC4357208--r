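## independent oracles and hand-built fixtures used across the suite

## Gaussian-elimination rank (independent of qr(), which the package uses)
rref_rank <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  r <- 0L
  for (j in seq_len(ncol(M))) {
    if (r == nrow(M)) break
    p <- which.max(abs(M[(r + 1):nrow(M), j])) + r
    if (abs(M[p, j]) < tol) next
    M[c(r + 1L, p), ] <- M[c(p, r + 1L), ]
    r <- r + 1L
    M[r, ] <- M[r, ] / M[r, j]
    for (i in setdiff(seq_len(nrow(M)), r)) M[i, ] <- M[i, ] - M[i, j] * M[r, ]
  }
  r
}

## brute-force vertex enumeration of {x >= 0, R x <= rhs, x <= up} in d <= 4
## dimensions by intersecting all d-subsets of candidate active constraints
brute_vertices <- function(R, rhs, up, tol = 1e-8) {
  d <- ncol(R)
  rows <- rbind(R, diag(d), -diag(d))         # R x <= rhs; x <= up; -x <= 0
  cons <- c(rhs, up, rep(0, d))
  idx <- utils::combn(nrow(rows), d)
  V <- NULL
  for (k in seq_len(ncol(idx))) {
    S <- rows[idx[, k], , drop = FALSE]
    if (abs(det(S)) < tol) next
    x <- solve(S, cons[idx[, k]])
    if (all(rows %*% x <= cons + 1e-7)) V <- rbind(V, x)
  }
  unique(round(V, 7))
}

## hand-built stoichiometric-style system wrapping {R x <= rhs} via slack
## fluxes: A = [R | I], so the package LP machinery sees a genuine A r = b
slack_system <- function(R, rhs, up) {
  d <- ncol(R); m <- nrow(R)
  fl <- c(paste0("x", seq_len(d)), paste0("s", seq_len(m)))
  A <- cbind(R, diag(m))
  rownames(A) <- paste0("c", seq_len(m)); colnames(A) <- fl
  cof <- matrix(0, length(fl), 5, dimnames = list(fl, c("ATP", "NADH", "NADPH", "FADH2", "CO2")))
  sys <- structure(list(A = A, flux_order = fl,
                        carbon_counts = stats::setNames(rep(1, length(fl)), fl),
                        cofactors = cof,
                        respiration = c(NADH = NA_character_, FADH2 = NA_character_),
                        reversible = stats::setNames(rep(FALSE, length(fl)), fl)),
                   class = "stoich_system")
  bounds <- structure(list(lower = stats::setNames(rep(0, length(fl)), fl),
                           upper = stats::setNames(c(up, rep(1e6, m)), fl),
                           atp = list(coef = stats::setNames(rep(0, length(fl)), fl),
                                      lower = -1, upper = 1),
                           mu = 0.2, glucose_mw = 180),
                      class = "bound_set")
  list(system = sys, bounds = bounds, b = stats::setNames(rhs, rownames(A)))
}

## the study system, calibrated once per test file that needs it
study_setup <- function() {
  sys <- assemble_system(parse_network())
  ph <- read_phenotype_config()
  bounds <- build_bounds(sys, ph)
  list(system = sys, phenotype = ph, bounds = bounds)
}

## tiny 3-reaction chain A -> B -> C with only B balanced
toy_chain_network <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  net <- file.path(dir, "net.tsv"); met <- file.path(dir, "met.tsv")
  writeLines(c("id\tequation\treversible\tATP\tNADH\tNADPH\tFADH2\tCO2",
               "v1\tA -> B\tFALSE\t0\t0\t0\t0\t0",
               "v2\tB -> C\tFALSE\t0\t0\t0\t0\t0"), net)
  writeLines(c("id\tname\tbalanced\tcarbons",
               "A\ta\tFALSE\t1", "B\tb\tTRUE\t1", "C\tc\tFALSE\t1"), met)
  parse_network(net, met)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
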