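## synthetic-data generators: replicate phenotype measurements with stated
## CVs, and host-vs-transformant proteome abundance tables with planted
## fold-changes, so that every analysis stage is testable without downloads.

#' Generate replicate phenotype measurements
#'
#' Draws `n_replicates` Gaussian measurements around the true phenotype at
#' the stated coefficients of variation (the study's resolution: about 7% on
#' the glucose yield, 20% on acetate). Seeded runs are bit-reproducible.
#'
#' @param truth Named vector with `mu` (1/h), `yxs` (g/g), `acetate`
#'   (mmol/g h), `lactate` (mmol/g h).
#' @param cv Coefficients of variation for the same four quantities
#'   (zero-CV measurements repeat the truth exactly).
#' @param n_replicates Number of replicate measurements.
#' @param seed Integer seed.
#' @return Data frame of replicates, one row per replicate, of class
#'   `"synthetic_phenotype"` with attribute `truth`.
#' @export
generate_phenotype <- function(truth = c(mu = 0.2, yxs = 0.42, acetate = 1, lactate = 0),
                               cv = c(mu = 0.05, yxs = 0.07, acetate = 0.2, lactate = 0),
                               n_replicates = 3, seed = 1) {
  stopifnot(all(cv >= 0), n_replicates >= 1)
  set.seed(seed)
  qs <- names(truth)
  out <- as.data.frame(lapply(qs, function(q)
    stats::rnorm(n_replicates, truth[[q]], abs(truth[[q]]) * cv[[q]])))
  names(out) <- qs
  out$replicate <- seq_len(n_replicates)
  structure(out, truth = truth, class = c("synthetic_phenotype", "data.frame"))
}

#' Summarize replicate phenotype measurements into constraints
#'
#' Means define the point phenotype; the yield window is mean +/- half the
#' observed range (falling back to the stated resolution when replicates
#' collapse). Lactate is fixed at its mean; acetate tight at its mean or
#' loose over the observed range.
#'
#' @param measurements A `"synthetic_phenotype"` (or compatible data frame).
#' @param acetate_mode `"tight"` or `"loose"`.
#' @param ... Passed to [phenotype_constraints()] (e.g. P/O ratios).
#' @return A `"phenotype_constraints"`.
#' @export
summarize_phenotype <- function(measurements, acetate_mode = "tight", ...) {
  m <- colMeans(measurements[c("mu", "yxs", "acetate", "lactate")])
  half <- function(q, fallback) {
    r <- (max(measurements[[q]]) - min(measurements[[q]])) / 2
    if (r > 0) r else fallback
  }
  phenotype_constraints(mu = m[["mu"]],
                        yxs_range = m[["yxs"]] + c(-1, 1) * half("yxs", 0.03),
                        acetate_mode = acetate_mode,
                        acetate = m[["acetate"]],
                        acetate_range = m[["acetate"]] + c(-1, 1) * half("acetate", 0.2),
                        lactate = m[["lactate"]], ...)
}

#' Generate a synthetic host-vs-transformant proteome table
#'
#' Protein abundances are log-normal around per-protein baselines
#' (`baseline_log_sd` on the natural-log scale); replicate measurement noise
#' is multiplicative log-normal with standard deviation `noise_sd`.
#' `n_down` + `n_up` proteins carry planted fold-changes in the transformant
#' (each at most 0.5 or at least 2.0, the screen's design thresholds; planting
#' a fold inside (0.5, 2) is an error). The default planted split, 40 down
#' and 29 up, mirrors the 69 differentially expressed proteins of the study.
#'
#' @param n_proteins Total number of proteins.
#' @param n_down,n_up Numbers of planted down-/up-regulated proteins.
#' @param fold_range Magnitude range the planted folds are drawn from
#'   (log-uniform); down-regulations use the reciprocal.
#' @param noise_sd Replicate log-normal noise SD (natural log).
#' @param baseline_log_sd Spread of per-protein baselines (natural log).
#' @param n_replicates Replicates per condition (the study used 2).
#' @param seed Integer seed.
#' @return Object of class `"proteome_table"`: list with `abundance` (matrix
#'   protein x sample), `condition`, `replicate`, and `truth` (per-protein
#'   planted fold and label `up`/`down`/`unchanged`).
#' @export
generate_proteome <- function(n_proteins = 1000, n_down = 40, n_up = 29,
                              fold_range = c(2.5, 8), noise_sd = 0.1,
                              baseline_log_sd = 1, n_replicates = 2, seed = 1) {
  stopifnot(n_down + n_up <= n_proteins, noise_sd >= 0)
  if (min(fold_range) < 2)
    stop("planted fold magnitudes must be >= 2 (screen design)", call. = FALSE)
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(n_proteins))
  baseline <- exp(stats::rnorm(n_proteins, log(1000), baseline_log_sd))
  fold <- rep(1, n_proteins)
  picks <- sample(n_proteins, n_down + n_up)
  lo <- log(fold_range[1]); hi <- log(fold_range[2])
  if (n_down) fold[picks[seq_len(n_down)]] <- 1 / exp(stats::runif(n_down, lo, hi))
  if (n_up) fold[picks[n_down + seq_len(n_up)]] <- exp(stats::runif(n_up, lo, hi))
  label <- ifelse(fold <= 0.5, "down", ifelse(fold >= 2, "up", "unchanged"))
  cond <- rep(c("host", "transformant"), each = n_replicates)
  repl <- rep(seq_len(n_replicates), 2)
  ab <- matrix(0, n_proteins, length(cond),
               dimnames = list(ids, paste(cond, repl, sep = "_")))
  for (j in seq_along(cond)) {
    mean_j <- baseline * (if (cond[j] == "transformant") fold else 1)
    ab[, j] <- mean_j * exp(stats::rnorm(n_proteins, 0, noise_sd))
  }
  structure(list(abundance = ab, condition = cond, replicate = repl,
                 truth = data.frame(protein = ids, fold = fold, label = label)),
            class = "proteome_table")
}

#' @export
print.proteome_table <- function(x, ...) {
  cat("proteome_table:", nrow(x$abundance), "proteins x", ncol(x$abundance),
      "samples;", sum(x$truth$label != "unchanged"), "planted changes\n")
  invisible(x)
}
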