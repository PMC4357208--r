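## differential-abundance screen: the study's rule — a protein changes if its
## transformant/host ratio is < 0.5 or > 2.0 AND the t-test gives p < 0.05.

#' Differential-abundance screen on a protein table
#'
#' For each protein: ratio of mean transformant to mean host abundance, a
#' Welch t-test on natural-log abundances, and the flag `down` (ratio < 0.5
#' and p < alpha), `up` (ratio > 2.0 and p < alpha) or `unchanged`. The
#' thresholds are strict inequalities (a ratio of exactly 1.9 or 2.0 is
#' unchanged). With two replicates per condition this is a screening
#' heuristic, exactly as applied in the study, not a calibrated test; an
#' optional Benjamini-Hochberg adjustment is available but off by default to
#' mirror the published criterion.
#'
#' @param table A `"proteome_table"` (or list with `abundance`, `condition`).
#' @param ratio_low,ratio_high Fold-change thresholds (0.5, 2.0).
#' @param alpha Significance level (0.05).
#' @param adjust Apply Benjamini-Hochberg FDR to the p-values first.
#' @param host,transformant Condition labels.
#' @return Data frame with `protein`, `ratio`, `p_value`, `flag`.
#' @export
screen_proteome <- function(table, ratio_low = 0.5, ratio_high = 2.0,
                            alpha = 0.05, adjust = FALSE,
                            host = "host", transformant = "transformant") {
  ab <- table$abundance
  if (any(ab <= 0)) stop("non-positive abundances", call. = FALSE)
  hcol <- table$condition == host
  tcol <- table$condition == transformant
  if (sum(hcol) < 2 || sum(tcol) < 2)
    stop("need at least two replicates per condition", call. = FALSE)
  hmean <- rowMeans(ab[, hcol, drop = FALSE])
  if (any(hmean == 0)) stop("zero host mean abundance", call. = FALSE)
  ratio <- rowMeans(ab[, tcol, drop = FALSE]) / hmean
  la <- log(ab)
  p <- vapply(seq_len(nrow(ab)), function(i) {
    x <- la[i, tcol]; y <- la[i, hcol]
    if (stats::sd(x) == 0 && stats::sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    stats::t.test(x, y)$p.value
  }, 0)
  if (adjust) p <- stats::p.adjust(p, method = "BH")
  flag <- rep("unchanged", nrow(ab))
  flag[ratio < ratio_low & p < alpha] <- "down"
  flag[ratio > ratio_high & p < alpha] <- "up"
  data.frame(protein = rownames(ab), ratio = ratio, p_value = p, flag = flag,
             row.names = NULL)
}

#' Replicate correlation within a condition
#'
#' Pearson correlation of natural-log abundances between the two replicates
#' of one condition (the study reported > 0.90 for the proteins surviving the
#' screen).
#'
#' @param table A `"proteome_table"`.
#' @param condition Condition label.
#' @param proteins Optional subset of protein ids.
#' @return Correlation coefficient.
#' @export
replicate_correlation <- function(table, condition = "host", proteins = NULL) {
  cols <- which(table$condition == condition)
  if (length(cols) != 2) stop("need exactly two replicates", call. = FALSE)
  ab <- table$abundance
  if (!is.null(proteins)) ab <- ab[proteins, , drop = FALSE]
  stats::cor(log(ab[, cols[1]]), log(ab[, cols[2]]))
}

#' Recall and precision of a screen against planted truth
#'
#' @param result Data frame from [screen_proteome()].
#' @param truth Data frame with `protein` and `label` (as in
#'   `proteome_table$truth`).
#' @return Named vector `recall`, `precision`, `n_flagged`.
#' @export
screen_performance <- function(result, truth) {
  tr <- truth$label[match(result$protein, truth$protein)]
  planted <- tr != "unchanged"
  flagged <- result$flag != "unchanged"
  hit <- flagged & planted & (result$flag == tr)
  c(recall = sum(hit) / max(1, sum(planted)),
    precision = sum(hit) / max(1, sum(flagged)),
    n_flagged = sum(flagged))
}
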