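#' Total-sum normalisation of an iBAQ matrix
#'
#' Divides every sample (column) by its total intensity so that each column
#' sums to 1, removing per-sample loading/acquisition differences.
#'
#' @param mat Non-negative numeric matrix, proteins x samples (rownames =
#'   protein ids).
#' @return Matrix of the same shape with unit column sums. Idempotent.
#' @export
total_sum_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("iBAQ values must be >= 0")
  tot <- colSums(mat)
  bad <- colnames(mat)[tot <= 0]
  if (length(bad) > 0L)
    stop("zero total intensity in sample(s): ", paste(bad, collapse = ", "))
  sweep(mat, 2, tot, "/")
}

#' IP-MS enrichment scores (t-test and median log10 fold change)
#'
#' Normalised iBAQ values are log10 transformed (to obtain approximate
#' normality) after flooring zeros, then each protein is tested bait-IP
#' versus control with a two-sided equal-variance Student's t-test; the fold
#' change is the difference of group medians of the transformed values
#' (log10 units). Proteins with fewer than 2 finite values in either group
#' are flagged untestable.
#'
#' @param mat Total-sum-normalised matrix (see [total_sum_normalize()]).
#' @param groups Character vector (one per column) with labels `"bait_IP"`
#'   and `"control"`.
#' @param floor Positive value replacing zeros before log; default half the
#'   smallest nonzero normalised value in the matrix.
#' @return data.frame: `protein`, `p_value`, `median_log10_fc`, `testable`.
#' @export
enrichment_scores <- function(mat, groups, floor = NULL) {
  mat <- as.matrix(mat)
  if (length(groups) != ncol(mat))
    stop("'groups' must have one label per sample")
  if (!all(groups %in% c("bait_IP", "control")))
    stop("group labels must be 'bait_IP' or 'control'")
  if (is.null(floor)) {
    nz <- mat[!is.na(mat) & mat > 0]
    if (length(nz) == 0L) stop("matrix is all zero")
    floor <- min(nz) / 2
  }
  if (floor <= 0) stop("'floor' must be > 0")
  lx <- log10(pmax(mat, floor))
  bait <- lx[, groups == "bait_IP", drop = FALSE]
  ctrl <- lx[, groups == "control", drop = FALSE]

  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    b <- bait[i, ][is.finite(bait[i, ])]
    c_ <- ctrl[i, ][is.finite(ctrl[i, ])]
    if (length(b) < 2L || length(c_) < 2L)
      return(c(NA_real_, NA_real_, 0))
    p <- if (stats::sd(b) == 0 && stats::sd(c_) == 0) {
      if (isTRUE(all.equal(mean(b), mean(c_)))) 1 else 0
    } else {
      stats::t.test(b, c_, var.equal = TRUE)$p.value
    }
    c(p, stats::median(b) - stats::median(c_), 1)
  }, numeric(3)))
  data.frame(protein = rownames(mat),
             p_value = res[, 1],
             median_log10_fc = res[, 2],
             testable = res[, 3] == 1,
             row.names = NULL)
}

#' Rank candidate complex members
#'
#' Proteins passing both cutoffs (p below `p_cut`, median log10 fold change
#' above `fc_cut`), ordered by fold change descending.
#'
#' @param scores An [enrichment_scores()] result.
#' @param p_cut p-value cutoff.
#' @param fc_cut Log10 fold-change cutoff (enrichment in the bait IP).
#' @return Subset of `scores`, ranked.
#' @export
rank_candidates <- function(scores, p_cut = 0.01, fc_cut = 0) {
  hit <- scores$testable & !is.na(scores$p_value) &
    scores$p_value < p_cut & scores$median_log10_fc > fc_cut
  out <- scores[hit, , drop = FALSE]
  out[order(out$median_log10_fc, decreasing = TRUE), , drop = FALSE]
}
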