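#' Small RNA count table with sample annotation
#'
#' Container for gene x sample small-RNA counts together with the per-sample
#' normalisation denominators: `unique_mapped_total` (uniquely mapping reads,
#' used for reads-per-million) and optionally `h2b_total` (histone-2B-mapping
#' reads, used for piRNA-sensor normalisation), plus genotype labels.
#'
#' @param counts Non-negative integer matrix, genes in rows (rownames = gene
#'   ids), samples in columns.
#' @param samples data.frame with columns `sample`, `genotype`,
#'   `unique_mapped_total` (> 0) and optionally `h2b_total`; one row per
#'   column of `counts`, matched by `sample`.
#' @return Object of class `small_rna_table`.
#' @export
small_rna_table <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("'counts' needs gene ids as rownames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  req <- c("sample", "genotype", "unique_mapped_total")
  if (!all(req %in% names(samples)))
    stop("'samples' needs columns: ", paste(req, collapse = ", "))
  if (!setequal(samples$sample, colnames(counts)))
    stop("sample names must match count matrix columns")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  bad <- samples$sample[samples$unique_mapped_total <= 0]
  if (length(bad) > 0L)
    stop("zero unique-mapped total for sample(s): ",
         paste(bad, collapse = ", "))
  structure(list(counts = counts, samples = samples),
            class = "small_rna_table")
}

#' @export
print.small_rna_table <- function(x, ...) {
  cat(sprintf("small_rna_table: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(unique(x$samples$genotype), collapse = ", ")))
  invisible(x)
}

#' Reads-per-million normalisation
#'
#' Corrects each sample for library size using its uniquely mapping read
#' total: `rpm = count * 1e6 / unique_mapped_total`.
#'
#' @param table A [small_rna_table()].
#' @return Object of class `abundance_table`: list with `rpm` matrix and the
#'   `samples` annotation.
#' @examples
#' tab <- small_rna_table(
#'   matrix(c(50L, 100L), 1, 2, dimnames = list("g1", c("s1", "s2"))),
#'   data.frame(sample = c("s1", "s2"), genotype = "wt",
#'              unique_mapped_total = c(1e6, 2e6)))
#' rpm_normalize(tab)$rpm   # both 50 rpm
#' @export
rpm_normalize <- function(table) {
  stopifnot(inherits(table, "small_rna_table"))
  rpm <- sweep(table$counts, 2, table$samples$unique_mapped_total, "/") * 1e6
  structure(list(rpm = rpm, samples = table$samples),
            class = "abundance_table")
}

#' Expression filter: genes over a mean-rpm threshold
#'
#' Keeps genes whose mean rpm across all samples is strictly greater than
#' `threshold_rpm` (default 50, the "over 50 reads per million on average
#' across all samples" cutoff).
#'
#' @param ab An [rpm_normalize()] result.
#' @param threshold_rpm Mean-rpm cutoff (strict).
#' @return Character vector of gene ids (the expressed universe).
#' @export
filter_expressed <- function(ab, threshold_rpm = 50) {
  rownames(ab$rpm)[rowMeans(ab$rpm) > threshold_rpm]
}

#' Per-gene genotype fold change of small RNA abundance
#'
#' Fold change = mean rpm in the mutant genotype divided by mean rpm in the
#' wild-type genotype; the natural-log fold change is reported alongside
#' (heatmap display convention). Genes with wild-type mean 0 have undefined
#' fold change and are flagged so they can be excluded from set construction.
#'
#' @param ab An [rpm_normalize()] result.
#' @param wild_type_label,mutant_label Genotype labels present in the sample
#'   annotation.
#' @return data.frame: `gene`, `wt_mean_rpm`, `mut_mean_rpm`, `fold_change`,
#'   `ln_fold_change`, `defined`.
#' @export
genotype_fold_change <- function(ab, wild_type_label, mutant_label) {
  g <- ab$samples$genotype
  for (lab in c(wild_type_label, mutant_label))
    if (!lab %in% g) stop(sprintf("genotype '%s' not present", lab))
  wt <- rowMeans(ab$rpm[, g == wild_type_label, drop = FALSE])
  mut <- rowMeans(ab$rpm[, g == mutant_label, drop = FALSE])
  fc <- ifelse(wt > 0, mut / wt, NA_real_)
  data.frame(gene = rownames(ab$rpm),
             wt_mean_rpm = wt, mut_mean_rpm = mut,
             fold_change = fc, ln_fold_change = log(fc),
             defined = wt > 0, row.names = NULL)
}

#' Genes with greater than twofold reduction
#'
#' @param fcs A [genotype_fold_change()] result.
#' @return Character vector of genes with defined fold change strictly below
#'   0.5.
#' @export
twofold_reduced <- function(fcs) {
  fcs$gene[fcs$defined & !is.na(fcs$fold_change) & fcs$fold_change < 0.5]
}

#' Exact hypergeometric tail probability in log space
#'
#' Exact over/under-representation test of an observed overlap `k` between a
#' draw of size `n` and `K` successes in a universe of size `N`. The tail sum
#' is evaluated in log space (log-gamma terms combined by a shifted
#' log-sum-exp), so p values far below double underflow (down to ~1e-300 and
#' beyond on the log10 scale) are computed accurately. Upper tail is
#' `P(X >= k)` (enrichment), lower tail `P(X <= k)` (depletion).
#'
#' @param N Universe size.
#' @param K Successes in the universe.
#' @param n Draw size.
#' @param k Observed overlap.
#' @param tail `"upper"` or `"lower"`.
#' @return Object of class `enrichment_result`: list with `N`, `K`, `n`,
#'   `k`, `tail`, `log10_p` (<= 0) and `p` (0 when underflowed).
#' @examples
#' hypergeometric_tail(2012, 704, 447, 259, "upper")  # log10 p < -29
#' @export
hypergeometric_tail <- function(N, K, n, k, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  if (k < max(0, n + K - N) || k > min(K, n))
    stop("k outside the hypergeometric support")
  xs <- if (tail == "upper") seq.int(k, min(K, n)) else
    seq.int(max(0, n + K - N), k)
  logp <- logsumexp(log_hyper_pmf(N, K, n, xs))
  logp <- min(logp, 0)  # clamp tiny positive rounding
  structure(list(N = N, K = K, n = n, k = k, tail = tail,
                 log10_p = logp / log(10), p = exp(logp)),
            class = "enrichment_result")
}

# log pmf of Hypergeometric(N, K, n) at x (vectorised), via log-gamma
log_hyper_pmf <- function(N, K, n, x) {
  lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "hypergeometric %s tail: k = %d of n = %d vs K = %d of N = %d; log10 p = %.4g\n",
    x$tail, x$k, x$n, x$K, x$N, x$log10_p))
  invisible(x)
}

#' Gene-set enrichment of an observed overlap
#'
#' Convenience wrapper computing the overlap of two gene sets inside a
#' universe and its hypergeometric tail probability. Members outside the
#' universe are dropped before counting.
#'
#' @param universe Character vector: the expressed-gene universe (size N).
#' @param set_a Character vector (e.g. genes twofold-reduced in one mutant);
#'   gives n.
#' @param set_b Character vector (e.g. a published target list); gives K.
#' @param tail `"upper"` for enrichment, `"lower"` for depletion.
#' @return An `enrichment_result` (see [hypergeometric_tail()]).
#' @export
set_enrichment <- function(universe, set_a, set_b,
                           tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  universe <- unique(universe)
  a <- unique(intersect(set_a, universe))
  b <- unique(intersect(set_b, universe))
  hypergeometric_tail(length(universe), length(b), length(a),
                      length(intersect(a, b)), tail)
}

#' Classify small RNA reads into 21U / 22G classes
#'
#' Applies the read-length window (18-32 nt retained) and 5' nucleotide
#' rules: 21-mers starting with U (encoded T) are piRNAs ("21U"); 22-mers
#' starting with G are secondary endo-siRNAs ("22G"); everything else in the
#' window is "other"; reads outside the window are "discarded".
#'
#' @param sequences Character vector of read sequences (A/C/G/T; U accepted
#'   and treated as T).
#' @return Character vector in `{"21U", "22G", "other", "discarded"}`.
#' @examples
#' classify_reads(c("TGGTACGTAGCTAGCTAGCTA", "GGATCCGATCGATCGATCGATC"))
#' @export
classify_reads <- function(sequences) {
  seqs <- toupper(sequences)
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (any(grepl("[^ACGT]", seqs)))
    stop("sequences contain non-DNA characters")
  len <- nchar(seqs)
  first <- substr(seqs, 1L, 1L)
  ifelse(len < 18L | len > 32L, "discarded",
         ifelse(len == 21L & first == "T", "21U",
                ifelse(len == 22L & first == "G", "22G", "other")))
}

#' piRNA-sensor abundance normalised by H2B-mapping reads
#'
#' The piRNA sensor is an H2B fluorophore transgene; small RNAs mapping to it
#' are normalised per sample by the H2B-mapping read count rather than the
#' library total.
#'
#' @param sensor_counts Numeric vector of sensor-mapping read counts per
#'   sample.
#' @param h2b_counts Matching vector of H2B-mapping read counts (> 0).
#' @return Numeric vector `sensor_counts / h2b_counts`.
#' @export
sensor_abundance <- function(sensor_counts, h2b_counts) {
  if (length(sensor_counts) != length(h2b_counts))
    stop("count vectors must have equal length")
  if (any(h2b_counts <= 0)) stop("H2B counts must be > 0")
  sensor_counts / h2b_counts
}
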