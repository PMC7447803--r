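mk_table <- function(counts, totals, genotypes = NULL) {
  if (is.null(genotypes)) genotypes <- rep("wt", length(totals))
  small_rna_table(counts, data.frame(
    sample = colnames(counts), genotype = genotypes,
    unique_mapped_total = totals))
}

test_that("rpm normalisation corrects counts by unique-mapped totals", {
  cts <- matrix(c(50L, 100L, 0L, 0L), 2, 2, byrow = TRUE,
                dimnames = list(c("gA", "gB"), c("s1", "s2")))
  ab <- rpm_normalize(mk_table(cts, c(1e6, 2e6)))
  expect_equal(unname(ab$rpm["gA", ]), c(50, 50))
  expect_equal(unname(ab$rpm["gB", ]), c(0, 0))
  expect_error(mk_table(cts, c(1e6, 0)), "zero unique-mapped total.*s2")
})

test_that("the expression filter is strict at the rpm threshold", {
  cts <- matrix(as.integer(c(50, 50, 51, 49, 200, 10)), 3, 2, byrow = TRUE,
                dimnames = list(c("at", "just_over", "mixed"),
                                c("s1", "s2")))
  ab <- rpm_normalize(mk_table(cts, c(1e6, 1e6)))
  expect_setequal(filter_expressed(ab, 50), c("mixed"))
  # mean exactly 50 ("at", and "just_over" = (51+49)/2) is excluded
  expect_false("at" %in% filter_expressed(ab, 50))
  expect_true("just_over" %in% filter_expressed(ab, 49.9))
  # planted counts above/below the cutoff are recovered exactly
  n_hi <- 120L; n_lo <- 80L
  cts2 <- matrix(rep(c(rep(60L, n_hi), rep(40L, n_lo)), 2), ncol = 2,
                 dimnames = list(sprintf("g%03d", 1:(n_hi + n_lo)),
                                 c("s1", "s2")))
  ab2 <- rpm_normalize(mk_table(cts2, c(1e6, 1e6)))
  expect_length(filter_expressed(ab2, 50), n_hi)
})

test_that("genotype fold changes divide mutant by wild-type mean rpm", {
  cts <- matrix(as.integer(c(10, 10, 5, 5,
                             8, 8, 8, 8,
                             0, 0, 4, 4)), 3, 4, byrow = TRUE,
                dimnames = list(c("down", "flat", "wt_zero"),
                                c("w1", "w2", "m1", "m2")))
  ab <- rpm_normalize(mk_table(cts, rep(1e6, 4),
                               c("wt", "wt", "mut", "mut")))
  fc <- genotype_fold_change(ab, "wt", "mut")
  expect_equal(fc$fold_change[fc$gene == "down"], 0.5)
  expect_equal(fc$ln_fold_change[fc$gene == "down"], log(0.5))
  expect_equal(fc$fold_change[fc$gene == "flat"], 1)
  expect_equal(fc$ln_fold_change[fc$gene == "flat"], 0)
  expect_false(fc$defined[fc$gene == "wt_zero"])
  expect_error(genotype_fold_change(ab, "wt", "absent"), "not present")
  # strict twofold boundary
  fcs <- data.frame(gene = c("a", "b", "c"),
                    fold_change = c(0.49, 0.5, 2.0),
                    defined = TRUE)
  expect_equal(twofold_reduced(fcs), "a")
})

test_that("rpm and fold changes are invariant to joint count/total scaling", {
  set.seed(9)
  cts <- matrix(rpois(40, 50), 10, 4,
                dimnames = list(sprintf("g%02d", 1:10),
                                c("w1", "w2", "m1", "m2")))
  tab1 <- mk_table(cts, rep(2e6, 4), c("wt", "wt", "mut", "mut"))
  cts2 <- cts; cts2[, 2] <- cts2[, 2] * 5L
  tab2 <- mk_table(cts2, c(2e6, 1e7, 2e6, 2e6), c("wt", "wt", "mut", "mut"))
  fc1 <- genotype_fold_change(rpm_normalize(tab1), "wt", "mut")
  fc2 <- genotype_fold_change(rpm_normalize(tab2), "wt", "mut")
  expect_equal(fc1$fold_change, fc2$fold_change)
})

test_that("hypergeometric tails are exact on small cases", {
  r <- hypergeometric_tail(10, 5, 5, 5, "upper")
  expect_equal(r$p, 1 / choose(10, 5))
  expect_equal(hypergeometric_tail(40, 10, 8, 0, "upper")$p, 1)
  # symmetric in (K, n)
  a <- hypergeometric_tail(100, 30, 12, 8, "upper")
  b <- hypergeometric_tail(100, 12, 30, 8, "upper")
  expect_equal(a$log10_p, b$log10_p, tolerance = 1e-12)
  expect_error(hypergeometric_tail(10, 5, 5, 6), "support")
})

test_that("log-space tails agree with brute-force sums for all small cases", {
  set.seed(13)
  for (rep in 1:40) {
    N <- sample(10:60, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    lo <- max(0, n + K - N); hi <- min(K, n)
    k <- sample(lo:hi, 1)
    for (tail in c("upper", "lower")) {
      got <- hypergeometric_tail(N, K, n, k, tail)$log10_p
      want <- log10(brute_hyper_tail(N, K, n, k, tail))
      # relative in log10 p, switching to absolute near log10 p = 0 where
      # the relative measure is ill-conditioned
      expect_lt(abs(got - want), 1e-9 * max(1, abs(want)))
    }
  }
})

test_that("upper and lower tails overlap by exactly the point mass", {
  set.seed(14)
  for (rep in 1:20) {
    N <- sample(50:2500, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    lo <- max(0, n + K - N); hi <- min(K, n)
    k <- sample(lo:hi, 1)
    up <- hypergeometric_tail(N, K, n, k, "upper")$p
    low <- hypergeometric_tail(N, K, n, k, "lower")$p
    pmf <- exp(perigranule:::log_hyper_pmf(N, K, n, k))
    expect_equal(up + low, 1 + pmf, tolerance = 1e-10)
  }
})

test_that("extreme tails agree with phyper's log-scale tails", {
  # independent route: stats::phyper with log.p
  cases <- list(c(2012, 704, 447, 259), c(2012, 761, 447, 428),
                c(11088, 8986, 63, 55))
  for (cs in cases) {
    got <- hypergeometric_tail(cs[1], cs[2], cs[3], cs[4], "upper")$log10_p
    want <- phyper(cs[4] - 1, cs[2], cs[1] - cs[2], cs[3],
                   lower.tail = FALSE, log.p = TRUE) / log(10)
    expect_equal(got, want, tolerance = 1e-10)
  }
  got_l <- hypergeometric_tail(2012, 162, 447, 4, "lower")$log10_p
  want_l <- phyper(4, 162, 1850, 447, log.p = TRUE) / log(10)
  expect_equal(got_l, want_l, tolerance = 1e-10)
})

test_that("read classification applies length and 5' nucleotide rules", {
  r21u <- paste(c("T", rep("A", 20)), collapse = "")
  r22g <- paste(c("G", rep("C", 21)), collapse = "")
  r21a <- paste(c("A", rep("T", 20)), collapse = "")
  short <- paste(rep("A", 17), collapse = "")
  long <- paste(rep("A", 33), collapse = "")
  expect_equal(classify_reads(c(r21u, r22g, r21a, short, long)),
               c("21U", "22G", "other", "discarded", "discarded"))
  # U accepted as T; boundary lengths 18 and 32 retained
  expect_equal(classify_reads(gsub("T", "U", r21u)), "21U")
  expect_equal(classify_reads(paste(rep("A", 18), collapse = "")), "other")
  expect_equal(classify_reads(paste(rep("A", 32), collapse = "")), "other")
  expect_error(classify_reads("ACGTN"), "non-DNA")
})

test_that("sensor abundance is the per-sample sensor/H2B ratio", {
  expect_equal(sensor_abundance(c(10, 0), c(100, 50)), c(0.1, 0))
  expect_equal(sensor_abundance(20, 200), sensor_abundance(10, 100))
  expect_error(sensor_abundance(1, 0), "H2B")
  expect_error(sensor_abundance(c(1, 2), 1), "length")
})
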