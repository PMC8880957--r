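test_that("call_peaks applies the 1 kb span rule with chaining", {
  expect_equal(nrow(call_peaks(c(100, 2000, 5000), chrom = "I")), 0)
  p1 <- call_peaks(c(100, 200, 900), chrom = "I")
  expect_equal(as.data.frame(p1)[, c("start", "end", "n_sig_snps")],
               data.frame(start = 100, end = 900, n_sig_snps = 3L))
  # chaining through a shared member: {200, 900, 1050} qualifies and extends
  p2 <- call_peaks(c(100, 200, 900, 1050), chrom = "I")
  expect_equal(nrow(p2), 1)
  expect_equal(c(p2$start, p2$end, p2$n_sig_snps), c(100, 1050, 4))
  # {900, 1500, 1600} spans 700 <= 1000 and chains both clusters: one peak
  p3 <- call_peaks(c(100, 200, 900, 1500, 1600, 1700), chrom = "I")
  expect_equal(nrow(p3), 1)
  expect_equal(c(p3$start, p3$end), c(100, 1700))
  # a real gap (> window between runs) keeps two peaks
  p4 <- call_peaks(c(100, 200, 900, 2500, 2600, 2700), chrom = "I")
  expect_equal(p4$start, c(100, 2500))
  expect_equal(p4$end, c(900, 2700))
})

test_that("call_peaks equals the brute-force oracle on random position sets", {
  set.seed(606)
  for (rep in 1:60) {
    n <- sample(3:120, 1)
    pos <- sort(sample.int(15000, n))
    k <- sample(c(3L, 5L), 1)
    mine <- call_peaks(pos, chrom = "I", min_snps = k)
    oracle <- peak_oracle(pos, min_snps = k)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(oracle)) {
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
      expect_equal(mine$n_sig_snps, oracle$n_sig_snps)
    }
  }
})

test_that("peak invariants: membership, counts and min_snps nesting", {
  set.seed(77)
  pos <- sort(sample.int(50000, 300))
  p3 <- call_peaks(pos, chrom = "I", min_snps = 3)
  p5 <- call_peaks(pos, chrom = "I", min_snps = 5)
  expect_lte(sum(p3$n_sig_snps), length(pos))
  # every min_snps = 5 peak is contained in a min_snps = 3 peak
  if (nrow(p5)) {
    contained <- vapply(seq_len(nrow(p5)), function(i)
      any(p3$start <= p5$start[i] & p3$end >= p5$end[i]), logical(1))
    expect_true(all(contained))
  }
  # member SNPs lie within their peak and are counted exactly
  for (i in seq_len(nrow(p3))) {
    inside <- pos >= p3$start[i] & pos <= p3$end[i]
    expect_equal(sum(inside), p3$n_sig_snps[i])
  }
})

test_that("peaks merge within genes but not across boundaries", {
  genes <- toy_genes()  # gA = I:1000-3000, gB = I:5000-6000
  peaks <- call_peaks(c(1100, 1150, 1200, 2500, 2550, 2600, 5100, 5150, 5200),
                      chrom = "I")
  expect_equal(nrow(peaks), 3)
  merged <- merge_within_genes(peaks, genes)
  expect_equal(nrow(merged), 2)
  gA <- merged[merged$gene_id == "gA", ]
  expect_equal(c(gA$start, gA$end, gA$n_sig_snps), c(1100, 2600, 6))
  # a peak straddling a gene boundary is not merged into the gene
  straddle <- call_peaks(c(2900, 2950, 3100), chrom = "I")
  ms <- merge_within_genes(straddle, genes)
  expect_true(is.na(ms$gene_id))
})

test_that("peak classification covers genic, pseudogenic, intergenic and mixed", {
  genes <- toy_genes()
  peaks <- data.frame(chrom = "I",
                      start = c(1100, 8100, 4000, 4900),
                      end = c(1200, 8200, 4100, 5100),
                      n_sig_snps = 3L)
  class(peaks) <- c("peak_set", "data.frame")
  cls <- classify_peaks(peaks, genes)
  expect_equal(cls$annotation_class, c("genic", "pseudogenic", "intergenic", "genic"))
  # overlapping both a coding gene and a pseudogene -> mixed
  genes2 <- c(toy_genes(),
              GenomicRanges::GRanges("I", IRanges::IRanges(1150, 1300),
                                     gene_id = "gP2", biotype = "pseudogene"))
  cls2 <- classify_peaks(peaks, genes2)
  expect_equal(cls2$annotation_class[1], "mixed")
})

test_that("cross-regime overlap forms transitive unions with combination counts", {
  mk <- function(df) { class(df) <- c("peak_set", "data.frame"); df }
  a <- mk(data.frame(chrom = "I", start = 100, end = 200, n_sig_snps = 3L))
  b <- mk(data.frame(chrom = "I", start = 150, end = 250, n_sig_snps = 3L))
  c3 <- mk(data.frame(chrom = "I", start = 180, end = 300, n_sig_snps = 3L))
  d <- mk(data.frame(chrom = "I", start = 5000, end = 5100, n_sig_snps = 4L))
  ov <- peak_overlap(list(r1 = a, r2 = b, r3 = c3, r4 = d))
  expect_equal(sort(ov$combinations$combination), sort(c("r1+r2+r3", "r4")))
  expect_equal(ov$combinations$n, c(1L, 1L))
  # identical peaksets across 4 regimes: everything in the 4-way cell
  ov2 <- peak_overlap(list(r1 = a, r2 = a, r3 = a, r4 = a))
  expect_equal(ov2$combinations$combination, "r1+r2+r3+r4")
  # fully disjoint peaksets: all unique cells
  e <- mk(data.frame(chrom = "II", start = 100, end = 200, n_sig_snps = 3L))
  ov3 <- peak_overlap(list(r1 = a, r2 = e))
  expect_setequal(ov3$combinations$combination, c("r1", "r2"))
})

test_that("width stats use inclusive widths", {
  mk <- function(s, e) {
    df <- data.frame(chrom = "I", start = s, end = e, n_sig_snps = 3L)
    class(df) <- c("peak_set", "data.frame"); df
  }
  w1 <- width_stats(mk(100, 152))
  expect_equal(unlist(w1), c(median = 53, mean = 53, max = 53))
  w2 <- width_stats(mk(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(unlist(w2), c(median = 1, mean = 1, max = 1))
  w3 <- width_stats(mk(c(1, 1, 1), c(10, 53, 1000)))
  expect_equal(w3$median, 53)
  expect_equal(round(w3$mean, 2), 354.33)
  empty <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_sig_snps = integer(0))
  class(empty) <- c("peak_set", "data.frame")
  expect_error(width_stats(empty), "no peaks")
})

test_that("arm/center enrichment reproduces the hand chi-square", {
  dm <- default_domain_map(c(I = 40000), arm_frac = 0.25)
  mk <- function(mids) {
    df <- data.frame(chrom = "I", start = mids - 5, end = mids + 5, n_sig_snps = 3L)
    class(df) <- c("peak_set", "data.frame"); df
  }
  # 30 peaks on arms (mid < 10000), 10 in the center
  peaks <- mk(c(seq(500, 9500, length.out = 30), seq(15000, 24000, length.out = 10)))
  r <- arm_center_enrichment(peaks, dm, c(arm = 0.55, center = 0.45))
  expect_equal(r$chisq, 64 / 22 + 64 / 18)
  expect_equal(round(r$chisq, 3), 6.465)
  expect_equal(r$df, 1)
  # observed equal to expected -> chi-square 0
  peaks2 <- mk(c(seq(500, 9500, length.out = 11), seq(15000, 24000, length.out = 9)))
  r2 <- arm_center_enrichment(peaks2, dm, c(arm = 0.55, center = 0.45))
  expect_equal(r2$chisq, 0)
  expect_warning(arm_center_enrichment(mk(500), dm, c(arm = 0.55, center = 0.45)),
                 "below 1")
})

test_that("null peak placement gives calibrated enrichment p-values", {
  dm <- default_domain_map(c(I = 100000), arm_frac = 0.25)
  set.seed(9)
  ps <- replicate(200, {
    mids <- sample.int(100000, 40)
    df <- data.frame(chrom = "I", start = mids, end = mids, n_sig_snps = 3L)
    class(df) <- c("peak_set", "data.frame")
    arm_center_enrichment(df, dm, c(arm = 0.5, center = 0.5))$p
  })
  # discrete statistic: check type-I error near nominal rather than exact uniformity
  expect_lte(mean(ps < 0.05), 0.09)
  expect_gte(mean(ps < 0.05), 0.005)
})
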