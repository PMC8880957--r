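test_that("counts TSV round-trips bit-identically", {
  x <- toy_counts(pos = c(100L, 250L),
                  cells = list(s1 = list(ref = c(5L, 0L), alt = c(5L, 9L)),
                               s2 = list(ref = c(7L, 3L), alt = c(3L, 4L))))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_counts(x, f)
  y <- read_counts(f, format = "tsv")$counts
  expect_identical(x$sites, y$sites)
  expect_identical(x$ref, y$ref)
  expect_identical(x$alt, y$alt)
})

test_that("site_counts rejects malformed input", {
  expect_error(toy_counts(cells = list(s1 = list(ref = c(-1L, 1L), alt = c(1L, 1L)))),
               "non-negative")
  expect_error(site_counts(data.frame(chrom = "I", pos = 1, ref = "A", alt = "A"),
                           matrix(1, dimnames = list(NULL, "s1")),
                           matrix(1, dimnames = list(NULL, "s1"))),
               "differ")
  expect_error(toy_counts(pos = c(100L, 100L)), "duplicate")
})

test_that("VCF ingestion parses AD and drops indels/multiallelics with a count", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=I,length=1000000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", sep = "\t"),
    paste("I", "100", ".", "A", "G", ".", "PASS", ".", "GT:AD", "0/1:7,3", "0/0:10,0", sep = "\t"),
    paste("I", "200", ".", "C", "T,G", ".", "PASS", ".", "GT:AD", "0/1:5,2,1", "0/1:6,1,2", sep = "\t"),
    paste("I", "300", ".", "CA", "C", ".", "PASS", ".", "GT:AD", "0/1:4,4", "0/1:3,5", sep = "\t"),
    paste("I", "400", ".", "T", "A", ".", "PASS", ".", "GT:AD", "0/1:8,2", "0/1:9,1", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  r <- suppressMessages(read_counts(f, format = "vcf_ad"))
  expect_equal(n_sites(r$counts), 2)  # SNVs at 100 and 400 only
  expect_equal(r$counts$ref[1, ], c(s1 = 7L, s2 = 10L))  # AD "7,3" -> ref 7
  expect_equal(r$counts$alt[1, ], c(s1 = 3L, s2 = 0L))   #           alt 3
  expect_equal(unname(r$dropped), c(1L, 1L))
  # a VCF without AD is a format error
  novcf <- vcf[-4]
  novcf <- sub("GT:AD", "GT", novcf)
  novcf <- sub(":7,3", "", sub(":10,0", "", novcf))
  f2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(novcf[1:6], f2)
  expect_error(suppressWarnings(read_counts(f2, format = "vcf_ad")), "AD")
})

test_that("repeat masking respects BED half-open coordinates", {
  x <- toy_counts(pos = c(100L, 150L, 300L),
                  cells = list(s1 = list(ref = c(5L, 5L, 5L), alt = c(1L, 1L, 1L))))
  # BED [50, 100): covers 0-based 50..99 -> 1-based 51..100 -> pos 100 removed
  bed1 <- GenomicRanges::GRanges("I", IRanges::IRanges(51, 100))
  m1 <- mask_repeats(x, bed1)
  expect_equal(m1$sites$pos, c(150L, 300L))
  # BED [100, 200): 1-based 101..200 -> pos 100 retained, 150 removed
  bed2 <- GenomicRanges::GRanges("I", IRanges::IRanges(101, 200))
  m2 <- mask_repeats(x, bed2)
  expect_equal(m2$sites$pos, c(100L, 300L))
  # empty mask is the identity; unknown chromosomes warn and are ignored
  expect_equal(mask_repeats(x, GenomicRanges::GRanges())$sites, x$sites)
  expect_warning(m3 <- mask_repeats(x, GenomicRanges::GRanges("chr99", IRanges::IRanges(1, 10))),
                 "ignored")
  expect_equal(m3$sites, x$sites)
  # BED file round trip (0-based half-open on disk)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("I\t50\t100", f)
  gr <- read_bed_mask(f)
  expect_equal(GenomicRanges::start(gr), 51)
  expect_equal(GenomicRanges::end(gr), 100)
})

test_that("coverage tail filter uses nearest-rank quantiles with the right inequalities", {
  # coverages 1..100 -> thresholds 5 and 95 -> retain coverage 6..95
  x <- toy_counts(pos = seq_len(100) * 10L,
                  cells = list(s1 = list(ref = seq_len(100) - rep(0:1, 50),
                                         alt = rep(0:1, 50))))
  y <- filter_coverage_tails(x)
  expect_equal(n_sites(y), 90)
  expect_equal(range(coverage(y)), c(6, 95))
  expect_equal(unname(attr(y, "coverage_thresholds")), c(5, 95))
  expect_equal(drop_log(y)$n, 10)
  # all-equal coverages: warn, remove nothing
  z <- toy_counts(pos = c(10L, 20L),
                  cells = list(s1 = list(ref = c(5L, 5L), alt = c(5L, 5L))))
  expect_warning(zz <- filter_coverage_tails(z), "identical")
  expect_equal(n_sites(zz), 2)
})

test_that("presence filter applies scope, boundaries and ancestor requirement", {
  te <- toy_experiment()
  ex <- te$ex
  x <- ex$counts
  # boundary: exactly min_present evolved samples qualifies
  p24 <- presence_filter(x, ex$meta, min_present = 24, scope = "all_evolved")
  expect_true(n_sites(p24) <= n_sites(x))
  expect_error(presence_filter(x, ex$meta, min_present = 25, scope = "all_evolved"),
               "exceeds")
  # per-regime scope counts that regime's 18 samples
  expect_error(presence_filter(x, ex$meta, min_present = 19, scope = "per_regime",
                               regime = "BS-PO"), "exceeds")
  # hand-built case: ancestor present, 8 of 18 regime samples covered -> dropped at 9
  meta <- sample_meta(
    c("ANC_p1", sprintf("E_r%d_g%d", rep(1:6, each = 3), rep(c(13, 22, 31), 6))),
    c("ANC", rep("BS-PO", 18)), c(0L, rep(1:6, each = 3)),
    c(0L, rep(c(13L, 22L, 31L), 6)))
  cov1 <- c(1L, rep(1L, 8), rep(0L, 10))
  cells <- lapply(seq_along(cov1), function(i) list(ref = cov1[i], alt = 0L))
  names(cells) <- meta$sample_id
  xx <- toy_counts(pos = 100L, cells = cells)
  kept <- presence_filter(xx, meta, min_present = 9, scope = "per_regime", regime = "BS-PO")
  expect_equal(n_sites(kept), 0)
  kept8 <- presence_filter(xx, meta, min_present = 8, scope = "per_regime", regime = "BS-PO")
  expect_equal(n_sites(kept8), 1)
  # zero ancestor coverage -> dropped when required, kept when not
  cells$ANC_p1 <- list(ref = 0L, alt = 0L)
  xa <- toy_counts(pos = 100L, cells = cells)
  expect_equal(n_sites(presence_filter(xa, meta, 8, "per_regime", "BS-PO")), 0)
  expect_equal(n_sites(presence_filter(xa, meta, 8, "per_regime", "BS-PO",
                                       require_ancestor = FALSE)), 1)
})

test_that("filters are idempotent and conserve site counts in the drop log", {
  te <- toy_experiment()
  x <- te$ex$counts
  mask <- GenomicRanges::GRanges("I", IRanges::IRanges(1, 2e5))
  f1 <- filter_coverage_tails(mask_repeats(x, mask))
  n_in <- n_sites(x)
  expect_equal(n_in, n_sites(f1) + sum(drop_log(f1)$n))
  # idempotence: re-masking removes nothing more
  f2 <- mask_repeats(f1, mask)
  expect_equal(n_sites(f2), n_sites(f1))
  p1 <- presence_filter(f1, te$ex$meta, min_present = 9, scope = "per_regime",
                        regime = "WS-PO")
  p2 <- presence_filter(p1, te$ex$meta, min_present = 9, scope = "per_regime",
                        regime = "WS-PO")
  expect_identical(p1$sites, p2$sites)
})
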