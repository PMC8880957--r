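#' Per-SNP, per-sample allele read counts
#'
#' Container for diallelic SNP read counts from pooled sequencing: a site table
#' (chromosome, 1-based position, ref/alt alleles) plus two integer matrices of
#' per-sample reference and alternate read counts, one column per sample.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param ref,alt Integer matrices, sites x samples, with identical dimnames.
#' @return An object of class `site_counts`.
#' @export
site_counts <- function(sites, ref, alt) {
  .assert(is.data.frame(sites) && all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
          "`sites` needs columns chrom, pos, ref, alt")
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  .assert(all(dim(ref) == dim(alt)), "ref/alt count matrices must have equal dimensions")
  .assert(nrow(ref) == nrow(sites), "count matrices must have one row per site")
  .assert(all(ref >= 0) && all(alt >= 0), "read counts must be non-negative")
  .assert(!is.null(colnames(ref)), "count matrices need sample ids as column names")
  .assert(identical(colnames(ref), colnames(alt)), "ref/alt sample columns must match")
  .assert(all(sites$ref != sites$alt), "ref and alt alleles must differ")
  sites <- data.frame(chrom = as.character(sites$chrom), pos = sites$pos,
                      ref = as.character(sites$ref), alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos)
  if (is.unsorted(o)) { sites <- sites[o, , drop = FALSE]; ref <- ref[o, , drop = FALSE]; alt <- alt[o, , drop = FALSE] }
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) entries", call. = FALSE)
  sites$pos <- as.integer(sites$pos)
  rownames(sites) <- NULL
  structure(list(sites = sites, ref = ref, alt = alt), class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf("site_counts: %d SNPs x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(unique(x$sites$chrom))))
  invisible(x)
}

#' @rdname site_counts
#' @param x A `site_counts` object.
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname site_counts
#' @export
n_samples <- function(x) ncol(x$ref)

#' @rdname site_counts
#' @export
sample_ids <- function(x) colnames(x$ref)

#' Per-sample or total read coverage at each site
#'
#' @param x A `site_counts` object.
#' @param total If `TRUE` (default) return the per-site row sum across samples.
#' @return Matrix (sites x samples) or numeric vector of totals.
#' @export
coverage <- function(x, total = TRUE) {
  cov <- x$ref + x$alt
  if (total) rowSums(cov) else cov
}

# internal: subset sites, carrying a drop-log entry
subset_sites <- function(x, keep, reason) {
  out <- site_counts(x$sites[keep, , drop = FALSE],
                     x$ref[keep, , drop = FALSE],
                     x$alt[keep, , drop = FALSE])
  log0 <- attr(x, "drop_log")
  if (is.null(log0)) log0 <- data.frame(reason = character(), n = integer())
  attr(out, "drop_log") <- rbind(log0, data.frame(reason = reason,
                                                  n = n_sites(x) - sum(keep)))
  out
}

#' Drop log of a filtered count table
#'
#' Every filtering operation appends a row (reason, number of sites dropped),
#' so input sites always reconcile as retained + sum of drops.
#'
#' @param x A `site_counts` object that has been through one or more filters.
#' @return data.frame with columns `reason`, `n` (possibly empty).
#' @export
drop_log <- function(x) {
  log0 <- attr(x, "drop_log")
  if (is.null(log0)) data.frame(reason = character(), n = integer()) else log0
}

#' Sample metadata for an E&R count table
#'
#' @param sample_id Character, matching the count-table columns.
#' @param regime One of `"ANC"` or [REGIMES].
#' @param replicate Integer 1-6 (0 for ancestor pools).
#' @param generation Integer in {0, 13, 22, 31}.
#' @return Validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, regime, replicate, generation) {
  m <- data.frame(sample_id = as.character(sample_id), regime = as.character(regime),
                  replicate = as.integer(replicate), generation = as.integer(generation))
  .assert(all(m$regime %in% c("ANC", REGIMES)), "unknown regime label")
  .assert(all(m$generation[m$regime == "ANC"] == 0L), "ancestor samples must be generation 0")
  .assert(!anyDuplicated(m$sample_id), "duplicate sample ids")
  class(m) <- c("sample_meta", "data.frame")
  m
}

# internal: check meta covers exactly the count columns
check_meta <- function(counts, meta) {
  .assert(setequal(meta$sample_id, sample_ids(counts)),
          "metadata sample ids do not match count columns")
  meta[match(sample_ids(counts), meta$sample_id), , drop = FALSE]
}

#' Write an allele-count table to TSV
#'
#' Dialect: header `chrom pos ref alt <sample>:ref <sample>:alt ...`,
#' tab-separated, one row per site.
#'
#' @param x A `site_counts` object.
#' @param path Output file path.
#' @export
write_counts <- function(x, path) {
  ids <- sample_ids(x)
  cnt <- matrix(0L, n_sites(x), 2L * length(ids))
  cnt[, seq(1L, by = 2L, length.out = length(ids))] <- x$ref
  cnt[, seq(2L, by = 2L, length.out = length(ids))] <- x$alt
  df <- cbind(x$sites[, c("chrom", "pos", "ref", "alt")], as.data.frame(cnt))
  names(df) <- c("chrom", "pos", "ref", "alt",
                 as.vector(rbind(paste0(ids, ":ref"), paste0(ids, ":alt"))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an allele-count table
#'
#' Reads either the package's tab-separated counts dialect (see
#' [write_counts()]) or a VCF carrying per-sample allelic depths (`AD`).
#' Indels and multiallelic VCF records are dropped and counted.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf_ad"`.
#' @param meta Optional path to a sample-metadata TSV
#'   (columns sample_id, regime, replicate, generation).
#' @return List with elements `counts` (a [site_counts()]), `meta` (a
#'   [sample_meta()] or `NULL`) and `dropped` (named integer of record drops).
#' @export
read_counts <- function(path, format = c("tsv", "vcf_ad"), meta = NULL) {
  format <- match.arg(format)
  out <- switch(format, tsv = .read_counts_tsv(path), vcf_ad = .read_counts_vcf(path))
  if (!is.null(meta)) {
    m <- read_sample_meta(meta)
    out$meta <- check_meta(out$counts, m)
  }
  out
}

.read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .assert(all(c("chrom", "pos", "ref", "alt") == names(df)[1:4]),
          "counts TSV must start with columns chrom, pos, ref, alt")
  cc <- names(df)[-(1:4)]
  .assert(length(cc) %% 2 == 0 && all(grepl(":(ref|alt)$", cc)),
          "count columns must come in <sample>:ref / <sample>:alt pairs")
  ids <- unique(sub(":(ref|alt)$", "", cc))
  ref <- as.matrix(df[, paste0(ids, ":ref"), drop = FALSE])
  alt <- as.matrix(df[, paste0(ids, ":alt"), drop = FALSE])
  colnames(ref) <- colnames(alt) <- ids
  list(counts = site_counts(df[, 1:4], ref, alt), meta = NULL,
       dropped = c(indel = 0L, multiallelic = 0L))
}

.read_counts_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  if (!("AD" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf)))))
    stop("VCF lacks per-sample allelic depth (AD) field", call. = FALSE)
  rr <- SummarizedExperiment::rowRanges(vcf)
  refs <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alts <- rep(NA_character_, length(refs))
  alts[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  multi <- n_alt != 1L
  snv <- !multi & nchar(refs) == 1L & nchar(alts) == 1L & !is.na(alts)
  indel <- !multi & !snv
  keep <- which(snv)
  ad <- VariantAnnotation::geno(vcf)$AD
  get_cnt <- function(i) vapply(seq_len(ncol(ad)), function(j) {
    v <- ad[[keep[i], j]]
    if (length(v) < 2 || anyNA(v[1:2])) c(0L, 0L) else as.integer(v[1:2])
  }, integer(2))
  cnts <- lapply(seq_along(keep), get_cnt)
  ref_m <- do.call(rbind, lapply(cnts, function(m) m[1, ]))
  alt_m <- do.call(rbind, lapply(cnts, function(m) m[2, ]))
  colnames(ref_m) <- colnames(alt_m) <- colnames(ad)
  sites <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr))[keep],
                      pos = GenomicRanges::start(rr)[keep],
                      ref = refs[keep], alt = alts[keep])
  if (anyDuplicated(sites[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) records in VCF", call. = FALSE)
  dropped <- c(indel = sum(indel), multiallelic = sum(multi))
  message(sprintf("read_counts: dropped %d indel and %d multiallelic record(s)",
                  dropped[["indel"]], dropped[["multiallelic"]]))
  list(counts = site_counts(sites, ref_m, alt_m), meta = NULL, dropped = dropped)
}

#' Read / write sample metadata TSV
#'
#' @param path File path.
#' @return [sample_meta()] data.frame.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_meta(df$sample_id, df$regime, df$replicate, df$generation)
}

#' @rdname read_sample_meta
#' @param meta A [sample_meta()] data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED repeat mask into genomic ranges
#'
#' BED intervals are 0-based half-open on disk; the returned
#' [GenomicRanges::GRanges] is 1-based inclusive (the usual conversion).
#'
#' @param path BED file.
#' @return `GRanges` of masked regions (merged).
#' @export
read_bed_mask <- function(path) {
  if (file.size(path) == 0) return(GenomicRanges::GRanges())
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
  } else {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  }
  GenomicRanges::reduce(gr)
}

#' Remove SNPs falling in repeat-masked regions
#'
#' A site at 1-based position P is removed iff its 0-based coordinate P-1 lies
#' in a half-open mask interval, i.e. iff P is inside the mask after BED ->
#' 1-based conversion.
#'
#' @param x A [site_counts()] object.
#' @param mask A `GRanges` mask (e.g. from [read_bed_mask()]).
#' @return Filtered `site_counts` with a drop-log entry `"repeat_mask"`.
#' @export
mask_repeats <- function(x, mask) {
  if (length(mask) == 0) return(subset_sites(x, rep(TRUE, n_sites(x)), "repeat_mask"))
  extra <- setdiff(as.character(GenomicRanges::seqnames(mask)), unique(x$sites$chrom))
  if (length(extra))
    warning("mask chromosomes absent from counts, ignored: ", paste(extra, collapse = ", "))
  snp <- GenomicRanges::GRanges(x$sites$chrom, IRanges::IRanges(x$sites$pos, x$sites$pos))
  # the explicit warning above already covers disjoint seqlevels
  hit <- suppressWarnings(IRanges::overlapsAny(snp, mask))
  subset_sites(x, !hit, "repeat_mask")
}

#' Remove SNPs in the tails of the total-coverage distribution
#'
#' Total coverage per site is summed over samples; nearest-rank (type-1)
#' quantiles define the thresholds and sites with coverage `<=` the lower or
#' `>` the upper threshold are removed (matching the inequality senses of the
#' original pipeline's ">342x" / "<=20x" cuts).
#'
#' @param x A [site_counts()] object.
#' @param lower_q,upper_q Tail quantiles (defaults 0.05, 0.95).
#' @return Filtered `site_counts` with drop-log entry `"coverage_tails"`;
#'   thresholds are attached as attribute `"coverage_thresholds"`.
#' @export
filter_coverage_tails <- function(x, lower_q = 0.05, upper_q = 0.95) {
  .assert(n_sites(x) >= 1, "no sites")
  cov <- coverage(x)
  if (length(unique(cov)) == 1L) {
    warning("all sites have identical total coverage; tail filter skipped")
    out <- subset_sites(x, rep(TRUE, n_sites(x)), "coverage_tails")
    attr(out, "coverage_thresholds") <- c(lower = NA_real_, upper = NA_real_)
    return(out)
  }
  lo <- stats::quantile(cov, lower_q, type = 1, names = FALSE)
  hi <- stats::quantile(cov, upper_q, type = 1, names = FALSE)
  out <- subset_sites(x, cov > lo & cov <= hi, "coverage_tails")
  attr(out, "coverage_thresholds") <- c(lower = lo, upper = hi)
  out
}

#' Filter SNPs on sample presence
#'
#' A SNP is "present" in a sample when that sample's coverage at the site is
#' at least 1 read (set `present = "alt"` to require an alternate-allele read
#' instead).  With `scope = "all_evolved"` presence is counted over the
#' final-generation evolved samples (one per regime x replicate, the Model 1
#' convention, default minimum 10 of 24); with `scope = "per_regime"` over one
#' regime's samples across all time points (the Model 2 convention, default
#' minimum 9 of 18). Ancestor presence means combined ancestor-pool coverage
#' of at least 1 read.
#'
#' @param x A [site_counts()] object.
#' @param meta Matching [sample_meta()].
#' @param min_present Minimum number of qualifying evolved samples.
#' @param scope `"all_evolved"` or `"per_regime"`.
#' @param regime Regime label, required for `scope = "per_regime"`.
#' @param require_ancestor Require presence in the (pooled) ancestor.
#' @param present `"coverage"` (default) or `"alt"`.
#' @param generations Generations over which evolved presence is counted;
#'   defaults to the final generation for `all_evolved` and all generations
#'   for `per_regime`.
#' @return Filtered `site_counts` with drop-log entry `"presence"`.
#' @export
presence_filter <- function(x, meta, min_present = 10, scope = c("all_evolved", "per_regime"),
                            regime = NULL, require_ancestor = TRUE,
                            present = c("coverage", "alt"), generations = NULL) {
  scope <- match.arg(scope); present <- match.arg(present)
  meta <- check_meta(x, meta)
  obs <- if (present == "coverage") x$ref + x$alt else x$alt
  evo <- meta$regime != "ANC"
  if (scope == "per_regime") {
    .assert(!is.null(regime), "per_regime scope needs a regime")
    evo <- evo & meta$regime == regime
    if (!is.null(generations)) evo <- evo & meta$generation %in% generations
  } else {
    if (is.null(generations)) generations <- max(meta$generation)
    evo <- evo & meta$generation %in% generations
  }
  if (min_present > sum(evo))
    stop(sprintf("min_present (%d) exceeds available evolved samples (%d)",
                 min_present, sum(evo)), call. = FALSE)
  n_pres <- rowSums(obs[, evo, drop = FALSE] >= 1L)
  keep <- n_pres >= min_present
  if (require_ancestor) {
    anc <- meta$regime == "ANC"
    keep <- keep & rowSums(obs[, anc, drop = FALSE]) >= 1L
  }
  subset_sites(x, keep, "presence")
}
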