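#' Call significance peaks from significant SNP positions
#'
#' A peak is any maximal cluster of significant SNPs in which at least
#' `min_snps` SNPs co-occur within a `window`-bp span (default: 3 SNPs in
#' 1 kb).  In the default `"span"` mode the criterion slides: every run of
#' `min_snps` consecutive significant SNPs whose positions span at most
#' `window` bp qualifies, and overlapping qualifying runs are chained into one
#' peak whose interval is the span of its member SNPs.  `"tile"` mode instead
#' counts SNPs in fixed windows `[1, window]`, `[window+1, 2*window]`, ...
#' (a sensitivity analysis; tiling introduces phase artifacts).
#'
#' @param x Either a numeric vector of positions (with `chrom` giving a single
#'   chromosome name) or a data.frame with columns `chrom`, `pos` of
#'   significant SNPs (e.g. a filtered `scan_result`).
#' @param chrom Chromosome label when `x` is a numeric vector.
#' @param min_snps Minimum significant SNPs per window (3, or 5 for the
#'   conservative call).
#' @param window Window length in bp (default 1000).
#' @param mode `"span"` (default) or `"tile"`.
#' @return data.frame of class `peak_set`: chrom, start, end (1-based
#'   inclusive, the span of member SNPs), n_sig_snps.
#' @export
call_peaks <- function(x, chrom = "chr", min_snps = 3L, window = 1000L,
                       mode = c("span", "tile")) {
  mode <- match.arg(mode)
  if (is.numeric(x)) x <- data.frame(chrom = chrom, pos = x)
  .assert(all(c("chrom", "pos") %in% names(x)), "need chrom/pos columns")
  res <- lapply(split(x$pos, x$chrom), function(pos) {
    pos <- sort(unique(pos))
    n <- length(pos)
    if (n < min_snps) return(NULL)
    if (mode == "span") {
      k <- min_snps
      seed <- which(pos[seq_len(n - k + 1L) + k - 1L] - pos[seq_len(n - k + 1L)] <= window)
      if (!length(seed)) return(NULL)
      # chain overlapping seed runs [i, i+k-1] in index space
      lo <- seed; hi <- seed + k - 1L
      brk <- c(TRUE, lo[-1] > hi[-length(hi)])  # new cluster when no shared SNP
      grp <- cumsum(brk)
      starts <- tapply(lo, grp, min); ends <- tapply(hi, grp, max)
      data.frame(start = pos[starts], end = pos[ends],
                 n_sig_snps = as.integer(ends - starts + 1L))
    } else {
      w <- (pos - 1L) %/% window
      tab <- table(w)
      qual <- as.integer(names(tab))[tab >= min_snps]
      if (!length(qual)) return(NULL)
      grp <- cumsum(c(TRUE, diff(qual) > 1L))  # merge adjacent qualifying tiles
      do.call(rbind, lapply(split(qual, grp), function(ws) {
        member <- pos[w %in% ws]
        data.frame(start = min(member), end = max(member),
                   n_sig_snps = length(member))
      }))
    }
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_sig_snps = integer())
  } else {
    out <- do.call(rbind, Map(function(ch, df) cbind(chrom = ch, df), names(res), res))
  }
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

# peak_set -> GRanges
.peaks_gr <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(peaks$start, peaks$end))
}

#' Merge peaks falling within the same gene
#'
#' Peaks whose intervals lie entirely within the same gene are combined into a
#' single intragenic peak (interval union, SNP counts summed). Peaks that only
#' partially overlap a gene, or that lie in different genes, are left alone.
#'
#' @param peaks A `peak_set` (from [call_peaks()]).
#' @param genes `GRanges` with `gene_id` (e.g. [read_gff3_genes()]).
#' @return A `peak_set` with a `gene_id` column (`NA` where not intragenic).
#' @export
merge_within_genes <- function(peaks, genes) {
  if (!nrow(peaks)) { peaks$gene_id <- character(0); return(peaks) }
  hits <- GenomicRanges::findOverlaps(.peaks_gr(peaks), genes, type = "within")
  gene_of <- rep(NA_character_, nrow(peaks))
  # a peak inside several (overlapping) genes is attributed to the first
  first <- !duplicated(S4Vectors::queryHits(hits))
  gene_of[S4Vectors::queryHits(hits)[first]] <-
    genes$gene_id[S4Vectors::subjectHits(hits)[first]]
  keyed <- !is.na(gene_of)
  merged <- do.call(rbind, lapply(split(which(keyed), gene_of[keyed]), function(idx) {
    data.frame(chrom = peaks$chrom[idx[1]], start = min(peaks$start[idx]),
               end = max(peaks$end[idx]), n_sig_snps = sum(peaks$n_sig_snps[idx]),
               gene_id = gene_of[idx[1]])
  }))
  rest <- peaks[!keyed, , drop = FALSE]
  rest$gene_id <- rep(NA_character_, nrow(rest))
  out <- rbind(merged, as.data.frame(rest)[, c("chrom", "start", "end", "n_sig_snps", "gene_id")])
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_set", "data.frame")
  out
}

#' Classify peaks against gene annotation
#'
#' Overlap-based (>= 1 bp) classification: `genic` (coding gene only),
#' `pseudogenic` (pseudogene only), `mixed` (both), `intergenic` (neither).
#' `gene_id` records the gene with the largest overlap.
#'
#' @param peaks A `peak_set`.
#' @param genes `GRanges` with `gene_id` and `biotype`
#'   (`protein_coding`/`pseudogene`).
#' @return The `peak_set` with `annotation_class` and `gene_id` columns.
#' @export
classify_peaks <- function(peaks, genes) {
  if (!nrow(peaks)) { peaks$annotation_class <- character(0); peaks$gene_id <- character(0); return(peaks) }
  gr <- .peaks_gr(peaks)
  hits <- GenomicRanges::findOverlaps(gr, genes)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  coding <- pseudo <- rep(FALSE, nrow(peaks))
  coding[unique(qh[genes$biotype[sh] == "protein_coding"])] <- TRUE
  pseudo[unique(qh[genes$biotype[sh] == "pseudogene"])] <- TRUE
  peaks$annotation_class <- ifelse(coding & pseudo, "mixed",
                            ifelse(coding, "genic",
                            ifelse(pseudo, "pseudogenic", "intergenic")))
  gene_of <- rep(NA_character_, nrow(peaks))
  if (length(hits)) {
    ov <- GenomicRanges::width(GenomicRanges::pintersect(gr[qh], genes[sh]))
    best <- tapply(seq_along(qh), qh, function(i) i[which.max(ov[i])])
    gene_of[as.integer(names(best))] <- genes$gene_id[sh[unlist(best)]]
  }
  peaks$gene_id <- gene_of
  peaks
}

#' Cross-regime peak overlap (upset-style combination counts)
#'
#' Peaks from different regimes are the "same" peak iff their intervals
#' overlap by at least 1 bp, chained transitively; each resulting merged peak
#' is counted once under the combination of regimes contributing to it.
#'
#' @param peaksets Named list of `peak_set` objects, one per regime.
#' @return List: `combinations` (data.frame `combination`, `n`) and `merged`
#'   (data.frame chrom, start, end, regimes).
#' @export
peak_overlap <- function(peaksets) {
  .assert(length(peaksets) >= 2, "need >= 2 peak sets")
  .assert(!is.null(names(peaksets)), "peaksets must be named by regime")
  tagged <- do.call(rbind, lapply(names(peaksets), function(r) {
    p <- peaksets[[r]]
    if (!nrow(p)) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end, regime = r)
  }))
  if (is.null(tagged))
    return(list(combinations = data.frame(combination = character(), n = integer()),
                merged = data.frame(chrom = character(), start = integer(),
                                    end = integer(), regimes = character())))
  gr <- GenomicRanges::GRanges(tagged$chrom, IRanges::IRanges(tagged$start, tagged$end))
  red <- GenomicRanges::reduce(gr)  # transitive union of >=1 bp overlaps
  cl <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(gr, red))
  regs <- vapply(split(tagged$regime, cl), function(r)
    paste(sort(unique(r)), collapse = "+"), character(1))
  merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                       start = GenomicRanges::start(red),
                       end = GenomicRanges::end(red),
                       regimes = regs[as.character(seq_along(red))])
  tab <- table(merged$regimes)
  list(combinations = data.frame(combination = names(tab), n = as.integer(tab)),
       merged = merged)
}

#' Peak width summaries
#'
#' Widths are `end - start + 1` bp (span of member SNPs).
#'
#' @param peaks A `peak_set` with at least one peak.
#' @return List: `median`, `mean`, `max`.
#' @export
width_stats <- function(peaks) {
  .assert(nrow(peaks) >= 1, "no peaks")
  w <- peaks$end - peaks$start + 1
  list(median = stats::median(w), mean = mean(w), max = max(w))
}

#' Arm/center enrichment of peaks vs the ancestral SNP distribution
#'
#' 1-df goodness-of-fit chi-square of observed peak domain counts (peaks
#' assigned to arm/center by their midpoint) against expected fractions taken
#' from the ancestral SNP distribution.
#'
#' @param peaks A `peak_set`.
#' @param domain_map Domain map (see [assign_domain()]).
#' @param expected_fractions Named numeric `c(arm=, center=)`, summing to 1.
#' @return List: `chisq`, `df`, `p`, `observed`, `expected`.
#' @export
arm_center_enrichment <- function(peaks, domain_map, expected_fractions) {
  .assert(abs(sum(expected_fractions) - 1) < 1e-8, "expected fractions must sum to 1")
  mid <- floor((peaks$start + peaks$end) / 2)
  dom <- assign_domain(peaks$chrom, mid, domain_map)
  obs <- table(factor(dom, c("arm", "center")))
  exp_n <- sum(obs) * expected_fractions[c("arm", "center")]
  if (any(exp_n < 1)) warning("expected cell count below 1; chi-square unreliable")
  chisq <- sum((as.numeric(obs) - exp_n)^2 / exp_n)
  list(chisq = unname(chisq), df = 1,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       observed = obs, expected = exp_n)
}
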