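# Shared in-code fixtures: tiny count tables, a toy experiment, and the
# independent brute-force peak oracle used by the property tests.

# minimal hand-built count table: `cells` is a list sample_id -> list(ref=, alt=)
toy_counts <- function(pos = c(100L, 200L), chrom = "I",
                       cells = list(s1 = list(ref = c(5L, 8L), alt = c(5L, 2L)))) {
  n <- length(pos)
  ref <- do.call(cbind, lapply(cells, function(c) c$ref))
  alt <- do.call(cbind, lapply(cells, function(c) c$alt))
  colnames(ref) <- colnames(alt) <- names(cells)
  site_counts(data.frame(chrom = rep_len(chrom, n), pos = pos,
                         ref = rep_len("A", n), alt = rep_len("G", n)),
              ref, alt)
}

# cached small simulated experiment shared across test files
toy_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      # pick a selected site with a workable starting frequency (site placement
      # is deterministic in the seed, so this pre-pass matches the final draw)
      pre <- gen_ancestral_sites(sim_config(seed = 42, n_sites = 300))
      target <- which.min(abs(pre$freq0 - 0.25))
      cfg <- sim_config(seed = 42, n_sites = 300,
                        selected_sites = data.frame(site = target, s = 0.15,
                                                    regime = "BS-PO"))
      cache <<- list(cfg = cfg, ex = gen_experiment(cfg), sel_site = target)
    }
    cache
  }
})

# Independent brute-force peak caller: enumerate every consecutive index
# interval [i, j], keep those with >= k SNPs spanning <= window bp, and merge
# intervals transitively whenever they share a SNP.
peak_oracle <- function(pos, min_snps = 3L, window = 1000L) {
  pos <- sort(unique(pos))
  n <- length(pos)
  qual <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (pos[j] - pos[i] > window) break  # sorted: span only grows with j
      if (j - i + 1L >= min_snps) qual[[length(qual) + 1L]] <- c(i, j)
    }
  }
  if (!length(qual))
    return(data.frame(start = integer(), end = integer(), n_sig_snps = integer()))
  m <- do.call(rbind, qual)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  merged <- list()
  cur <- m[1, ]
  for (r in seq_len(nrow(m))[-1]) {
    if (m[r, 1] <= cur[2]) cur[2] <- max(cur[2], m[r, 2])
    else { merged[[length(merged) + 1L]] <- cur; cur <- m[r, ] }
  }
  merged[[length(merged) + 1L]] <- cur
  do.call(rbind, lapply(merged, function(iv)
    data.frame(start = pos[iv[1]], end = pos[iv[2]],
               n_sig_snps = iv[2] - iv[1] + 1L)))
}

# toy gene annotation for peak classification tests
toy_genes <- function() {
  GenomicRanges::GRanges(
    rep("I", 3),
    IRanges::IRanges(start = c(1000, 5000, 8000), end = c(3000, 6000, 9000)),
    gene_id = c("gA", "gB", "gPseudo"),
    biotype = c("protein_coding", "protein_coding", "pseudogene"))
}
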