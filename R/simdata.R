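#' Simulation configuration for a pool-seq E&R experiment
#'
#' Defaults mirror the experimental design the package targets: census of
#' 5,000 worms per replicate, four selection regimes x six replicates sampled
#' at generations 0/13/22/31, three independent ancestor pool extractions,
#' pools of ~2,500 diploids, and mean sequencing coverages of 162x, 24x, 26x
#' and 50x for generations 0, 13, 22 and 31.  The ancestral site pool has an
#' arm-biased SNP density (arm:center 5:3) and a low-MAF-skewed spectrum whose
#' default shape (`0.5 * Beta(0.26, 3.5)`) gives a mean expected
#' heterozygosity 2p(1-p) of about 0.06, the ancestral genome-wide mean pi of
#' the emulated study.  `true_ne = 500` reflects the study's estimated Ne of
#' roughly 10% of census.
#'
#' @param seed Master integer seed; every emitted byte is a deterministic
#'   function of it (sub-streams via [derive_seed()]).
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#'   Default: six 1-Mb chromosomes I-V and X (a scaled-down worm genome).
#' @param domain_map data.frame (chrom, start, end, label) tiling each
#'   chromosome into `arm_left`/`center`/`arm_right`; default 25/50/25%.
#' @param n_sites Number of ancestral SNPs to draw.
#' @param arm_density_ratio Arm:center per-bp SNP density ratio (default 5/3).
#' @param maf_alpha,maf_beta Beta shape parameters of the ancestral MAF
#'   spectrum (minor allele frequency = 0.5 * Beta draw).
#' @param true_ne Diploid effective size driving drift (may be `Inf`).
#' @param census Diploid census size per replicate.
#' @param n_replicates Replicates per regime.
#' @param regimes Regime labels (default [REGIMES]).
#' @param sampled_generations Generations at which pools are sequenced;
#'   strictly increasing, starting at 0.
#' @param selected_sites data.frame (site, s, regime) of sites under
#'   selection; `regime = NA` applies the coefficient in every regime.
#' @param pool_individuals Diploid individuals per sequencing pool.
#' @param coverage_mean Named numeric: mean read depth per sampled generation.
#' @param n_ancestor_pools Independent ancestor pool extractions.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = stats::setNames(rep(1e6, 6), c("I", "II", "III", "IV", "V", "X")),
                       domain_map = default_domain_map(chrom_lengths),
                       n_sites = 5000L,
                       arm_density_ratio = 5 / 3,
                       maf_alpha = 0.26, maf_beta = 3.5,
                       true_ne = 500,
                       census = 5000L,
                       n_replicates = 6L,
                       regimes = REGIMES,
                       sampled_generations = c(0L, 13L, 22L, 31L),
                       selected_sites = data.frame(site = integer(), s = numeric(), regime = character()),
                       pool_individuals = 2500L,
                       coverage_mean = c(`0` = 162, `13` = 24, `22` = 26, `31` = 50),
                       n_ancestor_pools = 3L) {
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              domain_map = domain_map, n_sites = as.integer(n_sites),
              arm_density_ratio = arm_density_ratio,
              maf_alpha = maf_alpha, maf_beta = maf_beta,
              true_ne = true_ne, census = as.integer(census),
              n_replicates = as.integer(n_replicates), regimes = regimes,
              sampled_generations = as.integer(sampled_generations),
              selected_sites = selected_sites,
              pool_individuals = as.integer(pool_individuals),
              coverage_mean = coverage_mean,
              n_ancestor_pools = as.integer(n_ancestor_pools))
  .assert(all(cfg$chrom_lengths > 0) && cfg$n_sites > 0 && cfg$census > 0 &&
            cfg$n_replicates > 0 && cfg$pool_individuals > 0 &&
            cfg$n_ancestor_pools > 0, "all counts must be positive")
  .assert(cfg$maf_alpha > 0 && cfg$maf_beta > 0, "MAF shape parameters must be > 0")
  .assert(cfg$true_ne > 0, "true_ne must be positive")
  .assert(nrow(selected_sites) == 0 || all(abs(selected_sites$s) < 1), "|s| must be < 1")
  g <- cfg$sampled_generations
  .assert(g[1] == 0L && all(diff(g) > 0), "sampled generations must start at 0 and increase")
  .assert(all(as.character(g) %in% names(cfg$coverage_mean) | length(cfg$coverage_mean) == 1),
          "coverage_mean must name every sampled generation (or be scalar)")
  .assert(all(cfg$domain_map$end >= cfg$domain_map$start),
          "degenerate (zero-length) domains in domain_map")
  .assert(cfg$n_sites <= sum(cfg$chrom_lengths), "n_sites exceeds total genome length")
  structure(cfg, class = "sim_config")
}

#' Default arm/center domain map
#'
#' Tiles each chromosome into `arm_left` (first `arm_frac`), `center`, and
#' `arm_right` (last `arm_frac`), 1-based inclusive, mirroring the arm/center
#' recombination-domain structure of the worm genome.
#'
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param arm_frac Fraction of each chromosome per arm (default 0.25).
#' @return data.frame (chrom, start, end, label).
#' @export
default_domain_map <- function(chrom_lengths, arm_frac = 0.25) {
  .assert(arm_frac > 0 && arm_frac < 0.5, "arm_frac must be in (0, 0.5)")
  do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    b1 <- floor(L * arm_frac); b2 <- L - floor(L * arm_frac)
    data.frame(chrom = ch, start = c(1, b1 + 1, b2 + 1), end = c(b1, b2, L),
               label = c("arm_left", "center", "arm_right"))
  }))
}

#' Draw an ancestral SNP pool
#'
#' Site positions are placed with per-domain density proportional to
#' `arm_density_ratio` for arms versus 1 for centers; true alternate-allele
#' frequencies are the minor allele frequencies, drawn as `0.5 * Beta(alpha,
#' beta)` (folded to (0, 0.5]).
#'
#' @param config A [sim_config()].
#' @return data.frame of class `ancestral_sites`: chrom, pos, ref, alt,
#'   domain (arm/center) and `freq0`, the true generation-0 frequency.
#' @export
gen_ancestral_sites <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "ancestral_sites"))
  dm <- config$domain_map
  is_arm <- dm$label %in% c("arm_left", "arm_right")
  len <- dm$end - dm$start + 1
  w <- len * ifelse(is_arm, config$arm_density_ratio, 1)
  dom_idx <- sample.int(nrow(dm), config$n_sites, replace = TRUE, prob = w / sum(w))
  pos <- dm$start[dom_idx] + floor(stats::runif(config$n_sites) * len[dom_idx])
  chrom <- dm$chrom[dom_idx]
  # resample coordinate collisions so positions are unique per chromosome
  repeat {
    dup <- duplicated(paste(chrom, pos))
    if (!any(dup)) break
    pos[dup] <- dm$start[dom_idx[dup]] + floor(stats::runif(sum(dup)) * len[dom_idx[dup]])
  }
  maf <- 0.5 * stats::rbeta(config$n_sites, config$maf_alpha, config$maf_beta)
  maf <- pmax(maf, 1e-6)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  out <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = unname(alt),
                    domain = ifelse(is_arm[dom_idx], "arm", "center"), freq0 = maf)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ancestral_sites", "data.frame")
  out
}

#' Simulate Wright-Fisher allele-frequency trajectories
#'
#' One unbroken diploid Wright-Fisher lineage: per generation a deterministic
#' (haploid-equivalent, multiplicative) selection update
#' `p' = p(1+s) / (1 + p s)` followed by binomial resampling of `2 * ne`
#' allele copies.  `ne = Inf` skips resampling (the deterministic limit).
#' Fixed and lost sites are absorbing.
#'
#' @param freq0 Numeric vector of starting frequencies in \[0, 1\].
#' @param generations Increasing integer vector of generations to record,
#'   starting at 0.
#' @param ne Diploid effective size (may be `Inf`).
#' @param s Selection coefficient, scalar or per-site vector (`|s| < 1`).
#' @return Matrix sites x generations of true frequencies (columns named by
#'   generation).
#' @export
simulate_trajectories <- function(freq0, generations = c(0, 13, 22, 31), ne = 500, s = 0) {
  .assert(all(freq0 >= 0 & freq0 <= 1), "freq0 must lie in [0, 1]")
  .assert(generations[1] == 0 && all(diff(generations) > 0), "generations must start at 0 and increase")
  .assert(all(abs(s) < 1), "|s| must be < 1")
  n <- length(freq0)
  s <- rep_len(s, n)
  out <- matrix(NA_real_, n, length(generations),
                dimnames = list(NULL, as.character(generations)))
  p <- freq0
  out[, 1] <- p
  if (length(generations) > 1) {
    for (g in seq_len(max(generations))) {
      p <- p * (1 + s) / (1 + p * s)
      if (is.finite(ne)) p <- stats::rbinom(n, 2 * ne, p) / (2 * ne)
      hit <- match(g, generations)
      if (!is.na(hit)) out[, hit] <- p
    }
  }
  out
}

#' Two-stage pool-seq sampling of read counts
#'
#' Models pooled DNA extraction plus short-read sampling: the pool allele
#' frequency is `q ~ Binomial(2 * pool_individuals, p_true) / (2 *
#' pool_individuals)`, then `alt ~ Binomial(coverage, q)`.
#' `pool_individuals = Inf` collapses to single-stage binomial read sampling.
#'
#' @param p_true True frequencies in \[0, 1\] (vectorised).
#' @param pool_individuals Diploid individuals in the pool.
#' @param coverage Read depth per site (scalar or vector).
#' @param seed Optional seed (set before drawing).
#' @return List with integer vectors `alt` and `ref` (`ref = coverage - alt`).
#' @export
pool_seq_sample <- function(p_true, pool_individuals, coverage, seed = NULL) {
  .assert(all(p_true >= 0 & p_true <= 1), "p_true must lie in [0, 1]")
  .assert(all(pool_individuals >= 1), "pool_individuals must be >= 1")
  .assert(all(coverage >= 0), "coverage must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(p_true)
  coverage <- rep_len(coverage, n)
  q <- if (is.finite(pool_individuals))
    stats::rbinom(n, 2 * pool_individuals, p_true) / (2 * pool_individuals)
  else p_true
  alt <- stats::rbinom(n, coverage, q)
  list(alt = as.integer(alt), ref = as.integer(coverage - alt))
}

#' Simulate a full pool-seq E&R experiment
#'
#' Draws an ancestral SNP pool, evolves one Wright-Fisher lineage per regime x
#' replicate (regime-specific selection coefficients via
#' `config$selected_sites`), and emits two-stage pool-seq counts: ancestor
#' pools at generation 0 plus one sample per regime x replicate x evolved
#' generation — with defaults, 3 + 4 x 6 x 3 = 75 columns.  Per-site read
#' depths are Poisson around the generation's mean coverage.
#'
#' @param config A [sim_config()].
#' @return List: `counts` ([site_counts()]), `meta` ([sample_meta()]),
#'   `truth` (list with `freq`, a 4-d array site x generation x replicate x
#'   regime of true frequencies, and `selected`, the selected-site table),
#'   and `ancestral` (the [gen_ancestral_sites()] table).
#' @export
gen_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  anc <- gen_ancestral_sites(config)
  n <- nrow(anc)
  gens <- config$sampled_generations
  evolved_gens <- gens[gens > 0]
  regs <- config$regimes
  freq <- array(NA_real_, dim = c(n, length(gens), config$n_replicates, length(regs)),
                dimnames = list(NULL, as.character(gens), NULL, regs))
  s_for_regime <- function(regime) {
    s <- rep(0, n)
    ss <- config$selected_sites
    if (nrow(ss)) {
      use <- is.na(ss$regime) | ss$regime == "" | ss$regime == regime
      s[ss$site[use]] <- ss$s[use]
    }
    s
  }
  cov_for <- function(g) {
    cm <- config$coverage_mean
    if (length(cm) == 1 && is.null(names(cm))) cm else cm[[as.character(g)]]
  }
  ids <- character(0); ref_l <- list(); alt_l <- list(); meta_l <- list()
  for (k in seq_len(config$n_ancestor_pools)) {
    id <- sprintf("ANC_p%d", k)
    set.seed(derive_seed(config$seed, "pool", "ANC", k))
    cov <- stats::rpois(n, cov_for(0))
    cnt <- pool_seq_sample(anc$freq0, config$pool_individuals, cov)
    ids <- c(ids, id); ref_l[[id]] <- cnt$ref; alt_l[[id]] <- cnt$alt
    meta_l[[id]] <- data.frame(sample_id = id, regime = "ANC", replicate = 0L, generation = 0L)
  }
  for (r in regs) {
    s <- s_for_regime(r)
    for (j in seq_len(config$n_replicates)) {
      set.seed(derive_seed(config$seed, "trajectory", r, j))
      traj <- simulate_trajectories(anc$freq0, gens, config$true_ne, s)
      freq[, , j, r] <- traj
      for (g in evolved_gens) {
        id <- sprintf("%s_r%d_g%d", regime_code(r), j, g)
        set.seed(derive_seed(config$seed, "pool", r, j, g))
        cov <- stats::rpois(n, cov_for(g))
        cnt <- pool_seq_sample(traj[, as.character(g)], config$pool_individuals, cov)
        ids <- c(ids, id); ref_l[[id]] <- cnt$ref; alt_l[[id]] <- cnt$alt
        meta_l[[id]] <- data.frame(sample_id = id, regime = r, replicate = j, generation = g)
      }
    }
  }
  ref <- do.call(cbind, ref_l); alt <- do.call(cbind, alt_l)
  colnames(ref) <- colnames(alt) <- ids
  meta <- do.call(rbind, meta_l)
  counts <- site_counts(anc[, c("chrom", "pos", "ref", "alt")], ref, alt)
  list(counts = counts,
       meta = sample_meta(meta$sample_id, meta$regime, meta$replicate, meta$generation),
       truth = list(freq = freq, selected = config$selected_sites),
       ancestral = anc)
}

#' Simulate a toy gene annotation
#'
#' Places non-overlapping gene models (coding genes and pseudogenes) uniformly
#' along each chromosome, for exercising peak classification.
#'
#' @param config A [sim_config()].
#' @param genes_per_chrom Genes per chromosome.
#' @param mean_len Mean gene length (bp).
#' @param pseudogene_frac Fraction of genes that are pseudogenes.
#' @return [GenomicRanges::GRanges] with metadata columns `gene_id`, `biotype`.
#' @export
gen_annotation <- function(config, genes_per_chrom = 30L, mean_len = 2000L,
                           pseudogene_frac = 0.15) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "annotation"))
  rows <- lapply(names(config$chrom_lengths), function(ch) {
    L <- config$chrom_lengths[[ch]]
    len <- pmax(200L, stats::rpois(genes_per_chrom, mean_len))
    slot <- floor(L / genes_per_chrom)
    start <- (seq_len(genes_per_chrom) - 1L) * slot +
      floor(stats::runif(genes_per_chrom) * pmax(1L, slot - len))
    start <- pmax(1L, as.integer(start))
    data.frame(chrom = ch, start = start, end = pmin(L, start + len - 1L),
               gene_id = sprintf("gene_%s_%03d", ch, seq_len(genes_per_chrom)),
               biotype = ifelse(stats::runif(genes_per_chrom) < pseudogene_frac,
                                "pseudogene", "protein_coding"))
  })
  df <- do.call(rbind, rows)
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         gene_id = df$gene_id, biotype = df$biotype)
}

#' Write a simulated experiment to plain-text files
#'
#' Emits the counts TSV, sample-metadata TSV, a BED repeat mask (optionally
#' empty), a GFF3 toy annotation, a domain-map TSV, and a ground-truth TSV of
#' true frequencies.
#'
#' @param experiment Result of [gen_experiment()].
#' @param dir Output directory (created if needed).
#' @param config The [sim_config()] used (for domains/annotation).
#' @param mask Optional `GRanges` repeat mask to write (default empty).
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim_dataset <- function(experiment, dir, config, mask = GenomicRanges::GRanges()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             meta = file.path(dir, "meta.tsv"),
             mask = file.path(dir, "mask.bed"),
             gff = file.path(dir, "genes.gff3"),
             domains = file.path(dir, "domains.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(experiment$counts, paths[["counts"]])
  write_sample_meta(experiment$meta, paths[["meta"]])
  if (length(mask)) {
    utils::write.table(data.frame(as.character(GenomicRanges::seqnames(mask)),
                                  GenomicRanges::start(mask) - 1L,
                                  GenomicRanges::end(mask)),
                       paths[["mask"]], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else file.create(paths[["mask"]])
  write_gff3(gen_annotation(config), paths[["gff"]])
  utils::write.table(config$domain_map, paths[["domains"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fr <- experiment$truth$freq
  dn <- dimnames(fr)
  long <- do.call(rbind, lapply(dn[[4]], function(r)
    do.call(rbind, lapply(seq_len(dim(fr)[3]), function(j)
      data.frame(site = seq_len(dim(fr)[1]), regime = r, replicate = j,
                 generation = rep(as.integer(dn[[2]]), each = dim(fr)[1]),
                 freq = as.vector(fr[, , j, r]))))))
  utils::write.table(long, paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write a GRanges gene annotation as GFF3
#'
#' @param genes `GRanges` with `gene_id` and `biotype` metadata columns.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(genes)) {
    df <- data.frame(seqid = as.character(GenomicRanges::seqnames(genes)),
                     source = "poolsel", type = "gene",
                     start = GenomicRanges::start(genes),
                     end = GenomicRanges::end(genes),
                     score = ".", strand = "+", phase = ".",
                     attr = sprintf("ID=%s;biotype=%s", genes$gene_id, genes$biotype))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a GFF3 gene annotation
#'
#' Keeps `gene` (and `pseudogene`) features; the biotype is taken from a
#' `biotype` attribute when present, else from the feature type.
#'
#' @param path GFF3 file.
#' @return `GRanges` with `gene_id`, `biotype`.
#' @export
read_gff3_genes <- function(path) {
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- rtracklayer::import(path, format = "GFF3")
    gr <- gr[gr$type %in% c("gene", "pseudogene")]
    bt <- if (!is.null(gr$biotype)) as.character(gr$biotype) else as.character(gr$type)
    bt[is.na(bt)] <- as.character(gr$type)[is.na(bt)]
    id <- if (!is.null(gr$ID)) as.character(gr$ID) else sprintf("gene_%d", seq_along(gr))
    out <- GenomicRanges::granges(gr)
    out$gene_id <- id
    out$biotype <- ifelse(bt == "gene", "protein_coding", bt)
    return(out)
  }
  df <- utils::read.table(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE)
  df <- df[df[[3]] %in% c("gene", "pseudogene"), , drop = FALSE]
  id <- sub(".*ID=([^;]+).*", "\\1", df[[9]])
  bt <- ifelse(grepl("biotype=", df[[9]]), sub(".*biotype=([^;]+).*", "\\1", df[[9]]),
               ifelse(df[[3]] == "pseudogene", "pseudogene", "protein_coding"))
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[4]], df[[5]]))
  gr$gene_id <- id
  gr$biotype <- bt
  gr
}

#' Fertility-assay simulation configuration
#'
#' Defaults mirror the competitive-fertility assay design: the ancestor plus
#' four regimes x six replicates, two conditions (`total` competitive success
#' and `post`-insemination-only success), three assays per population with
#' ~342 progeny scored each (so the three pooled ancestor assays total ~1,026,
#' the scale of the emulated study), and mild beta-binomial overdispersion.
#' Ancestral siring probabilities default to the study's printed means (44.5%
#' total, 4.1% post); evolved probabilities are fold-changes on the ancestor
#' (post-insemination folds of 5.0/4.5/5.5/6.8 for WS-P&P/WS-PO/BS-P&P/BS-PO).
#'
#' @param seed Integer seed.
#' @param anc_prob Named numeric `c(total=, post=)` ancestral siring
#'   probabilities.
#' @param fold_total,fold_post Named numeric per-regime fold changes on the
#'   ancestral probabilities.
#' @param n_replicates Evolved replicates per regime.
#' @param progeny_per_assay Progeny scored per assay (>= 200 by design).
#' @param n_assays Assays per population x condition.
#' @param overdispersion_rho Beta-binomial intra-class correlation in `[0, 1)`;
#'   0 degenerates to binomial.
#' @return List of class `fertility_sim_config`.
#' @export
fertility_sim_config <- function(seed = 1L,
                                 anc_prob = c(total = 0.445, post = 0.041),
                                 fold_total = c("WS-P&P" = 1.35, "WS-PO" = 1.25,
                                                "BS-P&P" = 1.15, "BS-PO" = 1.30),
                                 fold_post = c("WS-P&P" = 5.0, "WS-PO" = 4.5,
                                               "BS-P&P" = 5.5, "BS-PO" = 6.8),
                                 n_replicates = 6L,
                                 progeny_per_assay = 342L,
                                 n_assays = 3L,
                                 overdispersion_rho = 0.02) {
  cfg <- list(seed = as.integer(seed), anc_prob = anc_prob,
              fold_total = fold_total, fold_post = fold_post,
              n_replicates = as.integer(n_replicates),
              progeny_per_assay = as.integer(progeny_per_assay),
              n_assays = as.integer(n_assays),
              overdispersion_rho = overdispersion_rho)
  .assert(all(anc_prob > 0 & anc_prob < 1), "ancestral probabilities must lie in (0, 1)")
  .assert(all(anc_prob["total"] * fold_total < 1) && all(anc_prob["post"] * fold_post < 1),
          "fold changes push a siring probability outside (0, 1)")
  .assert(cfg$progeny_per_assay >= 1 && cfg$n_assays >= 1 && cfg$n_replicates >= 1,
          "counts must be positive")
  .assert(overdispersion_rho >= 0 && overdispersion_rho < 1, "rho must be in [0, 1)")
  structure(cfg, class = "fertility_sim_config")
}

# beta-binomial draw with mean prob p and intra-class correlation rho
.rbetabinom <- function(n, size, p, rho) {
  if (rho == 0) return(stats::rbinom(n, size, p))
  nu <- 1 / rho - 1
  stats::rbinom(n, size, stats::rbeta(n, p * nu, (1 - p) * nu))
}

#' Simulate competitive-fertility assay counts
#'
#' Per population x condition x assay, the focal-male progeny count is drawn
#' beta-binomially around the population's true siring probability; the
#' remainder are competitor progeny.
#'
#' @param config A [fertility_sim_config()].
#' @return data.frame of class `fertility_assays`: population, regime,
#'   replicate, condition, assay, n_focal, n_competitor, plus a `true_prob`
#'   column of ground truth.
#' @export
gen_fertility_assays <- function(config) {
  stopifnot(inherits(config, "fertility_sim_config"))
  set.seed(derive_seed(config$seed, "fertility"))
  pops <- rbind(data.frame(population = "ANC", regime = "ANC", replicate = 0L),
                do.call(rbind, lapply(names(config$fold_total), function(r)
                  data.frame(population = sprintf("%s_r%d", regime_code(r),
                                                  seq_len(config$n_replicates)),
                             regime = r, replicate = seq_len(config$n_replicates)))))
  rows <- lapply(seq_len(nrow(pops)), function(i) {
    do.call(rbind, lapply(c("total", "post"), function(cond) {
      p <- config$anc_prob[[cond]]
      if (pops$regime[i] != "ANC")
        p <- p * (if (cond == "total") config$fold_total else config$fold_post)[[pops$regime[i]]]
      nf <- .rbetabinom(config$n_assays, config$progeny_per_assay, p,
                        config$overdispersion_rho)
      data.frame(population = pops$population[i], regime = pops$regime[i],
                 replicate = pops$replicate[i], condition = cond,
                 assay = seq_len(config$n_assays), n_focal = nf,
                 n_competitor = config$progeny_per_assay - nf, true_prob = p)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("fertility_assays", "data.frame")
  out
}
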