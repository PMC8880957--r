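#' Default end-to-end run configuration
#'
#' Every analysis threshold surfaces as a named key with the pipeline's
#' canonical value as default: 5% coverage tails, presence minima of 10
#' (Model 1) and 9 (Model 2), alpha = 0.05 with genome-wide Bonferroni,
#' peaks of >= 3 significant SNPs per 1 kb window (5 for the conservative
#' call), t = 31 generations, and Nf = 2,500 breeding females.
#'
#' @param outdir Output directory.
#' @param seed Integer seed (drives simulation when no counts are supplied).
#' @param counts,meta,mask,gff,domains,assays Optional input file paths; any
#'   that are `NULL` are simulated via [gen_experiment()] /
#'   [gen_fertility_assays()].
#' @param n_sites Simulated SNP count when simulating (default 2000).
#' @return List of class `run_config`.
#' @export
run_config <- function(outdir, seed = 1L, counts = NULL, meta = NULL, mask = NULL,
                       gff = NULL, domains = NULL, assays = NULL, n_sites = 2000L) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              counts = counts, meta = meta, mask = mask, gff = gff,
              domains = domains, assays = assays, n_sites = as.integer(n_sites),
              lower_q = 0.05, upper_q = 0.95,
              min_present_model1 = 10L, min_present_model2 = 9L,
              alpha = 0.05, min_snps = 3L, min_snps_conservative = 5L,
              window = 1000L, t_generations = 31L, nf = 2500,
              pool_individuals = 2500L)
  for (p in c("counts", "meta", "mask", "gff", "domains", "assays"))
    .assert(is.null(cfg[[p]]) || file.exists(cfg[[p]]),
            sprintf("input file for '%s' does not exist", p))
  structure(cfg, class = "run_config")
}

.log_stage <- function(stage, msg, level = "INFO")
  message(sprintf("[%s] %s: %s", level, stage, msg))

#' Run the end-to-end pool-seq E&R analysis
#'
#' Executes, in pipeline order: simulate (when no inputs are given) ->
#' filter (repeat mask, coverage tails) -> diversity -> temporal Ne ->
#' allele-frequency-change scans (Model 1 and Model 2 per regime) -> peak
#' calling/classification -> fertility statistics.  Writes per-stage TSVs and
#' a JSON manifest (seed, record counts, drop accounting) under
#' `config$outdir`; re-running with an identical config reproduces identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = as.character(utils::packageVersion("poolsel")),
                   seed = config$seed, stages = list())
  note <- function(stage, ...) manifest$stages[[stage]] <<- list(...)

  # -- stage 1: simulate or load ------------------------------------------
  if (is.null(config$counts)) {
    .log_stage("simulate", sprintf("generating %d-SNP experiment, seed %d",
                                   config$n_sites, config$seed))
    scfg <- sim_config(seed = config$seed, n_sites = config$n_sites)
    exper <- gen_experiment(scfg)
    counts <- exper$counts; meta <- exper$meta
    genes <- gen_annotation(scfg)
    domain_map <- scfg$domain_map
    mask <- GenomicRanges::GRanges()
    fa <- gen_fertility_assays(fertility_sim_config(seed = config$seed))
    write_sim_dataset(exper, file.path(config$outdir, "simulated"), scfg)
    note("simulate", n_sites = n_sites(counts), n_samples = n_samples(counts))
  } else {
    .log_stage("load", config$counts)
    rc <- read_counts(config$counts, format = "tsv", meta = config$meta)
    counts <- rc$counts; meta <- rc$meta
    mask <- if (!is.null(config$mask)) read_bed_mask(config$mask) else GenomicRanges::GRanges()
    genes <- if (!is.null(config$gff)) read_gff3_genes(config$gff) else NULL
    domain_map <- if (!is.null(config$domains))
      utils::read.delim(config$domains, stringsAsFactors = FALSE) else NULL
    fa <- if (!is.null(config$assays)) {
      df <- utils::read.delim(config$assays, stringsAsFactors = FALSE)
      class(df) <- c("fertility_assays", "data.frame"); df
    } else NULL
    note("load", n_sites = n_sites(counts), n_samples = n_samples(counts))
  }
  .assert(!is.null(meta), "sample metadata is required")
  n_in <- n_sites(counts)

  # -- stage 2: filters ----------------------------------------------------
  counts <- mask_repeats(counts, mask)
  counts <- filter_coverage_tails(counts, config$lower_q, config$upper_q)
  dl <- drop_log(counts)
  .log_stage("filter", sprintf("%d -> %d sites (%s)", n_in, n_sites(counts),
                               paste(sprintf("%s=%d", dl$reason, dl$n), collapse = ", ")))
  note("filter", input = n_in, retained = n_sites(counts),
       dropped = stats::setNames(as.list(dl$n), dl$reason))
  write_counts(counts, file.path(config$outdir, "counts_filtered.tsv"))

  # -- stage 3: ancestral diversity ---------------------------------------
  anc_cols <- meta$sample_id[meta$regime == "ANC"]
  anc <- site_counts(counts$sites,
                     counts$ref[, anc_cols, drop = FALSE],
                     counts$alt[, anc_cols, drop = FALSE])
  div <- diversity_summary(anc, domain_map = domain_map, window = config$window)
  utils::write.table(div$windows, file.path(config$outdir, "theta_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .log_stage("diversity", sprintf("mean pi = %.4f over %d SNPs", div$mean_pi, n_sites(anc)))
  note("diversity", mean_pi = div$mean_pi, n_windows = nrow(div$windows))

  # -- stage 4: temporal Ne -----------------------------------------------
  net <- ne_table(counts, meta, method = "both",
                  pool_individuals = config$pool_individuals)
  utils::write.table(net, file.path(config$outdir, "ne_estimates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gw <- stats::aggregate(ne ~ regime + replicate + method,
                         data = net[is.finite(net$ne), ], FUN = mean)
  aov_res <- tryCatch({
    d <- gw[gw$method == "jonas_planII", ]
    regime_anova(d$ne, d$regime)
  }, error = function(e) NULL)
  note("ne", n_estimates = nrow(net),
       anova_p = if (is.null(aov_res)) NA else aov_res$p)
  .log_stage("ne", sprintf("%d chromosome x replicate estimates", nrow(net)))

  # -- stage 5: scans ------------------------------------------------------
  scans <- list()
  for (r in setdiff(unique(meta$regime), "ANC")) {
    scans[[r]] <- model2_scan(counts, meta, regime = r, alpha = config$alpha,
                              min_present = config$min_present_model2)
    utils::write.table(scans[[r]],
                       file.path(config$outdir, sprintf("scan_model2_%s.tsv", regime_code(r))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  m1 <- model1_contrasts(counts, meta, alpha = config$alpha,
                         min_present = config$min_present_model1)
  utils::write.table(m1, file.path(config$outdir, "scan_model1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  n_sig2 <- vapply(scans, function(s) sum(s$significant), integer(1))
  note("scan", model1_m = attr(m1, "m"), model1_sig = sum(m1$significant),
       model2_m = lapply(scans, attr, "m"), model2_sig = as.list(n_sig2))
  .log_stage("scan", sprintf("Model 2 significant SNPs: %s",
                             paste(sprintf("%s=%d", names(n_sig2), n_sig2), collapse = ", ")))

  # -- stage 6: peaks ------------------------------------------------------
  peaksets <- lapply(scans, function(s)
    call_peaks(s[s$significant, c("chrom", "pos")], min_snps = config$min_snps,
               window = config$window))
  if (!is.null(genes))
    peaksets <- lapply(peaksets, function(p)
      classify_peaks(merge_within_genes(p, genes), genes))
  all_peaks <- do.call(rbind, lapply(names(peaksets), function(r) {
    p <- peaksets[[r]]
    if (!nrow(p)) return(NULL)
    cbind(regime = r, as.data.frame(p))
  }))
  if (!is.null(all_peaks))
    utils::write.table(all_peaks, file.path(config$outdir, "peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  n_peaks <- vapply(peaksets, nrow, integer(1))
  note("peaks", n = as.list(n_peaks))
  .log_stage("peaks", paste(sprintf("%s=%d", names(n_peaks), n_peaks), collapse = ", "))

  # -- stage 7: fertility --------------------------------------------------
  if (!is.null(fa)) {
    res <- list()
    for (cond in unique(fa$condition)) {
      sub <- fa[fa$condition == cond, , drop = FALSE]
      pooled <- pool_assays(sub[sub$population == "ANC", , drop = FALSE])
      pt <- prop_test_one_sample(pooled$x, pooled$n)
      fc <- fold_change(sub)
      res[[cond]] <- list(anc_chisq = pt$chisq, anc_p = pt$p,
                          anc_prop = pt$estimate,
                          folds = stats::setNames(fc$regimes$mean_fold, fc$regimes$regime))
    }
    if (all(c("total", "post") %in% names(res))) {
      res$contribution_pct <- contribution_fraction(res$post$anc_prop, res$total$anc_prop)
      .log_stage("fertility", sprintf("post-insemination contribution = %.1f%%",
                                      res$contribution_pct))
    }
    note("fertility", summary = res)
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
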