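#' Per-locus standardized temporal variance in allele frequency (Fc)
#'
#' `Fc = (x - y)^2 / ((x + y)/2 - x*y)` for frequencies `x` at the first and
#' `y` at the second time point. Loci whose denominator is not positive (fixed
#' for the same allele at both ends) are inadmissible and return `NA`.
#'
#' @param x,y Allele frequencies in \[0, 1\] (vectorised).
#' @return Numeric vector of Fc values (`NA` = excluded locus).
#' @export
fc_per_locus <- function(x, y) {
  .assert(all(x >= 0 & x <= 1) && all(y >= 0 & y <= 1), "frequencies must lie in [0, 1]")
  den <- (x + y) / 2 - x * y
  out <- (x - y)^2 / den
  out[den <= 0] <- NA_real_
  out
}

# per-stage sampling correction, as Fc-scale variance fraction
.stage_correction <- function(method, depth, pool) {
  if (method == "waples_planII") {
    # reads treated as the (diploid-equivalent) temporal sample: 1/(2*S), S = depth
    ifelse(is.finite(depth), 1 / (2 * depth), 0)
  } else {
    # two-stage pool-seq correction: read sampling from a finite pool of
    # 2*pool chromosomes contributes var/(p(1-p)) = 1/R + (1 - 1/R)/(2*N_pool)
    r_term <- ifelse(is.finite(depth), 1 / depth, 0)
    p_term <- ifelse(is.finite(pool), (1 - r_term) / (2 * pool), 0)
    r_term + p_term
  }
}

#' Temporal Ne estimate from paired allele frequencies
#'
#' The multi-locus `Fc_bar` is corrected for sampling noise at the two stages
#' and inverted:
#' `Ne = t / (2 * (Fc_bar - c0 - ct))`.
#' By default `Fc_bar` pools information across loci as a ratio of sums,
#' `sum((x-y)^2) / sum((x+y)/2 - x*y)` — equivalent to weighting each locus's
#' Fc by its heterozygosity — which is essentially unbiased under drift even
#' with many low-frequency loci.  `aggregate = "mean"` instead averages the
#' per-locus Fc values; that unweighted form is strongly upward-biased for Ne
#' when the allele-frequency spectrum is skewed toward rare alleles (rare
#' loci drifting to loss drop out of the admissible set) and is provided for
#' comparison only.
#' With `method = "waples_planII"` the per-stage correction is `1/(2*S)` with
#' `S` the read depth (reads standing in for the sampled individuals); with
#' `method = "jonas_planII"` the full two-stage pool-seq correction
#' `1/R + (1 - 1/R)/(2*N_pool)` is used, accounting for both read sampling
#' and the finite pool of individuals. A non-positive corrected Fc means the
#' drift signal is below the sampling noise and yields `Ne = Inf` (flagged).
#'
#' @param x,y Frequencies at generation 0 and generation `t`.
#' @param t Generations elapsed (>= 1).
#' @param method `"jonas_planII"` (default) or `"waples_planII"`.
#' @param depth0,deptht Read depths per stage (scalar or per-locus; may be
#'   `Inf` for exact frequencies).
#' @param pool0,poolt Diploid pool sizes per stage (may be `Inf`); only used
#'   by the two-stage method.
#' @param aggregate `"ratio_of_sums"` (default) or `"mean"`.
#' @return List of class `ne_estimate`: `method`, `fc_bar`, `ne`,
#'   `n_loci`, `n_excluded`, `t`, `infinite` flag.
#' @export
estimate_ne <- function(x, y, t, method = c("jonas_planII", "waples_planII"),
                        depth0 = Inf, deptht = Inf, pool0 = Inf, poolt = Inf,
                        aggregate = c("ratio_of_sums", "mean")) {
  method <- match.arg(method)
  aggregate <- match.arg(aggregate)
  .assert(t >= 1, "t must be >= 1")
  fc <- fc_per_locus(x, y)
  ok <- !is.na(fc)
  .assert(any(ok), "no admissible loci")
  n <- length(fc)
  c0 <- mean(rep_len(.stage_correction(method, depth0, pool0), n)[ok])
  ct <- mean(rep_len(.stage_correction(method, deptht, poolt), n)[ok])
  fc_bar <- if (aggregate == "mean") mean(fc[ok]) else
    sum((x - y)[ok]^2) / sum(((x + y) / 2 - x * y)[ok])
  denom <- 2 * (fc_bar - c0 - ct)
  ne <- if (denom <= 0) Inf else t / denom
  structure(list(method = method, fc_bar = fc_bar, ne = ne, t = t,
                 n_loci = sum(ok), n_excluded = sum(!ok),
                 infinite = !is.finite(ne)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf("Ne estimate (%s): Ne = %s (Fc_bar = %.5g, t = %d, %d loci, %d excluded)\n",
              x$method, format(x$ne, digits = 5), x$fc_bar, x$t, x$n_loci, x$n_excluded))
  invisible(x)
}

#' Per chromosome x regime x replicate temporal Ne table
#'
#' For each regime x replicate, frequencies from the merged ancestor pools
#' (counts summed, generation 0) are paired with that replicate's
#' final-generation sample; Ne is estimated per chromosome on the common SNP
#' set (coverage >= 1 in both samples and admissible Fc denominator), with
#' per-locus read depths and the configured pool sizes.
#'
#' @param counts A [site_counts()] object.
#' @param meta Matching [sample_meta()].
#' @param method Passed to [estimate_ne()] (`"both"` runs the two methods).
#' @param pool_individuals Diploid pool size used for both stages.
#' @param generation Final generation (default: maximum in `meta`).
#' @return data.frame: chrom, regime, replicate, method, fc_bar, ne, n_loci.
#' @export
ne_table <- function(counts, meta, method = "both", pool_individuals = 2500,
                     generation = NULL) {
  meta <- check_meta(counts, meta)
  if (is.null(generation)) generation <- max(meta$generation)
  t_gen <- generation
  methods <- if (identical(method, "both")) c("waples_planII", "jonas_planII") else method
  anc_cols <- meta$regime == "ANC"
  .assert(any(anc_cols), "no ancestor samples in metadata")
  ref0 <- rowSums(counts$ref[, anc_cols, drop = FALSE])
  alt0 <- rowSums(counts$alt[, anc_cols, drop = FALSE])
  cov0 <- ref0 + alt0
  rows <- list()
  for (r in setdiff(unique(meta$regime), "ANC")) {
    for (j in sort(unique(meta$replicate[meta$regime == r]))) {
      col <- which(meta$regime == r & meta$replicate == j & meta$generation == t_gen)
      if (length(col) != 1) next
      covt <- counts$ref[, col] + counts$alt[, col]
      common <- cov0 >= 1 & covt >= 1
      x <- alt0 / cov0
      yv <- counts$alt[, col] / covt
      for (ch in unique(counts$sites$chrom)) {
        idx <- common & counts$sites$chrom == ch
        if (!any(idx)) next
        for (m in methods) {
          est <- estimate_ne(x[idx], yv[idx], t = t_gen, method = m,
                             depth0 = cov0[idx], deptht = covt[idx],
                             pool0 = pool_individuals, poolt = pool_individuals)
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = ch, regime = r, replicate = j, method = m,
            fc_bar = est$fc_bar, ne = est$ne, n_loci = est$n_loci)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA of Ne by selection regime
#'
#' Fixed-effects one-way analysis of variance of (genome-wide) Ne estimates
#' across regimes.
#'
#' @param ne Numeric vector of Ne estimates (one per replicate, typically the
#'   per-replicate mean over chromosomes).
#' @param regime Grouping factor.
#' @return List: `F`, `df` (between, within), `p`.
#' @export
regime_anova <- function(ne, regime) {
  keep <- is.finite(ne)
  ne <- ne[keep]; regime <- factor(regime[keep])
  .assert(nlevels(regime) >= 2, "need >= 2 regimes")
  .assert(all(table(regime) >= 2), "need >= 2 values per regime")
  fit <- stats::anova(stats::lm(ne ~ regime))
  list(F = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]), p = fit$`Pr(>F)`[1])
}

#' Welch t-test of autosomal vs X-chromosome Ne
#'
#' @param ne Numeric vector of per-chromosome Ne estimates.
#' @param chrom Chromosome labels; `x_chrom` names the sex chromosome.
#' @param x_chrom Label of the X chromosome (default `"X"`).
#' @return List: `t`, `df`, `p`, `mean_auto`, `mean_x`.
#' @export
autosome_x_ttest <- function(ne, chrom, x_chrom = "X") {
  keep <- is.finite(ne)
  ne <- ne[keep]; chrom <- chrom[keep]
  a <- ne[chrom != x_chrom]; xs <- ne[chrom == x_chrom]
  .assert(length(a) >= 2 && length(xs) >= 2, "need >= 2 values per group")
  tt <- stats::t.test(a, xs)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_auto = mean(a), mean_x = mean(xs))
}

#' Upper bound on the number of breeding males
#'
#' Solves `Ne = 4 * Nm * Nf / (Nm + Nf)` for `Nm`, assuming all `Nf` females
#' reproduced: `Nm = Ne * Nf / (4 * Nf - Ne)`. Monotone increasing in Ne on
#' `(0, 4 * Nf)`; the formula has a pole at `Ne = 4 * Nf`.
#'
#' @param ne Effective population size(s), `0 < ne < 4 * nf`.
#' @param nf Number of breeding females (default 2500, half a census of 5000).
#' @return Numeric vector of implied breeding-male numbers.
#' @export
breeding_males <- function(ne, nf = 2500) {
  .assert(all(ne > 0 & ne < 4 * nf), "requires 0 < ne < 4 * nf (formula pole at 4*nf)")
  ne * nf / (4 * nf - ne)
}
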