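#' Per-site minor allele frequency from read counts
#'
#' `p-hat = alt / (ref + alt)`, folded to the minor allele:
#' `MAF = min(p-hat, 1 - p-hat)`.
#'
#' @param ref_count,alt_count Non-negative integer vectors.
#' @return Numeric vector in \[0, 0.5\]; `NA` (with a message) where total
#'   coverage is zero.
#' @export
site_maf <- function(ref_count, alt_count) {
  C <- ref_count + alt_count
  p <- alt_count / C
  bad <- C == 0
  if (any(bad)) message(sprintf("site_maf: %d site(s) with zero coverage skipped", sum(bad)))
  out <- pmin(p, 1 - p)
  out[bad] <- NA_real_
  out
}

#' Per-site coverage-weighted heterozygosity (pi)
#'
#' The unbiased pooled-read heterozygosity
#' `pi = C/(C-1) * 2 * p-hat * (1 - p-hat)` with `C` the read depth; the
#' C/(C-1) factor corrects for resampling the same chromosome in finite read
#' samples. Converges to `2p(1-p)` as coverage grows.
#'
#' @inheritParams site_maf
#' @return Numeric vector; `NA` where coverage is below 2.
#' @export
site_pi <- function(ref_count, alt_count) {
  C <- ref_count + alt_count
  p <- alt_count / C
  out <- C / (C - 1) * 2 * p * (1 - p)
  out[C < 2] <- NA_real_
  out
}

#' Windowed Watterson theta (SNP density) per bp
#'
#' Non-overlapping windows (default 1 kb tiles; set `stride < window` for
#' sliding windows) per chromosome. Per window, `S` is the number of SNPs,
#' the representative sample size `n_eff` is the rounded mean total read
#' coverage of those SNPs, and `theta_w` per bp is `S / (a(n_eff) * L)` with
#' `a(n) = sum_{i=1}^{n-1} 1/i`. Empty windows report 0.
#'
#' @param x A [site_counts()] object.
#' @param window Window length in bp (default 1000).
#' @param stride Step between window starts (default `window`: tiling).
#' @param chrom_lengths Optional named lengths; defaults to the maximum SNP
#'   position per chromosome.
#' @return data.frame: chrom, start, end (1-based inclusive), S, n_eff,
#'   theta_w_per_bp (NA, flagged `undefined`, when `S > 0` but `n_eff < 2`).
#' @export
theta_w_windows <- function(x, window = 1000L, stride = window, chrom_lengths = NULL) {
  cov <- coverage(x)
  res <- lapply(split(seq_len(n_sites(x)), x$sites$chrom), function(idx) {
    ch <- x$sites$chrom[idx[1]]
    pos <- x$sites$pos[idx]
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[ch]] else max(pos)
    starts <- seq(1L, L, by = stride)
    ends <- pmin(starts + window - 1L, L)
    w <- findInterval(pos, starts)  # tiling assignment; sliding handled below
    if (stride == window) {
      S <- tabulate(w, nbins = length(starts))
      csum <- rep(0, length(starts))
      agg <- tapply(cov[idx], w, mean)
      csum[as.integer(names(agg))] <- agg
    } else {
      S <- vapply(seq_along(starts), function(i) sum(pos >= starts[i] & pos <= ends[i]), integer(1))
      csum <- vapply(seq_along(starts), function(i) {
        m <- pos >= starts[i] & pos <= ends[i]
        if (any(m)) mean(cov[idx][m]) else 0
      }, numeric(1))
    }
    data.frame(chrom = ch, start = starts, end = ends, S = S, n_eff = round(csum))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  a_n <- vapply(out$n_eff, function(n) if (n >= 2) sum(1 / seq_len(n - 1)) else NA_real_,
                numeric(1))
  out$theta_w_per_bp <- ifelse(out$S == 0, 0, out$S / (a_n * (out$end - out$start + 1)))
  out$undefined <- out$S > 0 & out$n_eff < 2
  if (any(out$undefined)) warning(sprintf("%d window(s) with S > 0 but n_eff < 2", sum(out$undefined)))
  out
}

#' Assign chromosome domains (arm / center) to positions
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param domain_map data.frame (chrom, start, end, label) tiling each
#'   chromosome, labels `arm_left` / `center` / `arm_right` (or `arm` /
#'   `center`).
#' @param collapse Collapse `arm_left`/`arm_right` to `"arm"` (default TRUE).
#' @return Character vector of domain labels (`NA` outside the map).
#' @export
assign_domain <- function(chrom, pos, domain_map, collapse = TRUE) {
  lab <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(domain_map))) {
    hit <- chrom == domain_map$chrom[i] & pos >= domain_map$start[i] & pos <= domain_map$end[i]
    lab[hit] <- domain_map$label[i]
  }
  if (collapse) lab[lab %in% c("arm_left", "arm_right")] <- "arm"
  lab
}

#' Two-sample Kolmogorov-Smirnov test between chromosome domains
#'
#' `D = sup |F_arm - F_center|` with the asymptotic p-value, comparing the
#' distribution of a per-site statistic (MAF, pi, window theta, ...) between
#' arm and center sites.
#'
#' @param values Numeric vector.
#' @param labels Factor/character of two groups (e.g. "arm"/"center").
#' @return List: `D`, `p`, group `n`s.
#' @export
ks_domain_test <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  gr <- unique(labels)
  .assert(length(gr) == 2, "exactly two domain groups are required")
  a <- values[labels == gr[1]]; b <- values[labels == gr[2]]
  .assert(length(a) >= 2 && length(b) >= 2, "need >= 2 values per group")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value,
       n = stats::setNames(c(length(a), length(b)), gr))
}

#' Welch t-test of per-window SNP density: one chromosome vs the rest
#'
#' @param windows Output of [theta_w_windows()].
#' @param chrom Focal chromosome.
#' @param value Column to compare (default `"theta_w_per_bp"`).
#' @return List: `t`, `df`, `p`, and the two group means.
#' @export
chrom_density_test <- function(windows, chrom, value = "theta_w_per_bp") {
  a <- windows[[value]][windows$chrom == chrom]
  b <- windows[[value]][windows$chrom != chrom]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  .assert(length(a) >= 2 && length(b) >= 2, "need >= 2 windows per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                                        mean_focal = mean(a), mean_rest = mean(b)))
  }
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_focal = mean(a), mean_rest = mean(b))
}

#' Ancestral diversity summary
#'
#' Genome-wide mean pi (unweighted mean over SNP sites), MAF range, and
#' per-domain window theta means for an ancestral count table.
#'
#' @param x A [site_counts()] object (typically ancestor pools merged).
#' @param domain_map Optional domain map for arm/center summaries.
#' @param window Window size for theta (default 1000).
#' @return List: `mean_pi`, `maf_range`, `windows`, and (if a domain map is
#'   given) `theta_by_domain` and the arm/center SNP fractions.
#' @export
diversity_summary <- function(x, domain_map = NULL, window = 1000L) {
  ref <- rowSums(x$ref); alt <- rowSums(x$alt)
  pi <- site_pi(ref, alt)
  maf <- suppressMessages(site_maf(ref, alt))
  win <- theta_w_windows(x, window = window)
  out <- list(mean_pi = mean(pi, na.rm = TRUE),
              maf_range = range(maf[maf > 0], na.rm = TRUE),
              windows = win)
  if (!is.null(domain_map)) {
    sd_dom <- assign_domain(x$sites$chrom, x$sites$pos, domain_map)
    wd <- assign_domain(win$chrom, floor((win$start + win$end) / 2), domain_map)
    out$theta_by_domain <- tapply(win$theta_w_per_bp, wd, mean, na.rm = TRUE)
    out$snp_domain_fractions <- prop.table(table(factor(sd_dom, c("arm", "center"))))
  }
  out
}
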