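#' Binomial-logit GLM fit by iteratively reweighted least squares
#'
#' Fits grouped binomial counts `successes` of `totals` with a logit link by
#' IRLS (Fisher scoring).  Convergence when the maximum absolute score drops
#' below `tol` (default 1e-8) or after `max_iter` iterations; a step-halving
#' guard keeps the deviance non-increasing.  The coefficient covariance is the
#' inverse Fisher information at the optimum.
#'
#' @param X Design matrix (n x p), full rank.
#' @param successes,totals Non-negative integers, `totals >= successes`.
#' @param tol Score convergence tolerance.
#' @param max_iter Iteration cap.
#' @return List of class `glm_fit`: `coefficients`, `vcov`, `converged`,
#'   `n_obs`, `deviance`, `n_iter`.
#' @export
irls_binomial_fit <- function(X, successes, totals, tol = 1e-8, max_iter = 50L) {
  X <- as.matrix(X)
  .assert(all(totals >= successes) && all(successes >= 0), "need totals >= successes >= 0")
  .assert(nrow(X) == length(successes), "design rows must match observations")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  dev_fun <- function(mu) {
    # binomial deviance, safe at 0/1 fitted cells
    t1 <- ifelse(successes > 0, successes * log(successes / (totals * mu)), 0)
    t2 <- ifelse(totals - successes > 0,
                 (totals - successes) * log((totals - successes) / (totals * (1 - mu))), 0)
    2 * sum(t1 + t2)
  }
  p0 <- (sum(successes) + 0.5) / (sum(totals) + 1)
  beta <- c(stats::qlogis(p0), rep(0, ncol(X) - 1L))
  if (!all(X[, 1] == 1)) beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  dev <- dev_fun(mu)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- totals * mu * (1 - mu)
    score <- drop(crossprod(X, successes - totals * mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    XtWX <- crossprod(X, X * w)
    step <- tryCatch(solve(XtWX, score), error = function(e) NULL)
    if (is.null(step)) break
    # step halving: never let the deviance increase
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      mu_new <- stats::plogis(drop(X %*% beta_new))
      dev_new <- dev_fun(mu_new)
      if (dev_new <= dev + 1e-10 || lambda < 1e-4) break
      lambda <- lambda / 2
    }
    beta <- beta_new; mu <- mu_new; dev <- dev_new
    if (max(abs(beta)) > 30) break  # separation guard
  }
  w <- totals * mu * (1 - mu)
  vc <- tryCatch(solve(crossprod(X, X * w)), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  if (converged && max(abs(drop(crossprod(X, successes - totals * mu)))) >= tol)
    converged <- FALSE
  structure(list(coefficients = stats::setNames(beta, colnames(X)), vcov = vc,
                 converged = converged, n_obs = nrow(X), deviance = dev, n_iter = it),
            class = "glm_fit")
}

# Vectorised 2-parameter (intercept + slope) binomial-logit IRLS across many
# SNPs sharing one covariate vector. alt/cov are sites x observations.
.irls_slope_bulk <- function(xcov, alt, cov, tol = 1e-8, max_iter = 50L) {
  n <- nrow(alt)
  x <- matrix(xcov, n, length(xcov), byrow = TRUE)
  tot_alt <- rowSums(alt); tot <- rowSums(cov)
  b0 <- stats::qlogis((tot_alt + 0.5) / (tot + 1))
  b1 <- rep(0, n)
  active <- rep(TRUE, n)
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * x
    mu <- stats::plogis(eta)
    resid <- alt - cov * mu
    s0 <- rowSums(resid); s1 <- rowSums(resid * x)
    conv <- pmax(abs(s0), abs(s1)) < tol
    active <- active & !conv
    if (!any(active)) break
    w <- cov * mu * (1 - mu)
    i00 <- rowSums(w); i01 <- rowSums(w * x); i11 <- rowSums(w * x * x)
    det <- i00 * i11 - i01^2
    ok <- active & det > 1e-12
    d0 <- (i11 * s0 - i01 * s1) / det
    d1 <- (i00 * s1 - i01 * s0) / det
    b0[ok] <- b0[ok] + d0[ok]
    b1[ok] <- b1[ok] + d1[ok]
    # diverging fits (separation along the covariate) are frozen and flagged
    blown <- ok & (abs(b0) > 30 | abs(b1) > 30)
    active[blown] <- FALSE
    active[active & !ok] <- FALSE
  }
  eta <- b0 + b1 * x
  mu <- stats::plogis(eta)
  w <- cov * mu * (1 - mu)
  i00 <- rowSums(w); i01 <- rowSums(w * x); i11 <- rowSums(w * x * x)
  det <- i00 * i11 - i01^2
  se1 <- sqrt(i00 / det)
  resid <- alt - cov * mu
  converged <- pmax(abs(rowSums(resid)), abs(rowSums(resid * x))) < tol & det > 1e-12
  list(intercept = b0, slope = b1, se = se1, converged = converged)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  .assert(m >= 1, "m must be >= 1")
  alpha / m
}

#' Model 2: per-SNP allele-frequency trajectory scan within one regime
#'
#' For each SNP, a binomial-logit GLM of alternate read counts on numeric
#' generation is fit over the ancestor pools (generation 0) plus the regime's
#' replicate x time-point samples; the reported statistic is the two-sided
#' Wald test of the generation slope, with Bonferroni control over the number
#' of SNPs fit in the regime.
#'
#' @param counts A [site_counts()] object.
#' @param meta Matching [sample_meta()].
#' @param regime Regime to scan.
#' @param alpha Family-wise error rate (default 0.05).
#' @param apply_presence Apply the Model 2 presence filter (ancestor +
#'   `min_present` regime samples) before fitting (default TRUE).
#' @param min_present Presence minimum (default 9).
#' @return data.frame of class `scan_result`: chrom, pos, model, regime,
#'   estimate (slope per generation on the log-odds scale), se, z, p,
#'   significant, converged.  SNPs with fewer than 3 distinct informative
#'   generations, or monomorphic across all observations, are skipped
#'   (counted in attribute `"skipped"`); attributes `"m"` and `"threshold"`
#'   carry the Bonferroni accounting.
#' @export
model2_scan <- function(counts, meta, regime, alpha = 0.05,
                        apply_presence = TRUE, min_present = 9) {
  meta <- check_meta(counts, meta)
  .assert(regime %in% meta$regime, "regime not present in metadata")
  if (apply_presence)
    counts <- presence_filter(counts, meta, min_present = min_present,
                              scope = "per_regime", regime = regime,
                              require_ancestor = TRUE)
  meta <- check_meta(counts, meta)
  use <- meta$regime == "ANC" | meta$regime == regime
  gen <- meta$generation[use]
  alt <- counts$alt[, use, drop = FALSE]
  cov <- counts$ref[, use, drop = FALSE] + alt
  # informative generations: those with any coverage at the SNP
  n_gen <- vapply(sort(unique(gen)), function(g)
    rowSums(cov[, gen == g, drop = FALSE]) > 0, logical(nrow(alt)))
  n_gen <- if (is.matrix(n_gen)) rowSums(n_gen) else sum(n_gen)
  tot_alt <- rowSums(alt); tot_cov <- rowSums(cov)
  mono <- tot_alt == 0 | tot_alt == tot_cov
  fit_idx <- which(n_gen >= 3 & !mono)
  m <- length(fit_idx)
  .assert(m >= 1, "no SNPs eligible for Model 2 in this regime")
  fit <- .irls_slope_bulk(gen, alt[fit_idx, , drop = FALSE], cov[fit_idx, , drop = FALSE])
  z <- fit$slope / fit$se
  p <- 2 * stats::pnorm(-abs(z))
  p[!fit$converged] <- NA_real_
  thr <- bonferroni_threshold(alpha, m)
  out <- data.frame(chrom = counts$sites$chrom[fit_idx], pos = counts$sites$pos[fit_idx],
                    model = "model2", regime = regime,
                    estimate = fit$slope, se = fit$se, z = z, p = p,
                    significant = !is.na(p) & p < thr, converged = fit$converged)
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  attr(out, "skipped") <- nrow(alt) - m
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Model 1: ancestor-vs-evolved planned contrasts at the final generation
#'
#' A five-level (ancestor + four regimes) grouped binomial-logit fit per SNP —
#' the saturated maximum-likelihood solution, computed in closed form — with
#' four Wald contrasts `ANC - regime` on the log-odds scale, using only
#' final-generation evolved samples.  When a contrast's 2x2 table contains a
#' zero cell, 0.5 is added to all four cells (Haldane-Anscombe) and the fit is
#' flagged.  Bonferroni `m` is the number of SNPs fit (contrasts within a SNP
#' share the threshold).
#'
#' @param counts A [site_counts()] object.
#' @param meta Matching [sample_meta()].
#' @param alpha Family-wise error rate (default 0.05).
#' @param apply_presence Apply the Model 1 presence filter (default TRUE).
#' @param min_present Presence minimum over final-generation evolved samples
#'   (default 10).
#' @param generation Final generation (default: maximum in `meta`).
#' @return data.frame of class `scan_result`, one row per SNP x regime:
#'   chrom, pos, model, regime, estimate (`logit p_ANC - logit p_regime`),
#'   se, z, p, significant, adjusted (Haldane flag).
#' @export
model1_contrasts <- function(counts, meta, alpha = 0.05, apply_presence = TRUE,
                             min_present = 10, generation = NULL) {
  meta <- check_meta(counts, meta)
  if (is.null(generation)) generation <- max(meta$generation)
  if (apply_presence)
    counts <- presence_filter(counts, meta, min_present = min_present,
                              scope = "all_evolved", require_ancestor = TRUE,
                              generations = generation)
  meta <- check_meta(counts, meta)
  anc <- meta$regime == "ANC"
  alt_a <- rowSums(counts$alt[, anc, drop = FALSE])
  ref_a <- rowSums(counts$ref[, anc, drop = FALSE])
  m <- n_sites(counts)
  .assert(m >= 1, "no SNPs eligible for Model 1")
  thr <- bonferroni_threshold(alpha, m)
  rows <- lapply(setdiff(unique(meta$regime), "ANC"), function(r) {
    cols <- meta$regime == r & meta$generation == generation
    alt_r <- rowSums(counts$alt[, cols, drop = FALSE])
    ref_r <- rowSums(counts$ref[, cols, drop = FALSE])
    cells <- cbind(alt_a, ref_a, alt_r, ref_r)
    skip <- (alt_r + ref_r) == 0  # regime with no data: contrast skipped
    adj <- rowSums(cells == 0) > 0 & !skip
    cells[adj, ] <- cells[adj, , drop = FALSE] + 0.5
    est <- log(cells[, 1] / cells[, 2]) - log(cells[, 3] / cells[, 4])
    se <- sqrt(rowSums(1 / cells))
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    est[skip] <- se[skip] <- z[skip] <- p[skip] <- NA_real_
    data.frame(chrom = counts$sites$chrom, pos = counts$sites$pos,
               model = "model1", regime = r, estimate = est, se = se, z = z,
               p = p, significant = !is.na(p) & p < thr, adjusted = adj)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  attr(out, "threshold") <- thr
  class(out) <- c("scan_result", "data.frame")
  out
}
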