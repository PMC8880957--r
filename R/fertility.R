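#' One-sample equality-of-proportions test with Yates continuity correction
#'
#' `chi^2 = (max(0, |x - n p0| - 1/2))^2 / (n p0 (1 - p0))` with a 1-df
#' chi-square tail p-value, plus the continuity-corrected Wilson score
#' confidence interval (the convention of R's `prop.test`, which this
#' re-implements and is tested against).
#'
#' @param x Successes (focal-male progeny).
#' @param n Trials (total progeny scored).
#' @param p0 Null proportion (default 0.5, equal competitive ability).
#' @param correct Apply the Yates continuity correction (default TRUE).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `chisq`, `df`, `p`, `estimate` (x/n), `ci` (lower, upper).
#' @export
prop_test_one_sample <- function(x, n, p0 = 0.5, correct = TRUE, conf_level = 0.95) {
  .assert(length(x) == 1 && length(n) == 1 && x >= 0 && x <= n && n >= 1,
          "need 0 <= x <= n, n >= 1")
  phat <- x / n
  yates <- if (correct) min(0.5, abs(x - n * p0)) else 0
  chisq <- (abs(x - n * p0) - yates)^2 / (n * p0 * (1 - p0))
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  z22n <- z^2 / (2 * n)
  cc <- yates / n
  p_lo <- pmax(0, phat - cc); p_hi <- pmin(1, phat + cc)
  lower <- (p_lo + z22n - z * sqrt(p_lo * (1 - p_lo) / n + z22n / (2 * n))) / (1 + 2 * z22n)
  upper <- (p_hi + z22n + z * sqrt(p_hi * (1 - p_hi) / n + z22n / (2 * n))) / (1 + 2 * z22n)
  list(chisq = chisq, df = 1, p = p, estimate = phat,
       ci = c(lower = max(0, lower), upper = min(1, upper)))
}

#' Pool fertility assays into a single count pair
#'
#' Sums focal and total progeny across assays for one population x condition
#' (e.g. the three ancestral assays feeding the pooled proportion test).
#'
#' @param assays A `fertility_assays` data.frame (columns `condition`,
#'   `n_focal`, `n_competitor`; see [gen_fertility_assays()]).
#' @return List: `x` (focal), `n` (total).
#' @export
pool_assays <- function(assays) {
  .assert(nrow(assays) >= 1, "no assays")
  .assert(length(unique(assays$condition)) == 1,
          "cannot pool assays across conditions")
  list(x = sum(assays$n_focal), n = sum(assays$n_focal + assays$n_competitor))
}

#' Fraction of total reproductive success attributable to post-insemination
#' success
#'
#' `100 * mean_post / mean_total` (percent).
#'
#' @param mean_post_prop Mean post-insemination siring proportion.
#' @param mean_total_prop Mean total siring proportion (> 0).
#' @return Percentage.
#' @export
contribution_fraction <- function(mean_post_prop, mean_total_prop) {
  .assert(all(mean_total_prop > 0), "total proportion must be > 0")
  100 * mean_post_prop / mean_total_prop
}

#' Fold change in competitive success relative to the ancestor
#'
#' Aggregation follows the assay design: per replicate, the mean of its assay
#' proportions; the fold is the replicate mean divided by the ancestral mean
#' (itself the mean of the ancestral per-assay proportions); the regime
#' summary is the mean of its replicate folds.
#'
#' @param assays A `fertility_assays` data.frame (one condition).
#' @param ancestor_population Population id of the ancestor (default "ANC").
#' @return List: `replicates` (population, regime, replicate, mean_prop,
#'   fold), `regimes` (regime, mean_fold), `ancestor_mean`.
#' @export
fold_change <- function(assays, ancestor_population = "ANC") {
  .assert(length(unique(assays$condition)) == 1, "one condition at a time")
  prop <- assays$n_focal / (assays$n_focal + assays$n_competitor)
  anc <- assays$population == ancestor_population
  .assert(any(anc), "no ancestor assays found")
  anc_mean <- mean(prop[anc])
  .assert(anc_mean > 0, "ancestral mean proportion is zero")
  ev <- assays[!anc, , drop = FALSE]
  reps <- do.call(rbind, lapply(split(seq_len(nrow(ev)), ev$population), function(idx) {
    data.frame(population = ev$population[idx[1]], regime = ev$regime[idx[1]],
               replicate = ev$replicate[idx[1]],
               mean_prop = mean(prop[!anc][idx]))
  }))
  reps$fold <- reps$mean_prop / anc_mean
  regimes <- do.call(rbind, lapply(split(reps, reps$regime), function(d)
    data.frame(regime = d$regime[1], mean_fold = mean(d$fold))))
  rownames(reps) <- rownames(regimes) <- NULL
  list(replicates = reps, regimes = regimes, ancestor_mean = anc_mean)
}

#' Planned GLM contrasts on competitive-fertility assays
#'
#' Quasi-binomial logistic GLM of focal progeny counts on the population-level
#' factor (ancestor + four regimes), with replicate-level extra-binomial
#' variance absorbed by the estimated dispersion.  Two planned contrast
#' families are tested (two-sided Wald z): (i) each regime minus the
#' ancestor — evolutionary change from the ancestral population — and (ii)
#' each directed-selection regime minus the baseline regime.
#'
#' @param assays A `fertility_assays` data.frame, one condition, containing
#'   ancestor and evolved assays.
#' @param baseline Baseline regime for family (ii) (default `"WS-P&P"`).
#' @return data.frame: family, contrast, estimate (log-odds), se, z, p;
#'   attribute `"dispersion"` carries the estimated dispersion factor.
#' @export
evolved_glm_contrasts <- function(assays, baseline = "WS-P&P") {
  .assert(length(unique(assays$condition)) == 1, "one condition at a time")
  .assert("ANC" %in% assays$regime, "ancestor assays required")
  lev <- c("ANC", intersect(c(REGIMES, setdiff(unique(assays$regime), "ANC")),
                            unique(assays$regime)))
  lev <- unique(lev)
  g <- factor(assays$regime, levels = lev)
  fit <- stats::glm(cbind(assays$n_focal, assays$n_competitor) ~ g,
                    family = stats::quasibinomial())
  beta <- stats::coef(fit)
  vc <- stats::vcov(fit)
  contrast <- function(l) {
    est <- sum(l * beta); se <- sqrt(drop(t(l) %*% vc %*% l))
    z <- est / se
    c(estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  coef_of <- function(r) {  # position of the dummy coefficient for regime r
    i <- match(paste0("g", r), names(beta))
    l <- rep(0, length(beta)); if (!is.na(i)) l[i] <- 1
    l
  }
  rows <- list()
  for (r in setdiff(lev, "ANC")) {
    rows[[length(rows) + 1L]] <- data.frame(
      family = "vs_ancestor", contrast = sprintf("%s - ANC", r),
      t(contrast(coef_of(r))))
  }
  if (baseline %in% lev) {
    for (r in setdiff(lev, c("ANC", baseline))) {
      rows[[length(rows) + 1L]] <- data.frame(
        family = "vs_baseline", contrast = sprintf("%s - %s", r, baseline),
        t(contrast(coef_of(r) - coef_of(baseline))))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dispersion") <- summary(fit)$dispersion
  out
}
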