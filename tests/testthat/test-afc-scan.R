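test_that("IRLS matches the saturated closed form on two-group designs", {
  X <- cbind(1, c(0, 1))
  fit <- irls_binomial_fit(X, successes = c(20, 40), totals = c(100, 100))
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[2]), qlogis(0.4) - qlogis(0.2), tolerance = 1e-10)
  expect_equal(round(unname(fit$coefficients[2]), 5), 0.98083)
  # identical groups: zero effect
  fit0 <- irls_binomial_fit(X, c(30, 30), c(100, 100))
  expect_equal(unname(fit0$coefficients[2]), 0, tolerance = 1e-10)
})

test_that("Wald z for a 2x2 table equals the log-odds-ratio z", {
  # table 10/90 vs 30/70: SE = sqrt(1/10 + 1/90 + 1/30 + 1/70)
  fit <- irls_binomial_fit(cbind(1, c(0, 1)), c(10, 30), c(100, 100))
  est <- unname(fit$coefficients[2])
  se <- sqrt(fit$vcov[2, 2])
  expect_equal(est, qlogis(0.3) - qlogis(0.1), tolerance = 1e-10)
  expect_equal(se, sqrt(1 / 10 + 1 / 90 + 1 / 30 + 1 / 70), tolerance = 1e-10)
})

test_that("IRLS agrees with the reference GLM fitter on random designs", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    X <- cbind(1, rnorm(n), runif(n))
    tot <- sample(20:100, n, replace = TRUE)
    eta <- drop(X %*% c(-0.5, 0.8, 0.4))
    suc <- rbinom(n, tot, plogis(eta))
    mine <- irls_binomial_fit(X, suc, tot)
    ref <- suppressWarnings(glm(cbind(suc, tot - suc) ~ X - 1, family = binomial()))
    expect_true(mine$converged)
    expect_equal(unname(mine$coefficients), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(sqrt(diag(mine$vcov))),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  }
  expect_error(irls_binomial_fit(cbind(1, c(1, 1), c(2, 2)), c(1, 1), c(2, 2)),
               "rank deficient")
})

test_that("bonferroni_threshold is alpha/m", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 263373), 0.05 / 263373)
  expect_equal(bonferroni_threshold(0.05, 263373), 1.8985e-7, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(0.05, 202926), 2.4640e-7, tolerance = 1e-4)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("model2 slope recovers a logit-linear trajectory at negligible noise", {
  # frequencies on the logit line from 0.2 (G0) to 0.4 (G31), depth 1e5
  gens <- c(0L, 13L, 22L, 31L)
  slope_true <- (qlogis(0.4) - qlogis(0.2)) / 31
  p <- plogis(qlogis(0.2) + slope_true * gens)
  depth <- 1e5L
  cells <- list()
  meta_rows <- list()
  for (k in 1:3) {  # ancestor pools at G0
    id <- sprintf("ANC_p%d", k)
    cells[[id]] <- list(ref = as.integer(round(depth * (1 - p[1]))),
                        alt = as.integer(round(depth * p[1])))
    meta_rows[[id]] <- data.frame(sample_id = id, regime = "ANC",
                                  replicate = 0L, generation = 0L)
  }
  for (j in 1:6) for (g in gens[-1]) {
    id <- sprintf("BSPO_r%d_g%d", j, g)
    pg <- p[match(g, gens)]
    cells[[id]] <- list(ref = as.integer(round(depth * (1 - pg))),
                        alt = as.integer(round(depth * pg)))
    meta_rows[[id]] <- data.frame(sample_id = id, regime = "BS-PO",
                                  replicate = j, generation = g)
  }
  mm <- do.call(rbind, meta_rows)
  meta <- sample_meta(mm$sample_id, mm$regime, mm$replicate, mm$generation)
  x <- toy_counts(pos = 100L, cells = cells)
  sc <- model2_scan(x, meta, regime = "BS-PO", apply_presence = FALSE)
  expect_lt(abs(sc$estimate[1] - slope_true), 1e-6)  # rounding-only noise at depth 1e5
  expect_lt(abs(sc$estimate[1] - 0.031640), 1e-3)
  expect_true(sc$converged[1])
  # constant-frequency SNP: slope ~ 0, not significant
  cells0 <- lapply(cells, function(cc) list(ref = 70L, alt = 30L))
  x0 <- toy_counts(pos = 100L, cells = cells0)
  sc0 <- model2_scan(x0, meta, regime = "BS-PO", apply_presence = FALSE)
  expect_equal(sc0$estimate[1], 0, tolerance = 1e-8)
  expect_false(sc0$significant[1])
})

test_that("model2 scan detects a selected site across replicates", {
  te <- toy_experiment()  # one site with s = 0.15 in BS-PO only
  sc <- model2_scan(te$ex$counts, te$ex$meta, regime = "BS-PO")
  i <- te$sel_site
  key <- paste(te$ex$counts$sites$chrom[i], te$ex$counts$sites$pos[i])
  hit <- sc[paste(sc$chrom, sc$pos) == key, ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$estimate, 0)
  expect_true(hit$significant)
  # the same site is unremarkable in an unselected regime
  sc2 <- model2_scan(te$ex$counts, te$ex$meta, regime = "WS-P&P")
  hit2 <- sc2[paste(sc2$chrom, sc2$pos) == key, ]
  expect_false(isTRUE(hit2$significant))
})

test_that("model1 contrasts equal the saturated log-odds differences", {
  te <- toy_experiment()
  ex <- te$ex
  m1 <- model1_contrasts(ex$counts, ex$meta)
  expect_equal(sort(unique(m1$regime)), sort(REGIMES))
  expect_equal(attr(m1, "threshold"), 0.05 / attr(m1, "m"))
  # closed-form check on an arbitrary unadjusted row
  g31 <- ex$meta$generation == 31
  anc <- ex$meta$regime == "ANC"
  row <- m1[!m1$adjusted & m1$regime == "BS-PO", ][5, ]
  i <- which(ex$counts$sites$chrom == row$chrom & ex$counts$sites$pos == row$pos)
  cols_r <- ex$meta$regime == "BS-PO" & g31
  aA <- sum(ex$counts$alt[i, anc]); rA <- sum(ex$counts$ref[i, anc])
  aR <- sum(ex$counts$alt[i, cols_r]); rR <- sum(ex$counts$ref[i, cols_r])
  expect_equal(row$estimate, log(aA / rA) - log(aR / rR))
  expect_equal(row$se, sqrt(1 / aA + 1 / rA + 1 / aR + 1 / rR))
  # all-equal groups give z ~ 0 (hand-built)
  cells <- list()
  meta_rows <- list()
  for (k in 1:3) {
    id <- sprintf("ANC_p%d", k)
    cells[[id]] <- list(ref = 70L, alt = 30L)
    meta_rows[[id]] <- data.frame(sample_id = id, regime = "ANC", replicate = 0L,
                                  generation = 0L)
  }
  for (r in REGIMES) for (j in 1:3) {
    id <- sprintf("%s_r%d_g31", gsub("[^A-Za-z0-9]", "", r), j)
    cells[[id]] <- list(ref = 70L, alt = 30L)
    meta_rows[[id]] <- data.frame(sample_id = id, regime = r, replicate = j,
                                  generation = 31L)
  }
  mm <- do.call(rbind, meta_rows)
  meta <- sample_meta(mm$sample_id, mm$regime, mm$replicate, mm$generation)
  x <- toy_counts(pos = 100L, cells = cells)
  m0 <- model1_contrasts(x, meta, min_present = 10)
  expect_equal(m0$z, rep(0, 4), tolerance = 1e-12)
})

test_that("fixed cells get the Haldane-Anscombe adjustment and stay finite", {
  cells <- list()
  meta_rows <- list()
  for (k in 1:3) {
    id <- sprintf("ANC_p%d", k)
    cells[[id]] <- list(ref = 50L, alt = 10L)
    meta_rows[[id]] <- data.frame(sample_id = id, regime = "ANC", replicate = 0L,
                                  generation = 0L)
  }
  for (r in REGIMES) for (j in 1:3) {
    id <- sprintf("%s_r%d_g31", gsub("[^A-Za-z0-9]", "", r), j)
    # BS-PO fixed for alt (sweep completed); others intermediate
    cells[[id]] <- if (r == "BS-PO") list(ref = 0L, alt = 60L) else list(ref = 40L, alt = 20L)
    meta_rows[[id]] <- data.frame(sample_id = id, regime = r, replicate = j,
                                  generation = 31L)
  }
  mm <- do.call(rbind, meta_rows)
  meta <- sample_meta(mm$sample_id, mm$regime, mm$replicate, mm$generation)
  x <- toy_counts(pos = 100L, cells = cells)
  m1 <- model1_contrasts(x, meta, min_present = 10)
  bspo <- m1[m1$regime == "BS-PO", ]
  expect_true(bspo$adjusted)
  expect_true(is.finite(bspo$z))
  expect_false(m1$adjusted[m1$regime == "WS-PO"])
})
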