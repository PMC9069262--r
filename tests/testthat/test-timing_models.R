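test_that("PC-timing regression recovers constructed limits", {
  set.seed(111)
  n <- 60
  pc <- rnorm(n)
  # exact linear limit: day = 2 pc + tiny noise
  day <- round(250 + 2 * pc * 10 + rnorm(n, 0, 1e-4))
  gm_ids <- sprintf("m%02d", 1:n)
  meta <- data.frame(sample_id = gm_ids, capture_day = as.integer(day),
                     sex = rep(c("F", "M"), n / 2))
  fit <- fit_pc_timing(setNames(pc * 10, gm_ids), meta, sex_covariate = FALSE)
  expect_equal(unname(fit$coefficients["pc", 1]), 2, tolerance = 1e-2)
  expect_gt(fit$r_squared, 0.999)
  # orthogonal predictor: slope t-statistic ~ 0
  resid_pc <- residuals(lm(pc ~ day))
  fit0 <- fit_pc_timing(setNames(resid_pc, gm_ids), meta, sex_covariate = FALSE)
  expect_lt(abs(fit0$coefficients["pc", 3]), 1e-8)
  # unknown sex dropped with warning when the covariate is requested
  meta$sex[1] <- "unknown"
  expect_warning(fit_pc_timing(setNames(pc, gm_ids), meta), "unknown sex")
  expect_error(fit_pc_timing(setNames(rep(1, n), gm_ids), meta,
                             sex_covariate = FALSE), "constant")
})

test_that("PC1 passage-date association is powered under the chronotype model", {
  hits <- vapply(1:25, function(s) {
    d <- gen_scenario_dataset("chronotype", seed = 300 + s)
    cand <- gm_subset(d$migrants, loci = d$candidate_loci)
    fit <- fix_sign(fit_ordinal_pca(cand, n_dim = 2), d$timing_loci[1])
    tf <- fit_pc_timing(fit$object_scores, d$migrant_meta)
    tf$coefficients["pc", 4] < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("repolarize_major flips minor-allele loci and is idempotent", {
  codes <- cbind(a = c(0L, 0L, 1L, 0L), b = c(2L, 2L, 1L, 2L),
                 c = c(1L, 1L, 1L, 1L), d = c(0L, 2L, 2L, 0L))
  gm <- genotype_matrix(codes, counted_allele = "G", other_allele = "A")
  rp <- repolarize_major(gm)
  expect_equal(unname(allele_freq(rp)["a"]), 1 - 0.125)  # 0.3-type flip
  expect_equal(unname(rp$codes[, "a"]), c(2L, 2L, 1L, 2L))
  expect_equal(rp$counted_allele[1], "A")       # allele label swapped
  expect_identical(rp$codes[, "b"], gm$codes[, "b"])  # already major
  expect_identical(rp$codes[, "d"], gm$codes[, "d"])  # exactly 0.5: tie kept
  rp2 <- repolarize_major(rp)
  expect_identical(rp2$codes, rp$codes)
  # weekly frequencies after flip equal 1 - original at flipped loci
  meta <- make_meta(gm, capture_day = c(240L, 241L, 250L, 251L))
  wf0 <- weekly_frequencies(gm, meta, "a")
  wf1 <- weekly_frequencies(rp, meta, "a")
  expect_equal(wf1$freq, 1 - wf0$freq)
})

test_that("weekly binning counts alleles the way a brute tally does", {
  codes <- matrix(c(2L, 2L, 1L, 1L, 0L, NA, 1L, 2L), ncol = 1,
                  dimnames = list(NULL, "loc"))
  gm <- genotype_matrix(codes)
  meta <- make_meta(gm, capture_day = c(240L, 241L, 243L, 246L,
                                        250L, 251L, 253L, 254L))
  wf <- weekly_frequencies(gm, meta, "loc")
  # week 0 (240..246): genotypes 2,2,1,1 -> 6/8; week 1 (247..253): 0,NA,1
  expect_equal(wf$freq[1], 0.75)
  expect_equal(wf$n_called_alleles[1], 8)
  expect_equal(wf$midpoint_day, c(243, 250, 257))
  expect_equal(wf$freq[2], 1 / 4)
  expect_equal(wf$n_individuals[2], 3)
  # all-code-2 week has SE 0
  expect_equal(wf$freq[3], 1)
  expect_equal(wf$se[3], 0)
  # brute tally on a seeded series
  b <- gen_baseline(baseline_spec(n_loci = 10, seed = 112))
  m <- gen_migration_series(migration_spec(timing_loci = b$genotypes$locus_ids[1:2],
                                           seed = 113), b$truth)
  l <- b$genotypes$locus_ids[1]
  wf2 <- weekly_frequencies(m$genotypes, m$meta, l)
  day <- m$meta$capture_day
  start <- min(day)
  for (k in seq_len(nrow(wf2))) {
    in_bin <- day >= start + 7 * wf2$week_index[k] &
      day <= start + 7 * wf2$week_index[k] + 6
    g <- m$genotypes$codes[in_bin, l]
    expect_equal(wf2$n_called_alleles[k], 2 * sum(!is.na(g)))
    expect_equal(wf2$freq[k], sum(g, na.rm = TRUE) / (2 * sum(!is.na(g))))
  }
})

test_that("the nested-OLS LRT matches its closed-form finite-sample law", {
  set.seed(114)
  # statistic must equal n log(RSS_reduced / RSS_full) exactly
  wf <- data.frame(midpoint_day = seq(233, 310, by = 7),
                   freq = runif(12, 0.4, 0.8),
                   se = 0.05, n_called_alleles = 40)
  res <- fit_trend_lrt(wf, degree_full = 2)
  rss1 <- sum(residuals(res$linear$lm)^2)
  rss2 <- sum(residuals(res$full$lm)^2)
  expect_equal(res$lrt$statistic, 12 * log(rss1 / rss2), tolerance = 1e-10)
  expect_gte(res$lrt$ll_full, res$lrt$ll_reduced)
  expect_equal(res$lrt$ll_reduced,
               oracle_ols_loglik(wf$freq, wf$midpoint_day), tolerance = 1e-10)
  # under a linear truth the rejection rate follows the exact F(1, n-3) law,
  # not the nominal 5% of the chi-square reference (anticonservative at n=12)
  nrep <- 2000
  stats <- vapply(seq_len(nrep), function(i) {
    y <- 0.6 - 0.002 * wf$midpoint_day + rnorm(12, 0, 0.05)
    fit_trend_lrt(data.frame(midpoint_day = wf$midpoint_day, freq = y,
                             se = 0.05, n_called_alleles = 40))$lrt$p_value
  }, 0)
  crit <- 9 * (exp(qchisq(0.95, 1) / 12) - 1)
  expected_rate <- pf(crit, 1, 9, lower.tail = FALSE)  # ~0.098
  expect_equal(mean(stats < 0.05), expected_rate, tolerance = 0.3)
})

test_that("degenerate and constructed LRT cases behave", {
  wf <- data.frame(midpoint_day = seq(233, 310, by = 7),
                   freq = 0.9 - 0.00004 * (seq(233, 310, by = 7) - 270)^2,
                   se = 0.02, n_called_alleles = 40)
  # identical nested models: statistic 0, p 1
  same <- fit_trend_lrt(wf, degree_full = 1)
  expect_equal(same$lrt$statistic, 0)
  expect_equal(same$lrt$p_value, 1)
  # exact quadratic signal with tiny noise: decisively rejected
  set.seed(115)
  wf$freq <- wf$freq + rnorm(12, 0, 1e-4)
  quad <- fit_trend_lrt(wf, degree_full = 2)
  expect_lt(quad$lrt$p_value, 1e-6)
  # weighting options run and keep the nesting inequality
  iv <- fit_trend_lrt(wf, weighting = "inverse_variance")
  expect_gte(iv$lrt$ll_full, iv$lrt$ll_reduced)
  bi <- fit_trend_lrt(wf, weighting = "binomial")
  expect_gte(bi$lrt$ll_full, bi$lrt$ll_reduced)
  expect_error(fit_trend_lrt(wf[1:3, ], degree_full = 2), "weekly points")
})

test_that("planted timing loci outrank background loci on the LRT", {
  d <- gen_scenario_dataset("chronotype", seed = 117)
  gm <- repolarize_major(d$migrants)
  ps <- vapply(d$candidate_loci, function(l) {
    wf <- weekly_frequencies(gm, d$migrant_meta, l)
    ft <- fit_trend_lrt(wf)
    # single-locus evidence of any trend: linear-slope p or curvature p
    min(ft$linear$coefficients[2, 4], ft$lrt$p_value)
  }, 0)
  timing <- names(ps) %in% d$timing_loci
  expect_lt(median(ps[timing]), median(ps[!timing]))
})

test_that("sex timing test detects a planted shift and not a null", {
  set.seed(118)
  meta0 <- data.frame(sample_id = paste0("x", 1:160),
                      capture_day = as.integer(round(rnorm(160, 270, 5))),
                      sex = rep(c("F", "M"), each = 80))
  f0 <- sex_timing_test(meta0)
  expect_gt(f0$coefficients["sexM", 4], 0.001)  # no planted effect
  hits <- vapply(1:20, function(i) {
    m <- meta0
    m$capture_day <- as.integer(round(rnorm(160, 270, 5) +
                                        10 * (m$sex == "M")))
    sex_timing_test(m)$coefficients["sexM", 4] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.99)
  expect_error(sex_timing_test(meta0[meta0$sex == "F", ]), "both sexes")
})
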