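test_that("generators are deterministic given a seed", {
  b1 <- gen_baseline(baseline_spec(n_loci = 50, seed = 5))
  b2 <- gen_baseline(baseline_spec(n_loci = 50, seed = 5))
  expect_identical(b1$genotypes$codes, b2$genotypes$codes)
  expect_identical(b1$meta, b2$meta)
  m1 <- gen_migration_series(migration_spec(seed = 6, timing_loci = b1$genotypes$locus_ids[1:4]),
                             b1$truth)
  m2 <- gen_migration_series(migration_spec(seed = 6, timing_loci = b1$genotypes$locus_ids[1:4]),
                             b1$truth)
  expect_identical(m1$genotypes$codes, m2$genotypes$codes)
  expect_identical(m1$meta$capture_day, m2$meta$capture_day)
  f1 <- gen_flank_contexts(flank_spec(n_contexts = 20, seed = 7))
  f2 <- gen_flank_contexts(flank_spec(n_contexts = 20, seed = 7))
  expect_identical(f1$contexts[[3]]$flank_seq, f2$contexts[[3]]$flank_seq)
})

test_that("zero-divergence baseline has near-zero multi-locus theta", {
  b <- gen_baseline(baseline_spec(target_fst = 0, n_loci = 1500, seed = 41))
  fs <- fst_scan(b$genotypes, b$meta)
  expect_lt(abs(fst_ratio_of_sums(fs)), 0.01)
})

test_that("Balding-Nichols divergence is calibrated near the target", {
  b <- gen_baseline(baseline_spec(target_fst = 0.05, n_per_pop = 50,
                                  n_loci = 2000, seed = 42))
  fs <- fst_scan(b$genotypes, b$meta)
  expect_lt(abs(fst_ratio_of_sums(fs) - 0.05), 0.02)
})

test_that("planted outliers rank in the top theta decile across seeds", {
  hits <- vapply(1:6, function(s) {
    b <- gen_baseline(baseline_spec(n_loci = 1000, n_outliers = 20,
                                    outlier_delta = 0.4, seed = 100 + s))
    fs <- fst_scan(b$genotypes, b$meta)
    thr <- quantile(fs$theta[fs$status == "ok"], 0.9, na.rm = TRUE)
    planted <- fs$theta[fs$locus_id %in% b$truth$outlier_loci]
    mean(planted >= thr)
  }, 0)
  expect_gte(mean(hits), 0.9)  # pooled over seeds
})

test_that("non-planted loci satisfy HWE within populations", {
  b <- gen_baseline(baseline_spec(n_pops = 2, n_per_pop = 100, n_loci = 400,
                                  target_fst = 0.05, seed = 43))
  codes <- b$genotypes$codes[b$meta$pop == "P1", ]
  pvals <- apply(codes, 2, function(g) {
    n <- length(g); f <- mean(g) / 2
    if (f == 0 || f == 1) return(NA_real_)
    obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
    exp <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
    keep <- exp > 0
    stat <- sum((obs[keep] - exp[keep])^2 / exp[keep])
    pchisq(stat, df = 1, lower.tail = FALSE)
  })
  expect_gte(mean(pvals >= 0.01, na.rm = TRUE), 0.95)
})

test_that("chronotype series wires genotype effects into capture day", {
  b <- gen_baseline(baseline_spec(n_loci = 30, ancestral_freq_range = c(0.3, 0.7),
                                  seed = 51))
  tl <- b$genotypes$locus_ids[1:4]
  # no effect: slope of code on day ~ 0 at every locus
  m0 <- gen_migration_series(migration_spec(timing_loci = tl, effect_days = 0,
                                            n_migrants = 400, seed = 52),
                             b$truth)
  slopes0 <- apply(m0$genotypes$codes[, tl], 2, function(g)
    coef(lm(g ~ m0$meta$capture_day))[2])
  expect_lt(max(abs(slopes0)), 0.02)
  # negative effect: counted-allele weekly frequency declines over season
  m1 <- gen_migration_series(migration_spec(timing_loci = tl, effect_days = -5,
                                            n_migrants = 600, seed = 53),
                             b$truth)
  for (l in tl) {
    wf <- weekly_frequencies(m1$genotypes, m1$meta, l)
    expect_lt(coef(lm(freq ~ midpoint_day, data = wf))[2], 0)
  }
  # capture days stay inside the season
  expect_true(all(m1$meta$capture_day >= 230 & m1$meta$capture_day <= 321))
})

test_that("timing loci covary through the latent chronotype factor", {
  b <- gen_baseline(baseline_spec(n_loci = 20, ancestral_freq_range = c(0.4, 0.6),
                                  seed = 54))
  tl <- b$genotypes$locus_ids[1:4]
  m <- gen_migration_series(migration_spec(timing_loci = tl, timing_cor = 0.5,
                                           n_migrants = 2000, seed = 55),
                            b$truth)
  cm <- cor(m$genotypes$codes[, tl])
  off <- cm[upper.tri(cm)]
  expect_gt(min(off), 0.2)  # copula rho 0.5 on the latent scale
  # marginals stay HWE-binomial: frequencies near the source values
  f <- colMeans(m$genotypes$codes[, tl]) / 2
  expect_lt(max(abs(f - b$truth$pop_freqs["P1", tl])), 0.05)
})

test_that("confound series splits origins with different passage dates", {
  b <- gen_baseline(baseline_spec(n_loci = 30, seed = 61))
  m <- gen_migration_series(
    migration_spec("population_confound", n_migrants = 500,
                   timing_loci = b$genotypes$locus_ids[1:4], seed = 62),
    b$truth)
  expect_setequal(unique(m$truth$origin), c("P1", "P2"))
  expect_lt(mean(m$truth$origin == "P2"), 0.3)
  d1 <- m$meta$capture_day[m$truth$origin == "P1"]
  d2 <- m$meta$capture_day[m$truth$origin == "P2"]
  expect_gt(mean(d2) - mean(d1), 10)
})

test_that("flank contexts carry planted labels with exact counts", {
  fc <- gen_flank_contexts(flank_spec(n_contexts = 100, frac_gc = 0.25,
                                      frac_indel = 0.25, frac_snp = 0.25,
                                      seed = 71))
  expect_equal(as.integer(table(fc$truth$planted)[c("gc", "indel30", "snp20")]),
               c(25L, 25L, 25L))
  ctx <- fc$contexts[[which(fc$truth$planted == "gc")[1]]]
  expect_gte(gc_fraction(ctx$flank_seq,
                         c(ctx$target_offset - 50, ctx$target_offset + 50)),
             0.65)
  ctx2 <- fc$contexts[[which(fc$truth$planted == "indel30")[1]]]
  expect_true(any(ctx2$nearby_variants$kind == "indel" &
                    abs(ctx2$nearby_variants$offset - ctx2$target_offset) <= 30))
})

test_that("end-to-end dataset is byte-identical per seed and self-consistent", {
  d1 <- file.path(tempdir(), "e2e_a"); d2 <- file.path(tempdir(), "e2e_b")
  f1 <- gen_end_to_end(d1, seed = 3)
  f2 <- gen_end_to_end(d2, seed = 3)
  for (k in names(f1)) {
    expect_identical(readLines(f1[[k]]), readLines(f2[[k]]), label = k)
  }
  # the scan stage runs on the written fixture
  res <- suppressWarnings(read_vcf(f1[["vcf"]]))
  meta <- read_metadata(f1[["scan_meta"]])
  fs <- fst_scan(res$genotypes, meta)
  sel <- select_outliers(fs, 0.9)
  expect_gt(length(sel$locus_ids), 0)
  truth <- jsonlite::read_json(f1[["truth"]], simplifyVector = TRUE)
  expect_true(all(truth$scan_outlier_loci %in% res$genotypes$locus_ids))
  unlink(c(d1, d2), recursive = TRUE)
})
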