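test_that("baseline posteriors apply the half-allele prior", {
  codes <- rbind(matrix(1L, 10, 1), matrix(0L, 10, 1))
  colnames(codes) <- "l1"
  gm <- genotype_matrix(codes)
  meta <- make_meta(gm, pop = rep(c("A", "B"), each = 10))
  base <- build_baseline(gm, meta)
  # pop A: 10 copies of 20 alleles -> (10 + 0.5)/(20 + 1) = 0.5
  expect_equal(unname(base$freq["A", "l1"]), 0.5)
  # pop B: 0 of 20 -> 0.5/21, never exactly zero
  expect_equal(unname(base$freq["B", "l1"]), 0.5 / 21)
  expect_true(all(base$freq > 0 & base$freq < 1))
  expect_true(all(base$totals %% 2 == 0))
})

test_that("baseline count table equals a hand tally with missing data", {
  set.seed(121)
  codes <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 12, 5,
                  dimnames = list(NULL, paste0("l", 1:5)))
  gm <- genotype_matrix(codes)
  meta <- make_meta(gm, pop = rep(c("A", "B", "C"), each = 4))
  base <- suppressWarnings(build_baseline(gm, meta))
  for (p in c("A", "B", "C")) {
    rows <- which(meta$pop == p)
    for (l in paste0("l", 1:5)) {
      g <- codes[rows, l]
      expect_equal(unname(base$counts[p, l]), sum(g, na.rm = TRUE))
      expect_equal(unname(base$totals[p, l]), 2 * sum(!is.na(g)))
    }
  }
})

test_that("genotype log-likelihood equals the hand-computed HWE product", {
  set.seed(122)
  codes <- matrix(rbinom(200, 2, 0.4), 20, 10,
                  dimnames = list(NULL, paste0("l", 1:10)))
  gm <- genotype_matrix(codes)
  meta <- make_meta(gm, pop = rep(c("A", "B"), each = 10))
  base <- build_baseline(gm, meta)
  ind <- setNames(codes[3, ], paste0("l", 1:10))
  want <- 0
  for (l in names(ind)) {
    f <- base$freq["A", l]
    want <- want + log(c((1 - f)^2, 2 * f * (1 - f), f^2)[ind[[l]] + 1])
  }
  expect_equal(genotype_loglik(ind, base, "A"), want, tolerance = 1e-12)
  # single locus, f = 0.5, heterozygote -> log(0.5)
  b1 <- base; b1$freq[, ] <- 0.5
  expect_equal(genotype_loglik(setNames(1L, "l1"), b1, "A"), log(0.5))
  # all-missing individual is uninformative
  expect_equal(genotype_loglik(setNames(rep(NA_integer_, 10),
                                        paste0("l", 1:10)), base, "A"), 0)
})

test_that("EM mixture handles the degenerate one-population case", {
  set.seed(123)
  codes <- matrix(rbinom(100, 2, 0.5), 10, 10)
  gm <- genotype_matrix(codes)
  meta <- make_meta(gm, pop = "only")
  base <- build_baseline(gm, meta)
  mix <- mixture_em(gm, base)
  expect_equal(unname(mix$pi), 1)
  expect_true(all(mix$posterior == 1))
  expect_true(all(mix$map_label == "only"))
})

test_that("fixed differences at 50 loci give near-certain assignment", {
  nl <- 50
  ref <- rbind(matrix(2L, 20, nl), matrix(0L, 20, nl))
  colnames(ref) <- paste0("l", 1:nl)
  gm <- genotype_matrix(ref)
  meta <- make_meta(gm, pop = rep(c("E", "W"), each = 20))
  base <- build_baseline(gm, meta)
  mig <- genotype_matrix(rbind(matrix(2L, 5, nl), matrix(0L, 5, nl)),
                         locus_ids = paste0("l", 1:nl))
  mix <- mixture_em(mig, base)
  expect_true(all(mix$map_prob > 0.999))
  expect_equal(mix$map_label, rep(c("E", "W"), each = 5))
  expect_true(all(diff(mix$loglik_trace) >= -1e-8))
})

test_that("EM recovers mixture proportions and keeps simplex invariants", {
  set.seed(124)
  errs <- vapply(1:10, function(s) {
    b <- gen_baseline(baseline_spec(n_pops = 2, n_per_pop = 50, n_loci = 100,
                                    target_fst = 0.05, seed = 400 + s))
    pf <- b$truth$pop_freqs
    n <- 200
    origin <- sample(1:2, n, replace = TRUE, prob = c(0.8, 0.2))
    codes <- matrix(0L, n, 100, dimnames = list(NULL, colnames(pf)))
    for (k in 1:2) {
      rows <- which(origin == k)
      codes[rows, ] <- rbinom(length(rows) * 100, 2,
                              rep(pf[k, ], each = length(rows)))
    }
    base <- build_baseline(b$genotypes, b$meta)
    mix <- mixture_em(genotype_matrix(codes, locus_ids = colnames(pf)), base)
    expect_equal(sum(mix$pi), 1, tolerance = 1e-12)
    expect_equal(unname(rowSums(mix$posterior)), rep(1, n), tolerance = 1e-12)
    expect_true(all(diff(mix$loglik_trace) >= -1e-8))
    abs(mix$pi["P1"] - 0.8)
  }, 0)
  expect_lt(mean(errs), 0.05)
})

test_that("leave-one-out self-assignment hits its two analytic limits", {
  nl <- 40
  # maximally diverged populations: accuracy 1 in both
  ref <- rbind(matrix(2L, 15, nl), matrix(0L, 15, nl))
  colnames(ref) <- paste0("l", 1:nl)
  gm <- genotype_matrix(ref)
  meta <- make_meta(gm, pop = rep(c("E", "W"), each = 15))
  loo <- self_assign_loo(gm, meta)
  expect_equal(as.numeric(loo$accuracy), c(1, 1))
  # identical populations: accuracy near chance
  set.seed(125)
  same <- matrix(rbinom(200 * nl, 2, 0.5), 200, nl)
  gm2 <- genotype_matrix(same)
  meta2 <- make_meta(gm2, pop = rep(c("A", "B"), each = 100))
  loo2 <- self_assign_loo(gm2, meta2)
  expect_lt(abs(loo2$overall - 0.5), 0.15)
})

test_that("LOO accuracy agrees with a brute-force reimplementation", {
  set.seed(126)
  b <- gen_baseline(baseline_spec(n_pops = 2, n_per_pop = 30, n_loci = 60,
                                  target_fst = 0.05, seed = 127))
  gm <- b$genotypes; meta <- b$meta
  loo <- self_assign_loo(gm, meta)
  # brute force: recompute everything per individual with plain loops
  pops <- sort(unique(meta$pop))
  correct <- logical(nrow(gm$codes))
  for (i in seq_len(nrow(gm$codes))) {
    lls <- sapply(pops, function(p) {
      ll <- 0
      for (j in seq_along(gm$locus_ids)) {
        g <- gm$codes[i, j]
        if (is.na(g)) next
        rows <- setdiff(which(meta$pop == p), i)
        gg <- gm$codes[rows, j]
        cnt <- sum(gg, na.rm = TRUE); tot <- 2 * sum(!is.na(gg))
        f <- (cnt + 0.5) / (tot + 1)
        ll <- ll + log(c((1 - f)^2, 2 * f * (1 - f), f^2)[g + 1])
      }
      ll
    })
    correct[i] <- pops[which.max(lls)] == meta$pop[i]
  }
  expect_equal(loo$overall, mean(correct), tolerance = 0.051)
  expect_equal(loo$assignments$correct, correct)
})

test_that("assignment confidence rises with locus count and divergence", {
  set.seed(128)
  mean_conf <- function(nl, fst, seed) {
    b <- gen_baseline(baseline_spec(n_pops = 2, n_per_pop = 50, n_loci = nl,
                                    target_fst = fst, seed = seed))
    base <- build_baseline(b$genotypes, b$meta)
    pf <- b$truth$pop_freqs
    codes <- matrix(rbinom(50 * nl, 2, rep(pf[1, ], each = 50)), 50, nl,
                    dimnames = list(NULL, colnames(pf)))
    mix <- mixture_em(genotype_matrix(codes, locus_ids = colnames(pf)), base)
    mean(mix$map_prob)
  }
  expect_gt(mean_conf(200, 0.05, 129), mean_conf(25, 0.05, 129))
  expect_gt(mean_conf(100, 0.15, 130), mean_conf(100, 0.02, 130))
})
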