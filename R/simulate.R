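#' Specification for a multi-population SNP baseline
#'
#' Parameters of the Balding-Nichols generator behind the breeding-range
#' dataset: each population's allele frequency at a locus is drawn from
#' Beta(p0 (1-F)/F, (1-p0)(1-F)/F) around an ancestral frequency p0, so the
#' expected FST among populations equals `target_fst`, making the outlier
#' scan calibratable. Outlier loci planted between the migratory and
#' resident group get an additional ancestral-frequency shift of
#' `outlier_delta` for the resident populations.
#'
#' @param n_pops number of populations (first half migratory, rest resident).
#' @param n_per_pop diploid individuals per population.
#' @param n_loci number of biallelic loci.
#' @param target_fst Balding-Nichols divergence parameter in (0, 1); 0 means
#'   no divergence.
#' @param ancestral_freq_range interval for p0 (default (0.1, 0.9)).
#' @param n_outliers number of planted outlier loci.
#' @param outlier_delta group-level frequency shift at planted loci; drawn
#'   p0 are regenerated until the shifted frequency stays in [0.01, 0.99].
#' @param n_sites_per_pop sampling sites per population (latitude varies by
#'   site within a per-population band).
#' @param lat_bands list of c(lo, hi) latitude bands, one per population.
#' @param seed RNG seed.
#' @return list of class `baseline_spec`.
#' @export
baseline_spec <- function(n_pops = 2, n_per_pop = 50, n_loci = 2000,
                          target_fst = 0.05,
                          ancestral_freq_range = c(0.1, 0.9),
                          n_outliers = 0, outlier_delta = 0,
                          n_sites_per_pop = 3, lat_bands = NULL, seed = 1) {
  stopifnot(n_pops >= 1, target_fst >= 0, target_fst < 1,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1)
  if (n_outliers > 0 && abs(outlier_delta) > 0.98)
    stop("outlier_delta leaves no feasible ancestral frequency")
  if (is.null(lat_bands))
    lat_bands <- lapply(seq_len(n_pops), function(i) c(40, 48) + (i - 1) * 12)
  structure(list(n_pops = n_pops, n_per_pop = n_per_pop, n_loci = n_loci,
                 target_fst = target_fst,
                 ancestral_freq_range = ancestral_freq_range,
                 n_outliers = n_outliers, outlier_delta = outlier_delta,
                 n_sites_per_pop = n_sites_per_pop, lat_bands = lat_bands,
                 seed = seed),
            class = "baseline_spec")
}

#' Generate a breeding-range baseline dataset
#'
#' Draws per-population allele frequencies under the Balding-Nichols model,
#' genotypes under Hardy-Weinberg equilibrium within populations, and plants
#' `n_outliers` loci with an extra migratory-vs-resident frequency shift.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [baseline_spec()].
#' @return list: `genotypes` ([genotype_matrix()]), `meta` (sample metadata
#'   data.frame with pop, site, latitude, group, sex), `truth` (pop_freqs
#'   matrix, p0, outlier_loci, migratory_pops, spec).
#' @export
gen_baseline <- function(spec) {
  stopifnot(inherits(spec, "baseline_spec"))
  set.seed(spec$seed)
  k <- spec$n_pops; L <- spec$n_loci; F <- spec$target_fst
  pops <- paste0("P", seq_len(k))
  mig_pops <- pops[seq_len(ceiling(k / 2))]
  lo <- spec$ancestral_freq_range[1]; hi <- spec$ancestral_freq_range[2]
  p0 <- stats::runif(L, lo, hi)
  out_idx <- if (spec$n_outliers > 0)
    sort(sample.int(L, spec$n_outliers)) else integer(0)
  delta <- spec$outlier_delta
  bn <- function(p) {  # one population's frequencies
    if (F == 0) return(p)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  pop_freqs <- matrix(0, k, L, dimnames = list(pops, NULL))
  for (i in seq_len(k)) pop_freqs[i, ] <- pmin(0.999, pmax(0.001, bn(p0)))
  # plant the migratory-vs-resident shift on the realised resident
  # frequencies, so the planted between-group difference is exactly delta
  n_regen <- 0L
  shifts <- rep(0, L)
  res_pops <- setdiff(pops, mig_pops)
  for (j in out_idx) {
    m <- mean(pop_freqs[mig_pops, j])
    s <- sample(c(-1, 1), 1) * delta
    if (m + s < 0.01 || m + s > 0.99) {
      s <- -s
      n_regen <- n_regen + 1L  # infeasible direction flipped (logged)
      if (m + s < 0.01 || m + s > 0.99) stop("infeasible outlier_delta")
    }
    shifts[j] <- s
    pop_freqs[res_pops, j] <- pmin(0.99, pmax(0.01, m + s))
  }
  locus_ids <- sprintf("L%05d", seq_len(L))
  colnames(pop_freqs) <- locus_ids
  n <- k * spec$n_per_pop
  codes <- matrix(0L, n, L)
  pop <- rep(pops, each = spec$n_per_pop)
  for (i in seq_len(k)) {
    rows <- which(pop == pops[i])
    codes[rows, ] <- stats::rbinom(length(rows) * L, 2,
                                   rep(pop_freqs[i, ], each = length(rows)))
  }
  sample_ids <- sprintf("%s_%03d", pop, stats::ave(seq_len(n), pop, FUN = seq_along))
  site_of <- function(i) ((i - 1) %% spec$n_sites_per_pop) + 1
  site <- sprintf("%s_s%d", pop, site_of(stats::ave(seq_len(n), pop, FUN = seq_along)))
  site_lat <- new.env()
  lat <- numeric(n)
  for (s in unique(site)) {
    i <- match(sub("_s.*", "", s), pops)
    assign(s, stats::runif(1, spec$lat_bands[[i]][1], spec$lat_bands[[i]][2]),
           envir = site_lat)
  }
  lat <- vapply(site, function(s) get(s, envir = site_lat), 0)
  meta <- data.frame(sample_id = sample_ids, site = site, pop = pop,
                     latitude = round(lat, 3),
                     group = ifelse(pop %in% mig_pops, "migratory", "resident"),
                     capture_day = NA_integer_,
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     year = NA_integer_, stringsAsFactors = FALSE)
  gm <- genotype_matrix(codes, sample_ids = sample_ids, locus_ids = locus_ids,
                        counted_allele = "B", other_allele = "A")
  list(genotypes = gm, meta = meta,
       truth = list(pop_freqs = pop_freqs, p0 = as.numeric(p0),
                    outlier_loci = locus_ids[out_idx],
                    outlier_shift = shifts[out_idx],
                    migratory_pops = mig_pops, n_regenerated = n_regen,
                    spec = spec))
}

#' Specification for a migration-station time series
#'
#' Two scenarios share one surface. In the `chronotype` scenario all
#' migrants originate from a single source population; timing-locus
#' genotypes shift each bird's expected capture day additively
#' (`effect_days` per copy of the counted allele) around the season
#' midpoint, and timing loci covary through a latent chronotype factor
#' (Gaussian copula with correlation `timing_cor`, Hardy-Weinberg marginals
#' preserved), emulating the collinearity of candidate clock genes. In the
#' `population_confound` scenario capture day depends only on the origin
#' population: migrants are a mixture of two sources with mean passage dates
#' `passage_means` and no genotype effect — allele-frequency trends over the
#' season then arise purely from which population is passing.
#'
#' @param scenario `"chronotype"` or `"population_confound"`.
#' @param n_migrants number of migrants (default 165).
#' @param season c(start, end) day-of-year (default c(230, 321), ~13 weeks
#'   of autumn migration); must span at least 28 days.
#' @param timing_loci locus ids carrying timing effects.
#' @param effect_days per-copy shift of expected capture day (days), scalar
#'   or per timing locus; default -5 (counted-allele carriers migrate
#'   earlier).
#' @param passage_sd residual passage-date SD in days (default 14).
#' @param timing_cor latent-factor correlation among timing loci
#'   (chronotype scenario; default 0.5).
#' @param source_pops population label(s): 1 for chronotype, 2 for confound.
#' @param mix mixture proportions of the two sources (confound; default
#'   c(0.8, 0.2)).
#' @param passage_means mean passage day of each source (confound; default
#'   c(265, 286)).
#' @param seed RNG seed.
#' @return list of class `migration_spec`.
#' @export
migration_spec <- function(scenario = c("chronotype", "population_confound"),
                           n_migrants = 165, season = c(230, 321),
                           timing_loci = NULL, effect_days = -5,
                           passage_sd = 14, timing_cor = 0.5,
                           source_pops = NULL, mix = c(0.8, 0.2),
                           passage_means = c(265, 286), seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(diff(season) >= 28, is.finite(effect_days), passage_sd > 0,
            timing_cor >= 0, timing_cor < 1)
  structure(list(scenario = scenario, n_migrants = n_migrants,
                 season = season, timing_loci = timing_loci,
                 effect_days = effect_days, passage_sd = passage_sd,
                 timing_cor = timing_cor, source_pops = source_pops,
                 mix = mix / sum(mix), passage_means = passage_means,
                 seed = seed),
            class = "migration_spec")
}

# HWE genotype from a standard-normal latent value: thresholds at the
# quantiles of (1-f)^2 and (1-f)^2 + 2f(1-f); larger z = more counted copies.
latent_to_code <- function(z, f) {
  t0 <- stats::qnorm((1 - f)^2)
  t1 <- stats::qnorm((1 - f)^2 + 2 * f * (1 - f))
  ifelse(z < t0, 0L, ifelse(z < t1, 1L, 2L))
}

#' Generate a migration-station time series
#'
#' @param spec a [migration_spec()].
#' @param baseline_truth the `truth` element of [gen_baseline()] (supplies
#'   per-population allele frequencies and locus ids).
#' @return list: `genotypes`, `meta` (capture_day, sex, group =
#'   "migratory"), `truth` (origin per individual, timing loci and codes,
#'   expected days, truncation count).
#' @export
gen_migration_series <- function(spec, baseline_truth) {
  stopifnot(inherits(spec, "migration_spec"))
  set.seed(spec$seed)
  pf <- baseline_truth$pop_freqs
  loci <- colnames(pf)
  nm <- spec$n_migrants
  tl <- spec$timing_loci
  if (is.null(tl)) tl <- character(0)
  stopifnot(all(tl %in% loci))
  eff <- rep_len(spec$effect_days, length(tl))
  mid <- mean(spec$season)
  if (spec$scenario == "chronotype") {
    src <- spec$source_pops %||% rownames(pf)[1]
    origin <- rep(src, nm)
  } else {
    src <- spec$source_pops %||% rownames(pf)[1:2]
    stopifnot(length(src) == 2)
    origin <- src[sample.int(2, nm, replace = TRUE, prob = spec$mix)]
  }
  codes <- matrix(0L, nm, length(loci), dimnames = list(NULL, loci))
  for (p in unique(origin)) {
    rows <- which(origin == p)
    codes[rows, ] <- stats::rbinom(length(rows) * length(loci), 2,
                                   rep(pf[p, ], each = length(rows)))
  }
  if (spec$scenario == "chronotype" && length(tl) > 0) {
    rho <- spec$timing_cor
    g <- stats::rnorm(nm)  # latent chronotype factor
    for (j in seq_along(tl)) {
      z <- sqrt(rho) * g + sqrt(1 - rho) * stats::rnorm(nm)
      codes[, tl[j]] <- latent_to_code(z, pf[origin[1], tl[j]])
    }
    expected <- mid + as.numeric((codes[, tl, drop = FALSE] - 1) %*% eff)
  } else if (spec$scenario == "chronotype") {
    expected <- rep(mid, nm)
  } else {
    expected <- spec$passage_means[match(origin, src)]
  }
  day <- round(expected + stats::rnorm(nm, 0, spec$passage_sd))
  n_trunc <- sum(day < spec$season[1] | day > spec$season[2])
  day <- pmin(pmax(day, spec$season[1]), spec$season[2])
  ids <- sprintf("M%03d", seq_len(nm))
  gm <- genotype_matrix(codes, sample_ids = ids, locus_ids = loci,
                        counted_allele = "B", other_allele = "A")
  meta <- data.frame(sample_id = ids, site = "MIG", pop = NA_character_,
                     latitude = NA_real_, group = "migratory",
                     capture_day = as.integer(day),
                     sex = sample(c("F", "M"), nm, replace = TRUE),
                     year = NA_integer_, stringsAsFactors = FALSE)
  list(genotypes = gm, meta = meta,
       truth = list(origin = origin, timing_loci = tl,
                    timing_codes = codes[, tl, drop = FALSE],
                    expected_day = expected, n_truncated = n_trunc,
                    spec = spec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specification for assay flanking-sequence contexts
#'
#' @param n_contexts number of contexts.
#' @param flank_len bases on each side of the target (default 100).
#' @param frac_gc,frac_indel,frac_snp,frac_multimap fractions of contexts
#'   built to violate (exactly) the GC, indel-proximity, SNP-proximity and
#'   multi-mapping rules; must sum to at most 1.
#' @param k seed length the uniqueness rule will use (duplicate placement).
#' @param seed RNG seed.
#' @return list of class `flank_spec`.
#' @export
flank_spec <- function(n_contexts = 100, flank_len = 100, frac_gc = 0.25,
                       frac_indel = 0.25, frac_snp = 0.25,
                       frac_multimap = 0, k = 20, seed = 1) {
  stopifnot(flank_len >= 50,
            frac_gc + frac_indel + frac_snp + frac_multimap <= 1)
  structure(list(n_contexts = n_contexts, flank_len = flank_len,
                 frac_gc = frac_gc, frac_indel = frac_indel,
                 frac_snp = frac_snp, frac_multimap = frac_multimap,
                 k = k, seed = seed),
            class = "flank_spec")
}

#' Generate flanking-sequence contexts with planted rule violations
#'
#' Each context is a random AT-rich flank (GC ~ 0.40, far below the 0.65
#' rule) with the target base in the middle. Planted violations: a high-GC
#' window (GC ~ 0.85) around the target; an indel within 30 bp; an extra SNP
#' within 20 bp; or a duplicated flanking seed elsewhere in the reference
#' set. Clean contexts sometimes carry benign variants just outside the
#' windows (SNP at 25-40 bp, indel at 35-50 bp) so that passing is a
#' decision, not an absence of input. Violation counts equal the planted
#' fractions exactly.
#'
#' @param spec a [flank_spec()].
#' @return list: `contexts` (list of [assay_context()]), `reference`
#'   (`DNAStringSet`: every context plus planted duplicates), `truth`
#'   (data.frame locus_id, planted in
#'   none/gc/indel30/snp20/multimap).
#' @export
gen_flank_contexts <- function(spec) {
  stopifnot(inherits(spec, "flank_spec"))
  set.seed(spec$seed)
  n <- spec$n_contexts; fl <- spec$flank_len
  len <- 2 * fl + 1
  n_gc <- round(spec$frac_gc * n); n_ind <- round(spec$frac_indel * n)
  n_snp <- round(spec$frac_snp * n); n_mm <- round(spec$frac_multimap * n)
  planted <- sample(c(rep("gc", n_gc), rep("indel30", n_ind),
                      rep("snp20", n_snp), rep("multimap", n_mm),
                      rep("none", n - n_gc - n_ind - n_snp - n_mm)))
  rand_seq <- function(len, gc = 0.40) {
    paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  }
  contexts <- vector("list", n)
  extra_ref <- character(0)
  for (i in seq_len(n)) {
    seq_i <- rand_seq(len)
    nv <- data.frame(offset = integer(), kind = character())
    if (planted[i] == "gc") {
      win <- rand_seq(101, gc = 0.85)
      seq_i <- paste0(substr(seq_i, 1, fl - 50), win,
                      substr(seq_i, fl + 52, len))
    } else if (planted[i] == "indel30") {
      d <- sample(c(-(5:30), 5:30), 1)
      nv <- rbind(nv, data.frame(offset = fl + d, kind = "indel"))
    } else if (planted[i] == "snp20") {
      d <- sample(c(-(1:20), 1:20), 1)
      nv <- rbind(nv, data.frame(offset = fl + d, kind = "snp"))
    } else if (planted[i] == "multimap") {
      seed_kmer <- substr(seq_i, fl - spec$k + 1, fl)
      extra_ref <- c(extra_ref,
                     paste0(rand_seq(30), seed_kmer, rand_seq(30)))
    } else if (stats::runif(1) < 0.5) {  # benign far variants on some passes
      nv <- rbind(nv,
                  data.frame(offset = fl + sample(25:40, 1), kind = "snp"),
                  data.frame(offset = fl - sample(35:50, 1), kind = "indel"))
    }
    contexts[[i]] <- assay_context(sprintf("ctx%03d", i), seq_i, fl, nv)
  }
  ref <- Biostrings::DNAStringSet(
    c(vapply(contexts, `[[`, "", "flank_seq"), extra_ref))
  names(ref) <- c(sprintf("ctx%03d", seq_len(n)),
                  if (length(extra_ref)) sprintf("dup%03d", seq_along(extra_ref)))
  list(contexts = contexts, reference = ref,
       truth = data.frame(locus_id = sprintf("ctx%03d", seq_len(n)),
                          planted = planted, stringsAsFactors = FALSE))
}

#' Generate a paired breeding + migration scenario dataset
#'
#' Builds the inputs the disambiguation pipeline consumes: a two-population
#' (west/east) breeding baseline of `n_panel` assay loci at divergence
#' `target_fst`, of which the first `n_candidate` are the candidate-gene
#' panel and the first `n_timing` of those the timing loci, plus a
#' migration-station series under one of the two scenarios.
#'
#' Under `chronotype`, candidate-locus frequencies are set equal in both
#' populations (clock variation is shared range-wide), all migrants come
#' from the western population, and timing genotypes shift passage date.
#' Under `population_confound`, the timing loci get a west-east frequency
#' differential of `confound_delta`, migrants are a west/east mixture with
#' different mean passage dates, and genotype has no direct timing effect.
#'
#' @param scenario `"chronotype"` or `"population_confound"`.
#' @param seed RNG seed.
#' @param n_panel,n_candidate,n_timing panel sizes (defaults 120 / 9 / 4).
#' @param n_per_pop breeding individuals per population (default 60).
#' @param target_fst west-east divergence (default 0.10).
#' @param confound_delta west-east frequency differential at timing loci in
#'   the confound scenario (default 0.30).
#' @param n_migrants migrants in the station series (default 165).
#' @param effect_days,passage_sd,timing_cor passed to [migration_spec()].
#' @return list: `breeding`, `breeding_meta`, `migrants`, `migrant_meta`,
#'   `candidate_loci`, `timing_loci`, `scenario`, `truth`.
#' @export
gen_scenario_dataset <- function(scenario = c("chronotype", "population_confound"),
                                 seed = 1, n_panel = 120, n_candidate = 9,
                                 n_timing = 4, n_per_pop = 60,
                                 target_fst = 0.10, confound_delta = 0.30,
                                 n_migrants = 165, effect_days = -5,
                                 passage_sd = 14, timing_cor = 0.5) {
  scenario <- match.arg(scenario)
  bspec <- baseline_spec(n_pops = 2, n_per_pop = n_per_pop, n_loci = n_panel,
                         target_fst = target_fst,
                         ancestral_freq_range = c(0.25, 0.75),
                         lat_bands = list(c(42, 50), c(52, 60)), seed = seed)
  base <- gen_baseline(bspec)
  loci <- base$genotypes$locus_ids
  cand <- loci[seq_len(n_candidate)]
  tl <- cand[seq_len(n_timing)]
  pf <- base$truth$pop_freqs
  if (scenario == "chronotype") {
    pf[2, cand] <- pf[1, cand]  # shared clock polymorphism, no structure
  } else {
    half <- confound_delta / 2
    mid <- (pf[1, tl] + pf[2, tl]) / 2
    pf[1, tl] <- pmax(0.02, mid - half)
    pf[2, tl] <- pmin(0.98, mid + half)
  }
  # redraw breeding genotypes at adjusted loci so data match the planted freqs
  set.seed(seed + 1000L)
  adj <- if (scenario == "chronotype") cand else tl
  pop <- base$meta$pop
  codes <- base$genotypes$codes
  for (p in rownames(pf)) {
    rows <- which(pop == p)
    codes[rows, adj] <- stats::rbinom(length(rows) * length(adj), 2,
                                      rep(pf[p, adj], each = length(rows)))
  }
  breeding <- genotype_matrix(codes, sample_ids = base$genotypes$sample_ids,
                              locus_ids = loci, counted_allele = "B",
                              other_allele = "A")
  truth <- base$truth; truth$pop_freqs <- pf
  mspec <- migration_spec(scenario = scenario, n_migrants = n_migrants,
                          timing_loci = tl,
                          effect_days = if (scenario == "chronotype") effect_days else 0,
                          passage_sd = passage_sd, timing_cor = timing_cor,
                          source_pops = if (scenario == "chronotype") "P1" else c("P1", "P2"),
                          seed = seed + 2000L)
  mig <- gen_migration_series(mspec, truth)
  list(breeding = breeding, breeding_meta = base$meta,
       migrants = mig$genotypes, migrant_meta = mig$meta,
       candidate_loci = cand, timing_loci = tl, scenario = scenario,
       truth = list(baseline = truth, migration = mig$truth))
}

#' Write a complete synthetic dataset to disk
#'
#' Produces an on-disk fixture exercising every pipeline stage in the
#' formats the readers consume: a VCF + metadata CSV + gene BED for the
#' outlier scan, flank FASTA + nearby-variant TSV + reference FASTA for the
#' assay filter, and breeding/migrant genotype CSVs + metadata CSVs for the
#' PCA, timing, assignment and classification stages, plus a truth JSON.
#' Byte-identical across runs with the same seed.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed (default 1).
#' @return named character vector of the files written, invisibly.
#' @export
gen_end_to_end <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  scan <- gen_baseline(baseline_spec(n_pops = 2, n_per_pop = 40,
                                     n_loci = 400, target_fst = 0.05,
                                     n_outliers = 20, outlier_delta = 0.4,
                                     seed = seed))
  ann <- data.frame(locus_id = scan$genotypes$locus_ids, chrom = "chr1",
                    pos = seq_along(scan$genotypes$locus_ids) * 1000L,
                    ref = "A", alt = "G", stringsAsFactors = FALSE)
  write_vcf(scan$genotypes, f("scan.vcf"), annotation = ann)
  utils::write.csv(scan$meta, f("scan_meta.csv"), row.names = FALSE, na = "")
  # genes of width 2500 tiled so ~60% of loci fall inside one
  gene_start <- seq(500L, max(ann$pos), by = 4000L)
  bed <- data.frame(chrom = "chr1", start = gene_start,
                    end = gene_start + 2500L,
                    name = sprintf("gene%03d", seq_along(gene_start)))
  utils::write.table(bed, f("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fc <- gen_flank_contexts(flank_spec(n_contexts = 60, frac_multimap = 0.15,
                                      seed = seed))
  flanks <- Biostrings::DNAStringSet(
    vapply(fc$contexts, `[[`, "", "flank_seq"))
  names(flanks) <- vapply(fc$contexts, `[[`, "", "locus_id")
  Biostrings::writeXStringSet(flanks, f("flanks.fasta"))
  Biostrings::writeXStringSet(fc$reference, f("reference.fasta"))
  nv <- do.call(rbind, lapply(fc$contexts, function(ctx)
    if (nrow(ctx$nearby_variants))
      cbind(locus_id = ctx$locus_id, ctx$nearby_variants,
            target_offset = ctx$target_offset)))
  if (is.null(nv))
    nv <- data.frame(locus_id = character(), offset = integer(),
                     kind = character(), target_offset = integer())
  utils::write.table(nv, f("nearby_variants.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc <- gen_scenario_dataset("chronotype", seed = seed)
  write_genotype_csv(sc$breeding, f("breeding_genotypes.csv"))
  utils::write.csv(sc$breeding_meta, f("breeding_meta.csv"),
                   row.names = FALSE, na = "")
  write_genotype_csv(sc$migrants, f("migrant_genotypes.csv"))
  utils::write.csv(sc$migrant_meta, f("migrant_meta.csv"),
                   row.names = FALSE, na = "")
  truth <- list(seed = seed,
                scan_outlier_loci = scan$truth$outlier_loci,
                flank_truth = fc$truth,
                candidate_loci = sc$candidate_loci,
                timing_loci = sc$timing_loci,
                migrant_origin = sc$truth$migration$origin)
  jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE, digits = NA)
  files <- c(vcf = f("scan.vcf"), scan_meta = f("scan_meta.csv"),
             bed = f("genes.bed"), flanks = f("flanks.fasta"),
             reference = f("reference.fasta"),
             nearby_variants = f("nearby_variants.tsv"),
             breeding = f("breeding_genotypes.csv"),
             breeding_meta = f("breeding_meta.csv"),
             migrants = f("migrant_genotypes.csv"),
             migrant_meta = f("migrant_meta.csv"),
             truth = f("truth.json"))
  invisible(files)
}
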