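#' Baseline allele-frequency posteriors from reference populations
#'
#' Tallies counted-allele copies and called-allele totals per population and
#' locus over reference (breeding) samples, and forms posterior mean allele
#' frequencies (count + prior) / (total + 2 * prior) with a prior of 1/2 per
#' allele (1/A for A = 2 alleles), the conditional-GSI convention. The prior
#' keeps frequencies strictly inside (0, 1), so a migrant carrying an allele
#' unseen in some baseline population never gets a zero likelihood there. A
#' population with no called genotype at a locus falls back to the prior
#' alone (frequency 0.5) with a warning.
#'
#' @param gm reference [genotype_matrix()].
#' @param meta metadata containing the population column.
#' @param pop_field metadata column naming the population (default `"pop"`).
#' @param prior per-allele prior count (default 0.5).
#' @return object of class `gsi_baseline`: `pops`, `loci`, `counts`
#'   (pop x locus counted-allele copies), `totals` (called alleles), `freq`
#'   (posterior means).
#' @export
build_baseline <- function(gm, meta, pop_field = "pop", prior = 0.5) {
  m <- meta[match(gm$sample_ids, meta$sample_id), , drop = FALSE]
  if (!pop_field %in% names(m)) stop("no metadata column ", pop_field)
  pop <- as.character(m[[pop_field]])
  if (anyNA(pop)) stop("reference sample(s) without a population label")
  pops <- sort(unique(pop))
  L <- ncol(gm$codes)
  counts <- totals <- matrix(0, length(pops), L,
                             dimnames = list(pops, gm$locus_ids))
  for (i in seq_along(pops)) {
    cg <- gm$codes[pop == pops[i], , drop = FALSE]
    counts[i, ] <- colSums(cg, na.rm = TRUE)
    totals[i, ] <- 2 * colSums(!is.na(cg))
  }
  if (any(totals == 0))
    warning(sum(totals == 0),
            " population x locus cell(s) with no called genotype; prior only")
  freq <- (counts + prior) / (totals + 2 * prior)
  structure(list(pops = pops, loci = gm$locus_ids, counts = counts,
                 totals = totals, freq = freq, prior = prior),
            class = "gsi_baseline")
}

#' HWE genotype log-likelihood of an individual under one baseline population
#'
#' Sum over called loci of log P(code | f) with P(2) = f^2, P(1) = 2f(1-f),
#' P(0) = (1-f)^2, f the population's posterior mean frequency. Missing loci
#' contribute nothing; an individual with no called locus scores 0
#' (uninformative).
#'
#' @param codes named integer vector of genotype codes (names = locus ids).
#' @param baseline a [build_baseline()] result.
#' @param pop population label.
#' @return log-likelihood (single numeric).
#' @export
genotype_loglik <- function(codes, baseline, pop) {
  i <- match(pop, baseline$pops)
  if (is.na(i)) stop("unknown population: ", pop)
  j <- match(names(codes), baseline$loci)
  ok <- !is.na(j) & !is.na(codes)
  if (!any(ok)) return(0)
  f <- baseline$freq[i, j[ok]]
  g <- codes[ok]
  sum(g * log(f) + (2 - g) * log(1 - f) + (g == 1) * log(2))
}

# n x npop matrix of per-individual log-likelihoods; loci absent from the
# baseline are dropped with a message.
loglik_matrix <- function(gm, baseline) {
  shared <- intersect(gm$locus_ids, baseline$loci)
  dropped <- length(gm$locus_ids) - length(shared)
  if (dropped > 0)
    message(dropped, " migrant locus/loci absent from baseline dropped")
  if (length(shared) == 0) stop("no loci shared with the baseline")
  C <- gm$codes[, shared, drop = FALSE]
  F <- baseline$freq[, shared, drop = FALSE]
  called <- !is.na(C)
  C0 <- ifelse(called, C, 0)
  het <- ifelse(called, C == 1, FALSE)
  # LL[i, k] = sum_j c_ij log f_kj + (2 called_ij - c_ij) log(1 - f_kj) + het log 2
  LL <- C0 %*% t(log(F)) + (2 * called - C0) %*% t(log(1 - F)) +
    rowSums(het) * log(2)
  dimnames(LL) <- list(gm$sample_ids, baseline$pops)
  LL
}

#' EM mixture model for genetic stock identification
#'
#' Estimates mixture proportions over baseline populations and per-individual
#' origin posteriors for a mixed sample (e.g. migrants at a banding station).
#' E-step: posterior_ic proportional to pi_c exp(loglik_ic); M-step: pi_c =
#' mean posterior_ic; iterated from uniform pi until the observed-data
#' log-likelihood changes by less than `tol`. Individuals whose maximum a
#' posteriori probability reaches `threshold` are flagged as assigned with
#' certainty.
#'
#' @param gm migrant [genotype_matrix()].
#' @param baseline a [build_baseline()] result.
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter maximum EM iterations (default 1000).
#' @param threshold MAP-probability cutoff for the certainty flag (default 0.8).
#' @return object of class `mixture_result`: `pi` (named simplex),
#'   `posterior` (individuals x populations), `map_label`, `map_prob`,
#'   `certain` (logical), `n_iter`, `loglik_trace`.
#' @export
mixture_em <- function(gm, baseline, tol = 1e-8, max_iter = 1000,
                       threshold = 0.8) {
  LL <- loglik_matrix(gm, baseline)
  if (any(!is.finite(LL)))
    stop("non-finite genotype log-likelihoods; check baseline frequencies")
  K <- ncol(LL)
  pi <- rep(1 / K, K)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    lp <- sweep(LL, 2, log(pi), `+`)
    mx <- apply(lp, 1, max)
    po <- exp(lp - mx)
    rs <- rowSums(po)
    post <- po / rs
    ll <- sum(mx + log(rs))
    trace <- c(trace, ll)
    pi_new <- colMeans(post)
    if (it > 1 && abs(trace[it] - trace[it - 1]) < tol) { pi <- pi_new; break }
    pi <- pi_new
  }
  map_idx <- max.col(post, ties.method = "first")
  structure(list(pi = stats::setNames(pi, colnames(LL)),
                 posterior = post,
                 map_label = colnames(LL)[map_idx],
                 map_prob = post[cbind(seq_len(nrow(post)), map_idx)],
                 certain = post[cbind(seq_len(nrow(post)), map_idx)] >= threshold,
                 threshold = threshold,
                 n_iter = length(trace), loglik_trace = trace),
            class = "mixture_result")
}

#' @exportS3Method base::print
print.mixture_result <- function(x, ...) {
  cat("GSI mixture:", length(x$map_label), "individuals,",
      length(x$pi), "populations\n  pi:",
      paste(sprintf("%s=%.3f", names(x$pi), x$pi), collapse = ", "),
      "\n  assigned with certainty (>=", x$threshold, "):",
      sum(x$certain), "\n")
  invisible(x)
}

#' Leave-one-out self-assignment of the baseline
#'
#' Scores each reference individual against baseline allele frequencies
#' recomputed with its own genotypes removed (all populations' priors kept),
#' assigns it to the population with the highest genotype likelihood, and
#' reports per-population accuracy. Populations of size 1 have undefined
#' accuracy and are flagged.
#'
#' @param gm reference [genotype_matrix()].
#' @param meta metadata with the population column.
#' @param pop_field metadata column naming the population.
#' @param prior per-allele prior count (default 0.5).
#' @return list: `assignments` (data.frame sample_id, true_pop, map_label,
#'   correct), `accuracy` (named per-population), `overall`.
#' @export
self_assign_loo <- function(gm, meta, pop_field = "pop", prior = 0.5) {
  base <- build_baseline(gm, meta, pop_field = pop_field, prior = prior)
  m <- meta[match(gm$sample_ids, meta$sample_id), , drop = FALSE]
  pop <- as.character(m[[pop_field]])
  n <- nrow(gm$codes)
  map <- character(n)
  for (i in seq_len(n)) {
    counts <- base$counts; totals <- base$totals
    k <- match(pop[i], base$pops)
    called <- !is.na(gm$codes[i, ])
    counts[k, called] <- counts[k, called] - gm$codes[i, called]
    totals[k, called] <- totals[k, called] - 2
    freq <- (counts + prior) / (totals + 2 * prior)
    b <- base; b$freq <- freq
    lls <- vapply(base$pops, function(p)
      genotype_loglik(stats::setNames(gm$codes[i, ], gm$locus_ids), b, p), 0)
    map[i] <- base$pops[which.max(lls)]
  }
  correct <- map == pop
  acc <- tapply(correct, pop, mean)
  singletons <- names(table(pop))[table(pop) == 1]
  if (length(singletons)) acc[singletons] <- NA_real_
  list(assignments = data.frame(sample_id = gm$sample_ids, true_pop = pop,
                                map_label = map, correct = correct,
                                stringsAsFactors = FALSE),
       accuracy = acc, overall = mean(correct))
}
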