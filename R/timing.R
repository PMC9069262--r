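#' Passage-date regression on a principal component score
#'
#' Ordinary least squares of capture day-of-year on a PC score, optionally
#' with a sex covariate (F = 0, M = 1) to absorb differential migration
#' between sexes, and optionally the PC-by-sex interaction (to ask whether
#' the genetic effect on timing differs between females and males). Only
#' migrants with a capture day enter; individuals of unknown sex are dropped
#' with a warning when a sex term is requested.
#'
#' @param scores named numeric vector of PC scores (names = sample ids), or
#'   a matrix/data.frame whose column `pc` is used.
#' @param meta metadata data.frame with sample_id, capture_day, sex.
#' @param pc column name when `scores` is a matrix (default "PC1").
#' @param sex_covariate include sex main effect (default TRUE).
#' @param interaction include PC x sex interaction (default FALSE).
#' @return object of class `timing_fit`: coefficient table (estimate, se, t,
#'   p), `r_squared`, `loglik` (Gaussian, MLE variance), `df_residual`, `n`,
#'   and the underlying `lm` fit.
#' @export
fit_pc_timing <- function(scores, meta, pc = "PC1", sex_covariate = TRUE,
                          interaction = FALSE) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    sc <- stats::setNames(as.numeric(scores[, pc]), rownames(scores))
  } else sc <- scores
  m <- meta[match(names(sc), meta$sample_id), , drop = FALSE]
  keep <- !is.na(m$capture_day)
  if (sex_covariate || interaction) {
    unk <- keep & (is.na(m$sex) | m$sex == "unknown")
    if (any(unk)) warning(sum(unk), " sample(s) of unknown sex dropped")
    keep <- keep & !unk
  }
  d <- data.frame(day = m$capture_day[keep], pc = sc[keep])
  form <- day ~ pc
  if (sex_covariate || interaction) {
    d$sex <- ifelse(m$sex[keep] == "M", 1, 0)
    form <- if (interaction) day ~ pc * sex else day ~ pc + sex
  }
  if (stats::sd(d$pc) == 0) stop("constant predictor: pc")
  fit <- stats::lm(form, data = d)
  if (fit$df.residual < 3) stop("fewer than 3 residual degrees of freedom")
  new_timing_fit(fit, response = "capture_day")
}

new_timing_fit <- function(fit, response) {
  s <- summary(fit)
  structure(list(response = response,
                 coefficients = stats::coef(s),
                 r_squared = s$r.squared,
                 loglik = as.numeric(stats::logLik(fit)),
                 df_residual = fit$df.residual,
                 n = length(fit$residuals),
                 lm = fit),
            class = "timing_fit")
}

#' @exportS3Method base::print
print.timing_fit <- function(x, ...) {
  cat("timing fit (", x$response, "), n =", x$n,
      ", R^2 =", signif(x$r_squared, 3), "\n")
  stats::printCoefmat(x$coefficients, signif.stars = FALSE)
  invisible(x)
}

#' Re-polarise genotype codes to the major allele
#'
#' Flips the counted allele at every locus whose counted-allele frequency in
#' the given sample subset is below 0.5 (codes mapped 0 <-> 2, allele labels
#' swapped), so that downstream weekly trajectories track the major allele.
#' Frequency exactly 0.5 keeps the original polarity; the operation is
#' idempotent. Loci with no called genotype in the subset are left unchanged
#' with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids defining the frequency reference (default: all).
#' @return a re-polarised `genotype_matrix`.
#' @export
repolarize_major <- function(gm, samples = NULL) {
  f <- allele_freq(gm, samples)
  if (anyNA(f)) {
    warning(sum(is.na(f)), " locus/loci with no called genotype left unchanged")
  }
  flip <- !is.na(f) & f < 0.5
  codes <- gm$codes
  codes[, flip] <- 2L - codes[, flip]
  counted <- gm$counted_allele
  other <- gm$other_allele
  counted[flip] <- gm$other_allele[flip]
  other[flip] <- gm$counted_allele[flip]
  genotype_matrix(codes, sample_ids = gm$sample_ids, locus_ids = gm$locus_ids,
                  counted_allele = counted, other_allele = other)
}

#' Weekly allele-frequency trajectory at one locus
#'
#' Bins migrants into 7-day windows from the season start (default: earliest
#' capture day in the data) and reports the counted-allele frequency per
#' week at its midpoint day (bin start + 3). The standard error is the
#' binomial sqrt(f(1-f)/n_alleles) with n_alleles = 2 x called genotypes.
#' Empty weeks are omitted.
#'
#' @param gm a [genotype_matrix()].
#' @param meta metadata with sample_id and capture_day.
#' @param locus locus id.
#' @param season_start optional first day of week 0.
#' @return data.frame: week_index, midpoint_day, n_individuals,
#'   n_called_alleles, freq, se.
#' @export
weekly_frequencies <- function(gm, meta, locus, season_start = NULL) {
  j <- match(locus, gm$locus_ids)
  if (is.na(j)) stop("locus not found: ", locus)
  m <- meta[match(gm$sample_ids, meta$sample_id), , drop = FALSE]
  mig <- !is.na(m$capture_day)
  if (!any(mig)) stop("no migrants with capture_day")
  day <- m$capture_day[mig]
  code <- gm$codes[mig, j]
  start <- if (is.null(season_start)) min(day) else season_start
  wk <- (day - start) %/% 7L
  out <- do.call(rbind, lapply(sort(unique(wk)), function(w) {
    cw <- code[wk == w]
    called <- sum(!is.na(cw))
    if (called == 0) return(NULL)
    na <- 2L * called
    f <- sum(cw, na.rm = TRUE) / na
    data.frame(week_index = w, midpoint_day = start + 7L * w + 3L,
               n_individuals = sum(wk == w), n_called_alleles = na,
               freq = f, se = sqrt(f * (1 - f) / na))
  }))
  rownames(out) <- NULL
  out
}

#' Linear vs polynomial trend in weekly allele frequency, with LRT
#'
#' Fits nested OLS models of weekly frequency on midpoint day: a straight
#' line (degree 1, reduced) and a polynomial of `degree_full` (default 2).
#' The likelihood-ratio statistic 2(llf - llr) uses Gaussian log-likelihoods
#' with maximum-likelihood variance, referred to chi-square with
#' `degree_full - 1` degrees of freedom — the standard nested-OLS LRT; note
#' it is anticonservative at few weekly points (see package vignette).
#' Points can be weighted by inverse binomial variance, or the trajectory
#' fitted as a binomial GLM of allele counts, as sensitivity options.
#'
#' @param wf data.frame from [weekly_frequencies()].
#' @param degree_full polynomial degree of the full model (default 2).
#' @param weighting `"none"` (default), `"inverse_variance"`, `"binomial"`.
#' @return list with `linear` and `full` (`timing_fit`s, or glm fits for the
#'   binomial option) and `lrt` = list(ll_reduced, ll_full, df_diff,
#'   statistic, p_value).
#' @export
fit_trend_lrt <- function(wf, degree_full = 2,
                          weighting = c("none", "inverse_variance", "binomial")) {
  weighting <- match.arg(weighting)
  stopifnot(degree_full >= 1)
  if (nrow(wf) < degree_full + 2)
    stop("need at least degree_full + 2 weekly points")
  if (weighting == "binomial") {
    cnt <- round(wf$freq * wf$n_called_alleles)
    resp <- cbind(cnt, wf$n_called_alleles - cnt)
    f1 <- stats::glm(resp ~ midpoint_day, family = stats::binomial, data = wf)
    f2 <- stats::glm(resp ~ stats::poly(midpoint_day, degree_full),
                     family = stats::binomial, data = wf)
    ll1 <- as.numeric(stats::logLik(f1)); ll2 <- as.numeric(stats::logLik(f2))
    lin <- f1; full <- f2
  } else {
    w <- if (weighting == "inverse_variance") {
      v <- wf$se^2
      v[v == 0] <- min(v[v > 0], 1e-6)
      1 / v
    } else NULL
    f1 <- stats::lm(freq ~ midpoint_day, data = wf, weights = w)
    f2 <- stats::lm(freq ~ stats::poly(midpoint_day, degree_full, raw = TRUE),
                    data = wf, weights = w)
    ll1 <- as.numeric(stats::logLik(f1)); ll2 <- as.numeric(stats::logLik(f2))
    lin <- new_timing_fit(f1, response = "weekly_freq")
    full <- new_timing_fit(f2, response = "weekly_freq")
  }
  stat <- max(0, 2 * (ll2 - ll1))
  df <- degree_full - 1
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(linear = lin, full = full,
       lrt = list(ll_reduced = ll1, ll_full = ll2, df_diff = df,
                  statistic = stat, p_value = p))
}

#' Sex difference in migration timing
#'
#' OLS of capture day on sex (F = 0, M = 1) over migrants of known sex; the
#' two-sided p-value on the sex coefficient tests differential migration
#' timing between sexes.
#'
#' @param meta metadata with sample_id, capture_day, sex.
#' @return a `timing_fit`.
#' @export
sex_timing_test <- function(meta) {
  d <- meta[!is.na(meta$capture_day) & meta$sex %in% c("F", "M"), , drop = FALSE]
  if (length(unique(d$sex)) < 2) stop("need migrants of both sexes")
  d$sexM <- ifelse(d$sex == "M", 1, 0)
  fit <- stats::lm(capture_day ~ sexM, data = d)
  new_timing_fit(fit, response = "capture_day")
}
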