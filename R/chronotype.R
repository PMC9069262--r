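#' Association between a per-sample response and breeding latitude
#'
#' OLS of a response (PC score or genotype code at a focal locus) on
#' latitude over a set of breeding samples. A significant slope indicates
#' the response is geographically structured — the signature expected if
#' temporal allele-frequency patterns at a migration station were driven by
#' different breeding populations passing at different times rather than by
#' chronotypes within one population.
#'
#' @param values named numeric vector (names = sample ids).
#' @param meta metadata with sample_id and latitude.
#' @param samples optional subset of sample ids (default: all with latitude).
#' @return list: slope, se, p_value, r_squared, n.
#' @export
latitude_association <- function(values, meta, samples = NULL) {
  if (!is.null(samples)) values <- values[names(values) %in% samples]
  m <- meta[match(names(values), meta$sample_id), , drop = FALSE]
  keep <- !is.na(m$latitude) & !is.na(values)
  lat <- m$latitude[keep]; y <- values[keep]
  if (length(y) < 10) stop("need at least 10 samples with latitude")
  if (stats::sd(lat) == 0) stop("constant latitude")
  fit <- stats::lm(y ~ lat)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       se = s$coefficients[2, 2],
       p_value = s$coefficients[2, 4],
       r_squared = s$r.squared, n = length(y))
}

#' Temporal spread of minority-assigned migrants
#'
#' Compares capture days of migrants assigned away from the modal population
#' against those assigned to it (two-sided Wilcoxon rank-sum). Minority
#' individuals clustered in one part of the season suggest a distinct
#' population passing at a particular time; minority individuals spanning
#' the season argue against breeding origin confounding the timing signal.
#' With fewer than 3 minority individuals the test is underpowered, so the
#' observed minority day range as a fraction of the season span is reported
#' instead, flagged `low_power`; with none, the result is `not_applicable`.
#'
#' @param assignments a [mixture_em()] result.
#' @param meta metadata with sample_id and capture_day for the migrants.
#' @return list: status (`"ok"`, `"low_power"`, `"not_applicable"`),
#'   modal_pop, n_minority, statistic, p_value (NA unless status `"ok"`),
#'   coverage (minority day range / season span; NA unless `"low_power"`).
#' @export
minority_spread_test <- function(assignments, meta) {
  ids <- rownames(assignments$posterior)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  day <- m$capture_day
  conf <- assignments$certain
  modal <- names(which.max(table(assignments$map_label[conf])))
  if (is.null(modal))
    modal <- names(which.max(table(assignments$map_label)))
  minority <- assignments$map_label != modal & !is.na(day)
  modal_set <- assignments$map_label == modal & !is.na(day)
  n_min <- sum(minority)
  if (n_min == 0)
    return(list(status = "not_applicable", modal_pop = modal, n_minority = 0L,
                statistic = NA_real_, p_value = NA_real_, coverage = NA_real_))
  if (n_min < 3) {
    span <- diff(range(day, na.rm = TRUE))
    cov <- if (span > 0) diff(range(day[minority])) / span else 0
    return(list(status = "low_power", modal_pop = modal, n_minority = n_min,
                statistic = NA_real_, p_value = NA_real_, coverage = cov))
  }
  wt <- stats::wilcox.test(day[minority], day[modal_set], exact = FALSE)
  list(status = "ok", modal_pop = modal, n_minority = n_min,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       coverage = NA_real_)
}

#' Classify temporal genetic structure: chronotypes vs population passage
#'
#' Combines three lines of evidence into an explicit, re-derivable verdict:
#' (i) the fraction of confidently assigned migrants mapping to the modal
#' population, (ii) latitude associations of PC1 and focal-locus genotypes
#' over breeding samples (Holm-adjusted across tests), and (iii) temporal
#' clustering of minority-assigned migrants. The verdict is
#' `chronotype_consistent` when the modal fraction reaches `modal_min`, no
#' adjusted latitude test is significant at `alpha`, and minority migrants
#' are not temporally clustered; `population_passage_consistent` when any
#' latitude test is significant and minority migrants are clustered;
#' otherwise `indeterminate`.
#'
#' @param fraction_confident_modal fraction in `[0, 1]`.
#' @param latitude_tests data.frame with columns `response` and `p_value`
#'   (one row per latitude association).
#' @param minority result of [minority_spread_test()].
#' @param modal_min threshold on the modal fraction (default 0.9).
#' @param alpha significance level (default 0.05).
#' @param coverage_max with a low-power minority set, day-range coverage
#'   below this fraction of the season counts as clustered (default 0.25).
#' @return object of class `chronotype_report` carrying all inputs, the
#'   Holm-adjusted p-values and the `verdict`.
#' @export
classify_scenario <- function(fraction_confident_modal, latitude_tests,
                              minority, modal_min = 0.9, alpha = 0.05,
                              coverage_max = 0.25) {
  lt <- latitude_tests
  lt$p_holm <- stats::p.adjust(lt$p_value, method = "holm")
  lat_signif <- any(lt$p_holm < alpha)
  clustered <- switch(minority$status,
    ok = minority$p_value < alpha,
    low_power = minority$coverage < coverage_max,
    not_applicable = FALSE)
  verdict <- if (fraction_confident_modal >= modal_min && !lat_signif &&
                 !clustered) {
    "chronotype_consistent"
  } else if (lat_signif && clustered) {
    "population_passage_consistent"
  } else "indeterminate"
  structure(list(fraction_confident_modal = fraction_confident_modal,
                 latitude_tests = lt, minority = minority,
                 thresholds = list(modal_min = modal_min, alpha = alpha,
                                   coverage_max = coverage_max),
                 verdict = verdict),
            class = "chronotype_report")
}

#' @exportS3Method base::print
print.chronotype_report <- function(x, ...) {
  cat("chronotype report\n",
      sprintf("  confident migrants assigned to modal population: %.3f\n",
              x$fraction_confident_modal),
      sprintf("  latitude tests (Holm-adjusted p): %s\n",
              paste(sprintf("%s=%.3g", x$latitude_tests$response,
                            x$latitude_tests$p_holm), collapse = ", ")),
      sprintf("  minority temporal spread: %s (p=%.3g, n=%d)\n",
              x$minority$status,
              ifelse(is.na(x$minority$p_value), NaN, x$minority$p_value),
              x$minority$n_minority),
      "  verdict:", x$verdict, "\n")
  invisible(x)
}

#' Run the full disambiguation pipeline on a scenario dataset
#'
#' Convenience wrapper tying the stages together for a dataset as produced
#' by [gen_scenario_dataset()]: builds the baseline from breeding samples,
#' assigns migrants by [mixture_em()], fits the ordinal PCA of candidate
#' loci over all individuals, tests PC1 and the four loci loading highest on
#' PC1 against breeding latitude, tests minority temporal spread, and
#' classifies the scenario.
#'
#' @param dataset list from [gen_scenario_dataset()].
#' @param modal_min,alpha,coverage_max passed to [classify_scenario()].
#' @param n_focal_loci number of top-|loading| loci tested against latitude.
#' @param assignment_threshold MAP cutoff for "assigned with certainty".
#' @return a `chronotype_report`; the assignment and PCA fits are attached
#'   as attributes `assignments` and `pca`.
#' @export
run_scenario_pipeline <- function(dataset, modal_min = 0.9, alpha = 0.05,
                                  coverage_max = 0.25, n_focal_loci = 4,
                                  assignment_threshold = 0.8) {
  breeding <- dataset$breeding; migrants <- dataset$migrants
  meta <- rbind(dataset$breeding_meta[, c("sample_id", "latitude", "capture_day")],
                dataset$migrant_meta[, c("sample_id", "latitude", "capture_day")])
  base <- build_baseline(breeding, dataset$breeding_meta, pop_field = "pop")
  mix <- mixture_em(migrants, base, threshold = assignment_threshold)
  conf <- mix$certain
  modal <- names(which.max(table(mix$map_label[conf])))
  frac <- if (any(conf)) mean(mix$map_label[conf] == modal) else 0
  # ordinal PCA of candidate loci across breeding + migrant samples
  cand <- dataset$candidate_loci
  all_codes <- rbind(gm_subset(breeding, loci = cand)$codes,
                     gm_subset(migrants, loci = cand)$codes)
  pca <- fit_ordinal_pca(all_codes, n_dim = 2)
  pca <- fix_sign(pca, rownames(pca$loadings)[1])
  focal <- rownames(pca$loadings)[
    order(abs(pca$loadings[, 1]), decreasing = TRUE)][seq_len(n_focal_loci)]
  bids <- breeding$sample_ids
  lat_tests <- list(latitude_association(
    stats::setNames(pca$object_scores[bids, 1], bids), meta))
  resp <- "PC1"
  for (l in focal) {
    v <- stats::setNames(breeding$codes[, l], bids)
    lat_tests <- c(lat_tests, list(latitude_association(v, meta)))
    resp <- c(resp, l)
  }
  lt <- data.frame(response = resp,
                   slope = vapply(lat_tests, `[[`, 0, "slope"),
                   p_value = vapply(lat_tests, `[[`, 0, "p_value"),
                   stringsAsFactors = FALSE)
  minority <- minority_spread_test(mix, dataset$migrant_meta)
  rep <- classify_scenario(frac, lt, minority, modal_min = modal_min,
                           alpha = alpha, coverage_max = coverage_max)
  attr(rep, "assignments") <- mix
  attr(rep, "pca") <- pca
  rep
}
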