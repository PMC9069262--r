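#' Weir-Cockerham variance components for one locus
#'
#' Computes the Weir & Cockerham (1984) variance components for a single
#' biallelic locus over r >= 2 groups of diploid genotypes: `a` (among
#' groups), `b` (among individuals within groups), `c` (within individuals,
#' i.e. half the average observed heterozygosity), and theta = a/(a+b+c).
#' Missing codes are excluded group-wise before the sample sizes, allele
#' frequencies and heterozygote proportions enter the formulas.
#'
#' @param codes_by_group list of >= 2 integer vectors of genotype codes
#'   (0/1/2/NA), one per group.
#' @param min_calls minimum called genotypes per group for status `"ok"`.
#' @return list with `a`, `b`, `c`, `theta`, `n_per_group`, `status`
#'   (`"ok"`, `"monomorphic"` or `"insufficient"`). `theta` is `NaN` when the
#'   total variance a+b+c is zero (monomorphic locus).
#' @export
wc_fst_locus <- function(codes_by_group, min_calls = 5) {
  if (!is.list(codes_by_group) || length(codes_by_group) < 2)
    stop("need genotype codes for at least 2 groups")
  n <- vapply(codes_by_group, function(g) sum(!is.na(g)), 0L)
  if (any(n == 0))
    return(list(a = NA_real_, b = NA_real_, c = NA_real_, theta = NA_real_,
                n_per_group = n, status = "insufficient"))
  p <- vapply(codes_by_group, function(g) mean(g, na.rm = TRUE) / 2, 0)
  h <- vapply(codes_by_group, function(g) mean(g == 1, na.rm = TRUE), 0)
  comp <- wc_components(matrix(n, 1), matrix(p, 1), matrix(h, 1))
  tot <- comp$a + comp$b + comp$c
  status <- if (any(n < min_calls)) "insufficient"
            else if (!is.na(tot) && tot == 0) "monomorphic" else "ok"
  theta <- if (is.na(tot)) NA_real_ else if (tot == 0) NaN else comp$a / tot
  list(a = comp$a, b = comp$b, c = comp$c, theta = theta,
       n_per_group = n, status = status)
}

# Vectorised WC (1984) components. n, p, h: loci x groups matrices of called
# sample sizes, counted-allele frequencies and heterozygote proportions.
wc_components <- function(n, p, h) {
  r <- ncol(n)
  nsum <- rowSums(n)
  nbar <- nsum / r
  nc <- (nsum - rowSums(n^2) / nsum) / (r - 1)
  pbar <- rowSums(n * p) / nsum
  s2 <- rowSums(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(n * h) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  deg <- nbar <= 1 | nc <= 0
  a[deg] <- NA_real_; b[deg] <- NA_real_; cc[deg] <- NA_real_
  list(a = a, b = b, c = cc)
}

#' Per-locus FST scan between phenotype-defined groups
#'
#' Runs the Weir-Cockerham estimator at every locus between groups resolved
#' from sample metadata. The default grouping pools sites into a migratory
#' class (metadata group `migratory` or `partial`) versus `resident`,
#' matching a two-group scan of migratory behaviour; passing
#' `group_by = "pop"` (or any metadata column) instead treats each level of
#' that column as a subpopulation. Sites listed in `exclude_sites` (e.g. a
#' site of ambiguous migratory status) are dropped before grouping; samples
#' whose group resolves to `unknown` are dropped likewise.
#'
#' @param gm a [genotype_matrix()].
#' @param meta metadata data.frame (see [read_metadata()]).
#' @param group_by `"migratory_class"` (default) or a metadata column name.
#' @param exclude_sites character vector of `site` values to drop first.
#' @param min_calls minimum called genotypes per group per locus.
#' @return data.frame (one row per locus): locus_id, a, b, c, theta,
#'   per-group called counts (`n_<group>`), status.
#' @export
fst_scan <- function(gm, meta, group_by = "migratory_class",
                     exclude_sites = NULL, min_calls = 5) {
  meta <- meta[match(gm$sample_ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("metadata missing for some genotyped samples")
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(exclude_sites) && "site" %in% names(meta))
    keep <- keep & !(meta$site %in% exclude_sites)
  if (group_by == "migratory_class") {
    grp <- ifelse(meta$group %in% c("migratory", "partial"), "migratory",
                  ifelse(meta$group == "resident", "resident", NA))
  } else {
    if (!group_by %in% names(meta)) stop("no metadata column ", group_by)
    grp <- as.character(meta[[group_by]])
  }
  keep <- keep & !is.na(grp) & grp != "unknown"
  grp <- factor(grp[keep])
  if (nlevels(grp) < 2)
    stop("fewer than 2 groups after exclusions")
  empty <- levels(grp)[tabulate(grp, nlevels(grp)) == 0]
  if (length(empty))
    stop("group(s) with zero samples after exclusions: ",
         paste(empty, collapse = ", "))
  codes <- gm$codes[keep, , drop = FALSE]
  L <- ncol(codes)
  r <- nlevels(grp)
  n <- p <- h <- matrix(0, L, r)
  for (g in seq_len(r)) {
    cg <- codes[grp == levels(grp)[g], , drop = FALSE]
    n[, g] <- colSums(!is.na(cg))
    p[, g] <- colSums(cg, na.rm = TRUE) / (2 * pmax(n[, g], 1))
    h[, g] <- colSums(cg == 1, na.rm = TRUE) / pmax(n[, g], 1)
  }
  comp <- wc_components(n, p, h)
  tot <- comp$a + comp$b + comp$c
  theta <- ifelse(is.na(tot), NA_real_, ifelse(tot == 0, NaN, comp$a / tot))
  status <- rep("ok", L)
  status[!is.na(tot) & tot == 0] <- "monomorphic"
  status[apply(n, 1, min) < min_calls | is.na(tot)] <- "insufficient"
  out <- data.frame(locus_id = gm$locus_ids, a = comp$a, b = comp$b,
                    c = comp$c, theta = theta, stringsAsFactors = FALSE)
  for (g in seq_len(r)) out[[paste0("n_", levels(grp)[g])]] <- n[, g]
  out$status <- status
  out
}

#' Multi-locus ratio-of-sums FST
#'
#' The standard multi-locus Weir-Cockerham estimate
#' \eqn{\sum_l a_l / \sum_l (a_l+b_l+c_l)} over loci with status `"ok"`.
#'
#' @param fst data.frame from [fst_scan()].
#' @return single numeric value.
#' @export
fst_ratio_of_sums <- function(fst) {
  ok <- fst$status == "ok"
  sum(fst$a[ok]) / sum(fst$a[ok] + fst$b[ok] + fst$c[ok])
}

#' Relaxed-percentile outlier selection
#'
#' Selects every locus whose theta is at or above the empirical quantile
#' (linear interpolation between order statistics) of theta over loci with
#' status `"ok"`. Ties at the threshold are all included — the threshold is
#' deliberately permissive so many small-effect loci are carried forward.
#'
#' @param fst data.frame from [fst_scan()].
#' @param percentile fraction in (0, 1); default 0.90.
#' @return list with `threshold_value`, `locus_ids` (selected), and `table`
#'   (the ok-loci rows with a `selected` flag).
#' @export
select_outliers <- function(fst, percentile = 0.90) {
  stopifnot(percentile > 0, percentile < 1)
  ok <- fst[fst$status == "ok" & !is.na(fst$theta), , drop = FALSE]
  if (nrow(ok) == 0) stop("no loci with status 'ok'")
  thr <- unname(stats::quantile(ok$theta, percentile, type = 7))
  ok$selected <- ok$theta >= thr
  list(threshold_value = thr,
       locus_ids = ok$locus_id[ok$selected],
       table = ok)
}

#' Annotate candidate loci with overlapping genes
#'
#' @param candidates list from [select_outliers()].
#' @param genes `GRanges` from [read_gene_intervals()].
#' @param annotation locus annotation data.frame (locus_id, chrom, pos).
#' @return `candidates` with added `gene_map` (named list locus_id -> gene
#'   symbols) and `n_genes` (distinct genes hit). Loci lacking annotation map
#'   to no gene, with a warning.
#' @export
annotate_genes <- function(candidates, genes, annotation) {
  ids <- candidates$locus_ids
  idx <- match(ids, annotation$locus_id)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " selected locus/loci missing annotation")
  gene_map <- rep(list(character(0)), length(ids))
  names(gene_map) <- ids
  has <- !is.na(idx)
  if (any(has)) {
    gene_map[has] <- genes_at(genes, annotation$chrom[idx[has]],
                              annotation$pos[idx[has]])
  }
  candidates$gene_map <- gene_map
  candidates$n_genes <- length(unique(unlist(gene_map)))
  candidates
}
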