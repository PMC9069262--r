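#' Genotype matrix container
#'
#' Holds biallelic genotypes for a set of individuals as copies of a
#' designated "counted" allele per locus: 0, 1, 2, or `NA` for a missing call.
#' This is the shared currency of the pipeline: the FST scan, the ordinal PCA,
#' the timing models and the mixture assignment all consume it.
#'
#' @param codes integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `codes`).
#' @param locus_ids character vector of unique locus identifiers
#'   (default: colnames of `codes`).
#' @param counted_allele per-locus label of the allele whose copies are
#'   counted (recycled if length 1).
#' @param other_allele per-locus label of the non-counted allele (optional;
#'   used when re-polarising to the major allele).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `sample_ids`, `locus_ids`, `counted_allele`, `other_allele`.
#' @export
genotype_matrix <- function(codes, sample_ids = rownames(codes),
                            locus_ids = colnames(codes),
                            counted_allele = "ALT", other_allele = NA_character_) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(codes)))
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(ncol(codes)))
  sample_ids <- as.character(sample_ids)
  locus_ids <- as.character(locus_ids)
  if (length(sample_ids) != nrow(codes))
    stop("length(sample_ids) must equal nrow(codes)")
  if (length(locus_ids) != ncol(codes))
    stop("length(locus_ids) must equal ncol(codes)")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(locus_ids)) stop("locus_ids must be unique")
  bad <- !is.na(codes) & !(codes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  counted_allele <- rep_len(as.character(counted_allele), ncol(codes))
  other_allele <- rep_len(as.character(other_allele), ncol(codes))
  dimnames(codes) <- list(sample_ids, locus_ids)
  structure(
    list(codes = codes, sample_ids = sample_ids, locus_ids = locus_ids,
         counted_allele = counted_allele, other_allele = other_allele),
    class = "genotype_matrix"
  )
}

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  miss <- mean(is.na(x$codes))
  cat(sprintf("genotype_matrix: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$codes), ncol(x$codes), 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids (or logical/integer index) to keep; `NULL` keeps all.
#' @param loci locus ids (or logical/integer index) to keep; `NULL` keeps all.
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- if (is.null(samples)) seq_along(gm$sample_ids) else {
    if (is.character(samples)) {
      idx <- match(samples, gm$sample_ids)
      if (anyNA(idx)) stop("unknown sample ids: ",
                           paste(samples[is.na(idx)], collapse = ", "))
      idx
    } else samples
  }
  li <- if (is.null(loci)) seq_along(gm$locus_ids) else {
    if (is.character(loci)) {
      idx <- match(loci, gm$locus_ids)
      if (anyNA(idx)) stop("unknown locus ids: ",
                           paste(loci[is.na(idx)], collapse = ", "))
      idx
    } else loci
  }
  genotype_matrix(gm$codes[si, li, drop = FALSE],
                  sample_ids = gm$sample_ids[si],
                  locus_ids = gm$locus_ids[li],
                  counted_allele = gm$counted_allele[li],
                  other_allele = gm$other_allele[li])
}

#' Counted-allele frequency per locus
#'
#' @param gm a [genotype_matrix()].
#' @param samples optional subset of sample ids.
#' @return Named numeric vector of counted-allele frequencies (NA where no
#'   genotype is called).
#' @export
allele_freq <- function(gm, samples = NULL) {
  if (!is.null(samples)) gm <- gm_subset(gm, samples = samples)
  called <- colSums(!is.na(gm$codes))
  f <- colSums(gm$codes, na.rm = TRUE) / (2 * called)
  f[called == 0] <- NA_real_
  stats::setNames(f, gm$locus_ids)
}
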