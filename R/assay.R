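#' Assay context for a candidate SNP
#'
#' Bundles what the designability filter needs for one targeted variant: the
#' flanking sequence, the 0-based offset of the target base within it, and
#' any known nearby variants (SNPs or indels) with their offsets.
#'
#' @param locus_id identifier.
#' @param flank_seq nucleotide string containing the target base.
#' @param target_offset 0-based index of the target base in `flank_seq`.
#' @param nearby_variants data.frame with columns `offset` (0-based) and
#'   `kind` (`"snp"` or `"indel"`); may be empty.
#' @return object of class `assay_context`.
#' @export
assay_context <- function(locus_id, flank_seq, target_offset,
                          nearby_variants = data.frame(offset = integer(),
                                                       kind = character())) {
  flank_seq <- toupper(as.character(flank_seq))
  n <- nchar(flank_seq)
  if (target_offset < 0 || target_offset >= n)
    stop("target_offset outside flank_seq for ", locus_id)
  if (nrow(nearby_variants) &&
      (any(nearby_variants$offset < 0) || any(nearby_variants$offset >= n)))
    stop("nearby variant offset outside flank_seq for ", locus_id)
  structure(list(locus_id = locus_id, flank_seq = flank_seq,
                 target_offset = as.integer(target_offset),
                 nearby_variants = nearby_variants),
            class = "assay_context")
}

#' GC fraction of a sequence window
#'
#' Case-insensitive count of G/C over the window, with ambiguity bases (`N`)
#' excluded from both numerator and denominator. A window that is entirely
#' `N` has undefined GC content (`NA`), which downstream fails the GC rule
#' conservatively.
#'
#' @param seq nucleotide string.
#' @param window optional `c(lo, hi)` of 0-based inclusive offsets; default
#'   whole sequence.
#' @return fraction in `[0, 1]`, or `NA` if no unambiguous base in window.
#' @export
gc_fraction <- function(seq, window = NULL) {
  s <- toupper(as.character(seq))
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
    s <- substr(s, window[1] + 1, window[2] + 1)
  }
  b <- strsplit(s, "")[[1]]
  b <- b[b != "N"]
  if (length(b) == 0) return(NA_real_)
  sum(b %in% c("G", "C")) / length(b)
}

#' Designability verdict for one assay context
#'
#' A target is designable when all of the following hold: GC content of the
#' window around the target is strictly below `gc_max`; no indel lies within
#' `indel_window` bases of the target (inclusive distance); no additional SNP
#' lies within `snp_window` bases (inclusive); and, when a reference sequence
#' set is supplied, neither flanking seed maps to more than one location
#' (see [check_unique_mapping()]). Without a reference the uniqueness rule is
#' reported `"not_evaluated"` and does not fail the verdict.
#'
#' @param ctx an [assay_context()].
#' @param gc_max GC threshold; the rule fails at GC >= `gc_max`.
#' @param indel_window,snp_window inclusive distances in bp.
#' @param gc_flank half-width of the GC window around the target (bases each
#'   side, truncated at sequence ends).
#' @param reference optional `DNAStringSet` for the uniqueness check.
#' @param k seed length for the uniqueness check.
#' @return list: locus_id, designable, failed_rules (subset of
#'   `c("gc","indel30","snp20","multimap")`), gc_fraction, multimap_status.
#' @export
check_designable <- function(ctx, gc_max = 0.65, indel_window = 30,
                             snp_window = 20, gc_flank = 50,
                             reference = NULL, k = 20) {
  stopifnot(inherits(ctx, "assay_context"))
  n <- nchar(ctx$flank_seq)
  lo <- max(0L, ctx$target_offset - gc_flank)
  hi <- min(n - 1L, ctx$target_offset + gc_flank)
  gc <- gc_fraction(ctx$flank_seq, c(lo, hi))
  failed <- character(0)
  if (is.na(gc) || gc >= gc_max) failed <- c(failed, "gc")
  d <- abs(ctx$nearby_variants$offset - ctx$target_offset)
  if (any(ctx$nearby_variants$kind == "indel" &
          d <= indel_window)) failed <- c(failed, "indel30")
  if (any(ctx$nearby_variants$kind == "snp" & d > 0 &
          d <= snp_window)) failed <- c(failed, "snp20")
  mm <- "not_evaluated"
  if (!is.null(reference)) {
    mm <- check_unique_mapping(ctx, reference, k = k)
    if (mm == "multimap") failed <- c(failed, "multimap")
  }
  list(locus_id = ctx$locus_id, designable = length(failed) == 0,
       failed_rules = failed, gc_fraction = gc, multimap_status = mm)
}

#' Primer-site uniqueness by exact k-mer lookup
#'
#' Approximates primer specificity by looking up the two k-base seeds
#' immediately flanking the target base, exactly, against both strands of a
#' reference sequence set. Either seed occurring more than once (forward plus
#' reverse-complement hits combined) marks the context `"multimap"`. Flanks
#' shorter than `k` give `"not_evaluated"` with a warning.
#'
#' @param ctx an [assay_context()].
#' @param reference a `Biostrings::DNAStringSet`.
#' @param k seed length (default 20).
#' @return `"unique"`, `"multimap"` or `"not_evaluated"`.
#' @export
check_unique_mapping <- function(ctx, reference, k = 20) {
  n <- nchar(ctx$flank_seq)
  if (ctx$target_offset < k || (n - 1 - ctx$target_offset) < k) {
    warning("flank shorter than k for ", ctx$locus_id)
    return("not_evaluated")
  }
  left <- substr(ctx$flank_seq, ctx$target_offset - k + 1, ctx$target_offset)
  right <- substr(ctx$flank_seq, ctx$target_offset + 2, ctx$target_offset + k + 1)
  hits <- function(seed) {
    pat <- Biostrings::DNAString(seed)
    sum(Biostrings::vcountPattern(pat, reference)) +
      sum(Biostrings::vcountPattern(Biostrings::reverseComplement(pat),
                                    reference))
  }
  if (hits(left) > 1 || hits(right) > 1) "multimap" else "unique"
}

#' Filter a batch of assay contexts
#'
#' @param contexts list of [assay_context()] objects.
#' @param ... passed to [check_designable()].
#' @return list with `verdicts` (data.frame: locus_id, designable,
#'   gc_fraction, multimap_status, failed_rules as a comma-joined string) and
#'   `summary` (named counts: contexts failing each rule, and n_designable).
#'   A context failing several rules counts once in designability but in each
#'   rule tally.
#' @export
filter_assays <- function(contexts, ...) {
  vs <- lapply(contexts, check_designable, ...)
  verdicts <- data.frame(
    locus_id = vapply(vs, `[[`, "", "locus_id"),
    designable = vapply(vs, `[[`, TRUE, "designable"),
    gc_fraction = vapply(vs, `[[`, 0, "gc_fraction"),
    multimap_status = vapply(vs, `[[`, "", "multimap_status"),
    failed_rules = vapply(vs, function(v)
      paste(v$failed_rules, collapse = ","), ""),
    stringsAsFactors = FALSE)
  rules <- c("gc", "indel30", "snp20", "multimap")
  per_rule <- vapply(rules, function(r)
    sum(vapply(vs, function(v) r %in% v$failed_rules, TRUE)), 0L)
  list(verdicts = verdicts,
       summary = c(per_rule, n_designable = sum(verdicts$designable),
                   n_total = length(vs)))
}
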