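#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses GT fields of a VCF 4.x file into a [genotype_matrix()] plus a locus
#' annotation table. Only biallelic SNP records (single-base REF and ALT) are
#' retained; multi-allelic records and indels are skipped with a warning. The
#' counted allele defaults to ALT, so a 0/1 genotype becomes code 1 and a
#' missing call (./.) becomes `NA`. Re-polarisation to the sample major allele
#' is a downstream concern, see [repolarize_major()].
#'
#' @param path VCF file (optionally bgzipped).
#' @param counted which allele to count: `"alt"` (default) or `"ref"`.
#' @return list with `genotypes` (a `genotype_matrix`) and `annotation`, a
#'   data.frame with columns locus_id, chrom, pos (1-based), ref, alt.
#' @export
read_vcf <- function(path, counted = c("alt", "ref")) {
  counted <- match.arg(counted)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  keep <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (sum(!keep) > 0)
    warning(sum(!keep), " non-biallelic-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records retained from ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  locus_id <- ifelse(is.na(fix$ID) | fix$ID == ".",
                     paste0(fix$CHROM, "_", fix$POS), fix$ID)
  # count ALT alleles from the GT string; tolerate phased separators
  alt_count <- function(g) {
    out <- rep(NA_integer_, length(g))
    g <- gsub("|", "/", g, fixed = TRUE)
    ok <- !is.na(g) & grepl("^[01]/[01]$", g)
    out[ok] <- (substr(g[ok], 1, 1) == "1") + (substr(g[ok], 3, 3) == "1")
    out
  }
  codes <- apply(gt, 2, alt_count)
  codes <- matrix(codes, nrow = nrow(gt), ncol = ncol(gt),
                  dimnames = dimnames(gt))
  codes <- t(codes)  # samples x loci
  if (counted == "ref") codes <- 2L - codes
  gm <- genotype_matrix(codes,
                        sample_ids = colnames(gt), locus_ids = locus_id,
                        counted_allele = if (counted == "alt") fix$ALT else fix$REF,
                        other_allele = if (counted == "alt") fix$REF else fix$ALT)
  ann <- data.frame(locus_id = locus_id, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  list(genotypes = gm, annotation = ann)
}

#' Write a genotype matrix as a minimal VCFv4.2 text file
#'
#' Companion to [read_vcf()] used by the synthetic end-to-end generator; emits
#' GT-only records. `annotation` supplies chrom/pos/ref/alt per locus; when
#' absent, loci are placed on a single synthetic contig with the counted
#' allele as ALT.
#'
#' @param gm a [genotype_matrix()] with ALT as the counted allele.
#' @param path output file.
#' @param annotation optional data.frame as returned by [read_vcf()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, annotation = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  p <- length(gm$locus_ids)
  if (is.null(annotation)) {
    annotation <- data.frame(locus_id = gm$locus_ids, chrom = "synth1",
                             pos = seq_len(p) * 1000L,
                             ref = ifelse(is.na(gm$other_allele), "A", gm$other_allele),
                             alt = ifelse(is.na(gm$counted_allele), "G", gm$counted_allele),
                             stringsAsFactors = FALSE)
  }
  ann <- annotation[match(gm$locus_ids, annotation$locus_id), , drop = FALSE]
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  for (j in seq_len(p)) {
    g <- gm$codes[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[as.character(g)])
    writeLines(paste(c(ann$chrom[j], ann$pos[j], gm$locus_ids[j], ann$ref[j],
                       ann$alt[j], ".", "PASS", ".", "GT", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read or write a wide genotype CSV (sample_id + one column per locus)
#'
#' Codes are copies of the counted allele; empty cells are missing calls.
#' The write/read pair round-trips codes exactly.
#'
#' @param path CSV file.
#' @return [genotype_matrix()] for the reader; `path` invisibly for the writer.
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("genotype CSV needs a sample_id column")
  codes <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  genotype_matrix(codes, sample_ids = df$sample_id,
                  locus_ids = setdiff(names(df), "sample_id"))
}

#' @rdname read_genotype_csv
#' @param gm a [genotype_matrix()].
#' @export
write_genotype_csv <- function(gm, path) {
  df <- data.frame(sample_id = gm$sample_ids, gm$codes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a CSV with a `sample_id` column; recognised columns are `site`,
#' `pop`, `latitude` (decimal degrees), `group` (migratory / partial /
#' resident / unknown), `capture_day` (day of year, migrants only), `sex`
#' (F / M / unknown) and `year`. Unknown group or sex categories are coerced
#' to `"unknown"` with a warning.
#'
#' @param path CSV file.
#' @return data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata needs a sample_id column")
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if ("group" %in% names(df)) {
    ok <- c("migratory", "partial", "resident", "unknown")
    bad <- !is.na(df$group) & !(df$group %in% ok)
    if (any(bad)) {
      warning(sum(bad), " unrecognised group value(s) set to 'unknown'")
      df$group[bad] <- "unknown"
    }
  }
  if ("sex" %in% names(df)) {
    bad <- !is.na(df$sex) & !(df$sex %in% c("F", "M", "unknown"))
    if (any(bad)) {
      warning(sum(bad), " unrecognised sex value(s) set to 'unknown'")
      df$sex[bad] <- "unknown"
    }
  }
  if ("capture_day" %in% names(df)) {
    df$capture_day <- as.integer(df$capture_day)
    bad <- !is.na(df$capture_day) & (df$capture_day < 1 | df$capture_day > 366)
    if (any(bad)) stop("capture_day outside [1, 366] for: ",
                       paste(df$sample_id[bad], collapse = ", "))
  }
  if ("latitude" %in% names(df)) {
    df$latitude <- as.numeric(df$latitude)
    bad <- !is.na(df$latitude) & abs(df$latitude) > 90
    if (any(bad)) stop("latitude outside [-90, 90] for: ",
                       paste(df$sample_id[bad], collapse = ", "))
  }
  df
}

#' Read gene intervals from BED or GFF3
#'
#' BED (0-based half-open) and GFF3 (1-based closed) conventions are
#' normalised at import into a `GRanges`, so the same physical interval gives
#' identical membership answers regardless of the source format. For GFF3,
#' only records of type `gene` are kept; the gene symbol is taken from the
#' `Name` attribute (falling back to `ID`). Malformed zero/negative-width
#' intervals are dropped with a warning.
#'
#' @param path BED or GFF3 file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return `GRanges` with a `gene` metadata column.
#' @export
read_gene_intervals <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3") {
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    nm <- S4Vectors::mcols(gr)$Name
    if (is.null(nm)) nm <- S4Vectors::mcols(gr)$ID
    gr$gene <- as.character(nm)
  } else {
    gr$gene <- if (!is.null(gr$name)) as.character(gr$name)
               else paste0("gene", seq_along(gr))
  }
  bad <- IRanges::width(gr) <= 0
  if (any(bad)) {
    warning(sum(bad), " malformed (empty) interval(s) skipped")
    gr <- gr[!bad]
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(gene = gr$gene)
  gr
}

#' Genes overlapping genomic positions
#'
#' @param genes `GRanges` from [read_gene_intervals()].
#' @param chrom,pos equal-length vectors of chromosome names and 1-based
#'   positions (VCF convention).
#' @return list (one element per position) of overlapping gene symbols;
#'   `character(0)` where the position falls in no gene.
#' @export
genes_at <- function(genes, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1))
  hits <- GenomicRanges::findOverlaps(q, genes, ignore.strand = TRUE)
  out <- rep(list(character(0)), length(pos))
  if (length(hits)) {
    sp <- split(genes$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (k in names(sp)) out[[as.integer(k)]] <- unique(sp[[k]])
  }
  out
}
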