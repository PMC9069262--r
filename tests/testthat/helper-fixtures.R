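# Small in-code fixtures shared across tests.

# 3-sample, 3-record VCF: two biallelic SNPs plus one indel record that the
# reader must skip. GT fields chosen so codes can be read off by hand.
write_tiny_vcf <- function(path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "ind1", "ind2", "ind3", sep = "\t"),
    paste("chr1", "150", "snpA", "A", "G", ".", "PASS", ".", "GT",
          "0/1", "1/1", "./.", sep = "\t"),
    paste("chr1", "500", "indel1", "AT", "A", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/0", sep = "\t"),
    paste("chr2", "42", "snpB", "C", "T", ".", "PASS", ".", "GT",
          "0/0", "0|1", "1/1", sep = "\t")
  ), path)
  path
}

make_meta <- function(gm, capture_day = NULL, sex = NULL, latitude = NULL,
                      group = "migratory", pop = NULL) {
  n <- length(gm$sample_ids)
  data.frame(sample_id = gm$sample_ids,
             site = "s1",
             pop = pop %||% "P1",
             latitude = latitude %||% NA_real_,
             group = group,
             capture_day = capture_day %||% NA_integer_,
             sex = sex %||% rep("F", n),
             year = NA_integer_,
             stringsAsFactors = FALSE)
}
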