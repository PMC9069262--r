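#!/usr/bin/env Rscript
# Stage 3: SNP-assay designability filter on the candidate flank contexts.
#
# Applies the four rules (GC < 0.65 around the target, no indel within
# 30 bp, no extra SNP within 20 bp, unique flanking seeds in the reference)
# and writes results/assay_verdicts.tsv.

suppressMessages(library(chronopop))

flanks <- Biostrings::readDNAStringSet("results/dataset/flanks.fasta")
reference <- Biostrings::readDNAStringSet("results/dataset/reference.fasta")
nv <- read.delim("results/dataset/nearby_variants.tsv",
                 stringsAsFactors = FALSE)

contexts <- lapply(names(flanks), function(id) {
  rows <- nv[nv$locus_id == id, c("offset", "kind"), drop = FALSE]
  assay_context(id, as.character(flanks[[id]]),
                target_offset = (nchar(as.character(flanks[[id]])) - 1) %/% 2,
                nearby_variants = rows)
})
res <- filter_assays(contexts, reference = reference)
write.table(res$verdicts, "results/assay_verdicts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json("results/dataset/truth.json",
                             simplifyVector = TRUE)
message(sprintf("designable: %d of %d contexts", res$summary[["n_designable"]],
                res$summary[["n_total"]]))
message("failures per rule: ",
        paste(sprintf("%s=%d", c("gc", "indel30", "snp20", "multimap"),
                      res$summary[c("gc", "indel30", "snp20", "multimap")]),
              collapse = ", "))
agree <- mean((res$verdicts$failed_rules == "") ==
                (truth$flank_truth$planted == "none"))
message(sprintf("agreement with planted truth: %.0f%%", 100 * agree))
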