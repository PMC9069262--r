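#!/usr/bin/env Rscript
# Stage 2: relaxed FST outlier scan of the breeding-range data.
#
# Weir-Cockerham theta per locus between the migratory/partial and resident
# groups, selection at the (intentionally permissive) 90th percentile, and
# gene annotation of the candidates. Writes results/fst_table.tsv and
# results/candidates.tsv.

suppressMessages(library(chronopop))

vcf <- suppressWarnings(read_vcf("results/dataset/scan.vcf"))
meta <- read_metadata("results/dataset/scan_meta.csv")
genes <- read_gene_intervals("results/dataset/genes.bed")

fs <- fst_scan(vcf$genotypes, meta)
write.table(fs, "results/fst_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sel <- select_outliers(fs, percentile = 0.90)
sel <- annotate_genes(sel, genes, vcf$annotation)
cand <- data.frame(locus_id = sel$locus_ids,
                   theta = fs$theta[match(sel$locus_ids, fs$locus_id)],
                   genes = vapply(sel$gene_map, paste, "", collapse = ";"))
write.table(cand, "results/candidates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- jsonlite::read_json("results/dataset/truth.json",
                             simplifyVector = TRUE)
message(sprintf("scan: %d loci; theta threshold %.4f; %d candidates in %d genes",
                nrow(fs), sel$threshold_value, length(sel$locus_ids),
                sel$n_genes))
message(sprintf("planted outlier recovery: %.0f%% of %d planted loci selected",
                100 * mean(truth$scan_outlier_loci %in% sel$locus_ids),
                length(truth$scan_outlier_loci)))
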