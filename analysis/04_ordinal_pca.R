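#!/usr/bin/env Rscript
# Stage 4: ordinal (optimal-scaling) PCA of the candidate-gene genotypes
# over all individuals (breeding + migrants).
#
# Writes results/pca_scores.tsv, results/pca_loadings.tsv and
# results/pca_fit.json (VAF per component, loss trace, quantifications).

suppressMessages(library(chronopop))

breeding <- read_genotype_csv("results/dataset/breeding_genotypes.csv")
migrants <- read_genotype_csv("results/dataset/migrant_genotypes.csv")
truth <- jsonlite::read_json("results/dataset/truth.json",
                             simplifyVector = TRUE)
cand <- truth$candidate_loci

codes <- rbind(gm_subset(breeding, loci = cand)$codes,
               gm_subset(migrants, loci = cand)$codes)
fit <- fix_sign(fit_ordinal_pca(codes, n_dim = 2), truth$timing_loci[1])

write.table(data.frame(sample_id = rownames(fit$object_scores),
                       fit$object_scores),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(locus_id = rownames(fit$loadings), fit$loadings),
            "results/pca_loadings.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(list(vaf_percent = fit$vaf_percent,
                          eigenvalues = fit$eigenvalues,
                          n_iter = fit$n_iter, converged = fit$converged,
                          loss_trace = fit$loss_trace,
                          quantifications = fit$quantifications),
                     "results/pca_fit.json", auto_unbox = TRUE, digits = NA)

message(sprintf("ordinal PCA over %d samples x %d candidate loci", nrow(codes),
                ncol(codes)))
message(sprintf("PC1 explains %.1f%%, PC2 %.1f%% of the genetic variation (%d ALS iterations)",
                fit$vaf_percent[1], fit$vaf_percent[2], fit$n_iter))
top <- rownames(fit$loadings)[order(abs(fit$loadings[, 1]),
                                    decreasing = TRUE)][1:4]
message("top PC1-loading loci: ", paste(top, collapse = ", "))
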