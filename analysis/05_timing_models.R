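#!/usr/bin/env Rscript
# Stage 5: migration-timing association models.
#
# PC1/PC2 passage-date regressions with a sex covariate (plus the PC1-by-sex
# interaction and a sex-only model), then single-locus weekly major-allele
# trajectories with linear-vs-quadratic likelihood-ratio tests for the four
# timing loci. Writes results/timing_models.json,
# results/weekly_frequencies.tsv and results/weekly_frequencies.pdf.

suppressMessages(library(chronopop))

migrants <- read_genotype_csv("results/dataset/migrant_genotypes.csv")
mmeta <- read_metadata("results/dataset/migrant_meta.csv")
scores <- read.delim("results/pca_scores.tsv", stringsAsFactors = FALSE)
truth <- jsonlite::read_json("results/dataset/truth.json",
                             simplifyVector = TRUE)

sc <- as.matrix(scores[, c("PC1", "PC2")])
rownames(sc) <- scores$sample_id
sc <- sc[rownames(sc) %in% migrants$sample_ids, ]

fits <- list(
  pc1 = fit_pc_timing(sc, mmeta, pc = "PC1"),
  pc2 = fit_pc_timing(sc, mmeta, pc = "PC2"),
  pc1_sex_interaction = fit_pc_timing(sc, mmeta, pc = "PC1",
                                      interaction = TRUE),
  sex_only = sex_timing_test(mmeta))
message(sprintf("PC1 ~ passage date: p = %.3g (R^2 = %.2f); PC2: p = %.3g",
                fits$pc1$coefficients["pc", 4], fits$pc1$r_squared,
                fits$pc2$coefficients["pc", 4]))
message(sprintf("PC1 x sex interaction: p = %.3g; sex alone: p = %.3g",
                fits$pc1_sex_interaction$coefficients["pc:sex", 4],
                fits$sex_only$coefficients["sexM", 4]))

gm <- repolarize_major(migrants)  # track the major allele, as in the figures
wk_all <- NULL
lrt <- list()
for (l in truth$timing_loci) {
  wf <- weekly_frequencies(gm, mmeta, l)
  wk_all <- rbind(wk_all, cbind(locus_id = l, wf))
  tr <- fit_trend_lrt(wf, degree_full = 2)
  lrt[[l]] <- list(slope_p = tr$linear$coefficients["midpoint_day", 4],
                   lrt_statistic = tr$lrt$statistic,
                   lrt_p = tr$lrt$p_value)
  message(sprintf("%s: weekly trend p = %.3g, curvature LRT p = %.3g",
                  l, lrt[[l]]$slope_p, lrt[[l]]$lrt_p))
}
write.table(wk_all, "results/weekly_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

coef_list <- lapply(fits, function(f)
  list(coefficients = as.data.frame(f$coefficients),
       r_squared = f$r_squared, loglik = f$loglik, n = f$n))
jsonlite::write_json(list(pc_models = coef_list, single_locus_lrt = lrt),
                     "results/timing_models.json", auto_unbox = TRUE,
                     digits = NA)

pdf("results/weekly_frequencies.pdf", width = 7, height = 6)
par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
for (l in truth$timing_loci) {
  wf <- wk_all[wk_all$locus_id == l, ]
  plot(wf$midpoint_day, wf$freq, cex = sqrt(wf$n_individuals) / 2,
       pch = 19, ylim = c(0, 1), xlab = "midpoint day of week",
       ylab = "major-allele frequency", main = l)
  wse <- wf[wf$se > 0, ]
  arrows(wse$midpoint_day, wse$freq - wse$se, wse$midpoint_day,
         wse$freq + wse$se, length = 0.02, angle = 90, code = 3)
  fit2 <- lm(freq ~ poly(midpoint_day, 2, raw = TRUE), data = wf)
  xx <- seq(min(wf$midpoint_day), max(wf$midpoint_day), length.out = 100)
  lines(xx, predict(fit2, data.frame(midpoint_day = xx)))
}
invisible(dev.off())
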