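#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset every later stage consumes.
#
# Produces, under results/dataset/: a 400-locus breeding-range VCF with 20
# planted migratory-vs-resident outlier loci (Balding-Nichols background,
# FST 0.05), sample metadata, a gene BED, 60 assay flank contexts with
# planted designability violations, and a chronotype-scenario breeding +
# migration-station panel (120 loci, 9 candidate, 4 timing; 165 migrants
# over a 13-week autumn season).

suppressMessages(library(chronopop))

seed <- 1
files <- gen_end_to_end("results/dataset", seed = seed)
message("wrote ", length(files), " files to results/dataset (seed ", seed, "):")
for (k in names(files)) message("  ", k, ": ", files[[k]])
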