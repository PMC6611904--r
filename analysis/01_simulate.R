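#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study dataset.
#
# A 2-Mb chromosome with 500 genes; the 7-bp element CGGAAAT planted in
# 20% of promoters; H3K36me3-like ChIP enrichment (fold 8 over depth 20)
# over the first 1 kb downstream of the TSS of every element gene; and a
# DEG table in which element genes are down-regulated (>1.5-fold,
# adjusted p < 0.05) more often than the rest. Writes the files every
# later stage reads, plus the ground truth.

suppressPackageStartupMessages(library(cismark))

out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L
cfg <- sim_config()

d <- simulate_dataset(cfg, seed)
write_fasta(d$genome, file.path(out, "genome.fa"))
write_genes_bed(d$annotation, file.path(out, "genes.bed"))
write_coverage_bedgraph(d$chip, file.path(out, "chip.bedgraph"))
write_coverage_bedgraph(d$input, file.path(out, "input.bedgraph"))
write_tsv(d$deg, file.path(out, "deg.tsv"))
jsonlite::write_json(d$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat(sprintf("simulated %d genes on %d bp (seed %d)\n",
            nrow(d$annotation), cfg$chrom_len, seed))
cat(sprintf("  element genes: %d | enriched genes: %d | true down: %d\n",
            length(d$truth$element_genes), length(d$truth$enriched_genes),
            length(d$truth$down_genes)))
cat("wrote genome.fa genes.bed chip.bedgraph input.bedgraph deg.tsv truth.json\n")
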