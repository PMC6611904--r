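#!/usr/bin/env Rscript
# Stage 3: sicer-like island calling (W = 200, G = 200, FDR < 1e-3,
# ChIP/input fold >= 2) and gene-level enrichment: a gene is
# H3K36me3-enriched when a significant island overlaps its 1-kb-upstream
# plus gene-body region.

suppressPackageStartupMessages(library(cismark))

run <- "results/run"
genome <- read_fasta(file.path(run, "genome.fa"))
sizes <- setNames(nchar(genome), names(genome))
ann <- read_genes_bed(file.path(run, "genes.bed"), sizes)
chip <- read_coverage_bedgraph(file.path(run, "chip.bedgraph"), sizes)
input <- read_coverage_bedgraph(file.path(run, "input.bedgraph"), sizes)

isl <- call_islands(chip, input, island_params())
enr <- call_gene_enrichment(ann, isl)
write_tsv(isl, file.path(run, "islands.tsv"))
write_tsv(enr, file.path(run, "gene_enrichment.tsv"))

truth <- jsonlite::read_json(file.path(run, "truth.json"), simplifyVector = TRUE)
called <- enr$gene_id[enr$enriched]
tp <- length(intersect(called, truth$enriched_genes))
cat(sprintf("%d islands, %d significant; %d genes enriched\n",
            nrow(isl), sum(isl$significant), length(called)))
cat(sprintf("  vs truth: recall %.3f, precision %.3f\n",
            tp / length(truth$enriched_genes), tp / length(called)))
cat("wrote islands.tsv gene_enrichment.tsv\n")
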