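#!/usr/bin/env Rscript
# Detect candidate retrogenes: reads spanning exon-exon junctions in
# transcript space (>= 10 bp aligned on both sides), kept only when they
# beat their best genomic alignment, called at >= 2 junctions and >= 3
# reads per gene.

suppressPackageStartupMessages(library(meltdownr))

corpus_root <- "results/corpus"
out_dir <- "results/retrogenes"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genes <- read_gene_models_gff3(file.path(corpus_root, "mainland", "annotation.gff3"))

for (nm in c("mainland", "island", "outgroup")) {
  tx <- read_sam_alignments(file.path(corpus_root, nm, "tx_alignments.sam"))
  gen <- read_sam_alignments(file.path(corpus_root, nm, "genome_alignments.sam"))
  jr <- find_junction_reads(tx, genes)
  fl <- filter_by_genomic_alignment(jr, gen)
  calls <- call_retrogenes(fl)
  truth <- utils::read.table(
    file.path(corpus_root, nm, "truth_retrocopies.tsv"), header = TRUE)
  recall <- mean(truth$gene_id %in% calls$gene_id)
  precision <- if (nrow(calls)) mean(calls$gene_id %in% truth$gene_id) else NA
  message(sprintf(
    "%-9s: %d junction reads -> %d after genomic filter -> %d retrogenes (recall %.2f, precision %.2f)",
    nm, nrow(jr), nrow(fl), nrow(calls), recall, precision))
  utils::write.table(calls, file.path(out_dir, paste0(nm, "_retrogenes.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
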