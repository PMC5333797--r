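#!/usr/bin/env Rscript
# Classify coding SNPs per sample, compute per-class heterozygosity (Hn,
# Hs) with and without the deamination-damage filter, and tally premature
# stop codons per gene and shared across samples.

suppressPackageStartupMessages(library(meltdownr))

corpus_root <- "results/corpus"
out_dir <- "results/effects"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome_fasta(file.path(corpus_root, "mainland", "reference.fasta"))
genes <- read_gene_models_gff3(file.path(corpus_root, "mainland", "annotation.gff3"))
sites <- count_syn_nonsyn_sites(genes, genome)
message(sprintf("callable sites: L_syn = %.1f, L_nonsyn = %.1f", sites$L_syn,
                sites$L_nonsyn))

samples <- c("mainland", "island", "outgroup")
effects <- list()
for (nm in samples) {
  v <- read_snp_vcf(file.path(corpus_root, nm, "variants.vcf"))
  eff <- annotate_variants(v, genes, genome)
  effects[[nm]] <- eff
  utils::write.table(eff, file.path(out_dir, paste0(nm, "_effects.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (dmg in c(FALSE, TRUE)) {
    hs <- heterozygosity_summary(eff, sites$L_syn, sites$L_nonsyn,
                                 damage_excluded = dmg)
    message(sprintf("%-9s%s Hs = %.5f, Hn = %.5f, Hn/Hs = %.3f", nm,
                    if (dmg) " (damage excluded)" else "",
                    hs$H[hs$class == "syn"], hs$H[hs$class == "nonsyn"],
                    attr(hs, "ratio")))
  }
}

cen <- stop_codon_census(effects)
cen_d <- stop_codon_census(effects, damage_excluded = TRUE)
utils::write.table(cen$per_gene, file.path(out_dir, "stop_codons_per_gene.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("stop codons per sample: %s",
                paste(sprintf("%s=%d", cen$per_sample$sample,
                              cen$per_sample$n_genes_truncated), collapse = ", ")))
message(sprintf("shared: %d identical sites, %d genes (any site); after damage filter: %d sites, %d genes",
                cen$shared_sites, cen$shared_genes, cen_d$shared_sites,
                cen_d$shared_genes))
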