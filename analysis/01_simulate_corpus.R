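#!/usr/bin/env Rscript
# Build the synthetic study trio: two "ancient" genomes sequenced at 11X and
# 17X plus one modern outgroup at 33X, all on a shared 1 Mb reference with
# planted SNPs, deletions >= 1 kb, and retrocopies. Every downstream driver
# reads the files this one writes, exactly as the real pipeline would consume
# VCF/GFF3/SAM/bedGraph produced by an aligner and caller.

suppressPackageStartupMessages(library(meltdownr))

out_root <- "results/corpus"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

base_cfg <- synth_config(genome_length = 1e6, n_genes = 20, seed = 2017)
ref <- generate_reference_and_annotation(base_cfg)

samples <- list(
  mainland = list(seed = 2018, mean_depth = 11, damage_rate = 0.03),
  island   = list(seed = 2019, mean_depth = 17, damage_rate = 0.03),
  outgroup = list(seed = 2020, mean_depth = 33, damage_rate = 0.00)
)

# one interval that is homozygous-deleted in every sample: an insertion in
# the reference assembly, which the deletion filter must remove downstream
ref_insertion <- data.frame(contig = "chr1", start = 700000, end = 703000,
                            zygosity = "hom")

for (nm in names(samples)) {
  s <- samples[[nm]]
  cfg <- synth_config(genome_length = 1e6, n_genes = 20, seed = s$seed,
                      mean_depth = s$mean_depth, damage_rate = s$damage_rate,
                      deletion_count = 8, deletion_spacing = 20000,
                      n_syn_snps = 60, n_nonsyn_snps = 50, n_nonsense_snps = 12,
                      retrocopy_count = 5)
  truth <- plant_variant_set(ref$genome, ref$genes, cfg)
  keep <- truth$deletions$end < 690000 | truth$deletions$start > 713000
  truth$deletions <- rbind(truth$deletions[keep, ], ref_insertion)
  depth <- render_depth_track(ref$genome, truth, cfg)
  reads <- render_junction_reads(ref$genome, ref$genes, truth, cfg)
  corpus <- structure(list(config = cfg, genome = ref$genome,
                           genes = ref$genes, truth = truth, depth = depth,
                           reads = reads), class = "synth_corpus")
  man <- emit_truth_and_files(corpus, file.path(out_root, nm))
  message(sprintf("%-9s %2dX: %3d SNPs, %d deletions, %d retrocopies -> %s",
                  nm, s$mean_depth, nrow(truth$snps), nrow(truth$deletions),
                  nrow(truth$retrocopies), file.path(out_root, nm)))
}
message("corpus written under ", out_root)
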