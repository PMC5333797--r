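#!/usr/bin/env Rscript
# Assemble the defect census across samples, apply the heterozygote
# false-negative corrections, run the excess chi-squared tests, compare
# deletion size distributions, count shared events, and render the report.

suppressPackageStartupMessages(library(meltdownr))

out_dir <- "results/census"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
samples <- c("mainland", "island", "outgroup")

read_calls <- function(nm) {
  f <- file.path("results/deletions", paste0(nm, "_deletions.bed"))
  x <- utils::read.table(f, col.names = c("contig", "start", "end", "name",
                                          "lambda", "zygosity", "zero_flag", "p"))
  x$length <- x$end - x$start
  x
}
inputs <- lapply(samples, function(nm) {
  list(
    deletions = read_calls(nm),
    retrogenes = utils::read.table(
      file.path("results/retrogenes", paste0(nm, "_retrogenes.tsv")),
      header = TRUE),
    genes_deleted = utils::read.table(
      file.path("results/deletions", paste0(nm, "_genes_deleted.tsv")),
      header = TRUE),
    effects = utils::read.table(
      file.path("results/effects", paste0(nm, "_effects.tsv")),
      header = TRUE)
  )
})
names(inputs) <- samples

census <- build_census_table(inputs, correction_config())
print(census)

tests <- list(
  genes_deleted_excess = pairwise_chisq(
    length(unique(inputs$island$genes_deleted$gene_id)),
    nrow(inputs$island$deletions),
    length(unique(inputs$mainland$genes_deleted$gene_id)),
    nrow(inputs$mainland$deletions)),
  stop_codon_excess = pairwise_chisq(
    sum(inputs$island$effects$effect_class == "nonsense"),
    sum(inputs$island$effects$effect_class != "noncoding"),
    sum(inputs$mainland$effects$effect_class == "nonsense"),
    sum(inputs$mainland$effects$effect_class != "noncoding")))
for (nm in names(tests)) {
  message(sprintf("%s: chi2 = %.3f, df = 1, p = %.3g", nm, tests[[nm]]$chi2,
                  tests[[nm]]$p_value))
}

sizes <- deletion_size_comparison(inputs$island$deletions$length,
                                  inputs$mainland$deletions$length)
message(sprintf("deletion sizes island vs mainland: mean %.0f vs %.0f bp, W_U = %.0f (rank-sum W = %.0f), p = %.3g",
                sizes$mean_a, sizes$mean_b, sizes$W_U, sizes$W_ranksum,
                sizes$p_value))

shared_del <- shared_events(list(inputs$mainland$deletions,
                                 inputs$island$deletions), "deletion")
shared_rg <- shared_events(list(inputs$mainland$retrogenes,
                                inputs$island$retrogenes), "retrogene")
shared_stop_gene <- shared_events(list(inputs$mainland$effects,
                                       inputs$island$effects), "stop_gene")
message(sprintf("shared between the two focal samples: %d deletions, %d retrogenes, %d truncated genes",
                shared_del, shared_rg, shared_stop_gene))

render_report(census, tests, list(deletion_sizes = sizes), out_dir)
message("report written under ", out_dir)
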