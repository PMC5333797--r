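test_that("planted truth SNPs are re-classified identically", {
  co <- small_corpus()
  eff <- annotate_variants(co$truth$snps, co$genes, co$genome)
  truth_coding <- co$truth$snps[co$truth$snps$effect_class != "noncoding", ]
  m <- merge(truth_coding, eff, by = c("contig", "pos"),
             suffixes = c(".truth", ".got"))
  expect_equal(nrow(m), nrow(truth_coding))
  expect_equal(m$effect_class.got, m$effect_class.truth)
  expect_equal(m$gene_id.got, m$gene_id.truth)
  # noncoding truth SNPs stay noncoding
  nc <- merge(co$truth$snps[co$truth$snps$effect_class == "noncoding", ],
              eff, by = c("contig", "pos"), suffixes = c(".truth", ".got"))
  expect_true(all(nc$effect_class.got == "noncoding"))
})

test_that("REF mismatches are rejected and logged", {
  co <- small_corpus()
  v <- co$truth$snps[1:5, ]
  v$ref[3] <- setdiff(c("A", "C", "G", "T"), v$ref[3])[1]
  expect_message(eff <- annotate_variants(v, co$genes, co$genome), "rejected")
  expect_equal(nrow(attr(eff, "rejected")), 1)
  expect_equal(sum(!is.na(eff$pos)), 4)
})

test_that("variants in introns are noncoding", {
  co <- small_corpus()
  g <- co$genes[[which(vapply(co$genes, function(x) nrow(x$exons), 0L) >= 2)[1]]]
  intron_pos <- g$exons$end[1]  # first base after exon 1
  seq <- substring(co$genome[[g$contig]], intron_pos + 1, intron_pos + 1)
  v <- data.frame(contig = g$contig, pos = intron_pos, ref = seq,
                  alt = setdiff(c("A", "C", "G", "T"), seq)[1],
                  genotype = "het")
  eff <- annotate_variants(v, co$genes, co$genome)
  expect_equal(eff$effect_class, "noncoding")
})

test_that("overlapping transcripts yield one effect record each", {
  genome <- c(chr1 = paste0("ATG", "AAA", "TGG", "TAA", "CCCCCC"))
  g1 <- gene_model("a", "chr1", "+", data.frame(start = 0, end = 12))
  g2 <- gene_model("b", "chr1", "+", data.frame(start = 0, end = 12))
  v <- data.frame(contig = "chr1", pos = 8, ref = "G", alt = "A",
                  genotype = "het")  # TGG -> TGA in both
  eff <- annotate_variants(v, list(g1, g2), genome)
  expect_equal(nrow(eff), 2)
  expect_setequal(eff$gene_id, c("a", "b"))
  expect_true(all(eff$effect_class == "nonsense"))
})

test_that("heterozygote under-call correction is exact and monotone", {
  expect_equal(correct_het_undercall(350, 150, 0.30), 650)
  expect_equal(correct_het_undercall(100, 40, 0), 140)
  expect_equal(correct_het_undercall(1000, 0, 0.005), 1000 / 0.995)
  fnrs <- seq(0, 0.9, by = 0.1)
  vals <- vapply(fnrs, function(f) correct_het_undercall(10, 5, f), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(correct_het_undercall(1, 1, 1), "fnr")
})

test_that("heterozygosity summary arithmetic and ratio are correct", {
  eff <- data.frame(
    contig = "chr1", pos = seq_len(160), ref = "A", alt = "C",
    genotype = c(rep("het", 150), rep("hom", 10)),
    gene_id = "g", codon_index = 1,
    effect_class = c(rep("synonymous", 130), rep("nonsynonymous", 25),
                     rep("nonsense", 5)),
    damage_flag = FALSE)
  hs <- heterozygosity_summary(eff, L_syn = 1e5, L_nonsyn = 2e5)
  expect_equal(hs$H[hs$class == "syn"], 130 / 1e5)
  expect_equal(hs$sigma[hs$class == "syn"],
               sqrt(0.0013 * (1 - 0.0013) / 1e5))
  # nonsyn class pools nonsynonymous + nonsense het sites (here 20 het)
  n_non_het <- sum(eff$genotype == "het" &
                     eff$effect_class %in% c("nonsynonymous", "nonsense"))
  expect_equal(hs$H[hs$class == "nonsyn"], n_non_het / 2e5)
  expect_equal(attr(hs, "ratio"),
               (n_non_het / 2e5) / (130 / 1e5))
  # zero het sites
  hs0 <- heterozygosity_summary(eff[eff$genotype == "hom", ], 100, 100)
  expect_equal(hs0$H, c(0, 0))
  expect_equal(hs0$sigma, c(0, 0))
})

test_that("recovered heterozygosity is within 3 sigma of the planted rate", {
  # plant het synonymous SNPs at a known per-site rate over the corpus
  co <- small_corpus()
  sc <- count_syn_nonsyn_sites(co$genes, co$genome)
  eff <- annotate_variants(co$truth$snps, co$genes, co$genome)
  hs <- heterozygosity_summary(eff, sc$L_syn, sc$L_nonsyn)
  # truth: het synonymous count / L_syn
  truth <- co$truth$snps
  h_expected <- sum(truth$effect_class == "synonymous" &
                      truth$genotype == "het") / sc$L_syn
  row <- hs[hs$class == "syn", ]
  expect_equal(row$H, h_expected)
  expect_true(abs(row$H - h_expected) <= 3 * row$sigma + 1e-12)
})

test_that("damage exclusion drops exactly the flagged effects", {
  co <- small_corpus()
  eff <- annotate_variants(co$truth$snps, co$genes, co$genome)
  sc <- count_syn_nonsyn_sites(co$genes, co$genome)
  hs_all <- heterozygosity_summary(eff, sc$L_syn, sc$L_nonsyn)
  hs_nod <- heterozygosity_summary(eff, sc$L_syn, sc$L_nonsyn,
                                   damage_excluded = TRUE)
  kept <- eff[eff$genotype == "het" & !eff$damage_flag, ]
  expect_equal(hs_nod$het_count[hs_nod$class == "syn"],
               sum(kept$effect_class == "synonymous"))
  expect_true(all(hs_nod$het_count <= hs_all$het_count))
})

test_that("stop codon census counts genes, sites, and sharing", {
  eff_a <- data.frame(contig = "chr1", pos = c(10, 50, 70), ref = "C",
                      alt = c("T", "T", "A"), genotype = "het",
                      gene_id = c("g1", "g2", "g2"), codon_index = 1,
                      effect_class = "nonsense",
                      damage_flag = c(TRUE, TRUE, FALSE))
  eff_b <- data.frame(contig = "chr1", pos = c(10, 99), ref = "C",
                      alt = c("T", "G"), genotype = "hom",
                      gene_id = c("g1", "g2"), codon_index = 1,
                      effect_class = "nonsense",
                      damage_flag = c(TRUE, FALSE))
  cen <- stop_codon_census(list(a = eff_a, b = eff_b))
  expect_equal(cen$per_sample$n_genes_truncated, c(2, 2))
  # same site in both: chr1:10:T; same gene regardless of site: g1 and g2
  expect_equal(cen$shared_sites, 1)
  expect_equal(cen$shared_genes, 2)
  # damage exclusion removes only transition-caused stops
  cen_d <- stop_codon_census(list(a = eff_a, b = eff_b), damage_excluded = TRUE)
  expect_equal(cen_d$per_sample$n_stop_sites, c(1, 1))
  expect_equal(cen_d$shared_sites, 0)
  expect_equal(cen_d$shared_genes, 1)  # g2 truncated in both at distinct sites
})
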