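test_that("empty and degenerate configurations behave", {
  cfg <- synth_config(genome_length = 5e4, n_genes = 0, n_syn_snps = 0,
                      n_nonsyn_snps = 0, n_nonsense_snps = 0,
                      deletion_count = 0, retrocopy_count = 0, seed = 5)
  ra <- generate_reference_and_annotation(cfg)
  expect_length(ra$genes, 0)
  expect_equal(nchar(ra$genome[[1]]), 5e4)
  expect_error(synth_config(deletion_len_range = c(500, 2000)), ">= 1000")
  expect_error(synth_config(read_len = 15), "overhang")
  expect_error(
    generate_reference_and_annotation(synth_config(genome_length = 1e4,
                                                   n_genes = 50)),
    "too small")
})

test_that("a fixed seed yields a byte-identical corpus", {
  cfg <- synth_config(genome_length = 1e5, n_genes = 5, deletion_count = 2,
                      retrocopy_count = 2, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- emit_truth_and_files(synth_corpus(cfg), d1)
  m2 <- emit_truth_and_files(synth_corpus(cfg), d2)
  expect_equal(m1$md5, m2$md5)
})

test_that("generated CDS are structurally valid and translate cleanly", {
  co <- small_corpus()
  expect_length(co$genes, 10)
  for (g in co$genes) {
    tx <- transcript_seq(g, co$genome)
    expect_equal(nchar(tx) %% 3, 0)
    expect_equal(substr(tx, 1, 3), "ATG")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(tx)))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1), fixed = TRUE))
  }
  # genes do not overlap
  spans <- t(vapply(co$genes, function(g) c(min(g$exons$start), max(g$exons$end)),
                    numeric(2)))
  spans <- spans[order(spans[, 1]), ]
  expect_true(all(spans[-1, 1] >= spans[-nrow(spans), 2]))
})

test_that("planted variant classes honour the request", {
  co <- small_corpus()
  tab <- table(co$truth$snps$effect_class)
  expect_equal(unname(tab["synonymous"]), 30)
  expect_equal(unname(tab["nonsynonymous"]), 30)
  expect_equal(unname(tab["nonsense"]), 8)
  # each planted nonsense creates a stop codon by construction
  ns <- co$truth$snps[co$truth$snps$effect_class == "nonsense", ]
  eff <- annotate_variants(ns, co$genes, co$genome)
  expect_true(all(eff$effect_class[!is.na(eff$gene_id)] == "nonsense"))
  # hom_del_fraction honoured exactly
  cfg_h <- synth_config(genome_length = 2e5, n_genes = 0, n_syn_snps = 0,
                        n_nonsyn_snps = 0, n_nonsense_snps = 0,
                        deletion_count = 4, hom_del_fraction = 1,
                        retrocopy_count = 0, seed = 11)
  ra <- generate_reference_and_annotation(cfg_h)
  tr <- plant_variant_set(ra$genome, ra$genes, cfg_h)
  expect_true(all(tr$deletions$zygosity == "hom"))
  # deletions do not overlap
  del <- co$truth$deletions[order(co$truth$deletions$start), ]
  if (nrow(del) > 1) expect_true(all(del$start[-1] >= del$end[-nrow(del)]))
})

test_that("depth track has the planted distributional structure", {
  cfg <- synth_config(genome_length = 1e5, n_genes = 0, n_syn_snps = 0,
                      n_nonsyn_snps = 0, n_nonsense_snps = 0,
                      deletion_count = 0, retrocopy_count = 0,
                      mean_depth = 30, depth_dispersion = 5, seed = 13)
  ra <- generate_reference_and_annotation(cfg)
  tr <- plant_variant_set(ra$genome, ra$genes, cfg)
  dt <- render_depth_track(ra$genome, tr, cfg)
  # NB mean within 3 SE of 30
  v <- 30 + 30^2 / 5
  se <- sqrt(v / length(dt$depth))
  expect_lt(abs(mean(dt$depth) - 30), 3 * se)

  # planted hom deletion -> near-zero depth; het -> half depth within 3 SE
  truth <- list(
    snps = tr$snps,
    deletions = data.frame(contig = "chr1",
                           start = c(10000, 50000), end = c(12000, 54000),
                           zygosity = c("hom", "het")),
    retrocopies = tr$retrocopies)
  dt2 <- render_depth_track(ra$genome, truth, cfg)
  hom_mean <- mean(dt2$depth[10001:12000])
  expect_lt(hom_mean, 0.1 * 30)
  het <- dt2$depth[50001:54000]
  se_het <- sqrt((15 + 0.25 * 30^2 / 5) / length(het))
  expect_lt(abs(mean(het) - 15), 3 * se_het)
})

test_that("read damage fraction matches the configured rate", {
  cfg <- synth_config(genome_length = 2e5, n_genes = 8, retrocopy_count = 4,
                      deletion_count = 0, n_background_reads = 400,
                      damage_rate = 0.05, seed = 17)
  co <- synth_corpus(cfg)
  raw <- strsplit(paste(co$reads$reads$raw, collapse = ""), "")[[1]]
  dmg <- strsplit(paste(co$reads$reads$seq, collapse = ""), "")[[1]]
  n_sus <- sum(raw %in% c("C", "G"))
  n_hit <- sum(raw == "C" & dmg == "T") + sum(raw == "G" & dmg == "A")
  p_hat <- n_hit / n_sus
  se <- sqrt(0.05 * 0.95 / n_sus)
  expect_lt(abs(p_hat - 0.05), 3 * se)
  # no other substitutions are introduced
  expect_equal(sum(raw != dmg), n_hit)
})

test_that("all standard-format files round-trip with coordinates intact", {
  co <- small_corpus()
  d <- tempfile()
  man <- emit_truth_and_files(co, d)
  expect_true(all(file.exists(file.path(d, man$file))))

  expect_identical(read_genome_fasta(file.path(d, "reference.fasta")),
                   co$genome)

  gm <- read_gene_models_gff3(file.path(d, "annotation.gff3"))
  gm <- gm[vapply(co$genes, `[[`, "", "gene_id")]
  for (i in seq_along(co$genes)) {
    expect_identical(gm[[i]]$exons, co$genes[[i]]$exons)
    expect_identical(gm[[i]]$strand, co$genes[[i]]$strand)
  }

  v <- read_snp_vcf(file.path(d, "variants.vcf"))
  tv <- co$truth$snps[order(co$truth$snps$pos), ]
  expect_equal(nrow(v), nrow(tv))
  expect_equal(v$pos, tv$pos)
  expect_equal(v$ref, tv$ref)
  expect_equal(v$alt, tv$alt)
  expect_equal(v$genotype, tv$genotype)

  bt <- read_depth_bedgraph(file.path(d, "depth.bedGraph"))[[co$config$contig]]
  expect_identical(bt$depth, co$depth$depth)

  sa <- read_sam_alignments(file.path(d, "tx_alignments.sam"))
  ix <- match(co$reads$tx_aln$qname, sa$qname)
  expect_false(anyNA(ix))
  expect_equal(sa$pos[ix], co$reads$tx_aln$pos)
  expect_equal(sa$score[ix], co$reads$tx_aln$score)
})

test_that("truth effect classes agree with the classifier on every planted SNP", {
  co <- small_corpus()
  eff <- annotate_variants(co$truth$snps, co$genes, co$genome)
  coding <- co$truth$snps[co$truth$snps$effect_class != "noncoding", ]
  m <- merge(coding, eff, by = c("contig", "pos"), suffixes = c(".t", ".g"))
  expect_equal(nrow(m), nrow(coding))
  expect_equal(mean(m$effect_class.t == m$effect_class.g), 1)
})
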