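test_that("changepoint fit equals the exhaustive brute-force oracle", {
  set.seed(21)
  for (rep in 1:6) {
    d <- rnbinom(6000, mu = 15, size = 5)
    if (rep %% 2 == 0) {
      s <- sample(500:3000, 1)
      len <- sample(10:25, 1) * 100
      d[(s + 1):(s + len)] <- rbinom(len, d[(s + 1):(s + len)], 0.4)
    }
    got <- fit_changepoint_window(d, min_len = 1000, max_len = 3000)
    want <- oracle_changepoint(d, min_len = 1000, max_len = 3000)
    expect_equal(got$lambda, want$lambda, tolerance = 1e-9)
    expect_equal(got$tract, want$tract)
  }
})

test_that("lambda is scale invariant and RSS2 <= RSS1", {
  set.seed(22)
  d <- rnbinom(20000, mu = 12, size = 4)
  f1 <- fit_changepoint_window(d)
  f2 <- fit_changepoint_window(d * 2)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-9)
  expect_equal(f1$tract, f2$tract)
  expect_lte(f1$rss2, f1$rss1)
  expect_gte(f1$lambda, 0)
})

test_that("masked positions are excluded from the fit", {
  set.seed(23)
  d <- rnbinom(20000, mu = 15, size = 5)
  mask <- rep(FALSE, 20000)
  mask[3001:4000] <- TRUE
  d[mask] <- 999  # absurd values that must be ignored
  got <- fit_changepoint_window(d, mask = mask)
  want <- oracle_changepoint(d, mask = mask)
  expect_equal(got$lambda, want$lambda, tolerance = 1e-9)
  expect_null(fit_changepoint_window(d, mask = rep(TRUE, 20000)))
})

test_that("a planted zero tract is recovered to within one grid step", {
  set.seed(24)
  d <- rnbinom(20000, mu = 30, size = 6)
  d[5001:7000] <- 0
  f <- fit_changepoint_window(d)
  expect_lte(abs(f$tract[1] - 5000), 100)
  expect_lte(abs(f$tract[2] - 7000), 100)
  expect_lt(f$p_value, 1e-10)
})

test_that("genotyping thresholds follow the strict 10% rule and zero flag", {
  g <- genotype_call(1.5, 30, 0.9)
  expect_equal(g$zygosity, "hom"); expect_true(g$zero_flag)
  g <- genotype_call(15, 30, 0.1)
  expect_equal(g$zygosity, "het"); expect_false(g$zero_flag)
  # boundary: 3.0 is NOT < 0.10 * 30
  g <- genotype_call(3.0, 30, 0.4)
  expect_equal(g$zygosity, "het")
  expect_true(genotype_call(0, 30, 0.5)$zero_flag)
})

test_that("scan recovers planted deletions and merges across window boundaries", {
  cfg <- synth_config(genome_length = 4e5, n_genes = 0, n_syn_snps = 0,
                      n_nonsyn_snps = 0, n_nonsense_snps = 0,
                      deletion_count = 0, retrocopy_count = 0,
                      mean_depth = 15, seed = 31)
  ra <- generate_reference_and_annotation(cfg)
  # one hom deletion straddling the 20 kb window boundary at 100 kb
  truth <- list(snps = ra$genes, deletions = data.frame(
    contig = "chr1", start = c(97000, 250000), end = c(103000, 253000),
    zygosity = c("hom", "het")), retrocopies = NULL)
  dt <- render_depth_track(ra$genome, truth, cfg)
  calls <- scan_genome(dt)
  expect_equal(nrow(calls), 2)
  # boundary-straddling deletion emerges as a single merged call
  c1 <- calls[which.min(abs(calls$start - 97000)), ]
  expect_lte(abs(c1$start - 97000), 200)
  expect_lte(abs(c1$end - 103000), 200)
  expect_equal(c1$zygosity, "hom")
  expect_true(c1$zero_flag)
  c2 <- calls[which.min(abs(calls$start - 250000)), ]
  expect_equal(c2$zygosity, "het")
  expect_false(c2$zero_flag)
  expect_true(all(calls$length >= 1000))
})

test_that("reference-insertion filter removes only all-sample homozygous intervals", {
  mk <- function(starts, zyg) data.frame(
    contig = "chr1", start = starts, end = starts + 2000, length = 2000,
    zygosity = zyg, tract_mean = 0, background = 15, zero_fraction = 1,
    zero_flag = TRUE, lambda = 100, p_value = 0)
  a <- mk(c(1e4, 5e4, 9e4), c("hom", "hom", "het"))
  b <- mk(c(1e4, 5e4), c("hom", "het"))
  cc <- mk(c(1e4, 7e4), c("hom", "hom"))
  out <- filter_reference_insertions(list(a = a, b = b, c = cc))
  # interval at 10 kb is hom in all three -> removed everywhere
  expect_false(1e4 %in% out$a$start)
  expect_false(1e4 %in% out$b$start)
  expect_false(1e4 %in% out$c$start)
  # 50 kb is hom in 2/3 (het in b) -> retained
  expect_true(5e4 %in% out$a$start)
  expect_true(5e4 %in% out$b$start)
  expect_true(7e4 %in% out$c$start)
  expect_warning(filter_reference_insertions(list(a = a)), "no-op")
})

test_that("gene overlap counts exon hits only, split by zygosity", {
  genes <- list(
    gene_model("g1", "chr1", "+", data.frame(start = c(1000, 5000),
                                             end = c(1500, 5500))),
    gene_model("g2", "chr1", "+", data.frame(start = 20000, end = 20500)))
  calls <- data.frame(contig = "chr1", start = c(900, 2000), end = c(1200, 4500),
                      zygosity = c("hom", "het"))
  ov <- gene_overlap(calls, genes)
  # first call hits g1 exon 1; second call lies wholly in the g1 intron
  expect_equal(nrow(ov), 1)
  expect_equal(ov$gene_id, "g1")
  expect_equal(ov$zygosity, "hom")
})

test_that("downsampling recall is computed against the full-depth call set", {
  cfg <- synth_config(genome_length = 3e5, n_genes = 0, n_syn_snps = 0,
                      n_nonsyn_snps = 0, n_nonsense_snps = 0,
                      deletion_count = 5, hom_del_fraction = 1,
                      deletion_spacing = 20000, retrocopy_count = 0,
                      mean_depth = 17, seed = 33)
  ra <- generate_reference_and_annotation(cfg)
  tr <- plant_variant_set(ra$genome, ra$genes, cfg)
  dt <- render_depth_track(ra$genome, tr, cfg)
  set.seed(1)
  est <- estimate_recall_downsample(dt, 11)
  expect_equal(est$n_full, 5)
  expect_gte(est$recall, 0)
  expect_lte(est$recall, 1)
  expect_error(estimate_recall_downsample(dt, 40), "below")
})

test_that("recall arithmetic matches the printed-count worked example", {
  # 999 of 1035 full-depth calls recovered after downsampling
  expect_equal(999 / 1035, 0.9652174, tolerance = 1e-6)
})
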