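test_that("pairwise chi-squared equals the brute-force Pearson computation", {
  brute <- function(tab) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  r <- pairwise_chisq(10, 100, 30, 100)
  expect_equal(r$chi2, brute(r$table), tolerance = 1e-12)
  expect_equal(r$chi2, 12.5)
  expect_equal(r$p_value, pchisq(12.5, 1, lower.tail = FALSE))
  # equal proportions -> 0
  expect_equal(pairwise_chisq(10, 100, 20, 200)$chi2, 0)
  # symmetric under row swap
  expect_equal(pairwise_chisq(30, 100, 10, 100)$chi2, r$chi2)
  # random tables against the brute force
  set.seed(8)
  for (i in 1:20) {
    ca <- sample(0:50, 1); cb <- sample(0:50, 1)
    ta <- ca + sample(1:100, 1); tb <- cb + sample(1:100, 1)
    rr <- suppressWarnings(pairwise_chisq(ca, ta, cb, tb))
    if (isTRUE(rr$zero_expected)) {
      expect_true(is.na(rr$p_value))
    } else {
      expect_equal(rr$chi2, brute(rr$table), tolerance = 1e-10)
    }
  }
  expect_true(pairwise_chisq(0, 10, 0, 10)$zero_expected)
})

test_that("rank-sum p agrees with exact enumeration for small samples", {
  exact_p <- function(a, b) {
    n1 <- length(a); n2 <- length(b)
    pooled <- c(a, b)
    u_of <- function(idx) {
      ra <- rank(pooled)[idx]
      sum(ra) - n1 * (n1 + 1) / 2
    }
    u_obs <- u_of(seq_len(n1))
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, u_of)
    mean(abs(us - n1 * n2 / 2) >= abs(u_obs - n1 * n2 / 2) - 1e-9)
  }
  set.seed(9)
  for (i in 1:5) {
    a <- sample(1000:9999, sample(4:8, 1))
    b <- sample(1000:9999, sample(4:8, 1))
    got <- deletion_size_comparison(a, b)
    expect_lt(abs(got$p_value - exact_p(a, b)), 0.06)
  }
})

test_that("size comparison conventions, null case, and eCDF shape hold", {
  set.seed(10)
  a <- rexp(1000, 1 / 1500) + 1000
  r0 <- deletion_size_comparison(a, a)
  n1 <- length(a)
  expect_equal(r0$W_U, n1 * n1 / 2)
  expect_equal(r0$W_ranksum, n1 * n1 / 2 + n1 * (n1 + 1) / 2)
  expect_gt(r0$p_value, 0.99)
  # a clear shift is detected
  b <- a + 500
  r1 <- deletion_size_comparison(b, a)
  expect_lt(r1$p_value, 1e-6)
  expect_gt(r1$mean_a, r1$mean_b)
  # eCDF is non-decreasing from >0 to 1
  expect_true(all(diff(r1$ecdf_a$F) > 0))
  expect_equal(max(r1$ecdf_a$F), 1)
  # all tied
  rt <- deletion_size_comparison(rep(5, 4), rep(5, 6))
  expect_true(rt$all_tied)
  expect_equal(rt$p_value, 1)
})

test_that("shared events follow reciprocal-overlap and key rules", {
  del_a <- data.frame(contig = "chr1", start = c(1000, 50000, 90000),
                      end = c(3000, 52000, 100000), zygosity = "hom")
  del_b <- data.frame(contig = "chr1", start = c(1000, 99000),
                      end = c(3000, 100000), zygosity = "het")
  # identical interval shared; 10 kb vs 1 kb nested (10%) not shared
  expect_equal(shared_events(list(del_a, del_b), "deletion"), 1)
  eff_a <- data.frame(contig = "chr1", pos = c(5, 9), alt = c("T", "A"),
                      gene_id = c("g1", "g2"), effect_class = "nonsense")
  eff_b <- data.frame(contig = "chr1", pos = c(5, 11), alt = c("T", "A"),
                      gene_id = c("g1", "g2"), effect_class = "nonsense")
  expect_equal(shared_events(list(eff_a, eff_b), "stop_site"), 1)
  expect_equal(shared_events(list(eff_a, eff_b), "stop_gene"), 2)
  rg_a <- data.frame(gene_id = c("g1", "g2"))
  rg_b <- data.frame(gene_id = c("g2", "g3"))
  expect_equal(shared_events(list(rg_a, rg_b), "retrogene"), 1)
})

test_that("census table applies corrections to heterozygous counts only", {
  dels <- data.frame(contig = "chr1", start = 1:10 * 1e4,
                     end = 1:10 * 1e4 + 2000,
                     zygosity = rep(c("hom", "het"), 5))
  eff <- data.frame(contig = "chr1", pos = 1:8, ref = "C",
                    alt = c(rep("T", 5), rep("A", 3)),
                    genotype = c(rep("het", 6), "hom", "hom"),
                    gene_id = paste0("g", 1:8), codon_index = 1,
                    effect_class = "nonsense",
                    damage_flag = c(rep(TRUE, 5), rep(FALSE, 3)))
  smp <- list(s1 = list(deletions = dels, effects = eff,
                        retrogenes = data.frame(gene_id = c("r1", "r2")),
                        genes_deleted = data.frame(gene_id = c("a", "b"),
                                                   zygosity = c("hom", "het"))))
  cc <- correction_config(het_fnr_snp = 0.30, het_fnr_del = 0.005)
  tab <- build_census_table(smp, cc)
  expect_equal(tab$deletions_raw, 10)
  expect_equal(tab$deletions_corrected, 5 + 5 / 0.995)
  expect_equal(tab$stop_codons_raw, 8)
  expect_equal(tab$stop_codons_corrected, 2 + 6 / 0.7)
  expect_equal(tab$stop_codons_no_damage, 3)
  expect_equal(tab$retrogenes, 2)
  expect_gte(tab$deletions_corrected, tab$deletions_raw)
  expect_lte(tab$stop_codons_no_damage, tab$stop_codons_raw)
  # fnr = 0 -> corrected equals raw
  tab0 <- build_census_table(smp, correction_config(0, 0))
  expect_equal(tab0$deletions_corrected, tab0$deletions_raw)
  expect_equal(tab0$stop_codons_corrected, tab0$stop_codons_raw)
  # missing stage -> NA, not zero
  tab_na <- build_census_table(list(s2 = list(effects = eff)), cc)
  expect_true(is.na(tab_na$deletions_raw))
  expect_true(is.na(tab_na$retrogenes))
})

test_that("reports are deterministic and machine-readable", {
  census <- build_census_table(list(s1 = list(
    deletions = data.frame(contig = "chr1", start = 1, end = 2001,
                           zygosity = "hom"))))
  cmpres <- deletion_size_comparison(c(1000, 2000, 1500), c(1200, 1800, 2200))
  tst <- list(gene_excess = pairwise_chisq(10, 100, 30, 100))
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- render_report(census, tst, list(sizes = cmpres), d1)
  f2 <- render_report(census, tst, list(sizes = cmpres), d2)
  expect_true(all(file.exists(f1)))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  parsed <- jsonlite::read_json(file.path(d1, "census_stats.json"))
  expect_equal(parsed$chisq$gene_excess$chi2, 12.5)
  expect_equal(parsed$census[[1]]$deletions_raw, 1)
  # empty inputs -> valid skeleton
  f3 <- render_report(build_census_table(list()), list(), list(), tempfile())
  expect_true(file.exists(f3[1]))
})
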