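# Shared small synthetic corpus, built once per test run.
small_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(genome_length = 3e5, n_genes = 10,
                          deletion_count = 3, retrocopy_count = 3,
                          n_syn_snps = 30, n_nonsyn_snps = 30,
                          n_nonsense_snps = 8, seed = 101)
      cache <<- synth_corpus(cfg)
    }
    cache
  }
})

# Independent brute-force oracle for the windowed change-point fit: direct
# RSS computation with plain sums over subvectors for every grid placement.
oracle_changepoint <- function(d, mask = NULL, grid = 100, min_len = 1000,
                               max_len = 10000) {
  n <- length(d)
  if (is.null(mask)) mask <- rep(FALSE, n)
  keep <- !mask
  rss <- function(x) if (length(x) < 1) 0 else sum((x - mean(x))^2)
  rss1 <- rss(d[keep])
  n_used <- sum(keep)
  n_bins <- n %/% grid
  best <- list(lambda = -Inf, tract = c(NA, NA))
  for (s_bin in 0:(n_bins - 1)) {
    for (e_bin in (s_bin + 1):n_bins) {
      len <- (e_bin - s_bin) * grid
      if (len < min_len || len > max_len) next
      tr <- (s_bin * grid + 1):(e_bin * grid)
      bg <- setdiff(seq_len(n), tr)
      tr_k <- tr[keep[tr]]
      bg_k <- bg[keep[bg]]
      if (!length(tr_k) || !length(bg_k)) next
      rss2 <- rss(d[tr_k]) + rss(d[bg_k])
      lam <- if (rss1 > 0) n_used * log(rss1 / max(rss2, .Machine$double.eps * rss1)) else 0
      if (lam > best$lambda) {
        best <- list(lambda = lam, tract = c(s_bin * grid, e_bin * grid))
      }
    }
  }
  best
}

# Brute-force genetic-code oracle via Biostrings translation.
oracle_classify <- function(codon, offset, alt_base, strand) {
  if (strand == "-") alt_base <- chartr("ACGT", "TGCA", alt_base)
  alt_codon <- codon
  substr(alt_codon, offset + 1, offset + 1) <- alt_base
  aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                            no.init.codon = TRUE))
  aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(alt_codon),
                                            no.init.codon = TRUE))
  if (aa1 == "*" && aa2 == "*") return("synonymous")
  if (aa1 == "*") return("stop_loss")
  if (aa2 == "*") return("nonsense")
  if (aa1 == aa2) "synonymous" else "nonsynonymous"
}
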