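#' Correction configuration for census counts
#'
#' @param het_fnr_snp heterozygote false-negative rate for SNP calls
#'   (default 0.30, the rate established for low-coverage ancient genomes).
#' @param het_fnr_del heterozygote false-negative rate for deletion calls
#'   (default 0.005, estimated by depth downsampling).
#' @return list of class `correction_config`.
#' @export
correction_config <- function(het_fnr_snp = 0.30, het_fnr_del = 0.005) {
  stopifnot(het_fnr_snp >= 0, het_fnr_snp < 1, het_fnr_del >= 0, het_fnr_del < 1)
  structure(list(het_fnr_snp = het_fnr_snp, het_fnr_del = het_fnr_del),
            class = "correction_config")
}

#' Assemble the per-sample defect census
#'
#' @param samples named list; each element a list with components
#'   `deletions` (call data.frame from [scan_genome()]), `retrogenes`
#'   (data.frame from [call_retrogenes()]), `genes_deleted` (data.frame from
#'   [gene_overlap()]), `effects` (data.frame from [annotate_variants()]).
#'   Missing components yield `NA` cells, not zeros.
#' @param correction a `correction_config`; false-negative corrections are
#'   applied to heterozygous counts only.
#' @return data.frame, one row per sample: raw and corrected deletion
#'   counts, retrogene count, genes with exons deleted (hom/het split),
#'   premature stop counts (raw, corrected, damage-excluded).
#' @export
build_census_table <- function(samples, correction = correction_config()) {
  if (!length(samples)) {
    return(data.frame(sample = character(), deletions_raw = numeric(),
                      deletions_corrected = numeric(), deletions_hom = numeric(),
                      deletions_het = numeric(), retrogenes = numeric(),
                      genes_deleted_hom = numeric(), genes_deleted_het = numeric(),
                      stop_codons_raw = numeric(), stop_codons_corrected = numeric(),
                      stop_codons_no_damage = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(samples), function(s) {
    x <- samples[[s]]
    del_raw <- del_corr <- del_hom <- del_het <- NA_real_
    if (!is.null(x$deletions)) {
      del_hom <- sum(x$deletions$zygosity == "hom")
      del_het <- sum(x$deletions$zygosity == "het")
      del_raw <- del_hom + del_het
      del_corr <- correct_het_undercall(del_het, del_hom, correction$het_fnr_del)
    }
    retro <- if (is.null(x$retrogenes)) NA_real_ else nrow(x$retrogenes)
    gdel_hom <- gdel_het <- NA_real_
    if (!is.null(x$genes_deleted)) {
      gdel_hom <- length(unique(x$genes_deleted$gene_id[
        x$genes_deleted$zygosity == "hom"]))
      gdel_het <- length(unique(x$genes_deleted$gene_id[
        x$genes_deleted$zygosity == "het"]))
    }
    stop_raw <- stop_corr <- stop_nodmg <- NA_real_
    if (!is.null(x$effects)) {
      ns <- x$effects[x$effects$effect_class == "nonsense", , drop = FALSE]
      stop_raw <- nrow(ns)
      stop_corr <- correct_het_undercall(sum(ns$genotype == "het"),
                                         sum(ns$genotype == "hom"),
                                         correction$het_fnr_snp)
      stop_nodmg <- sum(!ns$damage_flag)
    }
    data.frame(sample = s, deletions_raw = del_raw,
               deletions_corrected = del_corr, deletions_hom = del_hom,
               deletions_het = del_het, retrogenes = retro,
               genes_deleted_hom = gdel_hom, genes_deleted_het = gdel_het,
               stop_codons_raw = stop_raw, stop_codons_corrected = stop_corr,
               stop_codons_no_damage = stop_nodmg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pearson 2x2 chi-squared excess test
#'
#' Tests whether `count_a / total_a` differs from `count_b / total_b` with
#' a Pearson chi-squared test on the 2x2 table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]`,
#' without continuity correction.
#'
#' @param count_a,total_a,count_b,total_b non-negative counts,
#'   `total >= count`.
#' @return list of class `chisq_result`: `table`, `chi2`, `df` (1),
#'   `p_value` (`NA` with `zero_expected = TRUE` when an expected cell is
#'   zero).
#' @export
pairwise_chisq <- function(count_a, total_a, count_b, total_b) {
  stopifnot(count_a >= 0, count_b >= 0, total_a >= count_a, total_b >= count_b)
  tab <- matrix(c(count_a, total_a - count_a, count_b, total_b - count_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("hit", "miss")))
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cells == 0)) {
    return(structure(list(table = tab, chi2 = NA_real_, df = 1L,
                          p_value = NA_real_, zero_expected = TRUE),
                     class = "chisq_result"))
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  structure(list(table = tab, chi2 = unname(ct$statistic), df = 1L,
                 p_value = ct$p.value, zero_expected = FALSE),
            class = "chisq_result")
}

#' Compare two deletion size distributions
#'
#' Two-sided Wilcoxon rank-sum test with tie correction, plus empirical
#' CDF coordinates for plotting. The statistic is reported in both common
#' conventions: `W_U` (Mann-Whitney U for the first sample, as returned by
#' [stats::wilcox.test()]) and `W_ranksum` (`U + n1 (n1 + 1) / 2`).
#'
#' @param lengths_a,lengths_b non-empty numeric vectors (bp).
#' @return list of class `size_comparison`: `W_U`, `W_ranksum`, `p_value`,
#'   `mean_a`, `mean_b`, `ecdf_a`, `ecdf_b` (data.frames `x`, `F`),
#'   `all_tied` flag.
#' @export
deletion_size_comparison <- function(lengths_a, lengths_b) {
  stopifnot(length(lengths_a) >= 1, length(lengths_b) >= 1)
  n1 <- length(lengths_a)
  all_tied <- length(unique(c(lengths_a, lengths_b))) == 1
  if (all_tied) {
    wu <- n1 * length(lengths_b) / 2
    p <- 1
  } else {
    wt <- suppressWarnings(stats::wilcox.test(lengths_a, lengths_b,
                                              exact = FALSE, correct = FALSE))
    wu <- unname(wt$statistic)
    p <- wt$p.value
  }
  ecdf_pts <- function(x) {
    xs <- sort(unique(x))
    data.frame(x = xs, F = stats::ecdf(x)(xs))
  }
  structure(list(W_U = wu, W_ranksum = wu + n1 * (n1 + 1) / 2, p_value = p,
                 mean_a = mean(lengths_a), mean_b = mean(lengths_b),
                 ecdf_a = ecdf_pts(lengths_a), ecdf_b = ecdf_pts(lengths_b),
                 all_tied = all_tied),
            class = "size_comparison")
}

#' Count events shared across samples
#'
#' Deletions are shared when intervals have reciprocal overlap of at least
#' `reciprocal`; stop codons at the site level require identical position
#' and alternate allele, at the gene level just the gene; retrogenes share
#' at the gene level.
#'
#' @param event_sets named list (>= 2) of per-sample events: call
#'   data.frames for `kind = "deletion"`, effect data.frames for
#'   `kind = "stop_site"` / `"stop_gene"`, retrogene call data.frames for
#'   `kind = "retrogene"`.
#' @param kind one of `"deletion"`, `"stop_site"`, `"stop_gene"`,
#'   `"retrogene"`.
#' @param reciprocal reciprocal-overlap threshold for deletions.
#' @return integer count of events present in every sample (for deletions:
#'   events of the first sample with a reciprocal partner in all others).
#' @export
shared_events <- function(event_sets, kind = c("deletion", "stop_site",
                                               "stop_gene", "retrogene"),
                          reciprocal = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length(event_sets) >= 2)
  if (kind == "deletion") {
    ref <- event_sets[[1]]
    if (!nrow(ref)) return(0L)
    shared <- rep(TRUE, nrow(ref))
    for (j in 2:length(event_sets)) {
      shared <- shared & has_reciprocal_partner(ref, event_sets[[j]], reciprocal)
    }
    return(sum(shared))
  }
  keysets <- lapply(event_sets, function(e) {
    switch(kind,
           stop_site = unique(with(e[e$effect_class == "nonsense", ],
                                   paste(contig, pos, alt))),
           stop_gene = unique(e$gene_id[e$effect_class == "nonsense"]),
           retrogene = unique(e$gene_id))
  })
  length(Reduce(intersect, keysets))
}

#' Write the census report
#'
#' Emits deterministic TSV tables, eCDF plot data, and a machine-readable
#' JSON of every statistic.
#'
#' @param census data.frame from [build_census_table()].
#' @param tests named list of `chisq_result`s (may be empty).
#' @param comparisons named list of `size_comparison`s (may be empty).
#' @param dir output directory.
#' @return invisible character vector of files written.
#' @export
render_report <- function(census, tests = list(), comparisons = list(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  f_census <- file.path(dir, "census.tsv")
  utils::write.table(census, f_census, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, f_census)
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    f <- file.path(dir, sprintf("ecdf_%s.tsv", nm))
    utils::write.table(
      rbind(cbind(sample = "a", cmp$ecdf_a), cbind(sample = "b", cmp$ecdf_b)),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  stats_json <- list(
    census = census,
    chisq = lapply(tests, function(t) {
      list(table = as.vector(t$table), chi2 = t$chi2, df = t$df,
           p_value = t$p_value)
    }),
    size_comparisons = lapply(comparisons, function(cmp) {
      list(W_U = cmp$W_U, W_ranksum = cmp$W_ranksum, p_value = cmp$p_value,
           mean_a = cmp$mean_a, mean_b = cmp$mean_b)
    }))
  f_json <- file.path(dir, "census_stats.json")
  jsonlite::write_json(stats_json, f_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  files <- c(files, f_json)
  invisible(files)
}
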