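#' Annotate SNPs with coding effects
#'
#' Maps each biallelic SNV onto every overlapping transcript and classifies
#' the codon change. Variants outside any CDS are reported as `noncoding`.
#' Records whose reference allele disagrees with the genome sequence are
#' rejected (returned in the `rejected` attribute).
#'
#' @param variants data.frame with columns `contig`, `pos` (0-based),
#'   `ref`, `alt`, `genotype` (`"het"`/`"hom"`), as returned by
#'   [read_snp_vcf()].
#' @param genes list of `gene_model`s.
#' @param genome named character vector or `DNAStringSet`.
#' @return data.frame of variant effects, one row per variant x overlapping
#'   transcript (a single `noncoding` row for variants outside all CDS):
#'   columns `contig`, `pos`, `ref`, `alt`, `genotype`, `gene_id`,
#'   `codon_index`, `effect_class`, `damage_flag`.
#' @export
annotate_variants <- function(variants, genes, genome) {
  stopifnot(all(c("contig", "pos", "ref", "alt", "genotype") %in% names(variants)))
  keep_snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  variants <- variants[keep_snv, , drop = FALSE]

  # reference check
  ok <- logical(nrow(variants))
  for (ctg in unique(variants$contig)) {
    idx <- which(variants$contig == ctg)
    seq <- contig_seq(genome, ctg)
    ok[idx] <- substring(seq, variants$pos[idx] + 1, variants$pos[idx] + 1) ==
      toupper(variants$ref[idx])
  }
  rejected <- variants[!ok, , drop = FALSE]
  if (nrow(rejected)) {
    message("annotate_variants: rejected ", nrow(rejected),
            " record(s) whose REF disagrees with the genome")
  }
  variants <- variants[ok, , drop = FALSE]

  if (!nrow(variants)) {
    out <- empty_effects()
    attr(out, "rejected") <- rejected
    return(out)
  }

  # CDS overlap via GRanges
  v_gr <- GenomicRanges::GRanges(variants$contig,
                                 IRanges::IRanges(variants$pos + 1, width = 1))
  cds_rows <- do.call(rbind, lapply(genes, function(g) {
    data.frame(contig = g$contig, start = g$cds$start, end = g$cds$end,
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  }))
  hits_df <- NULL
  if (!is.null(cds_rows) && nrow(cds_rows)) {
    c_gr <- GenomicRanges::GRanges(cds_rows$contig,
                                   IRanges::IRanges(cds_rows$start + 1, cds_rows$end))
    ov <- GenomicRanges::findOverlaps(v_gr, c_gr)
    hits_df <- data.frame(v = S4Vectors::queryHits(ov),
                          gene_id = cds_rows$gene_id[S4Vectors::subjectHits(ov)])
    hits_df <- unique(hits_df)
  }

  rows <- vector("list", 0L)
  hit_v <- integer(0)
  if (!is.null(hits_df) && nrow(hits_df)) {
    hit_v <- unique(hits_df$v)
    gene_tbl <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
    tx_cache <- new.env(parent = emptyenv())
    rows <- lapply(seq_len(nrow(hits_df)), function(k) {
      i <- hits_df$v[k]
      g <- gene_tbl[[hits_df$gene_id[k]]]
      txpos <- genomic_to_tx(g, variants$pos[i])
      if (is.null(tx_cache[[g$gene_id]])) tx_cache[[g$gene_id]] <- transcript_seq(g, genome)
      tx <- tx_cache[[g$gene_id]]
      ci <- txpos %/% 3L
      off <- txpos %% 3L
      codon <- substr(tx, ci * 3 + 1, ci * 3 + 3)
      cls <- classify_codon_change(codon, off, variants$alt[i], g$strand)
      data.frame(contig = variants$contig[i], pos = variants$pos[i],
                 ref = variants$ref[i], alt = variants$alt[i],
                 genotype = variants$genotype[i], gene_id = g$gene_id,
                 codon_index = ci, effect_class = cls,
                 stringsAsFactors = FALSE)
    })
  }
  nc_idx <- setdiff(seq_len(nrow(variants)), hit_v)
  if (length(nc_idx)) {
    rows <- c(rows, list(data.frame(
      contig = variants$contig[nc_idx], pos = variants$pos[nc_idx],
      ref = variants$ref[nc_idx], alt = variants$alt[nc_idx],
      genotype = variants$genotype[nc_idx], gene_id = NA_character_,
      codon_index = NA_integer_, effect_class = "noncoding",
      stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$pos, out$gene_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out$damage_flag <- is_damage_pair(out$ref, out$alt)
  attr(out, "rejected") <- rejected
  out
}

empty_effects <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), genotype = character(), gene_id = character(),
             codon_index = integer(), effect_class = character(),
             damage_flag = logical(), stringsAsFactors = FALSE)
}

#' Correct a count for heterozygote under-calling
#'
#' Low-coverage genotyping misses a fraction of true heterozygotes; the
#' corrected total inflates the observed het count by `1/(1 - fnr)` and
#' leaves homozygotes untouched.
#'
#' @param het_count,hom_count observed counts.
#' @param fnr heterozygote false-negative rate in `[0, 1)`.
#' @return corrected total (numeric).
#' @export
#' @examples
#' correct_het_undercall(350, 150, 0.30) # 650
correct_het_undercall <- function(het_count, hom_count, fnr) {
  stopifnot(het_count >= 0, hom_count >= 0)
  if (any(fnr < 0) || any(fnr >= 1)) stop("fnr must be in [0, 1)")
  hom_count + het_count / (1 - fnr)
}

severity_rank <- function(cls) {
  match(cls, c("nonsense", "stop_loss", "nonsynonymous", "synonymous",
               "unknown", "noncoding"))
}

# Collapse multi-transcript effects to one row per site using the most
# severe class (avoids double counting in genome-wide heterozygosity).
collapse_effects_by_site <- function(effects) {
  if (!nrow(effects)) return(effects)
  key <- paste(effects$contig, effects$pos, effects$alt)
  ord <- order(key, severity_rank(effects$effect_class), method = "radix")
  effects <- effects[ord, , drop = FALSE]
  effects[!duplicated(paste(effects$contig, effects$pos, effects$alt)), , drop = FALSE]
}

#' Per-class heterozygosity summary (Hn, Hs)
#'
#' Computes per-site heterozygosity for the synonymous and non-synonymous
#' classes: `H = het sites / L` with binomial standard error
#' `sigma = sqrt(H (1 - H) / L)`. Sites observed in several transcripts are
#' counted once at their most severe effect; nonsense sites are pooled with
#' the non-synonymous class denominator convention (they are changes at
#' nonsynonymous-counted sites).
#'
#' @param effects data.frame from [annotate_variants()].
#' @param L_syn,L_nonsyn callable site counts (fractional allowed), e.g.
#'   from [count_syn_nonsyn_sites()].
#' @param damage_excluded drop effects flagged as possible deamination
#'   damage before counting.
#' @param het_fnr heterozygote false-negative rate applied to het counts
#'   (0 disables the correction).
#' @return data.frame with one row per class (`syn`, `nonsyn`): `het_count`,
#'   `L`, `H`, `sigma`; the ratio Hn/Hs is attached as attribute `ratio`.
#' @export
heterozygosity_summary <- function(effects, L_syn, L_nonsyn,
                                   damage_excluded = FALSE, het_fnr = 0) {
  stopifnot(L_syn > 0, L_nonsyn > 0)
  eff <- collapse_effects_by_site(effects)
  if (damage_excluded) eff <- eff[!eff$damage_flag, , drop = FALSE]
  eff <- eff[eff$genotype == "het", , drop = FALSE]
  n_syn <- sum(eff$effect_class == "synonymous")
  n_non <- sum(eff$effect_class %in% c("nonsynonymous", "nonsense"))
  if (het_fnr > 0) {
    n_syn <- correct_het_undercall(n_syn, 0, het_fnr)
    n_non <- correct_het_undercall(n_non, 0, het_fnr)
  }
  mk <- function(cnt, L) {
    H <- cnt / L
    data.frame(het_count = cnt, L = L, H = H,
               sigma = sqrt(H * (1 - H) / L))
  }
  out <- rbind(cbind(class = "syn", mk(n_syn, L_syn)),
               cbind(class = "nonsyn", mk(n_non, L_nonsyn)))
  rownames(out) <- NULL
  attr(out, "ratio") <- out$H[out$class == "nonsyn"] / out$H[out$class == "syn"]
  out
}

#' Premature-stop-codon census across samples
#'
#' Tallies genes carrying at least one nonsense effect per sample, and the
#' cross-sample intersections both at identical sites (same position and
#' alternate allele) and at the gene level regardless of site.
#'
#' @param effects_by_sample named list of effect data.frames (one per
#'   sample, from [annotate_variants()]).
#' @param damage_excluded drop damage-flagged effects first.
#' @return list with `per_gene` (sample, gene_id, n_sites), `per_sample`
#'   (sample, n_stop_sites, n_genes_truncated), `shared_sites` and
#'   `shared_genes` (counts present in every sample).
#' @export
stop_codon_census <- function(effects_by_sample, damage_excluded = FALSE) {
  stopifnot(length(effects_by_sample) >= 1)
  if (is.null(names(effects_by_sample))) {
    names(effects_by_sample) <- paste0("sample", seq_along(effects_by_sample))
  }
  nonsense <- lapply(effects_by_sample, function(e) {
    e <- e[e$effect_class == "nonsense", , drop = FALSE]
    if (damage_excluded) e <- e[!e$damage_flag, , drop = FALSE]
    e
  })
  per_gene <- do.call(rbind, lapply(names(nonsense), function(s) {
    e <- nonsense[[s]]
    if (!nrow(e)) {
      return(data.frame(sample = character(), gene_id = character(),
                        n_sites = integer()))
    }
    agg <- stats::aggregate(pos ~ gene_id, data = e,
                            FUN = function(x) length(unique(x)))
    data.frame(sample = s, gene_id = agg$gene_id, n_sites = agg$pos)
  }))
  per_sample <- do.call(rbind, lapply(names(nonsense), function(s) {
    e <- nonsense[[s]]
    data.frame(sample = s,
               n_stop_sites = length(unique(paste(e$contig, e$pos, e$alt))),
               n_genes_truncated = length(unique(e$gene_id)))
  }))
  site_sets <- lapply(nonsense, function(e) unique(paste(e$contig, e$pos, e$alt)))
  gene_sets <- lapply(nonsense, function(e) unique(e$gene_id))
  shared_sites <- length(Reduce(intersect, site_sets))
  shared_genes <- length(Reduce(intersect, gene_sets))
  list(per_gene = per_gene, per_sample = per_sample,
       shared_sites = shared_sites, shared_genes = shared_genes)
}
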