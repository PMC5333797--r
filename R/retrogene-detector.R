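#' Find reads spanning exon-exon junctions in transcript space
#'
#' A read aligned to a transcript is a junction read for junction `J` iff
#' its aligned span covers at least `min_overhang` bases on each side of
#' `J`. Overhang is measured in aligned bases: soft-clipped segments do not
#' count. One row is emitted per (read, junction).
#'
#' @param tx_aln data.frame of transcript alignments with columns `qname`,
#'   `rname` (transcript/gene id), `pos` (1-based), `cigar`, `score`
#'   (alignment score), as returned by [read_sam_alignments()].
#' @param genes list of `gene_model`s; transcript names must match `rname`.
#' @param min_overhang minimum aligned bases on each side of the junction
#'   (default 10).
#' @return data.frame: `qname`, `gene_id`, `junction` (intron ordinal,
#'   1-based), `left_overhang`, `right_overhang`, `tx_score`.
#' @export
find_junction_reads <- function(tx_aln, genes, min_overhang = 10) {
  gene_ids <- vapply(genes, `[[`, "", "gene_id")
  names(genes) <- gene_ids
  unknown <- !(tx_aln$rname %in% gene_ids)
  if (any(unknown)) {
    message("find_junction_reads: skipped ", sum(unknown),
            " alignment(s) to unknown transcripts")
    tx_aln <- tx_aln[!unknown, , drop = FALSE]
  }
  if (!nrow(tx_aln)) return(empty_junction_reads())
  rows <- vector("list", nrow(tx_aln))
  for (i in seq_len(nrow(tx_aln))) {
    g <- genes[[tx_aln$rname[i]]]
    J <- junction_positions(g)
    if (!length(J)) next
    a0 <- tx_aln$pos[i] - 1L                     # 0-based aligned start
    a1 <- a0 + cigar_ref_width(tx_aln$cigar[i])  # half-open aligned end
    lo <- J - a0
    ro <- a1 - J
    hit <- which(lo >= min_overhang & ro >= min_overhang)
    if (!length(hit)) next
    rows[[i]] <- data.frame(
      qname = tx_aln$qname[i], gene_id = g$gene_id, junction = hit,
      left_overhang = lo[hit], right_overhang = ro[hit],
      tx_score = tx_aln$score[i], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_junction_reads() else out
}

empty_junction_reads <- function() {
  data.frame(qname = character(), gene_id = character(), junction = integer(),
             left_overhang = integer(), right_overhang = integer(),
             tx_score = numeric(), stringsAsFactors = FALSE)
}

# Reference-consuming width of a CIGAR string (M/D/N/=/X ops).
cigar_ref_width <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1) return(0L)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Drop junction reads that align as well or better to the genome
#'
#' A junction read whose best genomic alignment score is greater than or
#' equal to its transcript alignment score is explained by the ordinary
#' (intron-containing) locus and discarded; ties discard. Reads without any
#' genomic alignment are retained.
#'
#' @param junction_reads data.frame from [find_junction_reads()].
#' @param genome_aln data.frame of genomic alignments with `qname` and
#'   `score`; multiple alignments per read are reduced to the maximum score.
#' @return filtered junction-read data.frame; attribute `n_missing_score`
#'   counts genomic records rejected for lacking a score.
#' @export
filter_by_genomic_alignment <- function(junction_reads, genome_aln) {
  miss <- is.na(genome_aln$score)
  if (any(miss)) genome_aln <- genome_aln[!miss, , drop = FALSE]
  best <- if (nrow(genome_aln)) {
    tapply(genome_aln$score, genome_aln$qname, max)
  } else {
    stats::setNames(numeric(0), character(0))
  }
  g <- best[junction_reads$qname]
  keep <- is.na(g) | junction_reads$tx_score > g
  out <- junction_reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_score") <- sum(miss)
  out
}

#' Call candidate retrogenes from filtered junction reads
#'
#' A gene is called iff its reads support at least `min_introns` distinct
#' junctions and at least `min_reads` distinct reads in total. A read
#' spanning two junctions supports both but counts once toward the read
#' total.
#'
#' @param junction_reads filtered data.frame from
#'   [filter_by_genomic_alignment()].
#' @param min_reads minimum distinct junction reads per gene (default 3).
#' @param min_introns minimum distinct junctions, i.e. introns lost
#'   (default 2).
#' @return data.frame: `gene_id`, `n_junctions`, `n_reads`, `introns_lost`.
#' @export
call_retrogenes <- function(junction_reads, min_reads = 3, min_introns = 2) {
  if (!nrow(junction_reads)) {
    return(data.frame(gene_id = character(), n_junctions = integer(),
                      n_reads = integer(), introns_lost = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(junction_reads, junction_reads$gene_id)
  out <- do.call(rbind, lapply(names(sp), function(gid) {
    x <- sp[[gid]]
    data.frame(gene_id = gid,
               n_junctions = length(unique(x$junction)),
               n_reads = length(unique(x$qname)),
               stringsAsFactors = FALSE)
  }))
  out$introns_lost <- out$n_junctions
  out <- out[out$n_junctions >= min_introns & out$n_reads >= min_reads, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
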