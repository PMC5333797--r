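#' Construct a gene model
#'
#' A transcript with ordered exons; all coordinates are internal 0-based
#' half-open genomic intervals on a single contig. The CDS defaults to the
#' full exon set (intron-containing genes whose spliced transcript is the
#' coding sequence). Exons are stored in ascending genomic order; transcript
#' (5'->3') order is ascending for `+` genes and descending for `-` genes.
#'
#' @param gene_id character id.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open).
#' @param cds optional data.frame like `exons`; defaults to `exons`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1,
            all(exons$end > exons$start))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  rownames(exons) <- NULL; rownames(cds) <- NULL
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons overlap in gene ", gene_id)
  }
  structure(
    list(gene_id = gene_id, contig = contig, strand = strand,
         exons = exons, cds = cds),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s %s:%d-%d (%s), %d exon(s)>\n",
              x$gene_id, x$contig, min(x$exons$start), max(x$exons$end),
              x$strand, nrow(x$exons)))
  invisible(x)
}

exon_widths_tx_order <- function(gene) {
  w <- gene$exons$end - gene$exons$start
  if (gene$strand == "-") rev(w) else w
}

#' Spliced transcript length of a gene model
#' @param gene a `gene_model`.
#' @return integer length in bp.
#' @export
transcript_length <- function(gene) sum(gene$exons$end - gene$exons$start)

#' Exon-exon junction positions in transcript coordinates
#'
#' @param gene a `gene_model`.
#' @return 0-based transcript positions of the junctions (the first base of
#'   each downstream exon); length `n_exons - 1`.
#' @export
junction_positions <- function(gene) {
  w <- exon_widths_tx_order(gene)
  if (length(w) < 2) return(integer(0))
  cumsum(w)[-length(w)]
}

#' Spliced transcript sequence of a gene model
#'
#' Concatenates exon sequences in transcript order; minus-strand genes are
#' reverse-complemented so the result reads 5'->3' in coding orientation.
#'
#' @param gene a `gene_model`.
#' @param genome named character vector (one element per contig) or
#'   `DNAStringSet`.
#' @return character transcript sequence.
#' @export
transcript_seq <- function(gene, genome) {
  seq <- contig_seq(genome, gene$contig)
  parts <- substring(seq, gene$exons$start + 1, gene$exons$end)
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

contig_seq <- function(genome, contig) {
  if (methods::is(genome, "DNAStringSet")) {
    as.character(genome[[contig]])
  } else {
    unname(genome[[contig]])
  }
}

#' Map a genomic position to transcript coordinates
#'
#' @param gene a `gene_model`.
#' @param pos 0-based genomic position(s).
#' @return 0-based transcript position(s); `NA` for positions outside exons.
#' @export
genomic_to_tx <- function(gene, pos) {
  ex <- gene$exons
  w <- ex$end - ex$start
  offs_plus <- cumsum(c(0, w[-length(w)]))
  res <- rep(NA_integer_, length(pos))
  for (i in seq_len(nrow(ex))) {
    in_ex <- pos >= ex$start[i] & pos < ex$end[i]
    res[in_ex] <- offs_plus[i] + (pos[in_ex] - ex$start[i])
  }
  if (gene$strand == "-") {
    L <- sum(w)
    res <- ifelse(is.na(res), NA_integer_, L - 1L - res)
  }
  as.integer(res)
}

# ---- GFF3 round trip -------------------------------------------------------

#' Write gene models to GFF3
#'
#' Emits gene/mRNA/exon/CDS rows, 1-based inclusive per the format.
#'
#' @param genes list of `gene_model`s.
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    gr_range <- c(min(g$exons$start), max(g$exons$end))
    feat <- function(type, start0, end0, attrs) {
      data.frame(seqid = g$contig, source = "meltdownr", type = type,
                 start = start0 + 1L, end = end0, score = ".",
                 strand = g$strand, phase = ".", attributes = attrs,
                 stringsAsFactors = FALSE)
    }
    out <- rbind(
      feat("gene", gr_range[1], gr_range[2], sprintf("ID=%s", g$gene_id)),
      feat("mRNA", gr_range[1], gr_range[2],
           sprintf("ID=%s.t1;Parent=%s", g$gene_id, g$gene_id))
    )
    ex <- do.call(rbind, lapply(seq_len(nrow(g$exons)), function(i) {
      feat("exon", g$exons$start[i], g$exons$end[i],
           sprintf("ID=%s.e%d;Parent=%s.t1", g$gene_id, i, g$gene_id))
    }))
    # CDS phase: cumulative length in transcript order
    cds_tx <- g$cds
    ord <- if (g$strand == "-") rev(seq_len(nrow(cds_tx))) else seq_len(nrow(cds_tx))
    clen <- cumsum(c(0, (cds_tx$end - cds_tx$start)[ord]))
    phase <- (3 - (clen[-length(clen)] %% 3)) %% 3
    cd <- do.call(rbind, lapply(seq_along(ord), function(k) {
      i <- ord[k]
      r <- feat("CDS", g$cds$start[i], g$cds$end[i],
                sprintf("ID=%s.c%d;Parent=%s.t1", g$gene_id, k, g$gene_id))
      r$phase <- as.character(phase[k])
      r
    }))
    rbind(out, ex, cd)
  })
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' @param path GFF3 file with gene/mRNA/exon rows (as written by
#'   [write_gene_models_gff3()] or equivalent).
#' @return list of `gene_model`s keyed by gene id.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- sub("\\.t1$", "", unlist(ex$Parent))
  genes <- split(seq_along(ex), parent)
  out <- lapply(names(genes), function(gid) {
    idx <- genes[[gid]]
    e <- ex[idx]
    gene_model(
      gene_id = gid,
      contig = as.character(GenomicRanges::seqnames(e))[1],
      strand = as.character(GenomicRanges::strand(e))[1],
      exons = data.frame(start = GenomicRanges::start(e) - 1L,
                         end = GenomicRanges::end(e))
    )
  })
  names(out) <- names(genes)
  out
}
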